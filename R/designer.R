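# Candidate enumeration and the design pipeline: slide a 23-nt window along
# the mRNA, derive guide and passenger strands, evaluate the five conditions,
# filter and rank.
#
# Window-to-strand convention (1-based inclusive): for a 23-nt target window
# w[1..23], the passenger strand is w[3..23] (sense, 21 nt) and the guide is
# reverse_complement(w[1..21]) (antisense, 21 nt). This gives the canonical
# 19-bp duplex core (guide positions 1-19 pair w[3..21]) with 2-nt 3'
# overhangs on both strands; guide position 1 pairs w[21] and the seed
# (guide 2-8) pairs w[14..20].

#' Design configuration
#'
#' Collects the tunable thresholds of the design filter. Defaults are the
#' five published conditions: A/U at position 1, at least 4 A/U in positions
#' 1-7, G/C at position 19, no G/C run longer than 9 nt, and seed-duplex
#' Tm at or below 21.5 degC.
#'
#' @param tm_threshold Seed-duplex Tm threshold in degC (inclusive).
#' @param min_au_1to7 Minimum A/U count at guide positions 1-7.
#' @param max_gc_stretch_allowed Longest admissible G/C run in the guide.
#' @param require_all_rules Keep only candidates passing all five conditions?
#' @param skip_ambiguous_windows Skip 23-nt windows containing non-A/C/G/U
#'   residues (counted and reported) instead of aborting?
#' @param restrict_to_region Optional `c(start, end)`, 1-based inclusive on
#'   the mRNA; only windows lying entirely inside are enumerated.
#' @return A list of class `design_config`.
#' @export
design_config <- function(tm_threshold = 21.5,
                          min_au_1to7 = 4L,
                          max_gc_stretch_allowed = 9L,
                          require_all_rules = TRUE,
                          skip_ambiguous_windows = FALSE,
                          restrict_to_region = NULL) {
  stopifnot(is.finite(tm_threshold), min_au_1to7 >= 0,
            max_gc_stretch_allowed >= 0)
  if (!is.null(restrict_to_region)) {
    stopifnot(length(restrict_to_region) == 2,
              restrict_to_region[1] >= 1,
              restrict_to_region[2] >= restrict_to_region[1])
  }
  structure(
    list(
      tm_threshold = tm_threshold,
      min_au_1to7 = as.integer(min_au_1to7),
      max_gc_stretch_allowed = as.integer(max_gc_stretch_allowed),
      require_all_rules = isTRUE(require_all_rules),
      skip_ambiguous_windows = isTRUE(skip_ambiguous_windows),
      restrict_to_region = restrict_to_region
    ),
    class = "design_config"
  )
}

#' Enumerate candidate siRNA target windows
#'
#' Slides a 23-nt window along each mRNA (one candidate per start position,
#' ascending) and derives the 21-nt guide and passenger strands. Sequences
#' shorter than 23 nt contribute no candidates (with a warning). Windows
#' containing ambiguous residues are skipped when `skip_ambiguous = TRUE`,
#' otherwise they abort the run.
#'
#' @param mrna A sequence tibble (columns `id`, `seq`) as from [rna_tbl()] or
#'   [read_fasta()], or a bare character vector of sequences.
#' @param region Optional `c(start, end)` restriction, 1-based inclusive;
#'   only windows fully inside the interval are kept.
#' @param skip_ambiguous Skip windows containing non-A/C/G/U residues?
#' @return A tibble with columns `target_id`, `window_start`,
#'   `target_window` (23 nt), `guide` (21 nt), `passenger` (21 nt).
#' @export
enumerate_candidates <- function(mrna, region = NULL, skip_ambiguous = FALSE) {
  if (is.character(mrna)) mrna <- rna_tbl(mrna)
  stopifnot(is.data.frame(mrna), all(c("id", "seq") %in% names(mrna)))
  empty <- tibble::tibble(
    target_id = character(), window_start = integer(),
    target_window = character(), guide = character(), passenger = character()
  )
  rows <- purrr::pmap(list(mrna$id, mrna$seq), function(id, s) {
    L <- nchar(s)
    if (L < 23) {
      warning("sequence '", id, "' is shorter than 23 nt (", L,
              "); no candidates", call. = FALSE)
      return(empty)
    }
    starts <- seq_len(L - 22L)
    if (!is.null(region)) {
      stopifnot(region[1] >= 1, region[2] <= L)
      starts <- starts[starts >= region[1] & (starts + 22L) <= region[2]]
      if (length(starts) == 0) return(empty)
    }
    win <- substring(s, starts, starts + 22L)
    amb <- grepl("[^ACGU]", win)
    if (any(amb)) {
      if (!skip_ambiguous) {
        stop("sequence '", id, "' contains ambiguous residues in ",
             sum(amb), " window(s); rerun with skip_ambiguous = TRUE to ",
             "skip them", call. = FALSE)
      }
      message(sum(amb), " window(s) with ambiguous residues skipped in '",
              id, "'")
      starts <- starts[!amb]
      win <- win[!amb]
      if (length(win) == 0) return(empty)
    }
    tibble::tibble(
      target_id = id,
      window_start = as.integer(starts),
      target_window = win,
      guide = revcomp(substr(win, 1, 21)),
      passenger = substr(win, 3, 23)
    )
  })
  dplyr::bind_rows(rows)
}

#' Design siRNAs against one or more mRNAs
#'
#' The full pipeline: enumerate all 23-nt target windows, evaluate every
#' candidate guide against the five design conditions, optionally keep only
#' candidates passing all of them, and rank. Passing candidates are ordered
#' by seed-duplex Tm ascending (weakest off-target inducer first), ties
#' broken by A/U count at positions 1-7 descending, then by target id and
#' window start. Ordering is presentation only and never changes the pass
#' set.
#'
#' @param mrna A sequence tibble (columns `id`, `seq`) or bare character
#'   vector.
#' @param config A [design_config()].
#' @param params An [nn_params()] parameter set.
#' @return A tibble of class `sirna_design`: candidate columns
#'   (`target_id`, `window_start`, `target_window`, `guide`, `passenger`),
#'   rule-report columns as in [evaluate_guides()], and `rank`. The config
#'   and the number of enumerated windows are attached as attributes.
#' @examples
#' mrna <- synthetic_mrna(200, gc_fraction = 0.45, seed = 7)
#' sirna_design(mrna, design_config(require_all_rules = FALSE))
#' @export
sirna_design <- function(mrna, config = design_config(),
                         params = nn_params()) {
  stopifnot(inherits(config, "design_config"))
  cand <- enumerate_candidates(
    mrna,
    region = config$restrict_to_region,
    skip_ambiguous = config$skip_ambiguous_windows
  )
  n_windows <- nrow(cand)
  if (n_windows == 0) {
    report <- evaluate_guides(character(0), params)
  } else {
    report <- evaluate_guides(
      cand$guide, params,
      tm_threshold = config$tm_threshold,
      min_au = config$min_au_1to7,
      max_gc_stretch_allowed = config$max_gc_stretch_allowed
    )
  }
  out <- dplyr::bind_cols(cand, dplyr::select(report, -"guide"))
  if (config$require_all_rules) out <- dplyr::filter(out, .data$all_pass)
  out <- dplyr::arrange(out, .data$seed_tm_celsius,
                        dplyr::desc(.data$au_count_1to7),
                        .data$target_id, .data$window_start)
  out$rank <- seq_len(nrow(out))
  structure(
    out,
    class = c("sirna_design", class(tibble::tibble()))
  ) -> out
  attr(out, "config") <- config
  attr(out, "n_windows") <- n_windows
  attr(out, "params_name") <- params$name
  out
}

#' @export
print.sirna_design <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("# siRNA design: ", nrow(x), " candidate(s) reported from ",
      attr(x, "n_windows"), " window(s)",
      if (cfg$require_all_rules) " (all-rules filter on)" else "",
      "\n", sep = "")
  cat("# Tm threshold ", cfg$tm_threshold, " degC; min A/U(1-7) ",
      cfg$min_au_1to7, "; max GC stretch ", cfg$max_gc_stretch_allowed,
      "\n", sep = "")
  NextMethod()
}

#' Tidy a design result
#'
#' Returns the design table as a plain tibble (one row per reported
#' candidate), dropping the class and attributes.
#'
#' @param x A `sirna_design` result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sirna_design
#' @export
tidy.sirna_design <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "config") <- NULL
  attr(out, "n_windows") <- NULL
  attr(out, "params_name") <- NULL
  out
}

#' One-row summary of a design result
#'
#' @param x A `sirna_design` result.
#' @param ... Unused.
#' @return A one-row tibble: windows enumerated, candidates reported, number
#'   passing all five conditions, and the minimum and median seed Tm among
#'   reported candidates.
#' @method glance sirna_design
#' @export
glance.sirna_design <- function(x, ...) {
  tibble::tibble(
    n_windows = attr(x, "n_windows"),
    n_reported = nrow(x),
    n_pass = sum(x$all_pass),
    min_seed_tm = if (nrow(x)) min(x$seed_tm_celsius) else NA_real_,
    median_seed_tm = if (nrow(x)) stats::median(x$seed_tm_celsius) else NA_real_,
    tm_threshold = attr(x, "config")$tm_threshold
  )
}

#' Write a design report to TSV
#'
#' Columns are written in a fixed, documented order: `target_id`,
#' `window_start`, `target_window`, `guide`, `passenger`, `pos1_au`,
#' `au_count_1to7`, `pos19_gc`, `max_gc_stretch`, `seed`,
#' `seed_tm_celsius`, `all_pass`, `rank`, followed by the remaining
#' rule-report columns.
#'
#' @param x A `sirna_design` result (or compatible tibble).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(x, path) {
  lead <- c("target_id", "window_start", "target_window", "guide",
            "passenger", "pos1_au", "au_count_1to7", "pos19_gc",
            "max_gc_stretch", "seed", "seed_tm_celsius", "all_pass", "rank")
  out <- dplyr::relocate(tidy.sirna_design(x), dplyr::all_of(lead))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
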