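# Off-target auditing: the seed-dependent off-target effect is triggered by
# perfect 7-nt base pairing between the guide seed (positions 2-8) and a
# site in a transcript's 3'-UTR. The scanner locates every such
# seed-complementary heptamer (exact Watson-Crick, no G:U wobble, overlaps
# counted) and the summary classifies the guide by seed-duplex stability:
# Tm at or above the benchmark marks a good ("strong") inducer of off-target
# activity, below it a poor ("weak") inducer.

#' Find seed-complementary sites in a sequence collection
#'
#' Scans each supplied sequence (typically 3'-UTRs, sense strand) for every
#' occurrence of the reverse complement of the guide seed (positions 2-8).
#' All overlapping occurrences are reported, ascending by input order and
#' position. Matching is exact Watson-Crick on the 7-mer; wobble pairing and
#' flanking-context conventions are deliberately out of scope.
#'
#' @param utrs A sequence tibble (columns `id`, `seq`) as from
#'   [read_fasta()], or a bare character vector.
#' @param guide A single 21-nt guide strand (5'->3').
#' @return A tibble with columns `utr_id`, `position` (1-based start of the
#'   match on the UTR), `matched_heptamer`, `guide_seed`.
#' @export
find_seed_matches <- function(utrs, guide) {
  if (is.character(utrs)) utrs <- rna_tbl(utrs)
  stopifnot(is.data.frame(utrs), all(c("id", "seq") %in% names(utrs)))
  stopifnot(length(guide) == 1)
  check_guide(guide)
  seed <- substr(guide, 2, 8)
  site <- revcomp(seed)
  empty <- tibble::tibble(
    utr_id = character(), position = integer(),
    matched_heptamer = character(), guide_seed = character()
  )
  if (nrow(utrs) == 0) return(empty)
  hits <- Biostrings::vmatchPattern(site, Biostrings::RNAStringSet(utrs$seq))
  starts <- Biostrings::startIndex(hits)
  rows <- purrr::map2(utrs$id, starts, function(id, st) {
    if (is.null(st) || length(st) == 0) return(empty)
    tibble::tibble(
      utr_id = id, position = as.integer(st),
      matched_heptamer = site, guide_seed = seed
    )
  })
  dplyr::bind_rows(rows)
}

#' Summarize a guide's off-target propensity
#'
#' Counts seed-complementary sites per supplied sequence and classifies the
#' guide by the melting temperature of its seed-target duplex: `"strong"`
#' inducer when seed Tm is at or above the benchmark, `"weak"` otherwise.
#' The class depends only on the seed and the thermodynamic parameters,
#' never on the sequence collection.
#'
#' @inheritParams find_seed_matches
#' @param params An [nn_params()] parameter set.
#' @param benchmark_tm Stability benchmark in degC. Default 21.5.
#' @return An object of class `offtarget_summary`: a list with the guide
#'   seed, its Tm, the inducer class, a per-UTR count tibble (including
#'   zero-count entries) and the total match count. Use [tidy()] for the
#'   per-UTR table and [glance()] for a one-row summary.
#' @export
offtarget_summary <- function(utrs, guide, params = nn_params(),
                              benchmark_tm = 21.5) {
  if (is.character(utrs)) utrs <- rna_tbl(utrs)
  matches <- find_seed_matches(utrs, guide)
  seed <- substr(guide, 2, 8)
  tm <- seed_tm(seed, params)
  per_utr <- dplyr::left_join(
    tibble::tibble(utr_id = utrs$id),
    dplyr::count(matches, .data$utr_id, name = "n_matches"),
    by = "utr_id"
  )
  per_utr$n_matches <- ifelse(is.na(per_utr$n_matches), 0L,
                              per_utr$n_matches)
  structure(
    list(
      guide = guide,
      guide_seed = seed,
      seed_tm_celsius = tm,
      inducer_class = if (tm >= benchmark_tm) "strong" else "weak",
      benchmark_tm = benchmark_tm,
      matches = matches,
      matches_per_utr = per_utr,
      total_matches = nrow(matches)
    ),
    class = "offtarget_summary"
  )
}

#' @export
print.offtarget_summary <- function(x, ...) {
  cat("<offtarget_summary>\n")
  cat("  guide seed (2-8): ", x$guide_seed, "\n", sep = "")
  cat(sprintf("  seed-duplex Tm: %.2f degC -> %s off-target inducer (benchmark %.1f degC)\n",
              x$seed_tm_celsius, x$inducer_class, x$benchmark_tm))
  cat("  ", x$total_matches, " seed-complementary site(s) across ",
      nrow(x$matches_per_utr), " sequence(s)\n", sep = "")
  invisible(x)
}

#' Per-UTR match counts of an off-target summary
#'
#' @param x An `offtarget_summary`.
#' @param ... Unused.
#' @return A tibble with one row per scanned sequence: `utr_id`,
#'   `n_matches`.
#' @method tidy offtarget_summary
#' @export
tidy.offtarget_summary <- function(x, ...) x$matches_per_utr

#' One-row overview of an off-target summary
#'
#' @param x An `offtarget_summary`.
#' @param ... Unused.
#' @return A one-row tibble: `guide_seed`, `seed_tm_celsius`,
#'   `inducer_class`, `n_utrs`, `total_matches`.
#' @method glance offtarget_summary
#' @export
glance.offtarget_summary <- function(x, ...) {
  tibble::tibble(
    guide_seed = x$guide_seed,
    seed_tm_celsius = x$seed_tm_celsius,
    inducer_class = x$inducer_class,
    n_utrs = nrow(x$matches_per_utr),
    total_matches = x$total_matches
  )
}

#' Write seed-match and summary tables to TSV
#'
#' Writes one row per seed match; the one-row summary is written to a
#' second file when `summary_path` is given.
#'
#' @param x An `offtarget_summary`.
#' @param path Output TSV path for the per-site table.
#' @param summary_path Optional TSV path for the one-row summary.
#' @return `path`, invisibly.
#' @export
write_offtarget_tsv <- function(x, path, summary_path = NULL) {
  readr::write_tsv(x$matches, path, progress = FALSE)
  if (!is.null(summary_path)) {
    readr::write_tsv(glance.offtarget_summary(x), summary_path,
                     progress = FALSE)
  }
  invisible(path)
}
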