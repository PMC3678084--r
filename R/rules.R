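# The four empirical sequence rules for highly functional siRNAs, evaluated
# on the 21-nt guide strand (positions 1-based from its 5' end):
#   (1) A or U at position 1
#   (2) four to seven A/U residues at positions 1-7 (A/U >= 57%)
#   (3) G or C at position 19
#   (4) no GC stretch longer than 9 nt
# plus the fifth, thermodynamic condition: seed-duplex Tm <= threshold.
# Rules (1)-(3) reflect the terminal asymmetry that selects the guide strand
# into the RISC; rule (4) avoids duplexes whose Ago2-cleaved passenger
# fragments cannot dissociate.

check_guide <- function(guide) {
  if (any(nchar(guide) != 21)) {
    stop("guide strands must be exactly 21 nt", call. = FALSE)
  }
  if (any(grepl("[^ACGU]", guide))) {
    stop("guide strands must be over A/C/G/U; normalize first", call. = FALSE)
  }
  invisible(guide)
}

#' Rule 1: A or U at guide position 1
#'
#' @param guide Character vector of 21-nt guide strands (5'->3').
#' @return Logical vector.
#' @export
rule_position1 <- function(guide) {
  check_guide(guide)
  substr(guide, 1, 1) %in% c("A", "U")
}

#' Rule 2: A/U count at guide positions 1-7
#'
#' Four or more of the seven 5'-terminal guide positions must be A or U
#' (equivalently A/U >= 57%, since floor(4/7 * 100) = 57).
#'
#' @inheritParams rule_position1
#' @param min_au Minimum A/U count to pass. Default 4.
#' @return A tibble with columns `au_count_1to7` and `au_rule_pass`.
#' @export
rule_au_1to7 <- function(guide, min_au = 4L) {
  check_guide(guide)
  count <- stringr::str_count(substr(guide, 1, 7), "[AU]")
  tibble::tibble(au_count_1to7 = count, au_rule_pass = count >= min_au)
}

#' Rule 3: G or C at guide position 19
#'
#' @inheritParams rule_position1
#' @return Logical vector.
#' @export
rule_position19 <- function(guide) {
  check_guide(guide)
  substr(guide, 19, 19) %in% c("G", "C")
}

#' Rule 4: longest G/C run in a sequence
#'
#' Length of the longest stretch of consecutive G or C residues; 0 when the
#' sequence contains no G/C. Candidates with a stretch longer than 9 nt are
#' disqualified by the design filter.
#'
#' @param seq Character vector of sequences over A/C/G/U (any length).
#' @return Integer vector of maximal run lengths.
#' @examples
#' max_gc_stretch("AGCGCGCGCGCA")  # 10
#' @export
max_gc_stretch <- function(seq) {
  runs <- stringr::str_extract_all(seq, "[GC]+")
  vapply(runs, function(r) if (length(r)) max(nchar(r)) else 0L, integer(1))
}

#' Evaluate all five design conditions on guide strands
#'
#' Applies the four sequence rules plus the seed-duplex Tm condition to each
#' 21-nt guide and reports per-rule outcomes, the overall verdict, and two
#' informational annotations from the wider design-rule literature
#' (`reynolds_pos1_A`: A specifically, not just A/U, at position 1;
#' `amarzguioui_pos19_not_U`: position 19 is G/C rather than U). The
#' annotations never enter `all_pass` - the verdict is the conjunction of
#' exactly the five conditions.
#'
#' The GC-stretch rule is evaluated on the guide 21-mer: within the 19-bp
#' duplex core any G/C run in the guide implies an equal-length run in the
#' passenger, so a single operand suffices.
#'
#' @param guide Character vector of 21-nt guide strands (5'->3').
#' @param params An [nn_params()] parameter set for the seed Tm.
#' @param tm_threshold Seed-duplex Tm threshold in degC (inclusive).
#'   Default 21.5.
#' @param min_au Minimum A/U count at positions 1-7. Default 4.
#' @param max_gc_stretch_allowed Longest admissible G/C run. Default 9.
#' @return A tibble, one row per guide, with columns `guide`, `seed`,
#'   `pos1_au`, `au_count_1to7`, `au_rule_pass`, `pos19_gc`,
#'   `max_gc_stretch`, `gc_stretch_pass`, `seed_tm_celsius`, `seed_tm_pass`,
#'   `all_pass`, `reynolds_pos1_A`, `amarzguioui_pos19_not_U`.
#' @export
evaluate_guides <- function(guide, params = nn_params(), tm_threshold = 21.5,
                            min_au = 4L, max_gc_stretch_allowed = 9L) {
  check_guide(guide)
  seed <- substr(guide, 2, 8)
  au <- rule_au_1to7(guide, min_au = min_au)
  gc_run <- max_gc_stretch(guide)
  tm <- seed_tm(seed, params)
  out <- tibble::tibble(
    guide = guide,
    seed = seed,
    pos1_au = rule_position1(guide),
    au_count_1to7 = au$au_count_1to7,
    au_rule_pass = au$au_rule_pass,
    pos19_gc = rule_position19(guide),
    max_gc_stretch = gc_run,
    gc_stretch_pass = gc_run <= max_gc_stretch_allowed,
    seed_tm_celsius = tm,
    seed_tm_pass = tm <= tm_threshold,
    reynolds_pos1_A = substr(guide, 1, 1) == "A",
    amarzguioui_pos19_not_U = substr(guide, 19, 19) %in% c("G", "C")
  )
  out$all_pass <- out$pos1_au & out$au_rule_pass & out$pos19_gc &
    out$gc_stretch_pass & out$seed_tm_pass
  out
}
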