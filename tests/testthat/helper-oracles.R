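# Independent naive re-implementations used as oracles. These deliberately
# avoid the package's own code paths (no revcomp(), no seed_tm() internals):
# string reversal is done by hand, rules are recomputed predicate by
# predicate, and scans compare every substring.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Hand-computed regression values for the shipped Freier 1986 table at
# CT = 100 uM, [Na+] = 100 mM:
#   AAAAAAA: dH = 6*(-6.6) = -39.6 kcal/mol; dS = 6*(-18.4) - 10.8 = -121.2
#            Tm = -39600/(-121.2 + 1.987*ln(25e-6)) - 273.15 - 16.6
#   GGGGGGG: dH = 6*(-12.2) = -73.2; dS = 6*(-29.7) - 10.8 = -189.0
# both cross-checked against an independent nearest-neighbor implementation.
ORACLE_TM_AAAAAAA <- -11.37766
ORACLE_TM_GGGGGGG <- 58.72931
ORACLE_TM_ACGUACG <- 28.54063

oracle_max_gc_stretch <- function(s) {
  chars <- strsplit(s, "")[[1]]
  best <- 0L
  run <- 0L
  for (ch in chars) {
    if (ch %in% c("G", "C")) {
      run <- run + 1L
      best <- max(best, run)
    } else {
      run <- 0L
    }
  }
  best
}

# Naive five-condition evaluation of a 21-nt guide; Tm via the package's
# public seed_tm (itself pinned by the hand-computed constants above).
oracle_rules <- function(guide, params, tm_threshold = 21.5) {
  chars <- strsplit(guide, "")[[1]]
  pos1 <- chars[1] == "A" || chars[1] == "U"
  au <- sum(chars[1:7] %in% c("A", "U"))
  pos19 <- chars[19] == "G" || chars[19] == "C"
  gc <- oracle_max_gc_stretch(guide)
  tm <- seed_tm(paste(chars[2:8], collapse = ""), params)
  list(
    pos1_au = pos1,
    au_count = au,
    au_pass = au >= 4,
    pos19_gc = pos19,
    max_gc = gc,
    gc_pass = gc <= 9,
    tm = tm,
    tm_pass = tm <= tm_threshold,
    all_pass = pos1 && au >= 4 && pos19 && gc <= 9 && tm <= tm_threshold
  )
}

# Exhaustive window evaluation of an mRNA string: returns the window starts
# whose guides satisfy all five conditions.
oracle_passing_starts <- function(mrna, params, tm_threshold = 21.5) {
  L <- nchar(mrna)
  starts <- seq_len(L - 22L)
  keep <- vapply(starts, function(s) {
    w <- substr(mrna, s, s + 22L)
    g <- oracle_revcomp(substr(w, 1, 21))
    oracle_rules(g, params, tm_threshold)$all_pass
  }, logical(1))
  starts[keep]
}

# Naive overlapping 7-mer scan: positions where `site` occurs in `utr`.
oracle_scan <- function(utr, site) {
  L <- nchar(utr)
  k <- nchar(site)
  if (L < k) return(integer())
  starts <- seq_len(L - k + 1L)
  starts[vapply(starts, function(i) substr(utr, i, i + k - 1L) == site,
                logical(1))]
}

random_rna <- function(n, len, seed) {
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1)))
}

# mRNA with a single compliant 23-nt window at position 31: the planted
# guide satisfies all five conditions, while the A-flank upstream forces a
# position-19 failure and the G overhang/flank downstream a position-1
# failure on every shifted window.
planted_fixture <- function() {
  guide <- "UUAAAUAACGAUACGAUCGUA"
  window <- paste0(oracle_revcomp(guide), "GG")
  list(
    guide = guide,
    window = window,
    start = 31L,
    mrna = paste0(strrep("A", 30), window, strrep("G", 30))
  )
}
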