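params <- nn_params()

test_that("candidate enumeration yields one window per start position", {
  m30 <- random_rna(1, 30, seed = 3)
  expect_equal(nrow(enumerate_candidates(m30)), 8)
  m23 <- random_rna(1, 23, seed = 3)
  expect_equal(nrow(enumerate_candidates(m23)), 1)
  expect_warning(x <- enumerate_candidates(random_rna(1, 20, seed = 3)),
                 "shorter than 23")
  expect_equal(nrow(x), 0)
})

test_that("guide and passenger derivation follows the 2-nt 3'-overhang geometry", {
  m <- random_rna(1, 60, seed = 19)
  cand <- enumerate_candidates(m)
  expect_equal(nrow(cand), 38)
  for (i in seq_len(nrow(cand))) {
    w <- substr(m, cand$window_start[i], cand$window_start[i] + 22L)
    expect_equal(cand$target_window[i], w)
    expect_equal(cand$guide[i], oracle_revcomp(substr(w, 1, 21)))
    expect_equal(cand$passenger[i], substr(w, 3, 23))
    expect_equal(nchar(cand$guide[i]), 21L)
    expect_equal(nchar(cand$passenger[i]), 21L)
  }
})

test_that("design output is invariant to case and T/U spelling", {
  rna <- random_rna(1, 120, seed = 31)
  dna <- tolower(chartr("U", "T", rna))
  d1 <- sirna_design(rna_tbl(rna, "x"), design_config(), params)
  d2 <- sirna_design(rna_tbl(dna, "x"), design_config(), params)
  expect_equal(tidy(d1), tidy(d2))
})

test_that("unfiltered design reports every window; filtered design is sound", {
  m <- random_rna(1, 200, seed = 47)
  all_rows <- sirna_design(m, design_config(require_all_rules = FALSE), params)
  expect_equal(nrow(all_rows), 200 - 23 + 1)

  filt <- sirna_design(m, design_config(), params)
  expect_true(all(filt$all_pass))
  # oracle equivalence: the passing set matches exhaustive naive evaluation
  expect_setequal(filt$window_start, oracle_passing_starts(m, params))
  # and every excluded window fails at least one condition in the full report
  excluded <- dplyr::anti_join(tidy(all_rows), tidy(filt),
                               by = "window_start")
  expect_true(all(!excluded$all_pass))
})

test_that("ranking is total, deterministic, and ordered by seed Tm", {
  m <- random_rna(1, 300, seed = 53)
  d <- sirna_design(m, design_config(require_all_rules = FALSE), params)
  expect_equal(d$rank, seq_len(nrow(d)))
  expect_true(all(diff(d$seed_tm_celsius) >= 0))
  # ties broken by A/U count descending, then window start: the stable
  # base-R ordering on the same keys reproduces the table exactly
  ord <- order(d$seed_tm_celsius, -d$au_count_1to7, d$window_start)
  expect_identical(ord, seq_len(nrow(d)))
  d2 <- sirna_design(m, design_config(require_all_rules = FALSE), params)
  expect_identical(tidy(d), tidy(d2))
})

test_that("lowering the Tm threshold never admits more candidates", {
  m <- random_rna(1, 400, seed = 61)
  counts <- vapply(c(30, 21.5, 15, 5, -5), function(th) {
    nrow(sirna_design(m, design_config(tm_threshold = th), params))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("an all-A mRNA yields zero passing designs", {
  d <- sirna_design(rna_tbl(strrep("A", 40), "polyA"), design_config(), params)
  expect_equal(nrow(d), 0)
  # reason: every guide is poly-U, so position 19 cannot be G/C
  full <- sirna_design(rna_tbl(strrep("A", 40), "polyA"),
                       design_config(require_all_rules = FALSE), params)
  expect_true(all(!full$pos19_gc))
})

test_that("a single planted compliant window is recovered at its position", {
  fx <- planted_fixture()
  d <- sirna_design(rna_tbl(fx$mrna, "planted"), design_config(), params)
  expect_equal(nrow(d), 1)
  expect_equal(d$window_start, fx$start)
  expect_equal(d$guide, fx$guide)
  expect_equal(d$rank, 1L)
})

test_that("region restriction keeps only fully contained windows", {
  m <- random_rna(1, 100, seed = 71)
  d <- sirna_design(rna_tbl(m, "x"),
                    design_config(require_all_rules = FALSE,
                                  restrict_to_region = c(20, 60)),
                    params)
  expect_true(all(d$window_start >= 20))
  expect_true(all(d$window_start + 22 <= 60))
  expect_equal(nrow(d), 60 - 22 - 20 + 1)
})

test_that("ambiguous residues abort by default and are skipped on request", {
  m <- paste0(random_rna(1, 40, seed = 83), "N", random_rna(1, 40, seed = 84))
  tbl <- rna_tbl(m, "amb", permissive = TRUE)
  expect_error(sirna_design(tbl, design_config(), params), "ambiguous")
  cfg <- design_config(require_all_rules = FALSE,
                       skip_ambiguous_windows = TRUE)
  expect_message(d <- sirna_design(tbl, cfg, params), "skipped")
  # the N sits at position 41 of an 81-nt sequence: windows starting
  # 19..41 cover it, so 59 - 23 = 36 windows remain
  expect_equal(nrow(d), (81 - 23 + 1) - 23)
  expect_false(any(grepl("N", d$target_window)))
})

test_that("tidy and glance summarize a design result consistently", {
  m <- random_rna(1, 150, seed = 91)
  d <- sirna_design(m, design_config(require_all_rules = FALSE), params)
  td <- tidy(d)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "sirna_design"))
  g <- glance(d)
  expect_equal(g$n_windows, 128L)
  expect_equal(g$n_reported, nrow(d))
  expect_equal(g$n_pass, sum(d$all_pass))
  expect_equal(g$min_seed_tm, min(d$seed_tm_celsius))
})

test_that("design reports serialize to TSV with the documented leading columns", {
  fx <- planted_fixture()
  d <- sirna_design(rna_tbl(fx$mrna, "planted"), design_config(), params)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_design_tsv(d, tf)
  back <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(names(back)[1:13],
               c("target_id", "window_start", "target_window", "guide",
                 "passenger", "pos1_au", "au_count_1to7", "pos19_gc",
                 "max_gc_stretch", "seed", "seed_tm_celsius", "all_pass",
                 "rank"))
  expect_equal(back$guide, fx$guide)
})
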