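# Nearest-neighbor thermodynamics of the 7-bp seed-target duplex.
#
# The seed region is guide-strand positions 2-8 (5'->3'). Its melting
# temperature against a perfectly complementary target is computed with the
# two-state nearest-neighbor model:
#
#   Tm(degC) = (1000 * dH) / (dS + R * ln(CT/4)) - 273.15 + 16.6 * log10([Na+])
#
# where dH (kcal/mol) and dS (cal/(mol*K)) sum the six interior dinucleotide
# stacks of the 7-bp helix plus the helix initiation terms, R is the gas
# constant, CT the total strand concentration and [Na+] the monovalent salt
# concentration. Dangling ends and flanking target context are ignored: seed
# stability is treated as a property of the 7-mer alone.

#' Load a nearest-neighbor parameter set
#'
#' Reads a dinucleotide-stack enthalpy/entropy table plus initiation terms
#' from a plain-text TSV and bundles it with solution conditions. The shipped
#' default is the RNA/RNA parameter set of Freier et al. (1986) with the
#' helix initiation entropy of -10.8 cal/(mol*K), evaluated at a total strand
#' concentration of 100 uM and 100 mM Na+, the conditions under which the
#' 21.5 degC off-target benchmark was established.
#'
#' @param path Path to a TSV with columns `stack`, `dH_kcal_mol`,
#'   `dS_cal_molK`, one row per dinucleotide plus an `initiation` row.
#'   Defaults to the packaged Freier et al. (1986) table.
#' @param total_strand_conc_M Total strand concentration CT in mol/L.
#' @param sodium_conc_M Monovalent Na+ concentration in mol/L.
#' @return An object of class `nn_params`: named `dH`/`dS` stack vectors,
#'   initiation terms, gas constant and solution conditions.
#' @export
nn_params <- function(path = NULL,
                      total_strand_conc_M = 100e-6,
                      sodium_conc_M = 0.1) {
  if (is.null(path)) {
    path <- system.file("extdata", "freier1986_rna_nn.tsv",
                        package = "sirnadesign", mustWork = TRUE)
  }
  stopifnot(total_strand_conc_M > 0, sodium_conc_M > 0)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  stopifnot(all(c("stack", "dH_kcal_mol", "dS_cal_molK") %in% names(tab)))
  init <- tab[tab$stack == "initiation", ]
  stacks <- tab[tab$stack != "initiation", ]
  expected <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                              paste0))
  if (!setequal(stacks$stack, expected)) {
    stop("parameter table must contain all 16 dinucleotide stacks over ACGU",
         call. = FALSE)
  }
  dH <- stats::setNames(stacks$dH_kcal_mol, stacks$stack)
  dS <- stats::setNames(stacks$dS_cal_molK, stacks$stack)
  # duplex symmetry: a stack read from the opposite strand is its reverse
  # complement and must carry identical parameters
  rc <- revcomp(names(dH))
  if (any(abs(dH - dH[rc]) > 1e-9) || any(abs(dS - dS[rc]) > 1e-9)) {
    stop("parameter table is not duplex-symmetric", call. = FALSE)
  }
  structure(
    list(
      dH = dH, dS = dS,
      init_dH = if (nrow(init)) init$dH_kcal_mol else 0,
      init_dS = if (nrow(init)) init$dS_cal_molK else 0,
      gas_constant_R = 1.987,
      total_strand_conc_CT = total_strand_conc_M,
      sodium_conc = sodium_conc_M,
      name = basename(path)
    ),
    class = "nn_params"
  )
}

#' @export
print.nn_params <- function(x, ...) {
  cat("<nn_params> ", x$name, "\n", sep = "")
  cat("  16 stacks; init dH = ", x$init_dH, " kcal/mol, init dS = ",
      x$init_dS, " cal/(mol*K)\n", sep = "")
  cat("  CT = ", x$total_strand_conc_CT * 1e6, " uM, [Na+] = ",
      x$sodium_conc * 1e3, " mM\n", sep = "")
  invisible(x)
}

#' Melting temperature of the seed-target duplex
#'
#' Computes the nearest-neighbor melting temperature (degC) of the fully
#' complementary 7-bp duplex formed by a 7-nt seed (guide positions 2-8).
#' Vectorized over seeds; deterministic for fixed parameters. Because the
#' stack table is duplex-symmetric, `seed_tm(x)` equals
#' `seed_tm(revcomp(x))` exactly.
#'
#' @param seed Character vector of 7-nt sequences over A/C/G/U.
#' @param params An [nn_params()] parameter set.
#' @return Numeric vector of melting temperatures in degC.
#' @examples
#' p <- nn_params()
#' seed_tm("AAAAAAA", p)
#' @export
seed_tm <- function(seed, params = nn_params()) {
  stopifnot(inherits(params, "nn_params"))
  if (length(seed) == 0) return(numeric())
  if (any(nchar(seed) != 7)) {
    stop("seed sequences must be exactly 7 nt (got length ",
         nchar(seed)[which(nchar(seed) != 7)[1]], ")", call. = FALSE)
  }
  if (any(grepl("[^ACGU]", seed))) {
    stop("seed sequences must be over A/C/G/U; normalize first", call. = FALSE)
  }
  dH <- rep(params$init_dH, length(seed))
  dS <- rep(params$init_dS, length(seed))
  for (i in 1:6) {
    st <- substr(seed, i, i + 1)
    dH <- dH + params$dH[st]
    dS <- dS + params$dS[st]
  }
  R <- params$gas_constant_R
  ct_term <- R * log(params$total_strand_conc_CT / 4)
  unname((dH * 1000) / (dS + ct_term) - 273.15 +
           16.6 * log10(params$sodium_conc))
}

#' Enumerate the full 7-mer seed space
#'
#' All 4^7 = 16,384 seeds over A/C/G/U in lexicographic order, each with its
#' seed-duplex melting temperature and a flag marking whether it falls at or
#' below the threshold. Only a limited part of seed space is thermodynamically
#' weak enough to avoid seed-dependent off-target effects; this table makes
#' that constraint explicit.
#'
#' @param params An [nn_params()] parameter set.
#' @param threshold Tm threshold in degC for the `below_threshold` flag
#'   (inclusive). Default 21 degC, the cut at which the seed-space fraction
#'   is usually quoted; the design filter itself defaults to 21.5 degC.
#' @return A tibble with columns `seed`, `tm_celsius`, `below_threshold`,
#'   16,384 rows.
#' @export
seed_space <- function(params = nn_params(), threshold = 21) {
  b <- c("A", "C", "G", "U")
  g <- expand.grid(rep(list(b), 7), stringsAsFactors = FALSE)[, 7:1]
  seeds <- do.call(paste0, g)
  tm <- seed_tm(seeds, params)
  tibble::tibble(
    seed = seeds,
    tm_celsius = tm,
    below_threshold = tm <= threshold
  )
}

#' Fraction of seed space at or below a Tm threshold
#'
#' @param threshold Tm threshold in degC (inclusive).
#' @param params An [nn_params()] parameter set.
#' @return A number in `[0, 1]`: the fraction of all 16,384 7-mers with
#'   seed-duplex Tm at or below `threshold`.
#' @export
fraction_below <- function(threshold, params = nn_params()) {
  stopifnot(is.finite(threshold) || is.infinite(threshold))
  mean(seed_space(params, threshold = threshold)$below_threshold)
}
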