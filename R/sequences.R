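# Sequence handling: alphabet normalization, reverse complement, FASTA I/O,
# and a reproducible synthetic-mRNA generator. Sequence collections are plain
# tibbles with columns id, seq, original_alphabet so that everything chains
# with dplyr verbs.

IUPAC_AMBIGUITY <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases, strips whitespace, and maps T to U. Positions are 1-based from
#' the 5' end throughout the package. By default any character outside
#' A/C/G/T/U is rejected with an error naming the first offending position;
#' with `permissive = TRUE`, IUPAC ambiguity codes (N, R, Y, ...) are kept so
#' that downstream window enumeration can skip over them explicitly.
#'
#' @param x Character vector of raw sequences (DNA or RNA spelling, any case).
#' @param permissive Keep IUPAC ambiguity codes instead of erroring? Default
#'   `FALSE`: the design rules and the nearest-neighbor model are undefined on
#'   ambiguous residues, so rejection is the fail-loud default.
#' @return Character vector of normalized sequences with attribute dropped;
#'   use [detect_alphabet()] on the raw input to record the original spelling.
#' @examples
#' normalize_rna("acgt")  # "ACGU"
#' @export
normalize_rna <- function(x, permissive = FALSE) {
  x <- gsub("[[:space:]]", "", x)
  x <- toupper(x)
  x <- chartr("T", "U", x)
  allowed <- if (permissive) {
    paste0("ACGU", paste(IUPAC_AMBIGUITY, collapse = ""))
  } else {
    "ACGU"
  }
  bad <- regexpr(paste0("[^", allowed, "]"), x)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf(
      "invalid character '%s' at position %d of sequence %d (allowed: %s)",
      substr(x[i], bad[i], bad[i]), bad[i], i,
      if (permissive) "A/C/G/T/U and IUPAC ambiguity codes" else "A/C/G/T/U"
    ), call. = FALSE)
  }
  x
}

#' Detect whether a raw sequence was spelled in DNA or RNA
#'
#' A sequence containing T (and no U) is recorded as DNA; everything else,
#' including sequences with neither T nor U, as RNA.
#'
#' @param x Character vector of raw sequences.
#' @return Character vector, "DNA" or "RNA".
#' @export
detect_alphabet <- function(x) {
  x <- toupper(gsub("[[:space:]]", "", x))
  ifelse(grepl("T", x) & !grepl("U", x), "DNA", "RNA")
}

#' Build a sequence tibble from raw strings
#'
#' The package's standard sequence container: one row per sequence with
#' columns `id`, `seq` (normalized RNA alphabet), `original_alphabet` and
#' `length`.
#'
#' @param seqs Character vector of raw sequences.
#' @param ids Identifiers; defaults to `seq1`, `seq2`, ...
#' @inheritParams normalize_rna
#' @return A tibble with one row per input sequence.
#' @export
rna_tbl <- function(seqs, ids = NULL, permissive = FALSE) {
  if (length(seqs) == 0) {
    return(tibble::tibble(
      id = character(), seq = character(),
      original_alphabet = character(), length = integer()
    ))
  }
  stopifnot(all(nzchar(gsub("[[:space:]]", "", seqs))))
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  alphabet <- detect_alphabet(seqs)
  norm <- normalize_rna(seqs, permissive = permissive)
  tibble::tibble(
    id = as.character(ids),
    seq = norm,
    original_alphabet = alphabet,
    length = nchar(norm)
  )
}

#' Reverse complement of RNA sequences
#'
#' Watson-Crick complement, reversed. Vectorized; the empty string maps to
#' itself.
#'
#' @param x Character vector over A/C/G/U.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AUGC")  # "GCAU"
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  out <- character(length(x))
  nonempty <- nzchar(x)
  if (any(nonempty)) {
    rc <- Biostrings::reverseComplement(Biostrings::RNAStringSet(x[nonempty]))
    out[nonempty] <- as.character(rc)
  }
  out
}

#' Read sequences from a FASTA file
#'
#' One row per record, in file order, normalized via [normalize_rna()].
#' Multi-line records are concatenated. Duplicate ids are retained with a
#' warning (downstream reports key on id plus window position); an empty file
#' yields an empty tibble with a warning; a record with an empty sequence is
#' an error.
#'
#' @param path Path to a FASTA file (DNA or RNA spelling).
#' @inheritParams normalize_rna
#' @return A sequence tibble as from [rna_tbl()].
#' @export
read_fasta <- function(path, permissive = FALSE) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning("no FASTA records found in ", path, call. = FALSE)
    return(rna_tbl(character()))
  }
  seqs <- unname(as.character(set))
  ids <- names(set)
  # keep only the first whitespace-delimited token of the header, FASTA-style
  ids <- sub("[[:space:]].*$", "", ids)
  if (any(!nzchar(seqs))) {
    stop("FASTA record '", ids[which(!nzchar(seqs))[1]], "' has an empty sequence",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids retained: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  rna_tbl(seqs, ids, permissive = permissive)
}

#' Write a sequence tibble to FASTA
#'
#' @param x A sequence tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  set <- Biostrings::BStringSet(x$seq)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Generate a synthetic mRNA with a controlled GC content
#'
#' Residues are drawn i.i.d. with P(G) = P(C) = `gc_fraction`/2 and
#' P(A) = P(U) = (1 - `gc_fraction`)/2. Output is bit-reproducible for a
#' fixed `(length, gc_fraction, seed)` triple and leaves the caller's RNG
#' state untouched.
#'
#' @param length Sequence length (>= 1; >= 23 for downstream design use).
#' @param gc_fraction Target GC fraction in `[0, 1]`. Default 0.5.
#' @param seed Integer seed for reproducibility.
#' @param id Identifier for the generated sequence.
#' @return A one-row sequence tibble.
#' @export
synthetic_mrna <- function(length, gc_fraction = 0.5, seed = 1L,
                           id = "synthetic_mrna") {
  stopifnot(length >= 1, gc_fraction >= 0, gc_fraction <= 1)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, U = (1 - gc_fraction) / 2)
  res <- withr::with_seed(seed,
    sample(names(p), size = length, replace = TRUE, prob = p))
  rna_tbl(paste(res, collapse = ""), ids = id)
}
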