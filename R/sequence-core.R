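# Nucleic-acid alphabet, complementarity (incl. G:U wobble) and
# composition statistics shared by every stage.
#
# Conventions: small RNAs and precursors are handled as RNA (U), the
# genome as DNA (T). A sequence never mixes T and U. N never pairs and is
# excluded from composition statistics.

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

check_alphabet <- function(x, moltype = c("rna", "dna"), allow_n = TRUE) {
  moltype <- match.arg(moltype)
  bad <- if (moltype == "rna") "[^ACGUN]" else "[^ACGTN]"
  if (!allow_n) bad <- sub("N", "", bad, fixed = TRUE)
  if (any(stringr::str_detect(x, bad))) {
    stop("invalid ", toupper(moltype), " alphabet in sequence", call. = FALSE)
  }
  invisible(x)
}

#' Convert between DNA and RNA representations
#'
#' `as_rna()` replaces T with U; `as_dna()` replaces U with T. Input is
#' uppercased first. Conversion between the two molecule types is always
#' explicit at module boundaries: reads and precursors live in RNA space,
#' the genome in DNA space.
#'
#' @param x Character vector of sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' as_rna("ACGT")
#' as_dna("ACGU")
as_rna <- function(x) chartr("Tt", "UU", toupper(x))

#' @rdname as_rna
#' @export
as_dna <- function(x) chartr("Uu", "TT", toupper(x))

#' Reverse complement
#'
#' Strand reversal for DNA or RNA character vectors. The molecule type is
#' taken from `moltype` ("auto" infers RNA when a U is present, otherwise
#' DNA). Applying the function twice returns the input.
#'
#' @param x Character vector of sequences (A/C/G/U/T/N, uppercase).
#' @param moltype "auto", "rna" or "dna".
#' @return Character vector of reverse complements, same molecule type.
#' @export
#' @examples
#' rev_comp("AUGC")
#' rev_comp("ACGT")
rev_comp <- function(x, moltype = c("auto", "rna", "dna")) {
  moltype <- match.arg(moltype)
  x <- toupper(x)
  if (length(x) == 0) return(character(0))
  is_rna <- switch(moltype,
    auto = stringr::str_detect(x, "U") | !stringr::str_detect(x, "T"),
    rna = rep(TRUE, length(x)),
    dna = rep(FALSE, length(x))
  )
  out <- character(length(x))
  if (any(is_rna)) {
    check_alphabet(x[is_rna], "rna")
    out[is_rna] <- as.character(
      Biostrings::reverseComplement(Biostrings::RNAStringSet(x[is_rna]))
    )
  }
  if (any(!is_rna)) {
    check_alphabet(x[!is_rna], "dna")
    out[!is_rna] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[!is_rna]))
    )
  }
  out
}

#' Base composition as percentages
#'
#' `gc_percent()` returns 100 * (G+C) / (A+C+G+U/T); `au_percent()` the
#' complementary A+U (or A+T) share. N residues are excluded from both
#' numerator and denominator, so for N-free sequences the two sum to 100.
#'
#' @param x Character vector of sequences.
#' @return Numeric vector of percentages in \[0, 100\].
#' @export
#' @examples
#' gc_percent("GGCC")
#' gc_percent("GAUC")
gc_percent <- function(x) {
  x <- toupper(x)
  if (any(!nzchar(x))) stop("empty sequence", call. = FALSE)
  counts <- Biostrings::letterFrequency(
    Biostrings::BStringSet(x), letters = c("G", "C", "A", "U", "T", "N")
  )
  denom <- rowSums(counts[, c("G", "C", "A", "U", "T"), drop = FALSE])
  if (any(denom == 0)) {
    stop("composition undefined: sequence contains only N", call. = FALSE)
  }
  unname(100 * rowSums(counts[, c("G", "C"), drop = FALSE]) / denom)
}

#' @rdname gc_percent
#' @export
au_percent <- function(x) 100 - gc_percent(x)

#' Classify one base pair
#'
#' Vectorised over pairs of single RNA bases. A-U and G-C are
#' Watson-Crick; G-U (either orientation) is a wobble; everything else,
#' including anything involving N, is a mismatch. The classification is
#' symmetric in its arguments.
#'
#' @param a,b Character vectors of single RNA bases (A/C/G/U/N).
#' @return Character vector with values `"watson_crick"`, `"wobble"` or
#'   `"mismatch"`.
#' @export
#' @examples
#' pair_class("G", "C")
#' pair_class("G", "U")
pair_class <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  ok <- c(RNA_BASES, "N")
  if (!all(a %in% ok) || !all(b %in% ok)) {
    stop("pair_class() expects RNA bases (A/C/G/U/N); got a DNA or invalid base",
         call. = FALSE)
  }
  key <- paste0(a, b)
  out <- rep("mismatch", length(key))
  out[key %in% c("AU", "UA", "GC", "CG")] <- "watson_crick"
  out[key %in% c("GU", "UG")] <- "wobble"
  out
}

# Split sequences into one-character vectors.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

# Nearest-neighbour helix stack energies, kcal/mol, in tenths
# (integer decikilocalories so that duplex comparisons are exact).
# Rows: pair at position i (5' strand base / 3' strand base), columns:
# pair at position i+1. Turner-flavoured values adjusted so that
# replacing a Watson-Crick pair by its wobble version never strengthens
# a stack; all entries are non-positive.
PAIR_LEVELS <- c("AU", "CG", "GC", "UA", "GU", "UG")

nn_stack_table <- function() {
  m <- matrix(c(
    # AU    CG    GC    UA    GU    UG
      -9,  -22,  -21,  -11,   -6,  -10,  # AU
     -21,  -33,  -24,  -21,  -14,  -21,  # CG
     -24,  -34,  -33,  -22,  -15,  -20,  # GC
     -13,  -24,  -21,   -9,  -10,   -8,  # UA
     -13,  -25,  -21,  -14,   -5,   -4,  # GU
     -10,  -15,  -14,   -6,   -2,   -5   # UG
  ), nrow = 6, byrow = TRUE, dimnames = list(PAIR_LEVELS, PAIR_LEVELS))
  m
}

# Integer pair index 1..6 for (top, bottom) base pairs, 0 when unpaired.
pair_index <- function(top, bottom) {
  key <- paste0(top, bottom)
  idx <- match(key, PAIR_LEVELS)
  idx[is.na(idx)] <- 0L
  idx
}
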