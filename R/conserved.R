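# Conserved miRNA identification against a miRBase-style reference
# (paired mature + hairpin FASTA linked by shared name prefixes), and
# seed-region comparison.
#
# Matching is unit-cost Levenshtein distance (substitutions and indels
# each cost 1, so gaps count as mismatches); at 18-30 nt a full dynamic
# programming distance is exact and deterministic. A read is a
# "conserved" call only when it matches a mature perfectly AND occurs as
# an exact substring of that mature's linked hairpin.

#' Load a mature + hairpin miRNA reference
#'
#' Mature and hairpin records are linked when one record name is a
#' prefix of the other after case-folding (e.g. `zma-miR156a` to
#' `zma-MIR156a`). Every mature must be contained in at least one linked
#' hairpin; containment up to 2 mismatches is tolerated with a warning.
#'
#' @param mature FASTA path or tibble (`name`, `seq`).
#' @param hairpin FASTA path or tibble (`name`, `seq`).
#' @return List with tibbles `mature` (`name`, `seq`, `hairpins`
#'   list-column) and `hairpin` (`name`, `seq`), sequences in RNA.
#' @export
load_mirna_ref <- function(mature, hairpin) {
  if (is.character(mature)) mature <- read_fasta(mature)
  if (is.character(hairpin)) hairpin <- read_fasta(hairpin)
  mature <- dplyr::mutate(mature, seq = as_rna(.data$seq))
  hairpin <- dplyr::mutate(hairpin, seq = as_rna(.data$seq))
  mkey <- tolower(mature$name)
  hkey <- tolower(hairpin$name)
  links <- lapply(mkey, function(mn) {
    hairpin$name[startsWith(mn, hkey) | startsWith(hkey, mn)]
  })
  for (i in seq_along(links)) {
    if (length(links[[i]]) == 0) next
    hseqs <- hairpin$seq[match(links[[i]], hairpin$name)]
    contained <- stringr::str_detect(hseqs, stringr::fixed(mature$seq[i]))
    if (!any(contained)) {
      near <- vapply(hseqs, function(h) {
        m <- Biostrings::matchPattern(mature$seq[i], Biostrings::RNAString(h),
                                      max.mismatch = 2)
        length(m) > 0
      }, logical(1))
      if (any(near)) {
        warning("mature ", mature$name[i],
                " only matches its hairpin with mismatches", call. = FALSE)
      } else {
        warning("mature ", mature$name[i],
                " is not contained in any linked hairpin", call. = FALSE)
      }
    }
  }
  mature$hairpins <- links
  list(mature = mature, hairpin = hairpin)
}

#' Match unique reads against known miRNAs
#'
#' Reports a hit for every read/mature pair within `max_mismatch` edit
#' distance (substitutions and indels cost 1 each). `conserved_call` is
#' true only for reads at distance 0 from a mature that also occur
#' exactly within a linked hairpin. With `cross_species = TRUE` the hits
#' are labelled as conserved in other species rather than native calls
#' (hairpin confirmation is not required, and `conserved_call` is FALSE).
#'
#' @param reads Collapsed read tibble (`read_id`, `seq`).
#' @param ref Reference from [load_mirna_ref()], or a tibble/FASTA of
#'   mature sequences only.
#' @param max_mismatch Maximum edit distance (default 2).
#' @param cross_species Label hits as cross-species conservation.
#' @return Tibble `read_id`, `mature_name`, `mismatches`,
#'   `perfect_mature`, `perfect_hairpin`, `conserved_call`,
#'   `cross_species`.
#' @export
match_known <- function(reads, ref, max_mismatch = 2L,
                        cross_species = FALSE) {
  if (is.character(ref)) ref <- read_fasta(ref)
  if (is.data.frame(ref)) {
    ref <- list(mature = dplyr::mutate(ref, seq = as_rna(.data$seq),
                                       hairpins = list(character(0))),
                hairpin = tibble::tibble(name = character(), seq = character()))
  }
  empty <- tibble::tibble(read_id = character(), mature_name = character(),
                          mismatches = integer(), perfect_mature = logical(),
                          perfect_hairpin = logical(),
                          conserved_call = logical(),
                          cross_species = logical())
  if (nrow(reads) == 0 || nrow(ref$mature) == 0) return(empty)
  d <- utils::adist(as_rna(reads$seq), ref$mature$seq)
  idx <- which(d <= max_mismatch, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  hits <- tibble::tibble(
    read_id = reads$read_id[idx[, 1]],
    mature_name = ref$mature$name[idx[, 2]],
    mismatches = d[idx],
    perfect_mature = d[idx] == 0L
  )
  hits$perfect_hairpin <- vapply(seq_len(nrow(hits)), function(i) {
    if (!hits$perfect_mature[i]) return(FALSE)
    hp_names <- ref$mature$hairpins[[idx[i, 2]]]
    if (length(hp_names) == 0) return(FALSE)
    hseqs <- ref$hairpin$seq[match(hp_names, ref$hairpin$name)]
    any(stringr::str_detect(hseqs,
                            stringr::fixed(as_rna(reads$seq[idx[i, 1]]))))
  }, logical(1))
  hits$conserved_call <- !cross_species & hits$perfect_mature &
    hits$perfect_hairpin
  hits$cross_species <- cross_species
  dplyr::arrange(hits, .data$read_id, .data$mismatches, .data$mature_name)
}

#' Are two miRNA seed regions identical?
#'
#' The seed is nucleotides 2-8, 1-based from the 5' end. Sequences
#' shorter than 8 nt are an error.
#'
#' @param a,b RNA sequences (character vectors, recycled).
#' @return Logical vector.
#' @export
#' @examples
#' seed_identical("AUGGAAGCUG", "CUGGAAGCAA")
seed_identical <- function(a, b) {
  if (any(nchar(c(a, b)) < 8)) {
    stop("seed comparison needs sequences of at least 8 nt", call. = FALSE)
  }
  substr(as_rna(a), 2, 8) == substr(as_rna(b), 2, 8)
}
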