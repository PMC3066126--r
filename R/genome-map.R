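# Perfect-match placement of unique reads on both strands of a
# reference genome. Reads are grouped by length and matched exactly with
# a Biostrings preprocessed dictionary (one pass per chromosome and
# strand); only full-length, mismatch-free hits are reported.

#' Map unique reads to a genome by perfect matching
#'
#' Finds every exact full-length occurrence of each read on either
#' strand. Minus-strand hits are occurrences of the read's reverse
#' complement, reported in plus-strand coordinates. Reads with more than
#' `max_loci` placements are flagged as highly repetitive and excluded
#' from the mapped set (they are siRNA/repeat-like, not hairpin
#' material).
#'
#' @param reads Collapsed read tibble (`read_id`, `seq` in RNA, `count`).
#' @param genome FASTA path, named character vector, or `DNAStringSet`.
#' @param max_loci Repetitive-read cap (default 20).
#' @return List with tibbles `loci` (`read_id`, `chrom`, `start`, `end`,
#'   `strand`, `count`; 0-based half-open, ordered by chrom, start,
#'   strand), `repetitive` (`read_id`, `n_loci`) and `unmapped`
#'   (`read_id`).
#' @export
map_reads <- function(reads, genome, max_loci = 20L) {
  genome <- load_genome(genome)
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0) {
    stop("empty genome", call. = FALSE)
  }
  if (nrow(reads) == 0) {
    empty <- tibble::tibble(read_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character(), count = integer())
    return(list(loci = empty,
                repetitive = tibble::tibble(read_id = character(), n_loci = integer()),
                unmapped = tibble::tibble(read_id = character())))
  }
  dna <- as_dna(reads$seq)
  hits <- vector("list", 2L * length(genome))
  h <- 0L
  for (w in sort(unique(nchar(dna)))) {
    sel <- which(nchar(dna) == w)
    fwd <- Biostrings::DNAStringSet(dna[sel])
    rev <- Biostrings::reverseComplement(fwd)
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(rev)
    for (ci in seq_along(genome)) {
      chrom <- names(genome)[ci]
      for (str in c("+", "-")) {
        pd <- if (str == "+") pd_f else pd_r
        m <- Biostrings::matchPDict(pd, genome[[ci]])
        cnt <- S4Vectors::elementNROWS(m)
        if (sum(cnt) == 0) next
        idx <- rep(sel, cnt)
        st <- unlist(Biostrings::startIndex(m), use.names = FALSE)
        h <- h + 1L
        hits[[h]] <- tibble::tibble(
          read_id = reads$read_id[idx], chrom = chrom,
          start = st - 1L, end = st - 1L + w, strand = str
        )
      }
    }
  }
  loci <- if (h > 0) dplyr::bind_rows(hits[seq_len(h)]) else
    tibble::tibble(read_id = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character())
  n_loci <- dplyr::count(loci, .data$read_id, name = "n_loci")
  repetitive <- dplyr::filter(n_loci, .data$n_loci > max_loci)
  loci <- loci |>
    dplyr::anti_join(repetitive, by = "read_id") |>
    dplyr::left_join(dplyr::select(reads, "read_id", "count"), by = "read_id") |>
    dplyr::arrange(.data$chrom, .data$start, .data$strand, .data$read_id)
  unmapped <- tibble::tibble(
    read_id = setdiff(reads$read_id, n_loci$read_id)
  )
  list(loci = loci, repetitive = repetitive, unmapped = unmapped)
}
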