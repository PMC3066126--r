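# File formats. FASTA/FASTQ through Biostrings, gene models through
# rtracklayer, tabular output through readr. Internal coordinates are
# 0-based half-open; BED stays 0-based, GFF3 output is 1-based inclusive.

#' Read sequences into a tibble
#'
#' `read_fasta()` returns `name`/`seq`; `read_fastq()` additionally
#' returns the Sanger-encoded quality string. Sequences are uppercased
#' and left in their file alphabet (DNA or RNA).
#'
#' @param path File path.
#' @return A tibble with one row per record.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  tibble::tibble(
    name = sub("\\s.*$", "", names(ss)),
    seq = unname(toupper(as.character(ss)))
  )
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    name = sub("\\s.*$", "", names(ss)),
    seq = unname(toupper(as.character(ss))),
    qual = unname(as.character(S4Vectors::mcols(ss)$qualities))
  )
}

#' Write sequences from a tibble
#'
#' `write_fasta()` writes `name`/`seq`. `write_collapsed_fasta()` writes
#' unique reads with the conventional `readID_xCOUNT` headers.
#' `write_fastq()` writes `name`/`seq`/`qual` (Sanger encoding).
#'
#' @param x Tibble with the columns named above.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  lines <- rbind(paste0(">", x$name), x$seq)
  writeLines(as.vector(lines), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_collapsed_fasta <- function(x, path) {
  write_fasta(
    tibble::tibble(name = paste0(x$read_id, "_x", x$count), seq = x$seq),
    path
  )
}

#' @rdname write_fasta
#' @export
write_fastq <- function(x, path) {
  lines <- rbind(paste0("@", x$name), x$seq, "+", x$qual)
  writeLines(as.vector(lines), path)
  invisible(path)
}

# Mean Sanger (Phred+33) quality of each quality string.
mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (!nzchar(q)) return(NA_real_)
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read and write mapped loci as BED6
#'
#' BED columns: chrom, start, end, name (read id), score (read count),
#' strand. BED is natively 0-based half-open, matching the package's
#' internal convention.
#'
#' @param x Tibble with columns `chrom`, `start`, `end`, `read_id`,
#'   `count`, `strand`.
#' @param path File path.
#' @return `read_bed()` a tibble; `write_bed()` the path, invisibly.
#' @export
write_bed <- function(x, path) {
  readr::write_tsv(
    dplyr::transmute(x, .data$chrom, .data$start, .data$end,
                     name = .data$read_id,
                     score = if ("count" %in% names(x)) .data$count else 0L,
                     .data$strand),
    path, col_names = FALSE
  )
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "read_id", "count", "strand"),
    col_types = "ciicic", progress = FALSE
  )
}

# Load a genome as a named DNAStringSet from a path / character vector /
# DNAStringSet.
load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    g <- Biostrings::readDNAStringSet(genome)
    names(g) <- sub("\\s.*$", "", names(g))
    return(g)
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("genome must be a FASTA path, a named character vector or a DNAStringSet",
       call. = FALSE)
}

# Exon table from a GFF3 gene model: tibble(chrom, start, end, strand,
# gene). GFF3 is 1-based inclusive; converted to 0-based half-open here.
read_gene_model <- function(gff) {
  if (is.null(gff)) return(NULL)
  if (is.data.frame(gff)) return(gff)
  gr <- rtracklayer::import(gff, format = "gff3")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) stop("gene model has no exon features", call. = FALSE)
  parent <- as.character(S4Vectors::mcols(ex)$Parent)
  if (length(parent) == 0 || all(is.na(parent))) parent <- as.character(seq_along(ex))
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene = parent
  )
}

#' Write hairpin candidates as GFF3
#'
#' Emits precursor, mature and star features (1-based inclusive
#' coordinates, as required by GFF3) with the candidate id, MFE and MFEI
#' in the attributes column.
#'
#' @param candidates Candidate tibble from [predict_mirnas()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates_gff3 <- function(candidates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##gff-version 3",
               "# coordinates are 1-based inclusive"), con)
  for (i in seq_len(nrow(candidates))) {
    cc <- candidates[i, ]
    attr_pre <- sprintf("ID=%s;mfe=%.2f;mfei=%.3f;arm=%s",
                        cc$candidate_id, cc$mfe, cc$mfei, cc$arm)
    rows <- c(
      sprintf("%s\tgermmir\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\t%s",
              cc$chrom, cc$pre_start + 1L, cc$pre_end, cc$strand, attr_pre),
      sprintf("%s\tgermmir\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s.mature;Parent=%s",
              cc$chrom, cc$mature_gstart + 1L, cc$mature_gend, cc$strand,
              cc$candidate_id, cc$candidate_id),
      sprintf("%s\tgermmir\tmiRNA_star\t%d\t%d\t.\t%s\t.\tID=%s.star;Parent=%s",
              cc$chrom, cc$star_gstart + 1L, cc$star_gend, cc$strand,
              cc$candidate_id, cc$candidate_id)
    )
    writeLines(rows, con)
  }
  invisible(path)
}
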