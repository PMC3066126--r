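# Partition mapped reads into noncoding-RNA classes, protein-coding
# exon/intron sense/antisense classes, and "other". A read is assigned
# the first matching class in a fixed priority order:
#   rRNA > tRNA > snoRNA > snRNA > siRNA >
#   exon_sense > exon_antisense > intron_sense > intron_antisense > other
# miRNA classes (known/novel) are assigned by downstream stages and
# override "other".

NCRNA_CLASSES <- c("rRNA", "tRNA", "snoRNA", "snRNA", "siRNA")
READ_CLASSES <- c(NCRNA_CLASSES,
                  "exon_sense", "exon_antisense",
                  "intron_sense", "intron_antisense",
                  "miRNA_known", "miRNA_novel", "other")

#' Classify mapped reads into RNA classes
#'
#' A read whose sequence occurs as an exact substring (either strand) of
#' a reference sequence of an ncRNA class is assigned that class, in the
#' priority order rRNA > tRNA > snoRNA > snRNA > siRNA. Reads matching
#' no ncRNA class are checked against the gene model (exon/intron,
#' sense/antisense of the read's mapped loci) when one is supplied, and
#' fall through to `"other"`. When no siRNA reference is given, a read is
#' called siRNA if another mapped read occupies the exact antisense
#' locus (a perfect duplex).
#'
#' @param mapping Result of [map_reads()] (or its `loci` tibble).
#' @param reads Collapsed read tibble.
#' @param ncrna_refs Named list of class -> FASTA path or character
#'   vector of reference sequences. Names must come from
#'   rRNA/tRNA/snoRNA/snRNA/siRNA.
#' @param gene_model Optional GFF3 path (exon features) or an exon
#'   tibble; `NULL` skips the gene-model classes.
#' @return Tibble `read_id`, `class`.
#' @export
classify_reads <- function(mapping, reads, ncrna_refs = list(),
                           gene_model = NULL) {
  loci <- if (is.data.frame(mapping)) mapping else mapping$loci
  ids <- unique(loci$read_id)
  seqs <- reads$seq[match(ids, reads$read_id)]
  cls <- rep(NA_character_, length(ids))

  bad <- setdiff(names(ncrna_refs), NCRNA_CLASSES)
  if (length(bad) > 0) {
    stop("unknown ncRNA class key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (k in NCRNA_CLASSES) {
    if (!k %in% names(ncrna_refs)) next
    ref <- ncrna_refs[[k]]
    if (is.character(ref) && length(ref) == 1 && file.exists(ref)) {
      ref <- read_fasta(ref)$seq
    }
    ref <- as_rna(ref)
    # concatenate references with a separator that can never match
    hay <- paste(c(ref, rev_comp(ref, "rna")), collapse = "#")
    todo <- which(is.na(cls))
    if (length(todo) == 0) break
    hit <- stringr::str_detect(hay, stringr::fixed(as_rna(seqs[todo])))
    cls[todo[hit]] <- k
  }

  # siRNA fallback: perfect antisense duplex between two mapped reads
  if (!"siRNA" %in% names(ncrna_refs)) {
    todo <- which(is.na(cls))
    if (length(todo) > 0) {
      key_p <- with(loci, paste(chrom, start, end, strand))
      flip <- c("+" = "-", "-" = "+")
      key_a <- with(loci, paste(chrom, start, end, flip[strand]))
      dup_ids <- unique(loci$read_id[key_a %in% key_p])
      cls[todo[ids[todo] %in% dup_ids]] <- "siRNA"
    }
  }

  gm <- read_gene_model(gene_model)
  if (!is.null(gm) && any(is.na(cls))) {
    todo_ids <- ids[is.na(cls)]
    sub <- loci[loci$read_id %in% todo_ids, , drop = FALSE]
    rg <- GenomicRanges::GRanges(sub$chrom,
                                 IRanges::IRanges(sub$start + 1L, sub$end),
                                 strand = sub$strand)
    ex <- GenomicRanges::GRanges(gm$chrom,
                                 IRanges::IRanges(gm$start + 1L, gm$end),
                                 strand = gm$strand)
    gene_rngs <- unlist(range(GenomicRanges::split(ex, gm$gene)))
    introns <- GenomicRanges::setdiff(gene_rngs, ex)
    assign_gm <- function(targets, same_strand) {
      ov <- GenomicRanges::findOverlaps(rg, targets, type = "within",
                                        ignore.strand = TRUE)
      qh <- S4Vectors::queryHits(ov)
      same <- as.character(GenomicRanges::strand(rg)[qh]) ==
        as.character(GenomicRanges::strand(targets)[S4Vectors::subjectHits(ov)])
      unique(sub$read_id[qh[same == same_strand]])
    }
    for (spec in list(list("exon_sense", ex, TRUE),
                      list("exon_antisense", ex, FALSE),
                      list("intron_sense", introns, TRUE),
                      list("intron_antisense", introns, FALSE))) {
      hit_ids <- assign_gm(spec[[2]], spec[[3]])
      cls[is.na(cls) & ids %in% hit_ids] <- spec[[1]]
    }
  }

  cls[is.na(cls)] <- "other"
  tibble::tibble(read_id = ids, class = cls)
}

#' Summarise read classes (Table-1-style)
#'
#' Distinct (unique-tag) and total (count-weighted) tallies per class
#' with fractions of the grand totals. Distinct counts over all classes
#' sum to the number of classified unique reads; likewise for totals.
#'
#' @param classes Tibble `read_id`, `class` from [classify_reads()]
#'   (possibly with miRNA classes patched in).
#' @param reads Collapsed read tibble (`read_id`, `count`).
#' @return Tibble `class`, `distinct_count`, `total_count`,
#'   `distinct_fraction`, `total_fraction`, one row per class in the
#'   canonical order (all-zero rows included).
#' @export
summarize_classes <- function(classes, reads) {
  joined <- dplyr::left_join(classes,
                             dplyr::select(reads, "read_id", "count"),
                             by = "read_id")
  if (anyNA(joined$count)) stop("every classified read needs a count")
  tall <- joined |>
    dplyr::group_by(class = factor(.data$class, levels = READ_CLASSES)) |>
    dplyr::summarise(distinct_count = dplyr::n(),
                     total_count = sum(.data$count), .groups = "drop") |>
    tidyr::complete(class,
                    fill = list(distinct_count = 0L, total_count = 0L))
  gd <- sum(tall$distinct_count)
  gt <- sum(tall$total_count)
  out <- tall |>
    dplyr::mutate(
      class = as.character(class),
      distinct_fraction = if (gd > 0) .data$distinct_count / gd else 0,
      total_fraction = if (gt > 0) .data$total_count / gt else 0
    )
  class(out) <- c("mir_class_summary", class(out))
  out
}
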