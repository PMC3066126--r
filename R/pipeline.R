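# Pipeline orchestration: clean -> collapse -> map -> annotate ->
# conserved -> predict -> cross-library confirmation -> targets, with
# per-stage attrition logging and the standard summary tables
# (class partition, length distribution, family sizes).

#' Assemble a pipeline configuration
#'
#' Bundles inputs and thresholds. Reads can be tibbles (from
#' [simulate_reads()] or [read_fastq()]) or FASTQ/FASTA paths; the
#' genome, references and transcripts likewise accept paths or in-memory
#' objects. Every threshold defaults to the pipeline's standard value
#' (see [mir_thresholds()]).
#'
#' @param reads_a,reads_b Raw reads of libraries A and (optionally) B.
#' @param genome Reference genome.
#' @param adapter3,adapter5 Adapter sequences.
#' @param ncrna_refs Named list of ncRNA reference sets.
#' @param gene_model Optional GFF3 path or exon tibble.
#' @param known_mature,known_hairpin miRBase-style reference pair.
#' @param cross_species Optional non-native mature set.
#' @param transcripts Optional transcript set for target scanning.
#' @param thresholds From [mir_thresholds()].
#' @param engine Folding engine.
#' @param out_dir Optional directory for stage outputs.
#' @return A `germmir_config` list.
#' @export
germmir_config <- function(reads_a, reads_b = NULL, genome,
                           adapter3, adapter5 = NULL,
                           ncrna_refs = list(), gene_model = NULL,
                           known_mature = NULL, known_hairpin = NULL,
                           cross_species = NULL, transcripts = NULL,
                           thresholds = mir_thresholds(),
                           engine = "auto", out_dir = NULL) {
  cfg <- list(reads_a = reads_a, reads_b = reads_b, genome = genome,
              adapter3 = adapter3, adapter5 = adapter5,
              ncrna_refs = ncrna_refs, gene_model = gene_model,
              known_mature = known_mature, known_hairpin = known_hairpin,
              cross_species = cross_species, transcripts = transcripts,
              thresholds = thresholds, engine = engine, out_dir = out_dir)
  class(cfg) <- "germmir_config"
  cfg
}

load_reads <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    if (grepl("\\.(fq|fastq)(\\.gz)?$", x)) return(read_fastq(x))
    return(read_fasta(x))
  }
  stop("reads must be a tibble or a FASTQ/FASTA path", call. = FALSE)
}

process_library <- function(raw, lib, cfg, log) {
  th <- cfg$thresholds
  cleaned <- clean_reads(raw, adapter3 = cfg$adapter3,
                         adapter5 = cfg$adapter5,
                         min_len = th$min_len, max_len = th$max_len,
                         min_mean_quality = th$min_quality)
  collapsed <- collapse_reads(cleaned, drop_singletons = TRUE)
  collapsed$library_id <- lib
  mapping <- map_reads(collapsed, cfg$genome, max_loci = th$max_loci)
  mapped_reads <- collapsed[collapsed$read_id %in% mapping$loci$read_id, ]
  classes <- classify_reads(mapping, collapsed, cfg$ncrna_refs,
                            cfg$gene_model)

  conserved_hits <- NULL
  if (!is.null(cfg$known_mature)) {
    ref <- load_mirna_ref(cfg$known_mature, cfg$known_hairpin)
    conserved_hits <- match_known(mapped_reads, ref,
                                  max_mismatch = th$max_mismatch)
    known_ids <- unique(conserved_hits$read_id[conserved_hits$conserved_call])
    classes$class[classes$read_id %in% known_ids] <- "miRNA_known"
  }
  candidates <- predict_mirnas(mapping, collapsed, cfg$genome,
                               classes = classes, thresholds = th,
                               engine = cfg$engine)
  classes$class[classes$read_id %in% candidates$read_id] <- "miRNA_novel"

  summary <- summarize_classes(classes, mapped_reads)
  lengths <- length_distribution(collapsed)

  log[[lib]] <- list(
    raw = nrow(raw),
    dropped = attr(cleaned, "drop_log"),
    cleaned = nrow(cleaned),
    cleaned_total = nrow(cleaned),
    distinct = nrow(collapsed),
    collapsed_total = sum(collapsed$count),
    mapped_distinct = nrow(mapped_reads),
    mapped_total = sum(mapped_reads$count),
    repetitive = nrow(mapping$repetitive),
    candidates = nrow(candidates)
  )
  list(cleaned = cleaned, collapsed = collapsed, mapping = mapping,
       classes = classes, conserved = conserved_hits,
       candidates = candidates, class_summary = summary,
       length_dist = lengths, log = log)
}

#' Run the full discovery pipeline
#'
#' Executes every stage in order for one or two libraries, confirms
#' candidates across libraries when both are given, scans targets for
#' confirmed matures, and collects the summary tables (read-class
#' partition, length distribution, family sizes, candidate statistics).
#' Re-running with the identical configuration and inputs reproduces
#' identical outputs.
#'
#' @param cfg From [germmir_config()].
#' @return A `germmir_run` list with per-library results (`libs`),
#'   `confirmed`, `families`, `targets`, `summary` and `log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "germmir_config"))
  t0 <- Sys.time()
  log <- list()
  libs <- list()
  raw_a <- load_reads(cfg$reads_a)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  libs$A <- stage("library A", process_library(raw_a, "A", cfg, log))
  log <- libs$A$log
  confirmed <- NULL
  if (!is.null(cfg$reads_b)) {
    raw_b <- load_reads(cfg$reads_b)
    libs$B <- stage("library B", process_library(raw_b, "B", cfg, log))
    log <- utils::modifyList(log, libs$B$log)
    confirmed <- stage("crosslib", intersect_candidates(
      libs$A$candidates, libs$B$candidates,
      expr_fold_limit = cfg$thresholds$expr_fold_limit,
      total_a = sum(libs$A$collapsed$count),
      total_b = sum(libs$B$collapsed$count)
    ))
  }
  final_set <- if (!is.null(confirmed)) confirmed else libs$A$candidates
  families <- group_families(final_set)
  targets <- NULL
  if (!is.null(cfg$transcripts) && nrow(final_set) > 0) {
    mirnas <- tibble::tibble(
      name = final_set$candidate_id, seq = final_set$mature_seq
    ) |> dplyr::distinct(.data$seq, .keep_all = TRUE)
    targets <- stage("targets", scan_transcripts(
      mirnas, cfg$transcripts, strict = TRUE,
      thresholds = cfg$thresholds
    ))
  }
  run <- list(
    libs = libs, confirmed = confirmed, families = families,
    targets = targets,
    summary = list(
      classes = lapply(libs, `[[`, "class_summary"),
      lengths = lapply(libs, `[[`, "length_dist"),
      family_sizes = dplyr::count(families, .data$family_size,
                                  name = "n_families"),
      n_candidates = vapply(libs, function(l) nrow(l$candidates),
                            integer(1)),
      n_confirmed = if (is.null(confirmed)) NA_integer_ else nrow(confirmed),
      n_targeted_mirnas = if (is.null(targets)) NA_integer_ else
        length(unique(targets$mirna_id))
    ),
    log = log,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  class(run) <- "germmir_run"
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

# Write the stage outputs of a run: per-library collapsed FASTA, BED,
# class table, length table, candidate GFF3 + TSV, confirmed set,
# target TSV and a plain-text summary.
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lib in names(run$libs)) {
    l <- run$libs[[lib]]
    write_collapsed_fasta(l$collapsed,
                          file.path(dir, paste0("collapsed_", lib, ".fa")))
    write_bed(l$mapping$loci, file.path(dir, paste0("mapped_", lib, ".bed")))
    readr::write_tsv(l$class_summary,
                     file.path(dir, paste0("classes_", lib, ".tsv")))
    readr::write_tsv(l$length_dist,
                     file.path(dir, paste0("lengths_", lib, ".tsv")))
    if (nrow(l$candidates) > 0) {
      write_candidates_gff3(l$candidates,
                            file.path(dir, paste0("candidates_", lib, ".gff3")))
    }
    readr::write_tsv(
      dplyr::select(l$candidates, dplyr::any_of(c(
        "candidate_id", "chrom", "pre_start", "pre_end", "strand",
        "mature_seq", "star_seq", "mfe", "mfei", "gc", "au",
        "duplex_unpaired", "loop_distance", "mature_count",
        "star_read_count", "structure"))),
      file.path(dir, paste0("candidates_", lib, ".tsv")))
  }
  if (!is.null(run$confirmed)) {
    readr::write_tsv(
      dplyr::select(run$confirmed, dplyr::any_of(c(
        "candidate_id", "chrom", "pre_start", "pre_end", "strand",
        "mature_seq", "mfe", "mfei", "mature_count", "mature_count_b",
        "count_ratio", "expression_consistent"))),
      file.path(dir, "confirmed.tsv"))
  }
  if (!is.null(run$targets)) {
    readr::write_tsv(run$targets, file.path(dir, "targets.tsv"))
  }
  readr::write_tsv(run$summary$family_sizes,
                   file.path(dir, "family_sizes.tsv"))
  summary_lines <- c(
    "germmir pipeline summary",
    paste0("libraries: ", paste(names(run$libs), collapse = ", ")),
    vapply(names(run$libs), function(lib) {
      lg <- run$log[[lib]]
      sprintf("%s: raw=%d cleaned=%d distinct=%d mapped_distinct=%d candidates=%d",
              lib, lg$raw, lg$cleaned, lg$distinct, lg$mapped_distinct,
              lg$candidates)
    }, character(1)),
    sprintf("confirmed: %s",
            ifelse(is.null(run$confirmed), "NA",
                   as.character(nrow(run$confirmed)))),
    sprintf("families: %d", nrow(unique(run$families["family"]))),
    sprintf("targeted miRNAs: %s",
            ifelse(is.null(run$targets), "NA",
                   as.character(length(unique(run$targets$mirna_id)))))
  )
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.germmir_run <- function(x, ...) {
  cat("<germmir_run>\n")
  for (lib in names(x$libs)) {
    lg <- x$log[[lib]]
    cat(sprintf(
      "  library %s: %d raw -> %d cleaned -> %d distinct -> %d candidates\n",
      lib, lg$raw, lg$cleaned, lg$distinct, lg$candidates))
  }
  if (!is.null(x$confirmed)) {
    cat(sprintf("  confirmed across libraries: %d\n", nrow(x$confirmed)))
  }
  if (!is.null(x$targets)) {
    cat(sprintf("  target hits: %d (%d miRNAs)\n", nrow(x$targets),
                length(unique(x$targets$mirna_id))))
  }
  invisible(x)
}
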