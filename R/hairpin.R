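# Novel-miRNA prediction core: extract genomic windows around
# unannotated mapped reads, fold them, derive the miRNA* span (2-nt 3'
# overhangs on both strands), and evaluate the candidate criteria:
#   (a) the window folds into a stem-loop containing the read,
#   (b) the read sits entirely on one arm,
#   (c) at most 6 unpaired nucleotides in the miRNA/miRNA* duplex,
#   (d) no terminal-loop residue or helix break inside miRNA or miRNA*,
#   (e) negative MFE (<= -20 kcal/mol), mature length 20-22 nt,
#       miRNA-miRNA* distance 5-240 nt, and MFEI > 0.85.
# Candidate statistics (MFE, MFEI, A+U%) refer to the trimmed precursor:
# the enclosing stem-loop refolded after trimming the window.

#' Default thresholds of the discovery pipeline
#'
#' Returns the full threshold set used across the pipeline, each at its
#' conventional value: insert length window 18-30 nt, at most 2
#' mismatches against known matures, precursor MFE at most -20 kcal/mol,
#' MFEI above 0.85, at most 6 unpaired duplex nucleotides,
#' miRNA-to-miRNA* distance 5-240 nt, mature length 20-22 nt, mature
#' dominance at least 50% of precursor-mapped counts, target strict mode
#' at 3 mismatches, and a duplex/perfect energy ratio of 75%.
#'
#' @param ... Named overrides of individual thresholds.
#' @return Named list of thresholds.
#' @export
mir_thresholds <- function(...) {
  th <- list(
    min_len = 18L, max_len = 30L, min_quality = 20,
    max_mismatch = 2L,
    flank = 250L, max_loci = 20L,
    mfe_max = -20, mfei_min = 0.85,
    max_unpaired = 6L, dist_min = 5L, dist_max = 240L,
    mature_min = 20L, mature_max = 22L,
    dominance = 0.5, star_slack = 1L,
    expr_fold_limit = 4,
    max_target_mismatch = 4, strict_target_mismatch = 3,
    region_target_mismatch = 2.5, energy_ratio = 0.75
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(th))
  if (length(bad) > 0) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  th[names(dots)] <- dots
  th
}

#' Minimal folding free energy index
#'
#' `MFEI = (|MFE| / length * 100) / GC%`: the length- and
#' composition-adjusted folding energy used to separate genuine
#' pre-miRNAs (typically MFEI > 0.85) from other structured RNAs.
#' Returns 0 for an unfolded sequence (MFE >= 0).
#'
#' @param mfe Minimum free energy, kcal/mol (non-positive for paired
#'   structures).
#' @param length Sequence length, nt (> 0).
#' @param gc G+C content as a percentage in (0, 100].
#' @return Dimensionless MFEI, positive when `mfe < 0`.
#' @export
#' @examples
#' mfei(-42.5, 100, 50) # 0.85
#' mfei(-46.56, 120, 40) # 0.97
mfei <- function(mfe, length, gc) {
  if (any(length <= 0)) stop("length must be positive", call. = FALSE)
  if (any(gc <= 0 | gc > 100)) {
    stop("MFEI undefined: GC percentage must be in (0, 100]", call. = FALSE)
  }
  ifelse(mfe >= 0, 0, (abs(mfe) / length * 100) / gc)
}

#' Extract candidate precursor windows around a mapped read
#'
#' Two anchored windows per locus: one placing the read near the 5' end
#' (genomic context downstream) and one near the 3' end (context
#' upstream), each with up to `flank` nt of context plus a short
#' `pad` on the anchored side. Windows are strand-adjusted to the read's
#' strand and transcribed to RNA; windows truncated at a contig edge are
#' returned with a warning.
#'
#' @param locus One-row tibble or list with `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @param genome Genome as for [map_reads()].
#' @param flank Context length, nt (default 250).
#' @param pad Context on the anchored side (default 20).
#' @return Tibble with `chrom`, `w_start`, `w_end`, `strand`, `seq`
#'   (RNA, read direction), `read_start`, `read_end` (0-based half-open
#'   within `seq`).
#' @export
extract_windows <- function(locus, genome, flank = 250L, pad = 20L) {
  genome <- load_genome(genome)
  chrom_len <- Biostrings::width(genome)[match(locus$chrom, names(genome))]
  if (is.na(chrom_len)) stop("unknown chromosome: ", locus$chrom, call. = FALSE)
  if (locus$start < 0 || locus$end > chrom_len || locus$start >= locus$end) {
    stop("locus out of bounds", call. = FALSE)
  }
  want <- list(c(locus$start - pad, locus$end + flank),
               c(locus$start - flank, locus$end + pad))
  bounds <- unique(lapply(want, function(b) {
    c(max(0L, as.integer(b[1])), min(chrom_len, as.integer(b[2])))
  }))
  if (!setequal(unlist(want), unlist(bounds)) &&
      any(unlist(want) < 0 | unlist(want) > chrom_len)) {
    warning("window truncated at contig edge", call. = FALSE)
  }
  rows <- lapply(bounds, function(b) {
    dna <- as.character(Biostrings::subseq(genome[[locus$chrom]],
                                           b[1] + 1L, b[2]))
    if (locus$strand == "-") {
      seq <- as_rna(rev_comp(dna, "dna"))
      rs <- b[2] - locus$end
    } else {
      seq <- as_rna(dna)
      rs <- locus$start - b[1]
    }
    tibble::tibble(chrom = locus$chrom, w_start = b[1], w_end = b[2],
                   strand = locus$strand, seq = seq,
                   read_start = rs, read_end = rs + (locus$end - locus$start))
  })
  dplyr::bind_rows(rows)
}

# Map a position interval in window RNA-direction coordinates (0-based
# half-open) back to genomic plus-strand coordinates.
window_to_genome <- function(w_start, w_end, strand, lo, hi) {
  if (strand == "-") c(w_end - hi, w_end - lo) else c(w_start + lo, w_start + hi)
}

#' Evaluate a folded window as a miRNA hairpin candidate
#'
#' Derives the miRNA* span as the duplex partner of the mature with 2-nt
#' 3' overhangs on both strands, trims the window to the enclosing
#' stem-loop, refolds the trimmed precursor, and evaluates all candidate
#' criteria on it.
#'
#' @param fold One-row tibble from [fold_rna()] (or list with `seq`,
#'   `structure`, `mfe`).
#' @param read_span Integer vector `c(start, end)`: the mature read's
#'   0-based half-open span within `fold$seq`.
#' @param thresholds From [mir_thresholds()].
#' @param engine Folding engine for the refold.
#' @param refold Trim and refold the enclosing stem-loop (default TRUE;
#'   FALSE evaluates the given fold as the precursor directly).
#' @return One-row tibble with the precursor (`pre_seq`, `structure`,
#'   `mfe`, `mfei`, `gc`, `au`, `trim_offset`), mature and star spans
#'   (0-based half-open within the precursor), `arm`, `duplex_unpaired`,
#'   `loop_distance`, per-criterion logicals (`crit_*`), `accepted` and
#'   `reject_reason`.
#' @export
evaluate_candidate <- function(fold, read_span, thresholds = mir_thresholds(),
                               engine = c("auto", "vienna", "internal"),
                               refold = TRUE) {
  engine <- match.arg(engine)
  seqc <- fold$seq[[1]]
  structure <- fold$structure[[1]]
  mfe <- fold$mfe[[1]]
  n <- nchar(seqc)
  m1 <- read_span[1] + 1L
  m2 <- read_span[2]
  if (m1 < 1 || m2 > n || m1 > m2) stop("read span outside window", call. = FALSE)

  fail <- function(reason, crit = list()) {
    base <- list(crit_hairpin = FALSE, crit_one_arm = FALSE,
                 crit_duplex = FALSE, crit_clean = FALSE,
                 crit_mature_len = FALSE, crit_loop_dist = FALSE,
                 crit_mfe = FALSE, crit_mfei = FALSE)
    base[names(crit)] <- crit
    tibble::tibble(
      pre_seq = seqc, structure = structure, mfe = mfe,
      mfei = NA_real_, gc = NA_real_, au = NA_real_,
      trim_offset = 0L,
      mature_start = m1 - 1L, mature_end = m2,
      star_start = NA_integer_, star_end = NA_integer_,
      arm = NA_character_, duplex_unpaired = NA_integer_,
      loop_distance = NA_integer_, star_read_count = 0L,
      !!!base, accepted = FALSE, reject_reason = reason
    )
  }

  pt <- pair_table(structure)
  geo <- stem_geometry(pt, m1, m2, n, mfe)
  if (!geo$ok) return(fail(geo$reason, geo$crit))
  arm <- geo$arm
  star_beg <- geo$star_beg
  star_end <- geo$star_end
  paired <- geo$paired
  crit_hairpin <- TRUE
  crit_one_arm <- TRUE

  if (refold) {
    tb <- trim_bounds(pt, m1, m2, star_beg, star_end, n)
    refolded <- fold_rna(substr(seqc, tb[1], tb[2]), engine = engine)
    out <- evaluate_candidate(refolded, c(m1 - tb[1], m2 - tb[1] + 1L),
                              thresholds, engine, refold = FALSE)
    out$trim_offset <- tb[1] - 1L
    return(out)
  }

  star_core <- c(star_beg, max(star_beg, star_end - 2L))
  star_ext <- c(star_beg - 3L, star_end + 3L)
  mature_ext <- c(m1 - 3L, m2 + 3L)

  # unpaired nucleotides in the miRNA/miRNA* duplex
  duplex_unpaired <- sum(!paired | pt[m1:m2] < star_ext[1] |
                           pt[m1:m2] > star_ext[2])
  crit_duplex <- duplex_unpaired <= thresholds$max_unpaired

  # terminal loop of the stem spanning mature and star
  region <- min(m1, star_beg):max(m2, star_end)
  stem_pos <- region[pt[region] > region]
  crit_clean <- TRUE
  loop_lo <- NA_integer_; loop_hi <- NA_integer_
  if (length(stem_pos) > 0) {
    p_in <- max(stem_pos)
    loop_lo <- p_in + 1L; loop_hi <- pt[p_in] - 1L
    mature_core_hi <- m2 - 2L
    if (loop_lo <= loop_hi) {
      overlaps <- function(a1, a2) max(a1, loop_lo) <= min(a2, loop_hi)
      if (overlaps(m1, mature_core_hi) ||
          overlaps(star_core[1], star_core[2])) crit_clean <- FALSE
    }
  }
  # helix break: duplex partners must stay within the opposite span
  mp <- pt[m1:m2]; mp <- mp[mp > 0]
  if (any(mp < star_ext[1] - 3L | mp > star_ext[2] + 3L)) crit_clean <- FALSE
  sp <- pt[star_core[1]:star_core[2]]; sp <- sp[sp > 0]
  if (any(sp < mature_ext[1] - 3L | sp > mature_ext[2] + 3L)) crit_clean <- FALSE

  mature_len <- m2 - m1 + 1L
  crit_mature_len <- mature_len >= thresholds$mature_min &&
    mature_len <= thresholds$mature_max

  loop_distance <- if (arm == "5p") star_beg - m2 - 1L else m1 - star_end - 1L
  crit_loop_dist <- loop_distance >= thresholds$dist_min &&
    loop_distance <= thresholds$dist_max

  gc <- gc_percent(seqc)
  au <- 100 - gc
  crit_mfe <- mfe < 0 && mfe <= thresholds$mfe_max
  mfei_val <- if (gc > 0) mfei(mfe, n, gc) else 0
  crit_mfei <- mfei_val > thresholds$mfei_min

  crits <- c(crit_hairpin = crit_hairpin, crit_one_arm = crit_one_arm,
             crit_duplex = crit_duplex, crit_clean = crit_clean,
             crit_mature_len = crit_mature_len,
             crit_loop_dist = crit_loop_dist,
             crit_mfe = crit_mfe, crit_mfei = crit_mfei)
  accepted <- all(crits)
  reject_reason <- if (accepted) NA_character_ else
    names(crits)[which(!crits)[1]]

  tibble::tibble(
    pre_seq = seqc, structure = structure, mfe = mfe,
    mfei = mfei_val, gc = gc, au = au, trim_offset = 0L,
    mature_start = m1 - 1L, mature_end = m2,
    star_start = star_beg - 1L, star_end = star_end,
    arm = arm, duplex_unpaired = as.integer(duplex_unpaired),
    loop_distance = as.integer(loop_distance), star_read_count = 0L,
    !!!as.list(crits), accepted = accepted, reject_reason = reject_reason
  )
}

# Shared stem geometry: mature pairing checks (stem containing the
# read, one arm only) and the miRNA* span derived as the duplex partner
# of the mature with 2-nt 3' overhangs, projected through bulges.
stem_geometry <- function(pt, m1, m2, n, mfe) {
  partners <- pt[m1:m2]
  paired <- partners > 0
  if (!(mfe < 0 && any(paired))) {
    return(list(ok = FALSE, reason = "no stem containing the read",
                crit = list()))
  }
  inside <- partners[paired] >= m1 & partners[paired] <= m2
  one_side <- all(partners[paired] > m2) || all(partners[paired] < m1)
  if (any(inside) || !one_side) {
    return(list(ok = FALSE, reason = "loop overlap",
                crit = list(crit_hairpin = TRUE)))
  }
  arm <- if (partners[paired][1] > m2) "5p" else "3p"
  proj <- function(p) {
    cand <- which(paired)
    near <- cand[which.min(abs(cand - (p - m1 + 1L)))]
    pt[m1 + near - 1L] + (near - (p - m1 + 1L))
  }
  star_beg <- proj(m2 - 2L)
  star_end <- proj(m1) + 2L
  if (star_beg > star_end) { tmp <- star_beg; star_beg <- star_end; star_end <- tmp }
  list(ok = TRUE, arm = arm, paired = paired,
       star_beg = max(1L, as.integer(star_beg)),
       star_end = min(n, as.integer(star_end)))
}

# Trim a window to the enclosing stem-loop (outermost pair enclosing
# mature and star), with 2 nt of margin for the star overhang.
trim_bounds <- function(pt, m1, m2, star_beg, star_end, n) {
  lo <- min(m1, star_beg); hi <- max(m2, star_end)
  enclosing <- which(pt > seq_len(n) & seq_len(n) <= lo & pt >= hi)
  t_lo <- if (length(enclosing) > 0) max(enclosing) else lo
  t_hi <- if (length(enclosing) > 0) pt[max(enclosing)] else hi
  c(max(1L, t_lo - 2L), min(n, t_hi + 2L))
}

#' Count sequenced miRNA* support for candidates
#'
#' Counts mapped reads whose genomic locus coincides with a candidate's
#' miRNA* span, tolerating `slack` nt at each end. Fills the
#' `star_read_count` column and a logical `star_supported`.
#'
#' @param candidates Candidate tibble from [predict_mirnas()] (must
#'   carry genomic star coordinates `star_gstart`, `star_gend`).
#' @param mapping Result of [map_reads()] or its `loci` tibble.
#' @param slack Coordinate slack per end (default 1).
#' @return The candidate tibble with `star_read_count`/`star_supported`.
#' @export
find_star_reads <- function(candidates, mapping, slack = 1L) {
  loci <- if (is.data.frame(mapping)) mapping else mapping$loci
  n <- nrow(candidates)
  counts <- integer(n)
  for (i in seq_len(n)) {
    cc <- candidates[i, ]
    if (is.na(cc$star_gstart)) next
    sel <- loci$chrom == cc$chrom & loci$strand == cc$strand &
      abs(loci$start - cc$star_gstart) <= slack &
      abs(loci$end - cc$star_gend) <= slack &
      loci$read_id != cc$read_id
    counts[i] <- sum(loci$count[sel])
  }
  candidates$star_read_count <- counts
  candidates$star_supported <- counts > 0
  candidates
}

#' Predict novel miRNA candidates from mapped reads
#'
#' For every locus of every eligible read (unannotated, i.e. class
#' `"other"` when a classification is given), extracts two anchored
#' genomic windows, folds them, and evaluates the hairpin criteria.
#' Overlapping accepted candidates on one strand keep the highest-MFEI
#' window (ties: lower start). The mature read must carry at least
#' `thresholds$dominance` of all read counts mapped within the precursor
#' (`crit_dominant`); miRNA* support is counted afterwards.
#'
#' @param mapping Result of [map_reads()].
#' @param reads Collapsed read tibble.
#' @param genome Genome as for [map_reads()].
#' @param classes Optional classification from [classify_reads()]; only
#'   reads of class `"other"` are considered when given.
#' @param thresholds From [mir_thresholds()].
#' @param engine Folding engine.
#' @param keep_rejected Also return rejected evaluations (default FALSE).
#' @return Candidate tibble (class `mir_candidates`): one row per
#'   accepted candidate with precursor/mature/star genomic coordinates,
#'   fold statistics, criterion flags and star support.
#' @export
predict_mirnas <- function(mapping, reads, genome, classes = NULL,
                           thresholds = mir_thresholds(),
                           engine = c("auto", "vienna", "internal"),
                           keep_rejected = FALSE) {
  engine <- match.arg(engine)
  genome <- load_genome(genome)
  loci <- mapping$loci
  if (!is.null(classes)) {
    other_ids <- classes$read_id[classes$class == "other"]
    loci <- dplyr::filter(loci, .data$read_id %in% other_ids)
  }
  # the mature-length criterion applies to the read itself, so windows
  # are only folded for reads that could satisfy it
  len_ok <- reads$read_id[nchar(reads$seq) >= thresholds$mature_min &
                            nchar(reads$seq) <= thresholds$mature_max]
  loci <- dplyr::filter(loci, .data$read_id %in% len_ok)
  if (nrow(loci) == 0) return(empty_candidates())

  windows <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    w <- extract_windows(loci[i, ], genome, flank = thresholds$flank)
    w$read_id <- loci$read_id[i]
    w$locus_start <- loci$start[i]
    w
  })
  # two batched folding passes: all windows, then all trimmed precursors
  folds <- fold_rna(windows$seq, engine = engine)
  trims <- lapply(seq_len(nrow(windows)), function(i) {
    m1 <- windows$read_start[i] + 1L
    m2 <- windows$read_end[i]
    n <- nchar(folds$seq[i])
    pt <- pair_table(folds$structure[i])
    geo <- stem_geometry(pt, m1, m2, n, folds$mfe[i])
    if (!geo$ok) return(NULL)
    trim_bounds(pt, m1, m2, geo$star_beg, geo$star_end, n)
  })
  live <- which(!vapply(trims, is.null, logical(1)))
  trimmed_seqs <- vapply(live, function(i)
    substr(windows$seq[i], trims[[i]][1], trims[[i]][2]), character(1))
  trimmed_folds <- fold_rna(trimmed_seqs, engine = engine)
  evals <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    ev <- if (i %in% live) {
      k <- match(i, live)
      e <- evaluate_candidate(
        trimmed_folds[k, ],
        c(windows$read_start[i] - trims[[i]][1] + 1L,
          windows$read_end[i] - trims[[i]][1] + 1L),
        thresholds, engine = engine, refold = FALSE
      )
      e$trim_offset <- trims[[i]][1] - 1L
      e
    } else {
      evaluate_candidate(folds[i, ],
                         c(windows$read_start[i], windows$read_end[i]),
                         thresholds, engine = engine, refold = FALSE)
    }
    dplyr::bind_cols(windows[i, c("chrom", "w_start", "w_end", "strand",
                                  "read_id")], ev)
  })

  # window -> genome coordinates for precursor, mature, star
  evals <- evals |>
    dplyr::mutate(
      pre_len = nchar(.data$pre_seq),
      g1 = purrr::pmap(list(.data$w_start, .data$w_end, .data$strand,
                            .data$trim_offset,
                            .data$trim_offset + .data$pre_len),
                       window_to_genome),
      pre_start = purrr::map_int(.data$g1, ~ as.integer(.x[1])),
      pre_end = purrr::map_int(.data$g1, ~ as.integer(.x[2])),
      g2 = purrr::pmap(list(.data$w_start, .data$w_end, .data$strand,
                            .data$trim_offset + .data$mature_start,
                            .data$trim_offset + .data$mature_end),
                       window_to_genome),
      mature_gstart = purrr::map_int(.data$g2, ~ as.integer(.x[1])),
      mature_gend = purrr::map_int(.data$g2, ~ as.integer(.x[2])),
      g3 = purrr::pmap(list(.data$w_start, .data$w_end, .data$strand,
                            .data$trim_offset + .data$star_start,
                            .data$trim_offset + .data$star_end),
                       window_to_genome),
      star_gstart = purrr::map_int(.data$g3, ~ as.integer(.x[1])),
      star_gend = purrr::map_int(.data$g3, ~ as.integer(.x[2]))
    ) |>
    dplyr::select(-"g1", -"g2", -"g3")

  accepted <- dplyr::filter(evals, .data$accepted)
  if (nrow(accepted) > 0) {
    # mature dominance within the precursor (before deduplication, so a
    # star-seeded duplicate of a hairpin never displaces the mature one)
    accepted$mature_count <- reads$count[match(accepted$read_id, reads$read_id)]
    accepted$precursor_count <- vapply(seq_len(nrow(accepted)), function(i) {
      cc <- accepted[i, ]
      sel <- mapping$loci$chrom == cc$chrom &
        mapping$loci$strand == cc$strand &
        mapping$loci$start >= cc$pre_start & mapping$loci$end <= cc$pre_end
      sum(mapping$loci$count[sel])
    }, numeric(1))
    accepted$crit_dominant <-
      accepted$mature_count >= thresholds$dominance * accepted$precursor_count
    accepted <- dplyr::filter(accepted, .data$crit_dominant)
  }
  if (nrow(accepted) > 0) {
    # overlapping candidates describe one hairpin locus (a stem-loop is
    # near-palindromic, so the same hairpin is typically recovered from
    # both strands): keep the best window per locus
    accepted <- accepted |>
      dplyr::arrange(.data$chrom, .data$pre_start) |>
      dplyr::group_by(.data$chrom) |>
      dplyr::mutate(cluster = cumsum(
        dplyr::lag(cummax(.data$pre_end), default = dplyr::first(.data$pre_start)) <=
          .data$pre_start)) |>
      dplyr::group_by(.data$chrom, .data$cluster) |>
      dplyr::arrange(dplyr::desc(.data$mfei), dplyr::desc(.data$mature_count),
                     .data$pre_start, .data$strand, .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup() |>
      dplyr::select(-"cluster")
  }
  if (nrow(accepted) > 0) {
    accepted <- find_star_reads(accepted, mapping,
                                slack = thresholds$star_slack)
    accepted$mature_seq <- substr(accepted$pre_seq,
                                  accepted$mature_start + 1L,
                                  accepted$mature_end)
    accepted$star_seq <- substr(accepted$pre_seq,
                                accepted$star_start + 1L,
                                accepted$star_end)
    accepted$candidate_id <- sprintf("cand-%s-%d-%s", accepted$chrom,
                                     accepted$pre_start, accepted$strand)
    accepted <- dplyr::arrange(accepted, .data$chrom, .data$pre_start,
                               .data$strand)
  } else {
    accepted <- empty_candidates()
  }
  out <- if (keep_rejected) {
    attr(accepted, "rejected") <- dplyr::filter(evals, !.data$accepted)
    accepted
  } else accepted
  class(out) <- c("mir_candidates", class(out))
  out
}

empty_candidates <- function() {
  tibble::tibble(
    chrom = character(), w_start = integer(), w_end = integer(),
    strand = character(), read_id = character(), pre_seq = character(),
    structure = character(), mfe = numeric(), mfei = numeric(),
    gc = numeric(), au = numeric(), trim_offset = integer(),
    mature_start = integer(), mature_end = integer(),
    star_start = integer(), star_end = integer(), arm = character(),
    duplex_unpaired = integer(), loop_distance = integer(),
    star_read_count = integer(), crit_hairpin = logical(),
    crit_one_arm = logical(), crit_duplex = logical(),
    crit_clean = logical(), crit_mature_len = logical(),
    crit_loop_dist = logical(), crit_mfe = logical(),
    crit_mfei = logical(), accepted = logical(),
    reject_reason = character(), pre_len = integer(),
    pre_start = integer(), pre_end = integer(),
    mature_gstart = integer(), mature_gend = integer(),
    star_gstart = integer(), star_gend = integer(),
    mature_count = numeric(), precursor_count = numeric(),
    crit_dominant = logical(), star_supported = logical(),
    mature_seq = character(), star_seq = character(),
    candidate_id = character()
  )
}

#' Group accepted matures into novel families
#'
#' Two matures belong to one family when their seed regions (nt 2-8) are
#' identical and their total edit distance is at most `max_dist`.
#' Families are connected components of this relation.
#'
#' @param candidates Candidate tibble (uses `mature_seq`), or a
#'   character vector of mature sequences.
#' @param max_dist Maximum edit distance within a family (default 2).
#' @return Tibble `mature_seq`, `family` (integer id), `family_size`.
#' @export
group_families <- function(candidates, max_dist = 2L) {
  seqs <- if (is.character(candidates)) unique(candidates)
          else unique(candidates$mature_seq)
  n <- length(seqs)
  if (n == 0) return(tibble::tibble(mature_seq = character(),
                                    family = integer(),
                                    family_size = integer()))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- utils::adist(seqs)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (d[i, j] <= max_dist && seed_identical(seqs[i], seqs[j])) {
        parent[find(j)] <- find(i)
      }
    }
  }
  fam <- vapply(seq_len(n), find, integer(1))
  fam <- match(fam, unique(fam))
  out <- tibble::tibble(mature_seq = seqs, family = fam) |>
    dplyr::add_count(.data$family, name = "family_size")
  out
}
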