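# Deterministic synthetic data: a genome with planted miRNA hairpins
# (plus decoys violating exactly one criterion each), ncRNA genes,
# protein-coding gene models, transcripts with planted target sites, and
# simulated adapter-ligated libraries — all traceable through a
# ground-truth manifest. All randomness flows through one seed; the same
# seed reproduces byte-identical output.

#' Default parameters of the synthetic study
#'
#' The defaults describe a desk-scale two-library small-RNA study:
#' a 100-kb genome, 30 planted canonical novel hairpins (24 expressed in
#' both libraries, 3 private to each), 6 known miRNA loci backing the
#' miRBase-style reference, 10 decoy loci (two per violation type),
#' 7 hairpins with sequenced miRNA* support, ncRNA and gene-model
#' decoys, log-normally skewed abundances, and 3' adapter-ligated reads
#' at roughly 15,000 reads per library.
#'
#' @param ... Named overrides.
#' @return Named parameter list.
#' @export
sim_params <- function(...) {
  p <- list(
    genome_size = 100000L, chrom = "chr1",
    n_novel = 30L, n_shared = 24L, n_private_a = 3L, n_private_b = 3L,
    n_known = 6L, n_star = 7L,
    decoy_types = rep(c("no_duplex", "unpaired7", "loop_overlap",
                        "loop_distance", "mature_len"), 2L),
    decoy_separation = 260L,
    lower_stem = 15L, loop_len = 8L, mature_len = 21L,
    abundance_meanlog = 3.5, abundance_sdlog = 1.2,
    abundance_min = 4L, abundance_max = 3000L,
    star_min_mature = 80L, star_frac = 0.05,
    error_rate = 0.002,
    adapter3 = "TCGTATGCCGTCTTCTGCTTG",
    adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
    n_transcripts = 40L, transcript_len = 800L, n_target_mirnas = 8L,
    depth = 15000L, libraries = c("A", "B")
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad) > 0) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  p
}

rand_seq <- function(len, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Draw a mature-like RNA sequence: balanced enough to survive the polyA
# filter on both strands and free of the 3' adapter seed.
draw_mature <- function(len, adapter_seed_dna) {
  repeat {
    m <- rand_seq(len)
    a <- stringr::str_count(m, "A") / len
    u <- stringr::str_count(m, "U") / len
    if (a <= 0.65 && u <= 0.65 &&
        !grepl(adapter_seed_dna, as_dna(m), fixed = TRUE)) return(m)
  }
}

#' Construct a planted hairpin precursor
#'
#' Builds a precursor around a mature sequence by reverse-complement
#' planting. `kind` selects the designed outcome:
#' * `canonical`: perfect mature/star duplex over a lower stem; passes
#'   every criterion.
#' * `unpaired7`: a designed block of star-arm mismatches (default 7)
#'   forming an internal loop in the duplex (violates the
#'   six-unpaired-duplex-nucleotide bound and nothing else).
#' * `loop_overlap`: the planted read spans the terminal loop.
#' * `no_duplex`: the star arm is shuffled; no miRNA/miRNA* duplex.
#' * `spacer`: mature at the outer end of a long perfect stem so that
#'   the miRNA-to-miRNA* separation equals `separation` nt.
#'
#' Loops are drawn from an A/C alphabet so they cannot base-pair.
#'
#' @param mature Mature RNA sequence (ignored for `loop_overlap`).
#' @param kind Designed outcome, see above.
#' @param lower_stem Length of the helix below the duplex (default 15).
#' @param loop_len Terminal loop length (default 8).
#' @param separation miRNA-to-miRNA* distance for `kind = "spacer"`.
#' @param n_mismatch Designed mismatch count for `kind = "unpaired7"`
#'   (default 7; a contiguous block starting at mature position 8).
#' @return List with `precursor` (RNA), `read_span`, `mature_span`,
#'   `star_span` (0-based half-open, designed geometry), `kind`.
#' @export
build_hairpin <- function(mature, kind = c("canonical", "unpaired7",
                                           "loop_overlap", "no_duplex",
                                           "spacer"),
                          lower_stem = 15L, loop_len = 8L,
                          separation = NULL, n_mismatch = 7L) {
  kind <- match.arg(kind)
  loop <- rand_seq(loop_len, c("A", "C"))
  if (kind == "spacer") {
    if (is.null(separation)) stop("spacer hairpins need a separation")
    ml <- nchar(mature)
    if ((separation - 40L + loop_len) %% 2L != 0L) loop_len <- loop_len + 1L
    loop <- rand_seq(loop_len, c("A", "C"))
    # total length L = separation + 2 + 2*mature_len, with the mature at
    # positions 3..(2 + mature_len) of a perfect stem: distance to the
    # star (star_beg - mature_end - 1) is then L - 2*mature_len - 2
    s <- (separation + 2L * ml + 2L - loop_len - 4L) %/% 2L
    arm <- paste0(mature, rand_seq(s - ml))
    pre <- paste0("AA", arm, loop, rev_comp(arm, "rna"), "AA")
    L <- nchar(pre)
    return(list(precursor = pre, kind = kind,
                read_span = c(2L, 2L + ml),
                mature_span = c(2L, 2L + ml),
                star_span = c(L - ml, L)))
  }
  lower <- rand_seq(lower_stem)
  if (kind == "loop_overlap") {
    loop <- rand_seq(9L, c("A", "C"))
    s18 <- rand_seq(18L)
    pre <- paste0(lower, s18, loop, rev_comp(s18, "rna"),
                  rev_comp(lower, "rna"))
    # read: last 8 nt of the arm + the 9-nt loop + 4 nt of the far arm
    rs <- lower_stem + 10L
    return(list(precursor = pre, kind = kind,
                read_span = c(rs, rs + 21L),
                mature_span = c(rs, rs + 21L),
                star_span = c(NA_integer_, NA_integer_)))
  }
  ml <- nchar(mature)
  star_arm <- rev_comp(mature, "rna")
  if (kind == "no_duplex") {
    star_arm <- paste(sample(seq_chars(star_arm)[[1]]), collapse = "")
  }
  if (kind == "unpaired7") {
    # a contiguous internal loop that cannot re-pair in any register:
    # the mature block becomes poly-A, the facing star block poly-C
    # (A and C pair with neither each other nor themselves), leaving
    # stable helices on both sides
    at <- seq(8L, length.out = n_mismatch)
    mc <- seq_chars(mature)[[1]]
    mc[at] <- "A"
    mature <- paste(mc, collapse = "")
    star_arm <- rev_comp(mature, "rna")
    sa <- seq_chars(star_arm)[[1]]
    sa[ml + 1L - at] <- "C"
    star_arm <- paste(sa, collapse = "")
  }
  pre <- paste0(lower, mature, loop, star_arm, rev_comp(lower, "rna"))
  L <- nchar(pre)
  m0 <- lower_stem
  # perfect-stem geometry: position i (1-based) pairs with L + 1 - i
  star_beg1 <- L + 1L - (m0 + ml - 2L)
  star_end1 <- L + 1L - (m0 + 1L) + 2L
  list(precursor = pre, kind = kind,
       read_span = c(m0, m0 + ml),
       mature_span = c(m0, m0 + ml),
       star_span = c(star_beg1 - 1L, star_end1))
}

# Place a DNA piece at the current cursor with a random upstream gap.
# Environment `asm` carries chars (list of fragments) and cursor.
place_piece <- function(asm, dna, min_gap = 300L, max_gap = 900L) {
  gap <- sample(min_gap:max_gap, 1L)
  asm$frags[[length(asm$frags) + 1L]] <- rand_seq(gap, c("A", "C", "G", "T"))
  start <- asm$cursor + gap
  asm$frags[[length(asm$frags) + 1L]] <- dna
  asm$cursor <- start + nchar(dna)
  asm$planted <- rbind(asm$planted,
                       data.frame(start = start, end = asm$cursor))
  start
}

#' Generate the synthetic truth set
#'
#' Builds the genome with planted hairpins (novel, known, decoys), ncRNA
#' genes, protein-coding gene models, a known-miRNA reference, target
#' transcripts with designed sites, and per-library abundances — plus
#' the manifest tying every planted element to its expected outcome.
#' The same seed and parameters reproduce the identical object.
#'
#' @param seed Integer seed driving all randomness.
#' @param params From [sim_params()].
#' @return A `mir_truth` list: `genome` (named character), `hairpins`,
#'   `ncrna_refs`, `ncrna_reads`, `gene_model`, `gene_reads`,
#'   `transcripts`, `target_sites`, `known_ref`, `background_mask`,
#'   `params`, `seed`.
#' @export
generate_truth_set <- function(seed = 20110318L, params = sim_params()) {
  withr::with_seed(seed, generate_truth_set_impl(seed, params))
}

generate_truth_set_impl <- function(seed, p) {
  if (p$genome_size < 20000L) stop("genome too small for the planted set")
  adapter_seed_dna <- substr(p$adapter3, 1, 8)
  chrom <- p$chrom
  asm <- new.env()
  asm$frags <- list()
  asm$cursor <- 0L
  asm$planted <- data.frame(start = integer(), end = integer())

  n_decoy <- length(p$decoy_types)
  roles <- c(rep("novel", p$n_novel), rep("known", p$n_known),
             rep("decoy", n_decoy))
  decoy_of <- c(rep(NA_character_, p$n_novel + p$n_known), p$decoy_types)

  hp_rows <- vector("list", length(roles))
  for (i in seq_along(roles)) {
    kind <- if (roles[i] == "decoy") decoy_of[i] else "canonical"
    mature <- draw_mature(
      if (identical(kind, "mature_len")) 24L else p$mature_len,
      adapter_seed_dna
    )
    hp <- switch(kind,
      loop_distance = build_hairpin(mature, "spacer",
                                    separation = p$decoy_separation),
      mature_len = build_hairpin(mature, "canonical",
                                 lower_stem = p$lower_stem,
                                 loop_len = p$loop_len),
      build_hairpin(mature, kind, lower_stem = p$lower_stem,
                    loop_len = p$loop_len)
    )
    strand <- sample(c("+", "-"), 1L)
    L <- nchar(hp$precursor)
    dna <- as_dna(hp$precursor)
    if (strand == "-") dna <- rev_comp(dna, "dna")
    gstart <- place_piece(asm, dna)
    to_genome <- function(span) {
      if (any(is.na(span))) return(c(NA_integer_, NA_integer_))
      if (strand == "+") c(gstart + span[1], gstart + span[2])
      else c(gstart + L - span[2], gstart + L - span[1])
    }
    rg <- to_genome(hp$read_span)
    sg <- to_genome(hp$star_span)
    read_seq <- substr(hp$precursor, hp$read_span[1] + 1L, hp$read_span[2])
    star_seq <- if (any(is.na(hp$star_span))) NA_character_ else
      substr(hp$precursor, hp$star_span[1] + 1L, hp$star_span[2])
    hp_rows[[i]] <- tibble::tibble(
      hairpin_id = sprintf("hp%03d", i), role = roles[i],
      decoy_type = decoy_of[i], chrom = chrom,
      start = gstart, end = gstart + L, strand = strand,
      precursor = hp$precursor, mature = read_seq, star = star_seq,
      mature_gstart = rg[1], mature_gend = rg[2],
      star_gstart = sg[1], star_gend = sg[2],
      expected_accept = roles[i] == "novel"
    )
  }
  hairpins <- dplyr::bind_rows(hp_rows)

  # expression design: which libraries see each hairpin
  novel_idx <- which(hairpins$role == "novel")
  expressed_a <- rep(TRUE, nrow(hairpins))
  expressed_b <- rep(TRUE, nrow(hairpins))
  priv_a <- novel_idx[seq_len(p$n_private_a) + p$n_shared]
  priv_b <- novel_idx[seq_len(p$n_private_b) + p$n_shared + p$n_private_a]
  expressed_b[priv_a] <- FALSE
  expressed_a[priv_b] <- FALSE
  starred <- rep(FALSE, nrow(hairpins))
  starred[novel_idx[seq_len(p$n_star)]] <- TRUE

  draw_counts <- function(n) {
    pmin(pmax(round(stats::rlnorm(n, p$abundance_meanlog, p$abundance_sdlog)),
              p$abundance_min), p$abundance_max)
  }
  cnt_a <- draw_counts(nrow(hairpins)) * expressed_a
  cnt_b <- draw_counts(nrow(hairpins)) * expressed_b
  cnt_a[starred & expressed_a] <- pmax(cnt_a[starred & expressed_a],
                                       p$star_min_mature)
  cnt_b[starred & expressed_b] <- pmax(cnt_b[starred & expressed_b],
                                       p$star_min_mature)
  star_cnt <- function(cnt) {
    ifelse(starred & cnt > 0,
           pmin(pmax(2L, round(cnt * p$star_frac)), 9L), 0L)
  }
  hairpins$count_A <- as.integer(cnt_a)
  hairpins$count_B <- as.integer(cnt_b)
  hairpins$star_count_A <- as.integer(star_cnt(cnt_a))
  hairpins$star_count_B <- as.integer(star_cnt(cnt_b))
  hairpins$starred <- starred
  hairpins$expected_accept <- hairpins$expected_accept &
    (hairpins$count_A >= 2 | hairpins$count_B >= 2)

  # ncRNA genes planted in the genome; the same sequences form the
  # per-class reference FASTAs
  nc_spec <- list(rRNA = c(3L, 500L), tRNA = c(3L, 75L),
                  snoRNA = c(2L, 120L), snRNA = c(2L, 150L),
                  siRNA = c(2L, 180L))
  ncrna_refs <- list()
  nc_read_rows <- list()
  for (klass in names(nc_spec)) {
    nref <- nc_spec[[klass]][1]; rlen <- nc_spec[[klass]][2]
    seqs <- character(nref)
    for (j in seq_len(nref)) {
      dna <- rand_seq(rlen, c("A", "C", "G", "T"))
      place_piece(asm, dna)
      seqs[j] <- as_rna(dna)
      # two planted reads per reference
      for (r in 1:2) {
        off <- sample(1:(rlen - 24L), 1L)
        len <- sample(20:24, 1L)
        rs <- substr(seqs[j], off, off + len - 1L)
        if (grepl(adapter_seed_dna, as_dna(rs), fixed = TRUE) ||
            stringr::str_count(rs, "A") / len >= 0.8) next
        nc_read_rows[[length(nc_read_rows) + 1L]] <- tibble::tibble(
          class = klass, seq = rs,
          count_A = sample(5:200, 1L), count_B = sample(5:200, 1L)
        )
      }
    }
    ncrna_refs[[klass]] <- tibble::tibble(
      name = sprintf("%s_%d", klass, seq_len(nref)), seq = seqs
    )
  }
  ncrna_reads <- dplyr::bind_rows(nc_read_rows)

  # protein-coding gene models: exon1 - intron - exon2
  gene_rows <- list(); gene_read_rows <- list()
  for (g in 1:3) {
    strand <- c("+", "-", "+")[g]
    dna <- rand_seq(950L, c("A", "C", "G", "T"))
    gstart <- place_piece(asm, dna)
    ex <- tibble::tibble(
      chrom = chrom,
      start = c(gstart, gstart + 650L), end = c(gstart + 300L, gstart + 950L),
      strand = strand, gene = sprintf("gene%02d", g)
    )
    gene_rows[[g]] <- ex
    pick <- function(lo, hi, sense) {
      off <- sample(lo:(hi - 22L), 1L)
      frag <- substr(dna, off - gstart + 1L, off - gstart + 21L)
      s <- as_rna(if (strand == "+") frag else rev_comp(frag, "dna"))
      if (!sense) s <- rev_comp(s, "rna")
      s
    }
    gene_read_rows[[g]] <- tibble::tibble(
      class = c("exon_sense", "exon_antisense",
                "intron_sense", "intron_antisense"),
      seq = c(pick(gstart, gstart + 300L, TRUE),
              pick(gstart + 650L, gstart + 950L, FALSE),
              pick(gstart + 320L, gstart + 630L, TRUE),
              pick(gstart + 320L, gstart + 630L, FALSE)),
      count_A = sample(3:30, 4L, replace = TRUE),
      count_B = sample(3:30, 4L, replace = TRUE)
    )
  }
  gene_model <- dplyr::bind_rows(gene_rows)
  gene_reads <- dplyr::bind_rows(gene_read_rows) |>
    dplyr::filter(!grepl(adapter_seed_dna, as_dna(.data$seq), fixed = TRUE))

  # finish the genome with random tail sequence
  tail_len <- p$genome_size - asm$cursor
  if (tail_len < 0) stop("planted elements exceed the genome size")
  asm$frags[[length(asm$frags) + 1L]] <- rand_seq(tail_len, c("A", "C", "G", "T"))
  genome <- stats::setNames(paste(unlist(asm$frags), collapse = ""), chrom)
  stopifnot(nchar(genome) == p$genome_size)

  # background-free mask: regions at least 300 nt away from any planted
  # element, for drawing background fragments
  mask <- rep(TRUE, p$genome_size)
  for (r in seq_len(nrow(asm$planted))) {
    lo <- max(1L, asm$planted$start[r] - 300L + 1L)
    hi <- min(p$genome_size, asm$planted$end[r] + 300L)
    mask[lo:hi] <- FALSE
  }

  # known-miRNA reference (mature + hairpin, linked by name prefix)
  kn <- hairpins[hairpins$role == "known", ]
  known_ref <- list(
    mature = tibble::tibble(name = sprintf("zma-miR90%02d", seq_len(nrow(kn))),
                            seq = kn$mature),
    hairpin = tibble::tibble(name = sprintf("zma-MIR90%02d", seq_len(nrow(kn))),
                             seq = kn$precursor)
  )

  # cross-species mature set: known matures with 1-2 substitutions
  cross <- vapply(kn$mature[seq_len(min(3L, nrow(kn)))], function(m) {
    ch <- seq_chars(m)[[1]]
    at <- sample(seq_along(ch), 2L)
    for (a in at) ch[a] <- sample(setdiff(RNA_BASES, ch[a]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  cross_ref <- tibble::tibble(
    name = sprintf("ath-miR80%02d", seq_along(cross)), seq = cross
  )

  # transcripts with designed target sites
  tx <- tibble::tibble(
    name = sprintf("tx%03d", seq_len(p$n_transcripts)),
    seq = vapply(seq_len(p$n_transcripts), function(i)
      rand_seq(p$transcript_len), character(1))
  )
  shared_novel <- hairpins[hairpins$role == "novel" &
                             hairpins$count_A > 0 & hairpins$count_B > 0, ]
  tmir <- shared_novel$mature[seq_len(min(p$n_target_mirnas,
                                          nrow(shared_novel)))]
  designs <- c("perfect", "wobble_pass", "strict_boundary",
               "rule1_fail", "rule2_fail", "rule3_fail",
               "rule4_fail", "rule5_fail")
  site_rows <- list()
  ti <- 0L
  for (mi in seq_along(tmir)) {
    for (ds in designs) {
      site <- design_site(tmir[mi], ds)
      if (is.null(site)) next
      ti <- ti + 1L
      tx_i <- (ti - 1L) %% p$n_transcripts + 1L
      pos <- 100L + 200L * ((ti - 1L) %/% p$n_transcripts)  # 0-based
      if (pos + nchar(site$seq) > p$transcript_len - 50L) next
      s <- tx$seq[tx_i]
      tx$seq[tx_i] <- paste0(substr(s, 1, pos),
                             site$seq,
                             substr(s, pos + nchar(site$seq) + 1L,
                                    p$transcript_len))
      site_rows[[length(site_rows) + 1L]] <- tibble::tibble(
        transcript = tx$name[tx_i], pos = pos, mirna = tmir[mi],
        site_seq = site$seq, design = ds,
        expected_hit = site$expected_hit,
        expected_strict = site$expected_strict
      )
    }
  }
  target_sites <- dplyr::bind_rows(site_rows)

  out <- list(
    genome = genome, hairpins = hairpins,
    ncrna_refs = ncrna_refs, ncrna_reads = ncrna_reads,
    gene_model = gene_model, gene_reads = gene_reads,
    transcripts = tx, target_sites = target_sites,
    known_ref = known_ref, cross_ref = cross_ref,
    background_mask = mask, params = p, seed = seed
  )
  class(out) <- "mir_truth"
  out
}

# Build a target site (transcript 5'->3') for a mature miRNA with a
# designed rule outcome. Mismatching substitutions avoid both the
# Watson-Crick and the wobble partner of the miRNA base.
design_site <- function(mature, design) {
  L <- nchar(mature)
  mc <- seq_chars(mature)[[1]]
  site <- seq_chars(rev_comp(mature, "rna"))[[1]]  # perfect site, 5'->3'
  # site index facing miRNA position k (1-based) is L + 1 - k
  mismatch_at <- function(site, ks) {
    sub_for <- c(A = "C", C = "A", G = "A", U = "C")
    for (k in ks) site[L + 1L - k] <- sub_for[[mc[k]]]
    site
  }
  wobble_at <- function(site, ks) {
    # G:U wobble from the site side: miRNA G faces site U, miRNA U faces G
    for (k in ks) {
      if (mc[k] == "G") site[L + 1L - k] <- "U"
      else if (mc[k] == "U") site[L + 1L - k] <- "G"
      else return(NULL)
    }
    site
  }
  gpos <- which(mc %in% c("G", "U"))
  res <- switch(design,
    perfect = list(site = site, hit = TRUE, strict = TRUE),
    wobble_pass = {
      ks <- utils::head(gpos[gpos >= 13], 2L)
      if (length(ks) < 2) NULL else {
        s <- wobble_at(site, ks)
        if (is.null(s)) NULL else list(site = s, hit = TRUE, strict = TRUE)
      }
    },
    strict_boundary = {
      # a mismatch score of exactly 3.5 (> 3, <= 4): passes the default
      # rules but fails the strict bound. Mismatch/wobble placements are
      # searched until one also clears the 75% duplex-energy rule.
      found <- NULL
      wob_opts <- gpos[gpos >= 13]
      mm_sets <- list(c(13L, 16L, 19L), c(13L, 17L, 21L), c(14L, 17L, 20L),
                      c(13L, 15L, 18L), c(15L, 18L, 21L))
      for (ks in wob_opts) {
        for (pos in mm_sets) {
          if (max(pos) > L || ks %in% pos) next
          s <- wobble_at(mismatch_at(site, pos), ks)
          if (is.null(s)) next
          d <- score_duplex(mature, paste(s, collapse = ""))
          v <- passes_filters(d, strict = FALSE)
          if (v[["overall"]] && !v[["strict_pass"]]) { found <- s; break }
        }
        if (!is.null(found)) break
      }
      if (is.null(found)) NULL else
        list(site = found, hit = TRUE, strict = FALSE)
    },
    rule1_fail = list(site = mismatch_at(site, c(13L, 15L, 17L, 19L, 21L)),
                      hit = FALSE, strict = FALSE),
    rule2_fail = list(site = mismatch_at(site, c(14L, 15L, 16L)),
                      hit = FALSE, strict = FALSE),
    rule3_fail = list(site = mismatch_at(site, c(5L, 6L)),
                      hit = FALSE, strict = FALSE),
    rule4_fail = list(site = mismatch_at(site, 10L),
                      hit = FALSE, strict = FALSE),
    rule5_fail = list(site = mismatch_at(site, c(3L, 6L, 9L)),
                      hit = FALSE, strict = FALSE)
  )
  if (is.null(res)) return(NULL)
  if (any(c("rule2_fail", "rule1_fail") == design) && L < 21) return(NULL)
  list(seq = paste(res$site, collapse = ""),
       expected_hit = res$hit, expected_strict = res$strict)
}

#' Simulate one adapter-ligated library
#'
#' Materialises reads from the truth set for one library: planted
#' matures and stars at their manifest abundances, ncRNA and gene-model
#' reads, genome-derived and random background (mostly singletons), and
#' junk classes exercising each cleaning filter (low quality, polyA, 5'
#' adapter contaminants, adapter-free reads, out-of-window inserts).
#' Each read is the DNA insert plus the full 3' adapter, with
#' Sanger-encoded qualities and uniform substitution errors at
#' `params$error_rate`.
#'
#' @param truth From [generate_truth_set()].
#' @param library_id One of `truth$params$libraries`.
#' @param depth Approximate total read count (default from params).
#' @param seed Seed for the library-specific randomness.
#' @return Tibble `name`, `seq` (DNA read), `qual`, `library_id`,
#'   `true_class`, `truth_id`, `true_insert` — one row per read.
#' @export
simulate_reads <- function(truth, library_id, depth = NULL, seed = 1L) {
  stopifnot(inherits(truth, "mir_truth"))
  p <- truth$params
  if (!library_id %in% p$libraries) stop("unknown library id")
  if (is.null(depth)) depth <- p$depth
  withr::with_seed(seed + 7919L * match(library_id, p$libraries),
                   simulate_reads_impl(truth, library_id, depth))
}

simulate_reads_impl <- function(truth, library_id, depth) {
  p <- truth$params
  cntcol <- paste0("count_", library_id)
  starcol <- paste0("star_count_", library_id)
  hp <- truth$hairpins

  ins_rows <- list(
    tibble::tibble(
      insert = hp$mature, count = hp[[cntcol]],
      true_class = dplyr::case_when(hp$role == "novel" ~ "miRNA_novel",
                                    hp$role == "known" ~ "miRNA_known",
                                    TRUE ~ "decoy"),
      truth_id = hp$hairpin_id
    ),
    tibble::tibble(
      insert = hp$star, count = hp[[starcol]],
      true_class = "miRNA_star", truth_id = paste0(hp$hairpin_id, "*")
    ),
    tibble::tibble(
      insert = truth$ncrna_reads$seq, count = truth$ncrna_reads[[cntcol]],
      true_class = truth$ncrna_reads$class,
      truth_id = sprintf("nc%03d", seq_len(nrow(truth$ncrna_reads)))
    ),
    tibble::tibble(
      insert = truth$gene_reads$seq, count = truth$gene_reads[[cntcol]],
      true_class = truth$gene_reads$class,
      truth_id = sprintf("gm%03d", seq_len(nrow(truth$gene_reads)))
    )
  )
  planted <- dplyr::bind_rows(ins_rows) |>
    dplyr::filter(!is.na(.data$insert), .data$count > 0)

  # background: genome fragments (count-skewed, mostly singletons) and
  # fully random sequences
  n_bg <- max(0L, depth - sum(planted$count))
  allowed <- which(truth$background_mask)
  allowed <- allowed[allowed <= p$genome_size - 30L]
  bg_rows <- list()
  bg_total <- 0L
  gseq <- truth$genome[[1]]
  adapter_seed_dna <- substr(p$adapter3, 1, 8)
  while (bg_total < round(0.8 * n_bg)) {
    pos <- sample(allowed, 1L)
    len <- sample(18:28, 1L)
    frag <- substr(gseq, pos, pos + len - 1L)
    if (grepl(adapter_seed_dna, frag, fixed = TRUE)) next
    if (stringr::str_count(frag, "A") / len >= 0.8) next
    if (sample(c(TRUE, FALSE), 1L)) frag <- rev_comp(frag, "dna")
    cnt <- sample(c(rep(1L, 18L), 2L, 3L), 1L)
    bg_rows[[length(bg_rows) + 1L]] <- tibble::tibble(
      insert = as_rna(frag), count = cnt, true_class = "background",
      truth_id = sprintf("bg@%d", pos)
    )
    bg_total <- bg_total + cnt
  }
  n_rand <- max(0L, n_bg - bg_total)
  if (n_rand > 0) {
    bg_rows[[length(bg_rows) + 1L]] <- tibble::tibble(
      insert = vapply(seq_len(n_rand), function(i) rand_seq(sample(18:28, 1L)),
                      character(1)),
      count = 1L, true_class = "background_random",
      truth_id = sprintf("rnd%05d", seq_len(n_rand))
    )
  }
  inserts <- dplyr::bind_rows(c(list(planted), bg_rows))

  # expand to individual reads and attach the 3' adapter
  idx <- rep(seq_len(nrow(inserts)), inserts$count)
  reads <- inserts[idx, c("insert", "true_class", "truth_id")]
  reads$seq <- paste0(as_dna(reads$insert), p$adapter3)
  reads$qual <- vapply(nchar(reads$seq), function(n)
    intToUtf8(33L + sample(30:40, n, replace = TRUE)), character(1))

  # junk classes exercising each cleaning filter
  junk <- list()
  mk <- function(n, insert_len, class, adapter = p$adapter3, prefix = "",
                 quality = 30:40, insert = NULL) {
    if (n == 0) return(NULL)
    ins <- if (is.null(insert))
      vapply(seq_len(n), function(i) rand_seq(insert_len, c("A", "C", "G", "T")),
             character(1))
    else rep(insert, length.out = n)
    sq <- paste0(prefix, ins, adapter)
    tibble::tibble(
      insert = as_rna(ins), true_class = class,
      truth_id = paste0(class, seq_len(n)), seq = sq,
      qual = vapply(nchar(sq), function(len)
        intToUtf8(33L + sample(quality, len, replace = TRUE)), character(1))
    )
  }
  junk[[1]] <- mk(40L, 22L, "junk_low_quality", quality = 5:14)
  junk[[2]] <- mk(15L, 22L, "junk_polyA",
                  insert = strrep("A", 22L))
  junk[[3]] <- mk(15L, 22L, "junk_adapter5",
                  prefix = p$adapter5)
  junk[[4]] <- mk(10L, 0L, "junk_adapter_only", insert = "")
  junk[[5]] <- mk(15L, 16L, "junk_short")
  junk[[6]] <- mk(15L, 33L, "junk_long")
  # reads with no adapter at all (random tail instead)
  no_ad <- mk(15L, 22L, "junk_no_adapter", adapter = "")
  no_ad$seq <- paste0(no_ad$seq,
                      vapply(seq_len(nrow(no_ad)), function(i)
                        rand_seq(20L, c("C", "G", "T")), character(1)))
  no_ad$qual <- vapply(nchar(no_ad$seq), function(len)
    intToUtf8(33L + sample(30:40, len, replace = TRUE)), character(1))
  junk[[7]] <- no_ad
  reads <- dplyr::bind_rows(c(list(reads), junk))

  # uniform substitution errors
  if (p$error_rate > 0) {
    reads$seq <- vapply(reads$seq, function(s) {
      n <- nchar(s)
      hitn <- stats::rbinom(1L, n, p$error_rate)
      if (hitn == 0) return(s)
      ch <- seq_chars(s)[[1]]
      at <- sample.int(n, hitn)
      for (a in at) ch[a] <- sample(setdiff(DNA_BASES, ch[a]), 1L)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }

  reads <- reads[sample.int(nrow(reads)), ]
  reads$name <- sprintf("%s_r%06d", library_id, seq_len(nrow(reads)))
  reads$library_id <- library_id
  tibble::as_tibble(reads[, c("name", "seq", "qual", "library_id",
                              "true_class", "truth_id", "insert")]) |>
    dplyr::rename(true_insert = "insert")
}

#' Write the truth set to a directory
#'
#' Emits `genome.fa`, per-class ncRNA FASTAs, `transcripts.fa`,
#' `known_mature.fa` / `known_hairpin.fa`, `cross_species.fa`,
#' `genes.gff3` (1-based inclusive) and `manifest.yml` (all planted
#' elements, abundances and generator parameters).
#'
#' @param truth From [generate_truth_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth_set <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(tibble::tibble(name = names(truth$genome),
                             seq = unname(truth$genome)),
              file.path(dir, "genome.fa"))
  for (klass in names(truth$ncrna_refs)) {
    write_fasta(truth$ncrna_refs[[klass]],
                file.path(dir, paste0("ncrna_", klass, ".fa")))
  }
  write_fasta(truth$transcripts, file.path(dir, "transcripts.fa"))
  write_fasta(truth$known_ref$mature, file.path(dir, "known_mature.fa"))
  write_fasta(truth$known_ref$hairpin, file.path(dir, "known_hairpin.fa"))
  write_fasta(truth$cross_ref, file.path(dir, "cross_species.fa"))
  gm <- truth$gene_model
  lines <- c("##gff-version 3")
  for (g in unique(gm$gene)) {
    ex <- gm[gm$gene == g, ]
    lines <- c(lines,
      sprintf("%s\tgermmir_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              ex$chrom[1], min(ex$start) + 1L, max(ex$end), ex$strand[1], g),
      sprintf("%s\tgermmir_sim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
              ex$chrom, ex$start + 1L, ex$end, ex$strand, g,
              seq_len(nrow(ex)), g))
  }
  writeLines(lines, file.path(dir, "genes.gff3"))
  manifest <- list(
    seed = truth$seed,
    params = truth$params,
    hairpins = as.list(truth$hairpins),
    ncrna_reads = as.list(truth$ncrna_reads),
    gene_reads = as.list(truth$gene_reads),
    target_sites = as.list(truth$target_sites)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}
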