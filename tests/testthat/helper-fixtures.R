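# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Reduced-size truth set for unit tests: same construction as the
# default study, fewer planted elements.
small_params <- function() {
  sim_params(genome_size = 60000L, n_novel = 10L, n_shared = 8L,
             n_private_a = 1L, n_private_b = 1L, n_known = 2L,
             n_star = 3L,
             decoy_types = c("no_duplex", "unpaired7", "loop_overlap",
                             "loop_distance", "mature_len"),
             n_transcripts = 10L, n_target_mirnas = 3L, depth = 4000L)
}

small_truth <- function() memo("small_truth", {
  generate_truth_set(seed = 424242L, params = small_params())
})

small_reads <- function(lib = "A") memo(paste0("small_reads_", lib), {
  simulate_reads(small_truth(), lib, seed = 11L)
})

# Library A of the small study processed through cleaning, collapsing,
# mapping and classification.
small_processed <- function(lib = "A") memo(paste0("small_proc_", lib), {
  t <- small_truth()
  raw <- small_reads(lib)
  cleaned <- clean_reads(raw, adapter3 = t$params$adapter3,
                         adapter5 = t$params$adapter5)
  collapsed <- collapse_reads(cleaned)
  mapping <- map_reads(collapsed, t$genome)
  classes <- classify_reads(mapping, collapsed,
                            lapply(t$ncrna_refs, function(x) x$seq),
                            t$gene_model)
  list(truth = t, raw = raw, cleaned = cleaned, collapsed = collapsed,
       mapping = mapping, classes = classes)
})

# Independent Levenshtein oracle: plain dynamic programming with unit
# costs, row-vectorised.
lev_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- c(i, pmin(prev[-1] + 1, prev[-(nb + 1)] + (ca[i] != cb)))
    for (j in seq_len(nb)) cur[j + 1] <- min(cur[j + 1], cur[j] + 1)
    prev <- cur
  }
  prev[nb + 1]
}

# Naive exact-match mapping oracle: enumerate every window of the
# needed lengths on both strands and compare strings.
naive_map_oracle <- function(reads, genome_str, chrom = "chr1") {
  out <- list()
  n <- nchar(genome_str)
  for (w in sort(unique(nchar(reads$seq)))) {
    windows <- substring(genome_str, 1:(n - w + 1), w:n)
    sel <- which(nchar(reads$seq) == w)
    for (i in sel) {
      dna <- as_dna(reads$seq[i])
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") dna else rev_comp(dna, "dna")
        at <- which(windows == pat)
        if (length(at) > 0) {
          out[[length(out) + 1]] <- tibble::tibble(
            read_id = reads$read_id[i], chrom = chrom,
            start = at - 1L, end = at - 1L + w, strand = strand
          )
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

# Vectorised whole-window target-scan oracle: states per position via
# matrix indexing, rules applied with matrix operations. Independent of
# the compiled scanner.
scan_oracle <- function(mirnas, transcripts, strict = TRUE,
                        thresholds = mir_thresholds()) {
  stk <- germmir:::nn_stack_table()
  hits <- list()
  for (mi in seq_len(nrow(mirnas))) {
    m <- strsplit(as_rna(mirnas$seq[mi]), "")[[1]]
    L <- length(m)
    pidx_of <- function(a, b) germmir:::pair_index(a, b)
    perfect <- c(A = "U", C = "G", G = "C", U = "A")[m]
    per_idx <- pidx_of(m, perfect)
    per_dc <- sum(stk[cbind(per_idx[-L], per_idx[-1])])
    for (ti in seq_len(nrow(transcripts))) {
      tch <- strsplit(as_rna(transcripts$seq[ti]), "")[[1]]
      n <- length(tch)
      if (n < L) next
      nwin <- n - L + 1
      # site base facing miRNA position i for window starting at w (1-based)
      # is tch[w + L - i]
      S2 <- matrix(0L, nrow = L, ncol = nwin)   # doubled scores
      P <- matrix(0L, nrow = L, ncol = nwin)    # pair indices
      for (i in seq_len(L)) {
        fac <- tch[(1:nwin) + L - i]
        pid <- pidx_of(rep(m[i], nwin), fac)
        P[i, ] <- pid
        S2[i, ] <- ifelse(pid == 0, 2L, ifelse(pid >= 5, 1L, 0L))
      }
      tot2 <- colSums(S2)
      mm <- S2 == 2L
      run3 <- rep(FALSE, nwin)
      if (L >= 3) {
        for (i in 1:(L - 2)) run3 <- run3 | (mm[i, ] & mm[i + 1, ] & mm[i + 2, ])
      }
      adj212 <- rep(FALSE, nwin)
      for (i in 2:11) adj212 <- adj212 | (mm[i, ] & mm[i + 1, ])
      r4bad <- mm[10, ] | mm[11, ]
      reg2 <- colSums(S2[1:12, , drop = FALSE])
      dup <- rep(0L, nwin)
      for (i in 1:(L - 1)) {
        both <- P[i, ] > 0 & P[i + 1, ] > 0
        if (any(both)) {
          dup[both] <- dup[both] + stk[cbind(P[i, both], P[i + 1, both])]
        }
      }
      pass <- tot2 <= 2 * thresholds$max_target_mismatch &
        !run3 & !adj212 & !r4bad &
        reg2 <= 2 * thresholds$region_target_mismatch &
        dup <= 0 & (-dup) >= thresholds$energy_ratio * (-per_dc)
      if (strict) pass <- pass & tot2 <= 2 * thresholds$strict_target_mismatch
      w <- which(pass)
      if (length(w) > 0) {
        hits[[length(hits) + 1]] <- tibble::tibble(
          mirna_id = mirnas$name[mi], transcript_id = transcripts$name[ti],
          start = w - 1L, end = w - 1L + L,
          mismatch_score = tot2[w] / 2
        )
      }
    }
  }
  dplyr::bind_rows(hits)
}

# Full two-library pipeline run on the small study.
small_run <- function() memo("small_run", {
  t <- small_truth()
  cfg <- germmir_config(
    reads_a = small_reads("A"), reads_b = small_reads("B"),
    genome = t$genome,
    adapter3 = t$params$adapter3, adapter5 = t$params$adapter5,
    ncrna_refs = lapply(t$ncrna_refs, function(x) x$seq),
    gene_model = t$gene_model,
    known_mature = t$known_ref$mature, known_hairpin = t$known_ref$hairpin,
    transcripts = t$transcripts
  )
  suppressWarnings(run_pipeline(cfg))
})

# A composition-balanced mature sequence (uses the generator's own
# rejection sampler; caller supplies the RNG state).
draw_mature_fixture <- function(len = 21L) {
  germmir:::draw_mature(len, "TCGTATGC")
}

# Deterministic RNA sequences for tests.
rand_rna <- function(n, len, seed = 1) {
  withr::with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    character(1)))
}

# Build a target site for a miRNA with designed full mismatches and
# G:U wobbles at given miRNA positions (1-based from the 5' end).
mk_site <- function(mirna, mism = integer(0), wob = integer(0)) {
  L <- nchar(mirna)
  mc <- strsplit(mirna, "")[[1]]
  site <- strsplit(rev_comp(mirna, "rna"), "")[[1]]
  sub_for <- c(A = "C", C = "A", G = "A", U = "C")
  for (k in mism) site[L + 1 - k] <- sub_for[[mc[k]]]
  for (k in wob) {
    stopifnot(mc[k] %in% c("G", "U"))
    site[L + 1 - k] <- if (mc[k] == "G") "U" else "G"
  }
  paste(site, collapse = "")
}
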