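eval_built <- function(hp, engine = "auto", thresholds = mir_thresholds()) {
  f <- fold_rna(hp$precursor, engine = engine)
  evaluate_candidate(f, hp$read_span, thresholds = thresholds,
                     engine = engine)
}

test_that("the MFEI formula matches its definition", {
  expect_equal(mfei(-42.5, 100, 50), 0.85)
  expect_equal(mfei(-46.56, 120, 40), 0.97)
  expect_equal(mfei(0, 80, 55), 0)
  expect_error(mfei(-30, 100, 0), "GC")
  expect_error(mfei(-30, 0, 50), "length")
  # scale invariance: doubling length and |MFE| leaves MFEI unchanged
  withr::with_seed(71, {
    mfe <- -runif(20, 20, 90); len <- sample(60:300, 20); gc <- runif(20, 20, 80)
  })
  expect_equal(mfei(2 * mfe, 2 * len, gc), mfei(mfe, len, gc))
})

test_that("windows anchor the read at both ends and keep its sequence", {
  withr::with_seed(72, {
    g <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  })
  locus <- tibble::tibble(chrom = "chr1", start = 2400L, end = 2421L,
                          strand = "+")
  w <- extract_windows(locus, c(chr1 = g), flank = 250)
  expect_equal(nrow(w), 2L)
  read <- as_rna(substr(g, 2401, 2421))
  for (i in 1:2) {
    expect_equal(substr(w$seq[i], w$read_start[i] + 1, w$read_end[i]), read)
  }
  # minus strand: window is reverse-complemented, read still contained
  locus$strand <- "-"
  wm <- extract_windows(locus, c(chr1 = g), flank = 250)
  readm <- rev_comp(read)
  expect_equal(substr(wm$seq[1], wm$read_start[1] + 1, wm$read_end[1]), readm)
  # contig edge: truncated window with a warning, read still contained
  edge <- tibble::tibble(chrom = "chr1", start = 10L, end = 31L, strand = "+")
  expect_warning(we <- extract_windows(edge, c(chr1 = g)), "truncated")
  expect_true(all(substr(we$seq, we$read_start + 1, we$read_end) ==
                    as_rna(substr(g, 11, 31))))
})

test_that("a canonical planted precursor passes every criterion", {
  withr::with_seed(73, m <- draw_mature_fixture())
  hp <- build_hairpin(m, "canonical")
  ev <- eval_built(hp)
  expect_true(ev$accepted)
  expect_equal(ev$duplex_unpaired, 0L)
  expect_equal(ev$arm, "5p")
  expect_gt(ev$mfei, 0.85)
  expect_lte(ev$mfe, -20)
  # derived star span equals the designed 2-nt-overhang geometry
  expect_equal(ev$star_start + ev$trim_offset, hp$star_span[1])
  expect_equal(ev$star_end + ev$trim_offset, hp$star_span[2])
})

test_that("six unpaired duplex nucleotides pass, seven are rejected", {
  withr::with_seed(74, m <- draw_mature_fixture())
  withr::with_seed(75, hp6 <- build_hairpin(m, "unpaired7", n_mismatch = 6,
                                            lower_stem = 20))
  withr::with_seed(75, hp7 <- build_hairpin(m, "unpaired7", n_mismatch = 7,
                                            lower_stem = 20))
  ev6 <- eval_built(hp6)
  ev7 <- eval_built(hp7)
  expect_lte(ev6$duplex_unpaired, 6L)
  expect_true(ev6$crit_duplex)
  expect_gte(ev7$duplex_unpaired, 7L)
  expect_false(ev7$crit_duplex)
  expect_false(ev7$accepted)
})

test_that("a read across the terminal loop is rejected as loop overlap", {
  withr::with_seed(76, hp <- build_hairpin("", "loop_overlap"))
  ev <- eval_built(hp)
  expect_false(ev$accepted)
  expect_false(ev$crit_hairpin && ev$crit_one_arm && ev$crit_clean)
  expect_true(ev$reject_reason %in%
                c("loop overlap", "crit_clean", "no stem containing the read"))
})

test_that("a shuffled star arm yields no acceptable duplex", {
  withr::with_seed(77, m <- draw_mature_fixture())
  withr::with_seed(78, hp <- build_hairpin(m, "no_duplex"))
  expect_false(eval_built(hp)$accepted)
})

test_that("mature length and separation criteria bound acceptance", {
  withr::with_seed(79, m24 <- draw_mature_fixture(24L))
  withr::with_seed(80, hp24 <- build_hairpin(m24, "canonical"))
  ev24 <- eval_built(hp24)
  expect_false(ev24$crit_mature_len)
  expect_false(ev24$accepted)

  withr::with_seed(81, m <- draw_mature_fixture())
  withr::with_seed(82, ok <- build_hairpin(m, "spacer", separation = 240L))
  withr::with_seed(82, far <- build_hairpin(m, "spacer", separation = 241L))
  evok <- eval_built(ok)
  evfar <- eval_built(far)
  expect_equal(evok$loop_distance, 240L)
  expect_true(evok$accepted)
  expect_equal(evfar$loop_distance, 241L)
  expect_false(evfar$crit_loop_dist)
  expect_false(evfar$accepted)
})

test_that("lowering the MFEI threshold never removes accepted candidates", {
  withr::with_seed(83, m <- draw_mature_fixture())
  hp <- build_hairpin(m, "canonical")
  f <- fold_rna(hp$precursor)
  strict <- evaluate_candidate(f, hp$read_span,
                               mir_thresholds(mfei_min = 0.85))
  loose <- evaluate_candidate(f, hp$read_span,
                              mir_thresholds(mfei_min = 0.2))
  expect_true(loose$accepted >= strict$accepted)
  high <- evaluate_candidate(f, hp$read_span, mir_thresholds(mfei_min = 10))
  expect_false(high$accepted)
})

test_that("star reads are counted at the star locus within slack", {
  cand <- tibble::tibble(candidate_id = "c1", chrom = "chr1", strand = "+",
                         read_id = "m", star_gstart = 500L, star_gend = 521L)
  loci <- tibble::tibble(
    read_id = c("m", "exact", "shift1", "shift3"),
    chrom = "chr1",
    start = c(400L, 500L, 501L, 503L),
    end = c(421L, 521L, 522L, 524L),
    strand = "+", count = c(50L, 4L, 2L, 9L)
  )
  out <- find_star_reads(cand, loci)
  expect_equal(out$star_read_count, 6L)  # exact + 1-nt shift, not 3-nt
  expect_true(out$star_supported)
})

test_that("novel families group by seed identity and edit distance", {
  base <- "UGGAAGCUGGUACGGAAUCGC"
  sib <- base; substr(sib, 15, 15) <- "A"; substr(sib, 21, 21) <- "A"
  other <- rand_rna(1, 21, seed = 85)
  fam <- group_families(c(base, sib, other))
  expect_equal(fam$family[fam$mature_seq == base],
               fam$family[fam$mature_seq == sib])
  expect_false(fam$family[fam$mature_seq == other][1] ==
                 fam$family[fam$mature_seq == base][1])
})

test_that("pipeline prediction recovers planted hairpins and no decoys", {
  proc <- small_processed()
  t <- proc$truth
  cand <- suppressWarnings(
    predict_mirnas(proc$mapping, proc$collapsed, t$genome,
                   classes = proc$classes)
  )
  hp <- t$hairpins
  novel <- hp[hp$role == "novel" & hp$count_A >= 2, ]
  recovered <- vapply(seq_len(nrow(novel)), function(i) {
    any(cand$chrom == novel$chrom[i] &
          cand$pre_start < novel$end[i] & cand$pre_end > novel$start[i])
  }, logical(1))
  expect_true(all(recovered))
  decoy_hit <- vapply(seq_len(nrow(cand)), function(i) {
    any(hp$role == "decoy" & hp$start < cand$pre_end[i] &
          hp$end > cand$pre_start[i])
  }, logical(1))
  expect_equal(sum(decoy_hit), 0L)
  # internal consistency: re-deriving the star from the reported
  # structure reproduces the stored star span
  for (i in seq_len(nrow(cand))) {
    pt <- pair_table(cand$structure[i])
    geo <- germmir:::stem_geometry(pt, cand$mature_start[i] + 1L,
                                   cand$mature_end[i],
                                   nchar(cand$pre_seq[i]), cand$mfe[i])
    expect_true(geo$ok)
    expect_equal(c(geo$star_beg - 1L, geo$star_end),
                 c(cand$star_start[i], cand$star_end[i]))
  }
  # star support flags exactly the starred planted hairpins
  starred <- hp[hp$role == "novel" & hp$starred & hp$count_A >= 2, ]
  flagged <- cand[cand$star_supported, ]
  matches <- vapply(seq_len(nrow(starred)), function(i) {
    any(flagged$pre_start < starred$end[i] & flagged$pre_end > starred$start[i])
  }, logical(1))
  expect_true(all(matches))
  expect_equal(nrow(flagged), nrow(starred))
})
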