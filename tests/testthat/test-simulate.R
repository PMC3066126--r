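test_that("the generator is byte-identical under a fixed seed", {
  p <- small_params()
  t1 <- generate_truth_set(seed = 7L, params = p)
  t2 <- generate_truth_set(seed = 7L, params = p)
  expect_identical(t1$genome, t2$genome)
  expect_identical(t1$hairpins, t2$hairpins)
  expect_identical(t1$target_sites, t2$target_sites)
  t3 <- generate_truth_set(seed = 8L, params = p)
  expect_false(identical(t1$genome, t3$genome))
  r1 <- simulate_reads(t1, "A", seed = 3L)
  r2 <- simulate_reads(t1, "A", seed = 3L)
  expect_identical(r1, r2)
})

test_that("planted elements are traceable in the genome", {
  t <- small_truth()
  g <- t$genome[[1]]
  hp <- t$hairpins
  for (i in seq_len(nrow(hp))) {
    dna <- as_dna(hp$precursor[i])
    if (hp$strand[i] == "-") dna <- rev_comp(dna, "dna")
    expect_equal(substr(g, hp$start[i] + 1, hp$end[i]), dna)
    # the mature genomic span spells the mature read
    frag <- substr(g, hp$mature_gstart[i] + 1, hp$mature_gend[i])
    if (hp$strand[i] == "-") frag <- rev_comp(frag, "dna")
    expect_equal(as_rna(frag), hp$mature[i])
  }
})

test_that("decoys violate their designed criterion by construction", {
  withr::with_seed(301, m <- draw_mature_fixture())
  withr::with_seed(302, hp <- build_hairpin(m, "unpaired7"))
  # count designed mismatches between the planted mature and the star arm
  planted <- substr(hp$precursor, hp$read_span[1] + 1, hp$read_span[2])
  star_arm <- substr(hp$precursor, 45, 65)
  states <- pair_class(strsplit(planted, "")[[1]],
                       rev(strsplit(star_arm, "")[[1]]))
  expect_equal(sum(states == "mismatch"), 7L)
  # spacer geometry gives the designed separation exactly
  withr::with_seed(303, sp <- build_hairpin(m, "spacer", separation = 230L))
  L <- nchar(sp$precursor)
  expect_equal(L - 2L * nchar(m) - 2L, 230L)
})

test_that("planted canonical hairpins fold into clean single stems", {
  t <- small_truth()
  hp <- t$hairpins[t$hairpins$role %in% c("novel", "known"), ]
  folds <- fold_rna(hp$precursor)
  for (i in seq_len(nrow(hp))) {
    # the constructed geometry puts the mature at offsets 15..36
    ev <- evaluate_candidate(folds[i, ], c(15L, 36L))
    expect_true(ev$crit_hairpin)
    expect_true(ev$crit_one_arm)
    expect_equal(ev$duplex_unpaired, 0L)
  }
})

test_that("read-class tallies equal the manifest tallies", {
  t <- small_truth()
  reads <- simulate_reads(t, "A", seed = 5L)
  tally <- table(reads$true_class)
  hp <- t$hairpins
  expect_equal(unname(tally[["miRNA_novel"]]),
               sum(hp$count_A[hp$role == "novel"]))
  expect_equal(unname(tally[["miRNA_known"]]),
               sum(hp$count_A[hp$role == "known"]))
  expect_equal(unname(tally[["decoy"]]),
               sum(hp$count_A[hp$role == "decoy"]))
  expect_equal(unname(tally[["miRNA_star"]]), sum(hp$star_count_A))
  expect_equal(unname(tally[["rRNA"]]),
               sum(t$ncrna_reads$count_A[t$ncrna_reads$class == "rRNA"]))
  # star counts never exceed mature counts
  expect_true(all(hp$star_count_A <= pmax(hp$count_A, 0)))
  expect_true(all(hp$star_count_A[hp$starred & hp$count_A > 0] >= 2))
})

test_that("the truth set writes to plain-text files", {
  t <- small_truth()
  dir <- withr::local_tempdir()
  write_truth_set(t, dir)
  expect_true(file.exists(file.path(dir, "genome.fa")))
  g <- read_fasta(file.path(dir, "genome.fa"))
  expect_equal(g$seq, unname(t$genome))
  man <- yaml::read_yaml(file.path(dir, "manifest.yml"))
  expect_equal(man$seed, t$seed)
  expect_equal(man$hairpins$hairpin_id, t$hairpins$hairpin_id)
  gff <- readLines(file.path(dir, "genes.gff3"))
  expect_true(any(grepl("\texon\t", gff)))
})
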