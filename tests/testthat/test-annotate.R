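fake_mapping <- function(ids) {
  list(loci = tibble::tibble(read_id = ids, chrom = "chr1",
                             start = seq_along(ids) * 100L,
                             end = seq_along(ids) * 100L + 21L,
                             strand = "+", count = 2L))
}

test_that("classes follow exact substring matching with fixed priority", {
  trna <- rand_rna(1, 75, seed = 51)
  rrna <- rand_rna(1, 200, seed = 52)
  shared <- substr(rrna, 20, 40)
  reads <- tibble::tibble(
    read_id = c("t", "both", "none"),
    seq = c(substr(trna, 10, 30), shared, rand_rna(1, 21, seed = 53)),
    count = 2L
  )
  refs <- list(rRNA = c(rrna, shared), tRNA = c(trna, shared))
  cls <- classify_reads(fake_mapping(reads$read_id), reads, refs)
  got <- cls$class[match(c("t", "both", "none"), cls$read_id)]
  expect_equal(got, c("tRNA", "rRNA", "other"))
})

test_that("reverse-complement occurrences in a reference also match", {
  ref <- rand_rna(1, 120, seed = 54)
  read <- rev_comp(substr(ref, 50, 70))
  reads <- tibble::tibble(read_id = "rc", seq = read, count = 2L)
  cls <- classify_reads(fake_mapping("rc"), reads, list(snoRNA = ref))
  expect_equal(cls$class, "snoRNA")
})

test_that("reference record order never changes assignments", {
  proc <- small_processed()
  refs <- lapply(proc$truth$ncrna_refs, function(x) x$seq)
  shuffled <- lapply(refs, rev)
  a <- classify_reads(proc$mapping, proc$collapsed, refs, proc$truth$gene_model)
  b <- classify_reads(proc$mapping, proc$collapsed, shuffled,
                      proc$truth$gene_model)
  expect_equal(a, b)
})

test_that("unknown class keys are a configuration error", {
  reads <- tibble::tibble(read_id = "a", seq = "ACGUACGUACGUACGUACGUA",
                          count = 2L)
  expect_error(classify_reads(fake_mapping("a"), reads,
                              list(junkRNA = "ACGU")), "unknown ncRNA class")
})

test_that("planted truth classes are recovered through the gene model", {
  proc <- small_processed()
  t <- proc$truth
  cls <- proc$classes
  joined <- dplyr::inner_join(
    cls, proc$collapsed[, c("read_id", "seq")], by = "read_id"
  )
  for (k in c("exon_sense", "intron_antisense")) {
    planted <- t$gene_reads$seq[t$gene_reads$class == k &
                                  t$gene_reads$count_A >= 2]
    got <- joined$class[match(planted, joined$seq)]
    got <- got[!is.na(got)]
    expect_true(length(got) > 0)
    expect_true(all(got == k))
  }
  planted_nc <- t$ncrna_reads[t$ncrna_reads$count_A >= 2, ]
  got_nc <- joined$class[match(planted_nc$seq, joined$seq)]
  keep <- !is.na(got_nc)
  expect_true(all(got_nc[keep] == planted_nc$class[keep]))
})

test_that("class summary partitions distinct and total counts", {
  reads <- tibble::tibble(read_id = c("a", "b"), seq = c("ACGU", "GGCC"),
                          count = c(3L, 5L))
  cls <- tibble::tibble(read_id = c("a", "b"), class = "rRNA")
  sm <- summarize_classes(cls, reads)
  expect_equal(sm$distinct_count[sm$class == "rRNA"], 2L)
  expect_equal(sm$total_count[sm$class == "rRNA"], 8L)
  expect_equal(sum(sm$distinct_count), 2L)
  expect_equal(sum(sm$total_fraction), 1)
  empty <- summarize_classes(tibble::tibble(read_id = character(),
                                            class = character()), reads)
  expect_true(all(empty$distinct_count == 0L))

  # partition conservation on the simulated study
  proc <- small_processed()
  mapped <- proc$collapsed[proc$collapsed$read_id %in%
                             proc$mapping$loci$read_id, ]
  sm2 <- summarize_classes(proc$classes, mapped)
  expect_equal(sum(sm2$distinct_count), nrow(proc$classes))
  expect_equal(sum(sm2$total_count), sum(mapped$count))
})
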