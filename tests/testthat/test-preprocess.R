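adapter <- "TCGTATGCCGTCTTCTGCTTG"

make_raw <- function(inserts, adapter3 = adapter, qual_phred = 38) {
  seqs <- paste0(inserts, adapter3)
  tibble::tibble(
    name = paste0("r", seq_along(inserts)),
    seq = seqs,
    qual = vapply(nchar(seqs), function(n)
      intToUtf8(rep(33L + qual_phred, n)), character(1))
  )
}

test_that("length window bounds are enforced after adapter trimming", {
  withr::with_seed(5, {
    ins <- vapply(c(17L, 18L, 30L, 31L), function(l)
      paste(sample(c("C", "G", "T"), l, replace = TRUE), collapse = ""),
      character(1))
  })
  out <- clean_reads(make_raw(ins), adapter3 = adapter)
  expect_equal(out$insert_len, c(18L, 30L))
  log <- attr(out, "drop_log")
  expect_equal(unname(log[c("too_short", "too_long")]), c(1L, 1L))
})

test_that("quality, polyA, 5' adapter and adapter-free reads are dropped", {
  withr::with_seed(6, {
    good <- paste(sample(c("C", "G", "T", "A"), 22, TRUE), collapse = "")
  })
  raw <- dplyr::bind_rows(
    make_raw(good),
    make_raw(good, qual_phred = 10),                       # low quality
    make_raw(strrep("A", 22)),                             # polyA
    dplyr::mutate(make_raw(good),
                  seq = paste0("GTTCAGAGTTCTACAGTCCGACGATC", .data$seq)),
    tibble::tibble(name = "x", seq = paste0(good, strrep("C", 21)),
                   qual = strrep("G", 43))                 # no adapter
  )
  out <- clean_reads(raw, adapter3 = adapter,
                     adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC")
  expect_equal(nrow(out), 1L)
  log <- attr(out, "drop_log")
  expect_equal(unname(log[c("low_quality", "polyA", "adapter5_contaminant",
                            "no_adapter")]),
               c(1L, 1L, 1L, 1L))
})

test_that("survivors of simulated cleaning match the length oracle", {
  # 200 reads with known adapters and planted insert lengths 15-35
  withr::with_seed(101, {
    lens <- sample(15:35, 200, replace = TRUE)
    ins <- vapply(lens, function(l) {
      repeat {
        s <- paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                   collapse = "")
        if (!grepl(substr(adapter, 1, 8), s, fixed = TRUE) &&
            stringr::str_count(s, "A") / l < 0.8) return(s)
      }
    }, character(1))
  })
  out <- clean_reads(make_raw(ins), adapter3 = adapter)
  # oracle: filter the manifest lengths directly
  expect_setequal(out$name, paste0("r", which(lens >= 18 & lens <= 30)))
  expect_equal(sort(out$insert_len), sort(lens[lens >= 18 & lens <= 30]))
})

test_that("collapsing counts, drops singletons, and is idempotent", {
  reads <- tibble::tibble(seq = c(rep("ACGTACGTACGTACGTAC", 3),
                                  "TGGAAGCTTGGAAGCTTG"))
  out <- collapse_reads(reads)
  expect_equal(nrow(out), 1L)
  expect_equal(out$seq, "ACGUACGUACGUACGUAC")
  expect_equal(out$count, 3L)
  keep_all <- collapse_reads(reads, drop_singletons = FALSE)
  expect_equal(sum(keep_all$count), nrow(reads))
  # monotonicity of the singleton filter
  expect_lte(nrow(out), nrow(keep_all))
  expect_lte(sum(out$count), sum(keep_all$count))
  # idempotence on an already collapsed set
  again <- collapse_reads(keep_all, drop_singletons = FALSE)
  expect_equal(dplyr::arrange(again, .data$seq)[c("seq", "count")],
               dplyr::arrange(keep_all, .data$seq)[c("seq", "count")])
  expect_equal(nrow(collapse_reads(tibble::tibble(seq = character()))), 0L)
})

test_that("collapsed counts equal a brute-force dictionary count", {
  withr::with_seed(77, {
    pool <- rand_rna(300, 21, seed = 78)
    draws <- sample(pool, 10000, replace = TRUE,
                    prob = stats::rlnorm(300))
  })
  out <- collapse_reads(tibble::tibble(seq = draws), drop_singletons = FALSE)
  oracle <- table(draws)
  expect_equal(out$count[match(names(oracle), out$seq)],
               unname(as.integer(oracle)))
  expect_equal(sum(out$count), 10000L)
})

test_that("length distribution fractions are conserved", {
  reads <- tibble::tibble(seq = c(strrep("ACU", 7), strrep("GACU", 6)),
                          count = c(3L, 7L))
  ld <- length_distribution(reads)
  expect_equal(ld$length, c(21L, 24L))
  expect_equal(ld$total_fraction, c(0.3, 0.7))
  expect_equal(sum(ld$total_count), sum(reads$count))
  single <- length_distribution(tibble::tibble(seq = strrep("ACGU", 6),
                                               count = 7L))
  expect_equal(single$distinct_count, 1L)
  expect_equal(single$total_fraction, 1)
})

test_that("simulated length fractions track the generator weights", {
  p <- small_truth()
  co <- small_processed()$collapsed
  ld <- length_distribution(co)
  expect_equal(sum(ld$total_fraction), 1)
  expect_true(all(ld$length >= 18 & ld$length <= 30))
  # planted matures are 21 nt and dominate the totals
  expect_equal(ld$length[which.max(ld$total_count)], 21L)
})
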