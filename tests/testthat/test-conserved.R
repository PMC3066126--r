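make_ref <- function(matures, hairpins = NULL) {
  if (is.null(hairpins)) {
    hairpins <- vapply(matures, function(m)
      paste0(rand_rna(1, 20, seed = nchar(m)), m, rand_rna(1, 25, seed = 7)),
      character(1), USE.NAMES = FALSE)
  }
  load_mirna_ref(
    tibble::tibble(name = paste0("zma-miR", seq_along(matures)),
                   seq = matures),
    tibble::tibble(name = paste0("zma-MIR", seq_along(matures)),
                   seq = hairpins)
  )
}

test_that("conserved calls need a perfect mature and hairpin match", {
  m <- rand_rna(1, 21, seed = 61)
  ref <- make_ref(m)
  flip <- function(s, at) {
    substr(s, at, at) <- setdiff(c("A", "C", "G", "U"),
                                 substr(s, at, at))[1]
    s
  }
  two_sub <- flip(flip(m, 3), 9)
  reads <- tibble::tibble(read_id = c("perfect", "twosub"),
                          seq = c(m, two_sub), count = 5L)
  hits <- match_known(reads, ref)
  perfect <- hits[hits$read_id == "perfect", ]
  expect_true(perfect$conserved_call)
  expect_equal(perfect$mismatches, 0L)
  ts <- hits[hits$read_id == "twosub", ]
  expect_equal(ts$mismatches, 2L)
  expect_false(ts$conserved_call)
})

test_that("a perfect mature not contained in its hairpin is not conserved", {
  m <- rand_rna(1, 21, seed = 62)
  ref <- suppressWarnings(make_ref(m, hairpins = rand_rna(1, 90, seed = 63)))
  hits <- match_known(tibble::tibble(read_id = "r", seq = m, count = 3L), ref)
  expect_true(hits$perfect_mature)
  expect_false(hits$perfect_hairpin)
  expect_false(hits$conserved_call)
})

test_that("edit distances agree with a dynamic-programming oracle", {
  reads <- rand_rna(100, 21, seed = 64)
  matures <- rand_rna(50, 21, seed = 65)
  # spike in near-misses so distances 0-3 are represented
  reads[1:6] <- c(matures[1],
                  sub("A", "G", matures[2]),
                  paste0("G", substr(matures[3], 1, 20)),
                  paste0(substr(matures[4], 2, 21), "C"),
                  sub("C", "U", sub("G", "A", matures[5])),
                  matures[6])
  d_impl <- utils::adist(reads, matures)
  sel <- cbind(sample(1:100, 120, TRUE), sample(1:50, 120, TRUE))
  sel <- rbind(sel, cbind(1:6, 1:6))
  d_oracle <- apply(sel, 1, function(ij) lev_oracle(reads[ij[1]], matures[ij[2]]))
  expect_equal(d_impl[sel], d_oracle)

  # hits reported by the matcher are exactly the pairs at distance <= 2
  ref <- make_ref(matures)
  hits <- match_known(tibble::tibble(read_id = paste0("r", 1:100),
                                     seq = reads, count = 2L), ref)
  got <- with(hits, paste(read_id, mature_name))
  want_idx <- which(d_impl <= 2, arr.ind = TRUE)
  want <- paste(paste0("r", want_idx[, 1]), paste0("zma-miR", want_idx[, 2]))
  expect_setequal(got, want)
  expect_true(all(hits$read_id[hits$conserved_call] %in%
                    hits$read_id[hits$mismatches == 0]))
})

test_that("cross-species hits are labelled, never native calls", {
  m <- rand_rna(1, 21, seed = 66)
  variant <- m; substr(variant, 5, 5) <- "A"
  hits <- match_known(tibble::tibble(read_id = "r", seq = variant, count = 2L),
                      tibble::tibble(name = "osa-miR1", seq = m),
                      cross_species = TRUE)
  expect_equal(nrow(hits), 1L)
  expect_true(hits$cross_species)
  expect_false(hits$conserved_call)
})

test_that("seed identity compares exactly nucleotides 2-8", {
  a <- "AUGGAAGCUGGAACGGAAUCG"
  b <- paste0("C", substr(a, 2, 21))           # differs only at position 1
  expect_true(seed_identical(a, b))
  c5 <- a; substr(c5, 5, 5) <- "C"  # position 5 is A in `a`
  expect_false(seed_identical(a, c5))
  c9 <- a; substr(c9, 9, 9) <- "A"
  expect_true(seed_identical(a, c9))           # position 9 outside the seed
  expect_error(seed_identical("AUGGAAG", a), "at least 8")
})
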