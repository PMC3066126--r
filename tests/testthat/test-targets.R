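# a 21-mer containing G and U in both halves, fixed for rule tests
M <- "UGGAAGCUGGUCAUGAAUGGC"

test_that("duplex scoring counts wobbles as half mismatches", {
  perfect <- score_duplex(M, mk_site(M))
  expect_equal(perfect$mismatch_score, 0)
  expect_true(all(perfect$states == "watson_crick"))
  expect_equal(perfect$duplex_mfe, perfect$perfect_mfe)
  expect_lt(perfect$perfect_mfe, 0)

  one_wob <- score_duplex(M, mk_site(M, wob = 2L))
  expect_equal(one_wob$mismatch_score, 0.5)
  expect_equal(sum(one_wob$states == "wobble"), 1L)

  d <- score_duplex(M, mk_site(M, mism = c(14L, 15L, 20L)))
  expect_equal(d$mismatch_score, 3)
  expect_equal(which(d$states == "mismatch"), c(14L, 15L, 20L))
  expect_error(score_duplex(M, substr(M, 1, 20)), "equal length")
})

test_that("energies are ordered perfect <= duplex <= 0", {
  withr::with_seed(91, ms <- rand_rna(15, 21, seed = 92))
  for (m in ms) {
    site <- mk_site(m)
    ch <- strsplit(site, "")[[1]]
    withr::with_seed(sum(utf8ToInt(m)), {
      at <- sample(21, 3)
      for (a in at) ch[a] <- sample(c("A", "C", "G", "U"), 1)
    })
    d <- score_duplex(m, paste(ch, collapse = ""))
    expect_lte(d$perfect_mfe, d$duplex_mfe)
    expect_lte(d$duplex_mfe, 0)
  }
})

test_that("each positional rule trips on its designed duplex", {
  pass <- passes_filters(score_duplex(M, mk_site(M)))
  expect_true(all(pass))

  r1 <- passes_filters(score_duplex(M, mk_site(M, mism = c(13, 15, 17, 19, 21))))
  expect_false(r1[["rule1"]])

  r2 <- passes_filters(score_duplex(M, mk_site(M, mism = c(14, 15, 16))))
  expect_false(r2[["rule2"]])
  expect_true(r2[["rule1"]])

  r3 <- passes_filters(score_duplex(M, mk_site(M, mism = c(5, 6))))
  expect_false(r3[["rule3"]])
  expect_true(r3[["rule2"]])

  r4 <- passes_filters(score_duplex(M, mk_site(M, mism = 10)))
  expect_false(r4[["rule4"]])
  r4b <- passes_filters(score_duplex(M, mk_site(M, mism = 11)))
  expect_false(r4b[["rule4"]])

  r5 <- passes_filters(score_duplex(M, mk_site(M, mism = c(3, 6, 9))))
  expect_false(r5[["rule5"]])
  expect_true(r5[["rule1"]])

  # wobbles score but are pairings: no adjacency, no 10-11 violation
  wob_heavy <- passes_filters(score_duplex(M, mk_site(M, wob = c(10, 11))))
  expect_true(wob_heavy[["rule4"]])
  expect_true(wob_heavy[["rule3"]])
})

test_that("strict mode bounds the total score at three mismatches", {
  s3 <- passes_filters(score_duplex(M, mk_site(M, mism = c(13, 15, 17))))
  expect_true(s3[["strict_pass"]])
  s35 <- passes_filters(score_duplex(M, mk_site(M, mism = c(13, 15, 17),
                                                wob = 2L)))
  expect_false(s35[["strict_pass"]])
  expect_true(s35[["rule1"]])
})

test_that("scanner hits equal per-window reference scoring on small input", {
  withr::with_seed(93, {
    mirnas <- tibble::tibble(name = c("m1", "m2"),
                             seq = rand_rna(2, 21, seed = 94))
    tx <- tibble::tibble(name = paste0("t", 1:3),
                         seq = rand_rna(3, 200, seed = 95))
  })
  # plant a perfect site and a rule4-failing site
  tx$seq[1] <- paste0(substr(tx$seq[1], 1, 50), mk_site(mirnas$seq[1]),
                      substr(tx$seq[1], 72, 200))
  tx$seq[2] <- paste0(substr(tx$seq[2], 1, 80),
                      mk_site(mirnas$seq[2], mism = 10L),
                      substr(tx$seq[2], 102, 200))
  hits <- scan_transcripts(mirnas, tx, strict = TRUE)
  # reference: every window through score_duplex + passes_filters
  ref <- list()
  for (mi in 1:2) {
    L <- nchar(mirnas$seq[mi])
    for (ti in 1:3) {
      n <- nchar(tx$seq[ti])
      for (w in 1:(n - L + 1)) {
        d <- score_duplex(mirnas$seq[mi], substr(tx$seq[ti], w, w + L - 1))
        v <- passes_filters(d, strict = TRUE)
        if (v[["overall"]]) {
          ref[[length(ref) + 1]] <- sprintf("%s:%s:%d", mirnas$name[mi],
                                            tx$name[ti], w - 1)
        }
      }
    }
  }
  expect_setequal(sprintf("%s:%s:%d", hits$mirna_id, hits$transcript_id,
                          hits$start),
                  unlist(ref))
  expect_true(any(hits$mirna_id == "m1" & hits$start == 50))
  expect_false(any(hits$mirna_id == "m2" & hits$start == 80))
})

test_that("strict hits are a subset of default hits", {
  t <- small_truth()
  mirnas <- tibble::tibble(
    name = sprintf("m%d", seq_along(unique(t$target_sites$mirna))),
    seq = unique(t$target_sites$mirna)
  )
  strict <- scan_transcripts(mirnas, t$transcripts, strict = TRUE)
  default <- scan_transcripts(mirnas, t$transcripts, strict = FALSE)
  key <- function(x) paste(x$mirna_id, x$transcript_id, x$start)
  expect_true(all(key(strict) %in% key(default)))
  expect_true(all(default$strict_pass[match(key(strict), key(default))]))
})

test_that("designed sites are hit or missed as planned", {
  t <- small_truth()
  ts <- t$target_sites
  mirnas <- tibble::tibble(name = unique(ts$mirna), seq = unique(ts$mirna))
  default <- scan_transcripts(mirnas, t$transcripts, strict = FALSE)
  strict <- scan_transcripts(mirnas, t$transcripts, strict = TRUE)
  key <- function(x) paste(x$mirna_id, x$transcript_id, x$start)
  skey <- paste(ts$mirna, ts$transcript, ts$pos)
  expect_equal(skey %in% key(default), ts$expected_hit)
  expect_equal(skey %in% key(strict), ts$expected_hit & ts$expected_strict)
})

test_that("grouped hits put the least-mismatch miRNA first", {
  m1 <- M
  m2 <- M; substr(m2, 15, 15) <- "A"  # position 15 is G in M
  tx <- tibble::tibble(name = "t", seq = paste0(strrep("A", 30), mk_site(m1),
                                                strrep("C", 30)))
  hits <- scan_transcripts(tibble::tibble(name = c("a", "b"),
                                          seq = c(m2, m1)), tx)
  shared <- hits[hits$site_group == hits$site_group[1], ]
  expect_equal(nrow(shared), 2L)
  expect_true(shared$mismatch_score[1] <= shared$mismatch_score[2])
  expect_equal(shared$mirna_id[1], "b")
})

test_that("alignments render three lines and round-trip to states", {
  d <- score_duplex(M, mk_site(M, wob = 2L))
  block <- render_alignment(d)
  lines <- strsplit(block, "\n")[[1]]
  expect_length(lines, 3L)
  glyphs <- substr(lines[2], 11, 10 + nchar(M))
  expect_equal(stringr::str_count(glyphs, stringr::fixed("|")), 20L)
  expect_equal(parse_alignment(block), d$states)
  perfect <- render_alignment(score_duplex(M, mk_site(M)))
  expect_equal(stringr::str_count(strsplit(perfect, "\n")[[1]][2],
                                  stringr::fixed("|")), 21L)
})
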