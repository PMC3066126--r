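# Plant-style miRNA target prediction: ungapped antiparallel duplexes,
# positional rules indexed 1..L from the miRNA 5' end, G:U wobble
# scoring half a mismatch. Scoring is kept in integer half-mismatch
# units and integer decikilocalories so the fast scanner and the
# per-pair reference functions agree exactly.
#
# Rules (all must pass for a reported hit):
#   1. total mismatch score <= 4 (G:U wobble = 0.5)
#   2. no more than two adjacent (full) mismatches anywhere
#   3. no adjacent (full) mismatches in positions 2-12
#   4. no (full) mismatch at positions 10-11
#   5. mismatch score over positions 1-12 <= 2.5
#   6. duplex MFE at least 75% of the miRNA's perfect-complement MFE
# Strict mode additionally requires total mismatch score <= 3.
# Wobbles count toward the numeric scores (rules 1, 5) but are pairings:
# they do not count as mismatches in rules 2-4.

#' Score one miRNA/target duplex
#'
#' The site is given 5'->3' on the transcript and must have the miRNA's
#' length (ungapped model); miRNA position `i` (1-based from its 5' end)
#' faces site position `L + 1 - i` in antiparallel orientation. Duplex
#' energies come from the package's nearest-neighbour stack table; the
#' perfect-complement energy of the miRNA is the reference for rule 6.
#'
#' @param mirna RNA sequence of the miRNA.
#' @param site RNA site sequence of equal length (transcript, 5'->3').
#' @return List with `states` (per-position `pair_class()` values,
#'   indexed from the miRNA 5' end), `mismatch_score` (half-integer),
#'   `duplex_mfe` and `perfect_mfe` (kcal/mol).
#' @export
#' @examples
#' m <- "UGGAAGCUGGUCAUCAAUGGC"
#' score_duplex(m, rev_comp(m))$mismatch_score
score_duplex <- function(mirna, site) {
  mirna <- as_rna(mirna); site <- as_rna(site)
  L <- nchar(mirna)
  if (nchar(site) != L) {
    stop("miRNA and site must have equal length (ungapped duplex model)",
         call. = FALSE)
  }
  mc <- seq_chars(mirna)[[1]]
  sc <- rev(seq_chars(site)[[1]])
  states <- pair_class(mc, sc)
  score2 <- sum((states == "mismatch") * 2L + (states == "wobble"))
  pidx <- pair_index(mc, sc)
  dup_dc <- duplex_energy_dc(pidx)
  perfect_idx <- pair_index(mc, vapply(mc, function(b)
    c(A = "U", C = "G", G = "C", U = "A", N = "N")[[b]], character(1)))
  per_dc <- duplex_energy_dc(perfect_idx)
  list(mirna = mirna, site = site, states = states,
       mismatch_score = score2 / 2,
       duplex_mfe = dup_dc / 10, perfect_mfe = per_dc / 10)
}

# Stack-energy sum (decikcal) over adjacent positions where both form a
# pair; the same model backs the scanner and rule 6.
duplex_energy_dc <- function(pidx) {
  stk <- nn_stack_table()
  e <- 0L
  for (i in seq_len(length(pidx) - 1L)) {
    if (pidx[i] > 0 && pidx[i + 1] > 0) e <- e + stk[pidx[i], pidx[i + 1]]
  }
  as.integer(e)
}

#' Apply the positional target rules to a scored duplex
#'
#' @param d Result of [score_duplex()].
#' @param strict Also require a total mismatch score of at most
#'   `strict_target_mismatch` (default 3).
#' @param thresholds From [mir_thresholds()].
#' @return Named logical vector `rule1`..`rule6`, `strict_pass`,
#'   `overall` (rules 1-6, plus the strict bound when `strict`).
#' @export
passes_filters <- function(d, strict = TRUE, thresholds = mir_thresholds()) {
  st <- d$states
  L <- length(st)
  mm <- st == "mismatch"
  sc2 <- (st == "mismatch") * 2L + (st == "wobble")
  r1 <- sum(sc2) <= 2 * thresholds$max_target_mismatch
  runs <- rle(mm)
  r2 <- !any(runs$values & runs$lengths > 2)
  idx <- 2:min(12L, L)
  r3 <- !any(mm[idx[-length(idx)]] & mm[idx[-1]])
  r4 <- !(mm[10] || mm[11])
  r5 <- sum(sc2[1:min(12L, L)]) <= 2 * thresholds$region_target_mismatch
  dup_dc <- round(d$duplex_mfe * 10)
  per_dc <- round(d$perfect_mfe * 10)
  r6 <- dup_dc <= 0 && (-dup_dc) >= thresholds$energy_ratio * (-per_dc)
  strict_pass <- sum(sc2) <= 2 * thresholds$strict_target_mismatch
  overall <- r1 && r2 && r3 && r4 && r5 && r6 && (!strict || strict_pass)
  c(rule1 = r1, rule2 = r2, rule3 = r3, rule4 = r4, rule5 = r5, rule6 = r6,
    strict_pass = strict_pass, overall = overall)
}

#' Scan transcripts for miRNA target sites
#'
#' Scores every window of miRNA length on every transcript (ungapped,
#' antiparallel) and reports windows passing all six rules (plus the
#' strict bound when `strict`). Hits are sorted by transcript and
#' position; hits of several miRNAs on the same site are grouped with
#' the least-mismatch miRNA first.
#'
#' @param mirnas Tibble (`name`, `seq`) or named character vector or
#'   FASTA path of mature miRNA sequences.
#' @param transcripts Tibble (`name`, `seq`) or named character vector
#'   or FASTA path of transcript sequences (DNA or RNA).
#' @param strict Strict mode (default TRUE): total mismatch score <= 3.
#' @param thresholds From [mir_thresholds()].
#' @return Tibble `mirna_id`, `transcript_id`, `start`, `end` (0-based
#'   half-open on the transcript), `mismatch_score`, `duplex_mfe`,
#'   `perfect_mfe`, `strict_pass`, `site_seq`, `alignment` (rendered
#'   text block), `site_group` (id shared by hits on one site).
#' @export
scan_transcripts <- function(mirnas, transcripts, strict = TRUE,
                             thresholds = mir_thresholds()) {
  mirnas <- as_seq_tbl(mirnas)
  transcripts <- as_seq_tbl(transcripts)
  if (nrow(transcripts) == 0) stop("no transcripts given", call. = FALSE)
  mseq <- as_rna(mirnas$seq)
  tseq <- as_rna(transcripts$seq)
  hits <- cpp_scan_targets(
    mseq, mirnas$name, tseq, transcripts$name, nn_stack_table(),
    strict,
    as.integer(2 * thresholds$max_target_mismatch),
    as.integer(2 * thresholds$strict_target_mismatch),
    as.integer(2 * thresholds$region_target_mismatch),
    thresholds$energy_ratio
  )
  hits <- tibble::as_tibble(hits)
  hits$mismatch_score <- hits$score2 / 2
  hits$duplex_mfe <- hits$duplex_dc / 10
  hits$perfect_mfe <- hits$perfect_dc / 10
  hits$site_seq <- substr(tseq[match(hits$transcript_id, transcripts$name)],
                          hits$start + 1L, hits$end)
  hits$alignment <- vapply(seq_len(nrow(hits)), function(i) {
    render_alignment(score_duplex(
      mseq[match(hits$mirna_id[i], mirnas$name)], hits$site_seq[i]
    ))
  }, character(1))
  hits |>
    dplyr::select(-"score2", -"duplex_dc", -"perfect_dc") |>
    dplyr::arrange(.data$transcript_id, .data$start, .data$end,
                   .data$mismatch_score, .data$mirna_id) |>
    dplyr::mutate(site_group = dplyr::consecutive_id(
      .data$transcript_id, .data$start, .data$end))
}

as_seq_tbl <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) return(read_fasta(x))
  if (is.character(x)) {
    nm <- names(x)
    if (is.null(nm)) nm <- paste0("seq", seq_along(x))
    return(tibble::tibble(name = nm, seq = unname(x)))
  }
  stop("expected a tibble, a named character vector or a FASTA path",
       call. = FALSE)
}

#' Render a duplex alignment as a three-line text block
#'
#' miRNA 5'->3' on top, pairing glyphs in the middle (vertical bar for a
#' Watson-Crick pair; space for mismatches and, by display convention,
#' G:U wobbles), target site 3'->5' at the bottom.
#'
#' @param d Result of [score_duplex()].
#' @return A single string with three newline-separated lines.
#' @export
render_alignment <- function(d) {
  glyphs <- ifelse(d$states == "watson_crick", "|", " ")
  site_rev <- paste(rev(seq_chars(d$site)[[1]]), collapse = "")
  paste(c(paste0("miRNA  5' ", d$mirna, " 3'"),
          paste0("          ", paste(glyphs, collapse = "")),
          paste0("target 3' ", site_rev, " 5'")),
        collapse = "\n")
}

#' Parse a rendered alignment back to its pairing states
#'
#' Recovers the per-position states from the two sequence lines of a
#' rendered block and checks them against the glyph line (a bar must sit
#' at every Watson-Crick position and nowhere else).
#'
#' @param block String from [render_alignment()].
#' @return Character vector of `pair_class()` states.
#' @export
parse_alignment <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  mirna <- sub(" 3'$", "", sub("^miRNA  5' ", "", lines[1]))
  site_rev <- sub(" 5'$", "", sub("^target 3' ", "", lines[3]))
  glyphs <- substr(lines[2], 11L, 10L + nchar(mirna))
  states <- pair_class(seq_chars(mirna)[[1]], seq_chars(site_rev)[[1]])
  bars <- seq_chars(glyphs)[[1]] == "|"
  if (!identical(bars, states == "watson_crick")) {
    stop("alignment glyphs inconsistent with sequences", call. = FALSE)
  }
  states
}
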