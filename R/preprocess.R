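# Raw-read cleaning, collapsing to unique tags, and the length
# distribution. Pipeline order: clean (adapter, quality, length, polyA)
# -> collapse to unique reads -> drop singletons -> map.

#' Clean raw small-RNA reads
#'
#' Locates the 3' adapter as the earliest ungapped occurrence of an
#' `adapter_seed`-long adapter prefix (exact first, then allowing one
#' mismatch), trims the read there, and drops reads that fail any
#' filter. Reads in which no adapter is located are dropped as
#' contaminants. Dropped reads are counted by reason in the `drop_log`
#' attribute.
#'
#' Drop reasons: `adapter5_contaminant` (read begins with the 5'
#' adapter), `no_adapter` (3' adapter not found), `empty_insert`,
#' `low_quality` (mean Phred below `min_mean_quality`; only applied when
#' a `qual` column is present), `too_short` / `too_long` (insert outside
#' `[min_len, max_len]`), `polyA` (insert at least 80% A), `ambiguous`
#' (insert contains N).
#'
#' @param reads Tibble with columns `name`, `seq` (DNA or RNA), and
#'   optionally `qual` (Sanger-encoded) and `library_id`.
#' @param adapter3 3' adapter sequence (required for trimming).
#' @param adapter5 Optional 5' adapter; reads starting with it (up to one
#'   mismatch) are dropped as contaminants.
#' @param min_len,max_len Retained insert length window (default 18-30).
#' @param min_mean_quality Mean Phred threshold (default 20).
#' @param adapter_seed Minimum adapter prefix that must be visible
#'   (default 8 nt).
#' @param polya_frac Fraction of A at or above which an insert is
#'   discarded as polyA (default 0.8).
#' @return Tibble of retained reads with trimmed `seq` (insert only) and
#'   an `insert_len` column; a named drop-count vector is attached as the
#'   `drop_log` attribute.
#' @export
clean_reads <- function(reads, adapter3, adapter5 = NULL,
                        min_len = 18L, max_len = 30L,
                        min_mean_quality = 20, adapter_seed = 8L,
                        polya_frac = 0.8) {
  if (missing(adapter3) || is.null(adapter3) || !nzchar(adapter3)) {
    stop("a 3' adapter sequence is required", call. = FALSE)
  }
  adapter3 <- as_dna(adapter3)
  check_alphabet(adapter3, "dna")
  if (!is.null(adapter5)) {
    adapter5 <- as_dna(adapter5)
    check_alphabet(adapter5, "dna")
  }
  seqs <- as_dna(reads$seq)
  n <- length(seqs)
  reason <- rep(NA_character_, n)

  # 5' adapter contaminants
  if (!is.null(adapter5) && n > 0) {
    k <- min(nchar(adapter5), 12L)
    pre <- substr(seqs, 1L, k)
    mm <- utils::adist(pre, substr(adapter5, 1L, k))[, 1]
    reason[is.na(reason) & nchar(seqs) >= k & mm <= 1] <- "adapter5_contaminant"
  }

  # locate the 3' adapter: best ungapped occurrence of an adapter prefix
  # (>= adapter_seed nt, <= 1 mismatch); trim the read there
  pos <- find_adapter(seqs, adapter3, adapter_seed)
  reason[is.na(reason) & pos < 0L] <- "no_adapter"
  insert <- ifelse(pos > 0L, substr(seqs, 1L, pos), "")
  reason[is.na(reason) & pos == 0L] <- "empty_insert"

  if (!is.null(reads$qual) && any(!is.na(reads$qual))) {
    mq <- mean_phred(substr(reads$qual, 1L, pmax(pos, 1L)))
    reason[is.na(reason) & !is.na(mq) & mq < min_mean_quality] <- "low_quality"
  }

  len <- nchar(insert)
  reason[is.na(reason) & len < min_len] <- "too_short"
  reason[is.na(reason) & len > max_len] <- "too_long"

  a_frac <- ifelse(len > 0,
                   stringr::str_count(insert, "A") / pmax(len, 1L), 0)
  reason[is.na(reason) & a_frac >= polya_frac] <- "polyA"
  reason[is.na(reason) & stringr::str_detect(insert, "N")] <- "ambiguous"

  keep <- is.na(reason)
  out <- reads[keep, , drop = FALSE]
  out$seq <- insert[keep]
  out$insert_len <- len[keep]
  out <- tibble::as_tibble(out)
  drop_log <- table(factor(reason[!keep]))
  attr(out, "drop_log") <- stats::setNames(as.integer(drop_log), names(drop_log))
  out
}

# Vectorised 3' adapter search. Fast path: earliest exact occurrence of
# the adapter_seed-long adapter prefix. Reads without an exact seed hit
# are rescanned allowing one mismatch in the seed window. Returns, per
# read, the insert length (position where the adapter starts), 0 for an
# adapter-only read, or -1 when no adapter occurrence is found.
find_adapter <- function(seqs, adapter3, adapter_seed = 8L) {
  n <- length(seqs)
  if (n == 0) return(integer(0))
  adapter_seed <- min(adapter_seed, nchar(adapter3))
  seed <- substr(adapter3, 1L, adapter_seed)
  hit <- regexpr(seed, seqs, fixed = TRUE)
  pos <- ifelse(hit > 0L, as.integer(hit) - 1L, -1L)
  miss <- which(pos < 0L)
  if (length(miss) > 0) {
    seed_chars <- seq_chars(seed)[[1]]
    for (r in miss) {
      s <- seqs[r]
      L <- nchar(s)
      if (L < adapter_seed) next
      for (p in 0:(L - adapter_seed)) {
        frag <- seq_chars(substr(s, p + 1L, p + adapter_seed))[[1]]
        if (sum(frag != seed_chars) <= 1L) { pos[r] <- p; break }
      }
    }
  }
  pos
}

#' Collapse cleaned reads to unique tags
#'
#' One row per distinct sequence with its read count (per library when a
#' `library_id` column is present). Sequences are converted to RNA.
#' Collapsing an already-collapsed set is a no-op on counts.
#'
#' @param reads Tibble of cleaned reads (`seq`; optional `library_id`,
#'   optional `count` for pre-aggregated input).
#' @param drop_singletons Drop tags seen only once (default TRUE).
#' @return Tibble with `read_id`, `seq` (RNA), `count`, `length` and
#'   `library_id` (when present), sorted by decreasing count.
#' @export
collapse_reads <- function(reads, drop_singletons = TRUE) {
  if (nrow(reads) == 0) {
    return(tibble::tibble(read_id = character(), seq = character(),
                          count = integer(), length = integer()))
  }
  reads <- dplyr::mutate(reads, seq = as_rna(.data$seq))
  grp <- if ("library_id" %in% names(reads)) c("library_id", "seq") else "seq"
  w <- if ("count" %in% names(reads)) reads$count else rep(1L, nrow(reads))
  reads$..w <- w
  out <- reads |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(count = sum(.data$..w), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$seq)
  if (drop_singletons) out <- dplyr::filter(out, .data$count >= 2L)
  out |>
    dplyr::mutate(read_id = sprintf("t%07d", dplyr::row_number()),
                  length = nchar(.data$seq)) |>
    dplyr::relocate("read_id")
}

#' Length distribution of unique reads
#'
#' Distinct and count-weighted tallies per insert length, with fractions
#' of the totals. Total fractions sum to 1 over the represented lengths.
#'
#' @param reads Collapsed read tibble (`seq`, `count`).
#' @return Tibble with `length`, `distinct_count`, `total_count`,
#'   `distinct_fraction`, `total_fraction`.
#' @export
length_distribution <- function(reads) {
  out <- reads |>
    dplyr::mutate(length = nchar(.data$seq)) |>
    dplyr::group_by(.data$length) |>
    dplyr::summarise(distinct_count = dplyr::n(),
                     total_count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(
      distinct_fraction = .data$distinct_count / sum(.data$distinct_count),
      total_fraction = .data$total_count / sum(.data$total_count)
    ) |>
    dplyr::arrange(.data$length)
  class(out) <- c("mir_length_dist", class(out))
  out
}
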