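# Cross-library confirmation: a candidate counts as confirmed only when
# the other, independently processed library produced a candidate with
# identical precursor sequence, identical mature sequence and identical
# genomic locus.

#' Confirm candidates across two libraries
#'
#' Intersects two candidate sets by strict identity of precursor
#' sequence, mature sequence and precursor locus (chrom, start, end,
#' strand). Confirmed pairs are additionally flagged
#' `expression_consistent` when the per-library-normalised mature count
#' ratio (larger over smaller) is at most `expr_fold_limit`; the flag
#' annotates and never filters.
#'
#' @param a,b Candidate tibbles from [predict_mirnas()] (one library
#'   each).
#' @param expr_fold_limit Normalised fold-change limit (default 4).
#' @param total_a,total_b Library sizes used for normalisation; default
#'   is the sum of mature counts in each candidate set.
#' @return Tibble of confirmed candidates (columns of `a` plus
#'   `mature_count_b`, `count_ratio`, `expression_consistent`).
#' @export
intersect_candidates <- function(a, b, expr_fold_limit = 4,
                                 total_a = NULL, total_b = NULL) {
  key <- c("chrom", "pre_start", "pre_end", "strand", "pre_seq", "mature_seq")
  if (nrow(a) > 0 && nrow(b) > 0 &&
      length(intersect(unique(a$chrom), unique(b$chrom))) == 0) {
    stop("candidate sets share no chromosome names; different genome builds?",
         call. = FALSE)
  }
  if (is.null(total_a)) total_a <- max(sum(a$mature_count), 1)
  if (is.null(total_b)) total_b <- max(sum(b$mature_count), 1)
  confirmed <- dplyr::inner_join(
    a,
    dplyr::select(b, dplyr::all_of(key), mature_count_b = "mature_count"),
    by = key
  )
  if (nrow(confirmed) > 0) {
    na <- confirmed$mature_count / total_a
    nb <- confirmed$mature_count_b / total_b
    confirmed$count_ratio <- pmax(na, nb) / pmin(na, nb)
    confirmed$expression_consistent <- confirmed$count_ratio <= expr_fold_limit
  } else {
    confirmed$mature_count_b <- numeric(0)
    confirmed$count_ratio <- numeric(0)
    confirmed$expression_consistent <- logical(0)
  }
  class(confirmed) <- c("mir_candidates", class(tibble::as_tibble(confirmed)))
  confirmed
}
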