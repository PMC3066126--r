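# RNA secondary structure prediction. The folding engine is a pluggable
# contract: sequence in, dot-bracket + MFE (kcal/mol) out. The default
# engine is ViennaRNA's RNAfold when the binary is on the PATH (folds are
# batched through one process call); otherwise the package's built-in
# deterministic nearest-neighbour model is used and a notice is logged.

the_fold_engine <- new.env(parent = emptyenv())

#' Which folding engine is active?
#'
#' `"vienna"` when the RNAfold binary is available, `"internal"` for the
#' built-in nearest-neighbour model. `fold_engine()` with an argument
#' forces an engine for the session.
#'
#' @param engine Optional: `"auto"`, `"vienna"` or `"internal"`.
#' @return The name of the engine in use, invisibly when setting.
#' @export
fold_engine <- function(engine = NULL) {
  if (!is.null(engine)) {
    engine <- match.arg(engine, c("auto", "vienna", "internal"))
    the_fold_engine$forced <- if (engine == "auto") NULL else engine
    return(invisible(fold_engine()))
  }
  if (!is.null(the_fold_engine$forced)) return(the_fold_engine$forced)
  if (nzchar(Sys.which("RNAfold"))) "vienna" else "internal"
}

#' Fold RNA sequences into minimum free energy structures
#'
#' Predicts one deterministic minimum-free-energy structure per input
#' sequence. Sequences must be RNA (U alphabet), 1 to 2000 nt.
#'
#' @param seqs Character vector of RNA sequences.
#' @param engine `"auto"` (default: RNAfold when available), `"vienna"`
#'   or `"internal"`.
#' @return Tibble with columns `seq`, `structure` (dot-bracket) and
#'   `mfe` (kcal/mol, 0 for unpaired sequences).
#' @export
#' @examples
#' fold_rna("GGGGGAAAACCCCC", engine = "internal")
fold_rna <- function(seqs, engine = c("auto", "vienna", "internal")) {
  engine <- match.arg(engine)
  if (engine == "auto") engine <- fold_engine()
  if (length(seqs) == 0) {
    return(tibble::tibble(seq = character(), structure = character(),
                          mfe = numeric()))
  }
  check_alphabet(seqs, "rna")
  if (engine == "vienna" && !nzchar(Sys.which("RNAfold"))) {
    message("RNAfold not found; falling back to the built-in folding model")
    engine <- "internal"
  }
  if (engine == "vienna") fold_vienna(seqs) else fold_internal(seqs)
}

fold_internal <- function(seqs) {
  stk <- nn_stack_table()
  res <- lapply(seqs, function(s) cpp_fold_nn(s, stk))
  tibble::tibble(
    seq = seqs,
    structure = vapply(res, `[[`, character(1), "structure"),
    mfe = vapply(res, `[[`, integer(1), "mfe_dc") / 10
  )
}

fold_vienna <- function(seqs) {
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa))
  writeLines(as.vector(rbind(paste0(">s", seq_along(seqs)), seqs)), fa)
  out <- suppressWarnings(
    system2("RNAfold", c("--noPS", "--infile", fa), stdout = TRUE)
  )
  # records of three lines: header, sequence, structure ( mfe )
  hdr <- grep("^>", out)
  if (length(hdr) != length(seqs)) stop("RNAfold output could not be parsed")
  struct_lines <- out[hdr + 2L]
  m <- stringr::str_match(struct_lines, "^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)")
  if (anyNA(m[, 1])) stop("RNAfold output could not be parsed")
  tibble::tibble(seq = seqs, structure = m[, 2], mfe = as.numeric(m[, 3]))
}

# Rescore a dot-bracket structure under the built-in parameter table
# (kcal/mol). Loop-decomposition rescoring of the internal engine's own
# output must reproduce its DP energy exactly.
eval_structure <- function(seq, structure) {
  cpp_eval_structure(seq, structure, nn_stack_table()) / 10
}

#' Pair table of a dot-bracket structure
#'
#' @param structure Dot-bracket string.
#' @return Integer vector `pt` with `pt[i]` the 1-based partner of
#'   position `i`, or 0 when unpaired.
#' @export
pair_table <- function(structure) {
  chars <- seq_chars(structure)[[1]]
  pt <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket structure")
  pt
}
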