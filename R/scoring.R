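#' Average reference profile
#'
#' The reference "genome" against which every genome is scored: the
#' arithmetic mean of the raw (untransformed) function counts across all
#' genomes, one value per function. Averaging precedes the log transform.
#'
#' @param mat Genomes-by-functions count matrix ([merge_profiles()]).
#' @return Named numeric vector of per-function mean counts.
#' @export
average_reference <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L)
  colMeans(mat)
}

#' Log2 transform of function counts
#'
#' `log2(count + pseudocount)`. With the default pseudocount of 1 an absent
#' function maps to 0, preserving the "no capacity" reading of a zero count.
#'
#' @param counts Non-negative numeric vector.
#' @param pseudocount Non-negative offset added before the log (default 1).
#' @return Numeric vector, same length and names.
#' @export
log_transform <- function(counts, pseudocount = 1) {
  stopifnot(all(counts >= 0), pseudocount >= 0)
  if (any(counts + pseudocount == 0))
    stop("log2(0) undefined: zero count with zero pseudocount")
  log2(counts + pseudocount)
}

#' Relative turnover / transport scores against a reference
#'
#' Computes, for every genome `x`, the score vector
#' `M %*% (log2(c_x + p) - log2(c_ref + p))` where `M` is an interaction
#' matrix (EIN or transporter-ligand), `c_x` the genome's function counts and
#' `c_ref` the reference counts (by default the across-genome average,
#' [average_reference()]). With an EIN this is the PRMT score: positive means
#' an increased relative capacity to synthesise the compound relative to the
#' reference, negative an increased relative capacity to consume it. With a
#' binary transporter-ligand matrix it is the PRTT score: positive means an
#' increased relative transport capacity for the ligand. Scores are relative
#' capacities only; they are not reaction rates, fluxes or concentrations.
#'
#' Functions named in `M` but absent from the profile matrix are treated as
#' count 0 in every genome and in the reference (with a warning), so
#' interaction matrices from a broader function catalogue than the genome set
#' remain usable. Functions present in the profiles but not in `M` are
#' ignored.
#'
#' @param M An [interaction_matrix()] (compounds x functions).
#' @param profiles Genomes-by-functions count matrix.
#' @param reference Named numeric vector of reference counts per function;
#'   default `NULL` means the average over `profiles`.
#' @param pseudocount Pseudocount for [log_transform()].
#' @return A `score_table`: numeric matrix genomes x compounds with a `kind`
#'   attribute (`"prmt"` or `"prtt"` from the matrix mode).
#' @examples
#' rx <- data.frame(reaction_id = c("r1", "r2"), ec = c("e1", "e2"),
#'                  substrates = I(list("A", "B")), products = I(list("B", "C")),
#'                  reversible = FALSE)
#' M <- build_ein(rx)
#' prof <- matrix(c(3L, 1L), 1, 2, dimnames = list("g1", c("e1", "e2")))
#' prmt_scores(M, prof, reference = c(e1 = 1, e2 = 1))
#' @export
prmt_scores <- function(M, profiles, reference = NULL, pseudocount = 1) {
  stopifnot(inherits(M, "interaction_matrix"), is.matrix(profiles))
  funs <- colnames(M)
  missing_funs <- setdiff(funs, colnames(profiles))
  if (length(missing_funs))
    warning("function(s) in the interaction matrix absent from all genomes, ",
            "treated as count 0: ", paste(missing_funs, collapse = ", "))
  counts <- matrix(0, nrow(profiles), length(funs),
                   dimnames = list(rownames(profiles), funs))
  common <- intersect(funs, colnames(profiles))
  counts[, common] <- profiles[, common]
  if (is.null(reference)) {
    ref <- average_reference(counts)
  } else {
    if (is.null(names(reference)))
      stop("'reference' must be a named numeric vector")
    extra <- setdiff(funs, names(reference))
    ref <- stats::setNames(rep(0, length(funs)), funs)
    ref[intersect(funs, names(reference))] <-
      reference[intersect(funs, names(reference))]
    if (length(extra))
      ref[extra] <- 0
  }
  delta <- sweep(log_transform(counts, pseudocount), 2L,
                 log_transform(ref, pseudocount), "-")
  scores <- delta %*% t(unclass(M))
  kind <- if (identical(attr(M, "mode_tag"), "transportome")) "prtt" else "prmt"
  structure(scores, class = c("score_table", "matrix", "array"), kind = kind)
}

#' @rdname prmt_scores
#' @details `prtt_scores()` is the transportome special case: the same
#'   computation with a validated binary transporter-ligand matrix.
#' @export
prtt_scores <- function(M, profiles, reference = NULL, pseudocount = 1) {
  stopifnot(identical(attr(M, "mode_tag"), "transportome"))
  prmt_scores(M, profiles, reference = reference, pseudocount = pseudocount)
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> kind=%s: %d genome(s) x %d compound(s)\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

#' Read and write score tables
#'
#' Wide tab-separated layout: rows = genomes, columns = compounds (the layout
#' commonly used for per-genome score tables).
#'
#' @param path File path.
#' @param kind Score kind tag for the object read back.
#' @return `read_score_table()`: a `score_table` matrix.
#' @export
read_score_table <- function(path, kind = c("prmt", "prtt")) {
  kind <- match.arg(kind)
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  structure(as.matrix(df), class = c("score_table", "matrix", "array"),
            kind = kind)
}

#' @rdname read_score_table
#' @param scores `score_table` to write.
#' @export
write_score_table <- function(scores, path) {
  df <- data.frame(genome = rownames(scores), unclass(scores),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
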