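#' Filter features before SVM training
#'
#' Keeps the features that carry usable signal: nonzero in strictly more than
#' `min_nonzero_fraction` of the genomes (strict majority by default) and with
#' sample standard deviation strictly greater than `min_sd`. The thresholds
#' are applied to the feature values exactly as they will be fed to the
#' classifier (counts for profile features, scores for model features).
#'
#' @param x Genomes-by-features numeric matrix.
#' @param min_nonzero_fraction Fraction of genomes that must be nonzero
#'   (strict `>`; default 0.5).
#' @param min_sd Minimum sample standard deviation (strict `>`; default 0.2).
#' @return The column-subset matrix. Removing every feature is an error with
#'   per-rule diagnostics.
#' @export
filter_features <- function(x, min_nonzero_fraction = 0.5, min_sd = 0.2) {
  stopifnot(is.matrix(x), nrow(x) >= 1L)
  nz_ok <- colSums(x != 0) > min_nonzero_fraction * nrow(x)
  sd_ok <- apply(x, 2L, sd) > min_sd
  keep <- nz_ok & sd_ok
  if (!any(keep))
    stop(sprintf(paste0("no features survive filtering: %d/%d fail the ",
                        "nonzero-fraction rule (> %g), %d/%d fail the SD rule (> %g)"),
                 sum(!nz_ok), ncol(x), min_nonzero_fraction,
                 sum(!sd_ok), ncol(x), min_sd))
  x[, keep, drop = FALSE]
}

#' F-score from a confusion count
#'
#' Harmonic mean of precision `tp/(tp+fp)` and recall `tp/(tp+fn)`. When both
#' precision and recall are zero (tp = 0 with errors present) the F-score is
#' reported as 0; when either denominator is zero (no predicted positives, or
#' no actual positives) it is not computable and `NA` is returned with a
#' warning.
#'
#' @param tp,fp,fn Non-negative integer counts of true positives, false
#'   positives and false negatives.
#' @return F-score in `[0, 1]`, or `NA`.
#' @examples
#' f_score(2, 1, 1)  # precision = recall = 2/3
#' @export
f_score <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp == 0 || tp + fn == 0) {
    warning("F-score undefined: no predicted positives or no actual positives")
    return(NA_real_)
  }
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' Prediction confidence from the decision-boundary distance
#'
#' The confidence of assigning a validation sample to the positive class is
#' `1 - integral_0^z phi(t) dt = 1 - (Phi(z) - 1/2)` for the standard normal
#' density `phi`, where `z = |d| / s` is the validation sample's distance `d`
#' to the separating hyperplane normalised by `s`, the sample standard
#' deviation of the absolute decision-value distances of the *positive*
#' training examples. The statistic lies in `(0.5, 1]`, equals 1 at the
#' hyperplane and decreases with distance; an assignment is called
#' significant when the confidence is at least 0.95.
#'
#' `mode = "centered"` instead normalises the distance from the positive
#' training mean, `z = |d - mean(d_pos)| / s`, an alternative reading under
#' which confidence grows as a sample approaches the bulk of the training
#' positives.
#'
#' @param decision_value Signed distance of the validation sample from the
#'   hyperplane.
#' @param training_positive_distances Decision values of the positive
#'   training examples (at least two; their absolute values must vary).
#' @param mode `"literal"` (default) or `"centered"`.
#' @return Confidence in `(0.5, 1]` (literal mode).
#' @examples
#' prediction_confidence(0, c(1, 2, 3))          # 1
#' prediction_confidence(sd(abs(c(1, 2, 3))), c(1, 2, 3))  # z = 1 -> 0.6587
#' @export
prediction_confidence <- function(decision_value, training_positive_distances,
                                  mode = c("literal", "centered")) {
  mode <- match.arg(mode)
  stopifnot(length(training_positive_distances) >= 2L)
  s <- sd(abs(training_positive_distances))
  if (!is.finite(s) || s == 0)
    stop("confidence undefined: zero variance in positive training distances")
  z <- if (mode == "literal") abs(decision_value) / s
  else abs(decision_value - mean(training_positive_distances)) / s
  1 - (pnorm(z) - 0.5)
}

#' Flag high-weight (most predictive) features
#'
#' A linear SVM assigns each feature a weight proportional to its predictive
#' contribution. A feature is flagged high-weight when its weight lies more
#' than two sample standard deviations above or below the mean weight.
#'
#' @param weights Numeric vector of feature weights (length >= 3).
#' @return Logical vector, `TRUE` for high-weight features. If the weights
#'   have zero variance nothing is flagged (with a warning).
#' @export
high_weight_features <- function(weights) {
  stopifnot(length(weights) >= 3L)
  s <- sd(weights)
  if (!is.finite(s) || s == 0) {
    warning("zero variance in weights: no high-weight features")
    return(stats::setNames(rep(FALSE, length(weights)), names(weights)))
  }
  abs(weights - mean(weights)) > 2 * s
}

#' Cross-niche overlap of high-weight feature sets
#'
#' For every non-empty subset of niches, counts the features exclusive to
#' exactly that subset (present in every niche of the subset and in no
#' other), as a count and as a percentage of the union of all sets. The
#' percentages sum to 100.
#'
#' @param feature_sets Named list (one element per niche) of character
#'   vectors of high-weight feature ids.
#' @return Data frame with columns `niches` (`+`-joined subset), `n_niches`,
#'   `count` and `percent`, one row per non-empty subset of niches (empty
#'   subsets included with count 0 for completeness of the partition table).
#' @export
niche_overlap <- function(feature_sets) {
  stopifnot(is.list(feature_sets), length(feature_sets) >= 2L,
            !is.null(names(feature_sets)))
  niches <- names(feature_sets)
  all_features <- sort(unique(unlist(feature_sets)))
  membership <- vapply(feature_sets,
                       function(s) all_features %in% s,
                       logical(length(all_features)))
  if (length(all_features) == 1L)
    membership <- matrix(membership, nrow = 1L,
                         dimnames = list(all_features, niches))
  pattern <- apply(membership, 1L, function(r) paste(niches[r], collapse = "+"))
  subsets <- unlist(lapply(seq_along(niches), function(k) {
    combn(niches, k, paste, collapse = "+", simplify = FALSE)
  }))
  counts <- vapply(subsets, function(s) sum(pattern == s), integer(1))
  total <- length(all_features)
  data.frame(
    niches = unlist(subsets),
    n_niches = vapply(strsplit(unlist(subsets), "+", fixed = TRUE),
                      length, integer(1)),
    count = counts,
    percent = if (total > 0) 100 * counts / total else rep(0, length(counts)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Hierarchical-clustering baseline of function profiles
#'
#' Agglomerative clustering of genomes on their feature rows — the classic
#' community-ecology workflow of a Bray-Curtis dissimilarity with
#' group-average (UPGMA) linkage by default. Used as the baseline showing
#' whether raw profiles alone group genomes by niche.
#'
#' @param x Genomes-by-features numeric matrix.
#' @param distance Dissimilarity index, any method of [vegan::vegdist()]
#'   (default `"bray"`), or `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param labels Optional character vector of niche annotations, pasted onto
#'   the leaf labels for visual comparison.
#' @return An `hclust` object over genomes.
#' @export
cluster_profiles <- function(x, distance = "bray", linkage = "average",
                             labels = NULL) {
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  d <- vegan::vegdist(x, method = distance)
  hc <- hclust(d, method = linkage)
  if (!is.null(labels))
    hc$labels <- paste(rownames(x), labels, sep = " | ")
  hc
}
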