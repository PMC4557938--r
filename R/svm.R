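#' One-vs-rest linear SVM niche classifier with leave-one-out validation
#'
#' Fits the niche-prediction model: for each ecological niche an independent
#' binary linear SVM (niche vs non-niche) is trained and validated
#' leave-one-out — each genome is held out once, the model is trained on the
#' remaining genomes with the soft-margin cost parameter selected by an
#' internal stratified 10-fold cross-validation over `cost_grid` (ties going
#' to the smallest cost), and the held-out genome's predicted class and
#' signed distance to the separating hyperplane are recorded. Each held-out
#' prediction receives the normal-theory confidence of
#' [prediction_confidence()], with confidence >= 0.95 flagged significant.
#' Per niche, the leave-one-out confusion counts give the F-score; a final
#' model refit on all genomes supplies the canonical feature-weight vector
#' from which high-weight features are flagged ([high_weight_features()]).
#'
#' Features are filtered once over all genomes before training
#' ([filter_features()]), the conventional single-pass approach; set
#' `filter_per_fold = TRUE` to refit the filter inside every leave-one-out
#' round instead, so the held-out genome can never influence feature
#' selection (the leakage-free mode used by the package's own recovery
#' tests).
#'
#' @param features Genomes-by-features numeric matrix (counts or scores).
#' @param labels Genomes-by-niches logical (or 0/1) matrix of non-exclusive
#'   niche memberships; row names must match `features`.
#' @param niches Niches to fit (default: all columns of `labels`). A niche
#'   with fewer than 2 positive or 2 negative genomes is skipped with a
#'   warning.
#' @param cost_grid Soft-margin cost grid for the internal cross-validation
#'   (default `c(0.01, 0.1, 1, 10, 100)`).
#' @param n_folds Folds of the internal cross-validation (default 10).
#' @param seed Integer seed governing the internal fold assignments (recorded
#'   in the fit).
#' @param filter Apply [filter_features()] before training (default `TRUE`).
#' @param min_nonzero_fraction,min_sd Filter thresholds.
#' @param filter_per_fold Refit the feature filter within each leave-one-out
#'   round (default `FALSE`).
#' @param confidence_mode Passed to [prediction_confidence()].
#' @param balanced Weight classes inversely to their frequency (default
#'   `FALSE`).
#' @param feature_type Optional tag naming the feature source (e.g.
#'   `"transportome"`), carried into reports.
#' @return An object of class `niche_svm` with components `niches` (per-niche
#'   fits: `predictions` data frame, `f_score`, `cost`, `weights`,
#'   `high_weight`, `fold_costs`, `model`), `feature_ids`, `feature_type`,
#'   `seed` and the call. Methods: [print()], [summary()], [coef()],
#'   [predict()], [plot()].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 6), 40, 6,
#'             dimnames = list(paste0("g", 1:40), paste0("f", 1:6)))
#' y <- x[, 1] + x[, 2] > 0
#' x[, 1] <- x[, 1] + 1  # keep the nonzero-fraction filter happy
#' labs <- cbind(nicheA = y)
#' rownames(labs) <- rownames(x)
#' fit <- niche_svm(x, labs, seed = 1, min_sd = 0)
#' summary(fit)
#' @export
niche_svm <- function(features, labels, niches = colnames(labels),
                      cost_grid = c(0.01, 0.1, 1, 10, 100), n_folds = 10,
                      seed = 1, filter = TRUE, min_nonzero_fraction = 0.5,
                      min_sd = 0.2, filter_per_fold = FALSE,
                      confidence_mode = c("literal", "centered"),
                      balanced = FALSE, feature_type = NULL) {
  confidence_mode <- match.arg(confidence_mode)
  stopifnot(is.matrix(features), !is.null(rownames(features)),
            !is.null(colnames(features)))
  labels <- as.matrix(labels)
  if (is.null(rownames(labels)))
    stop("'labels' must carry genome row names")
  missing_g <- setdiff(rownames(features), rownames(labels))
  if (length(missing_g))
    stop("genome(s) absent from labels: ", paste(missing_g, collapse = ", "))
  labels <- labels[rownames(features), , drop = FALSE] > 0
  if (!all(is.finite(features))) stop("non-finite feature values")
  stopifnot(length(niches) >= 1L, all(niches %in% colnames(labels)))

  x_global <- if (filter) {
    filter_features(features, min_nonzero_fraction, min_sd)
  } else features

  fits <- with_seed(seed, {
    out <- list()
    for (niche in niches) {
      out[[niche]] <- fit_one_niche(
        features = features, x_global = x_global, y = labels[, niche],
        niche = niche, cost_grid = cost_grid, n_folds = n_folds,
        filter = filter, min_nonzero_fraction = min_nonzero_fraction,
        min_sd = min_sd, filter_per_fold = filter_per_fold,
        confidence_mode = confidence_mode, balanced = balanced)
    }
    out
  })

  structure(list(niches = fits, feature_ids = colnames(x_global),
                 feature_type = feature_type, seed = seed,
                 cost_grid = cost_grid, n_folds = n_folds,
                 filter_per_fold = filter_per_fold,
                 confidence_mode = confidence_mode,
                 n_genomes = nrow(features), call = match.call()),
            class = "niche_svm")
}

# One niche: LOOV rounds + final all-genome model.
fit_one_niche <- function(features, x_global, y, niche, cost_grid, n_folds,
                          filter, min_nonzero_fraction, min_sd,
                          filter_per_fold, confidence_mode, balanced) {
  n <- nrow(features)
  if (sum(y) < 2L || sum(!y) < 2L) {
    warning(sprintf("niche '%s' skipped: needs >= 2 positive and >= 2 negative genomes",
                    niche))
    return(NULL)
  }
  genomes <- rownames(features)
  pred <- dec <- conf <- rep(NA_real_, n)
  fold_costs <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) next  # degenerate round, left undefined
    if (filter_per_fold && filter) {
      xtr_full <- tryCatch(
        filter_features(features[-i, , drop = FALSE],
                        min_nonzero_fraction, min_sd),
        error = function(e) x_global[-i, , drop = FALSE])
      cols <- colnames(xtr_full)
    } else {
      cols <- colnames(x_global)
      xtr_full <- x_global[-i, , drop = FALSE]
    }
    cost <- select_cost(xtr_full, ytr, cost_grid, n_folds, balanced)
    m <- fit_linear_svm(xtr_full, ytr, cost, balanced)
    d_val <- svm_decision(m, features[i, cols, drop = FALSE])
    d_tr_pos <- svm_decision(m, xtr_full[ytr, , drop = FALSE])
    dec[i] <- d_val
    pred[i] <- as.numeric(d_val > 0)
    fold_costs[i] <- cost
    conf[i] <- tryCatch(
      prediction_confidence(d_val, d_tr_pos, mode = confidence_mode),
      error = function(e) NA_real_)
  }

  ok <- !is.na(pred)
  tp <- sum(ok & pred == 1 & y)
  fp <- sum(ok & pred == 1 & !y)
  fn <- sum(ok & pred == 0 & y)
  f <- tryCatch(f_score(tp, fp, fn), warning = function(w) NA_real_)

  final_cost <- select_cost(x_global, y, cost_grid, n_folds, balanced)
  final <- fit_linear_svm(x_global, y, final_cost, balanced)
  w <- svm_weights(final, x_global)
  hw <- tryCatch(high_weight_features(w),
                 warning = function(w_) {
                   stats::setNames(rep(FALSE, length(w)), names(w))
                 })

  list(
    predictions = data.frame(
      genome = genomes, actual = y, predicted = pred == 1,
      decision = dec, confidence = conf,
      significant = !is.na(conf) & conf >= 0.95,
      stringsAsFactors = FALSE, row.names = NULL),
    tp = tp, fp = fp, fn = fn, f_score = f,
    cost = final_cost, fold_costs = fold_costs,
    weights = w, high_weight = hw, model = final,
    train_pos_decisions = svm_decision(final, x_global[y, , drop = FALSE]),
    n_features = length(w)
  )
}

# Linear SVM with the positive class as reference level; no internal scaling
# so weights live in the feature units.
fit_linear_svm <- function(x, y, cost, balanced = FALSE) {
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("pos", "neg"))
  cw <- if (balanced) {
    tab <- table(yf)
    stats::setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
  } else NULL
  m <- e1071::svm(x = x, y = yf, kernel = "linear", cost = cost,
                  scale = FALSE, class.weights = cw)
  # orient decision values so positives sit on the positive side
  d <- raw_decision(m, x)
  sgn <- sign(mean(d[y]) - mean(d[!y]))
  if (sgn == 0) sgn <- 1
  m$nichecast_sign <- sgn
  m
}

raw_decision <- function(model, x) {
  p <- predict(model, x, decision.values = TRUE)
  as.numeric(attr(p, "decision.values"))
}

svm_decision <- function(model, x) {
  model$nichecast_sign * raw_decision(model, x)
}

# Hyperplane weight vector of a linear e1071 SVM, oriented like the decisions.
svm_weights <- function(model, x) {
  w <- as.numeric(crossprod(model$coefs, model$SV)) * model$nichecast_sign
  stats::setNames(w, colnames(x))
}

# Internal stratified k-fold cross-validation over the cost grid.
# Returns the smallest cost attaining the best mean accuracy.
select_cost <- function(x, y, cost_grid, n_folds, balanced) {
  if (length(cost_grid) == 1L) return(cost_grid)
  n <- length(y)
  k <- min(n_folds, n)
  fold <- integer(n)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]  # length-1 safe, unlike sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  acc <- vapply(cost_grid, function(cost) {
    correct <- 0L; total <- 0L
    for (f in seq_len(k)) {
      te <- which(fold == f)
      tr <- which(fold != f)
      if (length(te) == 0L || length(unique(y[tr])) < 2L) next
      m <- fit_linear_svm(x[tr, , drop = FALSE], y[tr], cost, balanced)
      d <- svm_decision(m, x[te, , drop = FALSE])
      correct <- correct + sum((d > 0) == y[te])
      total <- total + length(te)
    }
    if (total == 0L) return(NA_real_)
    correct / total
  }, numeric(1))
  if (all(is.na(acc))) return(cost_grid[1L])
  cost_grid[which.max(acc)]  # which.max takes the first (smallest) on ties
}

#' @export
print.niche_svm <- function(x, ...) {
  cat("One-vs-rest linear SVM niche classifier (leave-one-out validated)\n")
  if (!is.null(x$feature_type))
    cat(sprintf("Feature type: %s\n", x$feature_type))
  cat(sprintf("%d genome(s), %d feature(s) after filtering; seed %d\n",
              x$n_genomes, length(x$feature_ids), x$seed))
  print(summary(x))
  invisible(x)
}

#' @export
summary.niche_svm <- function(object, ...) {
  rows <- lapply(names(object$niches), function(nm) {
    f <- object$niches[[nm]]
    if (is.null(f))
      return(data.frame(niche = nm, n_pos = NA_integer_, f_score = NA_real_,
                        cost = NA_real_, n_high_weight = NA_integer_,
                        n_significant = NA_integer_))
    data.frame(
      niche = nm, n_pos = sum(f$predictions$actual),
      f_score = f$f_score, cost = f$cost,
      n_high_weight = sum(f$high_weight),
      n_significant = sum(f$predictions$significant, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' @export
coef.niche_svm <- function(object, ...) {
  fitted_niches <- Filter(Negate(is.null), object$niches)
  if (length(fitted_niches) == 0L) return(NULL)
  sapply(fitted_niches, function(f) f$weights)
}

#' Predict niche membership for new genomes
#'
#' Applies each niche's final all-genome model to new feature rows.
#'
#' @param object A [niche_svm()] fit.
#' @param newdata Genomes-by-features matrix containing at least the fit's
#'   feature columns.
#' @param ... Unused.
#' @return List with matrices `class` (logical), `decision` and `confidence`
#'   (genomes x niches).
#' @export
predict.niche_svm <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  missing_f <- setdiff(object$feature_ids, colnames(newdata))
  if (length(missing_f))
    stop("newdata lacks feature(s): ", paste(missing_f, collapse = ", "))
  fitted_niches <- Filter(Negate(is.null), object$niches)
  x <- newdata[, object$feature_ids, drop = FALSE]
  dec <- sapply(fitted_niches, function(f) svm_decision(f$model, x))
  if (is.null(dim(dec)))
    dec <- matrix(dec, nrow = nrow(x),
                  dimnames = list(rownames(x), names(fitted_niches)))
  conf <- dec
  # confidence against each final model's positive training distances
  for (nm in names(fitted_niches)) {
    f <- fitted_niches[[nm]]
    conf[, nm] <- vapply(dec[, nm], function(d) {
      tryCatch(prediction_confidence(d, f$train_pos_decisions,
                                     mode = object$confidence_mode),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  rownames(dec) <- rownames(x)
  list(class = dec > 0, decision = dec, confidence = conf)
}

#' @export
plot.niche_svm <- function(x, ...) {
  s <- summary(x)
  graphics::barplot(s$f_score, names.arg = s$niche, ylim = c(0, 1),
                    ylab = "LOOV F-score",
                    main = x$feature_type %||% "niche_svm", ...)
  invisible(x)
}
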