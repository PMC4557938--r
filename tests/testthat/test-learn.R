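test_that("the feature filter applies both rules with strict inequalities", {
  x <- cbind(
    const = rep(5, 4),            # nonzero everywhere but SD 0
    half = c(1, 2, 0, 0),         # nonzero in exactly half: removed
    good = c(0, 1, 3, 2),         # nonzero in 3/4 and SD > 0.2
    tiny = c(1, 1.1, 1, 1.1)      # SD ~ 0.058 <= 0.2
  )
  rownames(x) <- paste0("g", 1:4)
  kept <- filter_features(x)
  expect_equal(colnames(kept), "good")

  expect_error(filter_features(x[, "const", drop = FALSE]),
               "no features survive")
})

test_that("the feature filter matches an independent two-pass oracle", {
  set.seed(44)
  for (rep in 1:5) {
    x <- matrix(rnbinom(20 * 50, mu = 1, size = 1) * runif(20 * 50), 20, 50,
                dimnames = list(paste0("g", 1:20), paste0("f", 1:50)))
    keep <- logical(50)
    for (j in 1:50) {
      keep[j] <- sum(x[, j] != 0) > 0.5 * 20 && sd(x[, j]) > 0.2
    }
    if (!any(keep)) next
    expect_equal(colnames(filter_features(x)), colnames(x)[keep])
  }
})

test_that("F-scores combine precision and recall with the zero convention", {
  expect_equal(f_score(5, 0, 0), 1)
  expect_equal(f_score(2, 1, 1), 2 / 3)
  expect_equal(f_score(0, 3, 2), 0)
  expect_warning(expect_true(is.na(f_score(0, 0, 2))), "undefined")
  expect_warning(expect_true(is.na(f_score(0, 3, 0))), "undefined")

  # symmetric in fp and fn for fixed tp; matches the direct formula
  set.seed(46)
  for (rep in 1:100) {
    tp <- sample(0:10, 1); fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    if (tp + fp == 0 || tp + fn == 0) next
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    direct <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    expect_equal(f_score(tp, fp, fn), direct)
    expect_equal(f_score(tp, fp, fn), f_score(tp, fn, fp))
  }
})

test_that("prediction confidence follows the folded normal-CDF form", {
  pos <- c(1, 2, 3)
  s <- sd(abs(pos))
  expect_equal(prediction_confidence(0, pos), 1)
  expect_equal(prediction_confidence(s, pos), 0.658655, tolerance = 1e-4)
  # the 95% significance rule sits at z = qnorm(0.55)
  z95 <- qnorm(0.55)
  expect_equal(prediction_confidence(z95 * s, pos), 0.95, tolerance = 1e-10)
  expect_equal(z95, 0.12566, tolerance = 1e-4)

  expect_error(prediction_confidence(1, c(2, 2, 2)), "zero variance")
  expect_error(prediction_confidence(1, 1), ".")

  # against numerical integration of the standard normal density
  set.seed(48)
  for (rep in 1:100) {
    d <- rnorm(1, sd = 3)
    pos <- rnorm(sample(2:10, 1), mean = 2)
    z <- abs(d) / sd(abs(pos))
    byint <- 1 - integrate(dnorm, 0, z)$value
    expect_equal(prediction_confidence(d, pos), byint, tolerance = 1e-8)
  }

  # strictly decreasing in |decision|, bounded in (0.5, 1]
  zz <- seq(0, 5, by = 0.25)
  cc <- vapply(zz, prediction_confidence, numeric(1),
               training_positive_distances = c(1, 2, 3))
  expect_true(all(diff(cc) < 0))
  expect_true(all(cc > 0.5 & cc <= 1))

  # centered mode peaks at the positive training mean
  expect_equal(prediction_confidence(2, c(1, 2, 3), mode = "centered"), 1)
})

test_that("high-weight features lie beyond two standard deviations", {
  expect_warning(flags <- high_weight_features(rep(1, 5)), "zero variance")
  expect_false(any(flags))

  w <- c(rep(1, 9), 11)
  expect_equal(which(high_weight_features(w)), 10L)

  set.seed(50)
  for (rep in 1:100) {
    w <- rnorm(sample(3:40, 1), sd = runif(1, 0.1, 4))
    oracle <- abs(w - mean(w)) > 2 * sd(w)
    expect_equal(unname(high_weight_features(w)), oracle)
  }
})

test_that("niche overlap partitions the feature union", {
  ov <- niche_overlap(list(a = "f1", b = "f2"))
  expect_equal(ov$count[ov$niches == "a"], 1L)
  expect_equal(ov$count[ov$niches == "a+b"], 0L)
  expect_equal(ov$percent[ov$niches == "a"], 50)

  same <- niche_overlap(list(a = c("f1", "f2"), b = c("f1", "f2")))
  expect_equal(same$percent[same$niches == "a+b"], 100)

  set.seed(52)
  for (rep in 1:5) {
    sets <- lapply(1:4, function(i) {
      sample(paste0("f", 1:30), sample(3:15, 1))
    })
    names(sets) <- paste0("n", 1:4)
    ov <- niche_overlap(sets)
    expect_equal(sum(ov$percent), 100)
    # brute-force membership-pattern tally
    uni <- sort(unique(unlist(sets)))
    pat <- vapply(uni, function(f) {
      paste(names(sets)[vapply(sets, function(s) f %in% s, logical(1))],
            collapse = "+")
    }, character(1))
    for (i in seq_len(nrow(ov))) {
      expect_equal(ov$count[i], sum(pat == ov$niches[i]))
    }
  }
})

test_that("profile clustering merges identical rows first and matches a naive
           average-linkage oracle", {
  x <- rbind(g1 = c(1, 2, 3, 1), g2 = c(1, 2, 3, 1), g3 = c(9, 0, 1, 4))
  hc <- cluster_profiles(x)
  expect_equal(hc$height[1], 0)
  expect_setequal(-hc$merge[1, ], which(rownames(x) %in% c("g1", "g2")))

  # naive O(n^3) UPGMA oracle on the same dissimilarity
  set.seed(54)
  y <- matrix(rpois(24, 4), 6, 4,
              dimnames = list(paste0("g", 1:6), paste0("f", 1:4)))
  d <- as.matrix(vegan::vegdist(y, method = "bray"))
  clusters <- as.list(1:6)
  heights <- numeric(0)
  members <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(j, i) }
    }
    heights <- c(heights, bestd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    members <- c(members, list(sort(merged)))
    clusters <- c(clusters[-best], list(merged))
  }
  hc2 <- cluster_profiles(y)
  expect_equal(hc2$height, heights)
  for (k in seq_along(members)) {
    got <- merge_members(hc2, k)
    expect_equal(got, members[[k]])
  }
})
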