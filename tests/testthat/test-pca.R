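test_that("profile normalization scales every gene to mean 1", {
  m <- rbind(flat = rep(3, 7), burst = c(2, rep(0, 6)), dead = rep(0, 7))
  colnames(m) <- paste0("s", 1:7)
  norm <- make_norm(m, times = c(-15, -10, -5, 5, 10, 40, 80))
  expect_message(pr <- profile_normalize(norm), "zero-mean")
  expect_equal(unname(pr["flat", ]), rep(1, 7))
  expect_equal(unname(pr["burst", ]), c(7, rep(0, 6)))
  expect_identical(attr(pr, "dropped"), "dead")
  expect_equal(unname(rowMeans(pr)), rep(1, 2))

  # outlier samples excluded by default; explicit inclusion respected
  norm2 <- make_norm(m[1:2, , drop = FALSE],
                     times = c(-15, -10, -5, 5, 10, 40, 80),
                     is_outlier = c(rep(FALSE, 4), TRUE, rep(FALSE, 2)))
  pr2 <- profile_normalize(norm2)
  expect_identical(ncol(pr2), 6L)
  pr3 <- profile_normalize(norm2, include_samples = paste0("s", 1:7))
  expect_identical(ncol(pr3), 7L)
  expect_error(profile_normalize(norm, include_samples = "s1"), "2 included")
  expect_error(profile_normalize(norm, include_samples = c("s1", "zz")),
               "unknown")
})

test_that("a single planted profile gives one component explaining all variance", {
  set.seed(11)
  times <- c(-15, -10, -5, 5, 10, 40, 80)
  step <- ifelse(times > 0, 1, 0)
  amp <- runif(40, -2, 2)
  m <- 1 + outer(amp, step)            # rows a +/- b * step, no noise
  m <- m / rowMeans(m)
  rownames(m) <- sprintf("g%02d", 1:40); colnames(m) <- paste0("s", 1:7)
  norm <- make_norm(m, times = times)
  res <- run_pca(profile_normalize(norm))
  expect_equal(res$explained_fraction[1], 1)
  expect_equal(sum(res$explained_fraction), 1)
  cstep <- step - mean(step)
  expect_gt(abs(cor(res$vectors[, 1], cstep)), 1 - 1e-9)
  # sign convention: high PC1 = up in starvation
  ss <- times <= 0
  expect_gt(res$vectors[length(times), 1] - mean(res$vectors[ss, 1]), 0)
})

test_that("two orthogonal planted profiles match an eigen-decomposition oracle", {
  set.seed(12)
  times <- c(-15, -10, -5, 5, 10, 40, 80)
  u <- ifelse(times > 0, 1, 0); u <- u - mean(u)
  v <- c(0, 0, 0, 1, -1, 0, 0); v <- v - mean(v)   # orthogonal to u
  expect_equal(sum(u * v), 0)
  a <- rnorm(120, 0, 1); b <- rnorm(120, 0, 0.3)
  m <- 1 + outer(a, u) + outer(b, v)
  rownames(m) <- sprintf("g%03d", 1:120); colnames(m) <- paste0("s", 1:7)
  norm <- make_norm(m / rowMeans(m), times = times)
  pr <- profile_normalize(norm)
  res <- run_pca(pr)

  # independent oracle: eigen() on the column covariance matrix
  mc <- scale(unclass(pr), center = TRUE, scale = FALSE)
  attr(mc, "scaled:center") <- NULL
  ev <- eigen(stats::cov(mc), symmetric = TRUE)
  expect_equal(res$explained_fraction,
               unname(ev$values / sum(ev$values)), tolerance = 1e-9)
  for (j in 1:2)
    expect_gt(abs(cor(res$vectors[, j], ev$vectors[, j])), 1 - 1e-9)
  # amplitude order: larger-amplitude profile first
  expect_gt(abs(cor(res$vectors[, 1], u)), 0.999)
  expect_gt(abs(cor(res$vectors[, 2], v)), 0.999)

  # permuting gene order changes nothing
  perm <- sample(nrow(m))
  norm_p <- make_norm((m / rowMeans(m))[perm, ], times = times)
  res_p <- run_pca(profile_normalize(norm_p))
  expect_equal(res_p$explained_fraction, res$explained_fraction)
  expect_equal(res_p$scores[rownames(res$scores), ], res$scores)

  # reconstruction: scores x t(vectors) + center restores the matrix
  rec <- res$scores %*% t(res$vectors)
  rec <- sweep(rec, 2, res$center, "+")
  m0 <- unclass(pr)
  attributes(m0) <- attributes(m0)[c("dim", "dimnames")]
  expect_equal(unname(rec), unname(m0), tolerance = 1e-9)
})

test_that("extreme-score selection counts and breaks ties deterministically", {
  scores <- matrix(c(10:1), 10, 1,
                   dimnames = list(sprintf("g%02d", 1:10), "PC1"))
  res <- structure(list(scores = scores, explained_fraction = 1),
                   class = "pca_result")
  ex <- select_extremes(res, 1, 0.1)
  expect_identical(ex$top, "g01")
  expect_identical(ex$bottom, "g10")
  halves <- select_extremes(res, 1, 0.5)
  expect_identical(length(halves$top), 5L)
  expect_identical(length(intersect(halves$top, halves$bottom)), 0L)

  tied <- matrix(c(5, 5, 5, 1, 1, 1), 6, 1,
                 dimnames = list(c("b", "a", "c", "z", "y", "x"), "PC1"))
  res_t <- structure(list(scores = tied, explained_fraction = 1),
                     class = "pca_result")
  ex_t <- select_extremes(res_t, 1, 1 / 3)
  expect_identical(ex_t$top, c("a", "b"))
  expect_identical(ex_t$bottom, c("x", "y"))
  expect_error(select_extremes(res, 2, 0.1), "component")
  expect_error(select_extremes(res, 1, 0.7), "fraction")
})

test_that("Fisher enrichment agrees with hypergeometric hand computation", {
  universe <- sprintf("g%02d", 1:20)
  set_half <- universe[1:10]
  subset <- universe[1:10]          # subset equals the set exactly
  et <- enrich(subset, list(half = set_half), universe)
  # oracle: tail of the hypergeometric by direct binomial-coefficient sums
  p_hand <- sum(choose(10, 10) * choose(10, 0) / choose(20, 10))
  expect_equal(et$p_value, p_hand, tolerance = 1e-12)
  expect_identical(et$overlap, 10L)

  # disjoint set smaller than universe - subset: one-sided p = 1
  et2 <- enrich(universe[1:5], list(disj = universe[11:14]), universe)
  expect_equal(et2$p_value, 1)
  # single tested set: BH leaves p unchanged
  expect_equal(et2$p_adjust, et2$p_value)

  # cross-check a composite case against fisher.test
  subset3 <- universe[1:8]
  set3 <- universe[c(1:4, 9:12)]
  et3 <- enrich(subset3, list(s = set3), universe)
  ft <- fisher.test(matrix(c(4, 4, 4, 8), 2), alternative = "greater")
  expect_equal(et3$p_value, ft$p.value, tolerance = 1e-9)
  expect_error(enrich(subset3, list(s = set3), character(0)), "universe")
  expect_error(enrich("zz", list(s = set3), universe), "outside")
})

test_that("BH adjustment is monotone and matches the step-up rule", {
  set.seed(9)
  for (rep in 1:5) {
    p <- runif(17)^2
    sets <- setNames(as.list(sprintf("g%d", seq_along(p))),
                     sprintf("set%02d", seq_along(p)))
    # brute-force step-up: q_i = min_{j >= i} m p_(j) / j, capped at 1
    m <- length(p)
    o <- order(p)
    q2 <- numeric(m)
    for (i in seq_len(m))
      q2[o[i]] <- min(1, min(vapply(i:m, function(j) m * p[o[j]] / j,
                                    numeric(1))))
    expect_equal(stats::p.adjust(p, "BH"), q2)
    expect_true(all(q2 >= p - 1e-12))
    expect_true(all(diff(q2[o]) >= 0))
  }
})

test_that("steady-replicate spread is reported per component", {
  set.seed(4)
  times <- c(-15, -10, -5, 5, 10, 40, 80)
  step <- ifelse(times > 0, 1, 0)
  m <- 1 + outer(rnorm(60), step) + matrix(rnorm(60 * 7, 0, 0.05), 60)
  rownames(m) <- sprintf("g%02d", 1:60); colnames(m) <- paste0("s", 1:7)
  norm <- make_norm(m / rowMeans(m), times = times)
  res <- run_pca(profile_normalize(norm))
  expect_identical(length(res$steady_spread),
                   length(res$explained_fraction))
  # the planted component is flat across steady replicates
  expect_lt(res$steady_spread[1], 0.5)
})
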