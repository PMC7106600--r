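test_that("OQ scoring reverses items 13/24/31 and passes item 8 through", {
  expect_equal(score_oq(c(oq_3 = 0, oq_13 = 4, oq_24 = 4, oq_31 = 4, oq_8 = 0)),
               list(oq_mean = 0, oq8 = 0L))
  expect_equal(score_oq(c(oq_3 = 4, oq_13 = 0, oq_24 = 0, oq_31 = 0, oq_8 = 4)),
               list(oq_mean = 4, oq8 = 4L))
  # hand-applied reversal: 3->2, 13: 4-1=3, 24: 4-3=1, 31: 4-4=0
  got <- score_oq(c(oq_3 = 2, oq_13 = 1, oq_24 = 3, oq_31 = 4, oq_8 = 1))
  expect_equal(got$oq_mean, (2 + 3 + 1 + 0) / 4)
  expect_equal(got$oq8, 1L)
  expect_error(score_oq(c(oq_3 = 2, oq_13 = 1, oq_24 = 3, oq_31 = 5, oq_8 = 1)),
               class = "pvq_scoring_error")
  expect_error(score_oq(c(oq_3 = 2, oq_13 = 1, oq_24 = 3, oq_8 = 1)),
               regexp = "oq_31")
})

test_that("RFL scoring excludes item 25 from the mean, no reversals", {
  ids <- c(2, 5, 10, 12, 14, 17, 19, 20, 22, 24, 25, 40, 45, 50)
  all6 <- stats::setNames(rep(6, 14), paste0("rfl_", ids))
  expect_equal(score_rfl(all6), list(rfl_mean = 6, rfl25 = 6L))
  all1 <- stats::setNames(rep(1, 14), paste0("rfl_", ids))
  expect_equal(score_rfl(all1), list(rfl_mean = 1, rfl25 = 1L))
  vals <- stats::setNames(c(2, 3, 4, 5, 6, 1, 2, 3, 4, 5, 5, 6, 1, 2),
                          paste0("rfl_", ids))
  got <- score_rfl(vals)
  expect_equal(got$rfl_mean, 44 / 13)  # independent hand sum over the 13
  expect_equal(got$rfl25, 5L)
})

test_that("composite scoring is permutation-invariant and monotone", {
  set.seed(21)
  oq <- c(oq_3 = 2, oq_8 = 1, oq_13 = 3, oq_24 = 0, oq_31 = 2)
  expect_equal(score_oq(oq), score_oq(sample(oq)))
  # raising a reversed item's answer lowers the distress mean
  oq2 <- oq; oq2[["oq_13"]] <- 4
  expect_lt(score_oq(oq2)$oq_mean, score_oq(oq)$oq_mean)
  oq3 <- oq; oq3[["oq_3"]] <- 4
  expect_gt(score_oq(oq3)$oq_mean, score_oq(oq)$oq_mean)
})

test_that("DEQ PCA matches an independent eigendecomposition oracle", {
  set.seed(31)
  X <- matrix(sample(1:7, 20 * 6, TRUE), 20, 6,
              dimnames = list(NULL, paste0("deq_", c(3, 16, 19, 48, 56, 62))))
  m <- fit_deq_pca(X)
  # oracle: prcomp on standardized columns
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  for (c in 1:2) {
    v_or <- pr$rotation[, c]
    v_got <- m$loadings[, c]
    expect_lt(min(max(abs(v_got - v_or)), max(abs(v_got + v_or))), 1e-8)
  }
  expect_equal(m$variance_proportions, pr$sdev^2 / 6, tolerance = 1e-10)
})

test_that("DEQ PCA model satisfies its invariants on random data", {
  set.seed(32)
  for (rep in 1:20) {
    n <- sample(8:60, 1)
    X <- matrix(sample(1:7, n * 6, TRUE), n, 6,
                dimnames = list(NULL, paste0("deq_", c(3, 16, 19, 48, 56, 62))))
    if (any(apply(X, 2, stats::sd) == 0)) next
    m <- fit_deq_pca(X)
    expect_equal(colSums(m$loadings^2), c(PC1 = 1, PC2 = 1), tolerance = 1e-9)
    expect_lt(abs(sum(m$loadings[, 1] * m$loadings[, 2])), 1e-10)
    expect_true(all(diff(m$variance_proportions) <= 1e-12))
    expect_true(all(m$variance_proportions > -1e-12 &
                      m$variance_proportions <= 1 + 1e-12))
    expect_gte(m$loadings["deq_19", 1], 0)
    expect_gte(m$loadings["deq_19", 2], 0)
  }
})

test_that("DEQ PCA handles isotropic and rank-2 structure as expected", {
  set.seed(33)
  # isotropy: six independent columns
  X <- matrix(rnorm(1e5 * 6), ncol = 6,
              dimnames = list(NULL, paste0("deq_", c(3, 16, 19, 48, 56, 62))))
  m <- fit_deq_pca(X)
  expect_true(all(abs(m$variance_proportions - 1 / 6) < 0.01))
  # rank 2: two blocks of three perfectly correlated columns
  x <- rnorm(50); y <- rnorm(50)
  X2 <- cbind(x, x, x, y, y, y)
  colnames(X2) <- paste0("deq_", c(3, 16, 19, 48, 56, 62))
  m2 <- fit_deq_pca(X2)
  expect_equal(sum(m2$variance_proportions[1:2]), 1, tolerance = 1e-9)
  # degenerate inputs
  X3 <- X2; X3[, 2] <- 4
  expect_error(fit_deq_pca(X3), class = "pvq_degenerate_error")
  expect_error(fit_deq_pca(X2[1:5, ]), class = "pvq_sample_size_error")
})

test_that("projection is centered, variance-preserving and linear", {
  set.seed(34)
  X <- matrix(sample(1:7, 200 * 6, TRUE), 200, 6,
              dimnames = list(NULL, paste0("deq_", c(3, 16, 19, 48, 56, 62))))
  m <- fit_deq_pca(X)
  at_means <- project_deq(m, m$means)
  expect_equal(c(at_means$pc1_score, at_means$pc2_score), c(0, 0),
               tolerance = 1e-12)
  sc <- project_deq(m, X)
  expect_equal(stats::var(sc$pc1_score), m$variance_proportions[1] * 6,
               tolerance = 1e-8)
  expect_equal(stats::var(sc$pc2_score), m$variance_proportions[2] * 6,
               tolerance = 1e-8)
  # +1 sd on item 19 shifts each score by its (non-negative) loading
  base <- m$means
  bumped <- base; bumped[["deq_19"]] <- bumped[["deq_19"]] + m$sds[["deq_19"]]
  shift <- project_deq(m, bumped)
  expect_equal(shift$pc1_score, unname(m$loadings["deq_19", 1]), tolerance = 1e-12)
  expect_equal(shift$pc2_score, unname(m$loadings["deq_19", 2]), tolerance = 1e-12)
  expect_gte(shift$pc1_score, 0)
  expect_gte(shift$pc2_score, 0)
})

test_that("quadrant coding partitions the plane with the boundary on high", {
  expect_equal(assign_quadrant(-0.5, 1.2), "01")
  expect_equal(assign_quadrant(0, 0), "11")
  expect_equal(assign_quadrant(1.3, -2), "10")
  expect_equal(assign_quadrant(-1, -1), "00")
  set.seed(35)
  x <- rnorm(300); y <- rnorm(300)
  q <- assign_quadrant(x, y)
  expect_true(all(q %in% c("00", "01", "10", "11")))
  expect_equal(length(q), 300L)
  # centered symmetric scores split evenly
  xs <- rnorm(1e5); ys <- rnorm(1e5)
  shares <- table(assign_quadrant(xs, ys)) / 1e5
  expect_true(all(abs(shares - 0.25) < 0.01))
  expect_error(assign_quadrant(NaN, 0), class = "pvq_scoring_error")
})

test_that("quantile discretizer bins evenly, clamps, and is monotone", {
  d <- fit_discretizer(1:100, k = 4)
  lv <- apply_discretizer(d, 1:100)
  expect_equal(as.integer(table(lv)), c(25L, 25L, 25L, 25L))
  expect_equal(apply_discretizer(d, -10), 1L)
  expect_equal(apply_discretizer(d, 1e6), 4L)
  set.seed(36)
  x <- rnorm(500)
  d3 <- fit_discretizer(x, k = 3)
  lv3 <- apply_discretizer(d3, x)
  # rank-based oracle: counts deviate from n/3 by at most the ties at edges
  expect_true(all(abs(as.integer(table(lv3)) - 500 / 3) <= 2))
  a <- sort(stats::runif(50, -3, 3))
  expect_true(all(diff(apply_discretizer(d3, a)) >= 0))
  expect_error(fit_discretizer(c(1, 1, 1, 2), k = 3),
               class = "pvq_degenerate_error")
  expect_error(fit_discretizer(1:10, k = 1), class = "pvq_degenerate_error")
})

test_that("feature table construction is deterministic and internally consistent", {
  co <- random_cohort(40, seed = 41)
  tr <- fit_feature_transforms(co)
  ft1 <- build_feature_table(co, tr)
  ft2 <- build_feature_table(co, tr)
  expect_identical(ft1, ft2)
  expect_equal(nrow(ft1), 40L)
  expect_equal(ft1$deq_quadrant,
               assign_quadrant(ft1$pc1_score, ft1$pc2_score,
                               tr$quadrant_threshold))
  expect_true(all(ft1$oq_level %in% 1:3) && all(ft1$rfl_level %in% 1:3))
  expect_equal(ft1$sb_group, derive_sb_group(co$sb_status))
})

test_that("fitted transforms survive a JSON round-trip exactly", {
  co <- random_cohort(60, seed = 42)
  tr <- fit_feature_transforms(co)
  f <- withr::local_tempfile(fileext = ".json")
  transforms_to_json(tr, f)
  tr2 <- transforms_from_json(f)
  ft1 <- build_feature_table(co, tr)
  ft2 <- build_feature_table(co, tr2)
  expect_equal(as.data.frame(ft1), as.data.frame(ft2), tolerance = 1e-12)
})
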