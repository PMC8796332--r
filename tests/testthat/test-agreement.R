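# Brute-force oracle: Spearman rho as Pearson correlation of ranks.
spearman_oracle <- function(x, y) cor(rank(x), rank(y))

test_that("Spearman rho is invariant under monotone transforms", {
  set.seed(5)
  x <- rexp(20)
  expect_equal(spearman_pairwise(x, exp(x))$rho, 1)
  expect_equal(spearman_pairwise(x, -x)$rho, -1)
  expect_equal(spearman_pairwise(x, x^3 + 2)$rho, 1)
})

test_that("Spearman rho matches the rank-then-Pearson oracle and cor.test", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  res <- spearman_pairwise(x, y)
  expect_equal(res$rho, 0.8)                       # hand ranks: sum d^2 = 4
  expect_equal(res$rho, spearman_oracle(x, y))
  expect_equal(res$rho, unname(cor.test(x, y, method = "spearman")$estimate))
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(15)
    expect_equal(spearman_pairwise(a, b)$rho, spearman_oracle(a, b),
                 tolerance = 1e-12)
  }
  expect_error(spearman_pairwise(rep(1, 5), 1:5), "constant")
  expect_error(spearman_pairwise(1:2, 2:1), "3 complete pairs")
})

test_that("partial Spearman degenerates to pairwise with no controls", {
  set.seed(13)
  d <- data.frame(x = rnorm(30), y = rnorm(30), z = rnorm(30))
  p0 <- spearman_partial(d, c("x", "y"), controls = character(0))
  expect_equal(p0$rho, spearman_pairwise(d$x, d$y)$rho)
  expect_error(spearman_partial(cbind(d, x2 = d$x), c("x", "y"),
                                controls = c("z", "x2", "x")), "collinear")
})

test_that("residual and inverse-matrix partial correlations agree to 1e-10", {
  set.seed(17)
  for (i in 1:20) {
    d <- as.data.frame(matrix(rnorm(40 * 5), 40, 5))
    names(d) <- letters[1:5]
    r1 <- spearman_partial(d, c("a", "b"), method = "residual")$rho
    r2 <- spearman_partial(d, c("a", "b"), method = "inverse")$rho
    expect_equal(r1, r2, tolerance = 1e-10)
  }
})

test_that("a shared driver is explained away by partialling it out", {
  set.seed(19)
  n <- 500
  c0 <- rnorm(n)
  d <- data.frame(x = c0 + rnorm(n, 0, 0.5), y = c0 + rnorm(n, 0, 0.5), c = c0)
  expect_gt(spearman_pairwise(d$x, d$y)$rho, 0.5)
  expect_lt(abs(spearman_partial(d, c("x", "y"), controls = "c")$rho), 0.1)
})

test_that("Lin's concordance matches the moment formula", {
  expect_equal(lin_ccc(1:10, 1:10)$ccc, 1)
  expect_equal(lin_ccc(1:10, 1:10)$bias_correction, 1)
  res <- lin_ccc(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$pearson_r, 1)
  expect_equal(res$ccc, 8 / 22)
  expect_equal(res$bias_correction, 8 / 22)
  expect_true(res$poor_agreement)
  expect_error(lin_ccc(rep(2, 5), 1:5), "variance")
})

test_that("concordance is bounded by Pearson correlation", {
  set.seed(23)
  for (i in 1:25) {
    x <- rnorm(20, sample(1:10, 1), sample(1:3, 1))
    y <- 0.5 * x + rnorm(20, sample(0:5, 1))
    res <- lin_ccc(x, y)
    expect_lte(abs(res$ccc), abs(res$pearson_r) + 1e-12)
    expect_true(res$bias_correction > 0 && res$bias_correction <= 1 + 1e-12)
    expect_equal(res$ccc, res$pearson_r * res$bias_correction, tolerance = 1e-12)
    expect_true(res$ci_lower <= res$ccc && res$ccc <= res$ci_upper)
  }
})

test_that("concordance is invariant to a common positive affine map", {
  set.seed(29)
  x <- rnorm(15, 10, 2); y <- x + rnorm(15, 1, 1)
  r0 <- lin_ccc(x, y)
  r1 <- lin_ccc(3 * x + 7, 3 * y + 7)
  expect_equal(r1$ccc, r0$ccc, tolerance = 1e-12)
  # bias correction is invariant to common rescaling
  r2 <- lin_ccc(5 * x, 5 * y)
  expect_equal(r2$bias_correction, r0$bias_correction, tolerance = 1e-12)
})

test_that("population and sample moment conventions differ as expected", {
  x <- c(1, 2, 3, 5); y <- c(2, 2, 4, 7)
  pop <- lin_ccc(x, y, moments = "population")
  smp <- lin_ccc(x, y, moments = "sample")
  # shift term (xbar - ybar)^2 is weighted more under 1/n moments
  expect_false(isTRUE(all.equal(pop$ccc, smp$ccc)))
  expect_equal(pop$pearson_r, smp$pearson_r)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(31)
  d <- as.data.frame(matrix(rnorm(35 * 4), 35, 4))
  names(d) <- c("w", "x", "y", "z")
  for (m in c("pairwise", "partial")) {
    mat <- spearman_matrix(d, m)
    expect_equal(mat$rho, t(mat$rho))
    expect_equal(unname(diag(mat$rho)), rep(1, 4))
    expect_true(all(abs(mat$rho) <= 1))
  }
})

test_that("agreement by combination compares S with threshold x N", {
  set.seed(37)
  combos <- default_combos()[1:2, ]
  sc <- sanctioning_scenario(
    true_requirement_per_centre = setNames(c(15, 2), combos$combo),
    sanction_bias = 1, fill_rate = 1,
    n_centres_by_state = setNames(sample(20:200, 12), sprintf("S%02d", 1:12)))
  tab <- generate_state_table(sc, combos = combos)
  th <- data.frame(combo = combos$combo, wisn_threshold = c(15L, 2L))
  agr <- agreement_by_combo(tab, th)
  # S = threshold x N exactly, so concordance is perfect for both combos
  expect_equal(nrow(agr), 2)
  expect_equal(agr$ccc, c(1, 1))
  expect_false(any(agr$poor_agreement))
  # a biased norm degrades concordance below the 0.90 line
  sc2 <- sanctioning_scenario(
    true_requirement_per_centre = setNames(c(15, 2), combos$combo),
    sanction_bias = 0.3, fill_rate = 1,
    n_centres_by_state = sc$n_centres_by_state)
  agr2 <- agreement_by_combo(generate_state_table(sc2, combos = combos), th)
  expect_true(all(agr2$poor_agreement))
  expect_true(all(abs(agr2$ccc) <= abs(agr2$pearson_r) + 1e-12))
})
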