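# Hand-coded tie-corrected Kruskal-Wallis H for the oracle comparison.
kw_oracle <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(g) length(g) * mean(g)^2)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

test_that("identical state distributions give H = 0, p = 1", {
  d <- data.frame(state = rep(c("A", "B"), each = 3),
                  wisn_raw = rep(c(1.2, 3.4, 5.6), 2))
  kw <- kruskal_wallis_by_state(d)
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p.value, 1)
  expect_error(kruskal_wallis_by_state(data.frame(state = "A", wisn_raw = 1)),
               "two states")
})

test_that("the heterogeneity test matches a hand-coded rank statistic", {
  set.seed(31)
  d <- data.frame(state = rep(c("A", "B", "C"), each = 15),
                  wisn_raw = c(rnorm(15, 2), rnorm(15, 5), rnorm(15, 9)))
  kw <- kruskal_wallis_by_state(d)
  expect_equal(kw$statistic, kw_oracle(d$wisn_raw, d$state), tolerance = 1e-10)
  expect_lt(kw$p.value, 0.001)
  # rank statistic is invariant to replacing values by their ranks
  d2 <- d; d2$wisn_raw <- rank(d2$wisn_raw)
  expect_equal(kruskal_wallis_by_state(d2)$statistic, kw$statistic)
})

test_that("independence GEE on singleton clusters equals Poisson GLM", {
  set.seed(7)
  n <- 120
  d <- data.frame(
    facility_id = sprintf("F%03d", seq_len(n)),
    state = sample(c("A", "B", "C"), n, replace = TRUE),
    year = sample(2010:2012, n, replace = TRUE))
  mu <- exp(log(4) + 0.4 * (d$state == "B") - 0.3 * (d$state == "C"))
  d$wisn_rounded <- rpois(n, mu)
  d$wisn_raw <- d$wisn_rounded
  fit <- fit_gee(d, "rounded", "independence")
  glm_fit <- glm(wisn_rounded ~ factor(state) + factor(year), poisson, data = d)
  expect_equal(unname(fit$coefficients), unname(coef(glm_fit)), tolerance = 1e-6)
})

test_that("intercept-only marginal mean equals the sample mean", {
  set.seed(11)
  d <- data.frame(facility_id = sprintf("F%02d", 1:50), state = "A",
                  year = 2010, wisn_rounded = rpois(50, 6))
  d$wisn_raw <- d$wisn_rounded
  fit <- fit_gee(d, "rounded", "independence")
  mm <- wisnstaff:::marginal_mean(fit, "observation")
  expect_equal(mm$mean, mean(d$wisn_rounded), tolerance = 1e-8)
})

test_that("a constant outcome is fitted exactly", {
  d <- expand.grid(facility_id = sprintf("F%02d", 1:10), year = 2010:2012)
  d$state <- "A"
  d$wisn_rounded <- 7L
  d$wisn_raw <- 7
  for (s in c("independence", "exchangeable", "ar1")) {
    fit <- fit_gee(d, "rounded", s)
    expect_equal(unname(exp(fit$coefficients[1])), 7, tolerance = 1e-7)
  }
})

test_that("QIC is deterministic and its penalty is near 2p under independence", {
  d <- recovery_results(5, seed = 2)
  f1 <- fit_gee(d, "rounded", "exchangeable")
  f2 <- fit_gee(d, "rounded", "exchangeable")
  expect_identical(qic(f1), qic(f2))

  # for iid Poisson data fitted with the correct independence model the
  # QIC penalty 2 trace(Omega_I V_robust) concentrates around 2p
  set.seed(17)
  pens <- replicate(30, {
    n <- 400
    dd <- data.frame(facility_id = sprintf("F%03d", seq_len(n)), state = "A",
                     year = 2010, wisn_rounded = rpois(n, 8))
    dd$wisn_raw <- dd$wisn_rounded
    fit <- fit_gee(dd, "rounded", "independence")
    mu <- fit$fitted
    ql <- sum(ifelse(fit$y > 0, fit$y * log(mu), 0) - mu)
    qic(fit) + 2 * ql   # isolate the penalty term
  })
  expect_equal(mean(pens), 2 * 1, tolerance = 0.15)
})

test_that("QIC prefers the exchangeable structure on exchangeable data", {
  # unbalanced clusters (as real facility panels are): balanced intercept-
  # only designs make all working structures numerically equivalent, so the
  # criterion can only discriminate when cluster sizes and covariates vary
  set.seed(23)
  wins <- 0
  for (rep in 1:10) {
    n_fac <- 40; n_years <- 6
    b <- rnorm(n_fac, 0, 0.6)               # shared facility effect
    d <- expand.grid(facility_id = sprintf("F%02d", 1:n_fac),
                     year = 2010 + seq_len(n_years) - 1)
    d$state <- "A"
    d$wisn_rounded <- rpois(nrow(d), exp(log(8) + b[as.integer(factor(d$facility_id))]))
    d$wisn_raw <- d$wisn_rounded
    d <- d[runif(nrow(d)) > 0.4, ]          # thin to an unbalanced panel
    qics <- sapply(c("independence", "exchangeable", "ar1"),
                   function(s) fit_gee(d, "rounded", s)$qic)
    wins <- wins + (names(which.min(qics)) == "exchangeable")
  }
  expect_gte(wins, 6)
})

test_that("a no-effect simulation recovers the true requirement", {
  d <- recovery_results(5, seed = 4)
  th <- select_and_predict(d, fit_raw = FALSE)
  expect_equal(th$wisn_threshold, 5L)
  expect_true(th$ci_lower <= th$mean_rounded && th$mean_rounded <= th$ci_upper)
  # single-structure run selects that structure
  th1 <- select_and_predict(d, structures = "ar1", fit_raw = FALSE)
  expect_equal(th1$structure, "ar1")
})

test_that("thresholds are invariant to state and year relabeling", {
  d <- recovery_results(4, seed = 6)
  d$state <- sample(c("X", "Y", "Z"), nrow(d), replace = TRUE)
  th <- select_and_predict(d, structures = "exchangeable", fit_raw = FALSE)
  relab <- d
  relab$state <- c(X = "Q3", Y = "Q1", Z = "Q2")[relab$state]
  relab$year <- relab$year + 100
  th2 <- select_and_predict(relab, structures = "exchangeable", fit_raw = FALSE)
  expect_equal(th2$mean_rounded, th$mean_rounded, tolerance = 1e-6)
  expect_equal(th2$wisn_threshold, th$wisn_threshold)
})

test_that("equal-cell and observation weighting agree on balanced panels", {
  d <- recovery_results(6, n_fac = 24, seed = 8)   # complete 24 x 4 panel
  # split facilities evenly across two states: every state-year cell has
  # exactly 12 observations
  d$state <- ifelse(as.integer(factor(d$facility_id)) %% 2 == 0, "A", "B")
  expect_true(all(table(d$state, d$year) == 12))
  fit <- fit_gee(d, "rounded", "independence")
  m1 <- wisnstaff:::marginal_mean(fit, "equal_cell")
  m2 <- wisnstaff:::marginal_mean(fit, "observation")
  expect_equal(m1$mean, m2$mean, tolerance = 1e-8)
})

test_that("non-converged structures are skipped, not silently reported", {
  d <- recovery_results(3, seed = 10)
  expect_error(select_and_predict(d, structures = character(0)), "converged|structure")
})
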