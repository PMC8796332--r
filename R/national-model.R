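#' Kruskal-Wallis test of across-state heterogeneity
#'
#' Rank-based one-way test of the raw (unrounded) facility WISN values
#' across states for one centre-cadre combination, used to decide whether
#' state variability must be averaged out before producing a national
#' threshold.  Raw values are used because the WISN rounding scheme
#' saturates small counts.
#'
#' @param results retained WISN results (rows of one combo) with columns
#'   `state` and `wisn_raw`.
#' @return list with `statistic` (tie-corrected H), `df` and `p.value`.
#' @export
kruskal_wallis_by_state <- function(results) {
  states <- unique(results$state)
  if (length(states) < 2L) {
    stop("Kruskal-Wallis needs observations from at least two states", call. = FALSE)
  }
  kt <- stats::kruskal.test(results$wisn_raw, factor(results$state))
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

# Working correlation matrix for one cluster.
working_corr <- function(n, structure, alpha) {
  switch(structure,
    independence = diag(n),
    exchangeable = {
      R <- matrix(alpha, n, n); diag(R) <- 1; R
    },
    ar1 = alpha^abs(outer(seq_len(n), seq_len(n), "-"))
  )
}

#' Population-averaged Poisson regression (GEE)
#'
#' Fits the marginal log-link Poisson model
#' `log E(y) = X beta` by generalized estimating equations with a working
#' correlation structure among repeated measures of the same cluster
#' (facility), moment estimation of the correlation parameter and the
#' dispersion, and a robust (sandwich) covariance for `beta`.  Quasi-
#' likelihood estimation only uses the mean-variance relation, so
#' non-integer outcomes (e.g. raw WISN values) are admissible.
#'
#' @param y nonnegative outcome vector.
#' @param X model matrix (including intercept).
#' @param id cluster identifier (one per observation).
#' @param time ordering variable within cluster (used by `ar1`).
#' @param structure `"independence"`, `"exchangeable"` or `"ar1"`.
#' @param tol convergence tolerance on the coefficient update (default 1e-8).
#' @param maxit maximum Fisher-scoring iterations (default 100).
#' @return object of class `gee_fit`: coefficients, robust and model-based
#'   covariance, working correlation parameter `alpha`, dispersion `phi`,
#'   `qic`, convergence flag, and the data needed for prediction.
#' @export
gee_poisson <- function(y, X, id, time = seq_along(y),
                        structure = c("independence", "exchangeable", "ar1"),
                        tol = 1e-8, maxit = 100L) {
  structure <- match.arg(structure)
  stopifnot(length(y) == nrow(X), length(id) == length(y))
  if (any(y < 0)) stop("outcome must be nonnegative", call. = FALSE)
  p <- ncol(X)
  n <- length(y)
  if (length(unique(id)) < 2L) stop("need at least two clusters", call. = FALSE)

  ord <- order(id, time)
  y <- y[ord]; X <- X[ord, , drop = FALSE]; id <- id[ord]
  cl <- split(seq_len(n), as.character(id))

  # start from the independence (GLM) solution via IRLS on log link
  # quasipoisson start: same IRLS solution, no integer-outcome AIC warnings
  beta <- stats::coef(stats::glm.fit(X, y, family = stats::quasipoisson()))
  if (anyNA(beta)) stop("model matrix is rank deficient", call. = FALSE)

  alpha <- 0
  phi <- 1
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    res <- (y - mu) / sqrt(mu)                    # Pearson residuals
    phi <- sum(res^2) / (n - p)

    # moment estimators of the working correlation parameter
    if (structure == "exchangeable") {
      num <- 0; npair <- 0
      for (ix in cl) {
        if (length(ix) < 2L) next
        r <- res[ix]
        num <- num + (sum(r)^2 - sum(r^2)) / 2
        npair <- npair + choose(length(ix), 2)
      }
      alpha <- if (npair > p) num / ((npair - p) * phi) else 0
      nmax <- max(lengths(cl))
      alpha <- min(max(alpha, -1 / (nmax - 1) + 1e-6), 0.99)
    } else if (structure == "ar1") {
      num <- 0; nlag <- 0
      for (ix in cl) {
        if (length(ix) < 2L) next
        r <- res[ix]
        num <- num + sum(r[-length(r)] * r[-1])
        nlag <- nlag + length(r) - 1L
      }
      alpha <- if (nlag > p) num / ((nlag - p) * phi) else 0
      alpha <- min(max(alpha, -0.99), 0.99)
    }

    B <- matrix(0, p, p)    # bread: sum D' V^-1 D
    U <- numeric(p)         # estimating function
    M <- matrix(0, p, p)    # meat: sum D' V^-1 S V^-1 D
    for (ix in cl) {
      ni <- length(ix)
      mui <- mu[ix]
      Di <- X[ix, , drop = FALSE] * mui
      Ri <- working_corr(ni, structure, alpha)
      Vi <- phi * (sqrt(mui) %o% sqrt(mui)) * Ri
      VinvD <- solve(Vi, Di)
      ei <- y[ix] - mui
      B <- B + crossprod(Di, VinvD)
      U <- U + drop(crossprod(VinvD, ei))
      g <- drop(crossprod(VinvD, ei))
      M <- M + g %o% g
    }
    delta <- solve(B, U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }

  eta <- drop(X %*% beta); mu <- exp(eta)
  # recompute bread/meat at the solution
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ix in cl) {
    mui <- mu[ix]
    Di <- X[ix, , drop = FALSE] * mui
    Ri <- working_corr(length(ix), structure, alpha)
    Vi <- phi * (sqrt(mui) %o% sqrt(mui)) * Ri
    VinvD <- solve(Vi, Di)
    B <- B + crossprod(Di, VinvD)
    g <- drop(crossprod(VinvD, y[ix] - mui))
    M <- M + g %o% g
  }
  Binv <- solve(B)
  vcov_robust <- Binv %*% M %*% Binv
  fit <- structure(list(
    coefficients = stats::setNames(drop(beta), colnames(X)),
    vcov_robust = vcov_robust, vcov_model = Binv,
    alpha = alpha, phi = phi, structure = structure,
    converged = converged, n = n, n_clusters = length(cl),
    y = y, X = X, fitted = mu
  ), class = "gee_fit")
  fit$qic <- qic(fit)
  fit
}

#' Quasi-likelihood under the independence criterion (QIC)
#'
#' Pan's model-selection criterion for GEE:
#' `QIC = -2 Q(beta; I) + 2 trace(Omega_I V_robust)`, where `Q` is the
#' Poisson quasi-likelihood evaluated under the independence working model
#' at the fitted coefficients and `Omega_I` is the model-based information
#' under independence.  Lower is better; the penalty reduces to `2p` when
#' the working structure is adequate.
#'
#' @param fit a [gee_poisson()] fit.
#' @return scalar QIC.
#' @export
qic <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  mu <- fit$fitted
  y <- fit$y
  ql <- sum(ifelse(y > 0, y * log(mu), 0) - mu)
  # model-based information under the independence working model, phi = 1
  omega_i <- crossprod(fit$X * sqrt(mu))
  penalty <- 2 * sum(diag(omega_i %*% fit$vcov_robust))
  -2 * ql + penalty
}

# Build the design for one combo: intercept + state and year factor
# contrasts (reference = first level in sort order); terms with a single
# level are dropped.
gee_design <- function(data) {
  state <- factor(data$state)
  year <- factor(data$year)
  terms <- "1"
  if (nlevels(state) > 1L) terms <- c(terms, "state")
  if (nlevels(year) > 1L) terms <- c(terms, "year")
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(f, data.frame(state = state, year = year))
  list(X = X, state = state, year = year)
}

#' Fit the national GEE model for one combination
#'
#' @param results retained WISN results for one centre-cadre combination
#'   (columns `facility_id`, `state`, `year`, `wisn_rounded`, `wisn_raw`).
#' @param outcome `"rounded"` (count model, default) or `"raw"`.
#' @param structure working correlation structure.
#' @param ... passed to [gee_poisson()].
#' @return a `gee_fit` with the design attached.
#' @export
fit_gee <- function(results, outcome = c("rounded", "raw"),
                    structure = c("independence", "exchangeable", "ar1"), ...) {
  outcome <- match.arg(outcome)
  structure <- match.arg(structure)
  # sort once so the stored design rows align with the fit's internal order
  results <- results[order(results$facility_id, results$year), , drop = FALSE]
  y <- if (outcome == "rounded") results$wisn_rounded else results$wisn_raw
  des <- gee_design(results)
  fit <- gee_poisson(y, des$X, id = results$facility_id, time = results$year,
                     structure = structure, ...)
  fit$design <- des
  fit$outcome <- outcome
  fit
}

# Marginal (population-averaged) mean over the observed state x year design.
# weighting = "equal_cell": every observed state-year cell counts once;
# "observation": every observation counts once.  SE by the delta method on
# the robust covariance; CI computed on the log scale and exponentiated.
marginal_mean <- function(fit, weighting = c("equal_cell", "observation")) {
  weighting <- match.arg(weighting)
  des <- fit$design
  grid <- data.frame(state = des$state, year = des$year)
  if (weighting == "equal_cell") {
    keep <- !duplicated(paste(grid$state, grid$year))
    Xg <- fit$X[keep, , drop = FALSE]
  } else {
    Xg <- fit$X
  }
  pred <- exp(drop(Xg %*% fit$coefficients))
  m <- mean(pred)
  grad <- drop(crossprod(Xg * pred, rep(1 / nrow(Xg), nrow(Xg))))
  se <- sqrt(drop(t(grad) %*% fit$vcov_robust %*% grad))
  se_log <- se / m
  ci <- exp(log(m) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  list(mean = m, se = se, ci_lower = ci[1], ci_upper = ci[2])
}

#' National WISN requirement threshold for one combination
#'
#' Fits the population-averaged Poisson model under each requested working
#' correlation structure, keeps the fit with the lowest QIC, and reports
#' the marginal mean requirement averaged over the observed state x year
#' design with a 95% asymptotic confidence interval.  A companion model on
#' the raw (unrounded) WISN values supplies the raw mean and its standard
#' error.  The integer `wisn_threshold` used for projections is the
#' half-up-rounded marginal mean of the count model.
#'
#' @param results retained WISN results for one combination.
#' @param structures working correlation structures to compare.
#' @param weighting `"equal_cell"` (default) or `"observation"` averaging.
#' @param fit_raw also fit the raw-value model (default TRUE).
#' @param ... passed to [gee_poisson()].
#' @return one-row data frame: `combo`, `n`, `mean_rounded`, `ci_lower`,
#'   `ci_upper`, `wisn_threshold`, `mean_raw`, `se_raw`, `qic`,
#'   `structure`.
#' @export
select_and_predict <- function(results,
                               structures = c("independence", "exchangeable", "ar1"),
                               weighting = c("equal_cell", "observation"),
                               fit_raw = TRUE, ...) {
  weighting <- match.arg(weighting)
  combo <- unique(results$combo %||% paste(results$centre_type, results$cadre, sep = "-"))
  stopifnot(length(combo) == 1L)
  fits <- list()
  for (s in structures) {
    f <- tryCatch(fit_gee(results, "rounded", s, ...), error = function(e) NULL)
    if (!is.null(f) && isTRUE(f$converged)) fits[[s]] <- f
  }
  if (!length(fits)) {
    stop(sprintf("no working-correlation structure converged for %s", combo),
         call. = FALSE)
  }
  qics <- vapply(fits, function(f) f$qic, numeric(1))
  best <- fits[[which.min(qics)]]
  mm <- marginal_mean(best, weighting)
  raw_mean <- NA_real_; raw_se <- NA_real_
  if (fit_raw) {
    fr <- tryCatch(fit_gee(results, "raw", best$structure, ...),
                   error = function(e) NULL)
    if (!is.null(fr) && isTRUE(fr$converged)) {
      mmr <- marginal_mean(fr, weighting)
      raw_mean <- mmr$mean; raw_se <- mmr$se
    }
  }
  data.frame(
    combo = combo, n = nrow(results),
    mean_rounded = mm$mean, ci_lower = mm$ci_lower, ci_upper = mm$ci_upper,
    wisn_threshold = as.integer(round_half_up(mm$mean)),
    mean_raw = raw_mean, se_raw = raw_se,
    qic = best$qic, structure = best$structure,
    stringsAsFactors = FALSE
  )
}

#' National thresholds for every combination in a WISN panel
#'
#' @param results retained WISN results (multiple combos).
#' @param ... passed to [select_and_predict()].
#' @return data frame, one row per combo (the modelled-requirements table).
#' @export
national_thresholds <- function(results, ...) {
  out <- lapply(split(results, results$combo), function(d) {
    tryCatch(select_and_predict(d, ...), error = function(e) {
      warning(sprintf("%s: %s", unique(d$combo), conditionMessage(e)), call. = FALSE)
      NULL
    })
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
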