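#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks with a t-approximation p value,
#' for association of workload pressure (state-level WISN ratios)
#' between two cadres.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @return list with `rho`, `p.value` and `n`.
#' @export
spearman_pairwise <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tv <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tv), df = n - 2)
  }
  list(rho = rho, p.value = p, n = n)
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms all variables, then computes the correlation between
#' the target pair after removing the (linear, on ranks) influence of the
#' control variables.  Two algebraically equivalent routes are provided:
#' `"residual"` correlates the residuals of regressing each target's ranks
#' on the controls' ranks; `"inverse"` reads the partial correlation off
#' the inverse of the full rank-correlation matrix.
#'
#' @param data data frame or matrix of numeric columns; rows with any
#'   missing value are dropped (listwise deletion).
#' @param pair character vector of the two target column names.
#' @param controls character vector of control column names (may be empty,
#'   in which case the result equals [spearman_pairwise()]).
#' @param method `"residual"` (default) or `"inverse"`.
#' @return list with `rho`, `p.value`, `n` and `df`.
#' @export
spearman_partial <- function(data, pair, controls = setdiff(colnames(data), pair),
                             method = c("residual", "inverse")) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  stopifnot(length(pair) == 2L, all(pair %in% names(data)),
            all(controls %in% names(data)))
  cols <- unique(c(pair, controls))
  data <- data[stats::complete.cases(data[, cols]), cols, drop = FALSE]
  n <- nrow(data)
  k <- length(controls)
  if (n <= k + 2L) stop("too few complete rows for the number of controls", call. = FALSE)
  rk <- as.data.frame(lapply(data, rank))
  if (k == 0L) {
    out <- spearman_pairwise(rk[[pair[1]]], rk[[pair[2]]])
    return(list(rho = out$rho, p.value = out$p.value, n = n, df = n - 2L))
  }
  Z <- as.matrix(rk[, controls, drop = FALSE])
  if (qr(cbind(1, Z))$rank < k + 1L) {
    stop("control variables are collinear (singular control matrix)", call. = FALSE)
  }
  rho <- if (method == "residual") {
    rx <- stats::lm.fit(cbind(1, Z), rk[[pair[1]]])$residuals
    ry <- stats::lm.fit(cbind(1, Z), rk[[pair[2]]])$residuals
    stats::cor(rx, ry)
  } else {
    R <- stats::cor(as.matrix(rk))
    P <- solve(R)
    i <- match(pair[1], cols); j <- match(pair[2], cols)
    -P[i, j] / sqrt(P[i, i] * P[j, j])
  }
  df <- n - 2L - k
  p <- if (abs(rho) >= 1) 0 else {
    tv <- rho * sqrt(df / (1 - rho^2))
    2 * stats::pt(-abs(tv), df = df)
  }
  list(rho = rho, p.value = p, n = n, df = df)
}

#' Correlation matrix of state-level ratios across cadres
#'
#' @param data data frame of state-level ratios, one column per cadre.
#' @param method `"pairwise"` Spearman correlations, or `"partial"`
#'   Spearman correlations of each pair controlling for all other columns.
#' @return list with matrices `rho` and `p.value` (symmetric, unit/NA
#'   diagonal) and the method used.
#' @export
spearman_matrix <- function(data, method = c("pairwise", "partial")) {
  method <- match.arg(method)
  vars <- colnames(data)
  m <- length(vars)
  rho <- diag(m); pmat <- matrix(NA_real_, m, m)
  dimnames(rho) <- dimnames(pmat) <- list(vars, vars)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      res <- if (method == "pairwise") {
        spearman_pairwise(data[[vars[i]]], data[[vars[j]]])
      } else {
        spearman_partial(data, c(vars[i], vars[j]),
                         controls = setdiff(vars, vars[c(i, j)]))
      }
      rho[i, j] <- rho[j, i] <- res$rho
      pmat[i, j] <- pmat[j, i] <- res$p.value
    }
  }
  list(rho = rho, p.value = pmat, method = method)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between sanctioned posts and workload-based requirements:
#' `R_C = 2 s_xy / (s_x^2 + s_y^2 + (xbar - ybar)^2)` with population
#' (1/n) moments by default.  `R_C` factors into the Pearson correlation
#' times a bias-correction factor `C_b` in (0, 1] measuring deviation from
#' the 45-degree line of perfect concordance.  The confidence interval
#' uses the Fisher z transform of `R_C` with Lin's (1989) asymptotic
#' variance.  Values below 0.90 are conventionally read as poor agreement.
#'
#' @param x,y paired numeric vectors (e.g. sanctioned posts and
#'   `threshold x N` by state); incomplete pairs dropped.
#' @param conf_level confidence level (default 0.95).
#' @param moments `"population"` (1/n, default) or `"sample"` (1/(n-1)).
#' @return list with `ccc`, `ci_lower`, `ci_upper`, `pearson_r`,
#'   `bias_correction`, `n`, `poor_agreement`.
#' @export
lin_ccc <- function(x, y, conf_level = 0.95, moments = c("population", "sample")) {
  moments <- match.arg(moments)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  denom_n <- if (moments == "population") n else n - 1L
  sx2 <- sum((x - mx)^2) / denom_n
  sy2 <- sum((y - my)^2) / denom_n
  sxy <- sum((x - mx) * (y - my)) / denom_n
  if (sx2 == 0 || sy2 == 0) {
    stop("concordance undefined when a variable has zero variance", call. = FALSE)
  }
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  cb <- if (r != 0) ccc / r else NA_real_
  # Lin (1989) variance of the Fisher z of R_C
  u <- (mx - my) / sqrt(sqrt(sx2 * sy2))
  z <- atanh(ccc)
  sz2 <- if (abs(ccc) < 1 && r != 0) {
    ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
       2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
       ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
  } else 0
  hw <- stats::qnorm(1 - (1 - conf_level) / 2) * sqrt(max(sz2, 0))
  ci <- tanh(z + c(-1, 1) * hw)
  list(ccc = ccc, ci_lower = ci[1], ci_upper = ci[2], pearson_r = r,
       bias_correction = cb, n = n, poor_agreement = ccc < 0.90)
}

#' Concordance of sanctioning with workload requirements, by combination
#'
#' For each centre-cadre combination, compares state-level sanctioned
#' posts `S` with the workload-based requirement `threshold x N` across
#' states using [lin_ccc()].
#'
#' @param state_table state staffing table (see [project_all()]).
#' @param thresholds thresholds table with `combo` and `wisn_threshold`.
#' @return data frame with one row per combo: `combo`, `n_states`, `ccc`,
#'   `ci_lower`, `ci_upper`, `pearson_r`, `bias_correction`,
#'   `poor_agreement`.
#' @export
agreement_by_combo <- function(state_table, thresholds) {
  st <- state_table
  st$combo <- paste(st$centre_type, st$cadre, sep = "-")
  out <- lapply(split(st, st$combo), function(d) {
    w <- thresholds$wisn_threshold[match(d$combo[1], thresholds$combo)]
    if (is.na(w)) return(NULL)
    ok <- stats::complete.cases(d$sanctioned, d$n_centres)
    d <- d[ok, , drop = FALSE]
    res <- tryCatch(lin_ccc(d$sanctioned, w * d$n_centres),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(combo = d$combo[1], n_states = res$n, ccc = res$ccc,
               ci_lower = res$ci_lower, ci_upper = res$ci_upper,
               pearson_r = res$pearson_r, bias_correction = res$bias_correction,
               poor_agreement = res$poor_agreement, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
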