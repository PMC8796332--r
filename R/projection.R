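#' WISN ratio
#'
#' In-position staff over the workload-based requirement for the centres
#' of a state (or the nation): `P / (threshold x N)`.  Ratios below 1
#' indicate workload pressure.
#'
#' @param P in-position staff count.
#' @param N functional centres.
#' @param threshold per-centre requirement (integer national threshold).
#' @return the ratio (>= 0).
#' @export
wisn_ratio <- function(P, N, threshold) {
  if (any(threshold <= 0)) stop("`threshold` must be positive", call. = FALSE)
  if (any(N < 1)) stop("`N` must be >= 1", call. = FALSE)
  P / (threshold * N)
}

#' WISN differences (per centre and overall)
#'
#' `per_centre = P/N - threshold`; `overall = P - threshold x N`.  Negative
#' values are workforce shortages, positive are surpluses.
#'
#' @inheritParams wisn_ratio
#' @return list with `per_centre` and `overall`.
#' @export
wisn_differences <- function(P, N, threshold) {
  if (any(threshold <= 0)) stop("`threshold` must be positive", call. = FALSE)
  if (any(N < 1)) stop("`N` must be >= 1", call. = FALSE)
  list(per_centre = P / N - threshold, overall = P - threshold * N)
}

#' Sanctioning differences (per centre and overall)
#'
#' As [wisn_differences()] with sanctioned posts `S` in place of
#' in-position staff: negative values indicate under-sanctioning relative
#' to the workload-based requirement.
#'
#' @param S sanctioned posts.
#' @inheritParams wisn_ratio
#' @return list with `per_centre` and `overall`.
#' @export
sanctioning_differences <- function(S, N, threshold) {
  wisn_differences(S, N, threshold)
}

#' Categorical interpretation of projection metrics
#'
#' Workforce problem by the sign of the WISN difference (balance /
#' surplus / shortage); workload pressure from the WISN ratio with
#' half-open bins \[0, 0.25) very high, \[0.25, 0.5) high, \[0.5, 0.75)
#' medium, \[0.75, 1) low, 1 (within `tolerance`) normal, > 1 none;
#' sanctioning problem by the sign of the sanctioning difference
#' (optimal / over / under).  Values within `tolerance` of 0 (differences)
#' or 1 (ratio) take the balance / optimal / normal label.
#'
#' @param ratio WISN ratio (>= 0).
#' @param diff overall WISN difference.
#' @param sanct_diff overall sanctioning difference.
#' @param tolerance numeric tolerance for the exact-balance cases.
#' @return list with `workforce_problem`, `workload_pressure`,
#'   `sanctioning_problem` (character vectors).
#' @export
categorise <- function(ratio, diff, sanct_diff, tolerance = 1e-9) {
  if (any(ratio < 0)) stop("`ratio` must be >= 0", call. = FALSE)
  sign_cat <- function(x, zero, pos, neg) {
    ifelse(abs(x) <= tolerance, zero, ifelse(x > 0, pos, neg))
  }
  pressure <- ifelse(abs(ratio - 1) <= tolerance, "normal",
              ifelse(ratio > 1, "none",
              ifelse(ratio < 0.25, "very_high",
              ifelse(ratio < 0.5, "high",
              ifelse(ratio < 0.75, "medium", "low")))))
  list(
    workforce_problem = sign_cat(diff, "balance", "surplus", "shortage"),
    workload_pressure = pressure,
    sanctioning_problem = sign_cat(sanct_diff, "optimal", "over", "under")
  )
}

#' Project national thresholds onto a state staffing table
#'
#' Computes, for every state x centre-cadre combination and for the
#' national aggregate (state label `"India"`, from summed P, S and N over
#' the included states), the WISN ratio, per-centre and overall WISN and
#' sanctioning differences, and their categorical labels.
#'
#' @param state_table data frame with columns `state`, `centre_type`,
#'   `cadre`, `in_position`, `sanctioned`, `n_centres`; rows with missing
#'   fields are skipped with a message.
#' @param thresholds data frame with columns `combo` and `wisn_threshold`
#'   (see [national_thresholds()]).
#' @param tolerance tolerance for exact balance; see [categorise()].
#' @return data frame with one row per state x combo plus one national row
#'   per combo, carrying the numeric metrics and category labels.
#' @export
project_all <- function(state_table, thresholds, tolerance = 1e-9) {
  needed <- c("state", "centre_type", "cadre", "in_position", "sanctioned",
              "n_centres")
  miss <- setdiff(needed, names(state_table))
  if (length(miss)) {
    stop(sprintf("state table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  st <- state_table
  st$combo <- paste(st$centre_type, st$cadre, sep = "-")
  absent <- setdiff(unique(st$combo), thresholds$combo)
  if (length(absent)) {
    stop(sprintf("no threshold for combination(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  incomplete <- !stats::complete.cases(st[, needed]) | st$n_centres < 1
  if (any(incomplete)) {
    message(sprintf("skipping %d state row(s) with missing or invalid fields: %s",
                    sum(incomplete),
                    paste(unique(st$state[incomplete]), collapse = ", ")))
    st <- st[!incomplete, , drop = FALSE]
  }
  national <- do.call(rbind, lapply(split(st, st$combo), function(d) {
    data.frame(state = "India", centre_type = d$centre_type[1],
               cadre = d$cadre[1], in_position = sum(d$in_position),
               sanctioned = sum(d$sanctioned), n_centres = sum(d$n_centres),
               combo = d$combo[1], stringsAsFactors = FALSE)
  }))
  all_rows <- rbind(st[, names(national)], national)
  w <- stats::setNames(thresholds$wisn_threshold, thresholds$combo)[all_rows$combo]
  ratio <- wisn_ratio(all_rows$in_position, all_rows$n_centres, w)
  wd <- wisn_differences(all_rows$in_position, all_rows$n_centres, w)
  sd_ <- sanctioning_differences(all_rows$sanctioned, all_rows$n_centres, w)
  cats <- categorise(ratio, wd$overall, sd_$overall, tolerance)
  out <- data.frame(
    state = all_rows$state, combo = all_rows$combo,
    centre_type = all_rows$centre_type, cadre = all_rows$cadre,
    in_position = all_rows$in_position, sanctioned = all_rows$sanctioned,
    n_centres = all_rows$n_centres, wisn_threshold = unname(w),
    wisn_ratio = ratio,
    diff_per_centre = wd$per_centre, diff_overall = wd$overall,
    sanct_diff_per_centre = sd_$per_centre, sanct_diff_overall = sd_$overall,
    workforce_problem = cats$workforce_problem,
    workload_pressure = cats$workload_pressure,
    sanctioning_problem = cats$sanctioning_problem,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
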