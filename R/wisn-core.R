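#' Annual leave policy for available working time
#'
#' Bundles the components of a cadre's annual Available Working Time (AWT):
#' working days per year minus annual, sick, public-holiday and other leave
#' days, times working hours per day.  The default (313 working days, 12
#' annual + 10 sick + 17 public-holiday + 10 other leave days, 8 h days,
#' i.e. AWT = 2112 h) is a documented assumption representative of leave
#' entitlements at Indian rural public health centres; real analyses should
#' substitute the locally applicable policy.
#'
#' @param working_days working days in a year (before leave).
#' @param annual_leave,sick_leave,public_holidays,other_leave leave days.
#' @param hours_per_day working hours per day.
#' @return an object of class `leave_policy`.
#' @examples
#' compute_awt(leave_policy())  # 2112 hours
#' @export
leave_policy <- function(working_days = 313, annual_leave = 12, sick_leave = 10,
                         public_holidays = 17, other_leave = 10,
                         hours_per_day = 8) {
  p <- list(working_days = working_days, annual_leave = annual_leave,
            sick_leave = sick_leave, public_holidays = public_holidays,
            other_leave = other_leave, hours_per_day = hours_per_day)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) || p[[nm]] < 0) {
      stop_config(nm, "must be a single nonnegative number")
    }
  }
  if (p$hours_per_day <= 0) stop_config("hours_per_day", "must be positive")
  structure(p, class = "leave_policy")
}

#' Available working time (AWT) in hours per year
#'
#' AWT = (working days - total leave days) x hours per day.
#'
#' @param policy a [leave_policy()].
#' @return hours per year (scalar).
#' @export
compute_awt <- function(policy) {
  stopifnot(inherits(policy, "leave_policy"))
  leave <- policy$annual_leave + policy$sick_leave + policy$public_holidays +
    policy$other_leave
  awt <- (policy$working_days - leave) * policy$hours_per_day
  if (awt <= 0) {
    stop("invalid leave policy: leave days consume all working days (AWT <= 0)",
         call. = FALSE)
  }
  awt
}

#' Standard workload for one service
#'
#' Annual number of service units one full-time worker can deliver:
#' AWT divided by the per-unit activity standard.
#'
#' @param awt available working time, hours/year.
#' @param unit_time_min activity standard, minutes per service unit.
#' @return units per year.
#' @export
compute_standard_workload <- function(awt, unit_time_min) {
  if (any(awt <= 0)) stop("`awt` must be positive", call. = FALSE)
  if (any(unit_time_min <= 0)) stop("`unit_time_min` must be positive", call. = FALSE)
  awt / (unit_time_min / 60)
}

#' Health-service-activity staffing requirement
#'
#' Sum over services of annual workload divided by standard workload.
#'
#' @param volumes named numeric vector of annual service volumes.
#' @param unit_times_min named numeric vector of activity standards
#'   (minutes per unit); must cover every service with nonzero volume.
#' @param awt available working time, hours/year.
#' @return required staff (real, >= 0).
#' @export
compute_hsa_requirement <- function(volumes, unit_times_min, awt) {
  if (length(volumes) == 0L) return(0)
  if (any(volumes < 0, na.rm = TRUE)) stop("service volumes must be >= 0", call. = FALSE)
  active <- names(volumes)[!is.na(volumes) & volumes > 0]
  missing_std <- setdiff(active, names(unit_times_min)[!is.na(unit_times_min)])
  if (length(missing_std)) {
    stop(sprintf("no activity standard for service(s) with nonzero volume: %s",
                 paste(missing_std, collapse = ", ")), call. = FALSE)
  }
  if (!length(active)) return(0)
  sw <- compute_standard_workload(awt, unit_times_min[active])
  sum(volumes[active] / sw)
}

#' Category allowance factor (CAF)
#'
#' Support activities performed by all members of a cadre are expressed as
#' shares of AWT (the category allowance standard, CAS); the CAF
#' 1 / (1 - CAS/100) inflates the health-service requirement to cover them.
#'
#' @param shares numeric vector of support-activity time shares (fractions
#'   of AWT, each in \[0, 1)); their sum must be < 1.
#' @return list with `total_cas_pct` (percent) and `caf` (>= 1).
#' @export
compute_caf <- function(shares) {
  if (length(shares) == 0L) return(list(total_cas_pct = 0, caf = 1))
  if (any(shares < 0, na.rm = TRUE)) stop("support shares must be >= 0", call. = FALSE)
  total <- sum(shares, na.rm = TRUE)
  if (total >= 1) {
    stop("support-activity shares sum to >= 1: allowance consumes all working time",
         call. = FALSE)
  }
  list(total_cas_pct = 100 * total, caf = 1 / (1 - total))
}

#' Individual allowance factor (IAF)
#'
#' Additional activities performed by select staff members contribute
#' IAS = annual hours x staff involved; IAF = total IAS / AWT is the extra
#' whole-staff requirement they represent.
#'
#' @param hours numeric vector of annual hours per additional activity.
#' @param staff numeric vector of staff members involved per activity.
#' @param awt available working time, hours/year.
#' @return list with `total_ias_hours` and `iaf`.
#' @export
compute_iaf <- function(hours, staff = rep(1, length(hours)), awt) {
  if (awt <= 0) stop("`awt` must be positive", call. = FALSE)
  if (length(hours) == 0L) return(list(total_ias_hours = 0, iaf = 0))
  if (any(hours < 0, na.rm = TRUE) || any(staff < 0, na.rm = TRUE)) {
    stop("additional-activity times and staff counts must be >= 0", call. = FALSE)
  }
  total <- sum(hours * staff, na.rm = TRUE)
  list(total_ias_hours = total, iaf = total / awt)
}

#' WISN staffing requirement
#'
#' WISN = HSA x CAF + IAF, rounded to whole staff under the configured rule.
#'
#' @param hsa health-service requirement (>= 0).
#' @param caf category allowance factor (>= 1).
#' @param iaf individual allowance factor (>= 0).
#' @param rounding `"half_up"` (default) or `"ceiling"`.
#' @return list with `wisn_raw` and integer `wisn_rounded`.
#' @export
compute_wisn <- function(hsa, caf, iaf, rounding = c("half_up", "ceiling")) {
  stopifnot(all(hsa >= 0), all(caf >= 1), all(iaf >= 0))
  raw <- hsa * caf + iaf
  list(wisn_raw = raw, wisn_rounded = as.integer(apply_rounding(raw, rounding)))
}

# Column-name conventions of the facility panel:
#   svc_<service>        annual service volume (units/year)
#   cas_<activity>       support-activity share of AWT (or hours, see cas_unit)
#   ias_<activity>_hours annual hours of an additional activity
#   ias_<activity>_staff staff members involved in that activity
panel_service_cols <- function(panel) grep("^svc_", names(panel), value = TRUE)
panel_cas_cols <- function(panel) grep("^cas_", names(panel), value = TRUE)
panel_ias_hour_cols <- function(panel) grep("^ias_.*_hours$", names(panel), value = TRUE)

#' Facility-level WISN results for a whole activity panel
#'
#' Applies the WISN calculation (AWT, HSA requirement, CAF, IAF) to every
#' facility x year x cadre row of an activity panel.  Exclusion flags are
#' initialised but not applied; see [apply_exclusions()].
#'
#' @param panel facility activity panel (see [generate_facility_panel()] for
#'   the column conventions): identifiers `facility_id`, `state`, `year`,
#'   `centre_type`, `cadre`, `weekly_hours`, plus `svc_*`, `cas_*` and
#'   `ias_*_hours` / `ias_*_staff` columns.
#' @param standards activity-standards table with columns `centre_type`,
#'   `cadre`, `service`, `unit_time_min`.
#' @param policy a [leave_policy()].
#' @param rounding integer-rounding rule, `"half_up"` or `"ceiling"`.
#' @param cas_unit `"fraction"` if `cas_*` columns are shares of AWT,
#'   `"hours"` if they are annual hours (converted via AWT).
#' @return data frame with one row per panel row: identifiers plus
#'   `awt_hours`, `hsa_requirement`, `total_cas_pct`, `caf`,
#'   `total_ias_hours`, `iaf`, `wisn_raw`, `wisn_rounded`, `excluded`,
#'   `exclusion_reason`.
#' @export
wisn_panel <- function(panel, standards, policy = leave_policy(),
                       rounding = c("half_up", "ceiling"),
                       cas_unit = c("fraction", "hours")) {
  rounding <- match.arg(rounding)
  cas_unit <- match.arg(cas_unit)
  req <- c("facility_id", "state", "year", "centre_type", "cadre", "weekly_hours")
  miss <- setdiff(req, names(panel))
  if (length(miss)) {
    stop(sprintf("panel is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  awt <- compute_awt(policy)
  svc_cols <- panel_service_cols(panel)
  services <- sub("^svc_", "", svc_cols)
  n <- nrow(panel)

  # HSA: per (centre_type, cadre) group, volumes %*% (unit_time/60) / AWT
  hsa <- numeric(n)
  combo <- paste(panel$centre_type, panel$cadre, sep = "-")
  for (cb in unique(combo)) {
    idx <- which(combo == cb)
    ct <- panel$centre_type[idx[1]]
    cd <- panel$cadre[idx[1]]
    std <- standards[standards$centre_type == ct & standards$cadre == cd, ]
    ut <- stats::setNames(std$unit_time_min, std$service)
    vols <- as.matrix(panel[idx, svc_cols, drop = FALSE])
    colnames(vols) <- services
    vols[is.na(vols)] <- 0
    if (any(vols < 0)) stop("service volumes must be >= 0", call. = FALSE)
    used <- services[colSums(vols) > 0]
    bad <- setdiff(used, std$service)
    if (length(bad)) {
      stop(sprintf("no activity standard for service(s) %s in combination %s",
                   paste(bad, collapse = ", "), cb), call. = FALSE)
    }
    have <- intersect(services, std$service)
    if (length(have)) {
      hsa[idx] <- as.vector(vols[, have, drop = FALSE] %*% (ut[have] / 60)) / awt
    }
  }

  cas_cols <- panel_cas_cols(panel)
  if (length(cas_cols)) {
    shares <- as.matrix(panel[, cas_cols, drop = FALSE])
    shares[is.na(shares)] <- 0
    if (cas_unit == "hours") shares <- shares / awt
    if (any(shares < 0)) stop("support-activity shares must be >= 0", call. = FALSE)
    total_share <- rowSums(shares)
    if (any(total_share >= 1)) {
      stop("support-activity shares sum to >= 1 for at least one record", call. = FALSE)
    }
  } else {
    total_share <- numeric(n)
  }
  caf <- 1 / (1 - total_share)

  hour_cols <- panel_ias_hour_cols(panel)
  total_ias <- numeric(n)
  for (hc in hour_cols) {
    sc <- sub("_hours$", "_staff", hc)
    hrs <- panel[[hc]]
    stf <- if (sc %in% names(panel)) panel[[sc]] else rep(1, n)
    hrs[is.na(hrs)] <- 0
    stf[is.na(stf)] <- 0
    if (any(hrs < 0) || any(stf < 0)) {
      stop("additional-activity times and staff counts must be >= 0", call. = FALSE)
    }
    total_ias <- total_ias + hrs * stf
  }
  iaf <- total_ias / awt

  raw <- hsa * caf + iaf
  data.frame(
    facility_id = panel$facility_id, state = panel$state, year = panel$year,
    centre_type = panel$centre_type, cadre = panel$cadre, combo = combo,
    weekly_hours = panel$weekly_hours, awt_hours = awt,
    hsa_requirement = hsa, total_cas_pct = 100 * total_share, caf = caf,
    total_ias_hours = total_ias, iaf = iaf, wisn_raw = raw,
    wisn_rounded = as.integer(apply_rounding(raw, rounding)),
    excluded = FALSE, exclusion_reason = "none",
    stringsAsFactors = FALSE
  )
}

#' WISN result for a single facility record
#'
#' Convenience wrapper over [wisn_panel()] for one facility x year x cadre
#' observation.
#'
#' @param record one-row data frame in the panel column convention.
#' @inheritParams wisn_panel
#' @return one-row result data frame.
#' @export
compute_facility_wisn <- function(record, standards, policy = leave_policy(),
                                  rounding = c("half_up", "ceiling"),
                                  cas_unit = c("fraction", "hours")) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  wisn_panel(record, standards, policy, rounding, cas_unit)
}

#' Apply the facility exclusion filters
#'
#' Flags records to be dropped before national modelling, with precedence
#' (first matching reason recorded):
#' \enumerate{
#'   \item `under_half_workweek`: average weekly hours below
#'     `min_weekly_hours` (default 24 h, half a 48 h standard workweek);
#'   \item `null_wisn`: a null requirement (rounded WISN of 0 by default;
#'     `null_rule = "raw"` uses the raw value instead);
#'   \item `null_iaf_nurse`: a nurse-cadre record whose additional-activity
#'     component is zero — for nurses that component is a substantial share
#'     of workload, so a zero indicates missing data rather than no work.
#' }
#'
#' @param results output of [wisn_panel()].
#' @param nurse_cadres cadre labels treated as nurses.
#' @param min_weekly_hours workweek threshold in hours.
#' @param null_rule `"rounded"` or `"raw"`: which WISN value a null test uses.
#' @return `results` with `excluded` and `exclusion_reason` filled in; keep
#'   rows with `!excluded` for downstream modelling.
#' @export
apply_exclusions <- function(results, nurse_cadres = "nurses",
                             min_weekly_hours = 24,
                             null_rule = c("rounded", "raw")) {
  null_rule <- match.arg(null_rule)
  reason <- rep("none", nrow(results))
  null_wisn <- if (null_rule == "rounded") results$wisn_rounded == 0L
               else results$wisn_raw == 0
  is_nurse <- results$cadre %in% nurse_cadres
  reason[is_nurse & results$total_ias_hours == 0] <- "null_iaf_nurse"
  reason[null_wisn] <- "null_wisn"
  reason[results$weekly_hours < min_weekly_hours] <- "under_half_workweek"
  results$exclusion_reason <- reason
  results$excluded <- reason != "none"
  results
}
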