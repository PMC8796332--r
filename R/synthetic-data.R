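#' Default centre-cadre combinations
#'
#' The eight rural centre-cadre combinations the pipeline models: doctors
#' and nurses at primary health centres (PHC) and nurses, general-duty
#' medical officers (GDMOs) and four specialist cadres at community health
#' centres (CHC).
#'
#' @return data frame with columns `centre_type`, `cadre`, `combo`.
#' @export
default_combos <- function() {
  df <- data.frame(
    centre_type = c("PHC", "PHC", "CHC", "CHC", "CHC", "CHC", "CHC", "CHC"),
    cadre = c("nurses", "doctors", "nurses", "GDMOs", "physicians",
              "surgeons", "OBGYNs", "paediatricians"),
    stringsAsFactors = FALSE
  )
  df$combo <- paste(df$centre_type, df$cadre, sep = "-")
  df
}

# Default activity standards (minutes per service unit) by combination.
# Unit times are in the range reported by Indian facility time studies:
# short outpatient contacts for generalists, longer specialist contacts,
# inpatient care, institutional deliveries, surgery and immunisation.
#' Default activity-standards table
#'
#' @return data frame with columns `centre_type`, `cadre`, `service`,
#'   `unit_time_min`.
#' @export
default_standards <- function() {
  rows <- list(
    c("PHC", "nurses", "outpatient", 10),
    c("PHC", "nurses", "immunisation", 15),
    c("PHC", "nurses", "delivery", 120),
    c("PHC", "doctors", "outpatient", 5),
    c("PHC", "doctors", "inpatient", 30),
    c("CHC", "nurses", "outpatient", 10),
    c("CHC", "nurses", "inpatient", 60),
    c("CHC", "nurses", "delivery", 120),
    c("CHC", "GDMOs", "outpatient", 5),
    c("CHC", "GDMOs", "inpatient", 30),
    c("CHC", "physicians", "outpatient", 15),
    c("CHC", "physicians", "inpatient", 30),
    c("CHC", "surgeons", "outpatient", 15),
    c("CHC", "surgeons", "surgery", 120),
    c("CHC", "OBGYNs", "outpatient", 15),
    c("CHC", "OBGYNs", "delivery", 60),
    c("CHC", "paediatricians", "outpatient", 10),
    c("CHC", "paediatricians", "inpatient", 30)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(centre_type = r[1], cadre = r[2], service = r[3],
               unit_time_min = as.numeric(r[4]), stringsAsFactors = FALSE)
  }))
  out
}

# Mean annual service volumes per combination.  Together with the default
# standards, leave policy (AWT 2112 h), 20% support allowance (CAF 1.25)
# and the default additional activities these give analytic mean WISN
# values of roughly 12 (PHC-nurses), 2 (PHC-doctors), 63 (CHC-nurses),
# 4 (CHC-GDMOs) and 2 (CHC specialists) — the magnitudes observed at
# Indian rural facilities.
default_base_volumes <- function() {
  list(
    "PHC-nurses" = c(outpatient = 60000, immunisation = 20000, delivery = 2200),
    "PHC-doctors" = c(outpatient = 30000, inpatient = 900),
    "CHC-nurses" = c(outpatient = 250000, inpatient = 40000, delivery = 6000),
    "CHC-GDMOs" = c(outpatient = 50000, inpatient = 4300),
    "CHC-physicians" = c(outpatient = 9000, inpatient = 1400),
    "CHC-surgeons" = c(outpatient = 6000, surgery = 730),
    "CHC-OBGYNs" = c(outpatient = 5000, delivery = 1700),
    "CHC-paediatricians" = c(outpatient = 12000, inpatient = 1900)
  )
}

# Support-activity shares of AWT (record keeping, meetings, upkeep; 20%
# total) and additional activities (hours/year x staff) per cadre.  Nurses
# carry a larger additional-activity component (outreach), reflecting that
# this component dominates nurse workload at PHCs/CHCs.
default_cas_shares <- function() c(records = 0.08, meetings = 0.07, upkeep = 0.05)
default_ias <- function(cadre) {
  if (cadre == "nurses") c(hours = 528, staff = 2) else c(hours = 264, staff = 2)
}

#' Configuration for the synthetic facility-panel generator
#'
#' Describes a facility activity panel: facilities clustered within states,
#' observed over several years, for a set of centre-cadre combinations.
#' Service volumes are negative-binomial (Poisson when `overdispersion = 0`)
#' with mean `base_volume x state_effect x year_trend^(year index)`.  The
#' panel is unbalanced: each facility-year-cadre cell is independently
#' missing with probability `missing_rate`, and a `partial_facility_rate`
#' share of facilities operate under 24 h/week.
#'
#' Defaults emulate a five-state, eight-year survey of rural PHCs and CHCs
#' with roughly 150 retained observations per centre-cadre combination and
#' strong across-state heterogeneity.
#'
#' @param n_states number of states.
#' @param years ordered vector of calendar years.
#' @param facilities_per_state_centretype facilities per state per centre type.
#' @param combos data frame of centre-cadre combinations ([default_combos()]).
#' @param state_effects multiplicative state factors on service volumes
#'   (length `n_states`).
#' @param year_trend multiplicative per-year volume factor.
#' @param base_volumes named list: combo -> named vector of mean annual
#'   volumes per service.
#' @param overdispersion negative-binomial overdispersion (variance =
#'   mu + overdispersion * mu^2); 0 gives Poisson volumes.
#' @param missing_rate probability a facility-year-cadre cell is absent.
#' @param partial_facility_rate probability a facility runs < 24 h/week.
#' @param cas_shares named vector of support-activity shares of AWT.
#' @param ias_by_cadre function(cadre) -> c(hours=, staff=) for the
#'   additional activity.
#' @param seed integer seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_states = 5,
                              years = 2007:2014,
                              facilities_per_state_centretype = 9,
                              combos = default_combos(),
                              state_effects = c(0.7, 0.9, 1.0, 1.15, 1.35),
                              year_trend = 1.02,
                              base_volumes = default_base_volumes(),
                              overdispersion = 0.2,
                              missing_rate = 0.6,
                              partial_facility_rate = 0.05,
                              cas_shares = default_cas_shares(),
                              ias_by_cadre = default_ias,
                              seed = 1L) {
  if (!is.numeric(n_states) || n_states < 1) stop_config("n_states", "need >= 1 state")
  if (length(years) < 1) stop_config("years", "need >= 1 year")
  if (facilities_per_state_centretype < 1) {
    stop_config("facilities_per_state_centretype", "need >= 1 facility")
  }
  if (nrow(combos) < 1) stop_config("combos", "need >= 1 centre-cadre combination")
  if (length(state_effects) != n_states) {
    stop_config("state_effects", "must have one factor per state")
  }
  if (any(state_effects <= 0) || year_trend <= 0) {
    stop_config("state_effects", "effects and year_trend must be positive")
  }
  for (p in c("missing_rate", "partial_facility_rate")) {
    v <- get(p)
    if (!is.numeric(v) || v < 0 || v > 1) stop_config(p, "must be in [0, 1]")
  }
  if (overdispersion < 0) stop_config("overdispersion", "must be >= 0")
  miss_vol <- setdiff(combos$combo, names(base_volumes))
  if (length(miss_vol)) {
    stop_config("base_volumes", paste("no volumes for", paste(miss_vol, collapse = ", ")))
  }
  if (any(unlist(base_volumes) <= 0)) {
    stop_config("base_volumes", "must be strictly positive")
  }
  structure(list(
    n_states = as.integer(n_states), years = as.integer(years),
    facilities_per_state_centretype = as.integer(facilities_per_state_centretype),
    combos = combos, state_effects = state_effects, year_trend = year_trend,
    base_volumes = base_volumes, overdispersion = overdispersion,
    missing_rate = missing_rate, partial_facility_rate = partial_facility_rate,
    cas_shares = cas_shares, ias_by_cadre = ias_by_cadre,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Generate a synthetic facility activity panel
#'
#' Draws one record per retained facility x year x cadre cell under the
#' structure described in [simulation_config()].  Output is reproducible
#' under a fixed config seed and leaves the caller's RNG state untouched.
#'
#' @param config a [simulation_config()].
#' @return data frame in the panel column convention of [wisn_panel()]:
#'   `facility_id`, `state`, `year`, `centre_type`, `cadre`,
#'   `weekly_hours`, `svc_*`, `cas_*`, `ias_extra_hours`, `ias_extra_staff`.
#' @export
generate_facility_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed, {
    states <- sprintf("ST%02d", seq_len(config$n_states))
    services <- sort(unique(unlist(lapply(config$base_volumes, names))))
    rows <- list()
    for (si in seq_along(states)) {
      for (ct in unique(config$combos$centre_type)) {
        fac_ids <- sprintf("%s_%s_F%02d", states[si], ct,
                           seq_len(config$facilities_per_state_centretype))
        partial <- stats::runif(length(fac_ids)) < config$partial_facility_rate
        weekly <- ifelse(partial, stats::runif(length(fac_ids), 8, 23.5), 48)
        cadres <- config$combos$cadre[config$combos$centre_type == ct]
        for (fi in seq_along(fac_ids)) {
          for (yi in seq_along(config$years)) {
            for (cd in cadres) {
              if (stats::runif(1) < config$missing_rate) next
              cb <- paste(ct, cd, sep = "-")
              mu <- config$base_volumes[[cb]] * config$state_effects[si] *
                config$year_trend^(yi - 1)
              vol <- vapply(mu, function(m) {
                if (config$overdispersion == 0) stats::rpois(1, m)
                else stats::rnbinom(1, size = 1 / config$overdispersion, mu = m)
              }, numeric(1))
              svc <- stats::setNames(rep(0, length(services)),
                                     paste0("svc_", services))
              svc[paste0("svc_", names(vol))] <- vol
              ias <- config$ias_by_cadre(cd)
              rows[[length(rows) + 1L]] <- c(
                list(facility_id = fac_ids[fi], state = states[si],
                     year = config$years[yi], centre_type = ct, cadre = cd,
                     weekly_hours = weekly[fi]),
                as.list(svc),
                as.list(stats::setNames(config$cas_shares,
                                        paste0("cas_", names(config$cas_shares)))),
                list(ias_extra_hours = unname(ias["hours"]),
                     ias_extra_staff = unname(ias["staff"]))
              )
            }
          }
        }
      }
    }
    if (!length(rows)) {
      stop("generator produced an empty panel (missing_rate too high?)", call. = FALSE)
    }
    do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  })
}

#' Analytic mean WISN of the generator's data-generating process
#'
#' Expected raw WISN of an average facility-year in the configured panel
#' (volume means averaged over states and years), per combination.  Used to
#' verify that simulated panels and the downstream model recover the
#' generator's own expectation.
#'
#' @param config a [simulation_config()].
#' @param standards activity-standards table.
#' @param policy a [leave_policy()].
#' @return named numeric vector, one expected raw WISN per combo.
#' @export
analytic_mean_wisn <- function(config, standards = default_standards(),
                               policy = leave_policy()) {
  awt <- compute_awt(policy)
  caf <- compute_caf(config$cas_shares)$caf
  eff <- mean(config$state_effects) *
    mean(config$year_trend^(seq_along(config$years) - 1))
  out <- vapply(seq_len(nrow(config$combos)), function(i) {
    cb <- config$combos$combo[i]
    std <- standards[standards$centre_type == config$combos$centre_type[i] &
                     standards$cadre == config$combos$cadre[i], ]
    ut <- stats::setNames(std$unit_time_min, std$service)
    mu <- config$base_volumes[[cb]] * eff
    hsa <- compute_hsa_requirement(mu, ut, awt)
    ias <- config$ias_by_cadre(config$combos$cadre[i])
    hsa * caf + unname(ias["hours"] * ias["staff"]) / awt
  }, numeric(1))
  stats::setNames(out, config$combos$combo)
}

#' Configuration for a known per-centre requirement
#'
#' Builds a single-combo panel configuration whose analytic mean raw WISN
#' equals `w` exactly, with no state or year effects: one service with a
#' 12.672-minute unit time (standard workload 10000 units/year at the
#' default AWT of 2112 h), CAF 1.25, IAF 0.25.  Used for parameter-recovery
#' studies of the national model.
#'
#' @param w target per-centre requirement (raw WISN of the mean facility).
#' @param n_facilities facilities (all in one state).
#' @param years years observed per facility.
#' @param overdispersion volume overdispersion (default Poisson).
#' @param seed integer seed.
#' @return a [simulation_config()].
#' @export
simulation_config_for_requirement <- function(w, n_facilities = 25,
                                              years = 2011:2014,
                                              overdispersion = 0,
                                              seed = 1L) {
  stopifnot(w > 0.25)
  combos <- data.frame(centre_type = "PHC", cadre = "doctors",
                       combo = "PHC-doctors", stringsAsFactors = FALSE)
  # HSA * 1.25 + 0.25 = w  with standard workload 10000 units/year
  base <- (w - 0.25) / 1.25 * 10000
  simulation_config(
    n_states = 1, years = years,
    facilities_per_state_centretype = n_facilities, combos = combos,
    state_effects = 1, year_trend = 1,
    base_volumes = list("PHC-doctors" = c(outpatient = base)),
    overdispersion = overdispersion, missing_rate = 0,
    partial_facility_rate = 0,
    cas_shares = c(support = 0.2),
    ias_by_cadre = function(cadre) c(hours = 0.25 * 2112, staff = 1),
    seed = seed
  )
}

#' Standards table matching [simulation_config_for_requirement()]
#' @return one-row standards data frame.
#' @export
recovery_standards <- function() {
  data.frame(centre_type = "PHC", cadre = "doctors", service = "outpatient",
             unit_time_min = 2112 * 60 / 10000, stringsAsFactors = FALSE)
}

#' Sanctioning scenario for the synthetic state table
#'
#' Describes how sanctioned posts relate to the workload-based requirement:
#' per state, S = round(true_requirement x sanction_bias x N) and
#' P = round(fill_rate x S) (in-position staff).  `fill_rate` may be a
#' scalar or one value per state; `fill_noise_sd` adds truncated Gaussian
#' state-level variation to the fill rate so that state-level ratios vary.
#'
#' @param true_requirement_per_centre named vector (per combo) or scalar.
#' @param sanction_bias multiplicative factor from requirement to
#'   sanctioned posts (1 = sanctioning matches workload need).
#' @param fill_rate fraction of sanctioned posts actually in position.
#' @param n_centres_by_state named integer vector: functional centres per
#'   state (per centre type).
#' @param fill_noise_sd sd of per-state fill-rate noise (truncated to [0,1]).
#' @return an object of class `sanctioning_scenario`.
#' @export
sanctioning_scenario <- function(true_requirement_per_centre,
                                 sanction_bias = 1,
                                 fill_rate = 1,
                                 n_centres_by_state,
                                 fill_noise_sd = 0) {
  if (any(true_requirement_per_centre <= 0)) {
    stop_config("true_requirement_per_centre", "must be positive")
  }
  if (any(fill_rate < 0) || any(fill_rate > 1)) {
    stop_config("fill_rate", "must be in [0, 1]")
  }
  if (any(n_centres_by_state < 1)) {
    stop_config("n_centres_by_state", "every state needs >= 1 centre")
  }
  if (sanction_bias < 0) stop_config("sanction_bias", "must be >= 0")
  structure(list(
    true_requirement_per_centre = true_requirement_per_centre,
    sanction_bias = sanction_bias, fill_rate = fill_rate,
    n_centres_by_state = n_centres_by_state, fill_noise_sd = fill_noise_sd
  ), class = "sanctioning_scenario")
}

#' Generate a synthetic state staffing table
#'
#' One row per state x centre-cadre combination with in-position staff `P`,
#' sanctioned posts `S` and functional centres `N`, in the shape of an
#' annual rural-health staffing report.
#'
#' @param scenario a [sanctioning_scenario()].
#' @param combos data frame of combinations ([default_combos()]).
#' @param seed integer seed (used only when `fill_noise_sd > 0`).
#' @return data frame with columns `state`, `centre_type`, `cadre`,
#'   `in_position`, `sanctioned`, `n_centres`.
#' @export
generate_state_table <- function(scenario, combos = default_combos(), seed = 1L) {
  stopifnot(inherits(scenario, "sanctioning_scenario"))
  states <- names(scenario$n_centres_by_state)
  if (is.null(states)) states <- sprintf("ST%02d", seq_along(scenario$n_centres_by_state))
  req <- scenario$true_requirement_per_centre
  if (is.null(names(req))) req <- stats::setNames(rep(req, nrow(combos))[seq_len(nrow(combos))], combos$combo)
  fill <- rep(scenario$fill_rate, length.out = length(states))
  with_local_seed(seed, {
    if (scenario$fill_noise_sd > 0) {
      # shared state-level noise plus smaller cadre-level noise, so fill
      # rates co-vary across cadres within a state without being identical
      fill <- pmin(1, pmax(0, fill + stats::rnorm(length(states), 0, scenario$fill_noise_sd)))
    }
    out <- list()
    for (si in seq_along(states)) {
      n <- scenario$n_centres_by_state[[si]]
      for (ci in seq_len(nrow(combos))) {
        cb <- combos$combo[ci]
        fill_cb <- if (scenario$fill_noise_sd > 0) {
          min(1, max(0, fill[si] + stats::rnorm(1, 0, scenario$fill_noise_sd / 2)))
        } else fill[si]
        s <- round(req[[cb]] * scenario$sanction_bias * n)
        p <- round(fill_cb * s)
        out[[length(out) + 1L]] <- data.frame(
          state = states[si], centre_type = combos$centre_type[ci],
          cadre = combos$cadre[ci], in_position = as.integer(p),
          sanctioned = as.integer(s), n_centres = as.integer(n),
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out)
  })
}
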