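# Fixture builders and independent oracles shared across the test files.

# Single-expression WISN oracle, written directly from the defining
# arithmetic (volumes x unit times summed over services, inflated by the
# support allowance, plus the additional-activity staff equivalent).  It is
# deliberately independent of wisn_panel()'s code path.
oracle_wisn_row <- function(row, standards, awt) {
  std <- standards[standards$centre_type == row$centre_type &
                   standards$cadre == row$cadre, ]
  ut <- setNames(std$unit_time_min, std$service)
  svc <- grep("^svc_", names(row), value = TRUE)
  vols <- unlist(row[svc])
  names(vols) <- sub("^svc_", "", svc)
  vols <- vols[vols > 0]
  shares <- unlist(row[grep("^cas_", names(row), value = TRUE)])
  hrs <- unlist(row[grep("^ias_.*_hours$", names(row), value = TRUE)])
  stf <- unlist(row[grep("^ias_.*_staff$", names(row), value = TRUE)])
  sum(vols * ut[names(vols)] / 60) / awt / (1 - sum(shares)) +
    sum(hrs * stf) / awt
}

# Random facility records over the default standards, with nonzero volumes
# only for services the combination has standards for.
random_panel <- function(n, seed = 1) {
  combos <- default_combos()
  std <- default_standards()
  services <- sort(unique(std$service))
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    idx <- sample(nrow(combos), n, replace = TRUE)
    rows <- lapply(seq_len(n), function(i) {
      ct <- combos$centre_type[idx[i]]
      cd <- combos$cadre[idx[i]]
      allowed <- std$service[std$centre_type == ct & std$cadre == cd]
      svc <- setNames(rep(0, length(services)), paste0("svc_", services))
      svc[paste0("svc_", allowed)] <- round(runif(length(allowed), 0, 50000))
      shares <- runif(2, 0, 0.3)
      data.frame(
        facility_id = sprintf("F%04d", i), state = sample(c("A", "B", "C"), 1),
        year = sample(2007:2014, 1), centre_type = ct, cadre = cd,
        weekly_hours = runif(1, 20, 60), as.list(svc),
        cas_a = shares[1], cas_b = shares[2],
        ias_x_hours = runif(1, 0, 400), ias_x_staff = sample(0:3, 1),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# Minimal one-service standards/panel pair for targeted arithmetic tests.
tiny_standards <- function(unit_time_min = 10) {
  data.frame(centre_type = "PHC", cadre = "doctors", service = "visits",
             unit_time_min = unit_time_min, stringsAsFactors = FALSE)
}

tiny_record <- function(volume = 0, cas = 0, ias_hours = 0, ias_staff = 1,
                        weekly_hours = 48, cadre = "doctors", state = "A",
                        year = 2010, facility_id = "F1") {
  data.frame(facility_id = facility_id, state = state, year = year,
             centre_type = "PHC", cadre = cadre, weekly_hours = weekly_hours,
             svc_visits = volume, cas_support = cas,
             ias_extra_hours = ias_hours, ias_extra_staff = ias_staff,
             stringsAsFactors = FALSE)
}

# Panel of independent Poisson-ish WISN outcomes for model tests: one
# combination, `n_fac` facilities over `years`, mean requirement `w`.
recovery_results <- function(w, n_fac = 25, years = 2011:2014, seed = 1,
                             overdispersion = 0) {
  cfg <- simulation_config_for_requirement(w, n_facilities = n_fac,
                                           years = years,
                                           overdispersion = overdispersion,
                                           seed = seed)
  res <- apply_exclusions(wisn_panel(generate_facility_panel(cfg),
                                     recovery_standards()))
  res[!res$excluded, , drop = FALSE]
}
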