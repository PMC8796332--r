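#' Pipeline run configuration
#'
#' Either point the run at input files (`panel_path`, `standards_path`,
#' `state_table_path`) or supply `simulate = list(config =, scenario =)`
#' to generate inputs with the synthetic module — exactly one of the two.
#'
#' @param panel_path,standards_path,state_table_path input CSV paths.
#' @param simulate list with elements `config` ([simulation_config()]) and
#'   `scenario` ([sanctioning_scenario()]).
#' @param policy a [leave_policy()].
#' @param rounding `"half_up"` or `"ceiling"`.
#' @param cas_unit `"fraction"` or `"hours"` for the panel's `cas_*` columns.
#' @param null_rule `"rounded"` or `"raw"` for the null-WISN exclusion.
#' @param weighting marginal-mean weighting, `"equal_cell"` or `"observation"`.
#' @param tolerance numeric tolerance for exact-balance categories.
#' @param seed integer seed governing all pipeline randomness.
#' @param output_dir directory for the output CSVs and manifest.
#' @return an object of class `run_config`.
#' @export
run_config <- function(panel_path = NULL, standards_path = NULL,
                       state_table_path = NULL, simulate = NULL,
                       policy = leave_policy(),
                       rounding = "half_up", cas_unit = "fraction",
                       null_rule = "rounded", weighting = "equal_cell",
                       tolerance = 1e-9, seed = 1L, output_dir = tempdir()) {
  have_paths <- !is.null(panel_path) || !is.null(state_table_path)
  if (have_paths == !is.null(simulate)) {
    stop_config("simulate", "provide either input paths or a simulate block, not both")
  }
  if (have_paths && (is.null(panel_path) || is.null(standards_path) ||
                     is.null(state_table_path))) {
    stop_config("panel_path", "file mode needs panel, standards and state-table paths")
  }
  structure(list(
    panel_path = panel_path, standards_path = standards_path,
    state_table_path = state_table_path, simulate = simulate,
    policy = policy, rounding = rounding, cas_unit = cas_unit,
    null_rule = null_rule, weighting = weighting, tolerance = tolerance,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "run_config")
}

#' Validate pipeline inputs
#'
#' Checks the three input tables without mutating them: required columns,
#' negative volumes or counts, services lacking an activity standard, and
#' state rows that the projection stage would skip.
#'
#' @param panel facility activity panel data frame.
#' @param standards activity-standards data frame.
#' @param state_table state staffing data frame.
#' @return data frame of issues with columns `severity` (`"error"` /
#'   `"exclusion"`), `where` and `message`; zero rows when all is well.
#' @export
validate_inputs <- function(panel, standards, state_table) {
  issues <- list()
  note <- function(severity, where, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, where = where, message = message,
      stringsAsFactors = FALSE)
  }
  svc_cols <- panel_service_cols(panel)
  for (sc in svc_cols) {
    if (any(panel[[sc]] < 0, na.rm = TRUE)) {
      note("error", "panel", sprintf("negative values in %s", sc))
    }
  }
  if (any(panel$weekly_hours < 0, na.rm = TRUE)) {
    note("error", "panel", "negative weekly_hours")
  }
  services <- sub("^svc_", "", svc_cols)
  for (cb in unique(paste(panel$centre_type, panel$cadre, sep = "-"))) {
    parts <- strsplit(cb, "-", fixed = TRUE)[[1]]
    std <- standards[standards$centre_type == parts[1] &
                     standards$cadre == paste(parts[-1], collapse = "-"), ]
    sub_p <- panel[panel$centre_type == parts[1] &
                   panel$cadre == paste(parts[-1], collapse = "-"), svc_cols,
                   drop = FALSE]
    used <- services[colSums(sub_p, na.rm = TRUE) > 0]
    for (s in setdiff(used, std$service)) {
      note("error", "standards", sprintf("no standard for service %s (%s)", s, cb))
    }
  }
  for (col in c("in_position", "sanctioned", "n_centres")) {
    bad <- is.na(state_table[[col]])
    if (any(bad)) {
      for (stn in unique(state_table$state[bad])) {
        note("exclusion", "state_table",
             sprintf("state %s missing %s; row will be skipped", stn, col))
      }
    }
    if (any(state_table[[col]] < 0, na.rm = TRUE)) {
      note("error", "state_table", sprintf("negative values in %s", col))
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(severity = character(), where = character(),
                  message = character(), stringsAsFactors = FALSE)
}

#' Run the full workload-based staffing pipeline
#'
#' Executes the stages in order: facility WISN calculation, exclusion
#' filtering, across-state heterogeneity check, national GEE thresholds,
#' state/national projection, and sanctioning-agreement statistics.
#' Writes five CSVs (`facility_wisn.csv`, `thresholds.csv`,
#' `projection.csv`, `agreement.csv`, `correlations.csv`) plus a JSON run
#' manifest to `config$output_dir`.  Deterministic given config and seed.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with all stage outputs and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate$config
    sim_cfg$seed <- config$seed
    panel <- generate_facility_panel(sim_cfg)
    standards <- config$simulate$standards %||% default_standards()
    state_table <- generate_state_table(config$simulate$scenario,
                                        combos = sim_cfg$combos,
                                        seed = config$seed + 1L)
  } else {
    panel <- read_facility_panel(config$panel_path)
    standards <- read_standards(config$standards_path)
    state_table <- read_state_table(config$state_table_path)
  }

  issues <- validate_inputs(panel, standards, state_table)
  if (any(issues$severity == "error")) {
    stop(paste(c("input validation failed:",
                 issues$message[issues$severity == "error"]), collapse = "\n  "),
         call. = FALSE)
  }

  results <- wisn_panel(panel, standards, config$policy,
                        rounding = config$rounding, cas_unit = config$cas_unit)
  results <- apply_exclusions(results, null_rule = config$null_rule)
  retained <- results[!results$excluded, , drop = FALSE]

  heterogeneity <- do.call(rbind, lapply(split(retained, retained$combo), function(d) {
    kw <- tryCatch(kruskal_wallis_by_state(d), error = function(e) NULL)
    if (is.null(kw)) return(NULL)
    data.frame(combo = d$combo[1], H = kw$statistic, df = kw$df,
               p.value = kw$p.value, stringsAsFactors = FALSE)
  }))

  thresholds <- national_thresholds(retained, weighting = config$weighting)
  projection <- project_all(state_table, thresholds, tolerance = config$tolerance)
  agreement <- agreement_by_combo(state_table, thresholds)

  # state-level workload-pressure co-occurrence: pairwise at PHCs,
  # partial at CHCs (when enough states are available)
  correlations <- NULL
  state_rows <- projection[projection$state != "India", ]
  for (ct in unique(state_rows$centre_type)) {
    d <- state_rows[state_rows$centre_type == ct, ]
    wide <- stats::reshape(d[, c("state", "cadre", "wisn_ratio")],
                           idvar = "state", timevar = "cadre",
                           direction = "wide")
    names(wide) <- sub("^wisn_ratio\\.", "", names(wide))
    cadres <- setdiff(names(wide), "state")
    if (length(cadres) < 2L) next
    method <- if (length(cadres) > 2L) "partial" else "pairwise"
    mat <- tryCatch(spearman_matrix(wide[, cadres], method),
                    error = function(e) NULL)
    if (is.null(mat)) next
    idx <- which(upper.tri(mat$rho), arr.ind = TRUE)
    correlations <- rbind(correlations, data.frame(
      centre_type = ct, method = method,
      cadre_a = rownames(mat$rho)[idx[, 1]],
      cadre_b = colnames(mat$rho)[idx[, 2]],
      rho = mat$rho[idx], p.value = mat$p.value[idx],
      stringsAsFactors = FALSE))
  }

  paths <- list(
    facility_wisn = file.path(config$output_dir, "facility_wisn.csv"),
    thresholds = file.path(config$output_dir, "thresholds.csv"),
    projection = file.path(config$output_dir, "projection.csv"),
    agreement = file.path(config$output_dir, "agreement.csv"),
    correlations = file.path(config$output_dir, "correlations.csv")
  )
  write_output_csv(results, paths$facility_wisn)
  write_output_csv(thresholds, paths$thresholds)
  write_output_csv(projection, paths$projection)
  if (!is.null(agreement)) write_output_csv(agreement, paths$agreement)
  if (!is.null(correlations)) write_output_csv(correlations, paths$correlations)

  manifest <- list(
    seed = config$seed,
    mode = if (is.null(config$simulate)) "files" else "simulate",
    rounding = config$rounding, null_rule = config$null_rule,
    weighting = config$weighting,
    n_panel_rows = nrow(panel), n_retained = nrow(retained),
    exclusions = as.list(table(results$exclusion_reason[results$excluded])),
    n_states_in_table = length(unique(state_table$state)),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("wisnstaff")),
    outputs = lapply(paths, basename)
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    panel = panel, results = results, retained = retained,
    heterogeneity = heterogeneity, thresholds = thresholds,
    projection = projection, agreement = agreement,
    correlations = correlations, issues = issues, manifest = manifest,
    output_dir = config$output_dir
  ))
}

#' Load a run configuration from YAML or JSON
#'
#' Reads the scalar fields of [run_config()] from a config file; the
#' `simulate` block is restricted to file-mode runs here (programmatic
#' simulate configs should be built in R).
#'
#' @param path YAML (.yml/.yaml) or JSON config file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  pol <- do.call(leave_policy, raw$leave_policy %||% list())
  run_config(
    panel_path = raw$panel_path, standards_path = raw$standards_path,
    state_table_path = raw$state_table_path, policy = pol,
    rounding = raw$rounding %||% "half_up",
    cas_unit = raw$cas_unit %||% "fraction",
    null_rule = raw$null_rule %||% "rounded",
    weighting = raw$weighting %||% "equal_cell",
    tolerance = raw$tolerance %||% 1e-9,
    seed = raw$seed %||% 1L,
    output_dir = raw$output_dir %||% tempdir()
  )
}
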