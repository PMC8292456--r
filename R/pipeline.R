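# Pipeline orchestration: generate/load -> filter -> kinetics -> rate
# models -> trajectories -> summary report, with deterministic outputs.

#' Pipeline configuration
#'
#' @param filters A [filter_config()].
#' @param h Integration step (years).
#' @param method `"heun"` or `"midpoint"`.
#' @param corridor_frac Extrapolation-corridor widening fraction.
#' @param t_min,t_max Estimation window (years from motor onset).
#' @param quantile_type Quantile convention for knot placement.
#' @param scale_basis Conditioning scale for the spline basis.
#' @param anchor_stat `"mean"` or `"median"` onset-level anchor.
#' @param stratify Also process the PDCU/PDCI and high/low amyloid
#'   strata (in addition to all-PD and control).
#' @param markers Optional subset of markers to process.
#' @param min_stratum_n Marker-stratum cells with fewer kinetics rows
#'   are skipped with a warning.
#' @param timestamps Record a wall-clock timestamp in the manifest;
#'   disabled by default so identical config + seed gives byte-identical
#'   output trees.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(filters = filter_config(),
                            h = 0.01,
                            method = c("heun", "midpoint"),
                            corridor_frac = 0.25,
                            t_min = -5, t_max = 30,
                            quantile_type = 7L,
                            scale_basis = TRUE,
                            anchor_stat = c("mean", "median"),
                            stratify = TRUE,
                            markers = NULL,
                            min_stratum_n = 12L,
                            timestamps = FALSE) {
  stopifnot(inherits(filters, "filter_config"), h > 0, t_min < t_max)
  structure(
    list(filters = filters, h = h, method = match.arg(method),
         corridor_frac = corridor_frac, t_min = t_min, t_max = t_max,
         quantile_type = as.integer(quantile_type),
         scale_basis = isTRUE(scale_basis),
         anchor_stat = match.arg(anchor_stat),
         stratify = isTRUE(stratify), markers = markers,
         min_stratum_n = as.integer(min_stratum_n),
         timestamps = isTRUE(timestamps)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()]; a `filters` map mirrors
#' [filter_config()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$filters))
    raw$filters <- do.call(filter_config, raw$filters)
  do.call(pipeline_config, raw)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
}

config_hash <- function(config) {
  txt <- yaml::as.yaml(rapply(unclass(config), unclass, how = "replace"))
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

scalar_or_na <- function(x) if (length(x) == 1L && is.finite(x)) x else NA_real_

#' Run the full trajectory-estimation pipeline
#'
#' Orchestrates generate/load -> validate -> filter -> per-subject
#' kinetics -> rate-versus-level spline models -> modified-Euler
#' trajectory integration -> summary report, for every marker and
#' stratum (all-PD, control, PDCU/PDCI, high/low amyloid). Writes, under
#' `out_dir`: `validation.tsv`, `filter_report.tsv`,
#' `filter_summary.json`, `kinetics.tsv`, `rate_models.json`,
#' `rate_curves.tsv`, `trajectories.tsv`, `summary.json` and
#' `manifest.json`. With default settings two runs with identical
#' configuration and seed produce byte-identical outputs.
#'
#' @param input `"synthetic"` (generate a cohort from `cohort_config`),
#'   a `biotraj_cohort`, a list with `visits`/`covariates`, or a
#'   directory containing `visits.csv` and `covariates.csv`.
#' @param config A [pipeline_config()].
#' @param cohort_config A [cohort_config()] used when
#'   `input = "synthetic"`.
#' @param seed Optional integer overriding the cohort seed.
#' @param out_dir Output directory (created if needed).
#' @param upto Run the pipeline through this stage only: `"filter"`,
#'   `"kinetics"`, `"rates"`, `"trajectories"` or `"report"` (default,
#'   everything).
#' @return Invisibly, a list with every intermediate product
#'   (`cohort`, `visits`, `filter`, `strata`, `reference`, `kinetics`,
#'   `models`, `trajectories`, `summary`, `manifest`, `skipped`).
#' @export
run_pipeline <- function(input = "synthetic",
                         config = pipeline_config(),
                         cohort_config = NULL,
                         seed = NULL,
                         out_dir = "biotraj_output",
                         upto = c("report", "trajectories", "rates",
                                  "kinetics", "filter")) {
  upto <- match.arg(upto)
  stopifnot(inherits(config, "pipeline_config"))
  stage_rank <- c(filter = 1, kinetics = 2, rates = 3, trajectories = 4,
                  report = 5)
  want <- function(stage) stage_rank[[upto]] >= stage_rank[[stage]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- obtain cohort ----
  input_desc <- "in-memory"
  if (identical(input, "synthetic")) {
    cc <- cohort_config %||% biotraj::cohort_config()
    if (!is.null(seed)) cc$seed <- as.integer(seed)
    cohort <- generate_cohort(cc)
    input_desc <- "synthetic"
  } else if (inherits(input, "biotraj_cohort") || is.list(input)) {
    cohort <- input
  } else if (is.character(input) && dir.exists(input)) {
    cohort <- read_cohort(input)
    input_desc <- normalizePath(input)
  } else {
    stop("'input' must be \"synthetic\", a cohort object/list, or a directory")
  }
  visits <- cohort$visits
  covariates <- cohort$covariates
  if (!is.null(config$markers))
    visits <- visits[visits$marker %in% config$markers, , drop = FALSE]

  issues <- validate_input(visits)
  write_tsv(issues, file.path(out_dir, "validation.tsv"))
  if (any(issues$problem == "missing_column"))
    stop("input is missing required column(s): ",
         paste(issues$column[issues$problem == "missing_column"],
               collapse = ", "))

  # ---- filters ----
  filt <- apply_filters(visits, config$filters)
  if (length(filt$skipped_stages))
    message("filter stage(s) skipped: ",
            paste(filt$skipped_stages, collapse = ", "))
  write_tsv(filt$report, file.path(out_dir, "filter_report.tsv"))
  write_json_file(filt$summary, file.path(out_dir, "filter_summary.json"))
  fvisits <- filt$visits

  result <- list(cohort = cohort, visits = fvisits, filter = filt)
  if (!want("kinetics")) {
    result$manifest <- write_manifest(out_dir, config, cohort, input_desc,
                                      filt, NULL, seed)
    return(invisible(result))
  }

  # ---- strata and reference ----
  strata_tbl <- stratify(covariates, config$filters)
  subj_of <- function(sel) strata_tbl$subject_id[sel]
  strata <- list(
    pd = subj_of(strata_tbl$group == "pd"),
    control = subj_of(strata_tbl$group == "control")
  )
  if (config$stratify) {
    strata$pdcu <- subj_of(strata_tbl$cognition %in% "PDCU")
    strata$pdci <- subj_of(strata_tbl$cognition %in% "PDCI")
    strata$abeta_high <- subj_of(strata_tbl$abeta %in% "high")
    strata$abeta_low <- subj_of(strata_tbl$abeta %in% "low")
  }
  reference <- control_reference(fvisits, covariates)

  # ---- kinetics ----
  kinetics <- fit_kinetics(fvisits)
  write_tsv(kinetics, file.path(out_dir, "kinetics.tsv"))
  result$strata <- strata
  result$reference <- reference
  result$kinetics <- kinetics
  if (!want("rates")) {
    result$manifest <- write_manifest(out_dir, config, cohort, input_desc,
                                      filt, kinetics, seed)
    return(invisible(result))
  }

  # ---- rate models / trajectories / summaries per marker-stratum ----
  markers <- sort(unique(fvisits$marker))
  models <- list()
  trajectories <- list()
  summaries <- list()
  skipped <- list()
  for (m in markers) {
    km <- kinetics[kinetics$marker == m, , drop = FALSE]
    for (s in names(strata)) {
      ks <- km[km$subject_id %in% strata[[s]], , drop = FALSE]
      cell <- paste(m, s, sep = ".")
      if (nrow(ks) < config$min_stratum_n) {
        skipped[[cell]] <- sprintf("only %d subjects", nrow(ks))
        next
      }
      fit <- tryCatch(
        fit_rate_model(ks$baseline_level, ks$rate,
                       n_subjects = nrow(ks),
                       quantile_type = config$quantile_type,
                       scale_basis = config$scale_basis,
                       marker = m, stratum = s),
        error = function(e) e)
      if (inherits(fit, "error")) {
        skipped[[cell]] <- conditionMessage(fit)
        next
      }
      models[[m]][[s]] <- fit
      if (!want("trajectories")) next
      traj <- tryCatch({
        tr <- if (s == "control") {
          anchor_control_trajectory(fit, reference, m,
                                    t_min = config$t_min,
                                    t_max = config$t_max, h = config$h,
                                    method = config$method,
                                    corridor_frac = config$corridor_frac)
        } else {
          integrate_trajectory(fit,
                               anchor = onset_anchor(ks, config$anchor_stat),
                               t_min = config$t_min, t_max = config$t_max,
                               h = config$h, method = config$method,
                               corridor_frac = config$corridor_frac,
                               marker = m, stratum = s)
        }
        suppressWarnings(to_zscores(tr, reference, m))
      }, error = function(e) e)
      if (inherits(traj, "error")) {
        skipped[[cell]] <- conditionMessage(traj)
        next
      }
      trajectories[[m]][[s]] <- traj
    }
  }
  if (length(skipped))
    warning("skipped marker-stratum cell(s): ",
            paste(names(skipped), collapse = ", "))
  result$models <- models
  result$trajectories <- trajectories
  result$skipped <- skipped

  model_json <- lapply(models, function(per_s) lapply(per_s, function(fit)
    list(marker = fit$marker, stratum = fit$stratum,
         knots = fit$knots,
         coefficients = as.list(fit$coefficients),
         scale_basis = fit$scale_basis,
         fit_range = fit$fit_range, n = fit$n)))
  write_json_file(model_json, file.path(out_dir, "rate_models.json"))

  curve_rows <- list()
  for (m in names(models)) for (s in names(models[[m]])) {
    fit <- models[[m]][[s]]
    g <- seq(fit$fit_range[1], fit$fit_range[2], length.out = 200)
    curve_rows[[paste(m, s)]] <- data.frame(
      marker = m, stratum = s, level = g, rate = evaluate_rate(fit, g),
      stringsAsFactors = FALSE)
  }
  write_tsv(do.call(rbind, curve_rows) %||%
              data.frame(marker = character(), stratum = character(),
                         level = numeric(), rate = numeric()),
            file.path(out_dir, "rate_curves.tsv"))

  if (want("trajectories")) {
    traj_rows <- list()
    for (m in names(trajectories)) for (s in names(trajectories[[m]])) {
      tr <- trajectories[[m]][[s]]
      traj_rows[[paste(m, s)]] <- data.frame(
        marker = m, stratum = s, duration_years = tr$time,
        level = tr$level, z = tr$z, stringsAsFactors = FALSE)
    }
    write_tsv(do.call(rbind, traj_rows) %||%
                data.frame(marker = character(), stratum = character(),
                           duration_years = numeric(), level = numeric(),
                           z = numeric()),
              file.path(out_dir, "trajectories.tsv"))
  }

  if (want("report")) {
    for (m in names(trajectories)) {
      ctrl <- trajectories[[m]][["control"]]
      for (s in names(trajectories[[m]])) {
        tr <- trajectories[[m]][[s]]
        fit <- models[[m]][[s]]
        roots <- rate_roots(fit)
        pc <- tryCatch(percent_change(tr, 0, min(30, config$t_max)),
                       error = function(e) NA_real_)
        cross_ctrl <- if (s != "control" && !is.null(ctrl))
          scalar_or_na(find_crossing(tr, ctrl)) else NA_real_
        summaries[[m]][[s]] <- list(
          n_subjects = fit$n,
          anchor_level = attr(tr, "anchor")$level,
          anchor_time = attr(tr, "anchor")$time,
          level_at_30 = scalar_or_na(approx(tr$time, tr$level, 30,
                                            rule = 1)$y),
          percent_change_0_30 = pc,
          rate_roots = if (nrow(roots)) roots else NULL,
          crossing_vs_control_years = cross_ctrl,
          z_zero_crossing_years = scalar_or_na(
            find_crossing(tr, 0, value = "z")),
          n_rate_clamped = attr(tr, "diagnostics")$n_clamped
        )
      }
    }
    write_json_file(summaries, file.path(out_dir, "summary.json"))
    result$summary <- summaries
  }

  result$manifest <- write_manifest(out_dir, config, cohort, input_desc,
                                    filt, kinetics, seed)
  invisible(result)
}

write_manifest <- function(out_dir, config, cohort, input_desc, filt,
                           kinetics, seed) {
  manifest <- list(
    package = "biotraj",
    version = as.character(utils::packageVersion("biotraj")),
    input = input_desc,
    seed = if (!is.null(seed)) as.integer(seed) else
      cohort$config$seed %||% NA_integer_,
    config_hash = config_hash(config),
    counts = list(
      input_rows = filt$summary$input$rows,
      filtered_rows = filt$summary$output$rows,
      subjects = filt$summary$output$subjects,
      kinetics_rows = if (!is.null(kinetics)) nrow(kinetics) else NA_integer_
    )
  )
  if (config$timestamps)
    manifest$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  manifest
}
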