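#' Read and validate a run configuration
#'
#' @param config Path to a YAML file or a list with the same structure.
#' @return Validated config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  need <- function(key, from = config, where = "config") {
    if (is.null(from[[key]]))
      stop("missing config key: ", where, "$", key)
    from[[key]]
  }
  ph <- need("phantom")
  need("name", ph, "phantom")
  if (!ph$name %in% c("homogeneous", "complex"))
    stop("phantom$name must be 'homogeneous' or 'complex'")
  config$mode <- config$mode %||% "simplified"
  if (!config$mode %in% c("simplified", "detailed"))
    stop("mode must be 'simplified' or 'detailed'")
  config$method <- config$method %||% "superposition"
  if (!config$method %in% c("direct", "superposition"))
    stop("method must be 'direct' or 'superposition'")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_phantom_from_config <- function(ph, mode) {
  if (ph$name == "homogeneous") {
    homogeneous_benchmark(ph$n_applicators %||% 18, ph$spacing %||% 9,
                          mode = mode, fine_step = ph$fine_step,
                          z_step = ph$z_step %||% 1)
  } else {
    complex_benchmark(ph$scale %||% "full", mode = mode,
                      fine_step = ph$fine_step,
                      z_step = ph$z_step %||% 1)
  }
}

#' Run the full planning pipeline from a configuration
#'
#' Orchestrates phantom construction, the field solve (direct
#' multi-electrode, or per-electrode basis + superposition), optional
#' per-electrode power normalization, SAR computation, optional
#' gamma validation against a detailed-geometry reference, optional
#' bioheat solve with the temperature-constraint report, and export of
#' all volumes and a JSON metrics report. Runs are deterministic:
#' identical configs produce identical metrics.
#'
#' @param config Path to a YAML config or an equivalent list; see the
#'   package vignette for the schema.
#' @param outdir Output directory (created if missing); overrides
#'   `config$output`.
#' @return The metrics list, invisibly (also written as
#'   `metrics.json`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- read_run_config(config)
  outdir <- outdir %||% cfg$output %||% stop("missing config key: output")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  model <- stage("phantom", build_phantom_from_config(cfg$phantom, cfg$mode))
  ne <- n_electrodes(model)
  tol <- cfg$solver_tol %||% 1e-9
  exc <- excitation(ne,
                    amplitude = cfg$excitation$amplitude %||% 13,
                    polarity = cfg$excitation$polarity %||% 1L)

  basis <- NULL
  if (cfg$method == "superposition" ||
      !is.null(cfg$excitation$target_power)) {
    basis <- stage("basis", compute_basis(model, tol = tol))
    if (!is.null(cfg$excitation$target_power)) {
      exc <- stage("normalize",
                   normalize_power(basis, exc, cfg$excitation$target_power))
    }
  }
  if (cfg$method == "superposition") {
    E <- stage("combine", combine_fields(basis, exc))
    sar <- total_sar(E, model)
    power <- basis_powers(basis, exc)
  } else {
    sol <- stage("solve", solve_electrodes(model, drive_voltages(exc),
                                           tol = tol))
    sar <- sol$sar
    power <- sol$power
  }

  stage("export", {
    export_model(model, file.path(outdir, "model.mhd"),
                 spacing = cfg$export_spacing %||% 0.5)
    export_volume(sar$sar, model$grid, file.path(outdir, "sar.mhd"),
                  spacing = cfg$export_spacing %||% 0.5,
                  sidecar = list(units = "W/kg"))
    if (!is.null(basis)) save_basis(basis, file.path(outdir, "basis.rds"))
  })

  voi <- voi_mask(model)
  metrics <- list(
    phantom = cfg$phantom$name, mode = cfg$mode, method = cfg$method,
    n_electrodes = ne,
    drive_voltage = drive_voltages(exc),
    electrode_power = power,
    total_power = sar$total_power,
    max_sar_voi = max(sar$sar[voi])
  )

  if (isTRUE(cfg$gamma$enabled)) {
    metrics$gamma <- stage("gamma", {
      criteria <- lapply(cfg$gamma$criteria %||%
                           list(strict = list(dd = 1, dta = 0.5),
                                lenient = list(dd = 2, dta = 2)),
                         function(cr) c(dd = cr$dd, dta = cr$dta))
      cmp <- benchmark_comparison(
        phantom = cfg$phantom$name,
        n_applicators = cfg$phantom$n_applicators %||% 2,
        spacing = cfg$phantom$spacing %||% 9,
        target_power = cfg$excitation$target_power %||% 0.7,
        criteria = criteria,
        comparison_step = cfg$gamma$comparison_step %||% 0.25,
        tol = tol, verbose = FALSE)
      step <- axis_spacing(cmp$sar_ref$x)
      write_mhd(cmp$sar_ref$values,
                file.path(outdir, "sar_reference.mhd"),
                spacing = rep(step, 3),
                origin = c(cmp$sar_ref$x[1], cmp$sar_ref$y[1],
                           cmp$sar_ref$z[1]))
      cmp$metrics
    })
  }

  if (!is.null(cfg$thermal$minutes)) {
    metrics$thermal <- stage("bioheat", {
      temp <- solve_pennes(model, sar,
                           thermal_model(dt = cfg$thermal$dt %||% 1),
                           duration = cfg$thermal$minutes * 60)
      export_volume(temp$T_cells, model$grid,
                    file.path(outdir, "temperature.mhd"),
                    spacing = cfg$export_spacing %||% 0.5,
                    sidecar = list(units = "degC"))
      rep <- constraint_report(temp)
      list(max_temperature = max(temp$T_cells),
           constraints = rep[, c("region", "max_temperature", "limit",
                                 "pass")])
    })
  }

  jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(metrics)
}
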