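#' SAR volume container
#'
#' A scalar volume sampled on a rectilinear grid: values plus the sample
#' coordinates per axis (cell centers when built from a solve).
#'
#' @param values 3D numeric array.
#' @param grid Optional [rectilinear_grid()]; its cell centers become
#'   the sample coordinates.
#' @param x,y,z Sample coordinates (mm), used when `grid` is `NULL`.
#' @return A `sar_volume`.
#' @export
sar_volume <- function(values, grid = NULL, x = NULL, y = NULL, z = NULL) {
  if (!is.null(grid)) {
    x <- grid$cx; y <- grid$cy; z <- grid$cz
  }
  if (!all(dim(values) == c(length(x), length(y), length(z))))
    stop("values dims do not match coordinates")
  structure(list(values = values, x = x, y = y, z = z),
            class = "sar_volume")
}

axis_spacing <- function(v) {
  d <- diff(v)
  if (length(d) == 0) stop("volume axis has a single sample")
  if (max(d) - min(d) > 1e-9 * max(d))
    stop("volume is not uniformly spaced on every axis")
  d[1]
}

#' Resample a volume at new axis coordinates (trilinear)
#'
#' @param vol A [sar_volume()].
#' @param x,y,z Target sample coordinates (mm). Queries outside the
#'   source extent are clamped (constant extrapolation).
#' @return A [sar_volume()] on the target coordinates.
#' @export
resample_volume <- function(vol, x, y, z) {
  vals <- resample_trilinear_cpp(vol$values, vol$x, vol$y, vol$z, x, y, z)
  sar_volume(array(vals, dim = c(length(x), length(y), length(z))),
             x = x, y = y, z = z)
}

#' Gamma-analysis configuration
#'
#' @param dd Dose-difference criterion as % of the normalization SAR.
#' @param dta Distance-to-agreement criterion (mm).
#' @param search_radius Spatial search radius (mm); the generalized
#'   Gamma grows at least linearly with distance, so minima beyond
#'   `3 * dta` can only occur at voxels already failing with `gamma > 3`.
#' @param interp_step Evaluated-field sampling step (mm); `NULL`
#'   disables interpolation and uses the evaluated volume's own samples
#'   (the unambiguous brute-force reference mode).
#' @param local Use local (per-voxel reference) dose normalization,
#'   floored at 1% of the global VOI maximum, instead of the global
#'   maximum.
#' @return A `gamma_config`.
#' @export
gamma_config <- function(dd = 1, dta = 0.5, search_radius = 3 * dta,
                         interp_step = dta / 3, local = FALSE) {
  if (dd <= 0 || dta <= 0) stop("dd and dta must be > 0")
  if (search_radius < dta) stop("search_radius must be >= dta")
  structure(list(dd = dd, dta = dta, search_radius = search_radius,
                 interp_step = interp_step, local = local),
            class = "gamma_config")
}

#' Per-voxel 3D gamma index
#'
#' For each reference voxel in the VOI, minimizes the generalized Gamma
#' `sqrt(dSAR^2/DD^2 + |dr|^2/DTA^2)` over evaluated samples within the
#' search radius. The evaluated volume is sampled on a uniform grid of
#' step `interp_step` by trilinear interpolation (or on its own samples
#' when interpolation is disabled). The dose criterion is `dd`% of the
#' maximum reference SAR in the VOI (global normalization).
#'
#' @param reference,evaluated [sar_volume()]s (any rectilinear grids).
#' @param cfg A [gamma_config()].
#' @param voi Logical array over reference voxels (default: all).
#' @return Gamma array over reference voxels (`NA` outside the VOI).
#' @export
gamma_map <- function(reference, evaluated, cfg = gamma_config(),
                      voi = NULL) {
  if (is.null(voi)) voi <- array(TRUE, dim = dim(reference$values))
  if (!any(voi)) stop("VOI is empty")
  normalization <- max(reference$values[voi])
  if (normalization <= 0) stop("normalization SAR is zero in the VOI")
  dd_abs <- if (cfg$local) {
    # per-voxel dose criterion, floored at 1% of the global maximum so
    # near-zero reference voxels keep a finite criterion
    cfg$dd / 100 * pmax(as.vector(reference$values), 0.01 * normalization)
  } else {
    cfg$dd / 100 * normalization
  }

  if (is.null(cfg$interp_step)) {
    ex <- evaluated$x; ey <- evaluated$y; ez <- evaluated$z
    es <- c(axis_spacing(ex), axis_spacing(ey), axis_spacing(ez))
    evalv <- evaluated$values
    e0 <- c(ex[1], ey[1], ez[1])
    edims <- dim(evalv)
  } else {
    h <- cfg$interp_step
    rng <- function(r, e) {
      lo <- max(min(r) - cfg$search_radius, min(e))
      hi <- min(max(r) + cfg$search_radius, max(e))
      seq(lo, hi, by = h)
    }
    qx <- rng(reference$x, evaluated$x)
    qy <- rng(reference$y, evaluated$y)
    qz <- rng(reference$z, evaluated$z)
    fine <- resample_volume(evaluated, qx, qy, qz)
    evalv <- fine$values
    e0 <- c(qx[1], qy[1], qz[1])
    es <- rep(h, 3)
    edims <- dim(evalv)
  }
  # no evaluated sample lies farther than the combined volume diagonal,
  # so cap the search radius there (keeps the offset table finite for
  # arbitrarily large DTA)
  diam <- sqrt(sum(((edims - 1) * es)^2)) +
    sqrt(diff(range(reference$x))^2 + diff(range(reference$y))^2 +
           diff(range(reference$z))^2) + max(es)
  radius <- min(cfg$search_radius, diam)
  gam <- gamma_search_cpp(reference$values, reference$x, reference$y,
                          reference$z, voi, evalv, as.integer(edims),
                          e0, es, dd_abs, cfg$dta, radius)
  array(gam, dim = dim(reference$values))
}

#' Gamma passing rate
#'
#' Percentage of VOI voxels with `gamma <= 1`.
#'
#' @param gamma Gamma array from [gamma_map()].
#' @param voi Optional logical array (default: all non-`NA` voxels).
#' @return Passing rate in percent.
#' @export
passing_rate <- function(gamma, voi = NULL) {
  g <- if (is.null(voi)) gamma[!is.na(gamma)] else gamma[voi & !is.na(gamma)]
  if (!length(g)) stop("no voxels to evaluate")
  100 * mean(g <= 1)
}

#' Voxel-wise accuracy (MAE) and bias (ME)
#'
#' Mean absolute and mean signed SAR difference over the VOI, as a
#' percentage of the maximum reference SAR in the VOI. The evaluated
#' volume is resampled to the reference samples first.
#'
#' @param reference,evaluated [sar_volume()]s.
#' @param voi Logical array over reference voxels (default: all).
#' @return Named vector `c(accuracy = , bias = )` in %.
#' @export
accuracy_bias <- function(reference, evaluated, voi = NULL) {
  if (is.null(voi)) voi <- array(TRUE, dim = dim(reference$values))
  ev <- resample_volume(evaluated, reference$x, reference$y, reference$z)
  mx <- max(reference$values[voi])
  if (mx <= 0) stop("reference maximum is zero in the VOI")
  d <- (ev$values - reference$values)[voi]
  c(accuracy = mean(abs(d)) / mx * 100, bias = mean(d) / mx * 100)
}

#' Full gamma agreement report
#'
#' Computes the gamma map, passing rate, and accuracy/bias in one call.
#'
#' @inheritParams gamma_map
#' @return A `gamma_result`: `gamma`, `passing_rate` (%), `accuracy`
#'   (%), `bias` (%), `normalization` (W/kg), and the settings.
#' @export
gamma_analysis <- function(reference, evaluated, cfg = gamma_config(),
                           voi = NULL) {
  gam <- gamma_map(reference, evaluated, cfg, voi)
  ab <- accuracy_bias(reference, evaluated, voi)
  if (is.null(voi)) voi <- array(TRUE, dim = dim(reference$values))
  structure(list(gamma = gam,
                 passing_rate = passing_rate(gam, voi),
                 accuracy = unname(ab["accuracy"]),
                 bias = unname(ab["bias"]),
                 normalization = max(reference$values[voi]),
                 settings = cfg),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %g%%/%g mm: passing rate %.2f%%, accuracy %.3f%%, bias %+.3f%% of max SAR\n",
    x$settings$dd, x$settings$dta, x$passing_rate, x$accuracy, x$bias))
  invisible(x)
}
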