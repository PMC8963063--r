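#' Applicator-envelope mask on arbitrary sample coordinates
#'
#' Marks sample points lying inside any applicator's outer envelope
#' (the detailed dielectric radius or the simplified dielectric
#' half-edge, whichever is hit), over the rod's axial extent. Used to
#' exclude non-tissue voxels from agreement analyses.
#'
#' @param applicators List of [applicator_spec()]s (z-parallel).
#' @param x,y,z Sample coordinates (mm).
#' @return Logical array (`TRUE` = inside an applicator).
#' @export
applicator_envelope_mask <- function(applicators, x, y, z) {
  out <- array(FALSE, dim = c(length(x), length(y), length(z)))
  for (sp in applicators) {
    if (abs(abs(sp$direction[3]) - 1) > 1e-9)
      stop("envelope mask implemented for z-parallel applicators")
    ext <- applicator_axial_extents(sp)
    zr <- sort(sp$tip_position[3] + sign(sp$direction[3]) * ext$rod)
    r_cyl <- sp$dielectric_od / 2
    he <- sp$simplified_dielectric_edges[2] / 2
    dx <- abs(x - sp$tip_position[1])
    dy <- abs(y - sp$tip_position[2])
    r2 <- outer(dx^2, dy^2, `+`)
    cheb <- outer(dx, dy, pmax)
    inside2d <- (r2 < r_cyl^2) | (cheb < he)
    inz <- z >= zr[1] & z <= zr[2]
    out <- out | outer(inside2d, inz, `&`)
  }
  out
}

uniform_centers <- function(lo, hi, step) {
  n <- max(1L, round((hi - lo) / step))
  lo + (seq_len(n) - 0.5) * ((hi - lo) / n)
}

#' Simplified-vs-detailed benchmark comparison
#'
#' Runs the full validation chain on a benchmark phantom: (1) build the
#' simplified-cuboid model, compute the per-electrode field basis, and
#' rescale amplitudes to the per-electrode input-power target; (2) solve
#' a detailed cylindrical-layer reference model normalized to the same
#' per-electrode input power (both models are driven at the same power,
#' the standard benchmark condition); (3) resample both SAR volumes
#' onto a uniform comparison grid over the VOI (applicator interiors
#' excluded) and compute the gamma passing rates and accuracy/bias for
#' each criterion.
#'
#' @param phantom `"homogeneous"` (parallel lattice in muscle) or
#'   `"complex"` (fat/muscle/prostate heterogeneity, non-uniform
#'   spacing).
#' @param n_applicators Applicator count for the homogeneous phantom.
#' @param spacing Lattice spacing (mm) for the homogeneous phantom.
#' @param target_power Per-electrode input power (W).
#' @param criteria Named list of `c(dd, dta)` gamma criteria.
#' @param comparison_step Uniform comparison-grid step (mm).
#' @param detailed_fine_step,simplified_fine_step Cross-section grid
#'   steps of the two models (mm).
#' @param tol Solver relative-residual tolerance.
#' @param verbose Emit progress messages.
#' @return List with `metrics` (data frame: one row per criterion),
#'   `accuracy`, `bias`, `excitation`, per-electrode `power_detailed`
#'   and `power_simplified`, the comparison-grid [sar_volume()]s
#'   `sar_ref` and `sar_eval`, and the VOI mask.
#' @export
benchmark_comparison <- function(phantom = c("homogeneous", "complex"),
                                 n_applicators = 2, spacing = 9,
                                 target_power = 0.7,
                                 criteria = list(strict = c(dd = 1, dta = 0.5),
                                                 lenient = c(dd = 2, dta = 2)),
                                 comparison_step = 0.25,
                                 detailed_fine_step = 0.02,
                                 simplified_fine_step = 0.1,
                                 tol = 1e-9, verbose = TRUE) {
  phantom <- match.arg(phantom)
  say <- function(...) if (verbose) message(sprintf(...))
  build <- function(mode, fine) {
    if (phantom == "homogeneous") {
      homogeneous_benchmark(n_applicators, spacing, mode = mode,
                            fine_step = fine)
    } else {
      complex_benchmark("reduced", mode = mode, fine_step = fine)
    }
  }

  say("building simplified model (%s phantom)...", phantom)
  simp <- build("simplified", simplified_fine_step)
  ne <- n_electrodes(simp)
  say("simplified grid: %s cells; computing %d basis fields...",
      format(prod(simp$grid$nc), big.mark = ","), ne)
  basis <- compute_basis(simp, reference_voltage = 13, tol = tol)
  exc <- normalize_power(basis, excitation(ne), target_power)
  say("normalized drive voltages: %s V",
      paste(sprintf("%.2f", exc$amplitude), collapse = ", "))
  Etot <- combine_fields(basis, exc)
  sar_s <- total_sar(Etot, simp)
  pow_s <- basis_powers(basis, exc)
  vol_eval <- sar_volume(sar_s$sar, grid = simp$grid)
  applicators <- simp$applicators
  voi_box <- simp$voi
  rm(basis, Etot)

  say("building detailed reference model...")
  det <- build("detailed", detailed_fine_step)
  say("detailed grid: %s cells; solving reference...",
      format(prod(det$grid$nc), big.mark = ","))
  # the reference is driven at the same per-electrode input power as the
  # evaluated model; fixed-point on the measured powers (re-solves are
  # warm-started from the rescaled previous potential, so they are cheap)
  volt_d <- drive_voltages(exc)
  sol_d <- solve_electrodes(det, volt_d, tol = tol)
  pow_d <- sol_d$power
  for (it in seq_len(5L)) {
    if (max(abs(pow_d - target_power)) <= 0.01 * target_power) break
    fac <- sqrt(target_power / pow_d)
    volt_d <- volt_d * fac
    say("  renormalizing reference drive (powers %s W)...",
        paste(sprintf("%.3f", pow_d), collapse = ", "))
    sol_d <- solve_electrodes(det, volt_d, tol = tol,
                              x0 = sol_d$V * mean(fac))
    pow_d <- sol_d$power
  }
  if (max(abs(pow_d - target_power)) > 0.01 * target_power)
    stop("reference power normalization did not converge")
  sar_d <- sol_d$sar
  vol_ref <- sar_volume(sar_d$sar, grid = det$grid)
  det_grid <- det$grid
  rm(sol_d, det)
  gc(verbose = FALSE)

  say("resampling to %.3g mm comparison grid and running gamma analysis...",
      comparison_step)
  qx <- uniform_centers(voi_box$lo[1], voi_box$hi[1], comparison_step)
  qy <- uniform_centers(voi_box$lo[2], voi_box$hi[2], comparison_step)
  qz <- uniform_centers(voi_box$lo[3], voi_box$hi[3], comparison_step)
  ref_c <- resample_volume(vol_ref, qx, qy, qz)
  eval_c <- resample_volume(vol_eval, qx, qy, qz)
  voi <- !applicator_envelope_mask(applicators, qx, qy, qz)

  rows <- lapply(names(criteria), function(nm) {
    cr <- criteria[[nm]]
    # evaluated-sampling step: finest divisor of the comparison step not
    # exceeding DTA/3, so reference voxel positions lie on the sampling
    # lattice (identical volumes then score gamma = 0 exactly)
    istep <- comparison_step /
      ceiling(comparison_step / (cr[["dta"]] / 3) - 1e-9)
    res <- gamma_analysis(ref_c, eval_c,
                          gamma_config(dd = cr[["dd"]], dta = cr[["dta"]],
                                       interp_step = istep),
                          voi)
    say("  %s (%g%%/%g mm): passing %.2f%%", nm, cr[["dd"]], cr[["dta"]],
        res$passing_rate)
    data.frame(criterion = nm, dd = cr[["dd"]], dta = cr[["dta"]],
               passing_rate = res$passing_rate, accuracy = res$accuracy,
               bias = res$bias)
  })
  metrics <- do.call(rbind, rows)
  ab <- accuracy_bias(ref_c, eval_c, voi)
  say("accuracy %.3f%%, bias %+.3f%% of max SAR", ab["accuracy"], ab["bias"])
  list(metrics = metrics, accuracy = unname(ab["accuracy"]),
       bias = unname(ab["bias"]), excitation = exc,
       power_detailed = pow_d, power_simplified = pow_s,
       sar_ref = ref_c, sar_eval = eval_c, voi = voi,
       detailed_cells = prod(det_grid$nc),
       simplified_cells = prod(simp$grid$nc))
}
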