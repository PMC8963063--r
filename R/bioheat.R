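#' Thermal model settings for the Pennes bioheat solve
#'
#' Blood-side parameters and numerical settings. Defaults use standard
#' literature values for blood (density 1050 kg/m^3, specific heat
#' 3617 J/kg/K, arterial temperature 37 degC) and a 1 s implicit time
#' step.
#'
#' @param rho_blood Blood density (kg/m^3).
#' @param c_blood Blood specific heat (J/kg/K).
#' @param T_blood Arterial blood temperature (degC).
#' @param baseline Initial tissue temperature (degC).
#' @param dt Implicit-Euler time step (s).
#' @param boundary `"fixed"` holds the domain faces at
#'   `boundary_temperature` (the default; the faces sit >= 10 mm from
#'   the VOI so the choice is weakly influential) or `"insulated"`
#'   (zero-flux, emulating an unbounded medium).
#' @param boundary_temperature Face temperature for `"fixed"` (degC).
#' @return A `thermal_model`.
#' @export
thermal_model <- function(rho_blood = 1050, c_blood = 3617, T_blood = 37,
                          baseline = 37, dt = 1,
                          boundary = c("fixed", "insulated"),
                          boundary_temperature = baseline) {
  boundary <- match.arg(boundary)
  if (rho_blood <= 0 || c_blood <= 0) stop("blood properties must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(rho_blood = rho_blood, c_blood = c_blood,
                 T_blood = T_blood, baseline = baseline, dt = dt,
                 boundary = boundary,
                 boundary_temperature = boundary_temperature),
            class = "thermal_model")
}

# node lumping of a per-cell density: each cell spreads value*volume/8
# onto its 8 corner nodes
lump_to_nodes <- function(cell_field, grid) {
  W <- cell_field * cell_volumes(grid) / 8
  pad_pair_sum(pad_pair_sum(pad_pair_sum(W, 1), 2), 3)
}

#' Transient Pennes bioheat solve
#'
#' Integrates `rho c dT/dt = div(k grad T) - rho_b c_b w_v (T - T_b)
#' + rho SAR` on the model grid with implicit Euler steps. The
#' volumetric perfusion rate is `w_v = perfusion * rho * 1e-6 / 60` (the
#' material table stores perfusion in mL/kg/min). Applicator internals
#' conduct with their material properties, have zero perfusion, and zero
#' SAR inside conductors. Node temperatures start at the baseline.
#'
#' @param model A [voxel_model()].
#' @param sar A [sar_from_field()] result (or a per-cell SAR array, W/kg).
#' @param thermal A [thermal_model()].
#' @param duration Heating time in seconds (default 20 min); `Inf`
#'   solves the steady state directly.
#' @param tol Linear-solve relative tolerance per step.
#' @return A `temperature_volume`: node array `T` (degC), cell-center
#'   array `T_cells`, and the elapsed `time` (s).
#' @export
solve_pennes <- function(model, sar, thermal = thermal_model(),
                         duration = 1200, tol = 1e-10) {
  g <- model$grid
  sar_arr <- if (is.list(sar)) sar$sar else sar
  mats <- model$materials
  getp <- function(f) vapply(mats, f, numeric(1))[model$material]
  k_c <- array(getp(function(m) m$k), dim = g$nc)
  rho_c <- array(getp(function(m) m$rho), dim = g$nc)
  c_c <- array(getp(function(m) m$c), dim = g$nc)
  w_ml <- getp(function(m) if (is.na(m$perfusion)) 0 else m$perfusion)
  w_v <- array(w_ml, dim = g$nc) * rho_c * 1e-6 / 60   # s^-1

  sys <- stencil_conductances(g, k_c + 0i)             # W/K edges
  cap_n <- lump_to_nodes(rho_c * c_c, g)               # J/K per node
  perf_n <- lump_to_nodes(thermal$rho_blood * thermal$c_blood * w_v, g)  # W/K
  src_n <- lump_to_nodes(rho_c * sar_arr, g)           # W

  nn <- g$nn
  dmask <- array(0L, dim = nn)
  if (thermal$boundary == "fixed") {
    dmask[c(1, nn[1]), , ] <- 1L
    dmask[, c(1, nn[2]), ] <- 1L
    dmask[, , c(1, nn[3])] <- 1L
  }
  dvals <- array(as.complex(thermal$boundary_temperature), dim = nn)

  solve_step <- function(extra, rhs, x0) {
    res <- eqs_bicgstab_cpp(sys$gx, sys$gy, sys$gz, as.complex(extra),
                            as.complex(rhs), dmask, dvals, as.complex(x0),
                            as.integer(nn), tol, 20000L, 1.5)
    if (!res$converged)
      stop(sprintf("bioheat solve did not converge (relres %.3e)", res$relres))
    array(Re(res$x), dim = nn)
  }

  if (is.infinite(duration)) {
    Tn <- solve_step(perf_n, src_n + perf_n * thermal$T_blood,
                     array(thermal$baseline, dim = nn))
    elapsed <- Inf
  } else {
    dt <- thermal$dt
    nstep <- max(1L, ceiling(duration / dt - 1e-9))
    dt <- duration / nstep
    Tn <- array(thermal$baseline, dim = nn)
    extra <- cap_n / dt + perf_n
    for (s in seq_len(nstep)) {
      rhs <- cap_n / dt * Tn + src_n + perf_n * thermal$T_blood
      Tn <- solve_step(extra, rhs, Tn)
    }
    elapsed <- duration
  }
  Tc <- adjacent_mean(adjacent_mean(adjacent_mean(Tn, 1), 2), 3)
  structure(list(T = Tn, T_cells = Tc, time = elapsed, thermal = thermal),
            class = "temperature_volume")
}

#' Temperature-constraint report
#'
#' Checks per-region maximum temperatures against clinical limits
#' (defaults: 47 degC in any tissue; urethra 43.5, bladder 42.5, rectum
#' 41.5 degC).
#'
#' @param temperature A [solve_pennes()] result.
#' @param region_masks Named list of logical cell masks; the `"all"`
#'   limit is checked over every cell.
#' @param limits Named numeric limits (degC); must cover every region in
#'   `region_masks`.
#' @return Data frame with `region`, `max_temperature`, `limit`, `pass`,
#'   and the linear cell index `where` of the maximum.
#' @export
constraint_report <- function(temperature, region_masks = list(),
                              limits = c(all = 47, urethra = 43.5,
                                         bladder = 42.5, rectum = 41.5)) {
  Tc <- temperature$T_cells
  regions <- c(list(all = array(TRUE, dim = dim(Tc))), region_masks)
  unknown <- setdiff(names(regions), names(limits))
  if (length(unknown))
    stop("no limit defined for region(s): ", paste(unknown, collapse = ", "))
  rows <- lapply(names(regions), function(nm) {
    m <- regions[[nm]]
    if (!any(m)) return(NULL)
    mx <- max(Tc[m])
    idx <- which(m & Tc == mx)[1]
    data.frame(region = nm, max_temperature = mx,
               limit = unname(limits[nm]),
               pass = mx <= limits[nm], where = idx)
  })
  do.call(rbind, rows)
}
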