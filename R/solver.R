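#' @useDynLib ihtplan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# sum of adjacent slices with zero padding: axis length n -> n + 1
pad_pair_sum <- function(A, axis) {
  d <- dim(A)
  d2 <- d; d2[axis] <- d[axis] + 1L
  out <- array(A[1] * 0, dim = d2)
  i1 <- seq_len(d[axis])
  i2 <- i1 + 1L
  if (axis == 1L) {
    out[i1, , ] <- A
    out[i2, , ] <- out[i2, , , drop = FALSE] + A
  } else if (axis == 2L) {
    out[, i1, ] <- A
    out[, i2, ] <- out[, i2, , drop = FALSE] + A
  } else {
    out[, , i1] <- A
    out[, , i2] <- out[, , i2, drop = FALSE] + A
  }
  out
}

# mean of adjacent slices: axis length n -> n - 1
adjacent_mean <- function(A, axis) {
  d <- dim(A)
  idx1 <- lapply(d, seq_len)
  idx1[[axis]] <- seq_len(d[axis] - 1L)
  idx2 <- idx1
  idx2[[axis]] <- seq_len(d[axis] - 1L) + 1L
  (do.call(`[`, c(list(A), idx1, list(drop = FALSE))) +
     do.call(`[`, c(list(A), idx2, list(drop = FALSE)))) / 2
}

# scale an array along one axis by a per-index factor
scale_axis <- function(A, axis, fac) {
  d <- dim(A)
  shape <- c(rep(1L, axis - 1L), d[axis], rep(1L, length(d) - axis))
  A * array(rep(fac, each = prod(d[seq_len(axis - 1L)])), dim = d)
}

#' Excitation settings
#'
#' Per-electrode drive for the quasistatic solve: a common frequency,
#' per-electrode voltage amplitudes and binary polarities (0 or 180
#' degrees, encoded +1/-1).
#'
#' @param n_electrodes Number of electrodes.
#' @param amplitude Voltage amplitude(s) in volts (recycled; default 13).
#' @param polarity +1/-1 per electrode (recycled).
#' @param frequency Frequency in Hz (default 27 MHz).
#' @param reference_voltage Reference voltage for superposition weights.
#' @return An `excitation` object.
#' @export
excitation <- function(n_electrodes, amplitude = 13, polarity = 1L,
                       frequency = DEFAULT_FREQUENCY,
                       reference_voltage = 13) {
  amplitude <- rep_len(amplitude, n_electrodes)
  polarity <- rep_len(polarity, n_electrodes)
  if (any(amplitude < 0)) stop("amplitudes must be >= 0")
  if (!all(polarity %in% c(-1, 1))) stop("polarity must be +1 or -1")
  if (frequency <= 0) stop("frequency must be > 0")
  structure(list(amplitude = amplitude, polarity = as.integer(polarity),
                 frequency = frequency,
                 reference_voltage = reference_voltage),
            class = "excitation")
}

#' Electrode drive voltages of an excitation
#' @param exc An [excitation()].
#' @return Signed voltages (V) per electrode.
#' @export
drive_voltages <- function(exc) exc$amplitude * exc$polarity

# per-cell complex admittivity array
model_kappa <- function(model, frequency) {
  kap <- vapply(model$materials, admittivity, complex(1),
                frequency = frequency)
  array(kap[model$material], dim = model$grid$nc)
}

# node-index list per electrode: nodes touching >= 1 cell of the electrode
electrode_nodes <- function(model) {
  ne <- n_electrodes(model)
  out <- vector("list", ne)
  for (e in seq_len(ne)) {
    cm <- (model$electrode == e) * 1
    nm <- pad_pair_sum(pad_pair_sum(pad_pair_sum(cm, 1), 2), 3)
    out[[e]] <- which(nm > 0)
  }
  out
}

#' Assemble the electro-quasistatic system
#'
#' Conservative finite-volume discretization of
#' `div((sigma + i omega eps) grad V) = 0` on the rectilinear grid:
#' node potentials, cell-centered admittivity, and edge conductances
#' formed from the four cells sharing each edge (quarter dual-face areas),
#' which reproduces the series/parallel composition of layered media
#' exactly. Electrode nodes are Dirichlet at the drive voltages;
#' conductor interiors carry no field. Outer faces are grounded Dirichlet
#' by default (`"neumann"` per axis available for validation setups).
#'
#' @param model A [voxel_model()].
#' @param voltages Complex/numeric drive voltage per electrode (V);
#'   electrodes not driven are held at 0 V.
#' @param frequency Frequency (Hz).
#' @param boundary Character length 3, `"dirichlet"` or `"neumann"` per
#'   axis (both faces).
#' @return An `eqs_system` (edge conductances, Dirichlet data, grid).
#' @export
assemble_system <- function(model, voltages, frequency = DEFAULT_FREQUENCY,
                            boundary = c("dirichlet", "dirichlet", "dirichlet")) {
  ne <- n_electrodes(model)
  if (ne < 1) stop("model has no electrodes")
  if (length(voltages) != ne)
    stop("need one drive voltage per electrode (", ne, ")")
  boundary <- match.arg(boundary, c("dirichlet", "neumann"), several.ok = TRUE)
  boundary <- rep_len(boundary, 3L)
  g <- model$grid
  kappa <- model_kappa(model, frequency)
  sys <- stencil_conductances(g, kappa)

  nn <- g$nn
  dmask <- array(0L, dim = nn)
  dvals <- array(0 + 0i, dim = nn)
  enodes <- electrode_nodes(model)
  seen <- array(0L, dim = nn)
  for (e in seq_len(ne)) {
    if (any(seen[enodes[[e]]] > 0L))
      stop("electrodes ", e, " share nodes with another electrode; refine the grid")
    seen[enodes[[e]]] <- e
    dmask[enodes[[e]]] <- 1L
    dvals[enodes[[e]]] <- as.complex(voltages[e])
  }
  if (boundary[1] == "dirichlet") dmask[c(1, nn[1]), , ] <- 1L
  if (boundary[2] == "dirichlet") dmask[, c(1, nn[2]), ] <- 1L
  if (boundary[3] == "dirichlet") dmask[, , c(1, nn[3])] <- 1L

  structure(list(grid = g, nn = nn, gx = sys$gx, gy = sys$gy, gz = sys$gz,
                 extra = array(0 + 0i, dim = nn), dmask = dmask,
                 dvals = dvals, electrode_nodes = enodes,
                 voltages = as.complex(voltages), frequency = frequency),
            class = "eqs_system")
}

# edge conductances (S) from cell coefficient field (S/m or W/m/K)
stencil_conductances <- function(g, coefs) {
  nc <- g$nc
  D2yz <- outer(g$dy, g$dz)
  W <- coefs * array(rep(D2yz, each = nc[1]), dim = nc)
  gx <- pad_pair_sum(pad_pair_sum(W, 2), 3)
  gx <- scale_axis(gx, 1, 1e-3 / (4 * g$dx))
  D2xz <- outer(g$dx, g$dz)
  Wy <- coefs * aperm(array(rep(D2xz, each = nc[2]),
                            dim = nc[c(2, 1, 3)]), c(2, 1, 3))
  gy <- pad_pair_sum(pad_pair_sum(Wy, 1), 3)
  gy <- scale_axis(gy, 2, 1e-3 / (4 * g$dy))
  D2xy <- outer(g$dx, g$dy)
  Wz <- coefs * array(rep(D2xy, times = nc[3]), dim = nc)
  gz <- pad_pair_sum(pad_pair_sum(Wz, 1), 2)
  gz <- scale_axis(gz, 3, 1e-3 / (4 * g$dz))
  list(gx = gx, gy = gy, gz = gz)
}

#' Solve the assembled system for the complex potential
#'
#' Preconditioned (SSOR) BiCGSTAB on the complex-symmetric stencil
#' system, converged to a relative residual of `tol`. Dirichlet values
#' are reproduced exactly.
#'
#' @param system An [assemble_system()] result.
#' @param tol Relative residual tolerance.
#' @param maxit Iteration budget.
#' @param x0 Optional initial guess (node array).
#' @param ssor_omega SSOR relaxation factor.
#' @return Complex node-potential array (V) with attribute `solve_info`.
#' @export
solve_potential <- function(system, tol = 1e-9, maxit = 10000L, x0 = NULL,
                            ssor_omega = 1.9) {
  nn <- system$nn
  if (is.null(x0)) x0 <- array(0 + 0i, dim = nn)
  res <- eqs_bicgstab_cpp(system$gx, system$gy, system$gz, system$extra,
                          array(0 + 0i, dim = nn), system$dmask,
                          system$dvals, as.complex(x0), as.integer(nn),
                          tol, as.integer(maxit), ssor_omega)
  if (!res$converged)
    stop(sprintf("EQS solve did not converge: relative residual %.3e after %d iterations",
                 res$relres, res$iterations))
  V <- array(res$x, dim = nn)
  attr(V, "solve_info") <- list(relres = res$relres,
                                iterations = res$iterations)
  V
}

#' Cell-centered electric field from node potentials
#'
#' `E = -grad V` by differencing node potentials across each cell face
#' (face-averaged), honoring the non-uniform spacing; components are
#' averaged to cell centers.
#'
#' @param V Complex node-potential array (V).
#' @param grid The [rectilinear_grid()].
#' @return List of complex cell arrays `Ex`, `Ey`, `Ez` (V/m).
#' @export
efield_from_potential <- function(V, grid) {
  nn <- grid$nn
  dVx <- V[-1, , , drop = FALSE] - V[-nn[1], , , drop = FALSE]
  Ex <- -scale_axis(adjacent_mean(adjacent_mean(dVx, 2), 3), 1,
                    1 / (grid$dx * 1e-3))
  dVy <- V[, -1, , drop = FALSE] - V[, -nn[2], , drop = FALSE]
  Ey <- -scale_axis(adjacent_mean(adjacent_mean(dVy, 1), 3), 2,
                    1 / (grid$dy * 1e-3))
  dVz <- V[, , -1, drop = FALSE] - V[, , -nn[3], drop = FALSE]
  Ez <- -scale_axis(adjacent_mean(adjacent_mean(dVz, 1), 2), 3,
                    1 / (grid$dz * 1e-3))
  list(Ex = Ex, Ey = Ey, Ez = Ez)
}

#' Specific absorption rate from the electric field
#'
#' Per cell, `SAR = sigma |E|^2 / (2 rho)` (W/kg) with the complex field
#' magnitude `|E|^2 = |Ex|^2 + |Ey|^2 + |Ez|^2`; zero wherever
#' `sigma = 0` (air, conductor interiors).
#'
#' @param E Field list from [efield_from_potential()] or
#'   [combine_fields()].
#' @param model The [voxel_model()].
#' @return List with `sar` (cell array, W/kg) and `total_power` (W).
#' @export
sar_from_field <- function(E, model) {
  sig <- vapply(model$materials, function(m) if (isTRUE(m$pec)) 0 else m$sigma,
                numeric(1))
  rho <- vapply(model$materials, function(m) m$rho, numeric(1))
  sig_c <- array(sig[model$material], dim = model$grid$nc)
  rho_c <- array(rho[model$material], dim = model$grid$nc)
  E2 <- Mod(E$Ex)^2 + Mod(E$Ey)^2 + Mod(E$Ez)^2
  sar <- sig_c * E2 / (2 * rho_c)
  list(sar = sar, total_power = sum(sar * rho_c * cell_volumes(model$grid)),
       rho = rho_c)
}

#' Per-electrode input power
#'
#' `P_e = Re(V_e conj(I_e)) / 2` with `I_e` the total complex current
#' (conduction + displacement) leaving the electrode's Dirichlet region,
#' obtained by applying the full stencil operator to the solved
#' potential and summing the net nodal currents over the electrode.
#'
#' @param V Solved node potentials.
#' @param system The [assemble_system()] used to solve.
#' @return Numeric vector of powers (W) per electrode.
#' @export
electrode_power <- function(V, system) {
  y <- eqs_apply_cpp(system$gx, system$gy, system$gz, system$extra,
                     as.complex(V), as.integer(system$nn))
  vapply(seq_along(system$electrode_nodes), function(e) {
    idx <- system$electrode_nodes[[e]]
    Ie <- sum(y[idx])
    0.5 * Re(system$voltages[e] * Conj(Ie))
  }, numeric(1))
}

#' One-call field solve for a set of electrode voltages
#'
#' Convenience wrapper: assemble, solve, differentiate, and compute SAR
#' and per-electrode powers.
#'
#' @inheritParams assemble_system
#' @inheritParams solve_potential
#' @return List with `V`, `E`, `sar` (a [sar_from_field()] result),
#'   `power` (W per electrode) and the `system`.
#' @export
solve_electrodes <- function(model, voltages, frequency = DEFAULT_FREQUENCY,
                             boundary = c("dirichlet", "dirichlet", "dirichlet"),
                             tol = 1e-9, maxit = 10000L, x0 = NULL) {
  system <- assemble_system(model, voltages, frequency, boundary)
  V <- solve_potential(system, tol = tol, maxit = maxit, x0 = x0)
  E <- efield_from_potential(V, model$grid)
  list(V = V, E = E, sar = sar_from_field(E, model),
       power = electrode_power(V, system), system = system)
}
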