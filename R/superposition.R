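#' Per-electrode field basis
#'
#' Solves the quasistatic problem once per electrode, driving that
#' electrode at the reference voltage with every other electrode
#' grounded. By linearity, the field of any amplitude/polarity setting
#' is a weighted sum of these basis fields ([combine_fields()]), so plan
#' re-evaluation needs no further solves.
#'
#' @param model A [voxel_model()].
#' @param reference_voltage Drive voltage of the active electrode (V).
#' @param frequency Frequency (Hz).
#' @param tol,maxit Solver settings, see [solve_potential()].
#' @param keep_potentials Keep the per-electrode potential arrays
#'   (memory-heavy; needed only for diagnostics).
#' @return A `field_basis`: per-electrode `E` fields, the electrode
#'   admittance-current matrix `currents` (`currents[e, i]` = complex
#'   current into electrode `e` during basis solve `i`), reference
#'   voltage and grid.
#' @export
compute_basis <- function(model, reference_voltage = 13,
                          frequency = DEFAULT_FREQUENCY, tol = 1e-9,
                          maxit = 10000L, keep_potentials = FALSE) {
  ne <- n_electrodes(model)
  fields <- vector("list", ne)
  pots <- if (keep_potentials) vector("list", ne) else NULL
  currents <- matrix(0 + 0i, ne, ne)
  for (i in seq_len(ne)) {
    v <- rep(0, ne)
    v[i] <- reference_voltage
    sol <- tryCatch(
      solve_electrodes(model, v, frequency, tol = tol, maxit = maxit),
      error = function(e) stop("basis solve for electrode ", i, " failed: ",
                               conditionMessage(e)))
    fields[[i]] <- sol$E
    if (keep_potentials) pots[[i]] <- sol$V
    y <- eqs_apply_cpp(sol$system$gx, sol$system$gy, sol$system$gz,
                       sol$system$extra, as.complex(sol$V),
                       as.integer(sol$system$nn))
    for (e in seq_len(ne)) {
      currents[e, i] <- sum(y[sol$system$electrode_nodes[[e]]])
    }
  }
  structure(list(fields = fields, currents = currents,
                 reference_voltage = reference_voltage,
                 frequency = frequency, grid = model$grid,
                 potentials = pots),
            class = "field_basis")
}

#' @export
print.field_basis <- function(x, ...) {
  cat(sprintf("<field_basis> %d electrode field(s) at %g V reference, %g MHz\n",
              length(x$fields), x$reference_voltage, x$frequency / 1e6))
  invisible(x)
}

#' Superpose basis fields for an excitation
#'
#' `E_tot = sum_i w_i E_i` with weights
#' `w_i = amplitude_i / reference_voltage * polarity_i`.
#'
#' @param basis A [compute_basis()] result.
#' @param exc An [excitation()] with one entry per basis field.
#' @return Field list (`Ex`, `Ey`, `Ez`) on the basis grid.
#' @export
combine_fields <- function(basis, exc) {
  ne <- length(basis$fields)
  if (length(exc$amplitude) != ne)
    stop("excitation has ", length(exc$amplitude),
         " electrodes but basis has ", ne)
  w <- drive_voltages(exc) / basis$reference_voltage
  Ex <- basis$fields[[1]]$Ex * w[1]
  Ey <- basis$fields[[1]]$Ey * w[1]
  Ez <- basis$fields[[1]]$Ez * w[1]
  for (i in seq_len(ne)[-1]) {
    if (w[i] == 0) next
    Ex <- Ex + basis$fields[[i]]$Ex * w[i]
    Ey <- Ey + basis$fields[[i]]$Ey * w[i]
    Ez <- Ez + basis$fields[[i]]$Ez * w[i]
  }
  list(Ex = Ex, Ey = Ey, Ez = Ez)
}

#' SAR of a superposed field
#'
#' Delegates to [sar_from_field()]; by linearity the result matches a
#' direct multi-electrode solve with the same drive voltages.
#'
#' @param Etot Combined field from [combine_fields()].
#' @param model The [voxel_model()].
#' @return A [sar_from_field()] result.
#' @export
total_sar <- function(Etot, model) sar_from_field(Etot, model)

#' Per-electrode powers of a superposed excitation
#'
#' Uses the basis current matrix: `I_e = sum_i w_i currents[e, i]`,
#' `P_e = Re(V_e conj(I_e)) / 2`. No solve required.
#'
#' @param basis A [compute_basis()] result.
#' @param exc An [excitation()].
#' @return Powers (W) per electrode.
#' @export
basis_powers <- function(basis, exc) {
  w <- drive_voltages(exc) / basis$reference_voltage
  Ie <- as.vector(basis$currents %*% w)
  Ve <- w * basis$reference_voltage
  0.5 * Re(Ve * Conj(Ie))
}

#' Rescale amplitudes to a per-electrode input power target
#'
#' Fixed-point iteration `a_e <- a_e sqrt(target / P_e)` on the basis
#' current matrix (no re-solves) until every active electrode's input
#' power is within `tol` of the target. Polarities are unchanged.
#'
#' @param basis A [compute_basis()] result.
#' @param exc Starting [excitation()].
#' @param target_power Target input power per electrode (W).
#' @param tol Relative power tolerance (default 1%).
#' @param maxit Maximum fixed-point iterations.
#' @return The rescaled [excitation()], with attribute `power`.
#' @export
normalize_power <- function(basis, exc, target_power, tol = 0.01,
                            maxit = 20L) {
  if (target_power < 0) stop("target_power must be >= 0")
  if (target_power == 0) {
    exc$amplitude[] <- 0
    attr(exc, "power") <- rep(0, length(exc$amplitude))
    return(exc)
  }
  a <- exc$amplitude
  if (all(a == 0)) a <- rep(basis$reference_voltage, length(a))
  for (it in seq_len(maxit)) {
    exc$amplitude <- a
    P <- basis_powers(basis, exc)
    if (any(P <= 0))
      stop("non-positive electrode input power during normalization; ",
           "check polarities")
    if (max(abs(P - target_power)) <= tol * target_power) {
      attr(exc, "power") <- P
      return(exc)
    }
    a <- a * sqrt(target_power / P)
  }
  stop(sprintf("power normalization did not converge in %d iterations (max dev %.2f%%)",
               maxit, 100 * max(abs(P / target_power - 1))))
}
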