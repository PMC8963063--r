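#' Impedance of two concentric cylindrical conductors
#'
#' Lumped impedance of the annular layer between two coaxial cylindrical
#' conductors of length `l`, filled with a material of conductivity
#' `sigma` and permittivity `eps`:
#' `Z = ln(d0/di) / (2 pi l (sigma + i omega eps))`.
#'
#' @param d0,di Outer/inner diameter (mm), `d0 > di > 0`.
#' @param l Length (mm), `> 0`.
#' @param sigma Conductivity (S/m).
#' @param eps Absolute permittivity (F/m).
#' @param frequency Frequency (Hz).
#' @return Complex impedance (Ohm).
#' @export
coaxial_impedance <- function(d0, di, l, sigma, eps,
                              frequency = DEFAULT_FREQUENCY) {
  check_shell(d0, di, l)
  if (sigma == 0 && eps == 0) stop("sigma and eps cannot both be zero")
  omega <- 2 * pi * frequency
  log(d0 / di) / (2 * pi * (l * 1e-3) * complex(real = sigma,
                                                imaginary = omega * eps))
}

#' Capacitance of a coaxial layer
#'
#' `C = 2 pi eps l / ln(d0/di)` for the annulus between concentric
#' cylindrical conductors.
#'
#' @inheritParams coaxial_impedance
#' @return Capacitance (F).
#' @export
coaxial_capacitance <- function(d0, di, l, eps) {
  check_shell(d0, di, l)
  if (eps <= 0) stop("eps must be > 0")
  2 * pi * eps * (l * 1e-3) / log(d0 / di)
}

#' Capacitance of a coaxial cuboid layer
#'
#' `C = 4 eps l / ln(a_o/a_i)` for the layer between two concentric
#' square cuboid shells with outer/inner edge lengths `a_o`/`a_i`.
#'
#' @param a_o,a_i Outer/inner edge lengths (mm), `a_o > a_i > 0`.
#' @param l Length (mm).
#' @param eps Absolute permittivity (F/m).
#' @return Capacitance (F).
#' @export
cuboid_capacitance <- function(a_o, a_i, l, eps) {
  check_shell(a_o, a_i, l)
  if (eps <= 0) stop("eps must be > 0")
  4 * eps * (l * 1e-3) / log(a_o / a_i)
}

#' Capacitance-preserving adapted permittivity
#'
#' When a thin dielectric layer with edges `a_o`/`a_i` is thickened to
#' `a_o_prime`/`a_i_prime` (to relax voxeling requirements), assigning
#' the layer `eps' = eps * ln(a_o'/a_i') / ln(a_o/a_i)` preserves the
#' layer capacitance exactly for any length, so the field outside the
#' applicator is unchanged.
#'
#' @param eps Original absolute permittivity (F/m).
#' @param a_o,a_i Original outer/inner edges (mm).
#' @param a_o_prime,a_i_prime Adapted outer/inner edges (mm).
#' @return Adapted absolute permittivity (F/m).
#' @export
equivalent_permittivity <- function(eps, a_o, a_i, a_o_prime, a_i_prime) {
  check_shell(a_o, a_i, 1)
  check_shell(a_o_prime, a_i_prime, 1)
  eps * log(a_o_prime / a_i_prime) / log(a_o / a_i)
}

#' Surface-equivalent cuboid edge of a cylinder
#'
#' Edge length of the square cuboid with the same lateral surface area
#' (and length) as a cylinder of diameter `d`: `a = pi d / 4`. Note that
#' the edge ratio of two such cuboids equals the diameter ratio of the
#' cylinders, so log-ratio quantities are preserved by this mapping.
#'
#' @param d Cylinder diameter (mm).
#' @return Edge length (mm).
#' @export
cuboid_edge_from_cylinder <- function(d) {
  if (d <= 0) stop("d must be > 0")
  pi * d / 4
}

check_shell <- function(outer, inner, l) {
  if (inner <= 0) stop("inner dimension must be > 0")
  if (outer <= inner) stop("outer dimension must exceed inner dimension")
  if (l <= 0) stop("length must be > 0")
  invisible(TRUE)
}

#' Lumped-element equivalence report for an applicator
#'
#' Computes, for a given applicator geometry: the impedance and
#' capacitance of the thin cylindrical dielectric layer, the
#' surface-equivalent cuboid edges, and the adapted relative permittivity
#' of the thickened simplified dielectric layer.
#'
#' @param spec An [applicator_spec()].
#' @param dielectric A [material()] for the dielectric layer (defaults to
#'   Parylene C from [tissue_table()]).
#' @param frequency Frequency (Hz).
#' @param match `"cuboid"` (default) preserves the capacitance of the
#'   surface-equivalent cuboid layer; `"coaxial"` matches the coaxial
#'   layer capacitance value instead (differs by a factor `pi/2`).
#' @return List with `Z` (Ohm), `C_coaxial`, `C_cuboid`, `C_simplified`
#'   (F), cuboid edges (mm) and `eps_prime_r` (relative).
#' @export
equivalence_report <- function(spec, dielectric = NULL,
                               frequency = DEFAULT_FREQUENCY,
                               match = c("cuboid", "coaxial")) {
  match <- match.arg(match)
  if (is.null(dielectric)) dielectric <- tissue_table()[["Parylene C"]]
  eps <- dielectric$eps_r * EPS0
  d0 <- spec$dielectric_od
  di <- spec$electrode_od
  l <- spec$electrode_length
  a_i <- cuboid_edge_from_cylinder(di)
  a_o <- cuboid_edge_from_cylinder(d0)
  ai_p <- spec$simplified_dielectric_edges[1]
  ao_p <- spec$simplified_dielectric_edges[2]
  eps_prime <- if (match == "cuboid") {
    equivalent_permittivity(eps, a_o, a_i, ao_p, ai_p)
  } else {
    # choose eps' so the cuboid layer capacitance equals the coaxial value
    (pi / 2) * equivalent_permittivity(eps, d0, di, ao_p, ai_p)
  }
  list(
    Z = coaxial_impedance(d0, di, l, dielectric$sigma, eps, frequency),
    C_coaxial = coaxial_capacitance(d0, di, l, eps),
    C_cuboid = cuboid_capacitance(a_o, a_i, l, eps),
    C_simplified = cuboid_capacitance(ao_p, ai_p, l, eps_prime),
    cuboid_edges = c(inner = a_i, outer = a_o),
    simplified_edges = c(inner = ai_p, outer = ao_p),
    eps_prime_r = eps_prime / EPS0,
    match = match
  )
}
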