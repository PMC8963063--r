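#' Physical constants
#'
#' Vacuum permittivity (F/m) and the default operating frequency of the
#' dual-electrode capacitive applicators (Hz).
#' @keywords internal
EPS0 <- 8.8541878128e-12

#' @rdname EPS0
#' @keywords internal
DEFAULT_FREQUENCY <- 27e6

#' Construct a material
#'
#' A material bundles the electrical properties that enter the
#' electro-quasistatic solve (conductivity `sigma` in S/m and relative
#' permittivity `eps_r` at the operating frequency) with the thermal
#' properties used by the Pennes bioheat solver (mass density `rho` in
#' kg/m^3, specific heat `c` in J/kg/K, thermal conductivity `k` in
#' W/m/K, and blood perfusion rate in mL/kg/min; `NA` for non-tissue
#' materials).
#'
#' @param name Material name.
#' @param sigma Electric conductivity (S/m), `>= 0`.
#' @param eps_r Relative permittivity (dimensionless), `>= 1`.
#' @param rho Mass density (kg/m^3), `> 0`.
#' @param c Specific heat capacity (J/kg/K).
#' @param k Thermal conductivity (W/m/K).
#' @param perfusion Perfusion rate (mL/kg/min) or `NA`.
#' @param pec Logical; `TRUE` marks a perfect electric conductor whose
#'   interior is excluded from the field solve.
#' @return An object of class `iht_material`.
#' @export
material <- function(name, sigma, eps_r, rho, c, k, perfusion = NA_real_,
                     pec = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!pec) {
    if (sigma < 0) stop("sigma must be >= 0")
    if (eps_r < 1) stop("eps_r must be >= 1")
  }
  if (rho <= 0) stop("rho must be > 0")
  if (!is.na(perfusion) && perfusion < 0) stop("perfusion must be >= 0")
  structure(
    list(name = name, sigma = sigma, eps_r = eps_r, rho = rho, c = c,
         k = k, perfusion = perfusion, pec = pec),
    class = "iht_material"
  )
}

#' @export
print.iht_material <- function(x, ...) {
  cat(sprintf(
    "<material> %s: sigma=%g S/m, eps_r=%g, rho=%g kg/m3, c=%g J/kg/K, k=%g W/m/K, perfusion=%s mL/kg/min%s\n",
    x$name, x$sigma, x$eps_r, x$rho, x$c, x$k,
    ifelse(is.na(x$perfusion), "-", format(x$perfusion)),
    if (isTRUE(x$pec)) " [PEC]" else ""))
  invisible(x)
}

#' Tissue and applicator material property table
#'
#' Returns the packaged table of electrical (27 MHz) and thermal
#' properties for the applicator materials (POM catheter, Parylene C
#' dielectric, air lumen) and the pelvic tissues used in the benchmark
#' and patient models.
#'
#' @param path Optional path to an alternative CSV with the same columns
#'   (`name, rho, sigma, eps_r, c, k, perfusion`).
#' @return A named list of [material()] objects.
#' @examples
#' tab <- tissue_table()
#' tab[["Muscle"]]$sigma
#' @export
tissue_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tissue_properties.csv", package = "ihtplan")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    material(df$name[i], df$sigma[i], df$eps_r[i], df$rho[i],
             df$c[i], df$k[i], df$perfusion[i])
  })
  names(out) <- df$name
  out
}

#' Perfect-electric-conductor placeholder material
#'
#' Electrode shells are modeled as equipotential Dirichlet regions; the
#' interior is excluded from the solve, so sigma/eps of this entry are
#' never used by the field solver. Thermal properties follow the POM
#' catheter (the copper shell is tens of micrometers thick and thermally
#' negligible).
#' @return An [material()] with `pec = TRUE`.
#' @export
pec_material <- function() {
  material("PEC", sigma = 0, eps_r = 1, rho = 1150, c = 1670, k = 0.230,
           perfusion = NA_real_, pec = TRUE)
}

#' Complex admittivity of a material
#'
#' `kappa = sigma + i * omega * eps0 * eps_r`, the coefficient of the
#' electro-quasistatic operator. PEC materials return 0 (their interior
#' carries no solved field).
#'
#' @param m An [material()].
#' @param frequency Frequency in Hz.
#' @return Complex scalar (S/m).
#' @export
admittivity <- function(m, frequency = DEFAULT_FREQUENCY) {
  if (isTRUE(m$pec)) return(0 + 0i)
  omega <- 2 * pi * frequency
  complex(real = m$sigma, imaginary = omega * EPS0 * m$eps_r)
}
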