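#' Dual-electrode applicator geometry
#'
#' Describes one interstitial applicator: a hollow POM catheter carrying
#' two 20 mm copper electrodes separated by a 5 mm gap, the whole rod
#' coated by a thin Parylene C dielectric. The simplified cuboid
#' equivalent uses thicker square shells (electrode edges 1.0 -> 1.4 mm,
#' dielectric 1.4 -> 1.8 mm) with a capacitance-preserving adapted
#' permittivity (see [equivalence_report()]).
#'
#' Axial layout, measured backwards from the tip: `tip_offset` of bare
#' catheter, distal electrode (`electrode_length`), `electrode_gap`,
#' proximal electrode, `back_margin` of bare catheter. The rod ends
#' there; feeder lines are not modeled (electrodes are driven directly
#' as equipotential regions).
#'
#' @param tip_position Numeric length-3, tip coordinates (mm).
#' @param direction Numeric length-3 axis direction (shaft -> tip);
#'   normalized internally.
#' @param catheter_od,catheter_id Catheter outer/inner diameter (mm).
#' @param electrode_od Outer diameter of the cylindrical electrode shell (mm).
#' @param dielectric_od Outer diameter of the dielectric coating (mm).
#' @param electrode_length,electrode_gap Electrode length and
#'   inter-electrode gap (mm).
#' @param simplified_electrode_edges,simplified_dielectric_edges Inner and
#'   outer full edge lengths of the simplified cuboid shells (mm).
#' @param tip_offset,back_margin Bare catheter lengths beyond the distal
#'   and proximal electrode (mm).
#' @param eps_prime_r Adapted relative permittivity of the simplified
#'   dielectric; computed from the geometry when `NULL`.
#' @return An `applicator_spec` object.
#' @export
applicator_spec <- function(tip_position, direction = c(0, 0, 1),
                            catheter_od = 2.0, catheter_id = 1.66,
                            electrode_od = 2.06, dielectric_od = 2.12,
                            electrode_length = 20, electrode_gap = 5,
                            simplified_electrode_edges = c(1.0, 1.4),
                            simplified_dielectric_edges = c(1.4, 1.8),
                            tip_offset = 2, back_margin = 2,
                            eps_prime_r = NULL) {
  stopifnot(length(tip_position) == 3L, length(direction) == 3L)
  if (!(catheter_id < catheter_od && catheter_od < electrode_od &&
        electrode_od < dielectric_od))
    stop("diameters must satisfy catheter_id < catheter_od < electrode_od < dielectric_od")
  if (electrode_length <= 0 || electrode_gap <= 0)
    stop("electrode length and gap must be > 0")
  if (diff(simplified_electrode_edges) <= 0 ||
      diff(simplified_dielectric_edges) <= 0)
    stop("simplified shell edges must be increasing")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be non-zero")
  spec <- structure(list(
    tip_position = as.numeric(tip_position),
    direction = as.numeric(direction) / nrm,
    catheter_od = catheter_od, catheter_id = catheter_id,
    electrode_od = electrode_od, dielectric_od = dielectric_od,
    electrode_length = electrode_length, electrode_gap = electrode_gap,
    simplified_electrode_edges = simplified_electrode_edges,
    simplified_dielectric_edges = simplified_dielectric_edges,
    tip_offset = tip_offset, back_margin = back_margin
  ), class = "applicator_spec")
  if (is.null(eps_prime_r)) {
    eps_prime_r <- equivalence_report(spec)$eps_prime_r
  }
  spec$eps_prime_r <- eps_prime_r
  spec
}

# axial intervals (distance from tip, negative = towards shaft):
# list(distal = c(lo, hi), proximal = c(lo, hi), rod = c(lo, hi))
applicator_axial_extents <- function(spec) {
  l <- spec$electrode_length; g <- spec$electrode_gap
  d_hi <- -spec$tip_offset
  d_lo <- d_hi - l
  p_hi <- d_lo - g
  p_lo <- p_hi - l
  list(distal = c(d_lo, d_hi), proximal = c(p_lo, p_hi),
       rod = c(p_lo - spec$back_margin, 0))
}

#' Active-electrode bounding box of a z-parallel applicator
#' @keywords internal
applicator_active_z <- function(spec) {
  ext <- applicator_axial_extents(spec)
  zt <- spec$tip_position[3]
  s <- sign(spec$direction[3])
  sort(zt + s * c(ext$proximal[1], ext$distal[2]))
}

#' Create an empty voxel model
#'
#' @param grid A [rectilinear_grid()].
#' @param materials Named list of [material()]s (defaults to
#'   [tissue_table()] plus the PEC placeholder).
#' @param background Name of the material filling the model.
#' @return A `voxel_model` with per-cell material ids, electrode index
#'   array (0 = none), applicator list, and an unset VOI.
#' @export
voxel_model <- function(grid, materials = NULL, background = "Muscle") {
  if (is.null(materials)) {
    materials <- tissue_table()
    materials[["PEC"]] <- pec_material()
  }
  if (!background %in% names(materials))
    stop("background material not in material table: ", background)
  m <- structure(list(
    grid = grid,
    materials = materials,
    material = array(match(background, names(materials)), dim = grid$nc),
    electrode = array(0L, dim = grid$nc),
    applicators = list(),
    voi = NULL
  ), class = "voxel_model")
  m
}

#' @export
print.voxel_model <- function(x, ...) {
  cat(sprintf("<voxel_model> %d x %d x %d cells, %d applicator(s), %d electrode(s)\n",
              x$grid$nc[1], x$grid$nc[2], x$grid$nc[3],
              length(x$applicators), n_electrodes(x)))
  tab <- table(names(x$materials)[x$material])
  cat("  materials:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of electrodes in a model
#' @param model A [voxel_model()].
#' @export
n_electrodes <- function(model) 2L * length(model$applicators)

material_id <- function(model, name) {
  i <- match(name, names(model$materials))
  if (is.na(i)) stop("unknown material: ", name)
  i
}

add_material <- function(model, mat) {
  if (!mat$name %in% names(model$materials))
    model$materials[[mat$name]] <- mat
  model
}

#' Assign a material to all cells inside a box
#' @param model A [voxel_model()].
#' @param box A [box3()] (half-open, cells selected by center).
#' @param name Material name present in the model's table.
#' @return The updated model.
#' @export
set_material_region <- function(model, box, name) {
  mask <- cells_in_box(model$grid, box)
  model$material[mask] <- material_id(model, name)
  model
}

#' Per-cell VOI mask
#' @param model A [voxel_model()] with a VOI box set.
#' @return Logical array over cells.
#' @export
voi_mask <- function(model) {
  if (is.null(model$voi)) stop("model has no VOI set")
  cells_in_box(model$grid, model$voi)
}

# index ranges of cell centers within [lo, hi]
range_idx <- function(centers, lo, hi) which(centers >= lo & centers <= hi)

#' Rasterize the detailed cylindrical applicator
#'
#' Assigns, from the axis outward: air lumen, POM catheter shell, copper
#' electrode shell (marked in the electrode index array over each
#' electrode's axial extent), and the Parylene C dielectric coating.
#' Cell materials are decided by a supersampled majority vote over the
#' cell cross-section (4x4 stratified sample points, offsets +/-1/8 and
#' +/-3/8 of the cell size, which keep sample points off the shell
#' boundaries and make the vote unbiased for thin shells), stabilizing
#' the rasterization of the 0.03 mm layers on non-uniform grids.
#' Restricted to z-parallel axes.
#'
#' @param model A [voxel_model()].
#' @param spec An [applicator_spec()] with `direction` parallel to z.
#' @return The updated model; the applicator is appended and its two
#'   electrodes (proximal, distal) receive consecutive indices.
#' @export
rasterize_applicator_detailed <- function(model, spec) {
  d <- spec$direction
  if (abs(abs(d[3]) - 1) > 1e-9)
    stop("detailed rasterization requires a z-parallel applicator axis")
  g <- model$grid
  ext <- applicator_axial_extents(spec)
  zt <- spec$tip_position[3]; s <- sign(d[3])
  zr <- sort(zt + s * ext$rod)
  zp <- sort(zt + s * ext$proximal)
  zd <- sort(zt + s * ext$distal)
  x0 <- spec$tip_position[1]; y0 <- spec$tip_position[2]
  rmax <- spec$dielectric_od / 2
  ix <- range_idx(g$cx, x0 - rmax - 0.5, x0 + rmax + 0.5)
  iy <- range_idx(g$cy, y0 - rmax - 0.5, y0 + rmax + 0.5)
  iz <- range_idx(g$cz, zr[1], zr[2])
  if (!length(ix) || !length(iy) || !length(iz))
    stop("applicator lies outside the grid")

  # transverse stratified supersample: vote for ring index per (x, y) cell
  # rings: 0 outside, 1 dielectric coat, 2 electrode shell annulus,
  #        3 catheter wall, 4 air lumen
  radii <- c(spec$catheter_id, spec$catheter_od, spec$electrode_od,
             spec$dielectric_od) / 2
  nx <- length(ix); ny <- length(iy)
  votes <- array(0L, dim = c(nx, ny, 5L))
  offs <- c(-3, -1, 1, 3) / 8
  for (ox in offs) for (oy in offs) {
    px <- g$cx[ix] + ox * g$dx[ix]
    py <- g$cy[iy] + oy * g$dy[iy]
    r <- sqrt(outer((px - x0)^2, (py - y0)^2, `+`))
    ring <- matrix(0L, nx, ny)
    ring[r < radii[4]] <- 1L
    ring[r < radii[3]] <- 2L
    ring[r < radii[2]] <- 3L
    ring[r < radii[1]] <- 4L
    for (k in 0:4) votes[, , k + 1L] <- votes[, , k + 1L] + (ring == k)
  }
  ring2d <- 5L - apply(votes[, , 5:1, drop = FALSE], c(1, 2), which.max)  # innermost wins ties

  id_air <- material_id(model, "Air")
  id_pom <- material_id(model, "POM")
  id_par <- material_id(model, "Parylene C")
  model <- add_material(model, pec_material())
  id_pec <- material_id(model, "PEC")

  napp <- length(model$applicators)
  e_prox <- 2L * napp + 1L
  e_dist <- 2L * napp + 2L

  claimed <- ring2d > 0L
  zc <- g$cz[iz]
  in_prox <- zc >= zp[1] & zc < zp[2]
  in_dist <- zc >= zd[1] & zc < zd[2]
  for (kk in seq_along(iz)) {
    k <- iz[kk]
    sub <- model$material[ix, iy, k]
    esub <- model$electrode[ix, iy, k]
    if (any(esub[claimed] > 0L))
      stop("applicator overlaps a previously rasterized applicator")
    on_elec <- in_prox[kk] || in_dist[kk]
    sub[ring2d == 1L] <- id_par
    if (on_elec) {
      sub[ring2d == 2L] <- id_pec
      esub[ring2d == 2L] <- if (in_prox[kk]) e_prox else e_dist
    } else {
      sub[ring2d == 2L] <- id_par
    }
    sub[ring2d == 3L] <- id_pom
    sub[ring2d == 4L] <- id_air
    model$material[ix, iy, k] <- sub
    model$electrode[ix, iy, k] <- esub
  }
  spec$mode <- "detailed"
  model$applicators <- c(model$applicators, list(spec))
  model
}

#' Rasterize the simplified cuboid applicator
#'
#' Point-in-cuboid classification in the applicator frame: POM core
#' (transverse Chebyshev half-edge < 0.5 mm), conducting electrode shell
#' (0.5 -> 0.7 mm, over each electrode's axial extent; POM in the gap),
#' and a dielectric shell (0.7 -> 0.9 mm) carrying the adapted
#' permittivity `eps_prime_r` with Parylene C conductivity. Arbitrary
#' axis directions are accepted.
#'
#' @inheritParams rasterize_applicator_detailed
#' @return The updated model.
#' @export
rasterize_applicator_simplified <- function(model, spec) {
  g <- model$grid
  d <- spec$direction
  # orthonormal transverse frame, deterministic
  ref <- if (abs(d[1]) <= abs(d[2]) && abs(d[1]) <= abs(d[3])) c(1, 0, 0)
         else if (abs(d[2]) <= abs(d[3])) c(0, 1, 0) else c(0, 0, 1)
  u <- ref - sum(ref * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])

  ext <- applicator_axial_extents(spec)
  he_core <- spec$simplified_electrode_edges[1] / 2
  he_elec <- spec$simplified_electrode_edges[2] / 2
  he_diel <- spec$simplified_dielectric_edges[2] / 2

  # bounding box of the rod in world coordinates
  ends <- cbind(spec$tip_position + d * ext$rod[1],
                spec$tip_position + d * ext$rod[2])
  pad <- he_diel * sqrt(2) + 0.2
  ix <- range_idx(g$cx, min(ends[1, ]) - pad, max(ends[1, ]) + pad)
  iy <- range_idx(g$cy, min(ends[2, ]) - pad, max(ends[2, ]) + pad)
  iz <- range_idx(g$cz, min(ends[3, ]) - pad, max(ends[3, ]) + pad)
  if (!length(ix) || !length(iy) || !length(iz))
    stop("applicator lies outside the grid")

  px <- g$cx[ix]; py <- g$cy[iy]; pz <- g$cz[iz]
  X <- array(rep(px, times = length(iy) * length(iz)),
             dim = c(length(ix), length(iy), length(iz)))
  Y <- array(rep(rep(py, each = length(ix)), times = length(iz)),
             dim = dim(X))
  Z <- array(rep(pz, each = length(ix) * length(iy)), dim = dim(X))
  rx <- X - spec$tip_position[1]
  ry <- Y - spec$tip_position[2]
  rz <- Z - spec$tip_position[3]
  ax <- round(rx * d[1] + ry * d[2] + rz * d[3], 9)  # axial coord from tip
  tu <- rx * u[1] + ry * u[2] + rz * u[3]
  tv <- rx * v[1] + ry * v[2] + rz * v[3]
  # snapped so half-open shell boundaries classify mirrored cells alike
  cheb <- round(pmax(abs(tu), abs(tv)), 9)

  in_rod <- ax >= ext$rod[1] & ax < ext$rod[2]
  in_prox <- ax >= ext$proximal[1] & ax < ext$proximal[2]
  in_dist <- ax >= ext$distal[1] & ax < ext$distal[2]

  core <- in_rod & cheb < he_core
  shell <- in_rod & cheb >= he_core & cheb < he_elec
  diel <- in_rod & cheb >= he_elec & cheb < he_diel

  esub <- model$electrode[ix, iy, iz]
  if (any(esub[core | shell | diel] > 0L))
    stop("applicator overlaps a previously rasterized applicator")

  diel_name <- sprintf("Dielectric eps_r=%.4f", spec$eps_prime_r)
  par <- model$materials[["Parylene C"]]
  model <- add_material(model, material(
    diel_name, sigma = par$sigma, eps_r = spec$eps_prime_r,
    rho = par$rho, c = par$c, k = par$k))
  model <- add_material(model, pec_material())
  id_pom <- material_id(model, "POM")
  id_pec <- material_id(model, "PEC")
  id_diel <- material_id(model, diel_name)

  napp <- length(model$applicators)
  e_prox <- 2L * napp + 1L
  e_dist <- 2L * napp + 2L

  sub <- model$material[ix, iy, iz]
  sub[core] <- id_pom
  sub[shell & !(in_prox | in_dist)] <- id_pom
  sub[shell & (in_prox | in_dist)] <- id_pec
  sub[diel] <- id_diel
  esub[shell & in_prox] <- e_prox
  esub[shell & in_dist] <- e_dist
  model$material[ix, iy, iz] <- sub
  model$electrode[ix, iy, iz] <- esub
  spec$mode <- "simplified"
  model$applicators <- c(model$applicators, list(spec))
  model
}
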