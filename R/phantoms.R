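#' Applicator lattice layout
#'
#' Transverse (x, y) positions of parallel applicators on a rectangular
#' lattice. Up to 6 applicators are placed on a single centered row; the
#' default 18-applicator layout is a 5-column, 4-row 9 mm lattice with
#' the two upper-central positions removed (mimicking the free corridor
#' left for the urethra in a prostate implant).
#'
#' @param n Number of applicators.
#' @param spacing Lattice spacing (mm).
#' @return Data frame with columns `x`, `y` (mm).
#' @export
applicator_layout <- function(n = 18, spacing = 9) {
  if (n < 1) stop("n must be >= 1")
  if (n <= 6) {
    return(data.frame(x = (seq_len(n) - (n + 1) / 2) * spacing, y = 0))
  }
  ncol <- 5L
  nrow <- ceiling((n + 2) / ncol)
  xs <- (seq_len(ncol) - (ncol + 1) / 2) * spacing
  ys <- (seq_len(nrow) - 1) * spacing
  pts <- expand.grid(x = xs, y = ys)
  # drop upper-central positions first (highest rows, central column)
  drop <- nrow(pts) - n
  if (drop > 0) {
    central <- order(abs(pts$x), -pts$y)
    pts <- pts[-central[seq_len(drop)], ]
  }
  pts$y <- pts$y - mean(range(pts$y))
  rownames(pts) <- NULL
  pts
}

default_fine_step <- function(mode) if (mode == "detailed") 0.02 else 0.1

# shared scaffolding: given a layout, build grid + model + VOI and
# rasterize z-parallel applicators with electrodes centered on z = 0
build_parallel_phantom <- function(layout, mode, fine_step, z_step,
                                   max_step, expansion_factor,
                                   voi_pad_xy, voi_pad_z, background,
                                   fine_halfwidth = 1.2,
                                   voi_pad_y = voi_pad_xy) {
  proto <- applicator_spec(tip_position = c(0, 0, 0))
  active_half <- (2 * proto$electrode_length + proto$electrode_gap) / 2
  tip_z <- active_half + proto$tip_offset
  voi <- box3(
    lo = c(min(layout$x) - voi_pad_xy, min(layout$y) - voi_pad_y,
           -active_half - voi_pad_z),
    hi = c(max(layout$x) + voi_pad_xy, max(layout$y) + voi_pad_y,
           active_half + voi_pad_z))
  regions <- lapply(seq_len(nrow(layout)), function(i) {
    box3(c(layout$x[i] - fine_halfwidth, layout$y[i] - fine_halfwidth,
           voi$lo[3]),
         c(layout$x[i] + fine_halfwidth, layout$y[i] + fine_halfwidth,
           voi$hi[3]))
  })
  grid <- build_grid(voi, regions, fine_step = fine_step, z_step = z_step,
                     max_step = max_step,
                     expansion_factor = expansion_factor)
  model <- voxel_model(grid, background = background)
  model$voi <- voi
  specs <- lapply(seq_len(nrow(layout)), function(i) {
    applicator_spec(tip_position = c(layout$x[i], layout$y[i], tip_z))
  })
  ras <- if (mode == "detailed") rasterize_applicator_detailed
         else rasterize_applicator_simplified
  for (sp in specs) model <- ras(model, sp)
  model
}

#' Homogeneous muscle benchmark phantom
#'
#' Parallel applicators on a 9 mm lattice in homogeneous muscle, the
#' standard benchmark for validating the simplified applicator model
#' against the detailed-geometry reference. The VOI is the applicator
#' bounding box expanded by one lattice spacing transversally and 4.5 mm
#' axially (matching the proportions of the full 54 x 43 x 54 mm
#' benchmark VOI relative to its 18-applicator lattice).
#'
#' @param n_applicators Number of applicators (default 18; small values
#'   give the reduced single-row test phantoms).
#' @param spacing Lattice spacing (mm).
#' @param mode `"detailed"` (cylindrical layers, 0.02 mm cross-section
#'   grid) or `"simplified"` (cuboid equivalent, 0.1 mm grid).
#' @param fine_step Transverse step in the applicator regions; defaults
#'   by mode.
#' @param z_step,max_step,expansion_factor Grid settings, see
#'   [build_grid()].
#' @return A [voxel_model()] with VOI set.
#' @export
homogeneous_benchmark <- function(n_applicators = 18, spacing = 9,
                                  mode = c("simplified", "detailed"),
                                  fine_step = NULL, z_step = 1,
                                  max_step = 2, expansion_factor = 1.2) {
  mode <- match.arg(mode)
  if (is.null(fine_step)) fine_step <- default_fine_step(mode)
  layout <- applicator_layout(n_applicators, spacing)
  # the full 18-applicator benchmark uses the documented 54 x 43 x 54 mm
  # VOI; reduced layouts scale the padding with the lattice spacing
  pad_y <- if (n_applicators == 18 && spacing == 9) 8 else spacing
  build_parallel_phantom(layout, mode, fine_step, z_step, max_step,
                         expansion_factor, voi_pad_xy = spacing,
                         voi_pad_z = 4.5, background = "Muscle",
                         voi_pad_y = pad_y)
}

#' Heterogeneous (complex) benchmark phantom
#'
#' Adds the three heterogeneity features of the complex benchmark to a
#' parallel-applicator phantom: (a) a planar prostate-fat interface
#' perpendicular to the applicators (crossed by them at z = 5 mm), (b) a
#' planar interface parallel to the applicators with the first
#' applicator centered on it, and (c) non-uniform inter-applicator
#' spacing. A muscle region below z = -15 mm keeps all three tissues
#' present.
#'
#' @param scale `"full"` (18 applicators, 4 rows with one row pair
#'   closer and one farther than 9 mm) or `"reduced"` (3 applicators in
#'   one row with 7.5 / 10.5 mm spacings).
#' @inheritParams homogeneous_benchmark
#' @return A [voxel_model()] with VOI set.
#' @export
complex_benchmark <- function(scale = c("full", "reduced"),
                              mode = c("simplified", "detailed"),
                              fine_step = NULL, z_step = 1, max_step = 2,
                              expansion_factor = 1.2) {
  scale <- match.arg(scale)
  mode <- match.arg(mode)
  if (is.null(fine_step)) fine_step <- default_fine_step(mode)
  if (scale == "reduced") {
    layout <- data.frame(x = c(-9, -1.5, 9), y = c(0, 0, 0))
  } else {
    base <- applicator_layout(18, 9)
    # squeeze rows 1-2 together and push rows 3-4 apart
    ys <- sort(unique(base$y))
    shift <- c(0, -1.5, 1.5, 3)[match(base$y, ys)]
    layout <- data.frame(x = base$x, y = base$y + shift)
  }
  model <- build_parallel_phantom(
    layout, mode, fine_step, z_step, max_step, expansion_factor,
    voi_pad_xy = 9, voi_pad_z = 4.5, background = "Muscle")

  # tissue regions (assigned before applicators would be overwritten, so
  # apply only where no applicator material sits)
  g <- model$grid
  x_if <- min(layout$x)          # vertical interface through applicator 1
  z_if <- 5                      # perpendicular interface crossed by applicators
  z_mu <- -15                    # muscle floor
  keep <- model$material
  bg <- material_id(model, "Muscle")
  id_fat <- material_id(model, "Fat")
  id_pro <- material_id(model, "Prostate")
  cxg <- array(rep(g$cx, times = g$nc[2] * g$nc[3]), dim = g$nc)
  czg <- array(rep(g$cz, each = g$nc[1] * g$nc[2]), dim = g$nc)
  tissue <- keep == bg
  fat <- tissue & ((cxg < x_if & czg >= z_mu) | (cxg >= x_if & czg >= z_if))
  pro <- tissue & (cxg >= x_if & czg >= z_mu & czg < z_if)
  model$material[fat] <- id_fat
  model$material[pro] <- id_pro
  model
}

#' Electrode shell volumes, rasterized vs analytic
#'
#' Sums rasterized electrode cell volumes per electrode index and
#' compares with the analytic shell volume (cylindrical annulus for
#' detailed applicators, square-shell cuboid for simplified ones).
#'
#' @param model A [voxel_model()].
#' @return Data frame with `electrode`, `rasterized_mm3`, `analytic_mm3`.
#' @export
electrode_volumes <- function(model) {
  vol <- cell_volumes(model$grid) * 1e9  # mm^3
  ne <- n_electrodes(model)
  ras <- vapply(seq_len(ne), function(e) sum(vol[model$electrode == e]),
                numeric(1))
  ana <- vapply(seq_len(ne), function(e) {
    sp <- model$applicators[[ceiling(e / 2)]]
    l <- sp$electrode_length
    if (identical(sp$mode, "detailed")) {
      pi * ((sp$electrode_od / 2)^2 - (sp$catheter_od / 2)^2) * l
    } else {
      (sp$simplified_electrode_edges[2]^2 -
         sp$simplified_electrode_edges[1]^2) * l
    }
  }, numeric(1))
  data.frame(electrode = seq_len(ne), rasterized_mm3 = ras,
             analytic_mm3 = ana)
}
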