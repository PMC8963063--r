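#' Axis-aligned box (mm)
#'
#' @param lo,hi Numeric length-3 vectors of lower/upper corners (mm).
#' @return A `box3` object.
#' @export
box3 <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(length(lo) == 3L, length(hi) == 3L)
  if (any(hi <= lo)) stop("box must have hi > lo on every axis")
  structure(list(lo = lo, hi = hi), class = "box3")
}

box_contains <- function(outer, inner) {
  all(inner$lo >= outer$lo - 1e-9) && all(inner$hi <= outer$hi + 1e-9)
}

#' Rectilinear grid from node coordinates
#'
#' Nodes are strictly increasing per axis (mm); materials and derived
#' fields live on the cells between nodes, potentials on the nodes.
#'
#' @param x,y,z Strictly increasing node coordinates (mm).
#' @return A `rect_grid` with node coords, cell sizes (`dx`,`dy`,`dz`),
#'   cell centers (`cx`,`cy`,`cz`), node dims `nn` and cell dims `nc`.
#' @export
rectilinear_grid <- function(x, y, z) {
  for (v in list(x, y, z)) {
    if (length(v) < 2L || any(diff(v) <= 0))
      stop("node coordinates must be strictly increasing with >= 2 nodes")
  }
  g <- list(
    x = x, y = y, z = z,
    dx = diff(x), dy = diff(y), dz = diff(z),
    cx = (x[-1] + x[-length(x)]) / 2,
    cy = (y[-1] + y[-length(y)]) / 2,
    cz = (z[-1] + z[-length(z)]) / 2,
    nn = c(length(x), length(y), length(z)),
    nc = c(length(x) - 1L, length(y) - 1L, length(z) - 1L)
  )
  class(g) <- "rect_grid"
  g
}

#' @export
print.rect_grid <- function(x, ...) {
  cat(sprintf(
    "<rect_grid> %d x %d x %d cells (%.3g M), extent [%.1f,%.1f]x[%.1f,%.1f]x[%.1f,%.1f] mm\n",
    x$nc[1], x$nc[2], x$nc[3], prod(x$nc) / 1e6,
    min(x$x), max(x$x), min(x$y), max(x$y), min(x$z), max(x$z)))
  cat(sprintf("  steps: dx %.3g..%.3g, dy %.3g..%.3g, dz %.3g..%.3g mm\n",
              min(x$dx), max(x$dx), min(x$dy), max(x$dy),
              min(x$dz), max(x$dz)))
  invisible(x)
}

# geometric one-sided grading: steps start at h0, grow by <= f, cap hmax,
# uniformly rescaled (downward) to fill L exactly. Ratios are preserved by
# the rescale, so adjacent growth never exceeds f and no step exceeds hmax.
grade_one_sided <- function(L, h0, hmax, f) {
  if (L <= 1e-12) return(numeric(0))
  if (h0 >= L) return(L)
  steps <- numeric(0)
  h <- h0
  total <- 0
  while (total < L) {
    steps <- c(steps, h)
    total <- total + h
    h <- min(h * f, hmax)
  }
  steps * (L / total)
}

# fill a gap flanked by fine regions on both sides: symmetric grading
grade_symmetric <- function(L, h0, hmax, f) {
  half <- grade_one_sided(L / 2, h0, hmax, f)
  c(half, rev(half))
}

# build one graded axis: fine_intervals is a k x 2 matrix of [lo, hi]
build_axis <- function(lo, hi, fine_intervals, fine_step, max_step, f) {
  if (is.null(fine_intervals) || nrow(fine_intervals) == 0L) {
    n <- max(1L, ceiling((hi - lo) / max_step))
    return(seq(lo, hi, length.out = n + 1L))
  }
  iv <- fine_intervals[order(fine_intervals[, 1]), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1L) {
    for (i in 2:nrow(iv)) {
      last <- nrow(merged)
      if (iv[i, 1] <= merged[last, 2] + 1e-9) {
        merged[last, 2] <- max(merged[last, 2], iv[i, 2])
      } else {
        merged <- rbind(merged, iv[i, , drop = FALSE])
      }
    }
  }
  merged[, 1] <- pmax(merged[, 1], lo)
  merged[, 2] <- pmin(merged[, 2], hi)
  nodes <- lo
  pos <- lo
  k <- nrow(merged)
  for (i in seq_len(k)) {
    a <- merged[i, 1]; b <- merged[i, 2]
    if (a > pos + 1e-9) {
      steps <- if (i == 1L) {
        rev(grade_one_sided(a - pos, fine_step, max_step, f))
      } else {
        grade_symmetric(a - pos, fine_step, max_step, f)
      }
      nodes <- c(nodes, pos + cumsum(steps))
    }
    n <- max(1L, ceiling((b - a) / fine_step - 1e-9))
    nodes <- c(nodes, seq(a, b, length.out = n + 1L)[-1])
    pos <- b
  }
  if (hi > pos + 1e-9) {
    steps <- grade_one_sided(hi - pos, fine_step, max_step, f)
    nodes <- c(nodes, pos + cumsum(steps))
  }
  nodes[length(nodes)] <- hi
  # snap to 1e-9 mm so mirrored geometry yields exactly mirrored nodes
  # (classification against half-open shell boundaries stays consistent)
  nodes <- round(nodes, 9)
  nodes[!duplicated(nodes)]
}

#' Build a graded rectilinear simulation grid
#'
#' Constructs the non-uniform grid used by the field solver: fine uniform
#' steps (`fine_step`) across every applicator cross-section region in x
#' and y, smoothly graded (geometric growth bounded by
#' `expansion_factor`) up to `max_step` elsewhere, and a uniform step
#' along z. The computational domain is the model extent expanded by
#' `margin` on every side, so that the grounded outer boundary stays away
#' from the volume of interest.
#'
#' @param model_extent [box3()] of the region of interest (mm).
#' @param applicator_regions List of [box3()] cross-section regions that
#'   require the fine transverse step. Must lie inside `model_extent`.
#' @param fine_step Transverse step inside applicator regions (mm).
#' @param z_step Uniform longitudinal step (mm).
#' @param max_step Maximum step outside the fine regions (mm).
#' @param expansion_factor Maximum ratio between adjacent cell sizes.
#' @param margin Margin added around `model_extent` (mm, default 10).
#' @return A [rectilinear_grid()].
#' @export
build_grid <- function(model_extent, applicator_regions = list(),
                       fine_step = 0.02, z_step = 1, max_step = 2,
                       expansion_factor = 1.2, margin = 10) {
  if (fine_step <= 0 || z_step <= 0 || max_step <= 0)
    stop("grid steps must be positive")
  if (fine_step > max_step) stop("fine_step must be <= max_step")
  if (expansion_factor <= 1) stop("expansion_factor must be > 1")
  for (r in applicator_regions) {
    if (!box_contains(model_extent, r))
      stop("applicator region lies outside the model extent")
  }
  lo <- model_extent$lo - margin
  hi <- model_extent$hi + margin
  ivx <- do.call(rbind, lapply(applicator_regions, function(r) c(r$lo[1], r$hi[1])))
  ivy <- do.call(rbind, lapply(applicator_regions, function(r) c(r$lo[2], r$hi[2])))
  x <- build_axis(lo[1], hi[1], ivx, fine_step, max_step, expansion_factor)
  y <- build_axis(lo[2], hi[2], ivy, fine_step, max_step, expansion_factor)
  nz <- max(1L, ceiling((hi[3] - lo[3]) / z_step - 1e-9))
  z <- seq(lo[3], hi[3], length.out = nz + 1L)
  rectilinear_grid(x, y, z)
}

#' Cell volumes of a grid
#' @param grid A [rectilinear_grid()].
#' @return 3D array of cell volumes in m^3.
#' @export
cell_volumes <- function(grid) {
  mm3 <- outer(outer(grid$dx, grid$dy), grid$dz)
  array(mm3 * 1e-9, dim = grid$nc)
}

#' Logical cell mask of an axis-aligned box
#'
#' Cells are selected by their centers; the box is half-open `[lo, hi)`.
#' @param grid A [rectilinear_grid()].
#' @param box A [box3()] in mm.
#' @return Logical 3D array over cells.
#' @export
cells_in_box <- function(grid, box) {
  inx <- grid$cx >= box$lo[1] & grid$cx < box$hi[1]
  iny <- grid$cy >= box$lo[2] & grid$cy < box$hi[2]
  inz <- grid$cz >= box$lo[3] & grid$cz < box$hi[3]
  outer(outer(inx, iny, `&`), inz, `&`)
}
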