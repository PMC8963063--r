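# shared fixtures, built in code

EPS0 <- 8.8541878128e-12

# block of tissue with two plate electrodes on the x faces; Neumann on the
# lateral faces makes the analytic solution a 1D ramp between the plates
plate_model <- function(nx = 20, ny = 10, nz = 10, background = "Muscle") {
  g <- rectilinear_grid(seq(0, nx), seq(0, ny), seq(0, nz))
  m <- voxel_model(g, background = background)
  m$applicators <- list(structure(list(mode = "manual"),
                                  class = "applicator_spec"))
  m$electrode[1, , ] <- 1L
  m$electrode[dim(m$electrode)[1], , ] <- 2L
  m$material[m$electrode > 0] <- match("PEC", names(m$materials))
  m
}

# 2D concentric-cylinder section: inner disc electrode at r < a, outer
# ground r > b, one cell thick in z (solved with Neumann faces)
cylinder_model <- function(h, a = 2, b = 8, L = 12) {
  n <- round(2 * L / h)
  g <- rectilinear_grid(seq(-L, L, length.out = n + 1),
                        seq(-L, L, length.out = n + 1), c(0, 1, 2))
  m <- voxel_model(g, background = "Muscle")
  r <- sqrt(outer(g$cx^2, g$cy^2, `+`))
  m$applicators <- list(structure(list(mode = "manual"),
                                  class = "applicator_spec"))
  for (k in 1:2) {
    m$electrode[, , k][r < a] <- 1L
    m$electrode[, , k][r > b] <- 2L
  }
  m$material[m$electrode > 0] <- match("PEC", names(m$materials))
  m
}

# coarse two-applicator phantom for solver/superposition tests
tiny_phantom <- function(mode = "simplified") {
  homogeneous_benchmark(2, mode = mode, fine_step = 0.2, z_step = 2)
}

# exhaustive gamma reference: minimize over every evaluated voxel within
# the search radius, no interpolation (same formula as the solver path,
# computed with plain R loops)
gamma_brute <- function(ref, evl, dd_abs, dta, radius) {
  stopifnot(identical(dim(ref$values), dim(evl$values)))
  d <- dim(ref$values)
  out <- array(NA_real_, dim = d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    best <- Inf
    for (kk in seq_len(d[3])) for (jj in seq_len(d[2])) for (ii in seq_len(d[1])) {
      dist2 <- (ref$x[i] - evl$x[ii])^2 + (ref$y[j] - evl$y[jj])^2 +
        (ref$z[k] - evl$z[kk])^2
      if (dist2 > radius^2) next
      g2 <- (ref$values[i, j, k] - evl$values[ii, jj, kk])^2 / dd_abs^2 +
        dist2 / dta^2
      if (g2 < best) best <- g2
    }
    out[i, j, k] <- sqrt(best)
  }
  out
}

rand_volume <- function(n = 9, spacing = 0.5, seed = 1, scale = 1) {
  set.seed(seed)
  co <- (seq_len(n) - 0.5) * spacing
  sar_volume(array(runif(n^3) * scale, dim = c(n, n, n)),
             x = co, y = co, z = co)
}
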