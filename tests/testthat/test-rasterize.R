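# single z-parallel applicator with electrodes centered on z = 0
one_applicator_model <- function(mode, fine_step, z_step = 1,
                                 pad = 2, margin = 2) {
  spec <- applicator_spec(c(0, 0, 24.5))
  extent <- box3(c(-pad, -pad, -24.5), c(pad, pad, 24.5))
  grid <- build_grid(extent, list(box3(c(-1.2, -1.2, -24.5),
                                       c(1.2, 1.2, 24.5))),
                     fine_step = fine_step, z_step = z_step,
                     margin = margin)
  m <- voxel_model(grid, background = "Muscle")
  if (mode == "detailed") rasterize_applicator_detailed(m, spec)
  else rasterize_applicator_simplified(m, spec)
}

cell_material_at <- function(m, p) {
  i <- which.min(abs(m$grid$cx - p[1]))
  j <- which.min(abs(m$grid$cy - p[2]))
  k <- which.min(abs(m$grid$cz - p[3]))
  names(m$materials)[m$material[i, j, k]]
}

cell_electrode_at <- function(m, p) {
  i <- which.min(abs(m$grid$cx - p[1]))
  j <- which.min(abs(m$grid$cy - p[2]))
  k <- which.min(abs(m$grid$cz - p[3]))
  m$electrode[i, j, k]
}

test_that("detailed rasterization assigns the cylindrical layers", {
  m <- one_applicator_model("detailed", fine_step = 0.02, z_step = 1)
  z_el <- 10  # inside the distal electrode band [2.5, 22.5]
  # radial layer sequence: lumen, catheter, copper shell, dielectric, tissue
  expect_equal(cell_material_at(m, c(0, 0, z_el)), "Air")
  expect_equal(cell_material_at(m, c(0.9, 0, z_el)), "POM")
  expect_equal(cell_material_at(m, c(1.015, 0, z_el)), "PEC")
  expect_gt(cell_electrode_at(m, c(1.015, 0, z_el)), 0)
  expect_equal(cell_material_at(m, c(1.05, 0, z_el)), "Parylene C")
  expect_equal(cell_material_at(m, c(1.2, 0, z_el)), "Muscle")
  expect_equal(cell_electrode_at(m, c(1.2, 0, z_el)), 0L)
  # the 5 mm gap carries no electrode marking
  expect_equal(cell_electrode_at(m, c(1.015, 0, 0)), 0L)
  # proximal vs distal electrodes get distinct indices
  expect_equal(cell_electrode_at(m, c(1.015, 0, -10)), 1L)
  expect_equal(cell_electrode_at(m, c(1.015, 0, 10)), 2L)
})

test_that("simplified rasterization assigns the cuboid shells", {
  m <- one_applicator_model("simplified", fine_step = 0.1)
  z_el <- 10
  expect_equal(cell_material_at(m, c(0, 0, z_el)), "POM")
  expect_equal(cell_material_at(m, c(0.55, 0, z_el)), "PEC")
  expect_gt(cell_electrode_at(m, c(0.55, 0, z_el)), 0)
  expect_match(cell_material_at(m, c(0.8, 0, z_el)), "^Dielectric")
  expect_equal(cell_material_at(m, c(1.0, 0, z_el)), "Muscle")
  # adapted permittivity on the dielectric shell
  diel <- m$materials[[cell_material_at(m, c(0.8, 0, z_el))]]
  expect_equal(diel$eps_r, 21.0084431713386, tolerance = 1e-9)
  expect_equal(diel$sigma, 1e-5)
  # inter-electrode gap: conducting shell position reverts to catheter
  expect_equal(cell_electrode_at(m, c(0.55, 0, 0)), 0L)
  expect_equal(cell_material_at(m, c(0.55, 0, 0)), "POM")
})

test_that("rasterized electrode volumes approximate the analytic shells", {
  ms <- one_applicator_model("simplified", fine_step = 0.1)
  vs <- electrode_volumes(ms)
  expect_equal(vs$rasterized_mm3, vs$analytic_mm3, tolerance = 0.05)
  md <- one_applicator_model("detailed", fine_step = 0.02)
  vd <- electrode_volumes(md)
  expect_equal(vd$rasterized_mm3, vd$analytic_mm3, tolerance = 0.05)
})

test_that("overlap and orientation restrictions are enforced", {
  m <- one_applicator_model("simplified", fine_step = 0.1)
  expect_error(rasterize_applicator_simplified(
    m, applicator_spec(c(0.3, 0, 24.5))), "overlap")
  m2 <- voxel_model(build_grid(box3(c(-2, -2, -10), c(2, 2, 10)),
                               list(box3(c(-1.2, -1.2, -10),
                                         c(1.2, 1.2, 10))),
                               fine_step = 0.1, margin = 2))
  expect_error(rasterize_applicator_detailed(
    m2, applicator_spec(c(0, 0, 0), direction = c(1, 1, 0))),
    "z-parallel")
})
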