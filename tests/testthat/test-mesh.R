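test_that("smallest closed triangulation: 12 vertices give the icosahedral counts", {
  m <- build_cell_mesh("sphere", 12, diameter = 1)
  expect_equal(nrow(m$vertices), 12)
  expect_equal(nrow(m$faces), 20)
  expect_equal(nrow(m$edges), 30)
  expect_equal(nrow(m$vertices) - nrow(m$edges) + nrow(m$faces), 2)
  expect_error(build_cell_mesh("sphere", 11), "closed triangulation")
})

test_that("red-cell mesh at 500 vertices has the Euler-formula element counts", {
  m <- build_cell_mesh("biconcave", 500, volume = 92.5)
  expect_equal(nrow(m$vertices), 500)
  expect_equal(nrow(m$faces), 2 * 500 - 4)   # 996 triangles
  expect_equal(nrow(m$edges), 3 * 500 - 6)   # 1494 edges
  # every edge shared by exactly two faces (validated inside mesh_area_volume)
  av <- mesh_area_volume(m)
  expect_equal(unname(av["volume"]), 92.5, tolerance = 1e-6)
  # near-uniform edge lengths
  expect_lt(max(m$l0) / min(m$l0), 3)
})

test_that("platelet mesh hits 48 vertices and the 0.38 bounding aspect ratio", {
  m <- build_cell_mesh("oblate", 48, aspect_ratio = 0.38, volume = 6)
  expect_equal(nrow(m$vertices), 48)
  thick <- diff(range(m$vertices[, 3]))
  dia <- max(diff(range(m$vertices[, 1])), diff(range(m$vertices[, 2])))
  expect_equal(thick / dia, 0.38, tolerance = 0.38 * 0.02)
  expect_equal(unname(mesh_area_volume(m)["volume"]), 6, tolerance = 1e-6)
})

test_that("mesh area/volume approach the analytic sphere and converge with refinement", {
  m1 <- build_cell_mesh("sphere", 160, diameter = 2)
  m2 <- build_cell_mesh("sphere", 640, diameter = 2)
  for (m in list(m1, m2)) {
    av <- mesh_area_volume(m)
    expect_lt(av["area"], 4 * pi)       # inscribed polyhedron
    expect_lt(av["volume"], 4 * pi / 3)
  }
  av1 <- mesh_area_volume(m1)
  av2 <- mesh_area_volume(m2)
  expect_equal(unname(av2["area"]), 4 * pi, tolerance = 0.02)
  expect_equal(unname(av2["volume"]), 4 * pi / 3, tolerance = 0.02)
  # refinement reduces the discretisation deficit
  expect_lt(abs(av2["area"] - 4 * pi), abs(av1["area"] - 4 * pi))
})

test_that("orientation flip negates the signed volume and open meshes error", {
  m <- build_cell_mesh("sphere", 40, diameter = 1.5)
  flipped <- m
  flipped$faces <- m$faces[, c(1, 3, 2)]
  expect_equal(mavessel:::mesh_volume_raw(flipped$vertices, flipped$faces),
               -unname(m$volume))
  open <- m
  open$faces <- m$faces[-1, ]
  expect_error(mesh_area_volume(open), "not closed")
})

test_that("surface-to-volume of the printed red-cell area and volume is 1.44", {
  expect_equal(round(132.9 / 92.5, 2), 1.44)
  m <- build_cell_mesh("biconcave", 200, volume = 92.5)
  # the built family reproduces the printed ratio to a few percent
  expect_equal(surface_to_volume(m), 1.44, tolerance = 0.05)
})

test_that("meshes survive an OFF round trip", {
  m <- build_cell_mesh("oblate", 30, volume = 6)
  path <- tempfile(fileext = ".off")
  write_off(m, path)
  m2 <- read_off(path)
  expect_equal(unname(m2$vertices), unname(m$vertices), tolerance = 1e-7)
  expect_equal(m2$faces, m$faces)
  expect_equal(unname(m2$volume), unname(m$volume), tolerance = 1e-6)
})
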