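test_that("spec validation names the violated constraint", {
  expect_error(tube_spec(-5, 100), "positive")
  expect_error(aorta_spec(19, 11, 12, ai_stenosis_factor = 0), "0, 1")
  expect_error(aorta_spec(19, 11, 12, ai_stenosis_factor = 1.2), "0, 1")
  expect_error(aorta_spec(19, 11, 12,
                          branch_diameters = c(BA = 20, LCCA = 6, LSA = 6)),
               "smaller than the inlet")
  expect_error(aorta_spec(19, 11, 12,
                          branch_angles_deg = c(BA = 100, LCCA = 98, LSA = 96)),
               "overlapping branches")
  expect_error(aorta_spec(19, 11, 12, asc_length = 10), "asc_length")
})

test_that("analytic diameters equal the spec values", {
  g <- build_aorta(tube_spec(20, 100))
  for (pl in c("inlet", "mid", "outlet"))
    expect_equal(measure_diameter(g, pl), 20, tolerance = 1e-12)
  # cone: linear radius interpolation
  cone <- build_aorta(tube_spec(20, 100, outlet_diameter = 10))
  expect_equal(measure_diameter(cone, "mid"), 15, tolerance = 1e-12)
  # full aorta at the cohort-mean diameters
  a <- build_aorta(aorta_spec(19.2, 10.9, 12.1))
  expect_equal(measure_diameter(a, "AscAo"), 19.2, tolerance = 1e-9)
  expect_equal(measure_diameter(a, "AI"), 12.1, tolerance = 1e-9)
  expect_equal(measure_diameter(a, "DAo"), 10.9, tolerance = 1e-9)
  # stenosis factor multiplies the isthmus diameter exactly
  s <- build_aorta(aorta_spec(19.2, 10.9, 12, ai_stenosis_factor = 0.5))
  expect_equal(measure_diameter(s, "AI"), 6, tolerance = 1e-9)
  expect_error(measure_diameter(a, "nowhere"), "unknown probe location")
})

test_that("aorta geometry invariants: one inlet, four outlets, AI placement", {
  a <- build_aorta(aorta_spec(19.2, 10.9, 12.1))
  dom <- suppressWarnings(voxelize(a, 0.8))
  expect_length(dom$caps$inlet$cells, length(dom$caps$inlet$cells))
  expect_setequal(names(dom$caps$outlets), c("DAo", "BA", "LCCA", "LSA"))
  expect_gt(length(dom$caps$inlet$cells), 0)
  # AI plane sits between the LSA attachment and the DAo outlet
  z_ai <- a$probes$AI$z
  z_lsa <- a$branches$LSA$base[3]
  expect_lt(z_ai, z_lsa)
  expect_gt(z_ai, 0)
  # every main-vessel fluid cell carries exactly one quadrant label
  main <- dom$mask == 1L & dom$sid == 0L
  expect_true(all(dom$quad[main] %in% 1:4))
})

test_that("voxelized cylinder volume and diameter converge", {
  g <- build_aorta(tube_spec(20, 100))  # R = 10 mm
  vol_true <- pi * 10^2 * 100
  dom <- voxelize(g, 0.5)
  expect_lt(abs(voxel_volume(dom) - vol_true) / vol_true, 0.03)
  expect_equal(measure_diameter(dom, "mid"), 20,
               tolerance = 2 * 0.5 / 20 * 20)  # within 2h
  # refinement reduces the error, and a tapered lumen (whose cross-section
  # radius sweeps continuously, averaging out grid-alignment effects) is
  # recovered to well under 1%
  errs <- vapply(c(1, 0.5), function(h)
    abs(voxel_volume(voxelize(g, h)) - vol_true) / vol_true, 0)
  expect_lt(errs[2], errs[1])
  gc2 <- build_aorta(tube_spec(21, 60, outlet_diameter = 13))
  vol_cone <- pi / 3 * 60 * (10.5^2 + 10.5 * 6.5 + 6.5^2)
  errs2 <- vapply(c(1, 0.5), function(h)
    abs(voxel_volume(voxelize(gc2, h)) - vol_cone) / vol_cone, 0)
  expect_lt(max(errs2), 0.005)
  # deterministic
  d2 <- voxelize(g, 0.5)
  expect_identical(d2$mask, dom$mask)
})

test_that("near-closed isthmus produces an explicit error", {
  s <- aorta_spec(19.2, 10.9, 12, ai_stenosis_factor = 0.02)
  g <- build_aorta(s)
  expect_error(suppressWarnings(voxelize(g, 0.9)), "too coarse|disconnected")
})

test_that("boundary faces partition into inlet, outlets and wall", {
  g <- build_aorta(tube_spec(12, 30))
  dom <- voxelize(g, 1)
  m <- dom$mask
  d <- dom$dims
  count_boundary <- function() {
    tot <- 0
    pad <- function(a) {
      out <- array(0L, dim(a) + 2)
      out[2:(dim(a)[1] + 1), 2:(dim(a)[2] + 1), 2:(dim(a)[3] + 1)] <- a
      out
    }
    mp <- pad(m)
    for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))) {
      nb <- mp[2:(d[1] + 1) + sh[1], 2:(d[2] + 1) + sh[2], 2:(d[3] + 1) + sh[3]]
      tot <- tot + sum(m == 1L & nb == 0L)
    }
    tot
  }
  field0 <- flow_field(dom)
  wss <- wall_shear_stress(field0, dom)
  n_wall <- nrow(wss)
  n_caps <- length(dom$caps$inlet$cells) +
    sum(vapply(dom$caps$outlets, function(o) length(o$cells), 0L))
  expect_equal(n_wall + n_caps, count_boundary())
  # every wall face appears exactly once
  expect_false(any(duplicated(wss[c("cell", "dir")])))
})

test_that("surface export is watertight and round-trips through STL", {
  g <- build_aorta(tube_spec(20, 60))
  stl <- tempfile(fileext = ".stl")
  vtk <- tempfile(fileext = ".vtk")
  mesh <- export_surface(g, stl, vtk_path = vtk)
  expect_true(is_watertight(mesh))
  back <- import_surface(stl)
  expect_true(is_watertight(back))
  expect_equal(nrow(back$faces), nrow(mesh$faces))
  d0 <- measure_diameter(mesh, 30)
  d1 <- measure_diameter(back, 30)
  expect_equal(d1, d0, tolerance = 1e-6)
  expect_equal(d0, 20, tolerance = 0.1)  # 32-segment polygonal section
  # STL structure: facet count matches and the VTK copy exists
  txt <- readLines(stl)
  expect_equal(sum(grepl("^facet", txt)), nrow(mesh$faces))
  expect_true(file.size(vtk) > 0)
  # the full aorta exports watertight too
  a <- build_aorta(aorta_spec(19.2, 10.9, 12.1))
  mesh_a <- export_surface(a, tempfile(fileext = ".stl"))
  expect_true(is_watertight(mesh_a))
  expect_error(import_surface(tempfile(fileext = ".stl")), "no such file")
})

test_that("voxel field exports as legacy VTK image data", {
  g <- build_aorta(tube_spec(12, 30))
  dom <- voxelize(g, 1)
  f <- tempfile(fileext = ".vtk")
  write_vtk_image(dom, f, fields = list(p = array(0, dom$dims)))
  txt <- readLines(f, n = 10)
  expect_match(txt[1], "vtk DataFile")
  expect_match(txt[4], "STRUCTURED_POINTS")
})
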