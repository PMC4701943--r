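test_that("surface area matches closed forms and ignores vertex order", {
  expect_equal(surface_area(cube_mesh()), 6)
  tri <- spine_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  expect_equal(surface_area(tri), 0.5)
  flipped <- spine_mesh(tri$vertices, rbind(c(3, 2, 1)))
  expect_equal(surface_area(flipped), 0.5)
  # closed tessellated prism: exact faceted-solid area
  fx <- make_cylinder_mesh(1, 2, n_seg = 128)
  sec <- polygon_section(1, 128)
  expect_equal(surface_area(fx$mesh), sec$perimeter * 2 + 2 * sec$area,
               tolerance = 1e-9)
})

test_that("enclosed volume is exact for solids and rejects open meshes", {
  expect_equal(enclosed_volume(cube_mesh()), 1)
  expect_equal(enclosed_volume(tetra_mesh()), 1 / 6)
  # translation invariance of the divergence-theorem sum
  shifted <- transform_mesh(cube_mesh(), translation = c(100, -30, 7))
  expect_equal(enclosed_volume(shifted), 1, tolerance = 1e-9)
  open_mesh <- spine_mesh(cube_mesh()$vertices, cube_mesh()$faces[-1, ])
  expect_false(is_watertight(open_mesh))
  expect_error(enclosed_volume(open_mesh), "3 boundary edges")
})

test_that("spine axis of a straight cylinder recovers its length", {
  fx <- make_cylinder_mesh(1, 2, n_seg = 64)
  ax <- spine_axis(fx$mesh, fx$attachment)
  expect_equal(ax$length, 2, tolerance = 0.02)
  # length never below the Euclidean attachment-tip distance
  expect_gte(ax$length,
             sqrt(sum((ax$tip - ax$attachment)^2)) - 1e-9)
  expect_error(spine_axis(fx$mesh, c(50, 0, 0)), "attachment")
})

test_that("mushroom axis length matches neck + head composition", {
  fx <- make_mushroom_spine_mesh(0.8, 0.8, 0.3, 1.5, n_seg = 64)
  ax <- spine_axis(fx$mesh, fx$attachment)
  expect_equal(ax$length, 2.3, tolerance = 0.05 * 2.3)
})

test_that("cross-section profile reproduces cylinder and mushroom diameters", {
  fx <- make_cylinder_mesh(1, 2, n_seg = 64)
  ax <- spine_axis(fx$mesh, fx$attachment)
  prof <- cross_section_profile(fx$mesh, ax, 32)
  expect_true(all(abs(prof$diameter - 1) < 0.02))
  # resolution stability of the maximum
  p8 <- cross_section_profile(fx$mesh, ax, 8)
  p64 <- cross_section_profile(fx$mesh, ax, 64)
  expect_equal(max_diameter(p8), max_diameter(p64), tolerance = 0.02)

  mf <- make_mushroom_spine_mesh(0.8, 0.8, 0.3, 1.5, n_seg = 64)
  axm <- spine_axis(mf$mesh, mf$attachment)
  pm <- cross_section_profile(mf$mesh, axm, 32)
  prox <- pm$diameter[pm$station < 1.2]
  dist <- pm$diameter[pm$station > 1.8]
  expect_true(all(abs(prox - 0.3) < 0.05 * 0.3))
  expect_true(all(abs(dist - 0.8) < 0.05 * 0.8))
  expect_error(cross_section_profile(fx$mesh, ax, 4), "at least 8")
})

test_that("diameter extraction follows the 0.7-max neck rule", {
  prof <- profile_of(c(0.3, 0.3, 0.8, 0.8))
  expect_equal(max_diameter(prof), 0.8)
  expect_equal(neck_mean_diameter(prof), 0.3)
  const <- profile_of(c(1, 1, 1, 1))
  expect_equal(max_diameter(const), 1)
  expect_true(is.na(neck_mean_diameter(const)))
  expect_error(max_diameter(profile_of(numeric())), "empty")
})

test_that("spine classification keys on neck presence and head size", {
  expect_equal(classify_spine(1, NA), "stubby")
  expect_equal(classify_spine(0.8, 0.3), "mushroom")   # head inside 0.43-1.04
  expect_equal(classify_spine(0.3, 0.15), "thin")      # below modelled heads
  expect_equal(classify_spine(c(1, 0.8, 0.3), c(NA, 0.3, 0.15)),
               c("stubby", "mushroom", "thin"))
})

test_that("full morphometry matches analytic truth on canonical fixtures", {
  cyl <- make_cylinder_mesh(1, 2, n_seg = 64)
  m <- spine_morphometry(cyl$mesh, cyl$attachment)
  expect_equal(m$volume, cyl$truth$volume, tolerance = 0.02)
  expect_equal(m$area, cyl$truth$area, tolerance = 0.02)
  expect_equal(m$length, cyl$truth$length, tolerance = 0.02)
  expect_equal(m$max_diameter, cyl$truth$max_diameter, tolerance = 0.02)
  expect_equal(m$spine_class, "stubby")

  mush <- make_mushroom_spine_mesh(0.8, 0.8, 0.3, 1.5, n_seg = 64)
  mm <- spine_morphometry(mush$mesh, mush$attachment)
  for (col in c("volume", "area", "length", "max_diameter",
                "neck_mean_diameter")) {
    expect_equal(mm[[col]], mush$truth[[col]], tolerance = 0.05)
  }
  expect_equal(mm$spine_class, "mushroom")

  thin <- make_mushroom_spine_mesh(0.3, 0.3, 0.15, 2, n_seg = 64)
  expect_equal(spine_morphometry(thin$mesh, thin$attachment)$spine_class,
               "thin")
})

test_that("morphometry is invariant under rigid motion", {
  set.seed(42)
  fx <- make_mushroom_spine_mesh(0.7, 0.6, 0.25, 1.2, n_seg = 32)
  base <- spine_morphometry(fx$mesh, fx$attachment)
  for (rep in 1:3) {
    R <- random_rotation()
    tr <- rnorm(3, sd = 50)
    moved <- transform_mesh(fx$mesh, R, tr)
    att <- as.numeric(R %*% fx$attachment + tr)
    m2 <- spine_morphometry(moved, att)
    for (col in c("volume", "area", "length", "max_diameter",
                  "neck_mean_diameter")) {
      expect_equal(m2[[col]], base[[col]], tolerance = 1e-6)
    }
    expect_identical(m2$spine_class, base$spine_class)
  }
})

test_that("volume and area errors shrink monotonically with resolution", {
  smooth_vol <- pi / 4 * 1^2 * 2
  smooth_area <- pi * 1 * 2 + 2 * pi / 4
  errs <- vapply(c(64, 128, 256), function(n) {
    fx <- make_cylinder_mesh(1, 2, n_seg = n)
    c(abs(enclosed_volume(fx$mesh) - smooth_vol) / smooth_vol,
      abs(surface_area(fx$mesh) - smooth_area) / smooth_area)
  }, double(2))
  expect_true(all(diff(errs[1, ]) <= 0))
  expect_true(all(diff(errs[2, ]) <= 0))
})

test_that("sampled fixtures stay within the oracle error budget", {
  fixtures <- make_spine_fixtures(4, seed = 5, n_seg = 64)
  for (fx in fixtures) {
    m <- spine_morphometry(fx$mesh, fx$attachment)
    expect_equal(m$volume, fx$truth$volume, tolerance = 0.02)
    expect_equal(m$area, fx$truth$area, tolerance = 0.02)
    expect_equal(m$length, fx$truth$length, tolerance = 0.05)
    expect_equal(m$max_diameter, fx$truth$max_diameter, tolerance = 0.05)
    if (!is.na(fx$truth$neck_mean_diameter)) {
      expect_equal(m$neck_mean_diameter, fx$truth$neck_mean_diameter,
                   tolerance = 0.05)
      expect_lte(m$neck_mean_diameter, m$max_diameter)
    }
    expect_identical(m$spine_class, fx$truth$spine_class)
  }
})
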