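test_that("rasterized straight-tube volume matches the analytic cylinder", {
  # radius = 5 * spacing puts lattice points exactly on the tube surface,
  # so the voxel count is phase-sensitive; the volume-consistency bound
  # for radius >= 2 * spacing is 5%
  ph <- ph_straight()
  vox <- sum(ph$coronary$data) * voxel_volume(ph$coronary)
  expect_lt(abs(vox / (pi * 2^2 * 60) - 1), 0.05)
  # at larger radius-to-spacing ratios lattice fluctuation drops below 3%
  ph2 <- generate_phantom(phantom_spec(
    vessel_straight(60, 2.5), spacing = rep(0.4, 3), seed = 7,
    aorta = ao_small, margin_mm = 4, blur_sigma = 0, noise_sd = 0))
  vox2 <- sum(ph2$coronary$data) * voxel_volume(ph2$coronary)
  expect_lt(abs(vox2 / (pi * 2.5^2 * 60) - 1), 0.03)
})

test_that("rasterized volume stays within 5% across radii and spacings", {
  for (cs in list(c(2, 0.5), c(3, 0.6), c(2.5, 0.4))) {
    ph <- generate_phantom(phantom_spec(
      vessel_straight(40, cs[1]), spacing = rep(cs[2], 3), seed = 1,
      aorta = ao_small, margin_mm = 3, blur_sigma = 0, noise_sd = 0))
    vox <- sum(ph$coronary$data) * voxel_volume(ph$coronary)
    expect_lt(abs(vox / (pi * cs[1]^2 * 40) - 1), 0.05)
  }
})

test_that("phantom generation is seed-deterministic and lesion-free truth is empty", {
  spec <- phantom_spec(vessel_straight(25, 2), spacing = rep(0.5, 3),
                       seed = 42, aorta = ao_small, margin_mm = 3)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$coronary$data, b$coronary$data)
  expect_equal(nrow(a$truth$lesions), 0)
  expect_equal(nrow(a$truth$bends), 0)
})

test_that("analytic tortuosity matches closed forms and a numeric chord oracle", {
  expect_identical(analytic_tortuosity(vessel_straight(50, 2)), 1.0)

  arc <- vessel_arc(10, 120, 2)
  expect_equal(analytic_tortuosity(arc, 10), 10 / (20 * sin(0.5)),
               tolerance = 1e-12)
  # full semicircle window: arc / diameter
  semi <- vessel_arc(10, 180, 2)
  expect_equal(analytic_tortuosity(semi, pi * 10), pi / 2, tolerance = 1e-12)

  hel <- vessel_helix(8, 10, 2, 2)
  # oracle: measure arc and chord on a finely sampled helix centerline
  cl <- vessel_centerline(hel, 0.01)
  mid <- max(cl$s) / 2
  a <- corochar:::point_at_abscissa(cl$points, cl$s, mid - 5)
  b <- corochar:::point_at_abscissa(cl$points, cl$s, mid + 5)
  oracle <- 10 / sqrt(sum((b - a)^2))
  expect_equal(analytic_tortuosity(hel, 10), oracle, tolerance = 1e-4)
  expect_error(analytic_tortuosity(make_bent_branch(c(50), 25)),
               "closed-form")
})

test_that("vessel and lesion spec invariants are enforced", {
  expect_error(vessel_straight(30, 0.5), ">= 0.75")
  expect_error(vessel_straight(-5, 2), "positive")
  expect_error(make_bent_branch(c(190), 25), "0, 180")
  expect_error(make_bent_branch(c(50), 10), ">= 20 mm")
  expect_error(lesion_spec(10, c(2, -1, 1)))
  expect_error(phantom_spec(vessel_straight(20, 2), spacing = rep(0.2, 3)),
               "0.3, 0.7")
  expect_error(phantom_spec(vessel_straight(20, 2),
                            lesions = list(lesion_spec(10, c(2, 2, 2),
                                                       peak_intensity = 450))),
               "2.5 SD")
})

test_that("make_bent_branch with no angles degenerates to a straight vessel", {
  spec <- make_bent_branch(numeric(0), 30)
  expect_equal(spec$kind, "straight")
  expect_equal(spec$params$length, 30)
})

test_that("bent-branch ground truth carries one entry per prescribed bend", {
  cl <- vessel_centerline(make_bent_branch(c(40, 55), 25), 0.1)
  expect_equal(nrow(cl$bends), 2)
  expect_equal(cl$bends$angle_deg, c(40, 55))
  expect_true(all(diff(cl$bends$abscissa) > 20))
})

test_that("overlapping distinct vessels are rejected, bifurcations allowed", {
  v1 <- vessel_straight(50, 2)
  v2 <- vessel_straight(50, 2, start = c(0, 10, 0), direction = c(1, -0.4, 0))
  expect_error(generate_phantom(phantom_spec(list(v1, v2), seed = 1,
                                             aorta = ao_small)),
               "merge lumens")
  expect_s3_class(ph_y()$coronary, "label_map")
})

test_that("every compliant lesion has voxels above the patient threshold", {
  ph <- ph_lesion()
  theta <- patient_threshold(ph$image, ph$aorta)
  for (i in seq_len(nrow(ph$truth$lesions))) {
    cl <- ph$truth$centerlines[[1]]
    ctr <- corochar:::point_at_abscissa(
      cl$points, cl$s,
      (ph$truth$lesions$min_abscissa_mm[i] +
         ph$truth$lesions$max_abscissa_mm[i]) / 2)
    ijk <- corochar:::world_voxel(ph$image, matrix(ctr, 1))
    expect_gt(ph$image$data[ijk[1], ijk[2], ijk[3]], theta)
  }
})
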