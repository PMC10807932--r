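test_that("ostium seed sits on the ostial cross-section nearest the aorta", {
  ph <- ph_straight()
  seeds <- find_ostium_seed(ph$coronary, ph$aorta)
  expect_equal(nrow(seeds), 1)
  # within one voxel of the vessel origin along the vessel axis, and
  # inside the ostial cross-section
  expect_lt(abs(seeds$x[1]), ph$coronary$spacing[1] + 1e-9)
  expect_lt(sqrt(seeds$y[1]^2 + seeds$z[1]^2), 2 + 1e-9)
  expect_error(find_ostium_seed(
    label_map(array(0, dim(ph$coronary$data)), ph$coronary$spacing,
              ph$coronary$origin), ph$aorta), "empty")
})

test_that("two disjoint coronary trees yield one seed per tree", {
  ph <- generate_phantom(phantom_spec(
    list(vessel_straight(40, 2, start = c(0, 0, -14)),
         vessel_straight(40, 2, start = c(0, 0, 14))),
    spacing = rep(0.5, 3), seed = 11,
    aorta = list(radius = 8, length = 44), margin_mm = 4))
  seeds <- find_ostium_seed(ph$coronary, ph$aorta)
  expect_equal(nrow(seeds), 2)
  expect_equal(sort(sign(seeds$z)), c(-1, 1))
})

test_that("geodesic field is normalized, monotone along the tube, NA off-component", {
  ph <- ph_straight()
  seeds <- find_ostium_seed(ph$coronary, ph$aorta)
  gf <- geodesic_field(ph$coronary, seeds[1, ])
  g <- gf$data
  expect_equal(max(g, na.rm = TRUE), 1)
  expect_equal(min(g, na.rm = TRUE), 0)
  # voxel nearest half the cylinder length has g ~ 0.5
  mid_ijk <- corochar:::world_voxel(ph$coronary, matrix(c(30, 0, 0), 1))
  expect_equal(g[mid_ijk[1], mid_ijk[2], mid_ijk[3]], 0.5, tolerance = 0.06)
  expect_true(all(is.na(g[ph$coronary$data == 0])))
  expect_error(geodesic_field(ph$coronary, c(1, 1, 1)), "outside the mask")
})

test_that("Dijkstra distances equal brute-force Bellman-Ford on small masks", {
  mask <- random_blob(c(7, 6, 5), seed = 21, fill = 0.5)
  spacing <- c(0.5, 0.6, 0.7)
  seed_lin <- which(mask)[1]
  res <- corochar:::.dijkstra_cpp(as.integer(mask), dim(mask), spacing,
                                  as.integer(seed_lin - 1), 1.0)
  oracle <- bellman_ford_dist(mask, spacing, seed_lin)
  expect_equal(res$dist[mask], oracle[mask], tolerance = 1e-12)
})

test_that("endpoint detection finds one tip per terminal branch", {
  ph <- ph_straight()
  seeds <- find_ostium_seed(ph$coronary, ph$aorta)
  gf <- geodesic_field(ph$coronary, seeds[1, ])
  ep <- detect_endpoints(gf)
  expect_equal(nrow(ep), 1)
  expect_gt(ep$x[1], 57)  # at the distal tip

  phy <- ph_y()
  sy <- find_ostium_seed(phy$coronary, phy$aorta)
  gy <- geodesic_field(phy$coronary, sy[1, ])
  epy <- detect_endpoints(gy)
  expect_equal(nrow(epy), 2)
  expect_equal(sort(sign(epy$y)), c(-1, 1))  # one tip per limb
  # every endpoint is within an integer number of delta steps of g = 1
  expect_true(all(epy$g > 1 - 0.05 * ceiling((1 - min(epy$g)) / 0.05) - 1e-9))
})

test_that("traced centerline stays medial and recovers the axial length", {
  tree <- tree_straight()
  b <- tree$branches[[1]]
  interior <- b$s > 2 & b$s < max(b$s) - 2
  dev <- sqrt(rowSums(b$points[interior, 2:3]^2))
  expect_lt(max(dev), sqrt(3) * 0.4)  # within one voxel diagonal of the axis
  expect_lt(abs(max(b$s) / 60 - 1), 0.03)
  # endpoints of the path match seed/endpoint voxels
  seeds <- find_ostium_seed(ph_straight()$coronary, ph_straight()$aorta)
  expect_lt(sqrt(sum((b$points[1, ] - unlist(seeds[1, c("x", "y", "z")]))^2)),
            0.26)
  expect_error(trace_centerline(ph_straight()$coronary, seeds[1, ],
                                c(1, 1, 1)), "outside the mask|connected")
})

test_that("zone assignment follows the quoted g boundaries exactly", {
  expect_equal(as.character(assign_zone(c(0, 0.33, 0.331, 0.66, 0.661, 1))),
               c("proximal", "proximal", "medial", "medial", "distal",
                 "distal"))
  expect_error(assign_zone(1.2), "0, 1")
  expect_error(assign_zone(-0.1), "0, 1")
  # partition covers [0,1] with no gaps or overlaps
  g <- seq(0, 1, by = 0.01)
  expect_false(any(is.na(assign_zone(g))))
})

test_that("build_tree recovers one branch per limb with monotone g from 0", {
  tree <- build_tree(ph_y()$coronary, ph_y()$aorta)
  expect_equal(length(tree$branches), 2)
  for (b in tree$branches) {
    expect_equal(b$g[1], 0)
    expect_true(all(diff(b$g) >= 0))
    expect_equal(max(b$g[length(b$g)]), 1, tolerance = 0.05)
  }
})

test_that("traced tree covers the true centerline within 1 mm on single vessels", {
  for (case in list(list(ph = ph_straight(), tr = 1),
                    list(ph = ph_bent50(), tr = 1))) {
    tree <- if (identical(case$ph, ph_straight())) tree_straight()
            else tree_bent50()
    truth <- case$ph$truth$centerlines[[case$tr]]
    dmax <- max(corochar:::nearest_point_dist(
      truth$points, tree$branches[[1]]$points))
    expect_lt(dmax, 1.0)
  }
})

test_that("duplicate branches sharing 90% of their voxels are dropped", {
  b1 <- structure(list(voxel_path = 1:100), class = "centerline_branch")
  b2 <- structure(list(voxel_path = 1:95), class = "centerline_branch")
  b3 <- structure(list(voxel_path = c(1:30, 201:260)),
                  class = "centerline_branch")
  kept <- corochar:::dedupe_branches(list(b1, b2, b3))
  expect_equal(length(kept), 2)
  lens <- sort(vapply(kept, function(b) length(b$voxel_path), integer(1)))
  expect_equal(lens, c(90, 100))
})
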