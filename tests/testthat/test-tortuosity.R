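test_that("local tortuosity is 1 on straight branches and matches arc closed forms", {
  br <- analytic_branch(vessel_straight(60, 2))
  prof <- local_tortuosity(br)
  expect_true(all(abs(prof$lt[prof$valid] - 1) < 1e-9))

  arc <- analytic_branch(vessel_arc(10, 120, 2))
  mid <- which.min(abs(arc$s - max(arc$s) / 2))
  expect_equal(local_tortuosity(arc, mid), 10 / (20 * sin(0.5)),
               tolerance = 0.01)

  hel <- analytic_branch(vessel_helix(8, 10, 2, 2))
  mid <- which.min(abs(hel$s - max(hel$s) / 2))
  expect_equal(local_tortuosity(hel, mid),
               analytic_tortuosity(vessel_helix(8, 10, 2, 2), 10),
               tolerance = 0.01)
  # endpoint windows are flagged invalid, not truncated
  expect_true(is.na(local_tortuosity(arc, 1)))
})

test_that("tortuosity angle is 0 on straight branches and near-exact at vertices", {
  br <- analytic_branch(vessel_straight(60, 2))
  prof <- tortuosity_angle(br)
  expect_true(all(prof$ta[prof$valid] < 0.2))

  sharp <- analytic_branch(make_bent_branch(c(60), 25, fillet_radius = 0.5))
  v_idx <- which.min(abs(sharp$s - sharp$bends$abscissa[1]))
  expect_equal(tortuosity_angle(sharp, v_idx), 60, tolerance = 2)

  # smooth arc: TA at center equals the window's subtended angle
  arc <- analytic_branch(vessel_arc(10, 120, 2))
  mid <- which.min(abs(arc$s - max(arc$s) / 2))
  expect_equal(tortuosity_angle(arc, mid), 10 / 10 * 180 / pi, tolerance = 2)
})

test_that("TA is invariant under rigid rotation and translation", {
  base <- analytic_branch(make_bent_branch(c(48, 62), 25))
  mid <- which.min(abs(base$s - base$bends$abscissa[1]))
  ta0 <- tortuosity_angle(base, mid)
  set.seed(8)
  for (rep in 1:4) {
    ax <- rnorm(3)
    R <- corochar:::rotation_about(ax, runif(1, 0, 2 * pi))
    shift <- rnorm(3, sd = 20)
    moved <- base
    moved$points <- sweep(base$points %*% t(R), 2, shift, "+")
    expect_equal(tortuosity_angle(moved, mid), ta0, tolerance = 1e-6)
  }
})

test_that("bends are maximal runs above 45 degrees with a 2 mm separation rule", {
  s <- seq(0, 60, by = 0.5)
  ta <- rep(10, length(s))
  ta[s >= 10 & s <= 13] <- 50       # one bend
  ta[s >= 14 & s <= 16] <- 55       # gap 1 mm: merges with the previous run
  ta[s >= 30 & s <= 33] <- 45       # exactly 45 counts
  prof <- data.frame(s = s, lt = 1, ta = ta, valid = TRUE)
  class(prof) <- c("tortuosity_profile", "data.frame")
  bends <- detect_bends(prof)
  expect_equal(nrow(bends), 2)
  expect_equal(bends$angle_deg, c(55, 45))
  # widening the gap splits the merged bend
  ta2 <- ta
  ta2[s > 13 & s < 16.5] <- 10
  ta2[s >= 16.5 & s <= 18] <- 55
  prof$ta <- ta2
  expect_equal(nrow(detect_bends(prof)), 3)
})

test_that("tortuosity score counts branches with three or more bends", {
  mk_bends <- function(n) data.frame(s_start = seq_len(n), s_end = seq_len(n),
                                     s_peak = seq_len(n),
                                     angle_deg = rep(50, n))
  expect_equal(tortuosity_score(list(mk_bends(3), mk_bends(2))), 1)
  expect_equal(tortuosity_score(list(mk_bends(0), mk_bends(1))), 0)
  expect_equal(tortuosity_score(lapply(rep(3, 4), mk_bends)), 4)
  # monotone: adding a bend never decreases the score
  sets <- list(mk_bends(2), mk_bends(3))
  before <- tortuosity_score(sets)
  sets[[1]] <- mk_bends(3)
  expect_gte(tortuosity_score(sets), before)
})

test_that("tract tortuosity matches closed forms per zone", {
  br <- analytic_branch(vessel_straight(60, 2))
  br$g <- br$s / max(br$s)
  for (z in c("proximal", "medial", "distal"))
    expect_equal(tract_tortuosity(br, z), 1, tolerance = 1e-6)

  # semicircular tract spanning one zone: arc / diameter = pi / 2
  semi <- analytic_branch(vessel_arc(10, 180, 2))
  semi$g <- rep(0.5, length(semi$s))  # entire branch in the medial zone
  expect_equal(tract_tortuosity(semi, "medial"), pi / 2, tolerance = 0.01)
  expect_true(is.na(tract_tortuosity(semi, "distal")))
})

test_that("phantom bends are recovered and shallow bends are not", {
  tree <- tree_bent50()
  prof <- tortuosity_profile(tree$branches[[1]])
  bends <- detect_bends(prof)
  expect_equal(nrow(bends), 3)
  expect_true(all(abs(bends$angle_deg - 50) < 3))
  expect_equal(tortuosity_score(tree), 1)

  tree30 <- build_tree(ph_bent30()$coronary, ph_bent30()$aorta)
  expect_equal(nrow(detect_bends(tortuosity_profile(tree30$branches[[1]]))), 0)
  expect_equal(tortuosity_score(tree30), 0)
})

test_that("per-patient summary aggregates zones, percentiles and severity", {
  summ <- summarize_tortuosity(tree_straight())
  expect_equal(summ$ts, 0)
  expect_equal(summ$severity, "none")
  expect_true(all(summ$tract >= 1, na.rm = TRUE))
  expect_lt(summ$tract["medial"], 1.02)
  expect_gte(summ$lt_95, 1)
  expect_equal(corochar:::ts_severity(4), "severe")
  expect_equal(corochar:::ts_severity(2), "moderate")
})
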