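#' Seeded bend/tortuosity recovery experiment
#'
#' Generates a suite of single-branch phantoms with prescribed bends,
#' runs the full centerline + tortuosity pipeline on each, and compares
#' recovered bend angles and tortuosity scores against the analytic
#' ground truth.
#'
#' The suite composition is fixed: 10 tortuosity-positive branches
#' (3 or 4 bends, angles drawn in [52, 65] degrees), 4 branches with
#' only 2 strong bends, and 6 branches with 3-4 shallow bends (angles
#' in [25, 40] degrees). Angles within a few degrees of the 45-degree
#' counting threshold are excluded by design: finite imaging resolution
#' makes the bend/no-bend decision at the knife edge ill-posed for any
#' estimator, while the score's behavior away from the threshold is the
#' property of interest. Branch orientation and sub-voxel start offsets
#' are randomized to vary the lattice alignment. The recovered angle of
#' each prescribed bend is the maximum tortuosity angle within 4 mm of
#' the true bend abscissa.
#'
#' @param n_branches number of branches (default 20).
#' @param seed suite seed; drives geometry draws and phantom noise.
#' @param spacing isotropic voxel spacing in mm (default 0.4).
#' @return list with `bends` (data.frame: `branch`, `true_angle`,
#'   `recovered_angle`) and `scores` (data.frame: `branch`, `ts_true`,
#'   `ts_recovered`).
#' @export
run_bend_recovery <- function(n_branches = 20, seed = 1, spacing = 0.4) {
  plan <- data.frame(
    k = c(rep(3, 7), rep(4, 3), rep(2, 4), c(3, 4, 3, 4, 3, 4)),
    strong = c(rep(TRUE, 14), rep(FALSE, 6)))
  plan <- plan[seq_len(min(n_branches, nrow(plan))), ]
  draws <- with_seed(seed, {
    lapply(seq_len(nrow(plan)), function(i) {
      rng <- if (plan$strong[i]) c(52, 65) else c(25, 40)
      list(angles = runif(plan$k[i], rng[1], rng[2]),
           seg = runif(1, 22, 27),
           rot = runif(1, -45, 45) * pi / 180,
           offset = runif(3, 0, spacing),
           phantom_seed = sample.int(1e6, 1))
    })
  })
  bends <- NULL
  scores <- NULL
  for (i in seq_along(draws)) {
    d <- draws[[i]]
    dir0 <- c(cos(d$rot), sin(d$rot), 0)
    spec <- make_bent_branch(d$angles, d$seg, start = d$offset,
                             direction = dir0)
    ph <- generate_phantom(phantom_spec(
      spec, spacing = rep(spacing, 3), seed = d$phantom_seed,
      aorta = list(radius = 8, length = 24), margin_mm = 4))
    tree <- build_tree(ph$coronary, ph$aorta)
    summ <- summarize_tortuosity(tree)
    prof <- do.call(rbind, lapply(tree$branches, tortuosity_profile))
    pv <- prof[prof$valid & !is.na(prof$ta), ]
    rec <- vapply(ph$truth$bends$abscissa, function(ab) {
      sel <- abs(pv$s - ab) < 4
      if (!any(sel)) NA_real_ else max(pv$ta[sel])
    }, numeric(1))
    bends <- rbind(bends, data.frame(branch = i,
                                     true_angle = ph$truth$bends$angle_deg,
                                     recovered_angle = rec))
    ts_true <- as.integer(plan$k[i] >= 3 && plan$strong[i])
    scores <- rbind(scores, data.frame(branch = i, ts_true = ts_true,
                                       ts_recovered = summ$ts))
  }
  list(bends = bends, scores = scores)
}

#' Seeded calcium recovery experiment
#'
#' Generates phantoms carrying ellipsoidal calcific lesions with
#' analytic volume/extent/position ground truth, runs the full
#' centerline + calcium pipeline, and pairs each detected lesion with
#' its nearest true lesion by distance from the ostium.
#'
#' Lesions are placed 18 mm apart along straight vessels of 2.5-3 mm
#' lumen radius, four per phantom; ellipsoid semi-axes are drawn
#' uniformly in [1.5, 4] mm (the first semi-axis is aligned with the
#' vessel, so true extent is twice it), at 800 HU peak attenuation.
#'
#' @param n_lesions number of lesions (multiple of 4, default 20).
#' @param seed suite seed.
#' @param spacing isotropic voxel spacing in mm (default 0.4).
#' @return data.frame, one row per true lesion: analytic
#'   `true_volume_mm3`, `true_extent_mm`, `true_min_abscissa_mm` and
#'   their detected counterparts (NA when a lesion went undetected).
#' @export
run_cac_recovery <- function(n_lesions = 20, seed = 1, spacing = 0.4) {
  n_phantoms <- ceiling(n_lesions / 4)
  draws <- with_seed(seed, {
    lapply(seq_len(n_phantoms), function(i)
      list(radius = runif(1, 2.5, 3),
           axes = matrix(runif(12, 1.5, 4), 4, 3),
           phantom_seed = sample.int(1e6, 1)))
  })
  centers <- c(14, 32, 50, 68)
  out <- NULL
  for (i in seq_along(draws)) {
    d <- draws[[i]]
    lesions <- lapply(seq_len(4), function(l)
      lesion_spec(centers[l], d$axes[l, ]))
    ph <- generate_phantom(phantom_spec(
      vessel_straight(80, d$radius), lesions = lesions,
      spacing = rep(spacing, 3), seed = d$phantom_seed,
      aorta = list(radius = 8, length = 24), margin_mm = 4))
    tree <- build_tree(ph$coronary, ph$aorta)
    rep_ <- analyze_calcium(ph$image, ph$coronary, ph$aorta, tree)
    truth <- ph$truth$lesions
    det <- rep_$lesions
    for (l in seq_len(nrow(truth))) {
      row <- data.frame(phantom = i, lesion = l,
                        true_volume_mm3 = truth$volume_mm3[l],
                        true_extent_mm = truth$extent_mm[l],
                        true_min_abscissa_mm = truth$min_abscissa_mm[l],
                        volume_mm3 = NA_real_, extent_mm = NA_real_,
                        min_abscissa_mm = NA_real_)
      if (nrow(det)) {
        j <- which.min(abs(det$min_abscissa_mm - truth$min_abscissa_mm[l]))
        if (abs(det$min_abscissa_mm[j] - truth$min_abscissa_mm[l]) < 9) {
          row$volume_mm3 <- det$volume_mm3[j]
          row$extent_mm <- det$extent_mm[j]
          row$min_abscissa_mm <- det$min_abscissa_mm[j]
        }
      }
      out <- rbind(out, row)
    }
  }
  out
}

#' Build the smoke-training phantom set
#'
#' Small straight-tube phantoms cropped to the vessel region (the
#' attached aorta is removed from the field of view so the 2D smoke
#' segmenter faces a clean lumen-versus-background task), with every
#' second axial slice kept.
#'
#' @param n number of phantoms (default 8).
#' @param seed suite seed.
#' @return list of `list(image, labels)` pairs for [smoke_train()].
#' @export
smoke_train_set <- function(n = 8, seed = 1) {
  seeds <- with_seed(seed, sample.int(1e6, n))
  lapply(seeds, function(sd) {
    ph <- generate_phantom(phantom_spec(
      vessel_straight(20, 2), spacing = rep(0.5, 3), seed = sd,
      aorta = list(radius = 8, length = 24), margin_mm = 3,
      blur_sigma = 0.4))
    d <- dim(ph$image$data)
    xs <- ph$image$origin[1] + (seq_len(d[1]) - 1) * ph$image$spacing[1]
    sel <- which(xs > 1)
    zsel <- seq(1, d[3], by = 2)
    list(image = image_volume(ph$image$data[sel, , zsel, drop = FALSE],
                              ph$image$spacing),
         labels = label_map(ph$coronary$data[sel, , zsel, drop = FALSE],
                            ph$image$spacing))
  })
}
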