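#' Parametric vessel specifications
#'
#' Vessel specs describe an analytic centerline (straight line, circular
#' arc, helix, or a polyline with filleted bends) plus a linearly tapering
#' lumen radius and an optional focal stenosis. They are consumed by
#' [generate_phantom()] and carry exact geometric ground truth.
#'
#' Radii must be at least 0.75 mm, half the 1.5 mm caliber floor below
#' which coronary branches are not clinically annotated.
#'
#' @param length_mm vessel length (mm) along the centerline.
#' @param radius_start,radius_end lumen radius (mm) at the two ends;
#'   linear taper in between.
#' @param start world position (mm) of the vessel origin.
#' @param direction initial tangent (normalized internally).
#' @param stenosis optional `list(abscissa, length, reduction)`: a cosine
#'   dip in the radius profile with fractional reduction at its center.
#' @return object of class `vessel_spec`.
#' @export
vessel_straight <- function(length_mm, radius_start, radius_end = radius_start,
                            start = c(0, 0, 0), direction = c(1, 0, 0),
                            stenosis = NULL) {
  new_vessel("straight", list(length = length_mm), radius_start, radius_end,
             start, direction, stenosis)
}

#' @rdname vessel_straight
#' @param arc_radius_mm radius of the circular arc (mm).
#' @param angle_deg subtended angle in degrees, in (0, 360].
#' @export
vessel_arc <- function(arc_radius_mm, angle_deg, radius_start,
                       radius_end = radius_start, start = c(0, 0, 0),
                       direction = c(1, 0, 0), stenosis = NULL) {
  stopifnot(arc_radius_mm > 0, angle_deg > 0, angle_deg <= 360)
  new_vessel("circular_arc",
             list(arc_radius = arc_radius_mm, angle = angle_deg),
             radius_start, radius_end, start, direction, stenosis)
}

#' @rdname vessel_straight
#' @param helix_radius_mm,pitch_mm helix radius and pitch (advance per
#'   turn) in mm.
#' @param turns number of turns (> 0, may be fractional).
#' @export
vessel_helix <- function(helix_radius_mm, pitch_mm, turns, radius_start,
                         radius_end = radius_start, start = c(0, 0, 0),
                         stenosis = NULL) {
  stopifnot(helix_radius_mm > 0, pitch_mm >= 0, turns > 0)
  new_vessel("helix",
             list(helix_radius = helix_radius_mm, pitch = pitch_mm,
                  turns = turns),
             radius_start, radius_end, start, c(0, 1, 0), stenosis)
}

new_vessel <- function(kind, params, radius_start, radius_end, start,
                       direction, stenosis) {
  if (radius_start < 0.75 || radius_end < 0.75)
    stop("lumen radii must be >= 0.75 mm")
  if (!is.null(params$length) && params$length <= 0)
    stop("vessel length must be positive")
  if (!is.null(stenosis)) {
    stopifnot(stenosis$length > 0, stenosis$reduction >= 0,
              stenosis$reduction < 1)
  }
  structure(list(kind = kind, params = params,
                 radius_start = radius_start, radius_end = radius_end,
                 start = as.numeric(start),
                 direction = as.numeric(direction) /
                   sqrt(sum(direction^2)),
                 stenosis = stenosis),
            class = "vessel_spec")
}

#' Build a planar branch with prescribed bends
#'
#' Constructs a polyline vessel of straight segments joined by smooth
#' circular fillets; the total direction change at bend `k` equals
#' `bend_angles[k]` (degrees). Bends alternate sides so the branch does
#' not self-intersect. An empty angle list yields a straight vessel.
#'
#' @param bend_angles numeric vector of bend angles, each in (0, 180).
#' @param segment_len straight-segment length between bends (mm);
#'   must be at least 20 mm (twice the 1 cm tortuosity reference arc).
#' @param fillet_radius fillet radius at each bend (mm).
#' @param radius_start,radius_end,start,direction,stenosis as in
#'   [vessel_straight()].
#' @return object of class `vessel_spec` (kind `polyline_with_bends`).
#' @export
make_bent_branch <- function(bend_angles, segment_len, fillet_radius = 1,
                             radius_start = 1.5, radius_end = radius_start,
                             start = c(0, 0, 0), direction = c(1, 0, 0),
                             stenosis = NULL) {
  if (length(bend_angles) == 0)
    return(vessel_straight(segment_len, radius_start, radius_end,
                           start, direction, stenosis))
  if (any(bend_angles <= 0 | bend_angles >= 180))
    stop("bend angles must lie in (0, 180) degrees")
  if (segment_len < 20)
    stop("segment_len must be >= 20 mm (twice the 1 cm reference arc)")
  tangent_cut <- fillet_radius * tan(bend_angles * pi / 360)
  if (any(2 * max(tangent_cut) >= segment_len))
    stop("segments shorter than the fillet arcs they must host")
  new_vessel("polyline_with_bends",
             list(bend_angles = as.numeric(bend_angles),
                  segment_len = segment_len,
                  fillet_radius = fillet_radius),
             radius_start, radius_end, start, direction, stenosis)
}

#' Sample a vessel centerline
#'
#' Returns the analytic centerline of a vessel spec sampled at a fixed
#' arc-length step, with cumulative abscissa, plus the abscissa and true
#' angle of every bend for `polyline_with_bends` vessels.
#'
#' @param spec a `vessel_spec`.
#' @param step sampling step (mm).
#' @return list with `points` (n x 3, mm), `s` (abscissa, mm), `bends`
#'   (data.frame of `abscissa`, `angle_deg`; empty unless bends exist).
#' @export
vessel_centerline <- function(spec, step = 0.1) {
  p0 <- spec$start
  d0 <- spec$direction
  bends <- data.frame(abscissa = numeric(0), angle_deg = numeric(0))
  if (spec$kind == "straight") {
    L <- spec$params$length
    s <- unique(c(seq(0, L, by = step), L))
    pts <- outer(s, d0) + matrix(p0, length(s), 3, byrow = TRUE)
  } else if (spec$kind == "circular_arc") {
    R <- spec$params$arc_radius
    phi <- spec$params$angle * pi / 180
    n0 <- orthogonal_unit(d0)
    L <- R * phi
    s <- unique(c(seq(0, L, by = step), L))
    th <- s / R
    pts <- matrix(p0, length(s), 3, byrow = TRUE) +
      outer(R * sin(th), d0) + outer(R * (1 - cos(th)), n0)
  } else if (spec$kind == "helix") {
    r <- spec$params$helix_radius
    c_ <- spec$params$pitch / (2 * pi)
    Tmax <- spec$params$turns * 2 * pi
    speed <- sqrt(r^2 + c_^2)
    L <- Tmax * speed
    s <- unique(c(seq(0, L, by = step), L))
    t <- s / speed
    pts <- cbind(r * (cos(t) - 1), r * sin(t), c_ * t) +
      matrix(p0, length(s), 3, byrow = TRUE)
  } else if (spec$kind == "polyline_with_bends") {
    out <- bent_branch_polyline(spec, step)
    pts <- out$points
    s <- arc_length(pts)
    bends <- out$bends
  } else stop("unknown vessel kind: ", spec$kind)
  list(points = pts, s = s, bends = bends)
}

# Straight segments + circular fillets, planar, alternating bend sides.
bent_branch_polyline <- function(spec, step) {
  angles <- spec$params$bend_angles * pi / 180
  seg <- spec$params$segment_len
  rf <- spec$params$fillet_radius
  d <- spec$direction
  normal <- c(0, 0, 1)
  if (abs(sum(d * normal)) > 0.99) normal <- c(0, 1, 0)
  p <- spec$start
  pts <- matrix(p, 1, 3)
  bends <- data.frame(abscissa = numeric(0), angle_deg = numeric(0))
  s_acc <- 0
  side <- 1
  for (k in seq_along(angles)) {
    a <- angles[k]
    cut <- rf * tan(a / 2)
    run <- seg - cut - (if (k == 1) 0 else rf * tan(angles[k - 1] / 2))
    # straight run up to the fillet entry
    ss <- seq(step, run, by = step)
    pts <- rbind(pts, matrix(p, length(ss), 3, byrow = TRUE) + outer(ss, d))
    p <- p + run * d
    s_acc <- s_acc + run
    # fillet arc turning by a toward alternating side
    turn_axis <- side * normal
    n_in <- rotation_about(turn_axis, pi / 2) %*% d  # toward arc center
    center <- p + rf * as.numeric(n_in)
    arc_len <- rf * a
    ss <- seq(step, arc_len, by = step)
    th <- ss / rf
    arc_pts <- t(sapply(th, function(t0) {
      rot <- rotation_about(turn_axis, t0)
      center + as.numeric(rot %*% (p - center))
    }))
    pts <- rbind(pts, arc_pts)
    bends <- rbind(bends, data.frame(abscissa = s_acc + arc_len / 2,
                                     angle_deg = spec$params$bend_angles[k]))
    d <- as.numeric(rotation_about(turn_axis, a) %*% d)
    p <- pts[nrow(pts), ]
    s_acc <- s_acc + arc_len
    side <- -side
  }
  run <- seg - rf * tan(angles[length(angles)] / 2)
  ss <- seq(step, run, by = step)
  pts <- rbind(pts, matrix(p, length(ss), 3, byrow = TRUE) + outer(ss, d))
  list(points = pts, bends = bends)
}

# Local lumen radius at abscissa s for a vessel spec with total length L.
vessel_radius_profile <- function(spec, s, L) {
  r <- spec$radius_start + (spec$radius_end - spec$radius_start) * s / L
  st <- spec$stenosis
  if (!is.null(st)) {
    inside <- abs(s - st$abscissa) <= st$length / 2
    dip <- 1 - st$reduction * 0.5 *
      (1 + cos(2 * pi * (s - st$abscissa) / st$length))
    r[inside] <- r[inside] * dip[inside]
  }
  r
}

#' Closed-form local tortuosity of an analytic vessel
#'
#' Arc-length / chord ratio for a window of arc length `window_mm`
#' centered at mid-vessel, using the exact chord of the analytic
#' centerline. Straight vessels give exactly 1; circular arcs give
#' `s / (2 R sin(s / (2R)))`; helices use the analytic helix chord.
#'
#' @param spec a `vessel_spec` with closed-form chord (straight,
#'   circular_arc, helix).
#' @param window_mm reference-arc length (mm), default the 1 cm arc.
#' @return dimensionless tortuosity >= 1.
#' @export
analytic_tortuosity <- function(spec, window_mm = 10) {
  stopifnot(window_mm > 0)
  if (spec$kind == "straight") return(1.0)
  if (spec$kind == "circular_arc") {
    R <- spec$params$arc_radius
    L <- R * spec$params$angle * pi / 180
    s <- min(window_mm, L)
    return(s / (2 * R * sin(s / (2 * R))))
  }
  if (spec$kind == "helix") {
    r <- spec$params$helix_radius
    c_ <- spec$params$pitch / (2 * pi)
    speed <- sqrt(r^2 + c_^2)
    L <- spec$params$turns * 2 * pi * speed
    s <- min(window_mm, L)
    dt <- s / speed
    chord <- sqrt(2 * r^2 * (1 - cos(dt)) + c_^2 * dt^2)
    return(s / chord)
  }
  stop("no closed-form chord for kind: ", spec$kind)
}

#' Calcific lesion specification
#'
#' An ellipsoidal hyperdense inclusion centered on a parent vessel
#' centerline; the first semi-axis is aligned with the local tangent, so
#' the analytic abscissa extent equals twice that semi-axis.
#'
#' @param center_abscissa position of the lesion center along the parent
#'   vessel (mm from its origin).
#' @param axis_lengths ellipsoid semi-axes (mm), length 3.
#' @param peak_intensity HU painted inside the ellipsoid (default 800).
#' @param vessel index of the parent vessel in the phantom spec.
#' @export
lesion_spec <- function(center_abscissa, axis_lengths,
                        peak_intensity = 800, vessel = 1L) {
  stopifnot(length(axis_lengths) == 3, all(axis_lengths > 0),
            center_abscissa > 0)
  structure(list(center_abscissa = center_abscissa,
                 axis_lengths = as.numeric(axis_lengths),
                 peak_intensity = peak_intensity, vessel = vessel),
            class = "lesion_spec")
}

#' Phantom specification
#'
#' Full description of a synthetic CCTA-like acquisition: vessels,
#' lesions, attached aorta, tissue intensities, PSF blur, noise, grid
#' spacing and RNG seed. The seed fully determines the generated output.
#'
#' Default intensities emulate a contrast-filled blood pool (400 +/- 30
#' HU) over soft-tissue background (50 +/- 20 HU) with 800 HU calcium,
#' so lesions sit near the top of the [-30, 800] HU preprocessing window.
#'
#' @param vessels list of `vessel_spec`.
#' @param lesions list of `lesion_spec`.
#' @param aorta `list(radius, length)` in mm; a cylinder whose surface
#'   passes within ~1 mm of the first vessel root.
#' @param intensities `list(blood_mean, blood_sd, bg_mean, bg_sd)` in HU.
#' @param blur_sigma PSF Gaussian sigma (mm); 0 disables blur.
#' @param noise_sd acquisition noise SD (HU) added after blur.
#' @param spacing voxel spacing (mm), each component in [0.3, 0.7].
#' @param margin_mm padding around the geometry (mm).
#' @param seed integer RNG seed.
#' @export
phantom_spec <- function(vessels, lesions = list(),
                         aorta = list(radius = 12, length = 40),
                         intensities = list(blood_mean = 400, blood_sd = 30,
                                            bg_mean = 50, bg_sd = 20),
                         blur_sigma = 0.5, noise_sd = 10,
                         spacing = c(0.4, 0.4, 0.4), margin_mm = 6,
                         seed = 1L) {
  if (inherits(vessels, "vessel_spec")) vessels <- list(vessels)
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  if (any(spacing < 0.3 | spacing > 0.7))
    stop("spacing components must lie in [0.3, 0.7] mm")
  bm <- intensities$blood_mean
  bs <- intensities$blood_sd
  for (l in lesions)
    if (l$peak_intensity <= bm + 2.5 * bs)
      stop("lesion peak intensity must exceed blood mean + 2.5 SD")
  structure(list(vessels = vessels, lesions = lesions, aorta = aorta,
                 intensities = intensities, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, spacing = as.numeric(spacing),
                 margin_mm = margin_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Paint spheres of radius r[i] at centers[i, ] into a logical array.
paint_tube <- function(mask, vol, centers, radii) {
  d <- dim(mask)
  sp <- vol$spacing
  o <- vol$origin
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, ]
    r <- radii[i]
    i0 <- pmax(1, floor((cx - r - o) / sp) + 1)
    i1 <- pmin(d, ceiling((cx + r - o) / sp) + 1)
    if (any(i0 > i1)) next
    xs <- o[1] + (seq(i0[1], i1[1]) - 1) * sp[1] - cx[1]
    ys <- o[2] + (seq(i0[2], i1[2]) - 1) * sp[2] - cx[2]
    zs <- o[3] + (seq(i0[3], i1[3]) - 1) * sp[3] - cx[3]
    d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
    sub <- mask[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]]
    sub[d2 <= r^2] <- TRUE
    mask[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- sub
  }
  mask
}

# Remove the spherical cap protruding past an end plane (point p, inward
# normal nrm): voxels within reach of the end sphere but behind the plane.
trim_cap <- function(mask, vol, p, nrm, r) {
  d <- dim(mask)
  sp <- vol$spacing
  o <- vol$origin
  reach <- r + max(sp)
  i0 <- pmax(1, floor((p - reach - o) / sp) + 1)
  i1 <- pmin(d, ceiling((p + reach - o) / sp) + 1)
  xs <- o[1] + (seq(i0[1], i1[1]) - 1) * sp[1] - p[1]
  ys <- o[2] + (seq(i0[2], i1[2]) - 1) * sp[2] - p[2]
  zs <- o[3] + (seq(i0[3], i1[3]) - 1) * sp[3] - p[3]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  proj <- outer(outer(xs * nrm[1], ys * nrm[2], "+"), zs * nrm[3], "+")
  d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  sub <- mask[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]]
  sub[proj < -1e-9 & d2 <= (r + max(sp))^2] <- FALSE
  mask[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- sub
  mask
}

gaussian_blur3d <- function(arr, sigma_mm, spacing) {
  for (a in 1:3) {
    sig <- sigma_mm / spacing[a]
    if (sig < 1e-6) next
    rad <- max(1L, ceiling(3 * sig))
    k <- exp(-(seq(-rad, rad))^2 / (2 * sig^2))
    k <- k / sum(k)
    n <- dim(arr)[a]
    K <- matrix(0, n, n)
    for (off in seq(-rad, rad))
      K[cbind(pmax(pmin(seq_len(n) + off, n), 1), seq_len(n))] <-
        K[cbind(pmax(pmin(seq_len(n) + off, n), 1), seq_len(n))] + k[off + rad + 1]
    perm <- c(a, setdiff(1:3, a))
    tmp <- aperm(arr, perm)
    dd <- dim(tmp)
    tmp <- array(K %*% matrix(tmp, dd[1]), dd)
    arr <- aperm(tmp, order(perm))
  }
  arr
}

#' Generate a synthetic CCTA phantom
#'
#' Rasterizes the vessels and aorta of a [phantom_spec()] onto a voxel
#' grid (a voxel belongs to the lumen when its center lies inside the
#' swept-radius tube), paints tissue intensities with per-tissue texture
#' noise and hyperdense lesions, applies a Gaussian PSF, adds seeded
#' acquisition noise, and returns exact analytic ground truth computed
#' before rasterization.
#'
#' @param spec a `phantom_spec`.
#' @return list with elements `image` (`image_volume`), `coronary` and
#'   `aorta` (`label_map`), and `truth`: `centerlines` (list of
#'   `points`/`s`), `bends` (data.frame `vessel`, `abscissa`, `angle_deg`),
#'   `lesions` (data.frame `volume_mm3`, `extent_mm`, `min_abscissa_mm`,
#'   `max_abscissa_mm`), and `tortuosity` (closed-form mid-vessel values
#'   where available).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  step <- min(sp) / 2

  cls <- lapply(spec$vessels, vessel_centerline, step = step)
  lens <- vapply(cls, function(cl) cl$s[length(cl$s)], numeric(1))
  radii <- lapply(seq_along(cls), function(v)
    vessel_radius_profile(spec$vessels[[v]], cls[[v]]$s, lens[v]))

  check_vessel_overlap(spec, cls, radii)

  roots <- t(sapply(spec$vessels, function(v) v$start))
  ao <- aorta_geometry(spec, roots)

  all_pts <- do.call(rbind, lapply(cls, function(cl) cl$points))
  rmax <- max(unlist(radii))
  lo <- pmin(apply(all_pts, 2, min), ao$lo) - rmax - spec$margin_mm
  hi <- pmax(apply(all_pts, 2, max), ao$hi) + rmax + spec$margin_mm
  dims <- pmax(ceiling((hi - lo) / sp) + 1, 8)
  origin <- lo

  grid <- image_volume(array(0, dims), sp, origin)

  lumen <- array(FALSE, dims)
  for (v in seq_along(cls))
    lumen <- paint_tube(lumen, grid, cls[[v]]$points, radii[[v]])
  for (v in seq_along(cls)) {
    pts <- cls[[v]]$points
    n <- nrow(pts)
    t0 <- pts[2, ] - pts[1, ]
    t1 <- pts[n, ] - pts[n - 1, ]
    lumen <- trim_cap(lumen, grid, pts[1, ], t0 / sqrt(sum(t0^2)),
                      radii[[v]][1])
    lumen <- trim_cap(lumen, grid, pts[n, ], -t1 / sqrt(sum(t1^2)),
                      radii[[v]][n])
  }

  aorta_mask <- rasterize_cylinder(grid, ao$point, ao$axis, spec$aorta$radius,
                                   spec$aorta$length) |
    rasterize_sphere(grid, ao$sphere, ao$bulge_r)
  coronary <- lumen & !aorta_mask

  ints <- spec$intensities
  truth_lesions <- data.frame()
  img <- with_seed(spec$seed, {
    arr <- array(rnorm(prod(dims), ints$bg_mean, ints$bg_sd), dims)
    pool <- lumen | aorta_mask
    arr[pool] <- rnorm(sum(pool), ints$blood_mean, ints$blood_sd)
    for (l in spec$lesions) {
      les <- paint_lesion(arr, grid, l, cls[[l$vessel]])
      arr <- les$arr
      truth_lesions <- rbind(truth_lesions, les$truth)
    }
    if (spec$blur_sigma > 0)
      arr <- gaussian_blur3d(arr, spec$blur_sigma, sp)
    if (spec$noise_sd > 0)
      arr <- arr + array(rnorm(prod(dims), 0, spec$noise_sd), dims)
    arr
  })

  truth_cl <- lapply(cls, function(cl) {
    pts <- resample_polyline(cl$points, 0.5)
    list(points = pts, s = arc_length(pts))
  })
  bends <- do.call(rbind, lapply(seq_along(cls), function(v)
    if (nrow(cls[[v]]$bends)) cbind(vessel = v, cls[[v]]$bends) else NULL))
  if (is.null(bends))
    bends <- data.frame(vessel = integer(0), abscissa = numeric(0),
                        angle_deg = numeric(0))
  tort <- lapply(spec$vessels, function(v)
    if (v$kind %in% c("straight", "circular_arc", "helix"))
      analytic_tortuosity(v) else NA_real_)

  list(image = image_volume(img, sp, origin),
       coronary = label_map(coronary * 1, sp, origin),
       aorta = label_map(aorta_mask * 1, sp, origin),
       truth = list(centerlines = truth_cl, bends = bends,
                    lesions = truth_lesions,
                    tortuosity = unlist(tort)),
       spec = spec)
}

# Vessels sharing a root may overlap in one contiguous region around that
# root (a bifurcation); any other lumen contact — between separately
# rooted vessels, or re-merging after limbs have separated — would make
# ground-truth abscissae ambiguous and is an error.
check_vessel_overlap <- function(spec, cls, radii) {
  nv <- length(cls)
  if (nv < 2) return(invisible(TRUE))
  for (a in seq_len(nv - 1)) for (b in seq(a + 1, nv)) {
    shared_root <- sqrt(sum((spec$vessels[[a]]$start -
                               spec$vessels[[b]]$start)^2)) < 1
    ka <- seq(1, nrow(cls[[a]]$points), by = max(1, nrow(cls[[a]]$points) %/% 300))
    kb <- seq(1, nrow(cls[[b]]$points), by = max(1, nrow(cls[[b]]$points) %/% 300))
    pb <- cls[[b]]$points[kb, , drop = FALSE]
    contact_s <- numeric(0)
    for (i in ka) {
      d <- sqrt(rowSums(sweep(pb, 2, cls[[a]]$points[i, ])^2))
      if (any(d < radii[[a]][i] + radii[[b]][kb]))
        contact_s <- c(contact_s, cls[[a]]$s[i])
    }
    if (!length(contact_s)) next
    if (!shared_root)
      stop("overlapping vessels would merge lumens ",
           "(vessels ", a, " and ", b, ")")
    gaps <- diff(sort(contact_s))
    if (min(contact_s) > 3 || (length(gaps) && max(gaps) > 3))
      stop("vessels ", a, " and ", b,
           " re-merge after separating from their shared root")
  }
  invisible(TRUE)
}

# Aorta = tubular body (axis along z) plus a sinus-like spherical bulge
# whose surface passes ~1 mm from the first vessel root. The bulge is
# strictly the nearest aortic feature to the root, so the closest-voxel
# ostium seeding has a unique argmin; a bare cylinder is equidistant to a
# whole line of voxels on a vessel start face.
aorta_geometry <- function(spec, roots) {
  r <- spec$aorta$radius
  len <- spec$aorta$length
  # the bulge is kept small (strong curvature) so that the distance from
  # a vessel start face to the aorta falls off clearly away from the
  # face center, beating voxelization jitter in the seeding argmin
  bulge_r <- min(4, r)
  sphere <- c(roots[1, 1] - bulge_r - 1, roots[1, 2], roots[1, 3])
  point <- c(roots[1, 1] - r - 3, roots[1, 2], mean(roots[, 3]))
  axis <- c(0, 0, 1)
  lo <- pmin(point - c(r, r, len / 2), sphere - bulge_r)
  hi <- pmax(point + c(r, r, len / 2), sphere + bulge_r)
  list(point = point, axis = axis, sphere = sphere, bulge_r = bulge_r,
       lo = lo, hi = hi)
}

rasterize_sphere <- function(vol, center, radius) {
  d <- dim(vol$data)
  sp <- vol$spacing
  o <- vol$origin
  xs <- o[1] + (seq_len(d[1]) - 1) * sp[1] - center[1]
  ys <- o[2] + (seq_len(d[2]) - 1) * sp[2] - center[2]
  zs <- o[3] + (seq_len(d[3]) - 1) * sp[3] - center[3]
  outer(outer(xs^2, ys^2, "+"), zs^2, "+") <= radius^2
}

rasterize_cylinder <- function(vol, point, axis, radius, length_mm) {
  d <- dim(vol$data)
  sp <- vol$spacing
  o <- vol$origin
  xs <- o[1] + (seq_len(d[1]) - 1) * sp[1] - point[1]
  ys <- o[2] + (seq_len(d[2]) - 1) * sp[2] - point[2]
  zs <- o[3] + (seq_len(d[3]) - 1) * sp[3] - point[3]
  proj <- outer(outer(xs * axis[1], ys * axis[2], "+"), zs * axis[3], "+")
  d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+") - proj^2
  d2 <= radius^2 & abs(proj) <= length_mm / 2
}

paint_lesion <- function(arr, vol, l, cl) {
  ctr <- point_at_abscissa(cl$points, cl$s, l$center_abscissa)
  i <- which.min(abs(cl$s - l$center_abscissa))
  i2 <- min(i + 1, length(cl$s))
  tangent <- cl$points[i2, ] - cl$points[max(1, i - 1), ]
  tangent <- tangent / sqrt(sum(tangent^2))
  n1 <- orthogonal_unit(tangent)
  n2 <- c(tangent[2] * n1[3] - tangent[3] * n1[2],
          tangent[3] * n1[1] - tangent[1] * n1[3],
          tangent[1] * n1[2] - tangent[2] * n1[1])
  ax <- l$axis_lengths
  d <- dim(arr)
  sp <- vol$spacing
  o <- vol$origin
  reach <- max(ax)
  i0 <- pmax(1, floor((ctr - reach - o) / sp) + 1)
  i1 <- pmin(d, ceiling((ctr + reach - o) / sp) + 1)
  xs <- o[1] + (seq(i0[1], i1[1]) - 1) * sp[1] - ctr[1]
  ys <- o[2] + (seq(i0[2], i1[2]) - 1) * sp[2] - ctr[2]
  zs <- o[3] + (seq(i0[3], i1[3]) - 1) * sp[3] - ctr[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  P <- as.matrix(g) %*% cbind(tangent, n1, n2)
  inside <- (P[, 1] / ax[1])^2 + (P[, 2] / ax[2])^2 + (P[, 3] / ax[3])^2 <= 1
  sub <- arr[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]]
  sub[inside] <- l$peak_intensity
  arr[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- sub
  truth <- data.frame(vessel = l$vessel,
                      volume_mm3 = 4 / 3 * pi * prod(ax),
                      extent_mm = 2 * ax[1],
                      min_abscissa_mm = l$center_abscissa - ax[1],
                      max_abscissa_mm = l$center_abscissa + ax[1])
  list(arr = arr, truth = truth)
}
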