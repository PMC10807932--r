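#' Pointwise local tortuosity
#'
#' Local tortuosity (LT) at a centerline point is the ratio of the actual
#' path length L0 of a reference arc of length `window_mm` (default 1 cm)
#' centered at the point, to the straight chord L between the arc's two
#' ends. A straight vessel has LT = 1 everywhere; LT grows with local
#' winding. Points whose reference arc would extend past either end of
#' the branch are flagged invalid and excluded from summaries.
#'
#' @param branch a `centerline_branch` (or any list with `points`, `s`).
#' @param index point index; omit to compute at all points.
#' @param window_mm reference-arc length (mm), default 10.
#' @return for a single index, a scalar (NA if invalid); otherwise a
#'   data.frame with `s`, `lt`, `valid`.
#' @export
local_tortuosity <- function(branch, index = NULL, window_mm = 10) {
  prof <- lt_profile(branch, window_mm)
  if (is.null(index)) return(prof)
  prof$lt[index]
}

lt_profile <- function(branch, window_mm = 10) {
  s <- branch$s
  pts <- branch$points
  h <- window_mm / 2
  valid <- s - h >= s[1] - 1e-9 & s + h <= s[length(s)] + 1e-9
  lt <- rep(NA_real_, length(s))
  for (i in which(valid)) {
    a <- point_at_abscissa(pts, s, s[i] - h)
    b <- point_at_abscissa(pts, s, s[i] + h)
    chord <- sqrt(sum((b - a)^2))
    lt[i] <- if (chord < 1e-9) Inf else window_mm / chord
  }
  data.frame(s = s, lt = lt, valid = valid)
}

#' Pointwise tortuosity angle
#'
#' The tortuosity angle (TA) at a centerline point is the arccosine of
#' the dot product of the unit direction vectors of straight lines
#' fitted, in the least-squares sense, to the upstream and downstream
#' halves of the reference arc. Both directions are oriented along
#' increasing abscissa, so a straight vessel gives TA = 0 and a sharp
#' direction change of x degrees gives TA ~ x.
#'
#' @inheritParams local_tortuosity
#' @return for a single index, TA in degrees (NA if invalid); otherwise
#'   a data.frame with `s`, `ta`, `valid`.
#' @export
tortuosity_angle <- function(branch, index = NULL, window_mm = 10) {
  prof <- ta_profile(branch, window_mm)
  if (is.null(index)) return(prof)
  prof$ta[index]
}

ta_profile <- function(branch, window_mm = 10) {
  s <- branch$s
  pts <- branch$points
  h <- window_mm / 2
  valid <- s - h >= s[1] - 1e-9 & s + h <= s[length(s)] + 1e-9
  ta <- rep(NA_real_, length(s))
  for (i in which(valid)) {
    up <- pts[s >= s[i] - h - 1e-9 & s <= s[i] + 1e-9, , drop = FALSE]
    dw <- pts[s >= s[i] - 1e-9 & s <= s[i] + h + 1e-9, , drop = FALSE]
    vu <- fit_direction(up)
    vd <- fit_direction(dw)
    if (is.null(vu) || is.null(vd)) {
      warning("degenerate half-arc fit; TA set to 0")
      ta[i] <- 0
      next
    }
    ta[i] <- acos(max(-1, min(1, sum(vu * vd)))) * 180 / pi
  }
  data.frame(s = s, ta = ta, valid = valid)
}

# Least-squares line direction of a point set, oriented with increasing
# abscissa (first -> last point). NULL if degenerate.
fit_direction <- function(pts) {
  if (nrow(pts) < 2) return(NULL)
  ctr <- sweep(pts, 2, colMeans(pts))
  if (max(abs(ctr)) < 1e-12) return(NULL)
  v <- svd(ctr, nu = 0, nv = 1)$v[, 1]
  span <- pts[nrow(pts), ] - pts[1, ]
  if (sum(v * span) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Tortuosity profile of a branch
#'
#' Computes LT and TA at every centerline point and marks which points
#' have a complete reference arc.
#'
#' @inheritParams local_tortuosity
#' @return object of class `tortuosity_profile`: data.frame with columns
#'   `s`, `g` (if present on the branch), `lt`, `ta`, `valid`.
#' @export
tortuosity_profile <- function(branch, window_mm = 10) {
  lt <- lt_profile(branch, window_mm)
  ta <- ta_profile(branch, window_mm)
  out <- data.frame(s = lt$s, lt = lt$lt, ta = ta$ta, valid = lt$valid)
  if (!is.null(branch$g)) out$g <- branch$g
  class(out) <- c("tortuosity_profile", "data.frame")
  attr(out, "window_mm") <- window_mm
  out
}

#' Detect bends along a branch
#'
#' A bend is a maximal contiguous run of valid points with TA at or
#' above `threshold_deg`; runs separated by less than `min_gap_mm` of
#' below-threshold abscissa are merged into one bend. The bend angle is
#' the maximum TA within the run.
#'
#' @param profile a `tortuosity_profile`.
#' @param threshold_deg TA threshold (degrees), default 45.
#' @param min_gap_mm minimum below-threshold separation between distinct
#'   bends (mm), default 2.
#' @return data.frame with one row per bend: `s_start`, `s_end`,
#'   `s_peak`, `angle_deg`.
#' @export
detect_bends <- function(profile, threshold_deg = 45, min_gap_mm = 2) {
  ok <- profile$valid & !is.na(profile$ta)
  hi <- ok & profile$ta >= threshold_deg
  if (!any(hi))
    return(data.frame(s_start = numeric(0), s_end = numeric(0),
                      s_peak = numeric(0), angle_deg = numeric(0)))
  runs <- logical_runs(hi)
  runs <- runs[runs$value, , drop = FALSE]
  # merge runs separated by < min_gap_mm of abscissa
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (r in 2:nrow(runs)) {
    gap <- profile$s[runs$start[r]] - profile$s[merged$end[nrow(merged)]]
    if (gap < min_gap_mm) merged$end[nrow(merged)] <- runs$end[r]
    else merged <- rbind(merged, runs[r, ])
  }
  out <- lapply(seq_len(nrow(merged)), function(r) {
    idx <- merged$start[r]:merged$end[r]
    peak <- idx[which.max(profile$ta[idx])]
    data.frame(s_start = profile$s[merged$start[r]],
               s_end = profile$s[merged$end[r]],
               s_peak = profile$s[peak],
               angle_deg = profile$ta[peak])
  })
  do.call(rbind, out)
}

#' Tract tortuosity of a zone
#'
#' L0/L ratio over the maximal contiguous sub-tract of a branch whose
#' points fall in the requested geodesic zone (proximal, medial,
#' distal). Returns NA when fewer than 2 branch points lie in the zone.
#'
#' @param branch a `centerline_branch` with `g` populated.
#' @param zone one of "proximal", "medial", "distal".
#' @return dimensionless tract tortuosity >= 1, or NA.
#' @export
tract_tortuosity <- function(branch, zone) {
  stopifnot(!is.null(branch$g))
  zl <- assign_zone(pmin(pmax(branch$g, 0), 1))
  inz <- zl == zone
  if (sum(inz) < 2) return(NA_real_)
  runs <- logical_runs(inz)
  runs <- runs[runs$value, , drop = FALSE]
  span <- runs$end - runs$start
  r <- runs[which.max(span), ]
  i0 <- r$start
  i1 <- r$end
  L0 <- branch$s[i1] - branch$s[i0]
  L <- sqrt(sum((branch$points[i1, ] - branch$points[i0, ])^2))
  if (L < 1e-9) return(Inf)
  L0 / L
}

#' Tortuosity score of a centerline tree
#'
#' Number of branches, among those at least `min_branch_mm` long, that
#' present three or more bends with TA >= 45 degrees along their course.
#' TS = 0 indicates no tortuosity; TS >= 4 is labeled severe.
#'
#' @param tree a `centerline_tree`, or a list of per-branch bend tables
#'   as returned by [detect_bends()].
#' @param min_branch_mm minimum qualifying branch length (mm).
#' @param window_mm reference-arc length for TA (mm).
#' @return integer score.
#' @export
tortuosity_score <- function(tree, min_branch_mm = 20, window_mm = 10) {
  bends <- if (inherits(tree, "centerline_tree"))
    lapply(branch_subset(tree, min_branch_mm), function(b)
      detect_bends(tortuosity_profile(b, window_mm)))
  else tree
  sum(vapply(bends, nrow, integer(1)) >= 3)
}

branch_subset <- function(tree, min_branch_mm) {
  Filter(function(b) max(b$s) >= min_branch_mm, tree$branches)
}

#' Per-patient tortuosity summary
#'
#' Computes, over all qualifying branches of a tree: tract tortuosity
#' per zone (mean over branches with points in the zone), the 95th
#' percentiles of LT and TA over all valid points (overall and per
#' zone), per-branch bend tables, and the tortuosity score with its
#' severity label.
#'
#' @param tree a `centerline_tree`.
#' @param window_mm reference-arc length (mm), default 10.
#' @param min_branch_mm minimum qualifying branch length (mm), default 20.
#' @return object of class `tortuosity_summary`: list with `tract`
#'   (named per-zone means), `lt_95`, `ta_95`, `lt_95_zone`, `ta_95_zone`,
#'   `bends` (data.frame with branch column), `ts`, `severity`.
#' @export
summarize_tortuosity <- function(tree, window_mm = 10, min_branch_mm = 20) {
  branches <- branch_subset(tree, min_branch_mm)
  zones <- c("proximal", "medial", "distal")
  profs <- lapply(branches, tortuosity_profile, window_mm = window_mm)
  bends <- do.call(rbind, lapply(seq_along(profs), function(b) {
    tb <- detect_bends(profs[[b]])
    if (nrow(tb)) cbind(branch = b, tb) else NULL
  }))
  if (is.null(bends))
    bends <- data.frame(branch = integer(0), s_start = numeric(0),
                        s_end = numeric(0), s_peak = numeric(0),
                        angle_deg = numeric(0))
  tract <- sapply(zones, function(z) {
    vals <- vapply(branches, tract_tortuosity, numeric(1), zone = z)
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  })
  all_prof <- do.call(rbind, profs)
  ok <- all_prof$valid & !is.na(all_prof$lt)
  q95 <- function(x) if (length(x)) unname(quantile(x, 0.95)) else NA_real_
  lt_95 <- q95(all_prof$lt[ok])
  ta_95 <- q95(all_prof$ta[ok & !is.na(all_prof$ta)])
  zone_of <- if (!is.null(all_prof$g))
    assign_zone(pmin(pmax(all_prof$g, 0), 1)) else NULL
  lt_95_zone <- ta_95_zone <- stats::setNames(rep(NA_real_, 3), zones)
  if (!is.null(zone_of)) for (z in zones) {
    sel <- ok & zone_of == z
    lt_95_zone[z] <- q95(all_prof$lt[sel])
    ta_95_zone[z] <- q95(all_prof$ta[sel & !is.na(all_prof$ta)])
  }
  ts <- sum(vapply(split(bends, bends$branch), nrow, integer(1)) >= 3)
  structure(list(tract = tract, lt_95 = lt_95, ta_95 = ta_95,
                 lt_95_zone = lt_95_zone, ta_95_zone = ta_95_zone,
                 bends = bends, ts = ts,
                 severity = ts_severity(ts),
                 n_branches = length(branches)),
            class = "tortuosity_summary")
}

ts_severity <- function(ts) {
  if (ts == 0) "none" else if (ts >= 4) "severe" else "moderate"
}

#' @export
print.tortuosity_summary <- function(x, ...) {
  cat(sprintf("<tortuosity_summary> TS = %d (%s), %d branch(es)\n",
              x$ts, x$severity, x$n_branches))
  cat(sprintf("  tract tortuosity: proximal %.3f, medial %.3f, distal %.3f\n",
              x$tract["proximal"], x$tract["medial"], x$tract["distal"]))
  cat(sprintf("  LT95 %.3f, TA95 %.1f deg, %d bend(s)\n",
              x$lt_95, x$ta_95, nrow(x$bends)))
  invisible(x)
}
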