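#' Ostium seeds from aorta proximity
#'
#' For each 26-connected component of the coronary label map, returns the
#' lumen voxel whose center minimizes the Euclidean distance to the aorta
#' voxel set; this voxel serves as the ostium seed of that coronary tree.
#' Ties are broken by the lowest linearized voxel index.
#'
#' @param coronary,aorta `label_map`s on the same grid.
#' @return data.frame with one row per component: `component`, voxel
#'   indices `i`,`j`,`k`, world coordinates `x`,`y`,`z` (mm), and
#'   `dist_mm` to the aorta.
#' @export
find_ostium_seed <- function(coronary, aorta) {
  check_same_grid(coronary, aorta)
  if (!any(coronary$data > 0)) stop("empty coronary mask")
  if (!any(aorta$data > 0)) stop("empty aorta mask")
  d <- dim(coronary$data)
  dist2 <- .edt_sq_cpp(as.integer(aorta$data == 0), d, coronary$spacing)
  labs <- .label_cc_cpp(as.integer(coronary$data > 0), d)
  out <- NULL
  for (comp in seq_len(max(labs))) {
    idx <- which(labs == comp)
    best <- idx[which.min(dist2[idx])]
    ijk <- unlin_index(best, d)
    w <- voxel_world(coronary, ijk)
    out <- rbind(out, data.frame(component = comp, i = ijk[1], j = ijk[2],
                                 k = ijk[3], x = w[1], y = w[2], z = w[3],
                                 dist_mm = sqrt(dist2[best])))
  }
  out
}

#' Normalized geodesic distance field
#'
#' Shortest-path distance from the seed over the 26-connected voxel graph
#' of the mask with Euclidean edge lengths, divided by its maximum over
#' the seed's connected component, so g(seed) = 0 and max g = 1. Voxels
#' outside the reachable component are NA.
#'
#' @param coronary a `label_map`.
#' @param seed seed location: either a length-3 voxel index (1-based) or
#'   a row of [find_ostium_seed()] output.
#' @return an `image_volume` whose data holds g; attribute `max_dist_mm`
#'   carries the normalizing geodesic length.
#' @export
geodesic_field <- function(coronary, seed) {
  d <- dim(coronary$data)
  ijk <- seed_to_ijk(seed)
  if (coronary$data[ijk[1], ijk[2], ijk[3]] == 0)
    stop("seed voxel lies outside the mask")
  lin0 <- lin_index(matrix(ijk, 1), d) - 1L
  res <- .dijkstra_cpp(as.integer(coronary$data > 0), d, coronary$spacing,
                       as.integer(lin0), 1.0)
  dist <- res$dist
  dist[!is.finite(dist)] <- NA
  dmax <- max(dist, na.rm = TRUE)
  g <- array(dist / dmax, d)
  out <- image_volume(replace(g, is.na(g), 0), coronary$spacing,
                      coronary$origin, coronary$direction)
  out$data[is.na(g)] <- NA
  attr(out, "max_dist_mm") <- dmax
  out
}

seed_to_ijk <- function(seed) {
  if (is.data.frame(seed)) as.integer(c(seed$i[1], seed$j[1], seed$k[1]))
  else as.integer(seed[1:3])
}

#' Recursive endpoint detection on the geodesic field
#'
#' Thresholds the field at `1 - delta` for `delta = delta_step,
#' 2*delta_step, ..., 1`. Each new 26-connected superlevel region that
#' does not already contain a claimed endpoint emits the point of maximal
#' g within it. Gradually increasing delta reveals one endpoint per
#' terminal branch of the vessel tree.
#'
#' @param gfield output of [geodesic_field()].
#' @param delta_step threshold increment, default 0.05.
#' @return data.frame of endpoints: voxel indices `i`,`j`,`k`, world
#'   `x`,`y`,`z`, and `g`.
#' @export
detect_endpoints <- function(gfield, delta_step = 0.05) {
  stopifnot(delta_step > 0, delta_step <= 1)
  d <- dim(gfield$data)
  g <- gfield$data
  claimed <- integer(0)
  for (delta in seq(delta_step, 1 + 1e-9, by = delta_step)) {
    above <- !is.na(g) & g > 1 - delta
    if (!any(above)) next
    labs <- .label_cc_cpp(as.integer(above), d)
    for (comp in seq_len(max(labs))) {
      idx <- which(labs == comp)
      if (length(claimed) && any(claimed %in% idx)) next
      best <- idx[which.max(g[idx])]
      claimed <- c(claimed, best)
    }
  }
  ijk <- unlin_index(claimed, d)
  w <- voxel_world(gfield, ijk)
  data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
             x = w[, 1], y = w[, 2], z = w[, 3], g = g[claimed])
}

#' Trace one centerline branch
#'
#' Minimal path from seed to endpoint on the 26-connected voxel graph
#' with medialness weighting: each edge costs its Euclidean length
#' divided by `eps + d_interior`, where `d_interior` is the Euclidean
#' distance (mm) of the voxel to the mask boundary, so paths hug the
#' lumen axis. The voxel path is resampled at `resample_mm` steps,
#' smoothed by a centered moving average, and the abscissa recomputed.
#'
#' @param coronary `label_map`.
#' @param seed,endpoint voxel indices (length-3) or data.frame rows with
#'   `i`,`j`,`k` columns.
#' @param resample_mm resampling step (mm), default 0.25.
#' @param smooth_window moving-average window in points, default 3.
#' @param eps medialness regularizer (voxel units), default 0.1.
#' @param refine_iters sub-voxel recentering iterations (0 disables).
#' @return a `centerline_branch`: list with `points` (n x 3 mm), `s`
#'   (abscissa, mm), `voxel_path` (linear indices), `g` (filled by
#'   [build_tree()]).
#' @export
trace_centerline <- function(coronary, seed, endpoint, resample_mm = 0.25,
                             smooth_window = 3L, eps = 0.1,
                             refine_iters = 3L) {
  d <- dim(coronary$data)
  s_ijk <- seed_to_ijk(seed)
  e_ijk <- seed_to_ijk(endpoint)
  dt <- sqrt(.edt_sq_cpp(as.integer(coronary$data > 0), d, coronary$spacing))
  cost <- 1 / (eps * mean(coronary$spacing) + dt)
  lin0 <- lin_index(matrix(s_ijk, 1), d) - 1L
  res <- .dijkstra_cpp(as.integer(coronary$data > 0), d, coronary$spacing,
                       as.integer(lin0), cost)
  e_lin <- lin_index(matrix(e_ijk, 1), d)
  if (!is.finite(res$dist[e_lin]))
    stop("endpoint not connected to seed")
  path <- integer(0)
  cur <- e_lin - 1L
  while (cur >= 0) {
    path <- c(path, cur + 1L)
    cur <- res$parent[cur + 1L]
  }
  path <- rev(path)
  pts <- voxel_world(coronary, unlin_index(path, d))
  pts_r <- resample_polyline(pts, resample_mm)
  if (refine_iters > 0) {
    reach <- max(dt[path]) + 1
    mask_pts <- voxel_world(coronary, unlin_index(which(coronary$data > 0), d))
    pts_r <- recenter_polyline(pts_r, mask_pts, reach,
                               0.75 * mean(coronary$spacing), refine_iters)
  }
  pts_s <- smooth_polyline(pts_r, smooth_window)
  structure(list(points = pts_s, s = arc_length(pts_s),
                 voxel_path = path, g = NULL),
            class = "centerline_branch")
}

# Sub-voxel recentering: move each path point, perpendicular to the local
# tangent, onto the centroid of the lumen voxels in a thin cross-sectional
# slab (a disc of radius `reach` around the point). Corrects the inward
# corner bias of discrete minimal paths at vessel bends and recenters the
# branch tip from the max-g face corner onto the lumen axis. Slab
# orientation uses tangents of a heavily smoothed copy of the path so
# that slabs near the vessel end faces stay perpendicular to the vessel
# rather than tilting with local voxel jitter.
recenter_polyline <- function(pts, mask_pts, reach, slab_half, iters) {
  for (it in seq_len(iters)) {
    n <- nrow(pts)
    if (n < 3) return(pts)
    ref <- smooth_polyline(pts, 11L)
    tang <- rbind(ref[2, ] - ref[1, ], ref[3:n, ] - ref[1:(n - 2), ],
                  ref[n, ] - ref[n - 1, ])
    tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
    # the tail of a minimal path dives toward the max-g face corner; use
    # the interior direction for its slabs so they stay cross-sectional
    s <- arc_length(pts)
    j <- which(s <= s[n] - 2)
    if (length(j) && max(j) < n)
      tang[seq(max(j) + 1, n), ] <- rep(tang[max(j), ], each = n - max(j))
    out <- pts
    for (i in seq(2, n)) {  # point 1 stays at the ostium seed
      rel <- sweep(mask_pts, 2, pts[i, ])
      proj_all <- rel %*% tang[i, ]
      perp2 <- rowSums(rel^2) - proj_all^2
      slab <- abs(proj_all) <= slab_half & perp2 <= reach^2
      if (sum(slab) < 3) next
      ctr <- colMeans(mask_pts[slab, , drop = FALSE])
      dvec <- ctr - pts[i, ]
      dvec <- dvec - sum(dvec * tang[i, ]) * tang[i, ]
      out[i, ] <- pts[i, ] + dvec
    }
    pts <- out
  }
  pts
}

#' Anatomical zone from normalized geodesic distance
#'
#' Proximal for g <= 0.33, medial for 0.33 < g <= 0.66, distal for
#' g > 0.66 (boundaries inclusive on the proximal side).
#'
#' @param g numeric vector in [0, 1].
#' @return factor with levels proximal, medial, distal.
#' @export
assign_zone <- function(g) {
  if (any(is.na(g)) || any(g < 0 | g > 1))
    stop("g must lie in [0, 1]")
  z <- ifelse(g <= 0.33, "proximal", ifelse(g <= 0.66, "medial", "distal"))
  factor(z, levels = c("proximal", "medial", "distal"))
}

#' Build the ostium-rooted centerline tree
#'
#' Composes seeding, geodesic field, recursive endpoint detection and
#' medial path tracing for every 26-connected component of the coronary
#' mask. Branches sharing at least 90% of their voxels with a longer
#' branch are dropped as duplicates. Each branch carries a monotone
#' normalized geodesic distance `g` per point.
#'
#' @param coronary,aorta `label_map`s on the same grid.
#' @param params list of `delta_step`, `resample_mm`, `smooth_window`,
#'   `min_branch_mm` (overrides of the defaults 0.05 / 0.5 / 5 / 20).
#' @return object of class `centerline_tree`: `ostia` (data.frame from
#'   [find_ostium_seed()]), `branches` (list of `centerline_branch`, each
#'   with `component` and monotone `g`), and `params`.
#' @export
build_tree <- function(coronary, aorta, params = list()) {
  p <- modify_defaults(list(delta_step = 0.05, resample_mm = 0.25,
                            smooth_window = 3L, min_branch_mm = 20,
                            eps = 0.1, refine_iters = 3L), params)
  seeds <- find_ostium_seed(coronary, aorta)
  d <- dim(coronary$data)
  labs <- array(.label_cc_cpp(as.integer(coronary$data > 0), d), d)
  branches <- list()
  for (r in seq_len(nrow(seeds))) {
    comp <- seeds$component[r]
    comp_mask <- label_map((labs == comp) * 1, coronary$spacing,
                           coronary$origin, coronary$direction)
    gf <- geodesic_field(comp_mask, seeds[r, ])
    eps_df <- detect_endpoints(gf, p$delta_step)
    comp_branches <- lapply(seq_len(nrow(eps_df)), function(e)
      trace_centerline(comp_mask, seeds[r, ], eps_df[e, ],
                       p$resample_mm, p$smooth_window, p$eps,
                       p$refine_iters))
    comp_branches <- dedupe_branches(comp_branches)
    for (b in comp_branches) {
      # map smoothed points back to nearest voxels for g lookup
      ijk <- world_voxel(coronary, b$points)
      gp <- gf$data[lin_index(ijk, d)]
      gp[is.na(gp)] <- 0
      b$g <- cummax(gp)
      b$component <- comp
      branches[[length(branches) + 1]] <- b
    }
  }
  structure(list(ostia = seeds, branches = branches, params = p),
            class = "centerline_tree")
}

dedupe_branches <- function(branches) {
  if (length(branches) <= 1) return(branches)
  lens <- vapply(branches, function(b) length(b$voxel_path), numeric(1))
  ord <- order(-lens)
  keep <- logical(length(branches))
  kept_paths <- list()
  for (i in ord) {
    vp <- branches[[i]]$voxel_path
    dup <- FALSE
    for (kp in kept_paths)
      if (sum(vp %in% kp) / length(vp) >= 0.9) { dup <- TRUE; break }
    if (!dup) {
      keep[i] <- TRUE
      kept_paths[[length(kept_paths) + 1]] <- vp
    }
  }
  branches[keep]
}

modify_defaults <- function(defaults, overrides) {
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

#' @export
print.centerline_tree <- function(x, ...) {
  cat(sprintf("<centerline_tree> %d component(s), %d branch(es)\n",
              nrow(x$ostia), length(x$branches)))
  for (b in seq_along(x$branches))
    cat(sprintf("  branch %d: %.1f mm, component %d\n", b,
                max(x$branches[[b]]$s), x$branches[[b]]$component))
  invisible(x)
}

#' Export a centerline tree
#'
#' `write_tree_json()` writes branches as JSON polylines with abscissa
#' and g; `write_tree_vtk()` writes VTK legacy polydata (ASCII).
#'
#' @param tree a `centerline_tree`.
#' @param path output file.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(
    ostia = tree$ostia,
    branches = lapply(tree$branches, function(b)
      list(points = unname(b$points), s = b$s, g = b$g,
           component = b$component)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
write_tree_vtk <- function(tree, path) {
  pts <- do.call(rbind, lapply(tree$branches, function(b) b$points))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "corochar centerlines",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(pts))), con)
  write(t(pts), con, ncolumns = 3)
  ns <- vapply(tree$branches, function(b) nrow(b$points), integer(1))
  writeLines(sprintf("LINES %d %d", length(ns), sum(ns) + length(ns)), con)
  off <- 0
  for (n in ns) {
    writeLines(paste(c(n, seq(off, off + n - 1)), collapse = " "), con)
    off <- off + n
  }
  invisible(path)
}
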