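# Internal geometry helpers shared across modules.

# Linearized (1-based) index from 1-based voxel indices.
lin_index <- function(ijk, dim) {
  ijk[, 1] + dim[1] * (ijk[, 2] - 1 + dim[2] * (ijk[, 3] - 1))
}

# 1-based voxel indices (n x 3) from linearized indices.
unlin_index <- function(idx, dim) {
  idx0 <- idx - 1
  k <- idx0 %/% (dim[1] * dim[2])
  r <- idx0 %% (dim[1] * dim[2])
  j <- r %/% dim[1]
  i <- r %% dim[1]
  cbind(i + 1, j + 1, k + 1)
}

# World coordinates (mm) of voxel centers, rows of ijk 1-based.
voxel_world <- function(vol, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1)
  local <- sweep(ijk - 1, 2, vol$spacing, "*")
  sweep(local %*% t(vol$direction), 2, vol$origin, "+")
}

# Nearest voxel index (1-based triplet) for world points (n x 3); clamped
# to the grid.
world_voxel <- function(vol, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  local <- sweep(pts, 2, vol$origin, "-") %*% vol$direction # direction orthonormal
  ijk <- round(sweep(local, 2, vol$spacing, "/")) + 1
  for (a in 1:3) ijk[, a] <- pmin(pmax(ijk[, a], 1), dim(vol$data)[a])
  ijk
}

# Cumulative arc length of a polyline (n x 3), first point at 0.
arc_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  steps <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(steps))
}

# Resample a polyline at fixed arc-length step (mm), keeping both ends.
resample_polyline <- function(pts, step) {
  s <- arc_length(pts)
  total <- s[length(s)]
  if (total <= step) return(pts[c(1, nrow(pts)), , drop = FALSE])
  snew <- seq(0, total, by = step)
  if (total - snew[length(snew)] > 1e-6) snew <- c(snew, total)
  else snew[length(snew)] <- total
  out <- sapply(1:3, function(a) approx(s, pts[, a], xout = snew)$y)
  matrix(out, ncol = 3)
}

# Centered moving average smoothing with odd window, endpoints kept.
smooth_polyline <- function(pts, window = 5L) {
  n <- nrow(pts)
  if (window <= 1 || n < window) return(pts)
  h <- window %/% 2
  out <- pts
  for (i in seq_len(n)) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    out[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
  }
  out[1, ] <- pts[1, ]
  out[n, ] <- pts[n, ]
  out
}

# Interpolate a point at arc length s0 on a polyline with abscissa s.
point_at_abscissa <- function(pts, s, s0) {
  vapply(1:3, function(a) approx(s, pts[, a], xout = s0)$y, numeric(1))
}

# Rotation matrix about a unit axis by angle (radians), Rodrigues form.
rotation_about <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Any unit vector orthogonal to v.
orthogonal_unit <- function(v) {
  v <- v / sqrt(sum(v^2))
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- ref - sum(ref * v) * v
  w / sqrt(sum(w^2))
}

# Run-length encoding of a logical vector as (start, end, value) rows.
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts, end = ends, value = r$values)
}

# Evaluate an expression with a private, seeded RNG stream, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
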