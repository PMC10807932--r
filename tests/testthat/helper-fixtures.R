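# Shared phantom fixtures (generated once per test run) and brute-force
# oracles used to cross-check the compiled kernels.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

ao_small <- list(radius = 8, length = 24)

ph_straight <- function() cached("ph_straight", generate_phantom(
  phantom_spec(vessel_straight(60, 2), spacing = rep(0.4, 3), seed = 7,
               aorta = ao_small, margin_mm = 4)))

tree_straight <- function() cached("tree_straight",
  build_tree(ph_straight()$coronary, ph_straight()$aorta))

ph_bent50 <- function() cached("ph_bent50", generate_phantom(
  phantom_spec(make_bent_branch(c(50, 50, 50), 25), spacing = rep(0.4, 3),
               seed = 3, aorta = ao_small, margin_mm = 4)))

tree_bent50 <- function() cached("tree_bent50",
  build_tree(ph_bent50()$coronary, ph_bent50()$aorta))

ph_bent30 <- function() cached("ph_bent30", generate_phantom(
  phantom_spec(make_bent_branch(c(30, 30), 25), spacing = rep(0.4, 3),
               seed = 4, aorta = ao_small, margin_mm = 4)))

ph_y <- function() cached("ph_y", generate_phantom(
  phantom_spec(list(
    make_bent_branch(c(35), 25, radius_start = 1.8, direction = c(1, 0.35, 0)),
    make_bent_branch(c(35), 25, radius_start = 1.8, direction = c(1, -0.35, 0))),
    spacing = rep(0.5, 3), seed = 9, aorta = ao_small, margin_mm = 4)))

ph_lesion <- function() cached("ph_lesion", generate_phantom(
  phantom_spec(vessel_straight(80, 2.5),
               lesions = list(lesion_spec(20, c(2.5, 1.8, 1.8)),
                              lesion_spec(55, c(1.5, 1.5, 1.5))),
               spacing = rep(0.4, 3), seed = 5, aorta = ao_small,
               margin_mm = 4)))

tree_lesion <- function() cached("tree_lesion",
  build_tree(ph_lesion()$coronary, ph_lesion()$aorta))

# A branch object straight from an analytic centerline (no tracing noise).
analytic_branch <- function(spec, step = 0.1) {
  cl <- vessel_centerline(spec, step)
  structure(list(points = cl$points, s = cl$s, bends = cl$bends),
            class = "centerline_branch")
}

# A hand-built straight centerline tree along +x with known abscissa and g.
synthetic_tree <- function(length_mm = 60, step = 0.5) {
  s <- seq(0, length_mm, by = step)
  pts <- cbind(s, 0, 0)
  branch <- structure(list(points = pts, s = s, g = s / length_mm,
                           component = 1L), class = "centerline_branch")
  structure(list(ostia = data.frame(component = 1L, i = 1L, j = 1L, k = 1L,
                                    x = 0, y = 0, z = 0, dist_mm = 1),
                 branches = list(branch), params = list()),
            class = "centerline_tree")
}

# Brute-force Bellman-Ford shortest paths on the 26-connected voxel graph.
bellman_ford_dist <- function(mask, spacing, seed_lin) {
  d <- dim(mask)
  idx <- which(mask > 0)
  pos <- cbind((idx - 1) %% d[1],
               ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  n <- length(idx)
  lookup <- integer(prod(d))
  lookup[idx] <- seq_len(n)
  edges <- NULL
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    ni <- pos[, 1] + di
    nj <- pos[, 2] + dj
    nk <- pos[, 3] + dk
    ok <- ni >= 0 & ni < d[1] & nj >= 0 & nj < d[2] & nk >= 0 & nk < d[3]
    nl <- 1 + ni + d[1] * (nj + d[2] * nk)
    ok[ok] <- lookup[nl[ok]] > 0
    w <- sqrt(sum((c(di, dj, dk) * spacing)^2))
    edges <- rbind(edges, cbind(which(ok), lookup[nl[ok]], w))
  }
  dist <- rep(Inf, n)
  dist[lookup[seed_lin]] <- 0
  for (iter in seq_len(n)) {
    nd <- pmin(dist, unname(tapply(dist[edges[, 1]] + edges[, 3],
                                   edges[, 2], min)[as.character(seq_len(n))]))
    nd[is.na(nd)] <- dist[is.na(nd)]
    if (isTRUE(all.equal(nd, dist, tolerance = 0))) break
    dist <- nd
  }
  out <- rep(Inf, prod(d))
  out[idx] <- dist
  out
}

# Brute-force region-growing closure: repeat single-step dilation gated on
# intensity until nothing changes.
brute_grow <- function(image, seeds, allowed, thr) {
  d <- dim(image)
  cur <- seeds > 0
  repeat {
    nxt <- cur
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      src_i <- pmin(pmax(seq_len(d[1]) - di, 1), d[1])
      src_j <- pmin(pmax(seq_len(d[2]) - dj, 1), d[2])
      src_k <- pmin(pmax(seq_len(d[3]) - dk, 1), d[3])
      shifted <- cur[src_i, src_j, src_k, drop = FALSE]
      if (di != 0) shifted[if (di > 0) 1 else d[1], , ] <- FALSE
      if (dj != 0) shifted[, if (dj > 0) 1 else d[2], ] <- FALSE
      if (dk != 0) shifted[, , if (dk > 0) 1 else d[3]] <- FALSE
      nxt <- nxt | (shifted & allowed > 0 & image > thr)
    }
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

# Connected random blob mask grown from a center voxel, for graph oracles.
random_blob <- function(dim3, seed, fill = 0.6) {
  corochar:::with_seed(seed, {
    mask <- array(FALSE, dim3)
    start <- ceiling(dim3 / 2)
    mask[start[1], start[2], start[3]] <- TRUE
    target <- ceiling(prod(dim3) * fill)
    frontier <- matrix(start, 1)
    while (sum(mask) < target && nrow(frontier) > 0) {
      p <- frontier[sample.int(nrow(frontier), 1), ]
      step <- sample(c(-1, 1), 1)
      ax <- sample(3, 1)
      q <- p
      q[ax] <- min(max(q[ax] + step, 1), dim3[ax])
      if (!mask[q[1], q[2], q[3]]) {
        mask[q[1], q[2], q[3]] <- TRUE
        frontier <- rbind(frontier, q)
      } else if (runif(1) < 0.1) {
        frontier <- frontier[-1, , drop = FALSE]
      }
    }
    mask
  })
}
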