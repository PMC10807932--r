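#' Voxel-overlap segmentation metrics
#'
#' Dice similarity coefficient `DSC = 2 TP / (2 TP + FP + FN)`,
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)` between a
#' predicted and a reference label map. When both masks are empty all
#' three are defined as 1 (perfect agreement convention).
#'
#' @param pred,ref `label_map`s on the same grid (or plain binary
#'   arrays of equal shape).
#' @return list with `dsc`, `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
overlap_metrics <- function(pred, ref) {
  p <- as_binary_array(pred)
  r <- as_binary_array(ref)
  if (inherits(pred, "image_volume") && inherits(ref, "image_volume"))
    check_same_grid(pred, ref)
  else if (!identical(dim(p), dim(r))) stop("shape mismatch")
  tp <- sum(p & r)
  fp <- sum(p & !r)
  fn <- sum(!p & r)
  if (tp + fp + fn == 0)
    return(list(dsc = 1, precision = 1, recall = 1, tp = 0, fp = 0, fn = 0))
  list(dsc = 2 * tp / (2 * tp + fp + fn),
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0,
       tp = tp, fp = fp, fn = fn)
}

as_binary_array <- function(x) {
  if (inherits(x, "image_volume")) x$data > 0 else x > 0
}

#' Boundary surface points of a binary mask
#'
#' World coordinates of the centers of mask voxels that have at least
#' one background 6-neighbor (or touch the grid edge); used as the
#' surface sample for [msd()].
#'
#' @param mask a `label_map`.
#' @return n x 3 matrix of points (mm).
#' @export
surface_points <- function(mask) {
  m <- mask$data > 0
  d <- dim(m)
  interior <- array(TRUE, d)
  shift_and <- function(acc, axis, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    n <- d[axis]
    idx[[axis]] <- seq_len(n)
    src[[axis]] <- pmin(pmax(seq_len(n) + by, 1), n)
    edge <- seq_len(n) + by < 1 | seq_len(n) + by > n
    nb <- do.call(`[`, c(list(m), src, list(drop = FALSE)))
    nb <- array(nb, d)
    sl <- slice.index(array(0, d), axis)
    nb[sl %in% which(edge)] <- FALSE
    acc & nb
  }
  for (axis in 1:3) for (by in c(-1, 1))
    interior <- shift_and(interior, axis, by)
  boundary <- m & !interior
  if (!any(boundary)) stop("mask has no surface (empty mask)")
  voxel_world(mask, unlin_index(which(boundary), d))
}

#' Mean surface distance
#'
#' Symmetric mean of nearest-neighbor distances between the two surface
#' point sets:
#' `MSD = (sum_i d(p_i, S') + sum_j d(p'_j, S)) / (n_S + n_S')`.
#' Surfaces are sampled at boundary-voxel centers.
#'
#' @param pred,ref `label_map`s.
#' @return distance in mm.
#' @export
msd <- function(pred, ref) {
  check_same_grid(pred, ref)
  sp <- surface_points(pred)
  sr <- surface_points(ref)
  d_pr <- nearest_point_dist(sp, sr)
  d_rp <- nearest_point_dist(sr, sp)
  (sum(d_pr) + sum(d_rp)) / (length(d_pr) + length(d_rp))
}

nearest_point_dist <- function(q, ref, chunk = 2000L) {
  out <- numeric(nrow(q))
  r2 <- rowSums(ref^2)
  for (i0 in seq(1, nrow(q), by = chunk)) {
    i1 <- min(i0 + chunk - 1, nrow(q))
    qq <- q[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(qq^2), r2, "+") - 2 * qq %*% t(ref)
    out[i0:i1] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Odds ratio with Pearson chi-squared test
#'
#' For a 2x2 exposure-by-outcome table with counts `a`, `b`, `c`, `d`
#' (a = exposed with outcome, b = exposed without, c = unexposed with,
#' d = unexposed without), computes `OR = (a d) / (b c)` and the
#' two-sided Pearson chi-squared p-value without continuity correction.
#'
#' @param a,b,c,d non-negative integer cell counts; alternatively `a`
#'   may be a 2x2 matrix.
#' @return list with `or`, `chisq`, `p`, `defined` (FALSE when a zero
#'   cell makes the OR undefined).
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), 2, 2)
  }
  stopifnot(all(tab >= 0), all(tab == round(tab)))
  defined <- all(tab[c(2, 3)] > 0)
  or <- if (defined) (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
  else NA_real_
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(or = or, chisq = unname(ct$statistic), p = unname(ct$p.value),
       defined = defined)
}

#' Rank-based and parametric cohort tests
#'
#' Thin, consistently parameterized wrappers over the standard tests
#' used in the cohort analyses: two-sided Mann-Whitney U (exact
#' enumeration when both samples have at most 8 observations and no
#' ties, normal approximation with tie correction otherwise), one-way
#' ANOVA (equal-variance F test), Shapiro-Wilk normality, and Pearson
#' correlation.
#'
#' @param x,y numeric samples.
#' @return `mann_whitney`: list with `u`, `p`; `anova_oneway`: list with
#'   `f`, `p`; `shapiro_gate`: list with `w`, `p`, `normal`;
#'   `pearson_cor`: list with `r`, `p`.
#' @export
mann_whitney <- function(x, y) {
  exact <- length(x) <= 8 && length(y) <= 8 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                     correct = !exact))
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' @rdname mann_whitney
#' @param groups list of numeric vectors (>= 2 groups, sizes >= 3).
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("ANOVA requires at least two groups")
  if (any(lengths(groups) < 3)) stop("each group needs >= 3 observations")
  vals <- unlist(groups)
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  ft <- oneway.test(vals ~ fac, var.equal = TRUE)
  list(f = unname(ft$statistic), p = ft$p.value)
}

#' @rdname mann_whitney
#' @param alpha significance level for the normality flag.
#' @export
shapiro_gate <- function(x, alpha = 0.05) {
  if (stats::sd(x) < 1e-12) stop("constant input")
  st <- shapiro.test(x)
  list(w = unname(st$statistic), p = st$p.value, normal = st$p.value > alpha)
}

#' @rdname mann_whitney
#' @export
pearson_cor <- function(x, y) {
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) stop("constant input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean of paired differences a - b) and 95% limits of agreement
#' `bias +/- 1.96 SD` of the differences (sample SD).
#'
#' @param a,b equal-length paired score vectors (n >= 2).
#' @return list with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired lists must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}
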