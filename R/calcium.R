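#' Calcium-analysis parameters
#'
#' @param k_sigma multiplier on the aortic attenuation SD in the
#'   patient-specific threshold, default 2.5.
#' @param growth_percentile percentile of coronary attenuation gating
#'   region growing, default 98.
#' @param min_lesion_area artifact filter (mm^2 of maximal axial
#'   cross-section, or mm^3 in volume mode), default 1.
#' @param search_dilation_mm ball radius (mm) by which the lumen mask is
#'   dilated to form the calcium search volume (plaque may sit at the
#'   wall, outside the lumen annotation), default 2.
#' @param area_mode `"axial_area"` (default) interprets
#'   `min_lesion_area` as the maximal per-slice cross-sectional area in
#'   mm^2; `"volume"` interprets it as mm^3.
#' @export
cac_params <- function(k_sigma = 2.5, growth_percentile = 98,
                       min_lesion_area = 1.0, search_dilation_mm = 2,
                       area_mode = c("axial_area", "volume")) {
  stopifnot(k_sigma >= 0, growth_percentile > 50, growth_percentile < 100,
            min_lesion_area >= 0, search_dilation_mm >= 0)
  list(k_sigma = k_sigma, growth_percentile = growth_percentile,
       min_lesion_area = min_lesion_area,
       search_dilation_mm = search_dilation_mm,
       area_mode = match.arg(area_mode))
}

#' Patient-specific calcium attenuation threshold
#'
#' theta_HU = mean + k_sigma * SD of the image attenuation inside the
#' aorta mask. With the default k_sigma = 2.5 this is the
#' patient-specific threshold used to separate calcium from
#' contrast-enhanced blood.
#'
#' @param image an `image_volume` (HU).
#' @param aorta aorta `label_map` on the same grid.
#' @param k_sigma SD multiplier, default 2.5.
#' @return threshold in HU.
#' @export
patient_threshold <- function(image, aorta, k_sigma = 2.5) {
  check_same_grid(image, aorta)
  vals <- image$data[aorta$data > 0]
  if (length(vals) == 0) stop("empty aorta mask")
  mean(vals) + k_sigma * stats::sd(vals)
}

# Binary dilation by a Euclidean ball of radius r mm.
dilate_mask <- function(mask_data, spacing, r_mm) {
  if (r_mm <= 0) return(mask_data > 0)
  d2 <- .edt_sq_cpp(as.integer(!(mask_data > 0)), dim(mask_data), spacing)
  array(d2 <= r_mm^2 + 1e-9, dim(mask_data))
}

#' Detect calcium candidate lesions
#'
#' Thresholds the image at `theta_hu` within the coronary search volume
#' (the lumen mask dilated by `search_dilation_mm`) and partitions the
#' result into 26-connected components.
#'
#' @param image `image_volume`.
#' @param coronary coronary `label_map`.
#' @param theta_hu attenuation threshold from [patient_threshold()].
#' @param search_dilation_mm dilation radius (mm), default 2.
#' @return list with `labels` (integer array, 0 = background),
#'   `n` components, and `search` (logical search-volume array).
#' @export
detect_candidates <- function(image, coronary, theta_hu,
                              search_dilation_mm = 2) {
  check_same_grid(image, coronary)
  search <- dilate_mask(coronary$data, coronary$spacing, search_dilation_mm)
  cand <- search & image$data >= theta_hu
  labs <- array(.label_cc_cpp(as.integer(cand), dim(cand)), dim(cand))
  list(labels = labs, n = max(labs), search = search)
}

#' Refine lesions by region growing
#'
#' Starting from the candidate voxels, iteratively absorbs 26-neighbors
#' within the search volume whose attenuation exceeds the
#' `growth_percentile`-th percentile of the attenuation inside the
#' coronary artery volume (the lumen mask itself, not the dilated search
#' volume: diluting the percentile with perivascular voxels would drag
#' the gate into the blood-pool tail and let lesions leak into bright
#' blood), until a fixpoint. The output always contains the input;
#' components are relabeled afterwards since growth can merge adjacent
#' lesions.
#'
#' @param image `image_volume`.
#' @param candidates output of [detect_candidates()].
#' @param coronary coronary `label_map` (gate reference volume).
#' @param growth_percentile percentile in (50, 100), default 98.
#' @return list with `labels`, `n`, `threshold` (the growth gate, HU).
#' @export
grow_lesions <- function(image, candidates, coronary,
                         growth_percentile = 98) {
  search <- candidates$search
  gate <- unname(quantile(image$data[coronary$data > 0],
                          growth_percentile / 100))
  grown <- .grow_cpp(as.numeric(image$data),
                     as.integer(candidates$labels > 0),
                     as.integer(search), dim(search), gate)
  labs <- array(.label_cc_cpp(grown, dim(search)), dim(search))
  list(labels = labs, n = max(labs), threshold = gate, search = search)
}

#' Remove sub-millimetric artifact lesions
#'
#' Drops lesions whose maximal axial (z-slice) cross-sectional area is
#' below `min_lesion_area` mm^2 (default mode), or whose volume is below
#' `min_lesion_area` mm^3 in volume mode. Sub-millimetric detections on
#' CCTA are overwhelmingly noise or blooming artifacts.
#'
#' @param lesions list with `labels` array as from [grow_lesions()].
#' @param spacing voxel spacing (mm).
#' @param min_lesion_area threshold, default 1.
#' @param area_mode `"axial_area"` or `"volume"`.
#' @return same structure with filtered, relabeled `labels`.
#' @export
filter_artifacts <- function(lesions, spacing, min_lesion_area = 1.0,
                             area_mode = c("axial_area", "volume")) {
  area_mode <- match.arg(area_mode)
  labs <- lesions$labels
  if (max(labs) == 0) return(lesions)
  keep <- logical(max(labs))
  pix_area <- spacing[1] * spacing[2]
  vox_vol <- prod(spacing)
  for (l in seq_len(max(labs))) {
    idx <- which(labs == l)
    if (area_mode == "axial_area") {
      kz <- unlin_index(idx, dim(labs))[, 3]
      keep[l] <- max(tabulate(kz)) * pix_area >= min_lesion_area
    } else {
      keep[l] <- length(idx) * vox_vol >= min_lesion_area
    }
  }
  out <- array(0L, dim(labs))
  new <- cumsum(keep)
  sel <- labs > 0
  out[sel] <- ifelse(keep[labs[sel]], new[labs[sel]], 0L)
  lesions$labels <- out
  lesions$n <- sum(keep)
  lesions
}

#' Project lesions onto the centerline tree
#'
#' Maps every lesion voxel to its nearest centerline point (Euclidean,
#' mm). The lesion's distance from the ostium is the minimum abscissa
#' over mapped points, its extent the difference between maximum and
#' minimum abscissa, and its zone the zone of the mapped point with
#' minimum abscissa.
#'
#' @param lesions list with `labels` as from [grow_lesions()] /
#'   [filter_artifacts()].
#' @param tree a `centerline_tree`.
#' @param image any volume on the lesion grid (for geometry).
#' @return data.frame, one row per lesion: `lesion`, `n_voxels`,
#'   `volume_mm3`, `mean_hu`, `min_abscissa_mm`, `max_abscissa_mm`,
#'   `extent_mm`, `zone`, `branch`.
#' @export
project_to_centerline <- function(lesions, tree, image) {
  labs <- lesions$labels
  if (length(tree$branches) == 0) stop("empty centerline tree")
  cl_pts <- do.call(rbind, lapply(tree$branches, function(b) b$points))
  cl_s <- unlist(lapply(tree$branches, function(b) b$s))
  cl_g <- unlist(lapply(tree$branches, function(b) b$g))
  cl_branch <- rep(seq_along(tree$branches),
                   vapply(tree$branches, function(b) nrow(b$points),
                          integer(1)))
  vox_vol <- voxel_volume(image)
  out <- NULL
  for (l in seq_len(max(0, max(labs)))) {
    idx <- which(labs == l)
    if (length(idx) == 0) next
    w <- voxel_world(image, unlin_index(idx, dim(labs)))
    near <- nearest_point_index(w, cl_pts)
    sv <- cl_s[near]
    imin <- which.min(sv)
    out <- rbind(out, data.frame(
      lesion = l, n_voxels = length(idx),
      volume_mm3 = length(idx) * vox_vol,
      mean_hu = mean(image$data[idx]),
      min_abscissa_mm = sv[imin],
      max_abscissa_mm = max(sv),
      extent_mm = max(sv) - sv[imin],
      zone = as.character(assign_zone(min(max(cl_g[near[imin]], 0), 1))),
      branch = cl_branch[near[imin]]))
  }
  if (is.null(out))
    out <- data.frame(lesion = integer(0), n_voxels = integer(0),
                      volume_mm3 = numeric(0), mean_hu = numeric(0),
                      min_abscissa_mm = numeric(0),
                      max_abscissa_mm = numeric(0), extent_mm = numeric(0),
                      zone = character(0), branch = integer(0))
  out
}

# Row index of the nearest point in `ref` for each row of `q`, chunked.
nearest_point_index <- function(q, ref, chunk = 2000L) {
  out <- integer(nrow(q))
  r2 <- rowSums(ref^2)
  for (i0 in seq(1, nrow(q), by = chunk)) {
    i1 <- min(i0 + chunk - 1, nrow(q))
    qq <- q[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(qq^2), r2, "+") - 2 * qq %*% t(ref)
    out[i0:i1] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Calcium report: volume score and percentage of plaque volume
#'
#' Aggregates characterized lesions into the volume score (VS, total
#' lesion volume in mm^3) per zone and overall, the percentage of plaque
#' volume PPV = 100 * VS_total / coronary vessel volume, and the
#' shortest/longest lesion distance from the ostium.
#'
#' @param lesion_table data.frame from [project_to_centerline()].
#' @param vessel_volume_mm3 coronary lumen volume (mm^3).
#' @param theta_hu,growth_threshold optional provenance values stored in
#'   the report.
#' @return object of class `calcium_report`.
#' @export
calcium_score <- function(lesion_table, vessel_volume_mm3,
                          theta_hu = NA_real_, growth_threshold = NA_real_) {
  if (vessel_volume_mm3 <= 0) stop("vessel volume must be positive")
  zones <- c("proximal", "medial", "distal")
  vs_zone <- sapply(zones, function(z)
    sum(lesion_table$volume_mm3[lesion_table$zone == z]))
  vs_total <- sum(lesion_table$volume_mm3)
  structure(list(
    lesions = lesion_table,
    vs_zone = vs_zone,
    vs_total = vs_total,
    ppv = 100 * vs_total / vessel_volume_mm3,
    shortest_distance_mm = if (nrow(lesion_table))
      min(lesion_table$min_abscissa_mm) else NA_real_,
    longest_distance_mm = if (nrow(lesion_table))
      max(lesion_table$min_abscissa_mm) else NA_real_,
    vessel_volume_mm3 = vessel_volume_mm3,
    theta_hu = theta_hu, growth_threshold = growth_threshold),
    class = "calcium_report")
}

#' @export
print.calcium_report <- function(x, ...) {
  cat(sprintf("<calcium_report> %d lesion(s), VS %.1f mm3, PPV %.2f%%\n",
              nrow(x$lesions), x$vs_total, x$ppv))
  cat(sprintf("  per zone: proximal %.1f, medial %.1f, distal %.1f mm3\n",
              x$vs_zone["proximal"], x$vs_zone["medial"],
              x$vs_zone["distal"]))
  invisible(x)
}

#' Full calcium analysis
#'
#' Runs the calcium stages in order: patient-specific threshold,
#' candidate detection in the dilated coronary volume, region growing at
#' the 98th-percentile gate, artifact filtering, centerline projection,
#' and scoring.
#'
#' @param image `image_volume`.
#' @param coronary,aorta `label_map`s.
#' @param tree `centerline_tree` from [build_tree()].
#' @param params a [cac_params()] list.
#' @return a `calcium_report`.
#' @export
analyze_calcium <- function(image, coronary, aorta, tree,
                            params = cac_params()) {
  theta <- patient_threshold(image, aorta, params$k_sigma)
  cand <- detect_candidates(image, coronary, theta,
                            params$search_dilation_mm)
  grown <- grow_lesions(image, cand, coronary, params$growth_percentile)
  filt <- filter_artifacts(grown, image$spacing, params$min_lesion_area,
                           params$area_mode)
  tab <- project_to_centerline(filt, tree, image)
  calcium_score(tab, sum(coronary$data > 0) * voxel_volume(coronary),
                theta_hu = theta, growth_threshold = grown$threshold)
}
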