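#' End-to-end patient characterization
#'
#' Runs the four analysis stages in order on aligned inputs: (i)
#' centerline-tree extraction, (ii) tortuosity analysis, (iii) calcific
#' lesion detection, (iv) calcium quantification. Per-stage wall times
#' and the resolved configuration (with a content hash) are embedded in
#' the report so a rerun with the same config is identical.
#'
#' @param image `image_volume` (HU).
#' @param coronary,aorta `label_map`s on the same grid.
#' @param config nested list of overrides with namespaces `centerline`
#'   (`delta_step`, `resample_mm`, `smooth_window`, `min_branch_mm`),
#'   `tortuosity` (`window_mm`), and `calcium` ([cac_params()] fields).
#' @return object of class `patient_report`: `tree`, `tortuosity`
#'   (a `tortuosity_summary`), `calcium` (a `calcium_report`), `zones`
#'   (per-zone cross table), `provenance`.
#' @export
characterize <- function(image, coronary, aorta, config = list()) {
  check_same_grid(image, coronary)
  check_same_grid(image, aorta)
  cfg <- list(
    centerline = modify_defaults(list(delta_step = 0.05, resample_mm = 0.25,
                                      smooth_window = 3L, min_branch_mm = 20,
                                      eps = 0.1, refine_iters = 3L),
                                 config$centerline %||% list()),
    tortuosity = modify_defaults(list(window_mm = 10),
                                 config$tortuosity %||% list()),
    calcium = do.call(cac_params, config$calcium %||% list()))
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  tree <- stage("centerline", build_tree(coronary, aorta, cfg$centerline))
  tort <- stage("tortuosity",
                summarize_tortuosity(tree, cfg$tortuosity$window_mm,
                                     cfg$centerline$min_branch_mm))
  cac <- stage("calcium",
               analyze_calcium(image, coronary, aorta, tree, cfg$calcium))
  zones <- zone_cross_table(tort, cac)
  structure(list(tree = tree, tortuosity = tort, calcium = cac,
                 zones = zones,
                 provenance = list(config = cfg,
                                   config_hash = config_hash(cfg),
                                   timings = timings,
                                   schema_version = "1.0")),
            class = "patient_report")
}

zone_cross_table <- function(tort, cac) {
  zones <- c("proximal", "medial", "distal")
  ext <- sapply(zones, function(z) {
    rows <- cac$lesions$zone == z
    if (any(rows)) mean(cac$lesions$extent_mm[rows]) else NA_real_
  })
  data.frame(zone = zones,
             vs_mm3 = as.numeric(cac$vs_zone[zones]),
             lesion_extent_mm = as.numeric(ext),
             tract_tortuosity = as.numeric(tort$tract[zones]),
             lt_95 = as.numeric(tort$lt_95_zone[zones]),
             ta_95 = as.numeric(tort$ta_95_zone[zones]))
}

# Deterministic content hash of the resolved config (FNV-1a over the
# canonical JSON serialization).
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(h %% 2^31, b) + (h %/% 2^31) * 2^31
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' @export
print.patient_report <- function(x, ...) {
  cat("<patient_report>\n")
  print(x$tortuosity)
  print(x$calcium)
  invisible(x)
}

#' Write a patient report
#'
#' Writes `report.json` (full machine-readable report), `lesions.csv`
#' (one row per lesion) and `zones.csv` (per-zone cross table) into a
#' directory.
#'
#' @param report a `patient_report`.
#' @param dir output directory (created if missing).
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  obj <- list(
    tortuosity = list(tract = as.list(report$tortuosity$tract),
                      lt_95 = report$tortuosity$lt_95,
                      ta_95 = report$tortuosity$ta_95,
                      ts = report$tortuosity$ts,
                      severity = report$tortuosity$severity,
                      bends = report$tortuosity$bends),
    calcium = list(vs_total = report$calcium$vs_total,
                   vs_zone = as.list(report$calcium$vs_zone),
                   ppv = report$calcium$ppv,
                   theta_hu = report$calcium$theta_hu,
                   shortest_distance_mm = report$calcium$shortest_distance_mm,
                   longest_distance_mm = report$calcium$longest_distance_mm,
                   lesions = report$calcium$lesions),
    zones = report$zones,
    provenance = report$provenance)
  jsonlite::write_json(obj, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write.csv(report$calcium$lesions, file.path(dir, "lesions.csv"),
            row.names = FALSE)
  write.csv(report$zones, file.path(dir, "zones.csv"), row.names = FALSE)
  invisible(dir)
}

#' Cohort-level statistical analysis
#'
#' Reproduces the shape of the cohort comparisons: Mann-Whitney U tests
#' of continuous features split by each binary condition, an odds-ratio
#' table for tortuosity incidence (TS >= 1) by condition, one-way ANOVA
#' of zone-resolved features across proximal/medial/distal, and a
#' TS-threshold sweep (thresholds 1-4) comparing calcium features
#' between less- and more-tortuous patients.
#'
#' @param features data.frame, one row per patient, with a `ts` column
#'   and continuous feature columns; zone-resolved features use the
#'   suffixes `_proximal`, `_medial`, `_distal`.
#' @param covariates data.frame with one logical/0-1 column per
#'   condition, rows aligned with `features` (or joined on a shared
#'   `patient` column).
#' @param continuous names of continuous feature columns to test;
#'   defaults to all numeric feature columns except `ts`.
#' @param sweep_features features compared in the TS-threshold sweep.
#' @return list of data.frames: `utests`, `or_table`, `zone_anova`,
#'   `ts_sweep`.
#' @export
cohort_analysis <- function(features, covariates,
                            continuous = NULL,
                            sweep_features = intersect(
                              c("vs_total", "lesion_extent_mm"),
                              names(features))) {
  if ("patient" %in% names(features) && "patient" %in% names(covariates)) {
    covariates <- covariates[match(features$patient, covariates$patient), ,
                             drop = FALSE]
  }
  if (nrow(covariates) != nrow(features))
    stop("covariates do not align with features")
  conds <- setdiff(names(covariates), "patient")
  if (!"ts" %in% names(features)) stop("missing covariate column: ts")
  if (is.null(continuous))
    continuous <- setdiff(names(features)[vapply(features, is.numeric,
                                                 logical(1))], "ts")

  utests <- do.call(rbind, lapply(conds, function(cn) {
    grp <- as.logical(covariates[[cn]])
    if (length(unique(grp)) < 2)
      return(data.frame(condition = cn, feature = continuous, n_yes = sum(grp),
                        n_no = sum(!grp), p = NA_real_))
    do.call(rbind, lapply(continuous, function(f) {
      mw <- mann_whitney(features[[f]][grp], features[[f]][!grp])
      data.frame(condition = cn, feature = f, n_yes = sum(grp),
                 n_no = sum(!grp), p = mw$p)
    }))
  }))

  or_table <- do.call(rbind, lapply(conds, function(cn) {
    grp <- as.logical(covariates[[cn]])
    cort <- features$ts >= 1
    if (length(unique(grp)) < 2)
      return(data.frame(condition = cn, or = NA_real_, p = NA_real_,
                        defined = FALSE))
    orr <- odds_ratio(sum(grp & cort), sum(grp & !cort),
                      sum(!grp & cort), sum(!grp & !cort))
    data.frame(condition = cn, or = orr$or, p = orr$p,
               defined = orr$defined)
  }))

  zones <- c("proximal", "medial", "distal")
  zone_bases <- unique(sub("_(proximal|medial|distal)$", "",
                           grep("_(proximal|medial|distal)$",
                                names(features), value = TRUE)))
  zone_anova <- do.call(rbind, lapply(zone_bases, function(b) {
    cols <- paste(b, zones, sep = "_")
    if (!all(cols %in% names(features))) return(NULL)
    groups <- lapply(cols, function(cl)
      features[[cl]][is.finite(features[[cl]])])
    if (any(lengths(groups) < 3)) return(NULL)
    an <- anova_oneway(groups)
    data.frame(feature = b, f = an$f, p = an$p)
  }))

  ts_sweep <- do.call(rbind, lapply(1:4, function(thr) {
    lo <- features$ts < thr
    if (sum(lo) < 3 || sum(!lo) < 3)
      return(data.frame(threshold = thr, feature = sweep_features,
                        n_below = sum(lo), n_above = sum(!lo),
                        median_below = NA_real_, median_above = NA_real_,
                        p = NA_real_))
    do.call(rbind, lapply(sweep_features, function(f) {
      mw <- mann_whitney(features[[f]][!lo], features[[f]][lo])
      data.frame(threshold = thr, feature = f, n_below = sum(lo),
                 n_above = sum(!lo),
                 median_below = stats::median(features[[f]][lo]),
                 median_above = stats::median(features[[f]][!lo]),
                 p = mw$p)
    }))
  }))

  list(utests = utests, or_table = or_table, zone_anova = zone_anova,
       ts_sweep = ts_sweep)
}

#' Flatten a patient report to one feature row
#'
#' Convenience extractor used to assemble cohort feature tables from
#' per-patient reports.
#'
#' @param report a `patient_report`.
#' @return one-row data.frame.
#' @export
report_features <- function(report) {
  z <- report$zones
  data.frame(ts = report$tortuosity$ts,
             vs_total = report$calcium$vs_total,
             ppv = report$calcium$ppv,
             lesion_extent_mm = if (nrow(report$calcium$lesions))
               mean(report$calcium$lesions$extent_mm) else 0,
             lt_95 = report$tortuosity$lt_95,
             ta_95 = report$tortuosity$ta_95,
             tract_proximal = z$tract_tortuosity[z$zone == "proximal"],
             tract_medial = z$tract_tortuosity[z$zone == "medial"],
             tract_distal = z$tract_tortuosity[z$zone == "distal"],
             vs_proximal = z$vs_mm3[z$zone == "proximal"],
             vs_medial = z$vs_mm3[z$zone == "medial"],
             vs_distal = z$vs_mm3[z$zone == "distal"])
}
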