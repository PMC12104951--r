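# Readers and writers for the pipeline's on-disk formats: multi-page TIFF
# stacks with JSON sidecars, cohort CSV tables, measurement CSVs, config and
# report JSON. External pixel coordinates are 0-based floats with depth
# increasing downward; internal R indices are 1-based.

# Intensity scale used when quantizing float images to 16-bit TIFF.
STACK_WRITE_SCALE <- 2.0

#' Write a B-scan stack as multi-page TIFF plus JSON sidecar
#'
#' Frames are scaled into \[0, 1\] and stored as 16-bit grayscale pages of
#' `<prefix>.tiff`; acquisition metadata and the ground-truth interface
#' depths (per-column 0-based pixel coordinates) go to `<prefix>.json`.
#'
#' @param stack A `bscan_stack`.
#' @param prefix Path prefix (without extension).
#' @return Invisibly, the two file paths.
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "bscan_stack"))
  pages <- lapply(stack$frames, function(f) clamp(f / STACK_WRITE_SCALE, 0, 1))
  tif <- paste0(prefix, ".tiff"); side <- paste0(prefix, ".json")
  tiff::writeTIFF(pages, tif, bits.per.sample = 16L)
  gt_px <- lapply(stack$ground_truth,
                  function(d) d / stack$axial_px_um_optical)  # 0-based px
  jsonlite::write_json(list(
    axial_px_um_optical = stack$axial_px_um_optical,
    lateral_px_um = stack$lateral_px_um,
    group_index = stack$group_index,
    n_frames = length(stack$frames),
    seed = stack$seed,
    intensity_scale = STACK_WRITE_SCALE,
    jitter_px = stack$jitter_px,
    ground_truth_paths = gt_px
  ), side, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff = tif, sidecar = side))
}

#' Read a B-scan stack written by [write_stack()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `bscan_stack` (without the generating `spec`; intensities carry
#'   16-bit quantization).
#' @export
read_stack <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(prefix, ".tiff"), all = TRUE)
  frames <- lapply(pages, function(p) p * side$intensity_scale)
  structure(list(
    frames = frames,
    axial_px_um_optical = side$axial_px_um_optical,
    lateral_px_um = side$lateral_px_um,
    group_index = side$group_index,
    ground_truth = lapply(side$ground_truth_paths,
                          function(p) p * side$axial_px_um_optical),
    jitter_px = side$jitter_px,
    spec = NULL,
    seed = side$seed
  ), class = "bscan_stack")
}

#' Write / read the cohort subject table as CSV
#'
#' Columns: `subject_id, group, age, sex, cct_um, kmax_d, et_true_um,
#' bt_true_um, capture_paths` (semicolon-joined stack prefixes, empty when
#' captures are kept in memory).
#'
#' @param cohort A `cohort`.
#' @param path CSV path.
#' @param capture_paths Optional named list (by subject) of written stack
#'   prefixes.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path, capture_paths = NULL) {
  df <- cohort$subjects
  out <- data.frame(subject_id = df$subject_id, group = df$group,
                    age = df$age_y, sex = df$sex, cct_um = df$cct_um,
                    kmax_d = df$kmax_d, et_true_um = df$et_true_um,
                    bt_true_um = df$bt_true_um,
                    capture_paths = vapply(df$subject_id, function(s) {
                      if (is.null(capture_paths) || is.null(capture_paths[[s]])) ""
                      else paste(capture_paths[[s]], collapse = ";")
                    }, character(1)),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "age"] <- "age_y"
  if ("capture_paths" %in% names(df))
    df$capture_paths[is.na(df$capture_paths)] <- ""
  df
}

#' Write per-capture measurements as CSV
#'
#' Columns: `capture_id, bt_um, et_um, local_sd_um, score, weight, excluded`.
#'
#' @param measurements Data frame (e.g. `report$measurements`) or list of
#'   `thickness_measurement`.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_measurements_csv <- function(measurements, path) {
  if (!is.data.frame(measurements)) {
    measurements <- do.call(rbind, lapply(measurements, function(m)
      data.frame(capture_id = m$capture_id, bt_um = m$bt_um, et_um = m$et_um,
                 local_sd_um = m$local_sd_um, score = m$quality_score,
                 weight = m$weight, excluded = isTRUE(m$excluded),
                 stringsAsFactors = FALSE)))
  }
  utils::write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}

# Serializable view of a pipeline config (drops function-free structures into
# plain lists so the JSON round-trips losslessly).
config_to_list <- function(config) {
  list(seed = config$seed,
       group_params = lapply(config$group_params, unclass),
       n_captures = config$n_captures,
       aggregation = config$aggregation,
       adjust = config$adjust,
       spec_overrides = config$spec_overrides,
       policy = unclass(config$policy),
       screen_policy = config$screen_policy,
       window_um = config$window_um)
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path JSON path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   reconstructed `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "group_params", "n_captures", "aggregation", "adjust",
             "spec_overrides", "policy", "screen_policy", "window_um")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  gps <- lapply(raw$group_params, function(g) do.call(group_params, as.list(g)))
  pol <- do.call(segmentation_policy, as.list(raw$policy))
  pipeline_config(seed = raw$seed, group_params = gps,
                  n_captures = raw$n_captures, aggregation = raw$aggregation,
                  adjust = raw$adjust,
                  spec_overrides = as.list(raw$spec_overrides),
                  policy = pol, screen_policy = as.list(raw$screen_policy),
                  window_um = raw$window_um)
}

#' Write a pipeline report as JSON
#'
#' Serializes the analyzable content of a `pipeline_report` (eye table,
#' measurements, summaries, test results) together with the config hash and
#' seed that produced it. Model objects are omitted.
#'
#' @param report A `pipeline_report`.
#' @param path JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  ratio <- report$ratio
  jsonlite::write_json(list(
    config_hash = report$config_hash,
    seed = report$seed,
    eyes = report$eyes,
    measurements = report$measurements,
    summary = report$summary,
    anova_bt = report$anova_bt[c("anova_f", "anova_p", "tukey", "degenerate")],
    regression = report$regression[c("slope", "intercept", "r_squared",
                                     "p_value", "n", "singular")],
    ratio = list(group_ratio = ratio$group_ratio,
                 factor_p = as.list(ratio$factor_p),
                 factor_p_adj = as.list(ratio$factor_p_adj),
                 n_rejected = ratio$n_rejected)
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
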