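# Geometric thickness extraction: optical-to-geometric conversion, the
# 450 um quasi-point central thickness of Bowman's layer and the epithelium,
# and quality-weighted aggregation of repeated captures per eye.

#' Convert optical path length to geometric tissue distance
#'
#' OCT measures optical path; dividing by the group refractive index gives
#' the geometric distance in tissue.
#'
#' @param d_optical_um Optical path length(s), um; must be non-negative.
#' @param n_G Group refractive index (> 1), default 1.387.
#' @return Geometric distance(s), um.
#' @export
optical_to_geometric <- function(d_optical_um, n_G = 1.387) {
  if (any(d_optical_um < 0))
    stop("negative optical distance: boundary ordering violated upstream")
  if (n_G < 1) stop("group index must be at least 1")
  d_optical_um / n_G
}

# Score-to-weight map: scores 3/4/5 carry weights 1/2/3; below 3 is excluded.
score_weight <- function(score) {
  w <- score - 2L
  w[score < 3L] <- 0L
  as.integer(w)
}

#' Quasi-point central thickness from a segmentation result
#'
#' Computes the per-column axial separation of the labelled boundaries,
#' converts it to geometric um, and averages over a lateral window (default
#' 450 um) centred in the field: a de facto single-point central measurement.
#' Bowman thickness (BT) uses epithelium-Bowman to Bowman-stroma; epithelial
#' thickness (ET) uses tear film to epithelium-Bowman. The within-window SD
#' of per-column BT is reported as the local variability.
#'
#' @param seg A `segmentation_result`.
#' @param window_um Lateral window length, um (default 450).
#' @param capture_id Optional identifier carried into the output.
#' @return Object of class `thickness_measurement`: `bt_um`, `et_um`,
#'   `local_sd_um`, `window_center_x`, `window_len_um`, `quality_score`,
#'   `weight` (0 when excluded), `excluded`, `failed`, `capture_id`.
#' @export
quasi_point_thickness <- function(seg, window_um = 450, capture_id = NA_character_) {
  stopifnot(inherits(seg, "segmentation_result"))
  score <- seg$quality_score
  base <- list(window_len_um = window_um, quality_score = score,
               weight = score_weight(score), excluded = score < 3L,
               capture_id = capture_id)
  if (seg$failed || is.null(seg$paths$epi_bowman) ||
      is.null(seg$paths$bowman_stroma)) {
    base$excluded <- TRUE
    base$weight <- 0L
    return(structure(c(list(bt_um = NA_real_, et_um = NA_real_,
                            local_sd_um = NA_real_, window_center_x = NA_real_,
                            failed = TRUE),
                       base),
                     class = "thickness_measurement"))
  }
  nx <- length(seg$paths$epi_bowman$z)
  wcols <- floor(window_um / seg$lateral_px_um)
  if (wcols > nx) stop("quasi-point window exceeds the lateral field")
  start <- floor((nx - wcols) / 2) + 1L
  win <- start:(start + wcols - 1L)
  to_geom <- seg$axial_px_um_optical / seg$group_index
  bt_cols <- (seg$paths$bowman_stroma$z - seg$paths$epi_bowman$z)[win] * to_geom
  et_cols <- if (!is.null(seg$paths$tear_film))
    (seg$paths$epi_bowman$z - seg$paths$tear_film$z)[win] * to_geom
  else rep(NA_real_, length(win))
  structure(c(list(bt_um = mean(bt_cols), et_um = mean(et_cols),
                   local_sd_um = stats::sd(bt_cols),
                   window_center_x = mean(win), failed = FALSE),
              base),
            class = "thickness_measurement")
}

#' Aggregate repeated captures of one eye
#'
#' Captures scoring below 3 are excluded. In `"weighted"` mode (default) the
#' remaining captures are combined as a weighted mean with weights 1/2/3 for
#' scores 3/4/5, giving prominence to better-quality images. In `"best"`
#' mode the single highest-scoring capture is used (ties broken by the
#' smallest local SD). An eye with no usable capture is a failed eye.
#'
#' @param measurements List of `thickness_measurement` objects.
#' @param mode `"weighted"` or `"best"`.
#' @return Object of class `eye_summary`: `bt_um`, `et_um`,
#'   `n_captures_used`, `mode`, `failed`.
#' @export
aggregate_eye <- function(measurements, mode = c("weighted", "best")) {
  mode <- match.arg(mode)
  if (!length(measurements)) stop("no measurements to aggregate")
  usable <- Filter(function(m) !isTRUE(m$failed) && !isTRUE(m$excluded) &&
                     is.finite(m$bt_um), measurements)
  if (!length(usable))
    return(structure(list(bt_um = NA_real_, et_um = NA_real_,
                          n_captures_used = 0L, mode = mode, failed = TRUE),
                     class = "eye_summary"))
  bt <- vapply(usable, `[[`, numeric(1), "bt_um")
  et <- vapply(usable, `[[`, numeric(1), "et_um")
  if (mode == "weighted") {
    w <- vapply(usable, `[[`, integer(1), "weight")
    out_bt <- sum(w * bt) / sum(w)
    out_et <- if (all(is.finite(et))) sum(w * et) / sum(w) else NA_real_
    n_used <- length(usable)
  } else {
    sc <- vapply(usable, `[[`, integer(1), "quality_score")
    lsd <- vapply(usable, `[[`, numeric(1), "local_sd_um")
    best <- which(sc == max(sc))
    if (length(best) > 1) best <- best[which.min(lsd[best])]
    out_bt <- bt[best]; out_et <- et[best]; n_used <- 1L
  }
  structure(list(bt_um = out_bt, et_um = out_et,
                 n_captures_used = as.integer(n_used), mode = mode,
                 failed = FALSE),
            class = "eye_summary")
}
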