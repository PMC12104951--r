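# Frame screening, axial-only alignment, and averaging of a B-scan capture.
#
# Frames within a capture differ by a rigid axial shift (subject/device
# motion) and independent speckle. Screening removes frames without usable
# signal; alignment estimates one axial shift per frame from the laterally
# averaged depth profile (lateral shifts are never estimated or applied);
# averaging takes the arithmetic mean of the shifted frames over the rows
# where all frames overlap.

# Per-frame signal statistic: 99th-percentile intensity minus the frame
# median, i.e. the brightness of the reflective interfaces above the bulk
# background.
frame_signal_stat <- function(frame) {
  stats::quantile(frame, 0.99, names = FALSE) - stats::median(frame)
}

#' Screen out low-signal frames
#'
#' A frame is kept when its signal statistic (99th percentile minus median)
#' both clears the frame's own background spread (`mad_k` times the median
#' absolute deviation) and is not a small fraction of the capture's typical
#' signal (`rel_frac` times the median statistic across frames). The first
#' test rejects flat or empty frames; the second rejects strongly attenuated
#' ones that are internally consistent but carry little light.
#'
#' @param stack A `bscan_stack`, or a plain list of frame matrices.
#' @param policy List with `mad_k` (default 3) and `rel_frac` (default 0.25).
#' @return Integer indices of kept frames, in original order. Zero-length
#'   (with a warning) when every frame fails: a capture-level failure.
#' @export
screen_frames <- function(stack, policy = list(mad_k = 3, rel_frac = 0.25)) {
  frames <- if (inherits(stack, "bscan_stack")) stack$frames else stack
  if (!length(frames)) stop("empty stack")
  s <- vapply(frames, frame_signal_stat, numeric(1))
  madv <- vapply(frames, function(f) stats::mad(f), numeric(1))
  keep <- (s > policy$mad_k * madv) & (s >= policy$rel_frac * stats::median(s))
  idx <- which(keep)
  if (!length(idx))
    warning("all frames screened out: capture failure")
  idx
}

# Cross-correlation (mean product over the overlap) of a profile against a
# reference at one integer lag; positive lag means the profile's features sit
# deeper than the reference's.
profile_xcorr <- function(ref, p, lag) {
  n <- length(ref)
  if (lag >= 0) {
    i <- seq_len(n - lag)
    mean(ref[i] * p[i + lag])
  } else {
    i <- seq_len(n + lag)
    mean(ref[i - lag] * p[i])
  }
}

#' Estimate per-frame axial shifts by 1D cross-correlation
#'
#' Each frame is collapsed to its laterally averaged axial profile. The first
#' frame seeds a running-average reference; every subsequent frame's shift is
#' the lag maximizing the cross-correlation of its (mean-subtracted) profile
#' against the reference, refined to subpixel precision by a parabolic fit
#' around the correlation peak, after which the integer-aligned profile is
#' folded into the reference. Only axial shifts are ever estimated; lateral
#' structure enters only through the lateral averaging.
#'
#' @param frames List of frame matrices (rows = depth).
#' @param max_shift_px Search half-range in pixels (default 20).
#' @return Numeric vector of subpixel shifts, one per frame; the first
#'   (reference) frame's shift is 0 by construction.
#' @export
axial_align <- function(frames, max_shift_px = 20L) {
  n <- length(frames)
  if (!n) stop("no frames to align")
  profs <- lapply(frames, rowMeans)
  nz <- length(profs[[1]])
  shifts <- numeric(n)
  center <- function(p) p - mean(p)
  ref <- center(profs[[1]])
  n_in_ref <- 1L
  for (f in seq_len(n)[-1]) {
    p <- center(profs[[f]])
    if (stats::sd(p) == 0 || stats::sd(ref) == 0) {
      warning("flat axial profile; assuming zero shift for frame ", f)
      shifts[f] <- 0
      next
    }
    lags <- -max_shift_px:max_shift_px
    cc <- vapply(lags, function(l) profile_xcorr(ref, p, l), numeric(1))
    k <- which.max(cc)
    s <- lags[k]
    if (k > 1 && k < length(lags)) {
      denom <- cc[k - 1] - 2 * cc[k] + cc[k + 1]
      if (denom < 0) s <- s + clamp(0.5 * (cc[k - 1] - cc[k + 1]) / denom, -0.5, 0.5)
    }
    shifts[f] <- s
    # fold the integer-aligned profile into the running reference
    si <- as.integer(round(shifts[f]))
    aligned <- shift_vector(p, -si)
    ok <- !is.na(aligned)
    upd <- ref
    upd[ok] <- (n_in_ref * ref[ok] + aligned[ok]) / (n_in_ref + 1)
    ref <- upd
    n_in_ref <- n_in_ref + 1L
  }
  shifts
}

# Shift a vector by s (positive = toward larger indices), NA outside.
shift_vector <- function(v, s) {
  n <- length(v)
  out <- rep(NA_real_, n)
  if (s >= 0) out[(1 + s):n] <- v[seq_len(n - s)]
  else out[seq_len(n + s)] <- v[(1 - s):n]
  out
}

# Rigid subpixel axial shift of a frame via linear interpolation between the
# two neighbouring integer shifts; rows without support are NA.
shift_frame <- function(m, s) {
  s0 <- floor(s)
  a <- s - s0
  lo <- apply_int_shift(m, as.integer(s0))
  if (a == 0) return(lo)
  hi <- apply_int_shift(m, as.integer(s0) + 1L)
  (1 - a) * lo + a * hi
}

apply_int_shift <- function(m, s) {
  nz <- nrow(m)
  out <- matrix(NA_real_, nz, ncol(m))
  if (s >= 0) {
    if (s < nz) out[(1 + s):nz, ] <- m[seq_len(nz - s), ]
  } else {
    if (-s < nz) out[seq_len(nz + s), ] <- m[(1 - s):nz, ]
  }
  out
}

#' Average aligned frames into one B-scan
#'
#' Applies the negated estimated shift to each frame (subpixel, by linear
#' interpolation), crops the depth rows where not all frames have support,
#' and returns the arithmetic mean. For independent speckle the residual
#' noise variance falls roughly as 1/n.
#'
#' @param frames List of frame matrices.
#' @param shifts Per-frame axial shifts as returned by [axial_align()].
#' @param axial_px_um_optical,lateral_px_um Pixel spacings carried through to
#'   downstream stages.
#' @param n_frames_screened_out Bookkeeping from [screen_frames()].
#' @param provenance Optional free-form metadata (e.g. the source spec).
#' @return Object of class `averaged_bscan`: `image`, `n_frames_used`,
#'   `n_frames_screened_out`, `shifts_px`, `crop_top_px` (rows removed above),
#'   pixel spacings and provenance.
#' @export
average_frames <- function(frames, shifts,
                           axial_px_um_optical = NA_real_,
                           lateral_px_um = NA_real_,
                           n_frames_screened_out = 0L,
                           provenance = NULL) {
  n <- length(frames)
  if (!n) stop("no frames to average")
  stopifnot(length(shifts) == n)
  shifted <- Map(function(f, s) shift_frame(f, -s), frames, shifts)
  ok_rows <- Reduce(`&`, lapply(shifted, function(m) !is.na(m[, 1])))
  if (!any(ok_rows)) stop("no overlapping rows after shifting")
  rows <- which(ok_rows)
  img <- Reduce(`+`, lapply(shifted, function(m) m[rows, , drop = FALSE])) / n
  structure(list(
    image = img,
    n_frames_used = n,
    n_frames_screened_out = as.integer(n_frames_screened_out),
    shifts_px = shifts,
    crop_top_px = rows[1] - 1L,
    axial_px_um_optical = axial_px_um_optical,
    lateral_px_um = lateral_px_um,
    provenance = provenance
  ), class = "averaged_bscan")
}

#' Screen, align and average a capture in one call
#'
#' @param stack A `bscan_stack`.
#' @param screen_policy Policy for [screen_frames()].
#' @param max_shift_px Search range for [axial_align()].
#' @return An `averaged_bscan`, or `NULL` when every frame is screened out
#'   (capture failure).
#' @export
preprocess_stack <- function(stack, screen_policy = list(mad_k = 3, rel_frac = 0.25),
                             max_shift_px = 20L) {
  keep <- suppressWarnings(screen_frames(stack, screen_policy))
  if (!length(keep)) return(NULL)
  frames <- stack$frames[keep]
  shifts <- axial_align(frames, max_shift_px)
  average_frames(frames, shifts,
                 axial_px_um_optical = stack$axial_px_um_optical,
                 lateral_px_um = stack$lateral_px_um,
                 n_frames_screened_out = length(stack$frames) - length(keep),
                 provenance = list(seed = stack$seed,
                                   kept_frames = keep,
                                   group_index = stack$group_index))
}
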