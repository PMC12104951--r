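# Iterative graph-search extraction of corneal interfaces from an averaged
# B-scan, with path blocking, a programmatic labelling policy standing in for
# a human supervisor, and 1-5 quality grading.
#
# The search graph has one node per pixel; a boundary is a left-to-right path
# visiting every column once with a bounded vertical step. Path cost is the
# sum of per-node transition costs built from the signed vertical intensity
# gradient, so minimum-cost paths hug dark-to-bright (or bright-to-dark)
# edges. Extracted paths are refined to the centre of the local intensity
# ridge, which is where an impulse-like interface reflector actually lies.

#' Build a transition-cost map from an image
#'
#' Cost is the negative signed vertical gradient (central differences inside,
#' one-sided full differences at the first and last row), with the sign set
#' by the requested polarity, min-max normalized to \[0, 1\], plus a small
#' epsilon so flat regions still carry nonzero cost. Minimum-cost rows are
#' thus the strongest dark-to-bright (or bright-to-dark) transitions.
#'
#' @param image Numeric matrix, rows = depth.
#' @param polarity `"dark_to_bright"` (cost low where intensity increases with
#'   depth) or `"bright_to_dark"`.
#' @param eps Cost floor added after normalization (default 1e-3).
#' @return Object of class `energy_map`: list with `cost` (matrix) and
#'   `polarity`.
#' @export
build_energy <- function(image, polarity = c("dark_to_bright", "bright_to_dark"),
                         eps = 1e-3) {
  polarity <- match.arg(polarity)
  nz <- nrow(image)
  if (nz < 2) stop("image must have at least 2 rows")
  g <- (image[c(2:nz, nz), ] - image[c(1, 1:(nz - 1)), ]) / 2
  g[1, ] <- image[2, ] - image[1, ]
  g[nz, ] <- image[nz, ] - image[nz - 1, ]
  raw <- if (polarity == "dark_to_bright") -g else g
  rng <- range(raw)
  if (diff(rng) == 0) {
    warning("constant image: energy map is uniform")
    cost <- matrix(eps, nz, ncol(image))
  } else {
    cost <- (raw - rng[1]) / diff(rng) + eps
  }
  structure(list(cost = cost, polarity = polarity, eps = eps),
            class = "energy_map")
}

#' Minimum-cost left-to-right path by dynamic programming
#'
#' Finds the monotone-lateral path (one node per column, vertical step at
#' most `max_step` pixels between adjacent columns) minimizing the summed
#' node cost, by a single forward dynamic-programming sweep and backtrace.
#' Blocked nodes have infinite cost and are never visited. The integer path
#' is refined per column by a parabolic fit of the cost at the path node and
#' its two vertical neighbours.
#'
#' @param energy An `energy_map` from [build_energy()], or a cost matrix.
#' @param blocked Optional logical matrix, `TRUE` = node unusable.
#' @param max_step Maximum |vertical step| per column (default 2).
#' @return Object of class `boundary_path`: `z` (subpixel row per column,
#'   1-based), `z_int` (integer path), `cost` (total path cost),
#'   `feasible`, `interface_label` (NA until assigned).
#' @export
find_path <- function(energy, blocked = NULL, max_step = 2L) {
  cost <- if (inherits(energy, "energy_map")) energy$cost else energy
  nz <- nrow(cost); nx <- ncol(cost)
  if (!is.null(blocked)) {
    stopifnot(identical(dim(blocked), dim(cost)))
    cost[blocked] <- Inf
  }
  steps <- -max_step:max_step
  D <- cost[, 1]
  ptr <- matrix(0L, nz, nx)
  for (x in 2:nx) {
    best <- rep(Inf, nz); bd <- integer(nz)
    for (d in steps) {
      idx <- seq_len(nz) - d
      cand <- rep(Inf, nz)
      ok <- idx >= 1 & idx <= nz
      cand[ok] <- D[idx[ok]]
      upd <- cand < best
      best[upd] <- cand[upd]
      bd[upd] <- d
    }
    D <- cost[, x] + best
    ptr[, x] <- bd
  }
  if (!any(is.finite(D)))
    return(structure(list(z = NULL, z_int = NULL, cost = Inf, feasible = FALSE,
                          interface_label = NA_character_),
                     class = "boundary_path"))
  zi <- integer(nx)
  zi[nx] <- which.min(D)
  for (x in nx:2) zi[x - 1] <- zi[x] - ptr[zi[x], x]
  # subpixel: parabolic fit of the cost around each path node
  z <- as.numeric(zi)
  for (x in seq_len(nx)) {
    zc <- zi[x]
    if (zc > 1 && zc < nz) {
      cm <- cost[zc - 1, x]; c0 <- cost[zc, x]; cp <- cost[zc + 1, x]
      den <- cm - 2 * c0 + cp
      if (is.finite(cm) && is.finite(cp) && den > 0)
        z[x] <- zc + clamp(0.5 * (cm - cp) / den, -0.5, 0.5)
    }
  }
  structure(list(z = z, z_int = zi, cost = min(D), feasible = TRUE,
                 interface_label = NA_character_),
            class = "boundary_path")
}

#' Policy controlling iterative segmentation and labelling
#'
#' The programmatic stand-in for the human supervisor: how many low-energy
#' paths to extract, how wide a band to block around each, and how extracted
#' paths are mapped to anatomical labels. Labelling is by depth order and
#' strength: the shallowest strong path is the tear film; the next strong
#' path at least `min_sep_um` (geometric) deeper is the epithelium-Bowman
#' interface (consistently hyper-reflective); the Bowman-stroma interface is
#' the strongest path lying `bowman_window_um` (geometric) below it,
#' accepting lower contrast since that interface is dimmer and rougher.
#' Paths matching nothing are left unassigned, emulating the incidental
#' low-energy paths that do not relate to a desired interface.
#'
#' @param max_paths Path extractions before labelling (default 10); repeat
#'   finds of an already-extracted ridge are blocked but not duplicated in
#'   the candidate list.
#' @param block_halfwidth_px Half-width of the axial band blocked around each
#'   extracted path (default 3).
#' @param max_step_px Vertical step bound of the path search (default 2).
#' @param ridge_halfwidth_px Search half-range for the intensity-ridge
#'   refinement around the raw path (default 5).
#' @param strong_frac Fraction of the strongest candidate's ridge brightness
#'   above which a candidate counts as strong (default 0.5).
#' @param weak_frac Lower brightness fraction a Bowman-stroma candidate must
#'   still reach (default 0.35): that interface is dimmer than the others but
#'   must stand clear of the bulk background.
#' @param min_sep_um Minimum geometric separation between tear film and
#'   epithelium-Bowman labels (default 15 um).
#' @param bowman_window_um Geometric depth window below the
#'   epithelium-Bowman interface in which the Bowman-stroma interface is
#'   accepted (default c(5, 25) um).
#' @param blocked_regions Optional integer matrix with columns z0, z1, x0, x1
#'   (1-based, inclusive): node regions blocked before any search, the
#'   supervisor's "block this wrong path" override.
#' @param label_overrides Optional named integer vector mapping labels to
#'   extraction indices, e.g. `c(epi_bowman = 3)`, overriding the automatic
#'   assignment for those labels.
#' @param score_override Optional integer 1-5 forced as the quality score.
#' @return Object of class `segmentation_policy`.
#' @export
segmentation_policy <- function(max_paths = 10L, block_halfwidth_px = 3L,
                                max_step_px = 2L, ridge_halfwidth_px = 5L,
                                strong_frac = 0.5, weak_frac = 0.35,
                                min_sep_um = 15,
                                bowman_window_um = c(5, 25),
                                blocked_regions = NULL,
                                label_overrides = NULL,
                                score_override = NULL) {
  structure(as.list(environment()), class = "segmentation_policy")
}

# Refine a raw path to the centre of the local intensity ridge: per column,
# the brightest pixel within +/- halfwidth of the path, with parabolic
# subpixel interpolation of the intensity peak. Nodes in `forbidden`
# (supervisor blocks) are never selected.
refine_to_ridge <- function(image, z_int, halfwidth, forbidden = NULL) {
  nz <- nrow(image); nx <- ncol(image)
  z <- numeric(nx); zi <- integer(nx); strength <- numeric(nx)
  for (x in seq_len(nx)) {
    lo <- max(1L, z_int[x] - halfwidth)
    hi <- min(nz, z_int[x] + halfwidth)
    w <- image[lo:hi, x]
    if (!is.null(forbidden)) w[forbidden[lo:hi, x]] <- -Inf
    m <- lo + which.max(w) - 1L
    zi[x] <- m
    strength[x] <- image[m, x]
    off <- 0
    if (m > 1 && m < nz) {
      im <- image[m - 1, x]; i0 <- image[m, x]; ip <- image[m + 1, x]
      den <- 2 * i0 - im - ip
      if (den > 0) off <- clamp(0.5 * (ip - im) / den, -0.5, 0.5)
    }
    z[x] <- m + off
  }
  list(z = z, z_int = zi, strength = mean(strength))
}

#' Iteratively segment the three corneal interfaces
#'
#' Repeatedly extracts the current minimum-cost dark-to-bright path from the
#' averaged B-scan's energy map, refines it to the local intensity ridge,
#' and blocks an axial band around it before the next extraction. The policy
#' then assigns the tear-film, epithelium-Bowman and Bowman-stroma labels by
#' depth order, strength and geometric plausibility; unmatched paths stay
#' unassigned. A missing label marks the result failed and caps its quality
#' score at 2.
#'
#' @param avg An `averaged_bscan` (or a list with `image` and pixel
#'   spacings).
#' @param policy A [segmentation_policy()].
#' @param group_index Group refractive index used for the geometric
#'   plausibility windows (default 1.387).
#' @return Object of class `segmentation_result`: `paths` (named list of
#'   `boundary_path` for the three interfaces, entries NULL when
#'   unassigned), `candidates` (all extracted paths with strengths),
#'   `failed`, `quality_score`, `flags`, and the pixel geometry needed by
#'   thickness extraction.
#' @export
segment_interfaces <- function(avg, policy = segmentation_policy(),
                               group_index = 1.387) {
  img <- avg$image
  nz <- nrow(img); nx <- ncol(img)
  dz <- avg$axial_px_um_optical
  energy <- build_energy(img, "dark_to_bright")
  blocked <- matrix(FALSE, nz, nx)
  if (!is.null(policy$blocked_regions)) {
    br <- policy$blocked_regions
    for (i in seq_len(nrow(br))) {
      z0 <- max(1L, br[i, 1]); z1 <- min(nz, br[i, 2])
      x0 <- max(1L, br[i, 3]); x1 <- min(nx, br[i, 4])
      blocked[z0:z1, x0:x1] <- TRUE
    }
  }
  user_blocked <- if (any(blocked)) blocked else NULL

  candidates <- list()
  for (k in seq_len(policy$max_paths)) {
    p <- find_path(energy, blocked, policy$max_step_px)
    if (!p$feasible) break
    r <- refine_to_ridge(img, p$z_int, policy$ridge_halfwidth_px, user_blocked)
    # the same interface ridge can be re-found from its gradient tails; keep
    # one candidate per ridge but still block the raw path so the search
    # progresses
    dup <- any(vapply(candidates, function(cc)
      mean(abs(cc$z - r$z)) < 2, logical(1)))
    if (!dup)
      candidates[[length(candidates) + 1L]] <-
        list(z = r$z, z_int = r$z_int, strength = r$strength,
             cost = p$cost, depth_px = mean(r$z))
    for (x in seq_len(nx)) {
      lo <- max(1L, min(r$z_int[x], p$z_int[x]) - policy$block_halfwidth_px)
      hi <- min(nz, max(r$z_int[x], p$z_int[x]) + policy$block_halfwidth_px)
      blocked[lo:hi, x] <- TRUE
    }
    if (!dup &&
        !anyNA(unlist(assign_labels(candidates, policy, dz, group_index))))
      break
  }

  labels <- assign_labels(candidates, policy, dz, group_index)
  paths <- list(tear_film = NULL, epi_bowman = NULL, bowman_stroma = NULL)
  for (lab in names(labels)) {
    if (is.na(labels[[lab]])) next
    cand <- candidates[[labels[[lab]]]]
    paths[[lab]] <- structure(list(z = cand$z, z_int = cand$z_int,
                                   cost = cand$cost, feasible = TRUE,
                                   interface_label = lab),
                              class = "boundary_path")
  }
  failed <- any(vapply(paths, is.null, logical(1)))
  ordering_ok <- TRUE
  if (!failed) {
    ordering_ok <- all(paths$tear_film$z < paths$epi_bowman$z) &&
      all(paths$epi_bowman$z < paths$bowman_stroma$z)
    if (!ordering_ok) failed <- TRUE
  }

  res <- structure(list(
    paths = paths,
    candidates = candidates,
    failed = failed,
    flags = list(failed = failed, ordering_violated = !ordering_ok,
                 n_candidates = length(candidates)),
    quality_score = NA_integer_,
    axial_px_um_optical = dz,
    lateral_px_um = avg$lateral_px_um,
    group_index = group_index,
    crop_top_px = if (!is.null(avg$crop_top_px)) avg$crop_top_px else 0L
  ), class = "segmentation_result")
  res$quality_score <- grade_segmentation(res, img,
                                          override = policy$score_override)
  res
}

# Depth-order + strength labelling policy (see segmentation_policy docs).
assign_labels <- function(candidates, policy, dz, group_index) {
  out <- c(tear_film = NA_integer_, epi_bowman = NA_integer_,
           bowman_stroma = NA_integer_)
  if (!is.null(policy$label_overrides)) {
    for (lab in names(policy$label_overrides)) {
      k <- policy$label_overrides[[lab]]
      if (k >= 1 && k <= length(candidates)) out[lab] <- as.integer(k)
    }
  }
  if (!length(candidates)) return(as.list(out))
  depth <- vapply(candidates, `[[`, numeric(1), "depth_px")
  strength <- vapply(candidates, `[[`, numeric(1), "strength")
  strong <- strength >= policy$strong_frac * max(strength)
  taken <- out[!is.na(out)]
  avail <- setdiff(seq_along(candidates), taken)
  ord <- avail[order(depth[avail])]
  min_sep_px <- policy$min_sep_um * group_index / dz
  win_px <- policy$bowman_window_um * group_index / dz

  if (is.na(out["tear_film"])) {
    cand <- ord[strong[ord]]
    if (length(cand)) out["tear_film"] <- cand[1]
  }
  if (is.na(out["epi_bowman"]) && !is.na(out["tear_film"])) {
    tf_depth <- depth[out["tear_film"]]
    cand <- ord[strong[ord] & depth[ord] >= tf_depth + min_sep_px &
                  ord != out["tear_film"]]
    if (length(cand)) out["epi_bowman"] <- cand[1]
  }
  if (is.na(out["bowman_stroma"]) && !is.na(out["epi_bowman"])) {
    eb_depth <- depth[out["epi_bowman"]]
    cand <- avail[depth[avail] >= eb_depth + win_px[1] &
                    depth[avail] <= eb_depth + win_px[2] &
                    strength[avail] >= policy$weak_frac * max(strength) &
                    !(avail %in% out)]
    if (length(cand)) out["bowman_stroma"] <- cand[which.max(strength[cand])]
  }
  as.list(out)
}

#' Grade a segmentation result 1-5
#'
#' A monotone proxy for the human interpretability grade: the residual
#' high-frequency contrast of the stromal region just below the deepest
#' assigned boundary (speckle left after averaging), penalized by the
#' roughness of the extracted paths. Failed segmentations score at most 2
#' (1 when no path was extracted at all); only scores 3-5 are usable
#' downstream, weighted 1/2/3.
#'
#' @param result A `segmentation_result`.
#' @param image The averaged image it was computed from (defaults to the
#'   geometry stored in the result when omitted at call sites that have it).
#' @param thresholds Increasing contrast thresholds separating scores
#'   5/4/3/2/1.
#' @param rough_penalty_px Mean second-difference roughness (px) above which
#'   one grade is deducted.
#' @param override Optional forced score 1-5 (the supervisor's prerogative).
#' @return Integer score in 1..5.
#' @export
grade_segmentation <- function(result, image,
                               thresholds = c(0.03, 0.09, 0.20, 0.40),
                               rough_penalty_px = 0.6,
                               override = NULL) {
  if (!is.null(override)) return(as.integer(clamp(override, 1, 5)))
  if (result$failed)
    return(if (!length(result$candidates)) 1L else 2L)
  nz <- nrow(image)
  deepest <- max(result$paths$bowman_stroma$z_int)
  lo <- min(nz, deepest + 8L); hi <- min(nz, deepest + 38L)
  region <- image[lo:hi, , drop = FALSE]
  # residual contrast: SD of the axially high-passed region over its mean
  smooth <- gauss_smooth2d(region, 3, 0)
  m <- stats::sd(region - smooth) / max(mean(region), .Machine$double.eps)
  rough <- mean(vapply(result$paths, function(p)
    stats::sd(diff(p$z, differences = 2)), numeric(1)))
  score <- 5L - findInterval(m, thresholds)
  if (is.finite(rough) && rough > rough_penalty_px) score <- score - 1L
  as.integer(clamp(score, 1L, 5L))
}
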