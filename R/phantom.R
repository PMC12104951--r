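# Synthetic corneal B-scan generation with known ground-truth geometry.
#
# The phantom is a layered anterior cornea seen by an ultra-high axial
# resolution OCT: four bulk regions (background above the tear film,
# epithelium, Bowman's layer, stroma) separated by three reflective
# interfaces (tear-film surface, epithelium-Bowman, Bowman-stroma).
# Interfaces are modelled as impulse reflectors on the bulk background;
# the whole reflectivity profile is convolved axially with a Gaussian PSF,
# multiplied by smoothed multiplicative speckle, and shifted axially by a
# per-frame jitter. Depth coordinates are optical-path micrometres; a group
# refractive index converts optical to geometric tissue distance.

#' Specification of a synthetic corneal B-scan capture
#'
#' Defines the geometry, optics and noise of one multi-frame capture. The
#' defaults describe a healthy central cornea imaged by an OCT with an axial
#' point-spread FWHM of 1.7 um in corneal tissue (group index 1.387), sampled
#' at 0.5 um optical per pixel axially and 2 um per pixel laterally over a
#' 1000 um field, wide enough to hold the 450 um quasi-point window.
#'
#' @param epithelial_thickness_um Geometric epithelial thickness (tear film to
#'   epithelium-Bowman interface), um.
#' @param bowman_thickness_um Geometric Bowman's layer thickness, um. Values
#'   outside \[5, 25\] um are allowed for stress tests but draw a warning.
#' @param anterior_radius_um Curvature radius of the tear-film surface in um
#'   (`Inf` for a flat phantom). Deeper interfaces are parallel to it.
#' @param layer_reflectivities Named numeric vector of relative brightness:
#'   `tear_film`, `epithelium_bulk`, `epi_bowman`, `bowman_bulk`,
#'   `bowman_stroma`, `stroma_bulk`. Interface entries are impulse amplitudes;
#'   bulk entries are background levels.
#' @param background_reflectivity Bulk level above the tear film.
#' @param psf_fwhm_tissue_um Axial PSF full width at half maximum expressed in
#'   geometric tissue um (default 1.7).
#' @param group_index Group refractive index converting optical path to
#'   geometric tissue distance (default 1.387).
#' @param speckle_contrast Relative SD of the multiplicative speckle field in
#'   \[0, 1\]. 0 disables speckle.
#' @param jitter_sd_px SD of the per-frame rigid axial shift, in axial pixels.
#' @param n_frames Frames per capture (1-50).
#' @param axial_px_um_optical Axial sampling, optical-path um per pixel.
#' @param lateral_px_um Lateral sampling, um per pixel.
#' @param lateral_extent_um Lateral field width, um; must be at least 450 so
#'   the quasi-point window fits.
#' @param axial_depth_um_optical Axial field depth, optical um.
#' @param tear_depth_um_optical Optical depth of the tear-film surface at the
#'   lateral field centre.
#' @param extra_reflectors Optional list of spurious impulse reflectors, each
#'   `list(depth_um_optical = , amplitude = )`, depth measured from the
#'   tear-film surface at each column (used to emulate reflections that do not
#'   correspond to a real interface).
#' @param contrast_degradation Optional local contrast loss in \[0, 1\): scales
#'   down interface amplitudes in the central third of the field, a crude
#'   stand-in for locally scattering tissue.
#' @param seed Integer seed; the same spec and seed reproduce the capture
#'   byte for byte.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(epithelial_thickness_um = 52.72,
                         bowman_thickness_um = 15.41,
                         anterior_radius_um = 7800,
                         layer_reflectivities = c(tear_film = 1.0,
                                                  epithelium_bulk = 0.15,
                                                  epi_bowman = 0.90,
                                                  bowman_bulk = 0.22,
                                                  bowman_stroma = 0.45,
                                                  stroma_bulk = 0.30),
                         background_reflectivity = 0.02,
                         psf_fwhm_tissue_um = 1.7,
                         group_index = 1.387,
                         speckle_contrast = 0.25,
                         jitter_sd_px = 2,
                         n_frames = 8,
                         axial_px_um_optical = 0.5,
                         lateral_px_um = 2,
                         lateral_extent_um = 1000,
                         axial_depth_um_optical = 240,
                         tear_depth_um_optical = 40,
                         extra_reflectors = NULL,
                         contrast_degradation = 0,
                         seed = 1L) {
  needed <- c("tear_film", "epithelium_bulk", "epi_bowman", "bowman_bulk",
              "bowman_stroma", "stroma_bulk")
  if (!all(needed %in% names(layer_reflectivities)))
    stop("layer_reflectivities must name: ", paste(needed, collapse = ", "))
  if (epithelial_thickness_um <= 0 || bowman_thickness_um <= 0)
    stop("layer thicknesses must be positive")
  if (bowman_thickness_um < 5 || bowman_thickness_um > 25)
    warning("bowman_thickness_um outside the realistic 5-25 um range")
  if (axial_px_um_optical <= 0 || lateral_px_um <= 0)
    stop("pixel spacings must be positive")
  if (lateral_extent_um < 450)
    stop("lateral field must be at least 450 um wide (quasi-point window)")
  if (n_frames < 1 || n_frames > 50)
    stop("n_frames must be between 1 and 50")
  if (speckle_contrast < 0 || speckle_contrast > 1)
    stop("speckle_contrast must lie in [0, 1]")
  if (psf_fwhm_tissue_um <= 0) stop("psf_fwhm_tissue_um must be positive")
  if (group_index <= 1) stop("group_index must exceed 1")

  spec <- list(
    epithelial_thickness_um = epithelial_thickness_um,
    bowman_thickness_um = bowman_thickness_um,
    anterior_radius_um = anterior_radius_um,
    layer_reflectivities = layer_reflectivities[needed],
    background_reflectivity = background_reflectivity,
    psf_fwhm_tissue_um = psf_fwhm_tissue_um,
    group_index = group_index,
    speckle_contrast = speckle_contrast,
    jitter_sd_px = jitter_sd_px,
    n_frames = as.integer(n_frames),
    axial_px_um_optical = axial_px_um_optical,
    lateral_px_um = lateral_px_um,
    lateral_extent_um = lateral_extent_um,
    axial_depth_um_optical = axial_depth_um_optical,
    tear_depth_um_optical = tear_depth_um_optical,
    extra_reflectors = extra_reflectors,
    contrast_degradation = contrast_degradation,
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  spec
}

#' Calibration phantom: a single isolated reflector, no noise
#'
#' A flat phantom whose only feature is the tear-film impulse, with speckle
#' and jitter disabled. Imaging it and measuring the axial profile width
#' verifies the generator's point-spread function.
#'
#' @param ... Overrides passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
calibration_spec <- function(...) {
  phantom_spec(
    anterior_radius_um = Inf,
    layer_reflectivities = c(tear_film = 1, epithelium_bulk = 0,
                             epi_bowman = 0, bowman_bulk = 0,
                             bowman_stroma = 0, stroma_bulk = 0),
    background_reflectivity = 0,
    speckle_contrast = 0,
    jitter_sd_px = 0,
    n_frames = 1,
    tear_depth_um_optical = 120,
    ...
  )
}

# Grid geometry shared by rendering and ground truth.
phantom_grid <- function(spec) {
  nz <- as.integer(round(spec$axial_depth_um_optical / spec$axial_px_um_optical))
  nx <- as.integer(round(spec$lateral_extent_um / spec$lateral_px_um))
  x_um <- (seq_len(nx) - 0.5) * spec$lateral_px_um - spec$lateral_extent_um / 2
  z_um <- (seq_len(nz) - 1) * spec$axial_px_um_optical
  list(nz = nz, nx = nx, x_um = x_um, z_um = z_um)
}

#' True interface depths of a phantom, per lateral column
#'
#' The analytic layer model: the tear-film surface follows a circular sag of
#' the anterior radius (flat when the radius is infinite) and the deeper
#' interfaces run parallel to it, separated by the geometric layer
#' thicknesses scaled by the group index.
#'
#' @param spec A `phantom_spec`.
#' @return List with `tear_film`, `epi_bowman`, `bowman_stroma`: per-column
#'   depths in optical-path um (row 1 centre = 0).
#' @export
interface_depths <- function(spec) {
  g <- phantom_grid(spec)
  sag <- if (is.infinite(spec$anterior_radius_um)) rep(0, g$nx)
         else g$x_um^2 / (2 * spec$anterior_radius_um)
  tear <- spec$tear_depth_um_optical + sag
  epi <- tear + spec$group_index * spec$epithelial_thickness_um
  bow <- epi + spec$group_index * spec$bowman_thickness_um
  list(tear_film = tear, epi_bowman = epi, bowman_stroma = bow)
}

# Axial PSF standard deviation in optical um.
psf_sigma_optical_um <- function(spec) {
  spec$psf_fwhm_tissue_um * spec$group_index / (2 * sqrt(2 * log(2)))
}

# Render one noise-free frame, interfaces displaced by jitter_um (optical).
# Bulk steps are Gaussian-blurred edges (error functions); interfaces are
# Gaussian impulse ridges with unit-peak kernels.
render_frame <- function(spec, jitter_um = 0) {
  g <- phantom_grid(spec)
  d <- interface_depths(spec)
  sig <- psf_sigma_optical_um(spec)
  r <- spec$layer_reflectivities
  amp_scale <- rep(1, g$nx)
  if (spec$contrast_degradation > 0) {
    mid <- abs(g$x_um) < spec$lateral_extent_um / 6
    amp_scale[mid] <- 1 - spec$contrast_degradation
  }

  img <- matrix(spec$background_reflectivity, g$nz, g$nx)
  bulk_after <- c(r[["epithelium_bulk"]], r[["bowman_bulk"]], r[["stroma_bulk"]])
  bulk_before <- c(spec$background_reflectivity, r[["epithelium_bulk"]],
                   r[["bowman_bulk"]])
  iface_amp <- c(r[["tear_film"]], r[["epi_bowman"]], r[["bowman_stroma"]])
  depths <- list(d$tear_film, d$epi_bowman, d$bowman_stroma)
  # the blurred step and ridge are flat beyond ~6 sigma of each interface, so
  # transcendental functions are only evaluated in that band
  band <- 6 * sig
  for (i in 1:3) {
    a <- outer(g$z_um, depths[[i]] + jitter_um, "-")
    step <- (a > 0) * 1.0
    idx <- which(abs(a) < band)
    step[idx] <- stats::pnorm(a[idx] / sig)
    img <- img + (bulk_after[i] - bulk_before[i]) * step
    if (iface_amp[i] > 0) {
      ridge <- matrix(0, g$nz, g$nx)
      ridge[idx] <- exp(-a[idx]^2 / (2 * sig^2))
      img <- img + (iface_amp[i] * rep(amp_scale, each = g$nz)) * ridge
    }
  }
  if (!is.null(spec$extra_reflectors)) {
    for (er in spec$extra_reflectors) {
      a <- outer(g$z_um, d$tear_film + er$depth_um_optical + jitter_um, "-")
      ridge <- matrix(0, g$nz, g$nx)
      idx <- which(abs(a) < band)
      ridge[idx] <- exp(-a[idx]^2 / (2 * sig^2))
      img <- img + er$amplitude * ridge
    }
  }
  img
}

# Multiplicative speckle field: iid Rayleigh draws smoothed to the PSF scale
# (axially) and one lateral pixel, standardized to mean 1 and SD = contrast.
speckle_field <- function(nz, nx, contrast, sigma_axial_px) {
  raw <- matrix(sqrt(-2 * log(stats::runif(nz * nx))), nz, nx)
  sm <- gauss_smooth2d(raw, sigma_axial_px, 1)
  f <- 1 + contrast * (sm - mean(sm)) / stats::sd(sm)
  pmax(f, 0)
}

#' Generate a multi-frame synthetic B-scan capture
#'
#' Renders `n_frames` frames of the layered phantom: each frame is the
#' analytic reflectivity profile (bulk steps plus impulse interfaces blurred
#' by the axial PSF), rigidly shifted in depth by a seeded per-frame jitter
#' and multiplied by an independent smoothed speckle field. Ground truth
#' (per-column interface depths before jitter, and the per-frame jitters) is
#' carried alongside the frames.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `bscan_stack`: list with `frames` (list of
#'   numeric matrices, rows = depth, columns = lateral position), pixel
#'   spacings, `ground_truth` (optical-um interface depths per column),
#'   `jitter_px`, the generating `spec` and `seed`.
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_grid(spec)
  sig_px <- psf_sigma_optical_um(spec) / spec$axial_px_um_optical
  with_seed(spec$seed, {
    jit_px <- if (spec$jitter_sd_px > 0)
      stats::rnorm(spec$n_frames, 0, spec$jitter_sd_px) else rep(0, spec$n_frames)
    frames <- vector("list", spec$n_frames)
    for (f in seq_len(spec$n_frames)) {
      img <- render_frame(spec, jitter_um = jit_px[f] * spec$axial_px_um_optical)
      if (spec$speckle_contrast > 0)
        img <- img * speckle_field(g$nz, g$nx, spec$speckle_contrast, sig_px)
      frames[[f]] <- img
    }
    structure(list(
      frames = frames,
      axial_px_um_optical = spec$axial_px_um_optical,
      lateral_px_um = spec$lateral_px_um,
      group_index = spec$group_index,
      ground_truth = interface_depths(spec),
      jitter_px = jit_px,
      spec = spec,
      seed = spec$seed
    ), class = "bscan_stack")
  })
}

#' Measure the axial point-spread FWHM from a calibration stack
#'
#' Takes the central-column axial intensity profile of the first frame,
#' checks that it contains a single peak, and returns the full width at half
#' maximum converted from optical to geometric tissue distance by dividing by
#' the group index. Half-maximum crossings are located by linear
#' interpolation, so the estimate is subpixel.
#'
#' @param stack A `bscan_stack` containing one isolated reflector and no
#'   noise, e.g. from [calibration_spec()].
#' @return FWHM in geometric tissue um.
#' @export
measure_psf_fwhm <- function(stack) {
  stopifnot(inherits(stack, "bscan_stack"))
  img <- stack$frames[[1]]
  col <- ceiling(ncol(img) / 2)
  p <- img[, col]
  pk <- max(p)
  if (pk <= 0) stop("profile has no peak")
  half <- pk / 2
  above <- p > half
  runs <- rle(above)
  if (sum(runs$values) != 1L)
    stop("axial profile has multiple peaks; not a valid calibration capture")
  i0 <- which.max(p)
  li <- max(which(p[seq_len(i0)] <= half))
  ri <- i0 - 1 + min(which(p[i0:length(p)] <= half))
  zl <- li + (half - p[li]) / (p[li + 1] - p[li])
  zr <- (ri - 1) + (half - p[ri - 1]) / (p[ri] - p[ri - 1])
  (zr - zl) * stack$axial_px_um_optical / stack$group_index
}
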