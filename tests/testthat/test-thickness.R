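# Optical-to-geometric conversion, quasi-point window thickness, and
# quality-weighted per-eye aggregation.

# Hand-built segmentation result with constant boundary separations.
fake_seg <- function(nx = 250, tear = 50, epi = 160, bow = 200,
                     score = 4L, dz = 0.5, dx = 2, n_G = 1.387) {
  path <- function(z, lab) structure(
    list(z = rep(z, nx), z_int = rep(as.integer(round(z)), nx), cost = 0,
         feasible = TRUE, interface_label = lab), class = "boundary_path")
  structure(list(
    paths = list(tear_film = path(tear, "tear_film"),
                 epi_bowman = path(epi, "epi_bowman"),
                 bowman_stroma = path(bow, "bowman_stroma")),
    candidates = list(), failed = FALSE,
    flags = list(failed = FALSE), quality_score = as.integer(score),
    axial_px_um_optical = dz, lateral_px_um = dx, group_index = n_G,
    crop_top_px = 0L), class = "segmentation_result")
}

meas <- function(bt, score, lsd = 0.1) {
  structure(list(bt_um = bt, et_um = bt * 3, local_sd_um = lsd,
                 window_center_x = 0, window_len_um = 450,
                 quality_score = as.integer(score),
                 weight = bowmetrics:::score_weight(as.integer(score)),
                 excluded = score < 3, failed = FALSE, capture_id = "c"),
            class = "thickness_measurement")
}

test_that("optical to geometric conversion", {
  expect_identical(optical_to_geometric(0), 0)
  expect_equal(optical_to_geometric(21.373670, 1.387), 15.41, tolerance = 1e-6)
  expect_identical(optical_to_geometric(12.5, 1), 12.5)
  expect_error(optical_to_geometric(-1), "negative")
})

test_that("constant separation gives the exact converted thickness", {
  seg <- fake_seg(tear = 50, epi = 160, bow = 200)
  m <- quasi_point_thickness(seg)
  expect_equal(m$bt_um, 40 * 0.5 / 1.387)
  expect_equal(m$et_um, 110 * 0.5 / 1.387)
  expect_equal(m$local_sd_um, 0)
  expect_identical(m$weight, 2L)
  expect_false(m$excluded)
})

test_that("unit consistency: halving the pixel size at doubled coordinates", {
  m1 <- quasi_point_thickness(fake_seg(tear = 50, epi = 160, bow = 200,
                                       dz = 0.5))
  m2 <- quasi_point_thickness(fake_seg(tear = 100, epi = 320, bow = 400,
                                       dz = 0.25))
  expect_equal(m1$bt_um, m2$bt_um)
})

test_that("flat phantom at true BT 15 is measured within 0.2 um", {
  sp <- tiny_spec(anterior_radius_um = Inf)
  seg <- segment_interfaces(preprocess_stack(generate_stack(sp)))
  m <- quasi_point_thickness(seg)
  expect_lt(abs(m$bt_um - 15), 0.2)
})

test_that("corneal curvature changes the windowed BT by under 0.1 um", {
  m_flat <- quasi_point_thickness(segment_interfaces(preprocess_stack(
    generate_stack(tiny_spec(anterior_radius_um = Inf)))))
  m_curv <- quasi_point_thickness(segment_interfaces(preprocess_stack(
    generate_stack(tiny_spec(anterior_radius_um = 7800)))))
  expect_lt(abs(m_flat$bt_um - m_curv$bt_um), 0.1)
})

test_that("window wider than the field or a missing label fails cleanly", {
  expect_error(quasi_point_thickness(fake_seg(nx = 100)), "window")
  seg <- fake_seg()
  seg$paths$bowman_stroma <- NULL
  seg$failed <- TRUE
  m <- quasi_point_thickness(seg)
  expect_true(m$failed)
  expect_true(m$excluded)
  expect_true(is.na(m$bt_um))
})

test_that("weighted aggregation uses weights 1/2/3 for scores 3/4/5", {
  ms <- list(meas(14, 3), meas(15, 4), meas(16, 5))
  eye <- aggregate_eye(ms, "weighted")
  expect_equal(eye$bt_um, (14 * 1 + 15 * 2 + 16 * 3) / 6)
  expect_identical(eye$n_captures_used, 3L)
  # captures scoring < 3 are dropped from the weighted mean
  eye2 <- aggregate_eye(c(ms, list(meas(99, 2))), "weighted")
  expect_equal(eye2$bt_um, eye$bt_um)
})

test_that("a single usable capture aggregates to itself", {
  eye <- aggregate_eye(list(meas(14.6, 4)), "weighted")
  expect_equal(eye$bt_um, 14.6)
  expect_identical(eye$n_captures_used, 1L)
})

test_that("an eye whose captures all score below 3 is a failed eye", {
  eye <- aggregate_eye(list(meas(14, 2), meas(15, 1)), "weighted")
  expect_true(eye$failed)
  expect_identical(eye$n_captures_used, 0L)
  expect_error(aggregate_eye(list()), "no measurements")
})

test_that("best mode picks the highest score, ties broken by local SD", {
  ms <- list(meas(14, 4, lsd = 0.3), meas(15, 5, lsd = 0.2),
             meas(16, 5, lsd = 0.1))
  eye <- aggregate_eye(ms, "best")
  expect_equal(eye$bt_um, 16)
  expect_identical(eye$n_captures_used, 1L)
})

test_that("the weighted mean lies within the range of included captures", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    ms <- lapply(seq_len(n), function(j)
      meas(stats::runif(1, 10, 20), sample(3:5, 1)))
    eye <- aggregate_eye(ms, "weighted")
    bts <- vapply(ms, `[[`, numeric(1), "bt_um")
    expect_gte(eye$bt_um, min(bts))
    expect_lte(eye$bt_um, max(bts))
  }
})
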