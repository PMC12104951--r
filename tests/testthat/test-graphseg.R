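# Energy construction, dynamic-programming path search against independent
# oracles, iterative interface extraction with blocking, and quality grading.

# Exhaustive enumeration of all monotone-lateral paths (|step| <= 2) on a
# small cost matrix: the brute-force oracle for the DP search.
enumerate_best_path <- function(cost, max_step = 2L) {
  nz <- nrow(cost); nx <- ncol(cost)
  best <- list(cost = Inf, path = NULL)
  recurse <- function(x, z, acc, path) {
    acc <- acc + cost[z, x]
    if (acc >= best$cost) return()
    path[x] <- z
    if (x == nx) {
      best <<- list(cost = acc, path = path)
      return()
    }
    for (nzt in max(1, z - max_step):min(nz, z + max_step))
      recurse(x + 1L, nzt, acc, path)
  }
  for (z0 in seq_len(nz)) recurse(1L, z0, 0, integer(nx))
  best
}

test_that("energy is minimal along a bright line's dark-to-bright edge", {
  img <- matrix(0, 20, 10)
  img[10, ] <- 1
  e <- build_energy(img, "dark_to_bright")
  expect_equal(unname(apply(e$cost, 2, which.min)), rep(9, 10))
})

test_that("inverting the image and flipping polarity gives the same energy", {
  img <- matrix(stats::runif(200), 20, 10)
  e1 <- build_energy(img, "dark_to_bright")
  e2 <- build_energy(max(img) - img, "bright_to_dark")
  expect_equal(e1$cost, e2$cost)
})

test_that("a constant image yields a uniform epsilon map with a warning", {
  expect_warning(e <- build_energy(matrix(2, 8, 8)), "constant")
  expect_true(all(e$cost == e$eps))
})

test_that("energy matches hand-computed gradients on a 5x5 example", {
  img <- matrix(c(0, 0, 1, 0, 0,
                  0, 1, 2, 1, 0,
                  1, 2, 3, 2, 1,
                  0, 1, 2, 1, 0,
                  0, 0, 1, 0, 0), 5, 5, byrow = TRUE)
  # independent arithmetic: one-sided differences at rows 1 and 5, central
  # elsewhere, negated, then min-max normalized and offset by eps
  g <- matrix(0, 5, 5)
  g[1, ] <- img[2, ] - img[1, ]
  g[5, ] <- img[5, ] - img[4, ]
  for (z in 2:4) g[z, ] <- (img[z + 1, ] - img[z - 1, ]) / 2
  raw <- -g
  expected <- (raw - min(raw)) / (max(raw) - min(raw)) + 1e-3
  expect_equal(build_energy(img, "dark_to_bright")$cost, expected)
})

test_that("the path follows the stronger of two lines until it is blocked", {
  img <- matrix(0, 20, 12)
  img[6, ] <- 0.5   # weaker line
  img[14, ] <- 1.0  # stronger line
  e <- build_energy(img, "dark_to_bright")
  p1 <- find_path(e)
  expect_true(all(p1$z_int == 13))  # dark-to-bright edge of the strong line
  blocked <- matrix(FALSE, 20, 12)
  blocked[12:16, ] <- TRUE
  p2 <- find_path(e, blocked)
  expect_true(all(p2$z_int == 5))
  # brute-force enumeration agrees on the blocked instance
  cost <- e$cost; cost[blocked] <- Inf
  oracle <- enumerate_best_path(cost[1:6, 1:6])
  expect_equal(find_path(e$cost[1:6, 1:6])$cost,
               enumerate_best_path(e$cost[1:6, 1:6])$cost)
  expect_equal(oracle$path, find_path(cost[1:6, 1:6])$z_int)
})

test_that("DP path cost equals Dijkstra on random 8x8 energy maps", {
  skip_if_not_installed("igraph")
  dijkstra_cost <- function(cost) {
    nz <- nrow(cost); nx <- ncol(cost)
    id <- function(z, x) (x - 1) * nz + z
    from <- integer(0); to <- integer(0); w <- numeric(0)
    for (x in 1:(nx - 1)) for (z in 1:nz) {
      zt <- max(1, z - 2):min(nz, z + 2)
      from <- c(from, rep(id(z, x), length(zt)))
      to <- c(to, id(zt, x + 1))
      w <- c(w, cost[zt, x + 1])
    }
    src <- nz * nx + 1L
    from <- c(from, rep(src, nz)); to <- c(to, id(1:nz, 1L))
    w <- c(w, cost[, 1])
    g <- igraph::graph_from_edgelist(cbind(from, to))
    d <- igraph::distances(g, v = src, to = id(1:nz, nx), mode = "out",
                           weights = w)
    min(d)
  }
  set.seed(404)
  for (i in 1:100) {
    cost <- matrix(stats::runif(64), 8, 8)
    expect_equal(find_path(cost)$cost, dijkstra_cost(cost), tolerance = 1e-12)
  }
})

test_that("blocked nodes never lie on a returned path", {
  set.seed(17)
  for (i in 1:20) {
    cost <- matrix(stats::runif(30 * 15), 30, 15)
    blocked <- matrix(stats::runif(30 * 15) < 0.15, 30, 15)
    p <- find_path(cost, blocked)
    if (!p$feasible) next
    expect_false(any(blocked[cbind(p$z_int, seq_len(15))]))
  }
})

test_that("an infeasible search returns a failure flag, not a crash", {
  cost <- matrix(1, 10, 5)
  blocked <- matrix(FALSE, 10, 5)
  blocked[, 3] <- TRUE
  p <- find_path(cost, blocked)
  expect_false(p$feasible)
})

test_that("clean phantom: all three interfaces found, ordered, subpixel-accurate", {
  stack <- generate_stack(tiny_spec())
  avg <- preprocess_stack(stack)
  seg <- segment_interfaces(avg)
  expect_false(seg$failed)
  truth <- truth_rows(stack)
  for (lab in c("tear_film", "epi_bowman", "bowman_stroma")) {
    expect_s3_class(seg$paths[[lab]], "boundary_path")
    rmse <- sqrt(mean((seg$paths[[lab]]$z - truth[[lab]])^2))
    expect_lt(rmse, 0.5)
  }
  expect_true(all(seg$paths$tear_film$z < seg$paths$epi_bowman$z))
  expect_true(all(seg$paths$epi_bowman$z < seg$paths$bowman_stroma$z))
})

test_that("a spurious bright reflection is extracted but left unassigned", {
  # a reflection just below the tear film: too shallow to be the
  # epithelium-Bowman interface, too bright to be ignored by the search
  sp <- tiny_spec(extra_reflectors = list(
    list(depth_um_optical = 12, amplitude = 0.6)))
  stack <- generate_stack(sp)
  seg <- segment_interfaces(preprocess_stack(stack))
  expect_false(seg$failed)
  truth <- truth_rows(stack)
  spur_row <- mean(truth$tear_film) + 12 / sp$axial_px_um_optical
  depths <- vapply(seg$candidates, `[[`, numeric(1), "depth_px")
  expect_true(any(abs(depths - spur_row) < 2))  # it was found...
  for (lab in names(seg$paths))                 # ...but labelled nothing
    expect_gt(abs(mean(seg$paths[[lab]]$z) - spur_row), 5)
  expect_lt(abs(mean(seg$paths$epi_bowman$z) - mean(truth$epi_bowman)), 1)
})

test_that("supervisor overrides: blocked regions steer, forced score sticks", {
  stack <- generate_stack(tiny_spec())
  avg <- preprocess_stack(stack)
  truth <- truth_rows(stack)
  # block a wide band over the true Bowman-stroma interface: nothing bright
  # enough remains in the plausible window, so segmentation fails
  row <- round(mean(truth$bowman_stroma))
  pol <- segmentation_policy(blocked_regions = matrix(
    c(row - 14, row + 14, 1, ncol(avg$image)), 1))
  seg <- segment_interfaces(avg, pol)
  expect_true(seg$failed)
  expect_lte(seg$quality_score, 2L)
  # forced score override
  seg2 <- segment_interfaces(avg, segmentation_policy(score_override = 3L))
  expect_identical(seg2$quality_score, 3L)
})

test_that("grading: clean is 5, failure caps at 2, speckle never raises it", {
  stack <- generate_stack(tiny_spec())
  avg <- preprocess_stack(stack)
  expect_identical(segment_interfaces(avg)$quality_score, 5L)
  scores <- vapply(c(0, 0.15, 0.3, 0.45, 0.6), function(s) {
    sp <- tiny_spec(speckle_contrast = s, n_frames = 1, seed = 13L)
    segment_interfaces(preprocess_stack(generate_stack(sp)))$quality_score
  }, integer(1))
  expect_true(all(diff(scores) <= 0))
})
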