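test_that("gap_fill is identity without gaps and never touches observed cells", {
  tr <- toy_trial(seed = 2L)
  expect_identical(gap_fill(tr), tr)

  model <- planted_cohort_model(noise_sd = 0)
  gappy <- generate_gappy_trial(model,
    list(list(marker = "LKNE", start = 40L, length = 10L)))
  filled <- gap_fill(gappy, rank = 3L)
  ok <- !gappy$missing_mask
  expect_equal(max(abs(filled$data[ok] - attr(gappy, "truth")[ok])), 0)
  expect_false(any(filled$missing_mask))
})

test_that("gap_fill recovers a rank-1 signal through a 10-frame gap", {
  # all columns scalar multiples of one sinusoid
  t <- seq(0, 10, by = 0.01)
  a <- sin(2 * pi * 0.7 * t)
  M <- outer(a, c(3, -1, 2, 0.5, 1, -2)) +
    matrix(c(1, 2, 3, 4, 5, 6), length(t), 6, byrow = TRUE)
  tr <- marker_dataset(M, c("p", "q"), 100)
  truth <- tr$data
  tr$missing_mask[301:310, 1:3] <- TRUE
  tr$data[tr$missing_mask] <- NA_real_
  filled <- gap_fill(tr, rank = 1L, tol = 1e-9)
  rel <- max(abs(filled$data - truth)) / max(abs(truth))
  expect_lt(rel, 1e-6)
})

test_that("gap_fill rejects fully-missing columns", {
  tr <- toy_trial()
  tr$missing_mask[, 2L] <- TRUE
  tr$data[tr$missing_mask] <- NA_real_
  expect_error(gap_fill(tr), "unrecoverable")
})

test_that("mirroring negates the axis, swaps pairs, and is an involution", {
  m <- matrix(c(1, 2, 3), 2, 3, byrow = TRUE)
  tr <- marker_dataset(m, "a", 100)
  expect_equal(mirror_trial(tr, "y")$data,
               matrix(c(1, -2, 3), 2, 3, byrow = TRUE))

  tr2 <- toy_trial(n_markers = 4L, seed = 5L)
  sw <- c(m1 = "m2", m3 = "m4")
  expect_equal(mirror_trial(mirror_trial(tr2, "y", sw), "y", sw)$data,
               tr2$data)
  expect_error(mirror_trial(tr2, "y", c(m1 = "nope")), "not in marker_labels")

  # a bilaterally symmetric static posture is a fixed point of mirroring
  lay <- humanoid_layout()
  post <- marker_dataset(matrix(lay$posture, 2, length(lay$posture),
                                byrow = TRUE), lay$labels, 100)
  mir <- mirror_trial(post, "y", lay$swap_map)
  expect_equal(max(abs(mir$data - post$data)), 0)
})

test_that("coordinate transforms follow the stated convention and round trip", {
  # point fixed at (1, 0, 0) -> spherical (1, 0, 0)
  tr <- marker_dataset(matrix(c(1, 0, 0), 3, 3, byrow = TRUE), "a", 100)
  sp <- transform_coordinates(tr, "spherical")
  expect_equal(sp$data, matrix(c(1, 0, 0), 3, 3, byrow = TRUE))

  set.seed(11)
  tr2 <- toy_trial(T = 50L, n_markers = 3L, seed = 11L)
  tr2$data <- tr2$data + 10   # keep radii well away from the origin
  for (sys in c("spherical", "cylindrical")) {
    rt <- inverse_transform_coordinates(
      transform_coordinates(tr2, sys, origin = c(1, 2, 3)))
    expect_equal_mat(rt$data, tr2$data, 1e-9)
  }

  # constant-radius arc: cylindrical radius column is constant
  arc <- generate_arc_trial(radius = 2, arc_degrees = 120)
  cyl <- transform_coordinates(arc, "cylindrical")
  expect_lt(diff(range(cyl$data[, 1L])), 1e-9)
  # azimuth is unwrapped: no 2*pi jumps even across the +-pi branch
  arc2 <- generate_arc_trial(arc_degrees = 350)
  cyl2 <- transform_coordinates(arc2, "cylindrical")
  expect_lt(max(abs(diff(cyl2$data[, 2L]))), pi)

  orig <- marker_dataset(matrix(0, 3, 3), "a", 100)
  expect_error(transform_coordinates(orig, "spherical"),
               "degenerate radius")
})

test_that("zero-phase low-pass passes DC, kills the stop band, adds no lag", {
  t <- seq(0, 10 - 0.01, by = 0.01)
  lo <- sin(2 * pi * 1 * t)
  hi <- sin(2 * pi * 30 * t)
  M <- cbind(lo + hi, rep(5, length(t)))
  tr <- marker_dataset(cbind(M, 0), "a", 100)
  filt <- lowpass_filter(tr, cutoff = 7, order = 4L)
  # amplitude via sinusoid regression
  amp_at <- function(x, f) {
    fit <- lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  expect_gt(1 - amp_at(filt$data[, 1L], 30) / amp_at(tr$data[, 1L], 30), 0.99)
  expect_lt(abs(amp_at(filt$data[, 1L], 1) - 1), 0.01)
  # DC gain exactly 1 on a constant column
  expect_equal_mat(filt$data[, 2L], tr$data[, 2L], 1e-9)
  # zero-phase: cross-correlation peak of the 1 Hz component at lag 0
  pure <- marker_dataset(cbind(lo, 0, 0), "a", 100)
  fl <- lowpass_filter(pure, 7)$data[, 1L]
  cc <- ccf(fl, lo, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("lowpass_filter enforces preconditions", {
  tr <- toy_trial(gaps = 3L)
  expect_error(lowpass_filter(tr, 7), "gaps")
  tr2 <- toy_trial()
  expect_error(lowpass_filter(tr2, 60), "Nyquist")
  short <- marker_dataset(matrix(rnorm(12), 4, 3), "a", 100)
  expect_error(lowpass_filter(short, 7), "too short")
})

test_that("center/weight/normalize matches the analytic examples", {
  tr <- marker_dataset(cbind(c(1, 3), c(3, 5), 0), "a", 100)
  pt <- center_weight_normalize(tr)
  expect_equal(pt$matrix[, 1:2], cbind(c(-1, 1), c(-1, 1)))
  expect_equal(pt$center_offset[1:2], c(2, 4))
  expect_equal(pt$norm_factor, 1)

  # centered rows of norm 5 -> MED = 5
  tr2 <- marker_dataset(cbind(c(3, -3), c(4, -4), 0), "a", 100)
  pt2 <- center_weight_normalize(tr2, preprocess_config(normalization = "MED"))
  expect_equal(pt2$norm_factor, 5)
  expect_equal(pt2$matrix[, 1:2], cbind(c(0.6, -0.6), c(0.8, -0.8)))
  # MED leaves mean posture-row norm exactly 1
  expect_equal(mean(sqrt(rowSums(pt2$matrix^2))), 1, tolerance = 1e-9)

  expect_error(
    center_weight_normalize(
      marker_dataset(matrix(1, 4, 3), "a", 100),
      preprocess_config(normalization = "MED")),
    "degenerate")
})

test_that("MED normalization is invariant to uniform rescaling", {
  tr <- toy_trial(T = 40L, seed = 13L)
  cfg <- preprocess_config(normalization = "MED")
  ref <- center_weight_normalize(tr, cfg)$matrix
  set.seed(99)
  for (c in exp(runif(4, -3, 3))) {
    scaled <- tr
    scaled$data <- tr$data * c
    expect_equal_mat(center_weight_normalize(scaled, cfg)$matrix, ref, 1e-9)
  }
})

test_that("height and range normalizations apply their stated factors", {
  tr <- toy_trial(seed = 21L)
  ph <- center_weight_normalize(
    tr, preprocess_config(normalization = "height",
                          height = c(S1 = 1800)))
  expect_equal(ph$norm_factor, 1800)
  p0 <- center_weight_normalize(tr)
  expect_equal_mat(ph$matrix * 1800, p0$matrix, 1e-9)

  pr <- center_weight_normalize(
    tr, preprocess_config(normalization = "range", range_axis = "z"))
  zcols <- seq(3L, ncol(tr$data), by = 3L)
  expect_equal(pr$norm_factor,
               max(apply(p0$matrix[, zcols], 2, function(v) diff(range(v)))))
})

test_that("weighting scales columns linearly before normalization", {
  tr <- toy_trial(n_markers = 2L, seed = 31L)
  mm <- build_mass_model(c(m1 = 0.7, m2 = 0.3), tr$marker_labels)
  pw <- center_weight_normalize(tr, preprocess_config(weighting = mm))
  p0 <- center_weight_normalize(tr)
  expect_equal_mat(pw$matrix, sweep(p0$matrix, 2, mm$column_weights, `*`),
                   1e-12)
})

test_that("com_recenter removes whole-body displacement", {
  lay <- humanoid_layout()
  mm <- build_mass_model(lay$mass_spec, lay$labels)
  model <- planted_cohort_model(noise_sd = 0, duration = 2)
  tr <- generate_trial(model)
  shifted <- tr
  shifted$data[, seq(1L, ncol(tr$data), by = 3L)] <-
    shifted$data[, seq(1L, ncol(tr$data), by = 3L)] + 123.4
  a <- com_recenter(tr, mm)
  b <- com_recenter(shifted, mm)
  expect_equal_mat(a$data, b$data, 1e-9)
  # frame-wise weighted marker mean of the output is the zero vector
  w <- mm$per_marker_mass / sum(mm$per_marker_mass)
  for (ai in 1:3) {
    idx <- seq(ai, by = 3L, length.out = 28L)
    expect_lt(max(abs(a$data[, idx] %*% w)), 1e-12 * max(abs(tr$data)))
  }
  # single marker with weight 1 collapses to the origin
  one <- marker_dataset(matrix(rnorm(9), 3, 3), "solo", 100)
  mm1 <- build_mass_model(c(solo = 1), "solo")
  expect_equal(max(abs(com_recenter(one, mm1)$data)), 0)
})

test_that("centering is idempotent", {
  tr <- toy_trial(seed = 41L)
  p1 <- center_weight_normalize(tr)
  tr2 <- tr; tr2$data <- p1$matrix
  p2 <- center_weight_normalize(tr2)
  expect_equal_mat(p2$matrix, p1$matrix, 1e-12)
  expect_lt(max(abs(colMeans(p1$matrix))), 1e-9 * max(abs(tr$data)))
})

test_that("preprocess_trial applies steps in the documented order", {
  model <- planted_cohort_model(noise_sd = 0.05, duration = 2)
  gappy <- generate_gappy_trial(model,
    list(list(marker = "RSHO", start = 10L, length = 5L)))
  lay <- humanoid_layout()
  cfg <- preprocess_config(do_gapfill = TRUE,
                           mirror_axis = "y", swap_map = lay$swap_map,
                           filter_cutoff = 7, normalization = "MED")
  pt <- preprocess_trial(gappy, cfg)
  steps <- vapply(pt$provenance, `[[`, character(1L), "step")
  expect_equal(steps, c("gap_fill", "mirror", "lowpass",
                        "center_weight_normalize"))
  expect_equal(mean(sqrt(rowSums(pt$matrix^2))), 1, tolerance = 1e-9)
})
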