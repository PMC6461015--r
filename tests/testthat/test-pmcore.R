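test_that("assemble stacks trials, records spans, and order does not matter", {
  t1 <- toy_trial(T = 100L, seed = 1L)
  t2 <- toy_trial(T = 50L, seed = 2L)
  p <- prep_plain(list(t1, t2))
  a <- assemble(p)
  expect_equal(nrow(a$matrix), 150L)
  expect_equal(a$trial_spans, list(c(1L, 100L), c(101L, 150L)))
  expect_equal(a$matrix[1:100, ], p[[1L]]$matrix)

  one <- assemble(p[1L])
  expect_equal(one$matrix, p[[1L]]$matrix)

  # permuting trial order permutes spans but not the spectrum
  s12 <- fit_posture_space(a)
  s21 <- fit_posture_space(assemble(p[c(2L, 1L)]))
  expect_equal(s12$all_eigenvalues, s21$all_eigenvalues, tolerance = 1e-9)

  bad <- p
  bad[[2L]]$marker_labels <- c("x", "y")
  expect_error(assemble(bad), "mismatched")
})

test_that("fit_posture_space matches the analytic two-point example", {
  s <- fit_posture_space(matrix(c(-1, 1, -1, 1), 2, 2))
  expect_equal(s$eigenvalues, c(4, 0))
  expect_equal(abs(s$components[, 1L]), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(s$rel_eigenvalues, c(100, 0))
})

test_that("posture space is orthonormal, sorted, and conserves variance", {
  co <- planted_cohort(n_trials = 3L, duration = 3)
  a <- assemble(prep_plain(co$trials))
  s <- fit_posture_space(a)
  G <- crossprod(s$components)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-10)
  expect_true(all(diff(s$all_eigenvalues) <= 0))
  expect_true(all(s$all_eigenvalues >= 0))
  expect_equal(sum(s$all_rel_eigenvalues), 100, tolerance = 1e-9)
  # conservation: sum EV == total column variance of the assembled matrix
  tot <- sum(apply(a$matrix, 2L, var))
  expect_equal(sum(s$all_eigenvalues) / tot, 1, tolerance = 1e-9)
})

test_that("SVD path matches brute-force covariance eigendecomposition", {
  set.seed(17)
  for (rep in 1:5) {
    M <- matrix(rnorm(12 * 6), 12, 6)
    s <- fit_posture_space(M)
    eg <- eigen(cov(M), symmetric = TRUE)
    expect_equal(s$all_eigenvalues, eg$values, tolerance = 1e-10)
    for (k in 1:6)
      expect_lt(1 - abs(sum(s$components[, k] * eg$vectors[, k])), 1e-8)
  }
})

test_that("row rotations leave the eigenvalue spectrum unchanged", {
  M <- toy_trial(T = 40L, seed = 23L)$data
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  s1 <- fit_posture_space(M)
  s2 <- fit_posture_space(M %*% Q)
  expect_equal(s1$all_eigenvalues, s2$all_eigenvalues, tolerance = 1e-9)
})

test_that("projection: rank-1 trials, back-projection, and pooled variance", {
  co <- planted_cohort(n_trials = 2L, duration = 3, noise_sd = 0)
  p <- prep_plain(co$trials)
  a <- assemble(p)
  s <- fit_posture_space(a)

  # rows all equal to c * PC_1' project to a constant first score
  cvec <- 2.5
  M <- cvec * matrix(s$components[, 1L], 10, nrow(s$components), byrow = TRUE)
  pp <- project(M, s)$PP
  expect_lt(max(abs(pp[, 1L] - (cvec - sum(s$grand_center * s$components[, 1L])))),
            1e-9)
  expect_lt(max(abs(pp[, -1L])), 1e-9)

  # full-basis back-projection reproduces the trial matrix
  pm1 <- project(p[[1L]], s)
  back <- sweep(pm1$PP %*% t(s$components), 2L, s$grand_center, `+`)
  expect_equal_mat(back, p[[1L]]$matrix, 1e-9)

  # pooled score variance equals EV_k
  S <- sweep(a$matrix, 2L, s$grand_center) %*% s$components
  expect_equal(apply(S, 2L, var)[1:3] / s$eigenvalues[1:3], rep(1, 3),
               tolerance = 1e-9)

  expect_error(project(matrix(0, 4, 5), s), "columns")
})

test_that("per-trial projections equal the sliced pooled score matrix", {
  co <- planted_cohort(n_trials = 3L, duration = 2)
  p <- prep_plain(co$trials)
  a <- assemble(p)
  s <- fit_posture_space(a)
  pooled <- sweep(a$matrix, 2L, s$grand_center) %*% s$components
  for (i in seq_along(p)) {
    span <- a$trial_spans[[i]]
    expect_equal_mat(project(p[[i]], s)$PP,
                     pooled[span[1L]:span[2L], , drop = FALSE], 1e-12)
  }
})

test_that("differentiation matches analytic derivatives", {
  fs <- 100
  Tn <- 1000L
  tt <- (seq_len(Tn) - 1L) / fs
  pm <- structure(list(subject_id = "S", trial_id = "T", sampling_rate = fs,
                       PP = cbind(3 * tt, sin(2 * pi * 1 * tt), rep(2, Tn))),
                  class = "pm_timeseries")
  pm <- differentiate(pm)
  interior <- 2:(Tn - 1L)
  # linear ramp: PV = slope * 1, PA = 0
  expect_equal_mat(pm$PV[interior, 1L], rep(3, length(interior)), 1e-9)
  expect_equal_mat(pm$PA[3:(Tn - 2L), 1L], rep(0, Tn - 4L), 1e-9)
  # sinusoid: interior PV amplitude ~ 2*pi*g*A within 0.1%
  amp <- max(abs(pm$PV[interior, 2L]))
  expect_lt(abs(amp - 2 * pi) / (2 * pi), 1e-3)
  # constant: PV = PA = 0 exactly
  expect_equal(max(abs(pm$PV[, 3L])), 0)
  expect_equal(max(abs(pm$PA[, 3L])), 0)
})

test_that("reconstruct_pm inverts projection and scales linearly", {
  # rank-1 world: one mode, no noise
  lay <- humanoid_layout()
  mode <- random_orthonormal_modes(length(lay$posture), 1L, seed = 5L)
  model <- planted_model(lay$posture, mode, list(amp_sinusoid(1, 3)),
                         noise_sd = 0, duration = 2, seed = 3L,
                         marker_labels = lay$labels)
  tr <- generate_trial(model)
  pt <- preprocess_trial(tr, preprocess_config(normalization = "MED"))
  s <- fit_posture_space(assemble(list(pt)))
  pp <- project(pt, s)$PP[, 1L]

  rec <- reconstruct_pm(s, 1L, pp, amplification = 1, ref = pt)
  expect_equal_mat(rec$data, tr$data, 1e-9 * max(abs(tr$data)))

  # amplification 2 doubles the excursion about the mean posture
  rec2 <- reconstruct_pm(s, 1L, pp, amplification = 2, ref = pt)
  mu <- matrix(pt$center_offset, nrow(rec$data), ncol(rec$data), byrow = TRUE)
  expect_equal_mat(rec2$data - mu, 2 * (rec$data - mu), 1e-12 * max(abs(tr$data)))

  # zero track -> static mean posture
  rec0 <- reconstruct_pm(s, 1L, rep(0, 5), ref = pt)
  expect_equal_mat(rec0$data,
                   matrix(pt$center_offset, 5, ncol(rec0$data), byrow = TRUE),
                   1e-12)

  # normalized space without inversion info refuses to guess
  expect_error(reconstruct_pm(s, 1L, pp), "cannot invert")
})
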