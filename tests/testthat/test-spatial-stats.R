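test_that("stripe patterns peak at the fundamental wavenumber", {
  w <- 16
  img <- make_pattern("stripes", size = 64, period = w)
  curve <- structure_factor(img)
  dq <- 2 * pi / 64
  # argmax lands in the exact fundamental bin
  pk_max <- sf_peak(curve, method = "argmax")
  expect_lt(abs(pk_max$q_m - 2 * pi / w), dq / 2)
  # first moment agrees with the independent direct-DFT oracle
  oracle <- oracle_radial_average(oracle_power_spectrum(img$grid))
  oracle <- oracle[oracle$q <= pi + 1e-12, ]
  q_m_oracle <- sum(oracle$q * oracle$S) / sum(oracle$S)
  pk_mom <- sf_peak(curve)
  expect_equal(pk_mom$q_m, q_m_oracle, tolerance = 1e-10)
})

test_that("the fft-based spectrum equals the direct DFT definition", {
  img <- make_pattern("labyrinth", size = 32, seed = 5)
  curve <- structure_factor(img)
  oracle <- oracle_radial_average(oracle_power_spectrum(img$grid))
  expect_equal(curve$q, oracle$q, tolerance = 1e-12)
  expect_equal(curve$S, oracle$S, tolerance = 1e-8)
})

test_that("i.i.d. random labels give a flat spectrum", {
  slopes <- vapply(1:10, function(seed) {
    cv <- structure_factor(make_pattern("random", size = 128, seed = seed))
    coef(lm(log(S) ~ log(q), data = cv[cv$q <= pi, ]))[2]
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.1)
})

test_that("Parseval's identity holds to machine precision", {
  for (kind in c("random", "labyrinth", "halves")) {
    img <- make_pattern(kind, size = 64, seed = 2)
    cv <- structure_factor(img)
    I <- img$grid - mean(img$grid)
    expect_equal(sum(cv$S * cv$n_modes), sum(I^2), tolerance = 1e-9)
  }
})

test_that("the radial average is invariant under rotation and cyclic shifts", {
  img <- make_pattern("labyrinth", size = 64, seed = 3)$grid
  base <- structure_factor(img)
  rot <- structure_factor(t(img[nrow(img):1, ])) # 90 degree rotation
  sh <- structure_factor(img[c(17:64, 1:16), c(40:64, 1:39)])
  expect_equal(base$S, rot$S, tolerance = 1e-10)
  expect_equal(base$S, sh$S, tolerance = 1e-10)
})

test_that("degenerate spectra are flagged or rejected", {
  expect_error(structure_factor(matrix(1, 64, 64)), "no fluctuations")
  expect_error(structure_factor(make_pattern("random", size = 16)),
               "at least 32")
  cv <- suppressWarnings(structure_factor(make_pattern("random", size = 64)))
  expect_warning(sf_peak(cv), "no characteristic scale")
})

test_that("two equal peaks average to their midpoint under the moment estimator", {
  q <- seq(0.1, 2, by = 0.1)
  S <- rep(0, length(q)); S[c(5, 15)] <- 7
  curve <- structure(tibble::tibble(q = q, S = S, n_modes = 1L),
                     class = c("sf_curve", "tbl_df", "tbl", "data.frame"),
                     band_max = pi)
  pk <- suppressWarnings(sf_peak(curve))
  expect_equal(pk$q_m, (q[5] + q[15]) / 2, tolerance = 1e-12)
})

test_that("a self-similar pattern series yields the -2 scaling by construction", {
  base <- make_pattern("labyrinth", size = 64, seed = 4)
  series <- make_scaled_series(base, factors = c(1L, 2L, 3L, 4L, 6L))
  fit <- coarsening_fit(series, times = c(1, 4, 9, 16, 36),
                        transient_frac = 0)
  expect_equal(fit$slope_sq_qm, -2, tolerance = 0.05)
  expect_equal(fit$slope_qm_t, -0.5, tolerance = 0.1)
  expect_error(coarsening_fit(series[1:3], times = c(1, 4, 9),
                              transient_frac = 0), "fewer than 5")
})

test_that("rescaling collapses self-similar curves onto one master curve", {
  base <- make_pattern("labyrinth", size = 64, seed = 6)
  series <- make_scaled_series(base, factors = c(1L, 2L, 4L))
  col <- collapse_curves(series)
  expect_lt(col$score, col$score_raw)
  # duplicated identical curves collapse perfectly
  cv <- structure_factor(make_pattern("labyrinth", size = 64, seed = 7))
  expect_equal(collapse_curves(list(cv, cv))$score, 0, tolerance = 1e-12)
})

test_that("assortment matches exhaustive window enumeration on a split image", {
  img <- make_pattern("halves", size = 8)
  got <- assortment(img, h = 1)
  expect_equal(got$r_g, oracle_assortment(img, 1, focal = 1),
               tolerance = 1e-12)
  expect_equal(got$r_c, oracle_assortment(img, 1, focal = -1),
               tolerance = 1e-12)
})

test_that("kernel assortment equals brute force on random and structured images", {
  rng <- make_rng(17, "assort-equiv")
  for (case in 1:6) {
    n <- c(16, 24, 32, 48, 64, 64)[case]
    g <- matrix(rng$sample(c(-1L, 0L, 1L), n * n, replace = TRUE,
                           prob = c(0.45, 0.1, 0.45)), n, n)
    for (h in 1:4) {
      got <- assortment(g, h)
      expect_equal(got$r_g, oracle_assortment(g, h, 1), tolerance = 1e-12)
      expect_equal(got$r_c, oracle_assortment(g, h, -1), tolerance = 1e-12)
    }
  }
})

test_that("checkerboards are exactly unassorted and fine stripes anti-assorted", {
  # Moore windows of a checkerboard balance same and opposite labels at
  # every h, so r = 0; period-2 stripes leave only 2 of 8 neighbours alike
  chk <- make_pattern("checkerboard", size = 16)
  expect_equal(assortment(chk, 1)$r_g, 0, tolerance = 1e-12)
  expect_equal(assortment(chk, 2)$r_g, 0, tolerance = 1e-12)
  st <- make_pattern("stripes", size = 16, period = 2)
  got <- assortment(st, 1)
  expect_lt(got$r_g, 0)
  expect_equal(got$r_g, oracle_assortment(st, 1, 1), tolerance = 1e-12)
  expect_equal(got$r_g, -0.5, tolerance = 1e-12)
})

test_that("assortment is bounded, label-swap invariant and errors on one strain", {
  rng <- make_rng(19, "assort-bounds")
  for (k in 1:20) {
    n <- 32
    g <- matrix(rng$sample(c(-1L, 0L, 1L), n * n, replace = TRUE,
                           prob = c(runif(1, 0.2, 0.6), 0.05, 0.5)), n, n)
    for (h in c(1, 3)) {
      a <- assortment(g, h)
      expect_true(a$r_g >= -1 && a$r_g <= 1)
      expect_true(a$r_c >= -1 && a$r_c <= 1)
      sw <- assortment(-g, h, focal = -1)
      expect_equal(a$r_g, sw$r_g, tolerance = 1e-12)
    }
  }
  expect_error(assortment(matrix(1L, 16, 16), 1), "assortment undefined")
  expect_error(assortment(make_pattern("halves", size = 16), 10),
               "h must satisfy")
})

test_that("profiles decay with radius on separated images and average replicates", {
  img <- make_pattern("halves", size = 64)
  prof <- assortment_profile(img, h_max = 4)
  expect_true(all(diff(prof$r_g) < 0)) # boundary fraction grows with h
  expect_true(all(prof$r_g > 0))
  reps <- lapply(1:3, function(s) make_pattern("random", size = 64, seed = s))
  mp <- assortment_profile(reps, h_max = 3)
  expect_true(all(c("ci_low", "ci_high") %in% names(mp)))
  expect_true(all(mp$ci_low <= mp$r_g & mp$r_g <= mp$ci_high))
})

test_that("coarsened killing lattices are highly assorted at short range", {
  run <- run_ibm(ibm_params(width = 64, height = 64, seed = 8), 200)
  prof <- assortment_profile(run$snapshots[["200"]], h_max = 8)
  expect_gt(prof$r_g[1], 0.5)
  expect_true(all(diff(prof$r_g) < 0))
})
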