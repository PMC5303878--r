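uniform_state <- function(a, b, n = 8, dx = 1, S = NULL)
  field_state(matrix(a, n, n), matrix(b, n, n),
              S = if (!is.null(S)) matrix(S, n, n), dx = dx)

test_that("the two-strain right-hand side vanishes at every printed equilibrium", {
  p <- two_strain_params()
  # single-strain A = r/s
  r1 <- rhs_two_strain(uniform_state(p$r / p$s, 0), p)
  expect_lt(max(abs(r1$dA), abs(r1$dB)), 1e-12)
  # coexistence
  den <- p$s * (p$alpha_ab + p$alpha_ba) + p$alpha_ab * p$alpha_ba
  r2 <- rhs_two_strain(uniform_state(p$alpha_ab * p$r / den,
                                     p$alpha_ba * p$r / den), p)
  expect_lt(max(abs(r2$dA), abs(r2$dB)), 1e-12)
  # extinction
  r3 <- rhs_two_strain(uniform_state(0, 0), p)
  expect_identical(max(abs(r3$dA), abs(r3$dB)), 0)
})

test_that("the public-goods rhs vanishes at the cooperator-only equilibrium", {
  p <- public_goods_params()
  Astar <- p$lambda * (p$r - p$c) / (p$lambda * p$s - p$rho * p$b)
  st <- uniform_state(Astar, 0, S = p$rho * Astar / p$lambda)
  r <- rhs_public_goods(st, p)
  expect_lt(max(abs(r$dA), abs(r$dB), abs(r$dS)), 1e-10)
  expect_error(rhs_public_goods(uniform_state(1, 1), p), "S field")
})

test_that("strain roles are exactly symmetric when cost and killing vanish", {
  p <- public_goods_params(c = 0, alpha = 0)
  set.seed(42)
  A <- matrix(runif(64, 0.2, 1), 8, 8); B <- matrix(runif(64, 0.2, 1), 8, 8)
  S <- matrix(runif(64), 8, 8)
  r1 <- rhs_public_goods(field_state(A, B, S = S), p)
  r2 <- rhs_public_goods(field_state(B, A, S = S), p)
  expect_identical(r1$dA, r2$dB)
  expect_identical(r1$dB, r2$dA)
})

test_that("without secretion the good decays and dynamics reduce to killing only", {
  p <- public_goods_params(rho = 0, c = 0)
  st <- uniform_state(0.4, 0.4, S = 0.3)
  run <- integrate_fields(st, p, t_end = 0.2, dt = 1e-3)
  expect_lt(max(run$states[[1]]$S), 0.3 * exp(-p$lambda * 0.19))
  r_goods <- rhs_public_goods(uniform_state(0.4, 0.4, S = 0), p)
  r_plain <- rhs_two_strain(uniform_state(0.4, 0.4),
                            two_strain_params(alpha_ab = p$alpha,
                                              alpha_ba = p$alpha, d = p$d))
  expect_equal(r_goods$dA, r_plain$dA, tolerance = 1e-12)
})

test_that("the integrator rejects steps outside the diffusive stability bound", {
  st <- uniform_state(0.5, 0.5, dx = 0.1)
  expect_error(integrate_fields(st, two_strain_params(d = 0.01), 1, dt = 1),
               "stability bound")
})

test_that("equilibria are fixed points of the integrator", {
  p <- two_strain_params()
  den <- p$s * (p$alpha_ab + p$alpha_ba) + p$alpha_ab * p$alpha_ba
  a <- p$alpha_ab * p$r / den
  st <- uniform_state(a, a, n = 16)
  run <- integrate_fields(st, p, t_end = 5, dt = 0.01)
  expect_lt(max(abs(run$states[[1]]$A - a)), 1e-10)
  pg <- public_goods_params()
  Astar <- pg$lambda * (pg$r - pg$c) / (pg$lambda * pg$s - pg$rho * pg$b)
  st2 <- uniform_state(Astar, 0, n = 16, S = pg$rho * Astar / pg$lambda)
  run2 <- integrate_fields(st2, pg, t_end = 1, dt = 1e-3)
  expect_lt(max(abs(run2$states[[1]]$A - Astar)) / Astar, 1e-8)
})

test_that("forward Euler converges at first order in dt", {
  p <- two_strain_params(d = 0.05)
  set.seed(7)
  A0 <- matrix(runif(256, 0.3, 0.6), 16, 16)
  B0 <- matrix(runif(256, 0.3, 0.6), 16, 16)
  final_A <- function(dt)
    integrate_fields(field_state(A0, B0), p, t_end = 1, dt = dt)$states[[1]]$A
  ref <- final_A(0.00125)
  e1 <- max(abs(final_A(0.01) - ref))
  e2 <- max(abs(final_A(0.005) - ref))
  expect_gt(e1 / e2, 1.6) # ratio 2 expected at first order
  expect_lt(e1 / e2, 2.6)
})

test_that("a fast good relaxes to its quasi-steady concentration", {
  # the residual lag |S - rho A / lambda| scales as 1/lambda at fixed
  # rho/lambda, vanishing in the separation-of-timescales limit
  qss_dev <- function(lambda) {
    p <- public_goods_params(alpha = 0, c = 0, rho = lambda, lambda = lambda)
    st <- uniform_state(0.7, 0.2, S = 0)
    run <- integrate_fields(st, p, t_end = 0.5, dt = 1e-3)
    s_end <- run$states[[1]]$S[1, 1]
    a_end <- run$states[[1]]$A[1, 1]
    abs(s_end - p$rho * a_end / p$lambda) / s_end
  }
  d100 <- qss_dev(100); d400 <- qss_dev(400)
  expect_lt(d100, 0.02)
  expect_lt(d400, d100 / 2)
})

test_that("swapping strains and killing rates relabels the dynamics exactly", {
  p <- two_strain_params(alpha_ab = 0.7, alpha_ba = 0.2)
  q <- two_strain_params(alpha_ab = 0.2, alpha_ba = 0.7)
  set.seed(9)
  A0 <- matrix(runif(64, 0.1, 0.8), 8, 8)
  B0 <- matrix(runif(64, 0.1, 0.8), 8, 8)
  r1 <- integrate_fields(field_state(A0, B0), p, t_end = 0.5, dt = 0.01)
  r2 <- integrate_fields(field_state(B0, A0), q, t_end = 0.5, dt = 0.01)
  expect_identical(r1$states[[1]]$A, r2$states[[1]]$B)
  expect_identical(r1$states[[1]]$B, r2$states[[1]]$A)
})

test_that("two-strain killing runs phase separate from uniform noise", {
  p <- two_strain_params()
  n <- 64; dx <- 0.2
  rng <- make_rng(3, "pde-sep")
  eq <- 0.4444444
  A0 <- matrix(eq * (1 + 0.02 * (rng$runif(n * n) - 0.5)), n, n)
  B0 <- 2 * eq - A0
  run <- integrate_fields(field_state(A0, B0, dx = dx), p,
                          t_end = 150, dt = 0.1, record_at = c(10, 150))
  phi_spread <- function(s) sd(s$A / (s$A + s$B))
  expect_gt(phi_spread(run$states[[2]]), 10 * phi_spread(run$states[[1]]))
  # domains are near the single-strain density, not the coexistence point
  expect_gt(max(run$states[[2]]$A), 0.9 * p$r / p$s)
})
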