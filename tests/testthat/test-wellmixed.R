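test_that("the four two-strain equilibria have the printed values and stability", {
  eq <- equilibria_two_strain(two_strain_params())
  expect_identical(nrow(eq), 4L)
  expect_true(all(eq$residual < 1e-12))
  expect_equal(eq$A[eq$equilibrium == "only_A"], 1.0)
  cx <- eq[eq$equilibrium == "coexistence", ]
  expect_equal(cx$A, 1 / 2.25, tolerance = 1e-12)
  expect_equal(cx$B, 1 / 2.25, tolerance = 1e-12)
  expect_identical(cx$classification, "saddle")
  expect_lt(cx$trace, 0); expect_lt(cx$det, 0)
  expect_identical(eq$classification[eq$equilibrium == "extinction"],
                   "unstable")
  expect_identical(eq$classification[eq$equilibrium == "only_A"], "stable")
  expect_identical(eq$classification[eq$equilibrium == "only_B"], "stable")
  expect_error(equilibria_two_strain(two_strain_params(s = 0)), "s = 0")
})

test_that("the coexistence composition is set by the killing-rate ratio", {
  rng <- make_rng(21, "coex-ratio")
  for (k in 1:50) {
    p <- two_strain_params(r = rng$runif(1, 0.5, 4),
                           s = rng$runif(1, 0.5, 4),
                           alpha_ab = rng$runif(1, 0.05, 2),
                           alpha_ba = rng$runif(1, 0.05, 2))
    cx <- equilibria_two_strain(p) |> dplyr::filter(equilibrium == "coexistence")
    expect_equal(cx$A / cx$B, p$alpha_ab / p$alpha_ba, tolerance = 1e-9)
    expect_identical(cx$classification, "saddle")
  }
})

test_that("domination is decided by the initial ratio against alpha_ab/alpha_ba", {
  p <- two_strain_params()
  expect_identical(domination_outcome(0.6, 0.4, p), "A")
  expect_identical(domination_outcome(0.5, 0.5, p), "separatrix")
  pa <- two_strain_params(alpha_ab = 0.8, alpha_ba = 0.2)
  expect_identical(domination_outcome(2, 1, pa), "B") # ratio 2 < threshold 4
  # ODE integration agrees away from the separatrix
  tr <- integrate_wellmixed(c(A = 2, B = 1), pa, t_end = 200)
  expect_lt(tail(tr$freq_a, 1), 0.01)
  tr2 <- integrate_wellmixed(c(A = 0.55, B = 0.45), p, t_end = 300)
  expect_gt(tail(tr2$freq_a, 1), 0.99)
})

test_that("cooperator stability threshold and equilibria match the closed forms", {
  p <- public_goods_params()
  expect_equal(alpha_crit(p), 1 / 190, tolerance = 1e-12)
  eq <- cooperator_equilibria(p)
  coop <- eq[eq$equilibrium == "cooperator", ]
  expect_equal(coop$A, p$lambda * (p$r - p$c) / (p$lambda * p$s - p$rho * p$b),
               tolerance = 1e-12)
  expect_identical(coop$classification, "stable") # alpha = 0.5 > 1/190
  expect_identical(eq$classification[eq$equilibrium == "cheat"], "stable")
  sad <- eq[eq$equilibrium == "saddle", ]
  expect_identical(sad$classification, "saddle")
  expect_gt(sad$A, sad$B) # cooperator basin is the smaller one when c > 0
  expect_true(all(eq$residual < 1e-12))
  # costless cooperation: threshold collapses to 0, so any positive killing
  # stabilises cooperators; at alpha = 0 exactly, cheat and cooperator are
  # the same strain and the equilibrium is neutral along their exchange
  expect_equal(alpha_crit(public_goods_params(c = 0)), 0)
  eq0 <- cooperator_equilibria(public_goods_params(c = 0, alpha = 0.01))
  expect_identical(eq0$classification[eq0$equilibrium == "cooperator"],
                   "stable")
  eqn <- cooperator_equilibria(public_goods_params(c = 0, alpha = 0))
  expect_identical(eqn$classification[eqn$equilibrium == "cooperator"],
                   "marginal")
  expect_error(public_goods_params(s = 1, b = 1.9, rho = 100, lambda = 100),
               "rho \\* b / lambda")
})

test_that("the cheat equilibrium is stable across random parameter draws", {
  rng <- make_rng(33, "cheat-stable")
  n_ok <- 0
  while (n_ok < 30) {
    r <- rng$runif(1, 0.5, 4); s <- rng$runif(1, 0.5, 4)
    b <- rng$runif(1, 0, 2); rho <- rng$runif(1, 1, 100)
    lambda <- rng$runif(1, 10, 200); cost <- rng$runif(1, 0, 0.5 * r)
    alpha <- rng$runif(1, 0, 1)
    if (s <= rho * b / lambda) next
    p <- public_goods_params(r = r, s = s, alpha = alpha, b = b, c = cost,
                             rho = rho, lambda = lambda)
    eq <- cooperator_equilibria(p)
    expect_identical(eq$classification[eq$equilibrium == "cheat"], "stable")
    n_ok <- n_ok + 1
  }
})

test_that("killing induces positive frequency dependence for the cooperator", {
  p <- public_goods_params()
  n_tot <- 1
  adv <- function(fa) cooperator_advantage(fa * n_tot, (1 - fa) * n_tot, p)
  expect_lt(adv(0.3), 0)
  expect_gt(adv(0.9), 0)
  # sign change sits where alpha (A - B) = c
  f_crit <- (1 + p$c / (p$alpha * n_tot)) / 2
  expect_equal(adv(f_crit), 0, tolerance = 1e-12)
  # and vanishes entirely without killing
  expect_equal(cooperator_advantage(0.9, 0.1, public_goods_params(alpha = 0)),
               -p$c, tolerance = 1e-12)
})

test_that("well-mixed trajectories hold equilibria and stay non-negative", {
  p <- two_strain_params()
  tr <- integrate_wellmixed(c(A = 1 / 2.25, B = 1 / 2.25), p, t_end = 100)
  expect_lt(max(abs(tr$A - 1 / 2.25)), 1e-6)
  pg <- public_goods_params()
  tr2 <- integrate_wellmixed(c(A = 0.99, B = 0.01),
                             public_goods_params(alpha = 0), t_end = 150)
  expect_true(all(diff(tr2$freq_a) < 1e-8)) # monotone decline of cooperators
  expect_true(all(tr2$A >= 0 & tr2$B >= 0))
})
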