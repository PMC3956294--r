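test_that("cytoplasmic trend evaluates the stated linear form", {
  p0 <- uniform_params(cyt_slope = 0)
  expect_equal(rho_cyt_at(p0, 7), p0$rho_cyt_ref)
  expect_equal(rho_cyt_at(p0, 14), p0$rho_cyt_ref)

  p <- uniform_params(cyt_slope = -0.01, L_ref = 10.5)
  expect_equal(rho_cyt_at(p, 14), 0.965 * p$rho_cyt_ref, tolerance = 1e-12)
  expect_equal(rho_cyt_at(p, 7), 1.035 * p$rho_cyt_ref, tolerance = 1e-12)
  # clamped at zero for absurd extrapolations
  expect_equal(rho_cyt_at(uniform_params(cyt_slope = -0.5), 1000), 0)
})

test_that("uniform-model closed form matches its limiting forms and the twofold scaling", {
  p <- params1_const()
  # nu = 0: pure area read-out
  pn0 <- params1_const(nu = 1e-300)  # nu > 0 required; effectively zero
  ss <- model1_closed_form(pn0, geom14())
  expect_equal(ss$rho_nod,
               (pn0$beta / pn0$eta) * (geom14()$A_cor / geom14()$A_nod),
               tolerance = 1e-10)
  # defaults with fixed A_nod: density ratio between 14 and 7 um cells
  ratio <- model1_closed_form(p, geom14())$rho_nod /
    model1_closed_form(p, geom7())$rho_nod
  expect_equal(ratio, 1.9771987, tolerance = 1e-6)  # "approximately twofold"
  # algebraic identity: nodal/cortical contrast is alpha/eta at every length
  for (L in c(7, 10, 14)) {
    s <- model1_closed_form(p, spherocylinder(L, 1.5, 3))
    expect_equal(s$rho_nod / s$rho_cor, p$alpha / p$eta, tolerance = 1e-12)
  }
})

test_that("uniform-model numeric solution matches the closed form to 1e-10", {
  for (L in c(7, 9.5, 12, 14)) {
    for (nu in c(5e-3, 0.05)) {
      p <- uniform_params(nu = nu)
      g <- spherocylinder(L, 1.5, 3)
      a <- model1_closed_form(p, g)
      b <- model1_numeric(p, g)
      expect_equal(b$rho_nod, a$rho_nod, tolerance = 1e-10)
      expect_equal(b$rho_cor, a$rho_cor, tolerance = 1e-10)
    }
  }
  # beta = 0: everything off the cytoplasm is empty
  z <- model1_numeric(uniform_params(beta = 0), geom14())
  expect_equal(z$rho_cor, 0)
  expect_equal(z$rho_nod, 0)
  # residuals of the balance equations vanish at the solution
  p <- uniform_params()
  g <- spherocylinder(10, 1.5, 3)
  s <- model1_numeric(p, g)
  flux_in <- p$beta * (g$A_cor / g$V) * (s$rho_cyt * g$V)
  r1 <- flux_in - p$nu * s$N_cor - p$alpha * (g$A_nod / g$A_cor) * s$N_cor
  r2 <- p$alpha * (g$A_nod / g$A_cor) * s$N_cor - p$eta * s$N_nod
  expect_lt(max(abs(c(r1, r2))), 1e-12 * flux_in)
})

test_that("direct-to-node null model is independent of cell size", {
  p <- params1_const()
  s7 <- model1_direct_null(p, geom7())
  s14 <- model1_direct_null(p, geom14())
  expect_equal(s14$rho_nod / s7$rho_nod, 1.0)
  expect_equal(model1_direct_null(params1_const(beta = 0), geom14())$rho_nod, 0)
  # beta/eta = 200 at unit cytoplasm
  expect_equal(s7$rho_nod, p$beta / p$eta, tolerance = 1e-12)
  expect_equal(p$beta / p$eta, 200)
  # zero slope of density vs length across the full range
  Ls <- seq(7, 14, by = 0.5)
  dens <- vapply(Ls, function(L)
    model1_direct_null(p, spherocylinder(L, 1.5, 3))$rho_nod, numeric(1))
  expect_equal(ols_closed_form(Ls, dens)[["slope"]], 0, tolerance = 1e-12)
})

test_that("modification-model closed form matches its stated forms", {
  g14 <- geom14()
  # no spontaneous reversion: pure area read-out
  p0 <- params2_const(mu = 0)
  expect_equal(model2_closed_form(p0, g14)$rho_nod,
               (p0$beta / p0$eta) * (g14$A_cor / g14$A_nod),
               tolerance = 1e-12)
  # extreme reversion kills the nodal pool
  pinf <- params2_const(mu = 1e12)
  expect_lt(model2_closed_form(pinf, g14)$rho_nod, 1e-9)
  # defaults: hand-evaluated 14:7 density ratio
  p <- params2_const()
  ratio <- model2_closed_form(p, g14)$rho_nod /
    model2_closed_form(p, geom7())$rho_nod
  expect_equal(ratio, 1.824271, tolerance = 1e-5)
  # alpha = 0 with mu > 0 cuts the nodal flux without erroring
  expect_equal(model2_closed_form(params2_const(alpha = 0), g14)$rho_nod, 0)
  # no nodal region is singular
  expect_error(model2_closed_form(p, spherocylinder(14, 1.5, 0)),
               "singular")
})

test_that("modification-model numeric solution matches the closed form on a (mu, L) grid", {
  for (mu in c(0, 1e-4, 3e-3, 0.03, 0.3)) {
    for (L in c(7, 9, 11, 14)) {
      p <- modification_params(mu = mu)
      g <- spherocylinder(L, 1.5, 3)
      a <- model2_closed_form(p, g)
      b <- model2_numeric(p, g)
      expect_equal(b$rho_nod, a$rho_nod, tolerance = 1e-10)
      expect_equal(b$rho_cor, a$rho_cor, tolerance = 1e-10)
      expect_equal(b$rho_cyt_mod, a$rho_cyt_mod, tolerance = 1e-10)
    }
  }
  # stationarity of the modified pool: in = out
  p <- modification_params()
  g <- spherocylinder(10, 1.5, 3)
  s <- model2_numeric(p, g)
  N_mod <- s$rho_cyt_mod * g$V
  lhs <- p$nu * s$N_cor
  rhs <- p$mu * N_mod + p$alpha * (g$A_nod / g$V) * N_mod
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("model invariants: monotone scaling, nu/alpha -> 0 limit, prefactor linearity, mu -> 0 continuity", {
  Ls <- seq(7, 14, by = 0.5)
  p <- params1_const()
  dens <- vapply(Ls, function(L)
    model1_closed_form(p, spherocylinder(L, 1.5, 3))$rho_nod, numeric(1))
  expect_true(all(diff(dens) > 0))  # strictly increasing in L

  # nu/alpha -> 0: log-log slope of rho_nod vs A_cor is 1
  p_small <- params1_const(nu = 1e-12)
  ld <- vapply(Ls, function(L) {
    g <- spherocylinder(L, 1.5, 3)
    c(log(g$A_cor), log(model1_closed_form(p_small, g)$rho_nod))
  }, numeric(2))
  expect_equal(ols_closed_form(ld[1, ], ld[2, ])[["slope"]], 1,
               tolerance = 1e-6)

  # beta is a pure prefactor in both models
  g <- spherocylinder(11, 1.5, 3)
  s1 <- model1_closed_form(params1_const(beta = 1), g)
  s2 <- model1_closed_form(params1_const(beta = 2), g)
  expect_equal(s2$rho_nod, 2 * s1$rho_nod, tolerance = 1e-14)
  expect_equal(s2$rho_cor, 2 * s1$rho_cor, tolerance = 1e-14)
  m1 <- model2_closed_form(params2_const(beta = 1), g)
  m2 <- model2_closed_form(params2_const(beta = 2), g)
  expect_equal(m2$rho_nod, 2 * m1$rho_nod, tolerance = 1e-14)

  # modification model is continuous in mu at 0
  m0 <- model2_closed_form(params2_const(mu = 0), g)
  meps <- model2_closed_form(params2_const(mu = 1e-9), g)
  expect_lt(abs(meps$rho_nod / m0$rho_nod - 1), 1e-6)
})

test_that("scaling-prefactor fit recovers a known prefactor and degrades sanely", {
  Ls <- seq(7.5, 13.5, by = 1)
  p <- params1_const()
  shape <- vapply(Ls, function(L)
    model1_closed_form(p, spherocylinder(L, 1.5, 3))$rho_nod, numeric(1))
  set.seed(42)
  noisy <- 7.3 * shape * (1 + 0.02 * rnorm(length(shape)))
  fit <- fit_scaling_prefactor(Ls, noisy, model = "uniform", params = p)
  expect_lt(abs(coef(fit)[["prefactor"]] / 7.3 - 1), 0.05)
  # noise-free fit is perfect
  fit0 <- fit_scaling_prefactor(Ls, 7.3 * shape, model = "uniform",
                                params = p)
  expect_equal(fit0$r_squared, 1.0, tolerance = 1e-12)
  expect_equal(unname(predict(fit0, Ls)), 7.3 * shape, tolerance = 1e-10)
  # degenerate inputs
  expect_error(fit_scaling_prefactor(c(8, 9), c(1, 2)), "at least 3")
  expect_error(fit_scaling_prefactor(Ls, rep(0, length(Ls))), "zero")
})
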