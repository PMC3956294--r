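test_that("decay-length fit recovers the generating gradient", {
  # noiseless recovery is exact
  p <- gen_pom1_profiles(1.5, fluctuation_cv = 0, n = 1, seed = 1)[[1]]
  f <- fit_decay_length(p)
  expect_true(f$ok)
  expect_equal(f$lam, 1.5, tolerance = 1e-3)

  # flat profile is flagged, not fitted
  flat <- intensity_profile(seq(0, 6, 0.05), rep(2, 121),
                            kind = "tip-gradient")
  ff <- fit_decay_length(flat)
  expect_false(ff$ok)
  expect_true(is.na(ff$lam))

  # Monte-Carlo recovery at 5% noise: mean within 3% of truth
  ps <- gen_pom1_profiles(1.0, fluctuation_cv = 0.05, n = 100, seed = 7)
  lams <- vapply(ps, function(pp) fit_decay_length(pp)$lam, numeric(1))
  expect_lt(abs(mean(lams) / 1.0 - 1), 0.03)
})

test_that("node-band Gaussian fit recovers parameters and applies the width filter", {
  x <- seq(-5, 5, 0.05)
  clean <- intensity_profile(x, 10 * exp(-x^2 / (2 * 1.2^2)) + 1,
                             kind = "axial-band")
  f <- fit_node_band(clean)
  expect_true(f$accepted)
  expect_equal(coef(f), c(a = 10, x0 = 0, sigma = 1.2, b = 1),
               tolerance = 1e-6)
  expect_equal(f$r_squared, 1.0, tolerance = 1e-10)

  # a narrow (single-bright-node) band is fitted but rejected by the filter
  narrow <- intensity_profile(x, 10 * exp(-x^2 / (2 * 0.3^2)) + 1,
                              kind = "axial-band")
  fn <- fit_node_band(narrow)
  expect_lt(fn$sigma, 0.5)
  expect_false(fn$accepted)
  expect_match(fn$reason, "sigma")

  expect_error(fit_node_band(intensity_profile(1:4, c(1, 2, 2.5, 2),
                                               kind = "axial-band")),
               "at least 5")
})

test_that("width-filter yield on a batch calibrated to a 62% acceptance rate", {
  # 385 profiles where 148/385 carry a distorted narrow band and the rest
  # a genuine wide band, mimicking the observed filtering yield (-> 237)
  set.seed(101)
  n <- 385
  n_bad <- 148
  x <- seq(-4, 4, 0.1)
  sigma_true <- c(runif(n_bad, 0.15, 0.4), runif(n - n_bad, 0.7, 1.8))
  accepted <- vapply(seq_len(n), function(i) {
    I <- 8 * exp(-x^2 / (2 * sigma_true[i]^2)) + 1
    I <- I * (1 + 0.03 * rnorm(length(x)))
    fit_node_band(intensity_profile(x, I, kind = "axial-band"))$accepted
  }, logical(1))
  # binomial fluctuation around the calibrated yield
  expect_lt(abs(sum(accepted) - 237), 3 * sqrt(385 * 0.616 * 0.384))
})

test_that("medial band intensity is background-subtracted, exact on clean input, and additive", {
  x <- seq(-6, 6, 0.05)
  # pure background nets to zero
  bg <- intensity_profile(x, rep(1.3, length(x)), background = 1.3,
                          kind = "axial-band")
  expect_equal(medial_band_intensity(bg, width = 3)$total, 0,
               tolerance = 1e-12)

  # known band signal recovered
  g <- spherocylinder(12, 1.5, 3)
  ss <- model1_closed_form(uniform_params(cyt_slope = 0), g)
  p <- gen_cdr2_profile(list(L = 12, R = 1.5), ss, noise = 0, seed = 1,
                        band_shape = "uniform")
  m <- medial_band_intensity(p, width = 3)
  expect_equal(m$mean, ss$rho_cor + ss$rho_nod, tolerance = 1e-9)

  # full-width band equals whole-profile background-subtracted sum
  whole <- medial_band_intensity(p, width = 12)
  expect_equal(whole$total, sum(p$I - p$background), tolerance = 1e-9)

  # additivity over disjoint sub-bands (edges between sample points)
  left <- medial_band_intensity(p, width = 1.5, center = -0.775)
  right <- medial_band_intensity(p, width = 1.55, center = 0.75)
  both <- medial_band_intensity(p, width = 3.05, center = 0)
  expect_equal(left$n + right$n, both$n)
  expect_equal(left$total + right$total, both$total, tolerance = 1e-9)

  expect_error(medial_band_intensity(p, width = 30), "exceeds")
})

test_that("node detection counts thresholded maxima and documents merging", {
  x <- seq(0, 14, by = 0.05)
  bg <- 0.5
  peaks <- seq(2, 12, length.out = 7)
  I <- rep(bg, length(x))
  for (p0 in peaks) I <- I + 3 * exp(-(x - p0)^2 / (2 * 0.12^2))
  prof <- intensity_profile(x, I, background = bg, kind = "axial-band")
  expect_equal(find_nodes(prof)$count, 7)

  # all-background profile has no nodes
  flat <- intensity_profile(x, rep(bg, length(x)), background = bg,
                            kind = "axial-band")
  expect_equal(find_nodes(flat)$count, 0)

  # two peaks within one resolution element merge: documented undercount
  I2 <- bg + 3 * exp(-(x - 7)^2 / (2 * 0.3^2)) +
    3 * exp(-(x - 7.2)^2 / (2 * 0.3^2))
  expect_equal(find_nodes(intensity_profile(x, I2, background = bg,
                                            kind = "axial-band"))$count, 1)

  # count is non-decreasing as the threshold drops
  set.seed(3)
  In <- I * (1 + 0.02 * rnorm(length(x)))
  pn <- intensity_profile(x, In, background = bg, kind = "axial-band")
  counts <- vapply(c(4, 3, 2, 1, 0.5),
                   function(tf) find_nodes(pn, tf)$count, numeric(1))
  expect_true(all(diff(counts) >= 0))

  # plateaus count once, at the leftmost point
  xp <- seq(0, 10, 0.5)
  Ip <- rep(bg, length(xp))
  Ip[8:10] <- 4
  fp <- find_nodes(intensity_profile(xp, Ip, background = bg,
                                     kind = "axial-band"))
  expect_equal(fp$count, 1)
  expect_equal(fp$positions, xp[8])
})

test_that("FRAP fit inverts the generator and flags non-recovering traces", {
  # noiseless inversion is exact
  cl <- gen_frap(k = log(2) / 180, noise = 0, n = 1, seed = 1)[[1]]
  f <- fit_frap(cl$t, cl$I)
  expect_true(f$ok)
  expect_equal(f$t_half, 180, tolerance = 1e-6)

  # 14 noisy cells: mean recovered half-time within 10% of 3 min
  curves <- gen_frap(k = log(2) / 180, noise = 0.05, n = 14, seed = 5)
  th <- vapply(curves, function(cv) fit_frap(cv$t, cv$I)$t_half, numeric(1))
  expect_lt(abs(mean(th) / 180 - 1), 0.10)

  # flat and decreasing traces are flagged
  t <- seq(0, 600, length.out = 20)
  expect_false(fit_frap(t, rep(1, 20))$ok)
  expect_false(fit_frap(t, 2 - 0.001 * t)$ok)
  expect_error(fit_frap(1:4, 1:4), "at least 5")
})

test_that("molecule counting is a pure intensity ratio against the standard", {
  expect_equal(count_molecules(10, 10), 22)           # sample = standard
  expect_equal(count_molecules(4.09, 1), 89.98, tolerance = 1e-6)
  expect_equal(count_molecules(0, 5), 0)
  expect_error(count_molecules(1, 0), "positive")
  # whole-cell standard route
  expect_equal(count_molecules(2, 1, standard_count = 9600), 19200)
})

test_that("profile fits are invariant to intensity rescaling", {
  p <- gen_pom1_profiles(1.2, fluctuation_cv = 0.03, n = 1, seed = 9)[[1]]
  p2 <- intensity_profile(p$x, 37 * p$I, background = 37 * p$background,
                          kind = "tip-gradient")
  expect_equal(fit_decay_length(p2)$lam, fit_decay_length(p)$lam,
               tolerance = 1e-6)

  x <- seq(-5, 5, 0.05)
  set.seed(11)
  I <- (6 * exp(-x^2 / (2 * 1.1^2)) + 0.8) * (1 + 0.03 * rnorm(length(x)))
  f1 <- fit_node_band(intensity_profile(x, I, kind = "axial-band"))
  f2 <- fit_node_band(intensity_profile(x, 5 * I, kind = "axial-band"))
  expect_lt(abs(f2$x0 - f1$x0), 1e-4)        # absolute: x0 is near zero
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-5)
})

test_that("parameter recovery across a seeded (lambda, sigma, k) sweep stays within 5% median error", {
  set.seed(77)
  errs <- c()
  for (lam in c(0.8, 1.1, 1.5)) {
    p <- gen_pom1_profiles(lam, fluctuation_cv = 0.05, n = 5,
                           seed = round(1000 * lam))
    errs <- c(errs, vapply(p, function(pp)
      abs(fit_decay_length(pp)$lam / lam - 1), numeric(1)))
  }
  x <- seq(-5, 5, 0.05)
  for (sg in c(0.8, 1.2, 1.6)) {
    for (i in 1:5) {
      I <- (9 * exp(-x^2 / (2 * sg^2)) + 1) * (1 + 0.05 * rnorm(length(x)))
      errs <- c(errs, abs(fit_node_band(intensity_profile(
        x, I, kind = "axial-band"))$sigma / sg - 1))
    }
  }
  for (k in log(2) / c(120, 180, 300)) {
    curves <- gen_frap(k, noise = 0.05, n = 5, seed = round(1e5 * k))
    errs <- c(errs, vapply(curves, function(cv)
      abs(fit_frap(cv$t, cv$I)$k / k - 1), numeric(1)))
  }
  expect_lt(median(errs), 0.05)
})

test_that("cortical loops convert to tip-distance profiles consistently", {
  # uniform loop: every sector keeps the uniform level
  lp <- gen_cortical_loop(list(L = 12, R = 1.5), lambda = Inf, noise = 0,
                          seed = 2, background = 0)
  cp <- cortical_profile_by_angle(lp, sectors = 100, L = 12, R = 1.5)
  expect_equal(cp$intensity, rep(1, 100), tolerance = 1e-12)
  expect_false(any(cp$missing))

  # painted tip gradient is recovered within binning error
  lp2 <- gen_cortical_loop(list(L = 12, R = 1.5), lambda = 1.5, noise = 0,
                           seed = 3, background = 0, n_points = 2000)
  cp2 <- cortical_profile_by_angle(lp2, sectors = 100, L = 12, R = 1.5)
  half_perim <- (12 - 3) + pi * 1.5
  d_near <- pmin(cp2$distance_um, half_perim - cp2$distance_um)
  expect_lt(max(abs(cp2$intensity - exp(-d_near / 1.5))), 0.05)

  # angle pi maps to the far tip (half-perimeter distance); monotone to there
  expect_equal(nodescale:::stadium_tip_distance(pi, 12, 1.5), half_perim,
               tolerance = 1e-9)
  expect_equal(nodescale:::stadium_tip_distance(0, 12, 1.5), 0,
               tolerance = 1e-9)
  th <- seq(0, pi, length.out = 200)
  expect_true(all(diff(nodescale:::stadium_tip_distance(th, 12, 1.5)) > 0))

  # empty sectors are flagged missing, not interpolated
  sparse <- intensity_profile(c(0.1, 0.2, 3.3), c(1, 1, 2),
                              kind = "cortical-loop")
  cps <- cortical_profile_by_angle(sparse, sectors = 100, L = 12, R = 1.5)
  expect_true(any(cps$missing))
  expect_true(all(is.na(cps$intensity[cps$missing])))
})

test_that("profiles round-trip through the CSV dialect with metadata", {
  p <- gen_pom1_profiles(1.5, 0.02, n = 1, seed = 4)[[1]]
  tf <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(p, tf, cell_id = "cell_007")
  back <- read_profile_csv(tf)
  expect_equal(back$x, p$x)
  expect_equal(back$I, p$I)
  expect_equal(back$background, p$background)
  expect_equal(back$kind, p$kind)
  expect_equal(attr(back, "cell_id"), "cell_007")
})
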