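test_that("zero concentration and zero noise reproduce the flesh spectrum", {
  lib <- endmember_library()
  ph <- tiny_phantom(concentration = 0)
  roi <- ph$masks$roi$data
  px <- cube_to_matrix(ph$cube, roi)
  expect_equal(max(abs(sweep(px, 2, lib$flesh_base))), 0)
})

test_that("Beer-Lambert attenuation matches the hand-computed factor", {
  lib <- endmember_library()
  ph <- tiny_phantom(concentration = 2)
  px <- cube_to_matrix(ph$cube, ph$masks$roi$data)
  expected <- lib$flesh_base * 10^(-2 * lib$astax_absorptivity)
  expect_equal(colMeans(px), expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  # explicit factor: absorbance 0.05 * 2 = 0.1 attenuates by 10^-0.1
  eps <- 0.05; c0 <- 2
  expect_equal(10^(-c0 * eps), 0.7943282, tolerance = 1e-7)
})

test_that("doubling concentration darkens exactly the absorbing bands", {
  lib <- endmember_library()
  s1 <- colMeans(cube_to_matrix(tiny_phantom(2)$cube,
                                tiny_phantom(2)$masks$roi$data))
  s2 <- colMeans(cube_to_matrix(tiny_phantom(4)$cube,
                                tiny_phantom(4)$masks$roi$data))
  absorbing <- lib$astax_absorptivity > 1e-9
  expect_true(all(s2[absorbing] < s1[absorbing]))
  # bands with (numerically) zero absorptivity are unchanged
  expect_equal(s2[!absorbing], s1[!absorbing], tolerance = 1e-8)
})

test_that("ground-truth masks partition the image", {
  ph <- tiny_phantom(noise_sd = 0.01)
  m <- ph$masks
  expect_true(all(xor(m$background$data, m$fillet$data)))
  expect_true(all(m$fat$data <= m$fillet$data))   # fat subset of fillet
  expect_true(!any(m$roi$data & m$fat$data))
  expect_identical(m$roi$data, m$fillet$data & !m$fat$data)
})

test_that("the concentration field averages to the nominal value", {
  # the normalization is defined over all fillet pixels, so use a
  # fat-free phantom where fillet == flesh and the stored map covers it
  for (amp in c(0, 0.2, 0.5)) {
    ph <- render_phantom(phantom_spec(height = 40, width = 50,
                                      concentration = 1.7, fat_stripes = 0,
                                      gradient_amplitude = amp,
                                      noise_sd = 0))
    expect_equal(mean(ph$concentration_map[ph$masks$fillet$data]), 1.7,
                 tolerance = 1e-6)
  }
})

test_that("an ellipse exceeding the image bounds is a geometry error", {
  expect_error(phantom_spec(height = 30, width = 30,
                            semi_axes = c(20, 10)), "geometry error")
  # all-background phantom is allowed
  ph <- render_phantom(phantom_spec(height = 20, width = 20,
                                    semi_axes = c(0, 0), noise_sd = 0))
  expect_false(any(ph$masks$fillet$data))
})

test_that("truncated normal sampling is bounded, seeded and degenerate-safe", {
  x <- truncated_normal_sample(5000, 1.69, 0.95, 0.2, 4.34, seed = 42)
  y <- truncated_normal_sample(5000, 1.69, 0.95, 0.2, 4.34, seed = 42)
  expect_identical(x, y)
  expect_true(all(x >= 0.2 & x <= 4.34))
  z <- truncated_normal_sample(200, 1.5, 1e-9, 0.2, 4.34, seed = 1)
  expect_equal(z, rep(1.5, 200), tolerance = 1e-6)
  expect_error(truncated_normal_sample(10, 1, 1, 2, 2), "domain error")
  expect_error(truncated_normal_sample(10, 1, -1, 0, 2), "domain error")
})

test_that("empirical CDF matches the analytic truncated-normal CDF", {
  mu <- 1.3; sg <- 1.1; lo <- 0.2; hi <- 4.34
  x <- truncated_normal_sample(1e5, mu, sg, lo, hi, seed = 7)
  grid <- seq(lo, hi, length.out = 400)
  analytic <- (pnorm(grid, mu, sg) - pnorm(lo, mu, sg)) /
    (pnorm(hi, mu, sg) - pnorm(lo, mu, sg))
  emp <- ecdf(x)(grid)
  expect_lt(max(abs(emp - analytic)), 0.01)
})

test_that("closed-form truncated moments agree with quadrature", {
  for (p in list(c(1.69, 0.95), c(1.176, 1.37), c(0.5, 2))) {
    cf <- truncated_normal_moments(p[1], p[2], 0.2, 4.34)
    qd <- truncnorm_moments_quadrature(p[1], p[2], 0.2, 4.34)
    expect_equal(cf, qd, tolerance = 1e-9)
  }
})

test_that("moment matching calibrates the parent to the target moments", {
  fit <- match_truncated_normal(1.69, 0.95, 0.2, 4.34)
  m <- truncnorm_moments_quadrature(fit$mean, fit$sd, 0.2, 4.34)
  expect_equal(unname(m["mean"]), 1.69, tolerance = 1e-5)
  expect_equal(unname(m["sd"]), 0.95, tolerance = 1e-5)
})

test_that("large cohorts land within 3 SE of the quadrature mean", {
  cs <- cohort_spec(seed = 5)
  x <- truncated_normal_sample(10000, cs$parent$mean, cs$parent$sd,
                               0.2, 4.34, seed = 5)
  qd <- truncnorm_moments_quadrature(cs$parent$mean, cs$parent$sd, 0.2, 4.34)
  se <- qd["sd"] / sqrt(10000)
  expect_lt(abs(mean(x) - qd["mean"]), 3 * se)
})

test_that("cohort generation is reproducible and correctly split", {
  cs <- cohort_spec(n_samples = 6, n_train = 3, n_test = 3,
                    height = 30, width = 40, seed = 9)
  a <- generate_cohort(cs)
  b <- generate_cohort(cs)
  expect_identical(a$reference, b$reference)
  expect_identical(a$samples[[3]]$cube$data, b$samples[[3]]$cube$data)
  expect_length(a$samples, 6)
  expect_true(all(a$concentrations >= 0.2 & a$concentrations <= 4.34))
  expect_equal(a$reference$concentration,
               (a$reference$replicate_a + a$reference$replicate_b) / 2)
  expect_error(cohort_spec(n_samples = 10, n_train = 4, n_test = 5),
               "n_train")
  expect_error(cohort_spec(conc_range = c(2, 2)), "domain error")
})

test_that("between-sample spectral variance peaks in the blue-green", {
  cs <- cohort_spec(n_samples = 20, n_train = 10, n_test = 10,
                    height = 30, width = 40, noise_sd = 0.002, seed = 3)
  co <- generate_cohort(cs)
  X <- do.call(rbind, lapply(co$samples, function(s)
    extract_mean_spectrum(s$cube, s$masks$roi)))
  wl <- videometer_bands()$wavelengths_nm
  peak <- wl[which.max(apply(X, 2, var))]
  expect_gte(peak, 450)
  expect_lte(peak, 525)
})
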