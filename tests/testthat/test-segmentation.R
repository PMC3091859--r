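test_that("Otsu separates a perfectly bimodal sample", {
  v <- c(0, 0, 0, 10, 10, 10)
  thr <- otsu_threshold(v)
  expect_gt(thr, 0)
  expect_lte(thr, 10)
  expect_identical(v > thr, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("Otsu equals the exhaustive between-class-variance search", {
  for (s in 1:20) {
    set.seed(200 + s)
    v <- c(rnorm(150, 0, 1), rnorm(100, 4 + s %% 3, 0.5 + 0.1 * (s %% 4)))
    expect_equal(otsu_threshold(v), otsu_oracle(v), tolerance = 1e-10)
  }
})

test_that("the Otsu threshold is equivariant under affine maps", {
  set.seed(21)
  v <- c(rnorm(200, 0), rnorm(120, 3))
  t0 <- otsu_threshold(v)
  for (ab in list(c(2, 5), c(0.3, -1), c(10, 0))) {
    t1 <- otsu_threshold(ab[1] * v + ab[2])
    expect_equal(t1, ab[1] * t0 + ab[2], tolerance = 1e-10)
  }
})

test_that("constant input is a degenerate-input error for Otsu", {
  expect_error(otsu_threshold(rep(3, 10)), "degenerate")
  expect_error(otsu_threshold(2), "degenerate")
})

test_that("fillet segmentation recovers the phantom mask", {
  ph <- render_phantom(phantom_spec(noise_sd = 0.01, seed = 1,
                                    concentration = 2))
  seg <- segment_fillet(ph$cube)
  acc <- mean(seg$fillet$data == ph$masks$fillet$data)
  expect_gte(acc, 0.99)
  expect_true(is.logical(seg$fillet$data))
  expect_identical(dim(seg$fillet$data), dim(ph$cube$data)[1:2])
  expect_identical(seg$background$data, !seg$fillet$data)
})

test_that("an all-background image is a segmentation error", {
  ph <- render_phantom(phantom_spec(height = 30, width = 30,
                                    semi_axes = c(0, 0), noise_sd = 0.01))
  expect_error(segment_fillet(ph$cube), "degenerate|segmentation error")
})

test_that("fat segmentation overlaps the ground truth", {
  ph <- render_phantom(phantom_spec(noise_sd = 0.01, seed = 2,
                                    concentration = 2))
  seg <- segment_fillet(ph$cube)
  fat <- segment_fat(ph$cube, seg$fillet,
                     list(meat = ph$masks$roi$data, fat = ph$masks$fat$data))
  dice <- 2 * sum(fat$data & ph$masks$fat$data) /
    (sum(fat$data) + sum(ph$masks$fat$data))
  expect_gte(dice, 0.9)
})

test_that("a fat classifier finds almost no fat on a stripe-free fillet", {
  # train the canonical discriminant and its threshold on a striped
  # phantom, then apply the decision rule to a phantom without stripes
  donor <- render_phantom(phantom_spec(noise_sd = 0.005, seed = 4,
                                       concentration = 2))
  X_donor <- cube_to_matrix(donor$cube)
  idx <- c(which(donor$masks$roi$data), which(donor$masks$fat$data))
  labels <- rep(c("meat", "fat"), c(sum(donor$masks$roi$data),
                                    sum(donor$masks$fat$data)))
  dec <- cda(X_donor[idx, ], labels, k = 1)
  donor_fil <- donor$masks$fillet$data
  donor_cv <- sweep(X_donor, 2, dec$center) %*% dec$vectors
  thr <- otsu_threshold(donor_cv[as.vector(donor_fil)])
  fat_is_upper <- mean(donor_cv[as.vector(donor$masks$fat$data)]) > thr

  ph <- render_phantom(phantom_spec(noise_sd = 0.005, seed = 3,
                                    fat_stripes = 0, concentration = 2))
  fil <- segment_fillet(ph$cube)$fillet$data
  cv <- matrix(sweep(cube_to_matrix(ph$cube), 2, dec$center) %*% dec$vectors,
               nrow(fil), ncol(fil))
  fat_found <- fil & (if (fat_is_upper) cv > thr else cv <= thr)
  expect_lte(sum(fat_found) / sum(fil), 0.01)
})

test_that("the fat discriminant leans on the blue end of the spectrum", {
  ph <- render_phantom(phantom_spec(noise_sd = 0.01, seed = 5,
                                    concentration = 2))
  X <- cube_to_matrix(ph$cube)
  idx <- c(which(ph$masks$roi$data), which(ph$masks$fat$data))
  labels <- rep(c("meat", "fat"), c(sum(ph$masks$roi$data),
                                    sum(ph$masks$fat$data)))
  w <- cda(X[idx, ], labels, k = 1)$vectors[, 1]
  wl <- videometer_bands()$wavelengths_nm
  blue_mass <- sum(abs(w[wl <= 570])) / sum(abs(w))
  expect_gt(blue_mass, 0.5)
})

test_that("mean-spectrum extraction matches a direct loop", {
  ph <- tiny_phantom(noise_sd = 0.02)
  roi <- ph$masks$roi$data
  sp <- extract_mean_spectrum(ph$cube, roi)
  manual <- numeric(dim(ph$cube$data)[3])
  for (b in seq_along(manual)) {
    plane <- ph$cube$data[, , b]
    manual[b] <- sum(plane[roi]) / sum(roi)
  }
  expect_equal(unname(sp), manual, tolerance = 1e-12)
})

test_that("mean-spectrum extraction handles constants and single pixels", {
  b <- band_set(c(450, 650))
  arr <- array(0.37, dim = c(4, 4, 2))
  cube <- spectral_cube(arr, b)
  m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE; m[3, 1] <- TRUE
  expect_equal(unname(extract_mean_spectrum(cube, m)), c(0.37, 0.37))
  one <- matrix(FALSE, 4, 4); one[1, 4] <- TRUE
  arr[1, 4, ] <- c(0.1, 0.9)
  cube2 <- spectral_cube(arr, b)
  expect_equal(unname(extract_mean_spectrum(cube2, one)), c(0.1, 0.9))
  expect_error(extract_mean_spectrum(cube, matrix(FALSE, 4, 4)), "empty roi")
})

test_that("mean-spectrum extraction is linear in the cube", {
  b <- band_set(c(450, 650))
  a1 <- array(runif(32), dim = c(4, 4, 2))
  a2 <- array(runif(32), dim = c(4, 4, 2))
  m <- matrix(c(TRUE, FALSE), 4, 4)
  s12 <- extract_mean_spectrum(spectral_cube(a1 + a2, b), m)
  s1 <- extract_mean_spectrum(spectral_cube(a1, b), m)
  s2 <- extract_mean_spectrum(spectral_cube(a2, b), m)
  expect_equal(s12, s1 + s2, tolerance = 1e-12)
})

test_that("roi spectra track the noiseless forward model within noise", {
  lib <- endmember_library()
  noise_sd <- 0.02
  ph <- render_phantom(phantom_spec(concentration = 1.5, noise_sd = noise_sd,
                                    seed = 6))
  roi <- ph$masks$roi$data
  sp <- extract_mean_spectrum(ph$cube, roi)
  ideal <- lib$flesh_base * 10^(-1.5 * lib$astax_absorptivity)
  # gradient defaults to 0 and the field is flat, so the roi mean equals
  # the forward model up to averaged noise
  tol <- 3 * noise_sd / sqrt(sum(roi))
  expect_true(all(abs(sp - ideal) < tol + 1e-12))
})
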