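test_that("generated fields hit the target density and respect the hard core", {
  f <- generate_field(c(50, 50, 50), rho = 0.03, min_sep = 1.8, seed = 101)
  n <- nrow(f$centers)
  # Poisson mean 3750: allow 5 sigma
  expect_gt(n, 3750 - 5 * sqrt(3750))
  expect_lt(n, 3750 + 5 * sqrt(3750))
  expect_gte(min(stats::dist(f$centers)), f$min_sep)
  expect_true(all(f$centers >= 0 & f$centers <= 50))
})

test_that("field generation is reproducible and can return empty fields", {
  f1 <- generate_field(c(10, 10, 10), rho = 0.01, seed = 7)
  f2 <- generate_field(c(10, 10, 10), rho = 0.01, seed = 7)
  expect_identical(f1$centers, f2$centers)
  expect_identical(f1$radii, f2$radii)

  # expected count << 1 in a tiny region: empty field is fine
  f0 <- generate_field(c(2.1, 2.1, 2.1), rho = 1e-4, seed = 1)
  expect_gte(nrow(f0$centers), 0)

  expect_error(generate_field(c(5, 5, 5), rho = 1, min_sep = 4, seed = 1),
               "packing infeasible")
})

test_that("rendered stacks are reproducible byte for byte", {
  f <- generate_field(c(8, 8, 8), rho = 0.02, seed = 3)
  spec <- render_spec(psf = anisotropic_psf(0.3), photon_scale = 100,
                      read_noise_sd = 0.01)
  s1 <- render_stack(f, spec, voxel_size = c(0.4, 0.34, 0.34), seed = 9)
  s2 <- render_stack(f, spec, voxel_size = c(0.4, 0.34, 0.34), seed = 9)
  expect_identical(s1$data, s2$data)
})

test_that("a bouton rendered with a delta PSF is isotropic; with an anisotropic PSF it elongates axially", {
  second_moments <- function(grid) {
    img <- grid$data
    d <- dim(img)
    w <- img / sum(img)
    vapply(1:3, function(a) {
      cc <- (seq_len(d[a]) - 0.5) * grid$voxel_size[a]
      p <- apply(w, a, sum)
      mu <- sum(p * cc)
      sum(p * (cc - mu)^2)
    }, numeric(1))
  }
  f <- manual_field(c(10, 4, 4), radii = 0.9, region = c(20, 8, 8))
  iso <- render_stack(f, render_spec(), voxel_size = c(0.1, 0.1, 0.1))
  m <- second_moments(iso)
  expect_equal(sqrt(m[1]) / sqrt(mean(m[2:3])), 1, tolerance = 0.02)

  # point-like bouton under sigma_z/sigma_xy = 3.84: image extent ratio
  # approaches the 3.3/0.86 axial-to-lateral size ratio
  fp <- manual_field(c(10, 4, 4), radii = 0.1, region = c(20, 8, 8))
  ani <- render_stack(fp, render_spec(psf = anisotropic_psf(0.3)),
                      voxel_size = c(0.05, 0.05, 0.05))
  ma <- second_moments(ani)
  expect_equal(sqrt(ma[1]) / sqrt(mean(ma[2:3])), 3.3 / 0.86, tolerance = 0.05)
})

test_that("depth attenuation decays slice means exponentially and matched compensation cancels it", {
  f <- generate_field(c(40, 20, 20), rho = 0.0256, min_sep = 1.8, seed = 3)
  slope_of <- function(spec) {
    st <- render_stack(f, spec, voxel_size = c(0.4, 0.4, 0.4), seed = 3)
    z <- (seq_len(dim(st$data)[1]) - 0.5) * 0.4
    mz <- apply(st$data, 1, mean)
    unname(stats::coef(stats::lm(log(mz[mz > 0]) ~ z[mz > 0]))[2])
  }
  s_none <- slope_of(render_spec())
  s_att <- slope_of(render_spec(attenuation_length = 100))
  s_comp <- slope_of(render_spec(attenuation_length = 100,
                                 compensation = matched_compensation(100, 0, 40)))
  # attenuation adds exactly -1/d to the structural slope
  expect_equal(s_att - s_none, -1 / 100, tolerance = 1e-6)
  # matched compensation restores the unattenuated profile
  expect_equal(s_comp, s_none, tolerance = 1e-6)
})

test_that("ROI counting rules nest and match their oracles", {
  sides <- c(10, 14)
  reps <- lapply(1:12, function(s) {
    f <- generate_field(c(24, 24, 24), rho = 0.02, min_sep = 1.8, seed = 300 + s)
    ci <- simulate_roi_counts(f, sides, rule = "intersect")
    cc <- simulate_roi_counts(f, sides, rule = "center")
    set.seed(s)
    cm <- simulate_roi_counts(f, sides, rule = "majority", mc_samples = 2000)
    # intersect-inside dominates center-inside for every field
    expect_true(all(ci$count >= cc$count))
    expect_true(all(ci$count >= cm$count))
    list(ci = ci$count, cc = cc$count)
  })
  ci <- colMeans(do.call(rbind, lapply(reps, `[[`, "ci")))
  cc <- colMeans(do.call(rbind, lapply(reps, `[[`, "cc")))
  # Minkowski-sum closed form for the mean intersect-inside count
  expected <- expected_intersect_count(sides, 0.02, 0.9)
  expect_equal(ci, expected, tolerance = 0.12)
  # center-inside is unbiased: mean = rho V
  expect_equal(cc, 0.02 * sides^3, tolerance = 0.12)
})

test_that("the relative boundary excess approximates 6 r / L", {
  # the premise of the surface-scaling correction, checked in silico
  excess <- vapply(1:15, function(s) {
    f <- generate_field(c(36, 36, 36), rho = 0.02, min_sep = 1.8,
                        seed = 400 + s)
    ci <- simulate_roi_counts(f, 20, rule = "intersect")$count
    cc <- simulate_roi_counts(f, 20, rule = "center")$count
    (ci - cc) / cc
  }, numeric(1))
  expect_equal(mean(excess), 6 * 0.9 / 20, tolerance = 0.2)
})

test_that("ROIs violating the field margins are rejected", {
  f <- generate_field(c(10, 10, 10), rho = 0.02, seed = 2)
  expect_error(simulate_roi_counts(f, list(roi_spec(c(8, 8, 8), 4))),
               "exceeds")
  expect_error(simulate_roi_counts(f, 10, rule = "intersect"), "margin")
  # zero boutons -> zero counts
  f0 <- generate_field(c(12, 12, 12), rho = 1e-5, seed = 4)
  if (nrow(f0$centers) == 0)
    expect_equal(simulate_roi_counts(f0, 6, rule = "center")$count, 0)
})
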