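# Layered-sample averaging, curve simulation, seeded force-volume
# generation with ground truth.

test_that("discrete slice averaging: two-layer oracle and partial slices", {
  s <- layered_sample(E_slices = c(10e3, 5e3), dh = 100e-9)
  # (10*100 + 5*100) / 200 = 7.5 kPa
  expect_rel_equal(average_modulus_of_sample(s, 200e-9), 7500, tol = 1e-12)
  # within the first slice the average is the slice value
  expect_rel_equal(average_modulus_of_sample(s, 60e-9), 10e3, tol = 1e-12)
  # partial second slice: (10*100 + 5*50) / 150
  expect_rel_equal(average_modulus_of_sample(s, 150e-9),
                   (10e3 * 100 + 5e3 * 50) / 150, tol = 1e-12)
  expect_error(average_modulus_of_sample(s, 300e-9), "beyond")
  expect_error(layered_sample(E_slices = c(1e3, -1), dh = 1e-9), ">= 0")
})

test_that("continuous averaging: constant function and quadrature accuracy", {
  s <- layered_sample(E_fun = function(y) rep(42e3, length(y)), depth_max = 1e-6)
  for (h in c(1e-9, 3.3e-7, 1e-6))
    expect_rel_equal(average_modulus_of_sample(s, h), 42e3, tol = 1e-9)
  # linear ramp E(y) = E0 + k y has closed-form average E0 + k h / 2
  E0 <- 5e3; k <- 2e13
  sl <- layered_sample(E_fun = function(y) E0 + k * y, depth_max = 1e-6)
  for (h in c(1e-7, 5e-7, 1e-6))
    expect_rel_equal(average_modulus_of_sample(sl, h), E0 + k * h / 2,
                     tol = 1e-9)
})

test_that("discrete refinement converges to the continuous average at O(dh)", {
  E_fun <- function(y) 30e3 * exp(-y / 400e-9) + 3e3
  h <- 800e-9
  cont <- average_modulus_of_sample(
    layered_sample(E_fun = E_fun, depth_max = 1e-6), h)
  err <- sapply(c(8, 32, 128), function(N) {
    dh <- h / N
    centers <- (seq_len(N) - 0.5) * dh
    disc <- layered_sample(E_slices = E_fun(centers), dh = dh)
    abs(average_modulus_of_sample(disc, h) - cont)
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[3] / cont, 1e-4)
})

test_that("monotone modulus functions give monotone averages", {
  dec <- layered_sample(E_fun = function(y) 20e3 * exp(-y / 2e-7), depth_max = 1e-6)
  inc <- layered_sample(E_fun = function(y) 5e3 + 1e13 * y, depth_max = 1e-6)
  hs <- seq(50e-9, 1e-6, length.out = 12)
  expect_true(all(diff(average_modulus_of_sample(dec, hs)) < 0))
  expect_true(all(diff(average_modulus_of_sample(inc, hs)) > 0))
})

test_that("simulate_curve: noiseless round-trips and determinism contract", {
  dg <- seq(0, 800e-9, length.out = 65)
  # constant modulus: windowed fit recovers it at every depth
  cu <- simulate_curve(20e3, geom_par(), 0.5, dg)
  for (d in c(200e-9, 800e-9))
    expect_rel_equal(as.numeric(fit_average_modulus(cu, geom_par(), 0.5, d)),
                     20e3, tol = 1e-9)
  expect_equal(cu$metadata$ground_truth$E_avg, rep(20e3, 65))
  # power-law profile: pointwise estimator reproduces it exactly at samples
  prof <- power_law_profile(50, -0.5, 5)
  cu2 <- simulate_curve(prof, geom_par(), 0.5, dg)
  d <- dg[c(17, 49)]
  expect_rel_equal(
    sapply(d, function(x) pointwise_average_modulus(cu2, geom_par(), 0.5, x)),
    prof(d), tol = 1e-9)
  # layered sample drives the force through its depth-average
  s <- layered_sample(E_slices = c(10e3, 5e3), dh = 400e-9)
  cu3 <- simulate_curve(s, geom_par(), 0.5, dg)
  expect_rel_equal(
    pointwise_average_modulus(cu3, geom_par(), 0.5, 800e-9), 7500, tol = 1e-9)
  # seeded noise: same seed bit-identical, different seed differs
  nz <- list(multiplicative = 0.02, additive = 0.01)
  a <- simulate_curve(20e3, geom_par(), 0.5, dg, noise = nz, seed = 7)
  b <- simulate_curve(20e3, geom_par(), 0.5, dg, noise = nz, seed = 7)
  c_ <- simulate_curve(20e3, geom_par(), 0.5, dg, noise = nz, seed = 8)
  expect_identical(a$F, b$F)
  expect_false(identical(a$F, c_$F))
  expect_error(simulate_curve(20e3, geom_par(), 0.5, dg, noise = nz), "seed")
  # exact Sneddon option for constant-modulus spheres
  cu4 <- simulate_curve(20e3, geom_sph(), 0.5, dg, sphere_exact = TRUE)
  expect_rel_equal(cu4$F[-1],
                   force_sneddon_sphere(elastic_params(20e3), geom_sph(), dg[-1]),
                   tol = 1e-12)
  expect_error(simulate_curve(prof, geom_sph(), 0.5, dg, sphere_exact = TRUE),
               "constant")
})

test_that("uniform synthetic field processes to uniform maps", {
  spec <- synthetic_field_spec(4, 4, list(type = "uniform", E = 20e3),
                               geom_par(), h_max = 600e-9, n_samples = 48,
                               seed = 3)
  sim <- simulate_force_volume(spec)
  stack <- build_depth_maps(sim$grid, geom_par(), 0.5, c(150e-9, 450e-9))
  for (m in stack$maps)
    expect_rel_equal(as.numeric(m$values), rep(20e3, 16), tol = 1e-9)
  # ground-truth stack records the same constants
  expect_true(all(abs(sim$truth$maps[[1]]$values - 20e3) < 1e-9))
})

test_that("normal field: recovered map matches field mean/SD within 3 SE", {
  mu <- kpa_to_pa(8.46); sd_ <- kpa_to_pa(2.78)
  spec <- synthetic_field_spec(8, 8, list(type = "normal", mu = mu, sd = sd_),
                               geom_par(), h_max = 400e-9, n_samples = 48,
                               noise = list(multiplicative = 0.01, additive = 0.005),
                               seed = 21)
  sim <- simulate_force_volume(spec)
  stack <- build_depth_maps(sim$grid, geom_par(), 0.5, 300e-9)
  got <- fit_gaussian(stack$maps[[1]]$values, 300e-9)
  truth_vals <- sim$truth$maps[[1]]$values
  n <- length(truth_vals)
  expect_lt(abs(got$mu - mean(truth_vals)), 3 * sd(truth_vals) / sqrt(n))
  expect_lt(abs(got$sigma - sd(truth_vals)), 3 * sd(truth_vals) / sqrt(2 * n))
})

test_that("same master seed regenerates an identical grid", {
  spec <- synthetic_field_spec(3, 3, list(type = "uniform", E = 10e3),
                               geom_par(), h_max = 500e-9, n_samples = 32,
                               noise = list(multiplicative = 0.02, additive = 0),
                               seed = 77)
  g1 <- simulate_force_volume(spec)$grid
  g2 <- simulate_force_volume(spec)$grid
  for (i in seq_along(g1$curves))
    expect_identical(g1$curves[[i]]$F, g2$curves[[i]]$F)
  # pixels use distinct substreams
  expect_false(identical(g1$curves[[1]]$F, g1$curves[[2]]$F))
})

test_that("inclusion phantom isolated by threshold masking", {
  spec <- synthetic_field_spec(
    6, 6, list(type = "inclusion", E = 8e3, E_inclusion = 24e3,
               rows = c(2, 3), cols = c(2, 3)),
    geometry = geom_par(), h_max = 500e-9, n_samples = 48,
    noise = list(multiplicative = 0.01, additive = 0), seed = 13)
  sim <- simulate_force_volume(spec)
  stack <- build_depth_maps(sim$grid, geom_par(), 0.5, 400e-9)
  masked <- mask_by_threshold(stack, list(max = 16e3))
  want <- matrix(FALSE, 6, 6); want[3:4, 3:4] <- TRUE
  expect_identical(masked$maps[[1]]$mask, want)
})
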