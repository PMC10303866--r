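test_that("uniform mode is flat background inside the nucleus, zero outside", {
  p <- image_sim_params(mode = "uniform", n_fibers = 0,
                        poisson_noise = FALSE, seed = 4L)
  sim <- simulate_nucleus_image(p)
  img <- sim$image
  inside <- img$nucleus_mask & !img$exclusion_mask
  expect_true(all(img$intensity[inside] == p$background))
  expect_true(all(img$intensity[!img$nucleus_mask] == 0))
  expect_identical(nrow(sim$truth), 0L)
})

test_that("planted beads sit at exact arc-length spacing when jitter is off", {
  sim <- simulate_nucleus_image(image_sim_params(spacing_jitter_sd = 0,
                                                 seed = 2L))
  for (f in unique(sim$truth$fiber)) {
    arc <- sim$truth$arc_um[sim$truth$fiber == f]
    if (length(arc) >= 2)
      expect_equal(diff(arc), rep(0.34, length(arc) - 1), tolerance = 1e-9)
  }
})

test_that("image generation is a pure function of its seed", {
  p <- image_sim_params(seed = 9L)
  a <- simulate_nucleus_image(p)
  b <- simulate_nucleus_image(p)
  expect_identical(a$image$intensity, b$image$intensity)
  expect_identical(a$truth, b$truth)
})

test_that("integrated bead signal scales linearly with bead count", {
  # noise-free: total above-background intensity per bead is constant
  sums <- vapply(c(1L, 3L), function(nf) {
    sim <- simulate_nucleus_image(image_sim_params(
      n_fibers = nf, poisson_noise = FALSE, seed = 20L + nf))
    img <- sim$image
    sum(img$intensity) - 30 * sum(img$nucleus_mask & !img$exclusion_mask)
  }, numeric(1))
  counts <- vapply(c(1L, 3L), function(nf)
    nrow(simulate_nucleus_image(image_sim_params(
      n_fibers = nf, poisson_noise = FALSE, seed = 20L + nf))$truth),
    numeric(1))
  expect_equal(sums[2] / sums[1], counts[2] / counts[1], tolerance = 0.02)
})

test_that("at high SNR nearly every planted bead is a local maximum", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    sim <- simulate_nucleus_image(image_sim_params(seed = s))  # SNR >> 10
    x <- sim$image$intensity
    for (i in seq_len(nrow(sim$truth))) {
      r <- round(sim$truth$x[i]); c <- round(sim$truth$y[i])
      win <- x[max(1, r - 2):min(nrow(x), r + 2),
               max(1, c - 2):min(ncol(x), c + 2)]
      ctr <- x[max(1, r - 1):min(nrow(x), r + 1),
               max(1, c - 1):min(ncol(x), c + 1)]
      total <- total + 1
      if (max(ctr) == max(win)) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.99)
})

test_that("unresolvable bead spacing and tiny nuclei are rejected", {
  expect_error(image_sim_params(bead_spacing = 0.08, psf_sigma = 0.05),
               "resolvable")
  expect_error(simulate_nucleus_image(image_sim_params(height = 16,
                                                       width = 16)),
               "PSF")
})

test_that("nucleolus exclusion masks contain no planted beads", {
  sim <- simulate_nucleus_image(image_sim_params(nucleolus_count = 2,
                                                 seed = 5L))
  excl <- sim$image$exclusion_mask
  if (nrow(sim$truth)) {
    at <- cbind(pmax(1, pmin(nrow(excl), round(sim$truth$x))),
                pmax(1, pmin(ncol(excl), round(sim$truth$y))))
    expect_false(any(excl[at]))
  }
  expect_gt(sum(excl), 0)
})

test_that("FRAP traces follow the biexponential model exactly when noise-free", {
  p <- frap_sim_params(A = 0.3, B = 0.5, tauA = 2, tauB = 30, dt = 1,
                       n_pre = 3, n_post = 300, noise_sd = 0)
  tr <- simulate_frap_trace(p)
  post <- tr$times >= 0
  expect_equal(tr$bleached[post],
               frap_recovery(tr$times[post], 0.3, 0.5, 2, 30),
               tolerance = 1e-5)   # positivity floor at the bleach frame
  expect_true(all(tr$bleached[!post] == 1))
  # plateau: value at t = 50*tauB within 1e-3 of A + B
  p2 <- frap_sim_params(A = 0.3, B = 0.5, tauA = 2, tauB = 30, dt = 50,
                        n_post = 40, noise_sd = 0)
  tr2 <- simulate_frap_trace(p2)
  expect_lt(abs(tr2$bleached[length(tr2$bleached)] - 0.8), 1e-3)
})

test_that("acquisition bleaching decays the reference channel geometrically", {
  p <- frap_sim_params(acquisition_bleach_rate = 0.002, noise_sd = 0)
  tr <- simulate_frap_trace(p)
  k <- seq_along(tr$reference) - 1
  expect_equal(tr$reference, (1 - 0.002)^k, tolerance = 1e-12)
  expect_error(frap_sim_params(n_pre = 0), "n_pre")
})

test_that("iFRAP traces start at 1 and match their closed form", {
  p <- frap_sim_params(mode = "ifrap", ifrap_tau = 100, ifrap_plateau = 0.6,
                       noise_sd = 0, n_post = 200)
  tr <- simulate_ifrap_trace(p)
  expect_equal(tr$bleached[1], 1)
  post <- tr$times > 0
  expect_equal(tr$bleached[post],
               0.4 * exp(-tr$times[post] / 100) + 0.6)
  flat <- simulate_ifrap_trace(frap_sim_params(mode = "ifrap",
                                               ifrap_plateau = 1,
                                               noise_sd = 0))
  expect_true(all(abs(flat$bleached - 1) < 1e-12))
})

test_that("noisy iFRAP traces average to the closed form", {
  vals <- sapply(1:20, function(s)
    simulate_ifrap_trace(frap_sim_params(mode = "ifrap", noise_sd = 0.02,
                                         n_post = 100, seed = s))$bleached)
  truth <- simulate_ifrap_trace(frap_sim_params(mode = "ifrap", noise_sd = 0,
                                                n_post = 100))$bleached
  expect_lt(max(abs(rowMeans(vals) - truth)), 0.02)
})

test_that("territory generator fills balls exactly and is seed-stable", {
  cl <- simulate_territory(territory_sim_params("ball", radius = 8))
  g <- expand.grid(x = -9:9, y = -9:9, z = -9:9)
  expect_identical(nrow(cl$coords), sum(g$x^2 + g$y^2 + g$z^2 <= 64))
  f1 <- simulate_territory(territory_sim_params("fiber", fiber_length = 200,
                                                seed = 3))
  f2 <- simulate_territory(territory_sim_params("fiber", fiber_length = 200,
                                                seed = 3))
  expect_identical(f1$coords, f2$coords)
  expect_error(territory_sim_params("ball", radius = 0.5), "radius")
})
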