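test_that("mask_and_rescale zeroes exclusions and hits the target mean", {
  img <- nucleus_image(matrix(50, 20, 20), 0.1)
  out <- mask_and_rescale(img, 100)
  expect_true(all(out$intensity == 100))
  # scale invariance
  img2 <- img; img2$intensity <- img$intensity * 3
  expect_equal(mask_and_rescale(img2, 100)$intensity, out$intensity)
  empty <- nucleus_image(matrix(1, 5, 5), 0.1,
                         nucleus_mask = matrix(FALSE, 5, 5))
  expect_error(mask_and_rescale(empty), "empty")
})

test_that("box intensities tile the image and discard zero-containing boxes", {
  img <- nucleus_image(matrix(7, 10, 10), 0.1)
  bd <- compute_box_intensities(img, box = 5, stride = 5)
  expect_length(bd$values, 4)
  expect_true(all(bd$values == 7))
  img$intensity[1:5, 1:5] <- 0
  bd2 <- compute_box_intensities(img, box = 5, stride = 5)
  expect_length(bd2$values, 3)
  expect_identical(bd2$n_discarded, 1L)
  expect_error(compute_box_intensities(img, box = 11), "exceeds")
})

test_that("box intensities equal the brute-force tiling oracle", {
  set.seed(31)
  x <- matrix(runif(2500, 1, 10), 50, 50)
  img <- nucleus_image(x, 0.1)
  bd <- compute_box_intensities(img, 5, 5)
  oracle <- brute_box_means(x, 5, 5)
  expect_length(bd$values, 100)
  expect_equal(bd$values, oracle$values)
})

test_that("two-population box values are decomposed at their separation", {
  seps <- vapply(1:20, function(s) {
    set.seed(s)
    v <- c(rnorm(400, 50, 5), rnorm(400, 150, 5))
    fit_double_gaussian(v)$heterogeneity
  }, numeric(1))
  expect_lt(abs(mean(seps) - 100), 3)
  expect_true(all(abs(seps - 100) < 10))
})

test_that("degenerate box distributions give near-zero heterogeneity", {
  expect_lt(fit_double_gaussian(rep(5, 100))$heterogeneity, 1e-6)
  expect_error(fit_double_gaussian(rnorm(10)), "insufficient")
})

test_that("unimodal input is flagged and agrees with an EM cross-check", {
  set.seed(7)
  v <- rnorm(600, 100, 10)
  res <- fit_double_gaussian(v)
  # the flag implements: separation below one pooled sd
  pooled <- sqrt(res$weight1 * res$sigma1^2 +
                   (1 - res$weight1) * res$sigma2^2)
  expect_identical(res$unimodal, res$heterogeneity < pooled)
  expect_lte(res$heterogeneity, 2 * sd(v))
  # EM mixture on raw values as an independent oracle
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this by name
  em <- mclust::Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
  em_sep <- abs(diff(em$parameters$mean))
  expect_lt(abs(res$heterogeneity - em_sep), 15)
  # and on well-separated data the two routes agree tightly
  set.seed(8)
  v2 <- c(rnorm(400, 50, 5), rnorm(400, 150, 5))
  em2 <- mclust::Mclust(v2, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(fit_double_gaussian(v2)$heterogeneity -
                  abs(diff(em2$parameters$mean))), 3)
})

test_that("vermicelli images score higher heterogeneity than uniform ones", {
  wins <- 0
  for (s in 1:20) {
    hu <- heterogeneity_level(simulate_nucleus_image(
      image_sim_params(mode = "uniform", n_fibers = 0, seed = s))$image)
    hv <- heterogeneity_level(simulate_nucleus_image(
      image_sim_params(seed = s))$image)
    if (hv$heterogeneity > hu$heterogeneity) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("heterogeneity rises with bead amplitude and ignores global scale", {
  med <- vapply(c(100, 300, 900), function(amp) {
    median(vapply(1:7, function(s)
      heterogeneity_level(simulate_nucleus_image(
        image_sim_params(bead_amplitude = amp, seed = s))$image)$heterogeneity,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
  img <- simulate_nucleus_image(image_sim_params(seed = 3))$image
  h1 <- heterogeneity_level(img)
  img$intensity <- img$intensity * 3.7
  h2 <- heterogeneity_level(img)
  expect_equal(h1$heterogeneity, h2$heterogeneity, tolerance = 1e-3)
  const <- nucleus_image(matrix(80, 60, 60), 0.1)
  expect_lt(heterogeneity_level(const)$heterogeneity, 1e-6)
})

test_that("beads on a noise-free straight fiber are all found, no extras", {
  fx <- straight_fiber_image(n_beads = 12, step = 10)
  bs <- detect_beads(fx$image, psf_sigma = 1.5 * 0.034)
  expect_identical(nrow(bs$beads), 12L)
  expect_equal(sort(bs$beads$y), fx$beads_x, tolerance = 0.3)
  sp <- bead_spacings(bs)
  expect_equal(sp$spacings, rep(10 * 0.034, 11), tolerance = 1e-2)
})

test_that("a single bright spot gives one bead and no spacings", {
  img <- matrix(10, 41, 41)
  img[19:23, 19:23] <- img[19:23, 19:23] +
    300 * exp(-(outer((-2:2)^2, (-2:2)^2, "+")) / (2 * 1.5^2))
  bs <- detect_beads(nucleus_image(img, 0.034), psf_sigma = 1.5 * 0.034)
  expect_identical(nrow(bs$beads), 1L)
  sp <- bead_spacings(bs)
  expect_true(sp$empty)
})

test_that("spacings never cross fibers", {
  beads <- data.frame(x = c(0, 10, 20, 100, 110), y = 0,
                      fiber = c(1, 1, 1, 2, 2), order = c(1, 2, 3, 1, 2))
  sp <- bead_spacings(beads, pixel_size = 0.034)
  expect_length(sp$spacings, 3)
  expect_equal(sp$spacings, c(0.34, 0.34, 0.34), tolerance = 1e-12)
})

test_that("detection stays accurate on jittered noisy fibers", {
  recalls <- precs <- c(); spac <- c()
  for (s in 1:20) {
    sim <- simulate_nucleus_image(image_sim_params(spacing_jitter_sd = 0.03,
                                                   seed = s))
    bs <- detect_beads(sim$image)
    m <- match_beads(sim$truth, bs$beads)
    recalls <- c(recalls, m$recall); precs <- c(precs, m$precision)
    spac <- c(spac, bead_spacings(bs)$spacings)
  }
  expect_gte(mean(recalls), 0.95)
  expect_gte(mean(precs), 0.95)
  expect_gte(length(spac), 200)
  expect_lt(abs(mean(spac) - 0.34), 0.02)
})

test_that("Pearson colocalization obeys its exact identities", {
  set.seed(5)
  a <- nucleus_image(matrix(runif(400, 1, 10), 20, 20), 0.1)
  b <- a; b$intensity <- 12 - a$intensity
  expect_equal(pearson_colocalization(a, a), 1)
  expect_equal(pearson_colocalization(a, b), -1)
  expect_equal(pearson_colocalization(a, b), pearson_colocalization(b, a))
  aff <- a; aff$intensity <- 3 * a$intensity + 2
  expect_equal(pearson_colocalization(a, aff), 1)
  const <- nucleus_image(matrix(1, 20, 20), 0.1)
  expect_error(pearson_colocalization(a, const), "constant")
})

test_that("independent channels decorrelate at large pixel counts", {
  ok <- 0
  for (s in 1:100) {
    set.seed(s)
    a <- nucleus_image(matrix(rexp(1e4), 100, 100), 0.1)
    b <- nucleus_image(matrix(rexp(1e4), 100, 100), 0.1)
    if (abs(pearson_colocalization(a, b)) < 0.05) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("cluster segmentation counts blocks and honors the size filter", {
  img <- nucleus_image(matrix(0, 40, 40), 0.1)
  img$intensity[5:8, 5:8] <- 100
  img$intensity[25:28, 25:28] <- 100
  cl <- segment_clusters(img, threshold = 25, min_diameter = 0.3)
  expect_identical(nrow(cl), 2L)
  expect_true(all(cl$n_pixels == 16))
  # a blob below the minimum equivalent diameter is removed
  img$intensity[15, 15] <- 100
  cl2 <- segment_clusters(img, threshold = 25, min_diameter = 0.3)
  expect_identical(nrow(cl2), 2L)
})

test_that("planted disc areas are recovered within 10%", {
  img <- nucleus_image(matrix(0, 120, 120), 0.1)
  centers <- list(c(25, 25), c(25, 85), c(85, 55))
  radii <- c(5, 8, 12)
  for (k in 1:3) {
    d2 <- outer((seq_len(120) - centers[[k]][1])^2,
                (seq_len(120) - centers[[k]][2])^2, "+")
    img$intensity[d2 <= radii[k]^2] <- 100
  }
  cl <- segment_clusters(img, threshold = 25, min_diameter = 0.2)
  expect_identical(nrow(cl), 3L)
  got <- sort(cl$area_um2)
  want <- sort(pi * (radii * 0.1)^2)
  expect_true(all(abs(got - want) / want < 0.1))
})

test_that("line profiles are flat on constant images and mirror correctly", {
  img <- nucleus_image(matrix(4, 30, 30), 0.1)
  pr <- line_profile(img, c(15, 5), c(15, 25))
  expect_true(all(pr$intensity == 1))
  expect_error(line_profile(img, c(5, 5), c(5, 5)), "zero-length")
  set.seed(2)
  x <- matrix(runif(900, 1, 5), 30, 30)
  imgA <- nucleus_image(x, 0.1)
  imgM <- nucleus_image(x[, 30:1], 0.1)
  pa <- line_profile(imgA, c(15, 3), c(15, 28))$intensity
  pm <- line_profile(imgM, c(15, 28), c(15, 3))$intensity
  expect_equal(as.numeric(pa), as.numeric(pm), tolerance = 1e-9)
})

test_that("two-channel profiles localize flanking spots at planted offsets", {
  blob <- matrix(1, 41, 61)
  ch2 <- matrix(1, 41, 61)
  gs <- function(m, r0, c0, amp) {
    for (r in 1:41) for (c in 1:61)
      m[r, c] <- m[r, c] + amp * exp(-((r - r0)^2 + (c - c0)^2) / (2 * 2^2))
    m
  }
  blob <- gs(blob, 21, 31, 50)           # central domain, channel 1
  ch2 <- gs(ch2, 21, 21, 50)             # flanking spots, channel 2
  ch2 <- gs(ch2, 21, 41, 50)
  pr <- line_profile(list(nucleus_image(blob, 0.1), nucleus_image(ch2, 0.1)),
                     c(21, 11), c(21, 51), width = 3)
  pos2 <- which(diff(sign(diff(pr$intensity[, 2]))) == -2) + 1
  expect_equal(which.max(pr$intensity[, 1]), 21, tolerance = 1)
  expect_true(any(abs(pos2 - 11) <= 1) && any(abs(pos2 - 31) <= 1))
})
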