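balanced_expected <- function(p) {
  ice_balance(simulate_contact_map(p)$matrix, min_coverage_mad = Inf)
}

test_that("PC1 recovers checkerboard labels perfectly without noise", {
  p <- hic_sim_params(n_bins = 100, epsilon = 0.4, sample = FALSE)
  sim <- simulate_contact_map(p)
  bal <- balanced_expected(p)
  prof <- compute_pc1(bal, ifelse(sim$truth$labels == "A", 1, -1))
  expect_identical(prof$label, sim$truth$labels)
  expect_false(prof$degenerate)
})

test_that("a plaid-free matrix raises the degenerate flag", {
  p <- hic_sim_params(n_bins = 60, epsilon = 0, sample = FALSE)
  sim <- simulate_contact_map(p)
  prof <- compute_pc1(sim$matrix, rep(c(1, -1), 30))
  expect_true(prof$degenerate)
})

test_that("negating the orientation track negates PC1 exactly", {
  p <- hic_sim_params(n_bins = 60, epsilon = 0.4, sample = FALSE)
  sim <- simulate_contact_map(p)
  bal <- balanced_expected(p)
  track <- ifelse(sim$truth$labels == "A", 1, -1)
  p1 <- compute_pc1(bal, track)
  p2 <- compute_pc1(bal, -track)
  expect_equal(p1$pc1, -p2$pc1)
  expect_warning(compute_pc1(bal, NULL), "orientation")
})

test_that("switch accounting is exact, symmetric and sums to one", {
  p <- hic_sim_params(n_bins = 100, epsilon = 0.4, sample = FALSE)
  sim <- simulate_contact_map(p)
  bal <- balanced_expected(p)
  track <- ifelse(sim$truth$labels == "A", 1, -1)
  prof <- compute_pc1(bal, track)
  sw <- compartment_switches(prof, prof)
  expect_equal(sw$a_to_b, 0)
  expect_equal(sw$b_to_a, 0)
  expect_equal(sw$stable_a + sw$stable_b, 1, tolerance = 1e-12)
  flipped <- prof
  flipped$pc1 <- -prof$pc1
  flipped$label <- c(A = "B", B = "A")[prof$label]
  sw2 <- compartment_switches(prof, flipped)
  expect_equal(sw2$a_to_b + sw2$b_to_a, 1, tolerance = 1e-12)
  sw3 <- compartment_switches(flipped, prof)
  expect_equal(sw2$a_to_b, sw3$b_to_a)
})

test_that("planted asymmetric switching fractions are recovered exactly", {
  sims <- lapply(c("control", "rad21_oe"), function(cond)
    simulate_contact_map(hic_preset(cond, sample = FALSE)))
  profs <- lapply(sims, function(s) {
    bal <- ice_balance(s$matrix, min_coverage_mad = Inf)
    compute_pc1(bal, ifelse(s$truth$labels == "A", 1, -1))
  })
  expect_identical(profs[[1]]$label, sims[[1]]$truth$labels)
  expect_identical(profs[[2]]$label, sims[[2]]$truth$labels)
  sw <- compartment_switches(profs[[1]], profs[[2]])
  expect_equal(sw$a_to_b, 0.02)
  expect_equal(sw$b_to_a, 0.06)
})

test_that("mixing ratio matches brute-force enumeration on an 8-bin toy", {
  bins <- genome_bins("chrT", 8 * 4e4, 4e4)
  W <- matrix(1, 8, 8)
  m <- contact_matrix(W, bins)
  labels <- rep(c("A", "B"), each = 4)
  prof <- structure(list(bins = bins, pc1 = ifelse(labels == "A", 1, -1),
                         label = labels, degenerate = FALSE, oriented = TRUE),
                    class = "compartment_profile")
  mr <- mixing_ratio(m, prof)
  expect_equal(mr$overall, 16 / (6 + 6))
  expect_equal(mr$overall, brute_mixing_ratio(W, labels))
  # block-diagonal: no A-B contact
  Wb <- matrix(0, 8, 8); Wb[1:4, 1:4] <- 1; Wb[5:8, 5:8] <- 1
  expect_equal(mixing_ratio(contact_matrix(Wb, bins), prof)$overall, 0)
  one_class <- prof; one_class$label <- rep("A", 8)
  expect_error(mixing_ratio(m, one_class), "class B")
})

test_that("mixing ratio equals brute force on random matrices", {
  set.seed(17)
  for (r in 1:3) {
    n <- sample(10:20, 1)
    W <- matrix(runif(n * n), n, n); W <- (W + t(W)) / 2
    labels <- sample(c("A", "B"), n, replace = TRUE,
                     prob = c(0.6, 0.4))
    if (sum(labels == "A") < 2 || sum(labels == "B") < 2) next
    bins <- genome_bins("chrT", n * 4e4, 4e4)
    prof <- structure(list(bins = bins, pc1 = ifelse(labels == "A", 1, -1),
                           label = labels, degenerate = FALSE,
                           oriented = TRUE),
                      class = "compartment_profile")
    expect_equal(mixing_ratio(contact_matrix(W, bins), prof)$overall,
                 brute_mixing_ratio(W, labels))
  }
})

test_that("mixing ratio decreases strictly with compartment strength", {
  ratios <- vapply(c(0, 0.2, 0.4, 0.6), function(eps) {
    p <- hic_sim_params(n_bins = 60, epsilon = eps, sample = FALSE)
    sim <- simulate_contact_map(p)
    bal <- ice_balance(sim$matrix, min_coverage_mad = Inf)
    labels <- sim$truth$labels
    prof <- structure(list(bins = sim$matrix$bins,
                           pc1 = ifelse(labels == "A", 1, -1),
                           label = labels, degenerate = FALSE,
                           oriented = TRUE),
                      class = "compartment_profile")
    mixing_ratio(bal, prof)$overall
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("saddle grids show corner enrichment and anti-corner depletion", {
  bins <- genome_bins("chrT", 20 * 4e4, 4e4)
  prof <- structure(list(bins = bins, pc1 = seq(-1, 1, length.out = 20),
                         label = rep(c("B", "A"), each = 10),
                         degenerate = FALSE, oriented = TRUE),
                    class = "compartment_profile")
  sad <- saddle(matrix(1, 20, 20), prof, n_quantiles = 5)
  expect_true(all(abs(sad$grid - 1) < 1e-12))
  expect_identical(sad$grid, t(sad$grid))

  p <- hic_sim_params(n_bins = 100, epsilon = 0.4, sample = FALSE)
  sim <- simulate_contact_map(p)
  bal <- ice_balance(sim$matrix, min_coverage_mad = Inf)
  oe <- observed_over_expected(bal)
  prof2 <- compute_pc1(bal, ifelse(sim$truth$labels == "A", 1, -1))
  sad2 <- saddle(oe, prof2, 5)
  expect_gt(sad2$grid[1, 1], 1)
  expect_gt(sad2$grid[5, 5], 1)
  expect_lt(sad2$grid[1, 5], 1)
  # grand mean of the grid stays near the O/E mean over determined bins
  det <- prof2$label != "undetermined"
  expect_lt(abs(mean(sad2$grid) - mean(oe[det, det], na.rm = TRUE)), 0.1)
})

test_that("preset saddle difference weakens corners in the OE-like map", {
  corner_diff <- anti_diff <- c()
  for (s in 1:5) {
    sads <- lapply(c("control", "rad21_oe"), function(cond) {
      sim <- simulate_contact_map(hic_preset(cond, seed = s))
      bal <- ice_balance(sim$matrix, min_coverage_mad = Inf)
      prof <- compute_pc1(bal, ifelse(sim$truth$labels == "A", 1, -1))
      saddle(observed_over_expected(bal), prof, 5)$grid
    })
    d <- sads[[2]] - sads[[1]]
    corner_diff <- c(corner_diff, d[1, 1], d[5, 5])
    anti_diff <- c(anti_diff, d[1, 5])
  }
  expect_lt(mean(corner_diff), 0)
  expect_gt(mean(anti_diff), 0)
})
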