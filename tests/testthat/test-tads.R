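make_cm <- function(W, bin_size = 4e4) {
  contact_matrix(W, genome_bins("chrT", nrow(W) * bin_size, bin_size))
}

test_that("insulation of a uniform matrix is zero at all valid bins", {
  prof <- insulation_score(make_cm(matrix(3, 40, 40)), window = 2e5)
  valid <- !is.na(prof$score)
  expect_gt(sum(valid), 25)
  expect_true(all(abs(prof$score[valid]) < 1e-12))
})

test_that("insulation equals the brute-force window computation", {
  set.seed(41)
  for (n in c(30, 60)) {
    W <- matrix(runif(n * n, 0.5, 3), n, n); W <- (W + t(W)) / 2
    w <- 5
    prof <- insulation_score(make_cm(W), window = w * 4e4)
    raw <- brute_insulation_raw(W, w)
    score <- log2(raw / mean(raw, na.rm = TRUE))
    expect_equal(prof$score, score)
  }
})

test_that("a two-TAD block matrix has its score minimum at the boundary", {
  n <- 40
  W <- matrix(1, n, n)
  W[1:20, 1:20] <- 10; W[21:40, 21:40] <- 10
  prof <- insulation_score(make_cm(W), window = 8 * 4e4)
  expect_identical(which.min(prof$score), 21L)   # left edge of second TAD
})

test_that("boundary calling is exact on noise-free maps and empty on flat ones", {
  flat <- insulation_score(make_cm(matrix(2, 50, 50)), window = 2e5)
  expect_identical(nrow(call_boundaries(flat)), 0L)
  p <- hic_sim_params(n_bins = 120, bin_size = 4e4, epsilon = 0, beta = 1,
                      tad_boundaries = c(30, 60, 90), sample = FALSE)
  sim <- simulate_contact_map(p)
  bal <- ice_balance(sim$matrix, min_coverage_mad = Inf)
  bd <- call_boundaries(insulation_score(bal))
  expect_identical(bd$bin, c(30L, 60L, 90L))
})

test_that("boundaries survive Poisson noise at moderate depth", {
  rec <- prec <- c()
  for (s in 1:20) {
    p <- hic_sim_params(n_bins = 100, bin_size = 4e4, epsilon = 0, beta = 1,
                        tad_boundaries = c(25, 50, 75), depth = 5e5, seed = s)
    sim <- simulate_contact_map(p)
    bal <- ice_balance(sim$matrix)
    bd <- call_boundaries(insulation_score(bal))
    truth <- sim$truth$boundaries
    if (nrow(bd)) {
      tp <- sum(vapply(bd$bin, function(b) min(abs(b - truth)) <= 1,
                       logical(1)))
      prec <- c(prec, tp / nrow(bd))
    } else prec <- c(prec, 0)
    rec <- c(rec, mean(vapply(truth, function(b) min(abs(bd$bin - b)) <= 1,
                              logical(1))))
  }
  expect_gte(mean(rec), 0.9)
  expect_gte(mean(prec), 0.9)
})

test_that("TAD construction tiles the chromosome and inverts boundaries", {
  bins <- genome_bins("chrT", 30 * 4e4, 4e4)
  tads <- tads_from_boundaries(c(10, 20), bins)
  expect_equal(tads$first_bin, c(0, 10, 20))
  expect_equal(tads$last_bin, c(10, 20, 30))
  expect_equal(tads$start, c(0, 10, 20) * 4e4)
  expect_equal(tads$end, c(10, 20, 30) * 4e4)
  expect_identical(boundaries_of(tads), c(10L, 20L))
  whole <- tads_from_boundaries(integer(0), bins)
  expect_identical(nrow(whole), 1L)
  expect_equal(whole$size_bp, 30 * 4e4)
})

test_that("TAD score is exactly 1 on uniform and 10 on 10:1 block matrices", {
  bins <- genome_bins("chrT", 30 * 4e4, 4e4)
  tads <- tads_from_boundaries(c(10, 20), bins)
  uni <- tad_score(make_cm(matrix(5, 30, 30)), tads)
  expect_equal(uni$score, rep(1, 3), tolerance = 1e-12)
  W <- matrix(1, 30, 30)
  for (k in 1:3) {
    idx <- ((k - 1) * 10 + 1):(k * 10)
    W[idx, idx] <- 10
  }
  ts <- tad_score(make_cm(W), tads)
  expect_equal(ts$score, rep(10, 3), tolerance = 1e-12)
  expect_equal(ts$score[2],
               brute_tad_score(W, 10, 20, c(1:10, 21:30)),
               tolerance = 1e-12)
  # invariance to global scaling
  ts2 <- tad_score(make_cm(W * 7.3), tads)
  expect_equal(ts2$score, ts$score)
  # 1-bin TADs are skipped
  tiny <- tads_from_boundaries(c(1, 2), genome_bins("chrT", 12e4, 4e4))
  sk <- tad_score(make_cm(matrix(1, 3, 3)), tiny)
  expect_true(all(is.na(sk$score)))
})

test_that("TAD score grows with block strength and shrinks with leakage", {
  score_at <- function(beta, adj = 0) {
    p <- hic_sim_params(n_bins = 120, bin_size = 4e4, epsilon = 0,
                        beta = beta, adjacent_boost = adj,
                        tad_boundaries = c(30, 60, 90), sample = FALSE)
    bal <- ice_balance(simulate_contact_map(p)$matrix,
                       min_coverage_mad = Inf)
    tads <- tads_from_boundaries(c(30, 60, 90), bal$bins)
    median(tad_score(bal, tads)$score, na.rm = TRUE)
  }
  by_beta <- vapply(c(0.5, 1, 2), score_at, numeric(1))
  expect_true(all(diff(by_beta) > 0))
  expect_lt(score_at(1, adj = 0.6), score_at(1, adj = 0))
})

test_that("single-TAD aggregation reproduces the TAD's own rescaled window", {
  p <- hic_sim_params(n_bins = 80, bin_size = 4e4, epsilon = 0, beta = 1,
                      gamma = 0.5, tad_boundaries = c(20, 40, 60),
                      sample = FALSE)
  sim <- simulate_contact_map(p)
  mat <- sim$matrix                  # expected-value mode: exactly balanced
  tads <- tads_from_boundaries(c(20, 40, 60), mat$bins)
  one <- tads[2, ]
  ata <- aggregate_tads(mat, one, min_size = 2e5, out_pixels = 60)
  oe <- observed_over_expected(mat)
  win <- oe[11:50, 11:50]
  ref <- vermicelli:::rescale_window(win, 60)
  expect_equal(ata$grid, ref, tolerance = 1e-10)
  expect_identical(ata$n_tads, 1L)
  # two identical interior TADs average to the same window
  ata2 <- aggregate_tads(mat, tads[2:3, ], min_size = 2e5, out_pixels = 60)
  expect_equal(ata2$grid, ref, tolerance = 1e-8)
  expect_error(aggregate_tads(mat, tads, min_size = 1e9), "size filter")
})

test_that("corner peaks enrich the ATA corner over the border", {
  p <- hic_sim_params(n_bins = 120, bin_size = 4e4, epsilon = 0, beta = 1,
                      gamma = 1, tad_boundaries = c(30, 60, 90),
                      sample = FALSE)
  bal <- ice_balance(simulate_contact_map(p)$matrix, min_coverage_mad = Inf)
  tads <- tads_from_boundaries(c(30, 60, 90), bal$bins)
  ata <- aggregate_tads(bal, tads)
  enr <- ata_corner_enrichment(ata)
  expect_gt(enr$enrichment, 1)
  expect_equal(ata$grid, t(ata$grid), tolerance = 1e-12)
})

test_that("differential ATA is positive at corners for the OE-like preset", {
  diffs <- vapply(1:5, function(s) {
    enr <- lapply(c("control", "rad21_oe"), function(cond) {
      sim <- simulate_contact_map(hic_preset(cond, seed = s))
      bal <- ice_balance(sim$matrix, min_coverage_mad = Inf)
      tads <- tads_from_boundaries(sim$truth$boundaries, bal$bins)
      ata_corner_enrichment(aggregate_tads(bal, tads))$enrichment
    })
    enr[[2]] - enr[[1]]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gte(mean(diffs > 0), 0.8)
})

test_that("TAD length statistics split at the long threshold", {
  bins <- genome_bins("chrT", 25 * 4e4, 4e4)
  tads <- tads_from_boundaries(c(10), bins)   # 400 kb and 600 kb
  st <- tad_length_stats(tads, long_threshold = 5e5)
  expect_identical(st$n_short, 1L)
  expect_identical(st$n_long, 1L)
  expect_equal(st$median_bp, 5e5)
})
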