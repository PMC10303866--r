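#' Parameters for the synthetic Hi-C contact-map generator
#'
#' The expected matrix combines a power-law distance decay with a
#' checkerboard compartment plaid, TAD blocks and TAD corner peaks:
#' `E[i,j] = scale * (|i-j|+1)^(-alpha) * c_ij * t_ij * p_ij` with
#' `c_ij = 1+epsilon` when bins i and j share a compartment label and
#' `1-epsilon` otherwise, `t_ij = 1+beta` inside a TAD, and
#' `p_ij = 1+gamma` within `corner_width` bins of a TAD corner (the bin
#' pair formed by a TAD's left boundary and right boundary - 1). `scale`
#' is set so the expected total equals `depth`; counts are then drawn
#' Poisson and symmetrized unless `sample = FALSE` (expected-value mode).
#'
#' @param n_bins number of bins.
#' @param bin_size bin width in bp.
#' @param alpha distance-decay exponent (dimensionless, > 0).
#' @param compartment_labels per-bin `"A"`/`"B"` vector, or `NULL` to use
#'   alternating blocks of `compartment_block` bins.
#' @param compartment_block block size in bins for the default checkerboard.
#' @param epsilon compartment strength in `[0, 1)`.
#' @param compartment_min_dist separation (bins) below which the
#'   compartment factor is not applied; the plaid is a long-range
#'   feature, so presets disable it within the TAD scale.
#' @param tad_boundaries sorted interior bin indices (0-based, strictly
#'   inside `(0, n_bins)`); TADs tile the span between them.
#' @param beta TAD block strength (>= 0).
#' @param adjacent_boost leakage factor for pairs in adjacent TADs
#'   (>= 0): models extruded loops crossing domain boundaries.
#' @param gamma corner-peak strength (>= 0).
#' @param corner_width corner half-width in bins.
#' @param depth target total contact count.
#' @param sample draw Poisson counts (`TRUE`) or return the expected matrix
#'   (`FALSE`, for analytic tests).
#' @param seed RNG seed consumed by the generator.
#' @return an object of class `hic_sim_params`.
#' @export
hic_sim_params <- function(n_bins = 200, bin_size = 150e3, alpha = 1.0,
                           compartment_labels = NULL, compartment_block = 10,
                           epsilon = 0.4, compartment_min_dist = 0,
                           tad_boundaries = integer(0),
                           beta = 0, adjacent_boost = 0, gamma = 0,
                           corner_width = 1, depth = 1e6, sample = TRUE,
                           seed = 1L) {
  if (epsilon >= 1 || epsilon < 0) stop("epsilon must be in [0, 1)")
  stopifnot(alpha > 0, beta >= 0, adjacent_boost >= 0,
            gamma >= 0, corner_width >= 0, compartment_min_dist >= 0,
            depth > 0, n_bins >= 2)
  if (is.null(compartment_labels)) {
    compartment_labels <-
      c("A", "B")[1 + (floor((seq_len(n_bins) - 1) / compartment_block) %% 2)]
  }
  stopifnot(length(compartment_labels) == n_bins,
            all(compartment_labels %in% c("A", "B")))
  tad_boundaries <- as.integer(tad_boundaries)
  if (length(tad_boundaries)) {
    if (is.unsorted(tad_boundaries, strictly = TRUE) ||
        min(tad_boundaries) <= 0 || max(tad_boundaries) >= n_bins)
      stop("tad_boundaries must be strictly increasing inside (0, n_bins)")
  }
  structure(list(n_bins = as.integer(n_bins), bin_size = bin_size,
                 alpha = alpha, compartment_labels = compartment_labels,
                 epsilon = epsilon,
                 compartment_min_dist = as.integer(compartment_min_dist),
                 tad_boundaries = tad_boundaries,
                 beta = beta, adjacent_boost = adjacent_boost,
                 gamma = gamma,
                 corner_width = as.integer(corner_width),
                 depth = depth, sample = isTRUE(sample),
                 seed = as.integer(seed)),
            class = "hic_sim_params")
}

expected_hic_matrix <- function(p) {
  n <- p$n_bins
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- (d + 1)^(-p$alpha)
  same <- outer(p$compartment_labels, p$compartment_labels, "==")
  comp <- ifelse(same, 1 + p$epsilon, 1 - p$epsilon)
  comp[d < p$compartment_min_dist] <- 1
  E <- E * comp
  tads <- tad_intervals_from_boundaries(p$tad_boundaries, n)
  tad_of <- integer(n)
  for (k in seq_len(nrow(tads)))
    tad_of[(tads$first[k] + 1):tads$last[k]] <- k
  E <- E * ifelse(outer(tad_of, tad_of, "=="), 1 + p$beta, 1)
  if (p$adjacent_boost > 0)
    E <- E * ifelse(abs(outer(tad_of, tad_of, "-")) == 1,
                    1 + p$adjacent_boost, 1)
  if (p$gamma > 0) {
    idx <- seq_len(n)
    for (k in seq_len(nrow(tads))) {
      l <- tads$first[k] + 1          # 1-based left boundary bin
      r <- tads$last[k]               # 1-based right boundary - 1 bin
      near_l <- abs(idx - l) <= p$corner_width
      near_r <- abs(idx - r) <= p$corner_width
      boost <- outer(near_l, near_r) | outer(near_r, near_l)
      E[boost] <- E[boost] * (1 + p$gamma)
    }
  }
  E * (p$depth / sum(E))
}

# 0-based half-open TAD intervals in bins: columns first (inclusive 0-based
# start) and last (exclusive 0-based end)
tad_intervals_from_boundaries <- function(boundaries, n_bins) {
  edges <- c(0L, boundaries, n_bins)
  data.frame(first = edges[-length(edges)], last = edges[-1])
}

#' Simulate a Hi-C contact map with known truth
#'
#' @param params a [hic_sim_params()] object.
#' @return list with `matrix` (a [contact_matrix()]), `truth` (per-bin
#'   compartment labels, TAD boundary bin indices and TAD interval table)
#'   and `expected` (the noiseless expected matrix).
#' @export
simulate_contact_map <- function(params) {
  stopifnot(inherits(params, "hic_sim_params"))
  E <- expected_hic_matrix(params)
  if (params$sample) {
    local_seed(params$seed)
    n <- params$n_bins
    up <- upper.tri(E, diag = TRUE)
    cnt <- matrix(0, n, n)
    # upper triangle drawn Poisson and mirrored: mirror entries of E carry
    # equal mass, so the total expectation equals depth
    cnt[up] <- stats::rpois(sum(up), E[up])
    cnt <- cnt + t(cnt) - diag(diag(cnt))
    M <- cnt
  } else {
    M <- E
  }
  bins <- genome_bins("chrS", params$n_bins * params$bin_size, params$bin_size)
  tads <- tad_intervals_from_boundaries(params$tad_boundaries, params$n_bins)
  list(matrix = contact_matrix(M, bins),
       truth = list(labels = params$compartment_labels,
                    boundaries = params$tad_boundaries,
                    tads = tads),
       expected = E)
}

#' Paired synthetic presets mimicking the control vs RAD21-over-expression
#' contrast
#'
#' Two parameter sets sharing the same TAD boundaries and compartment
#' pattern, designed so every contact-map statistic moves in the direction
#' observed when cohesin is over-loaded: the OE-like map has a steeper
#' distance decay (more short-range, fewer long-range contacts), weaker
#' compartment plaid (`epsilon` 0.2 vs 0.4), stronger TAD corner peaks
#' (`gamma` 1.0 vs 0.2) and boundary-crossing loop leakage
#' (`adjacent_boost` 0.6 vs 0, i.e. more inter-TAD contact), while TAD
#' positions — and hence TAD number and length — are identical.
#'
#' @param condition `"control"` or `"rad21_oe"`.
#' @param n_bins,depth,seed,sample passed through to [hic_sim_params()].
#' @param flip_fraction_b_to_a,flip_fraction_a_to_b fraction of bins whose
#'   compartment label is flipped in the OE-like truth (asymmetric
#'   switching; defaults 6% B->A and 2% A->B). Ignored for the control.
#' @return a [hic_sim_params()] object.
#' @export
hic_preset <- function(condition = c("control", "rad21_oe"),
                       n_bins = 200, depth = 2e6, seed = 1L, sample = TRUE,
                       flip_fraction_b_to_a = 0.06,
                       flip_fraction_a_to_b = 0.02) {
  condition <- match.arg(condition)
  bin_size <- 40e3
  boundaries <- as.integer(seq(20, n_bins - 20, by = 20))
  # compartment blocks span 1-3 whole TADs: transitions coincide with
  # domain boundaries (as they mostly do in real genomes) while block
  # sizes vary so that pairs at TAD-scale separations mix labels
  n_tads <- length(boundaries) + 1
  tad_sizes <- diff(c(0L, boundaries, n_bins))
  blocks <- rep_len(c(2, 1, 1, 3, 1, 2), n_tads)
  grp <- rep(seq_along(blocks), blocks)[seq_len(n_tads)]
  tad_label <- c("A", "B")[1 + (grp - 1) %% 2]
  labels <- rep(tad_label, tad_sizes)
  if (condition == "control") {
    hic_sim_params(n_bins = n_bins, bin_size = bin_size, alpha = 1.0,
                   compartment_labels = labels, epsilon = 0.4,
                   compartment_min_dist = 20, tad_boundaries = boundaries, beta = 1.0, gamma = 0.2,
                   corner_width = 1, depth = depth, sample = sample,
                   seed = seed)
  } else {
    # deterministic contiguous label flips (switching is regional, so the
    # flipped bins form a block centered in the longest run of the source
    # label) with exactly the planted switch fractions
    labels2 <- labels
    flip <- function(from, frac) {
      k <- round(frac * n_bins)
      if (k == 0) return(integer(0))
      r <- rle(labels2)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      cand <- which(r$values == from & r$lengths >= k)
      if (!length(cand)) stop("no run long enough to plant the label flips")
      run <- cand[which.max(r$lengths[cand])]
      mid <- starts[run] + floor((r$lengths[run] - k) / 2)
      mid:(mid + k - 1)
    }
    labels2[flip("B", flip_fraction_b_to_a)] <- "A"
    labels2[flip("A", flip_fraction_a_to_b)] <- "B"
    hic_sim_params(n_bins = n_bins, bin_size = bin_size, alpha = 1.15,
                   compartment_labels = labels2, epsilon = 0.2,
                   compartment_min_dist = 20, tad_boundaries = boundaries, beta = 1.2,
                   adjacent_boost = 0.6, gamma = 1.0,
                   corner_width = 1, depth = depth, sample = sample,
                   seed = seed)
  }
}

#' Simulate a two-chromosome genome with cis and trans contacts
#'
#' Cis blocks follow [simulate_contact_map()]'s model; trans contacts are
#' uniform with total mass set by `trans_fraction`.
#'
#' @param params_list list of [hic_sim_params()], one per chromosome.
#' @param trans_fraction expected fraction of total contacts that are
#'   inter-chromosomal.
#' @param seed RNG seed.
#' @return list with `matrix` (genome-wide [contact_matrix()]) and
#'   `chrom` per-bin chromosome names.
#' @export
simulate_genome_map <- function(params_list, trans_fraction = 0.2, seed = 1L) {
  stopifnot(trans_fraction >= 0, trans_fraction < 1)
  ns <- vapply(params_list, function(p) p$n_bins, integer(1))
  n <- sum(ns)
  M <- matrix(0, n, n)
  off <- cumsum(c(0L, ns))
  sizes <- numeric(0)
  chrom <- character(0)
  for (k in seq_along(params_list)) {
    p <- params_list[[k]]
    p$seed <- as.integer(p$seed + 7919L * k)
    sim <- simulate_contact_map(p)
    rng <- (off[k] + 1):(off[k] + ns[k])
    M[rng, rng] <- sim$matrix$counts
    sizes <- c(sizes, ns[k] * p$bin_size)
    chrom <- c(chrom, rep(paste0("chrS", k), ns[k]))
  }
  cis_total <- sum(M)
  if (trans_fraction > 0 && length(params_list) >= 2) {
    local_seed(seed)
    trans_total <- cis_total * trans_fraction / (1 - trans_fraction)
    pairs <- 0
    for (a in seq_along(ns)) for (b in seq_along(ns)) if (a < b)
      pairs <- pairs + ns[a] * ns[b]
    lam <- trans_total / (2 * pairs)   # symmetric: each unordered pair twice
    for (a in seq_along(ns)) for (b in seq_along(ns)) if (a < b) {
      ra <- (off[a] + 1):(off[a] + ns[a]); rb <- (off[b] + 1):(off[b] + ns[b])
      blk <- matrix(stats::rpois(ns[a] * ns[b], lam), ns[a], ns[b])
      M[ra, rb] <- blk
      M[rb, ra] <- t(blk)
    }
  }
  bins <- genome_bins(paste0("chrS", seq_along(ns)), sizes,
                      params_list[[1]]$bin_size)
  list(matrix = contact_matrix(M, bins), chrom = chrom)
}
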