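#' Iterative correction (ICE) balancing
#'
#' Equalizes bin marginals by iterative correction. Bins with raw
#' marginal below `median - min_coverage_mad * MAD` (or zero) are masked
#' first and excluded from all statistics. Iteration stops when the
#' coefficient of variation of the unmasked marginals drops below `tol`;
#' the balanced matrix is scaled so its mean over valid pixels is 1.
#'
#' @param m a [contact_matrix()].
#' @param tol convergence tolerance on the marginal CV.
#' @param max_iter iteration cap; hitting it sets `converged = FALSE`.
#' @param min_coverage_mad MAD multiplier for the low-coverage filter.
#' @return a balanced [contact_matrix()] with per-bin `weights`
#'   (`NA` = masked) and attributes `converged`, `n_iter`.
#' @export
ice_balance <- function(m, tol = 1e-5, max_iter = 200, min_coverage_mad = 3) {
  stopifnot(inherits(m, "contact_matrix"))
  W <- m$counts
  n <- nrow(W)
  marg <- rowSums(W, na.rm = TRUE)   # all-NA rows (already masked) drop out
  # low-coverage filter on log marginals (multiplicative outliers), the
  # usual MAD-max convention for Hi-C bin filtering
  lm_pos <- log(marg[marg > 0])
  cutoff <- stats::median(lm_pos) - min_coverage_mad * stats::mad(lm_pos)
  valid <- marg > 0 & log(pmax(marg, 1e-300)) >= cutoff
  if (sum(valid) < 2) stop("fewer than 2 unmasked bins after coverage filter")
  B <- W[valid, valid, drop = FALSE]
  bias <- rep(1, sum(valid))
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    s <- rowSums(B)
    cv <- stats::sd(s) / mean(s)
    if (is.finite(cv) && cv < tol) { converged <- TRUE; break }
    f <- s / mean(s)
    f[f == 0] <- 1
    B <- B / outer(f, f)
    bias <- bias * f
  }
  B <- B / mean(B)   # unit mean per valid pixel
  out <- matrix(NA_real_, n, n)
  out[valid, valid] <- B
  weights <- rep(NA_real_, n)
  weights[valid] <- 1 / bias
  res <- contact_matrix(replace(out, is.na(out), 0), m$bins,
                        weights = weights, balanced = TRUE)
  res$counts[!valid, ] <- NA_real_
  res$counts[, !valid] <- NA_real_
  attr(res, "converged") <- converged
  attr(res, "n_iter") <- it
  res
}

#' Mean contact by genomic distance
#'
#' `expected(d)` is the mean balanced contact over valid bin pairs at
#' separation `d` bins (one value per distance with at least one valid
#' pair).
#'
#' @param m a balanced (or otherwise prepared) [contact_matrix()].
#' @return data.frame of class `expected_profile`: `distance` (bins),
#'   `expected`, `n_pairs`.
#' @export
expected_by_distance <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  v <- valid_bins(m)
  W <- m$counts
  n <- nrow(W)
  out <- data.frame(distance = 0:(n - 1), expected = NA_real_,
                    n_pairs = 0L)
  vmask <- rep(FALSE, n); vmask[v] <- TRUE
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    j <- i + d
    ok <- vmask[i] & vmask[j]
    if (any(ok)) {
      vals <- W[cbind(i[ok], j[ok])]
      vals <- vals[!is.na(vals)]
      if (length(vals)) {
        out$expected[d + 1] <- mean(vals)
        out$n_pairs[d + 1] <- length(vals)
      }
    }
  }
  class(out) <- c("expected_profile", "data.frame")
  out
}

#' Observed-over-expected transform
#'
#' Divides each entry by the mean contact at its genomic distance,
#' removing the distance decay while preserving compartment plaid and
#' domain structure; per-distance means of the result are 1.
#'
#' @param m a [contact_matrix()].
#' @return numeric matrix (NA on masked bins / undefined distances).
#' @export
observed_over_expected <- function(m) {
  exp_prof <- expected_by_distance(m)
  n <- nrow(m$counts)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- matrix(exp_prof$expected[d + 1], n, n)
  oe <- m$counts / E
  bad <- setdiff(seq_len(n), valid_bins(m))
  if (length(bad)) { oe[bad, ] <- NA_real_; oe[, bad] <- NA_real_ }
  oe
}

#' Contact probability curve P(s)
#'
#' Mean contact per logarithmically increasing genomic-distance bin
#' (geometric factor `geometric_factor`), normalized to sum 1 over the
#' curve, with a least-squares log-log slope over `slope_range` (bins).
#' The zero diagonal (s = 0) is excluded.
#'
#' @param m a [contact_matrix()] (cis).
#' @param geometric_factor ratio between consecutive distance-bin edges.
#' @param slope_range range of separations (in bins) for the slope fit.
#' @return list of class `ps_curve`: data.frame `curve` (`s_bp`, `s_bins`,
#'   `p`, `n_pairs`) and `slope`.
#' @export
contact_probability <- function(m, geometric_factor = 1.12,
                                slope_range = c(5, 200)) {
  stopifnot(geometric_factor > 1)
  prof <- expected_by_distance(m)
  prof <- prof[prof$distance >= 1 & !is.na(prof$expected), ]
  if (nrow(prof) < 2) stop("matrix too small for a P(s) curve")
  edges <- geometric_factor^(0:ceiling(log(max(prof$distance) + 1) /
                                         log(geometric_factor)))
  edges <- unique(c(1, edges[edges <= max(prof$distance) + 1],
                    max(prof$distance) + 1))
  grp <- cut(prof$distance, breaks = edges, right = FALSE,
             include.lowest = TRUE)
  agg <- data.frame(
    s_bins = tapply(prof$distance * prof$n_pairs, grp, sum) /
             tapply(prof$n_pairs, grp, sum),
    p = tapply(prof$expected * prof$n_pairs, grp, sum) /
        tapply(prof$n_pairs, grp, sum),
    n_pairs = as.integer(tapply(prof$n_pairs, grp, sum)))
  agg <- agg[!is.na(agg$p), ]
  agg$p <- agg$p / sum(agg$p)
  agg$s_bp <- agg$s_bins * m$bin_size
  rownames(agg) <- NULL
  in_rng <- agg$s_bins >= slope_range[1] & agg$s_bins <= slope_range[2] &
            agg$p > 0
  slope <- if (sum(in_rng) >= 2)
    unname(stats::coef(stats::lm(log(p) ~ log(s_bins),
                                 data = agg[in_rng, ]))[2])
  else NA_real_
  structure(list(curve = agg[, c("s_bp", "s_bins", "p", "n_pairs")],
                 slope = slope, geometric_factor = geometric_factor),
            class = "ps_curve")
}

#' Inter-chromosomal (trans) contact fraction
#'
#' @param m a genome-wide [contact_matrix()] whose bin table spans
#'   multiple chromosomes.
#' @return fraction of total contacts joining different chromosomes.
#' @export
trans_ratio <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  chrom <- m$bins$chrom
  if (length(unique(chrom)) < 2) stop("need at least 2 chromosomes")
  tot <- sum(m$counts, na.rm = TRUE)
  if (tot <= 0) stop("zero total contacts")
  same <- outer(chrom, chrom, "==")
  sum(m$counts[!same], na.rm = TRUE) / tot
}
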