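#' A/B compartment profile from the leading eigenvector
#'
#' Per chromosome, PC1 is the leading eigenvector of the Pearson
#' correlation matrix of the observed-over-expected map. Its sign is
#' chosen so that PC1 correlates positively with `orientation_track`
#' (a gene-density-like activity proxy: compartment A is gene dense), and
#' bins are labeled `A` (PC1 > 0), `B` (PC1 < 0) or `undetermined`
#' (masked or exactly zero).
#'
#' @param m a balanced [contact_matrix()] at compartment resolution.
#' @param orientation_track per-bin numbers used only to fix the PC1 sign;
#'   `NULL` leaves the sign arbitrary (with a warning).
#' @return list of class `compartment_profile`: `bins`, `pc1`, `label`,
#'   `degenerate`, `oriented`.
#' @export
compute_pc1 <- function(m, orientation_track = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  n <- nrow(m$counts)
  if (!is.null(orientation_track) && length(orientation_track) != n)
    stop("orientation track length must equal number of bins")
  pc1 <- rep(NA_real_, n)
  degenerate <- FALSE
  for (ch in unique(m$bins$chrom)) {
    idx <- which(m$bins$chrom == ch)
    sub <- contact_matrix(m$counts[idx, idx, drop = FALSE],
                          genome_bins(ch, length(idx) * m$bin_size, m$bin_size),
                          weights = if (is.null(m$weights)) NULL
                                    else m$weights[idx],
                          balanced = m$balanced)
    oe <- observed_over_expected(sub)
    v <- valid_bins(sub)
    oe_v <- oe[v, v, drop = FALSE]
    sds <- apply(oe_v, 2, stats::sd, na.rm = TRUE)
    if (all(!is.finite(sds)) || max(sds, na.rm = TRUE) < 1e-10) {
      degenerate <- TRUE
      next
    }
    cc <- suppressWarnings(stats::cor(oe_v, use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    eg <- eigen(cc, symmetric = TRUE)
    if (abs(eg$values[1]) < 1e-12 ||
        (eg$values[1] - eg$values[2]) / abs(eg$values[1]) < 1e-8) {
      degenerate <- TRUE
      next
    }
    pc <- eg$vectors[, 1] * sqrt(abs(eg$values[1]))
    pc1[idx[v]] <- pc
  }
  oriented <- FALSE
  if (!is.null(orientation_track) && any(!is.na(pc1))) {
    ok <- !is.na(pc1) & !is.na(orientation_track)
    if (sum(ok) >= 2 && stats::sd(orientation_track[ok]) > 0 &&
        stats::sd(pc1[ok]) > 0) {
      if (stats::cor(pc1[ok], orientation_track[ok]) < 0) pc1 <- -pc1
      oriented <- TRUE
    }
  } else if (is.null(orientation_track)) {
    warning("no orientation track: PC1 sign is arbitrary")
  }
  label <- rep("undetermined", n)
  label[!is.na(pc1) & pc1 > 0] <- "A"
  label[!is.na(pc1) & pc1 < 0] <- "B"
  structure(list(bins = m$bins, pc1 = pc1, label = label,
                 degenerate = degenerate, oriented = oriented),
            class = "compartment_profile")
}

#' @export
print.compartment_profile <- function(x, ...) {
  cat(sprintf("compartment_profile: %d bins (%d A, %d B, %d undetermined)%s\n",
              length(x$pc1), sum(x$label == "A"), sum(x$label == "B"),
              sum(x$label == "undetermined"),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Compartment switching between two conditions
#'
#' Using zero as the PC1 cutoff, classifies every bin determined in both
#' profiles as stable A, stable B, A->B or B->A and reports the four
#' fractions (summing to 1) plus the number of excluded bins.
#'
#' @param p1,p2 [compute_pc1()] profiles on identical bins (condition 1 ->
#'   condition 2).
#' @return list of class `switch_summary`: `stable_a`, `stable_b`,
#'   `a_to_b`, `b_to_a`, `n_co_determined`, `n_excluded`.
#' @export
compartment_switches <- function(p1, p2) {
  stopifnot(inherits(p1, "compartment_profile"),
            inherits(p2, "compartment_profile"))
  if (!identical(p1$bins$start, p2$bins$start) ||
      !identical(p1$bins$chrom, p2$bins$chrom))
    stop("profiles are on different bins")
  ok <- p1$label != "undetermined" & p2$label != "undetermined"
  if (!any(ok)) stop("no co-determined bins")
  l1 <- p1$label[ok]; l2 <- p2$label[ok]
  n <- sum(ok)
  structure(list(stable_a = sum(l1 == "A" & l2 == "A") / n,
                 stable_b = sum(l1 == "B" & l2 == "B") / n,
                 a_to_b = sum(l1 == "A" & l2 == "B") / n,
                 b_to_a = sum(l1 == "B" & l2 == "A") / n,
                 n_co_determined = n, n_excluded = sum(!ok)),
            class = "switch_summary")
}

#' Inter- vs intra-compartment mixing ratio
#'
#' `AB / (AA + BB)`: the sum of balanced contacts over unordered A-B bin
#' pairs divided by the sum over same-class pairs, diagonal excluded,
#' computed per chromosome. Low values mean strict compartment
#' segregation.
#'
#' @param m a balanced [contact_matrix()].
#' @param profile a [compute_pc1()] profile on the same bins.
#' @param exclude_chroms chromosomes to drop (e.g. the X chromosome).
#' @return list of class `mixing_ratio`: data.frame `per_chrom`
#'   (`chrom`, `ratio`) and `overall` (pooled sums).
#' @export
mixing_ratio <- function(m, profile, exclude_chroms = character(0)) {
  stopifnot(inherits(m, "contact_matrix"),
            inherits(profile, "compartment_profile"))
  chroms <- setdiff(unique(m$bins$chrom), exclude_chroms)
  per <- data.frame(chrom = character(0), ratio = numeric(0))
  ab_tot <- 0; same_tot <- 0
  for (ch in chroms) {
    idx <- which(m$bins$chrom == ch)
    a <- idx[profile$label[idx] == "A"]
    b <- idx[profile$label[idx] == "B"]
    if (length(a) < 2) stop("class A absent or singleton on ", ch)
    if (length(b) < 2) stop("class B absent or singleton on ", ch)
    W <- m$counts
    ab <- sum(W[a, b], na.rm = TRUE)
    aa <- (sum(W[a, a], na.rm = TRUE) - sum(diag(W)[a], na.rm = TRUE)) / 2
    bb <- (sum(W[b, b], na.rm = TRUE) - sum(diag(W)[b], na.rm = TRUE)) / 2
    per <- rbind(per, data.frame(chrom = ch, ratio = ab / (aa + bb)))
    ab_tot <- ab_tot + ab; same_tot <- same_tot + aa + bb
  }
  structure(list(per_chrom = per, overall = ab_tot / same_tot),
            class = "mixing_ratio")
}

#' Saddle enrichment grid
#'
#' Bins determined in the profile are ranked by PC1 into `n_quantiles`
#' equal-count groups (group 1 = most negative PC1, i.e. strongest B);
#' cell (a, b) is the mean O/E over bin pairs from groups a and b. Strong
#' compartmentalization shows corner enrichment (B-B and A-A > 1) and
#' anti-corner depletion (A-B < 1).
#'
#' @param oe O/E matrix from [observed_over_expected()].
#' @param profile a [compute_pc1()] profile.
#' @param n_quantiles number of PC1 quantile groups.
#' @return list of class `saddle_result`: `grid` (symmetric
#'   `n_quantiles` x `n_quantiles`), `edges` (PC1 quantile edges).
#' @export
saddle <- function(oe, profile, n_quantiles = 5) {
  det <- which(profile$label != "undetermined")
  if (length(det) < n_quantiles)
    stop("fewer determined bins than quantile groups")
  pc <- profile$pc1[det]
  grp <- ceiling(rank(pc, ties.method = "first") / length(pc) * n_quantiles)
  G <- matrix(NA_real_, n_quantiles, n_quantiles)
  for (a in seq_len(n_quantiles)) for (b in a:n_quantiles) {
    ia <- det[grp == a]; ib <- det[grp == b]
    vals <- oe[ia, ib, drop = FALSE]
    if (a == b) vals[upper.tri(vals, diag = TRUE)] <- NA  # unordered, no diag
    mu <- mean(vals, na.rm = TRUE)
    G[a, b] <- mu; G[b, a] <- mu
  }
  structure(list(grid = G,
                 edges = stats::quantile(pc, seq(0, 1,
                                                 length.out = n_quantiles + 1))),
            class = "saddle_result")
}
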