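#' Insulation score profile
#'
#' For each bin, the raw score is the mean balanced contact in the
#' `w x w` bin square spanning `[i - w, i) x [i, i + w)` — contacts that
#' cross the bin's left edge; the reported score is
#' `log2(raw / chromosome mean raw)`. Bins where the window does not fit
#' inside the chromosome are masked.
#'
#' @param m a balanced [contact_matrix()] at TAD resolution.
#' @param window window size in bp (multiple of the bin size).
#' @return list of class `insulation_profile`: `bins`, `score` (log2),
#'   `raw`, `window_bins`.
#' @export
insulation_score <- function(m, window = 500e3) {
  stopifnot(inherits(m, "contact_matrix"))
  w <- max(1L, as.integer(round(window / m$bin_size)))  # window in whole bins
  n <- nrow(m$counts)
  if (2 * w > n) stop("window too large for the matrix")
  raw <- rep(NA_real_, n)
  W <- m$counts
  masked <- if (is.null(m$weights)) rep(FALSE, n) else is.na(m$weights)
  for (b in seq_len(n)) {        # 1-based bin; square rows (b-w):(b-1), cols b:(b+w-1)
    if (masked[b]) next
    if (b - w < 1 || b + w - 1 > n) next
    sq <- W[(b - w):(b - 1), b:(b + w - 1), drop = FALSE]
    if (all(is.na(sq))) next
    raw[b] <- mean(sq, na.rm = TRUE)
  }
  mu <- mean(raw, na.rm = TRUE)
  score <- log2(raw / mu)
  score[!is.finite(score)] <- NA_real_
  structure(list(bins = m$bins, score = score, raw = raw, window_bins = w),
            class = "insulation_profile")
}

#' Call TAD boundaries at insulation-score valleys
#'
#' The delta vector at bin i is the mean score over `delta_window` bp to
#' the left minus the mean to the right; boundaries sit at
#' positive-to-negative zero crossings of delta that are local minima of
#' the score, with boundary strength the delta swing (max delta over the
#' left window minus min over the right window). Boundaries weaker than
#' `min_strength` are dropped.
#'
#' @param profile an [insulation_score()] profile.
#' @param delta_window averaging window in bp.
#' @param min_strength minimum boundary strength (log2 units).
#' @return data.frame of class `boundary_set`: `bin` (0-based boundary
#'   index: the first bin of the downstream TAD), `strength`, `score`.
#' @export
call_boundaries <- function(profile, delta_window = 100e3,
                            min_strength = 0.1) {
  s <- profile$score
  n <- length(s)
  bin_size <- bin_size_of(profile$bins)
  dw <- max(1L, as.integer(round(delta_window / bin_size)))
  delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    l <- max(1, i - dw):(i - 1)
    r <- (i + 1):min(n, i + dw)
    if (i - dw < 1 || i + dw > n) next
    delta[i] <- mean(s[l], na.rm = TRUE) - mean(s[r], na.rm = TRUE)
  }
  out <- data.frame(bin = integer(0), strength = numeric(0),
                    score = numeric(0))
  for (i in seq_len(n - 1)) {
    if (is.na(delta[i]) || is.na(delta[i + 1])) next
    if (!(delta[i] >= 0 && delta[i + 1] < 0)) next
    # valley bin: score minimum in the crossing neighborhood
    nb <- max(1, i - 1):min(n, i + 2)
    nb <- nb[!is.na(s[nb])]
    if (!length(nb)) next
    vb <- nb[which.min(s[nb])]
    # valleys flanking a masked bin are balancing artifacts, not domain
    # boundaries
    if (vb > 1 && is.na(s[vb - 1])) next
    if (vb < n && is.na(s[vb + 1])) next
    lw <- max(1, vb - dw):vb
    rw <- vb:min(n, vb + dw)
    strength <- max(delta[lw], na.rm = TRUE) - min(delta[rw], na.rm = TRUE)
    if (!is.finite(strength) || strength < min_strength) next
    out <- rbind(out, data.frame(bin = vb - 1L, strength = strength,
                                 score = s[vb]))
  }
  out <- out[!duplicated(out$bin), ]
  rownames(out) <- NULL
  class(out) <- c("boundary_set", "data.frame")
  out
}

#' Build TAD intervals from boundaries
#'
#' TADs tile the chromosome between consecutive boundaries; the
#' chromosome ends close the first and last TAD. Intervals are half-open
#' in both bins and bp.
#'
#' @param boundaries 0-based boundary bin indices (vector or a
#'   `boundary_set`).
#' @param bins the [genome_bins()] table of the matrix (single chromosome).
#' @return data.frame of class `tad_set`: `chrom`, `start`, `end` (bp),
#'   `first_bin`, `last_bin` (0-based half-open), `size_bp`.
#' @export
tads_from_boundaries <- function(boundaries, bins) {
  if (is.data.frame(boundaries)) boundaries <- boundaries$bin
  boundaries <- sort(unique(as.integer(boundaries)))
  n <- nrow(bins)
  boundaries <- boundaries[boundaries > 0 & boundaries < n]
  edges <- c(0L, boundaries, n)
  firsts <- edges[-length(edges)]
  lasts <- edges[-1]
  out <- data.frame(chrom = bins$chrom[1],
                    start = bins$start[firsts + 1],
                    end = ifelse(lasts == n, bins$end[n],
                                 bins$start[pmin(lasts, n - 1) + 1]),
                    first_bin = firsts, last_bin = lasts)
  out$size_bp <- out$end - out$start
  class(out) <- c("tad_set", "data.frame")
  out
}

#' Boundaries of a TAD set
#' @param tads a `tad_set`.
#' @return 0-based interior boundary bin indices.
#' @export
boundaries_of <- function(tads) {
  b <- tads$first_bin
  b[b > 0]
}

#' TAD score: intra- over inter-TAD contact
#'
#' Per TAD, `intra` is the mean balanced contact over within-TAD bin
#' pairs (diagonal excluded) and `inter` the mean contact between the
#' TAD's bins and the bins of its adjacent TADs; the score is
#' `intra / inter`. TADs of fewer than 3 bins are skipped.
#'
#' @param m a balanced [contact_matrix()].
#' @param tads a [tads_from_boundaries()] table.
#' @return data.frame of class `tad_score_result`: `tad`, `intra`,
#'   `inter`, `score` (NA where skipped/undefined).
#' @export
tad_score <- function(m, tads) {
  W <- m$counts
  n <- nrow(W)
  out <- data.frame(tad = seq_len(nrow(tads)), intra = NA_real_,
                    inter = NA_real_, score = NA_real_)
  for (k in seq_len(nrow(tads))) {
    i0 <- tads$first_bin[k] + 1; i1 <- tads$last_bin[k]
    if (i1 > n || i1 - i0 + 1 < 3) next
    idx <- i0:i1
    sub <- W[idx, idx, drop = FALSE]
    sub[!upper.tri(sub)] <- NA
    intra <- mean(sub, na.rm = TRUE)
    nb <- integer(0)
    if (k > 1) nb <- c(nb, (tads$first_bin[k - 1] + 1):tads$last_bin[k - 1])
    if (k < nrow(tads)) nb <- c(nb, (tads$first_bin[k + 1] + 1):tads$last_bin[k + 1])
    if (!length(nb)) next
    inter <- mean(W[idx, nb], na.rm = TRUE)
    out$intra[k] <- intra
    out$inter[k] <- inter
    if (is.finite(inter) && inter > 0) out$score[k] <- intra / inter
  }
  class(out) <- c("tad_score_result", "data.frame")
  out
}

rescale_window <- function(x, out_pixels) {
  n <- nrow(x); m <- ncol(x)
  if (n == out_pixels && m == out_pixels) return(x)
  map <- function(P, N) if (N == 1) rep(1, P) else 1 + (seq_len(P) - 1) * (N - 1) / (P - 1)
  xi <- map(out_pixels, n); yi <- map(out_pixels, m)
  x0 <- pmin(floor(xi), n - 1); fx <- xi - x0
  y0 <- pmin(floor(yi), m - 1); fy <- yi - y0
  A <- x[x0, y0, drop = FALSE]; B <- x[x0 + 1, y0, drop = FALSE]
  C <- x[x0, y0 + 1, drop = FALSE]; D <- x[x0 + 1, y0 + 1, drop = FALSE]
  A * outer(1 - fx, 1 - fy) + B * outer(fx, 1 - fy) +
    C * outer(1 - fx, fy) + D * outer(fx, fy)
}

#' Aggregate TAD analysis (ATA)
#'
#' Each TAD larger than `min_size` is expanded by
#' `flank_fraction * size` on both sides, its O/E window rescaled by
#' bilinear interpolation to `out_pixels x out_pixels`, and the windows
#' averaged. With `flank_fraction = 0.5` and 90 output pixels the TAD
#' body occupies the central 45 pixels.
#'
#' @param m a balanced [contact_matrix()].
#' @param tads a `tad_set`.
#' @param min_size minimum TAD size in bp.
#' @param out_pixels output grid edge.
#' @param flank_fraction flank size as a fraction of TAD size.
#' @return list of class `ata_result`: `grid`, `n_tads`, `min_size`.
#' @export
aggregate_tads <- function(m, tads, min_size = 200e3, out_pixels = 90,
                           flank_fraction = 0.5) {
  oe <- observed_over_expected(m)
  n <- nrow(oe)
  acc <- matrix(0, out_pixels, out_pixels)
  wt <- matrix(0, out_pixels, out_pixels)
  used <- 0L
  for (k in seq_len(nrow(tads))) {
    if (tads$size_bp[k] < min_size) next
    len <- tads$last_bin[k] - tads$first_bin[k]
    fl <- round(flank_fraction * len)
    a <- tads$first_bin[k] - fl + 1     # 1-based window start
    b <- tads$last_bin[k] + fl          # 1-based window end
    if (a < 1 || b > n) next
    winm <- oe[a:b, a:b, drop = FALSE]
    # masked bins contribute zero weight; pixels average over the windows
    # that cover them
    wm <- (!is.na(winm)) * 1
    winm[is.na(winm)] <- 0
    acc <- acc + rescale_window(winm, out_pixels)
    wt <- wt + rescale_window(wm, out_pixels)
    used <- used + 1L
  }
  if (used == 0) stop("no TAD passes the size filter inside the matrix")
  grid <- acc / wt
  grid[wt < 1e-9] <- NA_real_
  structure(list(grid = grid, n_tads = used, min_size = min_size,
                 flank_fraction = flank_fraction),
            class = "ata_result")
}

#' Corner enrichment of an ATA grid
#'
#' Mean signal in neighborhoods around the two TAD corners of the
#' aggregated grid, relative to the mean over the off-corner border of
#' the TAD body; values above 1 indicate contacts piling up at TAD
#' corners.
#'
#' @param ata an `ata_result`.
#' @param halfwidth corner neighborhood half-width in pixels.
#' @return list: `corner_mean`, `border_mean`, `enrichment`.
#' @export
ata_corner_enrichment <- function(ata, halfwidth = 3) {
  G <- ata$grid
  P <- nrow(G)
  fl <- round(P * ata$flank_fraction / (1 + 2 * ata$flank_fraction))
  lo <- fl + 1; hi <- P - fl        # TAD body pixel range
  nb <- function(i, j) G[max(1, i - halfwidth):min(P, i + halfwidth),
                         max(1, j - halfwidth):min(P, j + halfwidth)]
  corner <- mean(c(nb(lo, hi), nb(hi, lo)), na.rm = TRUE)
  border <- G[lo:hi, c(lo, hi)]
  mid <- abs(seq(lo, hi) - (lo + hi) / 2) <= (hi - lo) / 4  # central stretch
  border_mean <- mean(border[mid, ], na.rm = TRUE)
  list(corner_mean = corner, border_mean = border_mean,
       enrichment = corner / border_mean)
}

#' TAD length statistics
#'
#' @param tads a `tad_set`.
#' @param long_threshold size separating short from long TADs, bp.
#' @return list: `n_short`, `n_long`, `median_bp`, `lengths_bp`.
#' @export
tad_length_stats <- function(tads, long_threshold = 500e3) {
  len <- tads$size_bp
  list(n_short = sum(len < long_threshold),
       n_long = sum(len > long_threshold),
       median_bp = if (length(len)) stats::median(len) else NA_real_,
       lengths_bp = len)
}
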