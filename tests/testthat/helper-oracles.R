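# Independent brute-force oracles used across the suite. These deliberately
# use naive loops so they share no code with the implementation.

brute_box_means <- function(x, box, stride) {
  vals <- numeric(0); dropped <- 0L
  for (i in seq(1, nrow(x) - box + 1, by = stride))
    for (j in seq(1, ncol(x) - box + 1, by = stride)) {
      tile <- x[i:(i + box - 1), j:(j + box - 1)]
      if (any(tile == 0)) dropped <- dropped + 1L
      else vals <- c(vals, sum(tile) / length(tile))
    }
  list(values = vals, n_discarded = dropped)
}

brute_expected_by_distance <- function(W) {
  n <- nrow(W)
  out <- rep(NA_real_, n)
  for (d in 0:(n - 1)) {
    acc <- c()
    for (i in 1:n) for (j in 1:n)
      if (j - i == d) acc <- c(acc, W[i, j])
    out[d + 1] <- mean(acc)
  }
  out
}

brute_insulation_raw <- function(W, w) {
  n <- nrow(W)
  raw <- rep(NA_real_, n)
  for (b in 1:n) {
    if (b - w < 1 || b + w - 1 > n) next
    acc <- c()
    for (i in (b - w):(b - 1)) for (j in b:(b + w - 1)) acc <- c(acc, W[i, j])
    raw[b] <- mean(acc)
  }
  raw
}

brute_mixing_ratio <- function(W, labels) {
  n <- nrow(W)
  ab <- aa <- bb <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (labels[i] != labels[j]) ab <- ab + W[i, j]
    else if (labels[i] == "A") aa <- aa + W[i, j]
    else bb <- bb + W[i, j]
  }
  ab / (aa + bb)
}

brute_rg <- function(coords, intensity, voxel_size) {
  voxel_size <- rep_len(voxel_size, 3)
  phys <- sweep(coords, 2, voxel_size, "*")
  ctr <- c(sum(phys[, 1] * intensity), sum(phys[, 2] * intensity),
           sum(phys[, 3] * intensity)) / sum(intensity)
  acc <- 0
  for (i in seq_len(nrow(phys)))
    acc <- acc + intensity[i] * sum((phys[i, ] - ctr)^2)
  sqrt(acc / sum(intensity))
}

brute_tad_score <- function(W, first_bin, last_bin, nb_bins) {
  idx <- (first_bin + 1):last_bin
  intra <- c()
  for (i in idx) for (j in idx) if (i < j) intra <- c(intra, W[i, j])
  inter <- c()
  for (i in idx) for (j in nb_bins) inter <- c(inter, W[i, j])
  mean(intra) / mean(inter)
}

# greedy matching of detected beads to planted truth within tol pixels
match_beads <- function(truth, found, tol = 2) {
  if (nrow(found) == 0)
    return(list(recall = 0, precision = NA_real_))
  D <- sqrt(outer(truth$x, found$x, "-")^2 + outer(truth$y, found$y, "-")^2)
  list(recall = mean(apply(D, 1, min) <= tol),
       precision = mean(apply(D, 2, min) <= tol))
}

# straight-fiber image with beads every `step` pixels, no noise unless asked
straight_fiber_image <- function(n_beads = 12, step = 10, amplitude = 300,
                                 background = 20, sigma_px = 1.5,
                                 pixel_size = 0.034, rows = 41,
                                 y0 = 15, x0 = 15) {
  w <- x0 * 2 + (n_beads - 1) * step
  img <- matrix(background, rows, w)
  xs <- x0 + (seq_len(n_beads) - 1) * step
  for (x in xs) {
    xr <- max(1, y0 - 6):min(rows, y0 + 6)
    yr <- max(1, x - 6):min(w, x + 6)
    d2 <- outer((xr - y0)^2, (yr - x)^2, "+")
    img[xr, yr] <- img[xr, yr] + amplitude * exp(-d2 / (2 * sigma_px^2))
  }
  list(image = nucleus_image(img, pixel_size), beads_x = xs, beads_y = y0)
}
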