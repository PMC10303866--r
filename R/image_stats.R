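#' Zero excluded regions and rescale to a common mean
#'
#' Nucleolar and extranuclear pixels are set to intensity 0; the remaining
#' nuclear pixels are rescaled so their mean equals `target_mean`,
#' removing expression-level differences between conditions before the
#' heterogeneity analysis.
#'
#' @param img a [nucleus_image()].
#' @param target_mean desired mean intensity over retained nuclear pixels.
#' @return a rescaled [nucleus_image()].
#' @export
mask_and_rescale <- function(img, target_mean = 100) {
  stopifnot(inherits(img, "nucleus_image"), target_mean > 0)
  keep <- img$nucleus_mask & !img$exclusion_mask
  if (!any(keep)) stop("nucleus mask is empty after exclusion")
  m <- mean(img$intensity[keep])
  if (m <= 0) stop("all-zero nucleus: cannot rescale")
  out <- img
  out$intensity[!keep] <- 0
  out$intensity[keep] <- img$intensity[keep] * (target_mean / m)
  out
}

#' Box-mean intensity distribution
#'
#' Traverses the image with a `box` x `box` pixel window (default stride =
#' box size, i.e. non-overlapping tiles) and records the mean intensity of
#' each box. A box containing any zero-intensity pixel (masked nucleolus /
#' extranuclear region) is discarded.
#'
#' @param img a [nucleus_image()] (typically after [mask_and_rescale()]).
#' @param box box edge in pixels.
#' @param stride step between box origins in pixels.
#' @return list of class `box_distribution`: `values`, `box`, `stride`,
#'   `n_discarded`.
#' @export
compute_box_intensities <- function(img, box = 5, stride = box) {
  stopifnot(inherits(img, "nucleus_image"), box >= 1, stride >= 1)
  x <- img$intensity
  if (box > nrow(x) || box > ncol(x))
    stop("box (", box, ") exceeds image dimension")
  xs <- seq(1, nrow(x) - box + 1, by = stride)
  ys <- seq(1, ncol(x) - box + 1, by = stride)
  vals <- numeric(0)
  dropped <- 0L
  for (i in xs) for (j in ys) {
    tile <- x[i:(i + box - 1), j:(j + box - 1)]
    if (any(tile == 0)) dropped <- dropped + 1L
    else vals <- c(vals, mean(tile))
  }
  structure(list(values = vals, box = box, stride = stride,
                 n_discarded = dropped),
            class = "box_distribution")
}

#' Fit a two-Gaussian decomposition to box intensities
#'
#' Nonlinear least squares of a two-component Gaussian density on the
#' density-normalized histogram (Freedman-Diaconis bin width), initialized
#' from the 25th/75th percentiles. The two peaks represent sparse and
#' dense nuclear regions; the heterogeneity level is the distance
#' `mu2 - mu1` between them. Degenerate single-population input yields
#' heterogeneity near 0 with `unimodal = TRUE` rather than an error.
#'
#' @param dist a `box_distribution` from [compute_box_intensities()], or a
#'   bare numeric vector of box values.
#' @return list of class `heterogeneity_result`: `mu1 <= mu2`, `sigma1`,
#'   `sigma2`, `weight1`, `heterogeneity`, `residual`, `unimodal`,
#'   `converged`.
#' @export
fit_double_gaussian <- function(dist) {
  v <- if (inherits(dist, "box_distribution")) dist$values else as.numeric(dist)
  if (length(v) < 50)
    stop("insufficient data: ", length(v), " box values (need >= 50)")
  if (stats::sd(v) < 1e-9 * max(abs(v), 1)) {
    return(structure(list(mu1 = mean(v), mu2 = mean(v), sigma1 = 0,
                          sigma2 = 0, weight1 = 1, heterogeneity = 0,
                          residual = 0, unimodal = TRUE, converged = TRUE),
                     class = "heterogeneity_result"))
  }
  bw <- 2 * stats::IQR(v) / length(v)^(1 / 3)   # Freedman-Diaconis
  if (bw <= 0) bw <- diff(range(v)) / 30
  brk <- seq(min(v) - bw, max(v) + bw, by = bw)
  h <- graphics::hist(v, breaks = brk, plot = FALSE)
  df <- data.frame(x = h$mids, d = h$density)
  # primary start from the 25th/75th percentiles; skewed distributions can
  # defeat it, so fall back to wider quantile splits
  starts <- list(
    list(w = 0.5, m1 = stats::quantile(v, 0.25)[[1]], s1 = stats::sd(v) / 2,
         m2 = stats::quantile(v, 0.75)[[1]], s2 = stats::sd(v) / 2),
    list(w = 0.5, m1 = stats::quantile(v, 0.1)[[1]], s1 = stats::sd(v) / 4,
         m2 = stats::quantile(v, 0.9)[[1]], s2 = stats::sd(v) / 4),
    list(w = 0.7, m1 = stats::median(v[v <= stats::median(v)]),
         s1 = stats::sd(v) / 4,
         m2 = stats::median(v[v > stats::median(v)]),
         s2 = stats::sd(v)))
  fit <- NULL
  for (st in starts) {
    f1 <- tryCatch(
      minpack.lm::nlsLM(
        d ~ w * stats::dnorm(x, m1, s1) + (1 - w) * stats::dnorm(x, m2, s2),
        data = df, start = st,
        lower = c(w = 0.01, m1 = -Inf, s1 = bw / 4, m2 = -Inf, s2 = bw / 4),
        upper = c(w = 0.99, m1 = Inf, s1 = Inf, m2 = Inf, s2 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f1) &&
        (is.null(fit) || sum(stats::resid(f1)^2) < sum(stats::resid(fit)^2)))
      fit <- f1
  }
  if (is.null(fit)) {
    return(structure(list(mu1 = mean(v), mu2 = mean(v),
                          sigma1 = stats::sd(v), sigma2 = stats::sd(v),
                          weight1 = 1, heterogeneity = 0,
                          residual = NA_real_, unimodal = TRUE,
                          converged = FALSE),
                     class = "heterogeneity_result"))
  }
  cf <- stats::coef(fit)
  m1 <- cf[["m1"]]; m2 <- cf[["m2"]]
  s1 <- cf[["s1"]]; s2 <- cf[["s2"]]; w <- cf[["w"]]
  if (m1 > m2) { tmp <- m1; m1 <- m2; m2 <- tmp
                 tmp <- s1; s1 <- s2; s2 <- tmp
                 w <- 1 - w }
  pooled <- sqrt(w * s1^2 + (1 - w) * s2^2)
  structure(list(mu1 = m1, mu2 = m2, sigma1 = s1, sigma2 = s2,
                 weight1 = w, heterogeneity = m2 - m1,
                 residual = sum(stats::resid(fit)^2),
                 unimodal = (m2 - m1) < pooled,
                 converged = TRUE),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf(
    "heterogeneity_result: mu1 %.3g, mu2 %.3g, separation %.3g%s\n",
    x$mu1, x$mu2, x$heterogeneity, if (x$unimodal) " (unimodal)" else ""))
  invisible(x)
}

#' Heterogeneity level of a nuclear signal
#'
#' Full composition of [mask_and_rescale()], [compute_box_intensities()]
#' and [fit_double_gaussian()]; higher values indicate stronger
#' accumulation of signal into dense fibrous structures relative to the
#' diffuse pool. `mean_intensity` is the nuclear mean before rescaling,
#' for expression-level vs heterogeneity plots.
#'
#' @param img a [nucleus_image()].
#' @param target_mean rescaling target.
#' @param box,stride box parameters in pixels.
#' @return a `heterogeneity_result` with `mean_intensity` added.
#' @export
heterogeneity_level <- function(img, target_mean = 100, box = 5, stride = box) {
  keep <- img$nucleus_mask & !img$exclusion_mask
  if (!any(keep)) stop("nucleus mask is empty after exclusion")
  pre_mean <- mean(img$intensity[keep])
  res <- fit_double_gaussian(
    compute_box_intensities(mask_and_rescale(img, target_mean), box, stride))
  res$mean_intensity <- pre_mean
  res
}

bilinear_at <- function(x, xi, yi) {
  h <- nrow(x); w <- ncol(x)
  xi <- pmin(pmax(xi, 1), h); yi <- pmin(pmax(yi, 1), w)
  x0 <- pmin(floor(xi), h - 1); y0 <- pmin(floor(yi), w - 1)
  fx <- xi - x0; fy <- yi - y0
  x[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    x[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    x[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    x[cbind(x0 + 1, y0 + 1)] * fx * fy
}

#' Detect beads and link them into fibers
#'
#' Beads are local maxima of a difference-of-Gaussians band-pass
#' (`psf_sigma` vs `2*psf_sigma`) above a relative threshold, kept at a
#' minimum pairwise separation, refined to sub-pixel position by quadratic
#' interpolation. Fibers are formed by linking mutually nearest maxima
#' (within `2 * expected_spacing`) into chains and ordering each chain by
#' walking from an endpoint.
#'
#' @param img a [nucleus_image()].
#' @param psf_sigma PSF sigma in um.
#' @param min_separation minimum bead separation in um.
#' @param threshold relative threshold on the band-passed image (fraction
#'   of its maximum).
#' @param expected_spacing expected inter-bead distance in um (chain
#'   linking radius is twice this).
#' @return list of class `bead_set`: data.frame `beads` (`x`, `y` in px,
#'   `fiber`, `order`) and `pixel_size`.
#' @export
detect_beads <- function(img, psf_sigma = 0.05, min_separation = 0.15,
                         threshold = 0.3, expected_spacing = 0.34) {
  stopifnot(inherits(img, "nucleus_image"))
  px <- img$pixel_size
  s1 <- max(0.8, psf_sigma / px)
  dog <- EBImage::gblur(img$intensity, sigma = s1) -
         EBImage::gblur(img$intensity, sigma = 2 * s1)
  dog[!img$nucleus_mask | img$exclusion_mask] <- -Inf
  h <- nrow(dog); w <- ncol(dog)
  # strict local maxima over the 8-neighborhood
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- dog
  ctr <- pad[2:(h + 1), 2:(w + 1)]
  is_max <- ctr > -Inf
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    is_max <- is_max & (ctr >= pad[(2 + dx):(h + 1 + dx), (2 + dy):(w + 1 + dy)])
  }
  lim <- threshold * max(dog[is.finite(dog)])
  cand <- which(is_max & ctr >= lim, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(structure(list(beads = data.frame(x = numeric(0), y = numeric(0),
                                             fiber = integer(0),
                                             order = integer(0)),
                          pixel_size = px), class = "bead_set"))
  ord <- order(dog[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  min_px <- min_separation / px
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(kept) == 0 ||
        min(sqrt((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2)) >= min_px)
      kept <- rbind(kept, p)
  }
  # sub-pixel refinement by 1D parabola through the 3-point neighborhood
  refine <- function(i, j) {
    rx <- 0; ry <- 0
    if (i > 1 && i < h) {
      a <- dog[i - 1, j]; b <- dog[i, j]; c <- dog[i + 1, j]
      den <- a - 2 * b + c
      if (is.finite(den) && den < 0) rx <- 0.5 * (a - c) / den
    }
    if (j > 1 && j < w) {
      a <- dog[i, j - 1]; b <- dog[i, j]; c <- dog[i, j + 1]
      den <- a - 2 * b + c
      if (is.finite(den) && den < 0) ry <- 0.5 * (a - c) / den
    }
    c(i + max(-0.5, min(0.5, rx)), j + max(-0.5, min(0.5, ry)))
  }
  pts <- t(apply(kept, 1, function(p) refine(p[1], p[2])))
  n <- nrow(pts)
  link_r <- 2 * expected_spacing / px
  if (n >= 2) {
    D <- as.matrix(stats::dist(pts))
    diag(D) <- Inf
    near2 <- t(apply(D, 1, function(r) order(r)[1:2]))
    el <- matrix(0L, 0, 2)
    for (i in seq_len(n)) for (j in near2[i, ]) {
      if (i < j && i %in% near2[j, ] && D[i, j] <= link_r)
        el <- rbind(el, c(i, j))
    }
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    igraph::E(g)$weight <- D[el]
    comp <- igraph::components(g)$membership
  } else {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    comp <- seq_len(max(n, 1))[seq_len(n)]
  }
  beads <- data.frame(x = pts[, 1], y = pts[, 2], fiber = NA_integer_,
                      order = NA_integer_)
  # each fiber is the weighted geodesic between the two farthest beads of
  # a linked component; beads hanging off that backbone (side branches)
  # become singleton fibers so they never contribute spurious spacings
  next_fiber <- 1L
  for (f in unique(comp)) {
    idx <- which(comp == f)
    if (length(idx) == 1) {
      beads$fiber[idx] <- next_fiber; beads$order[idx] <- 1L
      next_fiber <- next_fiber + 1L
      next
    }
    sub <- igraph::induced_subgraph(g, idx)
    dm <- igraph::distances(sub)
    ends <- which(dm == max(dm[is.finite(dm)]), arr.ind = TRUE)[1, ]
    sp <- igraph::shortest_paths(sub, from = ends[1], to = ends[2])$vpath[[1]]
    chain <- idx[as.integer(sp)]
    beads$fiber[chain] <- next_fiber
    beads$order[chain] <- seq_along(chain)
    next_fiber <- next_fiber + 1L
    for (v in setdiff(idx, chain)) {
      beads$fiber[v] <- next_fiber; beads$order[v] <- 1L
      next_fiber <- next_fiber + 1L
    }
  }
  structure(list(beads = beads, pixel_size = px), class = "bead_set")
}

#' Inter-bead spacings along fibers
#'
#' Euclidean distances between order-consecutive beads of the same fiber,
#' in um; cross-fiber pairs never contribute.
#'
#' @param bead_set a `bead_set` from [detect_beads()], or a data.frame
#'   with `x`, `y`, `fiber`, `order` plus a `pixel_size` argument.
#' @param pixel_size um per pixel (taken from the `bead_set` if absent).
#' @return list of class `bead_spacing_summary`: `spacings` (um), `mean`,
#'   `median`, `n`.
#' @export
bead_spacings <- function(bead_set, pixel_size = NULL) {
  if (inherits(bead_set, "bead_set")) {
    df <- bead_set$beads
    if (is.null(pixel_size)) pixel_size <- bead_set$pixel_size
  } else df <- bead_set
  stopifnot(!is.null(pixel_size))
  sp <- numeric(0)
  for (f in unique(df$fiber)) {
    b <- df[df$fiber == f, ]
    b <- b[order(b$order), ]
    if (nrow(b) < 2) next
    sp <- c(sp, sqrt(diff(b$x)^2 + diff(b$y)^2) * pixel_size)
  }
  structure(list(spacings = sp,
                 mean = if (length(sp)) mean(sp) else NA_real_,
                 median = if (length(sp)) stats::median(sp) else NA_real_,
                 n = length(sp), empty = length(sp) == 0),
            class = "bead_spacing_summary")
}

#' Pearson colocalization of two channels
#'
#' Whole-ROI Pearson correlation over the nucleus mask minus exclusion
#' mask (no intensity thresholding).
#'
#' @param img_a,img_b [nucleus_image()] objects on the same grid.
#' @param mask optional logical matrix overriding the default ROI.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_colocalization <- function(img_a, img_b, mask = NULL) {
  if (!identical(dim(img_a$intensity), dim(img_b$intensity)))
    stop("channel shapes differ")
  if (is.null(mask))
    mask <- img_a$nucleus_mask & !img_a$exclusion_mask &
            img_b$nucleus_mask & !img_b$exclusion_mask
  a <- img_a$intensity[mask]; b <- img_b$intensity[mask]
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: constant channel within mask")
  stats::cor(a, b)
}

#' Segment supra-threshold clusters
#'
#' Connected components (8-connectivity) of pixels above an absolute
#' intensity threshold, discarding components whose equivalent diameter
#' (diameter of the disc with the same area) is below `min_diameter`.
#' Defaults mirror a surface-based cluster search with a 0.492 um minimum
#' feature diameter at threshold 25.
#'
#' @param img a [nucleus_image()].
#' @param threshold absolute intensity threshold (> 0).
#' @param min_diameter minimum equivalent diameter in um.
#' @return data.frame of class `cluster_set`: `label`, `n_pixels`,
#'   `area_um2`, `equiv_diameter_um`.
#' @export
segment_clusters <- function(img, threshold = 25, min_diameter = 0.492) {
  stopifnot(threshold > 0)
  bw <- img$intensity > threshold & img$nucleus_mask & !img$exclusion_mask
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  if (max(lab) == 0)
    return(structure(data.frame(label = integer(0), n_pixels = integer(0),
                                area_um2 = numeric(0),
                                equiv_diameter_um = numeric(0)),
                     class = c("cluster_set", "data.frame")))
  npx <- tabulate(lab[lab > 0])
  area <- npx * img$pixel_size^2
  dia <- 2 * sqrt(area / pi)
  keep <- dia >= min_diameter
  out <- data.frame(label = seq_along(npx), n_pixels = npx,
                    area_um2 = area, equiv_diameter_um = dia)[keep, ]
  rownames(out) <- NULL
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Normalized intensity profile along a segment
#'
#' Samples each channel at 1-pixel steps along the segment, averaging
#' across `width` pixels perpendicular to it, then max-normalizes each
#' channel to 1.
#'
#' @param channels a [nucleus_image()] or list of 1-2 of them.
#' @param from,to segment endpoints, `c(x, y)` in pixel coordinates.
#' @param width averaging width in pixels (odd).
#' @return list of class `line_profile`: `position_um` and a matrix
#'   `intensity` with one column per channel.
#' @export
line_profile <- function(channels, from, to, width = 1) {
  if (inherits(channels, "nucleus_image")) channels <- list(channels)
  px <- channels[[1]]$pixel_size
  v <- c(to[1] - from[1], to[2] - from[2])
  len <- sqrt(sum(v^2))
  if (len == 0) stop("zero-length segment")
  u <- v / len
  perp <- c(-u[2], u[1])
  steps <- seq(0, len, by = 1)
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, by = 1)
  prof <- sapply(channels, function(ch) {
    x <- ch$intensity
    vapply(steps, function(s) {
      xs <- from[1] + s * u[1] + offs * perp[1]
      ys <- from[2] + s * u[2] + offs * perp[2]
      mean(bilinear_at(x, xs, ys))
    }, numeric(1))
  })
  prof <- as.matrix(prof)
  for (k in seq_len(ncol(prof))) {
    mx <- max(prof[, k])
    if (mx > 0) prof[, k] <- prof[, k] / mx
  }
  structure(list(position_um = steps * px, intensity = prof),
            class = "line_profile")
}
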