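#' Parameters for the synthetic nucleus-image generator
#'
#' Emulates super-resolution images of nuclear cohesin: either a uniform
#' nuclear signal or a "vermicelli" mode in which bright beads are placed
#' at regular arc-length intervals along smoothed random-walk fibers, then
#' rendered with a Gaussian PSF over a background, with optional nucleoli
#' (excluded discs) and Poisson and/or Gaussian camera noise.
#'
#' @param height,width image size in pixels.
#' @param pixel_size um per pixel.
#' @param mode `"uniform"` or `"vermicelli"`.
#' @param n_fibers number of fibers (vermicelli mode).
#' @param bead_spacing arc-length spacing between consecutive beads, um.
#'   The default 0.34 um matches the regular inter-bead distance seen
#'   along cohesin fibers.
#' @param spacing_jitter_sd Gaussian jitter of the arc position, um.
#' @param bead_amplitude peak intensity added per bead (photon units).
#' @param background uniform nuclear background intensity.
#' @param psf_sigma Gaussian PSF sigma, um.
#' @param nucleolus_count,nucleolus_radius number and radius (pixels) of
#'   excluded nucleolar discs.
#' @param poisson_noise draw Poisson shot noise.
#' @param gaussian_sd additive Gaussian read noise sd (0 = off).
#' @param seed RNG seed.
#' @return an object of class `image_sim_params`.
#' @export
image_sim_params <- function(height = 160, width = 160, pixel_size = 0.034,
                             mode = c("vermicelli", "uniform"),
                             n_fibers = 4, bead_spacing = 0.34,
                             spacing_jitter_sd = 0, bead_amplitude = 300,
                             background = 30, psf_sigma = 0.05,
                             nucleolus_count = 0, nucleolus_radius = 8,
                             poisson_noise = TRUE, gaussian_sd = 0,
                             seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(height >= 16, width >= 16, pixel_size > 0, psf_sigma > 0,
            bead_amplitude >= 0, background >= 0, gaussian_sd >= 0)
  if (mode == "vermicelli" && bead_spacing <= 2 * psf_sigma)
    stop("bead_spacing must exceed 2*psf_sigma for resolvable beads")
  structure(list(height = as.integer(height), width = as.integer(width),
                 pixel_size = pixel_size, mode = mode,
                 n_fibers = as.integer(n_fibers),
                 bead_spacing = bead_spacing,
                 spacing_jitter_sd = spacing_jitter_sd,
                 bead_amplitude = bead_amplitude, background = background,
                 psf_sigma = psf_sigma,
                 nucleolus_count = as.integer(nucleolus_count),
                 nucleolus_radius = nucleolus_radius,
                 poisson_noise = isTRUE(poisson_noise),
                 gaussian_sd = gaussian_sd, seed = as.integer(seed)),
            class = "image_sim_params")
}

#' Simulate a nucleus image with planted beads
#'
#' @param params an [image_sim_params()] object.
#' @return list with `image` (a [nucleus_image()]) and `truth`, a
#'   data.frame of planted beads (sub-pixel `x`, `y` in pixels, `fiber`,
#'   `order`, `arc_um` cumulative arc length along the fiber).
#' @export
simulate_nucleus_image <- function(params) {
  stopifnot(inherits(params, "image_sim_params"))
  p <- params
  local_seed(p$seed)
  h <- p$height; w <- p$width
  cx <- (h + 1) / 2; cy <- (w + 1) / 2
  r_nuc <- 0.42 * min(h, w)
  if (r_nuc < 6 * p$psf_sigma / p$pixel_size)
    stop("nucleus smaller than the PSF support")
  xg <- matrix(seq_len(h), h, w)
  yg <- matrix(seq_len(w), h, w, byrow = TRUE)
  nucleus <- (xg - cx)^2 + (yg - cy)^2 <= r_nuc^2
  exclusion <- matrix(FALSE, h, w)
  for (k in seq_len(p$nucleolus_count)) {
    repeat {
      nx <- cx + stats::runif(1, -0.6, 0.6) * r_nuc
      ny <- cy + stats::runif(1, -0.6, 0.6) * r_nuc
      if ((nx - cx)^2 + (ny - cy)^2 <= (0.7 * r_nuc)^2) break
    }
    exclusion <- exclusion |
      ((xg - nx)^2 + (yg - ny)^2 <= p$nucleolus_radius^2)
  }
  exclusion <- exclusion & nucleus

  # occupancy of previously drawn fibers: fibers avoid one another so that
  # beads on different fibers stay mutually resolvable
  occ <- matrix(FALSE, h, w)
  avoid_px <- max(4, ceiling(p$bead_spacing / p$pixel_size))
  inside <- function(x, y) {
    ok <- (x - cx)^2 + (y - cy)^2 <= (0.95 * r_nuc)^2
    if (ok) {
      xi <- pmin(pmax(round(x), 1), h); yi <- pmin(pmax(round(y), 1), w)
      ok <- !exclusion[xi, yi] && !occ[xi, yi]
    }
    ok
  }
  stamp <- function(path) {
    for (q in seq_len(nrow(path))) {
      xr <- max(1, round(path[q, 1]) - avoid_px):min(h, round(path[q, 1]) + avoid_px)
      yr <- max(1, round(path[q, 2]) - avoid_px):min(w, round(path[q, 2]) + avoid_px)
      occ[xr, yr] <<- TRUE
    }
  }

  beads <- data.frame(x = numeric(0), y = numeric(0), fiber = integer(0),
                      order = integer(0), arc_um = numeric(0))
  if (p$mode == "vermicelli" && p$n_fibers > 0) {
    step_px <- max(1, p$bead_spacing / p$pixel_size / 8)
    for (f in seq_len(p$n_fibers)) {
      # smoothed random walk confined to the nucleus
      repeat {
        x <- cx + stats::runif(1, -0.6, 0.6) * r_nuc
        y <- cy + stats::runif(1, -0.6, 0.6) * r_nuc
        if (inside(x, y)) break
      }
      theta <- stats::runif(1, 0, 2 * pi)
      path <- matrix(c(x, y), 1, 2)
      n_steps <- round(4 * r_nuc / step_px)
      lag <- ceiling(2 * avoid_px / step_px)   # ignore the recent segment
      far_from_own <- function(nx, ny) {
        if (nrow(path) <= lag) return(TRUE)
        old <- path[seq_len(nrow(path) - lag), , drop = FALSE]
        min((old[, 1] - nx)^2 + (old[, 2] - ny)^2) >= avoid_px^2
      }
      for (s in seq_len(n_steps)) {
        ok <- FALSE
        for (try in 1:20) {
          th <- theta + stats::rnorm(1, 0, 0.08)
          nx <- x + step_px * cos(th); ny <- y + step_px * sin(th)
          if (inside(nx, ny) && far_from_own(nx, ny)) {
            ok <- TRUE; theta <- th; x <- nx; y <- ny; break
          }
          theta <- theta + stats::runif(1, -pi / 2, pi / 2)
        }
        if (!ok) break
        path <- rbind(path, c(x, y))
      }
      if (nrow(path) < 3) next
      seg <- sqrt(rowSums((path[-1, , drop = FALSE] -
                           path[-nrow(path), , drop = FALSE])^2))
      arc_px <- c(0, cumsum(seg))
      arc_um <- arc_px * p$pixel_size
      total <- arc_um[length(arc_um)]
      targets <- seq(p$bead_spacing / 2, total, by = p$bead_spacing)
      if (p$spacing_jitter_sd > 0)
        targets <- targets + stats::rnorm(length(targets), 0, p$spacing_jitter_sd)
      targets <- targets[targets >= 0 & targets <= total]
      if (length(targets) < 1) next
      bx <- stats::approx(arc_um, path[, 1], xout = targets)$y
      by <- stats::approx(arc_um, path[, 2], xout = targets)$y
      keep <- vapply(seq_along(bx), function(i) inside(bx[i], by[i]), logical(1))
      stamp(path)
      if (!any(keep)) next
      beads <- rbind(beads, data.frame(x = bx[keep], y = by[keep], fiber = f,
                                       order = seq_len(sum(keep)),
                                       arc_um = targets[keep]))
    }
  }

  img <- matrix(0, h, w)
  img[nucleus & !exclusion] <- p$background
  sig_px <- p$psf_sigma / p$pixel_size
  win <- ceiling(4 * sig_px)
  for (i in seq_len(nrow(beads))) {
    xi <- round(beads$x[i]); yi <- round(beads$y[i])
    xr <- max(1, xi - win):min(h, xi + win)
    yr <- max(1, yi - win):min(w, yi + win)
    d2 <- outer((xr - beads$x[i])^2, (yr - beads$y[i])^2, "+")
    img[xr, yr] <- img[xr, yr] + p$bead_amplitude * exp(-d2 / (2 * sig_px^2))
  }
  if (p$poisson_noise)
    img[] <- stats::rpois(length(img), img)
  if (p$gaussian_sd > 0)
    img[] <- pmax(0, img + stats::rnorm(length(img), 0, p$gaussian_sd))

  list(image = nucleus_image(img, p$pixel_size, nucleus, exclusion),
       truth = beads)
}
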