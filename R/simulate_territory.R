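#' Parameters for the synthetic chromosome-territory generator
#'
#' Produces voxel clouds for radius-of-gyration analysis: a filled ball
#' (compact territory) or a random-walk fiber (elongated, vermicelli-like
#' territory) of a given voxel count.
#'
#' @param shape `"ball"` or `"fiber"`.
#' @param radius ball radius in voxels (>= 1).
#' @param fiber_length number of voxels in a fiber.
#' @param voxel_size um per voxel along x, y, z (scalar or length 3).
#' @param intensity_model `"uniform"` or `"gradient"` (intensity falls
#'   linearly from the cloud center to 0.5 at the periphery).
#' @param seed RNG seed (fiber shape only).
#' @return an object of class `territory_sim_params`.
#' @export
territory_sim_params <- function(shape = c("ball", "fiber"), radius = 20,
                                 fiber_length = 500, voxel_size = 1,
                                 intensity_model = c("uniform", "gradient"),
                                 seed = 1L) {
  shape <- match.arg(shape)
  intensity_model <- match.arg(intensity_model)
  if (shape == "ball" && radius < 1) stop("radius must be >= 1 voxel")
  stopifnot(fiber_length >= 1, all(voxel_size > 0))
  structure(list(shape = shape, radius = radius,
                 fiber_length = as.integer(fiber_length),
                 voxel_size = rep_len(as.numeric(voxel_size), 3),
                 intensity_model = intensity_model, seed = as.integer(seed)),
            class = "territory_sim_params")
}

#' Simulate a chromosome-territory voxel cloud
#'
#' @param params a [territory_sim_params()] object.
#' @return a [voxel_cloud()].
#' @export
simulate_territory <- function(params) {
  stopifnot(inherits(params, "territory_sim_params"))
  p <- params
  if (p$shape == "ball") {
    r <- p$radius
    ax <- seq(-ceiling(r), ceiling(r))
    g <- expand.grid(x = ax, y = ax, z = ax)
    keep <- g$x^2 + g$y^2 + g$z^2 <= r^2
    coords <- as.matrix(g[keep, ])
  } else {
    local_seed(p$seed)
    # lattice random walk, duplicates dropped, until fiber_length voxels
    steps <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
    pos <- c(0L, 0L, 0L)
    seen <- new.env(hash = TRUE)
    coords <- matrix(0L, p$fiber_length, 3)
    n <- 1L
    assign("0,0,0", TRUE, seen)
    coords[1, ] <- pos
    guard <- 0L
    while (n < p$fiber_length && guard < 200L * p$fiber_length) {
      guard <- guard + 1L
      pos2 <- pos + steps[sample.int(6, 1), ]
      key <- paste(pos2, collapse = ",")
      pos <- pos2
      if (!exists(key, seen, inherits = FALSE)) {
        assign(key, TRUE, seen)
        n <- n + 1L
        coords[n, ] <- pos2
      }
    }
    coords <- coords[seq_len(n), , drop = FALSE]
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  if (p$intensity_model == "uniform") {
    intensity <- rep(1, nrow(coords))
  } else {
    ctr <- colMeans(coords)
    d <- sqrt(rowSums(sweep(coords, 2, ctr)^2))
    dmax <- max(d, 1e-9)
    intensity <- 1 - 0.5 * d / dmax
  }
  voxel_cloud(coords, intensity, p$voxel_size)
}
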