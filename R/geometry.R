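#' Label 3D connected components
#'
#' Maximal connected components of a binary volume under 6- or
#' 26-connectivity, built as connected components of the voxel adjacency
#' graph. Intensities are attached from the source volume.
#'
#' @param volume logical (or 0/1) 3D array.
#' @param intensity optional numeric 3D array of the same shape; defaults
#'   to 1 everywhere.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @param voxel_size um per voxel along x, y, z.
#' @return list of [voxel_cloud()] objects, one per component, largest
#'   first; empty list for an empty volume.
#' @export
label_components <- function(volume, intensity = NULL, connectivity = 26,
                             voxel_size = 1) {
  stopifnot(length(dim(volume)) == 3, connectivity %in% c(6, 26))
  idx <- which(volume != 0)
  if (!length(idx)) return(list())
  dm <- dim(volume)
  coords <- arrayInd(idx, dm)
  pos <- integer(prod(dm))
  pos[idx] <- seq_along(idx)           # linear index -> voxel rank
  if (connectivity == 6) {
    offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
                 drop = FALSE]          # half the neighborhood, undirected
  }
  el <- matrix(0L, 0, 2)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
          nb[, 3] >= 1 & nb[, 3] <= dm[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1) * dm[1] + (nb[ok, 3] - 1) * dm[1] * dm[2]
    hit <- pos[lin] > 0
    if (any(hit))
      el <- rbind(el, cbind(which(ok)[hit], pos[lin][hit]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  if (is.null(intensity)) intensity <- array(1, dm)
  comp_ids <- order(tabulate(memb), decreasing = TRUE)
  lapply(seq_along(comp_ids), function(r) {
    cid <- comp_ids[r]
    sel <- memb == cid
    voxel_cloud(coords[sel, , drop = FALSE], intensity[idx[sel]],
                voxel_size, label = r)
  })
}

#' Intensity-weighted radius of gyration
#'
#' `Rg = sqrt( sum_i I_i * |r_i - r_c|^2 / sum_i I_i )` with `r_c` the
#' intensity-weighted centroid, distances in physical units (per-axis
#' voxel size applied before squaring, so anisotropic z spacing is
#' honored).
#'
#' @param cloud a [voxel_cloud()].
#' @return list of class `rg_result`: `center` (um), `rg` (um),
#'   `n_voxels`, `total_intensity`.
#' @export
radius_of_gyration <- function(cloud) {
  stopifnot(inherits(cloud, "voxel_cloud"))
  I <- cloud$intensity
  tot <- sum(I)
  if (tot <= 0) stop("zero total intensity")
  R <- sweep(cloud$coords, 2, cloud$voxel_size, "*")
  ctr <- colSums(R * I) / tot
  d2 <- rowSums(sweep(R, 2, ctr)^2)
  structure(list(center = ctr, rg = sqrt(sum(I * d2) / tot),
                 n_voxels = nrow(R), total_intensity = tot),
            class = "rg_result")
}

#' @export
print.rg_result <- function(x, ...) {
  cat(sprintf("rg_result: Rg %.4g um over %d voxels\n", x$rg, x$n_voxels))
  invisible(x)
}
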