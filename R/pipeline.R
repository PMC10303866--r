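#' Default analysis configuration
#'
#' Nested named parameter groups for every pipeline stage. All numeric
#' parameters carry units in their names (`_bp`, `_um`, `_s`) or are
#' dimensionless. [load_config()] merges a YAML file over these defaults
#' and rejects unknown keys.
#'
#' @return nested list of class `analysis_config`.
#' @export
default_config <- function() {
  structure(list(
    paths = list(image = NULL, image_b = NULL, matrix = NULL, bins = NULL,
                 traces = NULL, track = NULL, tads = NULL, volume = NULL),
    resolutions = list(compartment_bp = 150e3, tad_bp = 40e3),
    heterogeneity = list(box_px = 5, stride_px = 5, target_mean = 100),
    beads = list(psf_sigma_um = 0.05, min_separation_um = 0.15,
                 threshold_rel = 0.3, expected_spacing_um = 0.34),
    clusters = list(threshold = 25, min_diameter_um = 0.492),
    frap = list(pre_frames = 3),
    hic = list(ice_tol = 1e-5, ice_max_iter = 200, min_coverage_mad = 3,
               target_total = 160e6, geometric_factor = 1.12),
    compartments = list(n_quantiles = 5, exclude_chroms = character(0)),
    tads = list(window_bp = 500e3, delta_window_bp = 100e3,
                min_strength = 0.1),
    ata = list(min_size_bp = 200e3, out_pixels = 90, flank_fraction = 0.5),
    rg = list(connectivity = 26, voxel_size_um = c(0.1, 0.1, 0.3)),
    simulate = list(n_bins = 200, depth = 2e6, image_px = 160,
                    pixel_size_um = 0.034)
  ), class = "analysis_config")
}

merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    if (!k %in% names(base))
      stop("unknown config key: ", sub("^\\.", "", paste0(path, ".", k)))
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]],
                                paste0(path, ".", k))
    else base[[k]] <- override[[k]]
  }
  base
}

#' Load a YAML configuration over the defaults
#'
#' @param path YAML file with (a subset of) the groups of
#'   [default_config()]; unknown keys raise a named error.
#' @return an `analysis_config`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(unclass(default_config()), user)
  structure(cfg, class = "analysis_config")
}

pipeline_stages <- function() {
  c("simulate-hic", "simulate-image", "simulate-frap", "heterogeneity",
    "beads", "coloc", "clusters", "frap-fit", "ifrap", "hic-stats",
    "compartments", "tads", "ata", "rg", "demo-contrast")
}

#' Run one pipeline stage
#'
#' Dispatches to the analysis functions with parameters taken from the
#' config, reads inputs from `config$paths` (or simulates them when a
#' path is `NULL`), writes stage outputs under `out_dir` and a
#' `<stage>.log.json` recording the parameters used. Deterministic given
#' `config` and `seed`.
#'
#' @param stage one of the registered stage names.
#' @param config an `analysis_config`.
#' @param seed integer seed consumed by simulation stages.
#' @param out_dir output directory (created if needed).
#' @return list of output file paths, invisibly.
#' @export
run_pipeline <- function(stage, config = default_config(), seed = 1L,
                         out_dir = ".") {
  stages <- pipeline_stages()
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; available: ",
         paste(stages, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(out_dir, stage)
  paths <- character(0)
  emit <- function(p) { paths <<- c(paths, p); p }
  cfg <- config
  sim_map <- function(condition, sample = TRUE)
    simulate_contact_map(hic_preset(condition, n_bins = cfg$simulate$n_bins,
                                    depth = cfg$simulate$depth, seed = seed,
                                    sample = sample))

  if (stage == "simulate-hic") {
    for (cond in c("control", "rad21_oe")) {
      sim <- sim_map(cond)
      write_contact_matrix(sim$matrix,
                           emit(paste0(out, "-", cond, ".triplet.tsv")))
      write_track(ifelse(sim$truth$labels == "A", 1, -1), sim$matrix$bins,
                  emit(paste0(out, "-", cond, ".labels.bedgraph")))
      write_bed(tads_from_boundaries(sim$truth$boundaries, sim$matrix$bins),
                emit(paste0(out, "-", cond, ".tads.bed")))
    }
  } else if (stage == "simulate-image") {
    sim <- simulate_nucleus_image(image_sim_params(
      height = cfg$simulate$image_px, width = cfg$simulate$image_px,
      pixel_size = cfg$simulate$pixel_size_um, seed = seed))
    write_nucleus_image(sim$image, emit(paste0(out, ".tif")))
    utils::write.csv(sim$truth, emit(paste0(out, "-beads.csv")),
                     row.names = FALSE)
  } else if (stage == "simulate-frap") {
    write_trace(simulate_frap_trace(frap_sim_params(seed = seed,
                                                    noise_sd = 0.02)),
                emit(paste0(out, "-frap.csv")))
    write_trace(simulate_ifrap_trace(frap_sim_params(mode = "ifrap",
                                                     seed = seed,
                                                     noise_sd = 0.02)),
                emit(paste0(out, "-ifrap.csv")))
  } else if (stage %in% c("heterogeneity", "beads", "coloc", "clusters")) {
    img <- if (is.null(cfg$paths$image))
      simulate_nucleus_image(image_sim_params(seed = seed))$image
    else read_nucleus_image(cfg$paths$image, cfg$simulate$pixel_size_um)
    if (stage == "heterogeneity") {
      r <- heterogeneity_level(img, cfg$heterogeneity$target_mean,
                               cfg$heterogeneity$box_px,
                               cfg$heterogeneity$stride_px)
      jsonlite::write_json(r[c("mu1", "mu2", "heterogeneity",
                               "mean_intensity", "unimodal")],
                           emit(paste0(out, ".json")), auto_unbox = TRUE,
                           digits = NA)
    } else if (stage == "beads") {
      bs <- detect_beads(img, cfg$beads$psf_sigma_um,
                         cfg$beads$min_separation_um,
                         cfg$beads$threshold_rel,
                         cfg$beads$expected_spacing_um)
      sp <- bead_spacings(bs)
      utils::write.csv(bs$beads, emit(paste0(out, ".csv")), row.names = FALSE)
      jsonlite::write_json(list(n_beads = nrow(bs$beads),
                                mean_spacing_um = sp$mean,
                                median_spacing_um = sp$median),
                           emit(paste0(out, ".json")), auto_unbox = TRUE,
                           digits = NA)
    } else if (stage == "coloc") {
      img_b <- if (is.null(cfg$paths$image_b))
        simulate_nucleus_image(image_sim_params(seed = seed + 1L))$image
      else read_nucleus_image(cfg$paths$image_b, cfg$simulate$pixel_size_um)
      jsonlite::write_json(list(pearson_r =
                                  pearson_colocalization(img, img_b)),
                           emit(paste0(out, ".json")), auto_unbox = TRUE,
                           digits = NA)
    } else {
      cl <- segment_clusters(img, cfg$clusters$threshold,
                             cfg$clusters$min_diameter_um)
      utils::write.csv(as.data.frame(cl), emit(paste0(out, ".csv")),
                       row.names = FALSE)
    }
  } else if (stage == "frap-fit") {
    trace <- if (is.null(cfg$paths$traces))
      simulate_frap_trace(frap_sim_params(seed = seed, noise_sd = 0.02))
    else read_trace(cfg$paths$traces)
    fit <- fit_frap_trace(trace)
    jsonlite::write_json(fit[c("A", "B", "tauA", "tauB", "residence_time",
                               "converged", "degenerate")],
                         emit(paste0(out, ".json")), auto_unbox = TRUE,
                         digits = NA)
    nz <- normalize_frap(correct_photobleaching(trace))
    fitted <- frap_recovery(nz$times, fit$A, fit$B, fit$tauA, fit$tauB)
    utils::write.csv(data.frame(time = nz$times, value = nz$values,
                                fitted = fitted),
                     emit(paste0(out, "-curve.csv")), row.names = FALSE)
  } else if (stage == "ifrap") {
    trace <- if (is.null(cfg$paths$traces))
      simulate_ifrap_trace(frap_sim_params(mode = "ifrap", seed = seed,
                                           noise_sd = 0.02))
    else read_trace(cfg$paths$traces)
    nz <- normalize_ifrap(trace)
    utils::write.csv(data.frame(time = nz$times, value = nz$values),
                     emit(paste0(out, ".csv")), row.names = FALSE)
  } else if (stage %in% c("hic-stats", "compartments", "tads", "ata")) {
    sim <- sim_map("control")
    mat <- if (is.null(cfg$paths$matrix)) sim$matrix
    else read_contact_matrix(cfg$paths$matrix,
                             read_bins_table(cfg$paths$bins))
    bal <- ice_balance(mat, cfg$hic$ice_tol, cfg$hic$ice_max_iter,
                       cfg$hic$min_coverage_mad)
    if (stage == "hic-stats") {
      ps <- contact_probability(bal, cfg$hic$geometric_factor)
      utils::write.csv(ps$curve, emit(paste0(out, "-ps.csv")),
                       row.names = FALSE)
      write_contact_matrix(bal, emit(paste0(out, "-balanced.tsv")), "dense")
      jsonlite::write_json(list(ps_slope = ps$slope,
                                total = total_contacts(mat)),
                           emit(paste0(out, ".json")), auto_unbox = TRUE,
                           digits = NA)
    } else if (stage == "compartments") {
      track <- if (is.null(cfg$paths$track))
        ifelse(sim$truth$labels == "A", 1, -1)
      else read_track(cfg$paths$track, mat$bins)
      prof <- compute_pc1(bal, track)
      write_track(prof$pc1, mat$bins, emit(paste0(out, "-pc1.bedgraph")))
      oe <- observed_over_expected(bal)
      sad <- saddle(oe, prof, cfg$compartments$n_quantiles)
      utils::write.table(sad$grid, emit(paste0(out, "-saddle.tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      mr <- mixing_ratio(bal, prof, cfg$compartments$exclude_chroms)
      jsonlite::write_json(list(mixing_ratio = mr$overall),
                           emit(paste0(out, ".json")), auto_unbox = TRUE,
                           digits = NA)
    } else if (stage == "tads") {
      prof <- insulation_score(bal, cfg$tads$window_bp)
      write_track(prof$score, mat$bins, emit(paste0(out, "-is.bedgraph")))
      bd <- call_boundaries(prof, cfg$tads$delta_window_bp,
                            cfg$tads$min_strength)
      tads <- tads_from_boundaries(bd, mat$bins)
      write_bed(tads, emit(paste0(out, ".bed")))
      utils::write.csv(as.data.frame(tad_score(bal, tads)),
                       emit(paste0(out, "-score.csv")), row.names = FALSE)
    } else {
      tads <- if (is.null(cfg$paths$tads))
        tads_from_boundaries(sim$truth$boundaries, mat$bins)
      else {
        bed <- read_bed(cfg$paths$tads)
        bs <- bin_size_of(mat$bins)
        tads_from_boundaries(bed$start[bed$start > 0] / bs, mat$bins)
      }
      ata <- aggregate_tads(bal, tads, cfg$ata$min_size_bp,
                            cfg$ata$out_pixels, cfg$ata$flank_fraction)
      utils::write.table(ata$grid, emit(paste0(out, "-grid.tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    }
  } else if (stage == "rg") {
    clouds <- if (is.null(cfg$paths$volume)) {
      list(simulate_territory(territory_sim_params("ball", radius = 15,
                                                   voxel_size =
                                                     cfg$rg$voxel_size_um,
                                                   seed = seed)))
    } else stop("volume input requires programmatic use of label_components")
    rows <- do.call(rbind, lapply(clouds, function(cl) {
      r <- radius_of_gyration(cl)
      data.frame(label = cl$label, rg_um = r$rg, n_voxels = r$n_voxels,
                 cx = r$center[1], cy = r$center[2], cz = r$center[3])
    }))
    utils::write.csv(rows, emit(paste0(out, ".csv")), row.names = FALSE)
  } else if (stage == "demo-contrast") {
    demo <- demo_contrast(seed = seed, n_bins = cfg$simulate$n_bins,
                          depth = cfg$simulate$depth)
    jsonlite::write_json(demo, emit(paste0(out, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }

  jsonlite::write_json(list(stage = stage, seed = seed,
                            config = unclass(cfg)),
                       paste0(out, ".log.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(paths)
}

read_bins_table <- function(path) {
  bed <- read_bed(path)
  bed$bin <- seq_len(nrow(bed)) - 1L
  class(bed) <- c("genome_bins", "data.frame")
  validate_bins(bed)
}

#' End-to-end control vs RAD21-OE-like contrast demo
#'
#' Simulates the paired presets at a common seed, runs the full
#' contact-map pipeline on both, and reports each statistic with its
#' direction of change (OE-like relative to control): short-range P(s)
#' up, long-range P(s) down, mixing ratio up, saddle corner enrichment
#' down, ATA corner contacts up, TAD score down, TAD count and median
#' length unchanged.
#'
#' @param seed RNG seed shared by the pair.
#' @param n_bins,depth generator size.
#' @return list with per-statistic `control`, `oe` and `direction`
#'   entries.
#' @export
demo_contrast <- function(seed = 1L, n_bins = 200, depth = 2e6) {
  res <- list()
  sims <- lapply(c("control", "rad21_oe"), function(cond)
    simulate_contact_map(hic_preset(cond, n_bins = n_bins, depth = depth,
                                    seed = seed)))
  names(sims) <- c("control", "oe")
  # synthetic maps contain no unmappable bins, so the low-coverage filter
  # (a dropout guard on real data) is disabled here
  bals <- lapply(sims, function(s) ice_balance(s$matrix,
                                               min_coverage_mad = Inf))
  ps <- lapply(bals, contact_probability)
  # short range: around the TAD scale (0.55-1.1 Mb), where
  # boundary-crossing loops accumulate; long range: beyond ~2 Mb
  short_rng <- function(p) mean(p$curve$p[p$curve$s_bp >= 0.55e6 &
                                            p$curve$s_bp <= 1.1e6])
  long_rng <- function(p) mean(p$curve$p[p$curve$s_bp >= 2e6 &
                                           p$curve$s_bp <= 6e6])
  res$ps_short <- list(control = short_rng(ps$control),
                       oe = short_rng(ps$oe))
  res$ps_long <- list(control = long_rng(ps$control), oe = long_rng(ps$oe))
  profs <- lapply(names(sims), function(k)
    compute_pc1(bals[[k]], ifelse(sims[[k]]$truth$labels == "A", 1, -1)))
  names(profs) <- names(sims)
  mr <- lapply(names(sims), function(k) mixing_ratio(bals[[k]], profs[[k]]))
  names(mr) <- names(sims)
  res$mixing_ratio <- list(control = mr$control$overall,
                           oe = mr$oe$overall)
  oes <- lapply(bals, observed_over_expected)
  sads <- lapply(names(sims), function(k) saddle(oes[[k]], profs[[k]]))
  names(sads) <- names(sims)
  corner <- function(s) mean(c(s$grid[1, 1], s$grid[nrow(s$grid),
                                                    ncol(s$grid)]))
  res$saddle_corner <- list(control = corner(sads$control),
                            oe = corner(sads$oe))
  tads <- lapply(names(sims), function(k) {
    prof <- insulation_score(bals[[k]])
    tads_from_boundaries(call_boundaries(prof), sims[[k]]$matrix$bins)
  })
  names(tads) <- names(sims)
  atas <- lapply(names(sims), function(k)
    ata_corner_enrichment(aggregate_tads(bals[[k]], tads[[k]])))
  names(atas) <- names(sims)
  res$ata_corner <- list(control = atas$control$enrichment,
                         oe = atas$oe$enrichment)
  scores <- lapply(names(sims), function(k)
    stats::median(tad_score(bals[[k]], tads[[k]])$score, na.rm = TRUE))
  names(scores) <- names(sims)
  res$tad_score <- list(control = scores$control, oe = scores$oe)
  res$tad_count <- list(control = nrow(tads$control), oe = nrow(tads$oe))
  res$tad_median_length <- list(
    control = tad_length_stats(tads$control)$median_bp,
    oe = tad_length_stats(tads$oe)$median_bp)
  expect_dir <- c(ps_short = "up", ps_long = "down", mixing_ratio = "up",
                  saddle_corner = "down", ata_corner = "up",
                  tad_score = "down", tad_count = "unchanged",
                  tad_median_length = "unchanged")
  for (k in names(expect_dir)) {
    a <- res[[k]]$control; b <- res[[k]]$oe
    res[[k]]$direction <-
      if (abs(b - a) <= 0.01 * max(abs(a), abs(b), 1e-12)) "unchanged"
      else if (b > a) "up" else "down"
    res[[k]]$expected_direction <- unname(expect_dir[k])
  }
  res
}
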