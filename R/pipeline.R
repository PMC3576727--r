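## End-to-end workflow: simulate -> refine the exposure averages ->
## statistical movie processing -> polished reconstruction -> fixed
## partition baselines -> tilt-pair validation -> postprocessing summary.

#' Run configuration
#'
#' Validated bundle of every tunable of the pipeline, with defaults equal
#' to the method's working values (prior sigma 1 degree, searches +-3
#' degrees step 0.45, +-2 px step 0.5, window W = 5, FSC threshold 0.143,
#' mask falloff 5 px).  Unknown keys are rejected.
#'
#' @param ... overrides of the default fields; see `run_config()` output
#' @return class `run_config`
#' @export
run_config <- function(...) {
  defaults <- list(
    ## simulation
    n_particles = 200, n_frames = 16, box_size = 32, pixel_size = 1.77,
    total_dose = 16, snr_per_dose = 0.05, damage_rate = 3.0,
    trans_total_mean = 4.2, trans_total_sd = 2.3,
    rot_total_mean = 1.7, rot_total_sd = 1.2,
    tilt_angle = NA, tilt_axis_azimuth = 0,
    ## refinement
    angular_step = 7.5, min_angular_step = 1.875, max_iter = 6,
    trans_range = 2, trans_step = 1, initial_resolution = 60,
    ## movie processing
    sigma_angle = 1.0, sigma_trans = NA, angle_range = 3.0,
    angle_step = 0.45, movie_trans_range = 2.0, movie_trans_step = 0.5,
    window = 5,
    ## baseline partitions and postprocessing
    partitions = c(4), fsc_threshold = 0.143, mask_falloff = 5,
    tilt_bin_width = 0.5,
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$window %% 2 == 1, cfg$fsc_threshold > 0,
            cfg$sigma_angle > 0, cfg$angle_step > 0,
            cfg$movie_trans_step > 0, cfg$mask_falloff > 0)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path file path
#' @return a [run_config()]
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$tilt_angle) && is.na(vals$tilt_angle))
    vals$tilt_angle <- NA
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config a [run_config()]
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## sim_config derived from a run_config
as_sim_config <- function(cfg) {
  sim_config(n_particles = cfg$n_particles, n_frames = cfg$n_frames,
             box_size = cfg$box_size, pixel_size = cfg$pixel_size,
             total_dose = cfg$total_dose, snr_per_dose = cfg$snr_per_dose,
             damage_rate = cfg$damage_rate,
             trans_total_mean = cfg$trans_total_mean,
             trans_total_sd = cfg$trans_total_sd,
             rot_total_mean = cfg$rot_total_mean,
             rot_total_sd = cfg$rot_total_sd,
             tilt_angle = if (is.na(cfg$tilt_angle)) NULL else
               cfg$tilt_angle,
             tilt_axis_azimuth = cfg$tilt_axis_azimuth, seed = cfg$seed)
}

## refine the exposure averages of a set of movies
refine_averages <- function(movies, initial_reference, cfg) {
  images <- lapply(movies, movie_average)
  ctfs <- lapply(movies, `[[`, "ctf")
  gold_standard_refine(images, ctfs, initial_reference,
                       refine_config(angular_step = cfg$angular_step,
                                     min_angular_step =
                                       cfg$min_angular_step,
                                     trans_range = cfg$trans_range,
                                     trans_step = cfg$trans_step,
                                     max_iter = cfg$max_iter,
                                     initial_resolution =
                                       cfg$initial_resolution,
                                     seed = cfg$seed))
}

## sigma_trans default: sample sd of the refined offsets about the picked
## positions (which are the box centres here), pooled over x and y
estimate_sigma_trans <- function(refinement) {
  s <- stats::sd(c(refinement$pose_table$offset_x,
                   refinement$pose_table$offset_y))
  max(s, 0.25)
}

## Statistical movie processing for a whole dataset: per-particle priors
## centred on the refined exposure-average poses, frames aligned against
## the particle's own half-map, then a polished gold-standard
## reconstruction.
polish_movies <- function(movies, refinement, cfg, cap = NULL) {
  n <- grid_n(movies[[1]]$frames[[1]])
  ps <- movies[[1]]$frames[[1]]$pixel_size
  sigma_trans <- if (is.na(cfg$sigma_trans))
    estimate_sigma_trans(refinement) else cfg$sigma_trans
  refs <- lapply(refinement$half_maps, function(m)
    make_projector(lowpass_map(m, refinement$resolution)))
  ## individual frames carry little signal beyond ~quarter Nyquist; the
  ## alignment cap reflects that (reconstruction still uses all shells)
  if (is.null(cap))
    cap <- min(n %/% 4,
               ceiling(resolution_to_shell(refinement$resolution, n, ps)) + 3)
  tracks <- vector("list", length(movies))
  for (i in seq_along(movies)) {
    h <- refinement$half[i]
    pr <- orientation_prior(refinement$poses[[i]],
                            sigma_angle = cfg$sigma_angle,
                            sigma_trans = sigma_trans,
                            angle_range = cfg$angle_range,
                            angle_step = cfg$angle_step,
                            trans_range = cfg$movie_trans_range,
                            trans_step = cfg$movie_trans_step)
    tracks[[i]] <- align_frames(movies[[i]], refs[[h]], pr,
                                refinement$noise[[h]], W = cfg$window,
                                cap = cap)
  }
  rec <- polish_reconstruct(movies, tracks, refinement$half,
                            mask_falloff = cfg$mask_falloff)
  list(tracks = tracks, half_maps = rec$half_maps, fsc = rec$fsc,
       resolution = rec$resolution, sigma_trans = sigma_trans, cap = cap)
}

## Fixed-partition baseline: each w-frame average becomes an independent
## particle, aligned from scratch (global orientation search, then a
## local pass with fine translations) against its half-set reference,
## exactly as the multi-frame data sets of the naive approach are
## refined; then reconstructed per half.
partition_baseline <- function(movies, refinement, w, cfg, cap = NULL) {
  n <- grid_n(movies[[1]]$frames[[1]])
  ps <- movies[[1]]$frames[[1]]$pixel_size
  refs <- lapply(refinement$half_maps, function(m)
    make_projector(lowpass_map(m, refinement$resolution)))
  if (is.null(cap))
    cap <- min(n %/% 2 - 2,
               ceiling(resolution_to_shell(refinement$resolution, n, ps)) + 3)
  pl <- half_pixel_list(n, cap)
  plg <- half_pixel_list(n, min(cap, 10))  # orientation search saturates
  ## local sampling follows the engine's resolution-matched (Crowther)
  ## spacing; the sub-degree grids of movie processing are licensed by
  ## its priors, not available to the free re-refinement of the blocks
  step_loc <- max(cfg$min_angular_step,
                  min(cfg$angular_step,
                      rad2deg(refinement$resolution / (0.6 * n * ps))))
  gg <- sampling_grid(cfg$angular_step, trans_range = 1.5,
                      trans_step = 1.5)
  imgs <- list(); ctfs <- list(); poses <- list(); half <- integer(0)
  pose_by_part <- vector("list", length(movies))
  gslices <- lapply(refs, function(r) grid_slices(r, gg, plg))
  for (i in seq_along(movies)) {
    h <- refinement$half[i]
    iv <- pixel_weights(refinement$noise[[h]], pl)
    ivg <- pixel_weights(refinement$noise[[h]], plg)
    parts <- partition_average(movies[[i]], w)
    cv <- ctf_at_pixels(movies[[i]]$ctf, pl, ps)
    cvg <- ctf_at_pixels(movies[[i]]$ctf, plg, ps)
    xf <- lapply(parts, function(im) image_at_pixels(ft(im$values), pl))
    xfg <- lapply(parts, function(im)
      image_at_pixels(ft(im$values), plg))
    gres <- align_batch(xfg, rep(list(cvg), length(parts)), gslices[[h]],
                        gg, ivg, plg)
    pose_by_part[[i]] <- lapply(seq_along(parts), function(k) {
      ctr <- batch_pose(gres, gg, k)$map
      lg <- sampling_grid(step_loc, cfg$trans_range,
                          cfg$movie_trans_step, center = ctr,
                          angular_range = 2 * step_loc)
      lsl <- grid_slices(refs[[h]], lg, pl)
      lres <- align_batch(xf[k], list(cv), lsl, lg, iv, pl)
      batch_pose(lres, lg, 1)$map
    })
    for (k in seq_along(parts)) {
      imgs[[length(imgs) + 1]] <- parts[[k]]
      ctfs[[length(ctfs) + 1]] <- movies[[i]]$ctf
      poses[[length(poses) + 1]] <- pose_by_part[[i]][[k]]
      half <- c(half, h)
    }
  }
  maps <- lapply(1:2, function(h)
    reconstruct(imgs[half == h], ctfs[half == h], poses[half == h]))
  msk <- soft_spherical_mask(n, n / 2 - cfg$mask_falloff - 2,
                             cfg$mask_falloff, ps)
  curve <- fsc(maps[[1]], maps[[2]], mask = msk)
  list(half_maps = maps, fsc = curve,
       resolution = resolution_at(curve, cfg$fsc_threshold),
       poses = pose_by_part)
}

## masked FSC resolution of an exposure-average refinement (for the
## route-vs-route comparison)
masked_resolution <- function(refinement, cfg) {
  n <- grid_n(refinement$half_maps[[1]])
  msk <- soft_spherical_mask(n, n / 2 - cfg$mask_falloff - 2,
                             cfg$mask_falloff,
                             refinement$half_maps[[1]]$voxel_size)
  curve <- fsc(refinement$half_maps[[1]], refinement$half_maps[[2]],
               mask = msk)
  list(fsc = curve, resolution = resolution_at(curve, cfg$fsc_threshold))
}

#' Run the full movie-processing pipeline into a directory
#'
#' Simulates a dataset, refines the exposure averages (gold standard),
#' runs statistical movie processing and the polished reconstruction, the
#' fixed-partition baselines, optionally tilt-pair validation, and writes
#' all stage outputs (truth/pose STAR tables, FSC TSVs, summary JSON,
#' config YAML) into `dir`.  Re-running with the same config reproduces
#' the same outputs.
#'
#' @param config a [run_config()]
#' @param dir output directory (created if needed)
#' @return invisibly, the summary list (also written as `summary.json`)
#' @export
run_pipeline <- function(config = run_config(), dir = tempfile("run")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  write_run_config(config, file.path(dir, "config.yaml"))
  sim <- stage("simulate", simulate_dataset(as_sim_config(config)))
  write_star(sim$truth, file.path(dir, "truth.star"), "truth")
  tilted <- !is.na(config$tilt_angle)
  nu <- config$n_particles
  untilted <- sim$movies[seq_len(nu)]
  ref <- stage("refine", refine_averages(untilted, sim$phantom, config))
  write_star(pose_table_star(ref$pose_table, config$pixel_size),
             file.path(dir, "poses_average.star"))
  avg_res <- masked_resolution(ref, config)
  pol <- stage("polish", polish_movies(untilted, ref, config))
  tr_tab <- do.call(rbind, lapply(pol$tracks, function(t)
    cbind(particle = t$particle_id, t$track,
          offset_x_ang = t$track$offset_x * config$pixel_size,
          offset_y_ang = t$track$offset_y * config$pixel_size,
          W = t$W, sigma_angle = t$prior$sigma_angle,
          sigma_trans = t$prior$sigma_trans)))
  write_star(tr_tab, file.path(dir, "frame_tracks.star"), "frames")
  parts <- list()
  for (w in config$partitions)
    parts[[as.character(w)]] <-
      stage("partition", partition_baseline(untilted, ref, w, config))
  tilt_summary <- NULL
  if (tilted) {
    tilt_summary <- stage("tiltpair", {
      tilted_movies <- sim$movies[nu + seq_len(nu)]
      reft <- refine_averages(tilted_movies, sim$phantom, config)
      pairs <- data.frame(
        rot1 = ref$pose_table$rot, tilt1 = ref$pose_table$tilt,
        psi1 = ref$pose_table$psi,
        rot2 = reft$pose_table$rot, tilt2 = reft$pose_table$tilt,
        psi2 = reft$pose_table$psi)
      geom <- estimate_axis(pairs, tilt_geometry(config$tilt_angle,
                                                 config$tilt_axis_azimuth))
      errs <- vapply(seq_len(nrow(pairs)), function(i)
        pair_error(pose(pairs$rot1[i], pairs$tilt1[i], pairs$psi1[i]),
                   pose(pairs$rot2[i], pairs$tilt2[i], pairs$psi2[i]),
                   geom), numeric(1))
      tp <- precision_and_misaligned(errs, config$tilt_bin_width)
      utils::write.table(tp$histogram,
                         file.path(dir, "tilt_histogram.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      list(precision_deg = tp$precision, n_misaligned = tp$n_misaligned,
           n_total = tp$n_total, fitted_axis = geom$tilt_axis_azimuth)
    })
  }
  motion <- exposure_motion_summary(pol$tracks, config$pixel_size)
  for (nm in names(parts)) {
    crv <- parts[[nm]]$fsc
    utils::write.table(data.frame(freq = crv$freq, fsc = crv$fsc),
                       file.path(dir, sprintf("fsc_partition%s.tsv", nm)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(data.frame(freq = pol$fsc$freq, fsc = pol$fsc$fsc),
                     file.path(dir, "fsc_polished.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  summary <- list(
    n_particles = config$n_particles,
    per_frame_dose = config$total_dose / config$n_frames,
    resolution_average = avg_res$resolution,
    resolution_partition = lapply(parts, `[[`, "resolution"),
    resolution_polished = pol$resolution,
    sigma_trans = pol$sigma_trans,
    motion_rotation_mean = unname(motion$rotation["mean"]),
    motion_rotation_sd = unname(motion$rotation["sd"]),
    motion_translation_mean = unname(motion$translation["mean"]),
    motion_translation_sd = unname(motion$translation["sd"]),
    tilt_pair = tilt_summary,
    seed = config$seed)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
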