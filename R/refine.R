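## Gold-standard iterative refinement: two random half-sets refined fully
## independently, unmasked half-map FSC between iterations, step-halving
## local searches after a global first pass.

#' Refinement configuration
#'
#' @param angular_step global angular sampling in degrees (7.5 by default,
#'   halved per iteration down to `min_angular_step`)
#' @param min_angular_step finest local sampling in degrees
#' @param trans_range,trans_step translational search in pixels
#' @param max_iter iteration cap
#' @param initial_resolution low-pass (Angstrom) applied to the starting
#'   reference
#' @param cap_margin shells carried beyond the current resolution during
#'   alignment
#' @param min_cap minimum alignment cap in shells
#' @param assignment reconstruct from `"map"` poses (default) or the
#'   posterior-mean (`"expected"`) pose
#' @param noise_sample particles per half used to re-estimate the noise
#' @param particle_diameter Angstrom; sets the resolution-matched angular
#'   sampling (default 0.6 x box width)
#' @param align_threshold FSC threshold for the internal resolution used
#'   to filter references and cap the alignment (0.5: only shells the
#'   half-maps agree on confidently drive the alignment, limiting
#'   noise-fitting feedback; resolutions are still reported at 0.143)
#' @param seed seed for the half-split
#' @return a list of class `refine_config`
#' @export
refine_config <- function(angular_step = 7.5, min_angular_step = 1.875,
                          trans_range = 2, trans_step = 1, max_iter = 8,
                          initial_resolution = 60, cap_margin = 3,
                          min_cap = 6, assignment = c("map", "expected"),
                          noise_sample = 100, particle_diameter = NULL,
                          align_threshold = 0.5, seed = 1) {
  assignment <- match.arg(assignment)
  structure(as.list(environment()), class = "refine_config")
}

## low-pass a map at `res` Angstrom (2-shell raised-cosine edge)
lowpass_map <- function(map, res) {
  n <- grid_n(map)
  cutoff <- min(resolution_to_shell(res, n, map$voxel_size), n / 2 - 1)
  voxel_grid3d(Re(ift(ft(map$values) *
                        lowpass_transfer(n, 3, cutoff))), map$voxel_size)
}

## flat starting noise model from the image pixel variance
initial_noise <- function(images) {
  v <- mean(vapply(images, function(im) stats::var(as.numeric(im$values)),
                   numeric(1)))
  n <- grid_n(images[[1]])
  noise_model(rep(v, n_shells(n)))
}

## tau^2 from the half-map FSC and the mean half-map shell power
## (the standard SSNR relation, FSC clamped at 0.999)
tau2_from_fsc <- function(curve, half1, half2) {
  pw <- (shell_power(ft(half1$values)) + shell_power(ft(half2$values))) / 2
  fval <- c(1, pmax(0, pmin(curve$fsc, 0.999)))  # shell 0 has no FSC value
  pmax(fval / (1 - fval) * pw, 0)
}

## angular sampling matched to the current resolution: the Crowther
## spacing d/D (the angle subtended by one resolution element at the
## particle diameter), clamped to [min_angular_step, angular_step]
step_for_resolution <- function(resolution, diameter, cfg) {
  max(cfg$min_angular_step,
      min(cfg$angular_step, rad2deg(resolution / diameter)))
}

## align every particle of one half against its reference; returns pose
## list + data.frame
align_half <- function(images, ctfs, proj, noise, cfg, do_global, step,
                       cap, centers) {
  n <- length(images)
  nn <- grid_n(images[[1]])
  pl <- half_pixel_list(nn, cap)
  iv <- pixel_weights(noise, pl)
  xf <- lapply(images, function(im) image_at_pixels(ft(im$values), pl))
  cv <- lapply(ctfs, function(cc) ctf_at_pixels(cc, pl,
                                                images[[1]]$pixel_size))
  poses <- vector("list", n)
  info <- matrix(0, n, 2)  # log-evidence, max posterior
  if (do_global) {
    ## global orientation pass on a coarse translation grid, then a
    ## per-particle local pass with fine translations around the MAP;
    ## orientation discrimination saturates by ~shell 12, so the global
    ## pass is capped there for speed
    plg <- if (cap > 12) half_pixel_list(nn, 12) else pl
    ivg <- if (cap > 12) pixel_weights(noise, plg) else iv
    xfg <- if (cap > 12)
      lapply(images, function(im) image_at_pixels(ft(im$values), plg))
      else xf
    cvg <- if (cap > 12)
      lapply(ctfs, function(cc) ctf_at_pixels(cc, plg,
                                              images[[1]]$pixel_size))
      else cv
    gg <- sampling_grid(cfg$angular_step, trans_range = 1.5,
                        trans_step = 1.5)
    slices <- grid_slices(proj, gg, plg)
    res <- align_batch(xfg, cvg, slices, gg, ivg, plg)
    centers <- lapply(seq_len(n), function(j) batch_pose(res, gg, j)$map)
    rm(slices)
  }
  for (j in seq_len(n)) {
    lg <- sampling_grid(step, cfg$trans_range, cfg$trans_step,
                        center = centers[[j]], angular_range = 2 * step)
    slices <- grid_slices(proj, lg, pl)
    res <- align_batch(xf[j], cv[j], slices, lg, iv, pl)
    ps <- batch_pose(res, lg, 1)
    poses[[j]] <- if (cfg$assignment == "map") ps$map else ps$expected
    info[j, ] <- c(res$log_evidence[1], res$max_post[1])
  }
  list(poses = poses, log_evidence = info[, 1], max_post = info[, 2])
}

#' Gold-standard projection-matching refinement
#'
#' Splits the particles into two random halves (seeded), refines each half
#' against only its own reconstruction, and iterates: align (a global grid
#' on the first pass, then local searches with step halving), reconstruct
#' both halves with per-shell Wiener regularization, compute the unmasked
#' half-map FSC, and low-pass each half at the FSC = 0.143 resolution for
#' the next iteration.  Stops when the resolution changes by less than one
#' shell for two consecutive iterations, or at `max_iter`; if the
#' resolution worsens three iterations in a row the run is flagged and the
#' best iterate is returned.
#'
#' @param images list of [pixel_grid2d()] particle images (exposure
#'   averages)
#' @param ctfs list of [ctf_params()], one per image
#' @param initial_reference a [voxel_grid3d()] starting map (low-passed to
#'   `initial_resolution` internally)
#' @param config a [refine_config()]
#' @return an object of class `cryo_refine`; see [summary.cryo_refine()]
#' @export
gold_standard_refine <- function(images, ctfs, initial_reference,
                                 config = refine_config()) {
  np <- length(images)
  if (np < 100) stop("need at least 100 particles for half-set refinement")
  n <- grid_n(images[[1]])
  ps <- images[[1]]$pixel_size
  perm <- with_seed(child_seed(config$seed, "halfsplit"), sample.int(np))
  half <- integer(np)
  half[perm[seq_len(ceiling(np / 2))]] <- 1L
  half[perm[(ceiling(np / 2) + 1):np]] <- 2L
  ref0 <- lowpass_map(initial_reference, config$initial_resolution)
  refs <- list(ref0, ref0)
  noise <- list(initial_noise(images[half == 1]),
                initial_noise(images[half == 2]))
  res_trace <- numeric(0)
  fsc_list <- list()
  centers <- vector("list", np)
  poses <- vector("list", np)
  best <- NULL
  worse_streak <- 0L
  stable_streak <- 0L
  resolution <- config$initial_resolution
  resolution_align <- config$initial_resolution
  diameter <- if (is.null(config$particle_diameter)) 0.6 * n * ps else
    config$particle_diameter
  steps <- numeric(0)
  cap <- max(4, min(n %/% 2 - 2,
                    ceiling(resolution_to_shell(config$initial_resolution,
                                                n, ps)) + 2))
  for (it in seq_len(config$max_iter)) {
    step <- step_for_resolution(resolution, diameter, config)
    ## repeat the global search once after the bootstrap iteration (the
    ## first pass aligns against the heavily filtered start reference);
    ## afterwards particles keep their basin and only local searches run
    do_global <- it <= 2
    steps <- c(steps, step)
    ## the alignment cap follows the current resolution but may grow by
    ## at most 2 shells per iteration: a shared starting reference
    ## inflates the first FSC estimates, and chasing them would let
    ## reference imprint run away
    cap <- min(cap + 2,
               max(config$min_cap,
                   min(n %/% 2 - 2,
                       ceiling(resolution_to_shell(resolution_align, n,
                                                   ps)) +
                         config$cap_margin)))
    halves <- vector("list", 2)
    for (h in 1:2) {
      sel <- which(half == h)
      proj <- make_projector(refs[[h]])
      al <- align_half(images[sel], ctfs[sel], proj, noise[[h]], config,
                       do_global, step, cap, centers[sel])
      poses[sel] <- al$poses
      centers[sel] <- al$poses
      halves[[h]] <- list(sel = sel, al = al)
    }
    ## plain (ridge) reconstructions carry the FSC: a per-shell Wiener
    ## term filters unreliable shells so strongly that crop leakage of
    ## the shared low-frequency signal would correlate the half-maps
    maps <- vector("list", 2)
    for (h in 1:2) {
      sel <- halves[[h]]$sel
      maps[[h]] <- reconstruct(images[sel], ctfs[sel], poses[sel])
    }
    curve <- fsc(maps[[1]], maps[[2]])
    resolution_new <- resolution_at(curve, 0.143)
    align_resolution <- resolution_at(curve, config$align_threshold)
    fsc_list[[it]] <- curve
    res_trace <- c(res_trace, resolution_new)
    ## track best iterate (highest resolution)
    if (is.null(best) || resolution_new <= best$resolution) {
      best <- list(maps = maps, poses = poses, resolution = resolution_new,
                   iteration = it)
      worse_streak <- 0L
    } else {
      worse_streak <- worse_streak + 1L
    }
    shell_old <- resolution_to_shell(resolution, n, ps)
    shell_new <- resolution_to_shell(resolution_new, n, ps)
    stable_streak <- if (abs(shell_new - shell_old) < 1)
      stable_streak + 1L else 0L
    resolution <- resolution_new
    resolution_align <- align_resolution
    if (worse_streak >= 3) {
      warning("refinement diverging: resolution worsened 3 iterations; ",
              "returning the best iterate")
      maps <- best$maps
      poses <- best$poses
      resolution <- best$resolution
      break
    }
    if (stable_streak >= 2 || it == config$max_iter) break
    ## prepare next iteration
    for (h in 1:2) {
      sel <- halves[[h]]$sel
      refs[[h]] <- lowpass_map(maps[[h]], resolution_align)
      ns <- min(config$noise_sample, length(sel))
      sub <- sel[seq_len(ns)]
      noise[[h]] <- estimate_noise(images[sub], refs[[h]], ctfs[sub],
                                   poses[sub])
      ## guard against zero shells on noiseless data
      floor_v <- max(1e-12, 1e-8 * max(noise[[h]]$sigma2))
      noise[[h]] <- noise_model(pmax(noise[[h]]$sigma2, floor_v))
    }
  }
  pose_tab <- do.call(rbind, lapply(seq_len(np), function(i) {
    p <- poses[[i]]
    data.frame(particle = i, half = half[i], rot = p$rot, tilt = p$tilt,
               psi = p$psi, offset_x = p$offset_x, offset_y = p$offset_y)
  }))
  structure(list(
    half_maps = maps, poses = poses, pose_table = pose_tab, half = half,
    resolution = resolution, resolution_trace = res_trace,
    fsc = fsc_list, final_fsc = fsc_list[[length(fsc_list)]],
    noise = noise, tau2 = tau2_from_fsc(fsc_list[[length(fsc_list)]],
                                        maps[[1]], maps[[2]]),
    converged = stable_streak >= 2, diverged = worse_streak >= 3,
    n_iter = length(res_trace), step_trace = steps,
    final_angular_step = steps[length(steps)],
    config = config), class = "cryo_refine")
}

#' @export
print.cryo_refine <- function(x, ...) {
  cat(sprintf(
    paste0("<cryo_refine> %d particles, %d iterations, ",
           "FSC=0.143 resolution %.2f A%s\n"),
    nrow(x$pose_table), x$n_iter, x$resolution,
    if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Summarize a gold-standard refinement
#'
#' @param object a `cryo_refine` fit
#' @param ... unused
#' @return invisibly, a list with the resolution trace and pose table
#' @export
summary.cryo_refine <- function(object, ...) {
  print(object)
  cat("  resolution per iteration (A):",
      paste(sprintf("%.2f", object$resolution_trace), collapse = ", "),
      "\n")
  cat(sprintf("  half-sets: %d / %d particles; final angular step %.3g deg\n",
              sum(object$half == 1), sum(object$half == 2),
              object$final_angular_step))
  invisible(list(resolution_trace = object$resolution_trace,
                 pose_table = object$pose_table))
}

#' @export
plot.cryo_refine <- function(x, ...) {
  plot(x$final_fsc, ...)
  invisible(x)
}

#' @export
coef.cryo_refine <- function(object, ...) object$pose_table
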