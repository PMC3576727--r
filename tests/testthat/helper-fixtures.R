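## Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

## small phantom shared by geometry/alignment unit tests
small_phantom <- function() {
  fixture("small_phantom", make_phantom(32, 1.77, n_blobs = 20, seed = 2))
}

## noiseless CTF-filtered observation of the small phantom at a pose
render_clean <- function(phantom, p, ctf) {
  n <- dim(phantom)[1]
  pr <- project(phantom, p)
  cimg <- cryopolish:::ctf_image(ctf, n, phantom$voxel_size)
  pixel_grid2d(Re(cryopolish:::ift(cryopolish:::ft(pr$values) * cimg)),
               phantom$voxel_size)
}

## band-limited test image (no power at Nyquist) for shift round-trips
bandlimited_image <- function(n = 32, seed = 4) {
  set.seed(seed)
  v <- matrix(stats::rnorm(n * n), n, n)
  tr <- cryopolish:::lowpass_transfer(n, 2, n / 4)
  pixel_grid2d(Re(cryopolish:::ift(cryopolish:::ft(v) * tr)), 1.0)
}

## the shared movie dataset used by the acceptance-scale tests
## (1,000 particles, 48^3 box, default beam-induced motion), plus the
## exposure-average gold-standard refinement run on it
acceptance_dataset <- function() {
  fixture("acceptance_dataset", {
    cfg <- run_config(n_particles = 1000, box_size = 48, seed = 1)
    sim <- simulate_dataset(cryopolish:::as_sim_config(cfg))
    list(cfg = cfg, sim = sim)
  })
}

acceptance_refinement <- function() {
  fixture("acceptance_refinement", {
    ds <- acceptance_dataset()
    cryopolish:::refine_averages(ds$sim$movies, ds$sim$phantom, ds$cfg)
  })
}
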