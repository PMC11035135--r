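# shared fixture builders

one_disk_spec <- function(D = 1.0, S0 = 1000, radius = 12, noise = "none",
                          snr = 50, averages = 5L, seed = 1L,
                          bvalues = c(1.0, 1.67, 2.33, 3.0)) {
  pellet_phantom_spec(
    compartments = list(list(center = c(32, 32), radius = radius, D = D,
                             S0 = S0)),
    bvalues = bvalues, noise = noise, snr = snr, averages = averages,
    seed = seed)
}

two_disk_spec <- function(D0 = 1.0, D1 = 1.794, noise = "rician", snr = 50,
                          averages = 5L, seed = 1L) {
  pellet_phantom_spec(
    compartments = list(
      list(center = c(20, 32), radius = 12, D = D0, S0 = 1000),
      list(center = c(46, 32), radius = 12, D = D1, S0 = 1000)),
    noise = noise, snr = snr, averages = averages, seed = seed)
}

# digitized ball indicator on an isotropic unit grid
ball_array <- function(n, r) {
  ctr <- (n + 1) / 2
  ax <- seq_len(n) - ctr
  (outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= r^2) * 1L
}

single_sphere_scene <- function(r_um = 4, grid = c(64L, 64L, 40L),
                                voxel_um = c(0.202, 0.202, 0.363),
                                n_cell = 1.37, n_surr = 1.337, noise_sd = 0,
                                seed = 1L) {
  ext <- grid * voxel_um
  tomogram_scene_spec(
    grid = grid, voxel_um = voxel_um,
    cells = list(list(center = ext / 2, semiaxes = rep(r_um, 3),
                      n_cell = n_cell)),
    n_surr = n_surr, noise_sd = noise_sd, seed = seed)
}
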