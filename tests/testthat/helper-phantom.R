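# Shared small fixtures, built in code.  The "mini" geometry keeps unit
# tests fast; acceptance tests use the package defaults.

mini_spec <- function(...) {
  cord_phantom_spec(grid_shape = c(16L, 16L, 12L), voxel_size = c(1, 1, 3),
                    cord_radii = c(4, 3), n_volumes = 90L, tr = 2, ...)
}

mini_atlas <- function(...) build_atlas(mini_spec(...))

# 2 trials x 3 blocks x 15 s = 90 s = 45 volumes at TR 2
mini_protocol <- function(n_trials = 2L, seed = 1L)
  generate_protocol(n_trials = n_trials, seed = seed)

mini_run <- function(atlas = mini_atlas(), protocol = mini_protocol(),
                     noise = noise_spec(n_spikes = 0L), amplitude = 0.71,
                     lr = 0.3, seed = 1L) {
  truth <- ground_truth(atlas, amplitude = amplitude, lr_index = lr,
                        center_z = 6, z_halfwidth = 3L, seed = seed)
  simulate_run(atlas, protocol, truth, noise = noise, seed = seed)
}

# reflect a 3D array left<->right (x axis)
mirror_x <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
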