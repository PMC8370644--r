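# Shared desk-scale fixtures. The small grid keeps the cluster geometry
# (two shared clusters with adjacent condition-unique clusters, separated
# in y so spheres never collide) while shrinking the field of view.

small_truth_params <- function(...) {
  truth_params(grid_shape = c(24L, 24L, 16L),
               shared_centers = rbind(c(8, 8, 8), c(8, 16, 8)),
               ...)
}

small_design <- function(n_runs = 2L, ...) design_spec(n_runs = n_runs, ...)

quiet_noise <- function(...) noise_spec(artifact_rate = 0, ...)

# one noiseless subject for exact forward-model checks
noiseless_subject <- function(spec = small_design(), params = small_truth_params(),
                              seed = 1L) {
  truth <- make_ground_truth(params, 1L, seed = seed)[[1L]]
  runs <- simulate_subject(spec, truth,
                           quiet_noise(white_sd = 0, drift_amp = 0), seed = seed)
  list(truth = truth, runs = runs)
}

expect_map_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.vector(a), as.vector(b), tolerance = tol)
}
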