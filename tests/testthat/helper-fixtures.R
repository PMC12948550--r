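# Shared fixtures built in code.

iou <- function(a, b) sum(a & b) / sum(a | b)

# single-ellipse scene with exact geometry
ellipse_scene <- function(a = 30, b = 15, theta = 0.4, noise_sd = 0, seed = 1) {
  generate_multispectral_scene(scene_spec(
    n_leaves = 1,
    leaf_geometry = data.frame(cx = 60, cy = 60, a = a, b = b, theta = theta),
    noise_sd = noise_sd, seed = seed
  ))
}

# one full calendar day of constant PPFD at 300-s cadence
constant_day <- function(value = 100) {
  data.frame(timestamp = seq(0, 86100, by = 300), ppfd_umol_m2_s = value)
}

# small generic one-trait design for inference simulations
calib_design <- function(means = c(0, 0, 0), residual_sd = 1, block_sd = 0.5,
                         seed = 1, survival_prob = 1) {
  experiment_design(
    treatment_means = list(y = means),
    residual_sd = c(y = residual_sd), block_sd = c(y = block_sd),
    survival_prob = survival_prob, seed = seed
  )
}
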