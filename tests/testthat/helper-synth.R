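# Compact synthetic subjects used across the suite. Sizes are scaled for
# test speed; generator defaults carry the full study design.

make_subject <- function(seed, rotation = 0, snr = 5, timepoints = 6,
                         trials = 24, voxels = 40,
                         conditions = "no_distractor") {
  des <- design_spec(n_trials_per_condition_per_session = trials,
                     conditions = conditions, timepoints = timepoints)
  tun <- generate_tuned_voxels(voxels, seed = seed)
  generate_experiment(des, dynamics_spec(rotation_schedule = rotation,
                                         snr_schedule = snr),
                      tun, seed = seed + 500L)
}

make_distractor_subject <- function(seed, overlap, snr = 5,
                                    timepoints = 4, trials = 36,
                                    voxels = 40) {
  des <- design_spec(n_trials_per_condition_per_session = trials,
                     conditions = "orientation_distractor",
                     timepoints = timepoints)
  tun <- generate_tuned_voxels(voxels, seed = seed)
  generate_experiment(
    des, dynamics_spec(distractor_subspace_overlap = overlap,
                       snr_schedule = snr),
    tun, seed = seed + 500L)
}

# a hand-built tuning object with chosen bases/shifts
fixed_tuning <- function(basis, shifts) {
  tun <- structure(list(basis = basis, shifts = shifts,
                        n_voxels = length(basis), seed = NA_integer_),
                   class = "vwm_tuning")
  tun$responses <- tuning_response(tun, 1:180)
  tun
}

random_orthonormal_pair <- function(n, k = 2) {
  q <- qr.Q(qr(matrix(stats::rnorm(n * 2 * k), n, 2 * k)))
  list(v1 = q[, seq_len(k), drop = FALSE],
       v2 = qr.Q(qr(matrix(stats::rnorm(n * k), n, k))))
}
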