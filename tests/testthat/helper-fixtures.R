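# Small simulated fixtures shared across test files.

# A subject with controllable amplitudes on a reduced schedule; defaults
# keep single tests fast.
quick_subject <- function(seed, w_ctx = 0, w_mne = 0, w_ff = 0,
                          noise_sd = 1, n_voxels = 16L, n_runs = 4L,
                          reps = 3L, phase = "occlusion",
                          sensory_reps = 4L) {
  stim <- make_stimulus_set(seed = derive_seed(seed, 1))
  truth <- group_params("test", n_voxels = n_voxels, w_ctx = w_ctx,
                        w_mne_epi = w_mne, w_mne_sem = w_mne, w_ff = w_ff,
                        noise_sd = noise_sd)
  sched <- if (phase == "occlusion")
    make_occlusion_schedule(stim, n_runs = n_runs, reps = reps,
                            seed = derive_seed(seed, 2))
  else
    make_sensory_schedule(stim, reps = sensory_reps,
                          seed = derive_seed(seed, 2))
  sp <- simulate_subject_patterns(truth, sched, seed = derive_seed(seed, 3))
  list(stim = stim, truth = truth, patterns = sp)
}
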