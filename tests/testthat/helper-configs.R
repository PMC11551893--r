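# shared simulation configs for the tests

# pure-noise design: no condition-related signal anywhere
null_config <- function(n_voxels = 30, n_runs = 6, n_subjects = 12,
                        phase_offset = 0, seed = NA_integer_) {
  sim_config(n_voxels = n_voxels, n_runs = n_runs,
             var_s = 0, var_t = 0, var_i = 0, var_r = 1,
             var_e_prep = 1, var_e_prod = 1,
             phase_offset = phase_offset, n_subjects = n_subjects, seed = seed)
}

# exactly one signal component present, noise set so that
# signal variance / noise variance = snr
single_component_config <- function(component = c("order", "timing",
                                                  "integrated"),
                                    snr = 0.5, n_voxels = 160, n_runs = 6,
                                    n_subjects = 12, seed = NA_integer_) {
  component <- match.arg(component)
  v <- list(var_s = 0, var_t = 0, var_i = 0)
  v[[switch(component, order = "var_s", timing = "var_t",
            integrated = "var_i")]] <- 1
  sim_config(n_voxels = n_voxels, n_runs = n_runs,
             var_s = v$var_s, var_t = v$var_t, var_i = v$var_i, var_r = 1,
             var_e_prep = 1 / snr, var_e_prod = 1 / snr,
             phase_offset = 0, n_subjects = n_subjects, seed = seed)
}

# one-sided group rejection against 0; a zero-variance sample (e.g. every
# subject at ceiling accuracy, hence identical z) counts as a rejection when
# it sits above 0 -- the t statistic diverges there
rejects_above_zero <- function(z, alpha = 0.05) {
  if (sd(z) == 0) return(mean(z) > 0)
  one_sample_t(z, 0, tails = "one")$p_uncorrected < alpha
}
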