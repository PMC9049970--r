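# Shared small fixtures, built in code at test time.

default_protocol <- function(n_runs = 4L) protocol_params(n_runs = n_runs)

# fully deterministic generator settings: no noise, no jitter, no lapses
quiet_truth <- function(...) {
  ground_truth_spec(
    gain_noise_sd = 0, noise_sd = 0, drift_sd = 0,
    global_coupling = 0, physio_coupling = 0,
    jitter_sd_s = c(easy_correct = 0, hard_correct = 0, hard_incorrect = 0,
                    easy_incorrect = 0, lapse = 0), ...)
}

no_lapse_observer <- function(...) {
  observer_model(lapse_prob_easy = 0, lapse_prob_hard = 0, ...)
}

small_session <- function(seed = 1) {
  simulate_behavior(default_protocol(), observer_model(), staircase_spec(),
                    ground_truth_spec(), seed = seed)
}
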