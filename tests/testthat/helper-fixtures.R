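# Shared fixtures: everything is generated in code at test time.

# A short single-pulse protocol for paced single-cell / strip runs.
one_pulse <- function(onset = 20, duration = 1000, amplitude = NULL,
                      region = "pacing_site") {
  stimulus_protocol(pacing_train(onset, duration - 1, 1, 2, amplitude,
                                 region),
                    duration_ms = duration)
}

# Desk-scale pseudo-atria used by the repolarization-substrate checks:
# 3 x 2 cm, 500 um elements.
small_atria <- function() {
  build_pseudo_atria(pseudo_atria_config(nx = 60, ny = 40, dx_um = 500,
                                         bridge_rows = 6))
}

n_gates <- function(model) {
  cardiomod:::.cm_model_info(cardiomod:::.model_id(model))$n_gate
}

# RMS difference between two uniformly sampled traces on the common grid.
trace_rms <- function(a, b) {
  n <- min(nrow(a), nrow(b))
  sqrt(mean((a$v_m[seq_len(n)] - b$v_m[seq_len(n)])^2))
}
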