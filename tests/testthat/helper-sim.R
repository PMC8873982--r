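# Small simulation configs used across test files.

test_sim_config <- function(seed = 42L, ...) {
  sim_config(seed = seed, n_samples = 80L, ...)
}

# idealized observation conditions for recovery properties:
# perfect detection, no false positives, no artifacts, no QC failures
ideal_sim_config <- function(seed = 42L, jitter = 0.05, ...) {
  sim_config(seed = seed, n_samples = 400L,
             breakpoint_jitter_frac = jitter,
             fp_call_rate = 0, long_artifact_rate = 0, qc_fail_frac = 0,
             caller_detection_prob = c(penncnv = 1, cnvpartition = 1), ...)
}

jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2) + 1)
  inter / (max(e1, e2) - min(s1, s2) + 1)
}
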