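# shared fixture builders (everything generated in code at test time)

# tiny event matrix wrapped as dh_events by segmenting a random recording
make_events <- function(n_channels = 4, n_windows = 6, fs = 20, seed = 1) {
  set.seed(seed)
  rec <- recording(matrix(rnorm(n_channels * n_windows * fs),
                          n_channels, n_windows * fs), fs = fs,
                   subject_id = "fix")
  segment_events(rec, window_s = 1)
}

# small synthetic cohort for pipeline-level tests; fs stays above twice the
# 50 Hz notch so the default preprocessing applies
make_cohort <- function(n_per_group = 3, duration = 6, fs = 125,
                        couplings = c(control = 0.8, case = 0.2), seed = 42) {
  generate_cohort(lapply(seq_along(couplings), function(g)
    list(cfg = synth_config(duration = duration, fs = fs,
                            group_label = names(couplings)[g],
                            coupling = couplings[[g]]),
         n = n_per_group)), seed = seed)
}

# the worked 3-leaf tree from 1-D positions {0, 1, 10}
toy_tree3 <- function() build_tree(matrix(c(0, 1, 10), ncol = 1))
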