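# Shared small fixtures, built in code.

test_cal <- function() calibration_profile(rep(2, 8), rep(50, 8))

# one trained hold/release classifier reused across tests
test_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      cal <- test_cal()
      model <<- train_session_model(
        gen_training_recording("hold", cal, seed = 11L),
        gen_training_recording("release", cal, seed = 12L), cal)
    }
    model
  }
})

# fraction-of-time overlap (Jaccard) between estimated hold intervals and the
# scheduled ground-truth windows, on the recording's sample grid
hold_jaccard <- function(ml, schedule, fs) {
  n <- length(ml$labels)
  t <- (seq_len(n) - 1L) / fs
  in_true <- rep(FALSE, n)
  for (k in seq_len(nrow(schedule$hold_windows)))
    in_true <- in_true | (t >= schedule$hold_windows$start[k] &
                            t < schedule$hold_windows$end[k])
  in_est <- ml$labels == "hold"
  sum(in_true & in_est) / sum(in_true | in_est)
}
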