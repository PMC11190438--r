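# shared fixture builders; all synthetic, generated at test time

# a single-cell track table from a signal vector
one_track <- function(signal, dt = 0.1, control = 1, id = "c1") {
  tibble::tibble(cell_id = id,
                 time = seq(0, by = dt, length.out = length(signal)),
                 signal = signal,
                 control = rep_len(control, length(signal)))
}

sine_track <- function(baseline = 10, amp = 2, period = 2, duration = 10,
                       dt = 0.1) {
  t <- seq(0, duration, by = dt)
  baseline + amp * sin(2 * pi * t / period)
}

# tiny fast model parameterisation for simulator tests
tiny_params <- function(...) {
  model_params(rows = 2, cols = 2, t_end = 10, seed = 1, ...)
}
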