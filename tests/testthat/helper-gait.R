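# shared fixtures built in code

# exactly periodic, noise-free gait: every transition is a clean step
noise_free_template <- function(...) {
  args <- utils::modifyList(
    list(noise_sd = c(fsr = 0, accel = 0, gyro = 0, hip = 0, angle = 0,
                      cycle_rom = 0, cycle_offset = 0),
         cadence_jitter_sd = 0),
    list(...))
  do.call(gait_template, args)
}

# ground-truth-vs-detected offset (in samples) for each truth event
event_offsets <- function(truth_events, detected_events) {
  vapply(seq_len(nrow(truth_events)), function(i) {
    d <- detected_events$index[detected_events$kind == truth_events$kind[i]]
    if (length(d) == 0) return(Inf)
    min(abs(d - truth_events$index[i]))
  }, numeric(1))
}

# independently coded bilinear-transform discretization of the analog
# second-order Butterworth prototype 1 / ((s/wc)^2 + sqrt(2) s/wc + 1),
# as a difference-equation recursion driven by input x
butter2_recursion <- function(fc, fs, x) {
  K <- tan(pi * fc / fs)
  a0 <- 1 + sqrt(2) * K + K^2
  b <- K^2 * c(1, 2, 1) / a0
  a <- c(1, (2 * K^2 - 2) / a0, (1 - sqrt(2) * K + K^2) / a0)
  y <- numeric(length(x))
  for (n in seq_along(x)) {
    xm1 <- if (n > 1) x[n - 1] else 0
    xm2 <- if (n > 2) x[n - 2] else 0
    ym1 <- if (n > 1) y[n - 1] else 0
    ym2 <- if (n > 2) y[n - 2] else 0
    y[n] <- b[1] * x[n] + b[2] * xm1 + b[3] * xm2 - a[2] * ym1 - a[3] * ym2
  }
  y
}

# brute-force convolution of an impulse train with a kernel: explicit
# double sum over impulse positions
brute_force_response <- function(impulses, kernel, g) {
  n <- length(impulses)
  u <- numeric(n)
  for (pos in which(impulses != 0)) {
    idx <- pos:min(n, pos + length(kernel) - 1)
    u[idx] <- u[idx] + impulses[pos] * kernel[idx - pos + 1]
  }
  g * u
}
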