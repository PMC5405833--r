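test_that("kernel design enforces the valid cutoff range", {
  expect_error(design_kernel(50, fs = 100), "invalid cutoff")
  expect_error(design_kernel(0, fs = 100), "invalid cutoff")
  expect_error(design_kernel(-1, fs = 100), "invalid cutoff")
  expect_s3_class(design_kernel(2, fs = 100), "transfer_function")
})

test_that("kernels have unity DC gain, the -3 dB point at fc, and unit peak response", {
  for (fc in c(0.5, 1, 2, 5, 10)) {
    tf <- design_kernel(fc, fs = 100)
    expect_equal(sum(tf$kernel), 1, tolerance = 1e-3)
    w <- 2 * pi * fc / tf$fs
    H <- sum(tf$b * exp(-1i * w * (0:2))) / sum(tf$a * exp(-1i * w * (0:2)))
    expect_equal(Mod(H), 1 / sqrt(2), tolerance = 1e-3)
    expect_equal(tf$g * max(tf$kernel), 1, tolerance = 1e-12)
    u <- response_output(c(1, rep(0, 3 * tf$L)), tf)
    expect_equal(max(u), 1, tolerance = 1e-12)
    expect_true(all(u >= 0))
  }
})

test_that("kernel samples match an independent difference-equation recursion", {
  tf <- design_kernel(2, fs = 100)
  ref <- butter2_recursion(2, 100, c(1, rep(0, tf$L - 1)))
  expect_equal(tf$kernel, ref, tolerance = 1e-10)
})

test_that("kernel truncation leaves negligible tail energy", {
  tf <- design_kernel(1.5, fs = 100, tol = 1e-6)
  full <- butter2_recursion(1.5, 100, c(1, rep(0, 10 * tf$L)))
  tail_energy <- sum(full[-seq_len(tf$L)]^2)
  expect_lt(tail_energy, 1e-6 * sum(full^2) + 1e-12)
})

test_that("response output is zero for silence and matches brute-force convolution", {
  tf <- design_kernel(2, fs = 100)
  expect_equal(response_output(rep(0, 200), tf), rep(0, 200))
  # two impulses 50 samples apart vs the explicit double-sum oracle
  imp <- rep(0, 400); imp[c(40, 90)] <- 1
  got <- response_output(imp, tf, clamp = FALSE)
  ref <- brute_force_response(imp, tf$kernel, tf$g)
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("raw responses are linear in the impulse train", {
  tf <- design_kernel(1, fs = 100)
  set.seed(11)
  i1 <- rbinom(500, 1, 0.02); i2 <- rbinom(500, 1, 0.02)
  u12 <- response_output(i1 + i2, tf, clamp = FALSE)
  expect_equal(u12,
               response_output(i1, tf, clamp = FALSE) +
                 response_output(i2, tf, clamp = FALSE),
               tolerance = 1e-9)
})

test_that("a sampling-grid mismatch raises a resampling error", {
  tf <- design_kernel(2, fs = 100)
  expect_error(response_output(rep(0, 10), tf, fs = 200), "resampling required")
})

test_that("phase gates open only during each component's phases", {
  expect_identical(gate("SW", c("SW", "TSW")), 1L)   # TA during swing
  expect_identical(gate("TSW", c("SW", "TSW")), 1L)
  expect_identical(gate("LR", "LR"), 1L)             # LG heel-strike component
  expect_identical(gate("ST", c("SW", "TSW")), 0L)
  expect_identical(gate(c("LR", "PS", "SW"), "PS"), c(0L, 1L, 0L))
  expect_error(gate("XX", "SW"))
})

test_that("channel configuration derives delta_c and disjoint component gating", {
  cfg <- muscle_channel_config("LG", "left", cmin = 16, cmax = 22)
  expect_equal(cfg$delta_c, 6)
  expect_identical(cfg$id, "L_LG")
  sets <- lapply(cfg$components, `[[`, "phases")
  expect_length(Reduce(intersect, sets), 0)
  expect_error(muscle_channel_config("TA", "left", cmin = 20, cmax = 10))
})

test_that("default cutoffs follow the gated phase duration", {
  cfg <- muscle_channel_config("TA", "left", cmin = 10, cmax = 20,
                               cycle_duration = 2)
  d <- 2 * sum(default_phase_fractions()[c("SW", "TSW")])
  expect_equal(cfg$components[[1]]$tf$fc, 1 / (2 * d))
  cfg2 <- muscle_channel_config("RF", "left", cmin = 14, cmax = 20,
                                fc = c(3, 4))
  expect_equal(vapply(cfg2$components, function(x) x$tf$fc, 0), c(3, 4))
})

test_that("the current mapping spans [cmin, cmax] and gates to zero", {
  cfg <- muscle_channel_config("TA", "left", cmin = 10, cmax = 20)
  expect_equal(channel_current(1, 1, cfg), 20)
  expect_equal(channel_current(0, 1, cfg), 10)
  expect_equal(channel_current(0.5, 0, cfg), 0)
  expect_error(channel_current(1.5, 1, cfg), "contract violation")
  # multi-component channel sums its (disjointly gated) terms
  lg <- muscle_channel_config("LG", "left", cmin = 16, cmax = 22)
  expect_equal(channel_current(c(1, 0.5), c(1, 0), lg), 22)
  expect_equal(channel_current(c(1, 0.5), c(0, 1), lg), 19)
})

test_that("the packaged subject fixture reproduces the measured current bands", {
  cfgs <- load_stim_config("A", sides = c("left", "right"))
  expect_length(cfgs, 8)
  expect_equal(cfgs$L_TA$cmin, 10); expect_equal(cfgs$L_TA$cmax, 20)
  expect_equal(cfgs$R_LG$cmin, 12); expect_equal(cfgs$R_LG$cmax, 14)
  expect_equal(cfgs$L_BF$cmax, 26)
  g <- load_stim_config("G", sides = "right")
  expect_equal(g$R_RF$cmax, 28)
  expect_equal(cfgs$L_TA$pulse_width, 350)
  expect_equal(cfgs$L_TA$stim_frequency, 40)
  expect_error(load_stim_config("Z"), "unknown subject")
})

test_that("constant double support commands zero current on every channel", {
  frames <- data.frame(t = (0:199) / 100, GH = 1L, GT = 1L, PhiH = 0L)
  cmds <- run_controller(frames, load_stim_config("A", sides = "left"))
  cur <- as.matrix(cmds$commands[, -1])
  expect_true(all(cur == 0))
  expect_error(run_controller(frames, list()), "configuration error")
})

test_that("controller currents respect gating phases and subject bounds", {
  rec <- generate_gait(noise_free_template(), 8, seed = 6)
  frames <- process_sensors(rec$sensors)
  cfgs <- load_stim_config("A", sides = "left")
  cmds <- run_controller(frames, cfgs)
  # TA stimulates only while airborne
  ta <- cmds$commands$L_TA
  expect_true(all(cmds$phases[ta > 0] %in% c("SW", "TSW")))
  expect_true(any(ta > 0))
  # every nonzero current within the channel's measured band
  for (id in names(cfgs)) {
    nz <- cmds$commands[[id]][cmds$commands[[id]] > 0]
    expect_true(all(nz >= cfgs[[id]]$cmin - 1e-9))
    expect_true(all(nz <= cfgs[[id]]$cmax + 1e-9))
  }
  # LG and RF components never overlap: currents stay single-valued per phase
  lg <- cmds$commands$L_LG
  expect_true(all(cmds$phases[lg > 0] %in% c("LR", "PS")))
})

test_that("the controller is deterministic and its CSV writer round-trips", {
  rec <- generate_gait(noise_free_template(), 4, seed = 8)
  frames <- process_sensors(rec$sensors)
  cfgs <- load_stim_config("B", sides = "left")
  c1 <- run_controller(frames, cfgs)
  c2 <- run_controller(frames, cfgs)
  expect_identical(c1$commands, c2$commands)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stim_csv(c1, path)
  back <- utils::read.csv(path)
  expect_equal(back$L_TA, c1$commands$L_TA, tolerance = 1e-6)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$L_TA$pulse_width, 350)
  expect_equal(meta$L_TA$frequency, 40)
})
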