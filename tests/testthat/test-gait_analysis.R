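test_that("cycle segmentation extracts the requested complete cycles", {
  angles <- data.frame(t = (0:999) / 100, hip = sin((0:999) / 100))
  hs <- seq(0, 9.9, by = 0.33)                 # 31 heel strikes -> 30 cycles
  cycles <- segment_cycles(hs[1:31], angles, n_keep = 30)
  expect_length(cycles, 30)
  expect_true(all(vapply(cycles, nrow, 0L) >= 2))
  one <- segment_cycles(c(1, 2), angles, n_keep = 1)
  expect_length(one, 1)
  expect_equal(range(one[[1]]$t), c(1, 2))
  expect_error(segment_cycles(seq(0, 9, by = 1), angles, n_keep = 30),
               "9 complete cycle")
})

test_that("time normalization resamples onto 101 points, preserving endpoints", {
  cyc <- data.frame(t = seq(0, 1.7, length.out = 57),
                    hip = cumsum(rnorm(57)))
  norm <- normalize_cycle(cyc)
  expect_equal(nrow(norm), 101)
  expect_equal(norm$pct, seq(0, 100, 1))
  expect_equal(norm$hip[1], cyc$hip[1])
  expect_equal(norm$hip[101], cyc$hip[57])
  # constant input stays constant
  const <- normalize_cycle(data.frame(t = 0:10, knee = 7))
  expect_equal(const$knee, rep(7, 101))
  # linear ramp maps to the exact arithmetic progression
  ramp <- normalize_cycle(data.frame(t = seq(0, 2, 0.01),
                                     ankle = seq(-3, 5, length.out = 201)))
  expect_equal(ramp$ankle, seq(-3, 5, length.out = 101), tolerance = 1e-12)
})

test_that("normalized statistics are invariant to uniform time rescaling", {
  set.seed(5)
  cyc <- data.frame(t = seq(0, 1, length.out = 120),
                    hip = 20 * sin(2 * pi * seq(0, 1, length.out = 120)))
  slow <- cyc; slow$t <- cyc$t * 3.7
  expect_equal(compute_stats(normalize_cycle(cyc)),
               compute_stats(normalize_cycle(slow)), tolerance = 1e-12)
})

test_that("per-cycle statistics report max, min and RoM = max - min", {
  x <- seq(0, 100, 1)
  cyc <- data.frame(pct = x, hip = 10 + 4 * sin(2 * pi * x / 100), knee = 3)
  st <- compute_stats(cyc)
  expect_equal(st$rom, st$max - st$min)
  expect_true(all(st$rom >= 0))
  expect_equal(st$rom[st$joint == "knee"], 0)
  expect_equal(st$max[st$joint == "hip"], 14, tolerance = 0.01)
  expect_equal(st$min[st$joint == "hip"], 6, tolerance = 0.01)
})

test_that("statistics match the generator's per-cycle extrema exactly", {
  # 2.0 s cycles at 100 Hz: the 101-point grid lands on every 2nd sample,
  # so interpolation is exact and extrema can be cross-checked directly
  rec <- generate_gait(noise_free_template(), 4, seed = 1)
  cycles <- segment_cycles(rec$truth$hs_times, rec$angles, n_keep = 3)
  st <- compute_stats(lapply(cycles, normalize_cycle))
  for (i in 1:3) {
    sub <- cycles[[i]][seq(1, nrow(cycles[[i]]), by = 2), ]
    for (j in c("hip", "knee", "ankle")) {
      # absolute bound: extrema can sit near 0 deg where relative
      # comparison amplifies interpolation round-off
      expect_lt(abs(st$max[st$cycle == i & st$joint == j] - max(sub[[j]])), 1e-9)
      expect_lt(abs(st$min[st$cycle == i & st$joint == j] - min(sub[[j]])), 1e-9)
    }
  }
})

test_that("identical conditions give t = 0, p = 1 and no significance", {
  set.seed(3)
  st <- data.frame(cycle = rep(1:10, each = 1), joint = "hip",
                   max = rnorm(10, 30), min = rnorm(10, -10))
  st$rom <- st$max - st$min
  cmp <- compare_conditions(st, st)
  expect_equal(cmp$t, rep(0, 3))
  expect_equal(cmp$p, rep(1, 3))
  expect_false(any(cmp$significant))
})

test_that("the pooled t statistic matches the closed-form textbook formula", {
  a <- c(12.1, 11.8, 12.5, 12.0, 11.6)
  b <- c(13.0, 12.7, 13.4, 12.9, 13.1)
  stA <- data.frame(cycle = 1:5, joint = "ankle", max = a, min = 0, rom = a)
  stB <- data.frame(cycle = 1:5, joint = "ankle", max = b, min = 0, rom = b)
  cmp <- compare_conditions(stA, stB)
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  row <- cmp[cmp$parameter == "rom", ]
  expect_equal(row$t, t_ref, tolerance = 1e-12)
  expect_equal(row$df, 8)
  expect_equal(row$p, 2 * stats::pt(-abs(t_ref), 8), tolerance = 1e-12)
})

test_that("the Welch variant and Bonferroni divisor are honoured", {
  set.seed(9)
  a <- rnorm(20, 0, 1); b <- rnorm(20, 0.5, 4)
  stA <- data.frame(cycle = 1:20, joint = "hip", max = a, min = 0, rom = a)
  stB <- data.frame(cycle = 1:20, joint = "hip", max = b, min = 0, rom = b)
  pooled <- compare_conditions(stA, stB)
  welch <- compare_conditions(stA, stB, var_equal = FALSE)
  expect_false(isTRUE(all.equal(pooled$df[1], welch$df[1])))
  cmp <- compare_conditions(stA, stB, alpha = 0.05, n_comparisons = 12)
  expect_equal(attr(cmp, "alpha_corrected"), 0.05 / 12)
})

test_that("degenerate zero-variance comparisons are well-defined", {
  stA <- data.frame(cycle = 1:3, joint = "hip", max = 5, min = 1, rom = 4)
  stB_eq <- stA
  cmp <- compare_conditions(stA, stB_eq)
  expect_equal(cmp$t, rep(0, 3))
  expect_equal(cmp$p, rep(1, 3))
  stB_ne <- transform(stA, max = 6, rom = 5)
  cmp2 <- compare_conditions(stA, stB_ne)
  expect_equal(cmp2$p[cmp2$parameter == "rom"], 0)
})

test_that("stats and comparison writers produce the documented outputs", {
  set.seed(2)
  x <- rnorm(10, 25); y <- rnorm(10, 30)
  stA <- data.frame(cycle = 1:10, joint = "ankle", max = x, min = 0, rom = x)
  stB <- data.frame(cycle = 1:10, joint = "ankle", max = y, min = 0, rom = y)
  cmp <- compare_conditions(stA, stB)
  csv <- withr::local_tempfile(fileext = ".csv")
  txt <- withr::local_tempfile(fileext = ".txt")
  write_comparison_report(cmp, csv, txt)
  expect_named(utils::read.csv(csv),
               c("joint", "parameter", "mean_a", "mean_b", "diff",
                 "t", "df", "p", "significant"))
  expect_true(any(grepl("corrected p < 0.004", readLines(txt))))
  sp <- withr::local_tempfile(fileext = ".csv")
  write_stats_csv(stA, sp)
  expect_equal(nrow(utils::read.csv(sp)), 10)
})
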