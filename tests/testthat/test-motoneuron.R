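test_that("firing-rate curve passes through its defining points", {
  # slow-unit curve of the overlap sweep: 5 -> 18 Hz over activation [0, 0.5]
  s <- firing_curve(0, 5, 0.5, 18)
  expect_equal(firing_rate(s, 0.5), 18)
  expect_equal(firing_rate(s, 0.75), 18)          # saturated
  expect_equal(firing_rate(s, 0.25), 11.5)        # 5 + 26 * 0.25
  expect_equal(rate_slope(s), 26)

  ff <- firing_curve(0.5, 18, 1, 35)
  expect_equal(rate_slope(ff), 34)
  expect_equal(firing_rate(ff, 0.5 - 1e-9), 0)    # below threshold
  expect_equal(firing_rate(ff, 0.5), 0)           # fires strictly above x_thr
  expect_equal(firing_rate(ff, 1), 35)

  flat <- firing_curve(0.1, 12, 0.9, 12)
  expect_equal(rate_slope(flat), 0)
  expect_equal(firing_rate(flat, 0.5), 12)

  expect_error(firing_curve(0.5, 5, 0.5, 18), class = "lifesim_validation_error")
  expect_error(firing_curve(0, 0, 0.5, 18), class = "lifesim_validation_error")
  expect_error(rate_slope(list(x_thr = 0.3, x_sat = 0.3, f_thr = 1, f_sat = 2)),
               class = "lifesim_validation_error")
})

test_that("firing rate is non-decreasing in activation and bounded by f_sat", {
  set.seed(7)
  for (i in 1:20) {
    x_thr <- runif(1, 0, 0.6); x_sat <- runif(1, x_thr + 0.05, 1)
    f_thr <- runif(1, 1, 10); f_sat <- runif(1, f_thr, 40)
    cv <- firing_curve(x_thr, f_thr, x_sat, f_sat)
    x <- sort(runif(200))
    f <- firing_rate(cv, x)
    expect_true(all(diff(f) >= -1e-12))
    expect_true(all(f <= f_sat + 1e-12))
    expect_true(all(f[x <= x_thr] == 0))
    expect_true(all(f[f > 0] >= f_thr - 1e-9 | f[f > 0] == 0))
  }
})

test_that("ISI draws match their distributional contracts", {
  # identity: exactly regular
  expect_equal(draw_isi(point_process("identity"), 0.1, 5), rep(0.1, 5))

  withr_seed <- function(s, expr) { set.seed(s); expr }

  # poisson: exponential moments
  withr_seed(1, {
    x <- draw_isi(point_process("poisson"), 0.05, 1e5)
    expect_equal(mean(x), 0.05, tolerance = 0.01)
    expect_equal(sd(x) / mean(x), 1, tolerance = 0.02)
  })

  # gamma: requested mean and dispersion; tight dispersion concentrates
  withr_seed(2, {
    x <- draw_isi(point_process("gamma", dispersion = 0.005), 0.05, 1e5)
    expect_equal(mean(x), 0.05, tolerance = 0.01)
    expect_equal(sd(x), 0.005, tolerance = 0.05)
    y <- draw_isi(point_process("gamma", dispersion = 1e-5), 0.05, 1e4)
    expect_lt(max(abs(y - 0.05)), 1e-3)
  })

  # truncated gaussian: mean preserved away from the floor, never below it
  withr_seed(3, {
    x <- draw_isi(point_process("truncated_gaussian", dispersion = 0.003), 0.05, 1e5)
    expect_equal(mean(x), 0.05, tolerance = 0.01)
    expect_true(all(x >= 1e-3))
  })

  # uniform: support bounds
  withr_seed(4, {
    x <- draw_isi(point_process("uniform", width = 0.02), 0.05, 1e5)
    expect_true(all(x >= 0.04 - 1e-12 & x <= 0.06 + 1e-12))
    expect_equal(mean(x), 0.05, tolerance = 0.01)
  })

  expect_error(draw_isi(point_process("poisson"), 0), class = "lifesim_validation_error")
  expect_error(point_process("gamma"), class = "lifesim_validation_error")
  expect_error(point_process("uniform"), class = "lifesim_validation_error")
})

test_that("all stochastic ISI draws respect the 1 ms floor", {
  set.seed(11)
  specs <- list(point_process("poisson"),
                point_process("truncated_gaussian", dispersion = 0.004),
                point_process("gamma", dispersion = 0.004),
                point_process("uniform", width = 0.012))
  for (sp in specs) {
    x <- draw_isi(sp, 0.006, 1e4)   # mean close to the floor
    expect_true(all(x >= sp$isi_floor))
  }
})

test_that("spike-train generation follows the sequential-ISI contract", {
  g <- quick_grid(1)

  # below threshold everywhere: empty train
  mn <- unit_with_rate(10)
  tr0 <- generate_spike_times(mn, rep(0, g$n_samples), g, seed = 1)
  expect_length(tr0$event_times, 0)

  # identity at 10 Hz for 1 s: 10 regular events, first one ISI in
  tr <- generate_spike_times(mn, rep(1, g$n_samples), g, seed = 1)
  expect_equal(tr$event_times, seq(0.1, 1, by = 0.1))

  # events sorted, inside [0, T], spacing above the floor
  mnp <- unit_with_rate(30, process = point_process("poisson"))
  trp <- generate_spike_times(mnp, rep(1, g$n_samples), g, seed = 2)
  expect_true(all(diff(trp$event_times) >= mnp$process$isi_floor - 1e-12))
  expect_true(all(trp$event_times >= 0 & trp$event_times <= 1))

  # determinism and substream isolation
  tr_a <- generate_spike_times(mnp, rep(1, g$n_samples), g, seed = 5)
  tr_b <- generate_spike_times(mnp, rep(1, g$n_samples), g, seed = 5)
  tr_c <- generate_spike_times(mnp, rep(1, g$n_samples), g, seed = 6)
  expect_identical(tr_a$event_times, tr_b$event_times)
  expect_false(identical(tr_a$event_times, tr_c$event_times))
})

test_that("poisson event counts match rate x duration statistics", {
  g <- time_grid(2000, 200)  # coarse grid is fine for counting
  mn <- unit_with_rate(20, process = point_process("poisson"))
  tr <- generate_spike_times(mn, rep(1, g$n_samples), g, seed = 3)
  expect_lt(abs(length(tr$event_times) - 4000), 3 * sqrt(4000))
})

test_that("empirical mean ISI converges to 1/f under constant activation", {
  g <- time_grid(2000, 600)
  mn <- unit_with_rate(18, process = point_process("gamma", dispersion = 0.01))
  tr <- generate_spike_times(mn, rep(1, g$n_samples), g, seed = 8)
  isi <- diff(tr$event_times)
  se <- sd(isi) / sqrt(length(isi))
  expect_lt(abs(mean(isi) - 1 / 18), 3 * se + 1e-5)
})

test_that("pool sampling stays inside the requested ranges", {
  ranges <- list(duration = c(0.004, 0.006), amplitude = c(45, 65),
                 f_thr = c(1, 5), f_sat = c(16, 18),
                 x_thr = c(0, 0.10), x_sat = c(0.40, 0.50))
  pool <- sample_pool(ranges, 6, "S", seed = 10)
  expect_length(pool, 6)
  for (m in pool) {
    expect_true(m$duration >= 0.004 && m$duration <= 0.006)
    expect_true(m$amplitude >= 45 && m$amplitude <= 65)
    expect_true(m$curve$f_thr >= 1 && m$curve$f_thr <= 5)
    expect_true(m$curve$f_sat >= 16 && m$curve$f_sat <= 18)
    expect_true(m$curve$x_thr >= 0 && m$curve$x_thr <= 0.10)
    expect_true(m$curve$x_sat >= 0.40 && m$curve$x_sat <= 0.50)
  }

  # degenerate ranges are deterministic
  degen <- lapply(ranges, function(r) rep(mean(r), 2))
  p2 <- sample_pool(degen, 2, "S", seed = 1)
  expect_equal(p2[[1]]$curve$x_thr, mean(ranges$x_thr))
  expect_equal(p2[[1]]$duration, p2[[2]]$duration)

  expect_error(sample_pool(ranges, 0, "S"), class = "lifesim_config_error")
  bad <- ranges; bad$x_thr <- c(0.6, 0.7); bad$x_sat <- c(0.1, 0.2)
  expect_error(sample_pool(bad, 2, "S"), class = "lifesim_config_error")
})

test_that("run-1 threshold ranges give sequential S -> FF recruitment", {
  cfg <- build_run1(seed = 4, duration = 1)
  s_thr <- sapply(cfg$pool[1:6], function(m) m$curve$x_thr)
  ff_thr <- sapply(cfg$pool[7:12], function(m) m$curve$x_thr)
  expect_lt(max(s_thr), min(ff_thr))
})

test_that("pool tables and spike-event lists round-trip through text files", {
  pool <- sample_pool(list(duration = c(0.002, 0.004), amplitude = c(95, 105),
                           f_thr = c(12, 19), f_sat = c(25, 30),
                           x_thr = c(0.35, 0.65), x_sat = c(0.80, 1.00)),
                      4, "FF",
                      process = point_process("gamma", dispersion = 0.004),
                      seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_pool_table(pool, path)
  back <- read_pool_table(path)
  expect_equal(back, pool, tolerance = 1e-9)
  unlink(path)

  g <- quick_grid(1)
  trains <- list(manual_train(c(0.1, 0.5), g, id = 1),
                 manual_train(numeric(0), g, id = 2),
                 manual_train(0.25, g, id = 3))
  p2 <- tempfile(fileext = ".tsv")
  write_spike_events(trains, p2)
  ev <- read.table(p2, header = TRUE, sep = "\t")
  expect_equal(nrow(ev), 3)
  expect_setequal(ev$motoneuron_id, c(1, 1, 3))
  unlink(p2)
})
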