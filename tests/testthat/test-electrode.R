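test_that("H = C B composition matches hand-computed products", {
  # identity crosstalk: H == B
  B <- rbind(c(0.5, 1.0), c(0.2, 0))
  m <- compose_mapping(B)
  expect_equal(m$H, B)

  # single electrode
  m1 <- compose_mapping(matrix(c(0.5, 1.0), 1, 2), matrix(1))
  expect_equal(as.numeric(m1$H), c(0.5, 1.0))

  # 2x2 crosstalk mixing two one-hot rows
  B2 <- rbind(c(1, 0), c(0, 1))
  C2 <- rbind(c(1, 0.5), c(0.5, 1))
  m2 <- compose_mapping(B2, C2)
  expect_equal(m2$H, C2)
  expect_equal(m2$H, C2 %*% B2)

  expect_error(compose_mapping(B2, matrix(1, 3, 3)),
               class = "lifesim_validation_error")
  expect_error(compose_mapping(rbind(c(-1, 0), c(0, 1))),
               class = "lifesim_validation_error")
})

test_that("virtual electrodes are the B-weighted sums of axon traces", {
  g <- quick_grid(0.5)
  lib <- morphology_library()
  tpls <- list(scale_template(lib$symmetric_1peak, 50, 0.004, g),
               scale_template(lib$symmetric_1peak, 100, 0.002, g))
  axons <- render_pool(list(manual_train(c(0.1, 0.3), g, 1),
                            manual_train(0.2, g, 2)), tpls, g)

  one_hot <- compose_mapping(rbind(c(1, 0), c(0, 1)))
  v <- virtual_signals(axons, one_hot)
  expect_equal(v[1, ], axons$values[1, ])
  expect_equal(v[2, ], axons$values[2, ])

  zero <- compose_mapping(matrix(0, 1, 2))
  expect_true(all(virtual_signals(axons, zero) == 0))

  w <- compose_mapping(matrix(c(0.5, 1.0), 1, 2))
  expect_equal(as.numeric(virtual_signals(axons, w)),
               0.5 * axons$values[1, ] + 1.0 * axons$values[2, ])

  expect_error(virtual_signals(axons, compose_mapping(matrix(1, 1, 3))),
               class = "lifesim_validation_error")
})

test_that("noise sigma follows the percentile-span SNR convention", {
  # trace scaled so its 99.9-0.1 percentile span is exactly 9
  set.seed(21)
  raw <- rnorm(1e5)
  q <- quantile(raw, c(0.999, 0.001), names = FALSE)
  trace <- raw * (9 / (q[1] - q[2]))
  expect_equal(noise_sigma_from_snr(trace, 3), 1)

  # independent recomputation of the formula on an arbitrary trace
  u <- runif(1e6)
  qq <- quantile(u, c(0.999, 0.001), names = FALSE)
  expect_equal(noise_sigma_from_snr(u, 3), (qq[1] - qq[2]) / 9)
  expect_equal(noise_sigma_from_snr(u, 3), 0.1109, tolerance = 0.01)

  # snr -> infinity limit
  expect_lt(noise_sigma_from_snr(trace, 1e9), 1e-8)

  expect_error(noise_sigma_from_snr(rep(1, 1000), 3),
               class = "lifesim_validation_error")
  expect_error(noise_sigma_from_snr(trace, 0),
               class = "lifesim_validation_error")
})

test_that("power-law noise has the requested spectral exponent and scale", {
  g <- time_grid(20000, 10)
  n2 <- generate_powerlaw_noise(2, 1.5, g, seed = 5)
  expect_equal(sd(n2), 1.5, tolerance = 1e-9)
  expect_equal(psd_loglog_slope(n2, 20000), -2, tolerance = 0.2)

  n0 <- generate_powerlaw_noise(0, 2, g, seed = 6)
  expect_lt(abs(psd_loglog_slope(n0, 20000)), 0.1)
  expect_equal(sd(n0), 2, tolerance = 1e-9)

  n1 <- generate_powerlaw_noise(1, 1, g, seed = 7)
  expect_equal(psd_loglog_slope(n1, 20000), -1, tolerance = 0.2)

  # determinism
  expect_identical(generate_powerlaw_noise(2, 1, g, seed = 5),
                   generate_powerlaw_noise(2, 1, g, seed = 5))
  expect_error(generate_powerlaw_noise(-1, 1, g, 1),
               class = "lifesim_validation_error")
})

test_that("band-limited gaussian noise is calibrated to the target SNR", {
  g <- time_grid(20000, 10)
  set.seed(3)
  pure <- rnorm(g$n_samples) * 10
  spec <- noise_spec("gaussian_snr", snr = 3, band = c(100, 7500))
  w <- generate_gaussian_noise(spec, pure, g, seed = 9)
  expect_equal(sd(w), noise_sigma_from_snr(pure, 3), tolerance = 1e-9)
  expect_equal(measured_snr(pure, w), 3, tolerance = 0.05)
  expect_identical(w, generate_gaussian_noise(spec, pure, g, seed = 9))

  # narrow band concentrates the PSD there
  narrow <- noise_spec("gaussian_snr", snr = 3, band = c(900, 1100))
  wn <- generate_gaussian_noise(narrow, pure, g, seed = 10)
  psd <- psd_welch(wn, 20000)
  inband <- psd$frequency >= 800 & psd$frequency <= 1200
  expect_gt(sum(psd$power[inband]) / sum(psd$power), 0.9)

  bad <- noise_spec("gaussian_snr", snr = 3, band = c(100, 11000))
  expect_error(generate_gaussian_noise(bad, pure, g, 1),
               class = "lifesim_validation_error")
})

test_that("record() assembles z = H y + W with full ground truth", {
  g <- quick_grid(0.5)
  lib <- morphology_library()
  tpls <- list(scale_template(lib$symmetric_1peak, 50, 0.004, g),
               scale_template(lib$asymmetric_1peak, 100, 0.002, g))
  axons <- render_pool(list(manual_train(c(0.1, 0.3), g, 1),
                            manual_train(0.2, g, 2)), tpls, g)

  # zero noise + one-hot H: z equals the axon trace exactly
  rec <- record(axons, compose_mapping(rbind(c(1, 0), c(0, 1))))
  expect_equal(rec$values[1, ], axons$values[1, ])
  expect_equal(rec$values[2, ], axons$values[2, ])

  # silent axons: z equals the noise trace
  silent <- render_pool(list(manual_train(numeric(0), g, 1)),
                        list(tpls[[1]]), g)
  recn <- record(silent, compose_mapping(matrix(1, 1, 1)),
                 noise_spec("powerlaw", beta = 2, amplitude = 1), seed = 4)
  expect_equal(recn$values[1, ], recn$noise[1, ])
  expect_true(all(recn$pure == 0))
})

test_that("noise-free recordings equal brute-force per-event accumulation", {
  g <- quick_grid(2)
  set.seed(31)
  lib <- morphology_library()
  n_axons <- 6
  trains <- lapply(seq_len(n_axons), function(i)
    manual_train(sort(runif(sample(20:100, 1), 0, 1.9)), g, i))
  tpls <- lapply(seq_len(n_axons), function(i)
    scale_template(lib[[sample(3, 1)]], runif(1, 45, 105),
                   runif(1, 0.002, 0.006), g))
  axons <- render_pool(trains, tpls, g)
  B <- matrix(runif(3 * n_axons, 0, 1), nrow = 3)
  C <- diag(3) + matrix(runif(9, 0, 0.2), 3, 3)
  mapping <- compose_mapping(B, C)
  rec <- record(axons, mapping)
  expect_equal(rec$values, record_oracle(trains, tpls, mapping$H, g),
               tolerance = 1e-12)
})

test_that("scaling one B row scales that axon's contribution exactly", {
  g <- quick_grid(0.5)
  tpl <- scale_template(morphology_library()$symmetric_1peak, 50, 0.004, g)
  trains <- list(manual_train(c(0.1, 0.2), g, 1), manual_train(0.3, g, 2))
  axons <- render_pool(trains, list(tpl, tpl), g)
  B1 <- matrix(c(0.5, 0.8), 1, 2)
  B2 <- matrix(c(1.0, 0.8), 1, 2)
  r1 <- record(axons, compose_mapping(B1))
  r2 <- record(axons, compose_mapping(B2))
  contrib1 <- r1$values[1, ] - 0.8 * axons$values[2, ]
  contrib2 <- r2$values[1, ] - 0.8 * axons$values[2, ]
  expect_equal(contrib2, 2 * contrib1, tolerance = 1e-12)
})

test_that("per-electrode noise realizations are independent unless shared", {
  g <- time_grid(20000, 10)
  active <- render_pool(list(manual_train(seq(0.05, 9.95, by = 0.05), g, 1)),
                        list(scale_template(morphology_library()$symmetric_1peak,
                                            50, 0.004, g)), g)
  spec <- noise_spec("gaussian_snr", snr = 3, band = c(100, 7500))
  rec <- record(active, compose_mapping(matrix(1, 2, 1)), spec, seed = 12)
  expect_lt(abs(cor(rec$noise[1, ], rec$noise[2, ])), 0.05)

  shared <- noise_spec("gaussian_snr", snr = 3, band = c(100, 7500),
                       shared_across_electrodes = TRUE)
  rec2 <- record(active, compose_mapping(matrix(1, 2, 1)), shared, seed = 12)
  expect_identical(rec2$noise[1, ], rec2$noise[2, ])
})

test_that("file-based noise is read and resampled onto the grid", {
  g <- quick_grid(1)
  path <- tempfile(fileext = ".txt")
  set.seed(14)
  writeLines(format(rnorm(10000), digits = 10), path)  # 10 kHz source
  spec <- noise_spec("file", path = path, rate = 10000)
  silent <- render_pool(list(manual_train(numeric(0), g, 1)),
                        list(scale_template(morphology_library()$symmetric_1peak,
                                            50, 0.004, g)), g)
  rec <- record(silent, compose_mapping(matrix(1, 1, 1)), spec, seed = 1)
  expect_equal(ncol(rec$noise), g$n_samples)
  expect_gt(sd(rec$noise[1, ]), 0.5)  # resampling keeps the scale
  unlink(path)
})
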