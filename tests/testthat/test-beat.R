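test_that("median beat CSV round-trips losslessly and converts units", {
  path <- withr::local_tempfile(fileext = ".csv")
  # zero signal
  zb <- zero_beat()
  write_median_beat(zb, path)
  back <- read_median_beat(path)
  expect_identical(unclass(back)[, ], unclass(zb)[, ])
  expect_equal(attr(back, "fs"), 500)
  expect_true(all(back == 0))

  # a structured beat survives a uV round trip bitwise
  b <- make_beat(beat_spec(noise_sd = 3), seed = 42)
  write_median_beat(b, path)
  expect_identical(unclass(read_median_beat(path))[, ], unclass(b)[, ])

  # the same data written in mV reads back x1000 into uV
  write_median_beat(b, path, units = "mV")
  expect_equal(unclass(read_median_beat(path))[, ], unclass(b)[, ],
               tolerance = 1e-12)
})

test_that("reader rejects malformed files with hard errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  b <- make_beat(beat_spec(noise_sd = 0), seed = 1)
  write_median_beat(b, path)
  # missing lead
  lines <- readLines(path)
  lines[2] <- sub("V6", "V6x", lines[2])
  writeLines(lines, path)
  expect_error(read_median_beat(path), "V6")
  # unknown units
  lines <- readLines(path)
  lines[1] <- "# fs=500 units=volts"
  lines[2] <- sub("V6x", "V6", lines[2])
  writeLines(lines, path)
  expect_error(read_median_beat(path), "unknown units")
  # non-finite sample
  m <- unclass(b)[, ]
  m[5, 3] <- NA
  expect_error(median_beat(m, 500), "non-finite")
  expect_error(read_median_beat(withr::local_tempfile()), "no such file")
})

test_that("fiducial windows enforce their ordering invariant", {
  expect_s3_class(fiducials(0, 10, 10, 20, 30), "fiducials")
  expect_error(fiducials(10, 10, 20, 30, 40))   # empty P
  expect_error(fiducials(0, 30, 20, 40, 50))    # P overlaps QRS
  expect_error(fiducials(0, 10, 20, 40, 40))    # empty T
  expect_error(fiducials(0, 10, 20, 40, 50, n = 45))  # beyond signal
})

test_that("amplitudes read off deflections relative to the baseline", {
  fid <- std_fid()
  # single -1700 uV trough in V3 inside the QRS window
  b <- plateau_beat("V3", -1700, 160L, 180L)
  m <- measure_amplitudes(b, fid)
  expect_equal(m$S[["V3"]], 1.7)
  expect_equal(m$R[["V3"]], 0)
  expect_equal(m$qrs_ms, 100)  # (200 - 150) / 500 Hz
  expect_equal(m$sd_lead, "V3")
  expect_equal(m$sd_value, 1.7)

  # all-zero beat: every amplitude zero, deepest S zero
  mz <- measure_amplitudes(zero_beat(), fid)
  expect_true(all(mz$R == 0) && all(mz$S == 0))
  expect_equal(mz$sd_value, 0)

  expect_error(measure_amplitudes(zero_beat(), fiducials(0, 10, 20, 21, 40)),
               "shorter than 2")
})

test_that("generator-known Gaussian peaks are recovered within 1%", {
  # one wavelet per lead so peaks are not distorted by sibling waves
  comp <- data.frame(
    wave = c("P", "QRS", "QRS", "QRS", "T"),
    center = c(200, 400, 400, 400, 650),
    sigma = c(15, 10, 10, 10, 30),
    lead = c("I", "V5", "II", "V2", "V4"),
    amp = c(80, 1500, 900, -1100, 300))
  b <- make_beat(beat_spec(noise_sd = 0, components = comp))
  m <- measure_amplitudes(b, attr(b, "fiducials"))
  expect_equal(m$R[["V5"]], 1.5, tolerance = 0.01)
  expect_equal(m$R[["II"]], 0.9, tolerance = 0.01)
  expect_equal(m$S[["V2"]], 1.1, tolerance = 0.01)
  expect_equal(m$sd_lead, "V2")
})

test_that("amplitude measurement is invariant to constant lead offsets", {
  fid <- std_fid()
  set.seed(31)
  for (rep in 1:5) {
    b <- make_beat(beat_spec(noise_sd = 5))
    m0 <- measure_amplitudes(b, fid)
    shift <- matrix(rep(runif(12, -300, 300), each = nrow(b)), nrow(b))
    b2 <- median_beat(unclass(b)[, ] + shift, attr(b, "fs"))
    m1 <- measure_amplitudes(b2, fid)
    expect_equal(m1$R, m0$R, tolerance = 1e-9)
    expect_equal(m1$S, m0$S, tolerance = 1e-9)
  }
})

test_that("T-wave area matches closed forms in Ashman units", {
  # rectangular T: 0.1 mV plateau spanning a 40 ms T window -> 1 AU
  fid_rect <- fiducials(40L, 100L, 150L, 250L, 270L)
  b <- plateau_beat("I", 100, 250L, 270L)  # samples 250..270 @500 Hz = 40 ms
  expect_equal(t_wave_area(b, "I", fid_rect), 1.0)
  fid <- std_fid()
  # zero signal -> 0
  expect_equal(t_wave_area(zero_beat(), "V2", fid), 0)
  # triangle: peak 0.2 mV, base 80 ms -> 8 ms.mV / 4 = 2 AU
  n <- 600L
  m <- matrix(0, n, 12L, dimnames = list(NULL, LEADS12))
  base_samp <- 40L  # 80 ms
  tri <- c(seq(0, 200, length.out = base_samp / 2 + 1),
           seq(200, 0, length.out = base_samp / 2 + 1)[-1])
  m[fid_rows_t(250L, 250L + base_samp + 1L), "V5"] <- tri
  expect_equal(t_wave_area(median_beat(m, 500), "V5", fid), 2.0)
  # empty T window errors
  expect_error(t_wave_area(zero_beat(), "I",
                           structure(list(p_on = 0L, p_off = 10L,
                                          qrs_on = 20L, qrs_off = 40L,
                                          t_off = 40L),
                                     class = "fiducials")),
               "empty T window")
})

test_that("T-wave area is linear in amplitude scaling", {
  fid <- std_fid()
  b <- make_beat(beat_spec(noise_sd = 0), seed = 3)
  a1 <- t_wave_area(b, "V4", fid)
  for (k in c(0.5, 2, -3)) {
    bk <- median_beat(unclass(b)[, ] * k, attr(b, "fs"))
    expect_equal(t_wave_area(bk, "V4", fid), k * a1, tolerance = 1e-9)
  }
})

test_that("synthesized limb leads obey the Einthoven/Goldberger relations", {
  b <- make_beat(beat_spec(noise_sd = 10), seed = 9)
  expect_lt(max(abs(b[, "III"] - (b[, "II"] - b[, "I"]))), 1)
  expect_lt(max(abs(b[, "aVR"] + (b[, "I"] + b[, "II"]) / 2)), 1)
  expect_lt(max(abs(b[, "aVL"] - (b[, "I"] - b[, "II"] / 2))), 1)
  expect_lt(max(abs(b[, "aVF"] - (b[, "II"] - b[, "I"] / 2))), 1)
})
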