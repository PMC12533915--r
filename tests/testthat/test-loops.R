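test_that("loops are the samples of each half-open wave window", {
  sig <- vcg_synthesize(zero_beat(600L), "kors")
  fid <- fiducials(40L, 100L, 150L, 200L, 380L)
  loops <- segment_loops(sig, fid)
  expect_equal(nrow(loops$P$points), 60L)
  expect_equal(nrow(loops$QRS$points), 50L)
  expect_equal(nrow(loops$T$points), 180L)
  expect_lte(sum(vapply(loops, function(l) nrow(l$points), integer(1))),
             600L)
  expect_error(segment_loops(sig, fiducials(40L, 41L, 150L, 200L, 380L)))
})

test_that("fiducial detection recovers generator truth within 10 ms", {
  # noise-free beats: every boundary within 10 ms of the +/- 3 sigma truth
  for (seed in c(3, 14, 27)) {
    b <- make_beat(beat_spec(noise_sd = 0), seed = seed)
    truth <- attr(b, "fiducials")
    naked <- median_beat(unclass(b)[, ], attr(b, "fs"))
    det <- detect_fiducials(naked)
    for (f in c("p_on", "p_off", "qrs_on", "qrs_off", "t_off")) {
      err_ms <- abs(det[[f]] - truth[[f]]) / attr(b, "fs") * 1000
      expect_lt(err_ms, 10)
    }
  }
  # under measurement noise the boundaries degrade gracefully: the QRS stays
  # sharp and the low-amplitude P/T edges stay within the wave's own width
  b <- make_beat(beat_spec(noise_sd = 2), seed = 14)
  det <- detect_fiducials(median_beat(unclass(b)[, ], attr(b, "fs")))
  truth <- attr(b, "fiducials")
  expect_lt(abs(det$qrs_on - truth$qrs_on) / 500 * 1000, 10)
  expect_lt(abs(det$qrs_off - truth$qrs_off) / 500 * 1000, 10)
  expect_lt(max(abs(unlist(det) - unlist(truth))) / 500 * 1000, 80)
  # user-supplied fiducials always win
  b <- make_beat(beat_spec(noise_sd = 2), seed = 3)
  fid <- fiducials(1L, 5L, 10L, 20L, 30L)
  expect_identical(detect_fiducials(b, fid), fid)
  expect_identical(detect_fiducials(b), attr(b, "fiducials"))
  # all-zero beat has no QRS
  expect_error(detect_fiducials(zero_beat()), "no QRS")
})

test_that("decile features match closed forms", {
  # straight line at constant speed: Vel flat and exact
  v <- 7.5
  ll <- line_loop(M = 50L, v = v, dt = 2)
  d <- decile_features(ll)
  expect_equal(d$Vel, rep(v, 10), tolerance = 1e-9)
  # circle: Mag = r in every decile, OrbFrq = 1/T per decile
  r <- 400; Tms <- 250
  cl <- circle_loop(M = 100L, r = r, total_ms = Tms)
  dc <- decile_features(cl)
  expect_equal(dc$Mag, rep(r, 10), tolerance = 1e-9)
  expect_equal(dc$OrbFrq, rep(1 / Tms, 10), tolerance = 1e-9)
  # homogeneity: scaling the loop scales Mag and Vel, leaves OrbFrq alone
  k <- 3.2
  cl2 <- cl
  cl2$points <- cl$points * k
  dk <- decile_features(cl2)
  expect_equal(dk$Mag, k * dc$Mag, tolerance = 1e-9)
  expect_equal(dk$Vel, k * dc$Vel, tolerance = 1e-9)
  expect_equal(dk$OrbFrq, dc$OrbFrq, tolerance = 1e-9)
  expect_error(decile_features(line_loop(M = 9L)), "at least 10")
})

test_that("global features match the circle closed forms", {
  r <- 600
  cl <- circle_loop(M = 100L, r = r, total_ms = 200)
  g <- global_features(cl)
  expect_equal(g$GAV_raw, pi * r^2, tolerance = 0.005)
  expect_equal(g$GAV, pi, tolerance = 0.005)
  expect_equal(g$RangeAng, 360, tolerance = 2 / 360)
  # velocities: constant speed 2*pi*r/T
  expect_equal(g$VelMax, g$VelMin, tolerance = 1e-6)
  expect_equal(g$VelMin, 2 * pi * r / 200, tolerance = 1e-3)
})

test_that("degenerate loops yield zeros without error", {
  p <- matrix(rep(c(120, -40, 80), each = 7), 7,
              dimnames = list(NULL, c("X", "Y", "Z")))
  lp <- structure(list(points = p, dt = 2, wave = "QRS", method = "kors"),
                  class = "loop")
  g <- global_features(lp)
  expect_equal(g$GAV, 0)
  expect_equal(g$RangeAng, 0)
  expect_equal(g$VelMin, 0)
  expect_equal(g$VelMax, 0)
  expect_equal(g$TermMag, sqrt(sum(c(120, -40, 80)^2)) / 1000)
})

test_that("loop features are invariant under rigid rotation", {
  set.seed(21)
  b <- make_beat(beat_spec(noise_sd = 3))
  sig <- vcg_synthesize(b, "kors")
  loops <- segment_loops(sig, attr(b, "fiducials"))
  for (wave in names(loops)) {
    lp <- loops[[wave]]
    g0 <- global_features(lp)
    d0 <- decile_features(lp)
    Q <- random_rotation()
    lpr <- lp
    lpr$points <- lp$points %*% t(Q)
    gr <- global_features(lpr)
    dr <- decile_features(lpr)
    expect_equal(gr$GAV_raw, g0$GAV_raw, tolerance = 1e-6)
    expect_equal(gr$GAV, g0$GAV, tolerance = 1e-6)
    expect_equal(gr$VelMin, g0$VelMin, tolerance = 1e-6)
    expect_equal(gr$VelMax, g0$VelMax, tolerance = 1e-6)
    expect_equal(gr$TermMag, g0$TermMag, tolerance = 1e-6)
    expect_equal(dr$Mag, d0$Mag, tolerance = 1e-6)
    expect_equal(dr$Vel, d0$Vel, tolerance = 1e-6)
    expect_equal(dr$OrbFrq, d0$OrbFrq, tolerance = 1e-6)
  }
})

test_that("orbital frequency is flat for constant angular velocity and
           velocity bounds are ordered", {
  cl <- circle_loop(M = 120L, r = 300, total_ms = 360)
  d <- decile_features(cl)
  expect_lt(diff(range(d$OrbFrq)), 1e-9)
  set.seed(4)
  b <- make_beat(beat_spec(noise_sd = 5))
  loops <- segment_loops(vcg_synthesize(b, "kors"), attr(b, "fiducials"))
  for (wave in names(loops)) {
    g <- global_features(loops[[wave]])
    expect_gte(g$VelMin, 0)
    expect_lte(g$VelMin, g$VelMax)
    sm <- fourier_smooth(loops[[wave]], 6L)
    gs <- global_features(sm)
    expect_gte(gs$VelMin, 0)
    expect_lte(gs$VelMin, gs$VelMax)
  }
})

test_that("features are invariant to a uniform time shift of the window", {
  b <- make_beat(beat_spec(noise_sd = 0), seed = 33)
  fid <- attr(b, "fiducials")
  sig <- vcg_synthesize(b, "plsv")
  l1 <- segment_loops(sig, fid)$QRS
  # shift the whole beat by 25 samples and the window with it
  m <- unclass(b)[, ]
  shifted <- rbind(matrix(0, 25L, 12L, dimnames = list(NULL, LEADS12)),
                   m[seq_len(nrow(m) - 25L), ])
  b2 <- median_beat(shifted, attr(b, "fs"))
  fid2 <- fiducials(fid$p_on + 25L, fid$p_off + 25L, fid$qrs_on + 25L,
                    fid$qrs_off + 25L, fid$t_off + 25L)
  l2 <- segment_loops(vcg_synthesize(b2, "plsv"), fid2)$QRS
  expect_equal(global_features(l2), global_features(l1), tolerance = 1e-9)
  expect_equal(decile_features(l2), decile_features(l1), tolerance = 1e-9)
})
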