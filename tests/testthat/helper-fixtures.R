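# Fixture builders used across the test files. Everything is generated in
# code; no binary fixtures.

# a flat beat of zeros with workable fiducials
zero_beat <- function(n = 600L, fs = 500) {
  m <- matrix(0, n, 12L, dimnames = list(NULL, LEADS12))
  median_beat(m, fs = fs)
}

std_fid <- function() fiducials(40L, 100L, 150L, 200L, 380L)

# beat with one rectangular plateau per chosen lead inside a window
plateau_beat <- function(lead, value_uv, from, to, n = 600L, fs = 500) {
  m <- matrix(0, n, 12L, dimnames = list(NULL, LEADS12))
  m[fid_rows_t(from, to + 1L), lead] <- value_uv
  median_beat(m, fs = fs)
}

# 0-based half-open -> R rows (test-local copy of the package convention)
fid_rows_t <- function(on, off) seq.int(on + 1L, off)

# planar circle loop: M points, radius r (uV), one full revolution over
# total_ms, in the plane spanned by u1/u2 (defaults: XY plane)
circle_loop <- function(M = 100L, r = 500, total_ms = 200,
                        center = c(0, 0, 0),
                        u1 = c(1, 0, 0), u2 = c(0, 1, 0), wave = "QRS") {
  th <- 2 * pi * (seq_len(M) - 1L) / M
  pts <- outer(cos(th) * r, u1) + outer(sin(th) * r, u2)
  pts <- sweep(pts, 2, center, `+`)
  colnames(pts) <- c("X", "Y", "Z")
  structure(list(points = pts, dt = total_ms / M, wave = wave,
                 method = "kors"),
            class = "loop")
}

# straight-line loop at constant speed v (uV/ms)
line_loop <- function(M = 50L, v = 10, dt = 2, dir = c(1, 2, -1)) {
  dir <- dir / sqrt(sum(dir^2))
  pts <- outer((seq_len(M) - 1L) * v * dt, dir)
  colnames(pts) <- c("X", "Y", "Z")
  structure(list(points = pts, dt = dt, wave = "QRS", method = "kors"),
            class = "loop")
}

# random 3-D rotation matrix (Gram-Schmidt on a seeded Gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# lead_measurements fixture from explicit R/S amplitudes (mV)
fake_measurements <- function(R = NULL, S = NULL, qrs_ms = 80,
                              strain = FALSE, ptf = 0, axis = 40,
                              idt = c(V5 = 30, V6 = 30)) {
  r <- stats::setNames(rep(0, 12), LEADS12)
  s <- r
  if (!is.null(R)) r[names(R)] <- R
  if (!is.null(S)) s[names(S)] <- S
  structure(list(R = r, S = s, qrs_ms = qrs_ms,
                 t_area = stats::setNames(rep(0, 12), LEADS12),
                 sd_lead = LEADS12[which.max(s)], sd_value = max(s),
                 axis_deg = axis, ptf_v1 = ptf,
                 intrinsicoid_ms = idt, strain = strain),
            class = "lead_measurements")
}

# beat spec whose every wavelet has zero amplitude
default_zero_spec <- function() {
  comp <- beat_spec()$components
  comp$amp <- 0
  beat_spec(noise_sd = 0, components = comp)
}

# brute-force best depth-1 accuracy over a threshold grid (XOR oracle)
best_stump_accuracy <- function(X, y) {
  best <- 0
  for (j in seq_len(ncol(X))) {
    cand <- sort(unique(X[, j]))
    thr <- (cand[-1] + cand[-length(cand)]) / 2
    for (t in thr) {
      left <- X[, j] <= t
      for (labs in list(c(0, 1), c(1, 0))) {
        pred <- ifelse(left, labs[1], labs[2])
        best <- max(best, mean(pred == y))
      }
    }
  }
  best
}
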