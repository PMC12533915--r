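#' Detect P/QRS/T wave windows from a median beat
#'
#' Delineation by spatial-velocity thresholding on the Kors vectorcardiogram:
#' the spatial velocity `||d(xyz)/dt||` is computed, lightly smoothed, and the
#' QRS is taken as the run of samples around the global velocity maximum that
#' stay above 10% of that maximum (runs separated by gaps shorter than 20 ms
#' are merged). The P and T bounds are found by the same rule applied to the
#' pre- and post-QRS windows with their own local maxima. User-supplied
#' fiducials (the `fiducials` attribute of the beat, or the `fid` argument)
#' always win and are returned unchanged.
#'
#' @param beat a [median_beat()].
#' @param fid optional [fiducials()]; returned as-is when present.
#' @return a [fiducials()] object (0-based, half-open windows).
#' @export
detect_fiducials <- function(beat, fid = NULL) {
  stopifnot(inherits(beat, "median_beat"))
  if (!is.null(fid)) return(fid)
  if (!is.null(attr(beat, "fiducials"))) return(attr(beat, "fiducials"))
  fs <- attr(beat, "fs")
  xyz <- unclass(vcg_synthesize(beat, "kors"))
  v <- sqrt(rowSums(diff(xyz)^2)) * fs / 1000  # uV/ms, length N-1
  v <- as.numeric(stats::filter(v, rep(1 / 5, 5), sides = 2))
  v[is.na(v)] <- 0
  if (max(v) <= 0) stop("no QRS detected (flat spatial velocity)")
  gap <- max(1L, round(0.020 * fs))
  # 10% of the local maximum, floored above the window's noise level
  # (the 20th percentile tracks the quiet baseline, not the wave itself)
  thr_of <- function(win)
    max(0.10 * max(win), 3 * stats::quantile(win, 0.2, names = FALSE))
  qrs <- run_above(v, thr_of(v), which.max(v), gap)
  if (is.null(qrs)) stop("no QRS detected")
  # velocity sample i spans signal samples [i, i+1]; windows in 0-based idx
  qrs_on <- qrs[1L] - 1L
  qrs_off <- qrs[2L] + 1L
  n <- nrow(beat)
  margin <- max(2L, round(0.010 * fs))
  # P: pre-QRS window
  p_hi <- qrs_on - margin
  p_win <- if (p_hi >= 2L) v[seq_len(p_hi)] else numeric(0)
  p <- if (length(p_win) && max(p_win) > 0)
    run_above(p_win, thr_of(p_win), which.max(p_win), gap) else NULL
  if (is.null(p)) p <- c(max(1L, qrs_on - 2L), max(2L, qrs_on - 1L))
  p_on <- p[1L] - 1L
  p_off <- min(p[2L] + 1L, qrs_on)
  # T: post-QRS window
  t_lo <- qrs_off + margin
  t_win <- if (t_lo < n - 2L) v[seq.int(t_lo, n - 1L)] else numeric(0)
  tt <- if (length(t_win) && max(t_win) > 0)
    run_above(t_win, thr_of(t_win), which.max(t_win), gap) else NULL
  t_off <- if (is.null(tt)) min(qrs_off + 2L, n) else
    min(t_lo - 1L + tt[2L] + 1L, n)
  fiducials(p_on = max(0L, p_on), p_off = p_off, qrs_on = qrs_on,
            qrs_off = qrs_off, t_off = max(t_off, qrs_off + 1L), n = n)
}

# indices (1-based, into x) of the above-threshold run containing `center`,
# merging runs separated by gaps shorter than `gap` samples
run_above <- function(x, thr, center, gap) {
  above <- x >= thr
  if (!above[center]) center <- which(above)[which.min(abs(which(above) - center))]
  if (!length(center) || is.na(center)) return(NULL)
  lo <- center
  miss <- 0L
  for (i in seq.int(center, 1L)) {
    if (above[i]) { lo <- i; miss <- 0L } else {
      miss <- miss + 1L
      if (miss > gap) break
    }
  }
  hi <- center
  miss <- 0L
  for (i in seq.int(center, length(x))) {
    if (above[i]) { hi <- i; miss <- 0L } else {
      miss <- miss + 1L
      if (miss > gap) break
    }
  }
  c(lo, hi)
}

#' Segment a VCG signal into P, QRS and T loops
#'
#' @param sig a `vcg_signal` from [vcg_synthesize()].
#' @param fid a [fiducials()] object.
#' @return named list of three `loop` objects (`P`, `QRS`, `T`), each holding
#'   `points` (M x 3, microvolts), `dt` (ms), `wave` and `method`.
#' @export
segment_loops <- function(sig, fid) {
  stopifnot(inherits(sig, "vcg_signal"), inherits(fid, "fiducials"))
  dt <- 1000 / attr(sig, "fs")
  mk <- function(on, off, wave) {
    if (off - on < 2L) stop(wave, " window has fewer than 2 samples")
    structure(list(points = unclass(sig)[fid_rows(on, off), , drop = FALSE],
                   dt = dt, wave = wave, method = attr(sig, "method")),
              class = "loop")
  }
  list(P = mk(fid$p_on, fid$p_off, "P"),
       QRS = mk(fid$qrs_on, fid$qrs_off, "QRS"),
       T = mk(fid$qrs_off, fid$t_off, "T"))
}

#' @export
print.loop <- function(x, ...) {
  cat(sprintf("%s loop (%s): %d points, dt = %g ms\n",
              x$wave, x$method %||% "?", nrow(x$points), x$dt))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

row_norms <- function(m) sqrt(rowSums(m^2))

# unsigned angle between consecutive 3-D vectors (rows), atan2 form
vec_angles <- function(a, b) {
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  cr <- sqrt(cx^2 + cy^2 + cz^2)
  dt <- rowSums(a * b)
  ang <- atan2(cr, dt)
  ang[row_norms(a) == 0 | row_norms(b) == 0] <- 0
  ang
}

decile_index <- function(M) {
  lo <- floor((0:9) * M / 10)   # 0-based starts
  hi <- floor((1:10) * M / 10)  # 0-based exclusive ends
  cbind(lo + 1L, hi)            # 1-based inclusive ranges
}

#' Per-decile loop features
#'
#' The loop is cut into ten consecutive temporal deciles by sample index
#' (decile d covers samples `[floor((d-1)M/10), floor(dM/10))`, 0-based).
#' For each decile: `Mag` is the mean spatial vector magnitude (uV); `Vel`
#' the mean inter-sample speed (uV/ms, forward differences, the loop being
#' treated as closed); `OrbFrq` the total unsigned angle (in revolutions)
#' swept about the loop centroid divided by the decile duration (1/ms).
#'
#' @param loop a `loop` with at least 10 points.
#' @return list with numeric(10) elements `Mag`, `Vel`, `OrbFrq`.
#' @export
decile_features <- function(loop) {
  p <- loop$points
  M <- nrow(p)
  if (M < 10L) stop("decile features need at least 10 points")
  dt <- loop$dt
  idx <- decile_index(M)
  nxt <- p[c(seq.int(2L, M), 1L), , drop = FALSE]  # closed successor
  step <- row_norms(nxt - p) / dt                  # uV/ms per sample
  cen <- colMeans(p)
  vc <- sweep(p, 2, cen)
  vn <- sweep(nxt, 2, cen)
  ang <- vec_angles(vc, vn)                        # radians per sample
  mag <- row_norms(p)
  out <- list(Mag = numeric(10L), Vel = numeric(10L), OrbFrq = numeric(10L))
  for (d in 1:10) {
    s <- seq.int(idx[d, 1L], idx[d, 2L])
    out$Mag[d] <- mean(mag[s])
    # speed: forward differences; the artificial closing step M -> 1 is
    # excluded so a constant-speed trajectory has flat Vel across deciles
    sv <- s[s < M]
    if (!length(sv)) sv <- M - 1L
    out$Vel[d] <- mean(step[sv])
    out$OrbFrq[d] <- sum(ang[s]) / (2 * pi) / (length(s) * dt)
  }
  out
}

#' Global loop features
#'
#' Computes, for one P/QRS/T loop:
#' \itemize{
#'   \item `GAV_raw`: magnitude of the polygon vector area
#'     `0.5 * sum(p_i x p_{i+1})` with the loop closed last-to-first (uV^2);
#'   \item `GAV`: `GAV_raw / max(||p||)^2`, dimensionless;
#'   \item `RangeAng`: range (degrees) of the unwrapped rotation angle of the
#'     points projected onto the loop's least-squares plane, including the
#'     closing step;
#'   \item `VelMin`, `VelMax`: min/max inter-sample speed (uV/ms);
#'   \item `TermMag`: magnitude of the mean spatial vector over the final
#'     40 ms of the loop, in mV.
#' }
#' A degenerate loop (all points identical) yields zeros (and its `TermMag`).
#'
#' @param loop a `loop` with at least 3 points.
#' @return named list `GAV`, `GAV_raw`, `RangeAng`, `VelMin`, `VelMax`,
#'   `TermMag`.
#' @export
global_features <- function(loop) {
  p <- loop$points
  M <- nrow(p)
  if (M < 3L) stop("global features need at least 3 points")
  dt <- loop$dt
  nxt <- p[c(seq.int(2L, M), 1L), , drop = FALSE]
  cross_sum <- c(sum(p[, 2] * nxt[, 3] - p[, 3] * nxt[, 2]),
                 sum(p[, 3] * nxt[, 1] - p[, 1] * nxt[, 3]),
                 sum(p[, 1] * nxt[, 2] - p[, 2] * nxt[, 1]))
  gav_raw <- 0.5 * sqrt(sum(cross_sum^2))
  maxmag <- max(row_norms(p))
  gav <- if (maxmag > 0) gav_raw / maxmag^2 else 0
  # rotation angle range in the least-squares plane
  cen <- sweep(p, 2, colMeans(p))
  rng <- 0
  if (max(abs(cen)) > 0) {
    sv <- svd(cen, nu = 0, nv = 2)
    if (length(sv$d) >= 2L && sv$d[2L] > 1e-9 * sv$d[1L]) {
      q <- cen %*% sv$v
      phi <- atan2(q[, 2L], q[, 1L])
      dphi <- diff(c(phi, phi[1L]))           # include closing step
      dphi <- (dphi + pi) %% (2 * pi) - pi    # wrap to (-pi, pi]
      unw <- cumsum(c(phi[1L], dphi))
      rng <- (max(unw) - min(unw)) * 180 / pi
    }
  }
  step <- row_norms(p[-1L, , drop = FALSE] - p[-M, , drop = FALSE]) / dt
  vmin <- if (length(step)) min(step) else 0
  vmax <- if (length(step)) max(step) else 0
  k <- min(M, max(1L, ceiling(40 / dt)))
  term <- colMeans(p[seq.int(M - k + 1L, M), , drop = FALSE])
  list(GAV = gav, GAV_raw = gav_raw, RangeAng = rng,
       VelMin = vmin, VelMax = vmax, TermMag = sqrt(sum(term^2)) / 1000)
}
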