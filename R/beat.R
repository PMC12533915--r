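#' @keywords internal
"_PACKAGE"

#' Standard 12-lead order
#'
#' Lead names in the conventional order: limb leads I, II, III, the augmented
#' leads aVR, aVL, aVF, and the precordial leads V1-V6.
#' @export
LEADS12 <- c("I", "II", "III", "aVR", "aVL", "aVF",
             "V1", "V2", "V3", "V4", "V5", "V6")

#' The eight linearly independent leads
#'
#' III, aVR, aVL and aVF are linear combinations of I and II, so every linear
#' vectorcardiographic transform acts on these eight leads only.
#' @export
LEADS8 <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

#' Construct a 12-lead median beat
#'
#' A median beat is one representative averaged cardiac cycle. Samples are
#' stored as an N x 12 numeric matrix in microvolts, one column per lead in
#' the order of [LEADS12].
#'
#' @param samples numeric matrix, N samples x 12 leads (colnames = lead names,
#'   any order; reordered internally) or 12 x N (transposed automatically when
#'   rownames are lead names). Amplitudes in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param fiducials optional [fiducials()] object carrying known wave windows.
#' @return an object of class `median_beat`: the sample matrix with attributes
#'   `fs` and (optionally) `fiducials`.
#' @export
median_beat <- function(samples, fs, fiducials = NULL) {
  samples <- as.matrix(samples)
  if (!is.null(rownames(samples)) && all(LEADS12 %in% rownames(samples)))
    samples <- t(samples)
  if (is.null(colnames(samples)))
    stop("sample matrix must carry lead names")
  missing_leads <- setdiff(LEADS12, colnames(samples))
  if (length(missing_leads))
    stop("missing lead(s): ", paste(missing_leads, collapse = ", "))
  samples <- samples[, LEADS12, drop = FALSE]
  if (nrow(samples) < 2L) stop("a median beat needs at least 2 samples")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  bad <- which(!is.finite(samples))
  if (length(bad))
    stop("non-finite sample at matrix index ", bad[1L])
  storage.mode(samples) <- "double"
  structure(samples, fs = fs, fiducials = fiducials, class = "median_beat")
}

#' @export
print.median_beat <- function(x, ...) {
  cat(sprintf("12-lead median beat: %d samples @ %g Hz (%.0f ms)\n",
              nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs") * 1000))
  rng <- range(x)
  cat(sprintf("  amplitude range: %.1f to %.1f uV\n", rng[1L], rng[2L]))
  if (!is.null(attr(x, "fiducials"))) {
    f <- attr(x, "fiducials")
    cat(sprintf("  fiducials: P [%d,%d) QRS [%d,%d) T off %d\n",
                f$p_on, f$p_off, f$qrs_on, f$qrs_off, f$t_off))
  }
  invisible(x)
}

#' Wave-window fiducial marks
#'
#' Sample indices delimiting the P, QRS and T waves. Indices are 0-based and
#' windows are half-open `[on, off)`: the P wave occupies samples
#' `[p_on, p_off)`, the QRS `[qrs_on, qrs_off)` and the T wave
#' `[qrs_off, t_off)`.
#'
#' @param p_on,p_off,qrs_on,qrs_off,t_off integer sample indices satisfying
#'   `0 <= p_on < p_off <= qrs_on < qrs_off < t_off`.
#' @param n optional signal length; when given, `t_off <= n` is enforced.
#' @return an object of class `fiducials` (a named list).
#' @export
fiducials <- function(p_on, p_off, qrs_on, qrs_off, t_off, n = NULL) {
  v <- c(p_on = p_on, p_off = p_off, qrs_on = qrs_on,
         qrs_off = qrs_off, t_off = t_off)
  if (any(!is.finite(v)) || any(v != round(v)))
    stop("fiducials must be finite integers")
  v <- stats::setNames(as.integer(round(v)), names(v))
  ok <- v["p_on"] >= 0L && v["p_on"] < v["p_off"] &&
    v["p_off"] <= v["qrs_on"] && v["qrs_on"] < v["qrs_off"] &&
    v["qrs_off"] < v["t_off"]
  if (!ok)
    stop("fiducials must satisfy 0 <= p_on < p_off <= qrs_on < qrs_off < t_off")
  if (!is.null(n) && v["t_off"] > n)
    stop("t_off exceeds signal length")
  structure(as.list(v), class = "fiducials")
}

# 0-based half-open window [on, off) -> 1-based R row indices
fid_rows <- function(on, off) seq.int(on + 1L, off)

#' Read a 12-lead median beat from CSV
#'
#' The CSV dialect is: an initial metadata comment line
#' `# fs=<Hz> units=<uV|mV>`, then a header row of lead names, then one row
#' per sample with one column per lead. Amplitudes are converted to
#' microvolts on read (mV inputs are multiplied by 1000).
#'
#' @param path file path.
#' @param format_hint `"csv"` (the native dialect described above). Reserved
#'   for alternative waveform-record readers behind the same interface.
#' @return a [median_beat()].
#' @export
read_median_beat <- function(path, format_hint = "csv") {
  format_hint <- match.arg(format_hint, "csv")
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#"))
    stop("missing metadata line (expected '# fs=<Hz> units=<uV|mV>')")
  meta <- parse_meta_line(first)
  if (is.na(meta$fs)) stop("metadata line does not declare fs")
  if (is.na(meta$units)) stop("metadata line does not declare units")
  scale <- switch(meta$units, uV = 1, mV = 1000,
                  stop("unknown units: ", meta$units))
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  median_beat(as.matrix(df) * scale, fs = meta$fs)
}

parse_meta_line <- function(line) {
  toks <- strsplit(sub("^#\\s*", "", line), "[[:space:],;]+")[[1L]]
  kv <- strsplit(toks[nzchar(toks)], "=")
  out <- list(fs = NA_real_, units = NA_character_)
  for (p in kv) {
    if (length(p) != 2L) next
    if (p[1L] == "fs") out$fs <- as.numeric(p[2L])
    if (p[1L] == "units") out$units <- p[2L]
  }
  out
}

#' Write a median beat to the package CSV dialect
#'
#' @param beat a [median_beat()].
#' @param path destination file.
#' @param units `"uV"` (native) or `"mV"`.
#' @return `path`, invisibly.
#' @export
write_median_beat <- function(beat, path, units = c("uV", "mV")) {
  units <- match.arg(units)
  stopifnot(inherits(beat, "median_beat"))
  scale <- if (units == "mV") 1e-3 else 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%s units=%s",
                     format(attr(beat, "fs"), digits = 17), units), con)
  m <- unclass(beat) * scale
  # full double precision so a round trip is bitwise lossless
  chr <- as.data.frame(apply(m, 2, function(x) sprintf("%.17g", x)))
  utils::write.table(chr, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Per-lead baseline: mean over the 20 ms preceding p_on, clamped to the start.
beat_baseline <- function(beat, fid) {
  fs <- attr(beat, "fs")
  w <- max(1L, round(0.020 * fs))
  lo <- max(0L, fid$p_on - w)
  if (lo >= fid$p_on) lo <- max(0L, fid$p_on - 1L)
  colMeans(beat[fid_rows(lo, max(fid$p_on, lo + 1L)), , drop = FALSE])
}

#' Scalar lead measurements feeding the classical criteria
#'
#' Measures, per lead, the R (positive) and S (negative) QRS deflection
#' magnitudes relative to an isoelectric baseline, the QRS duration, the
#' signed T-wave area, and the ancillary quantities needed by the point-score
#' criteria (frontal-plane QRS axis, P terminal force in V1, intrinsicoid
#' deflection time in V5/V6, and lateral-lead strain pattern).
#'
#' The baseline is the mean amplitude over the 20 ms preceding the P onset
#' (clamped to the start of the record), subtracted per lead, so all
#' amplitudes are translation invariant.
#'
#' @param beat a [median_beat()], samples in microvolts.
#' @param fid a [fiducials()] object.
#' @return an object of class `lead_measurements`: a list with elements
#'   `R`, `S` (named numeric, mV, non-negative), `qrs_ms`, `t_area` (named
#'   numeric, Ashman units), `sd_lead`, `sd_value` (deepest S across leads,
#'   mV), `axis_deg`, `ptf_v1` (mV.s), `intrinsicoid_ms`, `strain` (logical).
#' @export
measure_amplitudes <- function(beat, fid) {
  stopifnot(inherits(beat, "median_beat"), inherits(fid, "fiducials"))
  n <- nrow(beat)
  if (fid$t_off > n) stop("fiducials exceed signal length")
  if (fid$qrs_off - fid$qrs_on < 2L) stop("QRS window shorter than 2 samples")
  fs <- attr(beat, "fs")
  base <- beat_baseline(beat, fid)
  qrs <- sweep(beat[fid_rows(fid$qrs_on, fid$qrs_off), , drop = FALSE], 2, base)
  R <- pmax(apply(qrs, 2, max), 0) / 1000
  S <- pmax(-apply(qrs, 2, min), 0) / 1000
  qrs_ms <- (fid$qrs_off - fid$qrs_on) / fs * 1000
  t_area <- vapply(LEADS12, function(ld) t_wave_area(beat, ld, fid),
                   numeric(1L))
  sd_lead <- LEADS12[which.max(S)]
  # frontal axis from net QRS deflection in I and aVF
  net <- R - S
  axis <- atan2(net[["aVF"]], net[["I"]]) * 180 / pi
  # P terminal force in V1: area of the negative part of the terminal half
  # of the P window (magnitude, mV.s)
  pw <- fid_rows(fid$p_on, fid$p_off)
  half <- pw[seq.int(ceiling(length(pw) / 2), length(pw))]
  v1 <- beat[half, "V1"] - base[["V1"]]
  ptf <- sum(pmin(v1, 0)) * (1 / fs) / 1000  # uV*s -> mV*s, negative
  # intrinsicoid deflection: onset to R peak in V5/V6
  idt <- vapply(c("V5", "V6"), function(ld) {
    x <- beat[fid_rows(fid$qrs_on, fid$qrs_off), ld] - base[[ld]]
    (which.max(x) - 1L) / fs * 1000
  }, numeric(1L))
  # strain: T polarity opposite the dominant QRS deflection in V5/V6
  tw <- fid_rows(fid$qrs_off, fid$t_off)
  strain <- vapply(c("V5", "V6"), function(ld) {
    dom <- if (R[[ld]] >= S[[ld]]) 1 else -1
    tm <- beat[tw, ld] - base[[ld]]
    tpk <- tm[which.max(abs(tm))]
    abs(tpk) > 50 && sign(tpk) == -dom  # needs a discernible (>50 uV) T
  }, logical(1L))
  structure(list(R = R, S = S, qrs_ms = qrs_ms, t_area = t_area,
                 sd_lead = sd_lead, sd_value = max(S),
                 axis_deg = axis, ptf_v1 = abs(ptf),
                 intrinsicoid_ms = idt, strain = any(strain)),
            class = "lead_measurements")
}

#' @export
print.lead_measurements <- function(x, ...) {
  cat("Lead measurements (mV):\n")
  print(round(rbind(R = x$R, S = x$S), 3))
  cat(sprintf("QRS duration %.1f ms; deepest S %.2f mV in %s; axis %.0f deg\n",
              x$qrs_ms, x$sd_value, x$sd_lead, x$axis_deg))
  invisible(x)
}

#' T-wave area in Ashman units
#'
#' Signed trapezoidal integral of the baseline-corrected signal over the
#' T window `[qrs_off, t_off)`, expressed in Ashman units
#' (1 AU = 40 ms x 0.1 mV = 4 ms.mV). The trapezoid is taken over the closed
#' sample range so that a plateau of 0.1 mV lasting exactly 40 ms integrates
#' to exactly 1 AU.
#'
#' @param beat a [median_beat()] (microvolts).
#' @param lead lead name.
#' @param fid a [fiducials()] object.
#' @return signed area in Ashman units.
#' @export
t_wave_area <- function(beat, lead, fid) {
  stopifnot(inherits(beat, "median_beat"))
  lead <- match.arg(lead, LEADS12)
  if (fid$t_off - fid$qrs_off < 1L) stop("empty T window")
  fs <- attr(beat, "fs")
  base <- beat_baseline(beat, fid)[[lead]]
  hi <- min(fid$t_off, nrow(beat) - 1L)
  y <- (beat[fid_rows(fid$qrs_off, hi + 1L), lead] - base) / 1000  # mV
  if (length(y) < 2L) stop("empty T window")
  dt <- 1000 / fs  # ms
  area <- sum((y[-1L] + y[-length(y)]) / 2) * dt  # ms.mV
  area / 4
}
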