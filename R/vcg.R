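#' Vectorcardiographic transform methods
#' @export
VCG_METHODS <- c("inverse_dower", "kors", "qlsv", "plsv")

# method tags used in feature names (D/K/Q/P)
method_tag <- function(method) {
  switch(method,
         inverse_dower = "D", kors = "K", qlsv = "Q", plsv = "P",
         stop("unknown VCG method: ", method))
}

matrix_file <- function(method) {
  fn <- switch(method,
               inverse_dower = "inverse_dower.txt",
               kors = "kors.txt",
               qlsv = "qlsv_synthetic.txt",
               plsv = "plsv_synthetic.txt",
               stop("unknown VCG method: ", method))
  system.file("extdata", "matrices", fn, package = "vcglvh", mustWork = TRUE)
}

#' Load a VCG transform coefficient matrix
#'
#' The coefficient files are whitespace-delimited 3 x 8 numeric grids
#' (rows X, Y, Z; columns I, II, V1-V6) with `#` comment headers, bundled
#' under `inst/extdata/matrices/`. The inverse Dower and Kors matrices are
#' transcriptions of their published sources; the QLSV/PLSV files are
#' synthetic stand-ins (see the file comments) and can be edited in place.
#'
#' @param method one of [VCG_METHODS], or `path` to read any other file.
#' @param path optional explicit coefficient file overriding the bundled one.
#' @return 3 x 8 numeric matrix, rows `X,Y,Z`, columns [LEADS8].
#' @export
vcg_matrix <- function(method = VCG_METHODS, path = NULL) {
  if (is.null(path)) {
    method <- match.arg(method)
    path <- matrix_file(method)
  }
  vals <- scan(path, comment.char = "#", quiet = TRUE)
  if (length(vals) != 24L || any(!is.finite(vals)))
    stop("coefficient file must hold a finite 3 x 8 grid: ", path)
  m <- matrix(vals, nrow = 3L, byrow = TRUE,
              dimnames = list(c("X", "Y", "Z"), LEADS8))
  m
}

#' Synthesize orthogonal X/Y/Z leads from a 12-lead beat
#'
#' Applies a 3 x 8 linear transform to the eight independent leads
#' (I, II, V1-V6): `xyz(t) = M %*% leads8(t)`. The redundant limb leads
#' (III, aVR, aVL, aVF) never enter the transform.
#'
#' @param beat a [median_beat()] (microvolts).
#' @param method one of [VCG_METHODS].
#' @param coefficients optional 3 x 8 matrix overriding the bundled one.
#' @return an object of class `vcg_signal`: N x 3 matrix (columns X, Y, Z,
#'   microvolts) with attributes `fs` and `method`.
#' @export
vcg_synthesize <- function(beat, method = "kors", coefficients = NULL) {
  stopifnot(inherits(beat, "median_beat"))
  method <- match.arg(method, VCG_METHODS)
  M <- if (is.null(coefficients)) vcg_matrix(method) else coefficients
  if (!is.matrix(M) || !all(dim(M) == c(3L, 8L)))
    stop("coefficient matrix must be 3 x 8")
  xyz <- beat[, LEADS8, drop = FALSE] %*% t(M)
  colnames(xyz) <- c("X", "Y", "Z")
  structure(xyz, fs = attr(beat, "fs"), method = method,
            class = "vcg_signal")
}

#' @export
print.vcg_signal <- function(x, ...) {
  cat(sprintf("VCG signal (%s): %d samples @ %g Hz\n",
              attr(x, "method"), nrow(x), attr(x, "fs")))
  invisible(x)
}

#' Truncated-Fourier smoothing of a periodic signal segment
#'
#' Replaces each channel by its truncated Fourier series over the segment:
#' the DC term plus the first `harmonics` harmonics of the segment-length
#' fundamental. Length and sampling rate are unchanged. Idempotent at a
#' fixed harmonic count, and variance-non-increasing (Parseval).
#'
#' @param sig a `vcg_signal`, a `loop`, or a plain numeric matrix
#'   (samples x channels).
#' @param harmonics number of harmonics retained (>= 1, < N/2).
#' @return object of the same class with smoothed samples.
#' @export
fourier_smooth <- function(sig, harmonics = 8L) {
  harmonics <- as.integer(harmonics)
  if (harmonics < 1L) stop("harmonics must be >= 1")
  m <- if (inherits(sig, "loop")) sig$points else unclass(sig)
  m <- as.matrix(m)
  n <- nrow(m)
  if (harmonics >= n / 2) stop("harmonics must be < N/2 (nothing to truncate)")
  sm <- apply(m, 2, function(x) {
    f <- stats::fft(x)
    keep <- c(seq_len(harmonics + 1L), seq.int(n - harmonics + 1L, n))
    f[-keep] <- 0
    Re(stats::fft(f, inverse = TRUE)) / n
  })
  if (inherits(sig, "loop")) {
    out <- sig
    out$points <- sm
    return(out)
  }
  attrs <- attributes(sig)
  attributes(sm) <- c(attributes(sm)["dim"],
                      list(dimnames = attrs$dimnames, fs = attrs$fs,
                           method = attrs$method, class = attrs$class))
  sm
}
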