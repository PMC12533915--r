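.matrix_cache <- new.env(parent = emptyenv())

cached_matrix <- function(method) {
  if (is.null(.matrix_cache[[method]]))
    .matrix_cache[[method]] <- vcg_matrix(method)
  .matrix_cache[[method]]
}

# published reference aliases for pinned predictors (alias = systematic name)
TABLE_ALIASES <- c(
  GAV_K = "QRSGAVK",
  RangeAngR = "QRSRangeAngD",
  Vel_Min_Kf_T = "TVelMinKf",
  Ang_Term_Num = "QRSTermMagK")

#' Extract vectorcardiographic loop features from one beat
#'
#' For every transform method and its Fourier-smoothed variant, the beat is
#' transformed to X/Y/Z, segmented into P/QRS/T loops, and each loop reduced
#' to per-decile magnitude/velocity/orbital-frequency features plus the
#' global features of [global_features()]. Feature names follow
#' `<wave><Metric><MethodTag><f?><decile?>` with method tags D (inverse
#' Dower), K (Kors), Q (QLSV), P (PLSV) and suffix `f` for Fourier-smoothed
#' variants (e.g. `PMagP2`, `POrbFrqD5`, `QRSMagPf9`, `TVelQ5`); the
#' published alias names `GAV_K`, `RangeAngR`, `Vel_Min_Kf_T` and
#' `Ang_Term_Num` are emitted as additional columns.
#'
#' @param beat a [median_beat()].
#' @param fid optional [fiducials()]; detected when absent.
#' @param methods subset of [VCG_METHODS].
#' @param harmonics harmonics kept by the smoothed variants (per wave
#'   window, clamped to the window length).
#' @return named numeric vector.
#' @export
extract_vcg_features <- function(beat, fid = NULL, methods = VCG_METHODS,
                                 harmonics = 8L) {
  fid <- detect_fiducials(beat, fid)
  out <- list()
  for (method in methods) {
    sig <- vcg_synthesize(beat, method, coefficients = cached_matrix(method))
    loops <- segment_loops(sig, fid)
    tag0 <- method_tag(method)
    for (smoothed in c(FALSE, TRUE)) {
      tag <- if (smoothed) paste0(tag0, "f") else tag0
      for (wave in names(loops)) {
        lp <- loops[[wave]]
        if (smoothed) {
          h <- min(harmonics, max(1L, (nrow(lp$points) - 1L) %/% 2L))
          lp <- fourier_smooth(lp, h)
        }
        out[[length(out) + 1L]] <- loop_feature_vector(lp, wave, tag)
      }
    }
  }
  v <- unlist(out)
  alias <- TABLE_ALIASES[TABLE_ALIASES %in% names(v)]
  c(v, stats::setNames(v[alias], names(alias)))
}

loop_feature_vector <- function(lp, wave, tag) {
  M <- nrow(lp$points)
  g <- global_features(lp)
  gv <- c(g$GAV, g$GAV_raw, g$RangeAng, g$VelMin, g$VelMax, g$TermMag)
  names(gv) <- paste0(wave, c("GAV", "GAVraw", "RangeAng",
                              "VelMin", "VelMax", "TermMag"), tag)
  if (M >= 10L) {
    d <- decile_features(lp)
    dv <- c(d$Mag, d$Vel, d$OrbFrq)
    names(dv) <- c(paste0(wave, "Mag", tag, 1:10),
                   paste0(wave, "Vel", tag, 1:10),
                   paste0(wave, "OrbFrq", tag, 1:10))
  } else {
    dv <- stats::setNames(rep(NA_real_, 30L),
                          c(paste0(wave, "Mag", tag, 1:10),
                            paste0(wave, "Vel", tag, 1:10),
                            paste0(wave, "OrbFrq", tag, 1:10)))
  }
  c(gv, dv)
}

#' Extract electrocardiographic scalar features from one beat
#'
#' Continuous values of every registry criterion (plus voltage-duration
#' products), per-lead R/S amplitudes and T-wave areas, QRS duration and
#' frontal axis. The published alias names `ECG21` (Cornell voltage) and
#' `T_AREA_DI` (T area in lead I) are included.
#'
#' @param beat a [median_beat()].
#' @param sex `"male"` or `"female"`.
#' @param fid optional [fiducials()].
#' @param registry criteria registry data.frame.
#' @return named numeric vector.
#' @export
extract_ecg_features <- function(beat, sex, fid = NULL,
                                 registry = criteria_registry()) {
  fid <- detect_fiducials(beat, fid)
  m <- measure_amplitudes(beat, fid)
  cr <- evaluate_criteria(m, sex, registry = registry)
  vals <- stats::setNames(cr$value, cr$name)
  lead_alias <- c(I = "DI", II = "DII", III = "DIII",
                  aVR = "aVR", aVL = "aVL", aVF = "aVF",
                  V1 = "V1", V2 = "V2", V3 = "V3",
                  V4 = "V4", V5 = "V5", V6 = "V6")
  tar <- stats::setNames(m$t_area, paste0("T_AREA_", lead_alias[LEADS12]))
  amps <- c(stats::setNames(m$R, paste0("R_", LEADS12)),
            stats::setNames(m$S, paste0("S_", LEADS12)))
  c(vals,
    ECG21 = unname(vals["cornell_voltage"]),
    tar, amps,
    QRSd = m$qrs_ms, axis_deg = m$axis_deg, ptf_v1 = m$ptf_v1,
    RE_score = romhilt_estes(m))
}

#' Build the patients-by-features table for a synthetic cohort
#'
#' Runs the full signal pipeline (fiducials, VCG synthesis for every method
#' and Fourier variant, loop features, lead measurements, criteria) on each
#' beat of a [make_cohort()] result and assembles a [feature_table()] with
#' `VCG`/`ECG` group tags; covariates and labels are carried through as
#' metadata columns.
#'
#' @param cohort a [make_cohort()] result.
#' @param methods subset of [VCG_METHODS].
#' @param harmonics Fourier harmonics for the smoothed variants.
#' @return a [feature_table()].
#' @export
cohort_features <- function(cohort, methods = VCG_METHODS, harmonics = 8L) {
  beats <- cohort$beats
  meta <- cohort$data
  registry <- criteria_registry()
  n <- length(beats)
  rows <- vector("list", n)
  vcg_n <- NA_integer_
  for (i in seq_len(n)) {
    fid <- detect_fiducials(beats[[i]])
    v <- extract_vcg_features(beats[[i]], fid, methods, harmonics)
    if (i == 1L) vcg_n <- length(v)
    rows[[i]] <- c(v, extract_ecg_features(beats[[i]], meta$sex[i], fid,
                                           registry))
  }
  feats <- do.call(rbind, rows)
  groups <- stats::setNames(
    c(rep("VCG", vcg_n), rep("ECG", ncol(feats) - vcg_n)),
    colnames(feats))
  feature_table(cbind(meta, as.data.frame(feats)), groups = groups)
}
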