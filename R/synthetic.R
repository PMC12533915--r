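# Default Gaussian wave components for the eight independent leads.
# Amplitudes in microvolts, times in ms; tuned to give physiologic polarity
# and an R-wave progression from V1 to V6.
default_components <- function() {
  lead_amp <- function(...) c(...)
  comp <- function(wave, center, sigma, amps)
    data.frame(wave = wave, center = center, sigma = sigma,
               lead = LEADS8, amp = amps, stringsAsFactors = FALSE)
  rbind(
    comp("P", 200, 18,
         lead_amp(60, 120, 40, 50, 50, 60, 60, 50)),
    comp("QRS", 385, 6,    # Q
         lead_amp(-60, -50, 0, 0, -30, -60, -90, -70)),
    comp("QRS", 402, 11,   # R
         lead_amp(600, 900, 150, 350, 700, 1200, 1500, 1100)),
    comp("QRS", 420, 8,    # S
         lead_amp(-150, -200, -900, -1100, -700, -400, -250, -150)),
    comp("T", 650, 38,
         lead_amp(200, 300, 100, 400, 450, 400, 350, 250)))
}

#' Specification of a synthetic 12-lead median beat
#'
#' A beat is a sum of Gaussian wavelets per lead plus white noise. Each row
#' of `components` gives one wavelet: `wave` (P/QRS/T), `center` and `sigma`
#' (ms), `lead` (one of [LEADS8]) and `amp` (microvolts). Only the eight
#' independent leads are specified; III, aVR, aVL and aVF are derived by the
#' Einthoven/Goldberger relations after noise is added, so the limb-lead
#' redundancy holds exactly. Ground-truth wave windows are the union of
#' `center +/- 3 sigma` over each wave's components and must not overlap.
#'
#' @param fs sampling rate (Hz).
#' @param duration_ms beat length (ms).
#' @param noise_sd white-noise standard deviation (microvolts).
#' @param components wavelet table; defaults to a physiologic template.
#' @return an object of class `beat_spec`.
#' @export
beat_spec <- function(fs = 500, duration_ms = 1000, noise_sd = 5,
                      components = default_components()) {
  stopifnot(fs > 0, duration_ms > 0, noise_sd >= 0)
  if (any(components$sigma <= 0)) stop("component widths must be positive")
  if (!all(components$lead %in% LEADS8)) stop("unknown lead in components")
  if (!all(components$wave %in% c("P", "QRS", "T")))
    stop("wave must be P, QRS or T")
  ctr <- tapply(components$center, components$wave, mean)
  if (!(ctr[["P"]] < ctr[["QRS"]] && ctr[["QRS"]] < ctr[["T"]]))
    stop("waves must be ordered P < QRS < T in center time")
  structure(list(fs = fs, duration_ms = duration_ms, noise_sd = noise_sd,
                 components = components), class = "beat_spec")
}

spec_windows <- function(spec) {
  out <- lapply(c("P", "QRS", "T"), function(w) {
    cc <- spec$components[spec$components$wave == w, ]
    c(min(cc$center - 3 * cc$sigma), max(cc$center + 3 * cc$sigma))
  })
  names(out) <- c("P", "QRS", "T")
  out
}

#' Generate a synthetic median beat with known ground truth
#'
#' @param spec a [beat_spec()].
#' @param seed optional integer; when given, generation is deterministic.
#' @return a [median_beat()] whose `fiducials` attribute holds the
#'   ground-truth wave windows (0-based, half-open, +/- 3 sigma bounds).
#' @export
make_beat <- function(spec = beat_spec(), seed = NULL) {
  stopifnot(inherits(spec, "beat_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- round(spec$duration_ms * spec$fs / 1000)
  t_ms <- (seq_len(n) - 1L) / spec$fs * 1000
  m8 <- matrix(0, n, 8L, dimnames = list(NULL, LEADS8))
  for (i in seq_len(nrow(spec$components))) {
    cc <- spec$components[i, ]
    m8[, cc$lead] <- m8[, cc$lead] +
      cc$amp * exp(-(t_ms - cc$center)^2 / (2 * cc$sigma^2))
  }
  if (spec$noise_sd > 0)
    m8 <- m8 + matrix(stats::rnorm(n * 8L, sd = spec$noise_sd), n, 8L)
  m <- cbind(m8[, "I"], m8[, "II"],
             III = m8[, "II"] - m8[, "I"],
             aVR = -(m8[, "I"] + m8[, "II"]) / 2,
             aVL = m8[, "I"] - m8[, "II"] / 2,
             aVF = m8[, "II"] - m8[, "I"] / 2,
             m8[, c("V1", "V2", "V3", "V4", "V5", "V6")])
  colnames(m) <- LEADS12
  w <- spec_windows(spec)
  to_idx <- function(ms) max(0L, min(n, as.integer(round(ms * spec$fs / 1000))))
  fid <- tryCatch(
    fiducials(p_on = to_idx(w$P[1L]), p_off = to_idx(w$P[2L]),
              qrs_on = to_idx(w$QRS[1L]), qrs_off = to_idx(w$QRS[2L]),
              t_off = to_idx(w$T[2L]), n = n),
    error = function(e) stop("ground-truth wave windows overlap: ",
                             conditionMessage(e)))
  median_beat(m, fs = spec$fs, fiducials = fid)
}

#' Specification of a synthetic Echo-LVH cohort
#'
#' Emulates the statistical structure the analysis assumes: a cohort with a
#' stated Echo-LVH prevalence in which hypertrophied patients show amplified
#' QRS voltages (a lognormal multiplicative gain on all QRS wavelets),
#' optional lateral-lead T-wave inversion (a repolarization "strain"
#' pattern) and a shrunken T area; every patient additionally receives an
#' independent lognormal beat-scale jitter so the classes overlap. Covariates
#' (sex, age, BMI, hypertension, ischemic heart disease, LV geometry,
#' severity) are drawn from stated marginal rates, independent of the beat
#' given the label.
#'
#' @param n cohort size.
#' @param prevalence Echo-LVH prevalence in (0, 1); default 0.428.
#' @param qrs_mult_meanlog,qrs_mult_sdlog lognormal parameters of the LVH QRS
#'   gain (default mean multiplier 1.5, sdlog 0.35).
#' @param strain_p probability of lateral T inversion in LVH (default 0.35).
#' @param t_shrink multiplicative T-amplitude factor in LVH (default 0.7).
#' @param jitter_sdlog per-patient lognormal beat-scale jitter (default
#'   0.35, matching the large inter-individual variability of ECG voltages).
#' @param sigma_jitter_sdlog per-patient lognormal jitter on wave widths
#'   (default 0.05), so QRS duration varies across the cohort.
#' @param lvh_qrs_widen multiplicative QRS-width factor in LVH (default 1.1,
#'   the modest QRS prolongation of hypertrophy).
#' @param beat base [beat_spec()] shared by the cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 664, prevalence = 0.428,
                        qrs_mult_meanlog = log(1.5), qrs_mult_sdlog = 0.35,
                        strain_p = 0.35, t_shrink = 0.7,
                        jitter_sdlog = 0.35, sigma_jitter_sdlog = 0.05,
                        lvh_qrs_widen = 1.1, beat = beat_spec()) {
  stopifnot(n >= 2, prevalence > 0, prevalence < 1,
            strain_p >= 0, strain_p <= 1, t_shrink > 0, lvh_qrs_widen > 0)
  structure(list(n = n, prevalence = prevalence,
                 qrs_mult_meanlog = qrs_mult_meanlog,
                 qrs_mult_sdlog = qrs_mult_sdlog,
                 strain_p = strain_p, t_shrink = t_shrink,
                 jitter_sdlog = jitter_sdlog,
                 sigma_jitter_sdlog = sigma_jitter_sdlog,
                 lvh_qrs_widen = lvh_qrs_widen, beat = beat),
            class = "cohort_spec")
}

# covariate marginals (population rates used for simulation)
draw_covariates <- function(n, lvh) {
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.429, 0.571))
  age <- pmax(18, stats::rnorm(n, 64.2, 15.1))
  bmi <- pmax(15, stats::rnorm(n, 28, 5.2))
  hypertension <- stats::rbinom(n, 1L, 0.578) == 1L
  ihd <- stats::rbinom(n, 1L, 0.175) == 1L
  geometry <- character(n)
  severity <- character(n)
  pos <- lvh == 1L
  geometry[pos] <- sample(c("concentric hypertrophy", "eccentric hypertrophy"),
                          sum(pos), replace = TRUE, prob = c(0.81, 0.19))
  geometry[!pos] <- sample(c("normal", "concentric remodeling"),
                           sum(!pos), replace = TRUE, prob = c(0.385, 0.615))
  severity[pos] <- sample(c("mild", "moderate", "severe"),
                          sum(pos), replace = TRUE, prob = c(0.38, 0.23, 0.39))
  severity[!pos] <- "none"
  data.frame(sex = sex, age = age, bmi = bmi, hypertension = hypertension,
             ihd = ihd, geometry = geometry, severity = severity,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort of labeled median beats
#'
#' @param spec a [cohort_spec()].
#' @param seed optional integer seed; the whole cohort is deterministic
#'   given the seed.
#' @return list with elements `beats` (list of [median_beat()] with
#'   ground-truth fiducials), `data` (data.frame: `id`, `lvh`, covariates)
#'   and `spec`.
#' @export
make_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n
  lvh <- stats::rbinom(n, 1L, spec$prevalence)
  cov <- draw_covariates(n, lvh)
  lateral <- c("I", "V5", "V6")
  beats <- vector("list", n)
  for (i in seq_len(n)) {
    bs <- spec$beat
    comp <- bs$components
    comp$amp <- comp$amp * stats::rlnorm(1L, 0, spec$jitter_sdlog)
    if (spec$sigma_jitter_sdlog > 0)
      for (w in c("P", "QRS", "T")) {
        ww <- comp$wave == w
        comp$sigma[ww] <- comp$sigma[ww] *
          stats::rlnorm(1L, 0, spec$sigma_jitter_sdlog)
      }
    if (lvh[i] == 1L) {
      g <- stats::rlnorm(1L, spec$qrs_mult_meanlog, spec$qrs_mult_sdlog)
      qrs <- comp$wave == "QRS"
      comp$amp[qrs] <- comp$amp[qrs] * g
      comp$sigma[qrs] <- comp$sigma[qrs] * spec$lvh_qrs_widen
      tw <- comp$wave == "T"
      comp$amp[tw] <- comp$amp[tw] * spec$t_shrink
      if (stats::runif(1L) < spec$strain_p) {
        flip <- tw & comp$lead %in% lateral
        comp$amp[flip] <- -comp$amp[flip]
      }
    }
    bs$components <- comp
    beats[[i]] <- make_beat(bs)
  }
  list(beats = beats,
       data = cbind(data.frame(id = seq_len(n), lvh = lvh), cov),
       spec = spec)
}

#' Generate a labeled feature table directly (bypassing signal synthesis)
#'
#' Fast fixture generator for the modeling and evaluation layers: draws a
#' binary label at the stated prevalence and builds standard-normal feature
#' columns, shifting the labeled class of each informative feature by its
#' standardized effect size.
#'
#' @param n rows (>= 20).
#' @param informative named numeric vector of standardized mean differences,
#'   one per informative feature (names become column names).
#' @param noise_features count of uninformative standard-normal columns
#'   (named `noise1`, `noise2`, ...).
#' @param prevalence label prevalence.
#' @param missing_rate fraction of feature cells set missing at random.
#' @param groups optional named character vector (`"VCG"`/`"ECG"`) tagging
#'   each feature column; defaults to tagging informative columns `VCG` and
#'   noise columns `ECG`... see Details.
#' @param seed optional integer seed.
#' @details When `groups` is not supplied, all columns are tagged `VCG`,
#'   which suits single-group selection tests; pass explicit tags for
#'   two-group scenarios.
#' @return a `feature_table` (see [feature_table()]).
#' @export
make_feature_table <- function(n, informative = c(signal = 1),
                               noise_features = 10L, prevalence = 0.428,
                               missing_rate = 0, groups = NULL, seed = NULL) {
  if (n < 20L) stop("feature tables need n >= 20")
  if (!is.null(seed)) set.seed(seed)
  lvh <- stats::rbinom(n, 1L, prevalence)
  cols <- list()
  for (nm in names(informative))
    cols[[nm]] <- stats::rnorm(n) + informative[[nm]] * lvh
  if (noise_features > 0L)
    for (j in seq_len(noise_features))
      cols[[paste0("noise", j)]] <- stats::rnorm(n)
  df <- as.data.frame(cols)
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n * ncol(df)) < missing_rate, n)
    df[mask] <- NA
  }
  if (is.null(groups))
    groups <- stats::setNames(rep("VCG", ncol(df)), names(df))
  feature_table(cbind(data.frame(id = seq_len(n), lvh = lvh), df),
                groups = groups)
}
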