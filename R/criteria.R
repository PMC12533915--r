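#' Load the classical ECG-LVH criteria registry
#'
#' The registry is a declarative catalogue of 23 classical electrocardiographic
#' left-ventricular-hypertrophy criteria: a name, a formula over the
#' measurement symbols (`RI`, `SV3`, `RaVL`, `SD`, `QRSd`, `RE`, `strain`,
#' `female`, ...), a unit, a comparator (`gt` strict, `ge` non-strict) and
#' sex-specific thresholds. It is bundled as a semicolon-separated text file
#' (`inst/extdata/criteria_registry.csv`) so individual cut-offs can be
#' corrected against a reference catalogue without code change. The Cornell
#' voltage and Peguero-Lo Presti rows carry their published comparators and
#' sex-specific cut-offs (> 2.8 / > 2.0 mV and >= 2.8 / >= 2.3 mV).
#'
#' @param path optional path to an alternative registry file.
#' @return data.frame with columns `name`, `label`, `formula`, `unit`,
#'   `comparator`, `threshold_m`, `threshold_f`.
#' @export
criteria_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "criteria_registry.csv",
                        package = "vcglvh", mustWork = TRUE)
  reg <- utils::read.csv(path, sep = ";", stringsAsFactors = FALSE)
  need <- c("name", "label", "formula", "unit", "comparator",
            "threshold_m", "threshold_f")
  if (!all(need %in% names(reg))) stop("malformed criteria registry")
  if (!all(reg$comparator %in% c("gt", "ge")))
    stop("comparator must be 'gt' or 'ge'")
  reg
}

# measurement symbols for criterion formulas (voltages in mV)
measurement_symbols <- function(m, sex) {
  stopifnot(inherits(m, "lead_measurements"))
  env <- c(as.list(stats::setNames(m$R, paste0("R", LEADS12))),
           as.list(stats::setNames(m$S, paste0("S", LEADS12))))
  env$SD <- m$sd_value
  env$QRSd <- m$qrs_ms
  env$RE <- romhilt_estes(m)
  env$strain <- as.numeric(isTRUE(m$strain))
  env$axis <- m$axis_deg
  env$female <- as.numeric(sex == "female")
  env
}

check_sex <- function(sex) {
  if (length(sex) != 1L || is.na(sex) || !sex %in% c("male", "female"))
    stop("sex must be 'male' or 'female' (criterion thresholds are sex-specific)")
  sex
}

criterion_result <- function(name, value, unit, threshold, comparator, sex) {
  call <- if (comparator == "gt") value > threshold else value >= threshold
  structure(list(name = name, value = value, unit = unit,
                 threshold = threshold, comparator = comparator,
                 call = call, sex = sex),
            class = "criterion_result")
}

#' @export
print.criterion_result <- function(x, ...) {
  cat(sprintf("%s: %.3f %s %s %.3g [%s] -> %s\n", x$name, x$value, x$unit,
              if (x$comparator == "gt") ">" else ">=", x$threshold, x$sex,
              if (isTRUE(x$call)) "POSITIVE" else "negative"))
  invisible(x)
}

#' Cornell voltage criterion
#'
#' `RaVL + SV3`, positive when strictly greater than 2.8 mV in men or
#' 2.0 mV in women.
#'
#' @param m a [measure_amplitudes()] result.
#' @param sex `"male"` or `"female"`.
#' @return a `criterion_result`.
#' @export
cornell_voltage <- function(m, sex) {
  sex <- check_sex(sex)
  value <- m$R[["aVL"]] + m$S[["V3"]]
  criterion_result("cornell_voltage", value, "mV",
                   if (sex == "male") 2.8 else 2.0, "gt", sex)
}

#' Peguero-Lo Presti criterion
#'
#' Deepest S in any lead plus `SV4`, positive at >= 2.8 mV in men or
#' >= 2.3 mV in women (non-strict comparator).
#'
#' @inheritParams cornell_voltage
#' @return a `criterion_result`.
#' @export
peguero_lo_presti <- function(m, sex) {
  sex <- check_sex(sex)
  value <- m$sd_value + m$S[["V4"]]
  criterion_result("peguero_lo_presti", value, "mV",
                   if (sex == "male") 2.8 else 2.3, "ge", sex)
}

#' Romhilt-Estes point score
#'
#' The standard six-component score: voltage (any limb R/S >= 2.0 mV, or
#' S in V1/V2 >= 3.0 mV, or R in V5/V6 >= 3.0 mV; 3 points), repolarization
#' strain in V5/V6 (3), left atrial abnormality (P terminal force in V1
#' >= 0.04 mV.s; 3), left axis deviation beyond -30 degrees (2), QRS
#' duration >= 90 ms (1), and delayed intrinsicoid deflection in V5/V6
#' (>= 50 ms; 1).
#'
#' @param m a [measure_amplitudes()] result.
#' @return integer score (0-13).
#' @export
romhilt_estes <- function(m) {
  limb <- LEADS12[1:6]
  pts <- 0L
  if (max(m$R[limb], m$S[limb]) >= 2.0 ||
      max(m$S[c("V1", "V2")]) >= 3.0 ||
      max(m$R[c("V5", "V6")]) >= 3.0) pts <- pts + 3L
  if (isTRUE(m$strain)) pts <- pts + 3L
  if (m$ptf_v1 >= 0.04) pts <- pts + 3L
  if (m$axis_deg < -30) pts <- pts + 2L
  if (m$qrs_ms >= 90) pts <- pts + 1L
  if (max(m$intrinsicoid_ms) >= 50) pts <- pts + 1L
  pts
}

#' Evaluate the full criteria registry
#'
#' Evaluates every registry criterion on one patient's measurements and also
#' emits, for each voltage (mV) criterion, its voltage-duration product
#' (`value * QRSd`, mV.ms, no cut-off). Criteria whose formula cannot be
#' evaluated (missing symbol) are skipped with a warning.
#'
#' @param m a [measure_amplitudes()] result.
#' @param sex `"male"` or `"female"`.
#' @param registry registry data.frame from [criteria_registry()].
#' @param products emit voltage-duration product rows (default `TRUE`).
#' @return data.frame with one row per criterion (and product variant):
#'   `name`, `value`, `unit`, `threshold`, `comparator`, `call`.
#' @export
evaluate_criteria <- function(m, sex, registry = criteria_registry(),
                              products = TRUE) {
  sex <- check_sex(sex)
  env <- list2env(measurement_symbols(m, sex), parent = baseenv())
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    value <- tryCatch(eval(parse(text = r$formula)[[1L]], env),
                      error = function(e) {
                        warning("skipping criterion ", r$name, ": ",
                                conditionMessage(e))
                        NULL
                      })
    if (is.null(value)) return(NULL)
    thr <- if (sex == "male") r$threshold_m else r$threshold_f
    call <- if (r$comparator == "gt") value > thr else value >= thr
    out <- data.frame(name = r$name, value = value, unit = r$unit,
                      threshold = thr, comparator = r$comparator,
                      call = call, stringsAsFactors = FALSE)
    if (products && r$unit == "mV")
      out <- rbind(out, data.frame(name = paste0(r$name, "_vdp"),
                                   value = value * env$QRSd, unit = "mV.ms",
                                   threshold = NA_real_, comparator = NA,
                                   call = NA))
    out
  })
  do.call(rbind, rows)
}
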