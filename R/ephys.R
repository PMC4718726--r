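# Current-sweep processing: baseline subtraction, on/off peak measurement,
# optional decay-time fitting, and patch-level quality control.

window_index <- function(time_s, win, what) {
  if (length(win) != 2L || win[2] <= win[1]) {
    stop(sprintf("measure_peaks: invalid %s window", what))
  }
  idx <- which(time_s >= win[1] & time_s < win[2])
  if (length(idx) == 0L) {
    stop(sprintf("measure_peaks: %s window [%g, %g] s lies outside the trace", what, win[1], win[2]))
  }
  idx
}

#' Measure baseline and peak currents of a sweep
#'
#' Baseline is the mean current over the pre-stimulus window; on- and
#' off-response peaks are the maximal baseline-subtracted inward
#' deflections (reported as non-negative magnitudes in pA, clipped at 0)
#' over the step window and the post-release window respectively.  An
#' optional single-exponential fit of the current decay from the on-peak
#' to the step end yields `decay_tau`.
#'
#' @param sweep a `sweep_record` (from [simulate_trace()] or
#'   [read_trace_csv()]), or any data.frame with `time_s`, `current_pa`
#'   columns.
#' @param baseline_window `c(start, end)` seconds before the stimulus.
#' @param step_window `c(start, end)` seconds of the test step; default
#'   from the sweep's segment table (the largest-|pressure| segment).
#' @param off_window `c(start, end)` seconds after release; default 500 ms
#'   following the step end.
#' @param inward_negative inward current is negative in the trace (holding
#'   at -80 mV); set FALSE for traces stored as magnitudes.
#' @param fit_decay also fit the decay time constant (off by default; the
#'   peak must exceed `prominence_pa`).
#' @param prominence_pa minimum on-peak (pA) for decay fitting.
#' @return list of class `peak_measurement`: `baseline_pa`, `peak_on_pa`,
#'   `peak_off_pa`, `decay_tau_s` (NA unless fitted).
#' @export
measure_peaks <- function(sweep, baseline_window = NULL, step_window = NULL,
                          off_window = NULL, inward_negative = TRUE,
                          fit_decay = FALSE, prominence_pa = 5) {
  tm <- sweep$time_s
  cur <- sweep$current_pa
  if (anyNA(cur) || anyNA(tm)) stop("measure_peaks: trace contains NA samples")
  seg <- attr(sweep, "segments")
  if (is.null(step_window)) {
    if (is.null(seg)) stop("measure_peaks: step_window required when the sweep carries no segment table")
    k <- which.max(abs(seg$amplitude))
    if (abs(seg$amplitude[k]) == 0 && nrow(seg) >= 2L) k <- 2L  # all-zero protocol
    step_window <- c(seg$start_s[k], seg$end_s[k])
  }
  if (is.null(baseline_window)) baseline_window <- c(0, step_window[1])
  if (is.null(off_window)) {
    off_window <- c(step_window[2], min(step_window[2] + 0.5, max(tm) + 1e-9))
  }
  if (baseline_window[2] > step_window[1] + 1e-9) {
    stop("measure_peaks: baseline window must precede the step window")
  }
  ib <- window_index(tm, baseline_window, "baseline")
  is_ <- window_index(tm, step_window, "step")
  io <- window_index(tm, off_window, "off")
  baseline <- mean(cur[ib])
  sig <- if (inward_negative) baseline - cur else cur - baseline
  peak_on <- max(max(sig[is_]), 0)
  peak_off <- max(max(sig[io]), 0)
  decay_tau <- NA_real_
  if (fit_decay && peak_on > prominence_pa) {
    kp <- is_[which.max(sig[is_])]
    idx <- kp:is_[length(is_)]
    if (length(idx) >= 5L) {
      tt <- tm[idx] - tm[kp]
      yy <- sig[idx]
      i0 <- c(min(yy), max(yy) - min(yy), max(diff(range(tt)) / 5, 1e-4))
      fn <- function(p) p[1] + p[2] * exp(-tt / p[3])
      jac <- function(p) {
        e <- exp(-tt / p[3])
        cbind(1, e, p[2] * e * tt / p[3]^2)
      }
      ft <- tryCatch(lm_fit(fn, jac, i0, yy, lower = c(-Inf, 0, 1e-6)),
                     error = function(e) NULL)
      if (!is.null(ft) && ft$converged) decay_tau <- ft$par[3]
    }
  }
  structure(list(baseline_pa = baseline, peak_on_pa = peak_on,
                 peak_off_pa = peak_off, decay_tau_s = decay_tau,
                 step_window = step_window, off_window = off_window),
            class = "peak_measurement")
}

#' @export
print.peak_measurement <- function(x, ...) {
  cat(sprintf("peaks: baseline %.3g pA, on %.4g pA, off %.4g pA%s\n",
              x$baseline_pa, x$peak_on_pa, x$peak_off_pa,
              if (is.finite(x$decay_tau_s)) sprintf(", decay tau %.3g s", x$decay_tau_s) else ""))
  invisible(x)
}

#' Patch-level quality control
#'
#' A patch passes when its seal resistance reaches `min_seal_gohm` and its
#' maximal pressure-induced current reaches the configuration-dependent
#' threshold: 50 pA for cell-attached and inside-out patches stimulated
#' with negative pressure, 20 pA for all other configurations.
#'
#' @param seal_gohm seal resistance, GOhm.
#' @param max_current_pa maximal pressure-induced current magnitude, pA.
#' @param configuration `"cell_attached"`, `"inside_out"` or
#'   `"outside_out"`.
#' @param polarity stimulus polarity, `"negative"` or `"positive"`.
#' @param min_seal_gohm seal threshold (default 1).
#' @param current_thresholds named thresholds `c(strict = 50, lenient = 20)` pA.
#' @return list of class `patch_qc`: `passed`, `reason`,
#'   `current_threshold_pa`, inputs.
#' @export
apply_qc <- function(seal_gohm, max_current_pa,
                     configuration = c("cell_attached", "inside_out", "outside_out"),
                     polarity = c("negative", "positive"),
                     min_seal_gohm = 1,
                     current_thresholds = c(strict = 50, lenient = 20)) {
  configuration <- match.arg(configuration)
  polarity <- match.arg(polarity)
  if (missing(seal_gohm) || missing(max_current_pa) ||
      !is.finite(seal_gohm) || !is.finite(max_current_pa)) {
    stop("apply_qc: seal resistance and maximal current are required")
  }
  strict <- configuration %in% c("cell_attached", "inside_out") && polarity == "negative"
  thr <- unname(if (strict) current_thresholds["strict"] else current_thresholds["lenient"])
  reasons <- character(0)
  if (seal_gohm < min_seal_gohm) reasons <- c(reasons, "seal")
  if (abs(max_current_pa) < thr) reasons <- c(reasons, "current")
  structure(list(passed = length(reasons) == 0L,
                 reason = if (length(reasons)) paste(reasons, collapse = "+") else "ok",
                 current_threshold_pa = thr,
                 seal_gohm = seal_gohm, max_current_pa = abs(max_current_pa),
                 configuration = configuration, polarity = polarity),
            class = "patch_qc")
}
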