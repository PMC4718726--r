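# Canonical computation of the headline recovered quantities.  Both the
# acceptance script and the acceptance tests call this, so the reported
# numbers are always produced by the same code path: full simulation at the
# standard cohort sizes followed by the complete analysis pipeline.

#' Compute the headline parameter-recovery targets
#'
#' Runs the full pipeline on freshly simulated cohorts and returns the
#' recovered quantities:
#' \describe{
#'   \item{t1, t2}{T50 and k from the pooled SD-weighted tension fit of a
#'     15-cell / 218-response cell-attached cohort (mN/m).}
#'   \item{t3}{T50 of a 10-cell / 123-response inside-out cohort (mN/m).}
#'   \item{t4}{T50 of the 11-patch, +5 mmHg-prepulse cohort (mN/m).}
#'   \item{t5}{T50 of the 11-patch, no-prepulse cohort (mN/m).}
#'   \item{t6}{recovery time constant tau from the exponential fit of
#'     off-response peak vs. prepulse duration, 11 patches (s).}
#'   \item{t7}{radius returned by detection + circle fit on a rendered
#'     2.87 um phantom at 61.5 px/um (um).}
#'   \item{t8}{mean per-cell half-activation pressure of a 15-cell
#'     negative-pressure cohort (mmHg, signed).}
#' }
#'
#' @param seed master seed; every cohort derives its own sub-stream.
#' @return named list; each element is `list(value =, n =)`.
#' @export
acceptance_targets <- function(seed = 1) {
  out <- list()
  cohort <- function(i, cnd) {
    resp <- simulate_response_set(simulation_config(seed = derive_seed(seed, 10L, i)), cnd)
    analyze_tension_cohort(resp, normalize = condition_params(cnd)$normalize)
  }
  ca <- cohort(1L, "cell_attached")
  out$t1 <- list(value = ca$fit$x50, n = nrow(ca$responses))
  out$t2 <- list(value = ca$fit$k, n = nrow(ca$responses))
  io <- cohort(2L, "inside_out")
  out$t3 <- list(value = io$fit$x50, n = nrow(io$responses))
  p0 <- cohort(3L, "prepulse_0")
  p5 <- cohort(4L, "prepulse_5")
  out$t4 <- list(value = p5$fit$x50, n = length(unique(p5$responses$cell_id)))
  out$t5 <- list(value = p0$fit$x50, n = length(unique(p0$responses$cell_id)))
  rec <- simulate_recovery_peaks(seed = derive_seed(seed, 10L, 6L))
  mp <- tapply(rec$peak_norm, rec$duration_s, mean)
  fr <- fit_recovery(as.numeric(names(mp)), as.numeric(mp),
                     t0 = attr(rec, "generative")$t0)
  out$t6 <- list(value = fr$tau, n = length(unique(rec$patch_id)))
  img <- render_patch_image(pipette_geometry(), radius = 2.87, noise_sd = 2,
                            seed = derive_seed(seed, 10L, 7L))
  cf <- measure_patch_radius(img)
  out$t7 <- list(value = cf$radius, n = cf$n_points)
  pc <- simulate_pressure_cohort(seed = derive_seed(seed, 10L, 8L))
  pr <- analyze_pressure_cohort(pc)
  out$t8 <- list(value = pr$p50_mean, n = length(pr$p50_cells))
  out
}
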