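# Orchestration: cohort-level analysis (normalize -> tension -> bin ->
# weighted fit), end-to-end runs with artifacts on disk, and the canned
# reproduction suite comparing recovered parameters to their generative
# values.

#' Analyze one cohort of responses into a tension-activation fit
#'
#' Runs the pooled-analysis pipeline on a per-response table: per-cell
#' normalization (fitted plateau or patch maximum), tension from measured
#' radius and pressure via Laplace's law, pooling and binning at
#' `bin_width`, and the SD-weighted Boltzmann fit of the binned means.
#'
#' @param responses data.frame with `cell_id`, `dp_mmhg`, `peak_pa` and
#'   either `radius_um` (tension computed here) or `tension_mN_per_m`.
#' @param normalize normalization mode, see [normalize_responses()].
#' @param bin_width tension bin width, mN/m.
#' @param weighted SD-weight the binned fit.
#' @return list with `responses` (normalized, with tension), `hist`
#'   (binned), `fit` (tension-domain `boltzmann_fit`), `cell_fits`
#'   (per-cell pressure fits when plateau normalization is used).
#' @export
analyze_tension_cohort <- function(responses,
                                   normalize = c("plateau_of_fit", "max_response"),
                                   bin_width = 1, weighted = TRUE) {
  normalize <- match.arg(normalize)
  if (!"tension_mN_per_m" %in% names(responses)) {
    if (!"radius_um" %in% names(responses)) {
      stop("analyze_tension_cohort: need radius_um or tension_mN_per_m")
    }
    responses$tension_mN_per_m <- laplace_tension(
      responses$radius_um, responses$dp_mmhg,
      flat = !is.finite(responses$radius_um))
  }
  norm <- normalize_responses(responses, mode = normalize)
  hist <- pool_and_bin(norm$tension_mN_per_m, norm$norm_current, bin_width,
                       stimulus = "tension")
  fit <- fit_tension_curve(hist, weighted = weighted)
  list(responses = norm, hist = hist, fit = fit,
       cell_fits = attr(norm, "cell_fits"))
}

#' Mean per-cell half-activation pressure of a pressure-domain cohort
#'
#' Fits each cell's current-pressure series with a Boltzmann and averages
#' the per-cell midpoints (signed).
#'
#' @param responses data.frame with `cell_id`, `dp_mmhg`, `peak_pa`.
#' @return list with `p50_mean`, `p50_se` (SEM over cells), `p50_cells`,
#'   `fits`.
#' @export
analyze_pressure_cohort <- function(responses) {
  cells <- split(responses, responses$cell_id)
  fits <- lapply(cells, function(d) fit_cell_pressure(d$dp_mmhg, d$peak_pa))
  p50 <- vapply(fits, function(f) f$p50_signed, 0)
  list(p50_mean = mean(p50), p50_se = stats::sd(p50) / sqrt(length(p50)),
       p50_cells = p50, fits = fits)
}

default_run_config <- function() {
  list(
    seed = 1,
    condition = "cell_attached",
    stages = list(simulate = TRUE, tension = TRUE, fits = TRUE),
    analysis = list(bin_width = 1, normalize = NULL, weighted = TRUE),
    simulation = list(n_cells = NULL, responses_total = NULL,
                      noise_current = 10, noise_radius = 0.05,
                      cell_heterogeneity = 0.08, radius_spread = 0.12),
    paths = list(responses = NULL))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a run configuration from JSON
#'
#' Unspecified fields take the package defaults (1 mN/m bins, 9-px
#' detection window, standard QC thresholds, 10 s inter-sweep interval).
#'
#' @param path JSON file, or a list already in config shape.
#' @return validated config list with a `hash` attribute.
#' @export
read_run_config <- function(path) {
  user <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = TRUE) else path
  cfg <- merge_config(default_run_config(), user)
  if (!cfg$condition %in% c("cell_attached", "inside_out", "prepulse_0",
                            "prepulse_5", "prepulse_10")) {
    stop("read_run_config: unknown condition ", cfg$condition)
  }
  if (!isTRUE(cfg$stages$simulate) && is.null(cfg$paths$responses)) {
    stop("read_run_config: simulation disabled but no responses path given")
  }
  attr(cfg, "hash") <- content_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 10))
  cfg
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages (simulate responses -> tension -> pooled
#' fit), writes intermediate artifacts to `out_dir` (responses.csv,
#' binned.csv, fits.json, report.json), and returns a run report.  All
#' outputs are deterministic given the config (including its seed); the
#' report embeds the config hash and a checksum of every file written.
#'
#' @param config a config list or JSON path (see [read_run_config()]).
#' @param out_dir output directory, created if needed.
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  cp <- condition_params(cfg$condition)
  files <- character(0)
  truth <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    sim_cfg <- simulation_config(
      seed = cfg$seed,
      n_cells = cfg$simulation$n_cells %||% cp$n_cells,
      responses_total = cfg$simulation$responses_total %||% cp$n_responses,
      noise_current = cfg$simulation$noise_current,
      noise_radius = cfg$simulation$noise_radius,
      cell_heterogeneity = cfg$simulation$cell_heterogeneity,
      radius_spread = cfg$simulation$radius_spread)
    responses <- simulate_response_set(sim_cfg, cfg$condition,
                                       override = is.null(cfg$simulation$n_cells))
    truth <- attr(responses, "generative")
    f <- file.path(out_dir, "responses.csv")
    utils::write.csv(responses, f, row.names = FALSE)
    files <- c(files, f)
    log_msg("simulate", "%d responses from %d cells (condition %s)",
            nrow(responses), length(unique(responses$cell_id)), cfg$condition)
  } else {
    responses <- utils::read.csv(cfg$paths$responses)
    log_msg("load", "%d responses from %s", nrow(responses), cfg$paths$responses)
  }
  res <- NULL
  if (isTRUE(cfg$stages$fits)) {
    normalize <- cfg$analysis$normalize %||% cp$normalize
    res <- analyze_tension_cohort(responses, normalize = normalize,
                                  bin_width = cfg$analysis$bin_width,
                                  weighted = isTRUE(cfg$analysis$weighted))
    n_dropped <- length(unique(responses$cell_id)) -
      length(unique(res$responses$cell_id))
    if (n_dropped > 0) log_msg("fits", "WARNING: %d cell(s) dropped during normalization", n_dropped)
    fb <- file.path(out_dir, "binned.csv")
    utils::write.csv(as.data.frame(res$hist), fb, row.names = FALSE)
    fj <- file.path(out_dir, "fits.json")
    fit <- res$fit
    jsonlite::write_json(list(
      domain = fit$domain, units = fit$units, n_bins = fit$n,
      normalization = normalize, weighted = fit$weighted,
      i_max = fit$i_max, t50 = fit$x50, k = fit$k,
      se_i_max = fit$se_i_max, se_t50 = fit$se_x50, se_k = fit$se_k,
      config_hash = attr(cfg, "hash")),
      fj, auto_unbox = TRUE, digits = 10)
    files <- c(files, fb, fj)
    log_msg("fits", "T50 = %.3f +/- %.3f mN/m, k = %.3f +/- %.3f (I_max %.3f)",
            fit$x50, fit$se_x50, fit$k, fit$se_k, fit$i_max)
  }
  report <- list(
    config_hash = attr(cfg, "hash"),
    condition = cfg$condition,
    n_responses = nrow(responses),
    n_cells = length(unique(responses$cell_id)),
    fit = if (!is.null(res)) list(i_max = res$fit$i_max, t50 = res$fit$x50,
                                  k = res$fit$k, se_t50 = res$fit$se_x50,
                                  se_k = res$fit$se_k) else NULL,
    truth = truth,
    delta = if (!is.null(res) && !is.null(truth))
      list(t50 = res$fit$x50 - truth$t50, k = res$fit$k - truth$k) else NULL,
    files = stats::setNames(lapply(files, file_hash), basename(files)))
  fr <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, fr, auto_unbox = TRUE, digits = 10, null = "null")
  class(report) <- "run_report"
  report
}

#' Reproduce the canned cohort suite against generative ground truth
#'
#' Runs the five cohort conditions at their standard sample sizes, the
#' recovery-duration series, the imaging phantom, and the pressure-domain
#' cohort, and tabulates recovered parameters against the generative
#' values.
#'
#' @param out_dir optional directory for per-cohort artifacts.
#' @param seed master seed.
#' @return data.frame with columns `quantity`, `units`, `generative`,
#'   `recovered`, `se`, `n`.
#' @export
reproduce_paper_suite <- function(out_dir = NULL, seed = 1) {
  rows <- list()
  add <- function(quantity, units, generative, recovered, se, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, units = units, generative = generative,
      recovered = recovered, se = se, n = n)
  }
  conds <- c("cell_attached", "inside_out", "prepulse_0", "prepulse_5", "prepulse_10")
  for (i in seq_along(conds)) {
    cnd <- conds[i]
    cp <- condition_params(cnd)
    cfg <- simulation_config(seed = derive_seed(seed, 10L, i))
    resp <- simulate_response_set(cfg, cnd)
    res <- analyze_tension_cohort(resp, normalize = cp$normalize)
    if (!is.null(out_dir)) {
      dir.create(file.path(out_dir, cnd), recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(resp, file.path(out_dir, cnd, "responses.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(res$hist),
                       file.path(out_dir, cnd, "binned.csv"), row.names = FALSE)
    }
    add(paste0("T50_", cnd), "mN/m", cp$t50, res$fit$x50, res$fit$se_x50, nrow(resp))
    add(paste0("k_", cnd), "mN/m", cp$k, res$fit$k, res$fit$se_k, nrow(resp))
  }
  rec <- simulate_recovery_peaks(seed = derive_seed(seed, 10L, 6L))
  gen <- attr(rec, "generative")
  mean_peaks <- tapply(rec$peak_norm, rec$duration_s, mean)
  fit_rec <- fit_recovery(as.numeric(names(mean_peaks)), as.numeric(mean_peaks),
                          t0 = gen$t0)
  add("tau_recovery", "s", gen$tau, fit_rec$tau, fit_rec$se_tau,
      length(unique(rec$patch_id)))
  img <- render_patch_image(pipette_geometry(), radius = 2.87, noise_sd = 2,
                            seed = derive_seed(seed, 10L, 7L))
  cf <- measure_patch_radius(img)
  add("radius_phantom", "um", img$truth$radius_um, cf$radius, cf$rms_um, cf$n_points)
  pc <- simulate_pressure_cohort(seed = derive_seed(seed, 10L, 8L))
  pgen <- attr(pc, "generative")
  pres <- analyze_pressure_cohort(pc)
  add("P50_cell_attached", "mmHg", pgen$p50_mean, pres$p50_mean, pres$p50_se,
      length(pres$p50_cells))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "suite_summary.csv"), row.names = FALSE)
  }
  out
}
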