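#' Analysis configuration
#'
#' Bundles every tunable constant of the pipeline.  Defaults reproduce the
#' published analysis regime: candidate periods between 12 and 36 h, the
#' 18--32 h circadian band for spectral features and the local nu-gap,
#' a 46% fitness threshold for link validation, stricter 80% (perturbation
#' scan) and 60% (hub scan) thresholds for genome-wide work, and a 0.2
#' nu-gap significance guide.
#'
#' @param period_range numeric length 2, admissible pseudo-sine half-cycle
#'   periods \code{p1}, \code{p2} in hours.
#' @param rhythm_band numeric length 2, period band (hours) used for the
#'   spectral band-power feature and the local nu-gap.
#' @param fit_threshold_pct link-validation fitness threshold (percent).
#' @param strict_fit_threshold_pct fitness threshold for the genome-wide
#'   perturbed-link scan.
#' @param hub_fit_threshold_pct fitness threshold for the clock-hub scan.
#' @param nugap_threshold nu-gap value above which a common link is flagged
#'   as dynamically altered.
#' @param grid_step_hours step of the exhaustive \code{(p1, p2)} period grid.
#' @param phase_grid_size number of phase-grid points in \code{[0, 2*pi)}.
#' @param freq_grid_size number of frequency-grid points for the global
#'   nu-gap sup search.
#' @param local_band frequency band (rad/h) for the local nu-gap; defaults to
#'   \code{2*pi / rev(rhythm_band)}.
#' @param fitness_root logical; \code{TRUE} uses the root (NRMSE) fitness
#'   form, \code{FALSE} the squared (NMSE) variant.
#' @param input_hold \code{"foh"} (linear interpolation of the input between
#'   samples) or \code{"zoh"} (zero-order hold).
#' @param stable_fits logical; constrain identified models to be stable
#'   (\code{b > 0}), matching the simulation-error identification
#'   convention.  Unstable first-order models can realize arbitrary phase
#'   shifts on oscillatory data and therefore act as universal
#'   approximators of any gene pair; allowing them (set \code{FALSE})
#'   inflates spurious link validation.
#' @param n_restarts random restarts added to the regression-based
#'   initialization in \code{\link{fit_first_order}}.
#' @param rng_seed integer seed controlling every stochastic step.
#'
#' @return object of class \code{dyde_config} (a named list).
#' @export
dyde_config <- function(period_range = c(12, 36),
                        rhythm_band = c(18, 32),
                        fit_threshold_pct = 46,
                        strict_fit_threshold_pct = 80,
                        hub_fit_threshold_pct = 60,
                        nugap_threshold = 0.2,
                        grid_step_hours = 0.2,
                        phase_grid_size = 64,
                        freq_grid_size = 2000,
                        local_band = NULL,
                        fitness_root = TRUE,
                        input_hold = c("foh", "zoh"),
                        stable_fits = TRUE,
                        n_restarts = 8,
                        rng_seed = 1L) {
  input_hold <- match.arg(input_hold)
  stopifnot(length(period_range) == 2, period_range[1] < period_range[2],
            period_range[1] > 0,
            length(rhythm_band) == 2, rhythm_band[1] < rhythm_band[2],
            rhythm_band[1] > 0)
  thr <- c(fit_threshold_pct, strict_fit_threshold_pct, hub_fit_threshold_pct)
  if (any(thr < 0 | thr > 100))
    stop("fitness thresholds must lie in [0, 100]")
  if (nugap_threshold < 0 || nugap_threshold > 1)
    stop("nugap_threshold must lie in [0, 1]")
  if (is.null(local_band))
    local_band <- 2 * pi / rev(rhythm_band)
  stopifnot(length(local_band) == 2, local_band[1] > 0,
            local_band[1] < local_band[2])
  structure(list(
    period_range = as.numeric(period_range),
    rhythm_band = as.numeric(rhythm_band),
    fit_threshold_pct = fit_threshold_pct,
    strict_fit_threshold_pct = strict_fit_threshold_pct,
    hub_fit_threshold_pct = hub_fit_threshold_pct,
    nugap_threshold = nugap_threshold,
    grid_step_hours = grid_step_hours,
    phase_grid_size = as.integer(phase_grid_size),
    freq_grid_size = as.integer(freq_grid_size),
    local_band = as.numeric(local_band),
    fitness_root = isTRUE(fitness_root),
    input_hold = input_hold,
    stable_fits = isTRUE(stable_fits),
    n_restarts = as.integer(n_restarts),
    rng_seed = as.integer(rng_seed)
  ), class = "dyde_config")
}

# period grid honouring the configured range and step; endpoints included
period_grid <- function(cfg) {
  g <- seq(cfg$period_range[1], cfg$period_range[2], by = cfg$grid_step_hours)
  if (tail_eps(g, cfg$period_range[2])) g else c(g, cfg$period_range[2])
}

tail_eps <- function(g, hi) abs(g[length(g)] - hi) < 1e-9

#' @export
print.dyde_config <- function(x, ...) {
  cat("dyde analysis configuration\n")
  cat(sprintf("  period range     : %g-%g h (grid step %g h, %d phases)\n",
              x$period_range[1], x$period_range[2], x$grid_step_hours,
              x$phase_grid_size))
  cat(sprintf("  rhythm band      : %g-%g h\n",
              x$rhythm_band[1], x$rhythm_band[2]))
  cat(sprintf("  fitness thresholds: %g%% (links), %g%% (scan), %g%% (hubs)\n",
              x$fit_threshold_pct, x$strict_fit_threshold_pct,
              x$hub_fit_threshold_pct))
  cat(sprintf("  nu-gap threshold : %g; seed %d\n",
              x$nugap_threshold, x$rng_seed))
  invisible(x)
}
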