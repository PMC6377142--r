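#' Pseudo-sinusoid parameters
#'
#' A pseudo-sinusoid joins half-cycles of two sinusoids with periods
#' \code{p1} and \code{p2}: over one overall period \eqn{P = (p1+p2)/2} the
#' waveform is \eqn{A \sin(2\pi t/p_1 + \phi_1)} for \eqn{t \in [0, p_1/2)}
#' and \eqn{A \sin(2\pi (t - p_1/2 + p_2/2)/p_2 + \phi_1)} for the remainder,
#' tiled periodically.  The junction is continuous by construction.  Such
#' waveforms capture asymmetric circadian profiles (e.g. fast rise, slow
#' decay) that pure cosine fits miss.
#'
#' @param A amplitude, \code{>= 0} (expression units).
#' @param phi1 phase in radians, canonicalized to \code{[0, 2*pi)}.
#' @param p1,p2 full periods (hours) of the two half-cycles, \code{> 0}.
#' @return object of class \code{pseudo_sine}; field \code{period} is
#'   \code{(p1 + p2) / 2}.
#' @export
pseudo_sine <- function(A, phi1, p1, p2) {
  if (p1 <= 0 || p2 <= 0) stop("p1 and p2 must be positive")
  if (A < 0) stop("amplitude must be non-negative")
  phi1 <- phi1 %% (2 * pi)
  structure(list(A = A, phi1 = phi1, p1 = p1, p2 = p2,
                 period = (p1 + p2) / 2),
            class = "pseudo_sine")
}

#' Evaluate a pseudo-sinusoid
#'
#' @param params a \code{\link{pseudo_sine}}.
#' @param times numeric vector of times (hours).
#' @return numeric vector of waveform values.
#' @export
pseudo_sine_eval <- function(params, times) {
  cpp_pseudo_sine_eval(params$A, params$phi1, params$p1, params$p2,
                       as.numeric(times))
}

#' Fit a pseudo-sinusoid by exhaustive grid search
#'
#' Searches every \code{(p1, p2)} pair on the configured period grid and
#' every phase on a uniform grid in \code{[0, 2*pi)}; for each candidate the
#' amplitude is the closed-form least-squares scalar, clamped at zero.  The
#' global minimizer of the residual 2-norm is returned; ties break toward
#' the smallest \code{(p1, p2, phi1)}.  The series is detrended defensively
#' before fitting.
#'
#' @param series numeric values over time (ideally already detrended).
#' @param times sampling times in hours.
#' @param cfg a \code{\link{dyde_config}}.
#' @return list of class \code{pseudo_sine_fit} with fields \code{params}
#'   (a \code{pseudo_sine}) and \code{l2_error}.
#' @export
fit_pseudo_sine <- function(series, times, cfg = dyde_config()) {
  if (length(series) < 6) stop("fit_pseudo_sine needs at least 6 points")
  if (length(series) != length(times)) stop("series/times length mismatch")
  y <- detrend(series, times)
  res <- cpp_fit_pseudo_sine(y, as.numeric(times), period_grid(cfg),
                             cfg$phase_grid_size)
  structure(list(params = pseudo_sine(res[1], res[2], res[3], res[4]),
                 l2_error = res[5]),
            class = "pseudo_sine_fit")
}

# Periodogram of a (detrended) series at the native Fourier frequencies
# (no zero padding: with a 24 h rhythm sampled every 4 h the fundamental
# falls exactly on a bin, so an in-band tone concentrates its power in the
# band; interpolating onto a padded grid smears the 12-sample main lobe
# across the band edges).  Returns data.frame with freq (cycles/h),
# period (h), power.
periodogram <- function(series, dt, n_pad = length(series)) {
  n <- length(series)
  n_pad <- max(n_pad, n)
  sp <- Mod(fft(c(series, rep(0, n_pad - n))))^2
  k <- seq_len(floor(n_pad / 2))            # positive frequencies, no DC
  freq <- k / (n_pad * dt)
  data.frame(freq = freq, period = 1 / freq, power = sp[k + 1])
}

# fraction of periodogram grid frequencies inside the rhythm band --
# the null expectation of the band-power ratio for white noise
band_fraction <- function(n, dt, band = c(18, 32)) {
  pg <- periodogram(rep(0, n), dt)
  mean(pg$period >= band[1] & pg$period <= band[2])
}

#' Spectral and fit features for rhythmicity classification
#'
#' Computes the 8-feature vector used by the classifier, from two signals:
#' A, the detrended replicate mean, and B, the detrended single replicate
#' with the lowest pseudo-sine fit error (lowest replicate index on ties;
#' B = A when only one replicate exists).  Features: band-power ratio in the
#' configured rhythm band (x1 for A, x2 for B), pseudo-sine L2 fit error
#' (x3, x4), variance of the periodogram ordinates (x5, x6), fitted
#' amplitude (x7, x8).
#'
#' @param replicates numeric matrix, one row per replicate, columns = time.
#' @param times sampling times in hours.
#' @param cfg a \code{\link{dyde_config}}.
#'
#' @details Spectral features use the demeaned (not slope-removed) series:
#' on a finite window the straight-line basis is not orthogonal to the
#' Fourier basis, so removing the OLS slope redistributes power of a pure
#' in-band tone across bins, while a genuine linear trend projects almost
#' entirely onto the DC and lowest-frequency bins, which already lie
#' outside the circadian band.  The pseudo-sine fit (x3/x4/x7/x8) works on
#' detrended series as in the period-estimation stage.
#' @return list of class \code{rhythm_features}: numeric \code{x} (length 8),
#'   \code{fit_A} (pseudo-sine fit of signal A), \code{best_replicate}.
#' @export
compute_features <- function(replicates, times, cfg = dyde_config()) {
  replicates <- rbind(replicates)
  if (nrow(replicates) < 1) stop("at least one replicate required")
  dt <- check_uniform_grid(times)
  sigA <- colMeans(replicates)
  fits <- lapply(seq_len(nrow(replicates)), function(r)
    fit_pseudo_sine(replicates[r, ], times, cfg))
  best <- which.min(vapply(fits, function(f) f$l2_error, 1))
  sigB <- replicates[best, ]
  fit_A <- fit_pseudo_sine(sigA, times, cfg)
  fit_B <- fits[[best]]
  feat1 <- function(sig) {
    pg <- periodogram(sig - mean(sig), dt)
    tot <- sum(pg$power)
    inb <- pg$period >= cfg$rhythm_band[1] & pg$period <= cfg$rhythm_band[2]
    c(ratio = if (tot > 0) sum(pg$power[inb]) / tot else 0,
      specvar = if (tot > 0) var(pg$power) else 0)
  }
  fA <- feat1(sigA); fB <- feat1(sigB)
  x <- c(fA["ratio"], fB["ratio"], fit_A$l2_error, fit_B$l2_error,
         fA["specvar"], fB["specvar"], fit_A$params$A, fit_B$params$A)
  names(x) <- paste0("x", 1:8)
  structure(list(x = x, fit_A = fit_A, best_replicate = best),
            class = "rhythm_features")
}

#' Train the rhythmic / arrhythmic logistic classifier
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares with a small L2 ridge (\code{1e-6}) for separable data.
#' Features are standardized internally (per-feature mean and sd from the
#' training set); the standardization is stored in the model so that raw
#' feature vectors can be classified directly.
#'
#' @param features list of \code{rhythm_features} (or a numeric matrix with
#'   8 columns).
#' @param labels logical vector, \code{TRUE} = rhythmic.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   max absolute weight change.
#' @return object of class \code{rhythm_classifier}: \code{intercept},
#'   \code{weights}, \code{center}, \code{scale}.
#' @export
train_classifier <- function(features, labels, max_iter = 100, tol = 1e-8) {
  X <- features_matrix(features)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("both classes must be present in labels")
  if (nrow(X) != length(y)) stop("features/labels length mismatch")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1          # constant feature carries no information
  Z <- cbind(1, sweep(sweep(X, 2, ctr), 2, scl, "/"))
  beta <- rep(0, ncol(Z))
  ridge <- diag(1e-6, ncol(Z))
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- plogis_safe(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(Z, Z * w) + ridge
    beta_new <- solve(H, crossprod(Z, w * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  structure(list(intercept = beta[1], weights = drop(beta[-1]),
                 center = ctr, scale = scl),
            class = "rhythm_classifier")
}

plogis_safe <- function(eta) 1 / (1 + exp(-pmin(pmax(eta, -30), 30)))

features_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  if (inherits(features, "rhythm_features")) features <- list(features)
  do.call(rbind, lapply(features, function(f)
    if (is.numeric(f)) f else f$x))
}

classifier_logit <- function(model, x) {
  z <- (x - model$center) / model$scale
  model$intercept + sum(model$weights * z)
}

#' Classify one gene as rhythmic or arrhythmic
#'
#' @param model a \code{rhythm_classifier}.
#' @param feats a \code{rhythm_features} (or numeric length-8 vector).
#' @param fit_A pseudo-sine fit of the replicate mean supplying period,
#'   phase and amplitude; taken from \code{feats} when omitted.
#' @return list of class \code{rhythm_call}: \code{probability},
#'   \code{is_rhythmic} (strictly \code{probability > 0.5}), \code{period},
#'   \code{phase}, \code{amplitude}, \code{l2_error}.
#' @export
classify <- function(model, feats, fit_A = NULL) {
  x <- if (is.numeric(feats)) feats else feats$x
  if (length(x) != length(model$weights))
    stop("feature count does not match classifier")
  if (is.null(fit_A) && !is.numeric(feats)) fit_A <- feats$fit_A
  p <- plogis_safe(classifier_logit(model, x))
  structure(list(
    probability = p,
    is_rhythmic = p > 0.5,
    period = if (!is.null(fit_A)) fit_A$params$period else NA_real_,
    phase = if (!is.null(fit_A)) fit_A$params$phi1 else NA_real_,
    amplitude = if (!is.null(fit_A)) fit_A$params$A else NA_real_,
    l2_error = if (!is.null(fit_A)) fit_A$l2_error else NA_real_
  ), class = "rhythm_call")
}

#' Screen a dataset for rhythmic genes
#'
#' Computes features and a rhythmicity call for every gene.  Per-gene
#' failures are flagged (column \code{failed}) and never abort the screen.
#' The normalized amplitude is the fitted amplitude divided by the standard
#' deviation of the detrended replicate-mean series.
#'
#' @param ds an \code{\link{expression_dataset}}.
#' @param model a trained \code{rhythm_classifier}.
#' @param cfg a \code{\link{dyde_config}}.
#' @return data.frame with columns gene, prob, is_rhythmic, period_h,
#'   phase_rad, amplitude, amplitude_norm, l2_error, failed; attribute
#'   \code{summary} holds counts and the period mean/sd over rhythmic genes.
#' @export
rhythm_screen <- function(ds, model, cfg = dyde_config()) {
  empty <- data.frame(gene = character(0), prob = numeric(0),
                      is_rhythmic = logical(0), period_h = numeric(0),
                      phase_rad = numeric(0), amplitude = numeric(0),
                      amplitude_norm = numeric(0), l2_error = numeric(0),
                      failed = logical(0))
  if (!length(ds$gene_ids)) {
    attr(empty, "summary") <- list(n_genes = 0L, n_rhythmic = 0L,
                                   period_mean_h = NA, period_sd_h = NA)
    return(empty)
  }
  rows <- lapply(ds$gene_ids, function(g) {
    reps <- rbind(ds$values[g, , , drop = TRUE])
    out <- tryCatch({
      fe <- compute_features(reps, ds$times, cfg)
      call <- classify(model, fe)
      s <- sd(detrend(colMeans(reps), ds$times))
      data.frame(gene = g, prob = call$probability,
                 is_rhythmic = call$is_rhythmic, period_h = call$period,
                 phase_rad = call$phase, amplitude = call$amplitude,
                 amplitude_norm = if (s > 0) call$amplitude / s else 0,
                 l2_error = call$l2_error, failed = FALSE)
    }, error = function(e)
      data.frame(gene = g, prob = NA_real_, is_rhythmic = FALSE,
                 period_h = NA_real_, phase_rad = NA_real_,
                 amplitude = NA_real_, amplitude_norm = NA_real_,
                 l2_error = NA_real_, failed = TRUE))
    out
  })
  tab <- do.call(rbind, rows)
  rhythmic <- tab$is_rhythmic & !tab$failed
  attr(tab, "summary") <- list(
    n_genes = nrow(tab), n_rhythmic = sum(rhythmic),
    period_mean_h = if (any(rhythmic)) mean(tab$period_h[rhythmic]) else NA,
    period_sd_h = if (sum(rhythmic) > 1) sd(tab$period_h[rhythmic]) else NA)
  tab
}

#' Save / load a trained classifier as JSON
#'
#' @param model a \code{rhythm_classifier}.
#' @param path JSON file path.
#' @return \code{path} (save) or the restored model (load).
#' @export
save_classifier <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m[c("intercept", "weights", "center", "scale")],
            class = "rhythm_classifier")
}
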