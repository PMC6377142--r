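#' First-order link model
#'
#' Continuous-time SISO model \eqn{dy/dt = a u(t) - b y + c} between a
#' regulator series \eqn{u} and a target series \eqn{y}.  The transfer
#' function is \eqn{P(s) = a/(s+b)}; \code{c} (constant offset) and
#' \code{x0} (initial output) are operating-point terms excluded from
#' \eqn{P(s)}.  \code{b > 0} flags a stable (decaying) link.
#'
#' @param a input gain (output units per input unit per hour).
#' @param b decay rate (1/h); may be negative (unstable link).
#' @param c_ constant offset (output units per hour).
#' @param x0 initial output value.
#' @param fitness_pct optional goodness of fit (percent).
#' @return object of class \code{first_order_model}.
#' @export
first_order_model <- function(a, b, c_ = 0, x0 = 0, fitness_pct = NA_real_) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c_), is.finite(x0))
  structure(list(a = a, b = b, c = c_, x0 = x0,
                 fitness_pct = fitness_pct, stable = b > 0),
            class = "first_order_model")
}

#' @export
print.first_order_model <- function(x, ...) {
  cat(sprintf(
    "first_order_model: dy/dt = %.4g u - %.4g y + %.4g, x0 = %.4g%s%s\n",
    x$a, x$b, x$c, x$x0,
    if (is.na(x$fitness_pct)) "" else sprintf(", fitness %.1f%%", x$fitness_pct),
    if (x$stable) "" else " [unstable]"))
  invisible(x)
}

#' Simulate a first-order model
#'
#' Integrates \eqn{dy/dt = a u(t) - b y + c} from \code{y(times[1]) = x0}
#' using the exact solution of the linear ODE on each sampling interval,
#' with the input linearly interpolated between samples (first-order hold,
#' the default) or held constant (zero-order hold).
#'
#' @param model a \code{\link{first_order_model}}.
#' @param u input series sampled at \code{times}.
#' @param times uniform time grid (hours).
#' @param hold \code{"foh"} or \code{"zoh"}.
#' @return simulated output at \code{times}.
#' @export
simulate_first_order <- function(model, u, times, hold = c("foh", "zoh")) {
  hold <- match.arg(hold)
  if (length(u) != length(times)) stop("u/times length mismatch")
  dt <- check_uniform_grid(times)
  cpp_simulate_foh(model$a, model$b, model$c, model$x0, as.numeric(u), dt,
                   hold == "foh")
}

#' Goodness of fit of a simulated output
#'
#' \code{100 * (1 - ||y - yhat|| / ||y - mean(y)||)} (normalized root mean
#' square error form, as in the MATLAB \code{compare} convention);
#' \code{root = FALSE} gives the squared-norm variant.  100 is a perfect
#' reproduction; the value is unbounded below.
#'
#' @param y observed series (non-constant).
#' @param yhat simulated series of equal length.
#' @param root use the root (NRMSE) form.
#' @return fitness in percent.
#' @export
fitness <- function(y, yhat, root = TRUE) {
  if (length(y) != length(yhat)) stop("y/yhat length mismatch")
  if (length(y) < 2) stop("fitness needs at least 2 points")
  den2 <- sum((y - mean(y))^2)
  if (den2 == 0) stop("fitness undefined for a constant observed series")
  num2 <- sum((y - yhat)^2)
  if (root) 100 * (1 - sqrt(num2 / den2)) else 100 * (1 - num2 / den2)
}

#' Initial parameter guess by forward-difference regression
#'
#' Linear least squares on \eqn{(y_{k+1}-y_k)/\Delta t \approx a u_k - b y_k + c};
#' \code{x0 = y[1]}.  Deterministic.  A rank-deficient regressor (e.g.
#' constant \code{u} and \code{y}) yields a flagged degenerate guess.
#'
#' @param u,y input and output series on the same uniform grid.
#' @param times time grid (hours), at least 4 points.
#' @return list \code{(a, b, c, x0, degenerate)}.
#' @export
initialize_params <- function(u, y, times) {
  if (length(y) < 4) stop("initialize_params needs at least 4 points")
  dt <- check_uniform_grid(times)
  n <- length(y)
  dy <- diff(y) / dt
  X <- cbind(u = u[-n], negy = -y[-n], const = 1)
  th <- suppressWarnings(qr.coef(qr(X), dy))   # NA for collinear columns
  degenerate <- is.na(th[2])                   # decay rate unidentifiable
  list(a = if (is.na(th[1])) 0 else unname(th[1]),
       b = if (degenerate) 0.1 else unname(th[2]),
       c = if (is.na(th[3])) mean(dy) else unname(th[3]),
       x0 = y[1], degenerate = degenerate)
}

# simulation-error RSS for fixed decay rate b, with (a, c, x0) profiled out
# by linear least squares (variable projection).  Returns list(rss, theta).
profile_b <- function(b, u, y, dt, foh) {
  B <- cpp_sim_basis(b, u, dt, foh)
  if (!all(is.finite(B))) return(list(rss = Inf, theta = c(0, 0, 0)))
  th <- tryCatch(qr.coef(qr(B), y), error = function(e) NULL)
  if (is.null(th) || anyNA(th)) {
    # rank-deficient basis (e.g. constant u): drop x0 redundancy gracefully
    th0 <- tryCatch(qr.solve(crossprod(B) + diag(1e-10, 3), crossprod(B, y)),
                    error = function(e) NULL)
    if (is.null(th0)) return(list(rss = Inf, theta = c(0, 0, 0)))
    th <- drop(th0)
  }
  r <- y - drop(B %*% th)
  list(rss = sum(r * r), theta = unname(th))
}

#' Fit a first-order model to a gene pair
#'
#' Minimizes the simulation-error sum of squares over \code{(a, b, c, x0)}.
#' Because the simulated output is linear in \code{(a, c, x0)} for a fixed
#' decay rate, those three parameters are profiled out in closed form and
#' the optimization reduces to one dimension in \code{b} (bounded to
#' \code{[-100, 100]} 1/h).  Local searches start from the
#' forward-difference initial guess plus \code{n_restarts} seeded random
#' decay rates; the best solution over all starts is returned.
#'
#' @param u,y regulator and target series on the same uniform grid.
#' @param times time grid (hours), at least 6 points.
#' @param cfg a \code{\link{dyde_config}} (hold convention, restarts,
#'   fitness form).
#' @param seed integer seed for the random restarts; defaults to
#'   \code{cfg$rng_seed}.
#' @return a \code{\link{first_order_model}} with \code{fitness_pct} set.
#' @export
fit_first_order <- function(u, y, times, cfg = dyde_config(),
                            seed = cfg$rng_seed) {
  if (length(u) != length(y) || length(y) != length(times))
    stop("u, y and times must have equal length")
  if (length(y) < 6) stop("fit_first_order needs at least 6 points")
  dt <- check_uniform_grid(times)
  foh <- cfg$input_hold == "foh"
  u <- as.numeric(u); y <- as.numeric(y)

  b_lo <- if (isTRUE(cfg$stable_fits)) 1e-3 else -100
  init <- initialize_params(u, y, times)
  starts <- clamp(init$b, b_lo, 100)
  if (cfg$n_restarts > 0) {
    starts <- c(starts,
                clamp(with_seed(seed, runif(cfg$n_restarts, -2, 2)), b_lo, 100))
  }
  # the profiled landscape in b can be multimodal with a narrow global
  # basin; a deterministic coarse scan locates candidate basins, which the
  # local optimizer then refines
  grid <- c(seq(-3, 3, length.out = 121),
            c(-1, 1) %o% c(5, 10, 25, 50, 90))
  grid <- grid[grid >= b_lo]
  obj <- function(b) {
    r <- profile_b(b, u, y, dt, foh)$rss
    if (!is.finite(r)) 1e300 else r
  }
  cand <- unique(c(starts, grid))
  vals <- vapply(cand, obj, 1)
  starts <- cand[order(vals)][seq_len(min(10, length(cand)))]
  best <- list(value = Inf, b = starts[1])
  for (b0 in starts) {
    o <- tryCatch(
      optim(b0, obj, method = "L-BFGS-B", lower = b_lo, upper = 100,
            control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(o) && is.finite(o$value) && o$value < best$value)
      best <- list(value = o$value, b = o$par)
  }
  if (!is.finite(best$value))
    stop("fit_first_order: optimizer failed to converge from every start")
  pr <- profile_b(best$b, u, y, dt, foh)
  m <- first_order_model(pr$theta[1], best$b, pr$theta[2], pr$theta[3])
  yhat <- simulate_first_order(m, u, times, cfg$input_hold)
  m$fitness_pct <- fitness(y, yhat, cfg$fitness_root)
  m
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# evaluate expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}
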