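# ---- reversed-sigmoid fat-front model ----------------------------------

#' Fat-front parameters
#'
#' Parametric form of the fat-infiltrating front: fat fraction along
#' relative muscle length `x` (0 = distal end, 1 = proximal end) follows a
#' reversed logistic,
#' `FF(x) = pi_base + (pi_top - pi_base) / (1 + exp((x - x0) / w))`,
#' i.e. a high distal plateau `pi_top` falling to a spared proximal plateau
#' `pi_base` across a transition centred at `x0` (the front position, the
#' half-maximum point) with width `w`. The front may sit beyond the muscle
#' ends (`x0` in `[-0.5, 1.5]`), which renders fully spared or fully
#' infiltrated muscles.
#'
#' @param pi_top distal plateau fat fraction (percent).
#' @param pi_base proximal plateau fat fraction (percent),
#'   `0 <= pi_base <= pi_top <= 100`.
#' @param x0 front position in relative length, in `[-0.5, 1.5]`.
#' @param w front width in relative length, `> 0`; larger values give the
#'   shallower slopes seen at higher overall fat content.
#' @return An object of class `front_params`.
#' @export
front_params <- function(pi_top, pi_base, x0, w) {
  if (!(pi_base >= 0 && pi_top >= pi_base && pi_top <= 100)) {
    stop("need 0 <= pi_base <= pi_top <= 100", call. = FALSE)
  }
  if (!is.finite(w) || w <= 0) stop("front width w must be > 0", call. = FALSE)
  if (x0 < -0.5 || x0 > 1.5) {
    stop("front position x0 must lie in [-0.5, 1.5]", call. = FALSE)
  }
  structure(list(pi_top = pi_top, pi_base = pi_base, x0 = x0, w = w),
            class = "front_params")
}

#' Evaluate the fat-front model
#'
#' @param params a [front_params()].
#' @param x relative positions in `[0, 1]` (vectorized).
#' @return fat fractions (percent), strictly decreasing in `x`.
#' @examples
#' p <- front_params(80, 5, 0.5, 0.05)
#' eval_front(p, 0.5)  # midpoint: (80 + 5) / 2
#' @export
eval_front <- function(params, x) {
  stopifnot(inherits(params, "front_params"))
  if (any(x < -1e-9 | x > 1 + 1e-9)) {
    stop("x must lie in [0, 1]", call. = FALSE)
  }
  params$pi_base + (params$pi_top - params$pi_base) /
    (1 + exp((x - params$x0) / params$w))
}

#' Whole-muscle mean fat fraction implied by front parameters
#'
#' Closed-form integral of the logistic front over `[0, 1]`:
#' `mean = pi_base + (pi_top - pi_base) * C(x0, w)` with coverage
#' `C = w * (log1p(exp(x0 / w)) - log1p(exp((x0 - 1) / w)))`.
#'
#' @param params a [front_params()].
#' @return percent, scalar.
#' @export
front_mean_ff <- function(params) {
  stopifnot(inherits(params, "front_params"))
  params$pi_base + (params$pi_top - params$pi_base) *
    front_coverage(params$x0, params$w)
}

# fraction of [0,1] covered by the high plateau, i.e. the integral of
# 1 / (1 + exp((x - x0)/w)) over [0, 1]; log1p form is stable for small w
front_coverage <- function(x0, w) {
  w * (log1p(exp(x0 / w)) - log1p(exp((x0 - 1) / w)))
}

#' Fit the fat-front model to a muscle profile
#'
#' Bounded nonlinear least squares of the four front parameters on the
#' per-slice fat fractions against relative position, with deterministic
#' multi-start: one data-driven start (plateaus from the profile extremes,
#' `x0` at the half-maximum crossing) plus `restarts - 1` seeded random
#' starts; the fit with the lowest RMSE wins. Internally the amplitude
#' `pi_top - pi_base` is the free parameter, so `pi_base <= pi_top` holds by
#' construction. A (near-)constant profile carries no front information:
#' the fit degenerates to the plateau-only model and is flagged
#' `converged = FALSE`.
#'
#' @param profile a [muscle_profile()] with at least 8 slices.
#' @param restarts number of starts (default 10).
#' @param seed integer seed for the random starts (mandatory for
#'   reproducibility).
#' @param bounds optional list overriding elements of the default box
#'   `list(pi_base = c(0, 100), amp = c(0, 100), x0 = c(-0.5, 1.5),
#'   w = c(1e-3, 1))`.
#' @return list of class `front_fit`: `params` ([front_params()]), `rmse`,
#'   `converged`, `n_points`.
#' @export
fit_front <- function(profile, restarts = 10, seed, bounds = list()) {
  stopifnot(inherits(profile, "muscle_profile"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (profile$n_slices < 8L) {
    stop("front fitting needs at least 8 slices", call. = FALSE)
  }
  x <- profile$relative_pos / 100
  y <- profile$ff
  b <- utils::modifyList(
    list(pi_base = c(0, 100), amp = c(0, 100), x0 = c(-0.5, 1.5),
         w = c(1e-3, 1)), bounds)

  if (stats::sd(y) < 1e-6) {
    p <- front_params(mean(y), mean(y), 0.5, 0.1)
    return(structure(list(params = p, rmse = sqrt(mean((y - mean(y))^2)),
                          converged = FALSE, n_points = length(y)),
                     class = "front_fit"))
  }

  lower <- c(b$pi_base[1], b$amp[1], b$x0[1], b$w[1])
  upper <- c(b$pi_base[2], b$amp[2], b$x0[2], b$w[2])
  clamp <- function(v) pmin(pmax(v, lower + 1e-9), upper - 1e-9)

  # data-driven start: x0 at the half-maximum crossing
  ymax <- max(y); ymin <- min(y)
  half <- (ymax + ymin) / 2
  x0g <- x[which.min(abs(y - half))]
  starts <- list(clamp(c(ymin, ymax - ymin, x0g, 0.1)))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (i in seq_len(max(0L, restarts - 1L))) {
    starts[[i + 1L]] <- clamp(c(
      stats::runif(1, 0, ymin + 1),
      stats::runif(1, max(1, ymax - ymin - 5), min(100, ymax - ymin + 20)),
      stats::runif(1, -0.3, 1.3),
      exp(stats::runif(1, log(0.01), log(0.5)))))
  }

  best <- NULL
  dat <- data.frame(x = x, y = y)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ base + amp / (1 + exp((x - x0) / w)),
        data = dat,
        start = list(base = st[1], amp = st[2], x0 = st[3], w = st[4]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rmse <- sqrt(mean(stats::residuals(fit)^2))
    if (is.null(best) || rmse < best$rmse) {
      cf <- stats::coef(fit)
      best <- list(cf = cf, rmse = rmse)
    }
  }
  if (is.null(best)) {
    p <- front_params(mean(y), mean(y), 0.5, 0.1)
    return(structure(list(params = p, rmse = stats::sd(y),
                          converged = FALSE, n_points = length(y)),
                     class = "front_fit"))
  }
  cf <- best$cf
  p <- front_params(pi_top = min(cf[["base"]] + cf[["amp"]], 100),
                    pi_base = cf[["base"]], x0 = cf[["x0"]], w = cf[["w"]])
  structure(list(params = p, rmse = best$rmse, converged = TRUE,
                 n_points = length(y)),
            class = "front_fit")
}

#' Progression configuration for front propagation
#'
#' Phenomenological rate law for the proximal advance of the fat front:
#' the front velocity depends on the current whole-muscle fat fraction
#' through a Gaussian bell,
#' `v(FF) = v_max * exp(-((FF - mu_v) / s_v)^2)`,
#' peaking at intermediate severity (defaults `mu_v = 35`%, `s_v = 20`%) so
#' progression is fastest in the 30-40% whole-muscle bin, and the width
#' grows linearly (`dw` per year), flattening the slope as infiltration
#' advances.
#'
#' @param v_max peak front velocity, relative length per year.
#' @param mu_v whole-muscle fat fraction (percent) of peak velocity.
#' @param s_v bell width (percentage points).
#' @param dw front-width growth per year (relative length / year).
#' @return list of class `progression_config`.
#' @export
progression_config <- function(v_max = 0.04, mu_v = 35, s_v = 20,
                               dw = 0.02) {
  stopifnot(v_max >= 0, s_v > 0, dw >= 0)
  structure(list(v_max = v_max, mu_v = mu_v, s_v = s_v, dw = dw),
            class = "progression_config")
}

#' Propagate a fat front forward in time
#'
#' Advances the front position by `v(FF_whole) * years`, with the velocity
#' evaluated at the whole-muscle fat fraction implied by the current
#' parameters ([front_mean_ff()]), and widens the front by `dw * years`.
#' Width growth is mean-conserving: after widening, the front position is
#' re-solved so the whole-muscle fat fraction equals the value reached by
#' the advance alone. Flattening the slope therefore never regresses the
#' infiltration — disease progression is monotone — and when `dw = 0` the
#' position advance is exactly `v * years`. If the front has saturated the
#' proximal end, width growth is capped at the largest value that can still
#' carry the attained mean.
#'
#' @param params a [front_params()].
#' @param years non-negative follow-up interval.
#' @param rate_law a [progression_config()].
#' @return The propagated [front_params()].
#' @export
propagate_front <- function(params, years, rate_law = progression_config()) {
  stopifnot(inherits(params, "front_params"),
            inherits(rate_law, "progression_config"))
  if (!is.finite(years) || years < 0) {
    stop("years must be non-negative", call. = FALSE)
  }
  ffw <- front_mean_ff(params)
  v <- rate_law$v_max * exp(-((ffw - rate_law$mu_v) / rate_law$s_v)^2)
  x0_adv <- min(params$x0 + v * years, 1.5)
  w_new <- params$w + rate_law$dw * years
  cstar <- front_coverage(x0_adv, params$w)   # coverage after the advance
  if (w_new > params$w) {
    if (front_coverage(1.5, w_new) < cstar) {
      # saturated front: cap widening so the mean is still attainable
      f <- function(ww) front_coverage(1.5, ww) - cstar
      w_new <- if (f(params$w) <= 0) params$w else
        stats::uniroot(f, c(params$w, w_new), tol = 1e-12)$root
    }
  }
  x0_new <- if (w_new <= params$w + 1e-15) {
    x0_adv
  } else {
    clo <- front_coverage(-0.5, w_new)
    chi <- front_coverage(1.5, w_new)
    cc <- min(max(cstar, clo), chi)
    stats::uniroot(function(x) front_coverage(x, w_new) - cc,
                   c(-0.5, 1.5), tol = 1e-12)$root
  }
  front_params(pi_top = params$pi_top, pi_base = params$pi_base,
               x0 = x0_new, w = w_new)
}
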