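#' Dose-response dataset
#'
#' Container tying a beam label to measured doses and responses. Responses
#' are either surviving fractions N/N0 (CFU of treated over control) or a
#' release-ratio statistic (the SERS Ca2+-DPA/Phe intensity ratio). Optional
#' CFU counts (`n`, `n0`) accompany survival data and enable Poisson-count
#' fitting where the log-ratio is undefined (zero survivors).
#'
#' @param ion Beam label.
#' @param doses Delivered doses (Gy), non-negative.
#' @param responses Measured responses, same length as `doses`; survival
#'   responses must be non-negative.
#' @param response_kind `"survival"` or `"release_ratio"`.
#' @param n,n0 Optional CFU counts per dose (treated, control).
#' @param meta Optional named list of annotations (e.g. generator truth).
#' @return An object of class `"dose_response"`.
#' @export
dose_response <- function(ion, doses, responses,
                          response_kind = c("survival", "release_ratio"),
                          n = NULL, n0 = NULL, meta = list()) {
  response_kind <- match.arg(response_kind)
  doses <- as.numeric(doses); responses <- as.numeric(responses)
  if (length(doses) != length(responses))
    stop("doses and responses must have equal length", call. = FALSE)
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  if (response_kind == "survival" && any(responses < 0))
    stop("survival responses must be non-negative", call. = FALSE)
  if (!is.null(n)) {
    if (is.null(n0)) stop("counts need both n and n0", call. = FALSE)
    if (length(n) != length(doses) ||
        (length(n0) != 1L && length(n0) != length(doses)))
      stop("counts must match doses in length", call. = FALSE)
    if (any(n0 <= 0)) stop("n0 must be positive", call. = FALSE)
    n0 <- rep_len(as.numeric(n0), length(doses))
  }
  structure(list(ion = ion, doses = doses, responses = responses,
                 response_kind = response_kind,
                 n = if (is.null(n)) NULL else as.numeric(n), n0 = n0,
                 meta = meta),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> %s, %d points, kind = %s\n",
              x$ion, length(x$doses), x$response_kind))
  invisible(x)
}

#' Erlang/Poisson hit probability
#'
#' Probability of exactly `k` hit events in a sensitive target when the
#' expected number of events is \eqn{\Phi/\lambda}:
#' \eqn{P_k(\Phi) = (\Phi/\lambda)^k e^{-\Phi/\lambda} / k!}. Survival is the
#' zero-event probability (`k = 0`) and single-event activation (Ca2+-DPA
#' release) is `k = 1`, which peaks at \eqn{\Phi = \lambda}.
#'
#' @param phi Equivalent dose(s) \eqn{\Phi} (Gy), non-negative (vectorized).
#' @param k Event count, non-negative integer.
#' @param lambda_gy Dose scale \eqn{\lambda} (Gy, mean dose per event); `> 0`.
#' @return Probabilities in `[0, 1]`.
#' @examples
#' erlang_hit_probability(258, 0, 258)  # exp(-1)
#' @export
erlang_hit_probability <- function(phi, k, lambda_gy) {
  if (!is.numeric(phi) || any(phi < 0))
    stop("phi must be non-negative", call. = FALSE)
  if (!is.numeric(lambda_gy) || lambda_gy <= 0)
    stop("lambda_gy must be positive", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k != round(k))
    stop("k must be a non-negative integer", call. = FALSE)
  mu <- phi / lambda_gy
  # log-space evaluation; k = 0 at phi = 0 handled by the 0*log(0) := 0 limit
  out <- numeric(length(mu))
  zero <- mu == 0
  out[zero] <- if (k == 0) 1 else 0
  if (any(!zero))
    out[!zero] <- exp(k * log(mu[!zero]) - mu[!zero] - lgamma(k + 1))
  out
}

#' Model curves: survival and release
#'
#' `survival_curve()` is the zero-event probability
#' \eqn{P_0(\Phi) = e^{-\Phi/\lambda}}, strictly decreasing in dose.
#' `release_curve()` is the single-event response
#' \eqn{b + A (\Phi/\lambda) e^{-\Phi/\lambda}}: baseline `b` at zero dose
#' (a little Ca2+-DPA is detectable even untreated), unique maximum
#' \eqn{b + A e^{-1}} at the threshold dose \eqn{\Phi = \lambda}.
#'
#' @param phi Equivalent dose(s) (Gy).
#' @param lambda_gy Dose scale \eqn{\lambda} (Gy).
#' @param amplitude Response scale \eqn{A \ge 0}.
#' @param baseline Offset \eqn{b}.
#' @return Predicted response(s).
#' @export
survival_curve <- function(phi, lambda_gy) {
  erlang_hit_probability(phi, 0, lambda_gy)
}

#' @rdname survival_curve
#' @export
release_curve <- function(phi, lambda_gy, amplitude = 1, baseline = 0) {
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  baseline + amplitude * erlang_hit_probability(phi, 1, lambda_gy)
}

new_hit_fit <- function(k, lambda_gy, amplitude, baseline, lambda_se,
                        covariance = NULL, residual_ss = NA_real_,
                        diagnostics = list()) {
  structure(list(k = k, lambda_gy = lambda_gy, amplitude = amplitude,
                 baseline = baseline, lambda_se = lambda_se,
                 covariance = covariance, residual_ss = residual_ss,
                 diagnostics = diagnostics),
            class = "hit_fit")
}

#' @export
print.hit_fit <- function(x, ...) {
  cat(sprintf("<hit_fit> k = %d, lambda = %.4g Gy (se %.3g)\n",
              x$k, x$lambda_gy, x$lambda_se))
  if (x$k == 1)
    cat(sprintf("  amplitude = %.4g, baseline = %.4g\n",
                x$amplitude, x$baseline))
  invisible(x)
}

#' Fit the zero-event survival model
#'
#' Estimates \eqn{\lambda} for \eqn{N/N_0 = e^{-\Phi/\lambda}} by no-intercept
#' least squares of \eqn{\ln(N/N_0)} on \eqn{\Phi} (the model forces
#' \eqn{N/N_0 = 1} at zero dose, so there is no free amplitude):
#' \eqn{\hat\lambda = -1/\hat\beta} with
#' \eqn{\hat\beta = \sum \Phi y / \sum \Phi^2}. The standard error follows
#' from regression theory via the delta method. Exactly-zero responses carry
#' no log-scale information and are excluded (reported in diagnostics);
#' with `method = "poisson"` and counts present, a Poisson log-linear count
#' model with offset \eqn{\log N_0} uses them instead.
#'
#' @param data A [dose_response()] with `response_kind = "survival"` and at
#'   least 2 distinct positive-response doses.
#' @param beam,reference Optional [ion_beam()] pair; when both are given,
#'   doses are converted to reference-equivalent \eqn{\Phi} before fitting.
#' @param method `"loglinear"` (default) or `"poisson"` (requires counts).
#' @return A `"hit_fit"` with `k = 0`.
#' @export
fit_survival <- function(data, beam = NULL, reference = NULL,
                         method = c("loglinear", "poisson")) {
  stopifnot(inherits(data, "dose_response"))
  method <- match.arg(method)
  if (data$response_kind != "survival")
    stop("fit_survival needs a survival dataset", call. = FALSE)
  phi <- data$doses
  if (!is.null(beam) && !is.null(reference))
    phi <- equivalent_dose(phi, beam, reference)

  if (method == "poisson") {
    if (is.null(data$n))
      stop("poisson method requires CFU counts", call. = FALSE)
    fit <- stats::glm(data$n ~ 0 + phi, family = stats::poisson(),
                      offset = log(data$n0))
    slope <- stats::coef(fit)[["phi"]]
    if (slope >= 0)
      stop("non-identifiable: no decay with dose", call. = FALSE)
    se_slope <- sqrt(stats::vcov(fit)[1, 1])
    lambda <- -1 / slope
    return(new_hit_fit(0L, lambda, 1, 0,
                       lambda_se = se_slope / slope^2,
                       residual_ss = sum(stats::residuals(fit)^2),
                       diagnostics = list(method = "poisson")))
  }

  keep <- data$responses > 0
  dropped <- sum(!keep)
  y <- log(data$responses[keep]); x <- phi[keep]
  if (length(unique(x)) < 2)
    stop("insufficient data: need >= 2 distinct doses with positive responses",
         call. = FALSE)
  sxx <- sum(x^2)
  slope <- sum(x * y) / sxx
  if (slope >= 0)
    stop("non-identifiable: responses do not decay with dose", call. = FALSE)
  res <- y - slope * x
  dfree <- length(x) - 1L
  se_slope <- if (dfree > 0) sqrt(sum(res^2) / dfree / sxx) else 0
  lambda <- -1 / slope
  new_hit_fit(0L, lambda, 1, 0,
              lambda_se = se_slope / slope^2,
              covariance = matrix(se_slope^2, dimnames = list("slope", "slope")),
              residual_ss = sum(res^2),
              diagnostics = list(method = "loglinear",
                                 dropped_zero_responses = dropped,
                                 n_used = length(x)))
}

#' Fit the single-event release model
#'
#' Least-squares fit of [release_curve()] \eqn{b + A (\Phi/\lambda)
#' e^{-\Phi/\lambda}} to a release-ratio dose series by bounded
#' Levenberg-Marquardt, multistarted over a log-spaced \eqn{\lambda} grid
#' (the curve is unimodal but its flat high-dose tail creates local minima).
#' \eqn{\lambda} is bounded below by `min(positive dose)/4`; a solution
#' pinned at that bound is flagged in the diagnostics, which happens when the
#' data are monotone decreasing with no interior maximum.
#'
#' @param data A [dose_response()] with `response_kind = "release_ratio"` and
#'   at least 3 distinct doses.
#' @param beam,reference Optional beams for equivalent-dose conversion.
#' @param n_starts Number of log-spaced lambda starting values.
#' @return A `"hit_fit"` with `k = 1`, Gaussian-approximation standard error
#'   from the Jacobian, and convergence diagnostics.
#' @export
fit_release <- function(data, beam = NULL, reference = NULL, n_starts = 10) {
  stopifnot(inherits(data, "dose_response"))
  if (data$response_kind != "release_ratio")
    stop("fit_release needs a release_ratio dataset", call. = FALSE)
  phi <- data$doses
  if (!is.null(beam) && !is.null(reference))
    phi <- equivalent_dose(phi, beam, reference)
  y <- data$responses
  if (length(unique(phi)) < 3)
    stop("insufficient data: need >= 3 distinct doses", call. = FALSE)

  pos <- phi[phi > 0]
  lam_lo <- min(pos) / 4
  lam_hi <- max(phi)
  starts <- exp(seq(log(lam_lo), log(lam_hi), length.out = n_starts))
  span <- max(y) - min(y)

  resid_fn <- function(p) y - (p[3] + p[2] * (phi / p[1]) * exp(-phi / p[1]))
  lower <- c(lam_lo, 0, -Inf)
  upper <- c(lam_hi * 4, Inf, Inf)
  best <- NULL
  for (lam0 in starts) {
    a0 <- max(span * exp(1), 1e-8)
    b0 <- min(y)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(lam0, a0, b0), lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info == 0) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("fit failure: no multistart converged (", n_starts, " starts, ",
         "lambda grid [", signif(lam_lo, 4), ", ", signif(lam_hi, 4), "] Gy)",
         call. = FALSE)

  co <- best$fit$par
  names(co) <- c("lam", "a", "b")
  dfree <- length(y) - 3L
  vc <- tryCatch({
    jtj <- best$fit$hessian          # J'J at the optimum
    v <- solve(jtj) * best$rss / max(dfree, 1L)
    dimnames(v) <- list(names(co), names(co))
    v
  }, error = function(e) NULL)
  lam_se <- if (!is.null(vc)) sqrt(vc["lam", "lam"]) else NA_real_
  pinned <- co[["lam"]] <= lam_lo * (1 + 1e-6)
  new_hit_fit(1L, co[["lam"]], co[["a"]], co[["b"]],
              lambda_se = lam_se, covariance = vc, residual_ss = best$rss,
              diagnostics = list(method = "nlsLM multistart",
                                 n_starts = n_starts,
                                 lambda_at_lower_bound = pinned,
                                 lambda_bounds = c(lam_lo, lam_hi * 4)))
}

#' Threshold dose of the single-event response
#'
#' The k = 1 release curve peaks at \eqn{\Phi = \lambda}: the fitted dose
#' scale is the release-threshold dose (about 258 Gy Fe-equivalent in the
#' spore experiments this package models).
#'
#' @param fit A `"hit_fit"` with `k = 1`.
#' @return Threshold dose (Gy).
#' @export
threshold_dose <- function(fit) {
  stopifnot(inherits(fit, "hit_fit"))
  if (fit$k != 1L)
    stop("invalid model: threshold is defined for k = 1 fits", call. = FALSE)
  fit$lambda_gy
}

#' Bootstrap percentile interval for lambda
#'
#' Case-resampling bootstrap over dose-response points: rows are resampled
#' with replacement, the fitter is re-run, and the percentile interval of the
#' resampled \eqn{\hat\lambda} values is returned. Deterministic for a fixed
#' seed.
#'
#' @param data A [dose_response()] with at least 3 points.
#' @param fitter Fitting function mapping a `dose_response` to a `hit_fit`
#'   (e.g. [fit_survival()] or [fit_release()]).
#' @param n_boot Number of resamples; `>= 100`.
#' @param seed Integer RNG seed.
#' @param level Confidence level (default 0.95).
#' @return List with `lower`, `upper`, `lambda_boot` (successful resample
#'   estimates) and `n_failed`.
#' @export
bootstrap_ci <- function(data, fitter = fit_survival, n_boot = 1000,
                         seed = 20220116, level = 0.95) {
  stopifnot(inherits(data, "dose_response"))
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  m <- length(data$doses)
  if (m < 3) stop("insufficient data: need >= 3 points", call. = FALSE)
  lam <- numeric(n_boot)
  failed <- 0L
  # private RNG stream; does not disturb the caller's RNG state
  lam <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(m, m, replace = TRUE)
      boot <- dose_response(data$ion, data$doses[idx], data$responses[idx],
                            data$response_kind,
                            n = data$n[idx], n0 = data$n0[idx])
      tryCatch(fitter(boot)$lambda_gy, error = function(e) NA_real_)
    }, numeric(1))
  })
  failed <- sum(is.na(lam))
  lam_ok <- lam[!is.na(lam)]
  if (length(lam_ok) < n_boot / 2)
    stop("bootstrap failure: more than half the resamples failed to fit",
         call. = FALSE)
  alpha <- (1 - level) / 2
  qs <- stats::quantile(lam_ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(lower = qs[1], upper = qs[2], lambda_boot = lam_ok, n_failed = failed)
}
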