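#' @title Four-parameter logistic dose-response fitting
#' @description Normalised activity (e.g. the exposure/baseline MBR ratio)
#' against dose is fitted with the four-parameter logistic
#' `R(d) = floor + (ceiling - floor) / (1 + (d / d50)^h)` by nonlinear
#' least squares (Levenberg-Marquardt, five deterministic starts).
#' Concentration fits run on log10 dose, physical-dose (SAR) fits on
#' linear dose. A Pearson-type lack-of-fit statistic against within-dose
#' replicate scatter provides a goodness-of-fit p-value.
#' @name dose_response
NULL

#' Simulate a dose-response panel of normalised MBR values
#'
#' Draws replicate normalised-MBR observations from a reference logistic
#' dose model with multiplicative log-normal noise. The built-in `agonist`
#' model emulates a GABA-A agonist concentration series (half-effect at
#' 0.25 uM, Hill slope 1.5, full suppression at high dose, 14 recordings
#' across 8 concentrations); the `sar` model emulates an RF power series
#' (half-effect at 28.6 W/kg with a steep slope so that inhibition only
#' becomes apparent above ~25 W/kg; at dose 0 the expected ratio is 1).
#'
#' @param type `"agonist"` or `"sar"`.
#' @param seed Integer seed.
#' @param noise_sd Multiplicative (log-scale) noise sd.
#' @param doses Dose levels; defaults per `type`.
#' @param n_per_dose Replicates per dose; defaults per `type`.
#' @param d50 True half-effect dose; defaults per `type`.
#' @param hill True Hill slope; defaults per `type`.
#' @return data.frame with `dose`, `replicate`, `R` and attribute `truth`.
#' @export
simulate_dose_panel <- function(type = c("agonist", "sar"), seed = 1,
                                noise_sd = 0.05, doses = NULL,
                                n_per_dose = NULL, d50 = NULL, hill = NULL) {
  type <- match.arg(type)
  if (type == "agonist") {
    if (is.null(doses)) doses <- c(1e-4, 0.1, 0.2, 0.25, 0.3, 0.4, 0.5, 1)
    if (is.null(n_per_dose)) n_per_dose <- c(2, 3, 1, 2, 1, 1, 2, 2)
    if (is.null(d50)) d50 <- 0.25
    if (is.null(hill)) hill <- 1.5
  } else {
    if (is.null(doses)) doses <- c(0, 5.5, 11, 20.35, 23.1, 25.3, 28.6, 30.6)
    if (is.null(n_per_dose)) n_per_dose <- c(21, 2, 3, 2, 3, 3, 5, 3)
    if (is.null(d50)) d50 <- 28.6
    if (is.null(hill)) hill <- 8
  }
  stopifnot(length(n_per_dose) == length(doses))
  set.seed(as.integer(seed))
  d <- rep(doses, n_per_dose)
  mu <- 1 / (1 + (d / d50)^hill)
  R <- mu * exp(stats::rnorm(length(d), 0, noise_sd))
  out <- data.frame(dose = d,
                    replicate = unlist(lapply(n_per_dose, seq_len)), R = R)
  attr(out, "truth") <- c(d50 = d50, hill = hill)
  out
}

.logistic4 <- function(d, floor, ceiling, d50, hill) {
  floor <- unname(floor); ceiling <- unname(ceiling)
  d50 <- unname(d50); hill <- unname(hill)
  floor + (ceiling - floor) / (1 + (d / d50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `R(d) = floor + (ceiling - floor) /
#' (1 + (d / d50)^h)` via Levenberg-Marquardt from five deterministic
#' initialisations (d50 started at a grid of dose quantiles); the best
#' converged fit is kept. With `log_dose = TRUE` the fit runs on log10
#' dose (zero doses excluded), matching concentration-series conventions;
#' SAR fits use the linear axis.
#'
#' @param dose Dose values (>= 4 distinct).
#' @param response Normalised response values.
#' @param log_dose Fit on the log10 dose axis?
#' @param floor_fixed Optionally fix the lower plateau (e.g. 0 for full
#'   suppression at high agonist dose); default free.
#' @return Object of class `dose_response_fit` with `coefficients`
#'   (`floor`, `ceiling`, `d50`, `hill`), the underlying `nls` fit, the
#'   data, and the residual sum of squares. Methods: `print`, `coef`,
#'   `summary`, `predict`, `residuals`, `plot`.
#' @seealso [pearson_gof()], [dose_at_response()]
#' @export
fit_dose_response <- function(dose, response, log_dose = FALSE,
                              floor_fixed = NULL) {
  keep <- is.finite(dose) & is.finite(response)
  if (log_dose) keep <- keep & dose > 0
  dose <- dose[keep]; response <- response[keep]
  if (length(unique(dose)) < 4)
    stop("need at least 4 distinct doses", call. = FALSE)
  x <- if (log_dose) log10(dose) else dose
  df <- data.frame(x = x, y = response)

  lo <- stats::quantile(dose, c(0.15, 0.3, 0.5, 0.7, 0.85), names = FALSE)
  if (log_dose) lo <- log10(lo)
  fits <- list()
  for (st in lo) {
    init <- list(ceiling = max(response), d50x = st, hill = 2)
    if (is.null(floor_fixed)) init$floor <- min(response)
    form <- if (log_dose) {
      if (is.null(floor_fixed))
        y ~ floor + (ceiling - floor) / (1 + 10^(hill * (x - d50x)))
      else y ~ floor_fixed + (ceiling - floor_fixed) / (1 + 10^(hill * (x - d50x)))
    } else {
      if (is.null(floor_fixed))
        y ~ floor + (ceiling - floor) / (1 + (x / d50x)^hill)
      else y ~ floor_fixed + (ceiling - floor_fixed) / (1 + (x / d50x)^hill)
    }
    env <- list2env(list(floor_fixed = floor_fixed), parent = environment())
    f <- tryCatch(
      minpack.lm::nlsLM(form, data = df, start = init,
                        control = minpack.lm::nls.lm.control(maxiter = 200),
                        lower = {
                          lw <- c(ceiling = -Inf, d50x = if (log_dose) -Inf else 1e-12,
                                  hill = 1e-6)
                          if (is.null(floor_fixed)) c(lw, floor = -Inf) else lw
                        }),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1]] <- f
  }
  if (!length(fits))
    stop("fit error: no start converged; check dose range and response scale",
         call. = FALSE)
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- stats::coef(best)
  co <- c(floor = if (is.null(floor_fixed)) unname(cf["floor"]) else floor_fixed,
          ceiling = unname(cf["ceiling"]),
          d50 = if (log_dose) 10^unname(cf["d50x"]) else unname(cf["d50x"]),
          hill = unname(cf["hill"]))
  structure(list(coefficients = co, fit = best, log_dose = log_dose,
                 dose = dose, response = response,
                 rss = min(rss), n = length(dose)),
            class = "dose_response_fit")
}

#' @export
coef.dose_response_fit <- function(object, ...) object$coefficients

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Four-parameter logistic dose-response fit",
      if (x$log_dose) "(log10 dose axis)" else "(linear dose axis)", "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("n = %d, residual SS = %.4g\n", x$n, x$rss))
  invisible(x)
}

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$dose else newdata$dose
  co <- object$coefficients
  .logistic4(d, co["floor"], co["ceiling"], co["d50"], co["hill"])
}

#' @export
residuals.dose_response_fit <- function(object, ...) {
  object$response - predict(object)
}

#' @export
summary.dose_response_fit <- function(object, ...) {
  g <- pearson_gof(object)
  out <- list(coefficients = object$coefficients, n = object$n,
              rss = object$rss, gof = g)
  class(out) <- "summary.dose_response_fit"
  out
}

#' @export
print.summary.dose_response_fit <- function(x, ...) {
  print(round(x$coefficients, 4))
  cat(sprintf("n = %d, RSS = %.4g, Pearson GOF X2 = %.3f (df = %d), p = %.4f\n",
              x$n, x$rss, x$gof$statistic, x$gof$df, x$gof$p_value))
  invisible(x)
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  d <- x$dose; r <- x$response
  if (x$log_dose) {
    graphics::plot(d, r, log = "x", xlab = "dose", ylab = "normalized response", ...)
    dd <- 10^seq(log10(min(d)), log10(max(d)), length.out = 200)
  } else {
    graphics::plot(d, r, xlab = "dose", ylab = "normalized response", ...)
    dd <- seq(min(d), max(d), length.out = 200)
  }
  graphics::lines(dd, predict(x, list(dose = dd)))
  invisible(x)
}

#' Dose producing a given response level
#'
#' Inverts the fitted logistic: the dose at which the fitted curve equals
#' `level` (e.g. `level = 0.5` for the half-suppression dose of a
#' normalised ratio).
#'
#' @param fit A [fit_dose_response()] result.
#' @param level Response level to invert at.
#' @return Dose (same units as the fit input).
#' @export
dose_at_response <- function(fit, level = 0.5) {
  co <- coef(fit)
  num <- (co["ceiling"] - co["floor"]) / (level - co["floor"]) - 1
  if (!is.finite(num) || num <= 0) return(NA_real_)
  unname(co["d50"] * num^(1 / co["hill"]))
}

#' Pearson-type goodness-of-fit test
#'
#' Lack-of-fit chi-square: per dose level, `n_j` times the squared
#' deviation of the replicate mean from the fitted value, scaled by the
#' pure-error (within-dose replicate) variance; degrees of freedom are
#' the number of dose levels minus the number of fitted parameters.
#' A perfect fit gives statistic 0 and p = 1. The statistic is invariant
#' to rescaling of the dose axis.
#'
#' @param fit A [fit_dose_response()] result.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
pearson_gof <- function(fit) {
  d <- fit$dose; r <- fit$response
  ud <- sort(unique(d))
  if (length(ud) < 5)
    warning("fewer than 5 dose bins; goodness-of-fit p-value is unreliable")
  pred <- predict(fit, list(dose = ud))
  nj <- vapply(ud, function(u) sum(d == u), numeric(1))
  mj <- vapply(ud, function(u) mean(r[d == u]), numeric(1))
  # pure-error variance from replicated doses; residual variance fallback
  rep_idx <- nj > 1
  s2 <- if (any(rep_idx)) {
    num <- sum(vapply(ud[rep_idx], function(u) {
      v <- r[d == u]; sum((v - mean(v))^2)
    }, numeric(1)))
    num / sum(nj[rep_idx] - 1)
  } else sum(residuals(fit)^2) / max(fit$n - 4, 1)
  lack <- sum(nj * (mj - pred)^2)
  scale0 <- max(sum(nj * mj^2), 1)
  stat <- if (lack < 1e-12 * scale0) 0
  else if (s2 <= 1e-15 * scale0) Inf
  else lack / s2
  df <- max(length(ud) - 4L, 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
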