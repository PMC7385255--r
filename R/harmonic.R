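#' Predict from the annual cosine model
#'
#' `Y = b1 + b2 * cos(2*pi*t/365 + b3)`; periodic with period 365 days.
#'
#' @param params a [harmonic_params()] (or list with b1, b2, b3).
#' @param t ordinal dates (numeric vector).
#' @return predicted values.
#' @export
harmonic_predict <- function(params, t) {
  params$b1 + params$b2 * cos(2 * pi * t / 365 + params$b3)
}

#' Ordinal date of the annual maximum
#'
#' The cosine peaks where its argument is a multiple of 2*pi, i.e. at
#' `((-b3) * 365 / (2*pi)) mod 365`; a result of 0 is reported as 365.
#'
#' @param params a [harmonic_params()] with b2 > 0.
#' @return peak ordinal date in (0, 365].
#' @export
peak_date <- function(params) {
  if (params$b2 <= 0) stop("Peak date undefined for zero amplitude")
  p <- (-params$b3 * 365 / (2 * pi)) %% 365
  if (p == 0) 365 else p
}

#' Fit the annual cosine model by Levenberg-Marquardt least squares
#'
#' Nonlinear least squares via [minpack.lm::nls.lm()], started from a grid
#' of 12 equally spaced phases (with b1 = mean(y), b2 = half the data
#' range) to avoid the cosine's local optima; the best converged start is
#' kept. Standard errors come from the Gauss-Newton Hessian (J'J) at the
#' optimum scaled by the residual variance RSS/(n-3); the 95% confidence
#' band over ordinals 1..365 is a delta-method band with a t quantile on
#' n - 3 degrees of freedom. The fit is canonicalized to b2 >= 0 and b3 in
#' (-pi, pi] (a negative amplitude maps to (-b2, b3 + pi), which predicts
#' identically).
#'
#' @param t ordinal dates (values outside 1..365 are folded by calendar
#'   periodicity).
#' @param y observed values, same length, n >= 4.
#' @param n_starts number of phase starting values (default 12).
#' @return object of class `harmonic_fit`: params, se (named b1/b2/b3),
#'   peak_ordinal, rss, n, converged, identifiable (FALSE when the
#'   amplitude is indistinguishable from zero), ci_band (data.frame t,
#'   fit, lower, upper), residuals.
#' @export
fit_harmonic <- function(t, y, n_starts = 12) {
  stopifnot(length(t) == length(y))
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok] %% 365
  t[t == 0] <- 365
  y <- y[ok]
  n <- length(y)
  if (n < 4) stop("Need at least 4 points to fit 3 parameters")

  resid_fn <- function(par) y - (par[1] + par[2] * cos(2 * pi * t / 365 + par[3]))
  b1_0 <- mean(y)
  b2_0 <- diff(range(y)) / 2
  best <- NULL
  for (ph in seq(-pi, pi, length.out = n_starts + 1)[seq_len(n_starts)]) {
    fit <- try(minpack.lm::nls.lm(
      par = c(b1_0, max(b2_0, 1e-8), ph), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                           ptol = 1e-10)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("Levenberg-Marquardt failed from every start")
  par <- best$par
  converged <- best$info %in% 1:4
  # canonicalize: non-negative amplitude, phase in (-pi, pi]
  if (par[2] < 0) {
    par[2] <- -par[2]
    par[3] <- par[3] + pi
  }
  par[3] <- wrap_phase(par[3])
  rss <- sum(resid_fn(par)^2)

  # Gauss-Newton covariance at the optimum
  ang <- 2 * pi * t / 365 + par[3]
  J <- cbind(b1 = rep(1, n), b2 = cos(ang), b3 = -par[2] * sin(ang))
  s2 <- rss / (n - 3)
  JtJ <- crossprod(J)
  cov <- try(solve(JtJ) * s2, silent = TRUE)
  if (inherits(cov, "try-error") || any(!is.finite(diag(cov))))
    cov <- matrix(NA_real_, 3, 3)
  se <- sqrt(pmax(0, diag(cov)))
  names(se) <- c("b1", "b2", "b3")
  # amplitude below numerical noise (relative to the mean level) cannot be
  # distinguished from a constant model
  identifiable <- all(is.finite(se)) &&
    par[2] > 1e-6 * (abs(par[1]) + diff(range(y)) + 1e-12)

  params <- harmonic_params(par[1], par[2], par[3])
  tq <- stats::qt(0.975, df = n - 3)
  tt <- 1:365
  angt <- 2 * pi * tt / 365 + params$b3
  fitv <- harmonic_predict(params, tt)
  Jt <- cbind(1, cos(angt), -params$b2 * sin(angt))
  sefit <- if (all(is.finite(cov))) sqrt(rowSums((Jt %*% cov) * Jt)) else rep(NA_real_, 365)
  band <- data.frame(t = tt, fit = fitv, lower = fitv - tq * sefit,
                     upper = fitv + tq * sefit)

  structure(list(params = params, se = se,
                 peak_ordinal = if (params$b2 > 0) peak_date(params) else NA_real_,
                 rss = rss, n = n, converged = converged,
                 identifiable = identifiable, ci_band = band,
                 residuals = resid_fn(par)),
            class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("harmonic fit: b1 = %.4g (se %.3g), b2 = %.4g (se %.3g), b3 = %.4g (se %.3g)\n",
              p$b1, x$se["b1"], p$b2, x$se["b2"], p$b3, x$se["b3"]))
  cat(sprintf("  peak ordinal %.1f, RSS %.4g, n %d, converged %s\n",
              x$peak_ordinal, x$rss, x$n, x$converged))
  if (!x$identifiable) cat("  amplitude not identifiable\n")
  invisible(x)
}

#' Fit the annual cosine to several series and order them by peak date
#'
#' Fits each named series and returns the fits sorted by peak ordinal date
#' (ties broken by name, so ordering is deterministic), the analysis behind
#' the seasonal-succession ordering of day length, temperature and the
#' diversity series.
#'
#' @param series named list, each element a list/data.frame with `t`
#'   (ordinal dates) and `y` (values).
#' @return data.frame with columns name, peak_ordinal, b1, b2, b3, rss,
#'   converged, sorted by peak date; fits attached as attribute `fits`.
#' @export
fit_all <- function(series) {
  stopifnot(length(series) >= 1, !is.null(names(series)))
  fits <- list()
  rows <- list()
  for (nm in names(series)) {
    s <- series[[nm]]
    f <- try(fit_harmonic(s$t, s$y), silent = TRUE)
    if (inherits(f, "try-error")) {
      warning("Series '", nm, "' failed to fit: ", attr(f, "condition")$message)
      next
    }
    fits[[nm]] <- f
    rows[[nm]] <- data.frame(name = nm, peak_ordinal = f$peak_ordinal,
                             b1 = f$params$b1, b2 = f$params$b2,
                             b3 = f$params$b3, rss = f$rss,
                             converged = f$converged)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$peak_ordinal, out$name), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
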