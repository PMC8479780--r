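#' Global multiexponential fit with decay-associated spectra
#'
#' Fits the separable model
#' \deqn{A(t, \lambda) = \sum_{i=1}^{n} D_i(\lambda)\, e^{-t/\tau_i} + D_\infty(\lambda)}
#' to a time-resolved matrix by variable projection: for any trial set of
#' time constants the per-wavelength amplitude spectra (the decay-associated
#' spectra, DAS, or decay-associated difference spectra, DADS, for
#' pump-probe data) and the optional non-decaying component are solved
#' exactly by linear least squares, so the nonlinear search runs only over
#' the time constants. The search is multi-started from a log-spaced grid of
#' initial values spanning `tau_bounds` and the best optimum over all starts
#' is returned. Time constants are reported sorted ascending, with the
#' amplitude spectra permuted accordingly.
#'
#' @param data A [trmatrix()]. Times must be in a consistent unit; the
#'   fitted time constants come out in that unit.
#' @param n_exp Number of exponential terms (1 or 2).
#' @param with_offset Include the non-decaying component `D_inf` (default
#'   `TRUE`).
#' @param tau_bounds Length-2 numeric `(lower, upper)` bounds for every time
#'   constant, in the data's time unit. Default: `min(diff(times))/2` to
#'   `20 * (range of times)`.
#' @param tau_init Optional numeric vector of additional initial guesses
#'   (recycled into the multi-start set).
#' @param n_starts Log-spaced initial values per time constant (default 5).
#' @return An object of class `"global_fit"` with components `taus`,
#'   `tau_se`, `das` (n_exp x n_wavelength matrix), `offset` (a [spectrum()]
#'   or `NULL`), `fitted` ([trmatrix()] of the model evaluation),
#'   `residual_rms`, `convergence` and the input grids. Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @seealso [evaluate_model()], [fit_ta()]
#' @examples
#' t <- seq(1, 150, by = 2)
#' wl <- seq(500, 700, by = 10)
#' das <- exp(-(wl - 650)^2 / 1800)
#' m <- trmatrix(t, wl, outer(exp(-t / 18), das))
#' f <- global_exp_fit(m, n_exp = 1)
#' coef(f)
#' @export
global_exp_fit <- function(data, n_exp = 1, with_offset = TRUE,
                           tau_bounds = NULL, tau_init = NULL, n_starts = 5) {
  stopifnot(inherits(data, "trmatrix"))
  n_exp <- as.integer(n_exp)
  if (!n_exp %in% 1:2)
    stop("global_exp_fit: n_exp must be 1 or 2", call. = FALSE)
  t <- data$times
  Y <- data$values
  n_min <- n_exp * 2L + 2L
  if (length(t) < n_min)
    stop("global_exp_fit: need at least ", n_min, " time points", call. = FALSE)
  if (is.null(tau_bounds)) {
    tau_bounds <- c(min(diff(t)) / 2, 20 * (max(t) - min(t)))
  }
  if (any(tau_bounds <= 0) || tau_bounds[1] >= tau_bounds[2])
    stop("global_exp_fit: tau_bounds must be positive with lower < upper",
         call. = FALSE)

  design <- function(taus) {
    X <- exp(-outer(t, 1 / taus))
    if (with_offset) X <- cbind(X, 1)
    X
  }
  # profiled residual sum of squares over the linear amplitudes
  rss <- function(log_taus) {
    X <- design(exp(log_taus))
    B <- tryCatch(qr.coef(qr(X), Y), error = function(e) NULL)
    if (is.null(B) || anyNA(B)) return(.Machine$double.xmax)
    sum((Y - X %*% B)^2)
  }

  lb <- log(tau_bounds[1]); ub <- log(tau_bounds[2])
  grid <- seq(lb, ub, length.out = n_starts)
  starts <- if (n_exp == 1L) {
    as.list(c(grid, if (!is.null(tau_init)) log(tau_init)))
  } else {
    pairs <- list()
    for (i in seq_len(n_starts - 1L))
      for (j in seq((i + 1L), n_starts))
        pairs[[length(pairs) + 1L]] <- c(grid[i], grid[j])
    if (!is.null(tau_init) && length(tau_init) == 2L)
      pairs[[length(pairs) + 1L]] <- sort(log(tau_init))
    pairs
  }

  best <- NULL
  n_conv <- 0L
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, rss, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 500, factr = 1e2)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("global_exp_fit: optimizer failed from every start", call. = FALSE)
  if (n_conv == 0L)
    stop(sprintf(
      "global_exp_fit: no start converged; best-found taus = %s (rss %.4g)",
      paste(signif(exp(sort(best$par)), 6), collapse = ", "), best$value),
      call. = FALSE)

  theta <- sort(best$par)
  taus <- exp(theta)
  warnings <- character()
  if (n_exp == 2L && taus[2] / taus[1] < 1.5)
    warnings <- c(warnings, sprintf(
      "degenerate tau pair: ratio %.3g < 1.5", taus[2] / taus[1]))

  X <- design(taus)
  B <- qr.coef(qr(X), Y)
  fit_vals <- X %*% B
  resid <- Y - fit_vals
  rss_val <- sum(resid^2)
  n_obs <- length(Y)
  n_par <- n_exp + ncol(X) * ncol(Y)
  sigma2 <- rss_val / max(n_obs - n_par, 1)

  # approximate standard errors from the curvature of the profiled rss
  tau_se <- rep(NA_real_, n_exp)
  H <- tryCatch(.fd_hessian(rss, theta), error = function(e) NULL)
  if (!is.null(H)) {
    cv <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
    if (!is.null(cv) && all(diag(cv) >= 0))
      tau_se <- taus * sqrt(diag(cv)) # delta method, theta = log tau
  }

  das <- matrix(B[seq_len(n_exp), , drop = FALSE], nrow = n_exp)
  offset <- if (with_offset)
    spectrum(data$wavelengths, B[n_exp + 1L, ], label = "non-decaying",
             unit = data$value_unit)
  else NULL

  structure(
    list(taus = taus, tau_se = tau_se, das = das, offset = offset,
         n_exp = n_exp, with_offset = with_offset,
         times = t, wavelengths = data$wavelengths,
         time_unit = data$time_unit, value_unit = data$value_unit,
         data = Y,
         fitted = trmatrix(t, data$wavelengths, fit_vals,
                           time_unit = data$time_unit,
                           value_unit = data$value_unit),
         residual_rms = sqrt(mean(resid^2)),
         convergence = list(n_starts = length(starts), n_converged = n_conv,
                            rss = rss_val, warnings = warnings),
         call = match.call()),
    class = "global_fit")
}

# central-difference Hessian of a scalar function
.fd_hessian <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    ei <- ej <- numeric(n); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * h^2)
  }
  H
}

#' Evaluate a fitted global model on an arbitrary time grid
#'
#' Closed-form evaluation of the fitted multiexponential model; used e.g.
#' to extrapolate the fitted signal to an early reference time in
#' quantum-yield estimation.
#'
#' @param result A `"global_fit"` object.
#' @param times Times (same unit as the fit).
#' @return A [trmatrix()].
#' @export
evaluate_model <- function(result, times) {
  stopifnot(inherits(result, "global_fit"))
  times <- as.numeric(times)
  X <- exp(-outer(times, 1 / result$taus))
  vals <- X %*% result$das
  if (result$with_offset)
    vals <- vals + rep(1, length(times)) %o% result$offset$values
  trmatrix(times, result$wavelengths, vals, time_unit = result$time_unit,
           value_unit = result$value_unit)
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("<global_fit> %d exponential(s)%s, %d x %d data\n",
              x$n_exp, if (x$with_offset) " + offset" else "",
              length(x$times), length(x$wavelengths)))
  tau_str <- sprintf("%.6g", x$taus)
  se_str <- ifelse(is.na(x$tau_se), "NA", sprintf("%.2g", x$tau_se))
  cat(sprintf("  tau%d = %s +/- %s %s\n", seq_len(x$n_exp), tau_str, se_str,
              x$time_unit), sep = "")
  cat(sprintf("  residual rms: %.4g %s\n", x$residual_rms, x$value_unit))
  invisible(x)
}

#' @export
coef.global_fit <- function(object, ...) {
  stats::setNames(object$taus, paste0("tau", seq_len(object$n_exp)))
}

#' @export
summary.global_fit <- function(object, ...) {
  out <- list(
    taus = object$taus, tau_se = object$tau_se,
    time_unit = object$time_unit,
    residual_rms = object$residual_rms,
    das_range = apply(object$das, 1, range),
    offset_range = if (!is.null(object$offset)) range(object$offset$values),
    convergence = object$convergence)
  class(out) <- "summary.global_fit"
  out
}

#' @export
print.summary.global_fit <- function(x, ...) {
  cat("Global multiexponential fit\n")
  for (i in seq_along(x$taus))
    cat(sprintf("  tau%d = %.6g %s (se %.3g), DAS range [%.4g, %.4g]\n",
                i, x$taus[i], x$time_unit, x$tau_se[i],
                x$das_range[1, i], x$das_range[2, i]))
  if (!is.null(x$offset_range))
    cat(sprintf("  offset range [%.4g, %.4g]\n",
                x$offset_range[1], x$offset_range[2]))
  cat(sprintf("  residual rms %.4g; %d/%d starts converged\n",
              x$residual_rms, x$convergence$n_converged,
              x$convergence$n_starts))
  if (length(x$convergence$warnings))
    cat("  warnings:", paste(x$convergence$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
predict.global_fit <- function(object, times = object$times, ...) {
  evaluate_model(object, times)
}

#' @export
fitted.global_fit <- function(object, ...) object$fitted

#' @export
residuals.global_fit <- function(object, ...) {
  object$data - object$fitted$values
}

#' Plot a global fit: kinetic traces and amplitude spectra
#'
#' Left panel: data (points) and fit (lines) at a few wavelengths; right
#' panel: DAS/DADS and the non-decaying component.
#'
#' @param x A `"global_fit"` object.
#' @param wl Wavelengths to show as kinetic traces (default: 4 spread over
#'   the grid).
#' @param log_time Plot time on a log axis (default `TRUE` when all times
#'   are positive).
#' @param ... Unused.
#' @export
plot.global_fit <- function(x, wl = NULL,
                            log_time = all(x$times > 0), ...) {
  if (is.null(wl))
    wl <- x$wavelengths[unique(round(seq(1, length(x$wavelengths),
                                         length.out = 4)))]
  idx <- vapply(wl, function(w) which.min(abs(x$wavelengths - w)), integer(1))
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  cols <- grDevices::hcl.colors(length(idx), "Dark 3")
  graphics::matplot(x$times, x$data[, idx, drop = FALSE], pch = 1, cex = 0.5,
                    col = cols, log = if (log_time) "x" else "",
                    xlab = paste0("time (", x$time_unit, ")"),
                    ylab = paste0("signal (", x$value_unit, ")"),
                    main = "kinetic traces")
  graphics::matlines(x$times, x$fitted$values[, idx, drop = FALSE],
                     lty = 1, col = cols)
  graphics::legend("topright", legend = sprintf("%.0f nm", x$wavelengths[idx]),
                   col = cols, lty = 1, bty = "n", cex = 0.8)
  ylim <- range(x$das, if (!is.null(x$offset)) x$offset$values)
  graphics::matplot(x$wavelengths, t(x$das), type = "l", lty = 1, ylim = ylim,
                    xlab = "wavelength (nm)", ylab = "amplitude",
                    main = "DAS / offset")
  if (!is.null(x$offset))
    graphics::lines(x$wavelengths, x$offset$values, lty = 2)
  graphics::abline(h = 0, col = "grey")
  graphics::legend("topright",
                   legend = c(sprintf("tau%d = %.3g %s", seq_len(x$n_exp),
                                      x$taus, x$time_unit),
                              if (!is.null(x$offset)) "non-decaying"),
                   lty = c(rep(1, x$n_exp), if (!is.null(x$offset)) 2),
                   col = c(seq_len(x$n_exp),
                           if (!is.null(x$offset)) "black"),
                   bty = "n", cex = 0.8)
  invisible(x)
}
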