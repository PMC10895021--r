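# Psychometric fitting (speech reception threshold), the clear-speech
# benefit, the four-parameter metric-to-intelligibility transformation, and
# the normalized RMS error used to score fits.

#' Two-parameter logistic psychometric function
#'
#' \eqn{f(SNR) = 1 / (1 + e^{-k(SNR - SRT)})}: intelligibility as a
#' function of SNR, with slope `k` (1/dB) and 50%-point `srt` (dB).
#'
#' @param snr SNR values in dB.
#' @param k Slope (1/dB).
#' @param srt Speech reception threshold (dB).
#' @return Predicted proportion-correct scores.
#' @export
logistic2 <- function(snr, k, srt) 1 / (1 + exp(-k * (snr - srt)))

#' Four-parameter logistic transformation
#'
#' \eqn{f(x) = d - (d - a) / (1 + (x/c)^b)}: maps a non-negative objective
#' metric value `x` to an intelligibility score. `a` and `d` are the lower
#' and upper asymptotes, `b` controls the slope and `c` (> 0) is the
#' half-way point, where `f(c) = (a + d)/2`.
#'
#' @param x Metric values (> 0).
#' @param a,b,c,d Parameters.
#' @return Transformed scores.
#' @export
logistic4 <- function(x, a, b, c, d) d - (d - a) / (1 + (x / c)^b)

#' Fit a speech reception threshold (SRT)
#'
#' Least-squares fit of the two-parameter logistic [logistic2()] to
#' (SNR, score) points, giving the slope `k` and the SRT -- the SNR at
#' which the fitted curve crosses 0.5 exactly. Quiet (no-noise) conditions
#' have no SNR and must be excluded before fitting.
#'
#' The fit is deterministic: the SRT is initialized at the interpolated
#' 0.5 crossing of the data (or the SNR of the score closest to 0.5) and
#' the slope at a logit-regression estimate, with a fixed grid of fallback
#' slope starts; the best bounded L-BFGS-B solution is returned.
#'
#' @param snr Numeric vector of SNRs in dB (at least 3 distinct values).
#' @param score Mean intelligibility scores in `[0, 1]`, same length.
#' @return An object of class `srt_fit` with elements `k`, `srt`,
#'   `residual` (RMSE of the fit), `fitted`, `data`, and
#'   `ill_conditioned` (`TRUE` when all scores lie on one side of 0.5, in
#'   which case the SRT is an extrapolation and a warning is issued).
#' @examples
#' snr <- seq(-15, 5, by = 2.5)
#' fit <- fit_srt(snr, logistic2(snr, k = 0.5, srt = -6))
#' coef(fit)
#' @export
fit_srt <- function(snr, score) {
  if (length(snr) != length(score) || length(snr) < 3L) {
    stop("need at least 3 (snr, score) points", call. = FALSE)
  }
  if (any(!is.finite(snr)) || any(!is.finite(score))) {
    stop("non-finite snr or score (exclude quiet conditions before ",
         "fitting)", call. = FALSE)
  }
  ord <- order(snr)
  s <- snr[ord]; y <- score[ord]

  ill <- all(y > 0.5) || all(y < 0.5)
  if (ill) {
    warning("all scores on one side of 0.5: SRT is an extrapolation ",
            "(ill-conditioned fit)", call. = FALSE)
  }

  # initializer: interpolated 0.5 crossing, logit-slope regression
  srt0 <- if (!ill) {
    i <- which(diff(sign(y - 0.5)) != 0)[1L]
    if (!is.na(i) && y[i + 1L] != y[i]) {
      s[i] + (0.5 - y[i]) * (s[i + 1L] - s[i]) / (y[i + 1L] - y[i])
    } else s[which.min(abs(y - 0.5))[1L]]
  } else s[which.min(abs(y - 0.5))[1L]]
  yc <- pmin(pmax(y, 1e-3), 1 - 1e-3)
  k0 <- tryCatch(unname(stats::coef(stats::lm(stats::qlogis(yc) ~ s))[2L]),
                 error = function(e) 0.5)
  if (!is.finite(k0) || k0 <= 0) k0 <- 0.5

  sse <- function(p) sum((logistic2(s, p[1L], p[2L]) - y)^2)
  sse_grad <- function(p) {
    f <- logistic2(s, p[1L], p[2L])
    r <- f - y
    c(2 * sum(r * f * (1 - f) * (s - p[2L])),
      -2 * p[1L] * sum(r * f * (1 - f)))
  }
  lower <- c(1e-4, min(s) - 30)
  upper <- c(10, max(s) + 30)
  starts <- unique(c(k0, 0.2, 0.5, 1))
  best <- NULL
  for (ks in starts) {
    fit <- stats::optim(c(ks, srt0), sse, gr = sse_grad,
                        method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(factr = 10, pgtol = 1e-12, maxit = 1000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  k <- best$par[1L]; srt <- best$par[2L]
  fitted <- logistic2(snr, k, srt)
  structure(list(k = k, srt = srt,
                 residual = sqrt(mean((fitted - score)^2)),
                 fitted = fitted,
                 data = data.frame(snr = snr, score = score),
                 ill_conditioned = ill),
            class = "srt_fit")
}

#' @export
print.srt_fit <- function(x, ...) {
  cat(sprintf("SRT fit: k = %.4g /dB, SRT = %.4g dB (RMSE %.3g)%s\n",
              x$k, x$srt, x$residual,
              if (x$ill_conditioned) " [ill-conditioned]" else ""))
  invisible(x)
}

#' @export
coef.srt_fit <- function(object, ...) c(k = object$k, srt = object$srt)

#' @export
predict.srt_fit <- function(object, newdata = NULL, ...) {
  snr <- if (is.null(newdata)) object$data$snr
         else if (is.data.frame(newdata)) newdata$snr else newdata
  logistic2(snr, object$k, object$srt)
}

#' @export
summary.srt_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  %d points, SNR %g..%g dB, scores %.2f..%.2f\n",
              nrow(object$data), min(object$data$snr),
              max(object$data$snr), min(object$data$score),
              max(object$data$score)))
  invisible(object)
}

#' Clear-speech benefit
#'
#' The difference in speech reception threshold between clear and
#' conversational speech, `SRT_clear - SRT_conv` in dB. Negative values
#' mean clear speech remains intelligible at worse SNRs.
#'
#' @param srt_clear,srt_conv SRTs in dB, as numbers or `srt_fit` objects.
#' @return The benefit in dB.
#' @examples
#' clear_benefit(-9.1, -5.2)  # -3.9 dB
#' @export
clear_benefit <- function(srt_clear, srt_conv) {
  pick <- function(x) if (inherits(x, "srt_fit")) x$srt else x
  a <- pick(srt_clear); b <- pick(srt_conv)
  if (!is.finite(a) || !is.finite(b)) stop("SRTs must be finite",
                                           call. = FALSE)
  a - b
}

#' Normalized root-mean-square error
#'
#' RMS difference between observed scores and predictions, normalized by
#' the range of the observed scores. Reported as a fraction; multiply by
#' 100 for the conventional percent form.
#'
#' @param scores Observed scores (non-constant).
#' @param predictions Predictions, same length.
#' @return The normalized error.
#' @export
nrmse <- function(scores, predictions) {
  if (length(scores) == 0L || length(scores) != length(predictions)) {
    stop("'scores' and 'predictions' must be equal-length, non-empty",
         call. = FALSE)
  }
  r <- max(scores) - min(scores)
  if (r <= 0) {
    stop("constant scores: range normalization undefined", call. = FALSE)
  }
  sqrt(mean((scores - predictions)^2)) / r
}

#' Fit the metric-to-intelligibility transformation
#'
#' Fits the four-parameter logistic [logistic4()] mapping mean objective
#' metric values to mean intelligibility scores by minimizing the
#' normalized RMS error ([nrmse()]). Optimization is bounded L-BFGS-B from
#' five fixed starting points -- `(b, c)` in {(1, median x), (2, 25th
#' percentile), (2, median), (2, 75th percentile), (4, median)} with `a`
#' and `d` started at the observed score extremes -- and the best solution
#' is returned; no randomness is involved.
#'
#' @param x Metric values, all > 0 (at least 5 conditions).
#' @param score Mean intelligibility scores, same length.
#' @return An object of class `transform_fit`: parameters `a`, `b`, `c`,
#'   `d`, the achieved `sigma` (NRMSE, as a fraction), `fitted`, `data`,
#'   and a `degenerate` flag (constant scores, `a` = `d`).
#' @export
fit_transform <- function(x, score) {
  if (length(x) != length(score) || length(x) < 5L) {
    stop("need at least 5 (metric, score) conditions", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    bad <- which(!is.finite(x) | x <= 0)
    stop("metric values must be positive and finite; offending ",
         "condition(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (max(score) == min(score)) {
    # constant scores: the flat transform fits exactly
    fitted <- rep(score[1L], length(x))
    return(structure(list(a = score[1L], b = 1, c = stats::median(x),
                          d = score[1L], sigma = 0, fitted = fitted,
                          data = data.frame(x = x, score = score),
                          degenerate = TRUE),
                     class = "transform_fit"))
  }

  sse <- function(p) {
    f <- logistic4(x, p[1L], p[2L], p[3L], p[4L])
    sum((score - f)^2)
  }
  sse_grad <- function(p) {
    a <- p[1L]; b <- p[2L]; cc <- p[3L]; d <- p[4L]
    u <- (x / cc)^b
    g <- 1 / (1 + u)
    f <- d - (d - a) * g
    r <- f - score
    c(2 * sum(r * g),
      2 * sum(r * (d - a) * u * log(x / cc) * g^2),
      -2 * sum(r * (d - a) * b * u * g^2 / cc),
      2 * sum(r * (1 - g)))
  }
  a0 <- min(score); d0 <- max(score)
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  starts <- list(c(a0, 1, qs[2L], d0),
                 c(a0, 2, qs[1L], d0),
                 c(a0, 2, qs[2L], d0),
                 c(a0, 2, qs[3L], d0),
                 c(a0, 4, qs[2L], d0))
  lower <- c(min(score) - 1, 0.01, min(x) * 1e-3, min(score))
  upper <- c(max(score), 50, max(x) * 1e3, max(score) + 1.5)
  best <- NULL
  for (p0 in starts) {
    fit <- stats::optim(p0, sse, gr = sse_grad, method = "L-BFGS-B",
                        lower = lower,
                        upper = upper,
                        control = list(factr = 10, pgtol = 1e-12, maxit = 2000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  p <- best$par
  fitted <- logistic4(x, p[1L], p[2L], p[3L], p[4L])
  structure(list(a = p[1L], b = p[2L], c = p[3L], d = p[4L],
                 sigma = nrmse(score, fitted), fitted = fitted,
                 data = data.frame(x = x, score = score),
                 degenerate = FALSE),
            class = "transform_fit")
}

#' @export
print.transform_fit <- function(x, ...) {
  cat(sprintf(
    "Transformation fit: a = %.3g, b = %.3g, c = %.3g, d = %.3g (sigma = %.2f%%)%s\n",
    x$a, x$b, x$c, x$d, 100 * x$sigma,
    if (x$degenerate) " [degenerate: constant scores]" else ""))
  invisible(x)
}

#' @export
coef.transform_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c, d = object$d)
}

#' @export
predict.transform_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x else newdata
  logistic4(x, object$a, object$b, object$c, object$d)
}

#' @export
summary.transform_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  %d conditions, metric %0.3g..%0.3g, scores %.2f..%.2f\n",
              nrow(object$data), min(object$data$x), max(object$data$x),
              min(object$data$score), max(object$data$score)))
  invisible(object)
}
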