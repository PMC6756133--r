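# Psychometric (speech reception threshold) fitting.

#' Logistic psychometric function
#'
#' \eqn{p(x) = guess + (1 - guess - lapse) / (1 + e^{-(x-\alpha)/\beta})}
#' with `alpha` the midpoint (the SRT when scores are word proportions) and
#' `beta` the spread in dB.
#'
#' @param x stimulus SNR in dB.
#' @param alpha midpoint in dB SNR.
#' @param beta spread in dB (> 0).
#' @param guess,lapse lower/upper asymptote offsets.
#' @export
psychometric_fun <- function(x, alpha, beta, guess = 0, lapse = 0) {
  guess + (1 - guess - lapse) / (1 + exp(-(x - alpha) / beta))
}

#' Fit a psychometric function to scores against SNR
#'
#' Two modes mirror behavioral and neural use: with `fix_rates = TRUE` the
#' guess and lapse rates are pinned at zero (word scores); with
#' `fix_rates = FALSE` they are free, so the curve can ride on the floor and
#' ceiling of a tracking measure. Binomial maximum likelihood is used when
#' `n_trials` is supplied, otherwise least squares. Multiple starts guard
#' against local optima; non-convergence is reported via `fit_ok`, never
#' silently.
#'
#' @param snrs stimulus SNRs in dB.
#' @param scores observed proportions (or tracking values in `[0, 1]` scale)
#'   per SNR.
#' @param fix_rates pin guess and lapse at zero (default TRUE).
#' @param n_trials optional trials per SNR; triggers binomial ML.
#' @return object of class `psychometric_fit` with `alpha` (SRT),
#'   `beta`, `guess`, `lapse`, `slope_pct_per_db`
#'   (\eqn{100 (1-guess-lapse)/(4\beta)}), and `fit_ok`.
#' @export
fit_psychometric <- function(snrs, scores, fix_rates = TRUE,
                             n_trials = NULL) {
  if (length(snrs) != length(scores))
    stop_invalid("`snrs` and `scores` lengths differ")
  n_par <- if (fix_rates) 2L else 4L
  if (length(unique(snrs)) < n_par)
    stop_invalid(sprintf("need at least %d distinct SNRs", n_par))
  rng <- range(snrs)
  spread0 <- max(diff(rng) / 4, 0.5)
  negloglik <- function(par) {
    a <- par[1]; b <- par[2]
    g <- if (fix_rates) 0 else par[3]
    l <- if (fix_rates) 0 else par[4]
    p <- psychometric_fun(snrs, a, b, g, l)
    if (!is.null(n_trials)) {
      p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      k <- scores * n_trials
      -sum(k * log(p) + (n_trials - k) * log(1 - p))
    } else {
      sum((scores - p)^2)
    }
  }
  lower <- c(rng[1] - diff(rng), 1e-3)
  upper <- c(rng[2] + diff(rng), diff(rng) * 3 + 1)
  if (!fix_rates) {
    lower <- c(lower, 0, 0)
    upper <- c(upper, 0.999, 0.999)
  }
  a_starts <- quantile(snrs, c(0.25, 0.5, 0.75), names = FALSE)
  best <- NULL
  for (a0 in a_starts) for (b0 in c(spread0 / 2, spread0, spread0 * 2)) {
    par0 <- c(a0, b0)
    if (!fix_rates) par0 <- c(par0, max(min(scores), 0), max(1 - max(scores), 0))
    fit <- tryCatch(
      optim(par0, negloglik, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(alpha = NA_real_, beta = NA_real_, guess = NA_real_,
                          lapse = NA_real_, slope_pct_per_db = NA_real_,
                          fit_ok = FALSE,
                          message = "all optimisation starts failed"),
                     class = "psychometric_fit"))
  }
  a <- best$par[1]; b <- best$par[2]
  g <- if (fix_rates) 0 else best$par[3]
  l <- if (fix_rates) 0 else best$par[4]
  ok <- best$convergence == 0 && g + l < 1
  structure(list(alpha = a, beta = b, guess = g, lapse = l,
                 slope_pct_per_db = 100 * (1 - g - l) / (4 * b),
                 fit_ok = ok, objective = best$value),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "psychometric fit: SRT %.2f dB, spread %.2f dB, slope %.1f %%/dB%s\n",
    x$alpha, x$beta, x$slope_pct_per_db,
    if (isTRUE(x$fit_ok)) "" else " [did not converge]"))
  if (x$guess != 0 || x$lapse != 0)
    cat(sprintf("  guess %.3f, lapse %.3f\n", x$guess, x$lapse))
  invisible(x)
}
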