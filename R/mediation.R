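#' Three-variable mediation by standardized path analysis
#'
#' Fits the classic X -> M -> Y mediation diagram with an additional direct
#' X -> Y path. With one indicator per construct, the PLS path algorithm's
#' outer estimation is degenerate and the inner model reduces exactly to two
#' OLS regressions on standardized variables: a from M ~ X, and (b, c') from
#' Y ~ M + X. The indirect effect is a*b, the total effect c' + a*b (which
#' equals the slope of Y ~ X exactly), and VAF = indirect / total.
#'
#' VAF is reported with sign; values outside [0, 1] indicate inconsistent
#' mediation and are flagged rather than clamped.
#'
#' @param x,m,y numeric vectors of equal length (>= 10): exposure, mediator,
#'   outcome. A binary outcome may be passed as 0/1 and is treated as
#'   numeric, as PLS path modeling does.
#' @return object of class \code{mediation_model} with fields \code{a},
#'   \code{b}, \code{c_direct}, \code{ide}, \code{total}, \code{vaf},
#'   \code{inconsistent}, \code{n}.
#' @export
fit_mediation <- function(x, m, y) {
  n <- length(x)
  if (length(m) != n || length(y) != n) stop("x, m, y must have equal length")
  if (n < 10) stop("need at least 10 observations")
  if (stats::sd(x) == 0 || stats::sd(m) == 0 || stats::sd(y) == 0)
    stop("zero-variance input")
  xs <- as.numeric(scale(x)); ms <- as.numeric(scale(m)); ys <- as.numeric(scale(y))
  a <- sum(xs * ms) / sum(xs * xs)
  # (b, c') from the bivariate normal equations of Y ~ M + X
  smm <- sum(ms * ms); sxx <- sum(xs * xs); smx <- sum(ms * xs)
  smy <- sum(ms * ys); sxy <- sum(xs * ys)
  det <- smm * sxx - smx^2
  if (det <= 0) stop("collinear mediator and exposure")
  b <- (sxx * smy - smx * sxy) / det
  c_direct <- (smm * sxy - smx * smy) / det
  ide <- a * b
  total <- c_direct + ide
  vaf <- if (total != 0) ide / total else NA_real_
  structure(list(a = a, b = b, c_direct = c_direct,
                 ide = ide, total = total, vaf = vaf,
                 inconsistent = is.na(vaf) || vaf < 0 || vaf > 1,
                 n = n, boot = NULL),
            class = "mediation_model")
}

#' @method print mediation_model
#' @export
print.mediation_model <- function(x, ...) {
  cat(sprintf("mediation_model (n = %d): a = %.3f, b = %.3f, c' = %.3f\n",
              x$n, x$a, x$b, x$c_direct))
  cat(sprintf("  indirect = %.3f, total = %.3f, VAF = %.3f%s\n",
              x$ide, x$total, x$vaf,
              if (isTRUE(x$inconsistent)) " [inconsistent mediation]" else ""))
  if (!is.null(x$boot)) {
    cat(sprintf("  bootstrap B = %d: p(a) = %.3g, p(b) = %.3g, p(c') = %.3g, p(ide) = %.3g\n",
                x$boot$B, x$boot$p["a"], x$boot$p["b"],
                x$boot$p["c_direct"], x$boot$p["ide"]))
  }
  invisible(x)
}

#' Case-resampling bootstrap for mediation paths
#'
#' Refits the path model on B case resamples and reports percentile 95
#' percent CIs and two-sided sign-based p-values for a, b, c' and the
#' indirect effect.
#'
#' @param x,m,y as in \code{fit_mediation}.
#' @param B number of resamples (default 500; below 100 a warning is
#'   issued).
#' @param seed integer seed.
#' @return a \code{mediation_model} with the \code{boot} field filled:
#'   \code{B}, \code{ci} (2 x 4 matrix), \code{p} (named vector),
#'   \code{skipped} (degenerate resamples).
#' @export
bootstrap_mediation <- function(x, m, y, B = 500, seed = 1) {
  if (B < 100) warning("B < 100 gives unstable percentile intervals")
  fit <- fit_mediation(x, m, y)
  n <- fit$n
  set.seed(seed)
  draws <- matrix(NA_real_, B, 4,
                  dimnames = list(NULL, c("a", "b", "c_direct", "ide")))
  skipped <- 0L
  for (bb in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    f <- tryCatch(fit_mediation(x[idx], m[idx], y[idx]),
                  error = function(e) NULL)
    if (is.null(f)) { skipped <- skipped + 1L; next }
    draws[bb, ] <- c(f$a, f$b, f$c_direct, f$ide)
  }
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975))
  pvals <- apply(draws, 2, function(d)
    min(1, 2 * min(mean(d <= 0), mean(d >= 0))))
  fit$boot <- list(B = B, ci = ci, p = pvals, skipped = skipped)
  fit
}
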