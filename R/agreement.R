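#' Bland-Altman agreement statistics
#'
#' Agreement between two measurement methods (or observers, or sessions) is
#' summarised by the differences of paired measurements: the bias (mean
#' difference) with its 95% CI, the coefficient of repeatability
#' `CR = 1.96 * SD(differences)`, the 95% limits of agreement
#' `LOA = bias +/- CR`, and CIs for each LOA using the approximation
#' `SE = sqrt(3 s^2 / n)`.
#'
#' @name agreement
NULL

# z multiplier: literal 1.96 at the conventional 95% level (the method is
# stated with the literal constant), exact quantile otherwise
z_mult <- function(conf) {
  if (abs(conf - 0.95) < 1e-12) 1.96 else stats::qnorm(1 - (1 - conf) / 2)
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences are `value_a - value_b` in pair order (the comparison "A-B").
#' The SD of differences uses the sample (n-1) denominator; all multipliers
#' are the literal 1.96.
#'
#' @param pairs a [paired_measurements()] object (or data frame with
#'   columns `value_a`, `value_b`)
#' @param loa_se_mode SE formula for the LOA CIs: `"bland"` (default) is
#'   the stated approximation `sqrt(3 s^2/n)`; `"table1"` is the
#'   compatibility variant `3 s/sqrt(n)` (wider by sqrt(3)), which some
#'   published tables match
#' @return an object of class `agreement_result` with fields `n`, `bias`,
#'   `sd`, `se_bias`, `bias_ci`, `cr`, `loa_lower`, `loa_upper`, `se_loa`,
#'   `loa_ci_lower`, `loa_ci_upper`, `means`, `diffs`, `comparison`
#' @examples
#' pm <- paired_measurements(c(1, 2, 3, 4), c(0, 0, 0, 0))
#' bland_altman(pm)
#' @export
bland_altman <- function(pairs, loa_se_mode = c("bland", "table1")) {
  loa_se_mode <- match.arg(loa_se_mode)
  a <- pairs$value_a
  b <- pairs$value_b
  n <- length(a)
  if (n < 3L) {
    octvol_stop(sprintf("Bland-Altman needs n >= 3 pairs, got %d", n),
                "octvol_insufficient_data")
  }
  diffs <- a - b
  means <- (a + b) / 2
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  if (s == 0) {
    octvol_warn("zero variance of differences; LOAs collapse to the bias",
                "octvol_zero_variance")
  }
  se_bias <- s / sqrt(n)
  cr <- 1.96 * s
  se_loa <- switch(loa_se_mode,
                   bland = sqrt(3 * s^2 / n),
                   table1 = 3 * s / sqrt(n))
  la <- attr(pairs, "method_a_label")
  lb <- attr(pairs, "method_b_label")
  structure(
    list(comparison = if (is.null(la)) "A-B" else paste(la, lb, sep = "-"),
         n = n,
         bias = bias,
         sd = s,
         se_bias = se_bias,
         bias_ci = c(bias - 1.96 * se_bias, bias + 1.96 * se_bias),
         cr = cr,
         loa_lower = bias - cr,
         loa_upper = bias + cr,
         loa_se_mode = loa_se_mode,
         se_loa = se_loa,
         loa_ci_lower = c(bias - cr - 1.96 * se_loa,
                          bias - cr + 1.96 * se_loa),
         loa_ci_upper = c(bias + cr - 1.96 * se_loa,
                          bias + cr + 1.96 * se_loa),
         means = means,
         diffs = diffs),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, digits = 4, ...) {
  r <- function(v) formatC(v, format = "f", digits = digits)
  cat(sprintf("<agreement_result %s, n = %d>\n", x$comparison, x$n))
  cat(sprintf("  bias %s mm^3 (95%% CI %s to %s)\n",
              r(x$bias), r(x$bias_ci[1]), r(x$bias_ci[2])))
  cat(sprintf("  CR   %s mm^3\n", r(x$cr)))
  cat(sprintf("  LOA  %s (95%% CI %s to %s)\n", r(x$loa_lower),
              r(x$loa_ci_lower[1]), r(x$loa_ci_lower[2])))
  cat(sprintf("       %s (95%% CI %s to %s)\n", r(x$loa_upper),
              r(x$loa_ci_upper[1]), r(x$loa_ci_upper[2])))
  invisible(x)
}

#' Reconstruct agreement columns from a published summary row
#'
#' Given the (bias, CR, n) triple a report prints for one comparison,
#' recompute the derived columns: `LOA = bias +/- CR` and
#' `bias CI = bias +/- CR/sqrt(n)` (since `CR/sqrt(n) = 1.96 * sd/sqrt(n)`).
#' Useful for internal-consistency checks of published tables.
#'
#' @param bias mean difference (mm^3)
#' @param cr coefficient of repeatability (mm^3)
#' @param n number of pairs
#' @return named list: `bias_ci_low`, `bias_ci_high`, `loa_lower`,
#'   `loa_upper`
#' @export
agreement_from_summary <- function(bias, cr, n) {
  hw <- cr / sqrt(n)
  list(bias_ci_low = bias - hw, bias_ci_high = bias + hw,
       loa_lower = bias - cr, loa_upper = bias + cr)
}

#' Data behind a Bland-Altman plot
#'
#' One row per pair (mean vs difference) plus the reference lines, exactly
#' the fields of the [bland_altman()] result. Rendering is left to the
#' caller.
#'
#' @param result an `agreement_result`
#' @return list with `points` (data frame `mean`, `diff`) and `lines`
#'   (data frame `name`, `value`)
#' @export
ba_plot_data <- function(result) {
  stopifnot(inherits(result, "agreement_result"))
  list(
    points = data.frame(mean = result$means, diff = result$diffs),
    lines = data.frame(
      name = c("bias", "bias_ci_low", "bias_ci_high",
               "loa_lower", "loa_lower_ci_low", "loa_lower_ci_high",
               "loa_upper", "loa_upper_ci_low", "loa_upper_ci_high"),
      value = c(result$bias, result$bias_ci,
                result$loa_lower, result$loa_ci_lower,
                result$loa_upper, result$loa_ci_upper))
  )
}

#' Power of a Bland-Altman agreement study
#'
#' Power is the probability, under differences ~ Normal(bias, sd^2), that
#' the CIs of both estimated limits of agreement fall inside the clinical
#' agreement interval (-delta, +delta), where the LOAs and their CIs are
#' computed exactly as in [bland_altman()] (sample SD, multiplier 1.96,
#' `SE = sqrt(3 s^2/n)`).
#'
#' `method = "approximate"` evaluates the probability by quadrature over
#' the sampling distribution of the sample SD (chi distribution), using the
#' independence of the sample mean and SD of a normal sample; it is exact
#' up to quadrature error. `method = "monte_carlo"` simulates whole
#' agreement studies and serves as the independent oracle.
#'
#' @param bias true mean difference (mm^3)
#' @param sd true SD of differences (mm^3), > 0
#' @param delta clinical agreement limit (mm^3), default 0.01: the largest
#'   paired difference considered clinically acceptable
#' @param n planned number of pairs, >= 3
#' @param loa_confidence LOA level (default 0.95, multiplier 1.96)
#' @param ci_confidence level of the LOA CIs (default 0.95)
#' @param method `"approximate"` or `"monte_carlo"`
#' @param sims Monte-Carlo replicates (>= 1000)
#' @param seed RNG seed for the Monte-Carlo method
#' @return list with `power`, `method`, `n`, and for Monte-Carlo the
#'   standard error `mc_se` plus per-tail failure rates
#' @export
agreement_power <- function(bias, sd, delta = 0.01, n,
                            loa_confidence = 0.95, ci_confidence = 0.95,
                            method = c("approximate", "monte_carlo"),
                            sims = 100000L, seed = 2024L) {
  method <- match.arg(method)
  if (!is.finite(delta) || delta <= 0) {
    octvol_stop("delta must be > 0", "octvol_config_error")
  }
  if (!is.finite(sd) || sd <= 0) {
    octvol_stop("sd must be > 0", "octvol_config_error")
  }
  if (n < 3L) octvol_stop("n must be >= 3", "octvol_config_error")
  z_loa <- z_mult(loa_confidence)
  z_ci <- z_mult(ci_confidence)
  # both CIs lie inside (-delta, delta)  <=>
  #   |dbar - bias_shift| stays within delta - c(s),  c(s) = s*(z_loa + z_ci*sqrt(3/n))
  cfac <- z_loa + z_ci * sqrt(3 / n)
  if (method == "approximate") {
    # s = sd * sqrt(q/(n-1)), q ~ chisq(n-1); dbar ~ N(bias, sd^2/n)
    f <- function(u) {
      q <- stats::qchisq(u, df = n - 1)
      s <- sd * sqrt(q / (n - 1))
      margin <- delta - cfac * s
      p <- stats::pnorm((margin - bias) * sqrt(n) / sd) -
        stats::pnorm((-margin - bias) * sqrt(n) / sd)
      ifelse(margin > 0, pmax(p, 0), 0)
    }
    val <- stats::integrate(f, 0, 1, rel.tol = 1e-9, abs.tol = 1e-12,
                            subdivisions = 500L)$value
    list(power = val, method = "approximate", n = n, delta = delta,
         bias = bias, sd = sd)
  } else {
    sims <- as.integer(sims)
    if (sims < 1000L) {
      octvol_stop("monte_carlo needs sims >= 1000", "octvol_config_error")
    }
    set.seed(as.integer(seed))
    ok <- logical(0)
    fail_lo <- 0; fail_hi <- 0
    chunk <- max(1L, min(sims, as.integer(2e6 / n)))
    done <- 0L
    while (done < sims) {
      k <- min(chunk, sims - done)
      x <- matrix(stats::rnorm(n * k, mean = bias, sd = sd), nrow = n)
      m <- colMeans(x)
      s <- sqrt(pmax(colSums(x^2) - n * m^2, 0) / (n - 1))
      upper_ok <- m + z_loa * s + z_ci * s * sqrt(3 / n) < delta
      lower_ok <- m - z_loa * s - z_ci * s * sqrt(3 / n) > -delta
      ok <- c(ok, upper_ok & lower_ok)
      fail_hi <- fail_hi + sum(!upper_ok)
      fail_lo <- fail_lo + sum(!lower_ok)
      done <- done + k
    }
    p <- mean(ok)
    list(power = p, method = "monte_carlo", n = n, delta = delta,
         bias = bias, sd = sd, sims = sims,
         mc_se = sqrt(p * (1 - p) / sims),
         fail_upper = fail_hi / sims, fail_lower = fail_lo / sims,
         seed = as.integer(seed))
  }
}
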