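z95 <- 1.959964

# Package an estimate row on the log-odds scale, with OR and 95% CI.
mr_estimate <- function(method, nsnp, beta, se, pval, ci_z = z95) {
  tibble::tibble(
    method = method, nsnp = as.integer(nsnp), beta = beta, se = se,
    pval = pval, or = exp(beta),
    ci_low = exp(beta - ci_z * se), ci_high = exp(beta + ci_z * se)
  )
}

#' Wald ratio causal estimate from a single instrument
#'
#' The per-SNP causal estimate: variant-outcome effect divided by
#' variant-exposure effect. The SE is the first-order delta approximation
#' `se_out / |beta_exp|`, which ignores exposure-side noise, so the p-value
#' equals the outcome association's p-value.
#'
#' @param inst One harmonized instrument (one-row data frame or list with
#'   `beta_exp`, `beta_out`, `se_out`).
#' @return A one-row estimate tibble (`method, nsnp, beta, se, pval, or,
#'   ci_low, ci_high`).
#' @export
wald_ratio <- function(inst) {
  if (inst$beta_exp == 0) stop("Wald ratio undefined: beta_exp = 0")
  beta <- inst$beta_out / inst$beta_exp
  se <- inst$se_out / abs(inst$beta_exp)
  mr_estimate("wald_ratio", 1L, beta, se, 2 * stats::pnorm(-abs(beta / se)))
}

# Shared plumbing: per-SNP ratios and inverse-variance weights.
ratio_weights <- function(insts) {
  list(ratio = insts$beta_out / insts$beta_exp,
       w = insts$beta_exp^2 / insts$se_out^2)
}

#' Random-effects inverse-variance-weighted causal estimate
#'
#' Weighted least squares of the outcome associations on the exposure
#' associations through the origin with weights `1/se_out^2` — equivalently
#' an inverse-variance meta-analysis of the per-SNP Wald ratios. Under the
#' multiplicative random-effects model the slope SE is scaled by the
#' residual standard deviation, floored at 1 so underdispersion can never
#' shrink the SE. The p-value uses the normal reference.
#'
#' @param insts An `instrument_set` (>= 1 instrument).
#' @param variance_model `"multiplicative_re"` (default) or `"fixed"`.
#' @return A one-row estimate tibble.
#' @export
ivw <- function(insts, variance_model = c("multiplicative_re", "fixed")) {
  variance_model <- match.arg(variance_model)
  k <- nrow(insts)
  if (k < 1) stop("IVW needs at least one instrument")
  w <- 1 / insts$se_out^2
  sxx <- sum(w * insts$beta_exp^2)
  slope <- sum(w * insts$beta_exp * insts$beta_out) / sxx
  se <- sqrt(1 / sxx)
  if (variance_model == "multiplicative_re" && k > 1) {
    resid <- insts$beta_out - slope * insts$beta_exp
    sigma2 <- sum(w * resid^2) / (k - 1)
    se <- se * sqrt(max(1, sigma2))
  }
  mr_estimate("ivw", k, slope, se, 2 * stats::pnorm(-abs(slope / se)))
}

#' MR-Egger regression with intercept (horizontal-pleiotropy) test
#'
#' Instruments are first oriented so every exposure beta is non-negative
#' (negating both betas where needed — the intercept is not invariant to
#' allele orientation), then outcome betas are regressed on exposure betas
#' with a free intercept and weights `1/se_out^2`. A nonzero intercept
#' indicates directional horizontal pleiotropy; the slope remains a
#' consistent causal estimate under the InSIDE assumption even when all
#' instruments are invalid. SEs use the residual scale floored at 1;
#' p-values use the t reference with `nsnp - 2` degrees of freedom.
#'
#' @param insts An `instrument_set` (>= 3 instruments).
#' @return A list with `slope` (estimate tibble) and `intercept`
#'   (list: `estimate`, `se`, `pval`).
#' @export
egger <- function(insts) {
  k <- nrow(insts)
  if (k < 3) stop("MR-Egger needs at least 3 instruments")
  s <- ifelse(insts$beta_exp < 0, -1, 1)
  x <- insts$beta_exp * s
  y <- insts$beta_out * s
  w <- 1 / insts$se_out^2
  fit <- stats::lm.wfit(cbind(intercept = 1, slope = x), y, w)
  xtx_inv <- chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE])
  sigma2 <- sum(w * fit$residuals^2) / (k - 2)
  scale2 <- max(1, sigma2)
  ses <- sqrt(diag(xtx_inv) * scale2)
  tvals <- fit$coefficients / ses
  pvals <- 2 * stats::pt(-abs(tvals), df = k - 2)
  list(
    slope = mr_estimate("egger", k, fit$coefficients[["slope"]],
                        ses[[2]], pvals[[2]]),
    intercept = list(estimate = fit$coefficients[["intercept"]],
                     se = ses[[1]], pval = pvals[[1]])
  )
}

# Interpolated weighted median of ratios r with weights w:
# cumulative standardized weights s_j = (cum_j - w_j/2) / total, linear
# interpolation at 0.5.
weighted_median_point <- function(r, w) {
  if (all(w <= 0)) stop("all weights are zero")
  o <- order(r)
  r <- r[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate with parametric-bootstrap SE
#'
#' The interpolated weighted median of the per-SNP Wald ratios with
#' inverse-variance weights stays consistent as long as at least half the
#' weight comes from valid instruments. The SE is a parametric bootstrap:
#' exposure and outcome betas are resampled from normal(beta, se), the
#' weighted median recomputed, and the bootstrap standard deviation taken.
#'
#' @param insts An `instrument_set` (>= 3 instruments).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed (mandatory: the reported p-value depends on it).
#' @return A one-row estimate tibble.
#' @export
weighted_median <- function(insts, n_boot = 1000, seed) {
  k <- nrow(insts)
  if (k < 3) stop("weighted median needs at least 3 instruments")
  stopifnot(n_boot >= 1)
  if (missing(seed)) stop("weighted_median requires an explicit seed")
  rw <- ratio_weights(insts)
  est <- weighted_median_point(rw$ratio, rw$w)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(k, insts$beta_exp, insts$se_exp)
      by <- stats::rnorm(k, insts$beta_out, insts$se_out)
      weighted_median_point(by / bx, bx^2 / insts$se_out^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_estimate("weighted_median", k, est, se, 2 * stats::pnorm(-abs(est / se)))
}

#' Cochran's Q heterogeneity test of the per-SNP ratios
#'
#' `Q = sum w_i (r_i - theta)^2` over the per-SNP Wald ratios with weights
#' `1/se_ratio^2`; the reference is chi-square with `nsnp - 1` degrees of
#' freedom. Evaluated at the fixed-effect IVW estimate, Q is minimal.
#'
#' @param insts An `instrument_set` (>= 2 instruments).
#' @param theta Causal effect to test around (typically the IVW estimate).
#' @return A list with `q_stat`, `df`, `pval`.
#' @export
cochran_q <- function(insts, theta) {
  k <- nrow(insts)
  if (k < 2) stop("Cochran's Q needs at least 2 instruments")
  rw <- ratio_weights(insts)
  q <- sum(rw$w * (rw$ratio - theta)^2)
  list(q_stat = q, df = k - 1L,
       pval = stats::pchisq(q, df = k - 1, lower.tail = FALSE))
}

#' Instrument strength F-statistics
#'
#' Per-SNP `F = (beta_exp / se_exp)^2` (the squared association z-score)
#' and the combined strength defined as their sum. Per-SNP F below ~10
#' flags weak-instrument bias risk.
#'
#' @param insts An `instrument_set` with exposure SEs.
#' @return A list with `per_snp_f` (named by rsID) and `combined_f`.
#' @export
instrument_strength <- function(insts) {
  f <- (insts$beta_exp / insts$se_exp)^2
  names(f) <- insts$snp_id
  list(per_snp_f = f, combined_f = sum(f))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; outputs are
#' returned in the input order and capped at 1.
#'
#' @param pvals P-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(pvals)
  o <- order(pvals)
  adj <- pvals[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Power of a two-sample MR study with a binary outcome
#'
#' Non-centrality approximation: with `b = ln(or_alt)` and
#' `v = n * r2_x * cf * (1 - cf)`, power at two-sided level alpha is
#' `pnorm(sqrt(v)*|b| - z) + pnorm(-sqrt(v)*|b| - z)` with
#' `z = qnorm(1 - alpha/2)`. Returns alpha at the null (`or_alt = 1`).
#'
#' @param n Total outcome-sample size.
#' @param case_fraction Proportion of cases in (0, 1).
#' @param r2_x Variance in the exposure explained by the instruments, (0, 1).
#' @param or_alt Hypothesized causal odds ratio.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in \[0, 1\].
#' @export
mr_power_binary <- function(n, case_fraction, r2_x, or_alt, alpha = 0.05) {
  stopifnot(n > 0, case_fraction > 0, case_fraction < 1,
            r2_x > 0, r2_x < 1, alpha > 0, alpha < 1, or_alt > 0)
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- sqrt(n * r2_x * case_fraction * (1 - case_fraction)) * abs(log(or_alt))
  stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
}
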