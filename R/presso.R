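# Leave-one-out fixed-effect IVW slopes for every SNP, via sum updates.
loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

# Weighted leave-one-out residual sum of squares of (bx, by).
presso_rss <- function(bx, by, w) {
  th <- loo_slopes(bx, by, w)
  res2 <- w * (by - th * bx)^2
  list(rss = sum(res2), res2 = res2, loo = th)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Detects horizontal-pleiotropy outlier instruments by comparing observed
#' leave-one-out IVW residuals with a simulated no-pleiotropy null, and
#' re-estimates the causal effect without the flagged outliers.
#'
#' The observed statistic is `RSS_obs`, the weighted sum over SNPs of the
#' squared residual of each SNP from the IVW slope fitted without it. The
#' null is simulated `n_sim` times by drawing `beta_exp* ~ N(beta_exp, se_exp)`
#' and `beta_out* ~ N(theta_loo * beta_exp, se_out)` and recomputing the same
#' statistic. The global p-value is the continuity-corrected exceedance
#' fraction; per-SNP outlier p-values compare each SNP's own squared
#' residual with its simulated counterparts, Bonferroni-multiplied by the
#' number of instruments. When outliers are flagged, the corrected estimate
#' is IVW on the remaining SNPs and a distortion test compares the raw vs
#' corrected slope shift against slopes from random outlier-sized subsets.
#'
#' The main (raw) causal estimate is the random-effects IVW slope with its
#' p-value taken from the t reference with `nsnp - 1` degrees of freedom.
#' Instruments are sorted by rsID before seeding, so results do not depend
#' on input order.
#'
#' @param insts An `instrument_set` (>= 4 instruments).
#' @param n_sim Number of simulated null datasets (>= 100; default 1000).
#' @param outlier_alpha Threshold on the Bonferroni-adjusted per-SNP
#'   p-value for calling an outlier (default 0.05).
#' @param seed Integer seed (mandatory).
#' @return A list of class `presso_result`: `rss_obs`, `global_pval`,
#'   `per_snp_pvals` (named), `outliers` (rsIDs), `raw_estimate`,
#'   `corrected_estimate` (or `NULL`), `distortion_pval` (or `NULL`),
#'   `estimate` (corrected if present, else raw).
#' @export
run_presso <- function(insts, n_sim = 1000, outlier_alpha = 0.05, seed) {
  k <- nrow(insts)
  if (k < 4) stop("MR-PRESSO needs at least 4 instruments")
  if (n_sim < 100) stop("n_sim must be at least 100")
  if (missing(seed)) stop("run_presso requires an explicit seed")
  insts <- insts[order(insts$snp_id), ]
  bx <- insts$beta_exp; by <- insts$beta_out
  sx <- insts$se_exp; sy <- insts$se_out
  w <- 1 / sy^2
  obs <- presso_rss(bx, by, w)

  sim <- withr::with_seed(seed, {
    bx_sim <- matrix(stats::rnorm(n_sim * k, mean = rep(bx, each = n_sim),
                                  sd = rep(sx, each = n_sim)), n_sim, k)
    by_sim <- matrix(stats::rnorm(n_sim * k, mean = rep(obs$loo * bx, each = n_sim),
                                  sd = rep(sy, each = n_sim)), n_sim, k)
    wm <- matrix(w, n_sim, k, byrow = TRUE)
    sxy <- rowSums(wm * bx_sim * by_sim)
    sxx <- rowSums(wm * bx_sim^2)
    th_loo <- (sxy - wm * bx_sim * by_sim) / (sxx - wm * bx_sim^2)
    res2 <- wm * (by_sim - th_loo * bx_sim)^2
    list(rss = rowSums(res2), res2 = res2)
  })

  global_pval <- (sum(sim$rss >= obs$rss) + 1) / (n_sim + 1)
  exceed <- colSums(sim$res2 >= rep(obs$res2, each = n_sim))
  per_snp <- pmin(1, (exceed + 1) / (n_sim + 1) * k)
  names(per_snp) <- insts$snp_id
  outliers <- insts$snp_id[per_snp < outlier_alpha]
  if (length(outliers) == k) stop("all instruments flagged as outliers; no estimate possible")

  raw <- ivw(insts)
  raw$method <- "presso"
  raw$pval <- 2 * stats::pt(-abs(raw$beta / raw$se), df = k - 1)

  corrected <- NULL
  distortion_pval <- NULL
  if (length(outliers) > 0) {
    keep <- insts[!insts$snp_id %in% outliers, ]
    corrected <- ivw(keep)
    corrected$method <- "presso_corrected"
    corrected$pval <- 2 * stats::pt(-abs(corrected$beta / corrected$se),
                                    df = nrow(keep) - 1)
    n_out <- length(outliers)
    null_shift <- withr::with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(b) {
        keep_i <- -sample.int(k, n_out)
        sum((w * bx * by)[keep_i]) / sum((w * bx^2)[keep_i])
      }, numeric(1))
    })
    obs_shift <- abs(corrected$beta - raw$beta)
    distortion_pval <- (sum(abs(null_shift - raw$beta) >= obs_shift) + 1) / (n_sim + 1)
  }

  structure(list(rss_obs = obs$rss, global_pval = global_pval,
                 per_snp_pvals = per_snp, outliers = outliers,
                 raw_estimate = raw, corrected_estimate = corrected,
                 distortion_pval = distortion_pval,
                 estimate = if (is.null(corrected)) raw else corrected),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS_obs = %.4g, global p = %.3g, %d outlier(s)\n",
              x$rss_obs, x$global_pval, length(x$outliers)))
  if (length(x$outliers)) {
    cat("outliers:", paste(x$outliers, collapse = ", "), "\n")
    cat(sprintf("distortion p = %.3g\n", x$distortion_pval))
  }
  print(x$estimate)
  invisible(x)
}
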