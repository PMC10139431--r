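#' Describe the generating truth of a synthetic two-sample dataset
#'
#' The linear instrumental-variable world every estimator here assumes:
#' each variant i has a true exposure effect gamma_i and a true outcome
#' effect `Gamma_i = theta * gamma_i + alpha_i`, where alpha_i is a direct
#' (pleiotropic) path bypassing the exposure. Observed summary statistics
#' add sampling noise at the stated SEs. Defaults mimic the signal-to-noise
#' regime of the packaged celiac-lymphoma fixture: exposure effects of
#' magnitude 0.1-0.35 with SEs ~0.03-0.04 and outcome SEs ~0.12-0.19.
#'
#' @param theta True causal effect (log-odds per exposure unit).
#' @param n_snps Number of instruments (default 11, the fixture's count).
#' @param gamma_range Magnitude range of true exposure effects (uniform).
#' @param gamma_sign `"mixed"` (random signs, emulating mixed allele
#'   coding, the default) or `"positive"` (all exposure effects oriented
#'   positive — the frame in which directional pleiotropy is defined, since
#'   the Egger intercept is not orientation-invariant).
#' @param se_exp_range,se_out_range Uniform SE ranges.
#' @param pleiotropy_mean,pleiotropy_sd Direct-effect distribution
#'   (balanced pleiotropy when the mean is 0; both 0 disables it).
#' @param outlier_frac Fraction of instruments given an extra pleiotropic
#'   offset, in \[0, 1).
#' @param outlier_shift Offset size in units of the outcome SE.
#' @param maf_range Effect-allele frequency range.
#' @param seed Integer seed (mandatory).
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(theta = 0, n_snps = 11,
                            gamma_range = c(0.1, 0.35),
                            gamma_sign = c("mixed", "positive"),
                            se_exp_range = c(0.03, 0.04),
                            se_out_range = c(0.12, 0.19),
                            pleiotropy_mean = 0, pleiotropy_sd = 0,
                            outlier_frac = 0, outlier_shift = 0,
                            maf_range = c(0.1, 0.5), seed) {
  stopifnot(n_snps >= 1, outlier_frac >= 0, outlier_frac < 1,
            all(se_exp_range > 0), all(se_out_range > 0),
            pleiotropy_sd >= 0, gamma_range[1] > 0)
  if (missing(seed)) stop("synthetic_truth requires an explicit seed")
  gamma_sign <- match.arg(gamma_sign)
  structure(list(theta = theta, n_snps = as.integer(n_snps),
                 gamma_range = gamma_range, gamma_sign = gamma_sign, se_exp_range = se_exp_range,
                 se_out_range = se_out_range,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 outlier_frac = outlier_frac, outlier_shift = outlier_shift,
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "synthetic_truth")
}

# Non-palindromic allele pairs only, so harmonization never rejects
# generated variants by default.
.nonpal_pairs <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"),
                       c("C", "A"), c("G", "A"), c("C", "T"), c("G", "T"))

#' Generate two-sample GWAS summary statistics with known causal truth
#'
#' Draws true per-variant effects under the truth's IV model, adds sampling
#' noise, and returns both a ready-to-estimate harmonized instrument set
#' and matching exposure/outcome association tables (with p-values computed
#' from the generated betas and SEs, so [se_from_pval()] round-trips
#' exactly). Deterministic given `truth$seed`.
#'
#' @param truth A [synthetic_truth()].
#' @return A list with `instruments` (an `instrument_set`), `exposure` and
#'   `outcome` (`assoc_tbl`s), and `truth` (the input extended with the
#'   drawn `gamma`, `alpha` and `outlier_idx`).
#' @export
generate_two_sample <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  k <- truth$n_snps
  out <- withr::with_seed(truth$seed, {
    gamma <- stats::runif(k, truth$gamma_range[1], truth$gamma_range[2])
    if (truth$gamma_sign == "mixed") {
      gamma <- gamma * sample(c(-1, 1), k, replace = TRUE)
    }
    se_exp <- stats::runif(k, truth$se_exp_range[1], truth$se_exp_range[2])
    se_out <- stats::runif(k, truth$se_out_range[1], truth$se_out_range[2])
    alpha <- if (truth$pleiotropy_sd > 0 || truth$pleiotropy_mean != 0) {
      stats::rnorm(k, truth$pleiotropy_mean, truth$pleiotropy_sd)
    } else {
      numeric(k)
    }
    n_out <- round(truth$outlier_frac * k)
    outlier_idx <- if (n_out > 0) sample.int(k, n_out) else integer()
    if (length(outlier_idx)) {
      alpha[outlier_idx] <- alpha[outlier_idx] +
        truth$outlier_shift * se_out[outlier_idx]
    }
    Gamma <- truth$theta * gamma + alpha
    beta_exp <- stats::rnorm(k, gamma, se_exp)
    beta_out <- stats::rnorm(k, Gamma, se_out)
    eaf <- stats::runif(k, truth$maf_range[1], truth$maf_range[2])
    pair <- .nonpal_pairs[sample.int(nrow(.nonpal_pairs), k, replace = TRUE), ,
                          drop = FALSE]
    list(gamma = gamma, alpha = alpha, outlier_idx = sort(outlier_idx),
         se_exp = se_exp, se_out = se_out, beta_exp = beta_exp,
         beta_out = beta_out, eaf = eaf, pair = pair)
  })
  ids <- sprintf("rs%07d", seq_len(k))
  pos <- 1e6 + seq_len(k) * 2e7  # spread out: no incidental clumping
  chrom <- rep_len(c(1:5, 7:12), k)
  p_exp <- 2 * stats::pnorm(-abs(out$beta_exp / out$se_exp))
  p_out <- 2 * stats::pnorm(-abs(out$beta_out / out$se_out))
  exposure <- association_records(ids, chrom, pos, out$pair[, 1], out$pair[, 2],
                                  out$beta_exp, pmax(p_exp, 1e-299),
                                  se = out$se_exp, eaf = out$eaf,
                                  trait_id = "synthetic_exposure")
  outcome <- association_records(ids, chrom, pos, out$pair[, 1], out$pair[, 2],
                                 out$beta_out, pmax(p_out, 1e-299),
                                 se = out$se_out, eaf = out$eaf,
                                 trait_id = "synthetic_outcome")
  insts <- instrument_set(
    tibble::tibble(snp_id = ids, beta_exp = out$beta_exp, se_exp = out$se_exp,
                   beta_out = out$beta_out, se_out = out$se_out,
                   eaf_out = out$eaf, flipped = FALSE),
    exposure_id = "synthetic_exposure", outcome_id = "synthetic_outcome",
    provenance = sprintf("generated under theta = %g, seed = %d",
                         truth$theta, truth$seed))
  truth$gamma <- out$gamma
  truth$alpha <- out$alpha
  truth$outlier_idx <- out$outlier_idx
  list(instruments = insts, exposure = exposure, outcome = outcome,
       truth = truth)
}

#' Generate association records with block-diagonal LD
#'
#' Builds `n_blocks` same-chromosome blocks of `snps_per_block` variants
#' each; within a block every pair has r-squared `r2_within`, across blocks
#' zero. With `r2_within` above the clumping threshold, exactly one SNP per
#' block (the smallest p) survives [select_instruments()].
#'
#' @param n_blocks,snps_per_block Block structure.
#' @param r2_within Within-block r-squared in \[0, 1).
#' @param seed Integer seed.
#' @return A list with `records` (`assoc_tbl`) and `ld` (long-format tibble
#'   `snp_a, snp_b, r2`).
#' @export
generate_ld_blocks <- function(n_blocks, snps_per_block, r2_within, seed) {
  stopifnot(r2_within >= 0, r2_within < 1)
  k <- n_blocks * snps_per_block
  out <- withr::with_seed(seed, {
    beta <- stats::rnorm(k, 0.25, 0.05) * sample(c(-1, 1), k, replace = TRUE)
    se <- stats::runif(k, 0.03, 0.04)
    list(beta = beta, se = se)
  })
  block <- rep(seq_len(n_blocks), each = snps_per_block)
  ids <- sprintf("rs9%03d%03d", block, sequence(rep(snps_per_block, n_blocks)))
  pos <- block * 1e6 + sequence(rep(snps_per_block, n_blocks)) * 1e3
  pval <- 2 * stats::pnorm(-abs(out$beta / out$se))
  records <- association_records(ids, chrom = 2L, pos_bp = pos,
                                 effect_allele = "A", other_allele = "C",
                                 beta = out$beta, pval = pmax(pval, 1e-299),
                                 se = out$se, trait_id = "synthetic_ld")
  pairs <- expand.grid(i = seq_len(k), j = seq_len(k))
  pairs <- pairs[pairs$i < pairs$j & block[pairs$i] == block[pairs$j], ]
  ld <- tibble::tibble(snp_a = ids[pairs$i], snp_b = ids[pairs$j],
                       r2 = r2_within)
  list(records = records, ld = ld)
}

#' Generate a synthetic multivariable MR input with known effects
#'
#' True exposure-effect matrix with the requested cross-exposure
#' correlation; outcome betas are the linear combination under
#' `true_effects` plus pleiotropy-free noise at the outcome SEs.
#'
#' @param k Instruments (e.g. 91, the celiac/smoking/waist union size).
#' @param m Exposures.
#' @param true_effects Length-m vector of true conditional effects.
#' @param correlation Cross-exposure correlation of true effects, |.| < 1.
#' @param se_exp_range,se_out_range Uniform SE ranges.
#' @param seed Integer seed.
#' @return A list with `input` (an [mvmr_input()]) and `truth`.
#' @export
generate_multivariable <- function(k, m, true_effects, correlation = 0,
                                   se_exp_range = c(0.01, 0.03),
                                   se_out_range = c(0.05, 0.1), seed) {
  stopifnot(k > m, length(true_effects) == m, abs(correlation) < 1)
  if (missing(seed)) stop("generate_multivariable requires an explicit seed")
  out <- withr::with_seed(seed, {
    Sigma <- matrix(correlation, m, m); diag(Sigma) <- 1
    L <- chol(Sigma)
    G <- matrix(stats::rnorm(k * m, 0, 0.15), k, m) %*% L
    S_exp <- matrix(stats::runif(k * m, se_exp_range[1], se_exp_range[2]), k, m)
    se_out <- stats::runif(k, se_out_range[1], se_out_range[2])
    B_exp <- G + matrix(stats::rnorm(k * m), k, m) * S_exp
    Gamma <- drop(G %*% true_effects)
    beta_out <- stats::rnorm(k, Gamma, se_out)
    list(G = G, B_exp = B_exp, S_exp = S_exp, beta_out = beta_out,
         se_out = se_out)
  })
  ids <- sprintf("rs8%06d", seq_len(k))
  labels <- paste0("exposure", seq_len(m))
  colnames(out$B_exp) <- labels
  input <- mvmr_input(ids, out$B_exp, out$S_exp, out$beta_out, out$se_out,
                      exposure_ids = labels)
  truth <- list(true_effects = true_effects, correlation = correlation,
                G = out$G, seed = as.integer(seed))
  list(input = input, truth = truth)
}
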