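#' Assemble a multivariable MR input
#'
#' @param snp_ids k rsIDs.
#' @param exposure_betas,exposure_ses k x m matrices (one column per
#'   exposure), column names taken as exposure labels if `exposure_ids`
#'   is missing.
#' @param outcome_beta,outcome_se Length-k outcome association vectors.
#' @param exposure_ids m exposure labels.
#' @return A list of class `mvmr_input`.
#' @export
mvmr_input <- function(snp_ids, exposure_betas, exposure_ses, outcome_beta,
                       outcome_se, exposure_ids = colnames(exposure_betas)) {
  exposure_betas <- as.matrix(exposure_betas)
  exposure_ses <- as.matrix(exposure_ses)
  k <- length(snp_ids); m <- ncol(exposure_betas)
  if (is.null(exposure_ids)) exposure_ids <- paste0("exposure", seq_len(m))
  stopifnot(nrow(exposure_betas) == k, all(dim(exposure_ses) == c(k, m)),
            length(outcome_beta) == k, length(outcome_se) == k,
            length(exposure_ids) == m)
  if (k <= m) stop("need more instruments than exposures (k > m)")
  stopifnot(all(exposure_ses > 0), all(outcome_se > 0))
  structure(list(snp_ids = as.character(snp_ids),
                 exposure_betas = exposure_betas, exposure_ses = exposure_ses,
                 outcome_beta = as.double(outcome_beta),
                 outcome_se = as.double(outcome_se),
                 exposure_ids = as.character(exposure_ids)),
            class = "mvmr_input")
}

#' Multivariable IVW regression
#'
#' Jointly regresses the outcome associations on all exposures' associations
#' (no intercept) with weights `1/outcome_se^2`, estimating each exposure's
#' direct causal effect conditional on the others. SEs use the residual
#' scale floored at 1; p-values use the normal reference. Exposure-side
#' measurement error is ignored (standard MVMR-IVW).
#'
#' @param input An [mvmr_input()].
#' @return An estimate tibble with one row per exposure (extra column
#'   `exposure`).
#' @export
mvmr_ivw <- function(input) {
  stopifnot(inherits(input, "mvmr_input"))
  X <- input$exposure_betas
  k <- nrow(X); m <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < m) {
    bad <- input$exposure_ids[qrX$pivot[(qrX$rank + 1):m]]
    stop("collinear exposure columns: ", paste(bad, collapse = ", "))
  }
  w <- 1 / input$outcome_se^2
  xtwx <- crossprod(X * sqrt(w))
  beta <- unname(drop(solve(xtwx, crossprod(X, w * input$outcome_beta))))
  resid <- input$outcome_beta - drop(X %*% beta)
  sigma2 <- sum(w * resid^2) / (k - m)
  ses <- unname(sqrt(diag(solve(xtwx)) * max(1, sigma2)))
  out <- mr_estimate("mvmr_ivw", k, beta, ses,
                     2 * stats::pnorm(-abs(beta / ses)))
  out$exposure <- input$exposure_ids
  out[, c("exposure", setdiff(names(out), "exposure"))]
}

#' Build a multivariable instrument set from per-exposure associations
#'
#' Pools the instruments selected for each exposure and clumps them into a
#' single independent set. In `"union"` mode all candidate instruments are
#' pooled first and clumped across the pool; in `"exposure_specific"` mode
#' each exposure's own candidates are clumped separately and the survivors
#' unioned (duplicates kept once). Cross-trait associations for every
#' surviving SNP must be supplied for all exposures and the outcome — no
#' imputation is attempted.
#'
#' @param per_exposure_records Named list of m association tables, each
#'   already filtered to its own significance threshold.
#' @param outcome_records Association table for the outcome, covering every
#'   surviving SNP.
#' @param cross_records Optional association table pool holding each
#'   surviving SNP's association with every exposure (defaults to the
#'   concatenation of `per_exposure_records`, which then must already be
#'   complete).
#' @param ld,r2_max,window_bp Clumping inputs as in [select_instruments()].
#' @param mode `"union"` or `"exposure_specific"`.
#' @return An [mvmr_input()].
#' @export
build_union_ivset <- function(per_exposure_records, outcome_records,
                              cross_records = NULL, ld = NULL,
                              r2_max = 0.001, window_bp = 5e6,
                              mode = c("union", "exposure_specific")) {
  mode <- match.arg(mode)
  stopifnot(is.list(per_exposure_records), length(per_exposure_records) >= 1)
  if (is.null(names(per_exposure_records))) {
    names(per_exposure_records) <- paste0("exposure", seq_along(per_exposure_records))
  }
  if (mode == "union") {
    pool <- dplyr::bind_rows(per_exposure_records)
    pool <- pool[!duplicated(pool$snp_id), ]
    kept <- select_instruments(pool, p_threshold = 1, ld = ld,
                               r2_max = r2_max, window_bp = window_bp)
    snps <- kept$snp_id
  } else {
    snps <- unique(unlist(lapply(per_exposure_records, function(rec) {
      select_instruments(rec, p_threshold = 1, ld = ld, r2_max = r2_max,
                         window_bp = window_bp)$snp_id
    })))
  }
  if (is.null(cross_records)) cross_records <- dplyr::bind_rows(per_exposure_records)
  m <- length(per_exposure_records)
  k <- length(snps)
  B <- matrix(NA_real_, k, m, dimnames = list(snps, names(per_exposure_records)))
  S <- B
  for (j in seq_len(m)) {
    src <- cross_records[cross_records$trait_id == names(per_exposure_records)[j], ]
    src <- fill_se(src)
    hit <- match(snps, src$snp_id)
    B[, j] <- src$beta[hit]
    S[, j] <- src$se[hit]
  }
  out <- fill_se(outcome_records)
  hit_out <- match(snps, out$snp_id)
  incomplete <- snps[apply(is.na(B) | is.na(S), 1, any) | is.na(hit_out)]
  if (length(incomplete)) {
    stop("missing cross-trait or outcome association(s) for: ",
         paste(incomplete, collapse = ", "))
  }
  mvmr_input(snps, B, S, out$beta[hit_out], out$se[hit_out],
             exposure_ids = names(per_exposure_records))
}
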