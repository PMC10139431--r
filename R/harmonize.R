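#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so allele labels alone
#' cannot resolve strand orientation.
#'
#' @param a1,a2 Alleles among A/C/G/T (vectorized).
#' @return Logical.
#' @export
is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  if (any(!a1 %in% c("A", "C", "G", "T")) || any(!a2 %in% c("A", "C", "G", "T"))) {
    stop("alleles must be one of A/C/G/T")
  }
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

complement_allele <- function(a) c(A = "T", T = "A", C = "G", G = "C")[a]

#' Align one exposure/outcome record pair onto a shared effect allele
#'
#' Orients the outcome association onto the exposure's effect allele:
#' matching labels are copied, swapped labels negate the outcome beta and
#' set `flipped`, and when neither orientation matches the outcome alleles
#' are strand-complemented and retried. Palindromic variants are rejected
#' (when `drop_palindromic`) unless the outcome allele frequency is extreme
#' enough (outside `[ambiguity_maf, 1 - ambiguity_maf]`) to resolve strand.
#'
#' @param exp_rec,out_rec Single association records (one-row data frames or
#'   named lists) for the same SNP; SEs missing are reconstructed with
#'   [se_from_pval()].
#' @param drop_palindromic Reject strand-ambiguous palindromic SNPs
#'   (default `TRUE`).
#' @param ambiguity_maf Frequency band treated as strand-ambiguous for
#'   palindromic SNPs (default 0.3).
#' @return A one-row tibble with `snp_id, beta_exp, se_exp, beta_out,
#'   se_out, eaf_out, flipped`, or an `mr_rejection` object (check with
#'   [is_rejection()]; the `$reason` field says why).
#' @export
harmonize <- function(exp_rec, out_rec, drop_palindromic = TRUE,
                      ambiguity_maf = 0.3) {
  if (exp_rec$snp_id != out_rec$snp_id) {
    stop("cannot harmonize different SNPs: ", exp_rec$snp_id, " vs ", out_rec$snp_id)
  }
  reject <- function(reason) {
    structure(list(snp_id = exp_rec$snp_id, reason = reason),
              class = "mr_rejection")
  }
  ea_x <- toupper(exp_rec$effect_allele); oa_x <- toupper(exp_rec$other_allele)
  ea_y <- toupper(out_rec$effect_allele); oa_y <- toupper(out_rec$other_allele)
  pal <- is_palindromic(ea_x, oa_x)
  eaf <- if (!is.null(out_rec$eaf)) out_rec$eaf else NA_real_
  if (pal && drop_palindromic) {
    ambiguous <- is.na(eaf) ||
      (eaf >= ambiguity_maf && eaf <= 1 - ambiguity_maf)
    if (ambiguous) return(reject("palindromic and strand-ambiguous"))
  }
  beta_out <- out_rec$beta
  flipped <- FALSE
  if (ea_y == ea_x && oa_y == oa_x) {
    # already co-oriented
  } else if (ea_y == oa_x && oa_y == ea_x) {
    beta_out <- -beta_out
    flipped <- TRUE
    if (!is.na(eaf)) eaf <- 1 - eaf
  } else if (!pal &&
             complement_allele(ea_y) == ea_x && complement_allele(oa_y) == oa_x) {
    # opposite strand, same orientation
  } else if (!pal &&
             complement_allele(ea_y) == oa_x && complement_allele(oa_y) == ea_x) {
    beta_out <- -beta_out
    flipped <- TRUE
    if (!is.na(eaf)) eaf <- 1 - eaf
  } else {
    return(reject(sprintf("unresolvable alleles %s/%s vs %s/%s",
                          ea_x, oa_x, ea_y, oa_y)))
  }
  se_x <- exp_rec$se
  if (is.null(se_x) || is.na(se_x)) se_x <- se_from_pval(exp_rec$beta, exp_rec$pval)
  se_y <- out_rec$se
  if (is.null(se_y) || is.na(se_y)) se_y <- se_from_pval(out_rec$beta, out_rec$pval)
  tibble::tibble(snp_id = exp_rec$snp_id, beta_exp = exp_rec$beta,
                 se_exp = se_x, beta_out = beta_out, se_out = se_y,
                 eaf_out = eaf, flipped = flipped)
}

#' Did harmonization reject this SNP?
#'
#' @param x A [harmonize()] result.
#' @return `TRUE` for an `mr_rejection` object.
#' @export
is_rejection <- function(x) inherits(x, "mr_rejection")

#' Build a harmonized instrument set from exposure and outcome tables
#'
#' Joins on `snp_id`, harmonizes each pair with [harmonize()], and records
#' every rejection in the set's provenance.
#'
#' @param exposure,outcome Association tables (`assoc_tbl`).
#' @param exposure_id,outcome_id Trait labels attached to the set.
#' @inheritParams harmonize
#' @return An `instrument_set`: a tibble of harmonized instruments with
#'   attributes `exposure_id`, `outcome_id` and `provenance`.
#' @export
harmonize_sets <- function(exposure, outcome,
                           exposure_id = exposure$trait_id[1],
                           outcome_id = outcome$trait_id[1],
                           drop_palindromic = TRUE, ambiguity_maf = 0.3) {
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  prov <- character()
  dropped <- setdiff(union(exposure$snp_id, outcome$snp_id), shared)
  if (length(dropped)) {
    prov <- c(prov, paste0("absent from one side: ", paste(dropped, collapse = ", ")))
  }
  rows <- list()
  for (id in shared) {
    h <- harmonize(exposure[exposure$snp_id == id, ][1, ],
                   outcome[outcome$snp_id == id, ][1, ],
                   drop_palindromic = drop_palindromic,
                   ambiguity_maf = ambiguity_maf)
    if (is_rejection(h)) {
      prov <- c(prov, paste0(id, " rejected: ", h$reason))
    } else {
      rows[[id]] <- h
    }
  }
  instrument_set(dplyr::bind_rows(rows), exposure_id = exposure_id,
                 outcome_id = outcome_id, provenance = prov)
}

#' Construct an instrument set
#'
#' @param instruments Tibble with columns `snp_id, beta_exp, se_exp,
#'   beta_out, se_out` (and optionally `eaf_out`, `flipped`).
#' @param exposure_id,outcome_id Trait labels.
#' @param provenance Character vector of audit notes.
#' @return The tibble classed `instrument_set` with the labels as attributes.
#' @export
instrument_set <- function(instruments, exposure_id = "exposure",
                           outcome_id = "outcome", provenance = character()) {
  needed <- c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out")
  if (nrow(instruments) > 0) {
    stopifnot(all(needed %in% names(instruments)))
    if (anyDuplicated(instruments$snp_id)) stop("duplicate snp_id in instrument set")
    stopifnot(all(instruments$se_exp > 0), all(instruments$se_out > 0))
  }
  structure(instruments, class = unique(c("instrument_set", class(instruments))),
            exposure_id = exposure_id, outcome_id = outcome_id,
            provenance = provenance)
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %s -> %s (%d SNPs)\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x)))
  print(tibble::as_tibble(x), ...)
  prov <- attr(x, "provenance")
  if (length(prov)) cat("provenance:", paste(prov, collapse = "; "), "\n")
  invisible(x)
}

# Keep attributes when subsetting rows of an instrument set.
#' @export
`[.instrument_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("snp_id", "beta_exp") %in% names(out))) {
    attr(out, "exposure_id") <- attr(x, "exposure_id")
    attr(out, "outcome_id") <- attr(x, "outcome_id")
    attr(out, "provenance") <- attr(x, "provenance")
    class(out) <- unique(c("instrument_set", class(out)))
  }
  out
}

# Normalize the many LD inputs (NULL, labelled matrix, long data frame,
# function) into a lookup function r2(a, b).
ld_lookup <- function(ld) {
  if (is.null(ld)) return(function(a, b) 0)
  if (is.function(ld)) return(ld)
  if (is.matrix(ld)) {
    stopifnot(!is.null(rownames(ld)), !is.null(colnames(ld)))
    return(function(a, b) {
      if (a %in% rownames(ld) && b %in% colnames(ld)) ld[a, b] else 0
    })
  }
  if (is.data.frame(ld)) {
    stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(ld)))
    key <- c(paste(ld$snp_a, ld$snp_b), paste(ld$snp_b, ld$snp_a))
    val <- c(ld$r2, ld$r2)
    return(function(a, b) {
      hit <- match(paste(a, b), key)
      if (is.na(hit)) 0 else val[hit]
    })
  }
  stop("unsupported LD input")
}

#' Select independent genome-wide-significant instruments by greedy clumping
#'
#' Records passing `p_threshold` are sorted by ascending p-value (ties
#' broken by chromosome then position, for determinism) and accepted
#' greedily: a record is kept iff its r-squared with every previously kept
#' record on the same chromosome within `window_bp` is at most `r2_max`.
#'
#' @param records Association table (`assoc_tbl`).
#' @param p_threshold Significance cutoff (default genome-wide, 5e-8).
#' @param ld Pairwise r-squared source: `NULL` (all independent), a
#'   labelled square matrix, a long data frame `(snp_a, snp_b, r2)`, or a
#'   function `(a, b) -> r2`.
#' @param r2_max Maximum allowed r-squared between retained pairs
#'   (default 0.001).
#' @param window_bp Clumping window, +/- bp (default 5 Mb).
#' @return The retained records, in input order.
#' @export
select_instruments <- function(records, p_threshold = 5e-8, ld = NULL,
                               r2_max = 0.001, window_bp = 5e6) {
  pass <- records[records$pval < p_threshold, , drop = FALSE]
  if (nrow(pass) == 0) return(pass)
  r2 <- ld_lookup(ld)
  ord <- order(pass$pval, pass$chrom, pass$pos_bp)
  kept <- integer()
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      same_chr <- !is.na(pass$chrom[i]) && !is.na(pass$chrom[j]) &&
        pass$chrom[i] == pass$chrom[j]
      if (same_chr && abs(pass$pos_bp[i] - pass$pos_bp[j]) <= window_bp &&
          r2(pass$snp_id[i], pass$snp_id[j]) > r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  pass[sort(kept), , drop = FALSE]
}
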