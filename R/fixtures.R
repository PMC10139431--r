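#' Load the packaged celiac-disease / lymphoma instrument fixture
#'
#' The complete instrument-level inputs of the celiac-disease MR study this
#' package reproduces: 11 non-HLA celiac-disease instruments (discovery
#' GWAS betas and p-values) against 8 malignancy outcomes (6 FinnGen
#' lymphoma subtypes plus two UK Biobank traits on the linear-probability
#' scale). Standard errors are not part of the source and are reconstructed
#' downstream with [se_from_pval()]. The proxy recorded for rs2327832
#' (rs6920220) in the FinnGen outcomes is kept in the `proxy` column.
#'
#' @return A list with `exposure` (an `assoc_tbl` of the 11 instruments'
#'   celiac-disease associations) and `outcomes` (a named list of 8
#'   `assoc_tbl`s with the instruments' outcome associations).
#' @export
celiac_lymphoma_fixture <- function() {
  path <- system.file("extdata", "celiac_lymphoma_ivs.tsv",
                      package = "mrceliac", mustWork = TRUE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  make <- function(df, beta, pval, eaf, trait) {
    association_records(df$snp, df$chr, df$pos, df$effect_allele,
                        df$other_allele, beta, pval, eaf = eaf,
                        trait_id = trait)
  }
  outcomes <- lapply(split(raw, raw$outcome), function(df) {
    make(df, df$beta_outcome, df$pval_outcome, df$eaf_outcome, df$outcome[1])
  })
  first <- raw[!duplicated(sub(" .*", "", raw$snp)), ]
  exposure <- make(first, first$beta_exposure, first$pval_exposure,
                   NA_real_, "Celiac disease")
  list(exposure = exposure, outcomes = outcomes[unique(raw$outcome)])
}

#' Published causal-estimate table for the celiac-lymphoma study
#'
#' The printed estimates (p-value, OR, 95% CI bounds) of the four 2SMR
#' methods for all 8 outcomes, as packaged regression surface for
#' [run_study()].
#'
#' @return A tibble with `outcome, method, pval, or, ci_low, ci_high`.
#' @export
published_estimates <- function() {
  path <- system.file("extdata", "published_estimates.csv",
                      package = "mrceliac", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Harmonized instrument set for one fixture outcome
#'
#' Convenience wrapper: selects the fixture's instruments (HLA mask, p <
#' 5e-8; all 11 survive) and harmonizes them against the named outcome.
#'
#' @param outcome Outcome name as in the fixture, e.g.
#'   `"Mature T/NK-cell lymphomas"`.
#' @return An `instrument_set` of 11 instruments.
#' @export
fixture_instruments <- function(outcome = "Mature T/NK-cell lymphomas") {
  fx <- celiac_lymphoma_fixture()
  if (!outcome %in% names(fx$outcomes)) {
    stop("unknown fixture outcome: ", outcome, "; available: ",
         paste(names(fx$outcomes), collapse = "; "))
  }
  kept <- filter_region(fx$exposure, hla_region())
  kept <- select_instruments(kept, p_threshold = 5e-8)
  harmonize_sets(kept, fx$outcomes[[outcome]],
                 exposure_id = "Celiac disease", outcome_id = outcome)
}
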