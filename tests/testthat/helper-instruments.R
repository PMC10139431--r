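# Small in-code fixtures shared across test files.

# Build an instrument set directly from vectors.
make_insts <- function(beta_exp, beta_out, se_exp = rep(0.03, length(beta_exp)),
                       se_out = rep(0.15, length(beta_exp)),
                       ids = sprintf("rs%04d", seq_along(beta_exp))) {
  instrument_set(tibble::tibble(
    snp_id = ids, beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out
  ))
}

# One association record as a one-row tibble.
make_record <- function(snp_id = "rs1", chrom = 1L, pos_bp = 1000L,
                        effect_allele = "A", other_allele = "C", beta = 0.1,
                        pval = 1e-3, se = NA_real_, eaf = NA_real_,
                        trait_id = "trait") {
  association_records(snp_id, chrom, pos_bp, effect_allele, other_allele,
                      beta, pval, se = se, eaf = eaf, trait_id = trait_id)
}

# The mature T/NK instrument set, loaded once per test run.
tnk_instruments <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fixture_instruments("Mature T/NK-cell lymphomas")
    cache
  }
})
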