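test_that("se_from_pval inverts the two-sided Wald test", {
  # oracle: z computed independently with qnorm on the fixture's own numbers
  expect_equal(se_from_pval(-0.267, 2.33e-2), 0.267 / 2.268, tolerance = 1e-3)
  expect_equal(se_from_pval(1.959964, 0.05), 1.0, tolerance = 1e-6)
  expect_equal(se_from_pval(-0.3239, 6.31e-18), 0.03755, tolerance = 1e-3)

  # exact inverse property: p(beta, se(beta, p)) == p to 1e-10 relative
  set.seed(11)
  beta <- stats::rnorm(200, 0, 0.5)
  p <- stats::runif(200, 1e-12, 0.999)
  se <- se_from_pval(beta, p)
  p_back <- 2 * stats::pnorm(-abs(beta / se))
  expect_equal(p_back, p, tolerance = 1e-10)
})

test_that("se_from_pval rejects degenerate inputs", {
  expect_error(se_from_pval(0.1, 0), "pval")
  expect_error(se_from_pval(0.1, 1), "pval")
  expect_error(se_from_pval(0, 0.5), "beta = 0")
  expect_error(se_from_pval(0.1, 1e-310), "supply the SE")
})

test_that("region filtering removes exactly the masked interval", {
  recs <- make_record(
    snp_id = c("rs1738074", "inHLA", "rs2327832"),
    chrom = c(6L, 6L, 6L),
    pos_bp = c(159465977L, 30000000L, 138006504L),
    beta = c(-0.14, 0.2, 0.23), pval = c(1e-8, 1e-9, 1e-10)
  )
  kept <- filter_region(recs, hla_region())
  expect_setequal(kept$snp_id, c("rs1738074", "rs2327832"))
  # partition property: kept + inside = input, no loss or duplication
  inside <- recs[!recs$snp_id %in% kept$snp_id, ]
  expect_setequal(c(kept$snp_id, inside$snp_id), recs$snp_id)
  expect_identical(kept$snp_id, setdiff(recs$snp_id, inside$snp_id))
})

test_that("palindromy detection matches complement pairs", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("T", "C"))  # the retained rs1738074 coding
  expect_false(is_palindromic("G", "A"))
  expect_error(is_palindromic("N", "A"), "A/C/G/T")
})

test_that("harmonization aligns, flips, and rejects correctly", {
  ex <- make_record("rs1738074", 6L, 159465977L, "C", "T", -0.1424, 3.14e-8)
  out_same <- make_record("rs1738074", 6L, 159465977L, "C", "T", -0.267, 2.33e-2)
  h <- harmonize(ex, out_same)
  expect_false(h$flipped)
  expect_equal(h$beta_out, -0.267)

  out_swapped <- make_record("rs1738074", 6L, 159465977L, "T", "C", 0.267, 2.33e-2)
  h2 <- harmonize(ex, out_swapped)
  expect_true(h2$flipped)
  expect_equal(h2$beta_out, -0.267)

  # involution safety: align of the aligned pair is a no-op; double swap
  # restores the original outcome beta
  h3 <- harmonize(ex, out_same)
  expect_equal(h3$beta_out, h$beta_out)
  expect_equal(-h2$beta_out, out_swapped$beta)

  # strand-complement rescue: outcome coded on the other strand (G/A vs C/T)
  out_strand <- make_record("rs1738074", 6L, 159465977L, "G", "A", -0.267, 2.33e-2)
  h4 <- harmonize(ex, out_strand)
  expect_false(h4$flipped)
  expect_equal(h4$beta_out, -0.267)

  # ambiguous palindromic SNP rejected
  ex_pal <- make_record("rsP", 1L, 100L, "A", "T", 0.2, 1e-9)
  out_pal <- make_record("rsP", 1L, 100L, "A", "T", 0.1, 0.5, eaf = 0.50)
  expect_true(is_rejection(harmonize(ex_pal, out_pal)))
  # ...but kept when frequency resolves the strand
  out_pal2 <- make_record("rsP", 1L, 100L, "A", "T", 0.1, 0.5, eaf = 0.05)
  expect_false(is_rejection(harmonize(ex_pal, out_pal2)))

  expect_error(harmonize(ex, make_record("rsX", 1L, 1L, "C", "T", 0.1, 0.5)),
               "different SNPs")
  out_bad <- make_record("rs1738074", 6L, 159465977L, "A", "C", 0.1, 0.5)
  rej <- harmonize(ex, out_bad)
  expect_true(is_rejection(rej))
  expect_match(rej$reason, "unresolvable")
})

test_that("greedy clumping keeps the most significant of linked pairs", {
  recs <- make_record(snp_id = c("rsA", "rsB", "rsC"),
                      chrom = c(1L, 1L, 1L), pos_bp = c(1e6, 2e6, 3e6),
                      beta = 0.3, pval = c(1e-10, 1e-9, 1e-12))
  # independent: all survive
  expect_equal(nrow(select_instruments(recs)), 3)
  # rsA-rsB linked at r2 = 0.5: the smaller p (rsA) wins
  ld <- tibble::tibble(snp_a = "rsA", snp_b = "rsB", r2 = 0.5)
  kept <- select_instruments(recs, ld = ld)
  expect_setequal(kept$snp_id, c("rsA", "rsC"))
  # outside the window the pair is not compared
  kept2 <- select_instruments(recs, ld = ld, window_bp = 5e5)
  expect_equal(nrow(kept2), 3)
})

test_that("clumping output never contains a linked same-chromosome pair", {
  blocks <- generate_ld_blocks(5, 4, r2_within = 0.8, seed = 42)
  kept <- select_instruments(blocks$records, p_threshold = 1, ld = blocks$ld)
  expect_equal(nrow(kept), 5)  # exactly one survivor per block
  r2 <- mrceliac:::ld_lookup(blocks$ld)
  for (i in seq_len(nrow(kept))) {
    for (j in seq_len(nrow(kept))) {
      if (i < j && kept$chrom[i] == kept$chrom[j] &&
          abs(kept$pos_bp[i] - kept$pos_bp[j]) <= 5e6) {
        expect_lte(r2(kept$snp_id[i], kept$snp_id[j]), 0.001)
      }
    }
  }
  # no LD: everything survives
  free <- generate_ld_blocks(3, 3, r2_within = 0, seed = 43)
  expect_equal(nrow(select_instruments(free$records, p_threshold = 1,
                                       ld = free$ld)), 9)
  one <- generate_ld_blocks(1, 1, r2_within = 0, seed = 44)
  expect_equal(nrow(select_instruments(one$records, p_threshold = 1,
                                       ld = one$ld)), 1)
})

test_that("the optional MAF filter drops rare variants and keeps unknowns", {
  recs <- make_record(snp_id = c("common", "rare", "flip", "unknown"),
                      chrom = 1L, pos_bp = 1:4 * 1000L, beta = 0.1, pval = 0.01,
                      eaf = c(0.3, 0.01, 0.98, NA))
  kept <- filter_maf(recs)
  expect_setequal(kept$snp_id, c("common", "unknown"))
  # every packaged instrument is a common variant in every outcome GWAS
  fx <- celiac_lymphoma_fixture()
  for (out in fx$outcomes) expect_equal(nrow(filter_maf(out)), 11)
})

test_that("the packaged fixture loads 11 instruments for each of 8 outcomes", {
  fx <- celiac_lymphoma_fixture()
  expect_length(fx$outcomes, 8)
  for (out in fx$outcomes) {
    expect_equal(nrow(out), 11)
    expect_equal(anyDuplicated(out$snp_id), 0)
  }
  expect_equal(nrow(fx$exposure), 11)
  # the proxy parenthetical is parsed: base rsID kept, proxy recorded
  dlbcl <- fx$outcomes[["Diffuse large B-cell lymphoma"]]
  expect_true("rs2327832" %in% dlbcl$snp_id)
  expect_equal(dlbcl$proxy[dlbcl$snp_id == "rs2327832"], "rs6920220")
  # all 11 pass genome-wide significance and clump as independent
  kept <- select_instruments(filter_region(fx$exposure, hla_region()))
  expect_equal(nrow(kept), 11)
})

test_that("summary TSV round-trips losslessly", {
  fx <- celiac_lymphoma_fixture()
  rec <- fx$outcomes[["Mature T/NK-cell lymphomas"]]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_tsv(rec, path)
  back <- read_summary_tsv(path)
  for (col in c("snp_id", "chrom", "pos_bp", "effect_allele", "other_allele",
                "beta", "pval", "eaf")) {
    expect_equal(back[[col]], rec[[col]], info = col)
  }
})

test_that("summary TSV reader reports schema and row-level errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("snp\tchr\tpos\teffect_allele\tother_allele\tbeta\tpval", path)
  expect_equal(nrow(read_summary_tsv(path)), 0)
  writeLines(c("snp\tchr\tpos\teffect_allele\tother_allele\tbeta\tpval",
               "rs1\t1\t100\tA\tC\tnot_a_number\t0.5"), path)
  expect_error(read_summary_tsv(path), "unparsable numeric")
  writeLines("snp\tchr\tpos\teffect_allele", path)
  expect_error(read_summary_tsv(path), "missing mandatory column")
})
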