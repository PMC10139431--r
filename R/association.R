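#' Construct a table of summary-association records
#'
#' The basic currency of a two-sample MR analysis: one row per SNP-trait
#' pair carrying the per-effect-allele association estimate from a GWAS.
#' Betas are on the log-odds scale for case-control traits; linear-model
#' betas are permitted (and passed through unconverted, see the package
#' vignette on mixed effect scales).
#'
#' @param snp_id Character rsIDs. A proxy recorded in the source as
#'   `"rs123 (rs456)"` is accepted: the first rsID is kept and the proxy
#'   noted in the `proxy` column.
#' @param chrom Integer chromosome, 1-22 (sex chromosomes out of scope).
#' @param pos_bp Integer 1-based base-pair position (GRCh37).
#' @param effect_allele,other_allele Single bases among A/C/G/T.
#' @param beta Per-effect-allele effect size.
#' @param se Positive standard error, or `NA` to reconstruct downstream
#'   from the p-value via [se_from_pval()].
#' @param pval Two-sided association p-value in (0, 1].
#' @param eaf Effect-allele frequency in (0, 1), or `NA`.
#' @param trait_id Character trait label.
#' @return A tibble with class `assoc_tbl`, one validated record per row.
#' @export
association_records <- function(snp_id, chrom, pos_bp, effect_allele,
                                other_allele, beta, pval, se = NA_real_,
                                eaf = NA_real_, trait_id = "trait") {
  proxy <- rep(NA_character_, length(snp_id))
  paren <- grepl("\\(", snp_id)
  if (any(paren)) {
    proxy[paren] <- sub("^.*\\(([^)]+)\\).*$", "\\1", snp_id[paren])
    snp_id[paren] <- trimws(sub("\\(.*$", "", snp_id[paren]))
  }
  rec <- tibble::tibble(
    snp_id = as.character(snp_id),
    chrom = as.integer(chrom),
    pos_bp = as.integer(pos_bp),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    beta = as.double(beta),
    se = rep_len(as.double(se), length(snp_id)),
    pval = as.double(pval),
    eaf = rep_len(as.double(eaf), length(snp_id)),
    trait_id = rep_len(as.character(trait_id), length(snp_id)),
    proxy = proxy
  )
  validate_associations(rec)
}

#' Validate a table of association records
#'
#' Checks the invariants every record must satisfy: valid distinct alleles,
#' p-values in (0, 1], positive SEs where present, frequencies in (0, 1)
#' where present.
#'
#' @param rec A data frame of association records.
#' @return The input, invisibly classed as `assoc_tbl`, or an error.
#' @export
validate_associations <- function(rec) {
  stopifnot(is.data.frame(rec))
  needed <- c("snp_id", "effect_allele", "other_allele", "beta", "pval")
  missing <- setdiff(needed, names(rec))
  if (length(missing)) {
    stop("association table lacks column(s): ", paste(missing, collapse = ", "))
  }
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  if (!all(ok_allele(rec$effect_allele)) || !all(ok_allele(rec$other_allele))) {
    stop("alleles must be one of A/C/G/T")
  }
  if (any(rec$effect_allele == rec$other_allele)) {
    stop("effect_allele must differ from other_allele")
  }
  if (any(!is.finite(rec$pval) | rec$pval <= 0 | rec$pval > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if ("se" %in% names(rec) && any(!is.na(rec$se) & rec$se <= 0)) {
    stop("standard errors must be positive where present")
  }
  if ("eaf" %in% names(rec) && any(!is.na(rec$eaf) & (rec$eaf <= 0 | rec$eaf >= 1))) {
    stop("effect-allele frequencies must lie in (0, 1) where present")
  }
  class(rec) <- unique(c("assoc_tbl", class(rec)))
  invisible(rec)
}

#' Reconstruct a standard error from a beta and its two-sided p-value
#'
#' Inverts the two-sided Wald test: `se = |beta| / z` with
#' `z = qnorm(p/2, lower.tail = FALSE)`. This is how per-SNP SEs are
#' recovered when a source reports only betas and p-values.
#'
#' @param beta Effect size (any real, nonzero unless `pval == 1`).
#' @param pval Two-sided p-value, strictly inside (0, 1).
#' @return Positive standard error, vectorized over inputs.
#' @examples
#' se_from_pval(-0.267, 2.33e-2)   # ~0.1177
#' se_from_pval(1.959964, 0.05)    # 1.0
#' @export
se_from_pval <- function(beta, pval) {
  if (any(!is.finite(pval) | pval <= 0 | pval >= 1)) {
    stop("pval must lie strictly inside (0, 1)")
  }
  if (any(pval < 1e-300)) {
    stop("p-value too small to invert reliably; supply the SE directly")
  }
  if (any(beta == 0)) {
    stop("beta = 0 with pval < 1: SE is undefined; supply the SE directly")
  }
  z <- stats::qnorm(pval / 2, lower.tail = FALSE)
  abs(beta) / z
}

# Fill missing SEs in an association table from (beta, pval).
fill_se <- function(rec) {
  if (!"se" %in% names(rec)) rec$se <- NA_real_
  idx <- is.na(rec$se)
  if (any(idx)) rec$se[idx] <- se_from_pval(rec$beta[idx], rec$pval[idx])
  rec
}

#' Define a genomic region
#'
#' 1-based inclusive coordinates on GRCh37, e.g. the extended HLA region
#' `genomic_region(6, 20e6, 40e6)` that is masked before instrument
#' selection in celiac disease MR.
#'
#' @param chrom Integer chromosome.
#' @param start_bp,end_bp Inclusive 1-based bounds, `start_bp <= end_bp`.
#' @return A `genomic_region` list.
#' @export
genomic_region <- function(chrom, start_bp, end_bp) {
  stopifnot(length(chrom) == 1, start_bp <= end_bp)
  structure(list(chrom = as.integer(chrom), start_bp = as.numeric(start_bp),
                 end_bp = as.numeric(end_bp)),
            class = "genomic_region")
}

#' The extended HLA region mask (chr6:20-40 Mb, GRCh37)
#'
#' Excluded from celiac-disease instrument sets because the strong, complex
#' LD of the DQ2/DQ8 haplotypes with disease risk would bias IV analysis.
#'
#' @return A [genomic_region()].
#' @export
hla_region <- function() genomic_region(6L, 2e7, 4e7)

#' Drop records falling inside a genomic region
#'
#' @param records An association table with `chrom` and `pos_bp`.
#' @param region A [genomic_region()].
#' @return The records NOT inside the region, order preserved.
#' @export
filter_region <- function(records, region) {
  stopifnot(inherits(region, "genomic_region"))
  inside <- records$chrom == region$chrom &
    records$pos_bp >= region$start_bp & records$pos_bp <= region$end_bp
  records[!inside, , drop = FALSE]
}

#' Keep only common variants
#'
#' Optional minor-allele-frequency filter (off by default in the study
#' pipeline: the source describes its instruments as common variants
#' without stating that MAF was an active selection criterion). Records
#' without a frequency are kept.
#'
#' @param records An association table with an `eaf` column.
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @return The records whose MAF is at least `maf_min`, order preserved.
#' @export
filter_maf <- function(records, maf_min = 0.05) {
  stopifnot(maf_min >= 0, maf_min <= 0.5)
  maf <- pmin(records$eaf, 1 - records$eaf)
  records[is.na(maf) | maf >= maf_min, , drop = FALSE]
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' @param path Path to a TSV with a header row.
#' @param column_map Named character vector mapping the canonical fields
#'   (`snp`, `chr`, `pos`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `pval`, `eaf`, `trait`) to the file's column names. `se`, `eaf` and
#'   `trait` may be absent from the file.
#' @return An `assoc_tbl` tibble (see [association_records()]).
#' @export
read_summary_tsv <- function(path, column_map = default_column_map()) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  mandatory <- c("snp", "chr", "pos", "effect_allele", "other_allele", "beta", "pval")
  have <- column_map[column_map %in% names(raw)]
  miss <- setdiff(mandatory, names(have))
  if (length(miss)) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(column_map[miss], collapse = ", "))
  }
  get_num <- function(field) {
    if (!field %in% names(have)) return(NA_real_)
    x <- raw[[have[[field]]]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad)) {
      stop("unparsable numeric value(s) in column '", have[[field]], "' at data line(s) ",
           paste(utils::head(bad, 5), collapse = ", "), " of ", path)
    }
    out
  }
  if (nrow(raw) == 0) {
    return(association_records(character(), integer(), integer(), character(),
                               character(), double(), double()))
  }
  association_records(
    snp_id = raw[[have[["snp"]]]],
    chrom = get_num("chr"),
    pos_bp = get_num("pos"),
    effect_allele = raw[[have[["effect_allele"]]]],
    other_allele = raw[[have[["other_allele"]]]],
    beta = get_num("beta"),
    se = get_num("se"),
    pval = get_num("pval"),
    eaf = get_num("eaf"),
    trait_id = if ("trait" %in% names(have)) raw[[have[["trait"]]]] else "trait"
  )
}

#' @rdname read_summary_tsv
#' @param records An `assoc_tbl` to serialize.
#' @export
write_summary_tsv <- function(records, path, column_map = default_column_map()) {
  out <- tibble::tibble(
    records$snp_id, records$chrom, records$pos_bp, records$effect_allele,
    records$other_allele, records$beta, records$se, records$pval,
    records$eaf, records$trait_id
  )
  names(out) <- unname(column_map[c("snp", "chr", "pos", "effect_allele",
                                    "other_allele", "beta", "se", "pval",
                                    "eaf", "trait")])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Default TSV column names for summary statistics
#' @return Named character vector (canonical field -> file column).
#' @export
default_column_map <- function() {
  c(snp = "snp", chr = "chr", pos = "pos", effect_allele = "effect_allele",
    other_allele = "other_allele", beta = "beta", se = "se", pval = "pval",
    eaf = "eaf", trait = "trait")
}
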