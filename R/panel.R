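#' Read a variant panel definition
#'
#' A panel is the ordered set of biallelic SNVs scored by the analysis.  Each
#' variant carries a designated risk allele (the allele reported by GWAS as
#' increasing AF risk) and that allele's population frequency, which drives
#' Hardy-Weinberg genotype simulation.  Column order in the file is preserved
#' and fixes the column order of every downstream genotype matrix.
#'
#' @param path Path to a CSV file with header
#'   `snv_id,gene,locus,risk_allele,other_allele,risk_allele_freq,location_class`.
#' @return A tibble with one row per variant, in file order.
#' @examples
#' panel <- af_panel()
#' panel
#' @export
read_panel <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  assert_columns(raw, c("snv_id", "gene", "locus", "risk_allele", "other_allele",
                        "risk_allele_freq", "location_class"), "panel file")
  panel <- tibble(
    snv_id = raw$snv_id,
    gene = raw$gene,
    locus = raw$locus,
    risk_allele = toupper(raw$risk_allele),
    other_allele = toupper(raw$other_allele),
    risk_allele_freq = parse_num(raw$risk_allele_freq, "risk_allele_freq"),
    location_class = tolower(raw$location_class)
  )
  validate_panel(panel)
}

#' The default eight-SNV atrial fibrillation panel
#'
#' Eight GWAS-reported AF risk variants in *CAV1*, *SOX5*, *MYH7*, *ZFHX3*,
#' *KCNN3*, *KCNJ5* and *PITX2* (two variants), with their designated risk
#' alleles and European population frequencies.  The complementary
#' (`other_allele`) bases are the standard dbSNP partners for each variant;
#' they matter only for resolving REF/ALT orientation when reading VCF.
#'
#' @return A tibble of 8 variants (see [read_panel()] for columns).
#' @export
af_panel <- function() {
  read_panel(system.file("extdata", "af_panel.csv", package = "afprs",
                         mustWork = TRUE))
}

validate_panel <- function(panel) {
  if (nrow(panel) < 1) abort("a panel needs at least one variant",
                             class = "afprs_validation_error")
  dup <- unique(panel$snv_id[duplicated(panel$snv_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate snv_id in panel: %s", paste(dup, collapse = ", ")),
          class = "afprs_panel_error")
  }
  if (any(panel$risk_allele == panel$other_allele)) {
    abort("risk_allele and other_allele must differ for every variant",
          class = "afprs_validation_error")
  }
  ok_base <- c("A", "C", "G", "T")
  if (!all(panel$risk_allele %in% ok_base) || !all(panel$other_allele %in% ok_base)) {
    abort("alleles must be single bases A/C/G/T", class = "afprs_validation_error")
  }
  bad_freq <- !is.finite(panel$risk_allele_freq) |
    panel$risk_allele_freq <= 0 | panel$risk_allele_freq >= 1
  if (any(bad_freq)) {
    abort(sprintf("risk_allele_freq must lie strictly in (0,1); offending: %s",
                  paste(panel$snv_id[bad_freq], collapse = ", ")),
          class = "afprs_validation_error")
  }
  ok_loc <- c("intron", "upstream", "downstream")
  if (!all(panel$location_class %in% ok_loc)) {
    abort(sprintf("location_class must be one of %s", paste(ok_loc, collapse = "/")),
          class = "afprs_validation_error")
  }
  panel
}
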