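# Genotype I/O.  Dosages are always stored relative to the panel's designated
# risk allele (0/1/2 copies, NA = missing); orientation is resolved once, at
# load time, so downstream code never looks at REF/ALT again.

#' Read risk-allele dosages from a VCF file
#'
#' Variants are matched to the panel by ID (rs number) only.  For a matched
#' record, each genotype is converted to the number of copies of the panel's
#' risk allele: if the record's ALT is the risk allele the dosage is the ALT
#' allele count; if REF/ALT are swapped relative to the panel the count is
#' complemented (`2 - ALT count`).  Records whose alleles match neither
#' orientation, and panel variants absent from the file, yield all-missing
#' columns with a warning (a likely strand or allele-label problem).
#' Half-calls and `./.` become missing.
#'
#' @param path Path to a VCF (v4.2, biallelic SNV records with a GT field).
#' @param panel A panel tibble from [read_panel()].
#' @return A tibble: `subject_id` plus one integer column per panel variant,
#'   in panel order.
#' @export
read_genotypes_vcf <- function(path, panel) {
  validate_panel(panel)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_m <- vcfR::getFIX(vcf)
  if (!is.matrix(fix_m)) fix_m <- matrix(fix_m, nrow = 1,
                                         dimnames = list(NULL, names(fix_m)))
  fix <- as.data.frame(fix_m, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  if (is.null(samples)) abort("VCF contains no sample genotypes",
                              class = "afprs_validation_error")
  out <- tibble(subject_id = samples)
  for (k in seq_len(nrow(panel))) {
    v <- panel[k, ]
    idx <- which(fix$ID == v$snv_id)
    col <- rep(NA_integer_, length(samples))
    if (length(idx) == 0) {
      warn(sprintf("panel variant %s not found in VCF; column set to missing",
                   v$snv_id))
    } else {
      i <- idx[[1]]
      ref <- toupper(fix$REF[i]); alt <- toupper(fix$ALT[i])
      alt_count <- unname(gt_to_alt_count(gt[i, ]))
      if (identical(ref, v$other_allele) && identical(alt, v$risk_allele)) {
        col <- alt_count
      } else if (identical(ref, v$risk_allele) && identical(alt, v$other_allele)) {
        col <- 2L - alt_count
      } else {
        warn(sprintf(
          "VCF alleles %s/%s for %s match neither panel orientation (%s/%s); column set to missing",
          ref, alt, v$snv_id, v$other_allele, v$risk_allele))
      }
    }
    out[[v$snv_id]] <- col
  }
  out
}

# "0/1", "1|1", "./." ... -> ALT allele count; any half-call -> NA.
gt_to_alt_count <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) {
    if (length(p) == 0 || anyNA(p) || any(p == ".")) return(NA_integer_)
    sum(p == "1")
  }, integer(1))
}

#' Write risk-allele dosages to a plain-text VCF
#'
#' Emits a minimal VCFv4.2 file (GT field only) with REF = other allele and
#' ALT = risk allele, so dosages round-trip exactly through
#' [read_genotypes_vcf()], missing entries included.  Positions are synthetic
#' (no genome build is attached to the panel); the chromosome is taken from
#' the leading digits of the panel locus.
#'
#' @param genotypes Dosage tibble (`subject_id` + one column per variant).
#' @param panel The matching panel tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, panel, path) {
  validate_genotypes(genotypes, panel)
  chrom <- stringr::str_extract(panel$locus, "^[0-9XY]+")
  chrom[is.na(chrom)] <- "0"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=afprs",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$subject_id), collapse = "\t"))
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(nrow(panel)), function(k) {
    dos <- genotypes[[panel$snv_id[k]]]
    gt <- ifelse(is.na(dos), "./.", code[as.character(dos)])
    paste(c(chrom[k], k * 1000L, panel$snv_id[k], panel$other_allele[k],
            panel$risk_allele[k], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read risk-allele dosages from a CSV matrix
#'
#' Alternative tabular input: a `subject_id` column plus one column per rs
#' identifier holding dosages 0/1/2 (empty = missing), already oriented to
#' the panel risk allele.
#'
#' @inheritParams read_genotypes_vcf
#' @return Same shape as [read_genotypes_vcf()].
#' @export
read_dosages_csv <- function(path, panel) {
  validate_panel(panel)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  assert_columns(raw, "subject_id", "dosage file")
  out <- tibble(subject_id = raw$subject_id)
  for (id in panel$snv_id) {
    if (!id %in% names(raw)) {
      warn(sprintf("panel variant %s not found in dosage file; column set to missing", id))
      out[[id]] <- rep(NA_integer_, nrow(raw))
    } else {
      x <- parse_num(raw[[id]], id)
      if (any(!is.na(x) & !x %in% c(0, 1, 2))) {
        abort(sprintf("dosages for %s must be 0, 1 or 2", id),
              class = "afprs_validation_error")
      }
      out[[id]] <- as.integer(x)
    }
  }
  out
}

validate_genotypes <- function(genotypes, panel) {
  assert_columns(genotypes, c("subject_id", panel$snv_id), "genotype matrix")
  if (anyDuplicated(genotypes$subject_id)) {
    abort("subject_id must be unique in the genotype matrix",
          class = "afprs_validation_error")
  }
  for (id in panel$snv_id) {
    x <- genotypes[[id]]
    if (any(!is.na(x) & !x %in% c(0L, 1L, 2L))) {
      abort(sprintf("dosages for %s must be 0, 1, 2 or missing", id),
            class = "afprs_validation_error")
    }
  }
  invisible(genotypes)
}
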