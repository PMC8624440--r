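# Shared builders for in-code fixtures.

mini_panel <- function(n = 2) {
  tibble::tibble(
    snv_id = paste0("rs", seq_len(n)),
    gene = paste0("G", seq_len(n)),
    locus = paste0(seq_len(n), "q11"),
    risk_allele = rep(c("T", "A"), length.out = n),
    other_allele = rep(c("C", "G"), length.out = n),
    risk_allele_freq = rep(c(0.3, 0.5), length.out = n),
    location_class = rep("intron", n))
}

write_panel_csv <- function(panel, path = tempfile(fileext = ".csv")) {
  readr::write_csv(panel, path)
  path
}

# Minimal VCF writer independent of the package's own writer, for oracle use.
write_test_vcf <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(id, ref, alt, gts, chrom = "1", pos = 100) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts), collapse = "\t")
}

# Phenotype CSV fixture with sensible defaults, overridable per column.
write_pheno_csv <- function(n = 3, path = tempfile(fileext = ".csv"), ...) {
  base <- tibble::tibble(
    subject_id = paste0("P", seq_len(n)),
    af_case = rep(1L, n), sex = rep("male", n),
    age = rep(60, n), bmi = rep(30, n),
    pah = 0L, chf = 0L, chd = 0L, stroke = 0L, diabetes = 0L,
    dyslipidemia = 0L, chronic_resp = 0L,
    duration_months = NA, age_at_onset = NA, recurred = NA,
    ef_percent = NA, lavi = NA)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  readr::write_csv(base, path, na = "")
  path
}

# An afprs_flips object flipping exactly `ids`, built through decide_flips.
flipset <- function(panel, ids) {
  res <- tibble::tibble(
    term = panel$snv_id,
    or = ifelse(panel$snv_id %in% ids, 0.5, 1.5),
    p_value = ifelse(panel$snv_id %in% ids, 0.01, 0.9))
  decide_flips(res, panel)
}

# The published descriptive-table rows whose printed OR and 95% CI are
# arithmetically consistent with their printed counts.  Each expectation was
# recomputed from the counts with the Woolf formula (z = qnorm(0.975)) and
# checked against the printed values before freezing.  The excluded rows
# (case/control sex, follow-up heart failure and diabetes, echo comorbidity)
# do not match their counts under any standard 2x2 computation.
published_2x2_rows <- function() {
  cols <- c("term", "a", "b", "c", "d", "or", "ci_low", "ci_high")
  m <- rbind(
    # case/control table
    c("pah_cc",      201,  58,  80,  28,  1.213, 0.721,  2.040),
    c("chf_cc",      161,  98,  14,  94, 11.031, 5.963, 20.404),
    c("chd_cc",       50, 209,   3, 105,  8.373, 2.551, 27.479),
    c("stroke_cc",    11, 248,   8, 100,  0.554, 0.217,  1.419),
    c("diabetes_cc",  24, 235,  20,  88,  0.449, 0.236,  0.854),
    c("dyslip_cc",    86, 173,  64,  44,  0.342, 0.215,  0.543),
    c("chronresp_cc", 17, 242,   5, 103,  1.447, 0.520,  4.027),
    # recurrence follow-up table (sex row: female is the exposed category)
    c("sex_rec",      23,  35,   8,  31,  2.546, 0.996,  6.509),
    c("pah_rec",      43,  15,  27,  12,  1.274, 0.519,  3.130),
    c("chd_rec",       7,  51,   7,  32,  0.627, 0.201,  1.956),
    c("stroke_rec",    3,  55,   2,  37,  1.009, 0.161,  6.335),
    c("dyslip_rec",   21,  37,  16,  23,  0.816, 0.355,  1.877),
    c("chronresp_rec", 3,  55,   4,  35,  0.477, 0.101,  2.262),
    c("cha2ds2_rec",  50,   8,  37,   2,  0.338, 0.068,  1.685),
    c("comorb_rec",   47,  11,  36,   3,  0.356, 0.092,  1.371),
    # echo-subgroup table
    c("sex_echo",     14,  21,   2,  13,  4.333, 0.845, 22.230))
  out <- tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  names(out) <- cols
  out[2:8] <- lapply(out[2:8], as.numeric)
  out
}

# Case/control data with a single binary exposure realizing exact 2x2 counts.
table_to_data <- function(a, b, c, d) {
  tibble::tibble(
    y = rep(c(1, 1, 0, 0), c(a, b, c, d)),
    x = rep(c(1, 0, 1, 0), c(a, b, c, d)))
}
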