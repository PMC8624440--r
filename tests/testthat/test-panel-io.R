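test_that("the bundled panel matches the published eight-variant design", {
  panel <- af_panel()
  expect_equal(nrow(panel), 8)
  expect_equal(anyDuplicated(panel$snv_id), 0L)
  pitx2 <- panel[panel$snv_id == "rs2200733", ]
  expect_equal(pitx2$risk_allele, "T")
  expect_equal(pitx2$risk_allele_freq, 0.15)
  expect_true(all(panel$risk_allele != panel$other_allele))
})

test_that("panel files are validated on read", {
  one <- mini_panel(1)
  one$risk_allele_freq <- 0.5
  expect_equal(nrow(read_panel(write_panel_csv(one))), 1)

  dup <- mini_panel(2)
  dup$snv_id <- c("rs2200733", "rs2200733")
  expect_error(read_panel(write_panel_csv(dup)), class = "afprs_panel_error")

  bad <- mini_panel(1)
  bad$risk_allele_freq <- 1.0
  expect_error(read_panel(write_panel_csv(bad)), class = "afprs_validation_error")
})

test_that("VCF genotypes become risk-allele dosages with orientation handling", {
  panel <- mini_panel(1)  # risk T, other C
  path <- write_test_vcf(c(
    vcf_record("rs1", "C", "T", c("0/1", "1/1", "0/0", "./.", "./1"))),
    samples = paste0("S", 1:5))
  g <- read_genotypes_vcf(path, panel)
  expect_equal(g$rs1, c(1L, 2L, 0L, NA, NA))

  # swapped orientation: dosage = 2 - ALT count
  path2 <- write_test_vcf(c(
    vcf_record("rs1", "T", "C", c("0/1", "1/1", "0/0", "./.", "0|0"))),
    samples = paste0("S", 1:5))
  g2 <- read_genotypes_vcf(path2, panel)
  expect_equal(g2$rs1, c(1L, 0L, 2L, NA, 2L))
})

test_that("allele mismatches and absent variants give missing columns with warnings", {
  panel <- mini_panel(2)
  path <- write_test_vcf(c(
    vcf_record("rs1", "G", "A", c("0/1", "1/1"))),  # wrong alleles for rs1
    samples = c("S1", "S2"))
  expect_warning(expect_warning(g <- read_genotypes_vcf(path, panel),
                                "match neither"), "not found")
  expect_true(all(is.na(g$rs1)))
  expect_true(all(is.na(g$rs2)))
})

test_that("orientation property: swapped REF/ALT with complemented genotypes is invariant", {
  panel <- mini_panel(1)
  set.seed(11)
  for (rep in 1:5) {
    dos <- sample(c(0:2, NA), 12, replace = TRUE)
    gt_fwd <- dplyr::case_when(is.na(dos) ~ "./.", dos == 0 ~ "0/0",
                               dos == 1 ~ "0/1", TRUE ~ "1/1")
    gt_rev <- dplyr::case_when(is.na(dos) ~ "./.", dos == 0 ~ "1/1",
                               dos == 1 ~ "0/1", TRUE ~ "0/0")
    s <- paste0("S", 1:12)
    fwd <- read_genotypes_vcf(write_test_vcf(vcf_record("rs1", "C", "T", gt_fwd), s), panel)
    rev <- read_genotypes_vcf(write_test_vcf(vcf_record("rs1", "T", "C", gt_rev), s), panel)
    expect_identical(fwd$rs1, rev$rs1)
    expect_identical(fwd$rs1, as.integer(dos))
  }
})

test_that("VCF round-trip reproduces dosages exactly, missing entries included", {
  panel <- af_panel()
  set.seed(21)
  g <- sample_genotypes(panel, 25, seed = 21)
  for (id in panel$snv_id[c(2, 5)]) g[[id]][sample(25, 4)] <- NA
  path <- tempfile(fileext = ".vcf")
  write_genotypes_vcf(g, panel, path)
  expect_identical(read_genotypes_vcf(path, panel), g)
})

test_that("dosage CSV reading validates values and fills absent variants", {
  panel <- mini_panel(2)
  path <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(subject_id = c("A", "B"), rs1 = c(0, 2)), path)
  expect_warning(g <- read_dosages_csv(path, panel), "rs2")
  expect_equal(g$rs1, c(0L, 2L))
  expect_true(all(is.na(g$rs2)))

  readr::write_csv(tibble::tibble(subject_id = "A", rs1 = 3, rs2 = 0), path)
  expect_error(read_dosages_csv(path, panel), class = "afprs_validation_error")
})

test_that("phenotype reading types columns and keeps optional fields missing", {
  p <- read_phenotypes(write_pheno_csv(3, age = c(50, 60, 70), chf = c(1L, 0L, 1L)))
  expect_equal(nrow(p), 3)
  expect_type(p$chf, "logical")
  expect_equal(p$age, c(50, 60, 70))
  expect_true(all(is.na(p$ef_percent)))   # empty optional column, no error
})

test_that("phenotype consistency and coding violations are errors", {
  expect_error(
    read_phenotypes(write_pheno_csv(2, af_case = c(0L, 1L), recurred = c(1L, NA))),
    class = "afprs_consistency_error")
  expect_error(
    read_phenotypes(write_pheno_csv(2, chf = c("yes", "no"))),
    class = "afprs_validation_error")
  expect_error(
    read_phenotypes(write_pheno_csv(2, sex = c("m", "f"))),
    class = "afprs_validation_error")
})

test_that("phenotype round-trip through CSV preserves content", {
  cohort <- generate_cohort(cohort_config(n_cases = 15, n_controls = 5,
                                          seed = 3))
  path <- tempfile(fileext = ".csv")
  write_phenotypes(cohort$phenotypes, path)
  back <- read_phenotypes(path)
  expect_equal(back$af_case, cohort$phenotypes$af_case)
  expect_equal(back$recurred, cohort$phenotypes$recurred)
  expect_equal(back$age, cohort$phenotypes$age, tolerance = 1e-12)
})
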