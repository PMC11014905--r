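test_that("profiles are derived from filtered calls and the karyotype", {
  rec <- list(patient = list(karyotype = "46,XY[20]"),
              mutations = rbind(mutation_row(gene = "NPM1", vaf = 38),
                                mutation_row(gene = "SRSF2", vaf = 1.5)))
  prof <- derive_profile(rec, vaf_cutoff = 2)
  expect_true(prof$npm1_mut)
  expect_false(prof$flt3_itd)
  expect_length(prof$mds_genes_mut, 0)    # SRSF2 below the cut-off

  rec$mutations <- mutation_row(gene = "CEBPA", vaf = 41,
                                allele_count = "biallelic", bzip_in_frame = TRUE)
  prof <- derive_profile(rec)
  expect_true(prof$cebpa_bzip_in_frame)
  expect_true(prof$cebpa_biallelic)

  rec$mutations <- rbind(mutation_row(gene = "TP53", vaf = 22),
                         mutation_row(gene = "FLT3-ITD", vaf = 35, allelic_ratio = 0.8))
  prof <- derive_profile(rec)
  expect_true(prof$tp53_mut)
  expect_equal(prof$tp53_vaf, 22)
  expect_equal(prof$flt3_itd_ar, 0.8)
})

test_that("the 2017 engine reproduces its defining group assignments", {
  expect_equal(classify_eln2017(profile_fixture(npm1_mut = TRUE, flt3_itd = TRUE,
                                                flt3_itd_ar = 0.3))$group,
               "favorable")
  expect_equal(classify_eln2017(profile_fixture(flt3_itd = TRUE,
                                                flt3_itd_ar = 0.8))$group,
               "adverse")
  expect_equal(classify_eln2017(profile_fixture(cebpa_bzip_in_frame = TRUE))$group,
               "intermediate")   # monoallelic bZIP was not favorable in 2017
  expect_equal(classify_eln2017(profile_fixture(cebpa_biallelic = TRUE))$group,
               "favorable")
  # favorable-defining lesion suppresses the ASXL1 adversity
  cbf_asxl1 <- profile_fixture("46,XX,t(8;21)(q22;q22.1)[20]",
                               mds_genes_mut = "ASXL1")
  call <- classify_eln2017(cbf_asxl1)
  expect_equal(call$group, "favorable")
  expect_match(paste(call$trace, collapse = ";"), "suppressed_mds")
  # NPM1-mutated with a high ratio stays intermediate; RUNX1 alone is adverse
  expect_equal(classify_eln2017(profile_fixture(npm1_mut = TRUE, flt3_itd = TRUE,
                                                flt3_itd_ar = 0.8))$group,
               "intermediate")
  expect_equal(classify_eln2017(profile_fixture(mds_genes_mut = "RUNX1"))$group,
               "adverse")
  expect_equal(classify_eln2017(profile_fixture(mds_genes_mut = "SRSF2"))$group,
               "intermediate")   # SRSF2 was not adverse in 2017
  # the allelic ratio is required whenever the ITD is present
  expect_error(classify_eln2017(profile_fixture(flt3_itd = TRUE)), "allelic ratio")
})

test_that("the 2022 engine applies the revised rules", {
  # AR is dropped: NPM1 with ITD is intermediate regardless of ratio
  expect_equal(classify_eln2022(profile_fixture(npm1_mut = TRUE, flt3_itd = TRUE,
                                                flt3_itd_ar = 0.3))$group,
               "intermediate")
  expect_equal(classify_eln2022(profile_fixture(npm1_mut = TRUE,
                                                flt3_itd = TRUE))$group,
               "intermediate")   # no error without the ratio
  # myelodysplasia-related mutation beats the NPM1+ITD intermediate call
  expect_equal(classify_eln2022(profile_fixture(npm1_mut = TRUE, flt3_itd = TRUE,
                                                flt3_itd_ar = 0.3,
                                                mds_genes_mut = "U2AF1"))$group,
               "adverse")
  # ...but is suppressed under NPM1 without ITD
  expect_equal(classify_eln2022(profile_fixture(npm1_mut = TRUE,
                                                mds_genes_mut = "SRSF2"))$group,
               "favorable")
  # adverse cytogenetics overrides NPM1
  expect_equal(classify_eln2022(profile_fixture("44,XY,-5,-7,del(17p)[18]",
                                                npm1_mut = TRUE))$group,
               "adverse")
  # SRSF2 alone: adverse in 2022, intermediate in 2017
  srsf2 <- profile_fixture(mds_genes_mut = "SRSF2")
  expect_equal(classify_eln2022(srsf2)$group, "adverse")
  expect_equal(classify_eln2017(srsf2)$group, "intermediate")
  # bZIP in-frame CEBPA is favorable regardless of allele count
  expect_equal(classify_eln2022(profile_fixture(cebpa_bzip_in_frame = TRUE))$group,
               "favorable")
  # wild-type NPM1 with high-AR ITD moves from adverse to intermediate
  expect_equal(classify_eln2022(profile_fixture(flt3_itd = TRUE,
                                                flt3_itd_ar = 0.8))$group,
               "intermediate")
  # TP53 below the VAF threshold does not qualify; absent VAF does
  expect_equal(classify_eln2022(profile_fixture(tp53_mut = TRUE, tp53_vaf = 5))$group,
               "intermediate")
  expect_equal(classify_eln2022(profile_fixture(tp53_mut = TRUE, tp53_vaf = 40))$group,
               "adverse")
  call <- classify_eln2022(profile_fixture(tp53_mut = TRUE))
  expect_equal(call$group, "adverse")
  expect_match(paste(call$trace, collapse = ";"), "vaf_absent")
})

test_that("both engines are deterministic, total and single-valued", {
  set.seed(7)
  for (rep in 1:200) {
    prof <- random_profile()
    c17a <- classify_eln2017(prof); c17b <- classify_eln2017(prof)
    c22a <- classify_eln2022(prof); c22b <- classify_eln2022(prof)
    expect_identical(c17a$group, c17b$group)
    expect_identical(c22a$group, c22b$group)
    expect_true(c17a$group %in% c("favorable", "intermediate", "adverse"))
    expect_true(c22a$group %in% c("favorable", "intermediate", "adverse"))
    expect_gte(length(c17a$trace), 1)
    expect_gte(length(c22a$trace), 1)
  }
})

test_that("myelodysplasia mutations never demote a clean favorable profile in 2022", {
  clean <- list(profile_fixture("46,XX,t(8;21)(q22;q22.1)[20]"),
                profile_fixture("46,XY,inv(16)(p13.1q22)[20]"),
                profile_fixture(npm1_mut = TRUE))
  for (base in clean) {
    expect_equal(classify_eln2022(base)$group, "favorable")
    for (g in mds_gene_set()) {
      with_mds <- base
      with_mds$mds_genes_mut <- g
      expect_equal(classify_eln2022(with_mds)$group, "favorable")
    }
  }
})

test_that("adding adverse cytogenetics never improves the 2022 group", {
  rank <- c(favorable = 1, intermediate = 2, adverse = 3)
  set.seed(11)
  for (rep in 1:50) {
    prof <- random_profile()
    if (prof$karyo$t_8_21 || prof$karyo$inv16_or_t16_16 ||
        prof$cebpa_bzip_in_frame) next
    worse <- prof
    worse$karyo <- parse_karyotype("44,XY,-5,-7,del(17p)[18]")
    expect_gte(rank[classify_eln2022(worse)$group],
               rank[classify_eln2022(prof)$group])
  }
})

test_that("a one-patient CBF cohort lands on the favorable diagonal", {
  co <- aml_cohort(patient_row(karyotype = "46,XY,t(8;21)(q22;q22.1)[20]"))
  xt <- reclassification_crosstab(co)
  expect_equal(xt$table["favorable", "favorable"], 1L)
  expect_equal(xt$reclassified, 0L)
  expect_equal(sum(xt$table), 1L)
})
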