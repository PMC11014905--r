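# Shared fixtures and independent oracles, built in code at test time.

normal_karyo <- function() parse_karyotype("46,XY[20]")

# genotype profile with a normal karyotype unless a string is given
profile_fixture <- function(karyotype = "46,XY[20]", ...) {
  genotype_profile(parse_karyotype(karyotype), ...)
}

# a minimal valid patient row; override any field
patient_row <- function(patient_id = "P1", karyotype = "46,XY[20]",
                        cr_achieved = FALSE, hct_received = FALSE,
                        hct_time = NA_real_, os_time = 12, os_event = TRUE,
                        efs_time = 12, efs_event = TRUE,
                        rfs_time = NA_real_, rfs_event = NA,
                        age_years = 50, sex = "male",
                        disease_type = "de_novo", wbc = 12000,
                        bm_blast_pct = 60) {
  data.frame(patient_id = patient_id, age_years = age_years, sex = sex,
             disease_type = disease_type, wbc = wbc,
             bm_blast_pct = bm_blast_pct, karyotype = karyotype,
             cr_achieved = cr_achieved, hct_received = hct_received,
             hct_time = hct_time, os_time = os_time, os_event = os_event,
             efs_time = efs_time, efs_event = efs_event,
             rfs_time = rfs_time, rfs_event = rfs_event,
             stringsAsFactors = FALSE)
}

mutation_row <- function(patient_id = "P1", gene = "NPM1", vaf = 40,
                         allelic_ratio = NA_real_,
                         allele_count = NA_character_, bzip_in_frame = NA) {
  data.frame(patient_id = patient_id, gene = gene, vaf = vaf,
             allelic_ratio = allelic_ratio, allele_count = allele_count,
             bzip_in_frame = bzip_in_frame, stringsAsFactors = FALSE)
}

# random genotype profile for fuzzing the engines
random_profile <- function() {
  karyos <- c("46,XY[20]", "46,XX,t(8;21)(q22;q22.1)[20]",
              "46,XY,inv(16)(p13.1q22)[20]", "46,XX,t(9;11)(p21.3;q23.3)[20]",
              "44,XY,-5,-7,del(17)(p13)[18]", "46,XX,t(9;22)(q34;q11.2)[20]",
              "46,XY,del(5)(q13q33)[20]", "49,XX,+8,+13,+21[20]",
              "46,XY,t(6;9)(p23;q34.1)[20]")
  itd <- runif(1) < 0.3
  genotype_profile(
    parse_karyotype(sample(karyos, 1)),
    npm1_mut = runif(1) < 0.3,
    flt3_itd = itd,
    flt3_itd_ar = if (itd) round(runif(1, 0.05, 1.5), 2) else NA_real_,
    cebpa_bzip_in_frame = runif(1) < 0.1,
    cebpa_biallelic = runif(1) < 0.1,
    tp53_mut = runif(1) < 0.1,
    tp53_vaf = if (runif(1) < 0.5) round(runif(1, 1, 60), 1) else NA_real_,
    mds_genes_mut = sample(mds_gene_set(), rbinom(1, 3, 0.15)))
}

# hand-rolled log-rank over explicit risk-set tables (two groups)
logrank_bruteforce <- function(time, event, group) {
  event <- as.logical(event)
  lv <- sort(unique(group))
  ut <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in ut) {
    risk <- time >= t
    n <- sum(risk)
    n1 <- sum(risk & group == lv[1])
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & group == lv[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# exhaustive O(n^2) concordance oracle with explicit pair loops
harrell_c_bruteforce <- function(score, time, event) {
  event <- as.logical(event)
  n <- length(time)
  conc <- comp <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    usable <- event[i] && (time[i] < time[j] || (time[i] == time[j] && !event[j]))
    if (!usable) next
    comp <- comp + 1
    if (score[i] > score[j]) conc <- conc + 1
    else if (score[i] == score[j]) conc <- conc + 0.5
  }
  conc / comp
}

# grid-search maximizer of the (untied) Cox partial likelihood, one covariate
cox_loglik_oracle <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

expect_cohort_valid <- function(cohort) {
  expect_s3_class(cohort, "aml_cohort")
  p <- cohort$patients
  expect_true(all(p$efs_time <= p$os_time + 1e-9))
  expect_true(all(p$cr_achieved == !is.na(p$rfs_time)))
  expect_true(all(p$hct_received == !is.na(p$hct_time)))
  expect_true(all(is.na(p$hct_time) | p$hct_time <= p$os_time + 1e-9))
}
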