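# Synthetic cohort generation. The blueprint stores genotype templates and
# outcome-simulation parameters only -- never a risk label: all group
# structure in generated data must be recovered by the classifiers, which
# guards every downstream test against circularity.

#' Default 624-patient cohort blueprint
#'
#' The shipped archetype table: 23 genotype templates (karyotype class,
#' mutation template, template count) whose classifier-derived 2017/2022
#' cross-tabulation reproduces the published reclassification structure, and
#' the outcome-simulation calibration. Outcome defaults: the favorable-group
#' baseline is an exponential hazard with five-year survival 0.55; overall
#' survival hazard multipliers 2.340 (intermediate) and 4.380 (adverse);
#' complete-remission probabilities 0.922 / 0.854 / 0.661; transplant
#' probability 0.449 among CR patients with timing uniform on \[3, 9\]
#' months; post-transplant hazard multipliers 1.0 / 0.5 / 0.5; and
#' administrative censoring uniform on \[48.4, 120.4\] months, whose median
#' (84.4) is the target median follow-up.
#'
#' @return Object of class `cohort_blueprint` with elements `archetypes`
#'   (list of templates) and `outcome_params`.
#' @export
default_blueprint <- function() {
  a <- function(id, count, karyo, genes = list())
    list(id = id, count = count, karyo = karyo, genes = genes)
  g <- function(gene, ar = NA_real_, allele_count = NA_character_,
                bzip = NA)
    list(gene = gene, ar = ar, allele_count = allele_count, bzip = bzip)
  archetypes <- list(
    a("B01", 59L, "t_8_21"),
    a("B02", 3L,  "t_8_21", list(g("ASXL1"))),
    a("B03", 25L, "inv16"),
    a("B04", 2L,  "inv16", list(g("TP53"))),
    a("B05", 68L, "normal", list(g("NPM1"))),
    a("B06", 13L, "normal", list(g("NPM1"), g("SRSF2"))),
    a("B07", 14L, "normal", list(g("CEBPA", allele_count = "biallelic", bzip = TRUE))),
    a("B08", 31L, "normal", list(g("NPM1"), g("FLT3-ITD", ar = 0.3))),
    a("B09", 3L,  "normal", list(g("NPM1"), g("FLT3-ITD", ar = 0.3), g("U2AF1"))),
    a("B10", 21L, "normal", list(g("CEBPA", allele_count = "monoallelic", bzip = TRUE))),
    a("B11", 153L, "normal", list(g("passenger"))),
    a("B12", 48L, "normal", list(g("FLT3-ITD", ar = 0.3))),
    a("B13", 30L, "normal", list(g("NPM1"), g("FLT3-ITD", ar = 0.8))),
    a("B14", 46L, "normal", list(g("SRSF2"))),
    a("B15", 33L, "normal", list(g("FLT3-ITD", ar = 0.8))),
    a("B16", 16L, "complex_monosomal"),
    a("B17", 1L,  "complex", list(g("U2AF1"))),
    a("B18", 7L,  "del5q"),
    a("B19", 5L,  "t_9_22"),
    a("B20", 1L,  "t_6_9"),
    a("B21", 17L, "normal", list(g("TP53"))),
    a("B22", 14L, "normal", list(g("RUNX1"))),
    a("B23", 14L, "normal", list(g("ASXL1"))))
  outcome_params <- list(
    baseline_hazard = -log(0.55) / 60,       # per month; 5-year S = 0.55
    hr = c(favorable = 1, intermediate = 2.340, adverse = 4.380),
    cr_prob = c(favorable = 0.922, intermediate = 0.854, adverse = 0.661),
    hct_prob = 0.449,
    hct_window = c(3, 9),
    post_hct_multiplier = c(favorable = 1, intermediate = 0.5, adverse = 0.5),
    censor_window = c(48.4, 120.4),
    cr_window = c(0.5, 1.5),
    induction_failure_window = c(0.5, 2))
  structure(list(archetypes = archetypes, outcome_params = outcome_params),
            class = "cohort_blueprint")
}

#' @export
print.cohort_blueprint <- function(x, ...) {
  counts <- vapply(x$archetypes, function(a) a$count, integer(1))
  cat(sprintf("cohort_blueprint: %d archetypes, %d patients\n",
              length(x$archetypes), sum(counts)))
  invisible(x)
}

karyo_string <- function(karyo, sex) {
  sx <- if (sex == "male") "XY" else "XX"
  switch(karyo,
    normal = sprintf("46,%s[20]", sx),
    t_8_21 = sprintf("46,%s,t(8;21)(q22;q22.1)[20]", sx),
    inv16 = sprintf("46,%s,inv(16)(p13.1q22)[20]", sx),
    complex_monosomal = sprintf("44,%s,-5,-7,del(17)(p13)[18]", sx),
    complex = sprintf("47,%s,del(5)(q13q33),+8,t(1;3)(p36;q21)[20]", sx),
    del5q = sprintf("46,%s,del(5)(q13q33)[20]", sx),
    t_9_22 = sprintf("46,%s,t(9;22)(q34;q11.2)[20]", sx),
    t_6_9 = sprintf("46,%s,t(6;9)(p23;q34.1)[20]", sx),
    stop("unknown karyotype template: ", karyo, call. = FALSE))
}

#' Generate genotypes from a blueprint
#'
#' Emits exactly `count` patients per archetype with concrete mutation calls
#' (VAFs uniform on \[20, 45\] percent, above the positivity cut-off) and a
#' karyotype string expressing the template. Demographics are drawn to
#' resemble an adult intensively treated AML cohort (median age around 51,
#' slight male excess, mostly de novo disease). Outcome fields are
#' placeholders until [simulate_outcomes()] fills them. Deterministic given
#' the seed; patient order is shuffled by the seed.
#'
#' @param blueprint A `cohort_blueprint`.
#' @param seed Integer seed.
#' @return An `aml_cohort` with placeholder outcomes.
#' @export
generate_genotypes <- function(blueprint = default_blueprint(), seed = 1L) {
  stopifnot(inherits(blueprint, "cohort_blueprint"))
  set.seed(seed)
  counts <- vapply(blueprint$archetypes, function(a) a$count, integer(1))
  n <- sum(counts)
  arche_idx <- sample(rep(seq_along(blueprint$archetypes), counts))
  ids <- sprintf("P%04d", seq_len(n))
  sex <- ifelse(stats::runif(n) < 0.519, "male", "female")
  age <- pmin(pmax(round(stats::rnorm(n, 51.5, 13)), 18L), 84L)
  disease <- sample(c("de_novo", "secondary", "treatment_related"), n,
                    replace = TRUE, prob = c(0.925, 0.054, 0.021))
  wbc <- round(exp(stats::rnorm(n, log(15000), 1.2)), 0)
  blast <- round(stats::runif(n, 20, 95), 1)

  karyos <- character(n)
  mut_rows <- vector("list", n)
  for (i in seq_len(n)) {
    arch <- blueprint$archetypes[[arche_idx[i]]]
    karyos[i] <- karyo_string(arch$karyo, sex[i])
    genes <- arch$genes
    # the no-lesion template still gets realistic passenger mutations
    if (length(genes) == 1L && identical(genes[[1]]$gene, "passenger")) {
      pg <- sample(c("DNMT3A", "TET2", "NRAS"), sample(1:2, 1))
      genes <- lapply(pg, function(gn) list(gene = gn, ar = NA_real_,
                                            allele_count = NA_character_,
                                            bzip = NA))
    }
    if (length(genes))
      mut_rows[[i]] <- data.frame(
        patient_id = ids[i],
        gene = vapply(genes, `[[`, character(1), "gene"),
        vaf = round(stats::runif(length(genes), 20, 45), 1),
        allelic_ratio = vapply(genes, `[[`, numeric(1), "ar"),
        allele_count = vapply(genes, `[[`, character(1), "allele_count"),
        bzip_in_frame = vapply(genes, function(x) as.logical(x$bzip), logical(1)),
        stringsAsFactors = FALSE)
  }
  patients <- data.frame(
    patient_id = ids, age_years = age, sex = sex, disease_type = disease,
    wbc = wbc, bm_blast_pct = blast, karyotype = karyos,
    cr_achieved = FALSE, hct_received = FALSE, hct_time = NA_real_,
    os_time = 0, os_event = FALSE, efs_time = 0, efs_event = FALSE,
    rfs_time = NA_real_, rfs_event = NA, stringsAsFactors = FALSE)
  mutations <- do.call(rbind, mut_rows[!vapply(mut_rows, is.null, logical(1))])
  if (is.null(mutations)) mutations <- empty_mutation_table()
  rownames(mutations) <- NULL
  aml_cohort(patients, mutations)
}

#' Simulate survival outcomes for a genotyped cohort
#'
#' Each patient's 2022 ELN group (computed internally, never stored) selects
#' an exponential death hazard: the favorable baseline times the group
#' hazard multiplier. Complete remission is Bernoulli with the group CR
#' rate; CR is reached uniformly within the CR window and relapse after CR
#' follows the same group hazard. Transplant is assigned among CR patients
#' with the configured probability and timing when the patient is still in
#' first remission at the drawn transplant time; from transplant onwards
#' both death and relapse hazards are multiplied by the group's
#' post-transplant factor (by default a benefit in the non-favorable groups
#' only). Non-CR patients fail induction at a uniform time within the
#' induction-failure window. Administrative censoring is uniform on the
#' censoring window. All outcome invariants hold for every seed: the
#' event-free time never exceeds the overall time, relapse-free fields exist
#' exactly for CR patients, and transplant times are bounded by follow-up.
#'
#' @param cohort An `aml_cohort` with genotypes (outcomes are overwritten).
#' @param blueprint A `cohort_blueprint` supplying `outcome_params`.
#' @param seed Integer seed.
#' @param vaf_cutoff Positivity threshold for the internal classification.
#' @param calls Optional precomputed classification from [classify_cohort()]
#'   (saves re-classifying when simulating many outcome draws for one
#'   genotype realization).
#' @return The cohort with outcome fields filled.
#' @export
simulate_outcomes <- function(cohort, blueprint = default_blueprint(),
                              seed = 1L, vaf_cutoff = 2, calls = NULL) {
  stopifnot(inherits(cohort, "aml_cohort"), inherits(blueprint, "cohort_blueprint"))
  op <- blueprint$outcome_params
  set.seed(seed)
  p <- cohort$patients
  n <- nrow(p)
  if (is.null(calls)) calls <- classify_cohort(cohort, vaf_cutoff)
  group <- calls$eln2022[match(p$patient_id, calls$patient_id)]

  for (i in seq_len(n)) {
    g <- group[i]
    lam <- op$baseline_hazard * op$hr[[g]]
    death <- stats::rexp(1, lam)
    cr <- stats::runif(1) < op$cr_prob[[g]]
    hct <- FALSE; hct_time <- NA_real_
    if (!cr) {
      fail <- stats::runif(1, op$induction_failure_window[1],
                           op$induction_failure_window[2])
      efs_raw <- min(fail, death)
      rfs_raw <- NA_real_; cr_time <- NA_real_
    } else {
      cr_time <- stats::runif(1, op$cr_window[1], op$cr_window[2])
      if (cr_time >= death) cr_time <- 0.9 * death
      relapse <- cr_time + stats::rexp(1, lam)
      if (stats::runif(1) < op$hct_prob) {
        h <- stats::runif(1, op$hct_window[1], op$hct_window[2])
        if (h < death && h < relapse) {      # transplanted in first remission
          hct <- TRUE; hct_time <- h
          mult <- op$post_hct_multiplier[[g]]
          death <- h + stats::rexp(1, lam * mult)
          relapse <- h + stats::rexp(1, lam * mult)
        }
      }
      efs_raw <- min(relapse, death)
      rfs_raw <- efs_raw - cr_time
    }
    censor <- stats::runif(1, op$censor_window[1], op$censor_window[2])
    p$os_time[i] <- round(min(death, censor), 3)
    p$os_event[i] <- death <= censor
    p$efs_time[i] <- round(min(efs_raw, censor), 3)
    p$efs_event[i] <- efs_raw <= censor
    p$cr_achieved[i] <- cr
    if (cr) {
      p$rfs_time[i] <- round(min(rfs_raw, censor - cr_time), 3)
      p$rfs_event[i] <- rfs_raw <= censor - cr_time
    } else {
      p$rfs_time[i] <- NA_real_; p$rfs_event[i] <- NA
    }
    p$hct_received[i] <- hct
    p$hct_time[i] <- if (hct) round(hct_time, 3) else NA_real_
  }
  aml_cohort(p, cohort$mutations)
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: [generate_genotypes()] followed by
#' [simulate_outcomes()] under sub-seeds derived from `seed`.
#'
#' @param blueprint A `cohort_blueprint`.
#' @param seed Integer seed.
#' @return An `aml_cohort` with genotypes and outcomes.
#' @export
synthetic_cohort <- function(blueprint = default_blueprint(), seed = 1L) {
  geno <- generate_genotypes(blueprint, seed = seed)
  simulate_outcomes(geno, blueprint, seed = seed + 1L)
}
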