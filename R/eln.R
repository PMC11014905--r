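# The two ELN rule engines. Both are explicit ordered rule lists evaluated
# top-down: favorable-defining lesions (which suppress molecular adversity),
# then adverse cytogenetics, then molecular adverse markers, then the
# FLT3/NPM1 intermediate block, then default intermediate. Ties are
# impossible by construction; every profile receives exactly one group.

.risk_levels <- c("favorable", "intermediate", "adverse")

#' Construct a genotype profile
#'
#' The classification inputs distilled from a patient record: cytogenetic
#' feature flags plus curated mutation flags. `flt3_itd_ar` is the FLT3-ITD
#' mutant/wild-type allelic ratio, consulted only by the 2017 engine;
#' `cebpa_bzip_in_frame` and `cebpa_biallelic` may hold independently
#' (a biallelic non-bZIP CEBPA mutation exists in the wild).
#'
#' @param karyo A `karyotype_features` object.
#' @param npm1_mut,flt3_itd,cebpa_bzip_in_frame,cebpa_biallelic,tp53_mut
#'   Logical lesion flags.
#' @param flt3_itd_ar FLT3-ITD allelic ratio (nonnegative) or NA.
#' @param tp53_vaf TP53 variant allele frequency in percent, or NA.
#' @param mds_genes_mut Character vector, subset of [mds_gene_set()].
#' @return Object of class `genotype_profile`.
#' @export
genotype_profile <- function(karyo,
                             npm1_mut = FALSE, flt3_itd = FALSE,
                             flt3_itd_ar = NA_real_,
                             cebpa_bzip_in_frame = FALSE,
                             cebpa_biallelic = FALSE,
                             tp53_mut = FALSE, tp53_vaf = NA_real_,
                             mds_genes_mut = character(0)) {
  stopifnot(inherits(karyo, "karyotype_features"))
  if (!is.na(flt3_itd_ar) && !flt3_itd)
    stop("flt3_itd_ar present requires flt3_itd", call. = FALSE)
  if (!is.na(flt3_itd_ar) && flt3_itd_ar < 0)
    stop("flt3_itd_ar must be nonnegative", call. = FALSE)
  bad <- setdiff(mds_genes_mut, mds_gene_set())
  if (length(bad))
    stop("not myelodysplasia-related genes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(karyo = karyo, npm1_mut = npm1_mut, flt3_itd = flt3_itd,
                 flt3_itd_ar = flt3_itd_ar,
                 cebpa_bzip_in_frame = cebpa_bzip_in_frame,
                 cebpa_biallelic = cebpa_biallelic,
                 tp53_mut = tp53_mut, tp53_vaf = tp53_vaf,
                 mds_genes_mut = mds_genes_mut),
            class = "genotype_profile")
}

#' Derive the classification inputs from a patient record
#'
#' Applies the mutation-positivity filter (VAF cut-off, default 2%) and the
#' karyotype parser, then reduces the surviving calls to the lesion flags the
#' rule engines consume. `cebpa_bzip_in_frame` is true iff any positive CEBPA
#' call carries the bZIP in-frame annotation; `cebpa_biallelic` iff any call
#' is annotated biallelic.
#'
#' @param record A record from [patient_record()], or a list with elements
#'   `patient` (with `$karyotype`) and `mutations`.
#' @param vaf_cutoff Positivity threshold in percent; default 2.
#' @return A `genotype_profile`.
#' @export
derive_profile <- function(record, vaf_cutoff = 2) {
  mut <- filter_positive_mutations(record$mutations, vaf_cutoff)
  karyo <- parse_karyotype(record$patient$karyotype)
  itd <- mut[mut$gene == "FLT3-ITD", , drop = FALSE]
  cebpa <- mut[mut$gene == "CEBPA", , drop = FALSE]
  tp53 <- mut[mut$gene == "TP53", , drop = FALSE]
  ar <- if (nrow(itd) && any(!is.na(itd$allelic_ratio)))
    max(itd$allelic_ratio, na.rm = TRUE) else NA_real_
  genotype_profile(
    karyo = karyo,
    npm1_mut = any(mut$gene == "NPM1"),
    flt3_itd = nrow(itd) > 0L,
    flt3_itd_ar = ar,
    cebpa_bzip_in_frame = nrow(cebpa) > 0L && any(cebpa$bzip_in_frame %in% TRUE),
    cebpa_biallelic = nrow(cebpa) > 0L && any(cebpa$allele_count %in% "biallelic"),
    tp53_mut = nrow(tp53) > 0L,
    tp53_vaf = if (nrow(tp53)) max(tp53$vaf) else NA_real_,
    mds_genes_mut = intersect(unique(mut$gene), mds_gene_set()))
}

risk_call <- function(group, edition, trace) {
  stopifnot(group %in% .risk_levels, length(trace) >= 1L)
  structure(list(group = group, edition = edition, trace = trace),
            class = "risk_call")
}

#' @export
print.risk_call <- function(x, ...) {
  cat(sprintf("ELN %d: %s [%s]\n", x$edition, x$group,
              paste(x$trace, collapse = " > ")))
  invisible(x)
}

#' Classify a genotype profile under the 2017 ELN rules
#'
#' Favorable: core-binding-factor AML (t(8;21) or inv(16)/t(16;16));
#' NPM1-mutated without FLT3-ITD or with a low allelic ratio (< 0.5) and
#' without adverse cytogenetics; or biallelic CEBPA. Adverse (when no
#' favorable rule fired): adverse cytogenetics (overridden by t(9;11), which
#' is intermediate by convention), TP53, RUNX1 or ASXL1, or
#' NPM1-wild-type FLT3-ITD with a high allelic ratio (>= 0.5). Everything
#' else is intermediate. The 2017 edition requires the allelic ratio whenever
#' FLT3-ITD is present.
#'
#' @param profile A `genotype_profile`.
#' @return A `risk_call` with the ordered trace of fired rules.
#' @export
classify_eln2017 <- function(profile) {
  stopifnot(inherits(profile, "genotype_profile"))
  p <- profile
  if (p$flt3_itd && is.na(p$flt3_itd_ar))
    stop("2017 classification requires the FLT3-ITD allelic ratio", call. = FALSE)
  trace <- character(0)
  adv_cyto <- is_adverse_cytogenetics(p$karyo, 2017)

  if (p$karyo$t_8_21 || p$karyo$inv16_or_t16_16)
    return(risk_call("favorable", 2017L, c("cbf", suppressed_trace(p))))
  if (p$npm1_mut && (!p$flt3_itd || p$flt3_itd_ar < 0.5) && !adv_cyto)
    return(risk_call("favorable", 2017L,
                     c(if (p$flt3_itd) "npm1_flt3_itd_low" else "npm1_no_itd",
                       suppressed_trace(p))))
  if (p$cebpa_biallelic)
    return(risk_call("favorable", 2017L, c("cebpa_biallelic", suppressed_trace(p))))

  if (adv_cyto && !p$karyo$t_9_11)
    return(risk_call("adverse", 2017L, "adverse_cytogenetics"))
  if (adv_cyto && p$karyo$t_9_11)
    trace <- c(trace, "t_9_11_overrides_adverse_cytogenetics")
  if (p$tp53_mut)
    return(risk_call("adverse", 2017L, c(trace, "tp53")))
  hit <- intersect(p$mds_genes_mut, c("RUNX1", "ASXL1"))
  if (length(hit))
    return(risk_call("adverse", 2017L, c(trace, paste0(tolower(hit), collapse = "+"))))
  if (!p$npm1_mut && p$flt3_itd && p$flt3_itd_ar >= 0.5)
    return(risk_call("adverse", 2017L, c(trace, "flt3_itd_high_wt_npm1")))

  trace <- c(trace,
             if (p$karyo$t_9_11) "t_9_11"
             else if (p$npm1_mut && p$flt3_itd) "npm1_flt3_itd_high"
             else if (p$flt3_itd) "flt3_itd_low_wt_npm1"
             else "no_classifying_lesion")
  risk_call("intermediate", 2017L, trace)
}

#' Classify a genotype profile under the 2022 ELN rules
#'
#' Favorable: core-binding-factor AML; NPM1-mutated without FLT3-ITD and
#' without adverse cytogenetics; or an in-frame bZIP CEBPA mutation, mono- or
#' biallelic. The FLT3-ITD allelic ratio is never consulted. Adverse (when no
#' favorable rule fired): adverse cytogenetics (2022 lesion set, including
#' t(3q26.2;v) and t(8;16), with the hyperdiploid exemption); TP53 at VAF of
#' at least `tp53_vaf_threshold` (an absent VAF qualifies, with a trace
#' note); or any myelodysplasia-related gene mutation. All remaining
#' profiles, including every other FLT3-ITD carrier, are intermediate.
#' Favorable-defining lesions suppress TP53/myelodysplasia-gene adversity;
#' the suppressed markers are recorded in the trace.
#'
#' @param profile A `genotype_profile`.
#' @param tp53_vaf_threshold Minimum TP53 VAF (percent) for adversity;
#'   default 10.
#' @return A `risk_call` with the ordered trace of fired rules.
#' @export
classify_eln2022 <- function(profile, tp53_vaf_threshold = 10) {
  stopifnot(inherits(profile, "genotype_profile"))
  p <- profile
  adv_cyto <- is_adverse_cytogenetics(p$karyo, 2022)

  if (p$karyo$t_8_21 || p$karyo$inv16_or_t16_16)
    return(risk_call("favorable", 2022L, c("cbf", suppressed_trace(p))))
  if (p$npm1_mut && !p$flt3_itd && !adv_cyto)
    return(risk_call("favorable", 2022L, c("npm1_no_itd", suppressed_trace(p))))
  if (p$cebpa_bzip_in_frame) {
    trace <- c("cebpa_bzip", suppressed_trace(p))
    if (p$tp53_mut)
      trace <- c(trace, "tp53_suppression_convention_dependent")
    return(risk_call("favorable", 2022L, trace))
  }

  if (adv_cyto)
    return(risk_call("adverse", 2022L, "adverse_cytogenetics"))
  tp53_adverse <- p$tp53_mut &&
    (is.na(p$tp53_vaf) || p$tp53_vaf >= tp53_vaf_threshold)
  if (tp53_adverse)
    return(risk_call("adverse", 2022L,
                     if (is.na(p$tp53_vaf)) c("tp53", "vaf_absent_assumed_qualifying")
                     else "tp53"))
  if (length(p$mds_genes_mut))
    return(risk_call("adverse", 2022L,
                     paste0("mds_genes:", paste(sort(p$mds_genes_mut), collapse = "+"))))

  trace <- if (p$karyo$t_9_11) "t_9_11"
    else if (p$npm1_mut && p$flt3_itd) "npm1_flt3_itd"
    else if (p$flt3_itd) "flt3_itd_wt_npm1"
    else "no_classifying_lesion"
  risk_call("intermediate", 2022L, trace)
}

# markers whose adversity is suppressed by the favorable lesion that fired
suppressed_trace <- function(p) {
  c(if (length(p$mds_genes_mut))
      paste0("suppressed_mds:", paste(sort(p$mds_genes_mut), collapse = "+")),
    if (p$tp53_mut) "suppressed_tp53")
}

#' Classify a genotype profile under a chosen ELN edition
#'
#' @param profile A `genotype_profile`.
#' @param edition 2017 or 2022.
#' @param ... Passed to the edition engine.
#' @return A `risk_call`.
#' @export
classify_eln <- function(profile, edition, ...) {
  switch(as.character(edition),
         "2017" = classify_eln2017(profile, ...),
         "2022" = classify_eln2022(profile, ...),
         stop("unknown ELN edition: ", edition, call. = FALSE))
}

#' Classify every patient of a cohort under both editions
#'
#' @param cohort An `aml_cohort`.
#' @param vaf_cutoff Mutation-positivity threshold in percent; default 2.
#' @return data.frame with columns `patient_id`, `eln2017`, `eln2022`,
#'   `trace2017`, `trace2022`.
#' @export
classify_cohort <- function(cohort, vaf_cutoff = 2) {
  stopifnot(inherits(cohort, "aml_cohort"))
  ids <- cohort$patients$patient_id
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rec <- patient_record(cohort, ids[i])
    prof <- tryCatch(derive_profile(rec, vaf_cutoff),
                     error = function(e) stop("patient ", ids[i], ": ",
                                              conditionMessage(e), call. = FALSE))
    c17 <- tryCatch(classify_eln2017(prof),
                    error = function(e) stop("patient ", ids[i], ": ",
                                             conditionMessage(e), call. = FALSE))
    c22 <- classify_eln2022(prof)
    out[[i]] <- data.frame(patient_id = ids[i],
                           eln2017 = c17$group, eln2022 = c22$group,
                           trace2017 = paste(c17$trace, collapse = ";"),
                           trace2022 = paste(c22$trace, collapse = ";"),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Reclassification cross-tabulation between the 2017 and 2022 calls
#'
#' Entry (i, j) counts the patients assigned group i by the 2017 engine and
#' group j by the 2022 engine. Also reports the off-diagonal (reclassified)
#' total and a Sankey-ready flow list.
#'
#' @param cohort An `aml_cohort`, or a classification data.frame from
#'   [classify_cohort()].
#' @param vaf_cutoff Positivity threshold, used when `cohort` is a cohort.
#' @return Object of class `eln_crosstab`: `table` (3x3 integer matrix with
#'   favorable/intermediate/adverse margins), `reclassified` (off-diagonal
#'   total), `flows` (data.frame `from`, `to`, `n` over nonzero cells).
#' @export
reclassification_crosstab <- function(cohort, vaf_cutoff = 2) {
  calls <- if (inherits(cohort, "aml_cohort"))
    classify_cohort(cohort, vaf_cutoff) else cohort
  stopifnot(all(c("eln2017", "eln2022") %in% names(calls)))
  tab <- table(factor(calls$eln2017, levels = .risk_levels),
               factor(calls$eln2022, levels = .risk_levels))
  tab <- matrix(as.integer(tab), 3, 3,
                dimnames = list(eln2017 = .risk_levels, eln2022 = .risk_levels))
  flows <- expand.grid(from = .risk_levels, to = .risk_levels,
                       stringsAsFactors = FALSE)
  flows$n <- as.vector(tab[cbind(flows$from, flows$to)])
  flows <- flows[flows$n > 0L, , drop = FALSE]
  rownames(flows) <- NULL
  structure(list(table = tab,
                 reclassified = sum(tab) - sum(diag(tab)),
                 flows = flows),
            class = "eln_crosstab")
}

#' @export
print.eln_crosstab <- function(x, ...) {
  cat("Reclassification between ELN 2017 (rows) and ELN 2022 (columns):\n")
  print(stats::addmargins(as.table(x$table)))
  cat(sprintf("reclassified: %d of %d (%.1f%%)\n", x$reclassified,
              sum(x$table), 100 * x$reclassified / sum(x$table)))
  invisible(x)
}
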