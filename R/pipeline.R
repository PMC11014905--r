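# End-to-end orchestration: simulate or ingest a cohort, classify under both
# editions, and emit the cross-tabulation, survival comparisons, hazard-ratio
# tables, concordance comparison, NRI series and transplant analyses as
# machine-readable reports.

#' Build a validation-run configuration
#'
#' @param input `"simulate"` (default) or `"files"`.
#' @param blueprint Blueprint for simulation mode.
#' @param patients_path,mutations_path Input TSVs for file mode.
#' @param vaf_cutoff Mutation-positivity threshold (percent).
#' @param endpoints Subset of `c("OS", "EFS", "RFS")`.
#' @param nri_horizons Horizons in months for the NRI series.
#' @param censor_at_hct Also run the censor-at-transplant sensitivity
#'   analysis.
#' @param n_boot Bootstrap replicates for NRI intervals (>= 100 when NRI is
#'   requested).
#' @param seed Integer seed governing simulation and bootstraps.
#' @param out_dir Output directory for the report files.
#' @return List of class `run_config`.
#' @export
run_config <- function(input = c("simulate", "files"),
                       blueprint = default_blueprint(),
                       patients_path = NULL, mutations_path = NULL,
                       vaf_cutoff = 2,
                       endpoints = c("OS", "EFS", "RFS"),
                       nri_horizons = c(12, 24, 36, 48, 60),
                       censor_at_hct = TRUE,
                       n_boot = 200L, seed = 1L, out_dir = tempfile("elnrun")) {
  input <- match.arg(input)
  stopifnot(all(endpoints %in% c("OS", "EFS", "RFS")),
            all(nri_horizons > 0))
  if (length(nri_horizons) && n_boot > 0L && n_boot < 100L)
    stop("use at least 100 bootstrap replicates for NRI intervals", call. = FALSE)
  structure(list(input = input, blueprint = blueprint,
                 patients_path = patients_path, mutations_path = mutations_path,
                 vaf_cutoff = vaf_cutoff, endpoints = endpoints,
                 nri_horizons = nri_horizons, censor_at_hct = censor_at_hct,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

endpoint_data <- function(patients, endpoint) {
  switch(endpoint,
         OS = list(time = patients$os_time, event = patients$os_event,
                   keep = rep(TRUE, nrow(patients))),
         EFS = list(time = patients$efs_time, event = patients$efs_event,
                    keep = rep(TRUE, nrow(patients))),
         RFS = list(time = patients$rfs_time, event = patients$rfs_event,
                    keep = patients$cr_achieved),
         stop("unknown endpoint ", endpoint, call. = FALSE))
}

group_dummies <- function(group) {
  cbind(intermediate = as.numeric(group == "intermediate"),
        adverse = as.numeric(group == "adverse"))
}

#' Run the full validation pipeline
#'
#' Produces, under `config$out_dir`: `risk_calls.tsv` (per-patient calls and
#' rule traces), `crosstab.json` (cross-tabulation with Sankey flows),
#' `curves.tsv` (stepwise KM per edition, endpoint and group),
#' `tests.json` (overall and pairwise log-rank), `cox.json` (univariable
#' hazard ratios vs the favorable reference for both editions and the
#' multivariable model with the 2022 group, screened clinical covariates and
#' the time-dependent transplant indicator), `modelcomp.json` (concordance
#' per edition, the paired difference, and the NRI series for all subjects
#' and for reclassified subjects only), `hct.json` (per-group Mantel-Byar
#' and time-dependent Cox among CR patients, plus the censor-at-transplant
#' sensitivity log-rank when enabled) and `manifest.json`. Reports are
#' deterministic given config and seed (numbers serialized at 6 significant
#' digits).
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with all report objects and the cohort.
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- switch(config$input,
    simulate = synthetic_cohort(config$blueprint, seed = config$seed),
    files = read_cohort(config$patients_path, config$mutations_path))
  pts <- cohort$patients
  calls <- classify_cohort(cohort, config$vaf_cutoff)
  xt <- reclassification_crosstab(calls)
  utils::write.table(calls, file.path(config$out_dir, "risk_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  group_of <- list(`2017` = calls$eln2017, `2022` = calls$eln2022)
  risk_rank <- c(favorable = 1, intermediate = 2, adverse = 3)

  # KM curves and log-rank per edition x endpoint
  curves <- list(); tests <- list()
  for (ed in names(group_of)) {
    for (ep in config$endpoints) {
      d <- endpoint_data(pts, ep)
      grp <- group_of[[ed]][d$keep]
      tm <- d$time[d$keep]; ev <- d$event[d$keep]
      for (g in unique(grp)) {
        fit <- km_fit(tm[grp == g], ev[grp == g])
        st <- fit$steps
        if (nrow(st))
          curves[[length(curves) + 1L]] <-
            cbind(edition = ed, endpoint = ep, group = g, st)
      }
      lr <- logrank_test(tm, ev, grp, pairwise = length(unique(grp)) > 2)
      tests[[paste0("eln", ed, "_", ep)]] <- list(
        chisq = lr$chisq, df = lr$df, p = lr$p,
        pairwise = if (!is.null(lr$pairwise)) lr$pairwise else NULL)
    }
  }
  curves <- do.call(rbind, curves)
  utils::write.table(curves, file.path(config$out_dir, "curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # univariable Cox (group vs favorable reference), both editions
  cox_report <- list()
  for (ed in names(group_of)) {
    for (ep in config$endpoints) {
      d <- endpoint_data(pts, ep)
      grp <- group_of[[ed]][d$keep]
      fit <- cox_fit(d$time[d$keep], d$event[d$keep], group_dummies(grp))
      cox_report[[paste0("eln", ed, "_", ep, "_univariable")]] <- list(
        hr = as.list(stats::setNames(fit$hr, names(fit$coef))),
        ci_lower = as.list(stats::setNames(fit$ci_lower, names(fit$coef))),
        ci_upper = as.list(stats::setNames(fit$ci_upper, names(fit$coef))),
        p = as.list(stats::setNames(fit$p, names(fit$coef))))
    }
  }

  # multivariable model on OS: 2022 group + screened clinical covariates +
  # time-dependent transplant indicator
  clin <- cbind(age_decade = pts$age_years / 10,
                sex_male = as.numeric(pts$sex == "male"),
                log_wbc = log(pts$wbc),
                bm_blast = pts$bm_blast_pct)
  screened <- character(0)
  uni_clin <- list()
  for (j in colnames(clin)) {
    f <- tryCatch(cox_fit(pts$os_time, pts$os_event, clin[, j, drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(f)) { uni_clin[[j]] <- list(flag = "not estimable"); next }
    uni_clin[[j]] <- list(hr = unname(f$hr), p = unname(f$p))
    if (f$p < 0.05) screened <- c(screened, j)
  }
  x_mv <- cbind(group_dummies(calls$eln2022), clin[, screened, drop = FALSE])
  fit_mv <- if (any(pts$hct_received)) {
    ep_mv <- td_episodes(pts$os_time, pts$os_event,
                         ifelse(pts$hct_received, pts$hct_time, NA_real_), x_mv)
    cox_fit(ep_mv$stop, ep_mv$event, ep_mv$x, start = ep_mv$start)
  } else cox_fit(pts$os_time, pts$os_event, x_mv)
  cox_report$univariable_clinical <- uni_clin
  cox_report$multivariable_os <- list(
    covariates = names(fit_mv$coef),
    hr = as.list(stats::setNames(fit_mv$hr, names(fit_mv$coef))),
    ci_lower = as.list(stats::setNames(fit_mv$ci_lower, names(fit_mv$coef))),
    ci_upper = as.list(stats::setNames(fit_mv$ci_upper, names(fit_mv$coef))),
    p = as.list(stats::setNames(fit_mv$p, names(fit_mv$coef))))

  # concordance comparison and NRI series (on OS)
  s17 <- risk_rank[calls$eln2017]
  s22 <- risk_rank[calls$eln2022]
  cc <- compare_c(s17, s22, pts$os_time, pts$os_event)
  nri <- list()
  for (h in config$nri_horizons) {
    for (sub in c("all", "reclassified")) {
      r <- tryCatch(
        nri_censored(calls$eln2017, calls$eln2022, pts$os_time, pts$os_event,
                     horizon = h, levels = names(risk_rank), subset = sub,
                     n_boot = config$n_boot, seed = config$seed + round(h)),
        error = function(e) NULL)
      nri[[sprintf("m%g_%s", h, sub)]] <- if (is.null(r))
        list(horizon = h, subset = sub, flag = "undefined") else
        list(horizon = h, subset = sub, total = r$total, event = r$event_nri,
             nonevent = r$nonevent_nri,
             ci_total = if (!is.null(r$ci)) r$ci$total else NULL,
             flagged_cells = r$flags)
    }
  }
  modelcomp <- list(c_2017 = cc$c_a, c_2022 = cc$c_b, delta_c = cc$delta,
                    se = cc$se, p = cc$p, nri = nri)

  # transplant analyses
  hct_rep <- hct_subgroup_report(cohort, edition = 2022,
                                 vaf_cutoff = config$vaf_cutoff, calls = calls)
  hct_out <- list(subgroups = hct_rep)
  if (config$censor_at_hct) {
    cens <- censor_at_event(pts$os_time, pts$os_event,
                            ifelse(pts$hct_received, pts$hct_time, NA_real_))
    lr <- logrank_test(cens$time, cens$event, calls$eln2022, pairwise = TRUE)
    hct_out$censor_at_hct_os <- list(chisq = lr$chisq, df = lr$df, p = lr$p,
                                     pairwise = lr$pairwise)
  }

  manifest <- list(package = "elnrisk",
                   version = as.character(utils::packageVersion("elnrisk")),
                   seed = config$seed, input = config$input,
                   vaf_cutoff = config$vaf_cutoff,
                   endpoints = config$endpoints,
                   n_patients = nrow(pts),
                   group_sizes_2022 = as.list(table(calls$eln2022)[
                     c("favorable", "intermediate", "adverse")]),
                   group_sizes_2017 = as.list(table(calls$eln2017)[
                     c("favorable", "intermediate", "adverse")]),
                   config_hash = config_hash(config))

  report <- list(crosstab = list(table = xt$table, reclassified = xt$reclassified,
                                 flows = xt$flows),
                 tests = tests, cox = cox_report, modelcomp = modelcomp,
                 hct = hct_out, manifest = manifest)
  write_report_json <- function(obj, name)
    jsonlite::write_json(obj, file.path(config$out_dir, name),
                         auto_unbox = TRUE, digits = 6, na = "null",
                         matrix = "rowmajor", dataframe = "rows")
  write_report_json(report$crosstab, "crosstab.json")
  write_report_json(report$tests, "tests.json")
  write_report_json(report$cox, "cox.json")
  write_report_json(report$modelcomp, "modelcomp.json")
  write_report_json(report$hct, "hct.json")
  write_report_json(report$manifest, "manifest.json")
  invisible(c(report, list(cohort = cohort, calls = calls)))
}

# split at a time-dependent state entry, carrying baseline covariates and
# appending the 0/1 state indicator column
td_episodes <- function(time, event, entry_time, x) {
  x <- as.matrix(x)
  entered <- !is.na(entry_time) & entry_time < time
  idx <- c(seq_along(time), which(entered))
  start <- c(rep(0, length(time)), entry_time[entered])
  stop_t <- c(ifelse(entered, entry_time, time), time[entered])
  ev <- c(ifelse(entered, FALSE, event), event[entered])
  hct <- c(rep(0, length(time)), rep(1, sum(entered)))
  keep <- stop_t > start
  list(start = start[keep], stop = stop_t[keep], event = as.logical(ev[keep]),
       x = cbind(x[idx[keep], , drop = FALSE], hct = hct[keep]))
}

#' Transplant-effect report per risk group
#'
#' Restricted to patients who achieved CR, reports per risk group the
#' Mantel-Byar test and the time-dependent Cox hazard ratio for allogeneic
#' transplant on overall survival. Groups with no CR patients, or in which
#' nobody was transplanted, are flagged and skipped.
#'
#' @param cohort An `aml_cohort`.
#' @param edition Which edition's grouping to use (2017 or 2022).
#' @param vaf_cutoff Positivity threshold.
#' @param calls Optional precomputed classification from [classify_cohort()].
#' @return Named list per group: either `flag` or `n_cr`, `n_hct`,
#'   `mantel_byar_chisq`, `p`, `hr`, `ci_lower`, `ci_upper`.
#' @export
hct_subgroup_report <- function(cohort, edition = 2022, vaf_cutoff = 2,
                                calls = NULL) {
  stopifnot(inherits(cohort, "aml_cohort"))
  if (is.null(calls)) calls <- classify_cohort(cohort, vaf_cutoff)
  grp <- if (edition == 2022) calls$eln2022 else calls$eln2017
  pts <- cohort$patients
  out <- list()
  for (g in c("favorable", "intermediate", "adverse")) {
    sel <- grp == g & pts$cr_achieved
    if (!any(sel)) { out[[g]] <- list(flag = "no CR patients"); next }
    entry <- ifelse(pts$hct_received[sel], pts$hct_time[sel], NA_real_)
    mb <- mantel_byar_test(pts$os_time[sel], pts$os_event[sel], entry)
    if (!mb$defined) { out[[g]] <- list(flag = "no transplanted patients"); next }
    out[[g]] <- list(n_cr = sum(sel), n_hct = mb$n_entered,
                     mantel_byar_chisq = mb$chisq, p = mb$p,
                     hr = unname(mb$fit$hr),
                     ci_lower = unname(mb$fit$ci_lower),
                     ci_upper = unname(mb$fit$ci_upper))
  }
  out
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config, digits.d = 10)),
             collapse = "\n")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}
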