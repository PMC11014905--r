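# -- gene panel ---------------------------------------------------------------

#' Default mutation panel vocabulary
#'
#' The classification-relevant genes of the targeted myeloid panel plus the
#' common passenger genes used by the synthetic generator. FLT3-ITD is a
#' distinct symbol from FLT3-TKD: only the internal tandem duplication enters
#' the risk rules. Unknown genes in input files are accepted with a warning,
#' since a diagnostic panel typically carries more genes than the risk rules
#' consume.
#'
#' @return Character vector of gene symbols.
#' @export
eln_gene_panel <- function() {
  c("NPM1", "FLT3-ITD", "FLT3-TKD", "CEBPA", "TP53",
    mds_gene_set(),
    "DNMT3A", "TET2", "NRAS", "KRAS", "IDH1", "IDH2", "KIT", "WT1")
}

#' Myelodysplasia-related gene set
#'
#' The nine genes whose mutations define adverse risk in the 2022 ELN
#' classification (unless suppressed by a favorable-defining lesion).
#' ASXL1 and RUNX1 were already adverse in the 2017 edition.
#'
#' @return Character vector of nine gene symbols.
#' @export
mds_gene_set <- function() {
  c("ASXL1", "BCOR", "EZH2", "RUNX1", "SF3B1", "SRSF2", "STAG2", "U2AF1", "ZRSR2")
}

# -- schemas ------------------------------------------------------------------

.patient_cols <- c("patient_id", "age_years", "sex", "disease_type", "wbc",
                   "bm_blast_pct", "karyotype", "cr_achieved", "hct_received",
                   "hct_time", "os_time", "os_event", "efs_time", "efs_event",
                   "rfs_time", "rfs_event")

.mutation_cols <- c("patient_id", "gene", "vaf", "allelic_ratio",
                    "allele_count", "bzip_in_frame")

# -- construction / validation ------------------------------------------------

#' Assemble and validate a cohort
#'
#' A cohort couples a patient table (one row per subject: clinical covariates,
#' karyotype string, outcome times and event flags) with a mutation table
#' (zero or more curated calls per subject). All structural invariants are
#' enforced at construction: unique patient ids, adult ages, VAF within
#' \[0,100\], FLT3-ITD-only allelic ratios, CEBPA-only allele annotations,
#' relapse-free-survival fields present exactly for CR patients, transplant
#' times present exactly for transplanted patients and bounded by follow-up.
#'
#' @param patients data.frame with columns
#'   `patient_id, age_years, sex, disease_type, wbc, bm_blast_pct, karyotype,
#'    cr_achieved, hct_received, hct_time, os_time, os_event, efs_time,
#'    efs_event, rfs_time, rfs_event`.
#' @param mutations data.frame with columns
#'   `patient_id, gene, vaf, allelic_ratio, allele_count, bzip_in_frame`.
#' @return An object of class `aml_cohort`.
#' @export
aml_cohort <- function(patients, mutations = NULL) {
  if (is.null(mutations)) {
    mutations <- empty_mutation_table()
  }
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  mutations <- as.data.frame(mutations, stringsAsFactors = FALSE)
  validate_patients(patients)
  validate_mutations(mutations, patients$patient_id)
  structure(list(patients = patients, mutations = mutations),
            class = "aml_cohort")
}

empty_mutation_table <- function() {
  data.frame(patient_id = character(), gene = character(), vaf = numeric(),
             allelic_ratio = numeric(), allele_count = character(),
             bzip_in_frame = logical(), stringsAsFactors = FALSE)
}

fail_row <- function(what, rows, file = NULL) {
  loc <- if (is.null(file)) sprintf("row %s", paste(rows, collapse = ", "))
         else sprintf("%s line %s", file, paste(rows + 1L, collapse = ", "))
  stop(sprintf("%s (%s)", what, loc), call. = FALSE)
}

validate_patients <- function(p, file = NULL) {
  missing_cols <- setdiff(.patient_cols, names(p))
  if (length(missing_cols))
    stop("patient table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(p) == 0L) stop("cohort must contain at least one patient", call. = FALSE)
  dup <- duplicated(p$patient_id)
  if (any(dup)) fail_row(sprintf("duplicate patient_id '%s'", p$patient_id[dup][1]),
                         which(dup), file)
  bad <- which(!is.finite(p$age_years) | p$age_years < 18)
  if (length(bad)) fail_row("age_years must be >= 18", bad[1], file)
  bad <- which(!p$sex %in% c("male", "female"))
  if (length(bad)) fail_row("sex must be 'male' or 'female'", bad[1], file)
  bad <- which(!p$disease_type %in% c("de_novo", "secondary", "treatment_related"))
  if (length(bad)) fail_row("unknown disease_type", bad[1], file)
  bad <- which(!is.finite(p$wbc) | p$wbc <= 0)
  if (length(bad)) fail_row("wbc must be > 0", bad[1], file)
  bad <- which(!nzchar(trimws(p$karyotype)) | is.na(p$karyotype))
  if (length(bad)) fail_row("karyotype string must be nonempty", bad[1], file)
  for (col in c("os_time", "efs_time")) {
    bad <- which(!is.finite(p[[col]]) | p[[col]] < 0)
    if (length(bad)) fail_row(sprintf("%s must be a nonnegative number", col), bad[1], file)
  }
  bad <- which(p$efs_time > p$os_time + 1e-9)
  if (length(bad)) fail_row("efs_time must not exceed os_time", bad[1], file)
  # rfs fields present iff CR achieved
  bad <- which(p$cr_achieved & (is.na(p$rfs_time) | is.na(p$rfs_event)))
  if (length(bad)) fail_row("rfs fields required when cr_achieved", bad[1], file)
  bad <- which(!p$cr_achieved & (!is.na(p$rfs_time) | !is.na(p$rfs_event)))
  if (length(bad)) fail_row("rfs fields must be absent when CR not achieved", bad[1], file)
  # hct_time present iff hct_received, and bounded by follow-up
  bad <- which(p$hct_received & is.na(p$hct_time))
  if (length(bad)) fail_row("hct_time required when hct_received", bad[1], file)
  bad <- which(!p$hct_received & !is.na(p$hct_time))
  if (length(bad)) fail_row("hct_time must be absent when hct_received is 0", bad[1], file)
  bad <- which(p$hct_received & p$hct_time > p$os_time + 1e-9)
  if (length(bad)) fail_row("hct_time must not exceed os_time", bad[1], file)
  invisible(p)
}

validate_mutations <- function(m, patient_ids, file = NULL) {
  missing_cols <- setdiff(.mutation_cols, names(m))
  if (length(missing_cols))
    stop("mutation table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(m) == 0L) return(invisible(m))
  bad <- which(!m$patient_id %in% patient_ids)
  if (length(bad))
    fail_row(sprintf("mutation row for unknown patient_id '%s'", m$patient_id[bad][1]),
             bad[1], file)
  bad <- which(!is.finite(m$vaf) | m$vaf < 0 | m$vaf > 100)
  if (length(bad)) fail_row("vaf must lie in [0,100]", bad[1], file)
  bad <- which(!is.na(m$allelic_ratio) & m$gene != "FLT3-ITD")
  if (length(bad)) fail_row("allelic_ratio is only defined for FLT3-ITD", bad[1], file)
  bad <- which(!is.na(m$allelic_ratio) & m$allelic_ratio < 0)
  if (length(bad)) fail_row("allelic_ratio must be nonnegative", bad[1], file)
  bad <- which(!is.na(m$allele_count) & m$gene != "CEBPA")
  if (length(bad)) fail_row("allele_count is only defined for CEBPA", bad[1], file)
  bad <- which(!is.na(m$allele_count) & !m$allele_count %in% c("monoallelic", "biallelic"))
  if (length(bad)) fail_row("allele_count must be monoallelic or biallelic", bad[1], file)
  bad <- which(!is.na(m$bzip_in_frame) & m$gene != "CEBPA")
  if (length(bad)) fail_row("bzip_in_frame is only defined for CEBPA", bad[1], file)
  unknown <- setdiff(unique(m$gene), eln_gene_panel())
  if (length(unknown))
    warning("mutation table contains genes outside the shipped panel: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  invisible(m)
}

#' @export
print.aml_cohort <- function(x, ...) {
  cat(sprintf("aml_cohort: %d patients, %d mutation calls\n",
              nrow(x$patients), nrow(x$mutations)))
  invisible(x)
}

# -- accessors ----------------------------------------------------------------

#' Extract a single patient record
#'
#' @param cohort An `aml_cohort`.
#' @param patient_id Subject identifier.
#' @return List with elements `patient` (one-row list of clinical and outcome
#'   fields) and `mutations` (data.frame of the subject's calls).
#' @export
patient_record <- function(cohort, patient_id) {
  i <- match(patient_id, cohort$patients$patient_id)
  if (is.na(i)) stop("unknown patient_id '", patient_id, "'", call. = FALSE)
  list(patient = as.list(cohort$patients[i, , drop = FALSE]),
       mutations = cohort$mutations[cohort$mutations$patient_id == patient_id, ,
                                    drop = FALSE])
}

#' Mutation-positivity filter
#'
#' Retains calls at or above the variant-allele-frequency cut-off that defines
#' mutation positivity (default 2%). Order is preserved and the input is not
#' modified; the filter is idempotent and monotone in the cut-off.
#'
#' @param mutations data.frame of mutation calls (`gene`, `vaf`, ...).
#' @param vaf_cutoff Positivity threshold in percent, in (0, 100]; default 2.
#' @return The subset of rows with `vaf >= vaf_cutoff`.
#' @export
filter_positive_mutations <- function(mutations, vaf_cutoff = 2) {
  stopifnot(is.numeric(vaf_cutoff), length(vaf_cutoff) == 1L,
            vaf_cutoff > 0, vaf_cutoff <= 100)
  mutations[mutations$vaf >= vaf_cutoff, , drop = FALSE]
}

# -- I/O ----------------------------------------------------------------------

#' Read a cohort from tab-separated files
#'
#' Booleans are encoded 0/1 and absent optional fields as the literal token
#' `NA`. Malformed rows are reported with their file line number.
#'
#' @param patients_path Path to the patient TSV.
#' @param mutations_path Path to the mutation TSV.
#' @return An `aml_cohort`.
#' @export
read_cohort <- function(patients_path, mutations_path) {
  for (pp in c(patients_path, mutations_path))
    if (!file.exists(pp)) stop("file not found: ", pp, call. = FALSE)
  p <- utils::read.delim(patients_path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "NA")
  m <- utils::read.delim(mutations_path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "NA")
  p <- coerce_patients(p, patients_path)
  m <- coerce_mutations(m, mutations_path)
  validate_patients(p, file = patients_path)
  validate_mutations(m, p$patient_id, file = mutations_path)
  structure(list(patients = p, mutations = m), class = "aml_cohort")
}

num_col <- function(x, col, file) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    fail_row(sprintf("column '%s' is not numeric ('%s')", col, x[bad][1]), bad[1], file)
  out
}

bool_col <- function(x, col, file) {
  out <- rep(NA, length(x))
  out[x %in% c("0", "FALSE", "false")] <- FALSE
  out[x %in% c("1", "TRUE", "true")] <- TRUE
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    fail_row(sprintf("column '%s' is not a 0/1 flag ('%s')", col, x[bad][1]), bad[1], file)
  as.logical(out)
}

coerce_patients <- function(p, file) {
  missing_cols <- setdiff(.patient_cols, names(p))
  if (length(missing_cols))
    stop(file, ": missing columns ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  p <- p[, .patient_cols]
  for (col in c("age_years", "wbc", "bm_blast_pct", "hct_time",
                "os_time", "efs_time", "rfs_time"))
    p[[col]] <- num_col(p[[col]], col, file)
  for (col in c("cr_achieved", "hct_received", "os_event", "efs_event", "rfs_event"))
    p[[col]] <- bool_col(p[[col]], col, file)
  p
}

coerce_mutations <- function(m, file) {
  missing_cols <- setdiff(.mutation_cols, names(m))
  if (length(missing_cols))
    stop(file, ": missing columns ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(m) == 0L) return(empty_mutation_table())
  m <- m[, .mutation_cols]
  m$vaf <- num_col(m$vaf, "vaf", file)
  m$allelic_ratio <- num_col(m$allelic_ratio, "allelic_ratio", file)
  m$bzip_in_frame <- bool_col(m$bzip_in_frame, "bzip_in_frame", file)
  m
}

#' Write a cohort to tab-separated files
#'
#' Inverse of [read_cohort()]: `read_cohort` applied to the two written files
#' reproduces the cohort field for field. Booleans are serialized 0/1 and
#' absent optional fields as `NA`.
#'
#' @param cohort An `aml_cohort`.
#' @param out_dir Writable directory; created if needed.
#' @return Named character vector with elements `patients` and `mutations`.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "aml_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir, call. = FALSE)
  p <- cohort$patients
  for (col in c("cr_achieved", "hct_received", "os_event", "efs_event", "rfs_event"))
    p[[col]] <- ifelse(is.na(p[[col]]), NA_integer_, as.integer(p[[col]]))
  m <- cohort$mutations
  if (nrow(m)) m$bzip_in_frame <- ifelse(is.na(m$bzip_in_frame), NA_integer_,
                                         as.integer(m$bzip_in_frame))
  pp <- file.path(out_dir, "patients.tsv")
  mp <- file.path(out_dir, "mutations.tsv")
  utils::write.table(p, pp, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(m, mp, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  c(patients = pp, mutations = mp)
}
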