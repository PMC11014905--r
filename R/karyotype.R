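# ISCN-like karyotype parsing: the dialect covers comma-separated abnormality
# tokens with optional clone sizes in brackets and clones separated by "/".
# Clone structure is flattened to the union of abnormalities.

.karyo_flags <- c("t_8_21", "inv16_or_t16_16", "t_9_11", "t_6_9", "t_v_11q23",
                  "t_9_22", "t_8_16", "inv3_or_t3_3", "t_3q26_v",
                  "del5q_or_minus5", "minus7", "minus17_or_abn17p",
                  "complex", "monosomal", "hyperdiploid", "normal")

#' Parse an ISCN-like karyotype string into cytogenetic feature flags
#'
#' Extracts the lesion flags consumed by the ELN risk rules, plus the
#' abnormality count and modal chromosome number. Conventions:
#' \itemize{
#'   \item complex: at least 3 abnormalities, not counting the
#'     favorable-defining CBF translocations t(8;21) / inv(16) / t(16;16);
#'   \item monosomal (Breems): at least 2 distinct autosomal monosomies, or
#'     1 autosomal monosomy plus at least 1 structural abnormality;
#'   \item hyperdiploid: modal chromosome number >= 49 with >= 3 numerical
#'     gains;
#'   \item loss of Y and constitutional abnormalities (token suffix `c`) are
#'     ignored for the abnormality count;
#'   \item multiple clones separated by `/` are flattened to the union of
#'     their abnormalities.
#' }
#' Unrecognized tokens still count toward `abnormality_count` and are
#' reported via a warning, never silently dropped. The keyword `normal` is
#' accepted as shorthand for a normal karyotype.
#'
#' @param iscn Karyotype string, e.g. `"46,XX,t(8;21)(q22;q22.1)[20]"`.
#' @return Object of class `karyotype_features`: named logical flags,
#'   `abnormality_count`, and `chromosome_count` (NA when unparseable).
#' @export
parse_karyotype <- function(iscn) {
  if (!is.character(iscn) || length(iscn) != 1L || is.na(iscn) ||
      !nzchar(trimws(iscn)))
    stop("karyotype string must be a nonempty string", call. = FALSE)
  s <- trimws(iscn)
  if (tolower(s) == "normal") s <- "46,XN"

  clones <- strsplit(s, "/", fixed = TRUE)[[1]]
  tokens <- character(0)
  modal <- NA_integer_
  for (cl in clones) {
    cl <- gsub("\\[[0-9]+\\]", "", cl)     # clone sizes
    toks <- split_iscn(cl)
    toks <- trimws(toks)
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) next
    if (grepl("^[0-9]+([~-][0-9]+)?$", toks[1])) {
      if (is.na(modal))
        modal <- as.integer(sub("([0-9]+).*", "\\1", toks[1]))
      toks <- toks[-1]
    }
    if (length(toks) && grepl("^[XYNxyn]+$", toks[1])) toks <- toks[-1]
    tokens <- c(tokens, toks)
  }
  tokens <- unique(tokens)

  # drop constitutional and sex-chromosome tokens
  tokens <- tokens[!grepl("c$", tokens)]
  tokens <- tokens[!grepl("^[+-][XYxy]$", tokens)]

  f <- stats::setNames(as.list(rep(FALSE, length(.karyo_flags))), .karyo_flags)
  n_gain <- 0L
  monosomies <- integer(0)
  n_structural <- 0L
  n_unrecognized <- 0L
  cbf_tokens <- 0L

  for (tok in tokens) {
    t <- tolower(gsub(" ", "", tok))
    if (grepl("^\\+[0-9]+$", t)) { n_gain <- n_gain + 1L; next }
    if (grepl("^-[0-9]+$", t)) {
      chr <- as.integer(sub("^-", "", t))
      monosomies <- union(monosomies, chr)
      if (chr == 5L)  f$del5q_or_minus5 <- TRUE
      if (chr == 7L)  f$minus7 <- TRUE
      if (chr == 17L) f$minus17_or_abn17p <- TRUE
      next
    }
    n_structural <- n_structural + 1L
    if (grepl("^t\\(8;21\\)", t)) { f$t_8_21 <- TRUE; cbf_tokens <- cbf_tokens + 1L }
    else if (grepl("^inv\\(16\\)", t) || grepl("^t\\(16;16\\)", t)) {
      f$inv16_or_t16_16 <- TRUE; cbf_tokens <- cbf_tokens + 1L
    }
    else if (grepl("^t\\(9;11\\)", t)) f$t_9_11 <- TRUE
    else if (grepl("^t\\(6;9\\)", t))  f$t_6_9 <- TRUE
    else if (grepl("^t\\(9;22\\)", t)) f$t_9_22 <- TRUE
    else if (grepl("^t\\(8;16\\)", t)) f$t_8_16 <- TRUE
    else if (grepl("^inv\\(3\\)", t) || grepl("^t\\(3;3\\)", t)) f$inv3_or_t3_3 <- TRUE
    else if (is_band_translocation(t, "3", "q26")) f$t_3q26_v <- TRUE
    else if (is_kmt2a_translocation(t)) f$t_v_11q23 <- TRUE
    else if (grepl("^del\\(5", t)) f$del5q_or_minus5 <- TRUE
    else if (grepl("17p", t) ||
             grepl("^(del|add|der|i|idic)\\(17\\)\\(p", t)) f$minus17_or_abn17p <- TRUE
    else if (grepl("^(t|inv|del|add|der|dup|ins|i|idic|dic|r|mar|trp)\\(", t) ||
             t == "mar") { }             # recognized structural, no rule flag
    else n_unrecognized <- n_unrecognized + 1L
  }

  if (n_unrecognized > 0L)
    warning(sprintf("%d unrecognized karyotype token(s) in '%s' counted as abnormalities",
                    n_unrecognized, iscn), call. = FALSE)

  count <- n_gain + length(monosomies) + n_structural
  f$normal <- count == 0L
  f$complex <- (count - cbf_tokens) >= 3L
  f$monosomal <- length(monosomies) >= 2L ||
    (length(monosomies) >= 1L && n_structural >= 1L)
  if (n_gain >= 3L && is.na(modal))
    stop("modal chromosome number unparseable but required by hyperdiploid logic: ",
         iscn, call. = FALSE)
  f$hyperdiploid <- !is.na(modal) && modal >= 49L && n_gain >= 3L

  structure(c(f, list(abnormality_count = count, chromosome_count = modal)),
            class = "karyotype_features")
}

# split a clone on commas that are not inside parentheses
split_iscn <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  depth <- 0L
  out <- character(0)
  cur <- character(0)
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) {
      out <- c(out, paste(cur, collapse = ""))
      cur <- character(0)
    } else cur <- c(cur, ch)
  }
  c(out, paste(cur, collapse = ""))
}

# translocation involving chromosome `chr` at a band starting with `band`,
# written either inline (e.g. t(v;11q23.3)) or with a separate band group
# (e.g. t(4;11)(q21;q23))
is_band_translocation <- function(t, chr, band) {
  if (!grepl("^t\\(", t)) return(FALSE)
  if (grepl(paste0(chr, band), t, fixed = TRUE)) return(TRUE)
  m <- regmatches(t, regexec("^t\\(([^)]*)\\)\\(([^)]*)\\)", t))[[1]]
  if (length(m) < 3L) return(FALSE)
  chroms <- strsplit(m[2], ";", fixed = TRUE)[[1]]
  bands <- strsplit(m[3], ";", fixed = TRUE)[[1]]
  i <- which(chroms == chr)
  length(i) == 1L && length(bands) >= i && startsWith(bands[i], band)
}

# any translocation involving 11q23 other than t(9;11)
is_kmt2a_translocation <- function(t) {
  if (grepl("^t\\(9;11\\)", t)) return(FALSE)
  is_band_translocation(t, "11", "q23")
}

#' @export
print.karyotype_features <- function(x, ...) {
  set <- .karyo_flags[vapply(x[.karyo_flags], isTRUE, logical(1))]
  cat(sprintf("karyotype_features: %s; %d abnormalities, modal %s\n",
              if (length(set)) paste(set, collapse = ", ") else "none",
              x$abnormality_count,
              ifelse(is.na(x$chromosome_count), "?", x$chromosome_count)))
  invisible(x)
}

#' Adverse-risk cytogenetics under a given ELN edition
#'
#' The adverse lesion set shared by both editions comprises t(6;9), t(9;22),
#' non-t(9;11) KMT2A translocations, inv(3)/t(3;3), -5/del(5q), -7,
#' -17/abn(17p), complex and monosomal karyotypes. The 2022 edition adds
#' t(3q26.2;v) and t(8;16), and exempts hyperdiploid karyotypes with multiple
#' trisomies from the complex-karyotype route (they remain adverse under
#' 2017). t(9;11) is intermediate in both editions and never adverse here.
#'
#' @param features A `karyotype_features` object.
#' @param edition 2017 or 2022.
#' @return Logical scalar.
#' @export
is_adverse_cytogenetics <- function(features, edition) {
  stopifnot(inherits(features, "karyotype_features"))
  if (!edition %in% c(2017, 2022)) stop("unknown ELN edition: ", edition, call. = FALSE)
  f <- features
  shared <- f$t_6_9 || f$t_9_22 || f$t_v_11q23 || f$inv3_or_t3_3 ||
    f$del5q_or_minus5 || f$minus7 || f$minus17_or_abn17p || f$monosomal
  if (edition == 2017) {
    shared || f$complex
  } else {
    shared || (f$complex && !f$hyperdiploid) || f$t_3q26_v || f$t_8_16
  }
}
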