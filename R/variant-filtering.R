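#' Filter thresholds for the somatic and germline post-filter cascades
#'
#' Defaults follow the reference pipeline: somatic calls require tumor VAF
#' > 5% at > 50x coverage with population frequency < 0.005 in every queried
#' database, and are removed when seen in more than two distinct non-tumor
#' samples; germline calls require VAF > 30% in both tumor and normal at
#' > 50x with population frequency < 0.01. All inequalities are strict, so a
#' depth of exactly 50 is rejected.
#'
#' @param somatic_min_vaf minimum tumor VAF for somatic retention (exclusive)
#' @param min_depth minimum total depth (exclusive)
#' @param somatic_max_popfreq maximum population frequency for somatic calls
#'   (exclusive); compared against the maximum over databases, absent = 0
#' @param germline_min_vaf minimum VAF in both tumor and normal (exclusive)
#' @param germline_max_popfreq maximum population frequency for germline calls
#' @param pon_max_normals maximum number of distinct normal samples a somatic
#'   variant may appear in (inclusive; `> pon_max_normals` is excluded)
#' @param normal_evidence_max_vaf somatic calls with matched-normal VAF at or
#'   above this are treated as germline contamination and dropped
#' @return object of class `filter_thresholds`
#' @export
filter_thresholds <- function(somatic_min_vaf = 0.05,
                              min_depth = 50,
                              somatic_max_popfreq = 0.005,
                              germline_min_vaf = 0.30,
                              germline_max_popfreq = 0.01,
                              pon_max_normals = 2L,
                              normal_evidence_max_vaf = 0.02) {
  th <- list(somatic_min_vaf = somatic_min_vaf,
             min_depth = min_depth,
             somatic_max_popfreq = somatic_max_popfreq,
             germline_min_vaf = germline_min_vaf,
             germline_max_popfreq = germline_max_popfreq,
             pon_max_normals = as.integer(pon_max_normals),
             normal_evidence_max_vaf = normal_evidence_max_vaf)
  if (any(vapply(th, function(x) x <= 0, logical(1))))
    abort("all filter thresholds must be positive")
  if (th$somatic_min_vaf >= th$germline_min_vaf)
    abort("somatic_min_vaf must be below germline_min_vaf")
  structure(th, class = "filter_thresholds")
}

variant_columns <- function() {
  c("case_id", "chrom", "pos", "ref", "alt", "gene", "transcript_id",
    "protein_change", "consequence", "exonic", "total_depth",
    "vaf_tumor", "vaf_normal", "popfreq_1kg", "popfreq_esp6500",
    "popfreq_exac", "origin")
}

required_variant_columns <- function() {
  c("case_id", "chrom", "pos", "ref", "alt", "gene", "total_depth",
    "vaf_tumor")
}

# "48.51%" -> 0.4851; "0.4851" -> 0.4851; "" / NA -> NA
parse_vaf <- function(x, column, path) {
  x <- trimws(as.character(x))
  pct <- grepl("%$", x)
  x <- sub("%$", "", x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad))
    abort(sprintf("non-numeric %s in %s at data line %d: '%s'",
                  column, path, bad[1], x[bad[1]]))
  out[pct] <- out[pct] / 100
  out
}

#' Read a variant table
#'
#' Reads the tab-separated variant-call dialect (one call per row, header
#' required). VAF and population-frequency columns may be percent-formatted
#' strings ("48.51%") or fractions; both are normalized to fractions.
#' Missing optional columns are filled with NA; `exonic` defaults to TRUE
#' when absent.
#'
#' @param path TSV file path
#' @return data.frame of variant calls with the canonical columns
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) abort("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""))
  miss <- setdiff(required_variant_columns(), names(df))
  if (length(miss))
    abort(sprintf("variant table %s is missing required column(s): %s",
                  path, paste(miss, collapse = ", ")))
  for (col in setdiff(variant_columns(), names(df))) df[[col]] <- NA_character_
  extra <- setdiff(names(df), variant_columns())
  df <- df[c(variant_columns(), extra)]
  df$pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(df$pos)) abort("non-numeric pos in ", path)
  dep <- suppressWarnings(as.numeric(df$total_depth))
  bad <- which(is.na(dep) & !is.na(df$total_depth))
  if (length(bad))
    abort(sprintf("non-numeric total_depth in %s at data line %d", path, bad[1]))
  df$total_depth <- dep
  for (col in c("vaf_tumor", "vaf_normal", "popfreq_1kg", "popfreq_esp6500",
                "popfreq_exac"))
    df[[col]] <- parse_vaf(df[[col]], col, path)
  df$exonic <- ifelse(is.na(df$exonic), TRUE, toupper(df$exonic) %in%
                        c("TRUE", "T", "1", "YES"))
  stopifnot(all(df$pos >= 1), all(df$total_depth >= 0, na.rm = TRUE))
  df
}

#' Write a variant table
#'
#' @param calls data.frame of variant calls
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_variant_table <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Classify a variant's protein-level consequence
#'
#' Maps an HGVS p. string (plus optional annotation terms) onto the coarse
#' classes used for cohort summaries: truncating (nonsense or frameshift),
#' missense, in-frame indel, splicing, other.
#'
#' @param protein_change HGVS protein change, e.g. "p.Arg2194Ter",
#'   "p.His1047Arg", "p.Glu280del", "p.Pro619LeufsTer43"
#' @param annotation_terms optional character vector of annotation terms;
#'   any term containing "splic" yields class "splicing"
#' @return one of "missense", "trunc", "in_frame", "splicing", "other"
#' @export
classify_consequence <- function(protein_change, annotation_terms = NULL) {
  if (!is.null(annotation_terms) &&
      any(grepl("splic", annotation_terms, ignore.case = TRUE)))
    return("splicing")
  p <- trimws(protein_change %||% "")
  if (is.na(p) || !nzchar(p)) return("other")
  p <- sub("^p\\.", "", gsub("[[:space:]*]", "", sub("^\\(|\\)$", "", p)))
  aa3 <- "[A-Z][a-z]{2}"
  if (grepl("fs", p) || grepl("Ter", p) || grepl("X$", p)) return("trunc")
  if (grepl("(del|dup|ins)", p)) return("in_frame")
  if (grepl(sprintf("^%s[0-9]+%s$", aa3, aa3), p)) return("missense")
  if (grepl("^[A-Z][0-9]+[A-Z]$", p)) return("missense")
  "other"
}

site_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Build a panel of normals
#'
#' Counts, per variant site-allele, the number of distinct non-tumor samples
#' in which it was called. Used to exclude recurrent artifacts / residual
#' germline variation from the somatic stream: variants present in more than
#' `pon_max_normals` distinct normals are removed.
#'
#' @param normal_tables a data.frame of normal-sample calls (with `case_id`),
#'   or a list of such data.frames
#' @return named integer vector, site-allele key -> distinct-normal count
#' @export
build_panel_of_normals <- function(normal_tables) {
  if (is.data.frame(normal_tables)) normal_tables <- list(normal_tables)
  all <- do.call(rbind, lapply(normal_tables, function(d)
    if (nrow(d)) data.frame(case_id = d$case_id, key = site_key(d)) else NULL))
  if (is.null(all) || !nrow(all)) return(integer(0))
  all <- unique(all)
  tab <- table(all$key)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

max_popfreq <- function(calls) {
  pf <- cbind(calls$popfreq_1kg, calls$popfreq_esp6500, calls$popfreq_exac)
  pf[is.na(pf)] <- 0
  if (!nrow(pf)) return(numeric(0))
  apply(pf, 1, max)
}

somatic_keep <- function(tumor, normal, pon, th) {
  if (!nrow(tumor)) return(logical(0))
  key <- site_key(tumor)
  keep <- tumor$vaf_tumor > th$somatic_min_vaf &
    tumor$total_depth > th$min_depth &
    (tumor$exonic | tumor$consequence %in% "splicing") &
    max_popfreq(tumor) < th$somatic_max_popfreq
  # matched-normal evidence: absent from normal, or present at trace VAF only
  if (!is.null(normal) && nrow(normal)) {
    nkey <- site_key(normal)
    nvaf <- normal$vaf_tumor
    # the normal table carries its own VAF in vaf_tumor (the sample measured)
    idx <- match(key, nkey)
    in_normal <- !is.na(idx)
    keep <- keep & (!in_normal | nvaf[idx] < th$normal_evidence_max_vaf)
  }
  if (length(pon)) {
    cnt <- pon[key]
    cnt[is.na(cnt)] <- 0L
    keep <- keep & cnt <= th$pon_max_normals
  }
  keep & !is.na(keep)
}

#' Somatic post-filter cascade
#'
#' Retains tumor calls with VAF above the somatic threshold, depth above the
#' coverage floor, exonic (or splice-site) annotation, maximum population
#' frequency below the somatic cap, no germline-level evidence in the matched
#' normal, and a panel-of-normals count within the allowed limit. Output is
#' sorted by (chrom, pos).
#'
#' @param tumor_calls data.frame of tumor-sample calls for one case
#' @param normal_calls matched normal table (its VAFs are in `vaf_tumor`,
#'   the measured sample); may be NULL only with `allow_tumor_only = TRUE`
#' @param pon panel of normals from [build_panel_of_normals()]
#' @param thresholds a [filter_thresholds()] object
#' @param allow_tumor_only proceed (with a warning) when no matched normal
#' @return filtered data.frame of somatic calls
#' @export
filter_somatic <- function(tumor_calls, normal_calls, pon = integer(0),
                           thresholds = filter_thresholds(),
                           allow_tumor_only = FALSE) {
  if (is.null(normal_calls)) {
    if (!allow_tumor_only) abort("missing matched normal table")
    warning("no matched normal: somatic filtering is tumor-only",
            call. = FALSE)
  }
  keep <- somatic_keep(tumor_calls, normal_calls, pon, thresholds)
  out <- tumor_calls[keep, , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Germline post-filter cascade
#'
#' Retains site-alleles present in both the tumor and matched normal tables
#' with VAF above the germline threshold in both samples, depth above the
#' coverage floor in the tumor, and all population frequencies below the
#' germline cap.
#'
#' @inheritParams filter_somatic
#' @return filtered data.frame of germline calls (tumor-table rows, with
#'   `vaf_normal` filled from the matched normal)
#' @export
filter_germline <- function(tumor_calls, normal_calls,
                            thresholds = filter_thresholds()) {
  if (is.null(normal_calls)) abort("missing matched normal table")
  if (!nrow(tumor_calls))
    return(tumor_calls[order(tumor_calls$chrom, tumor_calls$pos), ,
                       drop = FALSE])
  idx <- match(site_key(tumor_calls), site_key(normal_calls))
  nvaf <- normal_calls$vaf_tumor[idx]
  th <- thresholds
  keep <- !is.na(idx) &
    tumor_calls$vaf_tumor > th$germline_min_vaf &
    nvaf > th$germline_min_vaf &
    tumor_calls$total_depth > th$min_depth &
    max_popfreq(tumor_calls) < th$germline_max_popfreq
  out <- tumor_calls[keep & !is.na(keep), , drop = FALSE]
  out$vaf_normal <- nvaf[keep & !is.na(keep)]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Summarize germline calls by clinical-significance label
#'
#' Labels are externally supplied (no pathogenicity logic here); they are
#' normalized into Benign or Likely benign / VUS / Likely pathogenic /
#' Pathogenic, anything else counted under "other".
#'
#' @param labels character vector of clinical-significance labels (or a
#'   data.frame with a `clinical_significance` column)
#' @return list with `total` and named `counts`
#' @export
summarize_germline <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$clinical_significance
  norm <- vapply(tolower(trimws(labels)), function(x) {
    if (x %in% c("benign", "likely benign", "benign or likely benign",
                 "benign/likely benign")) "benign_or_likely_benign"
    else if (x %in% c("vus", "uncertain significance",
                      "variant of uncertain significance")) "vus"
    else if (x == "likely pathogenic") "likely_pathogenic"
    else if (x == "pathogenic") "pathogenic"
    else "other"
  }, character(1), USE.NAMES = FALSE)
  lv <- c("benign_or_likely_benign", "vus", "likely_pathogenic",
          "pathogenic", "other")
  counts <- table(factor(norm, levels = lv))
  if (counts[["other"]] > 0)
    message(counts[["other"]], " germline record(s) with unrecognized ",
            "clinical-significance label counted as 'other'")
  list(total = length(labels), counts = as.list(as.integer(counts)) |>
         stats::setNames(lv))
}

#' Normalize a protein change for recurrence pooling
#'
#' Deletions and duplications at the same residue range describe the same
#' recurrent event in cohort reports and are pooled (e.g. p.Gln1334del and
#' p.Gln1334dup -> p.Gln1334del/dup) unless pooling is disabled.
#'
#' @param protein_change HGVS p. strings
#' @param pool_del_dup pool same-residue del and dup events
#' @return normalized strings
#' @export
normalize_protein_change <- function(protein_change, pool_del_dup = TRUE) {
  p <- gsub("[[:space:]]", "", as.character(protein_change))
  if (pool_del_dup)
    p <- sub("(del|dup)$", "del/dup", p)
  p
}

#' Tally cohort-wide recurrent somatic variants
#'
#' Groups retained somatic calls by gene and normalized protein change and
#' reports events seen in two or more distinct cases, with the percentage of
#' the cohort carrying each (one count per case regardless of multiplicity).
#'
#' @param somatic_calls data.frame of retained somatic calls across the cohort
#' @param cohort_n number of cases in the cohort
#' @param pool_del_dup see [normalize_protein_change()]
#' @return data.frame (gene, protein_change, n_mutated_samples,
#'   pct_of_cohort) sorted by gene then descending count
#' @export
tally_recurrence <- function(somatic_calls, cohort_n, pool_del_dup = TRUE) {
  empty <- data.frame(gene = character(0), protein_change = character(0),
                      n_mutated_samples = integer(0),
                      pct_of_cohort = numeric(0))
  if (!nrow(somatic_calls)) return(empty)
  pc <- normalize_protein_change(somatic_calls$protein_change, pool_del_dup)
  grp <- unique(data.frame(case_id = somatic_calls$case_id,
                           gene = somatic_calls$gene, protein_change = pc))
  agg <- stats::aggregate(case_id ~ gene + protein_change, data = grp,
                          FUN = function(x) length(unique(x)))
  names(agg)[3] <- "n_mutated_samples"
  agg <- agg[agg$n_mutated_samples >= 2, , drop = FALSE]
  if (!nrow(agg)) return(empty)
  agg$pct_of_cohort <- round_half_up(100 * agg$n_mutated_samples / cohort_n, 1)
  agg <- agg[order(agg$gene, -agg$n_mutated_samples, agg$protein_change), ]
  rownames(agg) <- NULL
  agg
}
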