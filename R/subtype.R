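#' Serial molecular subtype assignment for one case
#'
#' Classification is serial, mirroring the TCGA decision sequence: an
#' EBV-positive tumor is EBV subtype regardless of other assays; among
#' EBV-negative tumors any marker instability (MSI-L or MSI-H) gives the MSI
#' subtype; among the remainder a somatic copy-number aberration gives CIN;
#' everything left is genomically stable (GS). Note that MSI-L counts as MSI
#' here: the reference cohort's MSI subtype (n = 19) is its 15 MSI-H plus 4
#' MSI-L cases, whereas TCGA proper uses MSI-H only.
#'
#' @param ebv_positive logical EBV qPCR positivity
#' @param msi_status "MSS", "MSI-L" or "MSI-H" (or an `msi_result`)
#' @param cna_positive logical: any gene-level non-normal CNA (panel- or
#'   array-derived)
#' @return one of "EBV", "MSI", "CIN", "GS"
#' @export
classify_case <- function(ebv_positive, msi_status, cna_positive) {
  if (inherits(msi_status, "msi_result")) msi_status <- msi_status$status
  if (is.na(ebv_positive)) abort("unresolved assay: EBV status")
  if (is.na(msi_status) || !msi_status %in% c("MSS", "MSI-L", "MSI-H"))
    abort("unresolved assay: MSI status")
  if (is.na(cna_positive)) abort("unresolved assay: CNA status")
  if (ebv_positive) return("EBV")
  if (msi_status %in% c("MSI-L", "MSI-H")) return("MSI")
  if (cna_positive) return("CIN")
  "GS"
}

#' Classify a cohort and summarize the subtype distribution
#'
#' @param cases data.frame with columns `case_id`, `ebv_positive`,
#'   `msi_status`, `cna_positive` (one row per case)
#' @return list with `labels` (data.frame case_id, subtype) and
#'   `distribution` (data.frame subtype, n, pct; pct to 1 decimal)
#' @export
classify_cohort <- function(cases) {
  if (!nrow(cases)) abort("empty cohort")
  lab <- vapply(seq_len(nrow(cases)), function(i)
    classify_case(cases$ebv_positive[i], cases$msi_status[i],
                  cases$cna_positive[i]), character(1))
  n <- as.integer(table(factor(lab, levels = subtype_labels())))
  dist <- data.frame(subtype = subtype_labels(), n = n,
                     pct = round_half_up(100 * n / nrow(cases), 1))
  list(labels = data.frame(case_id = cases$case_id, subtype = lab),
       distribution = dist)
}

#' Build an oncoprint-style gene x case mutation matrix
#'
#' Rows are genes, columns cases ordered by subtype (serial order) then case
#' id; entries 1 when the case carries a retained somatic variant in the
#' gene.
#'
#' @param somatic_calls cohort-wide retained somatic calls
#' @param labels data.frame (case_id, subtype) from [classify_cohort()]
#' @param genes gene order (default the 43-gene panel)
#' @return integer matrix genes x cases
#' @export
mutation_matrix <- function(somatic_calls, labels,
                            genes = gene_panel()) {
  ord <- order(match(labels$subtype, subtype_labels()), labels$case_id)
  cases <- labels$case_id[ord]
  m <- matrix(0L, length(genes), length(cases),
              dimnames = list(genes, cases))
  hit <- unique(somatic_calls[somatic_calls$gene %in% genes,
                              c("gene", "case_id")])
  hit <- hit[hit$case_id %in% cases, , drop = FALSE]
  if (nrow(hit)) m[cbind(hit$gene, hit$case_id)] <- 1L
  m
}
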