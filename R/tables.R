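#' Reference cohort tables
#'
#' The published 107-patient Korean gastric cancer cohort is available only as
#' printed summary tables; those tables are machine-readable inputs for the
#' synthetic generator and for table-level reproduction checks. This file
#' embeds them as plain constructors.
#'
#' @name gc_tables
NULL

#' Subtype labels in serial-classification order
#' @return character vector `c("EBV","MSI","CIN","GS")`
#' @export
subtype_labels <- function() c("EBV", "MSI", "CIN", "GS")

#' 43-gene targeted panel
#'
#' Gene symbols on the gastric cancer panel: the 39 genes with at least one
#' somatic call in the reference cohort plus the four with none.
#'
#' @return character vector of 43 gene symbols
#' @export
gene_panel <- function() {
  c(rownames(gc_table4()$counts),
    "C16orf74", "CCNE1", "PDCD1LG2", "MET")
}

#' Cohort-level assay marginals (reference Table 1)
#'
#' @return list with `n`, `ebv` (Negative/Positive counts) and `msi`
#'   (MSS/MSI-L/MSI-H counts). The printed "MSI-I" row is the low-frequency
#'   MSI class (MSI-L).
#' @export
gc_table1 <- function() {
  list(
    n = 107L,
    ebv = c(Negative = 100L, Positive = 7L),
    msi = c(MSS = 88L, `MSI-L` = 4L, `MSI-H` = 15L)
  )
}

#' Somatic mutation counts per gene and subtype (reference Table 4)
#'
#' @return list with `counts` (39 x 4 integer matrix of mutated-case counts,
#'   genes x subtypes) and `sizes` (named subtype sizes 7/19/46/35).
#' @export
gc_table4 <- function() {
  genes <- c("TP53", "ACVR1B", "ALK", "APC", "ARID1A", "BCOR", "BRAF",
             "CBWD1", "CCND1", "CD274", "CDH1", "CIC", "CR1", "CTNNB1",
             "EGFR", "ERBB2", "ERBB3", "FBXW7", "FGFR2", "HLA-B", "IRF2",
             "JAK2", "KDR", "KRAS", "LARP4B", "MDM2", "MEDAG", "MLH1",
             "MSH2", "MTOR", "MVK", "MYC", "PGM5", "PIK3CA", "PTEN",
             "RHOA", "SMAD4", "STK11", "ZBTB20")
  counts <- matrix(c(
    0, 5, 26, 10,
    0, 1, 1, 0,
    0, 3, 2, 1,
    2, 1, 8, 1,
    4, 14, 12, 9,
    1, 9, 2, 0,
    0, 3, 0, 0,
    0, 0, 1, 1,
    0, 3, 2, 2,
    1, 0, 0, 0,
    3, 1, 3, 4,
    0, 5, 3, 2,
    0, 5, 2, 8,
    1, 2, 0, 2,
    0, 4, 0, 1,
    0, 5, 2, 1,
    0, 5, 2, 2,
    0, 3, 3, 1,
    0, 2, 0, 0,
    0, 3, 2, 0,
    0, 2, 1, 1,
    0, 1, 1, 0,
    0, 3, 1, 0,
    0, 5, 1, 0,
    0, 3, 1, 0,
    0, 1, 0, 0,
    0, 2, 0, 0,
    0, 2, 0, 0,
    0, 4, 1, 0,
    0, 3, 3, 0,
    0, 4, 0, 0,
    1, 0, 0, 0,
    1, 4, 0, 0,
    2, 7, 1, 0,
    0, 2, 0, 1,
    2, 1, 2, 4,
    0, 1, 1, 0,
    0, 1, 1, 0,
    0, 5, 0, 0
  ), ncol = 4, byrow = TRUE,
  dimnames = list(genes, subtype_labels()))
  storage.mode(counts) <- "integer"
  list(counts = counts,
       sizes = c(EBV = 7L, MSI = 19L, CIN = 46L, GS = 35L))
}

#' Clinicopathological covariates per subtype (reference Table 5)
#'
#' Cross-tabulated counts of clinical covariates by molecular subtype, used
#' as multinomial parameters by the synthetic generator.
#'
#' @return named list; each element is a levels x 4 integer matrix
#'   (columns EBV/MSI/CIN/GS).
#' @export
gc_table5 <- function() {
  st <- subtype_labels()
  mk <- function(levels, x) {
    m <- matrix(as.integer(x), ncol = 4, byrow = TRUE,
                dimnames = list(levels, st))
    m
  }
  list(
    age_group = mk(c("<=50", "51-60", "61-70", "71-80", ">80"), c(
      0, 1, 3, 6,
      2, 1, 9, 6,
      1, 3, 13, 8,
      3, 12, 16, 13,
      1, 2, 5, 2)),
    sex = mk(c("Female", "Male"), c(
      1, 8, 16, 11,
      6, 11, 30, 24)),
    lauren_class = mk(c("Diffuse", "Intestinal", "Mixed"), c(
      3, 2, 9, 14,
      2, 15, 26, 15,
      2, 2, 11, 6)),
    who_class = mk(c("Tubular", "Mucinous", "Poorly cohesive", "Mixed",
                     "Uncommon"), c(
      2, 17, 32, 18,
      0, 0, 2, 1,
      0, 0, 5, 9,
      1, 1, 7, 7,
      4, 1, 0, 0)),
    pT = mk(c("T1", "T2", "T3", "T4a", "T4b"), c(
      2, 2, 10, 10,
      1, 3, 4, 3,
      1, 9, 17, 11,
      3, 5, 14, 11,   # printed pooled T4a/T4b split to match the cohort
      0, 0, 1, 0)),   # marginal of 33 T4a / 1 T4b
    pN = mk(c("N0", "N1", "N2", "N3"), c(
      3, 10, 16, 11,
      1, 3, 7, 5,
      1, 4, 9, 6,
      2, 2, 14, 13)),
    M = mk(c("M0", "M1"), c(
      6, 19, 43, 34,
      1, 0, 3, 1)),
    anatomical_region = mk(c("Antrum", "Antrum_Body", "Fundus_Body",
                             "GEJ_Cardia", "Diffuse", "Pylorus"), c(
      1, 15, 25, 13,
      1, 0, 2, 2,
      4, 4, 10, 18,
      1, 0, 7, 0,
      0, 0, 0, 1,
      0, 0, 2, 1)),
    lymphatic_invasion = mk(c("Positive", "Negative", "Missing"), c(
      4, 17, 34, 21,
      3, 2, 12, 13,
      0, 0, 0, 1)),
    venous_invasion = mk(c("Positive", "Negative", "Missing"), c(
      2, 1, 7, 5,
      5, 18, 39, 29,
      0, 0, 0, 1)),
    perineural_invasion = mk(c("Positive", "Negative", "Missing"), c(
      4, 6, 25, 17,
      3, 13, 21, 17,
      0, 0, 0, 1)),
    h_pylori = mk(c("Negative", "Positive"), c(
      3, 8, 21, 9,
      4, 11, 25, 26))
  )
}

#' Pathway gene sets used for the therapeutic-implication summary
#'
#' Receptor tyrosine kinase genes and RAS/PI3K axis genes whose somatic
#' substitutions or copy-number changes define a pathway-altered case.
#'
#' @return list with character vectors `rtk` and `ras_pi3k`
#' @export
pathway_gene_sets <- function() {
  list(rtk = c("ERBB2", "EGFR", "FGFR2", "KDR"),
       ras_pi3k = c("KRAS", "BRAF", "PIK3CA", "PTEN", "MTOR"))
}
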