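#' Gene x subtype mutated-case table
#'
#' Counts, per gene and subtype, the number of cases carrying at least one
#' retained somatic variant in the gene (a case counts once per gene
#' regardless of variant multiplicity).
#'
#' @param somatic_calls cohort-wide retained somatic calls (case_id, gene)
#' @param labels data.frame (case_id, subtype); every case must be labeled
#' @param genes genes to tabulate
#' @return list of class `gene_subtype_table`: `counts` (gene x subtype
#'   integer matrix), `sizes` (subtype sizes), `pct` (percentages to 1
#'   decimal)
#' @export
gene_subtype_table <- function(somatic_calls, labels, genes) {
  if (anyNA(labels$subtype)) abort("unlabeled case in cohort")
  st <- subtype_labels()
  sizes <- table(factor(labels$subtype, levels = st))
  counts <- matrix(0L, length(genes), 4, dimnames = list(genes, st))
  if (length(genes) && nrow(somatic_calls)) {
    hit <- unique(somatic_calls[somatic_calls$gene %in% genes,
                                c("case_id", "gene")])
    hit$subtype <- labels$subtype[match(hit$case_id, labels$case_id)]
    if (anyNA(hit$subtype)) abort("somatic call from an unlabeled case")
    tab <- table(factor(hit$gene, levels = genes),
                 factor(hit$subtype, levels = st))
    counts <- matrix(as.integer(tab), nrow = length(genes),
                     dimnames = dimnames(tab))
  }
  sz <- as.integer(sizes)
  names(sz) <- st
  pct <- sweep(counts, 2, pmax(sz, 1L), "/") * 100
  structure(list(counts = counts, sizes = sz,
                 pct = round_half_up(pct, 1)),
            class = "gene_subtype_table")
}

#' Mean mutated-gene count per case, by subtype
#'
#' The per-subtype mutation rate is the column sum of the gene x subtype
#' mutated-case counts divided by the subtype size, reported to 1 decimal.
#'
#' @param table a `gene_subtype_table` (or a list with `counts` and `sizes`)
#' @return named numeric vector of four rates (NA for empty subtypes)
#' @export
mutation_rate_per_subtype <- function(table) {
  cs <- colSums(table$counts)
  out <- ifelse(table$sizes > 0, round_half_up(cs / table$sizes, 1), NA_real_)
  names(out) <- names(table$sizes)
  out
}

# multivariate hypergeometric log-probability of first-row counts a given
# column totals cols and first-row total m: prod C(cols_j, a_j) / C(N, m)
ffh_table_logprob <- function(a_mat, cols, m) {
  n_tab <- nrow(a_mat)
  lp <- numeric(n_tab)
  for (j in seq_along(cols)) lp <- lp + lchoose(cols[j], a_mat[, j])
  lp - lchoose(sum(cols), m)
}

# all first-row count vectors compatible with the margins, as a matrix
ffh_enumerate <- function(cols, m) {
  k <- length(cols)
  grids <- lapply(cols[-k], function(cj) 0:min(cj, m))
  g <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  last <- m - rowSums(g)
  ok <- last >= 0 & last <= cols[k]
  cbind(g[ok, , drop = FALSE], last[ok])
}

#' Fisher-Freeman-Halton exact test for a 2 x K table
#'
#' Exact p-value for association in a 2 x K contingency table: all tables
#' with the observed margins are enumerated and the multivariate-
#' hypergeometric probabilities of tables no more probable than the observed
#' one (relative tie tolerance 1e-12) are summed. When the enumeration would
#' exceed `max_tables` first-row compositions, a seeded Monte Carlo estimate
#' over uniform margin-preserving tables (Patefield sampling) is returned
#' instead.
#'
#' @param counts 2 x K matrix of nonnegative integer counts
#' @param max_tables enumeration budget (first-row compositions)
#' @param n_draws Monte Carlo draws used beyond the budget
#' @param mc_seed seed for the Monte Carlo fallback (local RNG stream)
#' @return list of class `ffh_result`: `p_value`, `method`
#'   ("ffh_enumeration" or "ffh_montecarlo"), and `n_tables_enumerated` or
#'   `n_draws`
#' @export
ffh_exact_test <- function(counts, max_tables = 5e6, n_draws = 1e5,
                           mc_seed = 20170722) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2 || ncol(counts) < 2)
    abort("ffh_exact_test expects a 2 x K table with K >= 2")
  if (any(counts < 0) || any(counts != round(counts)))
    abort("counts must be nonnegative integers")
  cols <- colSums(counts)
  m <- sum(counts[1, ])
  if (m == 0 || m == sum(cols) || all(cols == 0)) {
    return(structure(list(p_value = 1, method = "ffh_enumeration",
                          n_tables_enumerated = 1L), class = "ffh_result"))
  }
  obs_lp <- ffh_table_logprob(matrix(counts[1, ], 1), cols, m)
  budget <- prod(pmin(cols[-length(cols)], m) + 1)
  if (budget <= max_tables) {
    a <- ffh_enumerate(cols, m)
    lp <- ffh_table_logprob(a, cols, m)
    p <- sum(exp(lp)[lp <= obs_lp + 1e-12 * abs(obs_lp) + 1e-300])
    structure(list(p_value = min(p, 1), method = "ffh_enumeration",
                   n_tables_enumerated = nrow(a)), class = "ffh_result")
  } else {
    draws <- with_seed(mc_seed, stats::r2dtable(n_draws, c(m, sum(cols) - m),
                                                cols))
    a <- t(vapply(draws, function(t2) t2[1, ], numeric(length(cols))))
    lp <- ffh_table_logprob(a, cols, m)
    hits <- sum(lp <= obs_lp + 1e-12 * abs(obs_lp))
    structure(list(p_value = (hits + 1) / (n_draws + 1),
                   method = "ffh_montecarlo", n_draws = as.integer(n_draws)),
              class = "ffh_result")
  }
}

#' Association tests for every gene row of a gene x subtype table
#'
#' For each gene, tests whether the mutated-case proportion differs across
#' subtypes: primary p from the exact Fisher-Freeman-Halton enumeration,
#' secondary from the chi-squared test (no continuity correction, no
#' multiple-testing adjustment; raw p-values as in the reference report).
#'
#' @param table a `gene_subtype_table`
#' @return data.frame (gene, p_ffh, p_chisq) in the table's gene order
#' @export
gene_association_tests <- function(table) {
  genes <- rownames(table$counts)
  res <- lapply(genes, function(g) {
    mut <- table$counts[g, ]
    tab <- rbind(mutated = mut, wild = table$sizes - mut)
    p_chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    data.frame(gene = g, p_ffh = ffh_exact_test(tab)$p_value,
               p_chisq = p_chi)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Two-sided exact interval from beta-distribution quantiles; the lower
#' bound is 0 when there are no successes and the upper bound 1 when all
#' trials succeed.
#'
#' @param successes,trials nonnegative integers, successes <= trials >= 1
#' @param level confidence level
#' @return numeric `c(lower, upper)`
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  x <- successes
  n <- trials
  if (length(x) != 1 || length(n) != 1 || is.na(x) || is.na(n) ||
      n < 1 || x < 0 || x > n || x != round(x) || n != round(n))
    abort("invalid counts: need 0 <= successes <= trials, trials >= 1")
  a <- (1 - level) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Pathway-level alteration summary
#'
#' A case is altered in a gene set when it carries a retained somatic
#' variant OR a non-normal gene-level CNA in any member gene. Cases altered
#' in both sets count once in the combined figure. The mutual-exclusivity
#' report lists, per gene, cases carrying both a substitution and a CNA.
#'
#' @param somatic_calls cohort-wide retained somatic calls (case_id, gene)
#' @param cna_calls cohort-wide gene CNA calls (case_id, gene, state)
#' @param cohort_ids all case ids (defines the denominator)
#' @param genesets list of gene sets (default [pathway_gene_sets()])
#' @return list with per-set and `combined` counts/fractions (pct to 1
#'   decimal) and `exclusivity_violations` (data.frame gene, case_id)
#' @export
pathway_alteration_summary <- function(somatic_calls, cna_calls, cohort_ids,
                                       genesets = pathway_gene_sets()) {
  n <- length(cohort_ids)
  mut <- unique(somatic_calls[, c("case_id", "gene")])
  cna <- cna_calls[cna_calls$state != "normal", c("case_id", "gene")]
  cna <- unique(cna)
  altered_cases <- function(genes) {
    union(mut$case_id[mut$gene %in% genes], cna$case_id[cna$gene %in% genes])
  }
  sets <- lapply(genesets, function(g) {
    cs <- altered_cases(g)
    list(n_altered = length(cs),
         pct = round_half_up(100 * length(cs) / max(n, 1), 1),
         cases = sort(cs))
  })
  comb <- altered_cases(unlist(genesets))
  both <- merge(mut, cna, by = c("case_id", "gene"))
  both <- both[both$gene %in% unlist(genesets), , drop = FALSE]
  c(sets,
    list(combined = list(n_altered = length(comb),
                         pct = round_half_up(100 * length(comb) / max(n, 1), 1)),
         exclusivity_violations = both[order(both$gene, both$case_id),
                                       c("gene", "case_id")]))
}
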