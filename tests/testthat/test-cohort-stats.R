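test_that("gene x subtype table counts cases once per gene", {
  labels <- data.frame(case_id = c("A", "B", "C"),
                       subtype = c("MSI", "MSI", "CIN"))
  calls <- rbind(mk_call(case_id = "A", gene = "ARID1A"),
                 mk_call(case_id = "A", gene = "ARID1A", pos = 101L),
                 mk_call(case_id = "A", gene = "ARID1A", pos = 102L),
                 mk_call(case_id = "B", gene = "TP53"),
                 mk_call(case_id = "C", gene = "TP53"))
  tab <- gene_subtype_table(calls, labels, c("ARID1A", "TP53"))
  expect_equal(tab$counts["ARID1A", "MSI"], 1L)  # multiplicity ignored
  expect_equal(tab$counts["TP53", "MSI"], 1L)
  expect_equal(tab$counts["TP53", "CIN"], 1L)
  expect_equal(tab$pct["TP53", "MSI"], 50)
  expect_equal(nrow(gene_subtype_table(calls, labels,
                                       character(0))$counts), 0)
  bad <- labels
  bad$subtype[1] <- NA
  expect_error(gene_subtype_table(calls, bad, "TP53"), "unlabeled")
})

test_that("per-subtype mutation rates are column sums over subtype sizes", {
  t4 <- gc_table4()
  tab <- structure(list(counts = t4$counts, sizes = t4$sizes),
                   class = "gene_subtype_table")
  expect_equal(unname(mutation_rate_per_subtype(tab)),
               c(2.6, 6.6, 1.8, 1.5))
  zero <- structure(list(counts = matrix(0L, 2, 4,
                                         dimnames = list(c("A", "B"),
                                                         subtype_labels())),
                         sizes = c(EBV = 3L, MSI = 0L, CIN = 2L, GS = 1L)),
                    class = "gene_subtype_table")
  r <- mutation_rate_per_subtype(zero)
  expect_equal(unname(r[c("EBV", "CIN", "GS")]), c(0, 0, 0))
  expect_true(is.na(r[["MSI"]]))
})

test_that("FFH exact p-values match hand enumeration and fisher.test", {
  # identical column proportions: the observed table is the most probable
  flat <- rbind(c(2, 2, 2), c(4, 4, 4))
  expect_equal(ffh_exact_test(flat)$p_value, 1, tolerance = 1e-12)
  # 2x2 hand enumeration: 5 hypergeometric outcomes, p = 34/70
  res <- ffh_exact_test(rbind(c(3, 1), c(1, 3)))
  expect_equal(res$p_value, 34 / 70, tolerance = 1e-12)
  expect_identical(res$method, "ffh_enumeration")
  # column permutation invariance
  tp53 <- rbind(c(0, 5, 26, 10), c(7, 14, 20, 25))
  p1 <- ffh_exact_test(tp53)$p_value
  perm <- sample(4)
  expect_equal(ffh_exact_test(tp53[, perm])$p_value, p1, tolerance = 1e-12)
  # agreement with the reference implementation on random tables
  set.seed(21)
  for (i in 1:30) {
    tab <- matrix(rpois(6, 4), nrow = 2)
    if (any(colSums(tab) == 0) || sum(tab[1, ]) %in% c(0, sum(tab)))
      next
    expect_equal(ffh_exact_test(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_error(ffh_exact_test(rbind(c(-1, 2), c(1, 1))), "nonnegative")
  expect_error(ffh_exact_test(matrix(1:9, 3)), "2 x K")
})

test_that("enumeration equals the independent lexicographic oracle", {
  # every 2x3 table with total n <= 9 (exhaustive margin coverage)
  for (n in 2:9) {
    comps <- expand.grid(a = 0:n, b = 0:n, c = 0:n, d = 0:n, e = 0:n)
    comps$f <- n - rowSums(comps)
    comps <- comps[comps$f >= 0, ]
    # subsample for runtime; seed fixed, all margins represented
    set.seed(n)
    comps <- comps[sample(nrow(comps), min(60, nrow(comps))), ]
    for (r in seq_len(nrow(comps))) {
      tab <- matrix(as.numeric(comps[r, ]), nrow = 2, byrow = TRUE)
      if (any(colSums(tab) == 0)) next
      expect_equal(ffh_exact_test(tab)$p_value, ffh_oracle(tab),
                   tolerance = 1e-12)
    }
  }
})

test_that("the Monte Carlo fallback approximates the exact answer", {
  tab <- rbind(c(3, 9, 1), c(7, 2, 8))
  exact <- ffh_exact_test(tab)$p_value
  mc <- ffh_exact_test(tab, max_tables = 2)
  expect_identical(mc$method, "ffh_montecarlo")
  expect_equal(mc$p_value, exact, tolerance = 0.02)
  # fixed seed: reproducible, and the caller's RNG stream is untouched
  set.seed(123)
  before <- runif(1)
  mc2 <- ffh_exact_test(tab, max_tables = 2)
  set.seed(123)
  expect_equal(runif(1), before)
  expect_identical(mc$p_value, mc2$p_value)
})

test_that("Clopper-Pearson intervals are exact and nested", {
  expect_equal(round(clopper_pearson(3, 4)[["lower"]], 3), 0.194)
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson(10, 10)[["upper"]], 1)
  # (39, 39): lower bound solves P(X = 39) = alpha/2, i.e. p^39 = 0.025
  expect_equal(clopper_pearson(39, 39)[["lower"]], 0.025^(1 / 39),
               tolerance = 1e-9)
  # cross-check against the exact binomial test
  set.seed(9)
  for (i in 1:25) {
    n <- sample(1:60, 1)
    x <- sample(0:n, 1)
    expect_equal(unname(clopper_pearson(x, n)),
                 as.numeric(stats::binom.test(x, n)$conf.int),
                 tolerance = 1e-9)
  }
  # nesting: the 99% interval contains the 95% interval
  for (n in 1:30) for (x in 0:n) {
    ci95 <- clopper_pearson(x, n, 0.95)
    ci99 <- clopper_pearson(x, n, 0.99)
    expect_lte(ci99[["lower"]], ci95[["lower"]])
    expect_gte(ci99[["upper"]], ci95[["upper"]])
  }
  expect_error(clopper_pearson(5, 4), "invalid")
  expect_error(clopper_pearson(-1, 4), "invalid")
})

test_that("pathway summary counts altered cases once and flags co-events", {
  ids <- sprintf("P%03d", 1:107)
  # 8 substitution-only + 5 amplification-only ERBB2 cases
  subs <- do.call(rbind, lapply(ids[1:8], function(id)
    mk_call(case_id = id, gene = "ERBB2")))
  # plus KRAS mutations overlapping two of the substitution cases
  subs <- rbind(subs, mk_call(case_id = ids[1], gene = "KRAS"),
                mk_call(case_id = ids[30], gene = "KRAS"))
  cna <- data.frame(case_id = ids[9:13], gene = "ERBB2",
                    state = "duplication")
  pw <- pathway_alteration_summary(subs, cna, ids)
  erbb2 <- union(ids[1:8], ids[9:13])
  expect_equal(pw$rtk$n_altered, 13)
  expect_setequal(pw$rtk$cases, erbb2)
  expect_equal(pw$combined$n_altered, 14)  # + the KRAS-only case
  expect_equal(nrow(pw$exclusivity_violations), 0)
  # a case with both ERBB2 substitution and amplification is flagged
  cna2 <- rbind(cna, data.frame(case_id = ids[1], gene = "ERBB2",
                                state = "duplication"))
  pw2 <- pathway_alteration_summary(subs, cna2, ids)
  expect_identical(pw2$exclusivity_violations$case_id, ids[1])
  # empty gene set alters nothing
  pw0 <- pathway_alteration_summary(subs, cna, ids,
                                    genesets = list(x = character(0)))
  expect_equal(pw0$x$n_altered, 0)
})

test_that("a 37-of-107 altered fixture reports 34.6%", {
  ids <- sprintf("Q%03d", 1:107)
  calls <- do.call(rbind, lapply(ids[1:37], function(id)
    mk_call(case_id = id, gene = "PIK3CA")))
  cna <- data.frame(case_id = character(0), gene = character(0),
                    state = character(0))
  pw <- pathway_alteration_summary(calls, cna, ids)
  expect_equal(pw$combined$n_altered, 37)
  expect_equal(pw$combined$pct, 34.6)
})
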