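test_that("default profiles carry the reference per-gene probabilities", {
  p <- default_subtype_profiles()
  prev <- vapply(p, `[[`, numeric(1), "prevalence")
  expect_equal(sum(prev), 1, tolerance = 1e-12)
  expect_equal(unname(prev), c(7, 19, 46, 35) / 107)
  expect_equal(p$MSI$per_gene_mutation_prob[["ARID1A"]], 14 / 19)
  expect_equal(p$EBV$per_gene_mutation_prob[["TP53"]], 0)
  for (pp in p) {
    expect_true(all(pp$per_gene_mutation_prob >= 0 &
                      pp$per_gene_mutation_prob <= 1))
    expect_identical(pp$ebv_positive, pp$subtype_label == "EBV")
  }
  expect_equal(p$MSI$expected_mutation_rate, 125 / 19)
})

test_that("invalid probabilities are rejected at spec construction", {
  p <- default_subtype_profiles()
  p$CIN$per_gene_mutation_prob[1] <- 1.5
  expect_error(cohort_spec(10, profiles = p), "probability")
})

test_that("empty cohorts and seed determinism behave as contracted", {
  expect_length(generate_cohort(cohort_spec(0, seed = 1)), 0)
  a <- generate_cohort(cohort_spec(8, seed = 99, mode = "sampling"))
  b <- generate_cohort(cohort_spec(8, seed = 99, mode = "sampling"))
  expect_identical(a, b)
  c <- generate_cohort(cohort_spec(8, seed = 100, mode = "sampling"))
  expect_false(identical(a, c))
})

test_that("exact-marginal mode reproduces the reference subtype sizes", {
  coh <- generate_cohort(cohort_spec(107, seed = 5, mode = "exact_marginal"))
  man <- attr(coh, "manifest")
  tab <- table(factor(man$subtype, levels = subtype_labels()))
  expect_equal(as.integer(tab), c(7L, 19L, 46L, 35L))
  msi <- table(factor(man$msi_status, levels = c("MSS", "MSI-L", "MSI-H")))
  expect_equal(as.integer(msi), c(88L, 4L, 15L))
})

test_that("case bundles are internally consistent with their truth", {
  coh <- small_cohort()
  man <- attr(coh, "manifest")
  for (i in seq_along(coh)) {
    cs <- coh[[i]]
    expect_identical(cs$truth$subtype, man$subtype[i])
    expect_identical(cs$clinical$case_id, cs$case_id)
    # EBV load present exactly for EBV-subtype cases
    expect_identical(cs$ebv_copies > 0, man$subtype[i] == "EBV")
    # noise-free coverage: log2 ratios are 0 outside the planted CNA gene
    nb <- normalize_coverage(cs$coverage)
    cna_gene <- if (is.na(man$cna_gene[i])) "" else man$cna_gene[i]
    outside <- nb$gene != cna_gene
    expect_true(all(abs(nb$log2_ratio[outside]) < 1e-9))
    if (!is.na(man$cna_gene[i])) {
      inside <- abs(nb$log2_ratio[nb$gene == man$cna_gene[i]])
      expect_true(all(abs(inside - log2(1.5)) < 1e-9 |
                        abs(inside - 1) < 1e-9))
    }
    # clinical sanity: follow-up nonnegative, M1 implies stage IV
    expect_gte(cs$clinical$followup_days, 0)
    if (cs$clinical$M == "M1") expect_identical(cs$clinical$ajcc_stage, "IV")
    if (cs$clinical$gc_death_event) expect_true(cs$clinical$relapse_event)
  }
})

test_that("MSI marker histograms encode the truth status", {
  coh <- small_cohort()
  man <- attr(coh, "manifest")
  for (i in seq_along(coh)) {
    cs <- coh[[i]]
    res <- call_msi_case(cs$msi_tumor, cs$msi_normal)
    expect_identical(res$status, man$msi_status[i])
    if (man$msi_status[i] != "MSS") {
      unstable <- names(which(res$per_marker_unstable))[1]
      tp <- cs$msi_tumor[[unstable]]
      np <- cs$msi_normal[[unstable]]
      novel <- setdiff(tp$lengths, np$lengths)
      expect_true(sum(tp$fractions[tp$lengths %in% novel]) >= 0.2)
    }
  }
})

test_that("sampling mode recovers profile mutation frequencies at n=2000", {
  coh <- generate_cohort(cohort_spec(2000, seed = 77, mode = "sampling"))
  man <- attr(coh, "manifest")
  profiles <- default_subtype_profiles()
  genes <- names(profiles$MSI$per_gene_mutation_prob)
  mut <- t(vapply(coh, function(cs) genes %in% cs$truth$mutated_genes,
                  logical(length(genes))))
  colnames(mut) <- genes
  for (s in subtype_labels()) {
    rows <- man$subtype == s
    n_s <- sum(rows)
    p <- profiles[[s]]$per_gene_mutation_prob
    obs <- colMeans(mut[rows, , drop = FALSE])
    tol <- 3 * sqrt(p * (1 - p) / n_s)
    expect_true(all(abs(obs - p) <= tol + 1e-12),
                info = paste("subtype", s))
  }
  # marginal subtype frequencies also within 3 binomial SDs
  prev <- vapply(profiles, `[[`, numeric(1), "prevalence")
  obs_prev <- as.numeric(table(factor(man$subtype,
                                      levels = subtype_labels()))) / 2000
  expect_true(all(abs(obs_prev - prev) <=
                    3 * sqrt(prev * (1 - prev) / 2000)))
})

test_that("cohorts round-trip through the on-disk TSV layout", {
  coh <- small_cohort()
  dir <- tempfile("cohort")
  on.exit(unlink(dir, recursive = TRUE))
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- read_cohort_dir(dir)
  expect_length(back, length(coh))
  ids <- vapply(back, `[[`, character(1), "case_id")
  orig <- coh[match(ids, vapply(coh, `[[`, character(1), "case_id"))]
  for (i in seq_along(back)) {
    expect_null(back[[i]]$truth)  # manifest withheld from the pipeline
    expect_equal(back[[i]]$tumor_variants$vaf_tumor,
                 orig[[i]]$tumor_variants$vaf_tumor, tolerance = 1e-6)
    expect_identical(back[[i]]$coverage$tumor_depth,
                     as.integer(orig[[i]]$coverage$tumor_depth))
    expect_equal(back[[i]]$msi_tumor[["BAT-26"]]$fractions,
                 orig[[i]]$msi_tumor[["BAT-26"]]$fractions,
                 tolerance = 1e-9)
  }
})
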