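test_that("variant tables round-trip and percent VAFs are normalized", {
  path <- system.file("extdata", "germline_variants.tsv",
                      package = "gastrosubtype")
  df <- read_variant_table(path)
  expect_equal(nrow(df), 30)
  alk <- df[df$case_id == "YMC54" & df$gene == "ALK", ]
  expect_equal(alk$total_depth, 637)
  expect_equal(alk$vaf_tumor, 0.4851)
  expect_equal(alk$vaf_normal, 0.6036)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_variant_table(df, tmp)
  back <- read_variant_table(tmp)
  expect_equal(back$vaf_tumor, df$vaf_tumor)
  expect_identical(back$protein_change, df$protein_change)
})

test_that("malformed tables raise informative format errors", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(c("case_id\tchrom\tpos", "C1\tchr1\t5"), tmp)
  expect_error(read_variant_table(tmp), "total_depth")
  writeLines(c(paste(c("case_id", "chrom", "pos", "ref", "alt", "gene",
                       "total_depth", "vaf_tumor"), collapse = "\t"),
               "C1\tchr1\t5\tA\tT\tTP53\tdeep\t0.5"), tmp)
  expect_error(read_variant_table(tmp), "total_depth.*line 1")
})

test_that("protein changes map to consequence classes", {
  cases <- list(
    list("p.Arg2194Ter", "trunc"),
    list("p.Pro619LeufsTer43", "trunc"),
    list("p.Asp1850ThrfsTer33", "trunc"),
    list("p.His1047Arg", "missense"),
    list("p.V832M", "missense"),
    list("p.Glu280del", "in_frame"),
    list("p.Gln1334dup", "in_frame"),
    list("???", "other"))
  for (cc in cases)
    expect_identical(classify_consequence(cc[[1]]), cc[[2]],
                     label = cc[[1]])
  expect_identical(classify_consequence("p.?", "splice_donor_variant"),
                   "splicing")
})

test_that("panel of normals counts distinct cases, not read support", {
  normals <- lapply(1:3, function(i)
    mk_call(case_id = paste0("N", i), pos = 100L))
  # same case listed twice still counts once
  normals[[4]] <- mk_call(case_id = "N1", pos = 100L)
  normals[[5]] <- mk_call(case_id = "N1", pos = 200L)
  pon <- build_panel_of_normals(normals)
  expect_identical(unname(pon[["chr1:100:A:T"]]), 3L)
  expect_identical(unname(pon[["chr1:200:A:T"]]), 1L)
  expect_length(build_panel_of_normals(list()), 0)
})

test_that("somatic cascade enforces each published threshold strictly", {
  nrm <- mk_call(pos = 999L)  # unrelated normal call
  keep <- function(call, pon = integer(0))
    nrow(filter_somatic(call, nrm, pon))
  expect_equal(keep(mk_call(total_depth = 40, vaf_tumor = 0.20)), 0)
  expect_equal(keep(mk_call(total_depth = 50, vaf_tumor = 0.20)), 0)  # strict >
  expect_equal(keep(mk_call(total_depth = 600, vaf_tumor = 0.04)), 0)
  expect_equal(keep(mk_call(vaf_tumor = 0.05)), 0)                    # strict >
  expect_equal(keep(mk_call(popfreq_exac = 0.02)), 0)
  expect_equal(keep(mk_call(popfreq_exac = 0.005)), 0)                # strict <
  expect_equal(keep(mk_call(exonic = FALSE)), 0)
  expect_equal(keep(mk_call(exonic = FALSE, consequence = "splicing")), 1)
  expect_equal(keep(mk_call()), 1)
  # panel of normals: seen in 3 normals excluded, in 2 retained
  pon3 <- stats::setNames(3L, "chr1:100:A:T")
  pon2 <- stats::setNames(2L, "chr1:100:A:T")
  expect_equal(keep(mk_call(), pon3), 0)
  expect_equal(keep(mk_call(), pon2), 1)
  # matched-normal evidence: germline-level VAF in normal excludes
  som <- mk_call()
  expect_equal(nrow(filter_somatic(som, mk_call(vaf_tumor = 0.5))), 0)
  expect_equal(nrow(filter_somatic(som, mk_call(vaf_tumor = 0.01))), 1)
  expect_error(filter_somatic(som, NULL), "matched normal")
  expect_warning(out <- filter_somatic(som, NULL, allow_tumor_only = TRUE),
                 "tumor-only")
  expect_equal(nrow(out), 1)
})

test_that("germline cascade requires presence in both samples", {
  tumor <- mk_call(case_id = "YMC29", chrom = "16", pos = 68867247L,
                   ref = "G", alt = "A", gene = "CDH1",
                   protein_change = "p.V832M", total_depth = 1337,
                   vaf_tumor = 0.5221, popfreq_exac = 0.001)
  normal <- tumor
  normal$vaf_tumor <- 0.4975
  normal$origin <- "normal_table"
  out <- filter_germline(tumor, normal)
  expect_equal(nrow(out), 1)
  expect_equal(out$vaf_normal, 0.4975)
  low <- tumor
  low$vaf_tumor <- 0.25
  expect_equal(nrow(filter_germline(low, normal)), 0)
  expect_equal(nrow(filter_germline(tumor, mk_call(pos = 1L))), 0)
  common <- tumor
  common$popfreq_1kg <- 0.05
  expect_equal(nrow(filter_germline(common, normal)), 0)
})

test_that("filter decisions match a row-by-row oracle on random records", {
  calls <- random_calls(1000)
  nrm <- mk_call(pos = 999999L)
  th <- filter_thresholds()
  got <- filter_somatic(calls, nrm, thresholds = th)
  pf <- pmax(ifelse(is.na(calls$popfreq_1kg), 0, calls$popfreq_1kg),
             ifelse(is.na(calls$popfreq_esp6500), 0, calls$popfreq_esp6500),
             ifelse(is.na(calls$popfreq_exac), 0, calls$popfreq_exac))
  want <- calls$vaf_tumor > 0.05 & calls$total_depth > 50 &
    (calls$exonic | calls$consequence == "splicing") & pf < 0.005
  expect_setequal(
    paste(got$chrom, got$pos, got$case_id, got$vaf_tumor),
    paste(calls$chrom, calls$pos, calls$case_id, calls$vaf_tumor)[want])
})

test_that("somatic filtering is idempotent and monotone in the VAF cut", {
  calls <- random_calls(400, seed = 7)
  nrm <- mk_call(pos = 999999L)
  once <- filter_somatic(calls, nrm)
  twice <- filter_somatic(once, nrm)
  expect_identical(once, twice)
  sizes <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.28), function(v)
    nrow(filter_somatic(calls, nrm,
                        thresholds = filter_thresholds(somatic_min_vaf = v))),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("somatic and germline outputs partition the planted truth", {
  coh <- small_cohort()
  pon <- build_panel_of_normals(lapply(coh, `[[`, "normal_variants"))
  for (cs in coh[1:8]) {
    som <- filter_somatic(cs$tumor_variants, cs$normal_variants, pon)
    ger <- filter_germline(cs$tumor_variants, cs$normal_variants)
    k_som <- paste(som$chrom, som$pos, som$ref, som$alt)
    k_ger <- paste(ger$chrom, ger$pos, ger$ref, ger$alt)
    expect_length(intersect(k_som, k_ger), 0)
    expect_setequal(sort(unique(som$gene)), sort(cs$truth$mutated_genes))
    expect_equal(nrow(ger), nrow(cs$normal_variants))
  }
})

test_that("germline significance labels are counted, not classified", {
  labs <- read_variant_table(system.file("extdata", "germline_variants.tsv",
                                         package = "gastrosubtype"))
  s <- summarize_germline(labs)
  expect_equal(s$total, 30)
  expect_equal(s$counts$benign_or_likely_benign, 16)
  expect_equal(s$counts$vus, 12)
  expect_equal(s$counts$likely_pathogenic, 2)
  expect_message(s2 <- summarize_germline(c("Benign", "frobnicated")),
                 "other")
  expect_equal(s2$counts$other, 1)
  s0 <- summarize_germline(character(0))
  expect_equal(s0$total, 0)
  expect_true(all(unlist(s0$counts) == 0))
})

test_that("recurrence tallies pool del/dup and count cases once", {
  calls <- do.call(rbind, c(
    lapply(1:12, function(i) mk_call(case_id = paste0("A", i),
                                     gene = "ARID1A", pos = 500L,
                                     protein_change = "p.Gln1334del")),
    lapply(1:11, function(i) mk_call(case_id = paste0("B", i),
                                     gene = "ARID1A", pos = 501L,
                                     protein_change = "p.Gln1334dup")),
    # one case with two TP53 variants of the same normalized change
    list(mk_call(case_id = "C1", gene = "TP53", pos = 600L),
         mk_call(case_id = "C1", gene = "TP53", pos = 600L),
         mk_call(case_id = "D1", gene = "KRAS", pos = 700L,
                 protein_change = "p.Gly13Asp"))))
  rec <- tally_recurrence(calls, cohort_n = 107)
  arid <- rec[rec$gene == "ARID1A", ]
  expect_equal(arid$n_mutated_samples, 23L)
  expect_equal(arid$pct_of_cohort, 21.5)
  expect_identical(arid$protein_change, "p.Gln1334del/dup")
  expect_false("TP53" %in% rec$gene)  # one case is not recurrent
  expect_false("KRAS" %in% rec$gene)
  unpooled <- tally_recurrence(calls, 107, pool_del_dup = FALSE)
  expect_equal(sort(unpooled$n_mutated_samples[unpooled$gene == "ARID1A"]),
               c(11L, 12L))
  expect_equal(nrow(tally_recurrence(calls[0, ], 107)), 0)
})
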