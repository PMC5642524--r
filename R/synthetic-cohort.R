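#' Default per-subtype generative profiles
#'
#' Profiles are parameterized directly from the reference cohort tables:
#' per-gene mutation probabilities are the mutated-case fractions of the
#' gene x subtype table (count / subtype size), prevalences are the subtype
#' sizes over 107, EBV positivity marks the EBV profile only, and the
#' marker-instability probability applies to MSI-subtype cases (per marker;
#' 0.45 gives roughly the observed 15:4 MSI-H:MSI-L split conditional on at
#' least one unstable marker).
#'
#' @return named list of four `subtype_profile` lists (EBV, MSI, CIN, GS)
#' @export
default_subtype_profiles <- function() {
  t4 <- gc_table4()
  st <- subtype_labels()
  prev <- t4$sizes / sum(t4$sizes)
  out <- lapply(st, function(s) {
    probs <- t4$counts[, s] / t4$sizes[[s]]
    structure(list(
      subtype_label = s,
      prevalence = unname(prev[[s]]),
      per_gene_mutation_prob = probs,
      cna_prob = if (s == "CIN") 1 else 0,
      msi_marker_instab_probs = stats::setNames(
        rep(if (s == "MSI") 0.45 else 0, 5), msi_markers()),
      ebv_positive = s == "EBV",
      expected_mutation_rate = sum(probs)
    ), class = "subtype_profile")
  })
  names(out) <- st
  out
}

validate_profiles <- function(profiles) {
  prev <- vapply(profiles, `[[`, numeric(1), "prevalence")
  if (abs(sum(prev) - 1) > 1e-9)
    abort("subtype prevalences must sum to 1")
  for (p in profiles) {
    probs <- c(p$per_gene_mutation_prob, p$cna_prob,
               p$msi_marker_instab_probs)
    if (any(probs < 0 | probs > 1))
      abort("invalid probability in profile ", p$subtype_label)
    if (p$ebv_positive && p$subtype_label != "EBV")
      abort("ebv_positive may be TRUE only for the EBV profile")
  }
  invisible(profiles)
}

#' Cohort generation specification
#'
#' Two generation modes: `"exact_marginal"` deterministically reproduces the
#' target marginal counts (subtype sizes, per-gene mutated-case counts,
#' MSI-H/L split) for table reproduction, with assay noise disabled;
#' `"sampling"` draws every case i.i.d. from the profiles, with noise
#' enabled, for statistical property tests.
#'
#' @param n_cases number of cases to generate
#' @param profiles four subtype profiles ([default_subtype_profiles()])
#' @param seed master integer seed; all subsidiary streams derive from it
#' @param mode "sampling" or "exact_marginal"
#' @param depth_model list(mean, size): negative-binomial sequencing depth,
#'   floored at `depth_floor`
#' @param vaf_model list(shape1, shape2, min): somatic VAF ~ Beta truncated
#'   to \[min, 1\]; germline VAF ~ Normal(0.5, 0.05) clipped to \[0.30, 0.70\]
#' @param coverage_depth mean per-target coverage for the CNV input
#' @param coverage_log2_sd multiplicative coverage noise (log2 SD); forced
#'   to 0 in exact_marginal mode
#' @param artifacts_per_case expected sub-threshold artifact calls injected
#'   per tumor table (sampling mode only)
#' @param germline_rate expected germline-pool variants per case
#' @param followup_model list(base_hazard, stage_mult, subtype_mult,
#'   censor_range, gc_death_frac): exponential relapse times with stage- and
#'   subtype-dependent hazards, uniform administrative censoring
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_cases,
                        profiles = default_subtype_profiles(),
                        seed = 1L,
                        mode = c("sampling", "exact_marginal"),
                        depth_model = list(mean = 500, size = 8),
                        vaf_model = list(shape1 = 2, shape2 = 5, min = 0.05),
                        coverage_depth = 400,
                        coverage_log2_sd = 0.12,
                        artifacts_per_case = 2,
                        germline_rate = 30 / 107,
                        followup_model = list(
                          base_hazard = 4e-4,
                          stage_mult = c(I = 0.5, II = 1, III = 2, IV = 3),
                          subtype_mult = c(EBV = 0.8, MSI = 0.6, CIN = 1,
                                           GS = 1.2),
                          censor_range = c(180, 1460),
                          gc_death_frac = 0.6)) {
  mode <- match.arg(mode)
  if (n_cases < 0) abort("n_cases must be >= 0")
  validate_profiles(profiles)
  if (mode == "exact_marginal") {
    coverage_log2_sd <- 0
    artifacts_per_case <- 0
  }
  structure(list(n_cases = as.integer(n_cases), profiles = profiles,
                 seed = as.integer(seed), mode = mode,
                 depth_model = depth_model, vaf_model = vaf_model,
                 coverage_depth = coverage_depth,
                 coverage_log2_sd = coverage_log2_sd,
                 artifacts_per_case = artifacts_per_case,
                 germline_rate = germline_rate,
                 followup_model = followup_model),
            class = "cohort_spec")
}

# largest-remainder apportionment of n into round(p*n)-like integer counts
apportion <- function(n, p) {
  raw <- p * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# synthetic genomic coordinates for the panel (stable gene -> locus map)
panel_map <- function() {
  genes <- gene_panel()
  data.frame(gene = genes,
             chrom = paste0("chr", (seq_along(genes) - 1) %% 22 + 1),
             pos_base = 1e6 * seq_along(genes))
}

# canonical recurrent protein changes observed in the reference cohort;
# other genes get a generic missense hotspot
hotspot_changes <- function() {
  c(ARID1A = "p.Gln1334del", ZBTB20 = "p.Pro619LeufsTer43",
    TP53 = "p.Arg248Trp", KRAS = "p.Gly13Asp", PIK3CA = "p.His1047Arg",
    CDH1 = "p.Leu15del", CR1 = "p.Arg2194Ter", CCND1 = "p.Glu280del",
    ERBB2 = "p.Arg678Gln", BCOR = "p.Gln1174ThrfsTer8",
    APC = "p.Glu1464ValfsTer8", RHOA = "p.Arg5Gln")
}

empty_variant_table <- function() {
  df <- as.data.frame(stats::setNames(
    rep(list(character(0)), length(variant_columns())), variant_columns()))
  df$pos <- integer(0)
  for (col in c("total_depth", "vaf_tumor", "vaf_normal", "popfreq_1kg",
                "popfreq_esp6500", "popfreq_exac"))
    df[[col]] <- numeric(0)
  df$exonic <- logical(0)
  df
}

variant_row <- function(case_id, gene, protein_change, vaf, depth, origin,
                        popfreq = 0, vaf_normal = NA_real_) {
  pm <- panel_map()
  i <- match(gene, pm$gene)
  data.frame(case_id = case_id, chrom = pm$chrom[i],
             pos = as.integer(pm$pos_base[i] +
                                sum(utf8ToInt(protein_change)) %% 9973),
             ref = "A", alt = "T", gene = gene, transcript_id = "NM_000000.1",
             protein_change = protein_change,
             consequence = classify_consequence(protein_change),
             exonic = TRUE, total_depth = depth, vaf_tumor = vaf,
             vaf_normal = vaf_normal, popfreq_1kg = popfreq,
             popfreq_esp6500 = popfreq, popfreq_exac = popfreq,
             origin = origin)
}

#' Germline variant pool
#'
#' The pool of germline site-alleles the generator samples from: the
#' germline variants printed for the reference cohort (shipped as a
#' plain-text fixture), each assigned a sub-threshold population frequency.
#'
#' @return data.frame of pool variants with clinical-significance labels
#' @export
default_germline_pool <- function() {
  path <- system.file("extdata", "germline_variants.tsv",
                      package = "gastrosubtype")
  df <- utils::read.delim(path, colClasses = "character")
  uniq <- !duplicated(paste(df$chrom, df$pos, df$ref, df$alt))
  data.frame(chrom = df$chrom[uniq], pos = as.integer(df$pos[uniq]),
             ref = df$ref[uniq], alt = df$alt[uniq], gene = df$gene[uniq],
             transcript_id = df$transcript_id[uniq],
             protein_change = df$protein_change[uniq],
             clinical_significance = df$clinical_significance[uniq],
             popfreq = 0.001)
}

draw_depth <- function(n, model, floor = 51) {
  pmax(floor, stats::rnbinom(n, mu = model$mean, size = model$size))
}

draw_somatic_vaf <- function(n, model) {
  # Beta truncated to [min, 1] by inverse-CDF sampling
  lo <- stats::pbeta(model$min, model$shape1, model$shape2)
  u <- stats::runif(n, lo, 1)
  stats::qbeta(u, model$shape1, model$shape2)
}

draw_germline_vaf <- function(n) {
  pmin(0.70, pmax(0.30, stats::rnorm(n, 0.5, 0.05)))
}

# assign hidden truths for the whole cohort
assign_truths <- function(spec) {
  n <- spec$n_cases
  st <- subtype_labels()
  prev <- vapply(spec$profiles, `[[`, numeric(1), "prevalence")
  genes <- names(spec$profiles[[1]]$per_gene_mutation_prob)
  if (spec$mode == "exact_marginal") {
    sizes <- apportion(n, prev)
    subtype <- rep(st, sizes)
  } else {
    subtype <- sample(st, n, replace = TRUE, prob = prev)
    sizes <- as.integer(table(factor(subtype, levels = st)))
  }
  names(sizes) <- st
  msi_status <- rep("MSS", n)
  idx_msi <- which(subtype == "MSI")
  if (length(idx_msi)) {
    if (spec$mode == "exact_marginal") {
      n_h <- apportion(length(idx_msi), c(15, 4) / 19)[1]
      msi_status[idx_msi] <- rep(c("MSI-H", "MSI-L"),
                                 c(n_h, length(idx_msi) - n_h))
    } else {
      q <- spec$profiles$MSI$msi_marker_instab_probs[1]
      for (i in idx_msi) {
        k <- 0
        while (k == 0) k <- stats::rbinom(1, 5, q)
        msi_status[i] <- if (k == 1) "MSI-L" else "MSI-H"
      }
    }
  }
  mut <- matrix(FALSE, n, length(genes), dimnames = list(NULL, genes))
  for (s in st) {
    rows <- which(subtype == s)
    if (!length(rows)) next
    probs <- spec$profiles[[s]]$per_gene_mutation_prob
    if (spec$mode == "exact_marginal") {
      for (g in genes) {
        k <- apportion(length(rows), c(probs[[g]], 1 - probs[[g]]))[1]
        if (k > 0) mut[rows[seq_len(k)], g] <- TRUE
      }
    } else {
      for (g in genes)
        mut[rows, g] <- stats::runif(length(rows)) < probs[[g]]
    }
  }
  amp_pool <- c("CCND1", "CCNE1", "ERBB2", "FGFR2", "KRAS", "MYC",
                "PIK3CA", "JAK2", "PTEN")
  cna_gene <- rep(NA_character_, n)
  idx_cin <- which(subtype == "CIN")
  if (length(idx_cin))
    cna_gene[idx_cin] <- amp_pool[(seq_along(idx_cin) - 1) %%
                                    length(amp_pool) + 1]
  list(subtype = subtype, sizes = sizes, msi_status = msi_status,
       mutated = mut, cna_gene = cna_gene)
}

msi_normal_profiles <- function() {
  base_len <- c(`BAT-25` = 25L, `BAT-26` = 26L, `NR-21` = 21L,
                `NR-24` = 24L, `NR-27` = 27L)
  lapply(stats::setNames(msi_markers(), msi_markers()), function(m) {
    l <- base_len[[m]]
    marker_profile(m, c(l - 1L, l, l + 1L), c(0.2, 0.6, 0.2))
  })
}

msi_tumor_profiles <- function(flags, instab_fraction = 0.3) {
  nrm <- msi_normal_profiles()
  out <- nrm
  for (m in names(flags)) {
    if (isTRUE(flags[[m]])) {
      p <- nrm[[m]]
      mode_l <- p$lengths[which.max(p$fractions)]
      out[[m]] <- marker_profile(
        m, c(mode_l - 3L, p$lengths),
        c(instab_fraction, p$fractions * (1 - instab_fraction)))
    }
  }
  out
}

#' Generate the assay bundle for one case
#'
#' Emits, consistently with the case's hidden truth: the tumor variant
#' table (somatic truth variants plus optional sub-threshold artifacts),
#' the matched normal table (germline-pool variants, present in the tumor
#' table too at ~50% VAF), tumor/normal MSI marker histograms, per-target
#' coverage with multiplicative shifts over the CNA gene, the EBV qPCR
#' copy number, and clinical covariates.
#'
#' @param case_id case identifier
#' @param truth list(subtype, msi_status, mutated_genes, cna_gene)
#' @param spec the [cohort_spec()]
#' @param seed per-case RNG seed
#' @return object of class `case_assay`
#' @export
generate_case_assay <- function(case_id, truth, spec, seed) {
  with_seed(seed, {
    dm <- spec$depth_model
    genes <- truth$mutated_genes
    hs <- hotspot_changes()
    tumor <- empty_variant_table()
    if (length(genes)) {
      pcs <- vapply(genes, function(g)
        if (g %in% names(hs)) hs[[g]] else "p.Ala100Val", character(1))
      tumor <- do.call(rbind, lapply(seq_along(genes), function(i)
        variant_row(case_id, genes[i], pcs[i],
                    vaf = draw_somatic_vaf(1, spec$vaf_model),
                    depth = draw_depth(1, dm), origin = "tumor_table")))
    }
    # germline-pool variants, shared by tumor and normal at ~50% VAF
    pool <- default_germline_pool()
    n_g <- stats::rpois(1, spec$germline_rate)
    normal <- empty_variant_table()
    if (n_g > 0) {
      pick <- pool[sample(nrow(pool), min(n_g, nrow(pool))), , drop = FALSE]
      mk <- function(origin) do.call(rbind, lapply(seq_len(nrow(pick)),
        function(i) {
          r <- variant_row(case_id, pick$gene[i], pick$protein_change[i],
                           vaf = draw_germline_vaf(1),
                           depth = draw_depth(1, dm), origin = origin,
                           popfreq = pick$popfreq[i])
          r$chrom <- pick$chrom[i]
          r$pos <- pick$pos[i]
          r$ref <- pick$ref[i]
          r$alt <- pick$alt[i]
          r$transcript_id <- pick$transcript_id[i]
          r
        }))
      normal <- mk("normal_table")
      tumor <- rbind(tumor, mk("tumor_table"))
    }
    # sub-threshold artifacts that the somatic filter must remove
    if (spec$artifacts_per_case > 0) {
      n_a <- stats::rpois(1, spec$artifacts_per_case)
      if (n_a > 0) {
        ag <- sample(gene_panel(), n_a, replace = TRUE)
        art <- do.call(rbind, lapply(seq_len(n_a), function(i) {
          low_vaf <- stats::runif(1) < 0.5
          variant_row(case_id, ag[i], "p.Gly10Gly",
                      vaf = if (low_vaf) stats::runif(1, 0.005, 0.045)
                            else draw_somatic_vaf(1, spec$vaf_model),
                      depth = draw_depth(1, dm), origin = "tumor_table",
                      popfreq = if (low_vaf) 0 else 0.02)
        }))
        tumor <- rbind(tumor, art)
      }
    }
    # MSI marker histograms consistent with the truth status
    n_unstable <- switch(truth$msi_status, MSS = 0L, `MSI-L` = 1L,
                         `MSI-H` = 2L + stats::rbinom(1, 3, 0.3))
    flags <- stats::setNames(rep(FALSE, 5), msi_markers())
    if (n_unstable > 0) flags[seq_len(n_unstable)] <- TRUE
    msi_normal <- msi_normal_profiles()
    msi_tumor <- msi_tumor_profiles(flags)
    # coverage with a multiplicative shift over the CNA gene
    pm <- panel_map()
    gi <- rep(seq_len(nrow(pm)), each = 4)
    ti <- rep(0:3, nrow(pm))
    cov <- data.frame(target_id = paste0(pm$gene[gi], "_t", ti + 1),
                      gene = pm$gene[gi], chrom = pm$chrom[gi],
                      start = as.integer(pm$pos_base[gi] + ti * 200 + 1),
                      end = as.integer(pm$pos_base[gi] + ti * 200 + 150))
    base_depth <- rep(spec$coverage_depth, nrow(cov))
    mult <- rep(1, nrow(cov))
    if (!is.na(truth$cna_gene)) {
      m <- if (truth$cna_gene == "PTEN") 0.5 else 1.5
      mult[cov$gene == truth$cna_gene] <- m
    }
    noise <- function() if (spec$coverage_log2_sd > 0)
      2^stats::rnorm(nrow(cov), 0, spec$coverage_log2_sd) else 1
    cov$tumor_depth <- round(base_depth * mult * noise())
    cov$normal_depth <- round(base_depth * noise())
    # EBV qPCR copies
    ebv_copies <- if (truth$subtype == "EBV")
      round(stats::rlnorm(1, 9, 1), 1) else 0
    clinical <- sample_clinical(case_id, truth$subtype, spec)
    structure(list(case_id = case_id, ebv_copies = ebv_copies,
                   msi_tumor = msi_tumor, msi_normal = msi_normal,
                   tumor_variants = tumor, normal_variants = normal,
                   coverage = cov, clinical = clinical,
                   truth = truth),
              class = "case_assay")
  })
}

# 7th-edition AJCC gastric stage from pT/pN/M categories
ajcc_stage <- function(pT, pN, M) {
  if (M == "M1") return("IV")
  t <- match(sub("T1[ab]?", "T1", pT), c("T1", "T2", "T3", "T4a", "T4b"))
  n <- match(pN, c("N0", "N1", "N2", "N3"))
  grid <- matrix(c(
    "IA",   "IB",   "IIA",  "IIB",
    "IB",   "IIA",  "IIB",  "IIIA",
    "IIA",  "IIB",  "IIIA", "IIIB",
    "IIB",  "IIIA", "IIIB", "IIIC",
    "IIIB", "IIIB", "IIIC", "IIIC"), nrow = 5, byrow = TRUE)
  grid[t, n]
}

stage_group <- function(stage) {
  if (stage == "IV") "IV"
  else if (grepl("^III", stage)) "III"
  else if (grepl("^II", stage)) "II"
  else "I"
}

sample_clinical <- function(case_id, subtype, spec) {
  t5 <- gc_table5()
  draw <- function(tab) {
    w <- tab[, subtype]
    if (sum(w) == 0) w <- rep(1, length(w))
    sample(rownames(tab), 1, prob = w)
  }
  pT <- draw(t5$pT)
  pN <- draw(t5$pN)
  M <- draw(t5$M)
  stage <- ajcc_stage(pT, pN, M)
  fm <- spec$followup_model
  haz <- fm$base_hazard * fm$stage_mult[[stage_group(stage)]] *
    fm$subtype_mult[[subtype]]
  t_event <- stats::rexp(1, haz)
  t_cens <- stats::runif(1, fm$censor_range[1], fm$censor_range[2])
  relapse <- t_event <= t_cens
  gc_death <- relapse && stats::runif(1) < fm$gc_death_frac
  data.frame(
    case_id = case_id,
    age = round(stats::runif(1, 32, 90)),
    sex = draw(t5$sex),
    lauren_class = draw(t5$lauren_class),
    who_class = draw(t5$who_class),
    pT = pT, pN = pN, M = M, ajcc_stage = stage,
    anatomical_region = draw(t5$anatomical_region),
    h_pylori = draw(t5$h_pylori) == "Positive",
    lymphatic_invasion = draw(t5$lymphatic_invasion),
    venous_invasion = draw(t5$venous_invasion),
    perineural_invasion = draw(t5$perineural_invasion),
    followup_days = round(min(t_event, t_cens)),
    relapse_event = relapse,
    gc_death_event = gc_death)
}

#' Generate a synthetic cohort of case assay bundles
#'
#' @param spec a [cohort_spec()]
#' @return list of `case_assay` objects with a `manifest` attribute (the
#'   hidden truth table: case_id, subtype, msi_status, cna_gene,
#'   n_mutated_genes). Identical specs produce identical cohorts.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_cases == 0) {
    out <- list()
    attr(out, "manifest") <- data.frame(case_id = character(0),
                                        subtype = character(0))
    return(out)
  }
  truths <- with_seed(sub_seed(spec$seed, "truths"), assign_truths(spec))
  ids <- sprintf("SYN%03d", seq_len(spec$n_cases))
  cases <- lapply(seq_len(spec$n_cases), function(i) {
    tr <- list(subtype = truths$subtype[i],
               msi_status = truths$msi_status[i],
               mutated_genes = names(which(truths$mutated[i, ])),
               cna_gene = truths$cna_gene[i])
    generate_case_assay(ids[i], tr, spec, sub_seed(spec$seed, ids[i]))
  })
  attr(cases, "manifest") <- data.frame(
    case_id = ids, subtype = truths$subtype,
    msi_status = truths$msi_status, cna_gene = truths$cna_gene,
    n_mutated_genes = rowSums(truths$mutated))
  cases
}

#' Reference status stubs for the published 107-case cohort
#'
#' Reconstructs per-case EBV / MSI / CNA statuses consistent with the
#' printed cohort marginals (7 EBV-positive, all microsatellite stable;
#' 15 MSI-H and 4 MSI-L cases, all EBV-negative; 46 CNA-positive among the
#' remaining EBV-negative MSS cases; 35 negative throughout), the input the
#' serial classifier needs to reproduce the published subtype distribution.
#'
#' @return data.frame (case_id, ebv_positive, msi_status, cna_positive)
#' @export
reference_status_table <- function() {
  t1 <- gc_table1()
  status <- rbind(
    data.frame(ebv_positive = TRUE, msi_status = "MSS", cna_positive = FALSE,
               n = t1$ebv[["Positive"]]),
    data.frame(ebv_positive = FALSE, msi_status = "MSI-H",
               cna_positive = FALSE, n = t1$msi[["MSI-H"]]),
    data.frame(ebv_positive = FALSE, msi_status = "MSI-L",
               cna_positive = FALSE, n = t1$msi[["MSI-L"]]),
    data.frame(ebv_positive = FALSE, msi_status = "MSS", cna_positive = TRUE,
               n = 46L),
    data.frame(ebv_positive = FALSE, msi_status = "MSS", cna_positive = FALSE,
               n = 35L))
  out <- status[rep(seq_len(nrow(status)), status$n), 1:3]
  out <- data.frame(case_id = sprintf("REF%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Serialize a cohort to a directory of per-case TSV files
#'
#' Writes one subdirectory per case (tumor/normal variant tables, MSI
#' marker profiles, coverage, clinical covariates) plus a top-level
#' `manifest.tsv` holding the hidden truth labels. The manifest is for
#' evaluation only and is ignored by [read_cohort_dir()].
#'
#' @param cohort output of [generate_cohort()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (case in cohort) {
    cd <- file.path(dir, case$case_id)
    dir.create(cd, showWarnings = FALSE)
    write_variant_table(case$tumor_variants,
                        file.path(cd, "tumor_variants.tsv"))
    write_variant_table(case$normal_variants,
                        file.path(cd, "normal_variants.tsv"))
    msi <- do.call(rbind, lapply(c(tumor = "msi_tumor", normal = "msi_normal"),
      function(f) do.call(rbind, lapply(case[[f]], function(p)
        data.frame(case_id = case$case_id,
                   sample = if (f == "msi_tumor") "tumor" else "normal",
                   marker = p$marker_name, allele_length = p$lengths,
                   fraction = p$fractions)))))
    utils::write.table(msi, file.path(cd, "msi_profiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(case$coverage, file.path(cd, "coverage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    clin <- cbind(case$clinical, ebv_copies = case$ebv_copies)
    utils::write.table(clin, file.path(cd, "clinical.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  man <- attr(cohort, "manifest")
  if (!is.null(man))
    utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory back into case assay bundles
#'
#' Reads only the assay files; the truth manifest, if present, is ignored
#' (the pipeline under test must not see it).
#'
#' @param dir cohort directory written by [write_cohort()]
#' @return list of `case_assay` objects (without truth fields)
#' @export
read_cohort_dir <- function(dir) {
  if (!dir.exists(dir)) abort("no such cohort directory: ", dir)
  case_dirs <- list.dirs(dir, recursive = FALSE)
  if (!length(case_dirs)) abort("cohort directory is empty: ", dir)
  lapply(case_dirs, read_case_dir)
}

#' Read a single case directory
#'
#' @param cd one case subdirectory of a cohort directory
#' @return a `case_assay` (without truth fields)
#' @export
read_case_dir <- function(cd) {
  clin <- utils::read.delim(file.path(cd, "clinical.tsv"))
  msi <- utils::read.delim(file.path(cd, "msi_profiles.tsv"),
                           check.names = FALSE)
  prof <- function(samp) {
    sub <- msi[msi$sample == samp, ]
    lapply(stats::setNames(unique(sub$marker), unique(sub$marker)),
           function(m) {
             s <- sub[sub$marker == m, ]
             marker_profile(m, s$allele_length, s$fraction)
           })
  }
  structure(list(
    case_id = clin$case_id[1],
    ebv_copies = clin$ebv_copies[1],
    msi_tumor = prof("tumor"), msi_normal = prof("normal"),
    tumor_variants = read_variant_table(file.path(cd, "tumor_variants.tsv")),
    normal_variants = read_variant_table(file.path(cd,
                                                   "normal_variants.tsv")),
    coverage = utils::read.delim(file.path(cd, "coverage.tsv")),
    clinical = clin[setdiff(names(clin), "ebv_copies")],
    truth = NULL), class = "case_assay")
}
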