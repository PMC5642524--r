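#' Pipeline configuration
#'
#' @param input_dir cohort directory (layout of [write_cohort()])
#' @param output_dir directory for report files (created if needed)
#' @param thresholds [filter_thresholds()]
#' @param msi_params [msi_params()]
#' @param hmm_params [hmm_params()]
#' @param genes gene panel for cohort tables
#' @param genesets pathway gene sets
#' @param ebv_cutoff qPCR copy-number cutoff for EBV positivity (any
#'   quantifiable amplification above the detection limit is positive)
#' @param stages_enabled character subset of
#'   c("filtering","msi","cnv","classify","stats","survival")
#' @param strict stop on the first malformed case instead of collecting
#'   per-case errors
#' @param seed recorded in the run manifest (the pipeline itself is
#'   deterministic given its inputs)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(input_dir, output_dir,
                            thresholds = filter_thresholds(),
                            msi_params = gastrosubtype::msi_params(),
                            hmm_params = gastrosubtype::hmm_params(),
                            genes = gene_panel(),
                            genesets = pathway_gene_sets(),
                            ebv_cutoff = 0,
                            stages_enabled = c("filtering", "msi", "cnv",
                                               "classify", "stats",
                                               "survival"),
                            strict = FALSE,
                            seed = 1L) {
  if (!length(genes)) abort("gene_panel must be nonempty")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 thresholds = thresholds, msi_params = msi_params,
                 hmm_params = hmm_params, genes = genes,
                 genesets = genesets, ebv_cutoff = ebv_cutoff,
                 stages_enabled = stages_enabled, strict = strict,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [pipeline_config()] arguments; threshold and
#' parameter blocks are passed to their constructors.
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(input_dir = y$input_dir, output_dir = y$output_dir)
  if (!is.null(y$thresholds))
    args$thresholds <- do.call(filter_thresholds, y$thresholds)
  if (!is.null(y$msi_params))
    args$msi_params <- do.call(msi_params, y$msi_params)
  if (!is.null(y$hmm_params))
    args$hmm_params <- do.call(hmm_params, y$hmm_params)
  for (k in c("genes", "ebv_cutoff", "stages_enabled", "strict", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Run the full cohort pipeline
#'
#' Reads a cohort directory, applies the somatic/germline filter cascades
#' with a cohort-wide panel of normals, calls MSI and gene-level CNAs per
#' case, classifies subtypes serially, builds the cohort summary tables
#' (gene x subtype counts with exact association tests, mutation rates,
#' recurrence, pathway alterations, germline summary), runs the survival
#' stage, and writes the report files into `output_dir`. Stage timings and
#' per-case filter attrition go to stderr; the run manifest records the
#' configuration and seed. Output files are deterministic given config and
#' inputs.
#'
#' @param config a [pipeline_config()]
#' @return a `cohort_summary` list (labels, distribution, tables, survival
#'   results, attrition), invisibly writes report files
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$input_dir))
    abort("no such cohort directory: ", config$input_dir)
  case_dirs <- list.dirs(config$input_dir, recursive = FALSE)
  if (!length(case_dirs))
    abort("cohort directory is empty: ", config$input_dir)
  errors <- list()
  cases <- list()
  for (cd in case_dirs) {
    res <- tryCatch(read_case_dir(cd), error = function(e) e)
    if (inherits(res, "error")) {
      if (config$strict)
        abort("case ", basename(cd), ": ", conditionMessage(res))
      errors[[basename(cd)]] <- conditionMessage(res)
    } else cases[[length(cases) + 1]] <- res
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage_on <- function(s) s %in% config$stages_enabled
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    message(sprintf("[%s] %.2fs", stage, proc.time()[["elapsed"]] - t0))
    res
  }
  per_case <- function(f) lapply(cases, function(cs) {
    tryCatch(f(cs), error = function(e) {
      if (config$strict) abort("case ", cs$case_id, ": ", conditionMessage(e))
      errors[[cs$case_id]] <<- conditionMessage(e)
      NULL
    })
  })

  somatic <- germline <- empty_variant_table()
  attrition <- NULL
  if (stage_on("filtering")) {
    pon <- build_panel_of_normals(lapply(cases, `[[`, "normal_variants"))
    filt <- tick("filtering", per_case(function(cs) {
      som <- filter_somatic(cs$tumor_variants, cs$normal_variants, pon,
                            config$thresholds)
      ger <- filter_germline(cs$tumor_variants, cs$normal_variants,
                             config$thresholds)
      n_in <- nrow(cs$tumor_variants)
      list(som = som, ger = ger,
           attr = data.frame(case_id = cs$case_id, input_variants = n_in,
                             retained_somatic = nrow(som),
                             retained_germline = nrow(ger),
                             rejected = n_in - nrow(som) - nrow(ger)))
    }))
    ok <- !vapply(filt, is.null, logical(1))
    somatic <- do.call(rbind, c(list(empty_variant_table()),
                                lapply(filt[ok], `[[`, "som")))
    germline <- do.call(rbind, c(list(empty_variant_table()),
                                 lapply(filt[ok], `[[`, "ger")))
    attrition <- do.call(rbind, lapply(filt[ok], `[[`, "attr"))
    write_tsv(somatic, file.path(config$output_dir, "somatic_calls.tsv"))
    write_tsv(germline, file.path(config$output_dir, "germline_calls.tsv"))
    write_tsv(attrition, file.path(config$output_dir, "filter_attrition.tsv"))
  }

  msi_res <- NULL
  if (stage_on("msi")) {
    msi_res <- tick("msi", per_case(function(cs)
      call_msi_case(cs$msi_tumor, cs$msi_normal, config$msi_params)))
    msi_tab <- data.frame(
      case_id = vapply(cases, `[[`, character(1), "case_id"),
      msi_status = vapply(msi_res, function(r)
        if (is.null(r)) NA_character_ else r$status, character(1)),
      n_unstable = vapply(msi_res, function(r)
        if (is.null(r)) NA_integer_ else r$n_unstable, integer(1)))
    write_tsv(msi_tab, file.path(config$output_dir, "msi_status.tsv"))
  }

  cnv_res <- NULL
  if (stage_on("cnv")) {
    cnv_res <- tick("cnv", per_case(function(cs)
      call_cnv_case(cs$coverage, config$hmm_params)))
    gene_calls <- do.call(rbind, lapply(seq_along(cases), function(i) {
      if (is.null(cnv_res[[i]])) return(NULL)
      cbind(case_id = cases[[i]]$case_id, cnv_res[[i]]$genes)
    }))
    write_tsv(gene_calls[gene_calls$state != "normal", , drop = FALSE],
              file.path(config$output_dir, "cna_gene_calls.tsv"))
  }

  summary <- list(errors = errors, attrition = attrition)
  if (stage_on("classify")) {
    if (is.null(msi_res) || is.null(cnv_res))
      abort("classify stage needs the msi and cnv stages enabled")
    status <- data.frame(
      case_id = vapply(cases, `[[`, character(1), "case_id"),
      ebv_positive = vapply(cases, function(cs)
        cs$ebv_copies > config$ebv_cutoff, logical(1)),
      msi_status = vapply(msi_res, function(r)
        if (is.null(r)) NA_character_ else r$status, character(1)),
      cna_positive = vapply(cnv_res, function(r)
        if (is.null(r)) NA else any(r$genes$state != "normal"), logical(1)))
    cls <- tick("classify", classify_cohort(status))
    summary$labels <- cls$labels
    summary$distribution <- cls$distribution
    write_tsv(cls$labels, file.path(config$output_dir, "subtype_labels.tsv"))
    jsonlite::write_json(cls$distribution,
                         file.path(config$output_dir,
                                   "subtype_distribution.json"),
                         dataframe = "rows", digits = NA)

    if (stage_on("stats")) {
      tab <- tick("stats", gene_subtype_table(somatic, cls$labels,
                                              config$genes))
      tests <- gene_association_tests(tab)
      report <- data.frame(gene = rownames(tab$counts))
      for (s in subtype_labels()) {
        report[[paste0(s, "_n")]] <- tab$counts[, s]
        report[[paste0(s, "_pct")]] <- tab$pct[, s]
      }
      report$p_ffh <- round(tests$p_ffh, 3)
      report$p_chisq <- round(tests$p_chisq, 3)
      write_tsv(report, file.path(config$output_dir,
                                  "gene_subtype_table.tsv"))
      rates <- mutation_rate_per_subtype(tab)
      write_tsv(data.frame(subtype = names(rates), mutation_rate = rates),
                file.path(config$output_dir, "mutation_rates.tsv"))
      rec <- tally_recurrence(somatic, length(cases))
      write_tsv(rec, file.path(config$output_dir, "recurrence.tsv"))
      gs <- summarize_germline(merge(
        germline,
        default_germline_pool()[, c("chrom", "pos", "ref", "alt",
                                    "clinical_significance")],
        by = c("chrom", "pos", "ref", "alt"), all.x = TRUE)
        [["clinical_significance"]] %||% character(0))
      jsonlite::write_json(gs, file.path(config$output_dir,
                                         "germline_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      cna_tab <- do.call(rbind, lapply(seq_along(cases), function(i) {
        if (is.null(cnv_res[[i]])) return(NULL)
        g <- cnv_res[[i]]$genes
        g <- g[g$state != "normal", c("gene", "state")]
        if (!nrow(g)) return(NULL)
        cbind(case_id = cases[[i]]$case_id, g)
      })) %||% data.frame(case_id = character(0), gene = character(0),
                          state = character(0))
      pw <- pathway_alteration_summary(
        somatic, cna_tab, vapply(cases, `[[`, character(1), "case_id"),
        config$genesets)
      jsonlite::write_json(pw, file.path(config$output_dir,
                                         "pathway_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      onco <- mutation_matrix(somatic, cls$labels, config$genes)
      write_tsv(data.frame(gene = rownames(onco), onco, check.names = FALSE),
                file.path(config$output_dir, "mutation_matrix.tsv"))
      summary$gene_table <- tab
      summary$tests <- tests
      summary$mutation_rates <- rates
      summary$recurrence <- rec
      summary$germline_summary <- gs
      summary$pathway_summary <- pw
    }

    if (stage_on("survival")) {
      clin <- do.call(rbind, lapply(cases, `[[`, "clinical"))
      recs <- survival_records(clin)
      recs$subtype <- cls$labels$subtype[match(recs$case_id,
                                               cls$labels$case_id)]
      sv <- tick("survival", list(
        rfs_km = km_curve(recs$time, recs$rfs_event),
        rfs_logrank = logrank_test(recs$time, recs$rfs_event, recs$subtype),
        gcss_logrank = logrank_test(recs$time, recs$gcss_event,
                                    recs$subtype)))
      km_by <- do.call(rbind, lapply(split(recs, recs$subtype), function(g) {
        if (!nrow(g)) return(NULL)
        cbind(subtype = g$subtype[1], km_curve(g$time, g$rfs_event))
      }))
      write_tsv(km_by, file.path(config$output_dir, "km_rfs_by_subtype.tsv"))
      write_tsv(data.frame(endpoint = c("RFS", "GCSS"),
                           chisq = c(sv$rfs_logrank$statistic,
                                     sv$gcss_logrank$statistic),
                           df = c(sv$rfs_logrank$df, sv$gcss_logrank$df),
                           p = c(sv$rfs_logrank$p_value,
                                 sv$gcss_logrank$p_value)),
                file.path(config$output_dir, "logrank_tests.tsv"))
      summary$survival <- sv
    }
  }

  manifest <- list(config = list(
    input_dir = config$input_dir, seed = config$seed,
    stages_enabled = config$stages_enabled,
    thresholds = unclass(config$thresholds)),
    n_cases = length(cases), n_case_errors = length(errors))
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  class(summary) <- "cohort_summary"
  invisible(summary)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  if (!is.null(x$distribution)) {
    cat("Subtype distribution:\n")
    print(x$distribution)
  }
  if (!is.null(x$mutation_rates)) {
    cat("Mutation rates per case:\n")
    print(x$mutation_rates)
  }
  invisible(x)
}
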