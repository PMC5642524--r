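#' Parameters of the three-state copy-number HMM
#'
#' States are deletion / normal / duplication with Gaussian emissions on the
#' per-target log2 coverage ratio. Defaults place the duplication mean at
#' +0.58 (a single-copy gain in a diploid genome, log2(3/2)) and the
#' deletion mean at -1 (single-copy loss); the prior strongly favors the
#' normal state and the transition matrix favors staying in state, which
#' merges multi-exon evidence and suppresses single-target outliers.
#'
#' @param state_means log2-ratio means for (deletion, normal, duplication)
#' @param emission_sd shared Gaussian emission SD; NULL = estimate robustly
#'   from the middle 50% of the observed ratios (IQR/1.349)
#' @param transition_stay_prob probability of remaining in the same state
#'   between adjacent targets
#' @param prior initial-state probabilities (deletion, normal, duplication)
#' @param min_targets minimum supporting targets for a non-normal gene call
#' @return object of class `hmm_params`
#' @export
hmm_params <- function(state_means = c(deletion = -1, normal = 0,
                                       duplication = 0.58),
                       emission_sd = NULL,
                       transition_stay_prob = 0.99,
                       prior = c(deletion = 0.005, normal = 0.99,
                                 duplication = 0.005),
                       min_targets = 2L) {
  if (!is.null(emission_sd) && emission_sd <= 0)
    abort("emission_sd must be positive")
  if (transition_stay_prob <= 0 || transition_stay_prob >= 1)
    abort("transition_stay_prob must be in (0, 1)")
  if (abs(sum(prior) - 1) > 1e-9) prior <- prior / sum(prior)
  structure(list(states = c("deletion", "normal", "duplication"),
                 state_means = state_means, emission_sd = emission_sd,
                 transition_stay_prob = transition_stay_prob,
                 prior = prior, min_targets = as.integer(min_targets)),
            class = "hmm_params")
}

#' Normalize tumor/normal coverage to log2 ratios
#'
#' Depths are median-normalized within sample, then the per-target log2 of
#' the tumor/normal normalized-count ratio is taken. Targets with zero depth
#' in either sample are masked (NA ratio) and excluded from decoding.
#'
#' @param bins data.frame with columns target_id, gene, chrom, start, end,
#'   tumor_depth, normal_depth
#' @return the input with a `log2_ratio` column added
#' @export
normalize_coverage <- function(bins) {
  stopifnot(all(c("tumor_depth", "normal_depth") %in% names(bins)))
  if (!nrow(bins) || all(bins$tumor_depth == 0) || all(bins$normal_depth == 0))
    abort("all-zero coverage: cannot normalize")
  med_t <- stats::median(bins$tumor_depth[bins$tumor_depth > 0])
  med_n <- stats::median(bins$normal_depth[bins$normal_depth > 0])
  ok <- bins$tumor_depth > 0 & bins$normal_depth > 0
  lr <- rep(NA_real_, nrow(bins))
  lr[ok] <- log2((bins$tumor_depth[ok] / med_t) /
                   (bins$normal_depth[ok] / med_n))
  bins$log2_ratio <- lr
  bins
}

resolve_emission_sd <- function(ratios, params) {
  if (!is.null(params$emission_sd)) return(params$emission_sd)
  iqr <- stats::IQR(ratios, na.rm = TRUE)
  sd <- iqr / (2 * stats::qnorm(0.75))  # robust sigma from the middle 50%
  max(sd, 0.05)                          # floor for near-constant input
}

#' Viterbi decoding of per-target copy-number states
#'
#' Maximum-probability state path under Gaussian emissions; masked (NA)
#' ratios contribute no emission term and inherit smoothing through the
#' transitions.
#'
#' @param log2_ratios numeric vector ordered by (chrom, start)
#' @param params [hmm_params()]
#' @return character vector of decoded states, one per input ratio
#' @export
hmm_segment <- function(log2_ratios, params = hmm_params()) {
  n <- length(log2_ratios)
  if (n == 0) return(character(0))
  states <- params$states
  sd <- resolve_emission_sd(log2_ratios, params)
  stay <- params$transition_stay_prob
  ltrans <- matrix(log((1 - stay) / 2), 3, 3)
  diag(ltrans) <- log(stay)
  emit <- function(x) {
    if (is.na(x)) return(c(0, 0, 0))
    stats::dnorm(x, mean = params$state_means, sd = sd, log = TRUE)
  }
  delta <- matrix(-Inf, n, 3)
  back <- matrix(0L, n, 3)
  delta[1, ] <- log(params$prior) + emit(log2_ratios[1])
  if (n > 1) for (t in 2:n) {
    e <- emit(log2_ratios[t])
    for (j in 1:3) {
      cand <- delta[t - 1, ] + ltrans[, j]
      back[t, j] <- which.max(cand)
      delta[t, j] <- cand[back[t, j]] + e[j]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  states[path]
}

#' Merge a decoded state path into segments
#'
#' @param bins data.frame ordered by (chrom, start)
#' @param states decoded states aligned to `bins`
#' @return data.frame of contiguous equal-state runs (chrom, start, end,
#'   state, n_targets, mean_log2_ratio)
#' @export
merge_segments <- function(bins, states) {
  if (!nrow(bins)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), state = character(0),
                      n_targets = integer(0), mean_log2_ratio = numeric(0)))
  }
  run <- cumsum(c(TRUE, states[-1] != states[-length(states)] |
                    bins$chrom[-1] != bins$chrom[-nrow(bins)]))
  do.call(rbind, lapply(split(seq_len(nrow(bins)), run), function(i) {
    data.frame(chrom = bins$chrom[i[1]], start = min(bins$start[i]),
               end = max(bins$end[i]), state = states[i[1]],
               n_targets = length(i),
               mean_log2_ratio = mean(bins$log2_ratio[i], na.rm = TRUE))
  }))
}

#' Gene-level copy-number calls from a decoded path
#'
#' A gene is called non-normal when a majority non-normal state is supported
#' by at least `min_targets` of its targets; otherwise normal.
#'
#' @param bins coverage bins with `gene` and `log2_ratio`
#' @param states decoded per-target states aligned to `bins`
#' @param params [hmm_params()] (supplies `min_targets`)
#' @return data.frame (gene, state, n_targets_supporting, mean_log2_ratio)
#' @export
gene_cna_calls <- function(bins, states, params = hmm_params()) {
  if (!nrow(bins)) {
    return(data.frame(gene = character(0), state = character(0),
                      n_targets_supporting = integer(0),
                      mean_log2_ratio = numeric(0)))
  }
  out <- lapply(split(seq_len(nrow(bins)), bins$gene), function(i) {
    st <- states[i]
    nn <- st[st != "normal"]
    call <- "normal"
    sup <- length(st[st == "normal"])
    if (length(nn)) {
      tab <- sort(table(nn), decreasing = TRUE)
      if (tab[1] >= params$min_targets && tab[1] > length(st) / 2) {
        call <- names(tab)[1]
        sup <- as.integer(tab[1])
      }
    }
    data.frame(gene = bins$gene[i[1]], state = call,
               n_targets_supporting = as.integer(sup),
               mean_log2_ratio = mean(bins$log2_ratio[i], na.rm = TRUE))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Call gene-level CNAs for one case from raw coverage
#'
#' Convenience wrapper: normalize, decode per chromosome, call genes.
#'
#' @param bins coverage data.frame (see [normalize_coverage()])
#' @param params [hmm_params()]
#' @return list with `bins` (with ratios), `states`, `segments`, `genes`
#' @export
call_cnv_case <- function(bins, params = hmm_params()) {
  bins <- bins[order(bins$chrom, bins$start), , drop = FALSE]
  bins <- normalize_coverage(bins)
  sd <- resolve_emission_sd(bins$log2_ratio, params)
  p2 <- params
  p2$emission_sd <- sd
  states <- unlist(lapply(split(seq_len(nrow(bins)), bins$chrom), function(i)
    hmm_segment(bins$log2_ratio[i], p2)), use.names = FALSE)
  # split() orders by factor level; realign to the row order
  ord <- order(unlist(split(seq_len(nrow(bins)), bins$chrom),
                      use.names = FALSE))
  states <- states[ord]
  list(bins = bins, states = states,
       segments = merge_segments(bins, states),
       genes = gene_cna_calls(bins, states, p2))
}

#' Concordance of binary calls against a reference
#'
#' Sensitivity and specificity with exact two-sided Clopper-Pearson 95%
#' confidence intervals, e.g. for panel CNA calls against IHC status.
#'
#' @param calls logical vector of pipeline calls
#' @param reference logical vector of reference labels
#' @param level confidence level
#' @return list with `sensitivity`, `specificity`, each a list
#'   (estimate, lower, upper, x, n); estimates are NA when undefined
#' @export
concordance_metrics <- function(calls, reference, level = 0.95) {
  stopifnot(length(calls) == length(reference))
  tp <- sum(calls & reference)
  fn <- sum(!calls & reference)
  tn <- sum(!calls & !reference)
  fp <- sum(calls & !reference)
  one <- function(x, n) {
    if (n == 0) return(list(estimate = NA_real_, lower = NA_real_,
                            upper = NA_real_, x = x, n = n))
    ci <- clopper_pearson(x, n, level)
    list(estimate = x / n, lower = ci[["lower"]], upper = ci[["upper"]],
         x = x, n = n)
  }
  list(sensitivity = one(tp, tp + fn), specificity = one(tn, tn + fp))
}
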