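# Shared fixture builders for the test suite.

# one variant-call row with sensible defaults, overridable per field
mk_call <- function(case_id = "C1", chrom = "chr1", pos = 100L, ref = "A",
                    alt = "T", gene = "TP53", transcript_id = "NM_1",
                    protein_change = "p.Arg248Trp", consequence = "missense",
                    exonic = TRUE, total_depth = 600, vaf_tumor = 0.30,
                    vaf_normal = NA_real_, popfreq_1kg = 0,
                    popfreq_esp6500 = 0, popfreq_exac = 0,
                    origin = "tumor_table") {
  data.frame(case_id = case_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, gene = gene,
             transcript_id = transcript_id,
             protein_change = protein_change, consequence = consequence,
             exonic = exonic, total_depth = total_depth,
             vaf_tumor = vaf_tumor, vaf_normal = vaf_normal,
             popfreq_1kg = popfreq_1kg, popfreq_esp6500 = popfreq_esp6500,
             popfreq_exac = popfreq_exac, origin = origin)
}

# n random variant records spanning the filter decision boundaries
random_calls <- function(n, seed = 42) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) mk_call(
    case_id = paste0("C", sample(5, 1)),
    chrom = paste0("chr", sample(5, 1)), pos = sample(1000L, 1),
    gene = sample(c("TP53", "KRAS", "ARID1A"), 1),
    exonic = runif(1) < 0.8,
    consequence = sample(c("missense", "trunc", "splicing"), 1),
    total_depth = sample(c(30, 50, 51, 200, 900), 1),
    vaf_tumor = round(runif(1, 0, 0.6), 3),
    popfreq_exac = sample(c(0, 0.001, 0.004, 0.005, 0.02, NA), 1))))
}

# flat marker profiles for MSI tests
flat_profile <- function(marker, mode_len, shifts = c(-1L, 0L, 1L),
                         fracs = c(0.2, 0.6, 0.2)) {
  marker_profile(marker, mode_len + shifts, fracs)
}

# coverage bins for one or more genes (4 targets per gene)
mk_bins <- function(genes, tumor_mult = rep(1, length(genes)), depth = 400,
                    log2_noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(seq_along(genes), function(i) {
    noise <- if (log2_noise_sd > 0) 2^rnorm(4, 0, log2_noise_sd) else 1
    data.frame(target_id = paste0(genes[i], "_t", 1:4), gene = genes[i],
               chrom = "chr1", start = i * 1000 + (0:3) * 200 + 1,
               end = i * 1000 + (0:3) * 200 + 150,
               tumor_depth = round(depth * tumor_mult[i] * noise),
               normal_depth = depth)
  }))
}

# log-probability of one state path (shared scorer for the oracle)
path_logprob <- function(path_states, ratios, params) {
  states <- c("deletion", "normal", "duplication")
  path <- match(path_states, states)
  sd <- params$emission_sd
  stay <- params$transition_stay_prob
  lp <- log(params$prior[path[1]])
  for (t in seq_along(path)) {
    if (!is.na(ratios[t]))
      lp <- lp + dnorm(ratios[t], params$state_means[path[t]], sd,
                       log = TRUE)
    if (t > 1)
      lp <- lp + if (path[t] == path[t - 1]) log(stay) else
        log((1 - stay) / 2)
  }
  unname(lp)
}

# independent brute-force Viterbi: enumerate all 3^n paths
brute_force_path <- function(ratios, params) {
  states <- c("deletion", "normal", "duplication")
  n <- length(ratios)
  sd <- params$emission_sd
  stay <- params$transition_stay_prob
  best <- NULL
  best_lp <- -Inf
  grid <- expand.grid(rep(list(1:3), n))
  for (r in seq_len(nrow(grid))) {
    path <- as.integer(grid[r, ])
    lp <- log(params$prior[path[1]])
    for (t in seq_len(n)) {
      if (!is.na(ratios[t]))
        lp <- lp + dnorm(ratios[t], params$state_means[path[t]], sd,
                         log = TRUE)
      if (t > 1)
        lp <- lp + if (path[t] == path[t - 1]) log(stay) else
          log((1 - stay) / 2)
    }
    if (lp > best_lp) {
      best_lp <- lp
      best <- path
    }
  }
  states[best]
}

# independent FFH oracle: lexicographic enumeration over 2xK tables with
# the observed margins, p = sum of hypergeometric probabilities of tables
# no more probable than the observed one
ffh_oracle <- function(counts) {
  cols <- colSums(counts)
  m <- sum(counts[1, ])
  k <- length(cols)
  tabs <- list()
  rec <- function(prefix) {
    j <- length(prefix) + 1
    left <- m - sum(prefix)
    if (j == k) {
      if (left >= 0 && left <= cols[k])
        tabs[[length(tabs) + 1]] <<- c(prefix, left)
      return()
    }
    for (a in 0:min(cols[j], left)) rec(c(prefix, a))
  }
  rec(integer(0))
  lp <- vapply(tabs, function(a)
    sum(lchoose(cols, a)) - lchoose(sum(cols), m), numeric(1))
  obs <- sum(lchoose(cols, counts[1, ])) - lchoose(sum(cols), m)
  sum(exp(lp)[lp <= obs + 1e-12 * abs(obs) + 1e-300])
}

# small exact-marginal cohort shared across tests (memoized per session)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_spec(20, seed = 11,
                                            mode = "exact_marginal"))
    cache
  }
})
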