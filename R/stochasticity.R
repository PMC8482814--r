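#' Null-model configuration for stochasticity estimation
#'
#' Controls the community randomization: number of randomizations used to
#' form the null expectation, the per-sample richness constraint and the
#' taxon selection weights. The default — proportional occurrence
#' frequency and proportional richness with 1000 randomizations — is the
#' standard parameterization for saliva-style metacommunities.
#'
#' @param n_randomizations number of null draws averaged into the expected
#'   similarity (default 1000; a warning is issued below 100, where the
#'   Monte-Carlo error of the expectation becomes appreciable).
#' @param richness_constraint `"proportional"` (null richness is random
#'   with expectation proportional to observed richness) or `"fixed"`
#'   (each null sample keeps exactly its observed richness).
#' @param frequency_constraint `"proportional"` (features enter null
#'   samples with probability proportional to their regional occurrence
#'   frequency) or `"equiprobable"`.
#' @param seed integer seed; every draw is reproducible from
#'   `(seed, draw_index)`.
#' @return an object of class `null_model_config`.
#' @export
null_model_config <- function(n_randomizations = 1000L,
                              richness_constraint = c("proportional", "fixed"),
                              frequency_constraint = c("proportional",
                                                       "equiprobable"),
                              seed = 1L) {
  richness_constraint <- match.arg(richness_constraint)
  frequency_constraint <- match.arg(frequency_constraint)
  .assert(n_randomizations >= 1, "n_randomizations must be >= 1")
  if (n_randomizations < 100) {
    warning("fewer than 100 randomizations: expected similarities will be noisy",
            call. = FALSE)
  }
  structure(list(n_randomizations = as.integer(n_randomizations),
                 richness_constraint = richness_constraint,
                 frequency_constraint = frequency_constraint,
                 seed = as.integer(seed)),
            class = "null_model_config")
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{\sum_i |x_i - y_i| / \sum_i (x_i + y_i)}; the corresponding
#' similarity is one minus this value.
#'
#' @param x,y non-negative numeric vectors of equal length with at least
#'   one positive entry between them.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  .assert(length(x) == length(y), "vectors differ in length")
  .assert(all(x >= 0) && all(y >= 0), "abundances must be non-negative")
  tot <- sum(x) + sum(y)
  .assert(tot > 0, "both vectors are all-zero")
  sum(abs(x - y)) / tot
}

# occurrence/abundance summaries for one cohort's regional pool
.cohort_pool_stats <- function(table, cohort_samples) {
  missing <- setdiff(cohort_samples, sample_ids(table))
  .assert(length(missing) == 0L, "unknown sample id: '%s'", missing[1L])
  .assert(length(cohort_samples) >= 2L,
          "need >= 2 samples in the cohort, got %d", length(cohort_samples))
  counts <- table$counts[cohort_samples, , drop = FALSE]
  pool <- colSums(counts) > 0
  counts <- counts[, pool, drop = FALSE]
  rel <- counts / rowSums(counts)
  list(counts = counts,
       pool_ids = colnames(counts),
       occ_freq = colMeans(counts > 0),
       mean_rel = colMeans(rel),
       richness = rowSums(counts > 0),
       totals = rowSums(counts))
}

# inclusion probabilities proportional to w with expected richness R,
# capping at 1 and redistributing the excess mass over uncapped features
.inclusion_probs <- function(w, R) {
  n <- length(w)
  if (R >= n) return(rep(1, n))
  p <- rep(0, n)
  free <- w > 0
  repeat {
    c0 <- (R - sum(!free & p == 1)) / sum(w[free])
    p[free] <- c0 * w[free]
    over <- free & p >= 1
    if (!any(over)) break
    p[over] <- 1
    free <- free & !over
    if (!any(free)) break
  }
  pmin(pmax(p, 0), 1)
}

# draw one null sample: feature ids and counts (>= 1 per selected feature)
.null_sample <- function(stats, n_total, target_rich, config) {
  npool <- length(stats$pool_ids)
  w <- switch(config$frequency_constraint,
              proportional = stats$occ_freq,
              equiprobable = rep(1, npool))
  if (target_rich > n_total) {
    warning(sprintf("null richness %d capped at sample total %d",
                    target_rich, n_total), call. = FALSE)
    target_rich <- n_total
  }
  if (config$richness_constraint == "fixed") {
    sel <- sample.int(npool, size = min(target_rich, npool),
                      replace = FALSE, prob = w)
  } else {
    p <- .inclusion_probs(w, min(target_rich, npool))
    sel <- which(stats::runif(npool) < p)
    if (length(sel) == 0L) sel <- sample.int(npool, 1L, prob = w)
    if (length(sel) > n_total) {
      sel <- sample(sel, n_total)
    }
  }
  k <- length(sel)
  cts <- rep(1, k)
  remainder <- n_total - k
  if (remainder > 0) {
    ab <- stats$mean_rel[sel]
    cts <- cts + as.vector(stats::rmultinom(1L, remainder, prob = ab / sum(ab)))
  }
  list(idx = sel, counts = cts)
}

#' One null randomization of a cohort
#'
#' Generates a randomized cohort table that (i) conserves every sample's
#' total count, (ii) preserves per-sample richness exactly (`fixed`) or in
#' expectation proportionally to the observed richness (`proportional`),
#' and (iii) fills samples with features drawn from the cohort's regional
#' pool with inclusion probability proportional to their occurrence
#' frequency (`proportional`) or uniformly (`equiprobable`). Every
#' selected feature receives at least one count; remaining reads are
#' distributed multinomially with weights equal to the regional mean
#' relative abundances renormalized over the selected features. The draw
#' is reproducible from `(config$seed, draw_index)`.
#'
#' @param table a [feature_table].
#' @param cohort_samples sample ids forming the cohort (>= 2).
#' @param config a [null_model_config].
#' @param draw_index index of the randomization (1-based).
#' @return a [feature_table] over the cohort's samples and regional pool.
#' @export
null_community <- function(table, cohort_samples, config = null_model_config(),
                           draw_index = 1L) {
  stats <- .cohort_pool_stats(table, cohort_samples)
  .with_seed(.mix_seed(config$seed, draw_index), {
    .null_community_impl(stats, config,
                         kind = table$feature_kind)
  })
}

# core randomization; assumes the RNG is already positioned
.null_community_impl <- function(stats, config, kind = "taxon") {
  n <- nrow(stats$counts)
  npool <- length(stats$pool_ids)
  if (config$richness_constraint == "proportional") {
    # allocate the observed occurrence total to samples in proportion to
    # their observed richness, then cap at the pool size
    occ_total <- sum(stats$richness)
    alloc <- as.vector(stats::rmultinom(1L, occ_total,
                                        prob = stats$richness / occ_total))
    target <- pmin(pmax(alloc, 1L), npool)
  } else {
    target <- stats$richness
  }
  out <- matrix(0, nrow = n, ncol = npool,
                dimnames = list(rownames(stats$counts), stats$pool_ids))
  for (i in seq_len(n)) {
    ns <- .null_sample(stats, stats$totals[i], target[i], config)
    out[i, ns$idx] <- ns$counts
  }
  feature_table(out, kind)
}

#' Null-expected Bray-Curtis similarity between cohort samples
#'
#' Averages the Bray-Curtis similarity of every sample pair over
#' `config$n_randomizations` independent null randomizations of the
#' cohort.
#'
#' @inheritParams null_community
#' @return symmetric matrix of expected similarities `E_ij` in `[0, 1]`,
#'   with unit diagonal left as `NA`.
#' @export
expected_similarity <- function(table, cohort_samples,
                                config = null_model_config()) {
  stats <- .cohort_pool_stats(table, cohort_samples)
  n <- nrow(stats$counts)
  acc <- matrix(0, n, n)
  for (k in seq_len(config$n_randomizations)) {
    null_tab <- .with_seed(.mix_seed(config$seed, k),
                           .null_community_impl(stats, config))
    sim <- 1 - as.matrix(vegan::vegdist(null_tab$counts, method = "bray"))
    acc <- acc + sim
  }
  e <- acc / config$n_randomizations
  dimnames(e) <- list(rownames(stats$counts), rownames(stats$counts))
  diag(e) <- NA_real_
  e
}

#' Selection strength from observed and expected similarity
#'
#' The normalized gap between observed (`C`) and null-expected (`E`)
#' similarity. When the community is more similar than expected
#' (`C > E`, homogenizing selection) the gap is normalized by `C`; when it
#' is less similar than expected (`C < E`, diverging selection) the gap of
#' the dissimilarities is normalized by `1 - C`. Either way the value lies
#' in `[0, 1]`, with 0 meaning assembly indistinguishable from the null.
#'
#' @param C,E observed and expected similarity in `[0, 1]` (vectorized).
#' @return selection strength in `[0, 1]`.
#' @export
selection_strength <- function(C, E) {
  .assert(all(C >= 0 & C <= 1, na.rm = TRUE) &&
            all(E >= 0 & E <= 1, na.rm = TRUE),
          "similarities must lie in [0, 1]")
  ss <- ifelse(C >= E,
               ifelse(C > 0, (C - E) / C, 0),
               (E - C) / (1 - C))
  pmin(pmax(ss, 0), 1)
}

#' Per-cohort stochasticity ratios
#'
#' For every unordered sample pair within each cohort, compares the
#' observed Bray-Curtis similarity with its null expectation (mean over
#' `config$n_randomizations` randomizations sharing the cohort's regional
#' feature pool), converts the gap to a selection strength `SS`, and
#' reports the stochasticity ratio `ST = 1 - SS`. Cohort summaries give
#' the mean and population standard deviation of `ST` across pairs, in
#' percent.
#'
#' @param table a [feature_table] (taxon or pathway abundances).
#' @param design a [cohort_design].
#' @param config a [null_model_config].
#' @return named list (one entry per cohort) of `stochasticity_result`
#'   objects: `pairs` data frame (`sample_i`, `sample_j`, `observed`,
#'   `expected`, `selection_strength`, `stochasticity`) and `summary`
#'   (`mean_st_pct`, `sd_st_pct`, `n_pairs`).
#' @export
stochasticity_ratio <- function(table, design, config = null_model_config()) {
  out <- list()
  for (co in design$cohort_order) {
    samp <- .cohort_samples(design, co)
    .assert(length(samp) >= 2L, "cohort '%s' has %d sample(s); need >= 2",
            co, length(samp))
    stats <- .cohort_pool_stats(table, samp)
    obs <- 1 - as.matrix(vegan::vegdist(stats$counts, method = "bray"))
    exp_sim <- expected_similarity(table, samp, config)
    n <- length(samp)
    ii <- which(upper.tri(obs), arr.ind = TRUE)
    C <- obs[upper.tri(obs)]
    E <- exp_sim[upper.tri(exp_sim)]
    ss <- selection_strength(C, E)
    st <- 1 - ss
    pairs <- data.frame(sample_i = samp[ii[, 1L]], sample_j = samp[ii[, 2L]],
                        observed = C, expected = E,
                        selection_strength = ss, stochasticity = st,
                        stringsAsFactors = FALSE)
    out[[co]] <- structure(
      list(cohort = co, pairs = pairs,
           summary = list(mean_st_pct = 100 * mean(st),
                          sd_st_pct = 100 * .sd_pop(st),
                          n_pairs = nrow(pairs))),
      class = "stochasticity_result")
  }
  out
}

#' @export
print.stochasticity_result <- function(x, ...) {
  cat(sprintf(
    "<stochasticity_result> cohort '%s': ST = %.2f +/- %.2f%% over %d pairs\n",
    x$cohort, x$summary$mean_st_pct, x$summary$sd_st_pct, x$summary$n_pairs))
  invisible(x)
}
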