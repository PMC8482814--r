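#' Pairwise Sorensen dissimilarity partitioned into turnover and nestedness
#'
#' For two feature sets A and B with a = |A intersect B|, b = |A \\ B| and
#' c = |B \\ A|, the Sorensen dissimilarity (b + c) / (2a + b + c) is split
#' into a Simpson-based turnover component min(b, c) / (a + min(b, c)) and
#' a residual nestedness component (their difference). The three values
#' satisfy beta_sor = beta_sim + beta_nes and are symmetric in (A, B).
#'
#' @param a,b feature sets (character or integer vectors; duplicates are
#'   ignored).
#' @return named numeric vector `c(beta_sor, beta_sim, beta_nes)`.
#' @export
pairwise_partition <- function(a, b) {
  a <- unique(a); b <- unique(b)
  .assert(length(a) + length(b) > 0L, "both feature sets are empty")
  shared <- length(intersect(a, b))
  only_a <- length(a) - shared
  only_b <- length(b) - shared
  mn <- min(only_a, only_b)
  denom_sor <- 2 * shared + only_a + only_b
  beta_sor <- if (denom_sor > 0) (only_a + only_b) / denom_sor else 0
  beta_sim <- if (shared + mn > 0) mn / (shared + mn) else 0
  c(beta_sor = beta_sor, beta_sim = beta_sim, beta_nes = beta_sor - beta_sim)
}

#' Multiple-site Sorensen dissimilarity with turnover/nestedness partition
#'
#' Computes the multiple-site Sorensen dissimilarity of n sites as a single
#' quantity (not an average of pairwise values) and partitions it into a
#' Simpson-based turnover component and a nestedness component. With
#' S_i the richness of site i, S_T the pooled richness, and, over all
#' unordered site pairs, b_ij the number of features present in i but not
#' in j:
#'
#' \deqn{\beta_{SIM} = \frac{\sum \min(b_{ij}, b_{ji})}
#'   {(\sum_i S_i - S_T) + \sum \min(b_{ij}, b_{ji})}}
#' \deqn{\beta_{SOR} = \frac{\sum \min + \sum \max}
#'   {2(\sum_i S_i - S_T) + \sum \min + \sum \max}}
#'
#' and \eqn{\beta_{NES} = \beta_{SOR} - \beta_{SIM}}. The result is
#' invariant to site and feature order and reduces to
#' [pairwise_partition] for two sites.
#'
#' @param incidence binary (or logical) matrix, sites as rows, features as
#'   columns. Features never observed are removed before computing.
#' @return an object of class `beta_partition` with fields `beta_sor`,
#'   `beta_sim`, `beta_nes`, `n_sites` and `nestedness_turnover_ratio`
#'   (`NA` with `ratio_defined = FALSE` when turnover is zero).
#' @export
multisite_partition <- function(incidence) {
  inc <- as.matrix(incidence)
  inc <- (inc > 0) * 1
  .assert(nrow(inc) >= 2L, "need at least 2 sites, got %d", nrow(inc))
  present <- colSums(inc) > 0
  inc <- inc[, present, drop = FALSE]
  empty <- rowSums(inc) == 0
  if (any(empty)) {
    nm <- rownames(incidence)
    lab <- if (is.null(nm)) as.character(which(empty)[1L]) else nm[which(empty)[1L]]
    stop(sprintf("site '%s' has no features", lab), call. = FALSE)
  }
  s_i <- rowSums(inc)
  s_t <- ncol(inc)
  shared <- inc %*% t(inc)           # a_ij
  b <- matrix(s_i, nrow(inc), nrow(inc)) - shared  # b_ij: in i, not in j
  ut <- upper.tri(b)
  sum_min <- sum(pmin(b[ut], t(b)[ut]))
  sum_max <- sum(pmax(b[ut], t(b)[ut]))
  core <- sum(s_i) - s_t
  beta_sim <- if (core + sum_min > 0) sum_min / (core + sum_min) else 0
  denom <- 2 * core + sum_min + sum_max
  beta_sor <- if (denom > 0) (sum_min + sum_max) / denom else 0
  beta_nes <- beta_sor - beta_sim
  ratio_defined <- beta_sim > 0
  structure(list(beta_sor = beta_sor, beta_sim = beta_sim,
                 beta_nes = beta_nes, n_sites = nrow(inc),
                 nestedness_turnover_ratio =
                   if (ratio_defined) beta_nes / beta_sim else NA_real_,
                 ratio_defined = ratio_defined),
            class = "beta_partition")
}

#' @export
print.beta_partition <- function(x, ...) {
  cat(sprintf(
    "<beta_partition> %d sites: beta_sor=%.4f (turnover %.4f + nestedness %.4f)\n",
    x$n_sites, x$beta_sor, x$beta_sim, x$beta_nes))
  invisible(x)
}

#' Per-cohort multiple-site beta-diversity partitions
#'
#' Converts counts to incidence (presence = count > 0), restricts to each
#' cohort's own samples and to the features observed there, and computes
#' the multiple-site partition per cohort. An optional resampling mode
#' equalizes site numbers across cohorts: `resample_n` sites are drawn
#' without replacement `resample_reps` times and component means (and
#' standard deviations, in attributes) are reported.
#'
#' @param table a [feature_table].
#' @param design a [cohort_design]; every cohort needs >= 2 samples.
#' @param resample_n optional number of sites to resample per cohort.
#' @param resample_reps repetitions for resampling mode (default 100).
#' @param seed RNG seed used only in resampling mode.
#' @return named list of [multisite_partition] results, one per cohort.
#' @export
cohort_partitions <- function(table, design, resample_n = NULL,
                              resample_reps = 100L, seed = 1L) {
  out <- list()
  for (co in design$cohort_order) {
    samp <- .cohort_samples(design, co)
    .assert(length(samp) >= 2L, "cohort '%s' has %d sample(s); need >= 2",
            co, length(samp))
    inc <- (table$counts[samp, , drop = FALSE] > 0) * 1
    inc <- inc[, colSums(inc) > 0, drop = FALSE]
    if (is.null(resample_n)) {
      out[[co]] <- multisite_partition(inc)
    } else {
      .assert(resample_n >= 2L && resample_n <= length(samp),
              "resample_n must lie in [2, %d] for cohort '%s'",
              length(samp), co)
      parts <- .with_seed(.mix_seed(seed, match(co, design$cohort_order)), {
        replicate(resample_reps, {
          keep <- sample(nrow(inc), resample_n)
          sub <- inc[keep, , drop = FALSE]
          p <- multisite_partition(sub[, colSums(sub) > 0, drop = FALSE])
          c(p$beta_sor, p$beta_sim, p$beta_nes)
        })
      })
      mean_p <- rowMeans(parts)
      res <- structure(list(beta_sor = mean_p[1L], beta_sim = mean_p[2L],
                            beta_nes = mean_p[3L], n_sites = resample_n,
                            nestedness_turnover_ratio =
                              if (mean_p[2L] > 0) mean_p[3L] / mean_p[2L]
                              else NA_real_,
                            ratio_defined = mean_p[2L] > 0),
                       class = "beta_partition")
      attr(res, "resample_sd") <- apply(parts, 1L, stats::sd)
      attr(res, "resample_reps") <- resample_reps
      out[[co]] <- res
    }
  }
  out
}
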