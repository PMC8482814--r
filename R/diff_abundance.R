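#' Kruskal-Wallis rank test across cohorts
#'
#' Thin wrapper over [stats::kruskal.test] returning the tie-corrected H
#' statistic and the chi-square p-value on k - 1 degrees of freedom. When
#' every value is identical the statistic is 0 and p = 1 by convention
#' (the rank test carries no information in that degenerate case).
#'
#' @param values numeric vector of per-sample abundances.
#' @param classes cohort label per sample (>= 2 classes, each non-empty).
#' @return named numeric vector `c(H, p)`.
#' @export
kruskal_wallis <- function(values, classes) {
  .assert(length(values) == length(classes), "values/classes length mismatch")
  classes <- as.factor(as.character(classes))
  .assert(nlevels(classes) >= 2L, "need >= 2 classes")
  .assert(all(table(classes) >= 1L), "every class needs >= 1 value")
  if (length(unique(values)) == 1L) return(c(H = 0, p = 1))
  kt <- stats::kruskal.test(values, classes)
  c(H = unname(kt$statistic), p = unname(kt$p.value))
}

# ridge-regularized two-class linear discriminant effect sizes for the
# group of candidate features sharing one enriched-vs-rest contrast.
# X: samples x features (1e6 scale), y: logical (enriched class membership)
.lda_block_effect <- function(X, y, ridge = 1e-6) {
  m1 <- colMeans(X[y, , drop = FALSE])
  m0 <- colMeans(X[!y, , drop = FALSE])
  dm <- m1 - m0
  p <- ncol(X)
  c1 <- scale(X[y, , drop = FALSE], center = m1, scale = FALSE)
  c0 <- scale(X[!y, , drop = FALSE], center = m0, scale = FALSE)
  sw <- (crossprod(c1) + crossprod(c0)) / max(1L, nrow(X) - 2L)
  tr <- sum(diag(sw))
  reg <- sw + diag(if (tr > 0) ridge * tr / p else 1, p)
  w <- solve(reg, dm)
  nw <- sqrt(sum(w^2))
  if (nw > 0) w <- w / nw
  # separation along the discriminant axis, attributed to features in
  # proportion to their contribution |w_f * dm_f|
  contrib <- abs(w * dm)
  axis_sep <- abs(sum(w * dm))
  attr_f <- if (sum(contrib) > 0) contrib / sum(contrib) * axis_sep else
    rep(0, p)
  (abs(dm) + attr_f) / 2
}

#' LDA-based effect sizes for candidate features
#'
#' Bootstrapped linear-discriminant effect sizes in the LEfSe spirit: the
#' table (relative abundances scaled to a per-sample total of 1e6) is
#' repeatedly subsampled within classes; per round, for each class that is
#' the enriched class of one or more candidate features, a
#' ridge-regularized linear discriminant of that class against the rest is
#' fit over those features. A feature's per-round effect is the average of
#' its raw between-class mean difference and the discriminant-axis
#' separation attributed to it; effects are averaged over rounds and
#' reported as log10 scores (effects below 1 on the 1e6 scale floor at
#' score 0).
#'
#' @param table a [feature_table] of relative abundances scaled to 1e6 per
#'   sample (as produced inside [signature_features]).
#' @param design a [cohort_design]; every cohort needs >= 3 samples.
#' @param candidates feature ids to score (typically the Kruskal-Wallis
#'   passers).
#' @param n_boot bootstrap rounds (default 30).
#' @param subsample_fraction within-class subsampling fraction (default 2/3).
#' @param seed RNG seed.
#' @param ridge ridge constant scaling the within-class scatter trace.
#' @return named numeric vector of log10 effect sizes.
#' @export
lda_effect_size <- function(table, design, candidates, n_boot = 30L,
                            subsample_fraction = 2 / 3, seed = 1L,
                            ridge = 1e-6) {
  .assert(length(candidates) > 0L, "no candidate features")
  missing <- setdiff(candidates, feature_ids(table))
  .assert(length(missing) == 0L, "unknown candidate feature: '%s'", missing[1L])
  labels <- design$assignments[sample_ids(table)]
  .assert(!anyNA(labels), "table contains samples missing from the design")
  sizes <- table(labels)
  .assert(all(sizes >= 3L), "every cohort needs >= 3 samples for the LDA")
  # canonical sample order so results do not depend on input row order
  ord <- order(sample_ids(table))
  X <- table$counts[ord, candidates, drop = FALSE]
  labels <- labels[ord]
  # enriched class per feature = argmax of cohort mean abundance
  cohort_means <- vapply(design$cohort_order, function(co) {
    colMeans(X[labels == co, , drop = FALSE])
  }, numeric(ncol(X)))
  if (ncol(X) == 1L) cohort_means <- matrix(cohort_means, nrow = 1L,
                                            dimnames = list(candidates,
                                                            design$cohort_order))
  enriched <- design$cohort_order[max.col(cohort_means, ties.method = "first")]
  names(enriched) <- candidates

  effects <- matrix(0, nrow = length(candidates), ncol = n_boot,
                    dimnames = list(candidates, NULL))
  .with_seed(.mix_seed(seed, 71L), {
    for (b in seq_len(n_boot)) {
      keep <- unlist(lapply(design$cohort_order, function(co) {
        idx <- which(labels == co)
        sample(idx, size = max(2L, ceiling(subsample_fraction * length(idx))))
      }), use.names = FALSE)
      Xb <- X[keep, , drop = FALSE]
      lb <- labels[keep]
      for (co in unique(enriched)) {
        feats <- candidates[enriched == co]
        effects[feats, b] <- .lda_block_effect(
          Xb[, feats, drop = FALSE], lb == co, ridge = ridge)
      }
    }
  })
  eff <- rowMeans(effects)
  scores <- ifelse(eff < 1, 0, log10(eff))
  stats::setNames(scores, candidates)
}

#' Screen for signature features across cohorts
#'
#' The full screening pipeline: rarefy (optional), convert to relative
#' abundance, scale each sample to 1e6, test every feature across cohorts
#' with the Kruskal-Wallis rank test, and assign bootstrapped LDA effect
#' sizes to the features passing the significance level. A feature is a
#' signature (`passes = TRUE`) when p < `alpha` and its log10 LDA score
#' exceeds `lda_cutoff` (defaults 0.05 and 3).
#'
#' @param table a [feature_table] of integer counts (or already-rarefied
#'   counts if `rarefy_depth = NULL`).
#' @param design a [cohort_design].
#' @param alpha Kruskal-Wallis significance level (default 0.05).
#' @param lda_cutoff log10 LDA score cutoff (default 3).
#' @param rarefy_depth optional rarefaction depth applied first.
#' @param n_boot bootstrap rounds for the LDA stage.
#' @param seed RNG seed for rarefaction and bootstrapping.
#' @return data frame of class `effect_size_records` with columns
#'   `feature_id`, `kw_statistic`, `p_value`, `enriched_cohort`,
#'   `lda_score`, `passes`, sorted by decreasing score.
#' @export
signature_features <- function(table, design, alpha = 0.05, lda_cutoff = 3,
                               rarefy_depth = NULL, n_boot = 30L, seed = 1L) {
  .assert(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  if (!is.null(rarefy_depth)) {
    table <- rarefy(table, rarefy_depth, seed = .mix_seed(seed, 11L))
    keep <- intersect(names(design$assignments), sample_ids(table))
    design <- cohort_design(design$assignments[keep],
                            design$cohort_order)
  }
  table <- .subset_table(table, samples = names(design$assignments))
  scaled <- to_relative(table)
  scaled$counts <- scaled$counts * 1e6
  labels <- design$assignments[sample_ids(scaled)]

  kw <- t(apply(scaled$counts, 2L, kruskal_wallis, classes = labels))
  cohort_means <- vapply(design$cohort_order, function(co) {
    colMeans(scaled$counts[labels == co, , drop = FALSE])
  }, numeric(ncol(scaled$counts)))
  enriched <- design$cohort_order[max.col(cohort_means, ties.method = "first")]

  records <- data.frame(feature_id = feature_ids(scaled),
                        kw_statistic = kw[, "H"], p_value = kw[, "p"],
                        enriched_cohort = enriched,
                        lda_score = NA_real_, passes = FALSE,
                        row.names = NULL, stringsAsFactors = FALSE)
  cand <- records$feature_id[records$p_value < alpha]
  if (length(cand) > 0L) {
    scores <- lda_effect_size(scaled, design, cand, n_boot = n_boot,
                              seed = seed)
    records$lda_score[match(cand, records$feature_id)] <- scores[cand]
    records$passes <- !is.na(records$lda_score) &
      records$p_value < alpha & records$lda_score > lda_cutoff
  }
  ord <- order(-ifelse(is.na(records$lda_score), -Inf, records$lda_score),
               records$p_value, records$feature_id)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("effect_size_records", "data.frame")
  attr(records, "alpha") <- alpha
  attr(records, "lda_cutoff") <- lda_cutoff
  records
}
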