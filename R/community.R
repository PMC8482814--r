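#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement down to `depth`
#' (QIIME-style), so every retained sample's counts sum exactly to `depth`.
#' Samples with fewer than `depth` reads are dropped with a warning or
#' raise an error, depending on `on_shallow`. Features left with all-zero
#' counts are removed. Reproducible for a given `seed`.
#'
#' @param table a [feature_table] with integer-valued counts.
#' @param depth positive integer target depth per sample.
#' @param seed integer seed for the subsampling RNG.
#' @param on_shallow `"drop"` (default) or `"error"` for samples whose
#'   total is below `depth`.
#' @return a rarefied [feature_table].
#' @export
rarefy <- function(table, depth, seed = 1L, on_shallow = c("drop", "error")) {
  on_shallow <- match.arg(on_shallow)
  .assert(length(depth) == 1L && depth >= 1 && depth == round(depth),
          "depth must be a positive integer")
  counts <- table$counts
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at sample '%s', feature '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]),
         call. = FALSE)
  }
  totals <- rowSums(counts)
  shallow <- totals < depth
  if (any(shallow)) {
    if (on_shallow == "error") {
      stop(sprintf("sample '%s' has %d reads, below rarefaction depth %d",
                   rownames(counts)[which(shallow)[1L]],
                   totals[which(shallow)[1L]], as.integer(depth)),
           call. = FALSE)
    }
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(shallow), as.integer(depth),
                    paste(rownames(counts)[shallow], collapse = ", ")),
            call. = FALSE)
    counts <- counts[!shallow, , drop = FALSE]
  }
  .assert(nrow(counts) > 0L, "no samples at or above depth %d",
          as.integer(depth))
  nf <- ncol(counts)
  out <- .with_seed(seed, {
    t(apply(counts, 1L, function(x) {
      reads <- rep.int(seq_len(nf), as.integer(x))
      tabulate(sample(reads, size = depth, replace = FALSE), nbins = nf)
    }))
  })
  dimnames(out) <- dimnames(counts)
  .drop_empty_features(feature_table(out, table$feature_kind, table$lineages))
}

#' Convert counts to relative abundances
#'
#' Each sample is scaled to sum to 1. Samples with zero total are rejected.
#'
#' @param table a [feature_table].
#' @return a [feature_table] of per-sample proportions.
#' @export
to_relative <- function(table) {
  totals <- rowSums(table$counts)
  zero <- totals <= 0
  .assert(!any(zero), "sample '%s' has zero total count",
          rownames(table$counts)[which(zero)[1L]])
  feature_table(table$counts / totals, table$feature_kind, table$lineages)
}

#' Collapse features to a taxonomic rank
#'
#' Aggregates features sharing the same name at lineage position
#' `rank_index` (1 = domain, ..., 7 = species for a full lineage) by
#' summing their counts. Features whose lineage is shorter than
#' `rank_index`, or empty at that position, are pooled under an
#' `Unclassified_at_rank<k>` feature. Per-sample totals are conserved
#' exactly.
#'
#' @param table a [feature_table] with lineages.
#' @param rank_index 1-based lineage position to collapse at.
#' @return a [feature_table] of rank-level features.
#' @export
collapse_rank <- function(table, rank_index) {
  .assert(length(rank_index) == 1L && rank_index == round(rank_index) &&
            rank_index >= 1, "rank_index must be a positive integer")
  .assert(!is.null(table$lineages), "table has no lineages to collapse on")
  fid <- feature_ids(table)
  pooled <- sprintf("Unclassified_at_rank%d", as.integer(rank_index))
  group <- vapply(fid, function(f) {
    lin <- table$lineages[[f]]
    if (length(lin) >= rank_index && nzchar(lin[[rank_index]])) {
      lin[[rank_index]]
    } else {
      pooled
    }
  }, character(1))
  groups <- unique(group)
  counts <- sapply(groups, function(g) {
    rowSums(table$counts[, group == g, drop = FALSE])
  })
  if (n_samples(table) == 1L) {
    counts <- matrix(counts, nrow = 1L,
                     dimnames = list(sample_ids(table), groups))
  }
  lineages <- lapply(groups, function(g) {
    if (g == pooled) return(character(0))
    f <- fid[group == g][1L]
    table$lineages[[f]][seq_len(rank_index)]
  })
  names(lineages) <- groups
  feature_table(counts, table$feature_kind, lineages)
}

#' Per-feature prevalence in a sample subset
#'
#' Fraction of the given samples in which each feature has a positive
#' count.
#'
#' @param table a [feature_table].
#' @param samples character vector of sample ids (default: all samples).
#' @return named numeric vector of fractions in `[0, 1]`.
#' @export
prevalence <- function(table, samples = sample_ids(table)) {
  .assert(length(samples) > 0L, "empty sample subset")
  missing <- setdiff(samples, sample_ids(table))
  .assert(length(missing) == 0L, "unknown sample id: '%s'", missing[1L])
  colMeans(table$counts[samples, , drop = FALSE] > 0)
}

#' Prevalence-based core microbiome sets
#'
#' A feature is "core" in a cohort when its prevalence there meets the
#' threshold (at least 75% by default; `inclusive = FALSE` demands strictly
#' greater). Returns the per-cohort cores, the full Venn-region
#' decomposition over cohorts, and each cohort's core fraction: core count
#' divided by the cohort's gamma richness (features observed at least once
#' in that cohort).
#'
#' @param table a [feature_table].
#' @param design a [cohort_design].
#' @param threshold prevalence fraction in `(0, 1]` (default 0.75).
#' @param inclusive if `TRUE` (default) prevalence equal to the threshold
#'   qualifies; if `FALSE` it must exceed it.
#' @return an object of class `core_set`.
#' @export
core_sets <- function(table, design, threshold = 0.75, inclusive = TRUE) {
  .assert(length(threshold) == 1L && threshold > 0 && threshold <= 1,
          "threshold must lie in (0, 1]")
  cohorts <- design$cohort_order
  missing <- setdiff(names(design$assignments), sample_ids(table))
  .assert(length(missing) == 0L, "design sample '%s' absent from table",
          missing[1L])
  per_core <- list()
  core_fraction <- stats::setNames(numeric(length(cohorts)), cohorts)
  for (co in cohorts) {
    samp <- .cohort_samples(design, co)
    .assert(length(samp) >= 1L, "cohort '%s' has no samples", co)
    prev <- prevalence(table, samp)
    hit <- if (inclusive) prev >= threshold else prev > threshold
    per_core[[co]] <- names(prev)[hit]
    gamma <- sum(colSums(table$counts[samp, , drop = FALSE]) > 0)
    core_fraction[[co]] <- if (gamma > 0) length(per_core[[co]]) / gamma else 0
  }
  # all 2^k - 1 exclusive Venn regions
  venn <- list()
  k <- length(cohorts)
  for (mask in seq_len(2^k - 1L)) {
    members <- cohorts[bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0]
    others <- setdiff(cohorts, members)
    feats <- Reduce(intersect, per_core[members])
    for (o in others) feats <- setdiff(feats, per_core[[o]])
    venn[[paste(members, collapse = "\u2229")]] <- sort(feats)
  }
  structure(list(threshold = threshold, inclusive = inclusive,
                 per_cohort_core = lapply(per_core, sort), venn = venn,
                 core_fraction = core_fraction),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("<core_set> prevalence %s %.0f%%\n",
              if (x$inclusive) ">=" else ">", 100 * x$threshold))
  for (co in names(x$per_cohort_core)) {
    cat(sprintf("  %s: %d core features (%.2f%% of cohort richness)\n",
                co, length(x$per_cohort_core[[co]]),
                100 * x$core_fraction[[co]]))
  }
  invisible(x)
}

#' Alpha diversity summaries
#'
#' Observed richness, Shannon entropy (natural log) and Pielou evenness
#' per sample, as a convenience companion to the beta-diversity analyses.
#'
#' @param table a [feature_table].
#' @return data frame with one row per sample.
#' @export
alpha_diversity <- function(table) {
  counts <- table$counts
  rich <- rowSums(counts > 0)
  shannon <- vegan::diversity(counts, index = "shannon")
  pielou <- ifelse(rich > 1, shannon / log(rich), 0)
  data.frame(sample_id = rownames(counts), observed = as.integer(rich),
             shannon = as.numeric(shannon), pielou = as.numeric(pielou),
             row.names = NULL, stringsAsFactors = FALSE)
}
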