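#' Sample-by-feature count table
#'
#' The pipeline's universal currency: a non-negative numeric matrix with
#' samples as rows and features (taxa or pathways) as columns, optionally
#' annotated with per-feature taxonomic lineages. Counts are stored as
#' doubles because inferred pathway abundances are fractional.
#'
#' @param counts numeric matrix, samples x features, with unique dimnames.
#' @param feature_kind `"taxon"` or `"pathway"`.
#' @param lineages optional list, one character vector of ranks
#'   (domain to species) per feature, named by feature id.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(counts, feature_kind = c("taxon", "pathway"),
                          lineages = NULL) {
  feature_kind <- match.arg(feature_kind)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  .assert(!is.null(rownames(counts)) && !is.null(colnames(counts)),
          "counts must have sample (row) and feature (column) names")
  dup_s <- rownames(counts)[duplicated(rownames(counts))]
  .assert(length(dup_s) == 0L, "duplicate sample id: '%s'", dup_s[1L])
  dup_f <- colnames(counts)[duplicated(colnames(counts))]
  .assert(length(dup_f) == 0L, "duplicate feature id: '%s'", dup_f[1L])
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("negative or non-finite count at sample '%s', feature '%s'",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]),
         call. = FALSE)
  }
  if (!is.null(lineages)) {
    .assert(length(lineages) == ncol(counts),
            "need one lineage per feature (%d lineages, %d features)",
            length(lineages), ncol(counts))
    if (is.null(names(lineages))) names(lineages) <- colnames(counts)
    lineages <- lineages[colnames(counts)]
  }
  structure(list(counts = counts, feature_kind = feature_kind,
                 lineages = lineages),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d %s features%s\n",
              nrow(x$counts), ncol(x$counts), x$feature_kind,
              if (is.null(x$lineages)) "" else " (with lineages)"))
  invisible(x)
}

#' @rdname feature_table
#' @param x object to query.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname feature_table
#' @export
feature_ids <- function(x) colnames(x$counts)

#' @rdname feature_table
#' @export
n_samples <- function(x) nrow(x$counts)

# subset a feature_table by sample ids and/or feature ids, keeping lineages
.subset_table <- function(table, samples = NULL, features = NULL) {
  counts <- table$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(features)) counts <- counts[, features, drop = FALSE]
  lin <- table$lineages
  if (!is.null(lin)) lin <- lin[colnames(counts)]
  feature_table(counts, table$feature_kind, lin)
}

# drop features with zero total count
.drop_empty_features <- function(table) {
  keep <- colSums(table$counts) > 0
  .subset_table(table, features = colnames(table$counts)[keep])
}

#' Sample-to-cohort design
#'
#' Maps each sample id to a cohort label; cohorts are ordered by first
#' appearance. Beta-diversity and stochasticity analyses treat each cohort
#' as a metacommunity and need at least two samples per cohort.
#'
#' @param assignments named character vector: names are sample ids, values
#'   cohort labels.
#' @param cohort_order optional explicit ordering of cohort labels.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(assignments, cohort_order = NULL) {
  .assert(length(assignments) > 0L, "empty design")
  .assert(!is.null(names(assignments)), "assignments must be named by sample id")
  dup <- names(assignments)[duplicated(names(assignments))]
  .assert(length(dup) == 0L, "duplicate sample id in design: '%s'", dup[1L])
  assignments <- vapply(assignments, as.character, character(1))
  if (is.null(cohort_order)) cohort_order <- unique(unname(assignments))
  .assert(setequal(cohort_order, unique(assignments)),
          "cohort_order must list exactly the cohorts present")
  structure(list(assignments = assignments, cohort_order = cohort_order),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  tab <- table(factor(x$assignments, levels = x$cohort_order))
  cat(sprintf("<cohort_design> %d samples in %d cohorts: %s\n",
              length(x$assignments), length(x$cohort_order),
              paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

# sample ids of one cohort, in design order
.cohort_samples <- function(design, cohort) {
  names(design$assignments)[design$assignments == cohort]
}

#' Feature-by-pathway trait (copy-number) matrix
#'
#' Gene/pathway copy numbers per taxon, used to project a taxon table into
#' a community-wide functional (pathway) profile.
#'
#' @param copies numeric matrix, features x pathways, unique dimnames,
#'   non-negative entries.
#' @return an object of class `trait_matrix`.
#' @export
trait_matrix <- function(copies) {
  copies <- as.matrix(copies)
  storage.mode(copies) <- "double"
  .assert(!is.null(rownames(copies)) && !is.null(colnames(copies)),
          "copies must have feature (row) and pathway (column) names")
  .assert(!anyDuplicated(rownames(copies)), "duplicate feature id in traits")
  .assert(!anyDuplicated(colnames(copies)), "duplicate pathway id in traits")
  .assert(all(is.finite(copies)) && all(copies >= 0),
          "copy numbers must be finite and non-negative")
  structure(list(copies = copies), class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("<trait_matrix> %d features x %d pathways\n",
              nrow(x$copies), ncol(x$copies)))
  invisible(x)
}
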