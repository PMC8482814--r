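#' Project a taxon table through a trait matrix
#'
#' Community-wide functional profile: pathway abundance of sample s is the
#' copy-number-weighted sum of the sample's taxon abundances,
#' `pathway[s, p] = sum_t count[s, t] * copies[t, p]` — a linear map, so
#' scaling the input scales the output. Taxa absent from the trait matrix
#' are dropped with a warning that reports the fraction of total abundance
#' lost.
#'
#' @param table a taxon [feature_table].
#' @param traits a [trait_matrix] whose features cover the table's taxa.
#' @return a pathway [feature_table].
#' @export
project_traits <- function(table, traits) {
  .assert(table$feature_kind == "taxon", "input table must hold taxa")
  covered <- intersect(feature_ids(table), rownames(traits$copies))
  missing <- setdiff(feature_ids(table), rownames(traits$copies))
  .assert(length(covered) > 0L, "no table feature is covered by the traits")
  if (length(missing) > 0L) {
    lost <- sum(table$counts[, missing, drop = FALSE]) /
      max(sum(table$counts), .Machine$double.eps)
    warning(sprintf(
      "%d taxa absent from the trait matrix dropped (%.2f%% of abundance)",
      length(missing), 100 * lost), call. = FALSE)
  }
  path_counts <- table$counts[, covered, drop = FALSE] %*%
    traits$copies[covered, , drop = FALSE]
  feature_table(path_counts, feature_kind = "pathway")
}
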