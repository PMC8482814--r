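# shared fixtures and independent oracles, built in code at test time

# small feature table: counts[sample, feature]
toy_table <- function(counts, samples = NULL, features = NULL,
                      lineages = NULL, kind = "taxon") {
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(nrow(counts)))
  if (is.null(features)) features <- sprintf("f%d", seq_len(ncol(counts)))
  dimnames(counts) <- list(samples, features)
  feature_table(counts, kind, lineages)
}

toy_design <- function(labels, samples = NULL) {
  if (is.null(samples)) samples <- sprintf("s%d", seq_along(labels))
  cohort_design(stats::setNames(labels, samples))
}

# independent multi-site partition oracle built from raw set operations
oracle_multisite <- function(inc) {
  inc <- inc > 0
  sets <- lapply(seq_len(nrow(inc)), function(i) which(inc[i, ]))
  n <- length(sets)
  smin <- 0
  smax <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      bij <- length(setdiff(sets[[i]], sets[[j]]))
      bji <- length(setdiff(sets[[j]], sets[[i]]))
      smin <- smin + min(bij, bji)
      smax <- smax + max(bij, bji)
    }
  }
  pooled <- length(unique(unlist(sets)))
  core <- sum(lengths(sets)) - pooled
  sim <- if (core + smin > 0) smin / (core + smin) else 0
  sor <- if (2 * core + smin + smax > 0) (smin + smax) / (2 * core + smin + smax) else 0
  c(sor = sor, sim = sim, nes = sor - sim)
}

# random non-degenerate incidence matrix (every site non-empty, every
# feature somewhere present)
random_incidence <- function(n_sites, n_features, p = 0.4) {
  repeat {
    inc <- matrix(stats::rbinom(n_sites * n_features, 1, p),
                  nrow = n_sites)
    if (all(rowSums(inc) > 0)) {
      inc <- inc[, colSums(inc) > 0, drop = FALSE]
      if (ncol(inc) >= 2) return(inc)
    }
  }
}

# independent water-filling of inclusion probabilities: p = c*w capped at 1
# with sum(p) = R
oracle_waterfill <- function(w, R) {
  n <- length(w)
  if (R >= n) return(rep(1, n))
  p <- rep(0, n)
  capped <- rep(FALSE, n)
  repeat {
    c0 <- (R - sum(capped)) / sum(w[!capped])
    p[!capped] <- c0 * w[!capped]
    newly <- !capped & p >= 1
    if (!any(newly)) break
    p[newly] <- 1
    capped <- capped | newly
  }
  pmin(pmax(p, 0), 1)
}

# gini coefficient of a non-negative vector
gini_coef <- function(x) {
  x <- sort(x)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}
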