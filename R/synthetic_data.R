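#' Specification for a synthetic multi-cohort dataset
#'
#' Describes a regional species pool with log-normal relative abundances
#' and a set of cohorts sampled from it, with tunable assembly process
#' (pure multinomial "neutral" sampling versus cohort-specific
#' environmental "filtered" selection of strength `filter_strength`),
#' tunable within-cohort incidence structure (species `turnover` via
#' rotated taxon blocks, `nestedness` via ranked-pool prefixes, or
#' `none`), optional planted core taxa at a target prevalence, optional
#' planted fold-enriched features for screen-recovery experiments, and a
#' taxa-to-pathway trait matrix with tunable functional redundancy.
#'
#' The defaults emulate a three-cohort saliva study: cohorts of 27, 21 and
#' 27 samples, a 600-species pool, log-normal(0, 2) abundances and
#' per-sample read depths drawn uniformly between 40,000 and 60,000.
#'
#' @param n_pool regional pool size (default 600).
#' @param abundance_lognormal `c(mu, sigma)` of log relative abundances
#'   (default `c(0, 2)`).
#' @param cohorts named integer vector of cohort sizes
#'   (default `c(normal = 27, OVH = 21, OSCC = 27)`).
#' @param depth_range inclusive range of per-sample read totals.
#' @param assembly `"neutral"` or `"filtered"`.
#' @param filter_strength non-negative selection strength `w`; at `w = 0`
#'   filtered assembly coincides with neutral assembly.
#' @param structure `"none"`, `"turnover"` or `"nestedness"`.
#' @param core_target optional `list(n_core =, prevalence =)`: per cohort,
#'   `n_core` designated taxa are made present in each sample with the
#'   given probability (and absent otherwise).
#' @param planted optional `list(cohort =, n =, fold =)`: `n` taxa from
#'   the rare-but-reliably-observed band get their sampling weight
#'   multiplied by `fold` in the named cohort. With `cohort = "each"`,
#'   every cohort receives its own disjoint set of `n` planted taxa, so
#'   the mass displaced from the rest of the community is the same in all
#'   cohorts and non-planted features stay exchangeable across cohorts.
#' @param n_pathways number of pathways in the trait matrix (default 300).
#' @param redundancy taxa carrying each pathway (default 3; use ~30 for a
#'   high-redundancy community).
#' @param seed integer master seed; everything is reproducible from it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pool = 600L,
                           abundance_lognormal = c(0, 2),
                           cohorts = c(normal = 27L, OVH = 21L, OSCC = 27L),
                           depth_range = c(40000L, 60000L),
                           assembly = c("neutral", "filtered"),
                           filter_strength = 0,
                           structure = c("none", "turnover", "nestedness"),
                           core_target = NULL,
                           planted = NULL,
                           n_pathways = 300L,
                           redundancy = 3L,
                           seed = 1L) {
  assembly <- match.arg(assembly)
  structure_mode <- match.arg(structure)
  .assert(n_pool >= 2L, "n_pool must be >= 2")
  .assert(length(cohorts) >= 1L && all(cohorts >= 1) &&
            !is.null(names(cohorts)), "cohorts must be a named size vector")
  .assert(length(depth_range) == 2L && depth_range[1L] <= depth_range[2L] &&
            depth_range[1L] >= 1, "invalid depth_range")
  .assert(filter_strength >= 0, "filter_strength must be >= 0")
  .assert(n_pathways >= 1L, "n_pathways must be >= 1")
  .assert(redundancy >= 1L, "redundancy must be >= 1")
  .assert(redundancy <= n_pool, "redundancy cannot exceed the pool size")
  if (!is.null(core_target)) {
    .assert(is.list(core_target) && !is.null(core_target$n_core) &&
              !is.null(core_target$prevalence), "malformed core_target")
    .assert(core_target$prevalence > 0 && core_target$prevalence <= 1,
            "core_target prevalence must lie in (0, 1]")
    .assert(core_target$n_core * length(cohorts) <= n_pool,
            "core_target n_core too large for the pool")
  }
  if (!is.null(planted)) {
    .assert(is.list(planted) && !is.null(planted$cohort) &&
              !is.null(planted$n) && !is.null(planted$fold),
            "malformed planted")
    .assert(identical(planted$cohort, "each") ||
              planted$cohort %in% names(cohorts),
            "planted cohort '%s' not among the cohorts", planted$cohort)
  }
  structure(list(n_pool = as.integer(n_pool),
                 abundance_lognormal = as.numeric(abundance_lognormal),
                 cohorts = cohorts, depth_range = as.integer(depth_range),
                 assembly = assembly, filter_strength = filter_strength,
                 structure = structure_mode, core_target = core_target,
                 planted = planted, n_pathways = as.integer(n_pathways),
                 redundancy = as.integer(redundancy),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic synthetic lineages: ~4 species per genus, ~5 genera per
# family, nested consistently up to domain
.pool_lineages <- function(ids) {
  n <- length(ids)
  genus <- (seq_len(n) - 1L) %/% 4L + 1L
  fam <- (genus - 1L) %/% 5L + 1L
  ord <- (fam - 1L) %/% 4L + 1L
  cls <- (ord - 1L) %/% 3L + 1L
  phy <- (cls - 1L) %/% 3L + 1L
  out <- lapply(seq_len(n), function(i) {
    c("Bacteria", sprintf("Phylum_%02d", phy[i]), sprintf("Class_%02d", cls[i]),
      sprintf("Order_%02d", ord[i]), sprintf("Family_%02d", fam[i]),
      sprintf("Genus_%03d", genus[i]), ids[i])
  })
  names(out) <- ids
  out
}

#' Regional relative-abundance pool
#'
#' Draws `n_pool` log-normal abundances and normalizes them to a strictly
#' positive relative-abundance vector summing to one. Species ids carry a
#' deterministic nested lineage (attribute `"lineages"`).
#'
#' @param spec a [synthetic_spec].
#' @return named numeric vector of relative abundances.
#' @export
make_pool <- function(spec) {
  ids <- sprintf("sp%04d", seq_len(spec$n_pool))
  ab <- .with_seed(.mix_seed(spec$seed, 1L), {
    stats::rlnorm(spec$n_pool, meanlog = spec$abundance_lognormal[1L],
                  sdlog = spec$abundance_lognormal[2L])
  })
  rel <- ab / sum(ab)
  names(rel) <- ids
  attr(rel, "lineages") <- .pool_lineages(ids)
  rel
}

# indices of the planted (fold-enriched) taxa: the n species whose
# regional share is closest to 5e-4 — rare enough that an 8-fold boost
# displaces only a percent or two of total mass, abundant enough to be
# observed reliably at realistic read depths
.planted_indices <- function(pool, n) {
  order(abs(as.numeric(pool) - 5e-4))[seq_len(n)]
}

# per-cohort designated core taxa: disjoint index blocks
.core_indices <- function(spec, cohort_index) {
  n_core <- spec$core_target$n_core
  seq.int((cohort_index - 1L) * n_core + 1L, cohort_index * n_core)
}

#' Sample one cohort's count block
#'
#' Draws `spec$cohorts[cohort_index]` samples from the regional pool under
#' the spec's assembly and structure settings. Neutral assembly is a
#' multinomial draw of each sample's depth from the pool; filtered
#' assembly reweights the pool by `exp(w * e)` with fixed standard-normal
#' taxon-by-cohort effects `e`, so `w = 0` reproduces the neutral draw
#' exactly. Turnover structure confines each sample to a rotated taxon
#' block; nestedness structure confines sample s to the top-ranked prefix
#' of the cohort pool with a random prefix length, so samples form nested
#' subsets.
#'
#' @param pool output of [make_pool].
#' @param spec a [synthetic_spec].
#' @param cohort_index 1-based index into `spec$cohorts`.
#' @param effects optional precomputed taxon-by-cohort effect matrix
#'   (drawn internally from the spec seed when `NULL`).
#' @return integer count matrix, samples x pool taxa.
#' @export
sample_cohort <- function(pool, spec, cohort_index, effects = NULL) {
  .assert(cohort_index >= 1L && cohort_index <= length(spec$cohorts),
          "cohort_index out of range")
  n_samp <- spec$cohorts[[cohort_index]]
  label <- names(spec$cohorts)[cohort_index]
  n_pool <- length(pool)
  if (is.null(effects)) {
    effects <- .with_seed(.mix_seed(spec$seed, 9901L),
                          matrix(stats::rnorm(n_pool * length(spec$cohorts)),
                                 nrow = n_pool))
  }
  base_w <- if (spec$assembly == "filtered") {
    as.numeric(pool) * exp(spec$filter_strength * effects[, cohort_index])
  } else {
    as.numeric(pool)
  }
  if (!is.null(spec$planted)) {
    if (identical(spec$planted$cohort, "each")) {
      band <- .planted_indices(pool, spec$planted$n * length(spec$cohorts))
      mine <- band[seq.int((cohort_index - 1L) * spec$planted$n + 1L,
                           cohort_index * spec$planted$n)]
      base_w[mine] <- base_w[mine] * spec$planted$fold
    } else if (spec$planted$cohort == label) {
      idx <- .planted_indices(pool, spec$planted$n)
      base_w[idx] <- base_w[idx] * spec$planted$fold
    }
  }
  rank_order <- order(base_w, decreasing = TRUE)
  core_idx <- if (!is.null(spec$core_target)) .core_indices(spec, cohort_index)
              else integer(0)

  counts <- .with_seed(.mix_seed(spec$seed, 100L + cohort_index), {
    depths <- sample(seq.int(spec$depth_range[1L], spec$depth_range[2L]),
                     n_samp, replace = TRUE)
    out <- matrix(0, nrow = n_samp, ncol = n_pool)
    for (j in seq_len(n_samp)) {
      allowed <- switch(spec$structure,
        none = seq_len(n_pool),
        turnover = {
          len <- max(2L, n_pool %/% 3L)
          stride <- max(1L, n_pool %/% n_samp)
          ((j - 1L) * stride + seq_len(len) - 1L) %% n_pool + 1L
        },
        nestedness = {
          frac_cohort <- max(0.3, 1 - 0.25 * (cohort_index - 1L))
          cohort_pool <- rank_order[seq_len(max(2L, round(frac_cohort * n_pool)))]
          s_j <- max(2L, round(stats::runif(1L, 0.3, 1) * length(cohort_pool)))
          cohort_pool[seq_len(s_j)]
        })
      allowed <- union(allowed, core_idx)
      w <- base_w
      keep <- logical(n_pool)
      keep[allowed] <- TRUE
      w[!keep] <- 0
      if (spec$structure == "nestedness") {
        # equal weights over the prefix so every allowed taxon is observed
        # at realistic depths and samples form true nested subsets
        w[keep] <- 1
      }
      present_core <- integer(0)
      if (length(core_idx) > 0L) {
        present <- stats::runif(length(core_idx)) < spec$core_target$prevalence
        present_core <- core_idx[present]
        w[core_idx[!present]] <- 0
      }
      x <- as.vector(stats::rmultinom(1L, depths[j], prob = w / sum(w)))
      # guarantee a read for every designated-present core taxon
      for (idx in present_core[x[present_core] == 0]) {
        donor <- which.max(x)
        x[donor] <- x[donor] - 1L
        x[idx] <- 1L
      }
      out[j, ] <- x
    }
    out
  })
  dimnames(counts) <- list(sprintf("%s_%02d", label, seq_len(n_samp)),
                           names(pool))
  counts
}

#' Synthetic taxa-to-pathway trait matrix
#'
#' Assigns each pathway to `redundancy` distinct taxa with copy numbers in
#' {1, 2, 3}. Taxa are dealt from shuffled cycles of the pool so that,
#' whenever `n_pathways * redundancy >= n_pool`, every taxon carries at
#' least one pathway (otherwise a coverage warning is issued).
#'
#' @param spec a [synthetic_spec].
#' @return a [trait_matrix] (pool taxa x pathways).
#' @export
make_traits <- function(spec) {
  n_pool <- spec$n_pool
  r <- spec$redundancy
  npw <- spec$n_pathways
  slots <- npw * r
  if (slots < n_pool) {
    warning("n_pathways * redundancy < n_pool: some taxa carry no pathway",
            call. = FALSE)
  }
  ids <- sprintf("sp%04d", seq_len(n_pool))
  pwy <- sprintf("pwy%04d", seq_len(npw))
  copies <- .with_seed(.mix_seed(spec$seed, 4242L), {
    deck <- unlist(replicate(ceiling(slots / n_pool),
                             sample.int(n_pool), simplify = FALSE))[seq_len(slots)]
    mat <- matrix(0, nrow = n_pool, ncol = npw)
    for (p in seq_len(npw)) {
      carriers <- deck[seq.int((p - 1L) * r + 1L, p * r)]
      dup <- duplicated(carriers)
      while (any(dup)) {  # cycle boundaries can repeat a taxon; patch them
        pooled <- setdiff(seq_len(n_pool), carriers)
        carriers[which(dup)[1L]] <- pooled[sample.int(length(pooled), 1L)]
        dup <- duplicated(carriers)
      }
      mat[carriers, p] <- sample(1:3, r, replace = TRUE)
    }
    mat
  })
  dimnames(copies) <- list(ids, pwy)
  trait_matrix(copies)
}

#' Assemble a full synthetic dataset
#'
#' Builds the regional pool, samples every cohort, and returns the count
#' table (with lineages), the matching cohort design and the trait matrix.
#' Byte-identical for identical specs. The planted enriched taxa and the
#' per-cohort designated core taxa (when configured) are recorded in the
#' attributes `"planted_ids"` and `"core_ids"` of the returned table.
#'
#' @param spec a [synthetic_spec].
#' @return list with elements `table` ([feature_table]), `design`
#'   ([cohort_design]) and `traits` ([trait_matrix]).
#' @export
make_dataset <- function(spec) {
  pool <- make_pool(spec)
  effects <- .with_seed(.mix_seed(spec$seed, 9901L),
                        matrix(stats::rnorm(spec$n_pool * length(spec$cohorts)),
                               nrow = spec$n_pool))
  blocks <- lapply(seq_along(spec$cohorts), function(ci) {
    sample_cohort(pool, spec, ci, effects = effects)
  })
  counts <- do.call(rbind, blocks)
  table <- feature_table(counts, "taxon", attr(pool, "lineages"))
  if (!is.null(spec$planted)) {
    if (identical(spec$planted$cohort, "each")) {
      band <- .planted_indices(pool, spec$planted$n * length(spec$cohorts))
      planted_ids <- lapply(seq_along(spec$cohorts), function(ci) {
        names(pool)[band[seq.int((ci - 1L) * spec$planted$n + 1L,
                                 ci * spec$planted$n)]]
      })
      names(planted_ids) <- names(spec$cohorts)
      attr(table, "planted_ids") <- planted_ids
    } else {
      attr(table, "planted_ids") <-
        names(pool)[.planted_indices(pool, spec$planted$n)]
    }
  }
  if (!is.null(spec$core_target)) {
    core_ids <- lapply(seq_along(spec$cohorts), function(ci) {
      names(pool)[.core_indices(spec, ci)]
    })
    names(core_ids) <- names(spec$cohorts)
    attr(table, "core_ids") <- core_ids
  }
  assignments <- stats::setNames(
    rep(names(spec$cohorts), times = as.integer(spec$cohorts)),
    rownames(counts))
  list(table = table,
       design = cohort_design(assignments, names(spec$cohorts)),
       traits = make_traits(spec))
}
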