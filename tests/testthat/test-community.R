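test_that("rarefaction conserves depth, drops shallow samples and is seeded", {
  tab <- toy_table(rbind(c(3, 2, 5), c(1, 2, 1)),
                   samples = c("deep", "shallow"))
  r <- suppressWarnings(rarefy(tab, 5, seed = 1))
  expect_equal(unname(rowSums(r$counts)), 5)
  expect_warning(rarefy(tab, 5, seed = 1), "shallow")
  expect_false("shallow" %in% sample_ids(suppressWarnings(rarefy(tab, 5, seed = 1))))
  expect_error(rarefy(tab, 5, seed = 1, on_shallow = "error"), "below")

  bad <- toy_table(matrix(c(1.5, 2, 3, 4), nrow = 2))
  expect_error(rarefy(bad, 2), "non-integer")

  big <- toy_table(matrix(rpois(60, 40), nrow = 3))
  expect_identical(rarefy(big, 50, seed = 9)$counts,
                   rarefy(big, 50, seed = 9)$counts)
  expect_false(identical(rarefy(big, 50, seed = 9)$counts,
                         rarefy(big, 50, seed = 10)$counts))
})

test_that("rarefaction is unbiased: mean subsampled proportion matches the input", {
  # one sample, 3 features, without-replacement draws; the per-draw count is
  # hypergeometric, giving a closed-form standard error for the check
  x <- c(30, 20, 50)
  depth <- 50
  tab <- toy_table(matrix(x, nrow = 1))
  n_rep <- 1000L
  props <- vapply(seq_len(n_rep), function(s) {
    rarefy_counts <- rep(0, 3)
    r <- rarefy(tab, depth, seed = s)
    rarefy_counts[match(feature_ids(r), feature_ids(tab))] <- r$counts[1L, ]
    rarefy_counts / depth
  }, numeric(3))
  N <- sum(x)
  var_prop <- depth * (x / N) * (1 - x / N) * (N - depth) / (N - 1) / depth^2
  se_mean <- sqrt(var_prop / n_rep)
  expect_true(all(abs(rowMeans(props) - x / N) <= 3 * se_mean))
})

test_that("relative abundance normalizes rows and rejects empty samples", {
  tab <- toy_table(matrix(c(2, 2, 4), nrow = 1))
  expect_equal(unname(to_relative(tab)$counts[1L, ]), c(0.25, 0.25, 0.5))
  expect_equal(to_relative(to_relative(tab))$counts, to_relative(tab)$counts)
  expect_error(to_relative(toy_table(matrix(c(0, 0, 0), nrow = 1))), "s1")
})

test_that("rank collapsing pools lineage groups and conserves totals", {
  lin <- list(f1 = c("Bacteria", "Firmicutes", "Negativicutes", "Veillonellales",
                     "Veillonellaceae", "Veillonella", "V. dispar"),
              f2 = c("Bacteria", "Firmicutes", "Negativicutes", "Veillonellales",
                     "Veillonellaceae", "Veillonella", "V. parvula"))
  tab <- toy_table(matrix(c(3, 4), nrow = 1), lineages = lin)
  fam <- collapse_rank(tab, 5)
  expect_identical(feature_ids(fam), "Veillonellaceae")
  expect_equal(unname(fam$counts[1L, 1L]), 7)

  # species-level collapse of a species table is a permutation of the input
  sp <- collapse_rank(tab, 7)
  expect_setequal(feature_ids(sp), c("V. dispar", "V. parvula"))
  expect_equal(sort(sp$counts[1L, ]), sort(tab$counts[1L, ]),
               ignore_attr = TRUE)

  # 5 species across 3 families: per-sample sums conserved, brute-force sums
  fams <- c("Fa", "Fb", "Fa", "Fc", "Fb")
  lin5 <- lapply(seq_len(5), function(i) {
    c("Bacteria", "P", "C", "O", fams[i], sprintf("G%d", i), sprintf("sp%d", i))
  })
  names(lin5) <- sprintf("f%d", 1:5)
  m <- matrix(c(1, 2, 3, 4, 5,
                5, 0, 2, 1, 0), nrow = 2, byrow = TRUE)
  t5 <- toy_table(m, lineages = lin5)
  col5 <- collapse_rank(t5, 5)
  expect_setequal(feature_ids(col5), c("Fa", "Fb", "Fc"))
  expect_equal(rowSums(col5$counts), rowSums(t5$counts))
  for (fam_id in c("Fa", "Fb", "Fc")) {
    expect_equal(unname(col5$counts[, fam_id]),
                 unname(rowSums(m[, fams == fam_id, drop = FALSE])))
  }

  # features missing the rank pool under the unclassified label
  lin_short <- list(f1 = c("Bacteria", "Firmicutes"), f2 = lin$f2)
  ts <- toy_table(matrix(c(2, 3), nrow = 1), lineages = lin_short)
  cs <- collapse_rank(ts, 5)
  expect_true("Unclassified_at_rank5" %in% feature_ids(cs))
  expect_equal(sum(cs$counts), 5)
  expect_error(collapse_rank(tab, -1), "positive")
})

test_that("prevalence is the fraction of positive samples", {
  m <- matrix(c(1, 0, 0,
                3, 2, 0,
                1, 1, 0,
                0, 4, 0), nrow = 4, byrow = TRUE)
  tab <- toy_table(m)
  prev <- prevalence(tab)
  expect_equal(unname(prev), c(3 / 4, 3 / 4, 0))
  expect_error(prevalence(tab, character(0)), "empty")

  # 21 of 27 samples
  m2 <- matrix(0, nrow = 27, ncol = 1)
  m2[1:21, 1] <- 1
  expect_equal(unname(prevalence(toy_table(m2))), 21 / 27)
})

test_that("core sets honor the threshold rule and partition into Venn regions", {
  # one feature at exactly 75% prevalence in a 4-sample cohort
  m <- matrix(c(1, 1, 1, 0), ncol = 1)
  tab <- toy_table(m)
  d <- toy_design(rep("A", 4))
  expect_identical(core_sets(tab, d, 0.75, inclusive = TRUE)$per_cohort_core$A,
                   "f1")
  expect_length(core_sets(tab, d, 0.75, inclusive = FALSE)$per_cohort_core$A,
                0L)

  # hand-built 3-cohort incidence with cores {A,B}, {B,C}, {B}
  inc <- rbind(c(1, 1, 0), c(1, 1, 0),            # cohort c1: core {fA, fB}
               c(0, 1, 1), c(0, 1, 1),            # cohort c2: core {fB, fC}
               c(0, 1, 0), c(0, 1, 1))            # cohort c3: core {fB} (fC at 50%)
  tab3 <- toy_table(inc, features = c("fA", "fB", "fC"))
  d3 <- toy_design(rep(c("c1", "c2", "c3"), each = 2))
  cs <- core_sets(tab3, d3, 0.75)
  expect_identical(cs$per_cohort_core, list(c1 = c("fA", "fB"),
                                            c2 = c("fB", "fC"),
                                            c3 = "fB"))
  expect_identical(cs$venn[["c1∩c2∩c3"]], "fB")
  # regions are disjoint and cover the union of cores
  all_feats <- unlist(cs$venn, use.names = FALSE)
  expect_identical(anyDuplicated(all_feats), 0L)
  expect_setequal(all_feats, unique(unlist(cs$per_cohort_core)))
  expect_true(all(cs$core_fraction >= 0 & cs$core_fraction <= 1))

  # identical cohorts give identical cores, all in the shared region
  tid <- toy_table(rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1)))
  did <- toy_design(c("A", "A", "B", "B"))
  cid <- core_sets(tid, did)
  expect_identical(cid$per_cohort_core$A, cid$per_cohort_core$B)
  expect_length(cid$venn[["A∩B"]], 2L)
  expect_length(cid$venn[["A"]], 0L)

  expect_error(core_sets(tab, d, threshold = 0), "threshold")
  expect_error(core_sets(tab, d, threshold = 1.2), "threshold")
})

test_that("raising the prevalence threshold never enlarges a core set", {
  set.seed(4)
  tab <- toy_table(matrix(rbinom(200, 1, 0.6), nrow = 10))
  d <- toy_design(rep(c("A", "B"), each = 5))
  prev_sets <- NULL
  for (thr in c(0.5, 0.6, 0.75, 0.9, 1)) {
    cs <- core_sets(tab, d, thr)
    if (!is.null(prev_sets)) {
      for (co in names(cs$per_cohort_core)) {
        expect_true(all(cs$per_cohort_core[[co]] %in% prev_sets[[co]]))
      }
    }
    prev_sets <- cs$per_cohort_core
  }
})

test_that("alpha diversity reports richness, Shannon and evenness", {
  tab <- toy_table(matrix(c(10, 10, 0, 30, 0, 0), nrow = 2, byrow = TRUE))
  a <- alpha_diversity(tab)
  expect_equal(a$observed, c(2L, 1L))
  expect_equal(a$shannon[1L], log(2))
  expect_equal(a$pielou, c(1, 0))
})
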