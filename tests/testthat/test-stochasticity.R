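test_that("Bray-Curtis matches direct sums and the vegan implementation", {
  expect_equal(bray_curtis(c(6, 2, 0), c(2, 2, 4)), 0.5)
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 7)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")

  set.seed(2)
  for (k in 1:20) {
    x <- rpois(12, 5)
    y <- rpois(12, 5)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(bray_curtis(x, y),
                 as.numeric(vegan::vegdist(rbind(x, y), method = "bray")),
                 tolerance = 1e-12)
  }
})

test_that("selection strength follows the two-branch definition and stays bounded", {
  expect_equal(selection_strength(0.4, 0.4), 0)
  expect_equal(selection_strength(0.9, 0.45), 0.5)
  # diverging branch: gap of dissimilarities normalized by 1 - C
  expect_equal(selection_strength(0.2, 0.5), 0.375)
  expect_equal(selection_strength(0, 0), 0)
  grid <- expand.grid(C = seq(0, 1, 0.05), E = seq(0, 1, 0.05))
  ss <- selection_strength(grid$C, grid$E)
  expect_true(all(ss >= 0 & ss <= 1))
  expect_true(all(ss[abs(grid$C - grid$E) < 1e-12] == 0))
})

test_that("null communities conserve totals, pool identity and seeded reproducibility", {
  set.seed(7)
  tab <- toy_table(matrix(rpois(8 * 40, 6), nrow = 8))
  cohort <- sample_ids(tab)
  cfg <- null_model_config(n_randomizations = 100, seed = 5)
  pool <- feature_ids(tab)[colSums(tab$counts) > 0]
  for (k in 1:10) {
    null <- null_community(tab, cohort, cfg, k)
    expect_equal(rowSums(null$counts), rowSums(tab$counts))
    expect_true(all(feature_ids(null) %in% pool))
    # every selected feature carries at least one read
    expect_true(all(null$counts[null$counts > 0] >= 1))
  }
  expect_identical(null_community(tab, cohort, cfg, 3)$counts,
                   null_community(tab, cohort, cfg, 3)$counts)
  expect_false(identical(null_community(tab, cohort, cfg, 3)$counts,
                         null_community(tab, cohort, cfg, 4)$counts))
})

test_that("fixed richness constraint preserves each sample's richness exactly", {
  set.seed(8)
  tab <- toy_table(matrix(rpois(6 * 30, 4), nrow = 6))
  cfg <- null_model_config(n_randomizations = 100,
                           richness_constraint = "fixed", seed = 2)
  obs_rich <- rowSums(tab$counts > 0)
  for (k in 1:10) {
    null <- null_community(tab, sample_ids(tab), cfg, k)
    nr <- rep(0L, 6)
    nr[match(sample_ids(null), sample_ids(tab))] <- rowSums(null$counts > 0)
    expect_identical(as.integer(nr), as.integer(unname(obs_rich)))
  }
})

test_that("expected similarity averages null draws and shrinks with more draws", {
  set.seed(9)
  tab <- toy_table(matrix(rpois(6 * 30, 8), nrow = 6))
  cohort <- sample_ids(tab)
  cfg1 <- suppressWarnings(null_model_config(n_randomizations = 1, seed = 77))
  e1 <- expected_similarity(tab, cohort, cfg1)
  null1 <- null_community(tab, cohort, cfg1, 1)
  direct <- 1 - as.matrix(vegan::vegdist(
    null1$counts[sample_ids(tab), ], method = "bray"))
  expect_equal(e1[upper.tri(e1)], direct[upper.tri(direct)], tolerance = 1e-12)
  expect_true(all(e1[upper.tri(e1)] >= 0 & e1[upper.tri(e1)] <= 1))

  # Monte-Carlo standard error scales as 1/sqrt(n): doubling n_randomizations
  # shrinks the spread of E by about sqrt(2)
  spread <- function(n_rand) {
    reps <- vapply(1:24, function(r) {
      cfg <- suppressWarnings(null_model_config(n_rand, seed = 1000 + r))
      e <- expected_similarity(tab, cohort, cfg)
      e[upper.tri(e)]
    }, numeric(15))
    mean(apply(reps, 1, sd))
  }
  ratio <- spread(25) / spread(50)
  expect_equal(ratio, sqrt(2), tolerance = 0.2 * sqrt(2))
})

test_that("stochasticity ratios are bounded, deterministic and flag selection", {
  set.seed(10)
  tab <- toy_table(matrix(rpois(10 * 40, 6), nrow = 10))
  d <- toy_design(rep(c("A", "B"), each = 5))
  cfg <- null_model_config(n_randomizations = 100, seed = 4)
  st <- stochasticity_ratio(tab, d, cfg)
  for (co in c("A", "B")) {
    p <- st[[co]]$pairs
    expect_true(all(p$selection_strength >= 0 & p$selection_strength <= 1))
    expect_equal(p$stochasticity, 1 - p$selection_strength)
    expect_true(st[[co]]$summary$mean_st_pct >= 0 &&
                  st[[co]]$summary$mean_st_pct <= 100)
    expect_equal(st[[co]]$summary$n_pairs, choose(5, 2))
  }
  st2 <- stochasticity_ratio(tab, d, cfg)
  expect_identical(st, st2)

  # two identical samples: observed similarity is 1, the null expectation is
  # below 1, so homogenizing selection registers
  m <- matrix(rep(c(8, 4, 2, 1, 0, 3), 2), nrow = 2, byrow = TRUE)
  ident <- toy_table(m)
  sti <- stochasticity_ratio(ident, toy_design(c("A", "A")),
                             null_model_config(200, seed = 3))
  expect_equal(sti$A$pairs$observed, 1)
  expect_gt(sti$A$pairs$selection_strength, 0)
})

test_that("sub-communities under opposing filters lower the stochasticity ratio", {
  # one metacommunity containing two strongly and oppositely filtered
  # sub-groups is less stochastic than its neutral counterpart
  st_at_w <- function(w, s) {
    spec <- synthetic_spec(n_pool = 120, cohorts = c(g1 = 6, g2 = 6),
                           depth_range = c(1500, 2500),
                           assembly = "filtered", filter_strength = w,
                           seed = s)
    ds <- make_dataset(spec)
    merged <- cohort_design(stats::setNames(rep("all", 12),
                                            sample_ids(ds$table)))
    cfg <- suppressWarnings(null_model_config(n_randomizations = 60,
                                              seed = s + 300))
    stochasticity_ratio(ds$table, merged, cfg)$all$summary$mean_st_pct
  }
  for (s in 1:3) expect_gt(st_at_w(0, s), st_at_w(4, s))
})
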