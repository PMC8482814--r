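test_that("pairwise partition matches hand-computed set arithmetic", {
  expect_equal(pairwise_partition(1:3, 2:4),
               c(beta_sor = 1 / 3, beta_sim = 1 / 3, beta_nes = 0))
  # pure nestedness: B a subset of A
  expect_equal(pairwise_partition(1:4, 1:2),
               c(beta_sor = 1 / 3, beta_sim = 0, beta_nes = 1 / 3))
  expect_equal(pairwise_partition(letters[1:5], letters[1:5]),
               c(beta_sor = 0, beta_sim = 0, beta_nes = 0))
  # symmetry
  expect_equal(pairwise_partition(1:4, 3:9), pairwise_partition(3:9, 1:4))
  expect_error(pairwise_partition(integer(0), integer(0)), "empty")
})

test_that("multi-site partition reproduces hand-computed instances", {
  rps <- multisite_partition(rbind(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1)))
  expect_equal(rps$beta_sor, 0.5, tolerance = 1e-12)
  expect_equal(rps$beta_sim, 0.5, tolerance = 1e-12)
  expect_equal(rps$beta_nes, 0, tolerance = 1e-12)

  chain <- multisite_partition(rbind(c(1, 1, 1, 1), c(1, 1, 1, 0),
                                     c(1, 1, 0, 0)))
  expect_equal(chain$beta_sim, 0, tolerance = 1e-12)
  expect_equal(chain$beta_sor, 4 / 14, tolerance = 1e-12)
  expect_equal(chain$beta_nes, 4 / 14, tolerance = 1e-12)
  expect_false(chain$ratio_defined)

  ident <- multisite_partition(matrix(1, nrow = 4, ncol = 6))
  expect_equal(c(ident$beta_sor, ident$beta_sim, ident$beta_nes), c(0, 0, 0))

  expect_error(multisite_partition(matrix(1, 1, 3)), "2 sites")
  expect_error(multisite_partition(rbind(c(1, 1), c(0, 0))), "no features")
})

test_that("two-site multi-site partition equals the pairwise form exactly", {
  set.seed(11)
  for (k in 1:50) {
    inc <- random_incidence(2, 15)
    m <- multisite_partition(inc)
    p <- pairwise_partition(which(inc[1, ] > 0), which(inc[2, ] > 0))
    expect_identical(c(m$beta_sor, m$beta_sim, m$beta_nes), unname(p))
  }
})

test_that("partition is invariant to site and feature permutations and additive", {
  set.seed(21)
  for (k in 1:50) {
    inc <- random_incidence(sample(3:8, 1), sample(6:25, 1))
    m <- multisite_partition(inc)
    expect_equal(m$beta_sor, m$beta_sim + m$beta_nes, tolerance = 1e-12)
    expect_true(m$beta_sim >= 0 && m$beta_sim <= m$beta_sor && m$beta_sor <= 1)
    perm <- multisite_partition(inc[sample(nrow(inc)), sample(ncol(inc)),
                                    drop = FALSE])
    expect_equal(m$beta_sor, perm$beta_sor, tolerance = 1e-12)
    expect_equal(m$beta_sim, perm$beta_sim, tolerance = 1e-12)
  }
})

test_that("a universally shared feature never increases dissimilarity", {
  set.seed(31)
  for (k in 1:40) {
    inc <- random_incidence(sample(3:7, 1), sample(5:20, 1))
    m0 <- multisite_partition(inc)
    m1 <- multisite_partition(cbind(inc, shared = 1))
    expect_lte(m1$beta_sor, m0$beta_sor + 1e-12)
    expect_lte(m1$beta_sim, m0$beta_sim + 1e-12)
  }
})

test_that("cohort partitions use cohort-restricted incidence", {
  # all samples identical: every component zero
  tab <- toy_table(matrix(rep(c(3, 1, 0, 2), 3), nrow = 3, byrow = TRUE))
  d <- toy_design(rep("A", 3))
  p <- cohort_partitions(tab, d)$A
  expect_equal(c(p$beta_sor, p$beta_sim, p$beta_nes), c(0, 0, 0))

  expect_error(cohort_partitions(tab, toy_design(c("A", "A", "B"))),
               "need >= 2")

  # generator cross-check: nestedness-structured cohorts are
  # nestedness-dominated, turnover-structured ones turnover-dominated
  for (s in 1:5) {
    nest <- make_dataset(synthetic_spec(n_pool = 150, cohorts = c(A = 10),
                                        depth_range = c(2000, 3000),
                                        structure = "nestedness", seed = s))
    pn <- cohort_partitions(nest$table, nest$design)$A
    expect_gt(pn$beta_nes, pn$beta_sim)
    turn <- make_dataset(synthetic_spec(n_pool = 150, cohorts = c(A = 10),
                                        depth_range = c(2000, 3000),
                                        structure = "turnover", seed = s))
    pt <- cohort_partitions(turn$table, turn$design)$A
    expect_gt(pt$beta_sim, pt$beta_nes)
  }
})

test_that("site resampling reports mean components at equal site numbers", {
  set.seed(5)
  tab <- toy_table(matrix(rbinom(200, 3, 0.3), nrow = 10))
  d <- toy_design(rep(c("A", "B"), c(6, 4)))
  res <- cohort_partitions(tab, d, resample_n = 4, resample_reps = 20, seed = 3)
  expect_equal(res$A$n_sites, 4)
  expect_equal(res$A$beta_sor, res$A$beta_sim + res$A$beta_nes,
               tolerance = 1e-12)
  res2 <- cohort_partitions(tab, d, resample_n = 4, resample_reps = 20, seed = 3)
  expect_identical(res$A$beta_sor, res2$A$beta_sor)
})
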