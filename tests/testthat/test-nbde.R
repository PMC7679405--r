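test_that("size factors scale with totals and have geometric mean 1", {
  m <- matrix(c(10L, 10L, 10L, 10L), nrow = 2,
              dimnames = list(c("f1", "f2"), c("a", "b")))
  expect_equal(size_factors(m), c(a = 1, b = 1))

  m2 <- matrix(c(40L, 60L, 150L, 250L), nrow = 2,
               dimnames = list(c("f1", "f2"), c("a", "b")))
  expect_equal(unname(size_factors(m2)), c(0.5, 2.0))

  # homogeneity: scaling one sample's counts x10 multiplies its factor x10
  m3 <- m2
  m3[, "b"] <- m3[, "b"] * 10L
  expect_equal(unname(size_factors(m3)[2] / size_factors(m3)[1]),
               unname(10 * size_factors(m2)[2] / size_factors(m2)[1]))

  m4 <- m2
  m4[, 2] <- 0L
  expect_error(size_factors(m4), "zero total")
})

test_that("moment dispersion floors Poisson-like data and recovers NB dispersion", {
  pois <- simulate_counts(de_plan(n_features = 1500, de_fraction = 0,
                                  baseline_mean = 100, dispersion = 1e-4,
                                  replicates_per_group = 3, seed = 31))
  f <- size_factors(pois$counts)
  expect_equal(estimate_dispersion(pois$counts, f, pois$groups), 0.01)

  dup <- matrix(rep(c(5L, 9L, 13L, 20L), each = 4), nrow = 4, byrow = TRUE)
  rownames(dup) <- sprintf("f%d", 1:4)
  expect_equal(estimate_dispersion(dup, rep(1, 4), c("A", "A", "B", "B")),
               0.01)

  nb <- simulate_counts(de_plan(n_features = 2000, de_fraction = 0,
                                baseline_mean = 100, dispersion = 0.2,
                                replicates_per_group = 3, seed = 32))
  f2 <- size_factors(nb$counts)
  phi <- estimate_dispersion(nb$counts, f2, nb$groups)
  expect_gt(phi, 0.1)
  expect_lt(phi, 0.3)
  # the Cox-Reid adjusted estimate is close to unbiased
  phi_cr <- estimate_dispersion_cr(nb$counts, f2, nb$groups)
  expect_gt(phi_cr, 0.15)
  expect_lt(phi_cr, 0.25)
})

test_that("LRT is exact-null on identical groups and matches a likelihood-grid oracle", {
  same <- nb_lrt(c(7L, 9L, 11L, 7L, 9L, 11L), rep(1, 6),
                 rep(c("A", "B"), each = 3), phi = 0.1)
  expect_equal(same$log2fc, 0)
  expect_equal(same$p, 1)

  y <- c(0L, 0L, 0L, 50L, 55L, 60L)
  grp <- rep(c("A", "B"), each = 3)
  res <- nb_lrt(y, rep(1, 6), grp, phi = 0.05)
  expect_lt(res$p, 1e-6)
  expect_gt(res$log2fc, 0)
  p_oracle <- nb_lrt_grid_oracle(y, grp, phi = 0.05)
  expect_equal(res$p, p_oracle, tolerance = 1e-4)

  y2 <- c(12L, 20L, 9L, 30L, 26L, 41L)
  res2 <- nb_lrt(y2, rep(1, 6), grp, phi = 0.1)
  expect_equal(res2$p, nb_lrt_grid_oracle(y2, grp, phi = 0.1),
               tolerance = 1e-4)
})

test_that("swapping group labels negates log2fc and leaves p unchanged", {
  withr::with_seed(33, y <- as.integer(rnbinom(6, size = 10, mu = 60)))
  fac <- c(0.9, 1.0, 1.1, 0.95, 1.05, 1.0)
  grp <- rep(c("A", "B"), each = 3)
  r1 <- nb_lrt(y, fac, grp, phi = 0.1)
  r2 <- nb_lrt(y, fac, rep(c("B", "A"), each = 3), phi = 0.1)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-6)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
})

test_that("BH adjustment equals the direct step-up computation", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  withr::with_seed(34, {
    for (i in 1:5) {
      p <- runif(sample(5:200, 1))
      q <- bh_adjust(p)
      expect_equal(q, bh_stepup_oracle(p))
      expect_true(all(q >= p))
    }
  })
})

test_that("run_de recovers planted directions and effect sizes", {
  cc <- simulate_counts(de_plan(n_features = 600, de_fraction = 0.3,
                                down_fraction_among_de = 0.5,
                                log2fc_magnitude = 3, seed = 35))
  de <- run_de(cc$counts, cc$groups, alpha_mode = "pvalue", alpha = 0.01)
  m <- merge(de, cc$truth, by = "feature_id", suffixes = c("", "_true"))
  truly <- m[m$direction_true != "null", ]
  # power: nearly all strong planted effects detected with the right sign
  expect_gte(mean(truly$direction == truly$direction_true), 0.9)
  expect_equal(mean(truly$log2fc[truly$direction_true == "up"]), 3,
               tolerance = 0.15)
})
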