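# inference: best-layer assignment, correspondence statistic, group tests,
# variance captured, BH-FDR.

test_that("best_layer_per_region is an argmax with lowest-index ties", {
  expect_identical(unname(best_layer_per_region(rbind(c(0.1, 0.5, 0.3)))), 2L)
  expect_message(bl <- best_layer_per_region(rbind(c(0.4, 0.4))), "tie")
  expect_identical(unname(bl), 1L)
  set.seed(5)
  tab <- matrix(rnorm(6 * 11), 6, 11)
  got <- best_layer_per_region(tab)
  for (r in 1:6) {
    best <- 1L
    for (l in 2:11) if (tab[r, l] > tab[r, best]) best <- l
    expect_identical(unname(got[r]), best)
  }
  tab[2, 5] <- NA
  expect_error(best_layer_per_region(tab), "undefined")
})

test_that("correspondence_statistic handles monotone, reversed, tied cases", {
  z_top <- fisher_z((1 + (1 - 12 / (6 * 35))) / 2)  # resolution midpoint, n=6
  expect_message(z <- correspondence_statistic(c(1, 2, 3, 4, 5, 6)),
                 "resolution midpoint")
  expect_equal(z, z_top)
  expect_message(zr <- correspondence_statistic(c(6, 5, 4, 3, 2, 1)),
                 "resolution midpoint")
  expect_equal(zr, -z_top)
  expect_message(z0 <- correspondence_statistic(rep(4, 6)), "defined as 0")
  expect_equal(z0, 0)
  bl <- c(2, 2, 5, 4, 9, 9)
  expect_equal(correspondence_statistic(bl),
               atanh(oracle_spearman(1:6, bl)), tolerance = 1e-12)
})

test_that("group_test_positive equals the textbook one-sample t", {
  z <- c(0.5, 0.7, 0.9, 1.1, 0.6, 0.8)
  got <- group_test_positive(z)
  want <- oracle_t_one_sample(z)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p_one_tailed, want$p_upper, tolerance = 1e-12)
  expect_identical(got$df, 5L)
  # null-centered sample: p near 0.5
  set.seed(9)
  eps <- rnorm(500, sd = 1e-3)
  expect_equal(group_test_positive(eps - mean(eps) + 1e-6)$p_one_tailed, 0.5,
               tolerance = 0.05)
  # all positive, tiny noise: p ~ 0
  expect_lt(group_test_positive(1 + rnorm(5, sd = 1e-4))$p_one_tailed, 1e-8)
  expect_warning(r0 <- group_test_positive(rep(0.3, 4)), "zero variance")
  expect_equal(r0$p_one_tailed, 0)
  expect_warning(r1 <- group_test_positive(rep(-0.3, 4)), "zero variance")
  expect_equal(r1$p_one_tailed, 1)
})

test_that("variance_captured is the squared ceiling-relative ratio", {
  expect_equal(variance_captured(0.8, 0.8), 1)
  expect_equal(variance_captured(0, 0.8), 0)
  expect_equal(variance_captured(0.6, 0.8), 0.5625)
  expect_equal(variance_captured(0.9, 0.8), (0.9 / 0.8)^2)  # not clipped
  expect_error(variance_captured(0.5, 0), "positive")
  expect_error(variance_captured(0.5, -0.2), "positive")
})

test_that("test_full_capture selects the group-best layer and tests vs 1", {
  vals <- c(0.5, 0.6, 0.55, 0.45, 0.5, 0.6)
  pr <- array(0.2, c(1, 3, 6), dimnames = list("LOT", NULL, NULL))
  pr[1, 2, ] <- vals
  res <- test_full_capture(pr)
  expect_identical(res$best_layer, 2L)
  want <- oracle_t_one_sample(-vals, mu = -1)
  expect_equal(res$t, want$t, tolerance = 1e-12)
  expect_equal(res$p_one_tailed, want$p_upper, tolerance = 1e-12)
  # all proportions exactly 1: no evidence below 1
  pr1 <- array(1, c(1, 2, 4))
  expect_warning(res1 <- test_full_capture(pr1), "zero variance")
  expect_equal(res1$p_one_tailed, 1)
  # per-subject-max variant upper-bounds the group-selected mean
  set.seed(13)
  pr2 <- array(runif(2 * 4 * 5), c(2, 4, 5))
  r_grp <- test_full_capture(pr2)
  r_max <- suppressWarnings(test_full_capture(pr2, per_subject_max = TRUE))
  expect_true(all(r_max$mean_proportion >= r_grp$mean_proportion - 1e-12))
})

test_that("bh_fdr reproduces the hand step-up computation", {
  p <- c(0.01, 0.02, 0.04, 0.2)
  got <- bh_fdr(p, q = 0.05)
  # m = 4: thresholds 0.0125, 0.025, 0.0375, 0.05 -> reject first two only
  expect_identical(got$rejected, c(TRUE, TRUE, FALSE, FALSE))
  want <- oracle_bh(p, 0.05)
  expect_equal(got$adjusted, want$adjusted, tolerance = 1e-12)
  expect_identical(got$rejected, want$rejected)
  expect_identical(bh_fdr(0.04, 0.05)$rejected, TRUE)
  expect_identical(bh_fdr(0.06, 0.05)$rejected, FALSE)
  allone <- bh_fdr(rep(1, 5))
  expect_false(any(allone$rejected))
  expect_equal(allone$adjusted, rep(1, 5))
  expect_length(bh_fdr(numeric(0))$adjusted, 0)
})

test_that("bh_fdr properties: monotone in q, order-invariant, oracle-equal", {
  set.seed(23)
  for (i in 1:10) {
    p <- runif(sample(3:12, 1))^2
    want <- oracle_bh(p, 0.05)
    got <- bh_fdr(p, 0.05)
    expect_equal(got$adjusted, want$adjusted, tolerance = 1e-12)
    expect_identical(got$rejected, want$rejected)
    # rejections monotone in q
    r1 <- bh_fdr(p, 0.01)$rejected
    r2 <- bh_fdr(p, 0.10)$rejected
    expect_true(all(r2[r1]))
    # adjusted p invariant to input order
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm])$adjusted, got$adjusted[perm],
                 tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("correspondence_test aggregates subject statistics", {
  bl <- rbind(c(1, 3, 2, 5, 9, 11),  # no row perfectly monotone (rho < 1)
              c(1, 3, 2, 6, 9, 10),
              c(2, 1, 4, 7, 8, 11),
              c(1, 2, 5, 4, 10, 9))
  res <- correspondence_test(bl)
  z <- apply(bl, 1, function(b) atanh(oracle_spearman(1:6, b)))
  want <- oracle_t_one_sample(z)
  expect_equal(res$mean_fisher_z, mean(z), tolerance = 1e-12)
  expect_equal(res$t_stat, want$t, tolerance = 1e-12)
  expect_equal(res$p_one_tailed, want$p_upper, tolerance = 1e-12)
  expect_identical(res$df, 3L)
})
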