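test_that("binomial test equals explicit pmf summation", {
  # spot grid here; the exhaustive n <= 50 sweep runs at acceptance scale
  p0 <- 0.0072
  for (n in c(1, 5, 10, 25, 50)) {
    for (k in unique(pmin(c(0, 1, 2, n %/% 2, n), n))) {
      expect_equal(binomial_mod_test(k, n, p0), pmf_tail_oracle(k, n, p0),
                   tolerance = 1e-12)
    }
  }
  expect_identical(binomial_mod_test(0, 7, 0.3), 1)
  expect_equal(binomial_mod_test(1, 5, 0.0072), 1 - (1 - 0.0072)^5)
  expect_error(binomial_mod_test(6, 5, 0.1), "exceed")
  expect_error(binomial_mod_test(1, 5, 0), "p0")
})

test_that("BH adjustment is step-up with preserved order and monotone in p", {
  expect_identical(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(3)
  p <- runif(50)
  q <- bh_adjust(p)
  # monotone transform (ties allowed): sorting by p never decreases q
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q >= p - 1e-15))
})

test_that("5hmC calling tests only covered sites and controls the FDR", {
  mk_mods <- function(k, n) data.table::data.table(
    contig = "c", pos0 = seq_along(k), strand = "+", context = "CpG",
    n_mod = k, n_unmod = n - k)
  # all-zero counts produce no calls
  calls <- call_hmc(mk_mods(rep(0L, 20), rep(10L, 20)))
  expect_identical(sum(calls$called), 0L)
  # a single fully converted site at minimum coverage is called
  one <- call_hmc(mk_mods(5L, 5L), p0 = 0.0072)
  expect_equal(one$p_value, 0.0072^5)
  expect_true(one$called)
  # sites under the coverage floor are not tested
  sparse <- call_hmc(mk_mods(c(4L, 4L), c(4L, 10L)), min_cov = 5)
  expect_identical(nrow(sparse), 1L)

  # simulation with known truth: false-discovery proportion stays near alpha
  ref <- generate_reference(1, 60000, 0.5, seed = 30)
  truth <- generate_methylome(
    ref, methylome_config(hmC_site_fraction = 0.2, hmC_mean_level = 0.4),
    seed = 31)
  obs <- simulate_observations(truth, default_profile("CAPS"), depth = 40,
                               seed = 32)
  calls <- call_hmc(obs, p0 = 0.0072)
  j <- merge(calls, truth[, .(contig, pos0, strand, hmC)],
             by = c("contig", "pos0", "strand"))
  called <- j[called == TRUE]
  expect_gt(nrow(called), 200)
  fdp <- mean(called$hmC == 0)
  expect_lt(fdp, 2 * 0.05)
})

test_that("two-assay closed forms match the simplex grid oracle", {
  # spec-anchored cases (nested = mC+hmC with mC; disjoint = mC with hmC)
  e1 <- mle_two_assay(assay_observation("TAPS", 8, 10),
                      assay_observation("TAPSB", 3, 10))
  expect_equal(c(e1$m_hat, e1$h_hat, e1$u_hat), c(0.3, 0.5, 0.2))
  expect_false(e1$conflict)
  o1 <- grid_mle_oracle(8, 10, 3, 10, "nested")
  expect_equal(unname(c(e1$m_hat, e1$h_hat)), unname(o1), tolerance = 1e-9)

  e2 <- mle_two_assay(assay_observation("TAPS", 2, 10),
                      assay_observation("TAPSB", 5, 10))
  expect_true(e2$conflict)
  expect_equal(c(e2$m_hat, e2$h_hat), c(0.35, 0))
  o2 <- grid_mle_oracle(2, 10, 5, 10, "nested")
  expect_equal(unname(c(e2$m_hat, e2$h_hat)), unname(o2), tolerance = 1e-9)

  e3 <- mle_two_assay(assay_observation("TAPSB", 0, 10),
                      assay_observation("CAPS", 0, 10))
  expect_equal(c(e3$m_hat, e3$h_hat, e3$u_hat), c(0, 0, 1))
  expect_false(e3$conflict)

  e4 <- mle_two_assay(assay_observation("TAPSB", 9, 10),
                      assay_observation("CAPS", 8, 10))
  expect_true(e4$conflict)
  expect_equal(c(e4$m_hat, e4$h_hat), c(0.55, 0.45))
  o4 <- grid_mle_oracle(9, 10, 8, 10, "disjoint")
  expect_equal(unname(c(e4$m_hat, e4$h_hat)), unname(o4), tolerance = 1e-9)

  # random draws on coverages whose proportions sit on the 1e-4 grid
  set.seed(40)
  ns <- list(c(10, 10), c(20, 20), c(40, 40), c(50, 50), c(10, 40))
  for (i in 1:200) {
    nn <- ns[[sample(length(ns), 1)]]
    k1 <- sample(0:nn[1], 1); k2 <- sample(0:nn[2], 1)
    est_n <- mle_two_assay(assay_observation("TAPS", k1, nn[1]),
                           assay_observation("TAPSB", k2, nn[2]))
    orc_n <- grid_mle_oracle(k1, nn[1], k2, nn[2], "nested")
    expect_equal(unname(c(est_n$m_hat, est_n$h_hat)), unname(orc_n),
                 tolerance = 1e-6)
    est_d <- mle_two_assay(assay_observation("TAPSB", k1, nn[1]),
                           assay_observation("CAPS", k2, nn[2]))
    orc_d <- grid_mle_oracle(k1, nn[1], k2, nn[2], "disjoint")
    expect_equal(unname(c(est_d$m_hat, est_d$h_hat)), unname(orc_d),
                 tolerance = 1e-6)
  }
})

test_that("estimates stay on the simplex; conflict iff unconstrained solution leaves it", {
  n <- 12
  for (k1 in 0:n) {
    for (k2 in 0:n) {
      nest <- mle_two_assay(assay_observation("TAPS", k1, n),
                            assay_observation("TAPSB", k2, n))
      expect_equal(nest$m_hat + nest$h_hat + nest$u_hat, 1,
                   tolerance = 1e-9)
      expect_true(min(nest$m_hat, nest$h_hat, nest$u_hat) >= -1e-12)
      expect_identical(nest$conflict, k1 / n < k2 / n)
      disj <- mle_two_assay(assay_observation("TAPSB", k1, n),
                            assay_observation("CAPS", k2, n))
      expect_true(min(disj$m_hat, disj$h_hat, disj$u_hat) >= -1e-12)
      expect_identical(disj$conflict, k1 / n + k2 / n > 1)
    }
  }
})

test_that("iterative multi-assay MLE agrees with closed forms and recovers truth", {
  cases <- list(c(8, 10, 3, 10), c(2, 10, 5, 10), c(7, 20, 9, 20))
  for (cs in cases) {
    em <- mle_multi_assay(list(assay_observation("TAPS", cs[1], cs[2]),
                               assay_observation("TAPSB", cs[3], cs[4])))
    cf <- mle_two_assay(assay_observation("TAPS", cs[1], cs[2]),
                        assay_observation("TAPSB", cs[3], cs[4]))
    expect_equal(em$m_hat, cf$m_hat, tolerance = 1e-6)
    expect_equal(em$h_hat, cf$h_hat, tolerance = 1e-6)
    expect_identical(em$conflict, cf$conflict)
  }
  # three consistent assays: proportions k/n exactly at (m+h, m, h)
  m <- 0.30; h <- 0.20; n <- 1000
  est <- mle_multi_assay(list(
    assay_observation("TAPS", (m + h) * n, n),
    assay_observation("TAPSB", m * n, n),
    assay_observation("CAPS", h * n, n)))
  orc <- grid_mle_oracle((m + h) * n, n, m * n, n, "nested")
  expect_equal(est$m_hat, m, tolerance = 1e-4)
  expect_equal(est$h_hat, h, tolerance = 1e-4)
  expect_equal(est$m_hat, unname(orc["m"]), tolerance = 1e-4)
  expect_false(est$conflict)
  # all failures: everything unmodified
  zero <- mle_multi_assay(list(assay_observation("TAPSB", 0, 10),
                               assay_observation("CAPS", 0, 10)))
  expect_equal(zero$u_hat, 1, tolerance = 1e-6)
  # designs that cannot separate m from h are rejected
  expect_error(mle_multi_assay(list(assay_observation("TAPS", 1, 10),
                                    assay_observation("TAPS", 2, 10))),
               "non-identifiable")
})

test_that("subtraction preserves and flags negative 5hmC estimates", {
  s <- subtract_estimate(c(0.8, 0.2), c(0.3, 0.5))
  expect_equal(s$h_naive, c(0.5, -0.3))
  expect_identical(s$negative, c(FALSE, TRUE))
})

test_that("subtraction is noisier than the direct 5hmC readout", {
  # matched truth and total depth: subtraction uses two assays of depth n,
  # the direct assay gets the same 2n reads
  set.seed(50)
  m <- 0.5; h <- 0.2; n <- 30; nsim <- 4000
  taps <- rbinom(nsim, n, m + h) / n
  tapsb <- rbinom(nsim, n, m) / n
  h_sub <- subtract_estimate(taps, tapsb)$h_naive
  h_direct <- rbinom(nsim, 2 * n, h) / (2 * n)
  expect_gt(var(h_sub), var(h_direct))
  # at h = 0 the subtraction goes negative about half the time
  taps0 <- rbinom(nsim, n, m) / n
  h0 <- subtract_estimate(taps0, tapsb)$h_naive
  expect_gt(mean(h0 < 0), 0.2)
})
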