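test_that("the one-sided KS statistic matches a brute-force ECDF sweep", {
  # complete separation and identity
  expect_equal(ea_ks(100, 0)$stat, 1)
  ident <- ea_ks(c(10, 20, 30), c(10, 20, 30))
  expect_equal(ident$stat, 0)
  expect_equal(ident$p, 1)
  # hand case
  obs <- c(90, 95); bg <- c(10, 20, 30, 40)
  expect_equal(ea_ks(obs, bg)$stat, bf_ks_stat(obs, bg))
  expect_equal(ea_ks(obs, bg)$stat, 1)  # all bg below all obs

  # random pools against the brute-force oracle, including ties
  withr::with_seed(42, {
    for (i in 1:60) {
      o <- sample(round(stats::runif(sample(1:20, 1), 0, 100), 1))
      b <- round(stats::runif(sample(2:150, 1), 0, 100), 1)
      expect_equal(ea_ks(o, b)$stat, bf_ks_stat(o, b), tolerance = 1e-12)
    }
  })
})

test_that("KS p-values are one-sided, shift-direction sensitive, and bounded", {
  # observed shifted HIGH -> small p; shifted LOW -> D+ = 0, p = 1
  hi <- ea_ks(c(95, 96, 97, 98, 99), 1:80)
  lo <- ea_ks(c(1, 2, 3, 4, 5), 20:99)
  expect_lt(hi$p, 0.01)
  expect_equal(lo$stat, 0)
  expect_equal(lo$p, 1)
  expect_equal(hi$p, exp(-2 * hi$stat^2 * 5 * 80 / 85))
  expect_error(ea_ks(numeric(0), 1:5), "empty")
})

test_that("the EA-sum Monte-Carlo p-value behaves at its exact edges", {
  # observed sum unreachable by the null -> the add-one floor
  r <- ea_sum_test(c(100, 100), c(1, 2, 3), n_mc = 500, seed = 1)
  expect_equal(r$sum_ea, 200)
  expect_equal(r$p, 1 / 501)

  # two-point pool {0,100}, single observation 50: exact null is
  # Bernoulli(0.5) on whether the draw is 100, so p ~ (1 + K)/(1 + M)
  # with K ~ Binomial(M, 0.5); check within 3 binomial sigma
  M <- 2000
  r2 <- ea_sum_test(50, c(0, 100), n_mc = M, seed = 2)
  K <- r2$p * (1 + M) - 1
  expect_lt(abs(K - M / 2), 3 * sqrt(M * 0.25))

  expect_error(ea_sum_test(numeric(0), 1:3), "empty")
  expect_error(ea_sum_test(50, numeric(0)), "empty")
})

test_that("adding an EA=100 mutation never increases the EA-sum p-value", {
  # exact two-point-pool case: P(sum_n >= s) vs P(sum_{n+1} >= s + 100)
  pool <- c(0, 100)
  for (seed in 1:5) {
    p1 <- ea_sum_test(50, pool, n_mc = 2000, seed = seed)$p
    p2 <- ea_sum_test(c(50, 100), pool, n_mc = 2000, seed = seed)$p
    expect_lte(p2, p1)
  }
})

test_that("the frequency p-value equals exact binomial tail summation", {
  expect_equal(frequency_test(0, 300, 50, 3000), 1)
  # gene spanning the whole coding genome: success probability 1
  expect_equal(frequency_test(7, 3000, 50, 3000), 1)
  # hand case L_g/L_tot = 0.1, N = 10, n_g = 5
  expect_equal(frequency_test(5, 300, 10, 3000), bf_binom_tail(5, 10, 0.1),
               tolerance = 1e-12)
  withr::with_seed(7, {
    for (i in 1:50) {
      N <- sample(1:500, 1)
      n <- sample(0:N, 1)
      p <- stats::runif(1, 0.001, 0.5)
      expect_equal(frequency_test(n, p * 3000, N, 3000), bf_binom_tail(n, N, p),
                   tolerance = 1e-10)
    }
  })
})

test_that("gene ranking orders by p with the documented tie-breaks and BH q-values", {
  fx <- calibration_fixture()
  rows <- withr::with_seed(3, eadriver:::draw_strain_mutations(fx$bg, 4, 25))
  res <- rank_drivers(rows, fx$bg, fx$genome, ranking_config(n_mc = 300, seed = 9))

  for (m in c("ks", "sum", "freq")) {
    r <- res[[paste0("rank_", m)]]
    expect_setequal(r, seq_len(nrow(res)))       # a permutation of 1..G
    p <- res[[paste0("p_", m)]]
    expect_true(all(diff(p[order(r)]) >= 0))     # ascending p along ranks
  }
  # ties in p broken by descending sumEA (EA methods) / count (frequency)
  ties <- res[res$p_ks == 1, ]
  if (nrow(ties) > 1) {
    o <- order(ties$rank_ks)
    expect_true(all(diff(ties$sum_ea[o]) <= 0))
  }
  # BH q-values against the step-up oracle, computed over tested genes
  tested <- res$n_missense_scored >= 1
  expect_equal(res$q_ks[tested], bf_bh(res$p_ks[tested]))
  expect_equal(res$q_sum[tested], bf_bh(res$p_sum[tested]))
  expect_equal(res$q_freq, bf_bh(res$p_freq))
  expect_true(all(is.na(res$q_ks[!tested])))
  # genes below the minimum scored-missense count sit at p = 1
  expect_true(all(res$p_ks[!tested] == 1 & res$p_sum[!tested] == 1))
  # sumEA = 0 iff no scored missense
  expect_equal(res$sum_ea == 0, res$n_missense_scored == 0)
})

test_that("hand-sized BH example: equal q for an arithmetic p ladder", {
  expect_equal(bf_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("Monte-Carlo rankings are reproducible under the config seed", {
  fx <- calibration_fixture()
  rows <- withr::with_seed(4, eadriver:::draw_strain_mutations(fx$bg, 3, 15))
  r1 <- rank_drivers(rows, fx$bg, fx$genome, ranking_config(n_mc = 300, seed = 5))
  r2 <- rank_drivers(rows, fx$bg, fx$genome, ranking_config(n_mc = 300, seed = 5))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})
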