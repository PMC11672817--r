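test_that("chain configuration is validated", {
  expect_error(chain_config(1000, 1000, 5), "burn_in")
  expect_error(chain_config(1000, 2000, 5), "burn_in")
  expect_error(chain_config(100, 90, 50), "stored")
  cfg <- chain_config(1000, 200, 4)
  expect_equal((cfg$n_iter - cfg$burn_in) %/% cfg$thin, 200L)
})

test_that("stored draw count matches the chain arithmetic and seeds
          reproduce bit-identical chains", {
  sim <- simulate_dataset(sim_config(n_founders = 40, seed = 3))
  ed <- edit_records(sim$records, edit_config(min_cg_size = 1))
  rec <- ed$records[!ed$records$censored, ]
  d <- build_design(rec, sim$pedigree)
  ainv <- build_A_inverse(sim$pedigree)
  cfg <- chain_config(600, 100, 7, seed = 99)
  ch1 <- gibbs_gaussian(d, ainv, cfg)
  ch2 <- gibbs_gaussian(d, ainv, cfg)
  expect_equal(nrow(ch1$draws), (600L - 100L) %/% 7L)
  expect_identical(ch1$draws, ch2$draws)
  expect_true(all(ch1$draws[, c("sigma_u2", "sigma_pe2", "sigma_e2")] > 0))
  # h2 column is recomputable from the component draws
  expect_equal(ch1$draws[, "h2"],
               ch1$draws[, "sigma_u2"] / rowSums(ch1$draws[, 1:3]))
})

test_that("with fixed variances the Gibbs means equal the MME solutions", {
  # Per effect, (posterior mean - BLUP) / MCSE is asymptotically standard
  # normal when the sampler is exact, so across a few hundred effects the
  # expected tail fraction beyond 3 is ~0.3%; a systematic defect shifts
  # many effects at once. Assert the tail fraction and a gross-error cap.
  for (sys in list(list(seed = 21, founders = 40),
                   list(seed = 22, founders = 60))) {
    sim <- simulate_dataset(sim_config(n_founders = sys$founders,
                                       seed = sys$seed))
    ed <- edit_records(sim$records)
    rec <- ed$records[!ed$records$censored, ]
    d <- build_design(rec, sim$pedigree)
    ainv <- build_A_inverse(sim$pedigree)
    vc <- variance_components(437.64, 705.76, 11932)
    mme <- solve_mme(d, ainv, vc)
    ch <- gibbs_gaussian(d, ainv, chain_config(24000, 2000, 4,
                                               seed = sys$seed + 100),
                         fix_variances = vc, store_effects = TRUE)
    sol <- c(mme$beta, mme$u, mme$pe)
    se <- apply(ch$effect_draws, 2, mcse)
    z <- abs(ch$effects$mean - sol) / pmax(se, 1e-12)
    expect_gte(mean(z < 3), 0.99)
    expect_lt(max(z), 6)
    expect_lt(mean(z^2), 1 + 3 * sqrt(2 / length(z)))
  }
})

test_that("the sampler recovers heritability on strong-signal data", {
  # high-heritability generator: posterior intervals should cover truth in
  # most replicates
  cover <- 0
  n_rep <- 8
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_founders = 250, sigma_u2 = 0.3 * 13075.4,
                      sigma_pe2 = 0.1 * 13075.4, sigma_e2 = 0.6 * 13075.4,
                      censoring_rate = 0, seed = 400 + r)
    h2_true <- 0.3
    sim <- simulate_dataset(cfg)
    ed <- edit_records(sim$records)
    rec <- ed$records[!ed$records$censored, ]
    d <- build_design(rec, sim$pedigree)
    ainv <- build_A_inverse(sim$pedigree)
    ch <- gibbs_gaussian(d, ainv, chain_config(8000, 2000, 5, seed = 500 + r))
    ci <- stats::quantile(ch$draws[, "h2"], c(0.025, 0.975))
    cover <- cover + (ci[1] <= h2_true && h2_true <= ci[2])
  }
  expect_gte(cover, n_rep - 1)
})

test_that("burn-in must stay below the iteration count", {
  expect_error(chain_config(n_iter = 500, burn_in = 500), "burn_in")
})

test_that("liability draws respect the sign constraint and the half-normal
          moment", {
  set.seed(77)
  # truncation constraint holds for any mean
  d1 <- sample_liability(1, rnorm(1000, 0, 10), 1)
  expect_true(all(d1 > 0))
  d0 <- sample_liability(0, rnorm(1000, 0, 10), 1)
  expect_true(all(d0 <= 0))
  # half-normal moment: mean of status-0 draws at mean 0, sd 1
  m <- mean(sample_liability(0, rep(0, 1e5), 1))
  expect_equal(m, -sqrt(2 / pi), tolerance = 0.01)
  # extreme means stay finite and on the right side
  expect_lte(sample_liability(0, 40, 1), 0)
  expect_gt(sample_liability(1, -40, 1), 0)
  expect_true(is.finite(sample_liability(0, 1e6, 1)))
  expect_error(sample_liability(2, 0, 1), "status")
})

test_that("Geweke diagnostic is calibrated and detects trends", {
  set.seed(123)
  z <- replicate(200, geweke_z(rnorm(1500)))
  frac <- mean(abs(z) < 1.96)
  expect_gte(frac, 0.93)
  expect_lte(frac, 0.97)
  # a deterministic linear trend fails loudly
  expect_gt(abs(geweke_z(seq_len(1500) * 0.01 + rnorm(1500, 0, 0.01))), 5)
  # constant chain: z = 0 by convention
  expect_equal(geweke_z(rep(1, 500)), 0)
  expect_error(geweke_z(rnorm(50)), "100")
})

test_that("autocorrelation function matches an AR(1) oracle", {
  set.seed(9)
  x <- rnorm(4000)
  ac <- autocorrelation(x, 10)
  expect_equal(unname(ac[1]), 1)
  expect_lt(abs(ac[2]), 3 / sqrt(4000))
  # AR(1) with phi = 0.9
  ar1 <- as.numeric(stats::arima.sim(list(ar = 0.9), 6000))
  expect_equal(unname(autocorrelation(ar1, 1)[2]), 0.9, tolerance = 0.05)
  expect_error(autocorrelation(rnorm(10), 20), "short")
})
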