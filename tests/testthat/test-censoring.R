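test_that("penalty imputation follows the group-maximum rule", {
  r <- toy_records_hys(3, do = c(100, 150, 80))
  r$censored[3] <- TRUE
  out <- impute_penalty(r)
  expect_equal(out$imputed_do[3], 150 + 21)
  expect_true(is.na(out$imputed_do[1]))
  expect_equal(out$provenance, c("observed", "observed", "imputed"))
  # never below the group's observed maximum
  expect_gte(out$imputed_do[3], max(r$do[!r$censored]))

  # no censored records: identity
  r2 <- toy_records_hys(3)
  out2 <- impute_penalty(r2)
  expect_equal(out2$do, r2$do)
  expect_true(all(is.na(out2$imputed_do)))

  # custom penalty constant
  out3 <- impute_penalty(r, penalty = 0)
  expect_equal(out3$imputed_do[3], 150)
  expect_error(impute_penalty(r, penalty = -1), "non-negative")
})

test_that("extreme-class groups fall back to the dataset maximum", {
  r <- toy_records_hys(5, do = c(100, 300, 120, 60, 70))
  # records 4 and 5 form their own, fully censored group
  r$calving_date[4:5] <- as.Date("2022-07-01")
  r$season <- assign_season(r$calving_date)
  r$hys <- interaction(r$herd, format(r$calving_date, "%Y"), r$season,
                       drop = TRUE, sep = "_")
  r$censored[4:5] <- TRUE
  expect_warning(out <- impute_penalty(r), "extreme-class")
  expect_equal(out$imputed_do[4], 300 + 21)
  expect_equal(out$imputed_do[5], 300 + 21)

  # entirely censored data cannot anchor a penalty
  r$censored[] <- TRUE
  expect_error(impute_penalty(r), "no uncensored")
})

test_that("LM and PLM coincide draw-for-draw without censoring", {
  sim <- simulate_dataset(sim_config(n_founders = 60, censoring_rate = 0,
                                     seed = 17))
  ed <- edit_records(sim$records)
  expect_equal(sum(ed$records$censored), 0L)
  cfg <- chain_config(800, 200, 3, seed = 5)
  lm <- fit_lm(ed$records, sim$pedigree, cfg)
  plm <- fit_plm(ed$records, sim$pedigree, cfg)
  expect_identical(lm$chain$draws, plm$chain$draws)
  expect_equal(lm$ebv$ebv, plm$ebv$ebv)
})

test_that("PLM keeps every record and LM drops the censored ones", {
  sim <- simulate_dataset(sim_config(n_founders = 80, seed = 19))
  ed <- edit_records(sim$records)
  n_cens <- sum(ed$records$censored)
  expect_gt(n_cens, 0)
  cfg <- chain_config(400, 100, 3, seed = 6)
  lm <- fit_lm(ed$records, sim$pedigree, cfg)
  # small populations can hold fully censored groups; the fallback warning
  # is exercised in its own test above
  plm <- suppressWarnings(fit_plm(ed$records, sim$pedigree, cfg))
  expect_equal(lm$n_records, nrow(ed$records) - n_cens)
  expect_equal(plm$n_records, nrow(ed$records))

  # all records censored: nothing left for LM
  allc <- ed$records
  allc$censored <- TRUE
  expect_error(fit_lm(allc, sim$pedigree, cfg), "no data")
})

test_that("penalty inflates the residual variance relative to LM", {
  # across seeded replicates the completed data carry extra spread
  res <- vapply(1:4, function(r) {
    sim <- simulate_dataset(sim_config(n_founders = 150, seed = 600 + r))
    ed <- edit_records(sim$records)
    cfg <- chain_config(3000, 1000, 5, seed = 700 + r)
    lm <- fit_lm(ed$records, sim$pedigree, cfg)
    plm <- fit_plm(ed$records, sim$pedigree, cfg)
    plm$vc["sigma_e2", "mean"] - lm$vc["sigma_e2", "mean"]
  }, numeric(1))
  expect_gt(mean(res), 0)
})

test_that("PTM liabilities respect the threshold sign constraint at every
          stored iteration", {
  sim <- simulate_dataset(sim_config(n_founders = 80, seed = 23))
  ed <- edit_records(sim$records)
  fit <- fit_ptm(ed$records, sim$pedigree, chain_config(600, 100, 4, seed = 8),
                 store_liabilities = TRUE)
  L <- fit$chain$liability_draws
  status <- matrix(ed$records$censored, nrow(L), ncol(L), byrow = TRUE)
  expect_true(all(L[status] > 0))
  expect_true(all(L[!status] <= 0))
  # summary table is shaped like a bivariate fit
  expect_true(all(c("sigma_u2", "h2", "r_g") %in% rownames(fit$vc)))
  expect_equal(nrow(fit$ebv), nrow(sim$pedigree))
  expect_equal(nrow(fit$ebv_liability), nrow(sim$pedigree))
})

test_that("PTM needs both censored and uncensored records", {
  sim <- simulate_dataset(sim_config(n_founders = 60, censoring_rate = 0,
                                     seed = 29))
  ed <- edit_records(sim$records)
  expect_error(fit_ptm(ed$records, sim$pedigree, chain_config(200, 50, 2)),
               "degenerate")
})

test_that("PTM recovers a positive genetic correlation when censorship is
          genetically linked to days open", {
  positive <- 0
  n_rep <- 6
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_founders = 200, censoring = "liability_correlated",
                      genetic_corr = 0.6, seed = 800 + r)
    sim <- simulate_dataset(cfg)
    ed <- edit_records(sim$records)
    if (sum(ed$records$censored) < 5) next
    fit <- suppressWarnings(
      fit_ptm(ed$records, sim$pedigree,
              chain_config(3000, 1000, 5, seed = 900 + r)))
    positive <- positive + (fit$vc["r_g", "mean"] > 0)
  }
  expect_gte(positive, n_rep - 1)
})
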