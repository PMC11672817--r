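test_that("LR identities hold for arbitrary vectors", {
  set.seed(31)
  x <- stats::setNames(rnorm(80), paste0("a", 1:80))
  expect_equal(bias_lr(x, x), 0)
  expect_equal(dispersion_lr(x, x), 1)
  ra <- rank_agreement(x, x)
  expect_equal(ra$spearman, 1)
  expect_equal(ra$overlap_pct, 100)
  # dispersion on u_w = 0.5 u_p is exactly 0.5
  expect_equal(dispersion_lr(0.5 * x, x), 0.5)
  # self-consistency limit of the accuracy
  f_bar <- 0.01
  sa2 <- stats::var(x) / (1 - f_bar)
  expect_equal(acc_lr(x, x, F_bar = f_bar, sigma_a2 = sa2), 1)
  expect_equal(acc_lr_squared(x, x, F_bar = f_bar, sigma_a2 = sa2), 1)
})

test_that("LR statistics respond to shifts as the formulas dictate", {
  set.seed(32)
  x <- stats::setNames(rnorm(60), paste0("a", 1:60))
  shifted <- x + 3
  expect_equal(bias_lr(x, shifted), 3)            # mean(partial) - mean(whole)
  expect_equal(bias_lr(shifted, x), -3)
  # accuracy and dispersion are shift-invariant, bias is not
  sa2 <- stats::var(x)
  expect_equal(acc_lr(x + 5, shifted + 5, sigma_a2 = sa2),
               acc_lr(x, shifted, sigma_a2 = sa2))
  expect_equal(dispersion_lr(x + 5, shifted + 5), dispersion_lr(x, shifted))
})

test_that("independent vectors give near-zero accuracy and chance overlap", {
  set.seed(33)
  n <- 1000
  ids <- paste0("a", 1:n)
  x <- stats::setNames(rnorm(n), ids)
  y <- stats::setNames(rnorm(n), ids)
  ra <- rank_agreement(x, y)
  expect_lt(abs(ra$spearman), 0.1)
  # null: overlap ~ hypergeometric, mean 20%, sd 2.7%; allow 4 sd
  expect_gt(ra$overlap_pct, 9); expect_lt(ra$overlap_pct, 31)
  # null: cov of two iid N(0,1) vectors has sd 1/sqrt(n-1); allow 4 sd
  expect_lt(abs(acc_lr_squared(x, y, F_bar = 0, sigma_a2 = 1)),
            4 / sqrt(length(x) - 1))
})

test_that("reversed ranks give the pigeonhole overlap", {
  n <- 50
  ids <- sprintf("a%02d", 1:n)
  x <- stats::setNames(seq_len(n), ids)
  rev_x <- stats::setNames(rev(seq_len(n)), ids)
  ra <- rank_agreement(x, rev_x, top_fraction = 0.2)
  expect_equal(ra$spearman, -1)
  k <- ceiling(0.2 * n)
  expect_equal(ra$overlap_pct, 100 * max(0, 2 * k - n) / k)
  # with a top fraction over one half the overlap is forced positive
  ra2 <- rank_agreement(x, rev_x, top_fraction = 0.6)
  k2 <- ceiling(0.6 * n)
  expect_equal(ra2$overlap_pct, 100 * (2 * k2 - n) / k2)
})

test_that("rank agreement is invariant to monotone transforms", {
  set.seed(34)
  ids <- paste0("a", 1:200)
  x <- stats::setNames(rnorm(200), ids)
  y <- stats::setNames(rnorm(200), ids)
  base <- rank_agreement(x, y)
  mono <- rank_agreement(stats::setNames(exp(2 * x), ids), y)
  expect_equal(mono$spearman, base$spearman)
  expect_equal(mono$overlap_pct, base$overlap_pct)
})

test_that("degenerate inputs are rejected or flagged", {
  ids <- paste0("a", 1:10)
  x <- stats::setNames(rnorm(10), ids)
  const <- stats::setNames(rep(1, 10), ids)
  expect_error(dispersion_lr(x, const), "constant")
  expect_warning(r2 <- acc_lr_squared(x, stats::setNames(-x, ids) - 10 * x,
                                      F_bar = 0, sigma_a2 = 1))
  expect_true(is.nan(r2))
  expect_error(acc_lr(x, x, F_bar = 1.2, sigma_a2 = 1), "F_bar")
  expect_error(acc_lr(x, x, F_bar = 0, sigma_a2 = -1), "positive")
})

test_that("the validation split removes only young phenotypes", {
  sim <- simulate_dataset(sim_config(n_founders = 150, seed = 37))
  ed <- edit_records(sim$records)
  sp <- make_split(ed$records, cutoff_year = 2020)
  expect_gt(length(sp$validation), 0)
  # partial plus removed phenotypes equals the whole dataset
  removed <- ed$records[as.character(ed$records$cow_id) %in% sp$validation, ]
  expect_equal(nrow(sp$partial) + nrow(removed), nrow(sp$whole))
  # every validation cow was born at or after the cutoff
  by <- as.integer(format(removed$birth_date, "%Y"))
  expect_true(all(by >= 2020))
  # validation animals are phenotyped animals only
  expect_true(all(sp$validation %in% as.character(ed$records$cow_id)))
  # the split captures roughly the youngest third of the cows
  frac <- length(sp$validation) / length(unique(ed$records$cow_id))
  expect_gt(frac, 0.2); expect_lt(frac, 0.45)
  # cutoffs excluding everyone fail loudly
  expect_error(make_split(ed$records, cutoff_year = 2100), "empty validation")
})

test_that("the full LR validation report is self-consistent", {
  sim <- simulate_dataset(sim_config(n_founders = 120, seed = 41))
  ed <- edit_records(sim$records)
  rep <- lr_validate(ed$records, sim$pedigree, models = c("LM", "PLM"),
                     config = chain_config(1200, 300, 3, seed = 43))
  expect_s3_class(rep, "lr_report")
  expect_equal(diag(rep$spearman), c(LM = 1, PLM = 1))
  expect_equal(diag(rep$overlap_pct), c(LM = 100, PLM = 100))
  expect_true(all(rep$overlap_pct >= 0 & rep$overlap_pct <= 100))
  # report equals recomputation from the persisted EBVs
  m <- "PLM"
  sa2 <- mean(rep$fits_whole[[m]]$chain$draws[, "sigma_u2"])
  expect_equal(rep$stats[[m]]$bias,
               bias_lr(rep$fits_whole[[m]]$ebv, rep$fits_partial[[m]]$ebv,
                       rep$fits_whole[[m]]$ebv$animal[
                         rep$fits_whole[[m]]$ebv$animal %in%
                           make_split(ed$records, 2020)$validation]))
  expect_equal(rep$stats[[m]]$acc_squared,
               rep$stats[[m]]$acc^2, tolerance = 1e-12)
  expect_equal(rep$F_bar, mean_inbreeding(sim$pedigree,
                                          make_split(ed$records, 2020)$validation))
  # CSV writer runs
  path <- withr::local_tempfile(fileext = ".csv")
  write_lr_report(rep, path)
  expect_true(file.exists(path))
  tab <- utils::read.csv(path)
  expect_equal(tab$statistic[1:3], c("acc_lr", "bias_lr", "dispersion_lr"))
})
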