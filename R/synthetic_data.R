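#' Simulation configuration
#'
#' Defaults emulate the structure of a small intensively managed Holstein
#' population: about 1,500 phenotyped cows with up to three lactations in
#' four herds over the 2017-2023 calving span, a right-censoring rate of
#' 14.51% of the days-open records, and true variance components
#' (437.64, 705.76, 11932.0) days^2 for the additive, permanent-environment
#' and residual parts (true h2 = 0.0335).
#'
#' @param n_founders number of founder animals.
#' @param sire_prop fraction of each cohort that is male.
#' @param n_generations number of generations including the founders.
#' @param progeny_per_dam progeny per dam and generation.
#' @param n_herds number of herds.
#' @param parity_probs probabilities that a cow records exactly 1, 2 or 3
#'   parities.
#' @param sigma_u2,sigma_pe2,sigma_e2 true variance components (days^2).
#' @param hys_sd SD of the herd-year-season fixed effects (days).
#' @param parity_effects fixed parity effects (days), length 3.
#' @param intercept overall mean days open (days).
#' @param beta_age,beta_dim covariate slopes (days of DO per day of age at
#'   calving / days in milk at first insemination).
#' @param censoring censoring mechanism: `value_dependent` (records in the
#'   upper within-HYS tail of latent days open are censored with elevated
#'   probability, mimicking cows not yet confirmed pregnant at data
#'   retrieval), `random` (independent of everything), or
#'   `liability_correlated` (a second breeding-value vector genetically
#'   correlated with days open drives a probit liability).
#' @param censoring_rate target fraction of censored records.
#' @param genetic_corr genetic correlation between days open and the
#'   censorship liability (mechanism `liability_correlated`).
#' @param residual `gaussian` (matching the model assumption) or
#'   `lognormal` (right-skewed stress test).
#' @param avoid_sib_mating disallow matings between animals sharing a known
#'   parent.
#' @param seed integer seed making the whole generator deterministic.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 600L, sire_prop = 0.2,
                       n_generations = 3L, progeny_per_dam = 2L,
                       n_herds = 4L, parity_probs = c(0.65, 0.25, 0.10),
                       sigma_u2 = 437.64, sigma_pe2 = 705.76,
                       sigma_e2 = 11932.0, hys_sd = 30,
                       parity_effects = c(0, 1, 4), intercept = 155,
                       beta_age = 0.005, beta_dim = 0.8,
                       censoring = c("value_dependent", "random",
                                     "liability_correlated"),
                       censoring_rate = 0.1451, genetic_corr = 0.5,
                       residual = c("gaussian", "lognormal"),
                       avoid_sib_mating = FALSE, seed = NULL) {
  censoring <- match.arg(censoring)
  residual <- match.arg(residual)
  if (n_founders < 2L) stop("need at least 2 founders")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must lie in [0, 1)")
  if (abs(genetic_corr) >= 1) stop("genetic_corr must lie in (-1, 1)")
  if (any(c(sigma_u2, sigma_pe2, sigma_e2) <= 0))
    stop("true variances must be positive")
  stopifnot(length(parity_probs) == 3L, abs(sum(parity_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a pedigree
#'
#' Non-overlapping generations with random mating. Sexes alternate
#' deterministically within each cohort, so the animal count per generation
#' is a closed-form function of the configuration: founders are split into
#' `floor(sire_prop * n_founders)` sires and the rest dams, and every
#' following generation holds `progeny_per_dam` progeny per dam of the
#' previous generation. Founder birth years are 2014-2015; later cohorts
#' are born in (2017, 2018), (2020, 2021), ... so a 2020 birth-year cutoff
#' captures roughly the youngest third of the phenotyped cows.
#'
#' @param config a [sim_config()]. Uses the current RNG state; seed it (or
#'   use [simulate_dataset()]) for reproducibility.
#' @return a `pedigree` with extra columns `sex` (`"M"`/`"F"`),
#'   `generation` and `birth_year`.
#' @export
simulate_pedigree <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_sires <- max(1L, floor(config$sire_prop * config$n_founders))
  n_dams <- config$n_founders - n_sires
  id <- seq_len(config$n_founders)
  sex <- rep(c("M", "F"), c(n_sires, n_dams))
  sire <- dam <- rep(0L, config$n_founders)
  gen <- rep(0L, config$n_founders)
  byear <- 2014L + (id %% 2L)

  for (g in seq_len(config$n_generations - 1L)) {
    sires_g <- id[sex == "M" & gen == g - 1L]
    dams_g <- id[sex == "F" & gen == g - 1L]
    if (length(sires_g) == 0L) sires_g <- id[sex == "M"] # fallback
    n_off <- length(dams_g) * config$progeny_per_dam
    if (n_off == 0L) break
    off_dam <- rep(dams_g, each = config$progeny_per_dam)
    off_sire <- vapply(off_dam, function(d) {
      cand <- sires_g
      if (config$avoid_sib_mating) {
        keep <- !(sire[cand] > 0L & sire[cand] == sire[d]) &
          !(dam[cand] > 0L & dam[cand] == dam[d])
        if (any(keep)) cand <- cand[keep]
      }
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    new_id <- max(id) + seq_len(n_off)
    id <- c(id, new_id)
    sire <- c(sire, off_sire)
    dam <- c(dam, off_dam)
    sex <- c(sex, rep_len(c("F", "M"), n_off)) # females first -> ~50/50
    gen <- c(gen, rep(g, n_off))
    byear <- c(byear, 2014L + 3L * g + (new_id %% 2L))
  }

  ped <- as_pedigree(data.frame(animal = id, sire = sire, dam = dam))
  ord <- match(ped$label, as.character(id))
  ped$sex <- sex[ord]
  ped$generation <- gen[ord]
  ped$birth_year <- byear[ord]
  ped
}

# recursive breeding values with Mendelian sampling shrunk by parental
# inbreeding; G is the (t x t) genetic covariance matrix
simulate_breeding_values <- function(ped, G) {
  G <- as.matrix(G)
  t_dim <- ncol(G)
  f <- inbreeding(ped)
  n <- nrow(ped)
  u <- matrix(0, n, t_dim)
  L <- chol(G)
  fs <- ifelse(ped$sire > 0L, f[pmax(ped$sire, 1L)], -1)
  fd <- ifelse(ped$dam > 0L, f[pmax(ped$dam, 1L)], -1)
  d <- 0.5 - 0.25 * (fs + fd)
  z <- matrix(stats::rnorm(n * t_dim), n, t_dim) %*% L
  for (i in seq_len(n)) {
    pa <- numeric(t_dim)
    if (ped$sire[i] > 0L) pa <- pa + 0.5 * u[ped$sire[i], ]
    if (ped$dam[i] > 0L) pa <- pa + 0.5 * u[ped$dam[i], ]
    u[i, ] <- pa + sqrt(d[i]) * z[i, ]
  }
  rownames(u) <- ped$label
  u
}

#' Simulate phenotype records with known ground truth
#'
#' Draws breeding values recursively down the pedigree (Mendelian-sampling
#' variance `0.5 - 0.25 (F_s + F_d)` times the genetic variance), one
#' permanent-environment effect per cow and one residual per record, and
#' assembles days open as intercept + HYS effect + parity effect +
#' covariate terms + u + pe + e, floored at 20 days. Censoring is applied
#' according to `config$censoring`; censored records carry the days
#' accumulated up to the (random) status date as a lower bound, with no
#' conception date.
#'
#' @param ped a pedigree from [simulate_pedigree()].
#' @param config a [sim_config()]. Uses the current RNG state.
#' @return list with `records` (phenotype data frame in the format of
#'   [read_phenotypes()]) and `truth` (list with per-animal `u` matrix,
#'   per-cow `pe`, per-record `e`, `latent_do`, `censored`, and the fixed
#'   effects used).
#' @export
simulate_phenotypes <- function(ped, config = sim_config()) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "sim_config"))
  two_trait <- config$censoring == "liability_correlated"
  G <- if (two_trait) {
    g12 <- config$genetic_corr * sqrt(config$sigma_u2)
    matrix(c(config$sigma_u2, g12, g12, 1), 2, 2)
  } else {
    matrix(config$sigma_u2, 1, 1)
  }
  u <- simulate_breeding_values(ped, G)

  cows <- which(ped$sex == "F")
  n_cows <- length(cows)
  n_par <- sample.int(3L, n_cows, replace = TRUE, prob = config$parity_probs)
  herd <- sample.int(config$n_herds, n_cows, replace = TRUE)
  pe <- stats::rnorm(n_cows, 0, sqrt(config$sigma_pe2))
  birth_doy <- sample.int(365L, n_cows, replace = TRUE)
  birth_date <- as.Date(paste0(ped$birth_year[cows], "-01-01")) + birth_doy - 1L

  rec <- do.call(rbind, lapply(seq_len(n_cows), function(k) {
    data.frame(cow_row = cows[k], cow_k = k, parity = seq_len(n_par[k]))
  }))
  nrec <- nrow(rec)
  age <- matrix(NA_real_, n_cows, 3L)
  age[, 1] <- pmax(540, round(stats::rnorm(n_cows, 771, 60)))
  age[, 2] <- age[, 1] + pmax(330, round(stats::rnorm(n_cows, 430, 60)))
  age[, 3] <- age[, 2] + pmax(330, round(stats::rnorm(n_cows, 427, 60)))
  rec$age_at_calving <- age[cbind(rec$cow_k, rec$parity)]
  rec$calving_date <- birth_date[rec$cow_k] + rec$age_at_calving
  rec$dim_first_ai <- pmin(250, pmax(20, round(stats::rnorm(nrec, 76, 25))))
  rec$herd <- herd[rec$cow_k]

  season <- assign_season(rec$calving_date)
  hys_key <- paste(rec$herd, format(rec$calving_date, "%Y"), season, sep = "_")
  hys_levels <- sort(unique(hys_key))
  hys_eff <- stats::rnorm(length(hys_levels), 0, config$hys_sd)
  names(hys_eff) <- hys_levels

  e <- if (config$residual == "gaussian") {
    stats::rnorm(nrec, 0, sqrt(config$sigma_e2))
  } else {
    raw <- stats::rlnorm(nrec, 0, 0.8)
    (raw - mean(raw)) / stats::sd(raw) * sqrt(config$sigma_e2)
  }

  latent <- config$intercept + hys_eff[hys_key] +
    config$parity_effects[rec$parity] +
    config$beta_age * (rec$age_at_calving - 1100) +
    config$beta_dim * (rec$dim_first_ai - 76) +
    u[rec$cow_row, 1] + pe[rec$cow_k] + e
  latent <- pmax(20, latent)

  censored <- switch(config$censoring,
    random = stats::runif(nrec) < config$censoring_rate,
    value_dependent = {
      thr <- stats::ave(latent, hys_key,
                        FUN = function(v) stats::quantile(v, 0.85))
      p_low <- config$censoring_rate / 1.45
      in_tail <- latent > thr
      stats::runif(nrec) < ifelse(in_tail, 4 * p_low, p_low)
    },
    liability_correlated = {
      liab <- u[rec$cow_row, 2] + stats::rnorm(nrec, 0, 1)
      tau <- stats::quantile(liab, 1 - config$censoring_rate)
      liab > tau
    })

  do_obs <- round(latent)
  lower <- pmax(20, round(latent * stats::runif(nrec, 0.35, 0.90)))
  do_obs[censored] <- lower[censored]

  records <- data.frame(
    cow_id = ped$label[rec$cow_row],
    herd = rec$herd,
    calving_date = rec$calving_date,
    birth_date = birth_date[rec$cow_k],
    parity = rec$parity,
    age_at_calving = rec$age_at_calving,
    dim_first_ai = rec$dim_first_ai,
    do = do_obs,
    conception_date = as.Date(ifelse(censored, NA,
                                     rec$calving_date + do_obs),
                              origin = "1970-01-01"),
    censored = censored,
    stringsAsFactors = FALSE)

  truth <- list(u = u, pe = stats::setNames(pe, ped$label[cows]),
                e = e, latent_do = latent, censored = censored,
                hys_effects = hys_eff,
                parity_effects = config$parity_effects,
                intercept = config$intercept,
                beta_age = config$beta_age, beta_dim = config$beta_dim)
  list(records = records, truth = truth)
}

#' Simulate a complete dataset
#'
#' Seeds the RNG from `config$seed` (when set) and runs
#' [simulate_pedigree()] + [simulate_phenotypes()]; the result is a
#' deterministic function of the configuration.
#'
#' @param config a [sim_config()].
#' @return list of class `do_simulation` with `pedigree`, `records`,
#'   `truth` and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ped <- simulate_pedigree(config)
  ph <- simulate_phenotypes(ped, config)
  structure(list(pedigree = ped, records = ph$records, truth = ph$truth,
                 config = config), class = "do_simulation")
}

#' @export
print.do_simulation <- function(x, ...) {
  cat("Synthetic days-open dataset:", nrow(x$records), "records from",
      length(unique(x$records$cow_id)), "cows;",
      nrow(x$pedigree), "pedigree animals;",
      sprintf("%.2f%%", 100 * mean(x$records$censored)), "censored\n")
  invisible(x)
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Writes `pedigree.txt` (animal sire dam, 0 = unknown),
#' `phenotypes.csv`, `truth_animals.csv` (per-animal true breeding values
#' and permanent-environment effects) and `truth_records.csv` (per-record
#' latent days open, residual and censorship). Re-reading with
#' [read_pedigree()] / [read_phenotypes()] round-trips losslessly, and the
#' same seed regenerates byte-identical files.
#'
#' @param sim a `do_simulation`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "do_simulation"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  ped <- sim$pedigree
  paths <- c(pedigree = file.path(dir, "pedigree.txt"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             truth_animals = file.path(dir, "truth_animals.csv"),
             truth_records = file.path(dir, "truth_records.csv"))
  utils::write.table(
    data.frame(animal = ped$label,
               sire = ifelse(ped$sire > 0L, ped$label[pmax(ped$sire, 1L)], "0"),
               dam = ifelse(ped$dam > 0L, ped$label[pmax(ped$dam, 1L)], "0")),
    paths["pedigree"], row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.csv(sim$records, paths["phenotypes"], row.names = FALSE,
                   na = "")
  tu <- data.frame(animal = rownames(sim$truth$u), sim$truth$u)
  names(tu)[-1] <- paste0("true_u", seq_len(ncol(sim$truth$u)))
  tu$true_pe <- sim$truth$pe[match(tu$animal, names(sim$truth$pe))]
  utils::write.csv(tu, paths["truth_animals"], row.names = FALSE, na = "")
  utils::write.csv(
    data.frame(latent_do = sim$truth$latent_do, e = sim$truth$e,
               censored = sim$truth$censored),
    paths["truth_records"], row.names = FALSE)
  invisible(paths)
}
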