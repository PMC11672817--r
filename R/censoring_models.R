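#' Penalty imputation of censored days open
#'
#' Each censored record is imputed as the maximum uncensored days open in
#' its herd-year-season contemporary group plus a penalty of one estrous
#' cycle (21 days by default), on the rationale that a cow not yet
#' confirmed pregnant would have conceived given one extra cycle.
#' A group in which every record is censored (an extreme-class group) has
#' no within-group maximum; such records fall back to the maximum
#' uncensored days open of the whole dataset plus the penalty, with a
#' warning naming the groups.
#'
#' @param records edited records (must carry `hys` and `censored`).
#' @param penalty penalty constant in days (>= 0).
#' @return `records` with added columns `imputed_do` (the imputed value for
#'   censored rows, `NA` otherwise) and `provenance`
#'   (`"observed"`/`"imputed"`).
#' @export
impute_penalty <- function(records, penalty = 21) {
  if (penalty < 0) stop("penalty must be non-negative")
  if (!all(c("hys", "censored") %in% names(records)))
    stop("records must carry 'hys' and 'censored'; run edit_records() first")
  unc <- !records$censored
  if (!any(unc)) stop("no uncensored record available to anchor the penalty")
  gmax <- tapply(records$do[unc], droplevels(factor(records$hys[unc])), max)
  global_max <- max(records$do[unc])
  key <- as.character(records$hys)
  base <- unname(gmax[key])
  fallback <- records$censored & is.na(base)
  if (any(fallback)) {
    warning("extreme-class contemporary group(s) with no uncensored record; ",
            "falling back to the dataset-wide maximum for: ",
            paste(unique(key[fallback]), collapse = ", "))
    base[fallback] <- global_max
  }
  records$imputed_do <- ifelse(records$censored, base + penalty, NA_real_)
  records$provenance <- ifelse(records$censored, "imputed", "observed")
  records
}

ebv_table <- function(effects, design, model, trait = "u") {
  sub <- effects[effects$type == trait, ]
  data.frame(animal = sub$label, model = model, ebv = sub$mean,
             posterior_sd = sub$sd, stringsAsFactors = FALSE)
}

vc_summary <- function(chain) {
  s <- posterior_summary(chain)
  s[, c("mean", "sd"), drop = FALSE]
}

new_do_fit <- function(model, chain, design, extra = list()) {
  structure(c(list(model = model, chain = chain,
                   ebv = ebv_table(chain$effects, design, model),
                   vc = vc_summary(chain), n_records = length(design$y)),
              extra),
            class = "do_fit")
}

#' @export
print.do_fit <- function(x, ...) {
  cat("Days-open fit (", x$model, "): ", x$n_records, " records\n", sep = "")
  print(round(x$vc, 4))
  invisible(x)
}

#' Linear model dropping censored records (LM)
#'
#' Fits the Gaussian repeatability animal model after omitting every
#' censored record.
#'
#' @param records edited records (see [edit_records()]).
#' @param ped a `pedigree`.
#' @param config a [chain_config()].
#' @param priors a [variance_priors()].
#' @param ... passed to [gibbs_gaussian()].
#' @return a `do_fit` with the posterior chain, the estimated breeding
#'   values (posterior means of `u`) and a variance-component summary.
#' @export
fit_lm <- function(records, ped, config = chain_config(),
                   priors = variance_priors(), ...) {
  kept <- records[!records$censored, ]
  if (nrow(kept) == 0L) stop("no data after omission of censored records")
  kept$hys <- droplevels(factor(kept$hys))
  design <- build_design(kept, ped)
  ainv <- build_A_inverse(ped)
  chain <- gibbs_gaussian(design, ainv, config, priors, ...)
  new_do_fit("LM", chain, design)
}

#' Penalized linear model (PLM)
#'
#' Imputes every censored record by [impute_penalty()] and fits the same
#' Gaussian animal model as [fit_lm()] on the completed data.
#'
#' @inheritParams fit_lm
#' @param penalty penalty constant in days.
#' @return a `do_fit`.
#' @export
fit_plm <- function(records, ped, config = chain_config(),
                    priors = variance_priors(), penalty = 21, ...) {
  aug <- impute_penalty(records, penalty)
  y <- ifelse(aug$censored, aug$imputed_do, aug$do)
  design <- build_design(aug, ped, y = y)
  ainv <- build_A_inverse(ped)
  chain <- gibbs_gaussian(design, ainv, config, priors, ...)
  new_do_fit("PLM", chain, design, list(penalty = penalty))
}

#' Penalized threshold-linear model (PTM)
#'
#' Bivariate Bayesian model: trait one is days open (observed records plus
#' penalty-imputed censored records, identical to the PLM values); trait
#' two is the censorship status modelled through a latent Gaussian
#' liability with threshold 0 (liability > 0 for censored records),
#' redrawn from its truncated-normal full conditional at every iteration.
#' Both traits share the fixed-effect structure (HYS, parity, the two
#' covariates) and carry additive genetic and permanent-environment
#' effects with unstructured 2x2 covariance matrices sampled from
#' inverse-Wishart full conditionals; the residual covariance is sampled
#' with the liability residual variance fixed at 1 for identifiability.
#'
#' @inheritParams fit_plm
#' @param resample_censored also redraw the days-open value of censored
#'   records from a normal truncated above the recorded lower bound
#'   (default `FALSE`: the penalty-imputed values are held fixed).
#' @param store_liabilities store the thinned liability draws (used to
#'   verify the sign constraint).
#' @param store_effects store thinned draws of all location effects.
#' @return a `do_fit`; `ebv` holds the days-open breeding values and
#'   `ebv_liability` the auxiliary liability-trait breeding values.
#' @export
fit_ptm <- function(records, ped, config = chain_config(),
                    priors = variance_priors(), penalty = 21,
                    resample_censored = FALSE, store_liabilities = FALSE,
                    store_effects = FALSE) {
  stopifnot(inherits(config, "chain_config"))
  n_cens <- sum(records$censored)
  if (n_cens == 0L || n_cens == nrow(records))
    stop("the censorship trait is degenerate (", n_cens, " of ",
         nrow(records), " records censored); use fit_lm()/fit_plm() instead")
  aug <- impute_penalty(records, penalty)
  y <- ifelse(aug$censored, aug$imputed_do, aug$do)
  design <- build_design(aug, ped, y = y)
  ainv <- build_A_inverse(ped)
  if (design$n_u + priors$nu_u < 2 || design$n_pe + priors$nu_pe < 2)
    stop("too few levels for the inverse-Wishart covariance updates")

  if (!is.null(config$seed)) set.seed(config$seed)
  M <- csc(Matrix::crossprod(design$W))
  Wt <- csc(Matrix::t(design$W))
  A <- csc(ainv)
  vy <- stats::var(design$y)
  res <- gibbs_threshold_cpp(
    M$i, M$p, M$x, Wt$i, Wt$p, Wt$x, A$i, A$p, A$x,
    design$y, as.integer(aug$censored),
    as.numeric(ifelse(aug$censored, aug$do, -Inf)), resample_censored,
    design$nf, design$n_u, design$n_pe,
    c(0.2 * vy, 0, 0.2), c(0.2 * vy, 0, 0.2), 0.6 * vy,
    c(priors$nu_u, priors$nu_pe, priors$nu_e),
    c(priors$s_u, priors$s_pe, priors$s_e),
    config$n_iter, config$burn_in, config$thin,
    store_effects, store_liabilities)

  colnames(res$draws) <- c("sigma_u2", "sigma_u_l", "sigma_u2_l",
                           "sigma_pe2", "sigma_pe_l", "sigma_pe2_l",
                           "sigma_e2", "sigma_e_l",
                           "h2", "h2_liability", "r_g")
  ptot <- design$nf + design$n_u + design$n_pe
  labels <- c(design$fixed_labels, design$animal_labels,
              design$animal_labels[design$pe_animal])
  effects <- data.frame(
    type = rep(rep(c("fixed", "u", "pe"),
                   c(design$nf, design$n_u, design$n_pe)), 2L),
    trait = rep(c("do", "liability"), each = ptot),
    label = rep(labels, 2L),
    mean = res$effect_mean, sd = res$effect_sd, stringsAsFactors = FALSE)
  chain <- structure(list(draws = res$draws,
                          effects = effects[effects$trait == "do", -2L],
                          effects_liability =
                            effects[effects$trait == "liability", -2L],
                          effect_draws = if (store_effects) res$effect_draws,
                          liability_draws =
                            if (store_liabilities) res$liability_draws,
                          config = config, model = "threshold-linear"),
                     class = "posterior_chain")
  fit <- new_do_fit("PTM", chain, design,
                    list(penalty = penalty,
                         ebv_liability = ebv_table(chain$effects_liability,
                                                   design, "PTM_liability")))
  fit
}

#' Fit one or more censoring treatments
#'
#' @param records edited records.
#' @param ped a `pedigree`.
#' @param models subset of `c("LM", "PLM", "PTM")`.
#' @param config a [chain_config()]; each model gets a seed derived from
#'   `config$seed` so runs are reproducible and models independent.
#' @param ... passed to the individual `fit_*` functions.
#' @return named list of `do_fit` objects.
#' @export
fit_models <- function(records, ped, models = c("LM", "PLM", "PTM"),
                       config = chain_config(), ...) {
  models <- match.arg(models, several.ok = TRUE)
  fits <- list()
  for (m in models) {
    cfg <- config
    if (!is.null(config$seed))
      cfg$seed <- config$seed + match(m, c("LM", "PLM", "PTM"))
    fits[[m]] <- switch(m,
      LM = fit_lm(records, ped, cfg, ...),
      PLM = fit_plm(records, ped, cfg, ...),
      PTM = fit_ptm(records, ped, cfg, ...))
  }
  fits
}
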