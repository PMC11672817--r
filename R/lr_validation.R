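#' Whole/partial validation split
#'
#' Builds the LR-method split: the validation set contains the phenotyped
#' cows born in `cutoff_year` or later, and the partial dataset is the
#' whole dataset with the phenotypes of those cows removed (the pedigree is
#' untouched, so validation animals keep their relationship links in the
#' partial fit).
#'
#' @param records edited records with a `birth_date` column.
#' @param cutoff_year first birth year of the validation cohort.
#' @return list with `whole`, `partial` (data frames of records) and
#'   `validation` (character vector of validation cow ids).
#' @export
make_split <- function(records, cutoff_year = 2020) {
  if (!"birth_date" %in% names(records))
    stop("records carry no 'birth_date' column")
  by <- as.integer(format(as.Date(records$birth_date), "%Y"))
  vcows <- unique(as.character(records$cow_id[!is.na(by) & by >= cutoff_year]))
  if (length(vcows) == 0L)
    stop("empty validation set: no phenotyped animal born in ",
         cutoff_year, " or later")
  partial <- records[!as.character(records$cow_id) %in% vcows, ]
  if (nrow(partial) == 0L)
    stop("empty partial dataset: every phenotyped animal is in the ",
         "validation set")
  partial$hys <- droplevels(factor(partial$hys))
  list(whole = records, partial = partial, validation = vcows)
}

align_ebv <- function(ebv_whole, ebv_partial, validation) {
  w <- if (is.data.frame(ebv_whole)) stats::setNames(ebv_whole$ebv, ebv_whole$animal) else ebv_whole
  p <- if (is.data.frame(ebv_partial)) stats::setNames(ebv_partial$ebv, ebv_partial$animal) else ebv_partial
  if (!is.null(validation)) {
    miss <- setdiff(as.character(validation), intersect(names(w), names(p)))
    if (length(miss))
      stop("EBVs missing for validation animal(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
    w <- w[as.character(validation)]
    p <- p[as.character(validation)]
  } else if (!is.null(names(w)) && !is.null(names(p))) {
    common <- intersect(names(w), names(p))
    w <- w[common]; p <- p[common]
  }
  if (length(w) != length(p)) stop("EBV vectors have different lengths")
  list(w = unname(w), p = unname(p))
}

#' LR-method accuracy
#'
#' `sqrt( cov(u_w, u_p) / ((1 - Fbar) * sigma_a2) )` over the validation
#' animals, where `u_w` and `u_p` are the whole- and partial-data EBVs,
#' `Fbar` the mean inbreeding of the validation set and `sigma_a2` the
#' estimated additive genetic variance of the model under study. A negative
#' covariance makes the accuracy undefined; `NaN` is returned with a
#' warning. [acc_lr_squared()] returns the unrooted ratio.
#'
#' @param ebv_whole,ebv_partial named EBV vectors (or `do_fit$ebv` data
#'   frames) from the whole and partial evaluations.
#' @param validation animal ids of the validation set (`NULL` = use the
#'   vectors as given).
#' @param F_bar mean inbreeding coefficient of the validation set.
#' @param sigma_a2 additive genetic variance used for scaling.
#' @return scalar accuracy.
#' @export
acc_lr <- function(ebv_whole, ebv_partial, validation = NULL, F_bar = 0,
                   sigma_a2) {
  if (sigma_a2 <= 0) stop("sigma_a2 must be positive")
  if (F_bar < 0 || F_bar >= 1) stop("F_bar must lie in [0, 1)")
  r2 <- acc_lr_squared(ebv_whole, ebv_partial, validation, F_bar, sigma_a2)
  if (is.nan(r2)) return(NaN)
  sqrt(r2)
}

#' @rdname acc_lr
#' @export
acc_lr_squared <- function(ebv_whole, ebv_partial, validation = NULL,
                           F_bar = 0, sigma_a2) {
  v <- align_ebv(ebv_whole, ebv_partial, validation)
  cv <- stats::cov(v$w, v$p)
  if (cv < 0) {
    warning("negative covariance between whole and partial EBVs; ",
            "LR accuracy undefined (NaN)")
    return(NaN)
  }
  cv / ((1 - F_bar) * sigma_a2)
}

#' LR-method bias
#'
#' Difference between the mean partial-data and mean whole-data EBV of the
#' validation animals, `mean(u_p) - mean(u_w)`, in trait units (days).
#'
#' @inheritParams acc_lr
#' @return scalar bias (days).
#' @export
bias_lr <- function(ebv_whole, ebv_partial, validation = NULL) {
  v <- align_ebv(ebv_whole, ebv_partial, validation)
  mean(v$p) - mean(v$w)
}

#' LR-method dispersion
#'
#' Slope of the regression of the whole-data EBVs on the partial-data EBVs
#' of the validation animals, `cov(u_w, u_p) / var(u_p)`; 1 means no
#' over- or under-dispersion of the partial evaluation.
#'
#' @inheritParams acc_lr
#' @return scalar slope.
#' @export
dispersion_lr <- function(ebv_whole, ebv_partial, validation = NULL) {
  v <- align_ebv(ebv_whole, ebv_partial, validation)
  vp <- stats::var(v$p)
  if (vp == 0) stop("partial EBVs are constant; dispersion slope undefined")
  stats::cov(v$w, v$p) / vp
}

#' Rank agreement between two evaluations
#'
#' Spearman rank correlation (average ranks for ties) and the percentage of
#' common animals among the top fraction of each list. For days open the
#' favourable direction is a short interval, so the "top" animals are those
#' with the smallest EBVs by default. The top-list size is
#' `ceiling(fraction * n)`; boundary ties are broken by animal id so the
#' result is deterministic.
#'
#' @param ebv_a,ebv_b named EBV vectors or `do_fit$ebv` data frames.
#' @param validation optional subset of animal ids.
#' @param top_fraction fraction of animals in the top list.
#' @param lower_is_better `TRUE` when small EBVs are favourable.
#' @return list with `spearman` and `overlap_pct`.
#' @export
rank_agreement <- function(ebv_a, ebv_b, validation = NULL,
                           top_fraction = 0.20, lower_is_better = TRUE) {
  v <- align_ebv(ebv_a, ebv_b, validation)
  n <- length(v$w)
  rho <- stats::cor(v$w, v$p, method = "spearman")
  k <- ceiling(top_fraction * n)
  ids <- if (!is.null(validation)) as.character(validation) else
    as.character(seq_len(n))
  sgn <- if (lower_is_better) 1 else -1
  top_a <- ids[order(sgn * v$w, ids)][seq_len(k)]
  top_b <- ids[order(sgn * v$p, ids)][seq_len(k)]
  list(spearman = rho,
       overlap_pct = 100 * length(intersect(top_a, top_b)) / k)
}

#' LR-method validation of the censoring treatments
#'
#' Runs the full cross-validation: fits each requested model on the whole
#' and on the partial dataset (phenotypes of cows born in `cutoff_year` or
#' later removed), then computes the LR accuracy (rooted and unrooted,
#' scaled by each model's own posterior-mean genetic variance from the
#' whole fit), bias and dispersion over the validation animals, and the
#' pairwise Spearman / top-overlap agreement between the models'
#' whole-data EBVs of the validation animals.
#'
#' @param records edited records.
#' @param ped a `pedigree`.
#' @param models subset of `c("LM", "PLM", "PTM")`.
#' @param config a [chain_config()].
#' @param cutoff_year first birth year of the validation cohort.
#' @param top_fraction fraction for the top-overlap statistic.
#' @param lower_is_better direction of merit for the top list.
#' @param ... passed to the `fit_*` functions.
#' @return an `lr_report`: per-model statistics, the agreement matrices
#'   (`spearman`, `overlap_pct`), `F_bar`, the validation size, and the
#'   underlying fits.
#' @export
lr_validate <- function(records, ped, models = c("LM", "PLM", "PTM"),
                        config = chain_config(), cutoff_year = 2020,
                        top_fraction = 0.20, lower_is_better = TRUE, ...) {
  split <- make_split(records, cutoff_year)
  f_bar <- mean_inbreeding(ped, split$validation)
  fits_w <- fit_models(split$whole, ped, models, config, ...)
  cfg_p <- config
  if (!is.null(config$seed)) cfg_p$seed <- config$seed + 100L
  fits_p <- fit_models(split$partial, ped, models, cfg_p, ...)

  stats <- lapply(models, function(m) {
    sa2 <- mean(fits_w[[m]]$chain$draws[, "sigma_u2"])
    list(model = m,
         acc = acc_lr(fits_w[[m]]$ebv, fits_p[[m]]$ebv, split$validation,
                      f_bar, sa2),
         acc_squared = acc_lr_squared(fits_w[[m]]$ebv, fits_p[[m]]$ebv,
                                      split$validation, f_bar, sa2),
         bias = bias_lr(fits_w[[m]]$ebv, fits_p[[m]]$ebv, split$validation),
         dispersion = dispersion_lr(fits_w[[m]]$ebv, fits_p[[m]]$ebv,
                                    split$validation),
         sigma_a2 = sa2)
  })
  names(stats) <- models

  k <- length(models)
  spearman <- matrix(1, k, k, dimnames = list(models, models))
  overlap <- matrix(100, k, k, dimnames = list(models, models))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    ra <- rank_agreement(fits_w[[models[i]]]$ebv, fits_w[[models[j]]]$ebv,
                         split$validation, top_fraction, lower_is_better)
    spearman[i, j] <- ra$spearman
    overlap[i, j] <- ra$overlap_pct
  }

  structure(list(stats = stats, spearman = spearman, overlap_pct = overlap,
                 F_bar = f_bar, n_validation = length(split$validation),
                 cutoff_year = cutoff_year, top_fraction = top_fraction,
                 fits_whole = fits_w, fits_partial = fits_p),
            class = "lr_report")
}

#' @export
print.lr_report <- function(x, ...) {
  cat("LR-method validation:", x$n_validation, "validation animals (born >=",
      x$cutoff_year, "), mean F =", round(x$F_bar, 4), "\n")
  tab <- do.call(rbind, lapply(x$stats, function(s)
    c(acc = s$acc, bias = s$bias, dispersion = s$dispersion)))
  print(round(tab, 3))
  cat("Spearman (above diagonal) / top-",
      100 * x$top_fraction, "% overlap (below):\n", sep = "")
  m <- x$spearman
  m[lower.tri(m)] <- x$overlap_pct[lower.tri(m)]
  print(round(m, 2))
  invisible(x)
}

#' Write an LR report as CSV
#'
#' One table with the accuracy/bias/dispersion rows per model followed by
#' the agreement matrix (Spearman above the diagonal, top-overlap
#' percentage below).
#'
#' @param report an `lr_report`.
#' @param path output CSV path.
#' @export
write_lr_report <- function(report, path) {
  stat_rows <- rbind(
    acc_lr = vapply(report$stats, function(s) s$acc, numeric(1)),
    bias_lr = vapply(report$stats, function(s) s$bias, numeric(1)),
    dispersion_lr = vapply(report$stats, function(s) s$dispersion, numeric(1)))
  agree <- report$spearman
  agree[lower.tri(agree)] <- report$overlap_pct[lower.tri(agree)]
  diag(agree) <- NA
  out <- rbind(stat_rows, agree)
  utils::write.csv(data.frame(statistic = rownames(out), out,
                              check.names = FALSE), path, row.names = FALSE)
  invisible(path)
}
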