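#' Variance components of the repeatability animal model
#'
#' @param sigma_u2 additive genetic variance (days^2).
#' @param sigma_pe2 permanent-environment variance (days^2).
#' @param sigma_e2 residual variance (days^2).
#' @return list of class `variance_components`.
#' @export
variance_components <- function(sigma_u2, sigma_pe2, sigma_e2) {
  if (any(c(sigma_u2, sigma_pe2, sigma_e2) <= 0))
    stop("all variance components must be strictly positive")
  structure(list(sigma_u2 = sigma_u2, sigma_pe2 = sigma_pe2,
                 sigma_e2 = sigma_e2), class = "variance_components")
}

#' Heritability
#'
#' `h2 = sigma_u2 / (sigma_u2 + sigma_pe2 + sigma_e2)`: the denominator is
#' the full phenotypic variance of the repeatability model, including the
#' permanent-environment component.
#'
#' @param vc a [variance_components()] object, or the additive variance when
#'   the three components are given as separate numbers.
#' @param sigma_pe2,sigma_e2 remaining components when `vc` is numeric.
#' @return scalar heritability in (0, 1).
#' @export
heritability <- function(vc, sigma_pe2 = NULL, sigma_e2 = NULL) {
  if (is.numeric(vc)) vc <- variance_components(vc, sigma_pe2, sigma_e2)
  total <- vc$sigma_u2 + vc$sigma_pe2 + vc$sigma_e2
  if (total <= 0) stop("total variance must be positive")
  vc$sigma_u2 / total
}

#' Assemble the design structure of the animal model
#'
#' Builds the incidence matrices of
#' `y = X beta + Z u + W pe + e`:
#' fixed effects are the HYS contemporary group (one column per level; the
#' HYS block absorbs the intercept), parity (drop-first treatment
#' contrasts) and the two linear covariates age at calving and days in milk
#' at first insemination (centred); `u` spans every animal in the pedigree;
#' `pe` spans the phenotyped cows.
#'
#' @param records edited records (must carry `hys`; see [edit_records()]).
#' @param ped a `pedigree` containing every cow in `records`.
#' @param y response values; defaults to `records$do`.
#' @return list of class `do_design` with sparse `X`, `Z`, `Wpe`, the
#'   combined incidence matrix `W = cbind(X, Z, Wpe)`, the response `y`,
#'   block sizes `nf`, `n_u`, `n_pe`, and level bookkeeping.
#' @export
build_design <- function(records, ped, y = records$do) {
  stopifnot(inherits(ped, "pedigree"))
  if (!"hys" %in% names(records))
    stop("records carry no 'hys' column; run edit_records() first")
  uidx <- match(as.character(records$cow_id), ped$label)
  if (anyNA(uidx))
    stop("cow(s) missing from pedigree: ",
         paste(unique(records$cow_id[is.na(uidx)]), collapse = ", "))
  n <- nrow(records)
  if (length(y) != n) stop("response length does not match records")
  if (anyNA(y)) stop("response contains missing values")

  hys <- droplevels(factor(records$hys))
  parity <- factor(records$parity)
  age_c <- as.numeric(records$age_at_calving)
  dim_c <- as.numeric(records$dim_first_ai)
  centers <- c(age_at_calving = mean(age_c), dim_first_ai = mean(dim_c))
  age_c <- age_c - centers[1]
  dim_c <- dim_c - centers[2]

  Xh <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(hys),
                             x = 1, dims = c(n, nlevels(hys)))
  parts <- list(Xh)
  fixed_labels <- paste0("hys_", levels(hys))
  if (nlevels(parity) > 1L) {
    Xp <- Matrix::sparseMatrix(
      i = which(as.integer(parity) > 1L),
      j = as.integer(parity)[as.integer(parity) > 1L] - 1L,
      x = 1, dims = c(n, nlevels(parity) - 1L))
    parts <- c(parts, list(Xp))
    fixed_labels <- c(fixed_labels, paste0("parity_", levels(parity)[-1L]))
  }
  covs <- cbind(age_at_calving = age_c, dim_first_ai = dim_c)
  keep_cov <- apply(covs, 2, function(v) any(v != 0)) # constant -> dropped
  if (any(keep_cov)) {
    parts <- c(parts, list(Matrix::Matrix(covs[, keep_cov, drop = FALSE],
                                          sparse = TRUE)))
    fixed_labels <- c(fixed_labels, colnames(covs)[keep_cov])
  }
  X <- do.call(cbind, parts)

  Z <- Matrix::sparseMatrix(i = seq_len(n), j = uidx, x = 1,
                            dims = c(n, nrow(ped)))
  cows <- sort(unique(uidx))
  Wpe <- Matrix::sparseMatrix(i = seq_len(n), j = match(uidx, cows), x = 1,
                              dims = c(n, length(cows)))

  structure(list(
    X = X, Z = Z, Wpe = Wpe, W = cbind(X, Z, Wpe),
    y = as.numeric(y),
    nf = ncol(X), n_u = nrow(ped), n_pe = length(cows),
    fixed_labels = fixed_labels,
    animal_labels = ped$label,
    pe_animal = cows,            # internal pedigree id per pe level
    record_animal = uidx,
    centers = centers
  ), class = "do_design")
}

#' @export
print.do_design <- function(x, ...) {
  cat("Animal-model design:", length(x$y), "records;",
      x$nf, "fixed-effect columns,", x$n_u, "animals,",
      x$n_pe, "permanent-environment levels\n")
  invisible(x)
}

#' Solve Henderson's mixed-model equations
#'
#' Deterministic BLUP at fixed variance ratios, used as the reference
#' solution for the Gibbs sampler: solves
#' `(W'W + blockdiag(0, lambda_u A^-1, lambda_pe I)) theta = W'y`
#' with `lambda_u = sigma_e2/sigma_u2` and `lambda_pe = sigma_e2/sigma_pe2`.
#'
#' @param design a [build_design()] object.
#' @param ainv sparse A-inverse from [build_A_inverse()].
#' @param vc a [variance_components()] object.
#' @return list with `beta`, `u`, `pe` (named solution vectors) and the
#'   relative residual of the normal equations.
#' @export
solve_mme <- function(design, ainv, vc) {
  stopifnot(inherits(design, "do_design"), inherits(vc, "variance_components"))
  lu <- vc$sigma_e2 / vc$sigma_u2
  lpe <- vc$sigma_e2 / vc$sigma_pe2
  C <- Matrix::crossprod(design$W) +
    Matrix::bdiag(Matrix::Diagonal(design$nf, 0),
                  lu * ainv,
                  Matrix::Diagonal(design$n_pe, lpe))
  rhs <- Matrix::crossprod(design$W, design$y)
  sol <- tryCatch(
    as.numeric(Matrix::solve(C, rhs)),
    error = function(e) stop("mixed-model equations are singular; the fixed-",
                             "effect block likely needs a constraint (",
                             conditionMessage(e), ")")
  )
  resid <- as.numeric(C %*% sol - rhs)
  relres <- sqrt(sum(resid^2)) / max(sqrt(sum(rhs^2)), 1e-300)
  beta <- sol[seq_len(design$nf)]
  names(beta) <- design$fixed_labels
  u <- sol[design$nf + seq_len(design$n_u)]
  names(u) <- design$animal_labels
  pe <- sol[design$nf + design$n_u + seq_len(design$n_pe)]
  names(pe) <- design$animal_labels[design$pe_animal]
  list(beta = beta, u = u, pe = pe, rel_residual = relres)
}
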