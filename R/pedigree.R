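#' Read a pedigree file
#'
#' Reads a whitespace- or comma-delimited pedigree file with columns
#' animal, sire, dam (in that order; extra columns are ignored). Unknown
#' parents are coded `0` (empty fields and `NA` are treated the same way).
#' A header line is auto-detected. Parents that appear only in the sire or
#' dam column are added as founders. Animals are renumbered to dense
#' internal ids `1..n` in topological order (parents before progeny); the
#' original labels are retained in the `label` column so external ids round
#' trip losslessly.
#'
#' @param path path to the pedigree file.
#' @return a `pedigree` object; see [as_pedigree()].
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  peek <- utils::read.table(path, sep = sep, header = FALSE, nrows = 1L,
                            colClasses = "character", strip.white = TRUE)
  if (ncol(peek) < 3L)
    stop("pedigree file must have at least 3 columns (animal, sire, dam)")
  has_header <- suppressWarnings(anyNA(as.numeric(unlist(peek[1L, 1:3]))))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          colClasses = "character", strip.white = TRUE)
  names(df)[1:3] <- c("animal", "sire", "dam")
  as_pedigree(df[, 1:3])
}

#' Build a pedigree object
#'
#' Validates, topologically orders and renumbers a pedigree given as animal /
#' sire / dam triples. The result underlies the numerator relationship
#' matrix A of the animal model: internal ids are dense `1..n`, every known
#' parent precedes its progeny, and unknown parents are coded `0` (treated
#' as unrelated, non-inbred base-population individuals; no genetic groups).
#'
#' @param df data frame whose first three columns are animal, sire and dam
#'   identifiers (any atomic type; `0`, `""` and `NA` mean unknown parent).
#' @return a data frame of class `pedigree` with columns `id`, `sire`,
#'   `dam` (internal ids, `0` = unknown), `label` (original id as character)
#'   and `founder`. Extra columns of `df` are carried through.
#' @details Duplicate animal ids and pedigree cycles (including an animal
#'   listed as its own ancestor) are hard errors; the cycle error names the
#'   offending animals. Ordering uses an iterative Kahn sort, so arbitrarily
#'   deep pedigrees do not overflow the call stack.
#' @export
as_pedigree <- function(df) {
  df <- as.data.frame(df)
  an <- as.character(df[[1]])
  si <- as.character(df[[2]])
  da <- as.character(df[[3]])
  unk <- function(x) is.na(x) | x == "0" | x == ""
  si[unk(si)] <- NA_character_
  da[unk(da)] <- NA_character_
  if (anyDuplicated(an))
    stop("duplicate animal id(s): ",
         paste(unique(an[duplicated(an)]), collapse = ", "))
  extra <- setdiff(c(si, da), c(an, NA_character_))
  if (length(extra)) { # parents without their own row become founders
    an <- c(an, extra)
    si <- c(si, rep(NA_character_, length(extra)))
    da <- c(da, rep(NA_character_, length(extra)))
  }
  n <- length(an)
  sidx <- match(si, an)
  didx <- match(da, an)

  # iterative Kahn topological sort
  indeg <- (!is.na(sidx)) + (!is.na(didx))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sidx[i], didx[i])) {
      if (!is.na(p)) {
        if (p == i) stop("pedigree cycle detected involving animal(s): ", an[i])
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order_out <- integer(n)
  queue <- which(indeg == 0L)
  head <- 1L; filled <- 0L
  while (length(queue) >= head) {
    v <- queue[head]; head <- head + 1L
    filled <- filled + 1L
    order_out[filled] <- v
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (filled < n) {
    stop("pedigree cycle detected involving animal(s): ",
         paste(an[indeg > 0L], collapse = ", "))
  }

  newid <- integer(n)
  newid[order_out] <- seq_len(n)
  out <- data.frame(
    id = seq_len(n),
    sire = ifelse(is.na(sidx[order_out]), 0L, newid[sidx[order_out]]),
    dam = ifelse(is.na(didx[order_out]), 0L, newid[didx[order_out]]),
    label = an[order_out],
    founder = is.na(sidx[order_out]) & is.na(didx[order_out]),
    stringsAsFactors = FALSE
  )
  if (ncol(df) > 3L) {
    extra_rows <- match(out$label, as.character(df[[1]]))
    for (cn in names(df)[-(1:3)]) out[[cn]] <- df[[cn]][extra_rows]
  }
  class(out) <- c("pedigree", "data.frame")
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "animals,", sum(x$founder), "founders\n")
  invisible(x)
}

#' Map original animal labels to internal pedigree ids
#'
#' @param ped a `pedigree`.
#' @param labels original animal identifiers.
#' @return integer internal ids (error if any label is unknown).
#' @export
pedigree_id <- function(ped, labels) {
  idx <- match(as.character(labels), ped$label)
  if (anyNA(idx))
    stop("animal(s) not in pedigree: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  ped$id[idx]
}

#' Inbreeding coefficients
#'
#' Computes the per-animal inbreeding coefficient F (half the additive
#' relationship between an animal's parents) by the Meuwissen-Luo
#' path-tracing algorithm; equals `diag(A) - 1` of the numerator
#' relationship matrix. Founders and animals with an unknown parent path get
#' the base-population value 0 contribution from that path.
#'
#' @param ped a `pedigree`.
#' @return numeric vector of F, one per animal in internal id order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  f <- inbreeding_cpp(as.integer(ped$sire), as.integer(ped$dam))
  names(f) <- ped$label
  f
}

#' Mean inbreeding of a subset of animals
#'
#' Arithmetic mean of the inbreeding coefficients over a subset, as used in
#' the denominator of the LR-method accuracy.
#'
#' @param ped a `pedigree`.
#' @param subset animal labels (or internal ids given as integers matching
#'   `ped$id`) defining the subset.
#' @return scalar mean F.
#' @export
mean_inbreeding <- function(ped, subset) {
  if (length(subset) == 0L) stop("subset of animals is empty")
  f <- inbreeding(ped)
  if (is.numeric(subset) && all(subset == floor(subset))) {
    if (any(subset < 1L | subset > nrow(ped))) stop("internal id out of range")
    mean(f[subset])
  } else {
    mean(f[pedigree_id(ped, subset)])
  }
}

#' Dense numerator relationship matrix (tabular method)
#'
#' Builds A by the tabular recursions: `a_ii = 1 + 0.5 a(s_i, d_i)` and
#' `a_ij = 0.5 (a(j, s_i) + a(j, d_i))`. Intended as a debugging / oracle
#' path for small pedigrees; model fitting uses the sparse inverse from
#' [build_A_inverse()].
#'
#' @param ped a `pedigree`.
#' @param max_n size guard; pedigrees larger than this refuse to build a
#'   dense matrix.
#' @return dense symmetric matrix with `dimnames` = animal labels.
#' @export
build_A <- function(ped, max_n = 5000L) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  if (n > max_n)
    stop("pedigree has ", n, " animals (> ", max_n,
         "); use build_A_inverse() for model fitting instead of a dense A")
  A <- build_A_cpp(as.integer(ped$sire), as.integer(ped$dam))
  dimnames(A) <- list(ped$label, ped$label)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with the inbreeding adjustment: each animal contributes
#' `alpha_i = 1/d_i` to the inverse, where the Mendelian-sampling variance
#' fraction is `d_i = 0.5 - 0.25 (F_s + F_d)` for two known parents,
#' `0.75 - 0.25 F_p` for one, and 1 for founders.
#'
#' @param ped a `pedigree`.
#' @param f inbreeding coefficients from [inbreeding()]; recomputed when
#'   missing.
#' @return a sparse symmetric `Matrix::dgCMatrix` A-inverse.
#' @export
build_A_inverse <- function(ped, f = inbreeding(ped)) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  s <- ped$sire
  d <- ped$dam
  fs <- ifelse(s > 0L, f[pmax(s, 1L)], -1)
  fd <- ifelse(d > 0L, f[pmax(d, 1L)], -1)
  alpha <- 1 / (0.5 - 0.25 * (fs + fd))

  i <- seq_len(n); ii <- i
  ti <- i; tj <- i; tx <- alpha                       # (i, i) += alpha
  ks <- which(s > 0L)
  kd <- which(d > 0L)
  ti <- c(ti, ks, s[ks]);  tj <- c(tj, s[ks], ks)     # (i, s), (s, i) -= a/2
  tx <- c(tx, rep(-alpha[ks] / 2, 2L))
  ti <- c(ti, kd, d[kd]);  tj <- c(tj, d[kd], kd)
  tx <- c(tx, rep(-alpha[kd] / 2, 2L))
  ti <- c(ti, s[ks], d[kd]); tj <- c(tj, s[ks], d[kd]) # (s, s), (d, d) += a/4
  tx <- c(tx, alpha[ks] / 4, alpha[kd] / 4)
  kb <- which(s > 0L & d > 0L)                        # (s, d), (d, s) += a/4
  ti <- c(ti, s[kb], d[kb]); tj <- c(tj, d[kb], s[kb])
  tx <- c(tx, rep(alpha[kb] / 4, 2L))

  methods::as(
    Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n)),
    "generalMatrix"
  )
}
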