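# Independent oracles, implemented from first principles so they share no
# code path with the package internals.

# additive relationship matrix by memoized recursion on kinship:
# a(i,i) = 1 + 0.5 a(s_i, d_i); a(i,j) = 0.5 (a(s_i, j) + a(d_i, j)), i > j.
oracle_A <- function(sire, dam) {
  n <- length(sire)
  A <- matrix(NA_real_, n, n)
  rel <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i < j) { tmp <- i; i <- j; j <- tmp }
    if (!is.na(A[i, j])) return(A[i, j])
    v <- if (i == j) {
      1 + 0.5 * rel(sire[i], dam[i])
    } else {
      0.5 * (rel(sire[i], j) + rel(dam[i], j))
    }
    A[i, j] <<- v
    A[j, i] <<- v
    v
  }
  for (i in seq_len(n)) for (j in seq_len(i)) rel(i, j)
  A
}

# random topologically ordered pedigree: each animal's parents (possibly
# unknown) are drawn among earlier animals
random_pedigree <- function(n, n_founders = max(3L, n %/% 5L),
                            p_unknown = 0.1) {
  sire <- dam <- integer(n)
  for (i in seq_len(n)) {
    if (i <= n_founders) next
    pool <- seq_len(i - 1L)
    sire[i] <- if (stats::runif(1) < p_unknown) 0L else sample(pool, 1L)
    dam[i] <- if (stats::runif(1) < p_unknown) 0L else sample(pool, 1L)
  }
  ped_df <- data.frame(animal = seq_len(n), sire = sire, dam = dam)
  as_pedigree(ped_df)
}

# minimal editable phenotype frame; defaults pass every editing rule
toy_records <- function(n = 6, cow_id = seq_len(n), herd = 1,
                        calving_date = as.Date("2021-04-10") + seq_len(n),
                        birth_date = as.Date("2019-01-01"),
                        parity = 1, age_at_calving = 800,
                        dim_first_ai = 75, do = 120, censored = FALSE) {
  data.frame(cow_id = cow_id, herd = herd, calving_date = calving_date,
             birth_date = birth_date, parity = parity,
             age_at_calving = age_at_calving, dim_first_ai = dim_first_ai,
             do = do, censored = censored, stringsAsFactors = FALSE)
}

# records pre-annotated with an hys column (skipping edit_records)
toy_records_hys <- function(...) {
  r <- toy_records(...)
  r$season <- assign_season(r$calving_date)
  r$hys <- interaction(r$herd, format(r$calving_date, "%Y"), r$season,
                       drop = TRUE, sep = "_")
  r
}
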