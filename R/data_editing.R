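#' Read a phenotype file
#'
#' Reads the phenotype CSV with named header columns `cow_id`, `herd`,
#' `calving_date`, `birth_date`, `parity`, `age_at_calving`,
#' `dim_first_ai`, `do` and optionally `conception_date` and `censored`.
#' Dates must be ISO-8601 (`YYYY-MM-DD`); anything else is a hard error.
#' Missing values are empty fields.
#'
#' @param path path to the CSV file.
#' @return data frame of phenotype records.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  required <- c("cow_id", "herd", "calving_date", "parity",
                "age_at_calving", "dim_first_ai")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("phenotype file lacks column(s): ", paste(missing_cols, collapse = ", "))
  for (dc in intersect(c("calving_date", "birth_date", "conception_date"),
                       names(df))) {
    df[[dc]] <- parse_iso_date(df[[dc]], dc)
  }
  if ("censored" %in% names(df)) df$censored <- as.logical(df$censored)
  df
}

parse_iso_date <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- !is.na(x) & (is.na(out) | format(out, "%Y-%m-%d") != x)
  if (any(bad))
    stop("non ISO-8601 date(s) in ", what, ": ",
         paste(utils::head(unique(x[bad]), 5L), collapse = ", "))
  out
}

#' Season of calving
#'
#' Month-based season classes used in the herd-year-season contemporary
#' group: winter = December-February, spring = March-May, summer =
#' June-August, fall = September-November. The year of the contemporary
#' group key remains the calving year (a December calving belongs to the
#' winter season of its own calendar year).
#'
#' @param calving_date `Date` vector.
#' @return factor with levels `winter`, `spring`, `summer`, `fall`.
#' @export
assign_season <- function(calving_date) {
  m <- as.integer(format(as.Date(calving_date), "%m"))
  s <- c("winter", "winter", rep("spring", 3), rep("summer", 3),
         rep("fall", 3), "winter")[m]
  factor(s, levels = c("winter", "spring", "summer", "fall"))
}

#' Flag right-censored records
#'
#' A days-open record is censored when no pregnancy is confirmed by either a
#' conception date or a subsequent calving of the same cow. When a
#' `censored` column is already present (e.g. written by the simulator) it
#' is kept as-is. When `do` is missing but a conception date exists, days
#' open is derived as conception minus calving date.
#'
#' @param records phenotype data frame.
#' @return `records` with logical column `censored` (and `do` filled in
#'   where derivable).
#' @export
flag_censored <- function(records) {
  if (!"censored" %in% names(records) || all(is.na(records$censored))) {
    has_conception <- if ("conception_date" %in% names(records)) {
      !is.na(records$conception_date)
    } else {
      rep(FALSE, nrow(records))
    }
    # a later calving of the same cow also confirms the pregnancy
    later <- rep(FALSE, nrow(records))
    if (all(c("cow_id", "calving_date") %in% names(records))) {
      last_calving <- stats::ave(as.numeric(records$calving_date),
                                 records$cow_id, FUN = max)
      later <- as.numeric(records$calving_date) < last_calving
    }
    records$censored <- !(has_conception | later)
  }
  if ("conception_date" %in% names(records)) {
    derivable <- (!records$censored) & is.na(records$do) &
      !is.na(records$conception_date)
    records$do[derivable] <- as.numeric(
      records$conception_date[derivable] - records$calving_date[derivable])
  }
  records
}

#' Editing configuration
#'
#' @param min_do minimum days open for an uncensored record (days).
#' @param min_first_calving_age cows calving for the first time younger than
#'   this (days) are removed entirely.
#' @param sd_mult multiplier of the standard deviation for the outlier
#'   filters (covariates: mean + k SD; days open: mean +/- k SD within
#'   parity).
#' @param min_cg_size minimum contemporary-group size.
#' @param max_parity highest parity retained.
#' @param covariate_filter_by_parity apply the covariate outlier filter
#'   within parity instead of overall.
#' @param censored_count_in_cg whether censored records count toward the
#'   contemporary-group size (they do by default: the penalty methods need a
#'   group maximum for them).
#' @return list of class `edit_config`.
#' @export
edit_config <- function(min_do = 20, min_first_calving_age = 530,
                        sd_mult = 3, min_cg_size = 3, max_parity = 3,
                        covariate_filter_by_parity = FALSE,
                        censored_count_in_cg = TRUE) {
  structure(list(min_do = min_do,
                 min_first_calving_age = min_first_calving_age,
                 sd_mult = sd_mult, min_cg_size = min_cg_size,
                 max_parity = max_parity,
                 covariate_filter_by_parity = covariate_filter_by_parity,
                 censored_count_in_cg = censored_count_in_cg),
            class = "edit_config")
}

#' Edit phenotype records
#'
#' Applies the editing pipeline in a fixed, documented order and returns an
#' auditable removal ledger:
#' 1. `parity`: keep parities 1 to `max_parity`;
#' 2. `calving_date`: drop records with a missing calving date and
#'    duplicated (cow, calving date) rows;
#' 3. `first_calving_age`: drop all records of cows whose first calving
#'    occurred before `min_first_calving_age` days of age;
#' 4. `covariate_outlier`: drop records where age at calving or days in
#'    milk at first insemination exceeds mean + k SD (computed once on the
#'    dataset entering this step);
#' 5. `do_min`: drop uncensored records with days open below `min_do`;
#' 6. `do_sd`: keep uncensored days open within mean +/- k SD within parity
#'    (statistics from uncensored records entering this step);
#' 7. `small_cg`: build herd x calving-year x season (HYS) contemporary
#'    groups and drop groups smaller than `min_cg_size`.
#'
#' Censored records are exempt from the two days-open filters (their value
#' is a lower bound, not an observation; the censoring models re-impute
#' them). Thresholds are computed once per step, never iteratively, so the
#' editing is idempotent.
#'
#' @param records phenotype data frame (censorship is flagged first if
#'   absent, see [flag_censored()]).
#' @param config an [edit_config()].
#' @param stats optional `stats` element of a previous [edit_records()] run;
#'   when supplied, the outlier thresholds are not recomputed, which makes
#'   editing exactly idempotent (`edit(edit(x)) = edit(x)`).
#' @return list with elements `records` (kept rows, with added columns
#'   `season` and `hys`), `ledger` (data frame `rule`, `removed`) and
#'   `stats` (the outlier thresholds used).
#' @export
edit_records <- function(records, config = edit_config(), stats = NULL) {
  stopifnot(inherits(config, "edit_config"))
  records <- flag_censored(records)
  records$do <- as.numeric(records$do)
  ledger <- data.frame(rule = character(), removed = integer(),
                       stringsAsFactors = FALSE)
  note <- function(rule, before, after) {
    ledger[nrow(ledger) + 1L, ] <<- list(rule, before - after)
  }

  n0 <- nrow(records)
  records <- records[!is.na(records$parity) & records$parity >= 1 &
                       records$parity <= config$max_parity, ]
  note("parity", n0, nrow(records))

  n0 <- nrow(records)
  records <- records[!is.na(records$calving_date), ]
  records <- records[!duplicated(records[, c("cow_id", "calving_date")]), ]
  note("calving_date", n0, nrow(records))

  n0 <- nrow(records)
  first_age <- records$age_at_calving[records$parity == 1]
  young <- unique(records$cow_id[records$parity == 1][
    !is.na(first_age) & first_age < config$min_first_calving_age])
  records <- records[!records$cow_id %in% young, ]
  note("first_calving_age", n0, nrow(records))

  n0 <- nrow(records)
  used_stats <- list()
  keep <- rep(TRUE, nrow(records))
  for (cv in c("age_at_calving", "dim_first_ai")) {
    x <- as.numeric(records[[cv]])
    grp <- if (config$covariate_filter_by_parity) as.character(records$parity)
           else rep("all", length(x))
    key <- paste0(cv, "_upper")
    if (is.null(stats)) {
      lev <- sort(unique(grp))
      used_stats[[key]] <- vapply(lev, function(g) {
        v <- x[grp == g]
        s <- stats::sd(v, na.rm = TRUE)
        if (is.na(s)) Inf else mean(v, na.rm = TRUE) + config$sd_mult * s
      }, numeric(1))
    } else {
      used_stats[[key]] <- stats[[key]]
    }
    upper <- unname(used_stats[[key]][grp])
    upper[is.na(upper)] <- Inf
    keep <- keep & !is.na(x) & x <= upper
  }
  records <- records[keep, ]
  note("covariate_outlier", n0, nrow(records))

  n0 <- nrow(records)
  records <- records[records$censored |
                       (!is.na(records$do) & records$do >= config$min_do), ]
  note("do_min", n0, nrow(records))

  n0 <- nrow(records)
  unc <- !records$censored
  if (is.null(stats)) {
    do_unc <- ifelse(unc, records$do, NA)
    bounds <- vapply(sort(unique(records$parity)), function(p) {
      v <- do_unc[records$parity == p]
      m <- mean(v, na.rm = TRUE)
      s <- stats::sd(v, na.rm = TRUE)
      if (is.na(s)) c(-Inf, Inf)
      else c(m - config$sd_mult * s, m + config$sd_mult * s)
    }, numeric(2))
    colnames(bounds) <- as.character(sort(unique(records$parity)))
    used_stats$do_bounds <- bounds
  } else {
    used_stats$do_bounds <- stats$do_bounds
  }
  b <- used_stats$do_bounds
  pcol <- match(as.character(records$parity), colnames(b))
  lo <- ifelse(is.na(pcol), -Inf, b[1L, pcol])
  hi <- ifelse(is.na(pcol), Inf, b[2L, pcol])
  records <- records[records$censored | (records$do >= lo & records$do <= hi), ]
  note("do_sd", n0, nrow(records))

  n0 <- nrow(records)
  records$season <- assign_season(records$calving_date)
  records$hys <- interaction(records$herd,
                             format(records$calving_date, "%Y"),
                             records$season, drop = TRUE, sep = "_")
  counted <- if (config$censored_count_in_cg) rep(TRUE, nrow(records)) else !records$censored
  sizes <- table(records$hys[counted])
  keep_cg <- names(sizes)[sizes >= config$min_cg_size]
  records <- records[records$hys %in% keep_cg, ]
  records$hys <- droplevels(records$hys)
  note("small_cg", n0, nrow(records))

  if (nrow(records) == 0L) stop("no records survive editing")
  rownames(records) <- NULL
  list(records = records, ledger = ledger, stats = used_stats)
}

#' Write the editing removal ledger
#'
#' @param ledger the `ledger` element returned by [edit_records()].
#' @param path output CSV path.
#' @export
write_edit_ledger <- function(ledger, path) {
  utils::write.csv(ledger, path, row.names = FALSE)
  invisible(path)
}
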