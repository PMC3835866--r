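#' From linked birth records to the analysis cohort
#'
#' The cohort is a data.frame with one row per linked birth, keyed by
#' `mother_id`, carrying the registry fields (`birth_date`, `plurality`,
#' `vital_status`, `gestational_weeks`, `sex`, `birthweight_grams`,
#' `reported_previous_pregnancies`, optionally `caesarean`) plus covariate
#' columns. Historical births (before the study period) stay in the table so
#' obstetric history can be derived; inclusion filters select the study-period
#' analysis rows.
#'
#' @name cohort_builder
#' @keywords internal
NULL

PRETERM_CUTOFF <- 37L

#' Read / write a cohort table
#'
#' Comma-separated, one row per birth, `mother_id` mandatory, dates ISO-8601.
#'
#' @param path CSV path.
#' @return `read_cohort`: the cohort data.frame with `birth_date` as `Date`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"mother_id" %in% names(df)) {
    stop_sgapaf("cohort table must have a mother_id column", "sgapaf_cohort_parse_error")
  }
  if ("birth_date" %in% names(df)) df$birth_date <- as.Date(df$birth_date)
  df
}

#' @rdname read_cohort
#' @param cohort cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check one mother's obstetric history for completeness
#'
#' A mother's history is complete when, at every study-period birth, her
#' reported number of previous pregnancies equals the count of her linked
#' birth records strictly earlier in the lookback window. Mothers whose
#' reports disagree with the linkage are excluded from analysis, because
#' their derived history covariates (parity, previous SGA, ...) would be
#' wrong.
#'
#' @param births_of_one_mother data.frame of one mother's births, ordered by
#'   `birth_date`.
#' @param study_period length-2 Date (or coercible) vector; only births inside
#'   it are checked (their histories still count all earlier linked births).
#'   `NULL` checks every birth.
#' @return `TRUE` if complete, `FALSE` otherwise.
#' @export
check_complete_history <- function(births_of_one_mother, study_period = NULL) {
  b <- births_of_one_mother
  d <- as.Date(b$birth_date)
  if (is.unsorted(d)) {
    stop_sgapaf("births must be ordered by date", "sgapaf_history_order_error")
  }
  if (anyDuplicated(d)) {
    warn_sgapaf(sprintf("mother %s has duplicate birth dates", b$mother_id[1]),
                "sgapaf_duplicate_date_warning")
  }
  prior <- seq_along(d) - 1L
  check <- rep(TRUE, length(d))
  if (!is.null(study_period)) {
    sp <- as.Date(study_period)
    check <- d >= sp[1] & d <= sp[2]
  }
  all(b$reported_previous_pregnancies[check] == prior[check])
}

# internal: vectorised completeness flag per mother over a whole cohort
complete_history_by_mother <- function(cohort, study_period = NULL) {
  ord <- order(cohort$mother_id, as.Date(cohort$birth_date))
  mid <- cohort$mother_id[ord]
  newg <- c(TRUE, mid[-1] != mid[-length(mid)])
  pos <- seq_along(mid) - cummax(seq_along(mid) * newg)  # 0-based within mother
  rep_prev <- cohort$reported_previous_pregnancies[ord]
  d <- as.Date(cohort$birth_date)[ord]
  check <- rep(TRUE, length(mid))
  if (!is.null(study_period)) {
    sp <- as.Date(study_period)
    check <- d >= sp[1] & d <= sp[2]
  }
  ok_row <- rep_prev == pos | !check
  ok <- tapply(ok_row, mid, all)
  stats::setNames(as.logical(ok), names(ok))
}

#' Apply the study inclusion filters
#'
#' Retains study-period singleton live births of 24--44 completed weeks whose
#' mothers have a complete obstetric history, tallying exclusions rule by rule
#' in a fixed order (plurality, vital status, gestational age, history) so the
#' counts are reproducible. Historical (pre-study-period) rows are dropped
#' from the output but still feed the completeness check.
#'
#' If the cohort already carries a `history_complete` column (from a previous
#' pass), it is reused rather than recomputed, so the filter is idempotent.
#'
#' @param cohort cohort data.frame (may include historical births).
#' @param study_period length-2 date range of the study window; `NULL` treats
#'   every row as a study birth.
#' @param ga_range inclusive gestational-age bounds in completed weeks.
#' @return list with `included` (analysis rows, plus a `history_complete`
#'   column) and `tally` (named integer vector: input, not_study_period, then
#'   one entry per exclusion rule, included).
#' @export
apply_inclusion_filters <- function(cohort, study_period = NULL,
                                    ga_range = c(24L, 44L)) {
  n_input <- nrow(cohort)
  if ("history_complete" %in% names(cohort)) {
    hist_ok_row <- cohort$history_complete
  } else {
    ok <- complete_history_by_mother(cohort, study_period)
    hist_ok_row <- as.logical(ok[as.character(cohort$mother_id)])
  }
  df <- cohort
  df$history_complete <- hist_ok_row

  if (!is.null(study_period)) {
    sp <- as.Date(study_period)
    d <- as.Date(df$birth_date)
    in_period <- d >= sp[1] & d <= sp[2]
  } else {
    in_period <- rep(TRUE, nrow(df))
  }
  n_not_period <- sum(!in_period)
  df <- df[in_period, , drop = FALSE]

  tally <- c(input = n_input, not_study_period = n_not_period)
  keep <- df$plurality == "singleton"
  tally["plurality"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  keep <- df$vital_status == "livebirth"
  tally["vital_status"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  keep <- df$gestational_weeks >= ga_range[1] & df$gestational_weeks <= ga_range[2]
  tally["gestation"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  keep <- df$history_complete
  tally["history"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  tally["included"] <- nrow(df)
  rownames(df) <- NULL
  list(included = df, tally = tally)
}

#' Derive obstetric-history covariates
#'
#' For every birth, computes counts over that mother's strictly earlier linked
#' births: parity, previous caesareans, previous preterm (< 37 weeks),
#' previous stillbirths and previous SGA infants (classified against the same
#' growth standard as the study period). The inter-pregnancy interval runs
#' from the immediately preceding birth to the conception of the current
#' pregnancy (current birth date minus gestational duration), in months of
#' 30.4375 days, and is categorised as in the analysis models:
#' `"6-41_or_nulliparous"` (reference) vs `"lt6_or_ge42"`.
#'
#' @param cohort full linked cohort (historical rows included); must be the
#'   same table the inclusion filters saw, so counts line up.
#' @param standard `growth_standard` used to classify historical births as
#'   SGA. Historical births outside 24--44 weeks cannot be classified and
#'   count as non-SGA.
#' @return data.frame aligned with `cohort` rows: `parity`,
#'   `interpregnancy_interval_months` (`NA` for first births),
#'   `ipi_category`, `prev_caesareans`, `prev_preterm`, `prev_stillbirths`,
#'   `prev_sga`, `nulliparous`.
#' @export
derive_obstetric_history <- function(cohort, standard) {
  n <- nrow(cohort)
  ord <- order(cohort$mother_id, as.Date(cohort$birth_date))
  mid <- cohort$mother_id[ord]
  d <- as.Date(cohort$birth_date)[ord]
  gw <- cohort$gestational_weeks[ord]
  newg <- c(TRUE, mid[-1] != mid[-length(mid)])

  before <- function(x) {
    x <- as.numeric(x)
    cs <- cumsum(x)
    start <- cs - x          # cumsum excluding current row, global
    base <- start[newg][cumsum(newg)]  # group-start offsets carried forward
    start - base
  }

  parity <- before(rep(1, n))
  prev_cs <- if ("caesarean" %in% names(cohort)) {
    before(cohort$caesarean[ord] %in% c(TRUE, 1))
  } else rep(NA_integer_, n)
  prev_pt <- before(gw < PRETERM_CUTOFF)
  prev_sb <- before(cohort$vital_status[ord] == "stillbirth")

  in_range <- gw >= GA_MIN & gw <= GA_MAX
  sga <- rep(FALSE, n)
  if (any(in_range)) {
    sga[in_range] <- classify_sga(standard,
                                  cohort$birthweight_grams[ord][in_range],
                                  gw[in_range], cohort$sex[ord][in_range])
  }
  prev_sga <- before(sga)

  prev_date <- c(as.Date(NA), d[-n])
  prev_date[newg] <- NA
  conception <- d - round(gw * 7)
  ipi_days <- as.numeric(conception - prev_date)
  if (any(ipi_days < 0, na.rm = TRUE)) {
    bad <- mid[which(ipi_days < 0)[1]]
    stop_sgapaf(sprintf("negative inter-pregnancy interval for mother %s: dates inconsistent", bad),
                "sgapaf_interval_error")
  }
  ipi_months <- ipi_days / 30.4375
  ipi_cat <- ifelse(parity == 0 | (ipi_months >= 6 & ipi_months < 42),
                    "6-41_or_nulliparous", "lt6_or_ge42")
  ipi_cat[parity > 0 & is.na(ipi_months)] <- NA

  out <- data.frame(parity = as.integer(parity),
                    interpregnancy_interval_months = ipi_months,
                    ipi_category = ipi_cat,
                    prev_caesareans = as.integer(prev_cs),
                    prev_preterm = as.integer(prev_pt),
                    prev_stillbirths = as.integer(prev_sb),
                    prev_sga = as.integer(prev_sga),
                    nulliparous = parity == 0)
  res <- out[order(ord), , drop = FALSE]  # invert the sort: align with input rows
  rownames(res) <- NULL
  res
}

#' Analysis-ready dataset for one stratum
#'
#' @param stratum one of `"preterm"`, `"term_diabetic"`, `"term_nondiabetic"`.
#' @param data covariate data.frame (factors declared as R factors with the
#'   reference level first).
#' @param outcome logical/0-1 vector: SGA vs not, aligned with `data` rows.
#' @param cluster_ids mother keys aligned with rows.
#' @param codings optional named list documenting collapsed codings applied.
#' @return a `stratum_dataset`.
#' @export
stratum_dataset <- function(stratum, data, outcome, cluster_ids, codings = list()) {
  stopifnot(nrow(data) == length(outcome), length(outcome) == length(cluster_ids))
  structure(list(stratum = stratum, data = data, outcome = as.logical(outcome),
                 cluster_ids = cluster_ids, codings = codings),
            class = "stratum_dataset")
}

#' @export
print.stratum_dataset <- function(x, ...) {
  cat(sprintf("stratum_dataset '%s': %d births (%d SGA, %.1f%%), %d mothers, %d covariates\n",
              x$stratum, length(x$outcome), sum(x$outcome),
              100 * mean(x$outcome), length(unique(x$cluster_ids)),
              ncol(x$data)))
  invisible(x)
}

#' Split the included cohort into the three analysis strata
#'
#' Preterm births (< `preterm_cutoff` completed weeks) form one stratum with
#' diabetes as an ordinary covariate; term births are split by maternal
#' diabetes (pre-existing or gestational combined). Within each stratum the
#' comparison is SGA vs non-SGA. The strata partition the included births.
#'
#' @param cohort included study births with logical columns `sga` and
#'   `diabetes` and a `mother_id` column.
#' @param covariates character vector of covariate column names to carry into
#'   each stratum's data (default: every column except identifiers, outcome
#'   ingredients and bookkeeping columns).
#' @param preterm_cutoff completed-weeks threshold defining preterm
#'   (default 37, the obstetric convention).
#' @param codings optional named list (per stratum) of level-collapse maps,
#'   each `list(column = c(old_level = new_level, ...))`, applied to that
#'   stratum's covariates and recorded in its metadata.
#' @return named list of three `stratum_dataset`s: `preterm`, `term_diabetic`,
#'   `term_nondiabetic`.
#' @export
stratify <- function(cohort, covariates = NULL, preterm_cutoff = PRETERM_CUTOFF,
                     codings = list()) {
  stopifnot(all(c("sga", "diabetes", "mother_id") %in% names(cohort)))
  drop_cols <- c("mother_id", "birth_id", "birth_date", "plurality",
                 "vital_status", "birthweight_grams", "sga",
                 "reported_previous_pregnancies", "history_complete",
                 "is_study_birth", "gestational_weeks", "sex", "caesarean",
                 "interpregnancy_interval_months", "parity")
  if (is.null(covariates)) covariates <- setdiff(names(cohort), drop_cols)
  idx <- list(
    preterm = cohort$gestational_weeks < preterm_cutoff,
    term_diabetic = cohort$gestational_weeks >= preterm_cutoff &
      cohort$diabetes %in% c(TRUE, 1),
    term_nondiabetic = cohort$gestational_weeks >= preterm_cutoff &
      !(cohort$diabetes %in% c(TRUE, 1))
  )
  out <- list()
  for (s in names(idx)) {
    covs <- covariates
    if (s != "preterm") covs <- setdiff(covs, "diabetes")
    dat <- cohort[idx[[s]], covs, drop = FALSE]
    cmap <- codings[[s]] %||% list()
    for (col in names(cmap)) {
      map <- cmap[[col]]
      v <- as.character(dat[[col]])
      hit <- v %in% names(map)
      v[hit] <- map[v[hit]]
      dat[[col]] <- factor(v)
    }
    dat <- as.data.frame(lapply(dat, function(v) {
      if (is.character(v)) factor(v) else v
    }), stringsAsFactors = FALSE)
    out[[s]] <- stratum_dataset(s, dat, cohort$sga[idx[[s]]],
                                cohort$mother_id[idx[[s]]], cmap)
  }
  out
}
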