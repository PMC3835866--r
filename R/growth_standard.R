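#' Gestational-age- and sex-specific birthweight percentile standards
#'
#' A `growth_standard` stores birthweight percentile cut-offs by completed week
#' of gestation (24--44) and infant sex, and classifies births as small for
#' gestational age (SGA): birthweight strictly below the 10th-percentile
#' cut-off for the infant's week and sex. Weights exactly at the cut-off are
#' not SGA. Gestational age is in completed weeks, so cut-offs are a per-week
#' lookup with no interpolation.
#'
#' @name growth_standard
#' @keywords internal
NULL

GA_MIN <- 24L
GA_MAX <- 44L
SEXES <- c("male", "female")

new_growth_standard <- function(table, provenance) {
  table <- table[order(table$sex, table$week, table$percentile), , drop = FALSE]
  rownames(table) <- NULL
  structure(list(table = table, provenance = provenance),
            class = "growth_standard")
}

validate_growth_standard <- function(std) {
  tab <- std$table
  # coverage: every (week, sex) needs a 10th-percentile cut-off
  need <- expand.grid(week = GA_MIN:GA_MAX, sex = SEXES,
                      stringsAsFactors = FALSE)
  have <- tab[tab$percentile == 10L, c("week", "sex")]
  key <- function(d) paste(d$week, d$sex)
  missing <- need[!(key(need) %in% key(have)), , drop = FALSE]
  if (nrow(missing) > 0) {
    stop_sgapaf(
      sprintf("growth standard missing 10th-percentile cut-offs for %d (week, sex) cells, e.g. week %d %s",
              nrow(missing), missing$week[1], missing$sex[1]),
      "sgapaf_standard_coverage_error", missing = missing)
  }
  if (any(tab$grams <= 0)) {
    bad <- tab[tab$grams <= 0, ][1, ]
    stop_sgapaf(
      sprintf("non-positive cut-off at week %d, %s, percentile %d",
              bad$week, bad$sex, bad$percentile),
      "sgapaf_standard_value_error")
  }
  # strictly increasing in percentile within (week, sex)
  for (s in unique(tab$sex)) {
    for (w in unique(tab$week[tab$sex == s])) {
      g <- tab[tab$sex == s & tab$week == w, ]
      if (is.unsorted(g$grams, strictly = TRUE)) {
        stop_sgapaf(
          sprintf("cut-offs not strictly increasing in percentile at week %d, %s", w, s),
          "sgapaf_standard_monotonicity_error")
      }
    }
  }
  # non-decreasing in week within (percentile, sex)
  for (s in unique(tab$sex)) {
    for (p in unique(tab$percentile[tab$sex == s])) {
      g <- tab[tab$sex == s & tab$percentile == p, ]
      g <- g[order(g$week), ]
      if (is.unsorted(g$grams)) {
        w_bad <- g$week[which(diff(g$grams) < 0)[1] + 1L]
        stop_sgapaf(
          sprintf("percentile %d cut-off for %s decreases at week %d", p, s, w_bad),
          "sgapaf_standard_monotonicity_error")
      }
    }
  }
  invisible(std)
}

#' Load a birthweight percentile standard from a delimited table
#'
#' Reads a comma-separated table with header `week,sex,percentile,grams`
#' (sex coded `male`/`female`, one row per cell) and validates it: complete
#' 10th-percentile coverage of weeks 24--44 for both sexes, cut-offs strictly
#' increasing in percentile, and non-decreasing in gestational week.
#'
#' @param path path to the CSV file, or a data.frame already holding the
#'   table columns.
#' @param provenance free-text label recorded on the standard.
#' @return a `growth_standard` object.
#' @export
load_standard <- function(path, provenance = NULL) {
  if (is.character(path)) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    provenance <- provenance %||% path
  } else {
    tab <- as.data.frame(path)
    provenance <- provenance %||% "in-memory table"
  }
  req <- c("week", "sex", "percentile", "grams")
  if (!all(req %in% names(tab))) {
    stop_sgapaf(paste("standard table must have columns", paste(req, collapse = ", ")),
                "sgapaf_standard_parse_error")
  }
  tab <- tab[req]
  if (any(is.na(tab$week)) || any(is.na(tab$grams)) || any(is.na(tab$percentile)) ||
      !all(tab$sex %in% SEXES)) {
    bad <- which(is.na(tab$week) | is.na(tab$grams) | is.na(tab$percentile) |
                   !(tab$sex %in% SEXES))[1]
    stop_sgapaf(sprintf("unparseable standard row %d", bad),
                "sgapaf_standard_parse_error")
  }
  tab$week <- as.integer(tab$week)
  tab$percentile <- as.integer(tab$percentile)
  std <- new_growth_standard(tab, provenance)
  validate_growth_standard(std)
  std
}

#' Write a standard back to its delimited-table form
#'
#' @param std a `growth_standard`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_standard <- function(std, path) {
  utils::write.csv(std$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.growth_standard <- function(x, ...) {
  cat("Birthweight percentile standard (", x$provenance, ")\n", sep = "")
  cat("  weeks ", min(x$table$week), "-", max(x$table$week),
      ", percentiles {", paste(sort(unique(x$table$percentile)), collapse = ","),
      "}\n", sep = "")
  m <- percentile_cutoff(x, 39L, "male", 10L)
  f <- percentile_cutoff(x, 39L, "female", 10L)
  cat(sprintf("  10th percentile at 39 weeks: male %.0f g, female %.0f g\n", m, f))
  invisible(x)
}

#' Look up a percentile cut-off
#'
#' Per-week lookup; completed weeks of gestation, no interpolation.
#'
#' @param std a `growth_standard`.
#' @param week completed weeks of gestation, 24--44.
#' @param sex `"male"` or `"female"`.
#' @param percentile percentile to look up (default 10, the SGA threshold).
#' @return cut-off in grams.
#' @export
percentile_cutoff <- function(std, week, sex, percentile = 10L) {
  stopifnot(inherits(std, "growth_standard"))
  if (any(week < GA_MIN | week > GA_MAX)) {
    stop_sgapaf(sprintf("gestational age outside %d-%d completed weeks", GA_MIN, GA_MAX),
                "sgapaf_ga_range_error")
  }
  tab <- std$table
  idx <- match(paste(week, sex, as.integer(percentile)),
               paste(tab$week, tab$sex, tab$percentile))
  if (anyNA(idx)) {
    stop_sgapaf("(week, sex, percentile) not present in the standard",
                "sgapaf_standard_lookup_error")
  }
  tab$grams[idx]
}

#' Classify births as small for gestational age
#'
#' SGA is birthweight strictly below the 10th-percentile cut-off for the
#' infant's completed gestational week and sex; a weight exactly at the
#' cut-off is not SGA. Vectorised over births.
#'
#' @param std a `growth_standard`.
#' @param birthweight_grams birthweight(s) in grams (registry grid: 5 g).
#' @param week completed weeks of gestation, 24--44.
#' @param sex `"male"`/`"female"`, recycled against `birthweight_grams`.
#' @return logical vector, `TRUE` = SGA.
#' @export
classify_sga <- function(std, birthweight_grams, week, sex) {
  if (any(birthweight_grams <= 0 | birthweight_grams > 7000)) {
    stop_sgapaf("birthweight outside (0, 7000] g: data error",
                "sgapaf_birthweight_error")
  }
  cut <- percentile_cutoff(std, week, sex, 10L)
  birthweight_grams < cut
}

#' Construct the synthetic default percentile standard
#'
#' Builds a standard from a normal location-scale family per (week, sex):
#' the mean birthweight follows a logistic growth curve
#' `mean(w) = m_max / (1 + exp(-rate * (w - midpoint)))` and the standard
#' deviation is `cv * mean(w)`. Percentile cut-offs are the normal quantiles
#' `mean + qnorm(p/100) * sd` at percentiles 3, 5, 10, 25, 50, 75, 90, 95, 97.
#' The default parameters are calibrated so the 10th percentile at 39 weeks is
#' approximately 2500 g for both sexes, the one anchor a national standard is
#' expected to reproduce. This is a synthetic stand-in for a real national
#' percentile chart, which can be supplied via [load_standard()] instead.
#'
#' @param mean_curve_params named list per sex of `m_max`, `rate`, `midpoint`.
#' @param sd_curve_params named list per sex of `cv` (coefficient of variation).
#' @param percentiles integer percentiles to tabulate.
#' @return a `growth_standard`.
#' @export
make_synthetic_standard <- function(
    mean_curve_params = list(
      male   = list(m_max = 4250, rate = 0.2, midpoint = 32),
      female = list(m_max = 4100, rate = 0.2, midpoint = 32)),
    sd_curve_params = list(
      male   = list(cv = 0.2081),
      female = list(cv = 0.1873)),
    percentiles = c(3L, 5L, 10L, 25L, 50L, 75L, 90L, 95L, 97L)) {
  weeks <- GA_MIN:GA_MAX
  rows <- list()
  for (s in SEXES) {
    mp <- mean_curve_params[[s]]
    sp <- sd_curve_params[[s]]
    mu <- mp$m_max / (1 + exp(-mp$rate * (weeks - mp$midpoint)))
    if (is.unsorted(mu, strictly = TRUE)) {
      stop_sgapaf("mean curve must be strictly increasing in gestational week",
                  "sgapaf_standard_value_error")
    }
    sd <- sp$cv * mu
    if (any(sd <= 0)) {
      stop_sgapaf("standard deviation curve must be positive",
                  "sgapaf_standard_value_error")
    }
    for (p in percentiles) {
      rows[[length(rows) + 1L]] <- data.frame(
        week = weeks, sex = s, percentile = as.integer(p),
        grams = mu + stats::qnorm(p / 100) * sd)
    }
  }
  std <- new_growth_standard(do.call(rbind, rows), "synthetic normal location-scale default")
  std$mean_curve_params <- mean_curve_params
  std$sd_curve_params <- sd_curve_params
  validate_growth_standard(std)
  std
}

# internal: mean and sd of the synthetic standard's generating distribution
# at given (week, sex); used by the cohort generator to draw birthweights.
standard_moments <- function(std, week, sex) {
  if (is.null(std$mean_curve_params)) {
    stop_sgapaf("standard has no generating distribution (loaded from table)",
                "sgapaf_standard_lookup_error")
  }
  mu <- numeric(length(week))
  sd <- numeric(length(week))
  for (s in SEXES) {
    i <- sex == s
    if (!any(i)) next
    mp <- std$mean_curve_params[[s]]
    mu[i] <- mp$m_max / (1 + exp(-mp$rate * (week[i] - mp$midpoint)))
    sd[i] <- std$sd_curve_params[[s]]$cv * mu[i]
  }
  list(mean = mu, sd = sd)
}
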