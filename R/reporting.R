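#' Cohort summary counts and percentages
#'
#' The descriptive counts reported for a classified cohort: total births and
#' mothers, preterm/term split, SGA total and its split across the three
#' strata, mothers by number of study births, and (when available) the
#' obstetric-history completeness pass rate. All percentages are rounded
#' half-up to one decimal, the registry reporting convention.
#'
#' @param cohort included study births with columns `sga`, `diabetes`,
#'   `gestational_weeks` and `mother_id`.
#' @param preterm_cutoff completed-weeks preterm threshold.
#' @param completeness optional fraction of mothers passing the completeness
#'   check, carried into the summary.
#' @return a `cohort_summary` list of named counts and percentages.
#' @export
summarize_cohort <- function(cohort, preterm_cutoff = PRETERM_CUTOFF,
                             completeness = NULL) {
  n <- nrow(cohort)
  preterm <- cohort$gestational_weeks < preterm_cutoff
  sga <- cohort$sga %in% c(TRUE, 1)
  dia <- cohort$diabetes %in% c(TRUE, 1)
  n_sga <- sum(sga)
  sga_strata <- c(
    preterm = sum(sga & preterm),
    term_diabetic = sum(sga & !preterm & dia),
    term_nondiabetic = sum(sga & !preterm & !dia))
  births_per_mother <- table(table(cohort$mother_id))
  m_counts <- c(`1` = 0, `2` = 0, `3+` = 0)
  for (nm in names(births_per_mother)) {
    key <- if (as.integer(nm) >= 3) "3+" else nm
    m_counts[key] <- m_counts[key] + births_per_mother[[nm]]
  }
  n_mothers <- sum(m_counts)
  structure(list(
    n_births = n,
    n_mothers = n_mothers,
    n_preterm = sum(preterm),
    n_term = sum(!preterm),
    preterm_pct = pct_of(sum(preterm), n),
    term_pct = pct_of(sum(!preterm), n),
    n_sga = n_sga,
    sga_pct = pct_of(n_sga, n),
    sga_by_stratum = sga_strata,
    sga_by_stratum_pct = pct_of(sga_strata, n_sga),
    mothers_by_births = m_counts,
    mothers_by_births_pct = pct_of(m_counts, n_mothers),
    completeness_pass_pct = if (is.null(completeness)) NULL else
      round_half_up(100 * completeness, 1)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("%d singleton live births to %d mothers\n", x$n_births, x$n_mothers))
  cat(sprintf("  preterm %d (%.1f%%), term %d (%.1f%%)\n",
              x$n_preterm, x$preterm_pct, x$n_term, x$term_pct))
  cat(sprintf("  SGA %d (%.1f%%): preterm %d (%.1f%%), term diabetic %d (%.1f%%), term non-diabetic %d (%.1f%%)\n",
              x$n_sga, x$sga_pct,
              x$sga_by_stratum[["preterm"]], x$sga_by_stratum_pct[[1]],
              x$sga_by_stratum[["term_diabetic"]], x$sga_by_stratum_pct[[2]],
              x$sga_by_stratum[["term_nondiabetic"]], x$sga_by_stratum_pct[[3]]))
  cat(sprintf("  mothers with 1/2/3+ births: %d (%.1f%%) / %d (%.1f%%) / %d (%.1f%%)\n",
              x$mothers_by_births[["1"]], x$mothers_by_births_pct[[1]],
              x$mothers_by_births[["2"]], x$mothers_by_births_pct[[2]],
              x$mothers_by_births[["3+"]], x$mothers_by_births_pct[[3]]))
  if (!is.null(x$completeness_pass_pct)) {
    cat(sprintf("  complete obstetric history: %.1f%% of mothers\n",
                x$completeness_pass_pct))
  }
  invisible(x)
}

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"file"` (read one).
#' @param cohort a [cohort_config()] (synthetic mode).
#' @param cohort_path cohort CSV (file mode).
#' @param standard a `growth_standard`, or `NULL` for the synthetic default.
#' @param selection a [selection_config()].
#' @param candidate_factors covariates offered to the screen; `NULL` uses the
#'   generated factor columns plus the derived history covariates
#'   (`nulliparous`, `ipi_category`, `prev_sga_cat`).
#' @param modifiable character vector (or per-stratum named list) of factors
#'   treated as causative and potentially modifiable: PAFs are computed for
#'   these only; other retained factors appear as aOR-only rows.
#' @param bootstrap_reps bootstrap replicates per PAF (headline analyses use
#'   10,000).
#' @param seed integer master seed for generation and resampling.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "file"),
                            cohort = cohort_config(),
                            cohort_path = NULL,
                            standard = NULL,
                            selection = selection_config(),
                            candidate_factors = NULL,
                            modifiable = c("smoking", "illicit_drug_use",
                                           "pregnancy_hypertension"),
                            bootstrap_reps = 500L,
                            seed = 20260101L,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "file" && is.null(cohort_path)) {
    stop_sgapaf("file mode needs cohort_path", "sgapaf_config_error")
  }
  structure(list(mode = mode, cohort = cohort, cohort_path = cohort_path,
                 standard = standard, selection = selection,
                 candidate_factors = candidate_factors,
                 modifiable = modifiable, bootstrap_reps = bootstrap_reps,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Generate or ingest the linked cohort, apply the inclusion filters, derive
#' obstetric history, classify SGA, stratify, run the selection protocol and
#' final GEE fit per stratum, estimate PAFs for the modifiable factors, and
#' (optionally) write the result tables, elimination traces, exclusion tally
#' and a JSON manifest under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage-boundary log lines.
#' @return (invisibly) a result bundle: `summary`, `tally`, `strata` (per
#'   stratum: screen, vif, selection, fit, ors, pafs, table), `manifest`,
#'   and in synthetic mode `ledger`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  t0 <- Sys.time()
  log_line <- function(...) if (!quiet) message(sprintf(...))
  std <- config$standard %||% make_synthetic_standard()

  ledger <- NULL
  if (config$mode == "synthetic") {
    cc <- config$cohort
    cc$seed <- config$seed
    gen <- generate_cohort(cc, std)
    cohort <- gen$cohort
    ledger <- gen$ledger
    study_period <- as.Date(cc$study_period)
    log_line("generated %d linked births for %d mothers", nrow(cohort), cc$n_mothers)
  } else {
    cohort <- read_cohort(config$cohort_path)
    study_period <- NULL
    if ("is_study_birth" %in% names(cohort)) {
      study_period <- range(as.Date(cohort$birth_date[cohort$is_study_birth]))
    }
    log_line("read %d linked births from %s", nrow(cohort), config$cohort_path)
  }

  hist_cov <- derive_obstetric_history(cohort, std)
  cohort <- cbind(cohort, hist_cov)
  flt <- apply_inclusion_filters(cohort, study_period)
  included <- flt$included
  log_line("inclusion filters: %s", paste(names(flt$tally), flt$tally,
                                          sep = "=", collapse = ", "))

  included$sga <- classify_sga(std, included$birthweight_grams,
                               included$gestational_weeks, included$sex)
  included$prev_sga_cat <- factor(
    ifelse(included$prev_sga >= 2, "2plus", as.character(included$prev_sga)),
    levels = c("0", "1", "2plus"))

  candidates <- config$candidate_factors
  if (is.null(candidates)) {
    spec_names <- if (config$mode == "synthetic") {
      vapply(config$cohort$factor_specs, `[[`, "", "name")
    } else {
      setdiff(names(cohort), c(names(hist_cov), "mother_id", "birth_id",
                               "birth_date", "is_study_birth", "plurality",
                               "vital_status", "gestational_weeks", "sex",
                               "birthweight_grams",
                               "reported_previous_pregnancies", "caesarean",
                               "history_complete"))
    }
    candidates <- c(spec_names, "nulliparous", "ipi_category", "prev_sga_cat")
  }
  candidates <- union(candidates, "diabetes")  # preterm covariate; dropped in term strata

  strata <- stratify(included, covariates = intersect(c(candidates, "diabetes"),
                                                      names(included)))
  n_complete <- mean(complete_history_by_mother(cohort, study_period))
  summary <- summarize_cohort(included, completeness = n_complete)
  if (!quiet) print(summary)

  seed_k <- config$seed
  results <- list()
  for (s in names(strata)) {
    st <- strata[[s]]
    avail <- intersect(candidates, names(st$data))
    scr <- univariate_screen(st, config$selection, avail)
    passed <- scr$factor[scr$included %in% TRUE]
    log_line("[%s] screen: %d of %d factors at P < %.2f", s, length(passed),
             length(avail), config$selection$screen_alpha)
    vif <- NULL
    if (length(passed) >= 2) {
      dm <- build_design(st, passed)
      vif <- tryCatch(compute_vif(dm$X[, -1, drop = FALSE],
                                  config$selection$vif_threshold),
                      error = function(e) NULL)
    }
    sel <- backward_eliminate(st, passed, config$selection)
    final <- c(sel$final_factors, sel$interactions)
    log_line("[%s] final model: %s", s,
             if (length(final)) paste(final, collapse = " + ") else "(intercept only)")
    fit <- fit_gee(st, final)
    ors <- adjusted_ors(fit)

    modif <- if (is.list(config$modifiable)) config$modifiable[[s]] else config$modifiable
    pafs <- list()
    for (f in intersect(modif, sel$final_factors)) {
      for (j in fit$term_map[[f]]) {        # per-level PAFs
        seed_k <- seed_k + 1L
        lev <- colnames(fit$X)[j]
        pafs[[lev]] <- bootstrap_paf(st, final, j,
                                     reps = config$bootstrap_reps,
                                     seed = seed_k)
        log_line("[%s] PAF %s: %.2f%% (%.2f, %.2f)", s, lev,
                 pafs[[lev]]$point_paf, pafs[[lev]]$ci_low, pafs[[lev]]$ci_high)
      }
    }

    tab <- ors
    tab$paf <- rep(NA_real_, nrow(tab))
    tab$paf_ci_low <- rep(NA_real_, nrow(tab))
    tab$paf_ci_high <- rep(NA_real_, nrow(tab))
    for (lev in names(pafs)) {
      i <- tab$term == lev
      tab$paf[i] <- pafs[[lev]]$point_paf
      tab$paf_ci_low[i] <- pafs[[lev]]$ci_low
      tab$paf_ci_high[i] <- pafs[[lev]]$ci_high
    }
    tab <- cbind(stratum = rep(s, nrow(tab)), tab)
    results[[s]] <- list(screen = scr, vif = vif, selection = sel, fit = fit,
                         ors = ors, pafs = pafs, table = tab)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sgapaf")),
    seed = config$seed,
    mode = config$mode,
    counts = list(input = unname(flt$tally[["input"]]),
                  included = unname(flt$tally[["included"]]),
                  strata = lapply(strata, function(x) length(x$outcome))),
    exclusion_tally = as.list(flt$tally),
    bootstrap_reps = config$bootstrap_reps,
    warnings = list(
      vif_flagged = lapply(results, function(r) attr(r$vif, "flagged")),
      failed_bootstrap_reps = lapply(results, function(r)
        vapply(r$pafs, function(p) p$bootstrap_reps - p$successful_reps, 0L)),
      nonconverged_fits = names(results)[!vapply(results, function(r) r$fit$converged, TRUE)]),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    if (config$mode == "synthetic") write_cohort(cohort, out("cohort.csv"))
    utils::write.csv(data.frame(rule = names(flt$tally), count = unname(flt$tally)),
                     out("exclusions.csv"), row.names = FALSE)
    for (s in names(results)) {
      utils::write.csv(results[[s]]$table, out(sprintf("aor_paf_%s.csv", s)),
                       row.names = FALSE)
      utils::write.csv(results[[s]]$selection$trace,
                       out(sprintf("elimination_trace_%s.csv", s)),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  invisible(list(summary = summary, tally = flt$tally, strata = results,
                 manifest = manifest, ledger = ledger, included = included))
}
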