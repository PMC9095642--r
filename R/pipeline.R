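#' Per-participant endpoint changes
#'
#' Change of an outcome from baseline (first visit) to end of follow-up,
#' per participant. If a medication change is recorded, the last visit with
#' unchanged medication is used instead of the final visit; no imputation.
#' Participants with fewer than two usable visits are omitted.
#'
#' @param visits long visits data.frame `id, day, <outcome>, med_change`.
#' @param outcome name of the outcome column (default `"hba1c"`).
#' @return A data.frame `id, delta, baseline, follow_days`.
#' @export
participant_deltas <- function(visits, outcome = "hba1c") {
  out <- lapply(split(visits, visits$id), function(v) {
    v <- v[order(v$day), ]
    mc <- which(v$med_change)
    if (length(mc)) v <- v[seq_len(mc[1] - 1), , drop = FALSE]
    v <- v[!is.na(v[[outcome]]), , drop = FALSE]
    if (nrow(v) < 2) return(NULL)
    data.frame(id = v$id[1],
               delta = v[[outcome]][nrow(v)] - v[[outcome]][1],
               baseline = v[[outcome]][1],
               follow_days = v$day[nrow(v)] - v$day[1],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Endpoint changes for matched registry controls
#'
#' For each matched control, the change of HbA1c from the index-date
#' measurement to the last measurement inside the follow-up window.
#'
#' @param match a `"match_result"` from [match_controls()].
#' @param registry the registry the match was drawn from.
#' @param follow_up_days follow-up window after the index date.
#' @return A data.frame `id, delta, baseline, follow_days`.
#' @export
control_deltas <- function(match, registry, follow_up_days = 730) {
  ids <- names(match$index_dates)
  out <- lapply(ids, function(cid) {
    r <- registry[registry$id == cid, , drop = FALSE]
    r <- r[order(r$day), ]
    i0 <- which(r$day == match$index_dates[[cid]])[1]
    win <- which(r$day > r$day[i0] & r$day <= r$day[i0] + follow_up_days)
    if (!length(win)) return(NULL)
    iend <- win[length(win)]
    data.frame(id = cid, delta = r$hba1c[iend] - r$hba1c[i0],
               baseline = r$hba1c[i0], follow_days = r$day[iend] - r$day[i0],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full simulate-measure-classify-score-infer pipeline
#'
#' Generates the synthetic cohort, registry and theme catalog, derives body
#' composition, classifies HbA1c progression patterns, computes the
#' quarterly exposure-response bins and BCT scores, matches registry
#' controls, estimates endpoint contrasts by usage class (unweighted and,
#' for the user-versus-non-user comparison, inverse-probability weighted),
#' runs the mediation decomposition and the design calculations, and
#' writes every stage output plus a run manifest to `out_dir`. The same
#' config and seed produce a byte-identical bundle.
#'
#' @param config a [cohort_config()]; its `seed` drives every stage.
#'   Alternatively a path to a YAML file whose entries override
#'   [cohort_config()] defaults.
#' @param out_dir writable output directory.
#' @param match_ratio controls per participant in matching.
#' @param n_boot bootstrap draws for mediation.
#' @param run_mediation,run_matching,run_weighting stage toggles.
#' @param max_trees,cv_folds propensity-model settings.
#' @param verbose print one log line per stage.
#' @return An invisible list of class `"pipeline_bundle"` with every stage
#'   result and the manifest.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         match_ratio = 2, n_boot = 5000,
                         run_mediation = TRUE, run_matching = TRUE,
                         run_weighting = TRUE, max_trees = 200, cv_folds = 5,
                         verbose = TRUE) {
  if (is.character(config)) config <- do.call(cohort_config, read_yaml_config(config))
  validate_cohort_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("output directory is not writable", call. = FALSE)
  say <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  bundle <- list(config = config)

  cohort <- stage("simulate", generate_cohort(config))
  registry <- stage("simulate", generate_registry(config))
  catalog <- stage("simulate", generate_theme_catalog(config$seed))
  write_cohort_files(cohort, registry, catalog, out_dir)
  say("simulate", "%d participants, %d registry patients, %d themes",
      nrow(cohort$participants), length(unique(registry$id)),
      length(catalog$themes))
  bundle$cohort <- cohort; bundle$registry <- registry; bundle$catalog <- catalog

  visits_derived <- stage("measure",
                          add_body_composition(cohort$visits, cohort$participants))
  utils::write.csv(visits_derived, file.path(out_dir, "visits.csv"),
                   row.names = FALSE, quote = FALSE)
  say("measure", "derived body composition for %d visits", nrow(visits_derived))
  bundle$visits_derived <- visits_derived

  patterns <- stage("patterns", classify_visit_patterns(cohort$visits))
  utils::write.csv(patterns, file.path(out_dir, "patterns.csv"), row.names = FALSE)
  reg_patterns <- stage("patterns", classify_visit_patterns(
    data.frame(id = registry$id, day = registry$day, hba1c = registry$hba1c,
               med_change = registry$med_change)))
  sustained <- stage("patterns", {
    users <- cohort$participants$id[cohort$participants$usage_class == "biweekly"]
    up <- patterns[patterns$id %in% users, ]
    compare_sustained_rates(
      nrow(up), sum(up$label == "sustained_decrease"),
      nrow(reg_patterns), sum(reg_patterns$label == "sustained_decrease"))
  })
  say("patterns", "%d participant and %d registry series classified",
      nrow(patterns), nrow(reg_patterns))
  bundle$patterns <- patterns; bundle$registry_patterns <- reg_patterns
  bundle$sustained_comparison <- sustained

  periods <- stage("exposure", all_quarterly_periods(cohort$visits,
                                                     cohort$completions))
  bins <- stage("exposure", exposure_response_bins(periods$themes_completed,
                                                   periods$delta_hba1c))
  utils::write.csv(bins, file.path(out_dir, "exposure_bins.csv"), row.names = FALSE)
  say("exposure", "%d quarterly periods in %d/%d/%d bins", nrow(periods),
      bins$n[1], bins$n[2], bins$n[3])
  bundle$periods <- periods; bundle$exposure_bins <- bins

  scores <- stage("bct", bct_scores(periods, catalog))
  utils::write.csv(scores, file.path(out_dir, "bct_scores.csv"), row.names = FALSE)
  bundle$bct_scores <- scores
  bundle$bct_test <- stage("bct", suppressWarnings(bct_chi_square(scores)))
  say("bct", "scored %d BCTs, chi-square %.2f (df %d)", nrow(scores),
      bundle$bct_test$statistic, bundle$bct_test$df)

  deltas <- stage("contrast", participant_deltas(cohort$visits))
  deltas <- merge(deltas, cohort$participants[c("id", "usage_class", "mod", "sex",
                                               "age", "bmi", "baseline_hba1c",
                                               "arm", "dropped_out")], by = "id")
  bundle$deltas <- deltas

  if (run_matching) {
    match <- stage("match", match_controls(cohort$participants, registry,
                                           ratio = match_ratio,
                                           seed = config$seed))
    utils::write.csv(match$balance, file.path(out_dir, "balance.csv"),
                     row.names = FALSE)
    say("match", "matched %d controls; max post-match |SMD| = %.3f",
        nrow(match$pairs), max(abs(match$balance$smd_post)))
    bundle$match <- match
    ctrl <- stage("contrast", control_deltas(match, registry))
    usage_sets <- list("biweekly" = "biweekly",
                       "monthly" = c("biweekly", "monthly"),
                       "bimonthly" = c("biweekly", "monthly", "bimonthly"))
    contrasts <- do.call(rbind, lapply(names(usage_sets), function(u) {
      ud <- deltas$delta[deltas$usage_class %in% usage_sets[[u]]]
      cd <- ctrl$delta
      est <- endpoint_contrast(ud, cd)
      data.frame(endpoint = "hba1c", usage = paste0("at_least_", u),
                 estimate = est$estimate, ci_lo = est$ci[1], ci_hi = est$ci[2],
                 p_value = est$p_value, n_users = length(ud),
                 n_controls = length(cd), stringsAsFactors = FALSE)
    }))
    utils::write.csv(contrasts, file.path(out_dir, "contrasts.csv"),
                     row.names = FALSE)
    say("contrast", "3 usage-class endpoint contrasts estimated")
    bundle$control_deltas <- ctrl; bundle$contrasts <- contrasts
  }

  if (run_weighting) {
    wd <- deltas[deltas$usage_class %in% c("biweekly", "nonuser"), ]
    feats <- wd[c("age", "bmi", "baseline_hba1c")]
    feats$male <- as.integer(wd$sex == "male")
    prop <- stage("weights", estimate_propensity(
      feats, wd$usage_class == "biweekly", max_trees = max_trees,
      cv_folds = cv_folds, seed = config$seed))
    w <- ipw_weights("user_vs_nonuser", prop$probabilities,
                     wd$usage_class == "biweekly")
    bundle$weighted_contrast <- stage("weights", weighted_group_difference(
      wd$delta, wd$usage_class == "biweekly", w))
    say("weights", "user-vs-nonuser IPW contrast %.2f (%d trees)",
        bundle$weighted_contrast$estimate, prop$n_trees)
    bundle$propensity <- prop
  }

  if (run_mediation) {
    wdel <- participant_deltas(cohort$visits, outcome = "weight")
    md <- merge(deltas, stats::setNames(wdel[c("id", "delta")],
                                        c("id", "weight_delta")), by = "id")
    themes_n <- table(cohort$completions$id)
    md$themes <- as.integer(themes_n[md$id])
    md$themes[is.na(md$themes)] <- 0L
    med <- stage("mediate", mediation(
      md$themes, md$weight_delta, md$delta,
      moderators = data.frame(bmi = md$bmi, male = md$sex == "male"),
      n_boot = n_boot, seed = config$seed))
    jsonlite::write_json(list(effects = med$effects,
                              ci = as.data.frame(med$boot_ci), n = med$n),
                         file.path(out_dir, "mediation.json"),
                         auto_unbox = TRUE, digits = NA)
    say("mediate", "indirect %.3f of total %.3f over %d subjects",
        med$effects$indirect, med$effects$total, med$n)
    bundle$mediation <- med
  }

  bundle$design <- stage("power", list(
    randomization = sample_size_two_groups(2, 6, 0.05, 0.80, 1),
    matched = sample_size_two_groups(5, 7, 0.05, 0.80, 2)
  ))
  say("power", "computed sample sizes %d and %d/%d",
      bundle$design$randomization$n_cases, bundle$design$matched$n_cases,
      bundle$design$matched$n_controls)

  manifest <- list(
    package_version = as.character(utils::packageVersion("glycotool")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(write_temp_config(config))),
    files = as.list(tools::md5sum(sort(list.files(out_dir, full.names = TRUE,
                                                  pattern = "\\.(csv|json)$"))))
  )
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bundle$manifest <- manifest
  class(bundle) <- "pipeline_bundle"
  invisible(bundle)
}

write_temp_config <- function(config) {
  p <- tempfile(fileext = ".R")
  writeLines(deparse(unclass(config)), p)
  p
}

read_yaml_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
  }
  yaml::read_yaml(path)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("Pipeline bundle (seed", x$config$seed, ")\n")
  cat("  participants:", nrow(x$cohort$participants),
      " registry:", length(unique(x$registry$id)), "\n")
  if (!is.null(x$contrasts)) {
    cat("  HbA1c contrasts vs matched controls:\n")
    print(x$contrasts[c("usage", "estimate", "ci_lo", "ci_hi")], row.names = FALSE)
  }
  invisible(x)
}

fmt_ci <- function(est, lo, hi, digits = 1) {
  sprintf("%.*f (%.*f to %.*f)", digits, est, digits, lo, digits, hi)
}

#' Render paper-shaped summary tables from a pipeline bundle
#'
#' Produces the baseline-characteristics table (mean (SD) / n (%)), the
#' key-endpoints table with "x (a to b)" formatted mean differences per
#' usage class, and the three-row exposure-response table.
#'
#' @param bundle a `"pipeline_bundle"` from [run_pipeline()].
#' @param dir optional directory; when given, each table is also written
#'   as CSV.
#' @return A list of data.frames: `baseline`, `endpoints`, `exposure`.
#' @export
render_tables <- function(bundle, dir = NULL) {
  if (is.null(bundle$cohort)) stop("bundle is missing the simulate stage output", call. = FALSE)
  p <- bundle$cohort$participants
  if (nrow(p) == 0) stop("empty cohort: nothing to render", call. = FALSE)
  msd <- function(x) sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
  npct <- function(flag) sprintf("%d (%.1f)", sum(flag), 100 * mean(flag))
  baseline <- data.frame(
    characteristic = c("Male sex - no. (%)", "Age - years", "Body mass index",
                       "Glycated hemoglobin - mmol/mol", "MOD - no. (%)"),
    value = c(npct(p$sex == "male"), msd(p$age), msd(p$bmi),
              msd(p$baseline_hba1c), npct(p$mod)),
    stringsAsFactors = FALSE
  )
  endpoints <- NULL
  if (!is.null(bundle$contrasts)) {
    cc <- bundle$contrasts
    endpoints <- data.frame(
      endpoint = cc$endpoint, usage = cc$usage,
      mean_difference = fmt_ci(cc$estimate, cc$ci_lo, cc$ci_hi),
      n = cc$n_users, stringsAsFactors = FALSE
    )
  }
  if (is.null(bundle$exposure_bins)) {
    stop("bundle is missing the exposure stage output", call. = FALSE)
  }
  eb <- bundle$exposure_bins
  exposure <- data.frame(
    themes_per_quarter = eb$bin, n_periods = eb$n,
    mean_delta_hba1c = round(eb$mean_delta, 2), sem = round(eb$sem, 3),
    stringsAsFactors = FALSE
  )
  out <- list(baseline = baseline, endpoints = endpoints, exposure = exposure)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      if (!is.null(out[[nm]])) {
        utils::write.csv(out[[nm]], file.path(dir, paste0("table_", nm, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  out
}
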