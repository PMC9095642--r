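#' Configuration for the synthetic trial cohort and registry pool
#'
#' Collects and validates every parameter of the synthetic-data generator.
#' Defaults encode the evaluated trial's conditions: 370 participants
#' (61.9% male, age 63.3 +/- 9.7 y, BMI 31.1 +/- 5.2, baseline HbA1c
#' 63.2 +/- 10.2 mmol/mol truncated at the 52 mmol/mol inclusion floor),
#' a 30% Mild Obesity-related Diabetes (MOD) subgroup, 1:1 randomization to
#' immediate access or a 12-week wait list with differential dropout
#' (14% vs 4%), usage-dependent HbA1c effects over follow-up
#' (-6.5 / -4.2 / -3.6 mmol/mol for biweekly / monthly / bimonthly users,
#' MOD extra -2.8), and a background secular drift of 0.15 NGSP %/year
#' (1.639 mmol/mol/year in IFCC units) shared with the registry controls.
#'
#' @param n_participants number of trial participants.
#' @param n_registry number of registry control patients; must be at least
#'   twice `n_participants` so 1:2 matching is feasible.
#' @param frac_male proportion of males.
#' @param age_mean_sd,bmi_mean_sd,hba1c_mean_sd length-2 numeric
#'   `c(mean, sd)` for age (years), BMI (kg/m^2) and baseline HbA1c
#'   (mmol/mol).
#' @param hba1c_floor inclusion threshold (mmol/mol); baseline HbA1c is
#'   drawn from a normal truncated below at this floor.
#' @param frac_mod proportion in the MOD subgroup.
#' @param dropout_tool,dropout_wait randomization-phase dropout
#'   probabilities per arm.
#' @param usage_class_probs probabilities of the four disjoint usage
#'   classes (biweekly, monthly, bimonthly, non-user); must sum to 1.
#' @param effect_biweekly,effect_monthly,effect_bimonthly usage-class HbA1c
#'   effects (mmol/mol) reached at full exposure, relative to control.
#' @param effect_mod_extra additional effect (mmol/mol) in MOD participants
#'   who actively use the tool.
#' @param control_drift_ngsp secular HbA1c drift in NGSP %/year applied to
#'   all subjects (participants and registry controls).
#' @param visit_noise_sd per-visit HbA1c measurement noise SD (mmol/mol).
#'   The default 6/sqrt(2) makes the SD of a between-visit change equal the
#'   6 mmol/mol used in the trial's power calculation.
#' @param med_change_prob per-visit probability of a glucose-lowering
#'   medication change (after baseline).
#' @param weight_effects usage-class body-weight effects in kg at full
#'   exposure (the mediated channel of the HbA1c response).
#' @param hba1c_per_kg mmol/mol HbA1c change per kg body-weight change;
#'   the generator splits each total usage effect into this weight-mediated
#'   part and a direct part.
#' @param follow_up_days length of follow-up (days).
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_participants = 370,
                          n_registry = 10000,
                          frac_male = 0.619,
                          age_mean_sd = c(63.3, 9.7),
                          bmi_mean_sd = c(31.1, 5.2),
                          hba1c_mean_sd = c(63.2, 10.2),
                          hba1c_floor = 52,
                          frac_mod = 0.30,
                          dropout_tool = 0.14,
                          dropout_wait = 0.04,
                          usage_class_probs = c(biweekly = 0.22, monthly = 0.31,
                                                bimonthly = 0.21, nonuser = 0.26),
                          effect_biweekly = -6.5,
                          effect_monthly = -4.2,
                          effect_bimonthly = -3.6,
                          effect_mod_extra = -2.8,
                          control_drift_ngsp = 0.15,
                          visit_noise_sd = 6 / sqrt(2),
                          med_change_prob = 0.01,
                          weight_effects = c(biweekly = -2.9, monthly = -2.2,
                                             bimonthly = -1.6, nonuser = 0),
                          hba1c_per_kg = 0.67,
                          follow_up_days = 1095,
                          seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants), n_registry = as.integer(n_registry),
    frac_male = frac_male, age_mean_sd = age_mean_sd, bmi_mean_sd = bmi_mean_sd,
    hba1c_mean_sd = hba1c_mean_sd, hba1c_floor = hba1c_floor, frac_mod = frac_mod,
    dropout_tool = dropout_tool, dropout_wait = dropout_wait,
    usage_class_probs = usage_class_probs,
    effect_biweekly = effect_biweekly, effect_monthly = effect_monthly,
    effect_bimonthly = effect_bimonthly, effect_mod_extra = effect_mod_extra,
    control_drift_ngsp = control_drift_ngsp, visit_noise_sd = visit_noise_sd,
    med_change_prob = med_change_prob, weight_effects = weight_effects,
    hba1c_per_kg = hba1c_per_kg, follow_up_days = as.integer(follow_up_days),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  prop_fields <- c("frac_male", "frac_mod", "dropout_tool", "dropout_wait",
                   "med_change_prob")
  for (f in prop_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      stop(sprintf("invalid configuration: '%s' must be a proportion in [0, 1]", f),
           call. = FALSE)
    }
  }
  p <- cfg$usage_class_probs
  if (length(p) != 4 || any(p < 0) || any(p > 1)) {
    stop("invalid configuration: 'usage_class_probs' must be 4 proportions in [0, 1]",
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("invalid configuration: 'usage_class_probs' must sum to 1", call. = FALSE)
  }
  for (f in c("age_mean_sd", "bmi_mean_sd", "hba1c_mean_sd")) {
    v <- cfg[[f]]
    if (length(v) != 2 || v[2] < 0) {
      stop(sprintf("invalid configuration: '%s' must be c(mean, sd) with sd >= 0", f),
           call. = FALSE)
    }
  }
  if (cfg$n_participants < 1) {
    stop("invalid configuration: 'n_participants' must be positive", call. = FALSE)
  }
  if (cfg$hba1c_floor > cfg$hba1c_mean_sd[1]) {
    stop("invalid configuration: 'hba1c_floor' must not exceed the HbA1c mean",
         call. = FALSE)
  }
  if (cfg$n_registry < 2 * cfg$n_participants) {
    stop("invalid configuration: 'n_registry' must be at least 2 x 'n_participants'",
         call. = FALSE)
  }
  if (cfg$visit_noise_sd < 0) {
    stop("invalid configuration: 'visit_noise_sd' must be non-negative", call. = FALSE)
  }
  invisible(cfg)
}

#' Convert an NGSP (%) HbA1c increment to IFCC units (mmol/mol)
#'
#' The master conversion is IFCC = 10.929 x (NGSP - 2.15); an increment
#' therefore converts with slope 10.929 alone.
#'
#' @param ngsp_delta change in NGSP percentage points.
#' @return Change in mmol/mol.
#' @export
ngsp_to_ifcc_delta <- function(ngsp_delta) 10.929 * ngsp_delta

USAGE_CLASSES <- c("biweekly", "monthly", "bimonthly", "nonuser")

# mean themes completed per quarter by usage class: a biweekly user completes
# ~6.5 themes per 91-day quarter; counts are overdispersed (negative binomial)
COMPLETION_MEANS <- c(biweekly = 6.5, monthly = 3.25, bimonthly = 1.6, nonuser = 0)
COMPLETION_NB_SIZE <- 5

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

rtruncnorm_floor <- function(n, mean, sd, floor) {
  if (sd == 0) return(rep(max(mean, floor), n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < floor)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

class_effect <- function(cfg, usage_class) {
  eff <- c(biweekly = cfg$effect_biweekly, monthly = cfg$effect_monthly,
           bimonthly = cfg$effect_bimonthly, nonuser = 0)
  unname(eff[usage_class])
}

#' Generate the synthetic trial cohort
#'
#' Draws participants, their visit series and their dated theme-completion
#' stream under the configured ground truth. The visit schedule is
#' quarterly (~91 days) in year 1 and semiannual (~182 days) thereafter,
#' with small jitter. Each HbA1c observation is
#' baseline + secular drift + usage effect + measurement noise, where the
#' usage effect ramps in linearly over the first year of active use (wait
#' arm: use starts at week 12) and is split into a direct part and a part
#' mediated through body-weight change. Dropouts contribute only their
#' baseline visit.
#'
#' @param config a [cohort_config()].
#' @return A list with class `"synthetic_cohort"`:
#'   `participants` (one row per participant), `visits` (long, one row per
#'   visit: `id, day, hba1c, weight, resistance, reactance, med_change`) and
#'   `completions` (`id, day, theme_id`).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    n <- config$n_participants
    sex <- ifelse(stats::runif(n) < config$frac_male, "male", "female")
    age <- stats::rnorm(n, config$age_mean_sd[1], config$age_mean_sd[2])
    height <- ifelse(sex == "male", stats::rnorm(n, 178, 7), stats::rnorm(n, 165, 7))
    bmi <- stats::rnorm(n, config$bmi_mean_sd[1], config$bmi_mean_sd[2])
    bmi <- pmax(bmi, 17)
    baseline_hba1c <- rtruncnorm_floor(n, config$hba1c_mean_sd[1],
                                       config$hba1c_mean_sd[2], config$hba1c_floor)
    arm <- sample(rep(c("tool", "wait"), length.out = n))
    mod <- stats::runif(n) < config$frac_mod
    usage_class <- sample(USAGE_CLASSES, n, replace = TRUE,
                          prob = config$usage_class_probs)
    dropped_out <- stats::runif(n) <
      ifelse(arm == "tool", config$dropout_tool, config$dropout_wait)
    education <- sample(c("basic", "medium", "college"), n, replace = TRUE,
                        prob = c(0.162, 0.315, 0.522))
    socioeconomic <- sample(c("employed", "unemployed", "retired", "sick_leave",
                              "own_household"), n, replace = TRUE,
                            prob = c(0.448, 0.021, 0.479, 0.043, 0.009))
    medication <- sample(c("none", "oral", "oral_insulin", "insulin"), n,
                         replace = TRUE, prob = c(0.039, 0.661, 0.219, 0.081))
    homa2_ir <- pmax(stats::rnorm(n, 2.6, 1.1), 0.3)
    homa2_b <- pmax(stats::rnorm(n, 75, 30), 10)
    # question counts: proportions ~55.5% concrete / 44.5% abstract of a
    # usage-scaled total
    q_total <- stats::rpois(n, 4 * COMPLETION_MEANS[usage_class] + 0.5)
    n_concrete <- stats::rbinom(n, q_total, 0.555)
    n_abstract <- q_total - n_concrete
    ffm_frac <- pmin(pmax(stats::rnorm(n, ifelse(sex == "male", 0.65, 0.55), 0.06),
                          0.40), 0.80)

    participants <- data.frame(
      id = sprintf("P%04d", seq_len(n)), sex = sex, age = age, height = height,
      bmi = bmi, baseline_hba1c = baseline_hba1c, arm = arm, mod = mod,
      usage_class = usage_class, dropped_out = dropped_out,
      education = education, socioeconomic = socioeconomic,
      medication = medication, homa2_ir = homa2_ir, homa2_b = homa2_b,
      n_abstract = n_abstract, n_concrete = n_concrete,
      stringsAsFactors = FALSE
    )

    drift_day <- ngsp_to_ifcc_delta(config$control_drift_ngsp) / 365.25
    weight_eff <- config$weight_effects

    visits_list <- vector("list", n)
    compl_list <- vector("list", n)
    for (i in seq_len(n)) {
      days <- visit_schedule(config$follow_up_days, dropped_out[i])
      start_day <- if (arm[i] == "tool") 0 else 84
      active <- usage_class[i] != "nonuser" && !dropped_out[i]
      ramp <- if (active) pmin(pmax(days - start_day, 0) / 365, 1) else rep(0, length(days))
      w_eff <- unname(weight_eff[usage_class[i]])
      total_eff <- class_effect(config, usage_class[i]) +
        if (mod[i] && usage_class[i] != "nonuser") config$effect_mod_extra else 0
      direct_eff <- total_eff - config$hba1c_per_kg * w_eff
      weight0 <- bmi[i] * (height[i] / 100)^2
      wnoise <- if (config$visit_noise_sd > 0) stats::rnorm(length(days), 0, 0.8) else
        rep(0, length(days))
      weight <- weight0 + ramp * w_eff + wnoise
      weight[1] <- weight0
      hnoise <- stats::rnorm(length(days), 0, config$visit_noise_sd)
      hnoise[1] <- 0
      hba1c <- baseline_hba1c[i] + drift_day * days + ramp * direct_eff +
        config$hba1c_per_kg * ramp * w_eff + hnoise
      reactance <- stats::rnorm(length(days), 50, 8)
      resistance <- invert_ffm_resistance(sex[i], height[i], weight,
                                          ffm_frac[i] * weight, reactance)
      med_change <- c(FALSE, stats::runif(length(days) - 1) < config$med_change_prob)
      visits_list[[i]] <- data.frame(
        id = participants$id[i], day = days, hba1c = hba1c, weight = weight,
        resistance = resistance, reactance = reactance, med_change = med_change,
        stringsAsFactors = FALSE
      )
      compl_list[[i]] <- draw_completions(participants$id[i], usage_class[i],
                                          start_day, days, dropped_out[i])
    }
    cohort <- list(
      participants = participants,
      visits = do.call(rbind, visits_list),
      completions = do.call(rbind, compl_list)
    )
    class(cohort) <- "synthetic_cohort"
    cohort
  })
}

# quarterly in year 1, semiannual thereafter, +/- a few days of jitter
visit_schedule <- function(follow_up_days, dropped_out) {
  if (dropped_out) return(0L)
  y1 <- 91 * 1:4 + sample(-7:7, 4, replace = TRUE)
  later <- if (follow_up_days >= 546) seq(546, follow_up_days, by = 182) else integer()
  if (length(later)) later <- later + sample(-10:10, length(later), replace = TRUE)
  days <- c(0L, y1, later)
  as.integer(days[days <= follow_up_days])
}

# solve the male/female FFM equation for resistance at a target FFM
invert_ffm_resistance <- function(sex, height, weight, target_ffm, reactance) {
  denom <- target_ffm + 4.104 - 0.231 * weight - 0.130 * reactance -
    4.229 * (sex == "male")
  if (any(denom <= 0)) {
    stop("bioimpedance inversion failed: target fat-free mass too low", call. = FALSE)
  }
  0.518 * height^2 / denom
}

draw_completions <- function(id, usage_class, start_day, days, dropped_out) {
  empty <- data.frame(id = character(), day = integer(), theme_id = character(),
                      stringsAsFactors = FALSE)
  if (dropped_out || usage_class == "nonuser") return(empty)
  last_day <- max(days)
  if (last_day <= start_day) return(empty)
  q_starts <- seq(start_day, last_day - 1, by = 91)
  mu <- COMPLETION_MEANS[usage_class]
  out <- lapply(q_starts, function(q0) {
    k <- stats::rnbinom(1, size = COMPLETION_NB_SIZE, mu = mu)
    span <- min(91, last_day - q0)
    if (k == 0 || span <= 0) return(empty)
    data.frame(
      id = id,
      day = as.integer(q0 + sort(sample.int(span, k, replace = TRUE))),
      theme_id = sprintf("theme%02d", sample.int(80, k, replace = TRUE)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Generate the synthetic registry control pool
#'
#' Registry patients carry baseline covariates drawn from the same
#' distributions as the trial participants (so matching is feasible),
#' a diagnosis date at day 0, routine-care HbA1c measurements every ~120
#' days over six years following the configured secular drift, and
#' stochastic medication-change events.
#'
#' @param config a [cohort_config()].
#' @return A long data.frame of class `"synthetic_registry"`, one row per
#'   measurement: `id, sex, age, bmi, diagnosis_day, day, hba1c, med_change`.
#'   `age` is age at diagnosis (day 0); `day` is days since diagnosis.
#' @export
generate_registry <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed + 1L, {
    n <- config$n_registry
    sex <- ifelse(stats::runif(n) < config$frac_male, "male", "female")
    age <- stats::rnorm(n, config$age_mean_sd[1], config$age_mean_sd[2])
    bmi <- pmax(stats::rnorm(n, config$bmi_mean_sd[1], config$bmi_mean_sd[2]), 17)
    hba1c0 <- rtruncnorm_floor(n, config$hba1c_mean_sd[1], config$hba1c_mean_sd[2],
                               # registry pool is not truncated at the trial floor;
                               # keep a physiologic lower bound
                               35)
    drift_day <- ngsp_to_ifcc_delta(config$control_drift_ngsp) / 365.25
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      gaps <- round(stats::runif(18, 90, 150))
      days <- as.integer(cumsum(gaps))
      days <- days[days <= 2190]
      noise <- stats::rnorm(length(days), 0, config$visit_noise_sd)
      rows[[i]] <- data.frame(
        id = sprintf("R%05d", i), sex = sex[i], age = age[i], bmi = bmi[i],
        diagnosis_day = 0L, day = days,
        hba1c = hba1c0[i] + drift_day * days + noise,
        med_change = stats::runif(length(days)) < config$med_change_prob,
        stringsAsFactors = FALSE
      )
    }
    registry <- do.call(rbind, rows)
    class(registry) <- c("synthetic_registry", class(registry))
    registry
  })
}

#' Generate the theme/BCT catalog
#'
#' Builds the 80-theme catalog in which each theme incorporates 2-4
#' behaviour change techniques (BCTs) drawn from a pool of 24, with
#' per-theme dominance weights normalised to sum to 1. Every one of the
#' 24 BCTs appears in at least one theme.
#'
#' @param seed integer seed.
#' @param n_themes,n_bct catalog dimensions.
#' @return An object of class `"theme_catalog"`: a named list `themes`
#'   mapping theme id to a named numeric vector of BCT weights.
#' @export
generate_theme_catalog <- function(seed = 1L, n_themes = 80L, n_bct = 24L) {
  with_seed(as.integer(seed) + 2L, {
    bct_ids <- sprintf("bct%02d", seq_len(n_bct))
    sizes <- sample(2:4, n_themes, replace = TRUE)
    themes <- lapply(sizes, function(k) sample(bct_ids, k))
    # guarantee full BCT coverage: plant missing BCTs into random slots
    missing <- setdiff(bct_ids, unique(unlist(themes)))
    for (b in missing) {
      repeat {
        t <- sample.int(n_themes, 1)
        slot <- sample.int(length(themes[[t]]), 1)
        cand <- themes[[t]]
        cand[slot] <- b
        if (!anyDuplicated(cand)) {
          themes[[t]] <- cand
          break
        }
      }
    }
    themes <- lapply(themes, function(ids) {
      w <- stats::rexp(length(ids))
      stats::setNames(w / sum(w), ids)
    })
    names(themes) <- sprintf("theme%02d", seq_len(n_themes))
    structure(list(themes = themes), class = "theme_catalog")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic trial cohort:", nrow(x$participants), "participants,",
      nrow(x$visits), "visits,", nrow(x$completions), "theme completions\n")
  cat(sprintf("  male: %.1f%%; MOD: %.1f%%; dropped out: %d\n",
              100 * mean(x$participants$sex == "male"),
              100 * mean(x$participants$mod), sum(x$participants$dropped_out)))
  invisible(x)
}

#' @export
print.theme_catalog <- function(x, ...) {
  sizes <- lengths(x$themes)
  cat("Theme catalog:", length(x$themes), "themes,",
      length(unique(names(unlist(unname(x$themes))))), "distinct BCTs,",
      "themes carry", min(sizes), "-", max(sizes), "BCTs each\n")
  invisible(x)
}

#' Write the synthetic data bundle as delimited text
#'
#' Writes `participants.csv`, `visits.csv` (long), `completions.csv`,
#' `registry.csv` and `themes.json` to `dir`. Comma-separated UTF-8 with a
#' header row; dates are integer day offsets. The round trip through
#' [read_cohort_files()] is lossless.
#'
#' @param cohort a `"synthetic_cohort"`.
#' @param registry a `"synthetic_registry"` (optional).
#' @param catalog a `"theme_catalog"` (optional).
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_files <- function(cohort, registry = NULL, catalog = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, file) {
    p <- file.path(dir, file)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    p
  }
  paths <- c(paths, wr(cohort$participants, "participants.csv"),
             wr(cohort$visits, "visits.csv"),
             wr(cohort$completions, "completions.csv"))
  if (!is.null(registry)) {
    paths <- c(paths, wr(as.data.frame(unclass(registry)), "registry.csv"))
  }
  if (!is.null(catalog)) {
    p <- file.path(dir, "themes.json")
    jsonlite::write_json(lapply(catalog$themes, as.list), p,
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a synthetic data bundle written by [write_cohort_files()]
#'
#' @param dir directory holding the CSV/JSON files.
#' @return A list with `cohort` (class `"synthetic_cohort"`), and, when
#'   present on disk, `registry` and `catalog`.
#' @export
read_cohort_files <- function(dir) {
  rd <- function(file) {
    utils::read.csv(file.path(dir, file), stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
  }
  cohort <- list(participants = rd("participants.csv"), visits = rd("visits.csv"),
                 completions = rd("completions.csv"))
  # logical columns survive the text round trip as "TRUE"/"FALSE" strings
  cohort$participants$mod <- as.logical(cohort$participants$mod)
  cohort$participants$dropped_out <- as.logical(cohort$participants$dropped_out)
  cohort$visits$med_change <- as.logical(cohort$visits$med_change)
  if (nrow(cohort$completions) == 0) {
    cohort$completions <- data.frame(id = character(), day = integer(),
                                     theme_id = character(), stringsAsFactors = FALSE)
  }
  class(cohort) <- "synthetic_cohort"
  out <- list(cohort = cohort)
  if (file.exists(file.path(dir, "registry.csv"))) {
    reg <- rd("registry.csv")
    reg$med_change <- as.logical(reg$med_change)
    class(reg) <- c("synthetic_registry", class(reg))
    out$registry <- reg
  }
  if (file.exists(file.path(dir, "themes.json"))) {
    raw <- jsonlite::read_json(file.path(dir, "themes.json"))
    themes <- lapply(raw, function(t) unlist(t))
    out$catalog <- structure(list(themes = themes), class = "theme_catalog")
  }
  out
}
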