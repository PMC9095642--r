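#' Standardized mean difference
#'
#' `(mean_a - mean_b) / sqrt((s_a^2 + s_b^2) / 2)`, the usual covariate
#' balance diagnostic. With weights, weighted means and weighted
#' (population-form) variances are used.
#'
#' @param a,b numeric samples for the two groups.
#' @param w_a,w_b optional non-negative weights.
#' @return The SMD; error if the pooled SD is zero.
#' @export
smd <- function(a, b, w_a = NULL, w_b = NULL) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty", call. = FALSE)
  if (is.null(w_a)) w_a <- rep(1, length(a))
  if (is.null(w_b)) w_b <- rep(1, length(b))
  m <- function(x, w) sum(w * x) / sum(w)
  v <- function(x, w) {
    mu <- m(x, w)
    sum(w * (x - mu)^2) / sum(w)
  }
  pooled <- sqrt((v(a, w_a) + v(b, w_b)) / 2)
  if (pooled == 0) stop("pooled standard deviation is zero; SMD undefined", call. = FALSE)
  (m(a, w_a) - m(b, w_b)) / pooled
}

#' Select matched registry controls
#'
#' Greedy 1:`ratio` nearest-neighbour matching without replacement, exact
#' on sex, on the Mahalanobis distance over the requested covariates. For
#' every registry patient an index date is first drawn uniformly at random
#' among admissible measurement dates - at least two years after the
#' diagnosis date and with no medication change during the follow-up
#' window after it. Covariates at the index date are age (baseline age
#' plus elapsed time) and the HbA1c measured at that date. The Mahalanobis
#' metric uses the covariance of the eligible candidate pool, per sex
#' stratum. Participants are processed in random order under `seed`.
#'
#' @param participants data.frame with `id, sex` and the matching
#'   covariates (default `age, bmi, baseline_hba1c` mapped to registry
#'   `age, bmi, hba1c` at index).
#' @param registry long registry data.frame from [generate_registry()].
#' @param ratio controls per participant (default 2).
#' @param follow_up_days medication-change-free follow-up window required
#'   after the index date.
#' @param seed integer seed for index-date draws and processing order.
#' @return An object of class `"match_result"`: `pairs` (data.frame
#'   `participant_id, control_id`), `index_dates` (named vector, day per
#'   control), and `balance` (pre/post SMD per covariate).
#' @export
match_controls <- function(participants, registry, ratio = 2,
                           follow_up_days = 730, seed = 1L) {
  with_seed(as.integer(seed) + 3L, {
    cand <- registry_candidates(registry, follow_up_days)
    covars_p <- c("age", "bmi", "baseline_hba1c")
    covars_c <- c("age_index", "bmi", "hba1c_index")
    pairs <- list()
    index_dates <- numeric()
    for (s in unique(participants$sex)) {
      ps <- participants[participants$sex == s, , drop = FALSE]
      cs <- cand[cand$sex == s, , drop = FALSE]
      if (nrow(cs) < ratio * nrow(ps)) {
        stop(sprintf(
          "insufficient eligible controls in stratum sex=%s: need %d, have %d",
          s, ratio * nrow(ps), nrow(cs)), call. = FALSE)
      }
      S <- stats::cov(cs[, covars_c])
      Sinv <- solve(S)
      avail <- rep(TRUE, nrow(cs))
      X <- as.matrix(cs[, covars_c])
      for (i in sample(nrow(ps))) {
        x <- as.numeric(ps[i, covars_p])
        d <- stats::mahalanobis(X[avail, , drop = FALSE], x, Sinv, inverted = TRUE)
        pick <- which(avail)[order(d)[seq_len(ratio)]]
        avail[pick] <- FALSE
        pairs[[length(pairs) + 1]] <- data.frame(
          participant_id = ps$id[i], control_id = cs$id[pick],
          stringsAsFactors = FALSE)
        index_dates[cs$id[pick]] <- cs$index_day[pick]
      }
    }
    pairs <- do.call(rbind, pairs)
    matched <- cand[match(pairs$control_id, cand$id), ]
    balance <- data.frame(
      covariate = covars_p,
      smd_pre = vapply(seq_along(covars_p), function(j)
        smd(participants[[covars_p[j]]], cand[[covars_c[j]]]), numeric(1)),
      smd_post = vapply(seq_along(covars_p), function(j)
        smd(participants[[covars_p[j]]], matched[[covars_c[j]]]), numeric(1)),
      stringsAsFactors = FALSE
    )
    structure(list(pairs = pairs, index_dates = index_dates, balance = balance,
                   candidates = cand),
              class = "match_result")
  })
}

# one row per registry patient with an admissible, randomly drawn index date
registry_candidates <- function(registry, follow_up_days) {
  out <- lapply(split(registry, registry$id), function(r) {
    r <- r[order(r$day), ]
    admissible <- r$day >= r$diagnosis_day[1] + 730
    ok <- vapply(seq_len(nrow(r)), function(j) {
      if (!admissible[j]) return(FALSE)
      win <- r$day > r$day[j] & r$day <= r$day[j] + follow_up_days
      any(win) && !any(r$med_change[win] | r$med_change[j])
    }, logical(1))
    if (!any(ok)) return(NULL)
    j <- sample(which(ok), 1)
    data.frame(id = r$id[1], sex = r$sex[1], bmi = r$bmi[1],
               index_day = r$day[j],
               age_index = r$age[1] + r$day[j] / 365.25,
               hba1c_index = r$hba1c[j],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat("Matched", length(unique(x$pairs$participant_id)), "participants to",
      nrow(x$pairs), "controls without replacement\n")
  cat("Covariate balance (SMD):\n")
  print(x$balance, row.names = FALSE)
  invisible(x)
}

#' Propensity scores by gradient boosting
#'
#' Estimates per-subject probabilities of the binary label with a
#' gradient-boosted tree ensemble (shrinkage 0.001, interaction depth 3 by
#' default). The number of trees is chosen to minimise the average
#' absolute standardized mean difference across features under the implied
#' inverse-probability weights, evaluated on cross-validated out-of-fold
#' probabilities. Missing feature values are handled natively by the
#' boosting algorithm, which splits only on observed values.
#'
#' @param features numeric matrix or data.frame of covariates (may contain
#'   `NA`).
#' @param labels binary vector (0/1 or logical): 1 = treated/user.
#' @param shrinkage learning rate.
#' @param depth maximum tree depth.
#' @param max_trees largest ensemble size considered.
#' @param cv_folds number of cross-validation folds.
#' @param grid_step tree counts are evaluated every `grid_step` trees.
#' @param seed integer seed (fold assignment).
#' @return A list: `probabilities` (in (0,1)), `n_trees` (selected count),
#'   `cv_smd` (mean |SMD| per candidate count).
#' @export
estimate_propensity <- function(features, labels, shrinkage = 0.001, depth = 3,
                                max_trees = 200, cv_folds = 5, grid_step = 20,
                                seed = 1L) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) {
    stop("labels must contain both classes", call. = FALSE)
  }
  X <- as.matrix(data.matrix(as.data.frame(features)))
  storage.mode(X) <- "double"
  with_seed(as.integer(seed) + 4L, {
    params <- list(objective = "binary:logistic", eta = shrinkage,
                   max_depth = depth, nthread = 1, subsample = 1,
                   colsample_bytree = 1)
    grid <- unique(c(seq(grid_step, max_trees, by = grid_step), max_trees))
    folds <- sample(rep(seq_len(cv_folds), length.out = nrow(X)))
    oof <- matrix(NA_real_, nrow(X), length(grid))
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      bst <- xgboost::xgb.train(
        params = params,
        data = xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = labels[tr]),
        nrounds = max_trees, verbose = 0)
      dte <- xgboost::xgb.DMatrix(X[!tr, , drop = FALSE])
      for (g in seq_along(grid)) {
        oof[!tr, g] <- stats::predict(bst, dte, iterationrange = c(1, grid[g]))
      }
    }
    mean_abs_smd <- apply(oof, 2, function(p) {
      p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
      w <- ifelse(labels == 1, 1 / p, 1 / (1 - p))
      vals <- vapply(seq_len(ncol(X)), function(j) {
        xj <- X[, j]
        ok <- !is.na(xj)
        tryCatch(abs(smd(xj[ok & labels == 1], xj[ok & labels == 0],
                         w[ok & labels == 1], w[ok & labels == 0])),
                 error = function(e) NA_real_)
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    })
    n_trees <- grid[which.min(mean_abs_smd)]
    bst <- xgboost::xgb.train(
      params = params,
      data = xgboost::xgb.DMatrix(X, label = labels),
      nrounds = n_trees, verbose = 0)
    p <- stats::predict(bst, xgboost::xgb.DMatrix(X))
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    list(probabilities = p, n_trees = n_trees,
         cv_smd = stats::setNames(mean_abs_smd, grid))
  })
}

#' Inverse-probability analysis weights
#'
#' The three weighting schemes of the analysis plan:
#' * `"dropout_adjust"`: weight = 1/p(non-dropout) in the treatment group,
#'   exactly 1 in the wait group;
#' * `"adherence_adjust"`: weight = 1/p(recommended use) in the access
#'   group, exactly 1 in the wait group;
#' * `"user_vs_nonuser"`: weight = 1/p(user) for users and 1/(1 - p(user))
#'   for non-users.
#'
#' Weights are returned as-is, never silently normalised.
#'
#' @param scheme one of the three scheme names.
#' @param probabilities per-subject probabilities in (0,1).
#' @param treated logical: in the treatment/access/user group.
#' @return Numeric weights, one per subject.
#' @export
ipw_weights <- function(scheme = c("dropout_adjust", "adherence_adjust",
                                   "user_vs_nonuser"),
                        probabilities, treated) {
  scheme <- match.arg(scheme)
  if (any(probabilities <= 0 | probabilities >= 1)) {
    stop("probabilities must lie strictly in (0, 1)", call. = FALSE)
  }
  treated <- as.logical(treated)
  if (scheme == "user_vs_nonuser") {
    ifelse(treated, 1 / probabilities, 1 / (1 - probabilities))
  } else {
    ifelse(treated, 1 / probabilities, 1)
  }
}

#' Weighted two-group difference with sandwich standard errors
#'
#' Weighted least squares of the outcome change on the group indicator,
#' with a heteroskedasticity-consistent (HC1) sandwich standard error to
#' account for the analysis weights.
#'
#' @param outcome_delta numeric outcome changes.
#' @param group two-level factor or logical (`TRUE` = treated); the
#'   estimate is treated minus reference.
#' @param weights non-negative analysis weights (default unweighted).
#' @param conf_level confidence level.
#' @return A list `estimate, se, ci, p_value, n`.
#' @export
weighted_group_difference <- function(outcome_delta, group, weights = NULL,
                                      conf_level = 0.95) {
  g <- if (is.logical(group)) factor(group, c(FALSE, TRUE)) else factor(group)
  if (nlevels(droplevels(g)) != 2) stop("exactly two groups are required", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(outcome_delta))
  if (any(weights < 0) || all(weights[g == levels(g)[1]] == 0) ||
      all(weights[g == levels(g)[2]] == 0)) {
    stop("weights must be non-negative with positive mass in both groups", call. = FALSE)
  }
  dat <- data.frame(y = outcome_delta, g = g, w = weights)
  fit <- stats::lm(y ~ g, data = dat, weights = w)
  est <- stats::coef(fit)[2]
  se <- sqrt(sandwich::vcovHC(fit, type = "HC1")[2, 2])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = unname(est), se = se,
       ci = unname(c(est - z * se, est + z * se)),
       p_value = 2 * stats::pnorm(-abs(est / se)),
       n = length(outcome_delta))
}

#' Unweighted endpoint contrast (Welch t-test)
#'
#' Two-sided independent-samples t-test with unequal variances; the
#' difference is reported as group a minus group b.
#'
#' @param a,b outcome changes in the two groups (n >= 2 each).
#' @param conf_level confidence level.
#' @return A list `estimate, ci, p_value, n`.
#' @export
endpoint_contrast <- function(a, b, conf_level = 0.95) {
  if (length(a) < 2 || length(b) < 2) {
    stop("at least 2 observations per group are required", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, conf.level = conf_level)
  list(estimate = unname(diff(rev(tt$estimate))), ci = as.numeric(tt$conf.int),
       p_value = tt$p.value, n = c(length(a), length(b)))
}

#' Group-by-subgroup interaction test
#'
#' Ordinary least squares of the outcome change on group, subgroup and
#' their product, optionally adjusted for covariates; reports the product
#' coefficient and its two-sided p-value.
#'
#' @param outcome_delta outcome changes.
#' @param group,subgroup logical or two-level factors.
#' @param covariates optional data.frame of adjustment covariates.
#' @return A list `interaction, se, p_value, fit`.
#' @export
interaction_test <- function(outcome_delta, group, subgroup, covariates = NULL) {
  g <- as.integer(as.logical(group))
  s <- as.integer(as.logical(subgroup))
  if (length(unique(g)) < 2 || length(unique(s)) < 2 || any(table(g, s) == 0)) {
    stop("all four group x subgroup cells must be non-empty", call. = FALSE)
  }
  dat <- data.frame(y = outcome_delta, g = g, s = s)
  form <- y ~ g * s
  if (!is.null(covariates)) {
    dat <- cbind(dat, covariates)
    form <- stats::reformulate(c("g * s", names(covariates)), response = "y")
  }
  fit <- stats::lm(form, data = dat)
  sm <- summary(fit)$coefficients
  list(interaction = sm["g:s", "Estimate"], se = sm["g:s", "Std. Error"],
       p_value = sm["g:s", "Pr(>|t|)"], fit = fit)
}

#' Mediation decomposition with bootstrap confidence intervals
#'
#' Linear no-interaction mediation: the a-path regresses the mediator on
#' the exposure (plus mean-centred moderator covariates), the b- and
#' direct paths come from the outcome model on exposure and mediator.
#' The indirect effect is a x b, the total effect is direct + indirect
#' (algebraically equal to the exposure coefficient of the reduced outcome
#' model), and the proportion mediated is indirect / total. Percentile
#' bootstrap intervals resample whole subjects.
#'
#' @param exposure,mediator,outcome numeric vectors per subject (e.g.
#'   themes completed, weight change, HbA1c change).
#' @param moderators optional data.frame of covariates, mean-centred
#'   internally.
#' @param n_boot bootstrap draws (>= 1000 advised for reported intervals).
#' @param conf_level confidence level.
#' @param seed integer seed.
#' @return An object of class `"mediation_result"`: `effects` (total,
#'   direct, indirect, prop_mediated), `boot_ci` (percentile interval per
#'   component), `n`, `n_boot`.
#' @export
mediation <- function(exposure, mediator, outcome, moderators = NULL,
                      n_boot = 5000, conf_level = 0.95, seed = 1L) {
  dat <- data.frame(x = exposure, m = mediator, y = outcome)
  if (!is.null(moderators)) {
    mods <- as.data.frame(lapply(as.data.frame(moderators), function(v) {
      v <- as.numeric(v)
      v - mean(v, na.rm = TRUE)
    }))
    names(mods) <- paste0("z", seq_along(mods))
    dat <- cbind(dat, mods)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 10) stop("fewer than 10 complete cases", call. = FALSE)
  zs <- grep("^z", names(dat), value = TRUE)
  point <- mediation_paths(dat, zs)
  boot <- with_seed(as.integer(seed) + 5L, {
    replicate(n_boot, {
      idx <- sample.int(nrow(dat), replace = TRUE)
      unlist(mediation_paths(dat[idx, , drop = FALSE], zs))
    })
  })
  alpha <- 1 - conf_level
  boot_ci <- apply(boot, 1, stats::quantile,
                   probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
  structure(list(effects = point, boot_ci = t(boot_ci), n = nrow(dat),
                 n_boot = n_boot),
            class = "mediation_result")
}

mediation_paths <- function(dat, zs) {
  rhs_x <- c("x", zs)
  fm_m <- stats::lm(stats::reformulate(rhs_x, "m"), data = dat)
  fm_y <- stats::lm(stats::reformulate(c("x", "m", zs), "y"), data = dat)
  a <- stats::coef(fm_m)[["x"]]
  b <- stats::coef(fm_y)[["m"]]
  direct <- stats::coef(fm_y)[["x"]]
  indirect <- a * b
  total <- direct + indirect
  list(total = total, direct = direct, indirect = indirect,
       prop_mediated = if (total != 0) indirect / total else NA_real_)
}

#' @export
print.mediation_result <- function(x, ...) {
  eff <- x$effects
  cat(sprintf("Mediation decomposition (n = %d, %d bootstrap draws)\n", x$n, x$n_boot))
  for (k in c("total", "direct", "indirect", "prop_mediated")) {
    ci <- x$boot_ci[k, ]
    cat(sprintf("  %-14s %8.4f  [%0.4f, %0.4f]\n", k, eff[[k]], ci[1], ci[2]))
  }
  invisible(x)
}

#' Sample size for a two-group comparison of means
#'
#' Normal-approximation formula for a two-sided test:
#' `n_cases = ceil((1 + 1/k) * (z_{1-alpha/2} + z_{power})^2 * sd^2 / delta^2)`
#' with `n_controls = k * n_cases` for allocation ratio `k` controls per
#' case.
#'
#' @param delta true difference in means (mmol/mol).
#' @param sd common standard deviation of the outcome change.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param allocation_ratio controls per case, k >= 1.
#' @return A list `n_cases, n_controls`.
#' @examples
#' sample_size_two_groups(2, 6)        # 142 per group
#' sample_size_two_groups(5, 7, allocation_ratio = 2)  # 24 cases, 48 controls
#' @export
sample_size_two_groups <- function(delta, sd, alpha = 0.05, power = 0.80,
                                   allocation_ratio = 1) {
  if (delta == 0) stop("delta must be non-zero", call. = FALSE)
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  }
  if (allocation_ratio < 1) stop("allocation_ratio must be >= 1", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n_cases <- ceiling((1 + 1 / allocation_ratio) * z^2 * sd^2 / delta^2)
  list(n_cases = n_cases, n_controls = allocation_ratio * n_cases)
}

#' Empirical power of the two-sided two-sample t-test
#'
#' Monte-Carlo rejection rate of the Welch t-test under a normal
#' alternative with the given mean difference and common SD.
#'
#' @param n_cases,n_controls per-group sample sizes.
#' @param delta true mean difference.
#' @param sd common standard deviation.
#' @param alpha two-sided level.
#' @param reps Monte-Carlo replicates.
#' @param seed integer seed.
#' @return Proportion of replicates rejecting the null.
#' @export
empirical_power <- function(n_cases, n_controls, delta, sd, alpha = 0.05,
                            reps = 10000, seed = 1L) {
  with_seed(as.integer(seed) + 6L, {
    A <- matrix(stats::rnorm(n_cases * reps, delta, sd), n_cases)
    B <- matrix(stats::rnorm(n_controls * reps, 0, sd), n_controls)
    ma <- colMeans(A); mb <- colMeans(B)
    va <- colSums((A - rep(ma, each = n_cases))^2) / (n_cases - 1)
    vb <- colSums((B - rep(mb, each = n_controls))^2) / (n_controls - 1)
    sa <- va / n_cases; sb <- vb / n_controls
    tstat <- (ma - mb) / sqrt(sa + sb)
    df <- (sa + sb)^2 / (sa^2 / (n_cases - 1) + sb^2 / (n_controls - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    mean(p < alpha)
  })
}
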