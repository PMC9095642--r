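#' Eligibility rule for trajectory analysis
#'
#' A series enters the HbA1c progression-pattern analysis when its baseline
#' (first measurement in the analysis frame) is at or above the inclusion
#' floor, it has a minimum number of measurements inside the time frame,
#' and - when required - no glucose-lowering medication change occurred
#' inside the frame.
#'
#' @param min_measurements minimum measurements inside the frame (default 3).
#' @param frame_days length of the analysis frame in days (default 1095,
#'   i.e. three years).
#' @param baseline_floor minimum baseline HbA1c in mmol/mol (default 52).
#' @param require_no_med_change drop series with a medication change inside
#'   the frame (default `TRUE`).
#' @return A list of class `"eligibility_rule"`.
#' @export
eligibility_rule <- function(min_measurements = 3L, frame_days = 1095L,
                             baseline_floor = 52, require_no_med_change = TRUE) {
  if (min_measurements < 2) stop("min_measurements must be >= 2", call. = FALSE)
  if (frame_days <= 0) stop("frame_days must be positive", call. = FALSE)
  structure(list(min_measurements = as.integer(min_measurements),
                 frame_days = as.integer(frame_days),
                 baseline_floor = baseline_floor,
                 require_no_med_change = isTRUE(require_no_med_change)),
            class = "eligibility_rule")
}

#' Is a visit series eligible for pattern classification?
#'
#' @param days integer day offsets of the HbA1c measurements, sorted
#'   ascending.
#' @param hba1c HbA1c values (mmol/mol) at those days.
#' @param med_change logical medication-change flags per measurement
#'   (optional; taken as all-`FALSE` when missing).
#' @param rule an [eligibility_rule()].
#' @return `TRUE` or `FALSE`.
#' @export
is_eligible <- function(days, hba1c, med_change = NULL, rule = eligibility_rule()) {
  if (length(days) == 0) stop("series is empty", call. = FALSE)
  if (is.unsorted(days, strictly = TRUE)) {
    stop("series days must be strictly increasing", call. = FALSE)
  }
  if (is.null(med_change)) med_change <- rep(FALSE, length(days))
  frame <- days - days[1] <= rule$frame_days
  keep <- frame & !is.na(hba1c)
  if (sum(keep) < rule$min_measurements) return(FALSE)
  if (hba1c[which(keep)[1]] < rule$baseline_floor) return(FALSE)
  if (rule$require_no_med_change && any(med_change[frame], na.rm = TRUE)) return(FALSE)
  TRUE
}

PATTERN_LEVELS <- c("sustained_decrease", "sustained_increase",
                    "oscillatory_decreasing", "oscillatory_increasing",
                    "unclassifiable")

#' Classify an HbA1c trajectory into a progression pattern
#'
#' Follow-up measurements are compared against the baseline (the first
#' measurement of the frame). Rules are applied in order, first match wins:
#'
#' 1. *Sustained decrease*: at least one measurement strictly below
#'    baseline and all others at or below baseline.
#' 2. *Sustained increase*: at least one strictly above and all others at
#'    or above baseline.
#' 3. *Oscillatory, predominantly decreasing*: the majority (strictly more
#'    than half), but not all, of the measurements at or below baseline.
#' 4. *Oscillatory, predominantly increasing*: half or more, but not all,
#'    of the measurements strictly above baseline.
#'
#' A series in which every follow-up equals baseline matches no rule and is
#' `"unclassifiable"`.
#'
#' @param baseline baseline HbA1c (mmol/mol).
#' @param followups numeric vector of follow-up HbA1c values, length >= 1.
#' @return One of `"sustained_decrease"`, `"sustained_increase"`,
#'   `"oscillatory_decreasing"`, `"oscillatory_increasing"`,
#'   `"unclassifiable"`.
#' @export
classify_pattern <- function(baseline, followups) {
  if (length(followups) < 1) stop("at least one follow-up value is required", call. = FALSE)
  if (anyNA(c(baseline, followups))) stop("missing HbA1c values", call. = FALSE)
  below <- followups < baseline
  above <- followups > baseline
  at_or_below <- followups <= baseline
  if (any(below) && all(at_or_below)) return("sustained_decrease")
  if (any(above) && all(!below)) return("sustained_increase")
  k <- length(followups)
  n_le <- sum(at_or_below)
  if (n_le > k / 2 && n_le < k) return("oscillatory_decreasing")
  n_gt <- sum(above)
  if (n_gt >= k / 2 && n_gt < k) return("oscillatory_increasing")
  "unclassifiable"
}

#' Tabulate pattern labels
#'
#' @param labels character vector of pattern labels from
#'   [classify_pattern()].
#' @return A data.frame with one row per label (`label`, `n`, `proportion`);
#'   counts sum to `length(labels)` and proportions to 1.
#' @export
pattern_table <- function(labels) {
  if (length(labels) == 0) stop("at least one classified series is required", call. = FALSE)
  f <- factor(labels, levels = PATTERN_LEVELS)
  if (anyNA(f)) stop("unknown pattern label", call. = FALSE)
  n <- as.vector(table(f))
  data.frame(label = PATTERN_LEVELS, n = n, proportion = n / length(labels),
             stringsAsFactors = FALSE)
}

#' Classify all eligible series in a long visits table
#'
#' Applies [is_eligible()] and [classify_pattern()] per subject. The
#' baseline is the first in-frame measurement; follow-ups are the remaining
#' in-frame measurements.
#'
#' @param visits long data.frame with columns `id`, `day`, `hba1c` and
#'   optionally `med_change`.
#' @param rule an [eligibility_rule()].
#' @return A data.frame `id, label, n_measurements, frame_span_days` with
#'   one row per eligible subject.
#' @export
classify_visit_patterns <- function(visits, rule = eligibility_rule()) {
  stopifnot(all(c("id", "day", "hba1c") %in% names(visits)))
  out <- lapply(split(visits, visits$id), function(v) {
    v <- v[order(v$day), ]
    mc <- if ("med_change" %in% names(v)) v$med_change else NULL
    ok <- tryCatch(is_eligible(v$day, v$hba1c, mc, rule), error = function(e) FALSE)
    if (!ok) return(NULL)
    infr <- v[v$day - v$day[1] <= rule$frame_days & !is.na(v$hba1c), ]
    data.frame(id = v$id[1],
               label = classify_pattern(infr$hba1c[1], infr$hba1c[-1]),
               n_measurements = nrow(infr),
               frame_span_days = max(infr$day) - min(infr$day),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(id = character(), label = character(),
                      n_measurements = integer(), frame_span_days = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Compare sustained-improvement rates by Fisher's exact test
#'
#' Two-sided exact p-value for the 2x2 table of sustained improvers versus
#' others in tool users and registry controls, from the hypergeometric
#' distribution with fixed margins.
#'
#' @param n_users,k_users_sustained group size and number with sustained
#'   improvement among tool users.
#' @param n_controls,k_controls_sustained likewise for controls.
#' @return A list with `p_value`, the 2x2 `table`, and the sample estimate
#'   of the two proportions.
#' @export
compare_sustained_rates <- function(n_users, k_users_sustained,
                                    n_controls, k_controls_sustained) {
  if (k_users_sustained > n_users || k_controls_sustained > n_controls ||
      any(c(n_users, k_users_sustained, n_controls, k_controls_sustained) < 0)) {
    stop("counts must satisfy 0 <= k <= n in both groups", call. = FALSE)
  }
  tab <- matrix(c(k_users_sustained, n_users - k_users_sustained,
                  k_controls_sustained, n_controls - k_controls_sustained),
                nrow = 2,
                dimnames = list(c("sustained", "other"), c("users", "controls")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(p_value = p, table = tab,
       proportions = c(users = k_users_sustained / n_users,
                       controls = k_controls_sustained / n_controls))
}
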