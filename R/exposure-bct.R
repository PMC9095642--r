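#' Quarterly exposure periods for one participant
#'
#' Builds one record per pair of adjacent first-year visits at which HbA1c
#' was measured: the number of themes completed during the period and the
#' change of HbA1c relative to the previous visit. Completions are counted
#' in the half-open interval (previous visit day, current visit day], so an
#' event on a visit day belongs to the period that ends that day. Periods
#' with a missing bounding HbA1c are omitted, not imputed.
#'
#' @param days,hba1c the participant's visit days (sorted, unique) and
#'   HbA1c values.
#' @param completion_days integer days of the participant's theme
#'   completions.
#' @param completion_themes optional theme ids parallel to
#'   `completion_days`; carried through for BCT scoring.
#' @param year1_days only visits up to this day form quarterly periods
#'   (default 400, covering the quarterly schedule of year 1).
#' @return A data.frame `quarter_index, start_day, end_day,
#'   themes_completed, delta_hba1c, themes` (list column of theme ids, when
#'   supplied).
#' @export
quarterly_periods <- function(days, hba1c, completion_days = integer(),
                              completion_themes = NULL, year1_days = 400) {
  if (anyDuplicated(days)) stop("duplicate visit days", call. = FALSE)
  if (is.unsorted(days)) stop("visit days must be sorted", call. = FALSE)
  keep <- days <= year1_days
  days <- days[keep]
  hba1c <- hba1c[keep]
  if (length(days) < 2) {
    return(data.frame(quarter_index = integer(), start_day = integer(),
                      end_day = integer(), themes_completed = integer(),
                      delta_hba1c = numeric()))
  }
  out <- vector("list", length(days) - 1)
  for (j in seq_len(length(days) - 1)) {
    if (is.na(hba1c[j]) || is.na(hba1c[j + 1])) next
    sel <- completion_days > days[j] & completion_days <= days[j + 1]
    rec <- data.frame(quarter_index = j, start_day = days[j], end_day = days[j + 1],
                      themes_completed = sum(sel),
                      delta_hba1c = hba1c[j + 1] - hba1c[j])
    if (!is.null(completion_themes)) {
      rec$themes <- I(list(completion_themes[sel]))
    }
    out[[j]] <- rec
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(quarter_index = integer(), start_day = integer(),
                      end_day = integer(), themes_completed = integer(),
                      delta_hba1c = numeric())
  }
  rownames(res) <- NULL
  res
}

#' Quarterly periods for every participant in a long visits table
#'
#' @param visits long data.frame `id, day, hba1c`.
#' @param completions data.frame `id, day, theme_id` of dated theme events.
#' @inheritParams quarterly_periods
#' @return Row-bound [quarterly_periods()] output with an `id` column and a
#'   `themes` list column.
#' @export
all_quarterly_periods <- function(visits, completions, year1_days = 400) {
  comp_split <- split(completions, completions$id)
  out <- lapply(split(visits, visits$id), function(v) {
    v <- v[order(v$day), ]
    cp <- comp_split[[v$id[1]]]
    if (is.null(cp)) cp <- data.frame(day = integer(), theme_id = character())
    qp <- quarterly_periods(v$day, v$hba1c, cp$day, cp$theme_id, year1_days)
    if (nrow(qp) == 0) return(NULL)
    cbind(id = v$id[1], qp, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exposure-response bins over quarterly periods
#'
#' Summarises the change of HbA1c per quarterly period in three exposure
#' bins: no completed themes, 1-4 themes, and at least 5 themes.
#'
#' @param themes_completed integer completions per period.
#' @param delta_hba1c HbA1c change per period (mmol/mol).
#' @return A data.frame `bin, n, mean_delta, sem` (SEM = sd/sqrt(n); an
#'   empty bin has n = 0 and undefined mean/SEM).
#' @export
exposure_response_bins <- function(themes_completed, delta_hba1c) {
  if (length(themes_completed) < 1) stop("at least one period is required", call. = FALSE)
  if (length(themes_completed) != length(delta_hba1c)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  bin <- cut(themes_completed, c(-Inf, 0, 4, Inf), labels = c("0", "1-4", ">=5"))
  out <- lapply(levels(bin), function(b) {
    d <- delta_hba1c[bin == b]
    n <- length(d)
    data.frame(bin = b, n = n,
               mean_delta = if (n) mean(d) else NA_real_,
               sem = if (n > 1) stats::sd(d) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Weighted BCT responder / non-responder scores
#'
#' For every theme and quarterly period, participants who completed the
#' theme during the period are split into responders (HbA1c lower at the
#' end of the period than at the start, i.e. delta < 0) and non-responders
#' (similar or higher, delta >= 0). Each count is multiplied by the theme's
#' BCT dominance weights and accumulated over the four quarters and over
#' all themes, giving one responder and one non-responder score per BCT.
#'
#' @param periods data.frame from [all_quarterly_periods()] with columns
#'   `id, quarter_index, delta_hba1c` and a `themes` list column of theme
#'   ids completed in the period. A theme completed several times in one
#'   period by one participant counts once for that participant-period
#'   (set `count_repeats = TRUE` to count every completion event).
#' @param catalog a `"theme_catalog"`.
#' @param count_repeats count repeated completions of the same theme within
#'   a period multiply (default `FALSE`).
#' @return A data.frame `bct, responder_score, nonresponder_score`, one row
#'   per BCT appearing in a completed theme.
#' @export
bct_scores <- function(periods, catalog, count_repeats = FALSE) {
  acc_r <- new.env(parent = emptyenv())
  acc_n <- new.env(parent = emptyenv())
  add <- function(env, key, val) {
    assign(key, val + (if (exists(key, env)) get(key, env) else 0), env)
  }
  for (i in seq_len(nrow(periods))) {
    th <- periods$themes[[i]]
    if (length(th) == 0) next
    if (!count_repeats) th <- unique(th)
    responder <- periods$delta_hba1c[i] < 0
    for (t in th) {
      w <- catalog$themes[[t]]
      if (is.null(w)) stop(sprintf("unknown theme id '%s'", t), call. = FALSE)
      for (b in names(w)) {
        add(if (responder) acc_r else acc_n, b, w[[b]])
        add(if (responder) acc_n else acc_r, b, 0)
      }
    }
  }
  bcts <- sort(ls(acc_r))
  data.frame(
    bct = bcts,
    responder_score = vapply(bcts, get, numeric(1), envir = acc_r),
    nonresponder_score = vapply(bcts, get, numeric(1), envir = acc_n),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Chi-square homogeneity test on the BCT score table
#'
#' Pearson chi-square on the 2 x K table of responder and non-responder
#' scores per BCT, treating the weighted scores as counts (as in the
#' source analysis). Because the scores are weighted sums, the statistic
#' scales with any common rescaling of the theme weights; a warning notes
#' this caveat whenever the scores are non-integer. BCTs with a zero column
#' total are excluded with a warning.
#'
#' @param scores data.frame from [bct_scores()].
#' @return A list `statistic, df, p_value, expected`.
#' @export
bct_chi_square <- function(scores) {
  tab <- rbind(responder = scores$responder_score,
               nonresponder = scores$nonresponder_score)
  colnames(tab) <- scores$bct
  zero <- colSums(tab) == 0
  if (any(zero)) {
    warning("excluding BCT column(s) with zero total: ",
            paste(colnames(tab)[zero], collapse = ", "))
    tab <- tab[, !zero, drop = FALSE]
  }
  if (ncol(tab) < 2) stop("at least 2 BCTs with positive totals are required", call. = FALSE)
  if (any(abs(tab - round(tab)) > 1e-9)) {
    warning("scores are non-integer weighted sums; the chi-square statistic ",
            "scales with the theme-weight normalisation")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- ncol(tab) - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}
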