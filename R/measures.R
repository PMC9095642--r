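#' Fat-free mass from single-frequency bioimpedance (Geneva equation)
#'
#' Sex-specific single bioelectrical-impedance-analysis prediction of
#' fat-free mass. Both sexes share the same resistance, weight and reactance
#' terms; males receive an additional constant of 4.229 kg.
#'
#' @param sex character vector, `"male"` or `"female"`.
#' @param height_cm standing height in centimetres.
#' @param weight_kg body weight in kilograms.
#' @param resistance_ohm whole-body resistance in ohms.
#' @param reactance_ohm whole-body reactance in ohms.
#' @return Fat-free mass in kg (vectorised over all arguments).
#' @examples
#' fat_free_mass("male", 175, 90, 480, 50)
#' @export
fat_free_mass <- function(sex, height_cm, weight_kg, resistance_ohm, reactance_ohm) {
  sex <- check_sex(sex)
  stop_if_nonpositive(height_cm, "height_cm")
  stop_if_nonpositive(weight_kg, "weight_kg")
  stop_if_nonpositive(resistance_ohm, "resistance_ohm")
  if (any(reactance_ohm < 0, na.rm = TRUE)) {
    stop("reactance_ohm must be non-negative", call. = FALSE)
  }
  -4.104 +
    0.518 * height_cm^2 / resistance_ohm +
    0.231 * weight_kg +
    0.130 * reactance_ohm +
    4.229 * (sex == "male")
}

#' Total body water from bioimpedance (Sun equations)
#'
#' Sex-specific multi-component prediction of total body water from the
#' height-squared-over-resistance index and body weight.
#'
#' @inheritParams fat_free_mass
#' @return Total body water in kg.
#' @export
total_body_water <- function(sex, height_cm, weight_kg, resistance_ohm) {
  sex <- check_sex(sex)
  stop_if_nonpositive(height_cm, "height_cm")
  stop_if_nonpositive(weight_kg, "weight_kg")
  stop_if_nonpositive(resistance_ohm, "resistance_ohm")
  ht2r <- height_cm^2 / resistance_ohm
  ifelse(sex == "male",
         1.20 + 0.45 * ht2r + 0.18 * weight_kg,
         3.75 + 0.45 * ht2r + 0.11 * weight_kg)
}

#' Body composition from raw bioimpedance
#'
#' Chains the fat-free-mass prediction into fat mass (weight minus FFM) and
#' muscle mass. Muscle mass is taken as the FFM remaining after removing
#' extracellular water (29%) and bone mineral (7%), i.e. 0.64 x FFM.
#' A predicted FFM at or above body weight is treated as an implausible
#' measurement and raised as an error rather than clipped.
#'
#' @inheritParams fat_free_mass
#' @return A data.frame with columns `ffm_kg`, `tbw_kg`, `fm_kg`, `mm_kg`,
#'   `fat_pct`, `muscle_pct` (percentages of body weight).
#' @export
body_composition <- function(sex, height_cm, weight_kg, resistance_ohm, reactance_ohm) {
  ffm <- fat_free_mass(sex, height_cm, weight_kg, resistance_ohm, reactance_ohm)
  if (any(ffm >= weight_kg, na.rm = TRUE)) {
    bad <- which(ffm >= weight_kg)
    stop(sprintf(
      "implausible measurement: predicted fat-free mass >= body weight for %d input(s) (first at index %d)",
      length(bad), bad[1]), call. = FALSE)
  }
  tbw <- total_body_water(sex, height_cm, weight_kg, resistance_ohm)
  fm <- weight_kg - ffm
  mm <- MM_FFM_FACTOR * ffm
  data.frame(
    ffm_kg = ffm,
    tbw_kg = tbw,
    fm_kg = fm,
    mm_kg = mm,
    fat_pct = 100 * fm / weight_kg,
    muscle_pct = 100 * mm / weight_kg
  )
}

# muscle mass = FFM - extracellular water (29%) - bone mineral (7%)
MM_FFM_FACTOR <- 1 - 0.29 - 0.07

#' IPAQ MET-minutes per week
#'
#' Weekly metabolic-equivalent minutes from self-reported activity, using
#' the IPAQ scoring protocol's MET values: 8.0 for vigorous activity, 4.0
#' for moderate activity and 3.3 for walking.
#'
#' @param vigorous_min_wk,moderate_min_wk,walking_min_wk minutes per week.
#' @return MET-minutes per week.
#' @export
ipaq_met_minutes <- function(vigorous_min_wk, moderate_min_wk, walking_min_wk) {
  if (any(c(vigorous_min_wk, moderate_min_wk, walking_min_wk) < 0, na.rm = TRUE)) {
    stop("activity minutes must be non-negative", call. = FALSE)
  }
  8.0 * vigorous_min_wk + 4.0 * moderate_min_wk + 3.3 * walking_min_wk
}

#' Convert MET-minutes to kilocalories
#'
#' MET-minute scores equal kilocalories for a 60-kg person; for other body
#' weights kcal = MET-minutes x weight / 60.
#'
#' @param met_minutes MET-minutes per week, non-negative.
#' @param weight_kg body weight in kilograms, positive.
#' @return Kilocalories per week.
#' @export
ipaq_to_kcal <- function(met_minutes, weight_kg) {
  if (any(met_minutes < 0, na.rm = TRUE)) {
    stop("met_minutes must be non-negative", call. = FALSE)
  }
  stop_if_nonpositive(weight_kg, "weight_kg")
  met_minutes * weight_kg / 60
}

#' Yearly per-user cost of providing the tool
#'
#' Sums non-negative per-user yearly cost components (server, email,
#' administration/technical personnel, ...) and also reports the total
#' rounded to one decimal.
#'
#' @param components numeric vector of $/user/year components; may be empty.
#' @return A list with `total` (exact sum) and `rounded` (one decimal).
#' @examples
#' tool_cost_per_user(c(0.13, 0.23, 7.12))
#' @export
tool_cost_per_user <- function(components = numeric()) {
  if (any(components < 0, na.rm = TRUE)) {
    stop("cost components must be non-negative", call. = FALSE)
  }
  total <- sum(components)
  list(total = total, rounded = round(total, 1))
}

#' Add derived body-composition columns to a long visits table
#'
#' Vectorised convenience wrapper: takes the long visits table (one row per
#' visit, with `weight`, `resistance`, `reactance`) plus per-participant sex
#' and height, and appends `ffm_kg, fm_kg, mm_kg, fat_pct, muscle_pct`.
#'
#' @param visits data.frame with columns `id`, `weight`, `resistance`,
#'   `reactance`.
#' @param participants data.frame with columns `id`, `sex`, `height`.
#' @return `visits` with the five derived columns appended.
#' @export
add_body_composition <- function(visits, participants) {
  need <- c("id", "weight", "resistance", "reactance")
  if (!all(need %in% names(visits))) {
    stop("visits must contain columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  idx <- match(visits$id, participants$id)
  if (anyNA(idx)) stop("visits reference ids absent from participants", call. = FALSE)
  bc <- body_composition(participants$sex[idx], participants$height[idx],
                         visits$weight, visits$resistance, visits$reactance)
  cbind(visits, bc[c("ffm_kg", "fm_kg", "mm_kg", "fat_pct", "muscle_pct")])
}

check_sex <- function(sex) {
  sex <- as.character(sex)
  bad <- !sex %in% c("male", "female") & !is.na(sex)
  if (any(bad)) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  sex
}

stop_if_nonpositive <- function(x, name) {
  if (any(x <= 0, na.rm = TRUE)) {
    stop(sprintf("%s must be positive", name), call. = FALSE)
  }
  invisible(x)
}
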