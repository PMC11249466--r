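#' Incisional hernia complexity score
#'
#' One point is awarded for each triggered risk category; comorbidity-related
#' risk factors are collapsed to a single joint point.  The point-bearing
#' categories are:
#'
#' 1. `large_defect` — defect width strictly above 10 cm,
#' 2. `lateral_site` — lateral defect site,
#' 3. `recurrent` — recurrent hernia,
#' 4. `age_over_80` — age strictly over 80 years,
#' 5. `bmi_over_30` — BMI strictly over 30 kg/m^2,
#' 6. `comorbidity` — any of: metabolic comorbidity (e.g. diabetes), elevated
#'    intra-abdominal pressure (e.g. chronic obstructive airways disease),
#'    increased bleeding risk, reduced wound healing, abnormal gait — at most
#'    one point jointly however many are present,
#' 7. `stoma_or_bowel` — concomitant stoma or intra-abdominal bowel repair,
#' 8. `intensified_surgery` — intensified surgery such as component
#'    separation.
#'
#' Age and BMI are treated as standalone categories, not part of the
#' comorbidity cluster; only the explicitly comorbidity-related factors
#' collapse.  The maximum attainable score is therefore 8.  Thresholds are
#' strict (`> 10` cm, `> 80` years, `> 30` kg/m^2).
#'
#' @param profile a single patient profile: a list or one-row data.frame with
#'   fields `age`, `bmi`, `defect_width`, `lateral_site`, `recurrent`,
#'   `metabolic_comorbidity`, `elevated_iap`, `bleeding_risk`,
#'   `reduced_wound_healing`, `abnormal_gait`, `concomitant_stoma_or_bowel`,
#'   `intensified_surgery`.
#' @return list of class `grip_complexity` with `score` (integer 0..8),
#'   `triggered_categories` (character) and `comorbidity_collapsed` (logical:
#'   whether two or more comorbidity flags were merged into the single point).
#' @examples
#' p <- list(age = 50, bmi = 25, defect_width = 4, lateral_site = FALSE,
#'           recurrent = FALSE, metabolic_comorbidity = FALSE,
#'           elevated_iap = FALSE, bleeding_risk = FALSE,
#'           reduced_wound_healing = FALSE, abnormal_gait = FALSE,
#'           concomitant_stoma_or_bowel = FALSE, intensified_surgery = FALSE)
#' score_complexity(p)$score   # 0
#' @export
score_complexity <- function(profile) {
  need <- c("age", "bmi", "defect_width", "lateral_site", "recurrent",
            "metabolic_comorbidity", "elevated_iap", "bleeding_risk",
            "reduced_wound_healing", "abnormal_gait",
            "concomitant_stoma_or_bowel", "intensified_surgery")
  missing <- setdiff(need, names(profile))
  if (length(missing))
    stop("validation error: profile missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  comorb_flags <- c(metabolic_comorbidity = isTRUE(as.logical(profile$metabolic_comorbidity)),
                    elevated_iap = isTRUE(as.logical(profile$elevated_iap)),
                    bleeding_risk = isTRUE(as.logical(profile$bleeding_risk)),
                    reduced_wound_healing = isTRUE(as.logical(profile$reduced_wound_healing)),
                    abnormal_gait = isTRUE(as.logical(profile$abnormal_gait)))
  cats <- c(
    large_defect = as.numeric(profile$defect_width) > 10,
    lateral_site = isTRUE(as.logical(profile$lateral_site)),
    recurrent = isTRUE(as.logical(profile$recurrent)),
    age_over_80 = as.numeric(profile$age) > 80,
    bmi_over_30 = as.numeric(profile$bmi) > 30,
    comorbidity = any(comorb_flags),
    stoma_or_bowel = isTRUE(as.logical(profile$concomitant_stoma_or_bowel)),
    intensified_surgery = isTRUE(as.logical(profile$intensified_surgery)))
  structure(
    list(score = as.integer(sum(cats)),
         triggered_categories = names(cats)[cats],
         comorbidity_collapsed = sum(comorb_flags) >= 2L),
    class = "grip_complexity")
}

#' @export
print.grip_complexity <- function(x, ...) {
  cat(sprintf("Incisional hernia complexity score: %d\n", x$score))
  if (length(x$triggered_categories))
    cat("  categories:", paste(x$triggered_categories, collapse = ", "), "\n")
  if (x$comorbidity_collapsed)
    cat("  (multiple comorbidity-related factors collapsed to one point)\n")
  invisible(x)
}

#' Score every row of a registry table
#'
#' Appends `complexity_score` and `triggered_categories` (semicolon-joined)
#' columns to a registry data.frame; the single-patient rule is
#' [score_complexity()].
#'
#' @param registry registry data.frame.
#' @return the registry with the two columns appended (an existing
#'   `complexity_score` column is overwritten with the recomputed value).
#' @export
score_registry <- function(registry) {
  stopifnot(is.data.frame(registry))
  res <- lapply(seq_len(nrow(registry)), function(i) score_complexity(registry[i, ]))
  registry$complexity_score <- vapply(res, `[[`, integer(1), "score")
  registry$triggered_categories <-
    vapply(res, function(r) paste(r$triggered_categories, collapse = ";"), character(1))
  registry
}
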