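#' Registry schema
#'
#' Column names and types of a registry table.  The schema carries the core
#' demographic, comorbidity and hernia risk-factor fields feeding the
#' complexity score, the mesh-plan extension fields recorded for
#' biomechanically calculated reconstruction (form of mesh, minimal overlap,
#' number and kind of fixation, pull-out/adapting sutures, peritoneal closure
#' type and the mesh-defect area ratio inputs), and the follow-up outcome
#' fields.  Files are comma-separated UTF-8 with a mandatory header; booleans
#' are encoded 0/1; categorical labels are a lower-snake-case controlled
#' vocabulary; decimal point, never comma.
#'
#' @return data.frame with columns `column`, `type` (`character`, `integer`,
#'   `numeric`, `logical`), `role`.
#' @export
registry_schema <- function() {
  rbind(
    data.frame(column = "patient_id", type = "character", role = "identity"),
    data.frame(column = c("age", "preop_pain"), type = "integer", role = "profile"),
    data.frame(column = "sex", type = "character", role = "profile"),
    data.frame(column = c("bmi", "defect_width", "defect_length", "distension"),
               type = "numeric", role = "profile"),
    data.frame(column = c("lateral_site", "recurrent", "metabolic_comorbidity",
                          "elevated_iap", "bleeding_risk", "reduced_wound_healing",
                          "abnormal_gait", "concomitant_stoma_or_bowel",
                          "intensified_surgery"),
               type = "logical", role = "profile"),
    data.frame(column = c("mesh_width", "mesh_length", "minimal_overlap"),
               type = "numeric", role = "mesh_plan"),
    data.frame(column = c("mesh_form", "adhesiveness_class", "position_class",
                          "fixation_type"),
               type = "character", role = "mesh_plan"),
    data.frame(column = "fixation_points", type = "integer", role = "mesh_plan"),
    data.frame(column = c("peritoneal_closure", "fascial_closure"),
               type = "logical", role = "mesh_plan"),
    data.frame(column = "los_days", type = "integer", role = "outcome"),
    data.frame(column = c("intraop_complication", "postop_complication",
                          "reoperation_30d", "recurrence_3y"),
               type = "logical", role = "outcome"),
    data.frame(column = c("pain_discharge", "pain_1m_rest", "pain_1m_exercise",
                          "pain_6m_rest", "pain_6m_exercise", "pain_1y_rest",
                          "pain_1y_exercise", "pain_3y_rest", "pain_3y_exercise"),
               type = "integer", role = "outcome"))
}

position_classes <- function() {
  c("onlay", "retromuscular", "preperitoneal", "intraperitoneal_underlay")
}

fixation_types <- function() {
  c("none", "absorbable_tack", "nonresorbable_suture", "pull_out_suture",
    "bone_anchor", "fibrin_glue")
}

#' Validate a registry table against the schema invariants
#'
#' Checks every row: pain scores in 0..10, positive dimensions and BMI,
#' non-negative age, distension and fixation counts, sex in
#' \{female, male\}, fixation type and mesh position in the controlled
#' vocabulary, length of stay >= 1.  Violations are reported with the row
#' index and the violated bound; exactly the violating rows are rejected.
#'
#' @param registry data.frame to validate.
#' @return the validated registry, invisibly, with logical columns coerced.
#' @export
validate_registry <- function(registry) {
  stopifnot(is.data.frame(registry))
  sch <- registry_schema()
  missing <- setdiff(sch$column, names(registry))
  if (length(missing))
    stop("schema error: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in sch$column[sch$type == "logical"]) {
    v <- registry[[col]]
    if (!all(v %in% c(0, 1, TRUE, FALSE)))
      bad_row(col, which(!v %in% c(0, 1, TRUE, FALSE)), "must be 0/1")
    registry[[col]] <- as.logical(as.integer(as.logical(v)))
  }
  check <- function(col, ok, msg) if (any(!ok)) bad_row(col, which(!ok), msg)
  nas <- function(v) is.finite(v) & v >= 0 & v <= 10 & v == round(v)
  check("age", is.finite(registry$age) & registry$age >= 0, "must be >= 0")
  check("sex", registry$sex %in% c("female", "male"), "must be 'female' or 'male'")
  check("bmi", is.finite(registry$bmi) & registry$bmi > 0, "must be > 0")
  check("preop_pain", nas(registry$preop_pain), "NAS bound: integer in [0, 10]")
  check("defect_width", is.finite(registry$defect_width) & registry$defect_width > 0,
        "must be > 0")
  check("defect_length", is.finite(registry$defect_length) & registry$defect_length > 0,
        "must be > 0")
  check("distension", is.finite(registry$distension) & registry$distension >= 0,
        "must be >= 0")
  check("mesh_width", is.finite(registry$mesh_width) & registry$mesh_width > 0,
        "must be > 0")
  check("mesh_length", is.finite(registry$mesh_length) & registry$mesh_length > 0,
        "must be > 0")
  check("minimal_overlap", is.finite(registry$minimal_overlap) & registry$minimal_overlap >= 0,
        "must be >= 0")
  check("position_class", registry$position_class %in% position_classes(),
        paste("must be one of:", paste(position_classes(), collapse = ", ")))
  check("fixation_type", registry$fixation_type %in% fixation_types(),
        paste("must be one of:", paste(fixation_types(), collapse = ", ")))
  check("fixation_points",
        is.finite(registry$fixation_points) & registry$fixation_points >= 0 &
          registry$fixation_points == round(registry$fixation_points),
        "must be a non-negative integer")
  check("los_days",
        is.finite(registry$los_days) & registry$los_days >= 1 &
          registry$los_days == round(registry$los_days),
        "must be an integer >= 1")
  for (col in grep("^pain_", sch$column, value = TRUE))
    check(col, nas(registry[[col]]), "NAS bound: integer in [0, 10]")
  for (col in sch$column[sch$type == "integer"])
    registry[[col]] <- as.integer(registry[[col]])
  invisible(registry)
}

bad_row <- function(col, rows, msg) {
  stop(sprintf("validation error: column '%s' %s (row %s)",
               col, msg, paste(utils::head(rows, 5), collapse = ", ")),
       call. = FALSE)
}

#' Read and write registry files
#'
#' Registry files are comma-separated UTF-8 text with a mandatory header row
#' naming all schema columns ([registry_schema()]); booleans are written as
#' 0/1.  Unknown columns are retained as opaque extras, so
#' `read_registry(write_registry(x)) == x` field for field.  Every row is
#' validated on read; a missing mandatory column raises a schema error naming
#' the column, an invariant violation a validation error with the row index.
#'
#' @param path CSV file path.
#' @return `read_registry()` returns a validated data.frame (logical columns
#'   as logicals).
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("schema error: file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_registry(raw)
}

#' @rdname read_registry
#' @param registry registry data.frame (validated before writing).
#' @export
write_registry <- function(registry, path) {
  registry <- validate_registry(registry)
  out <- registry
  for (col in names(out))
    if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
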