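#' GRIP coefficient tables
#'
#' A coefficient table holds the multipliers and additive factors entering the
#' gained-resistance (GRIP) score: a multiplier per mesh adhesiveness class,
#' per mesh position in the abdominal wall, a multiplier per fixation type
#' looked up by point-count band, and additive factors credited for peritoneal
#' and fascial closure.  All multipliers must be strictly positive; looking up
#' a class that is absent from the table is an error, never a silent default.
#'
#' The clinically validated coefficient values are published elsewhere and are
#' therefore always supplied by configuration.  The package ships two tables:
#' [identity_coefficients()], an explicitly labelled placeholder in which every
#' multiplier is 1 and every factor 0 (so GRIP reduces to the mesh-defect area
#' ratio), and [synthetic_coefficients()], an illustrative synthetic table
#' calibrated only in order of magnitude to published GRIP values, used by the
#' synthetic cohort generator.
#'
#' @param adhesiveness named numeric vector, multiplier per mesh adhesiveness
#'   class (e.g. `dis_class_a`).
#' @param position named numeric vector, multiplier per mesh position class
#'   (`onlay`, `retromuscular`, `preperitoneal`, `intraperitoneal_underlay`).
#' @param fixation named list, one element per fixation type; each element a
#'   data.frame with columns `max_points` (upper band edge, non-decreasing,
#'   last entry `Inf`) and `multiplier` (> 0).  A fixation count `p` uses the
#'   first band with `p <= max_points`.
#' @param peritoneal_closure_factor,fascial_closure_factor additive credit
#'   (>= 0) applied when the respective closure is performed.
#' @param placeholder logical; marks a table whose values are placeholders
#'   rather than clinically derived.  Planning and assessment functions refuse
#'   placeholder tables unless explicitly allowed.
#' @return An object of class `grip_coefficients`.
#' @seealso [read_coefficients()], [grip_score()]
#' @export
coefficient_table <- function(adhesiveness, position, fixation,
                              peritoneal_closure_factor = 0,
                              fascial_closure_factor = 0,
                              placeholder = FALSE) {
  check_multiplier_map(adhesiveness, "adhesiveness")
  check_multiplier_map(position, "position")
  adhesiveness <- stats::setNames(as.numeric(adhesiveness), names(adhesiveness))
  position <- stats::setNames(as.numeric(position), names(position))
  if (!is.list(fixation) || is.null(names(fixation)) || any(names(fixation) == ""))
    stop("config error: 'fixation' must be a named list of band tables", call. = FALSE)
  fixation <- lapply(fixation, as_fixation_bands)
  for (ty in names(fixation)) {
    b <- fixation[[ty]]
    if (any(!is.finite(b$multiplier)) || any(b$multiplier <= 0))
      stop(sprintf("config error: non-positive fixation multiplier for type '%s'", ty),
           call. = FALSE)
    if (is.unsorted(b$max_points, strictly = TRUE))
      stop(sprintf("config error: fixation bands for '%s' must have strictly increasing max_points", ty),
           call. = FALSE)
    if (!is.infinite(b$max_points[nrow(b)]))
      stop(sprintf("config error: last fixation band for '%s' must be open-ended (max_points Inf/null)", ty),
           call. = FALSE)
  }
  for (f in c(peritoneal_closure_factor, fascial_closure_factor))
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 0)
      stop("config error: closure factors must be single non-negative numbers", call. = FALSE)
  structure(
    list(adhesiveness = adhesiveness,
         position = position,
         fixation = fixation,
         peritoneal_closure_factor = as.numeric(peritoneal_closure_factor),
         fascial_closure_factor = as.numeric(fascial_closure_factor),
         placeholder = isTRUE(placeholder)),
    class = "grip_coefficients")
}

check_multiplier_map <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L || is.null(names(x)) || any(names(x) == ""))
    stop(sprintf("config error: '%s' must be a non-empty named numeric vector", what),
         call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("config error: non-positive multiplier in '%s' section", what),
         call. = FALSE)
  invisible(x)
}

as_fixation_bands <- function(b) {
  if (is.data.frame(b)) {
    if (!all(c("max_points", "multiplier") %in% names(b)))
      stop("config error: fixation band table needs 'max_points' and 'multiplier'", call. = FALSE)
    out <- b[, c("max_points", "multiplier")]
  } else if (is.list(b)) {
    # list of {max_points, multiplier} records as parsed from JSON/YAML
    out <- data.frame(
      max_points = vapply(b, function(e) {
        mp <- e[["max_points"]]
        if (is.null(mp)) Inf else as.numeric(mp)
      }, numeric(1)),
      multiplier = vapply(b, function(e) as.numeric(e[["multiplier"]]), numeric(1)))
  } else {
    stop("config error: fixation bands must be a data.frame or list of records", call. = FALSE)
  }
  out$max_points <- as.numeric(out$max_points)
  out$max_points[is.na(out$max_points)] <- Inf
  rownames(out) <- NULL
  out
}

#' @rdname coefficient_table
#' @export
identity_coefficients <- function() {
  types <- c("none", "absorbable_tack", "nonresorbable_suture",
             "pull_out_suture", "bone_anchor", "fibrin_glue")
  fix <- lapply(types, function(t) data.frame(max_points = Inf, multiplier = 1))
  names(fix) <- types
  coefficient_table(
    adhesiveness = c(dis_class_a = 1, dis_class_b = 1, standard = 1),
    position = c(onlay = 1, retromuscular = 1, preperitoneal = 1,
                 intraperitoneal_underlay = 1),
    fixation = fix,
    peritoneal_closure_factor = 0,
    fascial_closure_factor = 0,
    placeholder = TRUE)
}

#' @rdname coefficient_table
#' @export
synthetic_coefficients <- function() {
  # Synthetic, illustrative values: chosen so that GRIP magnitudes for typical
  # mesh plans resemble the hundreds-range scores reported for biomechanically
  # calculated repairs.  They are NOT the published clinical coefficients.
  coefficient_table(
    adhesiveness = c(dis_class_a = 4, dis_class_b = 2, standard = 1),
    position = c(onlay = 1, retromuscular = 2, preperitoneal = 1.5,
                 intraperitoneal_underlay = 1.2),
    fixation = list(
      none = data.frame(max_points = Inf, multiplier = 1),
      absorbable_tack = data.frame(max_points = c(25, 60, 120, Inf),
                                   multiplier = c(1.5, 2, 2.5, 3)),
      nonresorbable_suture = data.frame(max_points = c(20, 60, 120, Inf),
                                        multiplier = c(2, 3.5, 5, 6)),
      pull_out_suture = data.frame(max_points = Inf, multiplier = 4),
      bone_anchor = data.frame(max_points = c(100, Inf), multiplier = c(5, 8)),
      fibrin_glue = data.frame(max_points = Inf, multiplier = 1.5)),
    peritoneal_closure_factor = 10,
    fascial_closure_factor = 20,
    placeholder = FALSE)
}

#' Read or write a coefficient configuration
#'
#' Coefficient configs are JSON or YAML (decided by file extension) with the
#' five sections `adhesiveness`, `position`, `fixation`,
#' `peritoneal_closure_factor` and `fascial_closure_factor`, plus an optional
#' `placeholder` flag.  A missing section or a non-positive multiplier is a
#' config error.  `write_coefficients()` and `read_coefficients()` round-trip.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_coefficients()` returns a [coefficient_table()].
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = FALSE)
  }
  need <- c("adhesiveness", "position", "fixation",
            "peritoneal_closure_factor", "fascial_closure_factor")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("config error: missing section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  coefficient_table(
    adhesiveness = unlist(raw$adhesiveness),
    position = unlist(raw$position),
    fixation = raw$fixation,
    peritoneal_closure_factor = as.numeric(raw$peritoneal_closure_factor),
    fascial_closure_factor = as.numeric(raw$fascial_closure_factor),
    placeholder = isTRUE(raw$placeholder))
}

#' @rdname read_coefficients
#' @param coeffs a [coefficient_table()].
#' @export
write_coefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "grip_coefficients"))
  ser <- list(
    placeholder = coeffs$placeholder,
    adhesiveness = as.list(coeffs$adhesiveness),
    position = as.list(coeffs$position),
    fixation = lapply(coeffs$fixation, function(b) {
      lapply(seq_len(nrow(b)), function(i) {
        list(max_points = if (is.infinite(b$max_points[i])) NULL else b$max_points[i],
             multiplier = b$multiplier[i])
      })
    }),
    peritoneal_closure_factor = coeffs$peritoneal_closure_factor,
    fascial_closure_factor = coeffs$fascial_closure_factor)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(ser, path)
  } else {
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' Look up the fixation multiplier for a type and point count
#'
#' @param coeffs a [coefficient_table()].
#' @param type fixation type label(s).
#' @param points fixation point count(s), integer >= 0.
#' @return numeric vector of multipliers.
#' @export
fixation_multiplier <- function(coeffs, type, points) {
  stopifnot(inherits(coeffs, "grip_coefficients"))
  n <- max(length(type), length(points))
  type <- rep_len(as.character(type), n)
  points <- rep_len(points, n)
  if (any(!is.finite(points)) || any(points < 0))
    stop("domain error: fixation point counts must be non-negative", call. = FALSE)
  unknown <- setdiff(unique(type), names(coeffs$fixation))
  if (length(unknown))
    stop("config error: no fixation coefficient for class '", unknown[1], "'",
         call. = FALSE)
  vapply(seq_len(n), function(i) {
    b <- coeffs$fixation[[type[i]]]
    b$multiplier[which(points[i] <= b$max_points)[1]]
  }, numeric(1))
}

lookup_multiplier <- function(map, class, section) {
  class <- as.character(class)
  unknown <- setdiff(unique(class), names(map))
  if (length(unknown))
    stop(sprintf("config error: no %s coefficient for class '%s'", section, unknown[1]),
         call. = FALSE)
  unname(map[class])
}

#' @export
print.grip_coefficients <- function(x, ...) {
  cat("GRIP coefficient table",
      if (x$placeholder) "(identity placeholder)" else "", "\n")
  cat("  adhesiveness:", paste(sprintf("%s=%g", names(x$adhesiveness), x$adhesiveness),
                               collapse = ", "), "\n")
  cat("  position:    ", paste(sprintf("%s=%g", names(x$position), x$position),
                               collapse = ", "), "\n")
  cat("  fixation types:", paste(names(x$fixation), collapse = ", "), "\n")
  cat(sprintf("  closure factors: peritoneal +%g, fascial +%g\n",
              x$peritoneal_closure_factor, x$fascial_closure_factor))
  invisible(x)
}
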