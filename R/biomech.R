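#' Hernia defect area under the elliptical convention
#'
#' The "hernia size" entering the CRIP formula is taken as the defect area in
#' cm^2 under an elliptical model, `pi/4 * width * length`.  The convention is
#' isolated here so it can be swapped; the mesh-defect area ratio is
#' convention-independent as long as mesh and defect use the same shape model.
#'
#' @param width,length defect dimensions in cm, strictly positive.
#' @return defect area in cm^2.
#' @examples
#' defect_size(4, 6)   # 18.85 cm^2
#' @export
defect_size <- function(width, length) {
  if (any(!is.finite(width)) || any(!is.finite(length)) ||
      any(width <= 0) || any(length <= 0))
    stop("domain error: defect dimensions must be positive", call. = FALSE)
  pi / 4 * width * length
}

#' Critical resistance to impacts related to pressure (CRIP)
#'
#' The required strength of an incisional hernia repair:
#' `CRIP = (0.5 * size + 15) * distension`, where `size` is the hernia defect
#' area (cm^2, see [defect_size()]) and `distension` the maximum tissue
#' displacement under a Valsalva maneuver (cm).  CRIP is treated as a
#' dimensionless resistance score.
#'
#' @param size hernia defect area, cm^2, >= 0.
#' @param distension maximum tissue distension under Valsalva, cm, >= 0.
#' @return CRIP score, strictly increasing in each argument while the other is
#'   positive; `crip(s, 0) == 0` and `crip(0, d) == 15 * d`.
#' @examples
#' crip(100, 2)                  # 130
#' crip(defect_size(4, 6), 1)    # 24.42
#' @export
crip <- function(size, distension) {
  if (any(!is.finite(size)) || any(!is.finite(distension)) ||
      any(size < 0) || any(distension < 0))
    stop("domain error: size and distension must be non-negative", call. = FALSE)
  (0.5 * size + 15) * distension
}

#' Mesh-defect area ratio (MDAR)
#'
#' Mesh area divided by hernia defect area.  Any fixed shape constant cancels,
#' so the ratio equals `(mesh_width * mesh_length) / (defect_width *
#' defect_length)` and is invariant under rescaling mesh and defect together.
#' A mesh smaller than the defect in either dimension is flagged with a
#' warning but still scored.
#'
#' @param mesh_width,mesh_length mesh dimensions, cm.
#' @param defect_width,defect_length defect dimensions, cm.
#' @return dimensionless ratio > 0.
#' @export
mdar <- function(mesh_width, mesh_length, defect_width, defect_length) {
  dims <- c(mesh_width, mesh_length, defect_width, defect_length)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("domain error: all four dimensions must be positive", call. = FALSE)
  if (any(mesh_width < defect_width) || any(mesh_length < defect_length))
    warning("mesh smaller than defect in at least one dimension", call. = FALSE)
  (mesh_width * mesh_length) / (defect_width * defect_length)
}

#' Gained resistance to impacts related to pressure (GRIP)
#'
#' The achieved strength of a planned repair:
#' `GRIP = MDAR * c_adhesiveness * c_position * c_fixation(type, points)
#'         + peritoneal_factor * [peritoneal closed]
#'         + fascial_factor * [fascial closed]`.
#' Multipliers come from a [coefficient_table()]; a class missing from the
#' table is a config error naming the class.  With the identity table GRIP
#' reduces to the MDAR.
#'
#' @param mdar mesh-defect area ratio (>= 0).
#' @param adhesiveness_class,position_class mesh material / position labels.
#' @param fixation_type,fixation_points fixation descriptor; the multiplier is
#'   looked up by point-count band.
#' @param peritoneal_closure,fascial_closure logical, whether each closure is
#'   performed.
#' @param coeffs a [coefficient_table()].
#' @return GRIP score, strictly increasing in `mdar` and in each multiplier.
#' @export
grip_score <- function(mdar, adhesiveness_class, position_class,
                       fixation_type, fixation_points,
                       peritoneal_closure = FALSE, fascial_closure = FALSE,
                       coeffs) {
  stopifnot(inherits(coeffs, "grip_coefficients"))
  if (any(!is.finite(mdar)) || any(mdar < 0))
    stop("domain error: mdar must be non-negative", call. = FALSE)
  c_adh <- lookup_multiplier(coeffs$adhesiveness, adhesiveness_class, "adhesiveness")
  c_pos <- lookup_multiplier(coeffs$position, position_class, "position")
  c_fix <- fixation_multiplier(coeffs, fixation_type, fixation_points)
  mdar * c_adh * c_pos * c_fix +
    coeffs$peritoneal_closure_factor * as.numeric(peritoneal_closure) +
    coeffs$fascial_closure_factor * as.numeric(fascial_closure)
}

#' Tissue stability classification
#'
#' Tissue is stable when the maximum distension during a Valsalva maneuver
#' does not exceed 1.5 cm; the boundary itself is stable.
#'
#' @param distension maximum distension, cm, >= 0.
#' @param limit_cm stability limit, default 1.5 cm.
#' @return character vector, `"stable"` or `"unstable"`.
#' @export
classify_stability <- function(distension, limit_cm = 1.5) {
  if (any(!is.finite(distension)) || any(distension < 0))
    stop("domain error: distension must be non-negative", call. = FALSE)
  ifelse(distension <= limit_cm, "stable", "unstable")
}

#' Interobserver variation check for manual hernia measurement
#'
#' Manual assessment of hernia dimensions requires at least three observers
#' each taking at least four independent readings; the measurement is
#' considered reliable only when the coefficient of variation over all
#' readings is strictly below 5%.  The CV is the pooled sample SD divided by
#' the pooled mean and is invariant under permutation and rescaling of the
#' readings.
#'
#' @param readings numeric matrix, observers in rows, repeated readings in
#'   columns; all values > 0 (cm).
#' @param cv_limit reliability threshold on the CV, default 0.05 (strict).
#' @return list with `cv` (fraction), `reliable` (logical), `n_observers`,
#'   `n_readings`.
#' @export
interobserver_check <- function(readings, cv_limit = 0.05) {
  readings <- as.matrix(readings)
  if (!is.numeric(readings) || any(!is.finite(readings)))
    stop("domain error: readings must be finite numbers", call. = FALSE)
  if (nrow(readings) < 3L)
    stop("protocol error: at least three observers are required", call. = FALSE)
  if (ncol(readings) < 4L)
    stop("protocol error: at least four readings per observer are required", call. = FALSE)
  if (any(readings <= 0))
    stop("domain error: readings must be positive", call. = FALSE)
  x <- as.vector(readings)
  cv <- stats::sd(x) / mean(x)
  list(cv = cv, reliable = cv < cv_limit,
       n_observers = nrow(readings), n_readings = length(x))
}

#' Assess repairs recorded in a registry table
#'
#' Appends the biomechanical assessment to a registry data.frame: defect
#' area, CRIP, MDAR, GRIP, the stability classification of the tissue, the
#' margin `GRIP - CRIP` and the durability verdict `GRIP > CRIP` (strict).
#'
#' @param registry a registry data.frame as returned by [read_registry()] or
#'   [generate_cohort()]; needs the geometry, distension and mesh-plan columns.
#' @param coeffs a [coefficient_table()].
#' @param allow_placeholder permit a placeholder coefficient table (refused by
#'   default because placeholder GRIP values carry no clinical meaning).
#' @return the registry with columns `defect_size`, `crip`, `mdar`, `grip`,
#'   `margin`, `durable`, `stable_tissue` appended.
#' @export
assess_repair <- function(registry, coeffs, allow_placeholder = FALSE) {
  stopifnot(is.data.frame(registry), inherits(coeffs, "grip_coefficients"))
  refuse_placeholder(coeffs, allow_placeholder)
  need <- c("defect_width", "defect_length", "distension", "mesh_width",
            "mesh_length", "adhesiveness_class", "position_class",
            "fixation_type", "fixation_points", "peritoneal_closure",
            "fascial_closure")
  missing <- setdiff(need, names(registry))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  size <- defect_size(registry$defect_width, registry$defect_length)
  registry$defect_size <- size
  registry$crip <- crip(size, registry$distension)
  registry$mdar <- mdar(registry$mesh_width, registry$mesh_length,
                        registry$defect_width, registry$defect_length)
  registry$grip <- grip_score(registry$mdar,
                              registry$adhesiveness_class,
                              registry$position_class,
                              registry$fixation_type,
                              registry$fixation_points,
                              registry$peritoneal_closure,
                              registry$fascial_closure,
                              coeffs)
  registry$margin <- registry$grip - registry$crip
  registry$durable <- registry$margin > 0
  registry$stable_tissue <- classify_stability(registry$distension) == "stable"
  registry
}

refuse_placeholder <- function(coeffs, allow_placeholder) {
  if (coeffs$placeholder && !isTRUE(allow_placeholder))
    stop(paste("coefficient table is an identity placeholder; supply clinical",
               "coefficients or set allow_placeholder = TRUE"), call. = FALSE)
  invisible(NULL)
}
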