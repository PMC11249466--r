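#' Constraints and escalation policy for repair planning
#'
#' The planner escalates a candidate mesh plan along a documented, linear
#' order until the repair is durable (GRIP strictly above CRIP): first the
#' mesh overlap grows (larger meshes first), then the number of fixation
#' points, then the fixation type moves up the escalation list, finally the
#' peritoneal and fascial closure credits are switched on.  Each step changes
#' exactly one knob.  The order mirrors clinical practice (larger meshes for
#' larger hernias, then more fixation) and is configurable here; it is a
#' documented heuristic, not a claim of optimality across orders.
#'
#' @param max_mesh_width,max_mesh_length largest manufacturable mesh, cm
#'   (default 49, the largest mesh dimension observed in practice).
#' @param min_overlap smallest acceptable mesh overlap beyond the defect rim,
#'   cm (default 5).
#' @param overlap_step overlap escalation step, cm (default 1; mesh
#'   dimensions move on a 1 cm grid).
#' @param fixation_start,fixation_step,max_fixation_points fixation-point
#'   escalation grid.
#' @param fixation_types ordered escalation list of fixation types (first
#'   entry is the starting type).
#' @param use_peritoneal_closure,use_fascial_closure whether the closure
#'   credits may be used as final escalation steps.
#' @return list of class `grip_constraints`.
#' @export
planner_constraints <- function(max_mesh_width = 49, max_mesh_length = 49,
                                min_overlap = 5, overlap_step = 1,
                                fixation_start = 0, fixation_step = 10,
                                max_fixation_points = 300,
                                fixation_types = c("absorbable_tack",
                                                   "nonresorbable_suture",
                                                   "bone_anchor"),
                                use_peritoneal_closure = TRUE,
                                use_fascial_closure = TRUE) {
  stopifnot(max_mesh_width > 0, max_mesh_length > 0, min_overlap >= 0,
            overlap_step > 0, fixation_step > 0,
            fixation_start >= 0, max_fixation_points >= fixation_start,
            length(fixation_types) >= 1)
  structure(list(max_mesh_width = max_mesh_width,
                 max_mesh_length = max_mesh_length,
                 min_overlap = min_overlap, overlap_step = overlap_step,
                 fixation_start = fixation_start,
                 fixation_step = fixation_step,
                 max_fixation_points = max_fixation_points,
                 fixation_types = as.character(fixation_types),
                 use_peritoneal_closure = isTRUE(use_peritoneal_closure),
                 use_fascial_closure = isTRUE(use_fascial_closure)),
            class = "grip_constraints")
}

# Linear escalation path: one row per candidate plan, consecutive rows differ
# by exactly one escalation step.
escalation_candidates <- function(defect_width, defect_length, constraints) {
  cs <- constraints
  mesh_dims <- function(ov) {
    list(w = pmin(defect_width + 2 * ov, cs$max_mesh_width),
         l = pmin(defect_length + 2 * ov, cs$max_mesh_length))
  }
  # overlap values: escalate until both dimensions are capped
  ov_cap <- max((cs$max_mesh_width - defect_width) / 2,
                (cs$max_mesh_length - defect_length) / 2,
                cs$min_overlap)
  n_up <- ceiling(max(0, ov_cap - cs$min_overlap) / cs$overlap_step)
  overlaps <- cs$min_overlap + cs$overlap_step * (0:n_up)
  md <- mesh_dims(overlaps)
  keep <- !duplicated(cbind(md$w, md$l))   # drop steps past full capping
  overlaps <- overlaps[keep]
  mw <- md$w[keep]; ml <- md$l[keep]
  nA <- length(overlaps)
  pts <- if (cs$max_fixation_points >= cs$fixation_start + cs$fixation_step)
    seq(cs$fixation_start + cs$fixation_step, cs$max_fixation_points,
        by = cs$fixation_step) else numeric(0)
  nB <- length(pts)
  tys <- cs$fixation_types[-1]; nC <- length(tys)
  closures <- c(if (cs$use_peritoneal_closure) "peritoneal_closure",
                if (cs$use_fascial_closure) "fascial_closure")
  nD <- length(closures)
  total <- nA + nB + nC + nD
  tail_n <- nB + nC + nD
  max_pts <- if (nB) pts[nB] else cs$fixation_start
  last_ty <- cs$fixation_types[length(cs$fixation_types)]
  rows <- data.frame(
    overlap = c(overlaps, rep(overlaps[nA], tail_n)),
    mesh_width = c(mw, rep(mw[nA], tail_n)),
    mesh_length = c(ml, rep(ml[nA], tail_n)),
    fixation_points = c(rep(cs$fixation_start, nA), pts,
                        rep(max_pts, nC + nD)),
    fixation_type = c(rep(cs$fixation_types[1], nA + nB), tys,
                      rep(last_ty, nD)),
    peritoneal_closure = c(rep(FALSE, nA + nB + nC),
                           if (nD) cumsum(closures == "peritoneal_closure") > 0),
    fascial_closure = c(rep(FALSE, nA + nB + nC),
                        if (nD) cumsum(closures == "fascial_closure") > 0),
    action = c("base", rep("overlap_up", nA - 1L), rep("fixation_up", nB),
               rep("fixation_type_up", nC), closures),
    stringsAsFactors = FALSE)
  rows$minimal_overlap <- pmin((rows$mesh_width - defect_width) / 2,
                               (rows$mesh_length - defect_length) / 2)
  rows$step <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  rows
}

assess_candidates <- function(cand, defect_width, defect_length, distension,
                              coeffs, adhesiveness_class, position_class) {
  size <- defect_size(defect_width, defect_length)
  cand$crip <- crip(size, distension)
  cand$mdar <- (cand$mesh_width * cand$mesh_length) /
    (defect_width * defect_length)
  cand$grip <- grip_score(cand$mdar, adhesiveness_class, position_class,
                          cand$fixation_type, cand$fixation_points,
                          cand$peritoneal_closure, cand$fascial_closure,
                          coeffs)
  cand$margin <- cand$grip - cand$crip
  cand$durable <- cand$margin > 0
  cand
}

#' Plan a biomechanically calculated repair
#'
#' Iterates mesh size and fixation along the escalation order of
#' [planner_constraints()] and returns the first (hence minimal, under that
#' order) candidate plan whose gained resistance strictly exceeds the
#' critical resistance, `GRIP > CRIP`.  Deterministic for fixed inputs.  If
#' no candidate within the constraints is durable, an infeasibility error of
#' class `grip_infeasible` is raised reporting the best achievable margin
#' (or, with `on_infeasible = "value"`, the best candidate is returned with
#' `feasible = FALSE`).
#'
#' @param defect_width,defect_length hernia defect dimensions, cm.
#' @param distension maximum tissue distension under Valsalva, cm.
#' @param coeffs a [coefficient_table()]; placeholder tables are refused
#'   unless `allow_placeholder = TRUE`.
#' @param constraints a [planner_constraints()] object.
#' @param adhesiveness_class,position_class material and position of the
#'   planned mesh (inputs, not decision variables).
#' @param mesh_form free-text mesh form label carried into the plan.
#' @param allow_placeholder permit a placeholder coefficient table.
#' @param on_infeasible `"error"` (default) or `"value"`.
#' @return list of class `grip_plan` with elements `plan` (mesh dimensions,
#'   achieved minimal overlap, fixation, closures), `assessment` (`crip`,
#'   `mdar`, `grip`, `margin`, `durable`, `stable_tissue`), `feasible`,
#'   `steps` (number of escalation steps tried).
#' @examples
#' plan_repair(4, 6, 1.0, identity_coefficients(), allow_placeholder = TRUE)
#' @export
plan_repair <- function(defect_width, defect_length, distension, coeffs,
                        constraints = planner_constraints(),
                        adhesiveness_class = "dis_class_a",
                        position_class = "retromuscular",
                        mesh_form = "flat_textile",
                        allow_placeholder = FALSE,
                        on_infeasible = c("error", "value")) {
  on_infeasible <- match.arg(on_infeasible)
  stopifnot(inherits(constraints, "grip_constraints"),
            inherits(coeffs, "grip_coefficients"))
  if (defect_width <= 0 || defect_length <= 0 || distension < 0)
    stop("domain error: invalid geometry", call. = FALSE)
  refuse_placeholder(coeffs, allow_placeholder)
  cand <- escalation_candidates(defect_width, defect_length, constraints)
  cand <- assess_candidates(cand, defect_width, defect_length, distension,
                            coeffs, adhesiveness_class, position_class)
  hit <- which(cand$durable)[1]
  feasible <- !is.na(hit)
  pick <- if (feasible) hit else which.max(cand$margin)
  row <- cand[pick, ]
  out <- structure(list(
    plan = list(mesh_width = row$mesh_width, mesh_length = row$mesh_length,
                minimal_overlap = row$minimal_overlap, mesh_form = mesh_form,
                adhesiveness_class = adhesiveness_class,
                position_class = position_class,
                fixation_points = row$fixation_points,
                fixation_type = row$fixation_type,
                peritoneal_closure = row$peritoneal_closure,
                fascial_closure = row$fascial_closure),
    assessment = list(crip = row$crip, mdar = row$mdar, grip = row$grip,
                      margin = row$margin, durable = row$durable,
                      stable_tissue = classify_stability(distension) == "stable"),
    feasible = feasible, steps = row$step), class = "grip_plan")
  if (!feasible && on_infeasible == "error") {
    cond <- structure(
      class = c("grip_infeasible", "error", "condition"),
      list(message = sprintf(
        paste("no durable plan within constraints: best margin %.2f",
              "(GRIP %.2f vs CRIP %.2f)"), row$margin, row$grip, row$crip),
        call = NULL, best = out))
    stop(cond)
  }
  out
}

#' Escalation trace of the planning iteration
#'
#' Returns the full audit trail of the planning loop: one row per escalation
#' step in order, each with its assessment, ending at the first durable plan
#' (or, if none exists within the constraints, covering the whole grid with
#' the `feasible` attribute set to `FALSE`).  Consecutive rows differ by
#' exactly one escalation step; GRIP is non-decreasing along the trace for
#' coefficient tables that are monotone in the escalation direction.
#'
#' @inheritParams plan_repair
#' @return data.frame of candidate plans with columns `step`, `action`,
#'   `mesh_width`, `mesh_length`, `minimal_overlap`, `fixation_points`,
#'   `fixation_type`, `peritoneal_closure`, `fascial_closure`, `crip`,
#'   `mdar`, `grip`, `margin`, `durable`; attribute `feasible`.
#' @export
escalation_trace <- function(defect_width, defect_length, distension, coeffs,
                             constraints = planner_constraints(),
                             adhesiveness_class = "dis_class_a",
                             position_class = "retromuscular",
                             allow_placeholder = FALSE) {
  stopifnot(inherits(constraints, "grip_constraints"),
            inherits(coeffs, "grip_coefficients"))
  if (defect_width <= 0 || defect_length <= 0 || distension < 0)
    stop("domain error: invalid geometry", call. = FALSE)
  refuse_placeholder(coeffs, allow_placeholder)
  cand <- escalation_candidates(defect_width, defect_length, constraints)
  cand <- assess_candidates(cand, defect_width, defect_length, distension,
                            coeffs, adhesiveness_class, position_class)
  hit <- which(cand$durable)[1]
  feasible <- !is.na(hit)
  if (feasible) cand <- cand[seq_len(hit), ]
  cols <- c("step", "action", "mesh_width", "mesh_length", "minimal_overlap",
            "fixation_points", "fixation_type", "peritoneal_closure",
            "fascial_closure", "crip", "mdar", "grip", "margin", "durable")
  out <- cand[, cols]
  rownames(out) <- NULL
  attr(out, "feasible") <- feasible
  out
}

#' @export
print.grip_plan <- function(x, ...) {
  p <- x$plan; a <- x$assessment
  cat(sprintf("Repair plan (%s): mesh %g x %g cm, overlap %.1f cm\n",
              if (x$feasible) "durable" else "INFEASIBLE",
              p$mesh_width, p$mesh_length, p$minimal_overlap))
  cat(sprintf("  fixation: %d x %s; peritoneal closure: %s; fascial closure: %s\n",
              p$fixation_points, p$fixation_type,
              p$peritoneal_closure, p$fascial_closure))
  cat(sprintf("  CRIP %.2f | MDAR %.2f | GRIP %.2f | margin %.2f | tissue %s\n",
              a$crip, a$mdar, a$grip, a$margin,
              if (a$stable_tissue) "stable" else "unstable"))
  invisible(x)
}
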