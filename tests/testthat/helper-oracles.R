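# Shared fixtures and independent brute-force oracles used across tests.

make_profile <- function(age = 50, bmi = 25, defect_width = 4,
                         lateral_site = FALSE, recurrent = FALSE,
                         metabolic_comorbidity = FALSE, elevated_iap = FALSE,
                         bleeding_risk = FALSE, reduced_wound_healing = FALSE,
                         abnormal_gait = FALSE,
                         concomitant_stoma_or_bowel = FALSE,
                         intensified_surgery = FALSE) {
  list(age = age, bmi = bmi, defect_width = defect_width,
       lateral_site = lateral_site, recurrent = recurrent,
       metabolic_comorbidity = metabolic_comorbidity,
       elevated_iap = elevated_iap, bleeding_risk = bleeding_risk,
       reduced_wound_healing = reduced_wound_healing,
       abnormal_gait = abnormal_gait,
       concomitant_stoma_or_bowel = concomitant_stoma_or_bowel,
       intensified_surgery = intensified_surgery)
}

# Brute-force complexity count, written directly from the category list.
oracle_score <- function(p) {
  pts <- 0L
  if (p$defect_width > 10) pts <- pts + 1L
  if (p$lateral_site) pts <- pts + 1L
  if (p$recurrent) pts <- pts + 1L
  if (p$age > 80) pts <- pts + 1L
  if (p$bmi > 30) pts <- pts + 1L
  if (p$metabolic_comorbidity || p$elevated_iap || p$bleeding_risk ||
      p$reduced_wound_healing || p$abnormal_gait) pts <- pts + 1L
  if (p$concomitant_stoma_or_bowel) pts <- pts + 1L
  if (p$intensified_surgery) pts <- pts + 1L
  pts
}

# Direct GRIP evaluation with an explicit band scan (no package lookup code).
oracle_grip <- function(m, coeffs, ty, pts, pc, fc,
                        adh = "dis_class_a", pos = "retromuscular") {
  bands <- coeffs$fixation[[ty]]
  cf <- NA_real_
  for (j in seq_len(nrow(bands)))
    if (pts <= bands$max_points[j]) { cf <- bands$multiplier[j]; break }
  m * coeffs$adhesiveness[[adh]] * coeffs$position[[pos]] * cf +
    (if (pc) coeffs$peritoneal_closure_factor else 0) +
    (if (fc) coeffs$fascial_closure_factor else 0)
}

# Exhaustive enumeration of the escalation grid in the documented order,
# returning the first durable candidate or the best achievable margin.
oracle_plan <- function(w, l, d, coeffs, cs = planner_constraints(),
                        adh = "dis_class_a", pos = "retromuscular") {
  cands <- list()
  ov <- cs$min_overlap
  repeat {
    mw <- min(w + 2 * ov, cs$max_mesh_width)
    ml <- min(l + 2 * ov, cs$max_mesh_length)
    n <- length(cands)
    if (n > 0 && cands[[n]]$mw == mw && cands[[n]]$ml == ml) break
    cands[[n + 1]] <- list(mw = mw, ml = ml, pts = cs$fixation_start,
                           ty = cs$fixation_types[1], pc = FALSE, fc = FALSE)
    ov <- ov + cs$overlap_step
  }
  base <- cands[[length(cands)]]
  pts <- cs$fixation_start + cs$fixation_step
  while (pts <= cs$max_fixation_points) {
    base$pts <- pts
    cands[[length(cands) + 1]] <- base
    pts <- pts + cs$fixation_step
  }
  for (ty in cs$fixation_types[-1]) {
    base$ty <- ty
    cands[[length(cands) + 1]] <- base
  }
  if (cs$use_peritoneal_closure) {
    base$pc <- TRUE
    cands[[length(cands) + 1]] <- base
  }
  if (cs$use_fascial_closure) {
    base$fc <- TRUE
    cands[[length(cands) + 1]] <- base
  }
  size <- pi / 4 * w * l
  need <- (0.5 * size + 15) * d
  best <- NULL
  for (k in seq_along(cands)) {
    cc <- cands[[k]]
    m <- (cc$mw * cc$ml) / (w * l)
    g <- oracle_grip(m, coeffs, cc$ty, cc$pts, cc$pc, cc$fc, adh, pos)
    cc$grip <- g; cc$margin <- g - need; cc$step <- k
    if (g > need) return(c(cc, list(feasible = TRUE)))
    if (is.null(best) || cc$margin > best$margin) best <- cc
  }
  c(best, list(feasible = FALSE))
}

# Random strictly-positive coefficient table over a single class vocabulary.
random_coeffs <- function() {
  nb <- sample(1:3, 1)
  mp <- sort(runif(nb, 1, 200))
  mp[nb] <- Inf
  coefficient_table(
    adhesiveness = c(dis_class_a = runif(1, 0.1, 6)),
    position = c(retromuscular = runif(1, 0.1, 4)),
    fixation = list(absorbable_tack = data.frame(max_points = mp,
                                                 multiplier = runif(nb, 0.1, 8)),
                    nonresorbable_suture = data.frame(max_points = Inf,
                                                      multiplier = runif(1, 0.1, 8)),
                    bone_anchor = data.frame(max_points = Inf,
                                             multiplier = runif(1, 0.1, 8))),
    peritoneal_closure_factor = runif(1, 0, 30),
    fascial_closure_factor = runif(1, 0, 30))
}

# Double-loop pixel counting oracle for the unstable region.
oracle_unstable_pixels <- function(mag, thr) {
  cnt <- 0L
  for (i in seq_len(nrow(mag)))
    for (j in seq_len(ncol(mag)))
      if (mag[i, j] > thr) cnt <- cnt + 1L
  cnt
}

# Minimal valid registry row for I/O tests.
make_registry_row <- function(id = "p1", preop_pain = 3) {
  data.frame(
    patient_id = id, age = 55L, sex = "female", bmi = 27.5,
    preop_pain = preop_pain, defect_width = 4, defect_length = 6,
    distension = 1.2, lateral_site = FALSE, recurrent = FALSE,
    metabolic_comorbidity = TRUE, elevated_iap = FALSE, bleeding_risk = FALSE,
    reduced_wound_healing = FALSE, abnormal_gait = FALSE,
    concomitant_stoma_or_bowel = FALSE, intensified_surgery = FALSE,
    mesh_width = 15, mesh_length = 20, minimal_overlap = 5,
    mesh_form = "flat_textile", adhesiveness_class = "dis_class_a",
    position_class = "retromuscular", fixation_points = 20L,
    fixation_type = "nonresorbable_suture", peritoneal_closure = TRUE,
    fascial_closure = TRUE, los_days = 5L, intraop_complication = FALSE,
    postop_complication = FALSE, reoperation_30d = FALSE,
    pain_discharge = 2L, pain_1m_rest = 1L, pain_1m_exercise = 1L,
    pain_6m_rest = 0L, pain_6m_exercise = 0L, pain_1y_rest = 0L,
    pain_1y_exercise = 0L, pain_3y_rest = 0L, pain_3y_exercise = 0L,
    recurrence_3y = FALSE, stringsAsFactors = FALSE)
}
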