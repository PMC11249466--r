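test_that("the 4x6 example returns the smallest durable grid plan", {
  co <- identity_coefficients()
  p <- plan_repair(4, 6, 1.0, co, allow_placeholder = TRUE)
  expect_true(p$feasible)
  expect_equal(round(p$assessment$crip, 2), 24.42)
  expect_gt(p$assessment$mdar, p$assessment$crip)
  # with the identity table GRIP == MDAR, so the first overlap whose mesh
  # area ratio clears CRIP wins; the oracle agrees
  o <- oracle_plan(4, 6, 1.0, co)
  expect_true(o$feasible)
  expect_equal(p$plan$mesh_width, o$mw)
  expect_equal(p$plan$mesh_length, o$ml)
  expect_equal(p$assessment$grip, o$grip)
  # the step before was not durable (minimality along the escalation order)
  tr <- escalation_trace(4, 6, 1.0, co, allow_placeholder = TRUE)
  expect_false(any(tr$durable[-nrow(tr)]))
  expect_true(tr$durable[nrow(tr)])
})

test_that("zero distension needs no escalation", {
  p <- plan_repair(4, 6, 0, identity_coefficients(), allow_placeholder = TRUE)
  expect_equal(p$assessment$crip, 0)
  expect_equal(p$steps, 1L)
  tr <- escalation_trace(4, 6, 0, identity_coefficients(),
                         allow_placeholder = TRUE)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$action, "base")
})

test_that("a hopeless geometry is infeasible with the margin reported", {
  co <- identity_coefficients()
  err <- tryCatch(plan_repair(30, 40, 10, co, allow_placeholder = TRUE),
                  grip_infeasible = identity)
  expect_s3_class(err, "grip_infeasible")
  expect_match(conditionMessage(err), "best margin")
  best <- err$best
  expect_false(best$feasible)
  o <- oracle_plan(30, 40, 10, co)
  expect_false(o$feasible)
  expect_equal(best$assessment$margin, o$margin)
  # value-mode returns the same best candidate without raising
  v <- plan_repair(30, 40, 10, co, allow_placeholder = TRUE,
                   on_infeasible = "value")
  expect_false(v$feasible)
  expect_equal(v$assessment$margin, o$margin)
})

test_that("the trace is a single-step escalation path ending at the plan", {
  set.seed(31)
  co <- synthetic_coefficients()
  for (i in 1:25) {
    w <- runif(1, 2, 25); l <- runif(1, 2, 30); d <- runif(1, 0, 4)
    tr <- escalation_trace(w, l, d, co)
    # consecutive candidates differ by exactly one escalation knob
    if (nrow(tr) > 1) {
      knobs <- c("mesh_width", "mesh_length", "fixation_points",
                 "fixation_type", "peritoneal_closure", "fascial_closure")
      for (k in seq_len(nrow(tr) - 1)) {
        a <- tr[k, knobs]; b <- tr[k + 1, knobs]
        changed <- sum(
          (a$mesh_width != b$mesh_width) | (a$mesh_length != b$mesh_length),
          a$fixation_points != b$fixation_points,
          a$fixation_type != b$fixation_type,
          a$peritoneal_closure != b$peritoneal_closure,
          a$fascial_closure != b$fascial_closure)
        expect_equal(changed, 1L)
      }
    }
    # GRIP never decreases along the trace for this monotone table
    expect_true(all(diff(tr$grip) > -1e-9))
    if (attr(tr, "feasible")) {
      p <- plan_repair(w, l, d, co)
      last <- tr[nrow(tr), ]
      expect_equal(p$plan$mesh_width, last$mesh_width)
      expect_equal(p$plan$fixation_points, last$fixation_points)
      expect_equal(p$assessment$grip, last$grip)
      expect_gt(p$assessment$grip, p$assessment$crip)
    }
  }
})

test_that("more distension never buys a smaller mesh", {
  set.seed(32)
  co <- synthetic_coefficients()
  for (i in 1:30) {
    w <- runif(1, 2, 20); l <- runif(1, 2, 25)
    d <- sort(runif(2, 0, 3))
    p1 <- plan_repair(w, l, d[1], co, on_infeasible = "value")
    p2 <- plan_repair(w, l, d[2], co, on_infeasible = "value")
    a1 <- p1$plan$mesh_width * p1$plan$mesh_length
    a2 <- p2$plan$mesh_width * p2$plan$mesh_length
    expect_gte(a2, a1)
  }
})

test_that("planner refuses a placeholder table unless allowed", {
  expect_error(plan_repair(4, 6, 1, identity_coefficients()), "placeholder")
})
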