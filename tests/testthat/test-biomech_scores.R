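test_that("elliptical defect size behaves like pi/4 of the bounding rectangle", {
  expect_equal(round(defect_size(4, 6), 2), 18.85)
  d <- 3.7
  expect_equal(defect_size(d, d), pi / 4 * d^2)
  expect_equal(defect_size(2 * d, 2 * d), 4 * defect_size(d, d))
  set.seed(5)
  w <- runif(1000, 0.5, 40); l <- runif(1000, 0.5, 40)
  expect_equal(defect_size(w, l) / (w * l), rep(pi / 4, 1000))
  expect_error(defect_size(0, 5), "domain error")
  expect_error(defect_size(4, -1), "domain error")
})

test_that("CRIP follows its closed form and limits", {
  expect_equal(crip(0, 1.0), 15)
  expect_equal(crip(100, 2.0), 130)
  expect_equal(crip(430, 1.0), 230)   # magnitude of the illustrated cases
  d <- runif(20, 0, 8); s <- runif(20, 0, 500)
  expect_equal(crip(0, d), 15 * d)
  expect_equal(crip(s, 0), rep(0, 20))
  # strictly increasing in each argument while the other is positive
  expect_true(all(diff(crip(sort(s), 1.3)) > 0))
  expect_true(all(diff(crip(120, sort(d))) > 0))
  expect_error(crip(-1, 1), "domain error")
})

test_that("MDAR is the plain area ratio, invariant under joint rescaling", {
  expect_equal(mdar(15, 20, 4, 6), 12.5)
  expect_equal(mdar(4, 6, 4, 6), 1.0)
  set.seed(6)
  for (i in 1:1000) {
    k <- runif(1, 0.1, 10)
    dd <- runif(2, 1, 20); m <- dd + runif(2, 0, 20)
    expect_equal(mdar(k * m[1], k * m[2], k * dd[1], k * dd[2]),
                 mdar(m[1], m[2], dd[1], dd[2]))
  }
  expect_warning(mdar(3, 20, 4, 6), "smaller than defect")
  expect_error(mdar(0, 20, 4, 6), "domain error")
})

test_that("GRIP reduces to MDAR under the identity table and is monotone", {
  co <- identity_coefficients()
  expect_equal(grip_score(12.5, "dis_class_a", "retromuscular",
                          "nonresorbable_suture", 40, FALSE, FALSE, co), 12.5)
  # additive closure factor after the multiplicative chain
  co2 <- coefficient_table(
    adhesiveness = c(dis_class_a = 1), position = c(retromuscular = 1),
    fixation = list(nonresorbable_suture = data.frame(max_points = Inf,
                                                      multiplier = 2)),
    fascial_closure_factor = 10)
  expect_equal(grip_score(5, "dis_class_a", "retromuscular",
                          "nonresorbable_suture", 10, FALSE, TRUE, co2), 20)
  set.seed(7)
  for (i in 1:500) {
    tab <- random_coeffs()
    m <- sort(runif(2, 0, 60))
    pts <- sample(0:200, 1)
    g <- grip_score(m, "dis_class_a", "retromuscular", "absorbable_tack",
                    pts, FALSE, FALSE, tab)
    expect_lt(g[1], g[2])
    expect_equal(g[2], oracle_grip(m[2], tab, "absorbable_tack", pts,
                                   FALSE, FALSE))
  }
})

test_that("stability threshold is inclusive at 1.5 cm", {
  expect_equal(classify_stability(1.5), "stable")
  expect_equal(classify_stability(1.6), "unstable")
  expect_equal(classify_stability(0), "stable")
  expect_equal(classify_stability(c(0.3, 1.5, 1.50001)),
               c("stable", "stable", "unstable"))
})

test_that("interobserver CV is computed over all readings with a strict 5% limit", {
  same <- matrix(7.5, 3, 4)
  r <- interobserver_check(same)
  expect_equal(r$cv, 0)
  expect_true(r$reliable)

  # readings constructed to have CV exactly 0.18 (the recurrence case regime)
  construct_cv <- function(target, mean = 20, n = 12) {
    z <- rnorm(n)
    matrix(mean + target * mean * (z - mean(z)) / sd(z), 3, 4)
  }
  set.seed(8)
  r18 <- interobserver_check(construct_cv(0.18))
  expect_equal(r18$cv, 0.18)
  expect_false(r18$reliable)

  # boundary: exactly 5% is NOT reliable
  r05 <- interobserver_check(construct_cv(0.05))
  expect_equal(r05$cv, 0.05)
  expect_false(r05$reliable)

  expect_error(interobserver_check(matrix(5, 2, 4)), "three observers")
  expect_error(interobserver_check(matrix(5, 3, 3)), "four readings")
  expect_error(interobserver_check(matrix(c(-1, rep(5, 11)), 3, 4)), "positive")
})

test_that("interobserver CV is permutation- and scale-invariant", {
  set.seed(9)
  x <- matrix(runif(12, 10, 14), 3, 4)
  cv0 <- interobserver_check(x)$cv
  perm <- matrix(sample(as.vector(x)), 3, 4)
  expect_equal(interobserver_check(perm)$cv, cv0)
  expect_equal(interobserver_check(3.7 * x)$cv, cv0)
})

test_that("assess_repair refuses placeholder tables and appends the verdict", {
  reg <- make_registry_row()
  expect_error(assess_repair(reg, identity_coefficients()), "placeholder")
  out <- assess_repair(reg, identity_coefficients(), allow_placeholder = TRUE)
  expect_equal(out$mdar, 12.5)
  expect_equal(out$grip, 12.5)
  expect_equal(out$crip, crip(defect_size(4, 6), 1.2))
  expect_identical(out$durable, out$margin > 0)
  expect_true(out$stable_tissue)
})
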