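test_that("random_offset lands at exactly the step distance, in any direction", {
  set.seed(11)
  for (i in 1:200) {
    origin <- rnorm(3, sd = 1000)
    step <- runif(1, 1, 2000)
    p <- random_offset(origin, step)
    expect_equal(sqrt(sum((p - origin)^2)), step, tolerance = 1e-12)
  }
  expect_error(random_offset(c(0, 0, 0), -5))
})

test_that("random_offset directions are rotationally symmetric about the z axis", {
  set.seed(23)
  n <- 1e5
  pts <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) pts[i, ] <- random_offset(c(0, 0, 0), 1)
  az <- atan2(pts[, 2], pts[, 1])
  counts <- table(cut(az, breaks = seq(-pi, pi, length.out = 17)))
  gof <- chisq_gof(as.integer(counts),
                   proportions = rep(1 / 16, 16))
  expect_gt(gof$p_value, 1e-3)
  # and the z component is symmetric about the equator
  expect_lt(abs(mean(pts[, 3])), 0.01)
})

test_that("nucleolus radius bounds invert the volume fractions", {
  expect_equal(nucleolus_radius_bounds(1000, 0.064, 0.216),
               c(r_min = 400, r_max = 600))
  expect_equal(nucleolus_radius_bounds(2000, 0.001, 0.001)[["r_min"]], 200)
  b <- nucleolus_radius_bounds(1234, 0.05, 0.05)
  expect_equal(b[["r_min"]], b[["r_max"]])
  # volume-fraction recovery to 1e-9 relative tolerance
  set.seed(4)
  for (i in 1:50) {
    R <- runif(1, 500, 10000)
    v <- sort(runif(2, 0.001, 0.9))
    b <- nucleolus_radius_bounds(R, v[1], v[2])
    expect_equal((b[["r_min"]] / R)^3, v[1], tolerance = 1e-9)
    expect_equal((b[["r_max"]] / R)^3, v[2], tolerance = 1e-9)
  }
  expect_error(nucleolus_radius_bounds(1000, 0, 0.5))
  expect_error(nucleolus_radius_bounds(1000, 0.5, 1))
  expect_error(nucleolus_radius_bounds(-1, 0.1, 0.5))
})

test_that("distance windows follow the d1/d2 definitions", {
  cfg <- small_config(rad_bead = 250, eps_1 = 25, eps_2 = 50)
  w <- distance_windows(4000, cfg)
  expect_equal(w$d1_min, 500)
  expect_equal(w$d1_max, 4000 - 500 - 25)
  expect_equal(w$d2_min, 550)
  expect_equal(w$d2_max, 4000 - 250 - 250)
})

test_that("centromere candidates obey the C1-C3 conditions with strict bounds", {
  cfg <- small_config(rad_bead = 250, eps_2 = 50, eps_1 = 25)
  nucleus <- sphere(c(0, 0, 0), 5000)
  nucleolus <- sphere(c(3000, 0, 0), 500)
  none <- matrix(numeric(0), 0, 3)
  # inside margin R - (r_b + 5*eps_2) = 4500: 4499 passes, 4500 fails
  v <- centromere_candidate_ok(c(0, 0, -4499), nucleus, nucleolus, none, cfg)
  expect_true(v$ok)
  v <- centromere_candidate_ok(c(0, 0, -4500), nucleus, nucleolus, none, cfg)
  expect_false(v$ok); expect_identical(v$code, "C1")
  # nucleolus clearance r + r_b + eps_2 = 800, strictly greater than
  v <- centromere_candidate_ok(c(3000, 800, 0), nucleus, nucleolus, none, cfg)
  expect_false(v$ok); expect_identical(v$code, "C2")
  v <- centromere_candidate_ok(c(3000, 801, 0), nucleus, nucleolus, none, cfg)
  expect_true(v$ok)
  # centromere separation 2*r_b + eps_2 = 550, strictly greater than
  placed <- matrix(c(0, 0, 0), 1, 3)
  v <- centromere_candidate_ok(c(550, 0, 0), nucleus, nucleolus, placed, cfg)
  expect_false(v$ok); expect_identical(v$code, "C3")
  v <- centromere_candidate_ok(c(551, 0, 0), nucleus, nucleolus, placed, cfg)
  expect_true(v$ok)
})

test_that("domain candidates obey the C1'-C5 conditions with strict bounds", {
  cfg <- small_config(rad_bead = 250, eps_1 = 25, eps_2 = 50)
  nucleus <- sphere(c(0, 0, 0), 5000)
  nucleolus <- sphere(c(-3000, 0, 0), 500)
  none <- matrix(numeric(0), 0, 3)
  own <- matrix(c(0, 0, 0), 1, 3)
  # own-chromosome clearance 2*r_b - 2*eps_1 = 450
  v <- domain_candidate_ok(c(449, 0, 0), nucleus, nucleolus, own, none, cfg)
  expect_false(v$ok); expect_identical(v$code, "C3")
  v <- domain_candidate_ok(c(451, 0, 0), nucleus, nucleolus, own, none, cfg)
  expect_true(v$ok)
  # the precursory bead is exempt from the own-bead scan
  v <- domain_candidate_ok(c(250, 0, 0), nucleus, nucleolus, own, none, cfg,
                           precursory = 1L)
  expect_true(v$ok)
  # foreign clearance 2*r_b + eps_2 = 550
  foreign <- matrix(c(1000, 0, 0), 1, 3)
  v <- domain_candidate_ok(c(451, 0, 0), nucleus, nucleolus, own, foreign, cfg)
  expect_false(v$ok); expect_identical(v$code, "C5")
  v <- domain_candidate_ok(c(450, 0, 0), nucleus, nucleolus, own, foreign, cfg)
  expect_true(v$ok)  # 550 nm away exactly: >= threshold accepted
  # nucleus containment R - r_b, strict
  v <- domain_candidate_ok(c(4750, 0, 0), nucleus, nucleolus, none, none, cfg)
  expect_false(v$ok); expect_identical(v$code, "C1")
  # exactly on the nucleolus clearance surface is rejected (strict >)
  v <- domain_candidate_ok(c(-3000 + 800, 0, 0), nucleus, nucleolus,
                           none, none, cfg)
  expect_false(v$ok); expect_identical(v$code, "C2")
  # the literal-variant foreign threshold admits closer foreign beads
  cfg_lit <- small_config(rad_bead = 250, eps_1 = 25, eps_2 = 50,
                          paper_literal = TRUE)
  v <- domain_candidate_ok(c(451, 0, 0), nucleus, nucleolus, own, foreign,
                           cfg_lit)
  expect_true(v$ok)
})

test_that("the fast predicate agrees exactly with a brute-force all-pairs oracle", {
  set.seed(31)
  cfg <- small_config()
  nucleus <- sphere(c(0, 0, 0), 3000)
  nucleolus <- sphere(c(1200, 0, 0), 400)
  for (trial in 1:40) {
    n_own <- sample(0:25, 1)
    n_for <- sample(0:25, 1)
    own <- matrix(rnorm(3 * n_own, sd = 1200), ncol = 3)
    foreign <- matrix(rnorm(3 * n_for, sd = 1200), ncol = 3)
    prec <- if (n_own > 0) sample(n_own, 1) else NULL
    p <- rnorm(3, sd = 1500)
    expect_identical(
      domain_candidate_ok(p, nucleus, nucleolus, own, foreign, cfg,
                          precursory = prec)$ok,
      brute_force_domain_ok(p, nucleus, nucleolus, own, foreign, cfg,
                            precursory = prec))
  }
})

test_that("acceptance verdicts are invariant under global rotation", {
  set.seed(37)
  cfg <- small_config()
  nucleus <- sphere(c(0, 0, 0), 3000)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))  # random orthogonal matrix
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  for (trial in 1:25) {
    nucleolus <- sphere(rnorm(3, sd = 500), 300)
    own <- matrix(rnorm(30, sd = 1200), ncol = 3)
    foreign <- matrix(rnorm(30, sd = 1200), ncol = 3)
    p <- rnorm(3, sd = 1500)
    v1 <- domain_candidate_ok(p, nucleus, nucleolus, own, foreign, cfg)
    v2 <- domain_candidate_ok(
      as.numeric(rot %*% p), nucleus,
      sphere(as.numeric(rot %*% nucleolus$centre), nucleolus$radius),
      own %*% t(rot), foreign %*% t(rot), cfg)
    expect_identical(v1$ok, v2$ok)
    c1 <- centromere_candidate_ok(p, nucleus, nucleolus, own, cfg)
    c2 <- centromere_candidate_ok(
      as.numeric(rot %*% p), nucleus,
      sphere(as.numeric(rot %*% nucleolus$centre), nucleolus$radius),
      own %*% t(rot), cfg)
    expect_identical(c1$ok, c2$ok)
  }
})
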