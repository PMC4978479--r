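# Arm positions used to build hand-made territory layouts: single-bead arms
# (r_b = 250 nm), so border distance = centre distance - 500 exactly.

far <- c(0, 5000, 0)

test_that("border distance is the floored minimum surface-to-surface gap", {
  a <- matrix(c(0, 0, 0), 1, 3)
  b <- matrix(c(1000, 0, 0), 1, 3)
  expect_equal(border_distance(a, b, 250), 500)
  # overlapping beads floor at zero
  expect_equal(border_distance(a, matrix(c(100, 0, 0), 1, 3), 250), 0)
  expect_error(border_distance(a, matrix(numeric(0), 0, 3), 250), "non-empty")
  # oracle: exhaustive double loop over random bead clouds
  set.seed(43)
  for (trial in 1:10) {
    A <- matrix(rnorm(60, sd = 2000), ncol = 3)
    B <- matrix(rnorm(60, sd = 2000), ncol = 3)
    ref <- Inf
    for (i in 1:20) for (j in 1:20)
      ref <- min(ref, sqrt(sum((A[i, ] - B[j, ])^2)) - 500)
    expect_equal(border_distance(A, B, 250), max(ref, 0), tolerance = 1e-9)
  }
})

test_that("homologue arrangements map onto the five classes", {
  expect_length(arrangement_classes(), 5L)
  # all pairings beyond threshold
  m <- toy_model(list(
    list(cen = c(0, 2500, 0), top = c(0, 0, 0), bottom = far),
    list(cen = c(10000, 2500, 0), top = c(10000, 0, 0),
         bottom = c(10000, 5000, 0))))
  expect_identical(classify_homologue_pair(m, 1), "complete_separation")
  # only the two top arms within reach (centre distance 900 => border 400)
  m <- toy_model(list(
    list(cen = c(0, 2500, 0), top = c(0, 0, 0), bottom = far),
    list(cen = c(900, -2500, 0), top = c(900, 0, 0),
         bottom = c(900, -5000, 0))))
  expect_identical(classify_homologue_pair(m, 1), "top_top")
  cls <- classify_homologue_pair(m, 1, details = TRUE)
  expect_identical(unname(attr(cls, "pairings")),
                   c(TRUE, FALSE, FALSE, FALSE))
  # only the two bottom arms
  m <- toy_model(list(
    list(cen = c(0, 2500, 0), top = c(0, -5000, 0), bottom = c(0, 0, 0)),
    list(cen = c(900, 2500, 0), top = c(900, 5000, 0),
         bottom = c(900, 0, 0))))
  expect_identical(classify_homologue_pair(m, 1), "bottom_bottom")
  # both same-arm pairings associated
  m <- toy_model(list(
    list(cen = c(0, 2500, 0), top = c(0, 0, 0), bottom = far),
    list(cen = c(900, 2500, 0), top = c(900, 0, 0), bottom = c(900, 5000, 0))))
  expect_identical(classify_homologue_pair(m, 1), "both_arms")
  # cross pairing only: top of one homologue by the bottom of the other
  m <- toy_model(list(
    list(cen = c(0, 2500, 0), top = c(0, 0, 0), bottom = far),
    list(cen = c(900, -2500, 0), top = c(900, -5000, 0),
         bottom = c(900, 0, 0))))
  expect_identical(classify_homologue_pair(m, 1), "top_bottom")
  # composite case: same-arm evidence dominates cross-arm evidence
  m <- toy_model(list(
    list(cen = c(0, 2500, 0), top = c(0, 0, 0), bottom = far),
    list(cen = c(900, 2500, 0), top = c(900, 0, 0), bottom = c(0, 900, 0))))
  expect_identical(classify_homologue_pair(m, 1), "top_top")
  expect_error(classify_homologue_pair(m, 3), "pair 3")
})

test_that("lowering the threshold only moves pairs toward separation", {
  m <- toy_model(list(
    list(cen = c(0, 2500, 0), top = c(0, 0, 0), bottom = far),
    list(cen = c(900, -2500, 0), top = c(900, 0, 0),
         bottom = c(900, -5000, 0))))
  expect_identical(classify_homologue_pair(m, 1, threshold = 500), "top_top")
  expect_identical(classify_homologue_pair(m, 1, threshold = 400),
                   "complete_separation")
  # property: on simulated models, once separated at a threshold, a pair
  # stays separated at every lower threshold
  batch <- simulate_batch(small_config(), 5, seed = 47)
  for (m in batch$models) for (p in 1:2) {
    thr <- c(800, 500, 300, 100)
    sep <- vapply(thr, function(t)
      classify_homologue_pair(m, p, t) == "complete_separation", logical(1))
    expect_true(all(diff(sep) >= 0))  # separation is monotone in threshold
  }
})

test_that("classification is invariant under rigid rotation of the model", {
  set.seed(53)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  batch <- simulate_batch(small_config(), 3, seed = 59)
  for (m in batch$models) {
    m_rot <- m
    xyz <- as.matrix(m$beads[, c("x", "y", "z")]) %*% t(rot)
    m_rot$beads$x <- xyz[, 1]; m_rot$beads$y <- xyz[, 2]
    m_rot$beads$z <- xyz[, 3]
    for (p in 1:2)
      expect_identical(classify_homologue_pair(m, p),
                       classify_homologue_pair(m_rot, p))
    expect_identical(classify_heterologue_pair(m, c(1, 2)),
                     classify_heterologue_pair(m_rot, c(1, 2)))
  }
})

test_that("heterologue verdicts use the strict 500 nm whole-territory rule", {
  mk <- function(gap) {
    x0 <- gap + 500  # centre offset giving a border distance of exactly `gap`
    toy_model(list(
      list(cen = c(0, 2500, 0), top = c(0, 0, 0), bottom = far),
      list(cen = c(0, 7500, 0), top = c(0, 10000, 0), bottom = c(0, 12000, 0)),
      list(cen = c(x0, 2500, 0), top = c(x0, 0, 0), bottom = c(x0, 5000, 0)),
      list(cen = c(x0, 7500, 0), top = c(x0, 10000, 0),
           bottom = c(x0, 12000, 0))))
  }
  m <- mk(499)
  expect_identical(classify_heterologue_pair(m, c(1, 2)), "associated")
  expect_identical(classify_heterologue_pair(m, c(2, 1)), "associated")
  m <- mk(500)
  expect_identical(classify_heterologue_pair(m, c(1, 2)), "separated")
  expect_identical(classify_heterologue_pair(m, c(2, 1)), "separated")
  expect_error(classify_heterologue_pair(m, c(1, 1)), "distinct")
  expect_error(classify_heterologue_pair(m, c(1, 9)), "range")
})

test_that("frequency tables partition every pair of every model", {
  batch <- simulate_batch(small_config(), 6, seed = 61)
  tab <- tabulate_arrangements(batch)
  expect_s3_class(tab, "ct_freq_table")
  # each pair's counts sum to the number of models
  sums <- tapply(tab$count, tab$pair, sum)
  expect_true(all(sums == 6L))
  pcts <- tapply(tab$percent, tab$pair, sum)
  expect_equal(as.numeric(pcts), rep(100, 2))
  # a single model contributes exactly one class per pair
  tab1 <- tabulate_arrangements(batch$models[1])
  expect_true(all(tapply(tab1$count, tab1$pair, sum) == 1L))
  expect_true(all(tab1$count %in% c(0L, 1L)))
  # mixed configurations are refused
  other <- simulate_nucleus(ct_preset("set1"), seed = 2)
  expect_error(tabulate_arrangements(list(batch$models[[1]], other)),
               "configuration")
})

test_that("the Pearson goodness-of-fit statistic matches the textbook formula", {
  g <- chisq_gof(c(5, 5), expected = c(5, 5))
  expect_identical(g$statistic, 0)
  expect_identical(g$p_value, 1)
  g <- chisq_gof(c(10, 0), expected = c(5, 5))
  expect_identical(g$statistic, 10)
  expect_identical(g$df, 1L)
  # reference implementation as oracle on random tables
  set.seed(67)
  for (trial in 1:25) {
    k <- sample(2:8, 1)
    obs <- rpois(k, 20) + 1
    prop <- { p <- runif(k, 0.1, 1); p / sum(p) }
    ours <- chisq_gof(obs, proportions = prop)
    ref <- suppressWarnings(stats::chisq.test(obs, p = prop))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
    expect_identical(ours$df, as.integer(ref$parameter))
  }
  expect_error(chisq_gof(c(1, 2), expected = c(1, 0)), "positive")
  expect_error(chisq_gof(c(1, 2)), "exactly one")
  expect_error(chisq_gof(c(1, 2), expected = c(1, 1), proportions = c(.5, .5)),
               "exactly one")
})
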