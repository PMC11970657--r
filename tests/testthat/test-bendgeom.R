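# Projection frame, projected bend angle, convergence statistics and the
# two-condition comparison.

test_that("the projection frame follows the coiled-coil axes", {
  fr <- build_frame(B1 = c(-5, 0, 0), B2 = c(5, 0, 0),
                    E1 = c(-15, 0, 40), E2 = c(15, 0, 40))
  expect_equal(fr$C, c(0, 0, 0))
  expect_equal(abs(fr$z), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(abs(fr$x), c(0, 1, 0), tolerance = 1e-12)
  expect_lt(abs(sum(fr$x * fr$z)), 1e-8)

  # rigid rotation of the anchors rotates the frame identically
  tr <- random_rigid(seed = 3)
  fr2 <- build_frame(tr(matrix(c(-5, 0, 0), 1)),
                     tr(matrix(c(5, 0, 0), 1)),
                     tr(matrix(c(-15, 0, 40), 1)),
                     tr(matrix(c(15, 0, 40), 1)))
  # the rotated z axis is the transform of the original one
  R <- attr(tr, "R")
  expect_equal(abs(as.numeric(R %*% fr$z)), abs(fr2$z), tolerance = 1e-10)

  # parallel axis vectors trigger the documented fallback
  expect_warning(
    build_frame(c(-5, 0, 0), c(5, 0, 0), c(-5, 0, 40), c(5, 0, 40)),
    "parallel")
})

test_that("projection maps points to in-plane coordinates", {
  fr <- build_frame(c(-5, 0, 0), c(5, 0, 0), c(-15, 0, 40), c(15, 0, 40))
  expect_equal(as.numeric(project_onto_frame(fr$C, fr)), c(0, 0))
  p <- fr$C + 3 * fr$x + 4 * fr$z
  expect_equal(as.numeric(project_onto_frame(p, fr)), c(3, 4))
})

test_that("the bend angle is computed from antiparallel strand chords", {
  # parallel chords -> zero angle
  s1 <- rbind(matrix(0, 10, 2), c(0, 10))  # nt 1 at (0,0), nt 11 at (0,10)
  s1[1, ] <- c(0, 0)
  s2 <- rbind(c(0, 30), matrix(0, 9, 2), c(0, 20))  # b1 - b2 = (0, 10)
  expect_equal(bend_angle(s1, s2), 0)

  # clamping keeps the angle finite for numerically collinear vectors
  expect_true(is.finite(bend_angle(s1, s2)))
  expect_error(bend_angle(s1[1:5, , drop = FALSE], s2), "nucleotides")

  # planted planar bends are recovered through the full projection path
  for (ang in c(15, 30, 60)) {
    d <- generate_bent_dna(bent_dna_spec(bend_angle = ang, noise_sd = 0))
    got <- bend_angle_trajectory(d$coords, d$beads, d$anchors)
    expect_lt(abs(got - ang), 2)
  }
})

test_that("angle statistics: rolling means, trend, exclusions", {
  # constant series: rolling mean equals the constant, no trend
  const <- rep(25, 1200)
  st <- angle_statistics(list(const), window = 100)
  expect_true(all(abs(st$rolling[[1]][-(1:99)] - 25) < 1e-12))
  expect_false(st$trend$flagged[1])
  expect_equal(st$theta_i, 25)

  # stationary noisy series: mean recovered, no monotone trend
  set.seed(1)
  series <- lapply(1:5, function(i) rnorm(2000, mean = 30, sd = 5))
  st2 <- angle_statistics(series, window = 500)
  expect_false(any(st2$trend$flagged))
  expect_lt(max(abs(st2$theta_i - 30)), 1)

  # planted dissociation pattern: 16 of 20 trajectories excluded
  set.seed(2)
  bound <- lapply(1:20, function(i) {
    b <- rep(TRUE, 1200)
    if (i <= 16) b[700:850] <- FALSE  # 151 consecutive unbound frames
    b
  })
  series20 <- lapply(1:20, function(i) rnorm(1200, 20, 3))
  st3 <- angle_statistics(series20, window = 100, bound = bound, K = 100)
  expect_equal(st3$n_excluded, 16)
  expect_length(st3$theta_i, 4)

  # all excluded errors out
  expect_error(
    angle_statistics(series20[1:2], window = 100,
                     bound = list(rep(FALSE, 1200), rep(FALSE, 1200))),
    "all trajectories excluded")
})

test_that("condition comparisons match the closed-form t-tests", {
  # identical non-constant groups: t = 0, p = 1
  g <- c(10, 12, 14, 16)
  cc <- compare_conditions(g, g)
  expect_equal(cc$statistic, 0)
  expect_equal(cc$p.value, 1)

  # published summary statistics reproduce the printed p-value
  cc2 <- compare_conditions(c(mean = 31.0, sd = 14.5, n = 20),
                            c(mean = 3.1, sd = 7.6, n = 4))
  expect_equal(cc2$p.value, 0.00045, tolerance = 0.05)

  # pooled variant, hand-computed: (0,1,n=5) vs (1,1,n=5)
  cc3 <- compare_conditions(c(mean = 0, sd = 1, n = 5),
                            c(mean = 1, sd = 1, n = 5),
                            variant = "pooled")
  expect_equal(cc3$statistic, -1.5811, tolerance = 1e-4)
  expect_equal(cc3$df, 8)

  # Welch agrees with stats::t.test to 1e-10 on raw vectors
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(12, 20, 6); b <- rnorm(7, 10, 3)
    ours <- compare_conditions(a, b)
    ref <- t.test(a, b)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    expect_equal(unname(ours$statistic), unname(ref$statistic),
                 tolerance = 1e-10)
  }

  # zero variance in both groups is rejected
  expect_error(compare_conditions(rep(1, 4), rep(1, 4)), "zero variance")
})
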