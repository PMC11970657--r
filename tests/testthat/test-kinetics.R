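# Event extraction, survival curves, segmented fits and bootstrap rates.

test_that("events are maximal bound runs with gap merging and censoring", {
  tn <- manual_tensor(3, 10, 1, list(
    list(res = 1, frames = c(3, 4, 5, 9), copy = 1)))
  ev <- extract_events(tn, 1)
  expect_equal(ev$table$frames, c(3, 1))
  expect_equal(ev$lifetimes, c(3000, 1000))  # 1000 timesteps per frame
  expect_false(any(ev$censored))

  # gap tolerance 1 merges runs separated by a single unbound frame
  tn2 <- manual_tensor(3, 10, 1, list(
    list(res = 1, frames = c(3, 4, 5, 7, 8), copy = 1)))
  ev2 <- extract_events(tn2, 1, gap_tolerance = 1)
  expect_equal(ev2$table$frames, 6)
  expect_equal(ev2$table$start, 3)
  expect_equal(ev2$table$end, 8)

  # runs touching the last frame are censored
  tn3 <- manual_tensor(3, 10, 1, list(
    list(res = 2, frames = 8:10, copy = 1)))
  expect_true(extract_events(tn3, 1:2)$censored)

  # any patch residue in contact counts toward the run
  tn4 <- manual_tensor(3, 10, 1, list(
    list(res = 1, frames = 1:2, copy = 1),
    list(res = 2, frames = 3:4, copy = 1)))
  expect_equal(extract_events(tn4, 1:2)$table$frames, 4)
})

test_that("gap tolerance 0 reproduces the tensor run-length encoding", {
  spec <- contact_schedule_spec(10, list(1:3), n_frames = 2000,
                                n_dna_copies = 2, binding_rate = 0.05,
                                seed = 13)
  tn <- generate_contact_tensor(spec)$tensor
  ev <- extract_events(tn, 1:3)
  # direct enumeration oracle
  want <- integer(0)
  for (d in 1:2) {
    bound <- apply(tn$occ[1:3, , d, drop = FALSE], 2, any)
    r <- rle(bound)
    want <- c(want, r$lengths[r$values])
  }
  expect_equal(sort(ev$table$frames), sort(want))
})

test_that("survival curves are equally weighted step summaries", {
  # step function for equal lifetimes is degenerate: curve errors out
  expect_error(survival_curve(event_set(rep(5000, 50))),
               NA)  # building the curve itself is fine
  crv0 <- survival_curve(event_set(rep(5000, 50)), n_points = 5)
  expect_equal(crv0$P, c(1, 0))  # P = 1 before t = 5000, 0 at and after

  # lifetimes 1..10: P(5) = 0.5
  crv <- survival_curve(event_set(1:10 * 1.0, steps_per_frame = 1),
                        n_points = 10)
  expect_equal(crv$P[crv$t == 5], 0.5)

  # P(0) = 1 and monotone non-increase for arbitrary event sets
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(50:300, 1)
    tau <- exp(rnorm(n, 6, 2))
    crv <- survival_curve(event_set(tau), n_points = 30)
    expect_equal(crv$P[1], 1)
    expect_equal(crv$t[1], 0)
    expect_true(all(diff(crv$P) < 0))
  }

  expect_error(survival_curve(event_set(1:5 * 1.0), n_points = 10),
               "too few events")
})

test_that("segmented fits recover exact piecewise-linear curves", {
  t <- seq(0, 100, by = 2)
  y <- ifelse(t <= 20, -0.1 * t, -0.1 * 20 - 0.001 * (t - 20))
  crv <- data.frame(t = t, P = exp(y), N = round(exp(y) * 1000))
  class(crv) <- c("survival_curve", "data.frame")
  fit <- segmented_fit(crv)
  expect_lt(abs(fit$slope_fast - (-0.1)) / 0.1, 1e-6)
  expect_lt(abs(fit$slope_slow - (-0.001)) / 0.001, 1e-6)
  expect_lt(abs(fit$t1 - 20), fit$grid_step + 1e-9)
  expect_false(fit$single_regime)

  # non-monotone input rejected
  bad <- crv; bad$P[3] <- 1.5
  expect_error(segmented_fit(bad), "non-increasing")
})

test_that("pure single-exponential lifetimes raise the single-regime flag", {
  errs <- vapply(1:10, function(s) {
    tau <- generate_dwell_times(kinetic_spec(1e-2, 1e-3, weight_fast = 0,
                                             n_events = 1e4, seed = 40 + s))
    fit <- segmented_fit(survival_curve(event_set(tau)))
    expect_true(fit$single_regime)
    abs(fit$koff_slow - 1e-3) / 1e-3
  }, 0)
  expect_lt(mean(errs), 0.05)
})

test_that("two-mode mixtures recover the slow rate within 10 percent", {
  tau <- generate_dwell_times(kinetic_spec(1e-3, 1e-5, weight_fast = 0.7,
                                           n_events = 1e4, seed = 42))
  fit <- segmented_fit(survival_curve(event_set(tau)))
  expect_false(fit$single_regime)
  expect_lt(abs(fit$koff_slow - 1e-5) / 1e-5, 0.10)
})

test_that("bootstrap estimates are reproducible and flag degeneracy", {
  tau <- generate_dwell_times(kinetic_spec(1e-3, 1e-5, weight_fast = 0.7,
                                           n_events = 1500, seed = 43))
  ev <- event_set(tau)
  a <- bootstrap_koff(ev, B = 200, seed = 99)
  b <- bootstrap_koff(ev, B = 200, seed = 99)
  expect_identical(a[c("mean", "sd")], b[c("mean", "sd")])

  # all-equal lifetimes are degenerate
  expect_error(bootstrap_koff(event_set(rep(1000, 50)), B = 10, seed = 1),
               "degenerate")

  # lower-bound flag propagates
  lb <- bootstrap_koff(ev, B = 50, seed = 1, lower_bound = TRUE)
  expect_true(lb$lower_bound)
})

test_that("bootstrap mean tracks the full-sample point estimate", {
  tau <- generate_dwell_times(kinetic_spec(1e-3, 1e-5, weight_fast = 0.7,
                                           n_events = 4000, seed = 44))
  est <- bootstrap_koff(event_set(tau), B = 1000, seed = 7)
  expect_lt(abs(est$mean - est$koff_point) / est$koff_point, 0.02)
})
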