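# Synthetic generator: dwell-time law, contact schedules, bent duplexes,
# and coordinate-level realisations.

test_that("dwell times follow the prescribed mixture and are reproducible", {
  # pure slow mode: sample mean must approach the closed-form mean 1/k
  sp <- kinetic_spec(1e-2, 1e-3, weight_fast = 0, n_events = 1e5, seed = 11)
  tau <- generate_dwell_times(sp)
  expect_lt(abs(mean(tau) - 1e3) / 1e3, 0.02)

  # degenerate mixture: indistinguishable from a single exponential
  sp1 <- kinetic_spec(1e-3, 1e-5, weight_fast = 1, n_events = 2e4, seed = 12)
  ks <- suppressWarnings(
    stats::ks.test(generate_dwell_times(sp1), stats::pexp, rate = 1e-3))
  expect_gt(ks$p.value, 0.01)

  # determinism
  expect_identical(generate_dwell_times(sp), generate_dwell_times(sp))

  # invalid rates rejected
  expect_error(kinetic_spec(1e-5, 1e-3), "k_fast > k_slow")
  expect_error(kinetic_spec(1e-3, -1), "k_fast > k_slow")
  expect_error(kinetic_spec(1e-3, 1e-5, weight_fast = 1.2), "weight_fast")
})

test_that("empirical dwell survival matches the two-exponential closed form", {
  w <- 0.7; kf <- 1e-3; ks <- 1e-5
  sp <- kinetic_spec(kf, ks, w, n_events = 1e5, seed = 21)
  tau <- generate_dwell_times(sp)
  cdf <- function(q) 1 - (w * exp(-kf * q) + (1 - w) * exp(-ks * q))
  d <- suppressWarnings(stats::ks.test(tau, cdf))$statistic
  expect_lt(unname(d), 0.02)
})

test_that("contact schedules honour rates, competition and disjointness", {
  # binding rate zero: nothing ever binds
  sp0 <- contact_schedule_spec(20, list(1:4), n_frames = 500,
                               binding_rate = 0, seed = 1)
  sim0 <- generate_contact_tensor(sp0)
  expect_false(any(sim0$tensor$occ))
  expect_identical(nrow(sim0$events), 0L)

  # competition with fast binding and slow unbinding: the patch is held
  # by some copy essentially always
  spc <- contact_schedule_spec(
    10, list(1:3), n_frames = 4000, n_dna_copies = 3,
    kinetics = kinetic_spec(1e-3, 1e-5, weight_fast = 0.1),
    binding_rate = 0.8, competition = TRUE, seed = 2)
  simc <- generate_contact_tensor(spc)
  occ_frac <- patch_occupancy(simc$tensor, 1:3)$fraction
  expect_gt(occ_frac, 0.99)

  # overlapping planted patches rejected
  expect_error(contact_schedule_spec(20, list(1:4, 4:8), n_frames = 10),
               "disjoint")

  # fixed seed reproduces the tensor and the event log exactly
  rep1 <- generate_contact_tensor(spc)
  expect_identical(rep1$tensor$occ, simc$tensor$occ)
  expect_identical(rep1$events, simc$events)
})

test_that("ground-truth stable-mode dwells recover k_slow on re-analysis", {
  # frame-resolved schedule (one step per frame) so logged dwell times
  # can be fed straight back into the kinetics fit
  sp <- contact_schedule_spec(
    3, list(1:3), n_frames = 2e5, n_dna_copies = 3,
    kinetics = kinetic_spec(0.5, 0.01, weight_fast = 0.3),
    binding_rate = 0.9, steps_per_frame = 1, seed = 31)
  sim <- generate_contact_tensor(sp)
  slow <- sim$events$dwell_steps[sim$events$mode == "stable"]
  expect_gt(length(slow), 5000)
  fit <- segmented_fit(survival_curve(event_set(slow, steps_per_frame = 1)))
  expect_lt(abs(fit$koff_slow - 0.01) / 0.01, 0.10)
})

test_that("bent duplex geometry matches the planted rotation", {
  # no bend: sugar beads lie on a cylinder about a single straight axis
  d0 <- generate_bent_dna(bent_dna_spec(bend_angle = 0, noise_sd = 0))
  sug <- d0$coords[d0$beads$role == "sugar", , 1]
  expect_lt(max(abs(sqrt(sug[, 1]^2 + sug[, 2]^2) - sug[1, 1])), 1e-9)
  expect_lt(bend_angle_trajectory(d0$coords, d0$beads, d0$anchors), 2)

  # 30 degree bend: the downstream axis direction (paired-sugar centres
  # one full turn apart, so radial components cancel) makes 30 degrees
  # with the upstream axis direction
  d30 <- generate_bent_dna(bent_dna_spec(bend_angle = 30, noise_sd = 0))
  bp_centre <- function(d, bp) {
    rows <- d$beads$role == "sugar" & d$beads$bp == bp
    colMeans(d$coords[rows, , 1, drop = FALSE][, , 1, drop = TRUE])
  }
  v_up <- bp_centre(d30, 11) - bp_centre(d30, 1)
  v_dn <- bp_centre(d30, 24) - bp_centre(d30, 14)
  ang <- acos(sum(v_up * v_dn) / sqrt(sum(v_up^2) * sum(v_dn^2))) * 180 / pi
  expect_lt(abs(ang - 30), 0.5)

  # downstream angle computed through the projection machinery
  expect_lt(abs(bend_angle_trajectory(d30$coords, d30$beads, d30$anchors) - 30), 2)

  # rigid-body rotation of duplex plus anchors leaves the angle unchanged
  tr <- random_rigid(seed = 5)
  rot_coords <- array(tr(d30$coords[, , 1]), dim = dim(d30$coords))
  rot_anchors <- lapply(d30$anchors, function(a) as.numeric(tr(matrix(a, 1))))
  expect_equal(bend_angle_trajectory(rot_coords, d30$beads, rot_anchors),
               bend_angle_trajectory(d30$coords, d30$beads, d30$anchors),
               tolerance = 1e-10)

  # invalid bends rejected
  expect_error(bent_dna_spec(bend_angle = 180), "0, 180")
  expect_error(bent_dna_spec(bend_angle = -1), "0, 180")
})

test_that("coordinate realisations reproduce the schedule through the caller", {
  patches <- list(1:5, 11:15)
  cloud <- make_protein_cloud(40, patches, seed = 1)
  spec <- contact_schedule_spec(40, patches, n_frames = 150,
                                n_dna_copies = 2, binding_rate = 0.05,
                                seed = 3)
  traj <- generate_binding_trajectory(cloud, spec, box_side = 200)
  called <- call_contacts(traj$coords, traj$topology, threshold = 8)
  expect_identical(called$occ, traj$tensor$occ)

  # every logged bound frame yields at least one called contact
  for (i in seq_len(nrow(traj$events))) {
    ev <- traj$events[i, ]
    res <- spec$patches[[ev$patch]]
    sub <- called$occ[res, ev$start:ev$end, ev$copy, drop = FALSE]
    expect_true(all(apply(sub, 2, any)))
  }

  # zero DNA copies: empty tensor
  sp0 <- contact_schedule_spec(40, patches, n_frames = 5,
                               n_dna_copies = 0, seed = 1)
  traj0 <- generate_binding_trajectory(cloud, sp0, box_side = 200)
  expect_identical(dim(traj0$tensor$occ)[3], 0L)

  # free placements near the boundary stay non-contacts under the
  # minimum image, per the brute-force oracle
  orc <- oracle_contacts(traj$coords[, , 1:20, drop = FALSE],
                         traj$topology, 8)
  expect_identical(called$occ[, 1:20, , drop = FALSE], orc)

  # a box too small to place copies beyond twice the threshold fails
  expect_error(
    generate_binding_trajectory(make_protein_cloud(40, patches, seed = 1),
                                spec, box_side = 40),
    "box too small")
})
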