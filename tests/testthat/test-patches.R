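# Jaccard co-binding distances, patch clustering, ranking and strength.

test_that("Jaccard distances follow the same-copy co-binding definition", {
  # i and j always bound to the same copy -> dJ = 0
  tn <- manual_tensor(2, 10, 1, list(
    list(res = 1, frames = 1:10, copy = 1),
    list(res = 2, frames = 1:10, copy = 1)))
  expect_equal(jaccard_distances(tn)$d[1, 2], 0)

  # disjoint frame sets -> intersection 0 -> dJ = 1
  tn2 <- manual_tensor(2, 10, 1, list(
    list(res = 1, frames = 1:5, copy = 1),
    list(res = 2, frames = 6:10, copy = 1)))
  expect_equal(jaccard_distances(tn2)$d[1, 2], 1)

  # enumerated case: frames {1,2,3} vs {2,3,4} on the same copy
  tn3 <- manual_tensor(2, 10, 1, list(
    list(res = 1, frames = 1:3, copy = 1),
    list(res = 2, frames = 2:4, copy = 1)))
  expect_equal(jaccard_distances(tn3)$d[1, 2], 0.5)

  # simultaneous contacts with different copies count in the union only
  tn4 <- manual_tensor(2, 10, 2, list(
    list(res = 1, frames = 1:3, copy = 1),
    list(res = 2, frames = 1:3, copy = 2)))
  expect_equal(jaccard_distances(tn4)$d[1, 2], 1)

  # low-frequency residues are excluded; excluding everything errors
  tn5 <- manual_tensor(3, 100, 1, list(
    list(res = 1, frames = 1:50, copy = 1),
    list(res = 2, frames = 1, copy = 1)))
  jm <- jaccard_distances(tn5, min_frequency = 0.05)
  expect_identical(jm$residues, 1L)
  expect_error(jaccard_distances(tn5, min_frequency = 0.9), "min_frequency")
})

test_that("Jaccard matrices are symmetric, zero-diagonal and in [0,1]", {
  for (seed in 1:5) {
    spec <- contact_schedule_spec(30, list(1:4, 10:14, 20:26),
                                  n_frames = 800, n_dna_copies = 3,
                                  emission_prob = 0.6,
                                  binding_rate = 0.05, seed = seed)
    jm <- jaccard_distances(generate_contact_tensor(spec)$tensor,
                            min_frequency = 0)
    expect_equal(jm$d, t(jm$d))
    expect_true(all(diag(jm$d) == 0))
    expect_true(all(jm$d >= 0 & jm$d <= 1))
  }
})

test_that("clustering recovers planted patches", {
  patches <- list(1:6, 21:28, 41:45)
  spec <- contact_schedule_spec(60, patches, n_frames = 5000,
                                n_dna_copies = 3, binding_rate = 0.03,
                                seed = 7)
  sim <- generate_contact_tensor(spec)
  ps <- cluster_patches(jaccard_distances(sim$tensor))
  expect_length(ps$patches, 3)
  expect_identical(unname(ps$patches),
                   lapply(patches, as.integer))

  # single planted patch: one cluster equal to the planted set
  spec1 <- contact_schedule_spec(30, list(5:10), n_frames = 2000,
                                 binding_rate = 0.05, seed = 8)
  ps1 <- cluster_patches(jaccard_distances(generate_contact_tensor(spec1)$tensor))
  expect_identical(unname(ps1$patches), list(5:10))

  # partition is equivariant under residue relabelling
  sim2 <- sim
  perm <- sample(60)
  occ_p <- sim$tensor$occ[perm, , , drop = FALSE]
  tn_p <- contact_tensor(occ_p, residues = sim$tensor$residues[perm])
  ps_p <- cluster_patches(jaccard_distances(tn_p))
  expect_identical(lapply(ps_p$patches, sort), lapply(ps$patches, sort))
})

test_that("subset emission still yields near-perfect recovery", {
  patches <- list(1:6, 21:28, 41:45)
  truth <- rep(NA_integer_, 60)
  for (k in seq_along(patches)) truth[patches[[k]]] <- k
  spec <- contact_schedule_spec(60, patches, n_frames = 5000,
                                n_dna_copies = 3, binding_rate = 0.03,
                                emission_prob = 0.7, seed = 9)
  jm <- jaccard_distances(generate_contact_tensor(spec)$tensor)
  ps <- cluster_patches(jm)
  rec <- rep(NA_integer_, 60)
  for (k in seq_along(ps$patches)) rec[ps$patches[[k]]] <- k
  keep <- !is.na(truth) & !is.na(rec)
  expect_gte(partition_ari(truth[keep], rec[keep]), 0.9)
})

test_that("patches are ranked, named and classified by dissociation rate", {
  ps <- structure(list(patches = list(patch_1 = 1:3, patch_2 = 11:13,
                                      patch_3 = 21:23),
                       unassigned = integer(0)),
                  class = "patch_set")
  ranked <- rank_patches(ps, list(3e-6, 1e-7, 5e-5), label = "A")
  # rank 1 = smallest k_off
  expect_identical(ranked$patches,
                   list(A1 = 11:13, A2 = 1:3, A3 = 21:23))
  expect_identical(unname(ranked$strength), c("strong", "strong", "weak"))

  # single patch
  one <- structure(list(patches = list(patch_1 = 1:3),
                        unassigned = integer(0)), class = "patch_set")
  expect_identical(names(rank_patches(one, list(1e-6), label = "H")$patches),
                   "H1")

  # ties break on the smallest member residue index
  tied <- rank_patches(ps, list(1e-6, 1e-6, 1e-6), label = "B")
  expect_identical(tied$patches, list(B1 = 1:3, B2 = 11:13, B3 = 21:23))

  expect_error(rank_patches(ps, list(1e-6)), "one dissociation-rate")
})

test_that("strength classification is strict at the cutoff", {
  expect_identical(classify_strength(1.2e-7), "strong")
  expect_identical(classify_strength(2.0e-5), "weak")  # boundary: not strong
  expect_identical(classify_strength(3.0e-5), "weak")
  expect_error(classify_strength(-1e-6), "non-negative")
})
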