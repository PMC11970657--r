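# Synthetic-trajectory generator: prescribed two-mode binding kinetics,
# planted binding patches, ideal B-helix DNA with plantable planar bends,
# and coordinate-level realisations in a periodic box. These stand in for
# coarse-grained MD trajectories so that every analysis stage can be
# validated against known ground truth.

#' Two-mode dissociation kinetics specification
#'
#' Describes the dwell-time law of a binding patch as a mixture of a
#' transient (fast) and a stable (slow) exponential mode. Rates are per
#' simulation timestep, matching the units in which dissociation rate
#' constants are reported.
#'
#' @param k_fast Rate of the transient mode, per timestep. Must exceed
#'   `k_slow`.
#' @param k_slow Rate of the stable mode, per timestep. Must be positive.
#' @param weight_fast Mixture weight of the transient mode, in `[0, 1]`.
#' @param n_events Default number of dwell times to draw.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An object of class `kinetic_spec`.
#' @export
#' @examples
#' sp <- kinetic_spec(k_fast = 1e-3, k_slow = 1e-5, weight_fast = 0.7,
#'                    n_events = 100, seed = 1)
#' tau <- generate_dwell_times(sp)
kinetic_spec <- function(k_fast, k_slow, weight_fast = 0.7,
                         n_events = 1L, seed = NULL) {
  if (!is.numeric(k_fast) || !is.numeric(k_slow) ||
      !is.finite(k_fast) || !is.finite(k_slow) ||
      k_slow <= 0 || k_fast <= k_slow)
    stop("rates must satisfy k_fast > k_slow > 0", call. = FALSE)
  if (!is.numeric(weight_fast) || weight_fast < 0 || weight_fast > 1)
    stop("weight_fast must lie in [0, 1]", call. = FALSE)
  n_events <- as.integer(n_events)
  if (is.na(n_events) || n_events < 1L)
    stop("n_events must be a positive integer", call. = FALSE)
  structure(list(k_fast = k_fast, k_slow = k_slow,
                 weight_fast = weight_fast, n_events = n_events,
                 seed = seed),
            class = "kinetic_spec")
}

#' Draw dwell times from a two-exponential mixture
#'
#' Each lifetime is drawn from
#' `weight_fast * Exp(k_fast) + (1 - weight_fast) * Exp(k_slow)`,
#' in timesteps. Reproducible for a fixed seed.
#'
#' @param spec A [kinetic_spec()].
#' @param n Number of lifetimes; defaults to `spec$n_events`.
#' @return Numeric vector of lifetimes (timesteps).
#' @export
generate_dwell_times <- function(spec, n = spec$n_events) {
  stopifnot(inherits(spec, "kinetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- as.integer(n)
  fast <- stats::runif(n) < spec$weight_fast
  tau <- numeric(n)
  tau[fast] <- stats::rexp(sum(fast), rate = spec$k_fast)
  tau[!fast] <- stats::rexp(sum(!fast), rate = spec$k_slow)
  tau
}

#' Contact-schedule specification for planted binding patches
#'
#' Defines a system of `n_residues` protein residues carrying disjoint
#' planted patches, `n_dna_copies` identical DNA fragments, and a
#' per-patch two-state (free/bound) binding process: a free DNA copy binds
#' an available patch with probability `binding_rate` per frame, and a
#' bound copy stays for a dwell time drawn from the patch's
#' [kinetic_spec()] (rates per timestep, converted to frames via
#' `steps_per_frame`). With `competition = TRUE` a patch holds at most one
#' copy at a time, so copies compete for a strong patch and it can remain
#' occupied essentially always.
#'
#' @param n_residues Total number of protein residues.
#' @param patches List of disjoint integer residue-index sets.
#' @param n_frames Number of trajectory frames.
#' @param n_dna_copies Number of DNA copies (default 3, the multi-copy
#'   search setup used for the larger subunits).
#' @param kinetics A single [kinetic_spec()] applied to every patch, or a
#'   list with one spec per patch.
#' @param binding_rate Binding probability per free copy per patch per
#'   frame.
#' @param competition Logical; a patch holds at most one copy at a time.
#' @param emission_prob Probability that each patch residue is emitted as
#'   in-contact during a bound frame (at least one residue is always
#'   emitted). `1` emits the full patch every bound frame; lower values
#'   stress the co-binding clustering.
#' @param steps_per_frame Timesteps represented by one saved frame,
#'   used to convert per-timestep rates to frames (default 1000).
#' @param seed Integer seed.
#' @return An object of class `contact_schedule_spec`.
#' @export
contact_schedule_spec <- function(n_residues, patches, n_frames,
                                  n_dna_copies = 3L,
                                  kinetics = kinetic_spec(1e-3, 1e-5, 0.7),
                                  binding_rate = 0.01,
                                  competition = FALSE,
                                  emission_prob = 1,
                                  steps_per_frame = 1000,
                                  seed = 1L) {
  n_residues <- as.integer(n_residues)
  n_frames <- as.integer(n_frames)
  n_dna_copies <- as.integer(n_dna_copies)
  if (n_residues < 1L || n_frames < 1L || n_dna_copies < 0L)
    stop("counts must be positive (n_dna_copies may be zero)", call. = FALSE)
  if (!is.list(patches) || !length(patches))
    stop("patches must be a non-empty list of residue-index sets",
         call. = FALSE)
  patches <- lapply(patches, function(p) sort(as.integer(p)))
  all_idx <- unlist(patches)
  if (anyDuplicated(all_idx))
    stop("planted patches must be disjoint", call. = FALSE)
  if (any(all_idx < 1L | all_idx > n_residues))
    stop("patch residue indices out of range", call. = FALSE)
  if (inherits(kinetics, "kinetic_spec"))
    kinetics <- rep(list(kinetics), length(patches))
  if (length(kinetics) != length(patches))
    stop("need one kinetic_spec per patch", call. = FALSE)
  if (binding_rate < 0 || binding_rate > 1)
    stop("binding_rate must be a per-frame probability in [0, 1]",
         call. = FALSE)
  if (emission_prob <= 0 || emission_prob > 1)
    stop("emission_prob must lie in (0, 1]", call. = FALSE)
  structure(list(n_residues = n_residues, patches = patches,
                 n_frames = n_frames, n_dna_copies = n_dna_copies,
                 kinetics = kinetics, binding_rate = binding_rate,
                 competition = isTRUE(competition),
                 emission_prob = emission_prob,
                 steps_per_frame = steps_per_frame,
                 seed = as.integer(seed)),
            class = "contact_schedule_spec")
}

#' Simulate a contact tensor from planted binding patches
#'
#' Runs the per-copy binding schedule defined by a
#' [contact_schedule_spec()] and discretises it to frames, producing a
#' boolean residue x frame x copy occupancy tensor together with the
#' ground-truth event log listing every (patch, copy, start, end) binding
#' event and the mode (transient or stable) its dwell time was drawn from.
#'
#' @param spec A [contact_schedule_spec()].
#' @return A list with elements `tensor` (a [contact_tensor()]) and
#'   `events` (data frame: patch, copy, start, end, frames, dwell_steps,
#'   mode, censored).
#' @export
generate_contact_tensor <- function(spec) {
  stopifnot(inherits(spec, "contact_schedule_spec"))
  set.seed(spec$seed)
  P <- length(spec$patches)
  Dc <- spec$n_dna_copies
  Tn <- spec$n_frames
  state <- integer(Dc)   # 0 = free, else bound patch index
  expire <- integer(Dc)  # last bound frame
  ev_patch <- integer(0); ev_copy <- integer(0)
  ev_start <- integer(0); ev_end <- integer(0)
  ev_steps <- numeric(0); ev_mode <- character(0)
  if (Dc > 0L) {
    for (t in seq_len(Tn)) {
      state[state > 0L & expire < t] <- 0L
      for (d in which(state == 0L)) {
        avail <- seq_len(P)
        if (spec$competition && any(state > 0L))
          avail <- setdiff(avail, state[state > 0L])
        if (!length(avail)) next
        hit <- avail[stats::runif(length(avail)) < spec$binding_rate]
        if (!length(hit)) next
        p <- if (length(hit) > 1L) hit[sample.int(length(hit), 1L)] else hit
        ks <- spec$kinetics[[p]]
        fast <- stats::runif(1) < ks$weight_fast
        dwell <- stats::rexp(1, rate = if (fast) ks$k_fast else ks$k_slow)
        lf <- max(1L, as.integer(ceiling(dwell / spec$steps_per_frame)))
        end <- min(Tn, t + lf - 1L)
        ev_patch <- c(ev_patch, p); ev_copy <- c(ev_copy, d)
        ev_start <- c(ev_start, t); ev_end <- c(ev_end, end)
        ev_steps <- c(ev_steps, dwell)
        ev_mode <- c(ev_mode, if (fast) "transient" else "stable")
        state[d] <- p; expire[d] <- end
      }
    }
  }
  events <- data.frame(patch = ev_patch, copy = ev_copy,
                       start = ev_start, end = ev_end,
                       frames = ev_end - ev_start + 1L,
                       dwell_steps = ev_steps, mode = ev_mode,
                       censored = (ev_start + ceiling(ev_steps / spec$steps_per_frame) - 1L) > Tn,
                       stringsAsFactors = FALSE)
  occ <- array(FALSE, dim = c(spec$n_residues, Tn, max(Dc, 0L)))
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      res <- spec$patches[[events$patch[i]]]
      fr <- events$start[i]:events$end[i]
      if (spec$emission_prob >= 1) {
        occ[res, fr, events$copy[i]] <- TRUE
      } else {
        for (f in fr) {
          sel <- stats::runif(length(res)) < spec$emission_prob
          if (!any(sel)) sel[sample.int(length(res), 1L)] <- TRUE
          occ[res[sel], f, events$copy[i]] <- TRUE
        }
      }
    }
  }
  tensor <- contact_tensor(occ, threshold = NA_real_,
                           residues = seq_len(spec$n_residues),
                           steps_per_frame = spec$steps_per_frame)
  list(tensor = tensor, events = events)
}

#' Bent ideal B-helix DNA specification
#'
#' Parameters of an ideal two-strand, three-beads-per-nucleotide B-DNA
#' duplex with an optional planar bend planted between base pairs
#' `bend_pos` and `bend_pos + 1`. With the default 36 degree twist the
#' helix makes one turn every 10 base pairs, so the chord between the
#' sugar beads of nucleotides 1 and 11 of a strand is parallel to the
#' local helix axis.
#'
#' @param n_bp Number of base pairs (at least 12 so nucleotide 11 exists).
#' @param rise Rise per base pair, Angstrom (default 3.38).
#' @param twist Twist per base pair, degrees (default 36).
#' @param bend_angle Planted planar bend, degrees in `[0, 180)`.
#' @param bend_pos Base-pair index after which the bend is applied.
#' @param noise_sd Isotropic Gaussian noise added per bead, Angstrom.
#' @param n_frames Number of frames to emit (noise redrawn per frame).
#' @param anchors List of four 3-vectors `B1`, `B2`, `E1`, `E2` defining
#'   the projection frame in which the bend is planted; defaults place the
#'   frame so its bisector axis coincides with the upstream helix axis.
#' @param seed Integer seed.
#' @return An object of class `bent_dna_spec`.
#' @export
bent_dna_spec <- function(n_bp = 24L, rise = 3.38, twist = 36,
                          bend_angle = 0, bend_pos = 12L,
                          noise_sd = 0, n_frames = 1L,
                          anchors = NULL, seed = 1L) {
  n_bp <- as.integer(n_bp)
  if (n_bp < 12L) stop("n_bp must be at least 12", call. = FALSE)
  if (!is.finite(bend_angle) || bend_angle < 0 || bend_angle >= 180)
    stop("bend_angle must lie in [0, 180)", call. = FALSE)
  bend_pos <- as.integer(bend_pos)
  if (bend_pos < 1L || bend_pos >= n_bp)
    stop("bend_pos must lie between 1 and n_bp - 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (is.null(anchors))
    anchors <- list(B1 = c(-5, 0, 0), B2 = c(5, 0, 0),
                    E1 = c(-15, 0, 40), E2 = c(15, 0, 40))
  stopifnot(all(c("B1", "B2", "E1", "E2") %in% names(anchors)))
  structure(list(n_bp = n_bp, rise = rise, twist = twist,
                 bend_angle = bend_angle, bend_pos = bend_pos,
                 noise_sd = noise_sd, n_frames = as.integer(n_frames),
                 anchors = anchors, seed = as.integer(seed)),
            class = "bent_dna_spec")
}

# Idealised bead placement: radius (Angstrom) and phase offset (degrees)
# of each bead type relative to the nucleotide's helical phase.
.dna_bead_geometry <- list(
  phosphate = c(r = 10.2, off = 25),
  sugar     = c(r = 9.2,  off = 0),
  base      = c(r = 3.5,  off = 0)
)
.strand2_phase <- 140  # groove offset between paired nucleotides, degrees

#' Generate coordinates of an ideal (optionally bent) DNA duplex
#'
#' Builds a two-strand antiparallel duplex on an ideal helix along the
#' frame's bisector axis, rotates everything beyond the bend position by
#' `bend_angle` within the projection plane, and adds per-bead Gaussian
#' noise. Strand 1 runs 5' to 3' with ascending base-pair index; strand 2
#' is antiparallel, so its nucleotide 1 sits at the far (downstream) end.
#'
#' @param spec A [bent_dna_spec()].
#' @return A list: `coords` (array beads x 3 x frames), `beads` (data
#'   frame: strand, nt, bp, role), `anchors`, and the `spec`.
#' @export
generate_bent_dna <- function(spec) {
  stopifnot(inherits(spec, "bent_dna_spec"))
  set.seed(spec$seed)
  n <- spec$n_bp
  roles <- names(.dna_bead_geometry)
  rows <- list()
  for (strand in 1:2) {
    for (ntidx in seq_len(n)) {
      bp <- if (strand == 1L) ntidx else n + 1L - ntidx
      phase <- (bp - 1L) * spec$twist + if (strand == 2L) .strand2_phase else 0
      for (role in roles) {
        g <- .dna_bead_geometry[[role]]
        a <- (phase + g[["off"]]) * pi / 180
        rows[[length(rows) + 1L]] <- data.frame(
          strand = strand, nt = ntidx, bp = bp, role = role,
          x = g[["r"]] * cos(a), y = g[["r"]] * sin(a),
          z = (bp - 1L) * spec$rise,
          stringsAsFactors = FALSE)
      }
    }
  }
  beads <- do.call(rbind, rows)
  base <- as.matrix(beads[, c("x", "y", "z")])
  if (spec$bend_angle > 0) {
    pivot <- c(0, 0, (spec$bend_pos - 1L) * spec$rise + spec$rise / 2)
    R <- rotation_matrix(c(1, 0, 0), spec$bend_angle)
    down <- beads$bp > spec$bend_pos
    shifted <- sweep(base[down, , drop = FALSE], 2, pivot)
    base[down, ] <- sweep(shifted %*% t(R), 2, pivot, "+")
  }
  nb <- nrow(base)
  coords <- array(NA_real_, dim = c(nb, 3L, spec$n_frames))
  for (f in seq_len(spec$n_frames)) {
    noise <- if (spec$noise_sd > 0)
      matrix(stats::rnorm(nb * 3L, sd = spec$noise_sd), nb, 3L)
    else 0
    coords[, , f] <- base + noise
  }
  list(coords = coords,
       beads = beads[, c("strand", "nt", "bp", "role")],
       anchors = spec$anchors, spec = spec)
}

#' Protein bead cloud with spatially isolated planted patches
#'
#' Helper for coordinate-level tests: places each planted patch as a tight
#' cluster on a sphere of radius `patch_radius` around the origin (patch
#' directions maximally separated), and all remaining residues in a
#' compact core near the origin, so DNA placed against one patch cannot
#' graze another residue.
#'
#' @param n_residues Total number of residues.
#' @param patches List of disjoint residue-index sets.
#' @param patch_radius Radial distance of patch sites, Angstrom.
#' @param patch_spread Half-width of the in-patch scatter, Angstrom.
#' @param core_radius Radius of the non-patch core cluster, Angstrom.
#' @param seed Integer seed.
#' @return Matrix `n_residues` x 3 of coordinates (Angstrom), centred at
#'   the origin, with attribute `patch_directions` (unit vectors).
#' @export
make_protein_cloud <- function(n_residues, patches, patch_radius = 30,
                               patch_spread = 1.5, core_radius = 5,
                               seed = 1L) {
  set.seed(seed)
  n_residues <- as.integer(n_residues)
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  if (length(patches) > length(dirs))
    stop("at most ", length(dirs), " patches supported", call. = FALSE)
  xyz <- matrix(stats::rnorm(n_residues * 3, sd = core_radius / 2),
                n_residues, 3)
  pdirs <- matrix(NA_real_, length(patches), 3)
  for (k in seq_along(patches)) {
    u <- dirs[[k]]
    pdirs[k, ] <- u
    res <- patches[[k]]
    centre <- u * patch_radius
    xyz[res, ] <- matrix(centre, length(res), 3, byrow = TRUE) +
      matrix(stats::runif(length(res) * 3, -patch_spread, patch_spread),
             length(res), 3)
  }
  structure(xyz, patch_directions = pdirs)
}

#' Realise a contact schedule as a coordinate trajectory
#'
#' Converts the frame-level binding schedule of a
#' [contact_schedule_spec()] into bead coordinates in a periodic cubic
#' box: during bound frames a rigid 20-bp duplex is docked end-on against
#' the bound patch (every patch residue within the contact threshold of a
#' DNA bead); during free frames the copy is placed uniformly at random in
#' the box, rejected until every bead is farther than twice the threshold
#' from every protein bead under minimum-image distances.
#'
#' @param protein Matrix `n_residues` x 3 of protein bead coordinates,
#'   e.g. from [make_protein_cloud()]; it is translated to the box centre.
#' @param spec A [contact_schedule_spec()].
#' @param box_side Cubic box side, Angstrom (default 200).
#' @param threshold Contact threshold, Angstrom (default 8).
#' @param standoff Distance from the patch centroid to the base of the
#'   docked duplex, Angstrom.
#' @param dna_n_bp Base pairs per DNA copy (default 20).
#' @return A list: `topology` (a [cg_topology()]), `coords` (array beads
#'   x 3 x frames), `tensor` (ground-truth [contact_tensor()]), `events`
#'   (ground-truth event log), `box`.
#' @export
generate_binding_trajectory <- function(protein, spec, box_side = 200,
                                        threshold = 8, standoff = 3,
                                        dna_n_bp = 20L) {
  stopifnot(inherits(spec, "contact_schedule_spec"))
  if (nrow(protein) != spec$n_residues)
    stop("protein cloud size must match spec$n_residues", call. = FALSE)
  box <- validate_box(box_side)
  sim <- generate_contact_tensor(spec)
  Dc <- spec$n_dna_copies
  Tn <- spec$n_frames
  # rigid duplex template, base of the helix at the origin, axis +z
  tmpl <- generate_bent_dna(bent_dna_spec(n_bp = max(12L, dna_n_bp),
                                          bend_angle = 0, noise_sd = 0,
                                          bend_pos = 2L, seed = 1L))
  tcoords <- tmpl$coords[, , 1]
  nb <- nrow(tcoords)
  tmpl_reach <- max(sqrt(tcoords[, 1]^2 + tcoords[, 2]^2))
  centre <- box / 2
  prot <- sweep(protein, 2, colMeans(protein))
  prot <- sweep(prot, 2, centre, "+")
  # per-copy per-frame bound-patch index (0 = free), from the event log
  sched <- matrix(0L, max(Dc, 1L), Tn)
  ev <- sim$events
  if (nrow(ev)) for (i in seq_len(nrow(ev)))
    sched[ev$copy[i], ev$start[i]:ev$end[i]] <- ev$patch[i]
  patch_centres <- lapply(spec$patches, function(res)
    colMeans(prot[res, , drop = FALSE]))
  coords <- array(NA_real_, dim = c(spec$n_residues + Dc * nb, 3L, Tn))
  for (f in seq_len(Tn)) coords[seq_len(spec$n_residues), , f] <- prot
  prot_centre <- colMeans(prot)
  for (d in seq_len(Dc)) {
    rows <- spec$n_residues + (d - 1L) * nb + seq_len(nb)
    for (f in seq_len(Tn)) {
      p <- sched[d, f]
      if (p > 0L) {
        u <- unit_vector(patch_centres[[p]] - prot_centre)
        R <- rotation_z_to(u)
        pos <- patch_centres[[p]] + u * standoff
        coords[rows, , f] <- sweep(tcoords %*% t(R), 2, pos, "+")
      } else {
        placed <- FALSE
        for (try in 1:200) {
          q <- stats::runif(3) * box
          R <- rotation_matrix(stats::rnorm(3) + 1e-3, stats::runif(1) * 360)
          cand <- sweep(tcoords %*% t(R), 2, q, "+")
          d2 <- min_image_dist2(cand, prot, box)
          if (min(d2) > (2 * threshold)^2) {
            coords[rows, , f] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("box too small to place a free DNA copy beyond 2x threshold",
               call. = FALSE)
      }
    }
  }
  topo <- .assemble_topology(spec$n_residues, Dc, tmpl$beads, box)
  list(topology = topo, coords = coords, tensor = sim$tensor,
       events = sim$events, box = box)
}

# Build a cg_topology for n protein residues plus Dc copies of the duplex
# described by `beads` (the template bead table from generate_bent_dna).
#' @noRd
.assemble_topology <- function(n_residues, Dc, beads, box) {
  chains <- c(LETTERS, letters)
  prot <- data.frame(role = "protein", resid = seq_len(n_residues),
                     chain = chains[1L], strand = NA_integer_,
                     copy = NA_integer_, stringsAsFactors = FALSE)
  dna <- NULL
  if (Dc > 0L) {
    per_copy <- data.frame(role = beads$role, resid = beads$nt,
                           strand = beads$strand, stringsAsFactors = FALSE)
    dna <- do.call(rbind, lapply(seq_len(Dc), function(d) {
      out <- per_copy
      out$chain <- chains[1L + (d - 1L) * 2L + out$strand]
      out$copy <- d
      out
    }))
    dna <- dna[, c("role", "resid", "chain", "strand", "copy")]
  }
  cg_topology(rbind(prot, dna), box = box)
}
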