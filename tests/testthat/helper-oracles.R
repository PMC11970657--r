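# Shared fixtures and independent oracles, built in code at test time.

# Brute-force contact oracle: all-pairs distances over the 27 periodic
# images (or plain Euclidean without a box), independent of the
# wrapped-difference formula used by call_contacts.
oracle_contacts <- function(coords, topology, threshold) {
  beads <- topology$beads
  box <- topology$box
  prot <- which(beads$role == "protein")
  copies <- sort(unique(beads$copy[!is.na(beads$copy)]))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  Tn <- dim(coords)[3]
  occ <- array(FALSE, dim = c(length(prot), Tn, length(copies)))
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  for (f in seq_len(Tn)) for (k in seq_along(copies)) {
    drows <- which(beads$copy %in% copies[k])
    D <- coords[drows, , f, drop = FALSE]
    dim(D) <- c(length(drows), 3L)
    for (i in seq_along(prot)) {
      p <- coords[prot[i], , f]
      if (is.null(box)) {
        mind2 <- min(rowSums(sweep(D, 2, p)^2))
      } else {
        mind2 <- Inf
        for (s in seq_len(nrow(shifts))) {
          img <- sweep(D, 2, shifts[s, ] * box, "+")
          mind2 <- min(mind2, min(rowSums(sweep(img, 2, p)^2)))
        }
      }
      occ[i, f, k] <- sqrt(mind2) < threshold
    }
  }
  occ
}

# Random periodic system: n beads uniform in a cubic box, a protein /
# DNA split, DNA beads grouped into copies of whole nucleotides.
random_periodic_system <- function(n_beads = 100, n_frames = 2,
                                   box_side = 30, n_copies = 2,
                                   seed = 1) {
  set.seed(seed)
  n_prot <- floor(n_beads * 0.4)
  n_dna <- n_beads - n_prot
  n_nt <- n_dna %/% (3 * n_copies)
  n_dna <- n_nt * 3 * n_copies
  chains <- LETTERS
  prot <- data.frame(role = "protein", resid = seq_len(n_prot),
                     chain = "A", strand = NA_integer_,
                     copy = NA_integer_)
  dna <- do.call(rbind, lapply(seq_len(n_copies), function(d)
    data.frame(role = rep(c("phosphate", "sugar", "base"), n_nt),
               resid = rep(seq_len(n_nt), each = 3),
               chain = chains[1 + d], strand = 1L, copy = d)))
  topo <- cg_topology(rbind(prot, dna), box = box_side)
  nb <- n_prot + n_dna
  coords <- array(runif(nb * 3 * n_frames) * box_side,
                  dim = c(nb, 3, n_frames))
  list(topology = topo, coords = coords)
}

# Minimal one-residue, one-nucleotide topology for hand-placed tests.
tiny_topology <- function(box = NULL) {
  cg_topology(data.frame(
    role = c("protein", "phosphate", "sugar", "base"),
    resid = c(1L, 1L, 1L, 1L),
    chain = c("A", "B", "B", "B"),
    strand = c(NA, 1L, 1L, 1L),
    copy = c(NA, 1L, 1L, 1L)), box = box)
}

# Build a contact tensor directly from a per-residue list of
# (copy, frames) contact assignments.
manual_tensor <- function(n_res, n_frames, n_copies, contacts,
                          residues = seq_len(n_res)) {
  occ <- array(FALSE, dim = c(n_res, n_frames, n_copies))
  for (ct in contacts) occ[ct$res, ct$frames, ct$copy] <- TRUE
  contact_tensor(occ, residues = residues)
}

# Planted-vs-recovered partition agreement (adjusted Rand index).
partition_ari <- function(truth, recovered) {
  mclust::adjustedRandIndex(truth, recovered)
}

# Random rigid-body transform applied to an n x 3 matrix.
random_rigid <- function(seed) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- rnorm(3, sd = 20)
  structure(function(m) sweep(m %*% t(R), 2, shift, "+"),
            R = R, shift = shift)
}
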