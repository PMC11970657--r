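# Residue-DNA contact calling and per-residue contact statistics.

#' Boolean residue x frame x copy contact tensor
#'
#' Container for per-frame residue-DNA contacts of one trajectory. A
#' residue is in contact with a DNA copy in a frame when the minimum
#' distance from its bead to any bead of that copy is strictly below the
#' threshold.
#'
#' @param occ Logical array `residues x frames x copies`.
#' @param threshold Contact threshold used, Angstrom (`NA` for synthetic
#'   tensors generated directly at the schedule level).
#' @param residues Integer residue identifiers for the first dimension.
#' @param copies Integer DNA-copy identifiers for the third dimension.
#' @param steps_per_frame Timesteps represented by one frame.
#' @param trajectory Optional trajectory identifier.
#' @return An object of class `contact_tensor`.
#' @export
contact_tensor <- function(occ, threshold = NA_real_,
                           residues = seq_len(dim(occ)[1]),
                           copies = seq_len(dim(occ)[3]),
                           steps_per_frame = 1000,
                           trajectory = 1L) {
  if (!is.logical(occ) || length(dim(occ)) != 3L)
    stop("occ must be a 3-d logical array (residues x frames x copies)",
         call. = FALSE)
  if (length(residues) != dim(occ)[1] || length(copies) != dim(occ)[3])
    stop("residue/copy identifiers do not match tensor dimensions",
         call. = FALSE)
  structure(list(occ = occ,
                 residues = as.integer(residues),
                 copies = as.integer(copies),
                 n_frames = dim(occ)[2],
                 threshold = threshold,
                 steps_per_frame = steps_per_frame,
                 trajectory = trajectory),
            class = "contact_tensor")
}

#' @export
print.contact_tensor <- function(x, ...) {
  cat("<contact_tensor> ", dim(x$occ)[1], " residues x ", x$n_frames,
      " frames x ", dim(x$occ)[3], " DNA copies; threshold ",
      x$threshold, " A\n", sep = "")
  invisible(x)
}

# Normalise a tensor or list of tensors to a list, checking residue ids.
#' @noRd
as_tensor_list <- function(x) {
  if (inherits(x, "contact_tensor")) return(list(x))
  if (is.list(x) && length(x) && all(vapply(x, inherits, TRUE, "contact_tensor"))) {
    ref <- x[[1]]$residues
    for (t in x) if (!identical(t$residues, ref))
      stop("all tensors must share the same residue identifiers",
           call. = FALSE)
    return(x)
  }
  stop("expected a contact_tensor or a list of them", call. = FALSE)
}

#' Call residue-DNA contacts from a coordinate trajectory
#'
#' A residue is in contact with a DNA copy in a frame iff the minimum
#' distance between the residue bead and any bead (phosphate, sugar or
#' base) of that copy is strictly below `threshold`. When the topology
#' carries an orthorhombic box, distances follow the minimum-image
#' convention; without a box, plain Euclidean distances are used.
#'
#' @param coords Array `beads x 3 x frames` (or a `beads x 3` matrix for
#'   a single frame) conforming to `topology`.
#' @param topology A [cg_topology()].
#' @param threshold Contact threshold, Angstrom; default 8 (slightly
#'   larger than the Debye length at the simulated ionic strength).
#' @param trajectory Trajectory identifier stored in the result.
#' @return A [contact_tensor()].
#' @export
call_contacts <- function(coords, topology, threshold = 8,
                          trajectory = 1L) {
  stopifnot(inherits(topology, "cg_topology"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold) || threshold <= 0)
    stop("threshold must be a positive length", call. = FALSE)
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be a beads x 3 x frames array", call. = FALSE)
  beads <- topology$beads
  if (dim(coords)[1] != nrow(beads))
    stop("coords do not conform to the topology (",
         dim(coords)[1], " beads vs ", nrow(beads), ")", call. = FALSE)
  box <- topology$box
  prot_rows <- which(beads$role == "protein")
  if (!length(prot_rows)) stop("topology has no protein beads", call. = FALSE)
  copies <- sort(unique(beads$copy[!is.na(beads$copy)]))
  Tn <- dim(coords)[3]
  occ <- array(FALSE, dim = c(length(prot_rows), Tn, length(copies)))
  thr2 <- threshold^2
  copy_rows <- lapply(copies, function(d) which(beads$copy %in% d))
  for (f in seq_len(Tn)) {
    P <- coords[prot_rows, , f, drop = FALSE]
    dim(P) <- c(length(prot_rows), 3L)
    for (k in seq_along(copies)) {
      D <- coords[copy_rows[[k]], , f, drop = FALSE]
      dim(D) <- c(length(copy_rows[[k]]), 3L)
      d2 <- min_image_dist2(P, D, box)
      occ[, f, k] <- row_mins(d2) < thr2
    }
  }
  contact_tensor(occ, threshold = threshold,
                 residues = beads$resid[prot_rows],
                 copies = copies, trajectory = trajectory)
}

#' Per-residue contact frequency
#'
#' Fraction `f = N / N0` where `N` counts frames in which the residue is
#' in contact with any DNA copy and `N0` is the total number of frames,
#' pooled over trajectories.
#'
#' @param x A [contact_tensor()] or a list of them (one per trajectory).
#' @return Named numeric vector of frequencies in `[0, 1]`, one per
#'   residue.
#' @export
contact_frequency <- function(x) {
  tl <- as_tensor_list(x)
  n0 <- sum(vapply(tl, function(t) t$n_frames, 0))
  if (n0 == 0) stop("empty tensor: no frames", call. = FALSE)
  n <- 0
  for (t in tl) {
    any_copy <- .any_over_copies(t$occ)
    n <- n + rowSums(any_copy)
  }
  stats::setNames(n / n0, tl[[1]]$residues)
}

#' Patch occupancy fraction and always-occupied flag
#'
#' Fraction of frames in which at least one residue of the patch contacts
#' at least one DNA copy. The `always_occupied` flag is true iff the
#' fraction is exactly 1 in every trajectory; a dissociation rate
#' estimated for such a patch reflects competitive displacement rather
#' than spontaneous unbinding and is only a lower bound.
#'
#' @param x A [contact_tensor()] or list of them.
#' @param patch Integer residue identifiers of the patch.
#' @return List with `fraction` (pooled), `per_trajectory`, and
#'   `always_occupied`.
#' @export
patch_occupancy <- function(x, patch) {
  tl <- as_tensor_list(x)
  patch <- as.integer(patch)
  if (!length(patch)) stop("patch must be non-empty", call. = FALSE)
  unknown <- setdiff(patch, tl[[1]]$residues)
  if (length(unknown))
    stop("unknown residue identifiers: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  fr <- vapply(tl, function(t) {
    rows <- match(patch, t$residues)
    sub <- t$occ[rows, , , drop = FALSE]
    bound <- apply(sub, 2, any)
    mean(bound)
  }, 0)
  total <- sum(fr * vapply(tl, function(t) t$n_frames, 0)) /
    sum(vapply(tl, function(t) t$n_frames, 0))
  list(fraction = total, per_trajectory = fr,
       always_occupied = all(fr == 1))
}

# OR-reduce a residues x frames x copies array over its copy dimension.
#' @noRd
.any_over_copies <- function(occ) {
  if (dim(occ)[3] == 0L) return(matrix(FALSE, dim(occ)[1], dim(occ)[2]))
  out <- occ[, , 1, drop = TRUE]
  if (!is.matrix(out)) out <- matrix(out, dim(occ)[1], dim(occ)[2])
  d3 <- dim(occ)[3]
  if (d3 > 1L) for (k in 2:d3) out <- out | occ[, , k]
  out
}

# Per-frame bound indicator of a patch for one tensor and one copy set.
#' @noRd
patch_bound_series <- function(tensor, patch, copy = NULL) {
  rows <- match(as.integer(patch), tensor$residues)
  if (anyNA(rows)) stop("unknown residue identifiers", call. = FALSE)
  occ <- tensor$occ[rows, , , drop = FALSE]
  if (!is.null(copy)) {
    k <- match(copy, tensor$copies)
    if (anyNA(k)) stop("unknown copy identifier", call. = FALSE)
    occ <- occ[, , k, drop = FALSE]
  }
  apply(occ, 2, any)
}
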