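# Patch calling: Jaccard co-binding distances, hierarchical clustering,
# affinity ranking and strength classification.

#' Jaccard co-binding distance matrix
#'
#' For residues `i` and `j`, `Intersection(i, j)` counts trajectory
#' frames in which both are in contact with the same DNA copy, and
#' `Union(i, j)` counts frames in which either residue is in contact with
#' any DNA copy; the Jaccard distance is
#' `dJ(i, j) = 1 - Intersection / Union`, pooled over trajectories.
#' Contacts of the two residues to different copies in the same frame
#' count in the union but not the intersection. Residues whose pooled
#' contact frequency falls below `min_frequency` are excluded.
#'
#' @param x A [contact_tensor()] or list of them (one per trajectory).
#' @param min_frequency Minimum pooled contact frequency for a residue to
#'   enter the matrix (default 0.01).
#' @return An object of class `jaccard_matrix`: list with `d` (symmetric
#'   matrix, zero diagonal, values in `[0, 1]`) and `residues`.
#' @export
jaccard_distances <- function(x, min_frequency = 0.01) {
  tl <- as_tensor_list(x)
  freq <- contact_frequency(tl)
  keep <- which(freq >= min_frequency)
  if (!length(keep))
    stop("all residues fall below min_frequency", call. = FALSE)
  ids <- tl[[1]]$residues[keep]
  n <- length(keep)
  inter <- matrix(0, n, n)
  inter_any <- matrix(0, n, n)
  card <- numeric(n)
  for (t in tl) {
    occ <- t$occ[keep, , , drop = FALSE]
    d3 <- dim(occ)[3]
    A <- .any_over_copies(occ) * 1
    card <- card + rowSums(A)
    inter_any <- inter_any + tcrossprod(A)
    if (d3 > 6L)
      stop("more than 6 DNA copies not supported by the pooled ",
           "same-copy intersection", call. = FALSE)
    # inclusion-exclusion over copy subsets: frames where i and j share
    # at least one copy
    subsets <- .nonempty_subsets(d3)
    for (K in subsets) {
      M <- occ[, , K[1], drop = TRUE] * 1
      if (!is.matrix(M)) M <- matrix(M, n, dim(occ)[2])
      if (length(K) > 1L) for (k in K[-1]) M <- M * occ[, , k]
      inter <- inter + (-1)^(length(K) + 1) * tcrossprod(M)
    }
  }
  un <- outer(card, card, "+") - inter_any
  d <- 1 - inter / un
  d[un == 0] <- 1
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  structure(list(d = d, residues = ids, min_frequency = min_frequency),
            class = "jaccard_matrix")
}

#' @noRd
.nonempty_subsets <- function(d) {
  if (d == 0L) return(list())
  out <- list()
  for (m in 1:(2^d - 1)) out[[m]] <- which(bitwAnd(m, 2^(0:(d - 1))) > 0)
  out
}

#' Cluster residues into binding patches
#'
#' Agglomerative hierarchical clustering of the Jaccard co-binding
#' distance matrix (average linkage by default), cut either at a
#' dendrogram height or into a fixed number of clusters. Clusters smaller
#' than `min_size` are reported as unassigned rather than patches.
#'
#' @param jm A [jaccard_distances()] result.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @param cut_height Dendrogram cut height (default 0.7); ignored when
#'   `k` is given.
#' @param k Optional number of clusters.
#' @param min_size Minimum residues per patch (default 3).
#' @return An object of class `patch_set`: list with `patches` (named
#'   list of residue-id vectors, ordered by smallest member), `unassigned`
#'   residues, and clustering parameters.
#' @export
cluster_patches <- function(jm, linkage = "average", cut_height = 0.7,
                            k = NULL, min_size = 3L) {
  stopifnot(inherits(jm, "jaccard_matrix"))
  if (length(jm$residues) < 2L)
    stop("need at least two included residues to cluster", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(jm$d), method = linkage)
  memb <- if (!is.null(k)) stats::cutree(hc, k = k)
  else stats::cutree(hc, h = cut_height)
  groups <- split(jm$residues, memb)
  sizes <- lengths(groups)
  patches <- groups[sizes >= min_size]
  unassigned <- sort(unlist(groups[sizes < min_size], use.names = FALSE))
  if (!length(patches))
    stop("no cluster survives the minimum patch size; adjust the cut",
         call. = FALSE)
  patches <- lapply(patches, function(p) sort(as.integer(p)))
  ord <- order(vapply(patches, min, 0L))
  patches <- patches[ord]
  names(patches) <- paste0("patch_", seq_along(patches))
  structure(list(patches = patches,
                 unassigned = as.integer(unassigned),
                 linkage = linkage,
                 cut_height = if (is.null(k)) cut_height else NA_real_,
                 k = k, min_size = as.integer(min_size),
                 hclust = hc,
                 koff = NULL, strength = NULL, label = NULL),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("<patch_set> ", length(x$patches), " patches, ",
      length(x$unassigned), " unassigned residues\n", sep = "")
  for (nm in names(x$patches)) {
    line <- paste0("  ", nm)
    if (!is.null(x$koff))
      line <- paste0(line, sprintf("  koff %.3g", x$koff[[nm]]$mean))
    if (!is.null(x$strength))
      line <- paste0(line, "  [", x$strength[[nm]], "]")
    cat(line, " (", length(x$patches[[nm]]), " residues)\n", sep = "")
  }
  invisible(x)
}

#' Rank and name patches by dissociation rate
#'
#' Rank 1 is the patch with the smallest (slowest) dissociation rate
#' constant, i.e. the strongest binder; names combine the system label
#' with the rank (label "A", rank 2 gives "A2"). Ties are broken
#' deterministically by the smallest member residue identifier. Each
#' patch also receives a strength class from [classify_strength()].
#'
#' @param ps A [cluster_patches()] result.
#' @param koff List of [bootstrap_koff()] estimates (or bare numeric
#'   rates, per timestep), one per patch, in `names(ps$patches)` order.
#' @param label System label prepended to the rank.
#' @param strength_threshold Passed to [classify_strength()].
#' @return The `patch_set` with patches renamed `label + rank`, ordered
#'   by rank, and `koff`/`strength` attached.
#' @export
rank_patches <- function(ps, koff, label = "A",
                         strength_threshold = 2.0e-5) {
  stopifnot(inherits(ps, "patch_set"))
  if (length(koff) != length(ps$patches))
    stop("need exactly one dissociation-rate estimate per patch",
         call. = FALSE)
  est <- lapply(koff, function(e) {
    if (inherits(e, "koff_estimate")) e
    else if (is.numeric(e) && length(e) == 1)
      structure(list(mean = e, sd = NA_real_, lower_bound = FALSE),
                class = "koff_estimate")
    else stop("koff entries must be koff_estimate objects or numbers",
              call. = FALSE)
  })
  rates <- vapply(est, function(e) e$mean, 0)
  tie <- vapply(ps$patches, min, 0L)
  ord <- order(rates, tie)
  patches <- ps$patches[ord]
  est <- est[ord]
  names(patches) <- paste0(label, seq_along(patches))
  names(est) <- names(patches)
  strength <- vapply(rates[ord], classify_strength, "",
                     threshold = strength_threshold)
  names(strength) <- names(patches)
  ps$patches <- patches
  ps$koff <- est
  ps$strength <- strength
  ps$label <- label
  ps
}

#' Classify patch strength from its dissociation rate
#'
#' A patch is classified `"strong"` iff its dissociation rate constant is
#' strictly below the threshold (default `2.0e-5` per timestep, the rate
#' of the head-dimer top-surface patch used as the reference for
#' loop-extrusion relevance), otherwise `"weak"`.
#'
#' @param koff Dissociation rate constant, per timestep.
#' @param threshold Classification cutoff, per timestep.
#' @return `"strong"` or `"weak"`.
#' @export
classify_strength <- function(koff, threshold = 2.0e-5) {
  if (!is.numeric(koff) || length(koff) != 1 || !is.finite(koff) ||
      koff < 0)
    stop("koff must be a single non-negative rate", call. = FALSE)
  if (koff < threshold) "strong" else "weak"
}
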