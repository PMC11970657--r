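# Projected DNA bending angle: projection frame from four anchor beads,
# in-plane bend angle from the sugar beads of nucleotides 1 and 11 of
# each strand, convergence diagnostics, and the between-condition test.

#' Build the projection frame from four anchor beads
#'
#' The anchors mark the base (`B1`, `B2`) and end (`E1`, `E2`) of the two
#' coiled-coil arms. The origin `C` is the midpoint of `B1` and `B2`; the
#' in-plane axis `z` is the normalised bisector of the two arm axis
#' vectors `E1 - B1` and `E2 - B2`, and `x` is their normalised cross
#' product (the normal of the arm plane), so the `xz` plane cuts the ring
#' compartment perpendicular to the arm plane. `z` is re-orthogonalised
#' against `x`. When the two arm axes are (anti)parallel the cross
#' product degenerates; the fallback takes `x` as the component of
#' `B2 - B1` orthogonal to `z`, with a warning.
#'
#' @param B1,B2,E1,E2 Numeric 3-vectors (Angstrom).
#' @return An object of class `projection_frame`: `C`, unit vectors `x`,
#'   `z`, and the source anchors.
#' @export
build_frame <- function(B1, B2, E1, E2) {
  anchors <- list(B1 = as.numeric(B1), B2 = as.numeric(B2),
                  E1 = as.numeric(E1), E2 = as.numeric(E2))
  if (any(vapply(anchors, length, 0L) != 3L))
    stop("anchors must be 3-vectors", call. = FALSE)
  C <- (anchors$B1 + anchors$B2) / 2
  a1 <- unit_vector(anchors$E1 - anchors$B1)
  a2 <- unit_vector(anchors$E2 - anchors$B2)
  z <- unit_vector(a1 + a2)
  cr <- cross3(a1, a2)
  if (sqrt(sum(cr^2)) < 1e-6) {
    warning("coiled-coil axis vectors are (anti)parallel; ",
            "falling back to the base-line normal for x", call. = FALSE)
    bl <- anchors$B2 - anchors$B1
    x <- unit_vector(bl - sum(bl * z) * z)
  } else {
    x <- unit_vector(cr)
    z <- unit_vector(z - sum(z * x) * x)
  }
  structure(list(C = C, x = x, z = z, anchors = anchors),
            class = "projection_frame")
}

#' Project coordinates onto the frame's xz plane
#'
#' Maps each point `p` to `((p - C) . x, (p - C) . z)`.
#'
#' @param coords Numeric 3-vector or `n x 3` matrix.
#' @param frame A [build_frame()] result.
#' @return `n x 2` matrix of in-plane coordinates.
#' @export
project_onto_frame <- function(coords, frame) {
  stopifnot(inherits(frame, "projection_frame"))
  if (is.null(dim(coords))) coords <- matrix(coords, 1L, 3L)
  rel <- sweep(coords, 2, frame$C)
  cbind(x = as.numeric(rel %*% frame$x),
        z = as.numeric(rel %*% frame$z))
}

#' Projected DNA bending angle from strand chords
#'
#' Given the in-plane (projected) sugar-bead positions of both strands
#' ordered 5' to 3', takes the chord of each strand between its
#' nucleotides `picks[1]` and `picks[2]` (default 1 and 11, one helical
#' turn apart, so the chord tracks the duplex axis). With antiparallel
#' strands, strand 1 contributes `Va = a2 - a1` and strand 2 the
#' reversed chord `Vb = b1 - b2`, so both vectors run in the same
#' direction along an unbent duplex; the bending angle is
#' `theta = arccos(Va . Vb / (|Va| |Vb|))` in degrees, with the cosine
#' clamped to `[-1, 1]`.
#'
#' @param strand1,strand2 `n x 2` matrices of projected sugar positions
#'   ordered by nucleotide index from the 5' end of each strand.
#' @param picks Two nucleotide indices (default `c(1, 11)`).
#' @return Bending angle in degrees, in `[0, 180]`.
#' @export
bend_angle <- function(strand1, strand2, picks = c(1L, 11L)) {
  picks <- as.integer(picks)
  if (nrow(strand1) < max(picks) || nrow(strand2) < max(picks))
    stop("both strands need at least ", max(picks), " nucleotides",
         call. = FALSE)
  va <- strand1[picks[2], ] - strand1[picks[1], ]
  vb <- strand2[picks[1], ] - strand2[picks[2], ]
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na < 1e-12 || nb < 1e-12)
    stop("zero-length chord vector", call. = FALSE)
  acos(clamp(sum(va * vb) / (na * nb), -1, 1)) * 180 / pi
}

#' Per-frame bending angles of a DNA trajectory
#'
#' Convenience wrapper: builds the projection frame from the anchors,
#' projects the sugar beads of both strands in every frame, and computes
#' the bending angle per frame.
#'
#' @param coords Array `beads x 3 x frames`.
#' @param beads Data frame describing the DNA beads with columns
#'   `strand`, `nt`, `role` (as produced by [generate_bent_dna()], or
#'   derived from a [cg_topology()] for one DNA copy).
#' @param anchors List of 3-vectors `B1`, `B2`, `E1`, `E2`.
#' @param picks Nucleotide picks passed to [bend_angle()].
#' @return Numeric vector of angles (degrees), one per frame.
#' @export
bend_angle_trajectory <- function(coords, beads, anchors,
                                  picks = c(1L, 11L)) {
  frame <- build_frame(anchors$B1, anchors$B2, anchors$E1, anchors$E2)
  s1 <- which(beads$strand == 1 & beads$role == "sugar")
  s2 <- which(beads$strand == 2 & beads$role == "sugar")
  s1 <- s1[order(beads$nt[s1])]
  s2 <- s2[order(beads$nt[s2])]
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  vapply(seq_len(dim(coords)[3]), function(f) {
    p1 <- project_onto_frame(coords[s1, , f], frame)
    p2 <- project_onto_frame(coords[s2, , f], frame)
    bend_angle(p1, p2, picks)
  }, 0)
}

#' Detect trajectory dissociation from a patch-group contact series
#'
#' A trajectory counts as dissociated when the DNA has no contact with
#' the designated patch-group residues for at least `K` consecutive
#' frames within the analysed (post-equilibration) part.
#'
#' @param bound Logical per-frame indicator that the DNA contacts the
#'   patch group.
#' @param K Minimum consecutive unbound frames (default 100).
#' @param discard Fraction of initial frames excluded from the check.
#' @return Logical flag.
#' @export
detect_dissociation <- function(bound, K = 100L, discard = 0.5) {
  bound <- as.logical(bound)
  cut <- floor(length(bound) * discard)
  post <- bound[(cut + 1):length(bound)]
  runs <- true_runs(!post)
  nrow(runs) > 0 && max(runs$end - runs$start + 1L) >= K
}

#' Per-trajectory bending statistics and convergence diagnostics
#'
#' For each trajectory: computes the rolling mean of the angle series in
#' a moving window, discards the first `discard` fraction of frames to
#' remove initial-structure bias, reports a Mann-Kendall-style monotone
#' trend test (Kendall rank correlation of angle against time) on the
#' retained frames, and returns the per-trajectory mean angle.
#' Trajectories flagged dissociated (via `bound` series and the
#' consecutive-unbound-frames rule) are excluded from the means and
#' counted.
#'
#' @param series List of per-frame angle vectors (degrees), one per
#'   trajectory.
#' @param window Rolling-mean window in frames (default 500).
#' @param discard Fraction of initial frames discarded (default 0.5).
#' @param bound Optional list of logical contact series matching
#'   `series`, used with `K` to exclude dissociated trajectories.
#' @param K Consecutive-unbound-frames threshold for dissociation.
#' @param trend_alpha Significance level for flagging a trend.
#' @param trend_max_n Maximum frames entering the trend test (series are
#'   thinned evenly beyond this).
#' @return List: `theta_i` (per-trajectory means of retained
#'   trajectories), `all_means`, `excluded` (logical), `n_excluded`,
#'   `rolling` (list of rolling-mean vectors), `trend` (data frame with
#'   Kendall tau and p per trajectory, and `flagged`).
#' @export
angle_statistics <- function(series, window = 500L, discard = 0.5,
                             bound = NULL, K = 100L,
                             trend_alpha = 0.01, trend_max_n = 500L) {
  stopifnot(is.list(series), length(series) >= 1)
  if (!is.null(bound) && length(bound) != length(series))
    stop("bound must match series, one contact vector per trajectory",
         call. = FALSE)
  nt <- length(series)
  window <- as.integer(window)
  means <- numeric(nt)
  excluded <- logical(nt)
  rolling <- vector("list", nt)
  tau <- pvl <- numeric(nt)
  for (i in seq_len(nt)) {
    th <- as.numeric(series[[i]])
    if (length(th) <= window)
      stop("trajectory ", i, " shorter than the rolling window",
           call. = FALSE)
    rm_ <- stats::filter(th, rep(1 / window, window), sides = 1)
    rolling[[i]] <- as.numeric(rm_)
    cut <- floor(length(th) * discard)
    post <- th[(cut + 1):length(th)]
    means[i] <- mean(post)
    idx <- if (length(post) > trend_max_n)
      round(seq(1, length(post), length.out = trend_max_n)) else
        seq_along(post)
    if (stats::sd(post[idx]) == 0) {
      # constant series carries no trend
      tau[i] <- 0; pvl[i] <- 1
    } else {
      kt <- suppressWarnings(
        stats::cor.test(idx, post[idx], method = "kendall", exact = FALSE))
      tau[i] <- unname(kt$estimate)
      pvl[i] <- kt$p.value
    }
    if (!is.null(bound))
      excluded[i] <- detect_dissociation(bound[[i]], K = K,
                                         discard = discard)
  }
  if (all(excluded))
    stop("all trajectories excluded as dissociated", call. = FALSE)
  trend <- data.frame(trajectory = seq_len(nt), tau = tau, p = pvl,
                      flagged = pvl < trend_alpha)
  list(theta_i = means[!excluded], all_means = means,
       excluded = excluded, n_excluded = sum(excluded),
       rolling = rolling, trend = trend,
       window = window, discard = discard)
}

#' Compare two bending-angle conditions with a two-sample t-test
#'
#' Operates on per-trajectory mean angles (treated as independent), or
#' directly on summary statistics `c(mean =, sd =, n =)`. The default is
#' Welch's unequal-variance test with Welch-Satterthwaite degrees of
#' freedom; a pooled-variance Student variant is also available.
#'
#' @param group1,group2 Numeric vector of per-trajectory means, or a
#'   named vector/list with elements `mean`, `sd`, `n`.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return List of class `angle_comparison`: `statistic`, `df`,
#'   `p.value`, `variant`, `means`, `sds`, `ns`.
#' @export
compare_conditions <- function(group1, group2,
                               variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  g1 <- .group_summary(group1)
  g2 <- .group_summary(group2)
  if (g1$n < 2 || g2$n < 2)
    stop("each group needs at least 2 trajectories", call. = FALSE)
  if (g1$sd == 0 && g2$sd == 0)
    stop("zero variance in both groups", call. = FALSE)
  if (variant == "welch") {
    se2 <- g1$sd^2 / g1$n + g2$sd^2 / g2$n
    stat <- (g1$mean - g2$mean) / sqrt(se2)
    df <- se2^2 / ((g1$sd^2 / g1$n)^2 / (g1$n - 1) +
                     (g2$sd^2 / g2$n)^2 / (g2$n - 1))
  } else {
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) /
      (g1$n + g2$n - 2)
    stat <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
    df <- g1$n + g2$n - 2
  }
  p <- 2 * stats::pt(-abs(stat), df)
  structure(list(statistic = stat, df = df, p.value = p,
                 variant = variant,
                 means = c(g1$mean, g2$mean),
                 sds = c(g1$sd, g2$sd),
                 ns = c(g1$n, g2$n)),
            class = "angle_comparison")
}

#' @noRd
.group_summary <- function(g) {
  if (is.list(g) || (!is.null(names(g)) && all(c("mean", "sd", "n") %in% names(g)))) {
    g <- as.list(g)
    return(list(mean = as.numeric(g$mean), sd = as.numeric(g$sd),
                n = as.numeric(g$n)))
  }
  g <- as.numeric(g)
  list(mean = mean(g), sd = stats::sd(g), n = length(g))
}

#' @export
print.angle_comparison <- function(x, ...) {
  cat("<angle_comparison> ", x$variant, " t = ",
      format(x$statistic, digits = 4), ", df = ",
      format(x$df, digits = 4), ", p = ",
      format(x$p.value, digits = 3), "\n", sep = "")
  invisible(x)
}
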