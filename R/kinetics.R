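# Binding-event extraction, equally weighted survival curves, two-regime
# segmented fits in log space, and bootstrap dissociation-rate estimates.

#' Binding-event set
#'
#' Holds binding events of one patch: maximal runs of frames during which
#' at least one patch residue contacts the DNA copy of interest. May also
#' be built directly from raw lifetimes (in timesteps) for kinetics work
#' that does not start from a contact tensor.
#'
#' @param lifetimes Numeric lifetimes in timesteps.
#' @param censored Logical vector (recycled) marking events that touch
#'   the end of their trajectory.
#' @param steps_per_frame Timesteps per frame (used for unit conversion
#'   in reports).
#' @param table Optional full event table (patch, copy, trajectory,
#'   start, end, frames, lifetime, censored).
#' @return An object of class `event_set`.
#' @export
event_set <- function(lifetimes, censored = FALSE,
                      steps_per_frame = 1000, table = NULL) {
  lifetimes <- as.numeric(lifetimes)
  if (any(!is.finite(lifetimes)) || any(lifetimes <= 0))
    stop("lifetimes must be positive and finite", call. = FALSE)
  censored <- rep_len(as.logical(censored), length(lifetimes))
  structure(list(lifetimes = lifetimes, censored = censored,
                 n0 = length(lifetimes),
                 steps_per_frame = steps_per_frame,
                 table = table),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat("<event_set> ", x$n0, " events (", sum(x$censored), " censored), ",
      "median lifetime ", stats::median(x$lifetimes), " timesteps\n",
      sep = "")
  invisible(x)
}

#' Extract binding events of a patch from contact tensors
#'
#' A binding event is a maximal run of frames in which at least one patch
#' residue is in contact with the DNA copy of interest; runs separated by
#' at most `gap_tolerance` unbound frames are merged. Events touching the
#' last frame of a trajectory are flagged censored. Lifetimes are
#' `frames x steps_per_frame` timesteps. Events are pooled over copies
#' and trajectories and treated as independent.
#'
#' @param x A [contact_tensor()] or list of them (one per trajectory).
#' @param patch Integer residue identifiers of the patch.
#' @param gap_tolerance Maximum unbound gap (frames) bridged within one
#'   event (default 0).
#' @return An [event_set()].
#' @export
extract_events <- function(x, patch, gap_tolerance = 0L) {
  tl <- as_tensor_list(x)
  gap_tolerance <- as.integer(gap_tolerance)
  rows_list <- list()
  for (ti in seq_along(tl)) {
    tensor <- tl[[ti]]
    for (d in tensor$copies) {
      bound <- patch_bound_series(tensor, patch, copy = d)
      runs <- true_runs(bound)
      if (!nrow(runs)) next
      runs <- merge_runs(runs, gap_tolerance)
      runs$patch <- NA_character_
      runs$copy <- d
      runs$trajectory <- tensor$trajectory
      runs$censored <- runs$end == tensor$n_frames
      rows_list[[length(rows_list) + 1L]] <- runs
    }
  }
  spf <- tl[[1]]$steps_per_frame
  if (!length(rows_list)) {
    tab <- data.frame(patch = character(0), copy = integer(0),
                      trajectory = integer(0), start = integer(0),
                      end = integer(0), frames = integer(0),
                      lifetime = numeric(0), censored = logical(0))
    return(structure(list(lifetimes = numeric(0), censored = logical(0),
                          n0 = 0L, steps_per_frame = spf, table = tab),
                     class = "event_set"))
  }
  tab <- do.call(rbind, rows_list)
  tab$frames <- tab$end - tab$start + 1L
  tab$lifetime <- tab$frames * spf
  tab <- tab[, c("patch", "copy", "trajectory", "start", "end",
                 "frames", "lifetime", "censored")]
  event_set(tab$lifetime, tab$censored, steps_per_frame = spf,
            table = tab)
}

# Merge TRUE runs separated by gaps of at most `gap` frames.
#' @noRd
merge_runs <- function(runs, gap) {
  if (gap <= 0L || nrow(runs) < 2L) return(runs)
  out_s <- runs$start[1]; out_e <- runs$end[1]
  for (i in 2:nrow(runs)) {
    if (runs$start[i] - out_e[length(out_e)] - 1L <= gap) {
      out_e[length(out_e)] <- runs$end[i]
    } else {
      out_s <- c(out_s, runs$start[i]); out_e <- c(out_e, runs$end[i])
    }
  }
  data.frame(start = out_s, end = out_e)
}

# Shared core: equally weighted survival points from raw lifetimes.
# Time points are chosen so the survivor counts N(t_i) form an arithmetic
# progression (step ceiling(N0 / n_points)), which weights all points
# equally in the subsequent regression. N(t) = #{tau > t}.
#' @noRd
.survival_points <- function(tau, n_points) {
  n0 <- length(tau)
  s <- sort(tau)
  step <- ceiling(n0 / n_points)
  idx <- seq(step, n0, by = step)
  t_i <- unique(s[idx])
  n_i <- vapply(t_i, function(t) sum(tau > t), 0)
  keep <- !duplicated(n_i)
  t_i <- t_i[keep]; n_i <- n_i[keep]
  if (!length(t_i) || t_i[1] > 0) {
    t_i <- c(0, t_i); n_i <- c(n0, n_i)
  }
  list(t = t_i, n = n_i, p = n_i / n0, n0 = n0, step = step)
}

#' Survival curve of binding-event lifetimes
#'
#' Survival probability `P(t) = N(t) / N0` with `N(t)` the number of
#' events whose lifetime exceeds `t`. Time points are chosen so that the
#' survivor counts form an arithmetic progression, giving every point
#' equal weight in the subsequent log-linear regression.
#'
#' @param events An [event_set()].
#' @param n_points Target number of curve points (default 50).
#' @param include_censored Include events that touch the trajectory end
#'   as observed lifetimes (default `TRUE`).
#' @return An object of class `survival_curve`: data frame with columns
#'   `t` (timesteps), `N`, `P`, plus attributes `n0` and `step`.
#' @export
survival_curve <- function(events, n_points = 50, include_censored = TRUE) {
  stopifnot(inherits(events, "event_set"))
  tau <- events$lifetimes
  if (!include_censored) tau <- tau[!events$censored]
  n_points <- as.integer(n_points)
  if (n_points < 3L) stop("n_points must be at least 3", call. = FALSE)
  if (length(tau) < n_points)
    stop("too few events (", length(tau), ") for ", n_points,
         " curve points", call. = FALSE)
  pts <- .survival_points(tau, n_points)
  out <- data.frame(t = pts$t, N = pts$n, P = pts$p)
  attr(out, "n0") <- pts$n0
  attr(out, "step") <- pts$step
  class(out) <- c("survival_curve", "data.frame")
  out
}

# Continuous two-segment piecewise-linear fit of y ~ x.
# Returns slopes of both segments and the breakpoint. Breakpoint search:
# profile grid over interior x values (smallest x wins ties), refined by
# Muggeo-style iterative re-estimation using the gap term.
#' @noRd
.segmented_core <- function(x, y) {
  n <- length(x)
  if (n < 6L) stop("need at least 6 points for a two-segment fit",
                   call. = FALSE)
  # keep at least 4 points beyond the breakpoint (2 when the curve is
  # minimal) so the slow slope is never read off the extreme tail, where
  # the empirical survival of the largest order statistics drops faster
  # than the underlying rate
  hi <- if (n >= 8L) n - 4L else n - 2L
  cand <- unique(x[2:hi])
  cand <- cand[cand > min(x) & cand < max(x)]
  if (!length(cand)) stop("degenerate abscissa: no interior breakpoints",
                          call. = FALSE)
  rss_at <- function(psi) {
    X <- cbind(1, x, pmax(x - psi, 0))
    f <- stats::.lm.fit(X, y)
    sum(f$residuals^2)
  }
  rss <- vapply(cand, rss_at, 0)
  psi <- cand[which.min(rss)]  # which.min takes the first = smallest psi
  best_rss <- min(rss)
  # Muggeo refinement
  psi_ref <- psi
  for (it in 1:50) {
    U <- pmax(x - psi_ref, 0)
    V <- -(x > psi_ref)
    f <- tryCatch(stats::.lm.fit(cbind(1, x, U, V), y),
                  error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f$coefficients))) break
    beta2 <- f$coefficients[3]
    gamma <- f$coefficients[4]
    if (!is.finite(beta2) || abs(beta2) < 1e-300) break
    psi_new <- psi_ref + gamma / beta2
    if (!is.finite(psi_new) || psi_new < min(cand) || psi_new > max(cand))
      break
    if (abs(psi_new - psi_ref) < 1e-10 * diff(range(x))) {
      psi_ref <- psi_new
      break
    }
    psi_ref <- psi_new
  }
  if (psi_ref >= min(cand) && psi_ref <= max(cand)) {
    r2 <- rss_at(psi_ref)
    if (r2 < best_rss) {
      psi <- psi_ref
      best_rss <- r2
    }
  }
  X <- cbind(1, x, pmax(x - psi, 0))
  f <- stats::.lm.fit(X, y)
  b <- f$coefficients
  list(t1 = psi, slope_fast = b[2], slope_slow = b[2] + b[3],
       intercept = b[1], rss = best_rss, n_points = n,
       grid = cand)
}

#' Two-regime segmented fit of a survival curve
#'
#' Fits `ln P(t)` against `t` with a continuous two-segment
#' piecewise-linear model. The first segment captures transient
#' encounters, the second stable binding; the dissociation rate constant
#' of the stable mode is minus the slope beyond the breakpoint `t1`.
#' Points with `P = 0` are excluded (log undefined). When the two slopes
#' differ by less than 10 percent the breakpoint is unreliable and the
#' fit is flagged single-regime.
#'
#' @param curve A [survival_curve()].
#' @return An object of class `segmented_fit`: `t1`, `slope_fast`,
#'   `slope_slow`, `koff_slow` (= `-slope_slow`, per timestep),
#'   `single_regime`, `rss`, `n_points`, `grid_step`.
#' @export
segmented_fit <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  if (any(diff(curve$P) > 0))
    stop("survival probabilities must be non-increasing", call. = FALSE)
  d <- curve[curve$P > 0, ]
  fit <- .segmented_core(d$t, log(d$P))
  fit$koff_slow <- -fit$slope_slow
  fit$single_regime <-
    abs(fit$slope_fast - fit$slope_slow) < 0.1 * abs(fit$slope_fast)
  fit$grid_step <- if (length(fit$grid) > 1) max(diff(sort(fit$grid))) else NA_real_
  fit$grid <- NULL
  class(fit) <- "segmented_fit"
  fit
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("<segmented_fit> t1 = ", format(x$t1), ", slopes ",
      format(x$slope_fast, digits = 3), " / ",
      format(x$slope_slow, digits = 3),
      ", koff_slow = ", format(x$koff_slow, digits = 3),
      if (x$single_regime) " [single regime]" else "", "\n", sep = "")
  invisible(x)
}

# Fast path: lifetimes -> slow-mode rate, or NA on degenerate input.
#' @noRd
.koff_from_lifetimes <- function(tau, n_points) {
  out <- tryCatch({
    pts <- .survival_points(tau, n_points)
    keep <- pts$p > 0
    fit <- .segmented_core(pts$t[keep], log(pts$p[keep]))
    -fit$slope_slow
  }, error = function(e) NA_real_)
  if (is.na(out) || !is.finite(out) || out <= 0) NA_real_ else out
}

#' Bootstrap estimate of the stable-mode dissociation rate
#'
#' Resamples the event lifetimes with replacement (`B` resamples of size
#' `N0`, events treated as independent), rebuilds the equally weighted
#' survival curve and the two-regime segmented fit for each resample, and
#' reports the mean and standard deviation of the stable-mode rate. The
#' mean is used as the patch strength and the standard deviation as its
#' error. Replicates with degenerate fits (non-positive or failed rate)
#' are dropped and counted; more than `max_degenerate` of them marks the
#' estimate unreliable.
#'
#' @param events An [event_set()].
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the resampling.
#' @param n_points Survival-curve resolution per resample.
#' @param include_censored Include censored events as observed lifetimes.
#' @param lower_bound Set when the patch is always occupied (competitive
#'   displacement), so the rate is only a lower bound on the true
#'   dissociation rate; propagated to all reports.
#' @param max_degenerate Maximum tolerated fraction of degenerate
#'   replicates (default 0.2).
#' @return An object of class `koff_estimate`: `mean`, `sd` (both per
#'   timestep), `per_frame` rate, `t1`, `koff_point` (full-sample fit),
#'   `n_events`, `B`, `n_degenerate`, `reliable`, `lower_bound`.
#' @export
bootstrap_koff <- function(events, B = 1000, seed = NULL, n_points = 50,
                           include_censored = TRUE, lower_bound = FALSE,
                           max_degenerate = 0.2) {
  stopifnot(inherits(events, "event_set"))
  tau <- events$lifetimes
  if (!include_censored) tau <- tau[!events$censored]
  n0 <- length(tau)
  if (n0 < 10L) stop("need at least 10 events to bootstrap", call. = FALSE)
  if (length(unique(tau)) == 1L)
    stop("all lifetimes are equal: survival curve is degenerate",
         call. = FALSE)
  full <- tryCatch({
    pts <- .survival_points(tau, n_points)
    keep <- pts$p > 0
    .segmented_core(pts$t[keep], log(pts$p[keep]))
  }, error = function(e)
    stop("full-sample segmented fit failed: ", conditionMessage(e),
         call. = FALSE))
  if (!is.null(seed)) set.seed(seed)
  ks <- numeric(B)
  for (b in seq_len(B)) {
    smp <- tau[sample.int(n0, n0, replace = TRUE)]
    ks[b] <- .koff_from_lifetimes(smp, n_points)
  }
  ok <- !is.na(ks)
  n_deg <- sum(!ok)
  reliable <- n_deg <= max_degenerate * B
  if (!reliable)
    warning(sprintf("%d of %d bootstrap replicates degenerate; estimate unreliable",
                    n_deg, B), call. = FALSE)
  est <- structure(list(mean = mean(ks[ok]), sd = stats::sd(ks[ok]),
                        per_frame = mean(ks[ok]) * events$steps_per_frame,
                        t1 = full$t1,
                        koff_point = -full$slope_slow,
                        slope_fast = full$slope_fast,
                        n_events = n0, B = B,
                        n_degenerate = n_deg,
                        reliable = reliable,
                        lower_bound = isTRUE(lower_bound)),
                   class = "koff_estimate")
  est
}

#' @export
print.koff_estimate <- function(x, ...) {
  cat("<koff_estimate> ", sprintf("%.3g +/- %.1g", x$mean, x$sd),
      " per timestep (", x$n_events, " events, B = ", x$B, ")",
      if (x$lower_bound) " [lower bound: always-occupied patch]" else "",
      if (!x$reliable) " [UNRELIABLE]" else "", "\n", sep = "")
  invisible(x)
}
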