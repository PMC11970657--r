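# Configuration handling and the end-to-end analysis pipeline:
# contacts -> Jaccard clustering -> binding events -> survival curves ->
# bootstrap dissociation rates -> ranked patch tables, with an optional
# DNA-bending stage.

.pipeline_defaults <- function() {
  list(
    topology = NULL,
    trajectories = NULL,
    output_dir = NULL,
    contact_threshold = 8,
    steps_per_frame = 1000,
    linkage = "average",
    cut_height = 0.7,
    min_frequency = 0.01,
    min_patch_size = 3,
    gap_tolerance = 0,
    n_points = 50,
    bootstrap_B = 1000,
    include_censored = TRUE,
    strength_threshold = 2.0e-5,
    system_label = "A",
    seed = 1,
    bending = NULL  # list(anchors, copy, window, discard, K, patch_group)
  )
}

#' Assemble and validate a pipeline configuration
#'
#' Accepts a named list or the path to a YAML file; unspecified fields
#' take the package defaults (8 A contact threshold, average-linkage
#' clustering cut at Jaccard height 0.7, 1000 bootstrap resamples,
#' strength cutoff 2.0e-5 per timestep).
#'
#' @param x Named list of settings, or a YAML file path.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(x = list()) {
  if (inherits(x, "pipeline_config")) return(x)
  if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
  if (!is.list(x)) stop("config must be a list or a YAML path",
                        call. = FALSE)
  cfg <- utils::modifyList(.pipeline_defaults(), x)
  unknown <- setdiff(names(x), names(.pipeline_defaults()))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  num_pos <- c("contact_threshold", "steps_per_frame", "cut_height",
               "n_points", "bootstrap_B", "strength_threshold",
               "min_patch_size")
  for (f in num_pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 ||
        !is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a positive number",
           call. = FALSE)
  if (cfg$min_frequency < 0 || cfg$min_frequency >= 1)
    stop("min_frequency must lie in [0, 1)", call. = FALSE)
  if (cfg$gap_tolerance < 0)
    stop("gap_tolerance must be non-negative", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @noRd
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(name, " stage: ", conditionMessage(e), call. = FALSE))
}

#' @noRd
.output_header <- function(cfg) {
  plain <- unclass(cfg)
  c(paste0("# dnapatch ",
           as.character(utils::packageVersion("dnapatch"))),
    paste0("# seed: ", cfg$seed),
    paste0("# config_hash: ",
           fnv1a_hash(paste(utils::capture.output(utils::str(plain)),
                            collapse = "\n"))))
}

#' Run the full patch-calling and kinetics pipeline
#'
#' Stages, in order: read the topology and trajectories; call
#' residue-DNA contacts; compute Jaccard co-binding distances and
#' cluster residues into patches; extract binding events, bootstrap the
#' stable-mode dissociation rate per patch (flagging always-occupied
#' patches as lower-bound estimates); rank, name and classify the
#' patches; and, when a `bending` block is configured, compute projected
#' DNA bending angles with convergence diagnostics. All randomness is
#' governed by the config seed, so a rerun writes byte-identical tables.
#'
#' Outputs written to `output_dir`: `patches.tsv` (ranked patch table),
#' `koff_summary.tsv` (rate, error, breakpoint, event counts per patch),
#' `survival_<patch>.tsv`, optional `angles.tsv`, and `log.txt` with the
#' per-stage decision log.
#'
#' @param config A [pipeline_config()], a named list, or a YAML path.
#' @return Invisibly, a list with `tensors`, `patch_set`, `events`,
#'   `koff`, `angles` (or `NULL`) and the resolved `config`.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  if (is.null(cfg$topology) || is.null(cfg$trajectories) ||
      is.null(cfg$output_dir))
    stop("config must set topology, trajectories and output_dir",
         call. = FALSE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- .output_header(cfg)
  topo <- .stage("io", read_cg_topology(cfg$topology))

  coords_list <- .stage("io", lapply(cfg$trajectories, read_cg_trajectory,
                                     topology = topo))
  tensors <- .stage("contacts", {
    lapply(seq_along(coords_list), function(i) {
      tn <- call_contacts(coords_list[[i]], topo,
                          threshold = cfg$contact_threshold,
                          trajectory = i)
      tn$steps_per_frame <- cfg$steps_per_frame
      tn
    })
  })
  log_lines <- c(log_lines,
                 paste0("# trajectories: ", length(tensors),
                        "; frames: ",
                        paste(vapply(tensors, function(t) t$n_frames, 0),
                              collapse = ",")))

  jm <- .stage("patches", jaccard_distances(tensors,
                                            min_frequency = cfg$min_frequency))
  ps <- .stage("patches", cluster_patches(jm, linkage = cfg$linkage,
                                          cut_height = cfg$cut_height,
                                          min_size = cfg$min_patch_size))
  log_lines <- c(log_lines,
                 paste0("# patches called: ", length(ps$patches),
                        "; unassigned residues: ",
                        length(ps$unassigned)))

  events <- list(); ests <- list()
  for (k in seq_along(ps$patches)) {
    res <- ps$patches[[k]]
    occ <- .stage("kinetics", patch_occupancy(tensors, res))
    ev <- .stage("kinetics", extract_events(tensors, res,
                                            gap_tolerance = cfg$gap_tolerance))
    est <- .stage("kinetics", bootstrap_koff(
      ev, B = cfg$bootstrap_B, seed = cfg$seed + k,
      n_points = min(cfg$n_points, ev$n0),
      include_censored = cfg$include_censored,
      lower_bound = occ$always_occupied))
    events[[k]] <- ev; ests[[k]] <- est
    log_lines <- c(log_lines, sprintf(
      "# patch %d: %d events (%d censored), %d degenerate replicates%s",
      k, ev$n0, sum(ev$censored), est$n_degenerate,
      if (est$lower_bound) ", always occupied (lower-bound rate)" else ""))
  }
  ranked <- .stage("patches", rank_patches(ps, ests,
                                           label = cfg$system_label,
                                           strength_threshold = cfg$strength_threshold))
  # reorder events to ranked order (same key as rank_patches)
  ord <- order(vapply(ests, function(e) e$mean, 0),
               vapply(ps$patches, min, 0L))
  events <- events[ord]
  names(events) <- names(ranked$patches)

  hdr <- .output_header(cfg)
  write_patch_set(ranked, file.path(cfg$output_dir, "patches.tsv"),
                  header = hdr)
  summary_tab <- data.frame(
    patch = names(ranked$patches),
    koff = sprintf("%.3g", vapply(ranked$koff, function(e) e$mean, 0)),
    koff_sd = sprintf("%.3g", vapply(ranked$koff, function(e) e$sd, 0)),
    t1_timesteps = vapply(ranked$koff, function(e) e$t1, 0),
    n_events = vapply(ranked$koff, function(e) e$n_events, 0L),
    lower_bound = vapply(ranked$koff, function(e) e$lower_bound, TRUE),
    strength = unname(ranked$strength),
    residues = vapply(ranked$patches, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  .write_tsv(summary_tab, file.path(cfg$output_dir, "koff_summary.tsv"),
             hdr)
  for (nm in names(ranked$patches)) {
    crv <- survival_curve(events[[nm]],
                          n_points = min(cfg$n_points, events[[nm]]$n0),
                          include_censored = cfg$include_censored)
    .write_tsv(as.data.frame(crv),
               file.path(cfg$output_dir, paste0("survival_", nm, ".tsv")),
               hdr)
  }

  angles <- NULL
  if (!is.null(cfg$bending)) {
    angles <- .stage("bending",
                     .pipeline_bending(cfg, topo, coords_list, tensors))
    .write_tsv(angles$table, file.path(cfg$output_dir, "angles.tsv"), hdr)
    log_lines <- c(log_lines,
                   paste0("# bending: ", angles$stats$n_excluded,
                          " trajectories excluded as dissociated"))
  }

  writeLines(log_lines, file.path(cfg$output_dir, "log.txt"))
  invisible(list(tensors = tensors, patch_set = ranked, events = events,
                 koff = ranked$koff, angles = angles, config = cfg))
}

#' @noRd
.write_tsv <- function(tab, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Bending stage: anchors are protein beads given as chain + resid; the
# projection frame is rebuilt every frame from their instantaneous
# positions, and the angle uses the sugar beads of the configured DNA
# copy.
#' @noRd
.pipeline_bending <- function(cfg, topo, coords_list, tensors) {
  bcfg <- utils::modifyList(
    list(anchors = NULL, copy = 1L, window = 500L, discard = 0.5,
         K = 100L, patch_group = NULL, picks = c(1L, 11L)),
    cfg$bending)
  if (is.null(bcfg$anchors) ||
      !all(c("B1", "B2", "E1", "E2") %in% names(bcfg$anchors)))
    stop("bending config needs anchors B1, B2, E1, E2", call. = FALSE)
  beads <- topo$beads
  anchor_row <- function(a) {
    r <- which(beads$role == "protein" & beads$chain == a$chain &
                 beads$resid == a$resid)
    if (length(r) != 1L)
      stop("anchor ", a$chain, "/", a$resid,
           " does not identify one protein bead", call. = FALSE)
    r
  }
  arows <- vapply(bcfg$anchors[c("B1", "B2", "E1", "E2")], anchor_row, 0L)
  dna_rows <- which(beads$copy %in% bcfg$copy)
  dna_beads <- beads[dna_rows, ]
  s1 <- dna_rows[dna_beads$strand == 1 & dna_beads$role == "sugar"]
  s2 <- dna_rows[dna_beads$strand == 2 & dna_beads$role == "sugar"]
  s1 <- s1[order(beads$resid[s1])]
  s2 <- s2[order(beads$resid[s2])]
  series <- lapply(coords_list, function(coords) {
    vapply(seq_len(dim(coords)[3]), function(f) {
      fr <- build_frame(coords[arows[1], , f], coords[arows[2], , f],
                        coords[arows[3], , f], coords[arows[4], , f])
      p1 <- project_onto_frame(coords[s1, , f], fr)
      p2 <- project_onto_frame(coords[s2, , f], fr)
      bend_angle(p1, p2, bcfg$picks)
    }, 0)
  })
  bound <- NULL
  if (!is.null(bcfg$patch_group))
    bound <- lapply(tensors, patch_bound_series,
                    patch = bcfg$patch_group)
  stats <- angle_statistics(series, window = bcfg$window,
                            discard = bcfg$discard, bound = bound,
                            K = bcfg$K)
  tab <- data.frame(trajectory = seq_along(series),
                    theta_mean = sprintf("%.4f", stats$all_means),
                    excluded = stats$excluded,
                    trend_tau = sprintf("%.4f", stats$trend$tau),
                    trend_p = sprintf("%.4g", stats$trend$p),
                    stringsAsFactors = FALSE)
  list(series = series, stats = stats, table = tab)
}
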