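# Coarse-grained topology container and PDB/DCD/TSV interchange.
#
# The coarse-grained PDB dialect: protein beads are CA atom records (one
# per residue); DNA beads use atom names DP/DS/DB (phosphate, sugar,
# base, three per nucleotide). DNA strand chains appear in pairs, two
# chains per DNA copy, each strand numbered 1..n from its 5' end. An
# orthorhombic box, when present, is stored in a CRYST1 record.

.role_to_name <- c(protein = "CA", phosphate = "DP", sugar = "DS",
                   base = "DB")
.name_to_role <- c(CA = "protein", DP = "phosphate", DS = "sugar",
                   DB = "base", P = "phosphate", S = "sugar",
                   B = "base")

#' Coarse-grained topology
#'
#' One bead per amino acid (at the C-alpha position) and three beads per
#' nucleotide (phosphate, sugar, base). DNA beads carry a strand (1 or 2,
#' numbered from the 5' end) and a copy identifier grouping the two
#' strands of each DNA fragment.
#'
#' @param beads Data frame with columns `role` (one of `"protein"`,
#'   `"phosphate"`, `"sugar"`, `"base"`), `resid` (residue or nucleotide
#'   index; nucleotides are 1-based from the 5' end of each strand),
#'   `chain`, `strand` (`NA` for protein), `copy` (`NA` for protein).
#' @param box `NULL` or orthorhombic box side lengths (Angstrom; a
#'   scalar is expanded to a cube).
#' @return An object of class `cg_topology`.
#' @export
cg_topology <- function(beads, box = NULL) {
  need <- c("role", "resid", "chain", "strand", "copy")
  if (!is.data.frame(beads) || !all(need %in% names(beads)))
    stop("beads must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(beads$role %in% names(.role_to_name)))
    stop("unknown bead role(s): ",
         paste(setdiff(unique(beads$role), names(.role_to_name)),
               collapse = ", "), call. = FALSE)
  beads$resid <- as.integer(beads$resid)
  beads$strand <- as.integer(beads$strand)
  beads$copy <- as.integer(beads$copy)
  dna <- beads[beads$role != "protein", ]
  if (nrow(dna)) {
    if (anyNA(dna$strand) || anyNA(dna$copy))
      stop("DNA beads must carry strand and copy identifiers",
           call. = FALSE)
    for (cp in unique(dna$copy)) for (st in 1:2) {
      nt <- sort(unique(dna$resid[dna$copy == cp & dna$strand == st]))
      if (length(nt) && !identical(nt, seq_len(max(nt))))
        stop("nucleotide indices must be contiguous from 1 at the 5' ",
             "end (copy ", cp, ", strand ", st, ")", call. = FALSE)
    }
  }
  rownames(beads) <- NULL
  structure(list(beads = beads, box = validate_box(box)),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  b <- x$beads
  nres <- sum(b$role == "protein")
  ncopy <- length(unique(stats::na.omit(b$copy)))
  cat("<cg_topology> ", nres, " protein residues, ", ncopy,
      " DNA copies (", sum(b$role != "protein"), " DNA beads); box ",
      if (is.null(x$box)) "none" else paste(x$box, collapse = " x "),
      "\n", sep = "")
  invisible(x)
}

#' Write a coarse-grained topology and trajectory as multi-model PDB
#'
#' @param topology A [cg_topology()].
#' @param coords Array `beads x 3 x frames` (or `beads x 3` matrix).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cg_pdb <- function(topology, coords, path) {
  stopifnot(inherits(topology, "cg_topology"))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  beads <- topology$beads
  if (dim(coords)[1] != nrow(beads))
    stop("coords do not conform to the topology", call. = FALSE)
  lines <- character(0)
  if (!is.null(topology$box))
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     topology$box[1], topology$box[2], topology$box[3],
                     90, 90, 90)
  name <- .role_to_name[beads$role]
  resname <- ifelse(beads$role == "protein", "ALA", "DA ")
  nb <- nrow(beads)
  for (f in seq_len(dim(coords)[3])) {
    lines <- c(lines, sprintf("MODEL     %4d", f))
    lines <- c(lines, sprintf(
      "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nb), name, resname, beads$chain, beads$resid,
      coords[, 1, f], coords[, 2, f], coords[, 3, f]))
    lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a coarse-grained topology from a PDB file
#'
#' Bead roles are inferred from atom names (`CA` for protein residues;
#' `DP`/`DS`/`DB`, or bare `P`/`S`/`B`, for DNA phosphate, sugar and
#' base beads). DNA strand chains are grouped into copies pairwise in
#' order of appearance. An orthorhombic CRYST1 record, if present,
#' becomes the box.
#'
#' @param path PDB file path.
#' @return A [cg_topology()].
#' @export
read_cg_topology <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  elety <- trimws(at$elety)
  role <- .name_to_role[elety]
  if (anyNA(role)) {
    bad <- which(is.na(role))[1]
    stop("unrecognised atom name '", elety[bad], "' (atom serial ",
         at$eleno[bad], ")", call. = FALSE)
  }
  role <- unname(role)
  chain <- as.character(at$chain)
  chain[is.na(chain)] <- " "
  strand <- rep(NA_integer_, length(role))
  copy <- rep(NA_integer_, length(role))
  dna <- role != "protein"
  if (any(dna)) {
    dna_chains <- unique(chain[dna])
    if (length(dna_chains) %% 2 != 0)
      stop("DNA chains must come in strand pairs (two per copy)",
           call. = FALSE)
    k <- match(chain[dna], dna_chains)
    copy[dna] <- (k - 1L) %/% 2L + 1L
    strand[dna] <- (k - 1L) %% 2L + 1L
  }
  box <- .read_cryst1(path)
  cg_topology(data.frame(role = role, resid = as.integer(at$resno),
                         chain = chain, strand = strand, copy = copy,
                         stringsAsFactors = FALSE),
              box = box)
}

#' @noRd
.read_cryst1 <- function(path) {
  hdr <- readLines(path, n = 50L)
  cl <- grep("^CRYST1", hdr, value = TRUE)
  if (!length(cl)) return(NULL)
  box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                      substr(cl[1], 25, 33)))
  angles <- as.numeric(c(substr(cl[1], 34, 40), substr(cl[1], 41, 47),
                         substr(cl[1], 48, 54)))
  if (any(abs(angles - 90) > 1e-3))
    stop("only orthorhombic boxes are supported", call. = FALSE)
  box
}

#' Read a coordinate trajectory (multi-model PDB or DCD)
#'
#' @param path Trajectory file (`.pdb` multi-model, or `.dcd`).
#' @param topology Optional [cg_topology()] to validate the bead count
#'   against.
#' @return Array `beads x 3 x frames` (Angstrom).
#' @export
read_cg_trajectory <- function(path, topology = NULL) {
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nb <- ncol(xyz) / 3L
  coords <- aperm(array(t(xyz), dim = c(3L, nb, nrow(xyz))), c(2, 1, 3))
  if (!is.null(topology) && nb != nrow(topology$beads))
    stop("trajectory has ", nb, " beads but topology has ",
         nrow(topology$beads), call. = FALSE)
  coords
}

#' Write contact tensors as run-length-encoded TSV
#'
#' Each row records one maximal run of contact frames for a (trajectory,
#' residue, copy) triple, so the boolean tensor round-trips losslessly.
#'
#' @param x A [contact_tensor()] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contact_tensor <- function(x, path) {
  tl <- as_tensor_list(x)
  hdr <- c("# dnapatch contact_tensor v1",
           paste0("# threshold: ", tl[[1]]$threshold),
           paste0("# steps_per_frame: ", tl[[1]]$steps_per_frame),
           paste0("# residues: ", paste(tl[[1]]$residues, collapse = ",")),
           paste0("# copies: ", paste(tl[[1]]$copies, collapse = ",")),
           paste0("# frames: ",
                  paste(vapply(tl, function(t)
                    paste0(t$trajectory, ":", t$n_frames), ""),
                    collapse = " ")))
  rows <- list()
  for (t in tl) {
    for (ri in seq_along(t$residues)) for (ki in seq_along(t$copies)) {
      runs <- true_runs(t$occ[ri, , ki])
      if (!nrow(runs)) next
      rows[[length(rows) + 1L]] <- data.frame(
        trajectory = t$trajectory, residue = t$residues[ri],
        copy = t$copies[ki], start = runs$start, end = runs$end)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trajectory = integer(0), residue = integer(0),
               copy = integer(0), start = integer(0), end = integer(0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read contact tensors from run-length-encoded TSV
#'
#' @param path File written by [write_contact_tensor()].
#' @return A list of [contact_tensor()] objects, one per trajectory.
#' @export
read_contact_tensor <- function(path) {
  all_lines <- readLines(path)
  hdr <- grep("^#", all_lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, ": "), "",
                           grep(paste0("^# ", key, ":"), hdr, value = TRUE))
  threshold <- as.numeric(get("threshold"))
  spf <- as.numeric(get("steps_per_frame"))
  residues <- as.integer(strsplit(get("residues"), ",")[[1]])
  copies <- as.integer(strsplit(get("copies"), ",")[[1]])
  frames_spec <- strsplit(strsplit(get("frames"), " ")[[1]], ":")
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#")
  out <- lapply(frames_spec, function(fs) {
    tid <- as.integer(fs[1]); nf <- as.integer(fs[2])
    occ <- array(FALSE, dim = c(length(residues), nf, length(copies)))
    sub <- tab[tab$trajectory == tid, , drop = FALSE]
    if (nrow(sub)) for (i in seq_len(nrow(sub))) {
      ri <- match(sub$residue[i], residues)
      ki <- match(sub$copy[i], copies)
      occ[ri, sub$start[i]:sub$end[i], ki] <- TRUE
    }
    contact_tensor(occ, threshold = threshold, residues = residues,
                   copies = copies, steps_per_frame = spf,
                   trajectory = tid)
  })
  out
}

#' Write a patch set as TSV
#'
#' One row per patch: name, strength class, dissociation rate (mean and
#' sd, per timestep), lower-bound flag, and the comma-separated member
#' residues.
#'
#' @param ps A [rank_patches()] (or [cluster_patches()]) result.
#' @param path Output file path.
#' @param header Optional character vector of `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_patch_set <- function(ps, path, header = character(0)) {
  stopifnot(inherits(ps, "patch_set"))
  nm <- names(ps$patches)
  tab <- data.frame(
    patch = nm,
    strength = if (is.null(ps$strength)) NA_character_ else
      unname(ps$strength[nm]),
    koff_mean = if (is.null(ps$koff)) NA_real_ else
      vapply(ps$koff[nm], function(e) e$mean, 0),
    koff_sd = if (is.null(ps$koff)) NA_real_ else
      vapply(ps$koff[nm], function(e) e$sd, 0),
    lower_bound = if (is.null(ps$koff)) NA else
      vapply(ps$koff[nm], function(e) isTRUE(e$lower_bound), TRUE),
    residues = vapply(ps$patches[nm], paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a patch set written by [write_patch_set()]
#'
#' @param path TSV file path.
#' @return A `patch_set` with patches, strength classes and point rates.
#' @export
read_patch_set <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#",
                           stringsAsFactors = FALSE)
  patches <- lapply(strsplit(tab$residues, ","), as.integer)
  names(patches) <- tab$patch
  koff <- NULL
  if (!all(is.na(tab$koff_mean)))
    koff <- stats::setNames(lapply(seq_len(nrow(tab)), function(i)
      structure(list(mean = tab$koff_mean[i], sd = tab$koff_sd[i],
                     lower_bound = isTRUE(tab$lower_bound[i])),
                class = "koff_estimate")), tab$patch)
  structure(list(patches = patches,
                 unassigned = integer(0),
                 strength = if (all(is.na(tab$strength))) NULL else
                   stats::setNames(tab$strength, tab$patch),
                 koff = koff, label = NULL),
            class = "patch_set")
}
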