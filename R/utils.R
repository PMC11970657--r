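# Internal geometry and numeric helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector", call. = FALSE)
  v / n
}

#' @noRd
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation matrix: rotate by `angle_deg` degrees about `axis`.
#' @noRd
rotation_matrix <- function(axis, angle_deg) {
  u <- unit_vector(axis)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2],
                 u[3], 0, -u[1],
                 -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * ux + (1 - ct) * tcrossprod(u)
}

# Rotation taking the +z axis onto unit vector `u`.
#' @noRd
rotation_z_to <- function(u) {
  u <- unit_vector(u)
  z <- c(0, 0, 1)
  ax <- cross3(z, u)
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (u[3] > 0) return(diag(3))
    return(rotation_matrix(c(1, 0, 0), 180))
  }
  rotation_matrix(ax, atan2(s, sum(z * u)) * 180 / pi)
}

# Squared pairwise distances between rows of A (n x 3) and B (m x 3),
# under the minimum-image convention when an orthorhombic `box` (length-3
# side vector, Angstrom) is given.
#' @noRd
min_image_dist2 <- function(A, B, box = NULL) {
  d2 <- 0
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  d2
}

# Row minima without matrixStats.
#' @noRd
row_mins <- function(m) {
  if (ncol(m) == 1L) return(m[, 1L])
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used only to
# stamp output headers with a config fingerprint.
#' @noRd
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits; keeps h an exact double
    h <- (h - h %% 256) + bitwXor(h %% 256, b %% 256)
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @noRd
validate_box <- function(box) {
  if (is.null(box)) return(NULL)
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3L)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be NULL or three positive orthorhombic side lengths",
         call. = FALSE)
  box
}

# Maximal runs of TRUE in a logical vector: data.frame(start, end).
#' @noRd
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
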