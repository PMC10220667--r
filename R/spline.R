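#' Electrode montage on the unit sphere
#'
#' @param labels Character vector of channel labels.
#' @param positions Numeric n x 3 matrix of electrode coordinates.
#' @return Object of class `montage` with unit-norm positions (see
#'   [project_to_sphere()]).
#' @export
montage <- function(labels, positions) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, length(labels) == nrow(positions))
  project_to_sphere(structure(list(labels = as.character(labels),
                                   positions = positions),
                              class = "montage"))
}

#' Project electrode positions onto the unit sphere
#'
#' Divides every position by its Euclidean norm.  Spherical-spline
#' interpolation operates on the resulting unit-sphere montage.
#'
#' @param x A `montage`, or an n x 3 position matrix.
#' @return A `montage` with unit-norm positions.
#' @export
project_to_sphere <- function(x) {
  pos <- if (inherits(x, "montage")) x$positions else as.matrix(x)
  norms <- sqrt(rowSums(pos^2))
  if (any(norms < 1e-12)) {
    bad <- which(norms < 1e-12)
    lab <- if (inherits(x, "montage")) x$labels[bad] else bad
    stop("zero-norm electrode position(s): ", paste(lab, collapse = ", "))
  }
  pos <- pos / norms
  if (inherits(x, "montage")) {
    x$positions <- pos
    x
  } else {
    montage(paste0("ch", seq_len(nrow(pos))), pos)
  }
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d electrodes on the unit sphere\n",
              length(x$labels)))
  invisible(x)
}

#' Idealized spherical electrode layout
#'
#' A deterministic Fibonacci-lattice layout over the upper portion of the
#' unit sphere, standing in for a real high-density cap in tests and
#' examples (it is synthetic, not a vendor montage).
#'
#' @param n Number of electrodes (default 128).
#' @param coverage Fraction of the sphere covered from the vertex down
#'   (default 0.65, roughly a scalp cap).
#' @return A `montage`.
#' @export
ideal_montage <- function(n = 128, coverage = 0.65) {
  stopifnot(n >= 4, coverage > 0, coverage <= 1)
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * coverage * k / n
  phi <- pi * (1 + sqrt(5)) * k
  rho <- sqrt(pmax(0, 1 - z^2))
  montage(sprintf("E%d", seq_len(n)),
          cbind(rho * cos(phi), rho * sin(phi), z))
}

#' Read a montage from a (label, x, y, z) CSV
#'
#' @param path CSV with columns `label`, `x`, `y`, `z`.
#' @return A `montage` (positions projected to the unit sphere).
#' @export
read_montage <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("montage file must have columns ", paste(need, collapse = ", "))
  montage(df$label, as.matrix(df[, c("x", "y", "z")]))
}

# Legendre polynomials P_1..P_n evaluated at x (vector): recurrence
legendre_table <- function(x, n) {
  out <- matrix(0, length(x), n)
  p_prev <- rep(1, length(x))  # P_0
  p_cur <- x                   # P_1
  out[, 1] <- p_cur
  if (n >= 2) {
    for (k in 2:n) {
      p_next <- ((2 * k - 1) * x * p_cur - (k - 1) * p_prev) / k
      out[, k] <- p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  out
}

# spherical-spline g function: sum_n (2n+1) / (n (n+1))^m P_n(cos angle)
g_function <- function(cosang, stiffness, n_terms) {
  cosang <- as.matrix(cosang)
  x <- pmin(1, pmax(-1, as.vector(cosang)))
  P <- legendre_table(x, n_terms)
  n <- seq_len(n_terms)
  w <- (2 * n + 1) / (n * (n + 1))^stiffness
  matrix(P %*% w / (4 * pi), nrow(cosang))
}

#' Spherical-spline interpolation matrix
#'
#' Weights mapping good-channel values to bad-channel estimates via the
#' spherical-spline g-function (truncated Legendre series with the given
#' stiffness), solving the regularized spline system with the
#' constant-term constraint.  Constants are therefore reproduced exactly,
#' and the map is linear in the data.
#'
#' @param mont A `montage` covering all channels.
#' @param good_idx,bad_idx Disjoint channel index vectors;
#'   `length(good_idx) >= 4`.
#' @param stiffness Spline stiffness m (default 4).
#' @param n_terms Legendre series truncation (default 7).
#' @param reg Ridge regularization added to the kernel diagonal (default
#'   1e-5).
#' @return `length(bad_idx)` x `length(good_idx)` weight matrix.
#' @export
interpolation_matrix <- function(mont, good_idx, bad_idx, stiffness = 4,
                                 n_terms = 7, reg = 1e-5) {
  stopifnot(inherits(mont, "montage"))
  if (length(intersect(good_idx, bad_idx)) > 0L)
    stop("good and bad channel sets must be disjoint")
  if (length(good_idx) < 4L)
    stop("need at least 4 good channels for spherical-spline interpolation")
  pos <- mont$positions
  pg <- pos[good_idx, , drop = FALSE]
  pb <- pos[bad_idx, , drop = FALSE]
  ng <- nrow(pg)
  G <- g_function(tcrossprod(pg), stiffness, n_terms)
  Gb <- g_function(tcrossprod(pb, pg), stiffness, n_terms)
  A <- rbind(cbind(G + diag(reg, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  sol <- tryCatch(solve(A, rbind(diag(ng), rep(0, ng))),
                  error = function(e)
                    stop("singular spline system; try a larger 'reg'"))
  Gb %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(1, nrow(pb)) %*% sol[ng + 1L, , drop = FALSE]
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces the entire time series of every bad channel by the
#' spline-weighted combination of the good channels at each time point.
#' The method is purely spatial: it uses no temporal correlations and
#' regenerates whole channels, which is what makes it a meaningful
#' baseline for the blockwise completion approach.
#'
#' @param rec A `recording`.
#' @param bad_channels Integer indices (or labels) of channels to rebuild.
#' @param mont A `montage` covering all channels of `rec`, in order.
#' @param ... Passed to [interpolation_matrix()].
#' @return The `recording` with bad channels replaced.
#' @export
interpolate_bads <- function(rec, bad_channels, mont, ...) {
  stopifnot(inherits(rec, "recording"), inherits(mont, "montage"),
            length(mont$labels) == nrow(rec$data))
  if (is.character(bad_channels))
    bad_channels <- match(bad_channels, rec$channels)
  bad_channels <- sort(unique(as.integer(bad_channels)))
  if (length(bad_channels) == 0L) return(rec)
  good <- setdiff(seq_len(nrow(rec$data)), bad_channels)
  if (length(good) < 4L)
    stop("bad channel set leaves fewer than 4 good channels")
  W <- interpolation_matrix(mont, good, bad_channels, ...)
  rec$data[bad_channels, ] <- W %*% rec$data[good, , drop = FALSE]
  rec$mask[bad_channels, ] <- TRUE
  rec
}

#' Spline-repair a masked block (comparator pipeline)
#'
#' Marks every channel of the block containing at least one corrupted
#' entry as bad and rebuilds it entirely from the remaining channels by
#' spherical-spline interpolation -- the whole-channel, space-only
#' comparator to [complete_block()].
#'
#' @param block A `masked_matrix`.
#' @param mont A `montage` with one position per block row.
#' @param ... Passed to [interpolation_matrix()].
#' @return The repaired values matrix.
#' @export
spline_repair_block <- function(block, mont, ...) {
  stopifnot(inherits(block, "masked_matrix"))
  bad_ch <- which(rowSums(!block$mask) > 0L)
  if (length(bad_ch) == 0L) return(block$values)
  good <- setdiff(seq_len(nrow(block$values)), bad_ch)
  if (length(good) < 4L)
    stop("spline comparator needs at least 4 artifact-free channels")
  W <- interpolation_matrix(mont, good, bad_ch, ...)
  out <- block$values
  out[bad_ch, ] <- W %*% block$values[good, , drop = FALSE]
  out
}
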