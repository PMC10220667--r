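#' Orthonormal factor pair
#'
#' Rank-r model of a block, `M_hat = left %*% core %*% t(right)`, with
#' `left` (C x r) and `right` (Tk x r) having orthonormal columns and
#' `core` (r x r) carrying the scale.  The deviation `M - M_hat` is the
#' noise residual outside the fitted subspace.
#'
#' @param left Numeric matrix C x r with orthonormal columns.
#' @param core Numeric matrix r x r.
#' @param right Numeric matrix Tk x r with orthonormal columns.
#' @return Object of class `factorization`.
#' @export
factorization <- function(left, core, right) {
  r <- ncol(left)
  stopifnot(ncol(right) == r, identical(dim(core), c(r, r)))
  check_orthonormal(left, "left")
  check_orthonormal(right, "right")
  structure(list(left = left, core = core, right = right, rank = r),
            class = "factorization")
}

check_orthonormal <- function(m, what, tol = 1e-8) {
  dev <- max(abs(crossprod(m) - diag(ncol(m))))
  if (dev > tol)
    stop(sprintf("'%s' columns are not orthonormal (max deviation %.2e)",
                 what, dev))
  invisible(TRUE)
}

#' Low-rank model matrix of a factorization
#'
#' @param object A `factorization`.
#' @param ... Unused.
#' @return The C x Tk matrix `left %*% core %*% t(right)`.
#' @export
fitted.factorization <- function(object, ...) {
  object$left %*% object$core %*% t(object$right)
}

#' @export
print.factorization <- function(x, ...) {
  cat(sprintf("<factorization> rank %d: %d x %d\n",
              x$rank, nrow(x$left), nrow(x$right)))
  invisible(x)
}

#' Spectral initialization of the factors
#'
#' Computes the rank-r truncated SVD of the trimmed, zero-filled block,
#' rescaled by `(C * Tk) / |observed|` so that under uniform sampling the
#' zero-filled matrix is an unbiased estimate of the full block.  Singular
#' values are returned nonincreasing on the core diagonal, and the sign of
#' each left singular vector is fixed so its largest-magnitude entry is
#' positive (reproducible factorizations across platforms).
#'
#' @param block A `masked_matrix`, completable after trimming.
#' @param rank Target rank r, `1 <= r <= min(C, Tk)`.
#' @param degree_factor Passed to [trim_block()]; set `Inf` to disable
#'   trimming.
#' @return A `factorization` of rank `rank`.
#' @export
svd_initialize <- function(block, rank, degree_factor = 2) {
  stopifnot(inherits(block, "masked_matrix"))
  d <- dim(block)
  if (rank < 1 || rank > min(d))
    stop(sprintf("invalid rank %d for a %d x %d block", rank, d[1], d[2]))
  trimmed <- if (is.finite(degree_factor)) trim_block(block, degree_factor)
             else block
  # structured masks can make trimming destructive; fall back untrimmed
  if (sum(trimmed$mask) == 0L) trimmed <- block
  n_obs <- sum(trimmed$mask)
  if (n_obs == 0L)
    stop("block has no observed entries")
  scale <- prod(d) / n_obs
  sv <- svd(scale * zero_fill(trimmed), nu = rank, nv = rank)
  left <- sv$u
  right <- sv$v
  # sign convention: largest-|.| entry of each left vector positive
  for (k in seq_len(rank)) {
    s <- sign(left[which.max(abs(left[, k])), k])
    if (s < 0) {
      left[, k] <- -left[, k]
      right[, k] <- -right[, k]
    }
  }
  factorization(left, diag(sv$d[seq_len(rank)], rank, rank), right)
}

#' Optimal core matrix for fixed factors
#'
#' Solves `min_S || M - X S t(Y) ||_F` over the observed entries only, as
#' an exact linear least-squares problem in the r^2 unknowns of S.  The
#' normal equations are assembled without materializing the
#' `|observed| x r^2` design matrix.
#'
#' @param left,right Orthonormal factor matrices X (C x r) and Y (Tk x r).
#' @param block A `masked_matrix`.
#' @param block_index Optional label used in error messages.
#' @return The r x r core matrix S.
#' @export
solve_core <- function(left, right, block, block_index = NULL) {
  stopifnot(inherits(block, "masked_matrix"),
            ncol(left) == ncol(right))
  r <- ncol(left)
  W <- block$mask
  storage.mode(W) <- "double"
  M <- block$values
  ia <- rep(seq_len(r), each = r)   # slow index
  ib <- rep(seq_len(r), times = r)  # fast index
  # Xp[, (a-1)r + c] = X[,a] * X[,c]; G[(a,c), j] = sum_i W_ij X_ia X_ic
  Xp <- left[, ia, drop = FALSE] * left[, ib, drop = FALSE]
  Yp <- right[, ia, drop = FALSE] * right[, ib, drop = FALSE]
  H <- crossprod(Xp, W) %*% Yp  # H[(a,c),(b,d)] = sum_ij W x_ia x_ic y_jb y_jd
  r2 <- r * r
  # normal matrix indexed by vec(S): p = (b-1)r + a, q = (d-1)r + c
  p_a <- rep(ib - 1L, times = r2)           # a-1 for each p, recycled over q
  p_b <- rep(ia - 1L, times = r2)           # b-1
  q_c <- rep(ib - 1L, each = r2)            # c-1
  q_d <- rep(ia - 1L, each = r2)            # d-1
  AtA <- matrix(H[cbind(p_a * r + q_c + 1L, p_b * r + q_d + 1L)], r2, r2)
  Atb <- as.vector(crossprod(left, (W * M) %*% right))
  sol <- tryCatch(solve(AtA, Atb), error = function(e) NULL)
  if (is.null(sol)) {
    where <- if (is.null(block_index)) "" else sprintf(" (block %s)", block_index)
    stop(sprintf(paste0("singular core system%s: too few observed entries ",
                        "for rank %d"), where, r))
  }
  matrix(sol, r, r)
}

#' Observed-entry cost of a factor pair
#'
#' `F(X, Y) = || M - X S* t(Y) ||_F` over the observed entries, with the
#' core `S*` profiled out by [solve_core()].  Zero exactly when the
#' observed entries are fit exactly.
#'
#' @inheritParams solve_core
#' @return Nonnegative scalar cost.
#' @export
completion_cost <- function(left, right, block, block_index = NULL) {
  S <- solve_core(left, right, block, block_index)
  resid <- block$values - left %*% S %*% t(right)
  sqrt(sum(resid[block$mask]^2))
}

# squared observed-entry residual for a fixed core (line-search objective)
obs_sq_cost <- function(left, core, right, block) {
  resid <- block$values - left %*% core %*% t(right)
  sum(resid[block$mask]^2)
}

# one alternating-least-squares sweep: exact row-wise refit of the left
# factor's subspace given the right one, then vice versa.  Each half-step
# minimizes the profiled cost over one factor with the other fixed, so
# the cost is nonincreasing; orthonormalization preserves the span.
als_sweep <- function(X, Y, M, W, ridge = 1e-10) {
  r <- ncol(X)
  A <- matrix(0, nrow(M), r)
  for (i in seq_len(nrow(M))) {
    obs <- W[i, ]
    Yo <- Y[obs, , drop = FALSE]
    A[i, ] <- solve(crossprod(Yo) + diag(ridge, r),
                    crossprod(Yo, M[i, obs]))
  }
  X <- retract(A)
  B <- matrix(0, ncol(M), r)
  for (j in seq_len(ncol(M))) {
    obs <- W[, j]
    Xo <- X[obs, , drop = FALSE]
    B[j, ] <- solve(crossprod(Xo) + diag(ridge, r),
                    crossprod(Xo, M[obs, j]))
  }
  list(X = X, Y = retract(B))
}

# QR retraction to orthonormal columns with positive-diagonal convention
retract <- function(m) {
  qrm <- qr(m)
  q <- qr.Q(qrm)
  d <- sign(diag(qr.R(qrm)))
  d[d == 0] <- 1
  sweep(q, 2, d, `*`)
}

#' Complete a masked block by low-rank estimation
#'
#' Starting from the trimmed spectral initialization, minimizes the
#' observed-entry cost by steepest descent on the pair of orthonormal
#' factors: the Euclidean gradient is projected onto the tangent space of
#' the orthonormal frames, a backtracking (Armijo) line search picks the
#' step, the factors are re-orthonormalized by QR, and the core is
#' re-solved each iteration.  The accepted cost sequence is nonincreasing
#' by construction.  The returned block is the full low-rank model
#' `X S t(Y)` over all entries: observed entries are replaced by the model
#' too (callers wanting to keep observed data untouched overwrite them
#' back, see [repair_recording()]).
#'
#' @param block A `masked_matrix`; must be completable (every row and
#'   column observed somewhere), otherwise an error of class
#'   `optrepair_infeasible` lists the all-missing lines.
#' @param rank Model rank r.
#' @param max_iter Maximum number of descent iterations (default 200).
#' @param tol Convergence tolerance: stop when the relative cost decrease
#'   falls below `tol`, or when the cost is numerically zero (default 1e-6).
#' @param degree_factor Trimming factor for the initialization.
#' @param block_index Optional label for error messages.
#' @return Object of class `completion_result`: `completed` (C x Tk model
#'   matrix), `factorization`, `iterations` (gradient plus polish steps,
#'   so up to `2 * max_iter`), `final_cost`, `converged`, `cost_trace`,
#'   `infeasible_rows`, `infeasible_cols`.
#' @examples
#' set.seed(1)
#' truth <- tcrossprod(matrix(rnorm(40), 20, 2), matrix(rnorm(50), 25, 2))
#' mask <- matrix(runif(500) > 0.2, 20, 25)
#' res <- complete_block(masked_matrix(truth, mask), rank = 2)
#' cor(res$completed[!mask], truth[!mask])
#' @export
complete_block <- function(block, rank, max_iter = 200, tol = 1e-6,
                           degree_factor = 2, block_index = NULL) {
  stopifnot(inherits(block, "masked_matrix"))
  if (any(!is.finite(block$values[block$mask])))
    stop("observed entries contain non-finite values")
  bad <- infeasible_lines(block)
  if (length(bad$rows) > 0L || length(bad$cols) > 0L) {
    msg <- sprintf(
      "block%s is not completable: all-missing rows [%s], columns [%s]",
      if (is.null(block_index)) "" else sprintf(" %s", block_index),
      paste(bad$rows, collapse = ","), paste(bad$cols, collapse = ","))
    stop(structure(class = c("optrepair_infeasible", "error", "condition"),
                   list(message = msg, call = sys.call(-1),
                        rows = bad$rows, cols = bad$cols)))
  }
  d <- dim(block)
  if (rank < 1 || rank > min(d))
    stop(sprintf("invalid rank %d for a %d x %d block", rank, d[1], d[2]))

  fac <- svd_initialize(block, rank, degree_factor)
  X <- fac$left
  Y <- fac$right
  M <- block$values
  W <- block$mask
  scale0 <- sqrt(sum(M[W]^2))
  floor_cost <- 1e-10 * max(scale0, 1)

  S <- solve_core(X, Y, block, block_index)
  f_sq <- obs_sq_cost(X, S, Y, block)
  cost_trace <- sqrt(f_sq)
  converged <- FALSE
  step <- 1
  iter <- 0L
  Xp <- NULL; Yp <- NULL; GXp <- NULL; GYp <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    if (sqrt(f_sq) <= floor_cost) { converged <- TRUE; break }
    E <- (X %*% S %*% t(Y) - M)
    E[!W] <- 0
    GX <- 2 * E %*% Y %*% t(S)
    GY <- 2 * crossprod(E, X) %*% S
    # tangent-space projection on the orthonormal frames
    GX <- GX - X %*% crossprod(X, GX)
    GY <- GY - Y %*% crossprod(Y, GY)
    gsq <- sum(GX^2) + sum(GY^2)
    if (gsq <= 1e-30) { converged <- TRUE; break }
    # Barzilai-Borwein step guess (curvature along the last move),
    # safeguarded by the Armijo backtracking below
    if (!is.null(Xp)) {
      sx <- X - Xp; sy <- Y - Yp
      dgx <- GX - GXp; dgy <- GY - GYp
      sg <- sum(sx * dgx) + sum(sy * dgy)
      ss <- sum(sx^2) + sum(sy^2)
      if (is.finite(sg) && abs(sg) > 1e-30)
        step <- min(max(ss / abs(sg), 1e-12), 1e6)
    }
    Xp <- X; Yp <- Y; GXp <- GX; GYp <- GY
    # backtracking Armijo line search on the fixed-core objective
    t_step <- step
    accepted <- FALSE
    for (ls in 1:40) {
      Xn <- retract(X - t_step * GX)
      Yn <- retract(Y - t_step * GY)
      f_new <- obs_sq_cost(Xn, S, Yn, block)
      if (f_new <= f_sq - 1e-4 * t_step * gsq) { accepted <- TRUE; break }
      t_step <- t_step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    step <- min(t_step * 2, 1e6)
    X <- Xn
    Y <- Yn
    # re-solving the core can only decrease the profiled cost further
    S <- solve_core(X, Y, block, block_index)
    f_sq <- obs_sq_cost(X, S, Y, block)
    cost_new <- sqrt(f_sq)
    cost_prev <- cost_trace[length(cost_trace)]
    cost_trace <- c(cost_trace, cost_new)
    if (cost_prev - cost_new < tol * max(cost_prev, floor_cost)) {
      converged <- TRUE
      break
    }
  }
  # alternating-least-squares polish: steepest descent can crawl along
  # ill-conditioned valleys; exact alternating refits finish the job
  # while keeping the cost sequence nonincreasing
  polish <- 0L
  while (polish < max_iter && sqrt(f_sq) > floor_cost) {
    polish <- polish + 1L
    upd <- tryCatch(als_sweep(X, Y, M, W), error = function(e) NULL)
    if (is.null(upd)) break
    S_new <- tryCatch(solve_core(upd$X, upd$Y, block, block_index),
                      error = function(e) NULL)
    if (is.null(S_new)) break
    f_new <- obs_sq_cost(upd$X, S_new, upd$Y, block)
    if (f_new >= f_sq) break
    X <- upd$X; Y <- upd$Y; S <- S_new
    cost_prev <- sqrt(f_sq)
    f_sq <- f_new
    cost_trace <- c(cost_trace, sqrt(f_sq))
    if (cost_prev - sqrt(f_sq) < tol * max(cost_prev, floor_cost)) {
      converged <- TRUE
      break
    }
  }
  iter <- iter + polish
  fac <- factorization(X, S, Y)
  structure(list(completed = fitted(fac),
                 factorization = fac,
                 iterations = iter,
                 final_cost = cost_trace[length(cost_trace)],
                 converged = converged,
                 cost_trace = cost_trace,
                 infeasible_rows = integer(0),
                 infeasible_cols = integer(0)),
            class = "completion_result")
}

#' @export
print.completion_result <- function(x, ...) {
  cat(sprintf(
    "<completion_result> rank %d, %d iterations, final cost %.4g%s\n",
    x$factorization$rank, x$iterations, x$final_cost,
    if (x$converged) " (converged)" else ""))
  invisible(x)
}
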