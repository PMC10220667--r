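# shared fixture builders; everything is generated in code at test time

random_orthonormal <- function(n, r) {
  qr.Q(qr(matrix(rnorm(n * r), n, r)))
}

# exact rank-r matrix with N(0,1) factors
random_lowrank <- function(C, Tk, r) {
  tcrossprod(matrix(rnorm(C * r), C, r), matrix(rnorm(Tk * r), Tk, r))
}

# uniform observation mask guaranteed completable
uniform_mask <- function(C, Tk, p_hidden) {
  repeat {
    m <- matrix(runif(C * Tk) > p_hidden, C, Tk)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# all permutations of seq_len(n) (tiny n only), for exhaustive oracles
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# brute-force observed-entry least squares for the core matrix
brute_force_core <- function(X, Y, block) {
  r <- ncol(X)
  obs <- which(block$mask)
  ij <- arrayInd(obs, dim(block$mask))
  A <- t(matrix(vapply(seq_len(nrow(ij)), function(k)
    as.vector(outer(X[ij[k, 1], ], Y[ij[k, 2], ])), numeric(r * r)),
    nrow = r * r))
  matrix(qr.solve(A, block$values[obs]), r, r)
}

# generic numerical optimizer on the same factorized objective: oracle
# for the cost reached by complete_block on tiny instances
oracle_min_cost <- function(block, r, n_restarts = 2) {
  d <- dim(block)
  obj <- function(par) {
    X <- qr.Q(qr(matrix(par[seq_len(d[1] * r)], d[1], r)))
    Y <- qr.Q(qr(matrix(par[-seq_len(d[1] * r)], d[2], r)))
    tryCatch(completion_cost(X, Y, block), error = function(e) 1e6)
  }
  init <- svd_initialize(block, r)
  starts <- list(c(as.vector(init$left), as.vector(init$right)))
  for (k in seq_len(n_restarts))
    starts[[k + 1L]] <- rnorm((d[1] + d[2]) * r)
  best <- Inf
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < best) best <- fit$value
  }
  best
}
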