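#' Artifact mask of a bad block
#'
#' The binary corruption pattern of a bad block (`TRUE` = observed,
#' `FALSE` = corrupted), with its severity and, once classified, its
#' severity quantile class.  Overlaying a pattern on a fully observed
#' block yields a surrogate with known ground truth.
#'
#' @param pattern Logical C x Tk matrix, `TRUE` = observed.
#' @param severity_class Optional class label in `1..k`.
#' @return Object of class `artifact_mask`.
#' @export
artifact_mask <- function(pattern, severity_class = NA_integer_) {
  stopifnot(is.logical(pattern), is.matrix(pattern))
  structure(list(pattern = pattern, severity = severity(pattern),
                 severity_class = severity_class),
            class = "artifact_mask")
}

#' Build good/bad block libraries from a recording
#'
#' Contiguous chunks of `block_size` columns are drawn at random without
#' overlap from the recording (rejected channels excluded).  A chunk with
#' no corrupted entry joins the good library; a chunk with at least one
#' corrupted entry contributes its corruption pattern, severity and
#' severity class to the bad library.  Sampling continues until
#' `target_size` chunks are drawn or no nonoverlapping start remains.
#'
#' @param rec A `recording` with a populated mask, or a list of them
#'   (e.g. one per subject); chunks are pooled across recordings.
#' @param block_size Tk in samples.
#' @param target_size Maximum number of chunks to draw (default `Inf`:
#'   exhaust the recordings).
#' @param seed Integer seed for the random draw.
#' @param n_classes Number of severity classes (default 5).
#' @return Object of class `block_library` with elements `good` (list of
#'   `masked_matrix`), `bad` (list of `artifact_mask`), `block_size`,
#'   `quantile_edges`, `degenerate_classes`.
#' @export
build_library <- function(rec, block_size, target_size = Inf, seed = 1,
                          n_classes = 5) {
  recs <- if (inherits(rec, "recording")) list(rec) else rec
  stopifnot(all(vapply(recs, inherits, logical(1), "recording")),
            block_size >= 2)
  good <- list(); bad_patterns <- list()
  for (rr in seq_along(recs)) {
    r1 <- recs[[rr]]
    keep_ch <- setdiff(seq_len(nrow(r1$data)), r1$rejected_channels)
    data <- r1$data[keep_ch, , drop = FALSE]
    mask <- r1$mask[keep_ch, , drop = FALSE]
    T_len <- ncol(data)
    if (T_len < block_size) stop("recording shorter than one block")
    starts <- sample_nonoverlapping(T_len, block_size, target_size,
                                    seed + rr - 1L)
    for (s in starts) {
      if (length(good) + length(bad_patterns) >= target_size) break
      idx <- s:(s + block_size - 1L)
      m <- mask[, idx, drop = FALSE]
      if (all(m)) {
        good[[length(good) + 1L]] <-
          masked_matrix(data[, idx, drop = FALSE], m)
      } else {
        bad_patterns[[length(bad_patterns) + 1L]] <- m
      }
    }
  }
  if (length(good) == 0L)
    warning("no artifact-free blocks found: good library is empty")
  sev <- vapply(bad_patterns, severity, numeric(1))
  cls <- if (length(sev)) quantile_classes(sev, n_classes)
         else list(classes = integer(0), edges = numeric(0),
                   degenerate = FALSE)
  bad <- lapply(seq_along(bad_patterns), function(i)
    artifact_mask(bad_patterns[[i]], cls$classes[i]))
  structure(list(good = good, bad = bad, block_size = block_size,
                 quantile_edges = cls$edges,
                 degenerate_classes = cls$degenerate),
            class = "block_library")
}

# random nonoverlapping window starts, in random order until exhausted
sample_nonoverlapping <- function(T_len, width, target_size, seed) {
  withr_seed(seed)
  cand <- sample.int(T_len - width + 1L)
  occupied <- logical(T_len)
  starts <- integer(0)
  for (s in cand) {
    if (length(starts) >= target_size) break
    idx <- s:(s + width - 1L)
    if (!any(occupied[idx])) {
      occupied[idx] <- TRUE
      starts <- c(starts, s)
    }
  }
  starts
}

# set the RNG seed locally without clobbering the caller's stream
withr_seed <- function(seed) {
  seed <- as.integer(seed %% .Machine$integer.max)
  set.seed(seed)
  invisible(seed)
}

#' @export
print.block_library <- function(x, ...) {
  cat(sprintf("<block_library> Tk = %d: %d good, %d bad blocks\n",
              x$block_size, length(x$good), length(x$bad)))
  invisible(x)
}

#' Equiprobable severity classes
#'
#' Splits severities into `k` classes of (as near as possible) equal
#' size by empirical quantiles, ties broken by stable order.  Class sizes
#' differ by at most one.
#'
#' @param severities Numeric vector of block severities (percent).
#' @param k Number of classes (default 5).
#' @return List with `classes` (integer labels), `edges` (the `k - 1`
#'   interior empirical quantiles) and `degenerate` (`TRUE` when fewer
#'   than `k` distinct severities exist).
#' @export
quantile_classes <- function(severities, k = 5) {
  n <- length(severities)
  if (n == 0L) stop("empty severity list")
  ord <- order(severities)  # stable for ties
  sizes <- diff(round(seq(0, n, length.out = k + 1)))
  classes <- integer(n)
  classes[ord] <- rep(seq_len(k), times = sizes)
  degenerate <- length(unique(severities)) < k
  if (degenerate)
    warning(sprintf("fewer than %d distinct severities: classes degenerate",
                    k))
  edges <- unname(stats::quantile(severities, probs = seq_len(k - 1) / k))
  list(classes = classes, edges = edges, degenerate = degenerate)
}

#' Overlay an artifact mask on a good block
#'
#' Entry-wise multiplication of a fully observed block with a corruption
#' pattern gives a surrogate artifacted block whose hidden ground truth is
#' known.
#'
#' @param good A fully observed `masked_matrix`.
#' @param mask An `artifact_mask` (or logical pattern matrix) of the same
#'   shape.
#' @return List with `surrogate` (a `masked_matrix`) and `truth` (the
#'   original values).
#' @export
make_surrogate <- function(good, mask) {
  stopifnot(inherits(good, "masked_matrix"))
  pattern <- if (inherits(mask, "artifact_mask")) mask$pattern else mask
  if (!identical(dim(pattern), dim(good$values)))
    stop("good block and artifact mask shapes differ")
  vals <- good$values * pattern
  list(surrogate = masked_matrix(vals, pattern), truth = good$values)
}

# Pearson correlation that reports NA (not 0) for constant input
safe_cor <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0)
    return(NA_real_)
  stats::cor(x, y)
}

rel_frobenius <- function(truth, est) {
  denom <- sqrt(sum(truth^2))
  if (denom == 0) return(NA_real_)
  sqrt(sum((truth - est)^2)) / denom
}

#' Reconstruction metrics for a completed surrogate
#'
#' Pearson correlation and relative Frobenius distance
#' `||truth - completed||_F / ||truth||_F` between ground truth and
#' completion, over (i) all entries, (ii) observed entries, (iii) hidden
#' entries.  Correlation over a constant scope is reported as `NA`.
#'
#' @param truth Ground-truth matrix.
#' @param completed Completed matrix of the same shape.
#' @param pattern Logical mask (`TRUE` = observed) defining the scopes.
#' @return One-row data frame with `pearson_all`, `pearson_observed`,
#'   `pearson_missing`, `frobenius_all`, `frobenius_missing`.
#' @export
evaluate_completion <- function(truth, completed, pattern) {
  stopifnot(identical(dim(truth), dim(completed)),
            identical(dim(truth), dim(pattern)))
  obs <- which(pattern); mis <- which(!pattern)
  data.frame(
    pearson_all = safe_cor(as.vector(truth), as.vector(completed)),
    pearson_observed = safe_cor(truth[obs], completed[obs]),
    pearson_missing = safe_cor(truth[mis], completed[mis]),
    frobenius_all = rel_frobenius(as.vector(truth), as.vector(completed)),
    frobenius_missing = rel_frobenius(truth[mis], completed[mis]))
}

#' Permutation chance levels for the reconstruction metrics
#'
#' Correlation and relative Frobenius distance between the ground truth
#' and entry-permuted copies of itself estimate what a chance-level
#' "reconstruction" achieves.  Returns the 95th percentile of the
#' permuted correlations (`C_chance`) and the 5th percentile of the
#' permuted distances (`D_chance`); an observed correlation above
#' `C_chance` (distance below `D_chance`) beats chance with 95%
#' confidence.
#'
#' @param truth Ground-truth matrix.
#' @param pattern Optional logical mask restricting the scope to hidden
#'   entries (`NULL` or all-`TRUE` uses every entry).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `C_chance` and `D_chance`.
#' @export
chance_level <- function(truth, pattern = NULL, n_perm = 500, seed = 1) {
  stopifnot(n_perm >= 100)
  x <- if (is.null(pattern) || all(pattern)) as.vector(truth)
       else truth[!pattern]
  withr_seed(seed)
  cors <- numeric(n_perm); dists <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    xp <- x[sample.int(length(x))]
    cors[b] <- safe_cor(x, xp)
    dists[b] <- rel_frobenius(x, xp)
  }
  list(C_chance = unname(stats::quantile(cors, 0.95, na.rm = TRUE)),
       D_chance = unname(stats::quantile(dists, 0.05, na.rm = TRUE)))
}

#' Bootstrapped hyperparameter sweep over surrogate completions
#'
#' For every combination of block size (one library per Tk), severity
#' class and rank, draws `n_boot` (good block, bad mask) pairs with
#' replacement, overlays, completes, and scores the reconstruction.
#' Draws whose mask leaves an all-missing row or column in the surrogate
#' are resampled up to `max_retry` times (such blocks violate the
#' completability assumption); the resample count is recorded.  All
#' randomness flows from `seed` through a per-cell counter so any cell
#' can be reproduced independently.
#'
#' @param libraries A `block_library` or list of them (one per Tk).
#' @param r_grid Integer vector of ranks (default `c(4, 8, 12, 16, 20)`).
#' @param n_boot Bootstrap iterations per cell (500 at full scale;
#'   reduce for desk-scale runs).
#' @param seed Integer master seed.
#' @param classes Severity classes to sweep (default `1:5`); the special
#'   value `0` pools bad blocks across all classes (used for rank/block
#'   size analyses that marginalize over severity).
#' @param max_retry Resample cap for infeasible draws (default 10).
#' @param max_iter,tol Passed to [complete_block()].
#' @param paired If `TRUE`, the same (good block, artifact mask) draws
#'   are reused across every rank in `r_grid` (common random numbers),
#'   so that differences between rank medians reflect the rank and not
#'   draw-composition luck.  Default `FALSE`: every cell draws
#'   independently.
#' @return Object of class `benchmark_result`: a data frame with one row
#'   per iteration (`Tk`, `q`, `r`, `iter`, the five metrics of
#'   [evaluate_completion()], `resamples`, `converged`, `monotone`).
#' @export
sweep_benchmark <- function(libraries, r_grid = c(4, 8, 12, 16, 20),
                            n_boot = 50, seed = 1, classes = 1:5,
                            max_retry = 10, max_iter = 200, tol = 1e-6,
                            paired = FALSE) {
  if (inherits(libraries, "block_library")) libraries <- list(libraries)
  rows <- list()
  cell <- 0L
  emit <- function(Tk, q, r, it, surr, res, resamples) {
    if (is.null(res)) {
      data.frame(Tk = Tk, q = q, r = r, iter = it,
                 pearson_all = NA_real_, pearson_observed = NA_real_,
                 pearson_missing = NA_real_, frobenius_all = NA_real_,
                 frobenius_missing = NA_real_, resamples = resamples,
                 converged = NA, monotone = NA)
    } else {
      cbind(data.frame(Tk = Tk, q = q, r = r, iter = it),
            evaluate_completion(surr$truth, res$completed,
                                surr$surrogate$mask),
            data.frame(resamples = resamples, converged = res$converged,
                       monotone = !is.unsorted(rev(res$cost_trace),
                                               strictly = FALSE)))
    }
  }
  for (lib in libraries) {
    stopifnot(inherits(lib, "block_library"))
    if (length(lib$good) == 0L || length(lib$bad) == 0L)
      stop(sprintf("library (Tk = %d) needs both good and bad blocks",
                   lib$block_size))
    bad_class <- vapply(lib$bad, function(b) b$severity_class, integer(1))
    for (q in classes) {
      pool <- if (q == 0) seq_along(lib$bad) else which(bad_class == q)
      if (length(pool) == 0L) next
      if (paired) {
        cell <- cell + 1L
        withr_seed(seed + 7919L * cell)
        for (it in seq_len(n_boot)) {
          resamples <- 0L
          surr <- NULL
          repeat {
            g <- lib$good[[sample.int(length(lib$good), 1L)]]
            b <- lib$bad[[pool[sample.int(length(pool), 1L)]]]
            cand <- make_surrogate(g, b)
            if (is_completable(cand$surrogate)) { surr <- cand; break }
            resamples <- resamples + 1L
            if (resamples > max_retry) break
          }
          for (r in r_grid) {
            res <- NULL
            if (!is.null(surr)) {
              r_eff <- min(r, dim(surr$surrogate))
              res <- tryCatch(
                complete_block(surr$surrogate, rank = r_eff,
                               max_iter = max_iter, tol = tol),
                error = function(e) NULL)
            }
            rows[[length(rows) + 1L]] <-
              emit(lib$block_size, q, r, it, surr, res, resamples)
          }
        }
      } else {
        for (r in r_grid) {
          cell <- cell + 1L
          withr_seed(seed + 7919L * cell)
          for (it in seq_len(n_boot)) {
            resamples <- 0L
            res <- NULL
            surr <- NULL
            repeat {
              g <- lib$good[[sample.int(length(lib$good), 1L)]]
              b <- lib$bad[[pool[sample.int(length(pool), 1L)]]]
              surr <- make_surrogate(g, b)
              if (is_completable(surr$surrogate)) {
                r_eff <- min(r, dim(surr$surrogate))
                res <- tryCatch(
                  complete_block(surr$surrogate, rank = r_eff,
                                 max_iter = max_iter, tol = tol),
                  error = function(e) NULL)
                if (!is.null(res)) break
              }
              resamples <- resamples + 1L
              if (resamples > max_retry) break
            }
            rows[[length(rows) + 1L]] <-
              emit(lib$block_size, q, r, it, surr, res, resamples)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_result", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "n_boot") <- n_boot
  out
}

#' Write per-iteration benchmark metrics to CSV
#'
#' @param result A `benchmark_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
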