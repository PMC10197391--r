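# internal helpers shared across modules

# deterministic per-stage substream seed derived from a root seed; kept
# below 2^31 so it is always a valid R integer
.substream <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

.checkAligned <- function(...) {
  mats <- list(...)
  labs <- lapply(mats, pwLabels)
  for (i in seq_along(labs)[-1])
    if (!identical(labs[[1]], labs[[i]]))
      stop("pairwise matrices are not aligned on the same population labels")
  invisible(labs[[1]])
}

# Lawson-Hanson non-negative least squares: min ||Ax - b||^2 s.t. x >= 0.
# Active-set method; terminates with the exact KKT solution.
.nnls <- function(A, b, tol = NULL) {
  n <- ncol(A)
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  if (is.null(tol)) tol <- 1e-10 * max(abs(Atb), 1)
  x <- numeric(n)
  P <- rep(FALSE, n)
  w <- Atb - drop(AtA %*% x)
  outer <- 0L
  while (any(!P) && any(w[!P] > tol) && outer < 30L * n) {
    outer <- outer + 1L
    cand <- which(!P)
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(n)
      sol <- tryCatch(solve(AtA[P, P, drop = FALSE], Atb[P]),
                      error = function(e) NULL)
      if (is.null(sol)) { # rank deficiency: ridge fallback keeps us moving
        sol <- solve(AtA[P, P, drop = FALSE] +
                       diag(1e-12, sum(P)), Atb[P])
      }
      s[P] <- sol
      if (all(s[P] > tol)) { x <- s; break }
      viol <- P & (s <= tol)
      alpha <- min(x[viol] / (x[viol] - s[viol] + 1e-300))
      x <- x + alpha * (s - x)
      P[x <= tol & P] <- FALSE
      x[!P] <- 0
    }
    w <- Atb - drop(AtA %*% x)
  }
  x
}

# all permutations of 1..n (n <= 8), in lexicographic order
.allPerms <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .allPerms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}
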