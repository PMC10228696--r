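# Nonnegative least squares, Lawson-Hanson active set.
#
# The inner unconstrained solves use the SVD pseudoinverse, so passive sets
# that are rank deficient (duplicate or collinear genotype columns arise
# routinely during the hybrid-clone search) yield the minimum-norm solution
# instead of a failure. Iterations are bounded; on hitting the bound the
# best iterate found is returned, which keeps the surrounding pipeline
# total.
nnls_solve <- function(A, b, max_outer = NULL, tol = NULL) {
  n <- ncol(A)
  if (is.null(max_outer)) max_outer <- max(50L, 5L * n)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  resid <- b
  if (is.null(tol)) tol <- 1e-10 * max(abs(crossprod(A, b)), 1)

  ls_sub <- function(cols) {
    Ap <- A[, cols, drop = FALSE]
    sv <- svd(Ap)
    pos <- sv$d > max(sv$d[1], 1) * 1e-12
    if (!any(pos)) return(numeric(sum(cols)))
    as.vector(sv$v[, pos, drop = FALSE] %*%
                ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos]))
  }

  for (outer in seq_len(max_outer)) {
    w <- as.vector(crossprod(A, resid))
    w[passive] <- -Inf
    if (max(w) <= tol) break
    passive[which.max(w)] <- TRUE
    for (inner in seq_len(max_outer)) {
      z <- numeric(n)
      z[passive] <- ls_sub(passive)
      if (all(z[passive] > 1e-12)) break
      neg <- passive & z <= 1e-12
      alpha <- min(x[neg] / pmax(x[neg] - z[neg], 1e-30))
      x <- x + alpha * (z - x)
      passive <- passive & x > 1e-12
      x[!passive] <- 0
    }
    x <- z
    x[x < 0] <- 0
    resid <- b - A %*% x
  }
  x
}
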