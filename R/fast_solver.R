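# Direct solver for extruded domains.
#
# Every model domain is an extrusion along z: the system matrix is
# I_z (x) A2 + T_z (x) diag(gz), with A2 the in-plane conductance
# Laplacian, gz the per-column axial face conductance and T_z the 1-D
# Neumann Laplacian stencil.  Expanding the z dependence in the cosine
# eigenbasis of T_z decouples the solve into nz independent 2-D systems
# (A2 + lambda_k diag(gz)), each handled by a sparse Cholesky
# factorization that is re-used across modes through the diagonal
# similarity A2s = S A2 S with S = diag(gz)^(-1/2), so that the k-th
# system becomes A2s + lambda_k I.
#
# The route applies whenever the right-hand side is known per cell (point
# sources, uniform-current-density electrodes); the floating-equipotential
# electrode couples across slices and stays on the CG path.

dct_basis <- function(nz) {
  iz <- seq_len(nz) - 0.5
  q <- outer(iz, 0:(nz - 1), function(i, k) cos(i * k * pi / nz))
  q[, 1] <- q[, 1] / sqrt(nz)
  if (nz > 1) q[, -1] <- q[, -1] * sqrt(2 / nz)
  q
}

solve_separable <- function(domain, b) {
  n2 <- domain$n2
  nz <- domain$nz
  e2 <- domain$edges2d
  gz <- domain$gz2
  stopifnot(length(b) == n2 * nz, length(gz) == n2)

  a2 <- Matrix::sparseMatrix(
    i = c(e2$i, e2$j, seq_len(n2)),
    j = c(e2$j, e2$i, seq_len(n2)),
    x = c(-e2$g, -e2$g, rep(0, n2)),
    dims = c(n2, n2))
  Matrix::diag(a2) <- -Matrix::rowSums(a2)

  q <- dct_basis(nz)
  lam <- 2 - 2 * cos((0:(nz - 1)) * pi / nz)
  bh <- matrix(b, n2, nz) %*% q
  xh <- matrix(0, n2, nz)

  # k = 0: the pure-Neumann in-plane system; compatible by zero net
  # current, solved with one pinned degree of freedom and re-gauged
  b0 <- bh[, 1]
  if (max(abs(b0)) > 0) {
    a2p <- Matrix::forceSymmetric(a2[-1, -1])
    ch0 <- Matrix::Cholesky(a2p, LDL = FALSE, perm = TRUE)
    x0 <- c(0, as.numeric(Matrix::solve(ch0, b0[-1])))
    xh[, 1] <- x0 - mean(x0)
  }

  # k > 0: similarity-shifted systems share one symbolic factorization
  s <- 1 / sqrt(gz)
  sd <- Matrix::Diagonal(x = s)
  a2s <- Matrix::forceSymmetric(sd %*% a2 %*% sd)
  ch <- Matrix::Cholesky(a2s, Imult = lam[2], LDL = FALSE, perm = TRUE)
  for (k in 2:nz) {
    if (max(abs(bh[, k])) == 0) next
    chk <- Matrix::update(ch, a2s, mult = lam[k])
    xh[, k] <- s * as.numeric(Matrix::solve(chk, s * bh[, k]))
  }

  x <- as.numeric(xh %*% t(q))
  x <- x - mean(x)
  x
}

# apply the full 3-D operator through its separable structure
separable_apply <- function(domain, x) {
  n2 <- domain$n2; nz <- domain$nz
  e2 <- domain$edges2d
  a2 <- Matrix::sparseMatrix(
    i = c(e2$i, e2$j, seq_len(n2)),
    j = c(e2$j, e2$i, seq_len(n2)),
    x = c(-e2$g, -e2$g, rep(0, n2)),
    dims = c(n2, n2))
  Matrix::diag(a2) <- -Matrix::rowSums(a2)
  xm <- matrix(x, n2, nz)
  y <- as.matrix(a2 %*% xm)
  gz <- domain$gz2
  if (nz > 1) {
    d <- gz * (xm[, -1, drop = FALSE] - xm[, -nz, drop = FALSE])
    y[, -nz] <- y[, -nz] - d
    y[, -1] <- y[, -1] + d
  }
  as.numeric(y)
}

# true residual of the 3-D system, for reporting
residual_norm <- function(domain, x, b) {
  ax <- separable_apply(domain, x)
  sqrt(sum((b - ax)^2)) / sqrt(sum(b^2))
}

# assemble the 3-D edge list (used by the CG path for the equipotential
# electrode formulation)
assemble_edges3d <- function(domain) {
  n2 <- domain$n2; nz <- domain$nz
  e2 <- domain$edges2d
  n_in <- length(e2$g)
  offs <- (seq_len(nz) - 1L) * n2
  ei <- rep(e2$i, times = nz) + rep(offs, each = n_in)
  ej <- rep(e2$j, times = nz) + rep(offs, each = n_in)
  eg <- rep(e2$g, times = nz)
  zoff <- (seq_len(nz - 1L) - 1L) * n2
  list(i = c(ei, rep(seq_len(n2), times = nz - 1L) +
               rep(zoff, each = n2)),
       j = c(ej, rep(seq_len(n2) + n2, times = nz - 1L) +
               rep(zoff, each = n2)),
       g = c(eg, rep(domain$gz2, times = nz - 1L)))
}
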