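# Spectral machinery: eigenbases, Poisson solves, Helmholtz-Hodge decomposition.

#' Eigenbasis of a scalar Laplacian
#'
#' Solves the generalised symmetric eigenproblem for a Laplacian `L` that is
#' self-adjoint under a diagonal inner product `M` (i.e. `M L` symmetric),
#' via the similarity transform `M^(1/2) L M^(-1/2)`. Eigenvalues are returned
#' ascending; eigenmodes are M-orthonormal with a deterministic sign (the
#' largest-magnitude entry of each mode is positive). On a connected complex
#' the masked Laplacians have a single zero eigenvalue whose mode is uniform.
#'
#' @param L square Laplacian matrix (dense or sparse).
#' @param M diagonal inner-product matrix of matching size.
#' @param tol asymmetry tolerance for `M L` relative to its largest entry.
#' @return object of class `vm_spectrum`: `values` (ascending), `modes`
#'   (columns, M-orthonormal), `M`.
#' @export
eigenbasis <- function(L, M, tol = 1e-10) {
  Ld <- as.matrix(L)
  d <- Matrix::diag(M)
  if (nrow(Ld) != length(d))
    stop_bad_arg("inner product dimension does not match the Laplacian")
  Smat <- Ld * sqrt(d) * rep(1 / sqrt(d), each = nrow(Ld))
  asym <- max(abs(Smat - t(Smat)))
  if (asym > tol * max(1, max(abs(Smat))))
    stop_bad_arg("Laplacian is not self-adjoint under M (asymmetry ", asym, ")")
  es <- eigen((Smat + t(Smat)) / 2, symmetric = TRUE)
  ord <- order(es$values)
  vals <- es$values[ord]
  modes <- es$vectors[, ord, drop = FALSE] / sqrt(d)
  for (q in seq_len(ncol(modes))) {
    a <- which.max(abs(modes[, q]))
    if (modes[a, q] < 0) modes[, q] <- -modes[, q]
  }
  structure(list(values = vals, modes = modes, M = M), class = "vm_spectrum")
}

#' @export
print.vm_spectrum <- function(x, ...) {
  cat("<vm_spectrum> ", length(x$values), " modes; eigenvalues in [",
      format(min(x$values), digits = 4), ", ",
      format(max(x$values), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Solve a Poisson problem on the monolayer
#'
#' Minimum-norm solve of `L x = rhs` for a Laplacian self-adjoint under the
#' diagonal weight `M`. If `L` is singular with a uniform kernel (the masked
#' Laplacians), the right-hand side must be M-orthogonal to the uniform mode
#' (the discrete solvability condition); the solution is returned with zero
#' M-weighted mean. Invertible Laplacians are solved directly.
#'
#' @param L Laplacian matrix.
#' @param M diagonal inner-product matrix.
#' @param rhs right-hand side vector.
#' @param tol relative residual tolerance for the solvability check and the
#'   returned solution.
#' @return numeric solution vector with attribute `"residual"`.
#' @export
solve_poisson <- function(L, M, rhs, tol = 1e-9) {
  Ld <- as.matrix(L)
  d <- Matrix::diag(M)
  n <- length(rhs)
  Smat <- (Ld * sqrt(d) * rep(1 / sqrt(d), each = n))
  Smat <- (Smat + t(Smat)) / 2
  b <- rhs * sqrt(d)
  es <- eigen(Smat, symmetric = TRUE)
  lam <- es$values
  cutoff <- 1e-10 * max(abs(lam))
  keep <- abs(lam) > cutoff
  coef <- crossprod(es$vectors, b)
  if (any(!keep)) {
    viol <- sqrt(sum(coef[!keep]^2))
    if (viol > tol * max(sqrt(sum(b^2)), 1))
      stop_bad_arg("solvability violated: kernel component of rhs = ",
                   format(viol, digits = 4),
                   " (area-weighted integral of the forcing must vanish)")
    coef[!keep] <- 0
  }
  coef[keep] <- coef[keep] / lam[keep]
  x <- as.vector(es$vectors %*% coef) / sqrt(d)
  if (any(!keep)) x <- x - sum(d * x) / sum(d)    # zero M-weighted mean gauge
  res <- sqrt(sum((as.vector(Ld %*% x) - rhs)^2)) /
    max(sqrt(sum(rhs^2)), .Machine$double.eps)
  attr(x, "residual") <- res
  x
}

#' Helmholtz-Hodge decomposition over the primal network
#'
#' Splits a per-edge vector field into its edge-parallel and edge-perpendicular
#' parts, `h = h_par + h_perp`, with
#' `h_par = grad_v psi_v + tcurl_c Psi_c` and
#' `h_perp = tgrad_c psi_c + curl_v Psi_v`. The cell potentials solve the
#' (invertible, unmasked) face-Laplacian problems
#' `L_F psi_c = -div_c h`, `L_F Psi_c = curl_c h`; the vertex potentials solve
#' the singular problems `L_V psi_v = -tdiv_v h`, `L_V Psi_v = tcurl_v h`
#' (right-hand sides orthogonal to the kernel by construction), gauged to zero
#' M-weighted mean. On a simply connected complex the reconstruction is exact
#' to solver tolerance.
#'
#' @param ops a `vm_operators`.
#' @param h per-edge field: flat length-`2*n_edges` vector (interleaved) or an
#'   `n_edges` x 2 matrix.
#' @param tol reconstruction tolerance (relative); exceeding it is an error
#'   since it indicates an operator/inner-product inconsistency.
#' @return object of class `vm_potentials` with `psi_c`, `Psi_c`, `psi_v`,
#'   `Psi_v`, the parts `h_par`, `h_perp` (flat), the `network` tag and the
#'   relative `residual`.
#' @export
helmholtz_primal <- function(ops, h, tol = 1e-8) {
  hf <- as_edge_flat(h)
  psi_c <- solve(as.matrix(ops$L_F_full), -as.vector(ops$div_c %*% hf))
  Psi_c <- solve(as.matrix(ops$L_F_full), as.vector(ops$curl_c %*% hf))
  psi_v <- solve_poisson(ops$L_V, ops$M_V, -as.vector(ops$tdiv_v %*% hf))
  Psi_v <- solve_poisson(ops$L_V, ops$M_V, as.vector(ops$tcurl_v %*% hf))
  h_par <- as.vector(ops$grad_v %*% psi_v + ops$tcurl_c %*% Psi_c)
  h_perp <- as.vector(ops$tgrad_c %*% psi_c + ops$curl_v %*% Psi_v)
  resid <- sqrt(sum((h_par + h_perp - hf)^2)) /
    max(sqrt(sum(hf^2)), .Machine$double.eps)
  if (resid > tol)
    stop_bad_arg("Helmholtz reconstruction failed (relative residual ",
                 format(resid, digits = 4), ")")
  structure(list(psi_c = psi_c, Psi_c = Psi_c,
                 psi_v = as.vector(psi_v), Psi_v = as.vector(Psi_v),
                 h_par = h_par, h_perp = h_perp,
                 network = "primal", residual = resid),
            class = "vm_potentials")
}

#' Helmholtz-Hodge decomposition over the dual network
#'
#' The same field viewed over links: `h = h_par + h_perp` with
#' `h_par = grad_c psi_c + tCURL_v Psi_v` (link-parallel) and
#' `h_perp = tgrad_v psi_v + CURL_c Psi_c` (link-perpendicular). Cell
#' potentials solve the invertible `L_C_full` problems, vertex (triangle)
#' potentials the singular `L_T` problems.
#'
#' @inheritParams helmholtz_primal
#' @return object of class `vm_potentials` (fields named as in
#'   [helmholtz_primal()] but interpreted on the dual network;
#'   `network = "dual"`).
#' @export
helmholtz_dual <- function(ops, h, tol = 1e-8) {
  hf <- as_edge_flat(h)
  psi_c <- solve(as.matrix(ops$L_C_full), -as.vector(ops$tdiv_c %*% hf))
  Psi_c <- solve(as.matrix(ops$L_C_full), as.vector(ops$tCURL_c %*% hf))
  psi_v <- solve_poisson(ops$L_T, ops$M_V, -as.vector(ops$div_v %*% hf))
  Psi_v <- solve_poisson(ops$L_T, ops$M_V, as.vector(ops$CURL_v %*% hf))
  h_par <- as.vector(ops$grad_c %*% psi_c + ops$tCURL_v %*% Psi_v)
  h_perp <- as.vector(ops$tgrad_v %*% psi_v + ops$CURL_c %*% Psi_c)
  resid <- sqrt(sum((h_par + h_perp - hf)^2)) /
    max(sqrt(sum(hf^2)), .Machine$double.eps)
  if (resid > tol)
    stop_bad_arg("dual Helmholtz reconstruction failed (relative residual ",
                 format(resid, digits = 4), ")")
  structure(list(psi_c = psi_c, Psi_c = Psi_c,
                 psi_v = as.vector(psi_v), Psi_v = as.vector(Psi_v),
                 h_par = h_par, h_perp = h_perp,
                 network = "dual", residual = resid),
            class = "vm_potentials")
}

#' @export
print.vm_potentials <- function(x, ...) {
  cat("<vm_potentials> (", x$network, " network), reconstruction residual ",
      format(x$residual, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Spectral coefficients of a scalar potential
#'
#' Projects a potential onto the M-orthonormal eigenmodes of a Laplacian
#' basis; by Parseval the squared coefficients sum to the M-weighted squared
#' norm of the field.
#'
#' @param potential numeric vector (a cell or vertex scalar field).
#' @param basis a `vm_spectrum` from [eigenbasis()] on the matching space.
#' @return numeric vector of coefficients, one per mode, with attribute
#'   `"eigenvalues"`.
#' @export
spectrum <- function(potential, basis) {
  if (length(potential) != nrow(basis$modes))
    stop_bad_arg("potential length ", length(potential),
                 " does not match basis dimension ", nrow(basis$modes))
  d <- Matrix::diag(basis$M)
  co <- as.vector(crossprod(basis$modes, d * potential))
  attr(co, "eigenvalues") <- basis$values
  co
}
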