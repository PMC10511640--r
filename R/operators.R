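# The sixteen discrete operators, inner products and scalar Laplacians.

## build a (2*Ne x N) matrix whose row pair (2j-1, 2j) holds per-(j, col)
## vector weights
vecmat <- function(j, col, wx, wy, ne, n) {
  Matrix::sparseMatrix(i = c(2 * j - 1, 2 * j), j = c(col, col),
                       x = c(wx, wy), dims = c(2 * ne, n))
}
## build an (N x 2*Ne) matrix taking per-(row, j) dot products
dotmat <- function(row, j, wx, wy, n, ne) {
  Matrix::sparseMatrix(i = c(row, row), j = c(2 * j - 1, 2 * j),
                       x = c(wx, wy), dims = c(n, 2 * ne))
}

#' Assemble the discrete operator set of a monolayer
#'
#' Builds, as explicit sparse matrices, the eight primary and eight derived
#' (tilde) discrete operators acting between scalar fields on vertices
#' (`V`), cells (`F`/`C`) and per-edge 2-vectors (`E`/`L`, stored flat with
#' interleaved components), the three inner-product weights, and the four
#' scalar Laplacians
#' `L_V = E^-1 A' T_e^-1 A`, `L_T = E^-1 A' T_l A`,
#' `L_F = H^-1 B I_b T_e B'`, `L_C = H^-1 B I_b T_l^-1 B'`.
#' The unmasked (invertible) cell Laplacians `L_F_full`, `L_C_full` (without
#' the peripheral-link mask `I_b`) are also provided; they are the exact
#' operator compositions `-div^c o tgrad^c` and `-tdiv^c o grad^c` and are the
#' ones used by the Helmholtz decomposition.
#'
#' Kite-corrected variants `CURL_v_kite`, `div_v_kite`, `tCURL_v_kite`,
#' `tgrad_v_kite` replace the link `A_jk T_j` by the dual-face boundary side
#' sums of the geometry, making vertex divergence/circulation measures exact
#' at peripheral vertices (they agree with the plain operators at internal
#' vertices).
#'
#' @param geom a `vm_geometry` (orientation constraint `F_j > 0` already
#'   enforced there).
#' @return An object of class `vm_operators` containing the operator matrices
#'   (`grad_v`, `curl_v`, `curl_c`, `div_c`, `grad_c`, `CURL_c`, `CURL_v`,
#'   `div_v`, tilde variants prefixed `t`, and the kite variants), metric
#'   matrices `H`, `E`, `T_e`, `T_l`, mask `I_b`, Laplacians, and inner
#'   products `M_V`, `M_E`, `M_F`.
#' @export
build_operators <- function(geom) {
  topo <- geom$topology
  nc <- topo$n_cells; ne <- topo$n_edges; nv <- topo$n_vertices
  tA <- Matrix::summary(topo$A)
  tB <- Matrix::summary(topo$B)
  tvec <- geom$t; Tvec <- geom$T
  tl <- geom$t_len; Tl <- geom$T_len; Fj <- geom$F
  eps_t <- rot_cw(tvec); eps_T <- rot_cw(Tvec)
  Ai <- geom$A; Ek <- geom$E
  jA <- tA$i; kA <- tA$j; sA <- tA$x
  iB <- tB$i; jB <- tB$j; sB <- tB$x

  grad_v <- vecmat(jA, kA, sA * tvec[jA, 1] / tl[jA]^2,
                   sA * tvec[jA, 2] / tl[jA]^2, ne, nv)
  curl_v <- vecmat(jA, kA, sA * eps_t[jA, 1] / tl[jA]^2,
                   sA * eps_t[jA, 2] / tl[jA]^2, ne, nv)
  CURL_v <- dotmat(kA, jA, sA * Tvec[jA, 1] / Ek[kA],
                   sA * Tvec[jA, 2] / Ek[kA], nv, ne)
  div_v <- dotmat(kA, jA, -sA * eps_T[jA, 1] / Ek[kA],
                  -sA * eps_T[jA, 2] / Ek[kA], nv, ne)
  grad_c <- vecmat(jB, iB, sB * Tvec[jB, 1] / Tl[jB]^2,
                   sB * Tvec[jB, 2] / Tl[jB]^2, ne, nc)
  ## eps_i = -eps on cells, eps_k = +eps on triangles
  CURL_c <- vecmat(jB, iB, -sB * eps_T[jB, 1] / Tl[jB]^2,
                   -sB * eps_T[jB, 2] / Tl[jB]^2, ne, nc)
  curl_c <- dotmat(iB, jB, sB * tvec[jB, 1] / Ai[iB],
                   sB * tvec[jB, 2] / Ai[iB], nc, ne)
  div_c <- dotmat(iB, jB, sB * eps_t[jB, 1] / Ai[iB],
                  sB * eps_t[jB, 2] / Ai[iB], nc, ne)

  tCURL_v <- vecmat(jA, kA, sA * Tvec[jA, 1] / Fj[jA],
                    sA * Tvec[jA, 2] / Fj[jA], ne, nv)
  tgrad_v <- vecmat(jA, kA, sA * eps_T[jA, 1] / Fj[jA],
                    sA * eps_T[jA, 2] / Fj[jA], ne, nv)
  tdiv_c <- dotmat(iB, jB, -sB * Fj[jB] * Tvec[jB, 1] / Tl[jB]^2 / Ai[iB],
                   -sB * Fj[jB] * Tvec[jB, 2] / Tl[jB]^2 / Ai[iB], nc, ne)
  tCURL_c <- dotmat(iB, jB, -sB * Fj[jB] * eps_T[jB, 1] / Tl[jB]^2 / Ai[iB],
                    -sB * Fj[jB] * eps_T[jB, 2] / Tl[jB]^2 / Ai[iB], nc, ne)
  tcurl_c <- vecmat(jB, iB, sB * tvec[jB, 1] / Fj[jB],
                    sB * tvec[jB, 2] / Fj[jB], ne, nc)
  tgrad_c <- vecmat(jB, iB, -sB * eps_t[jB, 1] / Fj[jB],
                    -sB * eps_t[jB, 2] / Fj[jB], ne, nc)
  tdiv_v <- dotmat(kA, jA, -sA * Fj[jA] * tvec[jA, 1] / tl[jA]^2 / Ek[kA],
                   -sA * Fj[jA] * tvec[jA, 2] / tl[jA]^2 / Ek[kA], nv, ne)
  tcurl_v <- dotmat(kA, jA, sA * Fj[jA] * eps_t[jA, 1] / tl[jA]^2 / Ek[kA],
                    sA * Fj[jA] * eps_t[jA, 2] / tl[jA]^2 / Ek[kA], nv, ne)

  ## kite-corrected vertex operators from the dual-face side sums
  S <- geom$S
  eSx <- S$y; eSy <- -S$x                       # eps * S
  CURL_v_kite <- dotmat(S$k, S$j, S$x / Ek[S$k], S$y / Ek[S$k], nv, ne)
  div_v_kite <- dotmat(S$k, S$j, -eSx / Ek[S$k], -eSy / Ek[S$k], nv, ne)
  tCURL_v_kite <- vecmat(S$j, S$k, S$x / Fj[S$j], S$y / Fj[S$j], ne, nv)
  tgrad_v_kite <- vecmat(S$j, S$k, eSx / Fj[S$j], eSy / Fj[S$j], ne, nv)

  mm <- metric_matrices(geom)
  Ib <- topo$I_b
  tAm <- Matrix::t(topo$A); tBm <- Matrix::t(topo$B)
  L_V <- Matrix::Diagonal(nv, 1 / Ek) %*% tAm %*%
    Matrix::Diagonal(ne, Fj / tl^2) %*% topo$A
  L_T <- Matrix::Diagonal(nv, 1 / Ek) %*% tAm %*% mm$T_l %*% topo$A
  L_F_full <- Matrix::Diagonal(nc, 1 / Ai) %*% topo$B %*% mm$T_e %*% tBm
  L_C_full <- Matrix::Diagonal(nc, 1 / Ai) %*% topo$B %*%
    Matrix::Diagonal(ne, Fj / Tl^2) %*% tBm
  L_F <- Matrix::Diagonal(nc, 1 / Ai) %*% topo$B %*% Ib %*% mm$T_e %*% tBm
  L_C <- Matrix::Diagonal(nc, 1 / Ai) %*% topo$B %*% Ib %*%
    Matrix::Diagonal(ne, Fj / Tl^2) %*% tBm

  structure(list(
    geometry = geom, topology = topo,
    grad_v = grad_v, curl_v = curl_v, CURL_v = CURL_v, div_v = div_v,
    grad_c = grad_c, CURL_c = CURL_c, curl_c = curl_c, div_c = div_c,
    tCURL_v = tCURL_v, tgrad_v = tgrad_v, tdiv_c = tdiv_c, tCURL_c = tCURL_c,
    tcurl_c = tcurl_c, tgrad_c = tgrad_c, tdiv_v = tdiv_v, tcurl_v = tcurl_v,
    CURL_v_kite = CURL_v_kite, div_v_kite = div_v_kite,
    tCURL_v_kite = tCURL_v_kite, tgrad_v_kite = tgrad_v_kite,
    H = mm$H, E = mm$E, T_e = mm$T_e, T_l = mm$T_l, I_b = Ib,
    L_V = L_V, L_T = L_T, L_F = L_F, L_C = L_C,
    L_F_full = L_F_full, L_C_full = L_C_full,
    M_V = mm$E, M_F = mm$H,
    M_E = Matrix::Diagonal(2 * ne, rep(Fj, each = 2))
  ), class = "vm_operators")
}

#' Inner-product matrices
#'
#' The diagonal weights under which the operator pairs are adjoint and the
#' Laplacians self-adjoint: `M_V = diag(E_k)` on vertex (and triangle)
#' scalars, `M_F = diag(A_i)` on cell scalars, and
#' `M_E = diag(F_j) (x) I_2` on per-edge vectors. With these,
#' `[1, f]_F = sum_i A_i f_i` and `[1, phi]_V = sum_k E_k phi_k` are the
#' area-weighted integrals used in the solvability conditions, and
#' `[1,1] = total area` on both networks.
#'
#' @param x a `vm_geometry` or `vm_operators`.
#' @return list with `M_V`, `M_E`, `M_F`.
#' @export
inner_products <- function(x) {
  if (inherits(x, "vm_operators"))
    return(list(M_V = x$M_V, M_E = x$M_E, M_F = x$M_F))
  mm <- metric_matrices(x)
  list(M_V = mm$E,
       M_E = Matrix::Diagonal(2 * length(x$F), rep(x$F, each = 2)),
       M_F = mm$H)
}

#' Verify operator adjointness under the inner products
#'
#' For each of the eight primary/derived operator pairs, draws random field
#' pairs and compares `<P x, y>_target` with `s <x, D y>_source`, where the
#' sign `s` is `-1` for gradient/divergence pairs (as in the continuum) and
#' `+1` for the curl pairs. The two kite-corrected vertex pairs are checked
#' as well.
#'
#' @param ops a `vm_operators`.
#' @param n number of random field pairs per operator pair.
#' @param seed RNG seed for the random fields.
#' @param tol residual threshold for flagging a failure.
#' @return data.frame with one row per pair: `pair`, `sign`, `residual`,
#'   `ok`. An attribute `"max_residual"` carries the overall maximum.
#' @export
verify_adjointness <- function(ops, n = 50, seed = 1, tol = 1e-10) {
  set.seed(seed)
  nc <- ops$topology$n_cells; ne <- ops$topology$n_edges
  nv <- ops$topology$n_vertices
  dV <- Matrix::diag(ops$M_V); dE <- Matrix::diag(ops$M_E); dF <- Matrix::diag(ops$M_F)
  pairs <- list(
    list("grad_v ~ tdiv_v", ops$grad_v, ops$tdiv_v, nv, dV, -1),
    list("curl_v ~ tcurl_v", ops$curl_v, ops$tcurl_v, nv, dV, +1),
    list("grad_c ~ tdiv_c", ops$grad_c, ops$tdiv_c, nc, dF, -1),
    list("CURL_c ~ tCURL_c", ops$CURL_c, ops$tCURL_c, nc, dF, +1),
    list("tgrad_v ~ div_v", ops$tgrad_v, ops$div_v, nv, dV, -1),
    list("tCURL_v ~ CURL_v", ops$tCURL_v, ops$CURL_v, nv, dV, +1),
    list("tgrad_c ~ div_c", ops$tgrad_c, ops$div_c, nc, dF, -1),
    list("tcurl_c ~ curl_c", ops$tcurl_c, ops$curl_c, nc, dF, +1),
    list("tgrad_v_kite ~ div_v_kite", ops$tgrad_v_kite, ops$div_v_kite, nv, dV, -1),
    list("tCURL_v_kite ~ CURL_v_kite", ops$tCURL_v_kite, ops$CURL_v_kite, nv, dV, +1))
  res <- vapply(pairs, function(p) {
    up <- p[[2]]; down <- p[[3]]; nsc <- p[[4]]; Ms <- p[[5]]; sgn <- p[[6]]
    worst <- 0
    for (r in seq_len(n)) {
      x <- stats::rnorm(nsc); y <- stats::rnorm(2 * ne)
      lhs <- sum((up %*% x) * dE * y)           # <up x, y>_E
      rhs <- sgn * sum(x * Ms * (down %*% y))   # s <x, down y>_scalar
      worst <- max(worst, abs(lhs - rhs))
    }
    worst
  }, 0)
  out <- data.frame(pair = vapply(pairs, `[[`, "", 1),
                    sign = vapply(pairs, function(p) p[[6]], 0),
                    residual = res, ok = res <= tol)
  attr(out, "max_residual") <- max(res)
  out
}

#' @export
print.vm_operators <- function(x, ...) {
  cat("<vm_operators> 16 discrete operators + kite variants on ",
      x$topology$n_cells, " cells / ", x$topology$n_edges, " edges / ",
      x$topology$n_vertices, " vertices\n", sep = "")
  invisible(x)
}

#' Export an operator as coordinate-format sparse text
#'
#' @param ops a `vm_operators`.
#' @param name operator field name (e.g. `"grad_v"`, `"L_V"`).
#' @param file path of the text file to write (row, col, value triplets).
#' @return invisibly, `file`.
#' @export
export_operator <- function(ops, name, file) {
  M <- ops[[name]]
  if (is.null(M)) stop_bad_arg("unknown operator: ", name)
  s <- Matrix::summary(methods::as(M, "TsparseMatrix"))
  utils::write.table(data.frame(row = s$i, col = s$j, value = s$x), file,
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
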