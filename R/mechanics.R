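# Constitutive model, vertex forces, force potential, stresses and couples.

#' Energy parameters of the vertex model
#'
#' The per-cell mechanical energy is
#' `U(A_i, L_i) = (A_i - 1)^2 / 2 + Gamma (L_i - L0)^2 / 2`,
#' with cell pressure `P_i = A_i - 1` and tension `T_i = Gamma (L_i - L0)`.
#' The monolayer energy adds the external-pressure work `P_ext * Area`.
#' Defaults put the monolayer in the jammed (solid) regime.
#'
#' @param Gamma perimeter stiffness (dimensionless, > 0).
#' @param L0 target perimeter.
#' @param P_ext external pressure applied at the monolayer periphery.
#' @param eta vertex drag coefficient (> 0), absorbing the time unit of the
#'   overdamped dynamics.
#' @return list of class `vm_params`.
#' @export
energy_params <- function(Gamma = 0.2, L0 = 0.75, P_ext = 0.2, eta = 1) {
  if (Gamma <= 0 || eta <= 0) stop_bad_arg("Gamma and eta must be positive")
  structure(list(Gamma = Gamma, L0 = L0, P_ext = P_ext, eta = eta),
            class = "vm_params")
}

## fast area/perimeter evaluation used in the relaxation inner loop
cell_AL <- function(topo, pos) {
  xt <- pos[topo$edge_tail, 1]; yt <- pos[topo$edge_tail, 2]
  xh <- pos[topo$edge_head, 1]; yh <- pos[topo$edge_head, 2]
  cr <- xt * yh - xh * yt
  tlen <- sqrt((xh - xt)^2 + (yh - yt)^2)
  list(A = as.vector(topo$B %*% cr) / 2,
       L = as.vector(topo$Bbar %*% tlen),
       tvec = cbind(xh - xt, yh - yt), tlen = tlen)
}

energy_AL <- function(A, L, params) {
  U <- 0.5 * (A - 1)^2 + 0.5 * params$Gamma * (L - params$L0)^2
  list(U = U, total = sum(U) + params$P_ext * sum(A),
       P = A - 1, Tn = params$Gamma * (L - params$L0))
}

#' Cell energies, pressures and tensions
#'
#' @param geom a `vm_geometry`.
#' @param params a `vm_params`.
#' @return list: per-cell energy `U`, total energy `total` (including the
#'   `P_ext * Area` work term), cell pressures `P = A - 1` and tensions
#'   `Tn = Gamma (L - L0)`.
#' @export
cell_energy <- function(geom, params = energy_params()) {
  energy_AL(geom$A, geom$L, params)
}

dyn_context <- function(topo) {
  list(tA = Matrix::t(topo$A), tAbar = Matrix::t(topo$Abar),
       tB = Matrix::t(topo$B), tBbar = Matrix::t(topo$Bbar))
}

## net force on each vertex, -d(total energy)/dr_k, as an Nv x 2 matrix
vertex_resultants <- function(topo, pos, params, ctx = dyn_context(topo)) {
  g <- cell_AL(topo, pos)
  en <- energy_AL(g$A, g$L, params)
  a_j <- as.vector(ctx$tB %*% (en$P + params$P_ext))
  b_j <- as.vector(ctx$tBbar %*% en$Tn)
  eps_t <- rot_cw(g$tvec)
  that <- g$tvec / g$tlen
  area_part <- -0.5 * as.matrix(ctx$tAbar %*% (eps_t * a_j))
  per_part <- -as.matrix(ctx$tA %*% (that * b_j))
  list(force = area_part + per_part, energy = en$total,
       A = g$A, L = g$L, P = en$P, Tn = en$Tn)
}

#' Per-(cell, vertex) forces and vertex resultants
#'
#' Computes `f_ik`, the force cell `i` exerts on vertex `k`, as minus the
#' gradient of the cell's energy with respect to the vertex position, built
#' from `dA_i/dr_k = (1/2) sum_j Abar_jk n_ij` and
#' `dL_i/dr_k = sum_j Bbar_ij A_jk t_hat_j`. Two variants are returned: the
#' full force (including each cell's share of the external-pressure work,
#' which cancels at internal vertices and loads the periphery) drives the
#' dynamics and vanishes per vertex at equilibrium; the elastic-only force
#' (gradient of `U_i` alone) is the force whose rotated network defines the
#' force potential and the stress tensors. Both close around every cell
#' identically.
#'
#' @param geom a `vm_geometry`.
#' @param params a `vm_params`.
#' @return list of class `vm_forces`: `pairs` (the (i, k, jin, jout) table),
#'   `f_full` and `f_elastic` (rows matching `pairs`), vertex `resultant`
#'   (Nv x 2, sum of full forces), `P`, `Tn`, `max_resultant`.
#' @export
vertex_forces <- function(geom, params = energy_params()) {
  topo <- geom$topology
  pt <- pair_table(topo)
  en <- energy_AL(geom$A, geom$L, params)
  eps_t <- rot_cw(geom$t)
  that <- geom$t / geom$t_len
  Bs <- as.matrix(topo$B); As <- as.matrix(topo$A)
  b_in <- Bs[cbind(pt$i, pt$jin)]; b_out <- Bs[cbind(pt$i, pt$jout)]
  darea <- 0.5 * (eps_t[pt$jin, , drop = FALSE] * b_in +
                  eps_t[pt$jout, , drop = FALSE] * b_out)
  dper <- that[pt$jin, , drop = FALSE] * As[cbind(pt$jin, pt$k)] +
          that[pt$jout, , drop = FALSE] * As[cbind(pt$jout, pt$k)]
  f_el <- -en$P[pt$i] * darea - en$Tn[pt$i] * dper
  f_full <- f_el - params$P_ext * darea
  resultant <- matrix(0, topo$n_vertices, 2)
  resultant[, 1] <- rowsum(f_full[, 1], pt$k)[, 1]
  resultant[, 2] <- rowsum(f_full[, 2], pt$k)[, 1]
  structure(list(pairs = pt, f_full = f_full, f_elastic = f_el,
                 resultant = resultant, P = en$P, Tn = en$Tn,
                 energy = en$total,
                 max_resultant = max(sqrt(rowSums(resultant^2)))),
            class = "vm_forces")
}

#' Force potential of the rotated force network
#'
#' Integrates the pi/2-rotated elastic forces over a spanning tree of the
#' edge-adjacency graph (edges adjacent when they share a vertex and a cell)
#' to obtain the per-edge vector potential `h_j` — the vertices of the
#' Maxwell-Cremona force tiling — satisfying
#' `f_ik = -sum_j eps_i B_ij h_j A_jk`. At equilibrium every independent
#' cycle of the graph closes; the residual over all (cell, vertex) pairs is
#' checked and the operation refuses a non-equilibrium state.
#'
#' The additive gauge constant is anchored so that `h + P_ext m` has zero mean
#' over peripheral edges (the rotated peripheral force loop then traces
#' `-P_ext` times the periphery); all derived stresses are gauge-invariant.
#'
#' @param geom a `vm_geometry`.
#' @param params a `vm_params`.
#' @param forces optionally, a precomputed [vertex_forces()] result.
#' @param tol closure tolerance, relative to the typical force magnitude.
#' @return list of class `vm_hfield`: `h` (`n_edges` x 2), `residual`
#'   (worst constraint violation), `forces`.
#' @export
force_potential <- function(geom, params = energy_params(), forces = NULL,
                            tol = 1e-8) {
  topo <- geom$topology
  fo <- forces %||% vertex_forces(geom, params)
  pt <- fo$pairs
  Bs <- as.matrix(topo$B); As <- as.matrix(topo$A)
  s_in <- Bs[cbind(pt$i, pt$jin)] * As[cbind(pt$jin, pt$k)]
  s_out <- Bs[cbind(pt$i, pt$jout)] * As[cbind(pt$jout, pt$k)]
  stopifnot(all(s_in + s_out == 0))
  ## constraint per (i,k): h_jin - h_jout = -s_in * (eps f_ik)
  d <- -s_in * rot_cw(fo$f_elastic)
  ne <- topo$n_edges
  adj <- vector("list", ne)
  for (r in seq_len(pt$n)) {
    adj[[pt$jin[r]]] <- c(adj[[pt$jin[r]]], r)
    adj[[pt$jout[r]]] <- c(adj[[pt$jout[r]]], r)
  }
  h <- matrix(NA_real_, ne, 2)
  h[1, ] <- 0
  queue <- 1L
  while (length(queue)) {
    j <- queue[1]; queue <- queue[-1]
    for (r in adj[[j]]) {
      j2 <- if (pt$jin[r] == j) pt$jout[r] else pt$jin[r]
      if (is.na(h[j2, 1])) {
        h[j2, ] <- if (pt$jin[r] == j2) h[pt$jout[r], ] + d[r, ]
                   else h[pt$jin[r], ] - d[r, ]
        queue <- c(queue, j2)
      }
    }
  }
  if (anyNA(h)) stop_bad_arg("edge-adjacency graph not connected")
  resid <- max(abs(h[pt$jin, , drop = FALSE] - h[pt$jout, , drop = FALSE] - d))
  scale <- max(1, max(abs(fo$f_elastic)))
  if (resid > tol * scale)
    stop_bad_arg("force network does not close (worst cycle residual ",
                 format(resid, digits = 4),
                 "): monolayer is not in equilibrium")
  pj <- topo$edge_periph
  shift <- colMeans(h[pj, , drop = FALSE] + params$P_ext * geom$m[pj, , drop = FALSE])
  h <- sweep(h, 2, shift)
  structure(list(h = h, residual = resid, forces = fo), class = "vm_hfield")
}

## accumulate sum over rows of outer(a_r, b_r) grouped by index g
outer_by <- function(g, a, b, nlev) {
  out <- array(0, c(nlev, 2, 2))
  out[, 1, 1] <- rowsum_vec(a[, 1] * b[, 1], g, nlev)
  out[, 1, 2] <- rowsum_vec(a[, 1] * b[, 2], g, nlev)
  out[, 2, 1] <- rowsum_vec(a[, 2] * b[, 1], g, nlev)
  out[, 2, 2] <- rowsum_vec(a[, 2] * b[, 2], g, nlev)
  out
}
rowsum_vec <- function(x, g, nlev) {
  out <- numeric(nlev)
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

#' Force stresses, effective pressures and antisymmetric parts
#'
#' Computes the cell stress `sigma_c` (first moment of the elastic vertex
#' forces; equivalently `B (t (x) h) eps_i / A`) and the tricellular-junction
#' (triangle) stress `sigma_v` (moment of forces about cell centres;
#' equivalently the dual-face form built from `h`, with the kite-corrected
#' side sums on the periphery). Effective pressures are half-traces and, via
#' the operators, `-div_c h / 2` and `-div_v_kite h / 2`. The package uses the
#' compression-positive sign convention: the area-weighted mean of `P_eff`
#' equals `+P_ext` at equilibrium and `sum_i A_i sigma_c_i = +P_ext Area I`.
#'
#' At equilibrium the cell stress is symmetric (`curl_c h = 0` to numerical
#' tolerance) while the triangle stress is generically asymmetric; the
#' antisymmetric scalars returned are `a` such that the antisymmetric part is
#' `a * eps` (so `a_v = CURL_v_kite h / 2`).
#'
#' @param geom a `vm_geometry`.
#' @param params a `vm_params`.
#' @param hfield optionally a precomputed [force_potential()] result.
#' @param ops optionally a precomputed [build_operators()] result.
#' @return list of class `vm_stress`: arrays `sigma_c`, `sigma_v`
#'   (n x 2 x 2, h-based), `sigma_c_moment`, `sigma_v_moment` (moment forms;
#'   the triangle moment form uses the full forces so that it is
#'   origin-invariant at the periphery), `P_eff_c`, `P_eff_v`, antisymmetric
#'   scalars `antisym_c`, `antisym_v`, and `hfield`.
#' @export
stresses <- function(geom, params = energy_params(), hfield = NULL, ops = NULL) {
  topo <- geom$topology
  hf <- hfield %||% force_potential(geom, params)
  O <- ops %||% build_operators(geom)
  fo <- hf$forces
  pt <- fo$pairs
  h <- hf$h
  hflat <- as_edge_flat(h)

  ## cell stress: moment of elastic forces; h-form +B (t x h) eps_i
  rk <- geom$positions[pt$k, , drop = FALSE]
  sig_c_mom <- outer_by(pt$i, rk, fo$f_elastic, topo$n_cells)
  sB <- Matrix::summary(topo$B)
  tx <- geom$t[sB$j, , drop = FALSE]
  hx <- h[sB$j, , drop = FALSE]
  M <- outer_by(sB$i, tx * sB$x, hx, topo$n_cells)
  ## right-multiply each 2x2 slice by eps_i = -EPS_CW: (a b; c d)(0 -1; 1 0)
  sig_c <- array(c(M[, 1, 2], M[, 2, 2], -M[, 1, 1], -M[, 2, 1]),
                 c(topo$n_cells, 2, 2))
  sig_c <- sweep(sig_c, 1, geom$A, "/")
  sig_c_mom <- sweep(sig_c_mom, 1, geom$A, "/")

  ## triangle stress, h-form with kite side sums: + (S x h) eps_k
  S <- geom$S
  Sv <- cbind(S$x, S$y)
  hS <- h[S$j, , drop = FALSE]
  Mv <- outer_by(S$k, Sv, hS, topo$n_vertices)
  ## right-multiply by eps_k = +EPS_CW: (a b; c d)(0 1; -1 0) = (-b a; -d c)
  sig_v <- array(c(-Mv[, 1, 2], -Mv[, 2, 2], Mv[, 1, 1], Mv[, 2, 1]),
                 c(topo$n_vertices, 2, 2))
  sig_v <- sweep(sig_v, 1, geom$E, "/")
  ## moment form about cell centres (exact at internal vertices; at
  ## peripheral vertices the elastic forces do not balance, so the moment is
  ## origin-dependent there and the kite h-form is the defined quantity)
  Ri <- geom$R[pt$i, , drop = FALSE]
  sig_v_mom <- -outer_by(pt$k, Ri, fo$f_elastic, topo$n_vertices)
  sig_v_mom <- sweep(sig_v_mom, 1, geom$E, "/")

  P_eff_c <- -0.5 * as.vector(O$div_c %*% hflat)
  P_eff_v <- -0.5 * as.vector(O$div_v_kite %*% hflat)
  antisym_c <- 0.5 * as.vector(O$curl_c %*% hflat)
  antisym_v <- 0.5 * as.vector(O$CURL_v_kite %*% hflat)

  structure(list(sigma_c = sig_c, sigma_c_moment = sig_c_mom,
                 sigma_v = sig_v, sigma_v_moment = sig_v_mom,
                 P_eff_c = P_eff_c, P_eff_v = P_eff_v,
                 antisym_c = antisym_c, antisym_v = antisym_v,
                 hfield = hf), class = "vm_stress")
}

#' Affine (virtual-work) cell stress
#'
#' The stress conjugate to a uniform virtual strain: in the package's
#' compression-positive convention
#' `varsigma_i = -(P_i I + (T_i L_i / A_i) Q_i)`, with the shape tensor
#' `L_i Q_i = sum_j Bbar_ij t_j (x) t_hat_j` (so `Tr Q_i = 1`). At equilibrium
#' it equals the force stress `sigma_c` exactly, and its half-trace gives
#' `P_eff_i = -(P_i + T_i L_i / 2 A_i)`.
#'
#' @param geom a `vm_geometry`.
#' @param params a `vm_params`.
#' @return list: `Q` (n_cells x 2 x 2), `varsigma` (n_cells x 2 x 2),
#'   `P_eff` (affine effective pressures).
#' @export
affine_stress <- function(geom, params = energy_params()) {
  topo <- geom$topology
  en <- energy_AL(geom$A, geom$L, params)
  sB <- Matrix::summary(topo$Bbar)
  tx <- geom$t[sB$j, , drop = FALSE]
  th <- tx / geom$t_len[sB$j]
  Q <- outer_by(sB$i, tx, th, topo$n_cells)
  Q <- sweep(Q, 1, geom$L, "/")
  vs <- array(0, c(topo$n_cells, 2, 2))
  fac <- en$Tn * geom$L / geom$A
  vs[, 1, 1] <- -(en$P + fac * Q[, 1, 1])
  vs[, 1, 2] <- -fac * Q[, 1, 2]
  vs[, 2, 1] <- -fac * Q[, 2, 1]
  vs[, 2, 2] <- -(en$P + fac * Q[, 2, 2])
  list(Q = Q, varsigma = vs, P_eff = -(en$P + en$Tn * geom$L / (2 * geom$A)))
}

#' Scalar stress potentials (discrete Airy and Mindlin functions)
#'
#' Solves the Poisson problems for the seven nonzero scalar potentials of the
#' equilibrium force potential `h`, with the couple-free specialisation
#' `Psi_c = 0` (verified through `curl_c h ~ 0`). The face/triangle problems
#' use the corrected field `h_breve = h + P_ext m`, whose divergences have
#' zero area-weighted mean (the solvability condition); `psi_v`, `Psi_v`
#' right-hand sides are solvable automatically. All singular solves are
#' gauged to zero M-weighted mean.
#'
#' @param ops a `vm_operators`.
#' @param params a `vm_params`.
#' @param hfield optionally a precomputed [force_potential()] result.
#' @param tol solvability tolerance relative to `max(1, |h|)`.
#' @return list of class `vm_stress_potentials`: primal `psi_c`, `psi_v`,
#'   `Psi_v` (`Psi_c` identically zero), dual `psi_c_dual` (`check psi^c`),
#'   `psi_v_dual`, `Psi_v_dual`, `Psi_c_dual`, the corrected field `h_breve`
#'   (flat), and `solvability` (the four area-weighted integrals).
#' @export
stress_potentials <- function(ops, params = energy_params(), hfield = NULL,
                              tol = 1e-6) {
  geom <- ops$geometry
  hf <- hfield %||% force_potential(geom, params)
  h <- as_edge_flat(hf$h)
  hb <- h + params$P_ext * as_edge_flat(geom$m)
  dA <- Matrix::diag(ops$M_F); dE <- Matrix::diag(ops$M_V)
  solv <- c(
    div_c = sum(dA * as.vector(ops$div_c %*% hb)),
    div_v = sum(dE * as.vector(ops$div_v_kite %*% hb)),
    curl_c = sum(dA * as.vector(ops$curl_c %*% h)),
    CURL_v = sum(dE * as.vector(ops$CURL_v_kite %*% h)))
  scale <- max(1, max(abs(h)))
  if (max(abs(solv[c("div_c", "div_v")])) > tol * scale)
    stop_bad_arg("solvability violated: area-weighted divergence integrals = ",
                 paste(format(solv[1:2], digits = 4), collapse = ", "))
  psi_c <- solve_poisson(ops$L_F, ops$M_F, -as.vector(ops$div_c %*% hb))
  psi_v <- solve_poisson(ops$L_V, ops$M_V, -as.vector(ops$tdiv_v %*% h))
  Psi_v <- solve_poisson(ops$L_V, ops$M_V, as.vector(ops$tcurl_v %*% h))
  psi_v_dual <- solve_poisson(ops$L_T, ops$M_V, -as.vector(ops$div_v %*% hb))
  Psi_v_dual <- solve_poisson(ops$L_T, ops$M_V, as.vector(ops$CURL_v %*% h))
  ## the dual cell problems have no solvability guarantee under the masked
  ## Laplacian; the unmasked (invertible) form is the exact Helmholtz relation
  psi_c_dual <- solve(as.matrix(ops$L_C_full), -as.vector(ops$tdiv_c %*% hb))
  Psi_c_dual <- solve(as.matrix(ops$L_C_full), as.vector(ops$tCURL_c %*% h))
  structure(list(
    psi_c = as.vector(psi_c), Psi_c = numeric(length(psi_c)),
    psi_v = as.vector(psi_v), Psi_v = as.vector(Psi_v),
    psi_c_dual = as.vector(psi_c_dual), Psi_c_dual = as.vector(Psi_c_dual),
    psi_v_dual = as.vector(psi_v_dual), Psi_v_dual = as.vector(Psi_v_dual),
    h_breve = hb, solvability = solv, hfield = hf
  ), class = "vm_stress_potentials")
}

#' Couple-stress vector and junction torques
#'
#' The couple-stress vector is `mu = -curl_v Psi_v`, normal to every edge
#' (`mu_j . t_j = 0`) and divergence-free over cells (`div_c mu = 0`, an exact
#' operator sequence). Its dual representation
#' `mu_dual = -tCURL_v Psi_v_dual - CURL_c Psi_c_dual` satisfies
#' `CURL_v mu_dual = -L_T Psi_v_dual`, i.e. minus twice the triangle
#' antisymmetric stress measured from `h`.
#'
#' @param ops a `vm_operators`.
#' @param sp a `vm_stress_potentials`.
#' @return list of class `vm_couple`: `mu` (`n_edges` x 2), `mu_dual`,
#'   `torque_v` (`CURL_v_kite h`, the per-junction torque measure) and
#'   `curl_mu_dual` (`CURL_v mu_dual`).
#' @export
couple_stress <- function(ops, sp) {
  mu <- -as.vector(ops$curl_v %*% sp$Psi_v)
  mu_dual <- -as.vector(ops$tCURL_v %*% sp$Psi_v_dual) -
    as.vector(ops$CURL_c %*% sp$Psi_c_dual)
  h <- as_edge_flat(sp$hfield$h)
  structure(list(
    mu = as_edge_matrix(mu), mu_dual = as_edge_matrix(mu_dual),
    torque_v = as.vector(ops$CURL_v_kite %*% h),
    curl_mu_dual = as.vector(ops$CURL_v %*% mu_dual)
  ), class = "vm_couple")
}

#' Affine couple-stress vectors and junction couples
#'
#' Under the affine approximation, in-plane bending (curvature) couples to
#' pressure differences across cell edges. Per cell,
#' `m_c_i = (P_i + P_ext) / (12 A_i) * sum_j t_j^2 n_ij`; repartitioned onto
#' edges, `m_j = t_j^2 / (6 F_j) * sum_i (P_i + P_ext) n_ij`, satisfying the
#' exact identity `sum_i A_i (2 m_c_i . kappa) = sum_j (F_j / 2)(2 m_j . kappa)`
#' for any uniform curvature vector. The junction couple is its circulation,
#' `C_k = CURL_v m = -(1 / 6 E_k) sum_{i,j} P_i B_ij t_j^2 A_jk` at internal
#' vertices: it vanishes for uniform pressures or uniform edge lengths.
#'
#' @param geom a `vm_geometry`.
#' @param params a `vm_params`.
#' @return list of class `vm_affine_couple`: `m_c` (n_cells x 2), `m_e`
#'   (n_edges x 2), `C_k` (length n_vertices; the affine junction couple,
#'   `NA` at peripheral vertices where the affine argument does not apply).
#' @export
affine_couple <- function(geom, params = energy_params()) {
  topo <- geom$topology
  en <- energy_AL(geom$A, geom$L, params)
  sB <- Matrix::summary(topo$B)
  nij <- rot_cw(geom$t[sB$j, , drop = FALSE]) * sB$x   # n_ij = eps B_ij t_j
  w <- geom$t_len[sB$j]^2
  m_c <- cbind(rowsum_vec(w * nij[, 1], sB$i, topo$n_cells),
               rowsum_vec(w * nij[, 2], sB$i, topo$n_cells))
  m_c <- m_c * (en$P + params$P_ext) / (12 * geom$A)
  pf <- en$P[sB$i] + params$P_ext
  m_e <- cbind(rowsum_vec(pf * nij[, 1], sB$j, topo$n_edges),
               rowsum_vec(pf * nij[, 2], sB$j, topo$n_edges))
  m_e <- m_e * geom$t_len^2 / (6 * geom$F)
  ## C_k = CURL^v m at internal vertices (Table-1 form; exact there)
  sA <- Matrix::summary(topo$A)
  dots <- rowSums(geom$T[sA$i, , drop = FALSE] * m_e[sA$i, , drop = FALSE]) * sA$x
  C_k <- rowsum_vec(dots, sA$j, topo$n_vertices) / geom$E
  C_k[topo$vert_periph] <- NA_real_
  structure(list(m_c = m_c, m_e = m_e, C_k = C_k),
            class = "vm_affine_couple")
}
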