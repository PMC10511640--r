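# Metric layer: edges, links, areas, normals, kites, edge-link intersections.

#' Assemble the geometry of a positioned cell complex
#'
#' Computes every metric quantity of the monolayer: edge vectors `t_j` and
#' centroids `c_j`, cell centres `R_i` (plain vertex centroids), dual links
#' `T_j` (connecting the two adjacent cell centres, or a border-cell centre to
#' the peripheral edge centroid), trapezium areas `F_j` (twice the area spanned
#' by an edge and its link; positive by the orientation convention), cell areas
#' `A_i` and perimeters `L_i`, dual-face areas `E_k` (triangle of cell centres
#' at internal vertices; kite polygon at peripheral vertices), kite areas
#' `K_ik`, and the edge-link intersection points `m_j`.
#'
#' If all cells are supplied clockwise the complex is canonicalised by
#' reversing every cell; mixed orientations or nonpositive areas are errors.
#' The global closures `sum A_i = sum F_j / 2 = sum E_k` hold to machine
#' precision by construction.
#'
#' @param topo a `vm_topology`.
#' @param positions numeric `n_vertices` x 2 matrix of vertex coordinates.
#' @return An object of class `vm_geometry` with fields `topology`, `positions`,
#'   `t`, `t_len`, `c`, `R`, `T`, `T_len`, `C_link`, `m`, `F`, `A`, `L`, `E`,
#'   `K` (sparse cells x vertices kite areas), `S` (dual-face side sums, see
#'   Details), and `total_area`.
#' @details `S` stores, for each incident (edge `j`, vertex `k`) pair, the sum
#'   of the clockwise-oriented boundary sides of vertex `k`'s dual face that
#'   lie on the lines of edge `j` or its link. At internal vertices this is
#'   exactly `A_jk T_j`; at peripheral vertices it generalises the link to the
#'   kite-face boundary and yields exact divergence/circulation measures there
#'   (the peripheral-kite operator variants).
#' @export
assemble_geometry <- function(topo, positions) {
  pos <- as.matrix(positions)
  if (nrow(pos) != topo$n_vertices || ncol(pos) != 2)
    stop_bad_arg("positions must be an n_vertices x 2 matrix")
  sa <- vapply(topo$cells, function(v) shoelace(pos[v, , drop = FALSE]), 0)
  if (all(sa < 0)) {
    topo <- build_complex(lapply(topo$cells, rev))
    sa <- -sa
  } else if (any(sa <= 0)) {
    stop_bad_arg("cell(s) with nonpositive signed area: ",
                 paste(which(sa <= 0), collapse = ", "))
  }
  nc <- topo$n_cells; ne <- topo$n_edges; nv <- topo$n_vertices

  tvec <- pos[topo$edge_head, , drop = FALSE] - pos[topo$edge_tail, , drop = FALSE]
  tlen <- sqrt(rowSums(tvec^2))
  if (any(tlen == 0))
    stop_bad_arg("degenerate zero-length edge: ",
                 paste(which(tlen == 0), collapse = ", "))
  cj <- (pos[topo$edge_head, , drop = FALSE] + pos[topo$edge_tail, , drop = FALSE]) / 2
  R <- as.matrix(topo$C %*% pos) / topo$Z
  ## T_j = sum_i B_ij (R_i - c^p_j); the centroid term survives only on the
  ## periphery, where sum_i B_ij = +-1
  bsum <- as.vector(Matrix::t(topo$B) %*% rep(1, nc))
  Tvec <- as.matrix(Matrix::t(topo$B) %*% R) - bsum * cj
  Tlen <- sqrt(rowSums(Tvec^2))
  Fj <- cross2(tvec, Tvec)            # = T_j . (eps_i t_j), eps_i = -eps
  degen <- Fj <= 1e-12 * mean(abs(Fj))
  if (any(degen))
    stop_bad_arg("degenerate edge/link pair (F_j <= 0) at edge(s): ",
                 paste(which(degen), collapse = ", "))

  ## link centroids: midpoint of the link segment
  Cj <- as.matrix(Matrix::t(topo$Bbar) %*% R) / 2
  pj <- topo$edge_periph
  Cj[pj, ] <- Cj[pj, , drop = FALSE] + cj[pj, , drop = FALSE] / 2

  A_i <- sa
  L_i <- as.vector(topo$Bbar %*% tlen)

  ## edge-link intersection m_j (infinite-line intersection)
  alpha <- cross2(Cj - cj, Tvec) / Fj
  m <- cj + alpha * tvec

  ## dual faces: triangle of cell centres at internal k, kite polygon at
  ## peripheral k; store E_k and per-(j,k) clockwise side sums S_jk
  E_k <- numeric(nv)
  Sj <- integer(0); Sk <- integer(0); Sx <- numeric(0); Sy <- numeric(0)
  Asum <- Matrix::summary(topo$A)
  inc_e <- split(Asum$i, Asum$j)               # edges incident to each vertex
  sgnA <- split(Asum$x, Asum$j)
  Csum <- Matrix::summary(topo$C)
  inc_c <- split(Csum$i, Csum$j)

  for (k in seq_len(nv)) {
    js <- inc_e[[as.character(k)]] %||% inc_e[[k]]
    if (!topo$vert_periph[k]) {
      s <- sgnA[[as.character(k)]] %||% sgnA[[k]]
      Nk <- -(rot_cw(Tvec[js, , drop = FALSE]) * s)    # N_jk = -eps_k A_jk T_j
      E_k[k] <- sum(rowSums(Nk * Cj[js, , drop = FALSE])) / 2
      Sj <- c(Sj, js); Sk <- c(Sk, rep.int(k, length(js)))
      Sx <- c(Sx, s * Tvec[js, 1]); Sy <- c(Sy, s * Tvec[js, 2])
    } else {
      face <- peripheral_face(topo, k, js, inc_c[[as.character(k)]] %||% inc_c[[k]])
      poly <- rbind(pos[k, ], cj[face$jA, ], R[face$cells, , drop = FALSE],
                    cj[face$jB, ])
      ar <- shoelace(poly)
      E_k[k] <- abs(ar)
      sgn <- if (ar > 0) -1 else 1       # orient sides clockwise
      side <- (rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE]) - poly) * sgn
      ncell <- length(face$cells)
      ## sides 1,2 belong to edge jA; 2+a to the a-th crossed internal edge;
      ## the last two to edge jB
      ej <- c(face$jA, if (ncell > 1) face$mid, face$jB)
      sx <- c(side[1, 1] + side[2, 1],
              if (ncell > 1) side[2 + seq_len(ncell - 1), 1],
              side[ncell + 2, 1] + side[ncell + 3, 1])
      sy <- c(side[1, 2] + side[2, 2],
              if (ncell > 1) side[2 + seq_len(ncell - 1), 2],
              side[ncell + 2, 2] + side[ncell + 3, 2])
      Sj <- c(Sj, ej); Sk <- c(Sk, rep.int(k, length(ej)))
      Sx <- c(Sx, sx); Sy <- c(Sy, sy)
    }
  }

  ## kite areas K_ik: quadrilateral (R_i, c_in, r_k, c_out)
  pt <- pair_table(topo)
  Kx <- numeric(pt$n)
  for (r in seq_len(pt$n)) {
    q <- rbind(R[pt$i[r], ], cj[pt$jin[r], ], pos[pt$k[r], ], cj[pt$jout[r], ])
    Kx[r] <- abs(shoelace(q))
  }
  K <- Matrix::sparseMatrix(i = pt$i, j = pt$k, x = Kx, dims = c(nc, nv))

  structure(list(
    topology = topo, positions = pos,
    t = tvec, t_len = tlen, c = cj, R = R, T = Tvec, T_len = Tlen,
    C_link = Cj, m = m, F = Fj, A = A_i, L = L_i, E = E_k,
    S = list(j = Sj, k = Sk, x = Sx, y = Sy),
    K = K, total_area = sum(A_i)
  ), class = "vm_geometry")
}

## order the cells around a peripheral vertex by walking from one peripheral
## edge to the other across shared internal edges
peripheral_face <- function(topo, k, js, cs) {
  pj <- js[topo$edge_periph[js]]
  if (length(pj) != 2)
    stop_bad_arg("peripheral vertex ", k, " lacks two peripheral edges")
  jA <- pj[1]
  cell_seq <- which(topo$B[, jA] != 0)
  edge_seq <- jA
  cur <- cell_seq
  repeat {
    ecur <- js[as.logical(topo$Bbar[cur, js])]
    nxt_e <- setdiff(ecur, edge_seq[length(edge_seq)])
    edge_seq <- c(edge_seq, nxt_e)
    if (topo$edge_periph[nxt_e]) break
    cur <- setdiff(which(topo$B[, nxt_e] != 0), cur)
    cell_seq <- c(cell_seq, cur)
  }
  list(jA = jA, jB = edge_seq[length(edge_seq)], cells = cell_seq,
       mid = if (length(edge_seq) > 2) edge_seq[2:(length(edge_seq) - 1)] else integer(0))
}

#' Diagonal metric matrices of a geometry
#'
#' Returns the four positive diagonal matrices built from cell areas, dual-face
#' areas, and edge/link lengths scaled by the trapezium areas:
#' `H = diag(A_i)`, `E = diag(E_k)`, `T_e = diag(t_j^2 / F_j)`,
#' `T_l = diag(T_j^2 / F_j)`.
#'
#' @param geom a `vm_geometry`.
#' @return list with sparse diagonal matrices `H`, `E`, `T_e`, `T_l`.
#' @export
metric_matrices <- function(geom) {
  if (any(geom$A <= 0) || any(geom$E <= 0) || any(geom$F <= 0))
    stop_bad_arg("corrupt geometry: nonpositive metric entry")
  list(H = Matrix::Diagonal(length(geom$A), geom$A),
       E = Matrix::Diagonal(length(geom$E), geom$E),
       T_e = Matrix::Diagonal(length(geom$F), geom$t_len^2 / geom$F),
       T_l = Matrix::Diagonal(length(geom$F), geom$T_len^2 / geom$F))
}

#' Edge-link intersection points
#'
#' The point `m_j` where the (infinite) line through edge `j` meets the line
#' through its dual link. These points satisfy the exact identities
#' `div^c m / 2 = 1` on every cell and, with the peripheral-kite divergence,
#' `div^v m / 2 = 1` on every dual face, which underpin the solvability
#' correction of the stress-potential solves.
#'
#' @param geom a `vm_geometry`.
#' @return numeric `n_edges` x 2 matrix.
#' @export
edge_link_intersections <- function(geom) geom$m

#' @export
print.vm_geometry <- function(x, ...) {
  cat("<vm_geometry> ", x$topology$n_cells, " cells, total area ",
      format(x$total_area, digits = 6), "\n", sep = "")
  cat("  A_i in [", format(min(x$A), digits = 4), ", ",
      format(max(x$A), digits = 4), "]; min F_j ",
      format(min(x$F), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Export per-entity geometry tables
#'
#' @param geom a `vm_geometry`.
#' @param dir directory in which to write `cells.csv` (A, L, Z),
#'   `edges.csv` (t, T, F) and `vertices.csv` (E), keyed by index.
#' @return invisibly, the paths written.
#' @export
export_geometry <- function(geom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  topo <- geom$topology
  paths <- c(
    cells = file.path(dir, "cells.csv"),
    edges = file.path(dir, "edges.csv"),
    vertices = file.path(dir, "vertices.csv"))
  utils::write.csv(data.frame(cell = seq_len(topo$n_cells), A = geom$A,
                              L = geom$L, Z = topo$Z),
                   paths["cells"], row.names = FALSE)
  utils::write.csv(data.frame(edge = seq_len(topo$n_edges), t_len = geom$t_len,
                              T_len = geom$T_len, F = geom$F,
                              peripheral = topo$edge_periph),
                   paths["edges"], row.names = FALSE)
  utils::write.csv(data.frame(vertex = seq_len(topo$n_vertices), E = geom$E,
                              peripheral = topo$vert_periph),
                   paths["vertices"], row.names = FALSE)
  invisible(paths)
}
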