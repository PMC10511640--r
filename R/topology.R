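# Combinatorial cell complex: signed incidence matrices and topological moves.

#' Build the combinatorial cell complex of a monolayer
#'
#' Constructs the signed incidence matrices of a confluent planar monolayer
#' from per-cell, cyclically ordered vertex index lists. Edges are enumerated
#' canonically (sorted vertex pairs in lexicographic order), so rebuilding from
#' the same cell lists yields identical matrices. The edge-to-vertex matrix
#' `A` is signed by the canonical tail-to-head direction (lower to higher
#' vertex index); the cell-to-edge matrix `B` is `+1` where a cell traverses
#' an edge in its canonical direction and `-1` otherwise.
#'
#' Internal vertices must be tricellular: exactly three cells and three edges
#' meet there. Shared edges must appear in exactly two cells with opposite
#' traversal order, and the complex must be simply connected (Euler
#' characteristic `N_c - N_e + N_v = 1`).
#'
#' @param cells list of integer vectors; each is one cell's vertex indices in
#'   cyclic order (all cells consistently oriented).
#' @return An object of class `vm_topology`: counts `n_cells`, `n_edges`,
#'   `n_vertices`; sparse incidence matrices `A` (edges x vertices, entries
#'   -1/0/+1), `B` (cells x edges), their unsigned versions `Abar`, `Bbar`;
#'   the cell-vertex adjacency `C = Bbar Abar / 2`; per-cell edge counts `Z`;
#'   peripheral flags for edges, vertices and cells; the diagonal mask `I_b`
#'   that removes peripheral ("orphan") links; and the input `cells`.
#' @examples
#' topo <- build_complex(list(1:6))          # a single hexagon
#' topo$n_edges                              # 6
#' max(abs(topo$B %*% topo$A))               # 0: the boundary of a boundary
#' @export
build_complex <- function(cells) {
  if (!length(cells)) stop_bad_arg("no cells supplied")
  cells <- lapply(cells, as.integer)
  ids <- sort(unique(unlist(cells)))
  nv <- max(ids)
  if (!identical(ids, seq_len(nv)))
    stop_bad_arg("vertex indices must be 1..N_v without gaps")
  nc <- length(cells)

  ci <- integer(0); lo <- integer(0); hi <- integer(0); csgn <- integer(0)
  for (i in seq_len(nc)) {
    v <- cells[[i]]
    if (length(v) < 3) stop_bad_arg("cell ", i, " has fewer than 3 vertices")
    if (anyDuplicated(v)) stop_bad_arg("cell ", i, " repeats a vertex")
    w <- c(v[-1], v[1])
    ci <- c(ci, rep.int(i, length(v)))
    lo <- c(lo, pmin(v, w)); hi <- c(hi, pmax(v, w))
    csgn <- c(csgn, ifelse(v < w, 1L, -1L))
  }
  ord <- order(lo, hi)
  key <- lo * (nv + 1) + hi
  ukey <- unique(key[ord])
  ne <- length(ukey)
  jidx <- match(key, ukey)
  mult <- tabulate(jidx, ne)
  if (any(mult > 2)) {
    bad <- which(mult > 2)[1]
    stop_bad_arg("non-manifold edge (appears in >2 cells): vertices ",
                 ukey[bad] %/% (nv + 1), "-", ukey[bad] %% (nv + 1))
  }
  if (any(mult == 2)) {
    ssum <- vapply(which(mult == 2), function(j) sum(csgn[jidx == j]), 0L)
    if (any(ssum != 0L))
      stop_bad_arg("shared edge traversed twice in the same direction; ",
                   "cells are not consistently oriented")
  }
  edge_tail <- as.integer(ukey %/% (nv + 1))
  edge_head <- as.integer(ukey %% (nv + 1))

  A <- Matrix::sparseMatrix(i = rep(seq_len(ne), 2L),
                            j = c(edge_tail, edge_head),
                            x = rep(c(-1, 1), each = ne), dims = c(ne, nv))
  B <- Matrix::sparseMatrix(i = ci, j = jidx, x = as.numeric(csgn),
                            dims = c(nc, ne))
  Abar <- abs(A); Bbar <- abs(B)
  C <- Bbar %*% Abar / 2
  Z <- Matrix::rowSums(Bbar)

  edge_periph <- mult == 1L
  vert_periph <- Matrix::colSums(Abar[edge_periph, , drop = FALSE]) > 0
  cell_border <- Matrix::rowSums(B[, edge_periph, drop = FALSE] != 0) > 0
  vdeg <- Matrix::colSums(Abar)
  vcells <- Matrix::colSums(C)
  bad <- which(!vert_periph & (vdeg != 3 | vcells != 3))
  if (length(bad))
    stop_bad_arg("internal vertex not tricellular: ",
                 paste(bad, collapse = ", "))
  if (any(vdeg == 0)) stop_bad_arg("isolated vertex index present")
  euler <- nc - ne + nv
  if (euler != 1L) {
    msg <- if (n_components(C) > 1) "disconnected input" else "not simply connected"
    stop_bad_arg(msg, " (Euler characteristic ", euler, ")")
  }

  structure(list(
    n_cells = nc, n_edges = ne, n_vertices = nv,
    A = A, B = B, Abar = Abar, Bbar = Bbar, C = C, Z = Z,
    edge_tail = edge_tail, edge_head = edge_head,
    edge_periph = edge_periph,
    vert_periph = as.logical(vert_periph),
    cell_border = as.logical(cell_border),
    I_b = Matrix::Diagonal(ne, x = as.numeric(!edge_periph)),
    cells = cells
  ), class = "vm_topology")
}

## number of connected components of the cell adjacency implied by C
n_components <- function(C) {
  nc <- nrow(C)
  ## cells adjacent if they share a vertex
  adj <- Matrix::tcrossprod(C) > 0
  seen <- logical(nc); comp <- 0L
  for (s in seq_len(nc)) {
    if (seen[s]) next
    comp <- comp + 1L
    q <- s
    while (length(q)) {
      i <- q[[1]]; q <- q[-1]
      if (seen[i]) next
      seen[i] <- TRUE
      q <- c(q, which(adj[i, ] & !seen))
    }
  }
  comp
}

#' Diagnostic report on a cell complex
#'
#' Checks every structural invariant of a [build_complex()] topology and
#' reports violations instead of stopping: nonzero entries of `B A`,
#' the `C = Bbar Abar / 2` identity, internal-vertex valence, connectivity and
#' the Euler characteristic.
#'
#' @param topo a `vm_topology` (or a list with compatible fields, so corrupted
#'   objects can be diagnosed).
#' @return character vector of human-readable violations; empty if valid.
#' @export
validate_topology <- function(topo) {
  out <- character(0)
  BA <- topo$B %*% topo$A
  nz <- which(as.matrix(BA) != 0, arr.ind = TRUE)
  if (nrow(nz))
    out <- c(out, sprintf("B.A nonzero at (cell %d, vertex %d): %g",
                          nz[, 1], nz[, 2], as.matrix(BA)[nz]))
  dC <- max(abs(topo$C - topo$Bbar %*% topo$Abar / 2))
  if (dC > 0) out <- c(out, sprintf("C != Bbar Abar / 2 (max dev %g)", dC))
  vdeg <- Matrix::colSums(topo$Abar)
  vcells <- Matrix::colSums(topo$C)
  bad <- which(!topo$vert_periph & (vdeg != 3 | vcells != 3))
  if (length(bad))
    out <- c(out, sprintf("internal vertex %d has %d edges / %d cells",
                          bad, vdeg[bad], vcells[bad]))
  euler <- topo$n_cells - topo$n_edges + topo$n_vertices
  if (euler != 1L) out <- c(out, sprintf("Euler characteristic %d (expected 1)", euler))
  ncomp <- n_components(topo$C)
  if (ncomp != 1L) out <- c(out, sprintf("disconnected: %d components", ncomp))
  out
}

#' @export
print.vm_topology <- function(x, ...) {
  cat("<vm_topology> ", x$n_cells, " cells, ", x$n_edges, " edges, ",
      x$n_vertices, " vertices (Euler ",
      x$n_cells - x$n_edges + x$n_vertices, ")\n", sep = "")
  cat("  peripheral: ", sum(x$edge_periph), " edges, ",
      sum(x$vert_periph), " vertices, ", sum(x$cell_border),
      " border cells\n", sep = "")
  invisible(x)
}

## --- cell division (topological step) ---------------------------------------

## split the cyclic list of cell i between edge positions a and b (edges
## (v[a], v[a+1]) and (v[b], v[b+1])), inserting new vertex ids w1 on the
## first and w2 on the second; neighbours sharing the split edges get the
## new vertex inserted too.  Pure list surgery; validity is re-established by
## build_complex().
split_cell_lists <- function(cells, i, a, b, w1, w2) {
  v <- cells[[i]]; n <- length(v)
  if (a == b) stop_bad_arg("division must bisect two distinct edges")
  if (a > b) { tmp <- a; a <- b; b <- tmp; tmp <- w1; w1 <- w2; w2 <- tmp }
  seg1 <- v[(a + 1):b]
  seg2 <- if (b == n) v[1:a] else c(v[(b + 1):n], v[1:a])
  ea <- c(v[a], v[if (a == n) 1 else a + 1])
  eb <- c(v[b], v[if (b == n) 1 else b + 1])
  ins <- function(cells, u, w, new) {
    for (q in seq_along(cells)) {
      if (q == i) next
      cv <- cells[[q]]; nq <- length(cv)
      for (x in seq_len(nq)) {
        y <- if (x == nq) 1 else x + 1
        if ((cv[x] == u && cv[y] == w) || (cv[x] == w && cv[y] == u)) {
          cells[[q]] <- append(cv, new, after = x)
          return(cells)
        }
      }
    }
    cells
  }
  cells <- ins(cells, ea[1], ea[2], w1)
  cells <- ins(cells, eb[1], eb[2], w2)
  cells[[i]] <- c(w1, seg1, w2)
  cells[[length(cells) + 1]] <- c(w2, seg2, w1)
  cells
}

#' Divide a cell of the complex (topological step)
#'
#' Splits cell `i` by bisecting two of its edges: two new vertices are
#' inserted (one on each edge), joined by a new edge, and the cell is replaced
#' by two daughters. Divisions never pass through existing vertices, so all
#' internal vertices stay tricellular. Counts change by `N_c + 1`,
#' `N_e + 3`, `N_v + 2` and the Euler characteristic is preserved.
#'
#' The geometric placement of the new vertices is a separate concern (see
#' [grow()]); here the arcs are purely combinatorial.
#'
#' @param topo a `vm_topology`.
#' @param i index of the cell to divide.
#' @param edges integer vector of length 2: the edge indices (columns of
#'   `topo$B`) to bisect; both must belong to cell `i` and the two arcs they
#'   delimit must each retain at least two original vertices.
#' @return a new `vm_topology`; the two new vertices get indices
#'   `n_vertices + 1` and `n_vertices + 2` (on `edges[1]` and `edges[2]`).
#' @export
divide_cell <- function(topo, i, edges) {
  if (length(edges) != 2 || edges[1] == edges[2])
    stop_bad_arg("exactly two distinct edges must be given")
  if (any(topo$B[i, edges] == 0))
    stop_bad_arg("edge(s) ", paste(edges[topo$B[i, edges] == 0], collapse = ", "),
                 " do not bound cell ", i)
  v <- topo$cells[[i]]; n <- length(v)
  posn <- function(j) {
    tl <- topo$edge_tail[j]; hd <- topo$edge_head[j]
    for (a in seq_len(n)) {
      b <- if (a == n) 1 else a + 1
      if ((v[a] == tl && v[b] == hd) || (v[a] == hd && v[b] == tl)) return(a)
    }
    stop_bad_arg("edge ", j, " not on cell ", i)
  }
  a <- posn(edges[1]); b <- posn(edges[2])
  lo <- min(a, b); hi <- max(a, b)
  if ((hi - lo) < 2 || (n - (hi - lo)) < 2)
    stop_bad_arg("arcs do not partition the cell into valid daughters ",
                 "(each needs at least two original vertices)")
  nv <- topo$n_vertices
  build_complex(split_cell_lists(topo$cells, i, a, b, nv + 1L, nv + 2L))
}

## --- internal: per-(cell,vertex) pair table ---------------------------------

## rows: one per (cell i, vertex k) incidence, with the cell's two edges at k
## (jin enters k along the traversal, jout leaves).
pair_table <- function(topo) {
  nv1 <- topo$n_vertices + 1
  ekey <- topo$edge_tail * nv1 + topo$edge_head
  ii <- integer(0); kk <- integer(0); jin <- integer(0); jout <- integer(0)
  for (i in seq_along(topo$cells)) {
    v <- topo$cells[[i]]; n <- length(v)
    prv <- c(v[n], v[-n]); nxt <- c(v[-1], v[1])
    j1 <- match(pmin(prv, v) * nv1 + pmax(prv, v), ekey)
    j2 <- match(pmin(v, nxt) * nv1 + pmax(v, nxt), ekey)
    ii <- c(ii, rep.int(i, n)); kk <- c(kk, v)
    jin <- c(jin, j1); jout <- c(jout, j2)
  }
  list(i = ii, k = kk, jin = jin, jout = jout, n = length(ii))
}
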