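# Deterministic analytic fixtures: single hexagon, honeycomb patches, jitter.

#' Single regular hexagonal cell
#'
#' @param side edge length; the cell area is `3 sqrt(3) / 2 * side^2`.
#' @return list with `topology` (a `vm_topology`) and `positions`.
#' @export
regular_hexagon <- function(side = 1) {
  if (side <= 0) stop_bad_arg("side must be positive")
  th <- pi / 3 * (0:5)
  list(topology = build_complex(list(1:6)),
       positions = side * cbind(cos(th), sin(th)))
}

#' Honeycomb patch of hexagonal cells
#'
#' A patch of `3 n (n + 1) + 1` regular hexagons (`n = rings`) with
#' `6 (n + 1)^2` vertices; all internal vertices tricellular. Coordinates are
#' generated analytically, so the fixture is bit-reproducible.
#'
#' @param rings number of rings around the central cell (0 = single hexagon).
#' @param side hexagon edge length.
#' @return list with `topology` and `positions`.
#' @export
hex_patch <- function(rings = 1, side = 1) {
  if (rings < 0) stop_bad_arg("rings must be >= 0")
  centers <- list()
  for (q in -rings:rings)
    for (r in max(-rings, -q - rings):min(rings, -q + rings))
      centers[[length(centers) + 1]] <- c(q, r)
  axial <- function(qr) side * c(sqrt(3) * (qr[1] + qr[2] / 2), 1.5 * qr[2])
  corner_th <- pi / 6 + pi / 3 * (0:5)
  keymap <- new.env(parent = emptyenv())
  pos <- matrix(0, 0, 2); cells <- vector("list", length(centers))
  for (ci in seq_along(centers)) {
    ctr <- axial(centers[[ci]])
    pts <- sweep(side * cbind(cos(corner_th), sin(corner_th)), 2, ctr, `+`)
    idx <- integer(6)
    for (a in 1:6) {
      key <- paste(round(pts[a, 1] / side, 6), round(pts[a, 2] / side, 6))
      id <- keymap[[key]]
      if (is.null(id)) {
        pos <- rbind(pos, pts[a, ]); id <- nrow(pos); keymap[[key]] <- id
      }
      idx[a] <- id
    }
    cells[[ci]] <- idx
  }
  list(topology = build_complex(cells), positions = pos)
}

#' Jitter the interior vertices of a mesh
#'
#' Adds deterministic Gaussian displacements to all non-peripheral vertices,
#' producing the disorder needed by tests of junction couples and triangle
#' stress asymmetry. Errors if any cell area becomes nonpositive.
#'
#' @param topo a `vm_topology`.
#' @param positions vertex coordinates.
#' @param amplitude displacement standard deviation.
#' @param seed RNG seed (reproducible).
#' @return jittered positions matrix.
#' @export
perturb <- function(topo, positions, amplitude, seed = 1) {
  pos <- as.matrix(positions)
  if (amplitude == 0) return(pos)
  set.seed(seed)
  jit <- matrix(stats::rnorm(2 * nrow(pos), 0, amplitude), ncol = 2)
  jit[topo$vert_periph, ] <- 0
  out <- pos + jit
  if (any(cell_AL(topo, out)$A <= 0))
    stop_bad_arg("perturbation inverted a cell; reduce amplitude")
  out
}
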