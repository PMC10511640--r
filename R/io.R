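# Mesh JSON schema: {"vertices": [[x, y], ...], "cells": [[k0, k1, ...], ...]}
# with 0-based vertex indices in the file (1-based inside R).

#' Write a mesh to JSON
#'
#' Coordinates are serialised at full double precision so that a
#' write/read cycle is bit-exact.
#'
#' @param topo a `vm_topology` (or a [monolayer]; its topology and positions
#'   are used and `positions` may be omitted).
#' @param positions vertex coordinates.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_mesh <- function(topo, positions = NULL, file) {
  if (inherits(topo, "vm_monolayer")) {
    positions <- positions %||% topo$geometry$positions
    topo <- topo$topology
  }
  obj <- list(vertices = lapply(seq_len(nrow(positions)),
                                function(k) positions[k, ]),
              cells = lapply(topo$cells, function(v) v - 1L))
  jsonlite::write_json(obj, file, digits = I(17), auto_unbox = FALSE)
  invisible(file)
}

#' Read a mesh from JSON
#'
#' @param file path to a mesh JSON file.
#' @return list with `topology` and `positions`.
#' @export
read_mesh <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = FALSE)
  pos <- do.call(rbind, lapply(obj$vertices, function(v) as.numeric(unlist(v))))
  cells <- lapply(obj$cells, function(v) as.integer(unlist(v)) + 1L)
  list(topology = build_complex(cells), positions = pos)
}

#' Export the mechanical state as CSV tables
#'
#' Writes per-cell stresses and effective pressures, per-vertex triangle
#' stresses, and per-edge couple vectors, keyed by the mesh indices.
#'
#' @param mono an analysed [monolayer] (see [analyse()]).
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
export_mechanics <- function(mono, dir) {
  if (is.null(mono$mech)) mono <- analyse(mono)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- mono$mech$stress
  cp <- mono$mech$couple
  ac <- mono$mech$affine_couple
  geom <- mono$geometry
  paths <- c(cells = file.path(dir, "cell_stress.csv"),
             vertices = file.path(dir, "triangle_stress.csv"),
             edges = file.path(dir, "couple_vectors.csv"))
  utils::write.csv(data.frame(
    cell = seq_along(geom$A), A = geom$A, L = geom$L,
    sxx = st$sigma_c[, 1, 1], sxy = st$sigma_c[, 1, 2],
    syx = st$sigma_c[, 2, 1], syy = st$sigma_c[, 2, 2],
    P_eff = st$P_eff_c, antisym = st$antisym_c),
    paths["cells"], row.names = FALSE)
  utils::write.csv(data.frame(
    vertex = seq_along(geom$E), E = geom$E,
    sxx = st$sigma_v[, 1, 1], sxy = st$sigma_v[, 1, 2],
    syx = st$sigma_v[, 2, 1], syy = st$sigma_v[, 2, 2],
    P_eff = st$P_eff_v, antisym = st$antisym_v,
    C_affine = ac$C_k),
    paths["vertices"], row.names = FALSE)
  utils::write.csv(data.frame(
    edge = seq_along(geom$F),
    mu_x = cp$mu[, 1], mu_y = cp$mu[, 2],
    m_aff_x = ac$m_e[, 1], m_aff_y = ac$m_e[, 2]),
    paths["edges"], row.names = FALSE)
  invisible(paths)
}

#' Export a potential's eigenmode spectrum as CSV
#'
#' @param coefficients output of [spectrum()].
#' @param file output path; two columns, `eigenvalue` and `coefficient`.
#' @return invisibly, `file`.
#' @export
export_spectrum <- function(coefficients, file) {
  utils::write.csv(data.frame(eigenvalue = attr(coefficients, "eigenvalues"),
                              coefficient = as.numeric(coefficients)),
                   file, row.names = FALSE)
  invisible(file)
}
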