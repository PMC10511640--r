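# Top-level monolayer object: topology + geometry + parameters + analyses.

#' Construct a monolayer object
#'
#' Bundles a cell complex, vertex positions and energy parameters into the
#' package's central object. Heavier analyses (operators, force potential,
#' stresses, potentials) are attached on demand by [analyse()].
#'
#' @param topo a `vm_topology`.
#' @param positions vertex coordinates.
#' @param params a [energy_params()].
#' @param max_force largest vertex force resultant, if known (as reported by
#'   [relax()] or [grow()]).
#' @param config optionally, the [sim_config()] that produced the state.
#' @return object of class `vm_monolayer` with `topology`, `geometry`,
#'   `params`, `max_force`, `config`.
#' @export
monolayer <- function(topo, positions, params = energy_params(),
                      max_force = NA_real_, config = NULL) {
  geom <- assemble_geometry(topo, positions)
  structure(list(topology = geom$topology, geometry = geom, params = params,
                 max_force = max_force, config = config, mech = NULL),
            class = "vm_monolayer")
}

#' Analyse a monolayer: operators, force potential, stresses, potentials
#'
#' Runs the full pipeline on an equilibrium monolayer: discrete operators,
#' Maxwell-Cremona force potential, cell/triangle stresses and effective
#' pressures, affine stress, discrete Airy/Mindlin stress potentials, couple
#' stress and the affine junction couples.
#'
#' @param mono a [monolayer].
#' @return the monolayer with a `mech` component: `ops`, `forces`, `hfield`,
#'   `stress`, `affine`, `potentials`, `couple`, `affine_couple`, `energy`.
#' @export
analyse <- function(mono) {
  geom <- mono$geometry
  params <- mono$params
  ops <- build_operators(geom)
  fo <- vertex_forces(geom, params)
  hf <- force_potential(geom, params, forces = fo)
  st <- stresses(geom, params, hfield = hf, ops = ops)
  sp <- stress_potentials(ops, params, hfield = hf)
  mono$mech <- list(ops = ops, forces = fo, hfield = hf, stress = st,
                    affine = affine_stress(geom, params),
                    potentials = sp,
                    couple = couple_stress(ops, sp),
                    affine_couple = affine_couple(geom, params),
                    energy = cell_energy(geom, params))
  mono
}

#' @export
print.vm_monolayer <- function(x, ...) {
  t <- x$topology
  cat("<monolayer> ", t$n_cells, " cells, ", t$n_edges, " edges, ",
      t$n_vertices, " vertices; area ",
      format(x$geometry$total_area, digits = 5), "\n", sep = "")
  if (!is.na(x$max_force))
    cat("  equilibrium: max |force| = ", format(x$max_force, digits = 3),
        "\n", sep = "")
  cat("  params: Gamma = ", x$params$Gamma, ", L0 = ", x$params$L0,
      ", P_ext = ", x$params$P_ext, "\n", sep = "")
  if (!is.null(x$mech)) cat("  analysed (see $mech)\n")
  invisible(x)
}

#' @export
summary.vm_monolayer <- function(object, ...) {
  x <- if (is.null(object$mech)) analyse(object) else object
  st <- x$mech$stress
  geom <- x$geometry
  out <- list(
    n_cells = x$topology$n_cells,
    total_area = geom$total_area,
    mean_cell_area = mean(geom$A),
    P_eff_mean = sum(geom$A * st$P_eff_c) / geom$total_area,
    P_ext = x$params$P_ext,
    max_cell_torque = max(abs(st$antisym_c)),
    max_triangle_torque = max(abs(st$antisym_v)),
    force_residual = x$mech$hfield$residual)
  class(out) <- "summary.vm_monolayer"
  out
}

#' @export
print.summary.vm_monolayer <- function(x, ...) {
  cat("Monolayer of", x$n_cells, "cells, total area",
      format(x$total_area, digits = 5), "\n")
  cat("  area-weighted mean effective pressure:",
      format(x$P_eff_mean, digits = 6), "(P_ext =", x$P_ext, ")\n")
  cat("  cell torque (max |curl h| / 2):",
      format(x$max_cell_torque, digits = 3), "\n")
  cat("  junction torque (max |CURL h| / 2):",
      format(x$max_triangle_torque, digits = 3), "\n")
  invisible(x)
}

#' Plot a monolayer coloured by a per-cell field
#'
#' @param x a [monolayer].
#' @param field per-cell numeric vector, or the name of a built-in field
#'   (`"P_eff"`, `"area"`, `"pressure"`).
#' @param main title.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vm_monolayer <- function(x, field = "P_eff", main = NULL, ...) {
  geom <- x$geometry
  vals <- if (is.character(field)) {
    switch(field,
      P_eff = {
        if (is.null(x$mech)) x <- analyse(x)
        x$mech$stress$P_eff_c
      },
      area = geom$A,
      pressure = geom$A - 1,
      stop_bad_arg("unknown field: ", field))
  } else as.numeric(field)
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  rng <- range(vals)
  idx <- if (diff(rng) > 0) {
    1 + floor(63 * (vals - rng[1]) / diff(rng))
  } else rep(32, length(vals))
  pos <- geom$positions
  graphics::plot(pos, type = "n", asp = 1, xlab = "x", ylab = "y",
                 main = main %||% if (is.character(field)) field else "field",
                 ...)
  for (i in seq_along(x$topology$cells)) {
    v <- x$topology$cells[[i]]
    graphics::polygon(pos[v, 1], pos[v, 2], col = pal[idx[i]], border = "grey25")
  }
  invisible(x)
}
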