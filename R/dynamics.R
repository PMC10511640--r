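# Overdamped relaxation, T1 neighbour exchanges, and growth by cell division.

#' Simulation configuration
#'
#' @param params a [energy_params()] list.
#' @param tol force tolerance defining equilibrium (max vertex resultant).
#' @param tol_interim looser tolerance used for the relaxations between
#'   divisions while growing.
#' @param max_steps iteration cap for the relaxation.
#' @param dt0 initial descent step.
#' @param t1_threshold internal edges shorter than this undergo a T1
#'   neighbour exchange during growth; `0` disables T1s.
#' @param seed RNG seed for [grow()].
#' @return list of class `vm_config`.
#' @export
sim_config <- function(params = energy_params(), tol = 1e-10,
                       tol_interim = 1e-8, max_steps = 50000, dt0 = 0.05,
                       t1_threshold = 0.03, seed = 1) {
  if (tol <= 0 || dt0 <= 0) stop_bad_arg("tol and dt0 must be positive")
  structure(list(params = params, tol = tol, tol_interim = tol_interim,
                 max_steps = max_steps, dt0 = dt0,
                 t1_threshold = t1_threshold, seed = seed),
            class = "vm_config")
}

## Barzilai-Borwein-stepped forward Euler descent with energy backtracking.
relax_descent <- function(topo, pos, params, tol, max_steps, dt0) {
  ctx <- dyn_context(topo)
  vr <- vertex_resultants(topo, pos, params, ctx)
  en <- vr$energy; g <- vr$force
  energies <- en
  dt <- dt0 / params$eta; steps <- 0L
  while (max(sqrt(rowSums(g^2))) > tol && steps < max_steps) {
    repeat {
      cand <- pos + dt * g
      gg <- cell_AL(topo, cand)
      if (all(gg$A > 0)) {
        en_new <- energy_AL(gg$A, gg$L, params)$total
        if (en_new <= en + 1e-14 * abs(en)) break
      }
      dt <- dt / 2
      if (dt < 1e-16)
        return(list(positions = pos, steps = steps, energy = en,
                    energies = energies,
                    max_force = max(sqrt(rowSums(g^2))), converged = FALSE))
    }
    pos_old <- pos; g_old <- g
    pos <- cand
    vr <- vertex_resultants(topo, pos, params, ctx)
    en <- vr$energy; energies <- c(energies, en)
    g <- vr$force
    s <- pos - pos_old; y <- -(g - g_old)
    sy <- sum(s * y)
    dt <- if (sy > 0) min(max(sum(s * s) / sy, 1e-12), 10) else dt0
    steps <- steps + 1L
  }
  list(positions = pos, steps = steps, energy = en, energies = energies,
       max_force = max(sqrt(rowSums(g^2))), converged = steps < max_steps)
}

## L-BFGS energy minimisation with a finite-difference Newton polish.
relax_minimise <- function(topo, pos, params, tol, max_steps, polish = TRUE) {
  ctx <- dyn_context(topo)
  nv <- nrow(pos)
  fn <- function(x) {
    g <- cell_AL(topo, matrix(x, nv, 2))
    energy_AL(g$A, g$L, params)$total
  }
  grf <- function(x)
    -as.vector(vertex_resultants(topo, matrix(x, nv, 2), params, ctx)$force)
  mfun <- function(x) max(sqrt(rowSums(matrix(grf(x), nv, 2)^2)))
  x <- as.vector(pos)
  mf <- mfun(x)
  for (round in 1:4) {
    o <- stats::optim(x, fn, grf, method = "L-BFGS-B",
                      control = list(maxit = max_steps, factr = 1, pgtol = 0))
    x <- o$par
    mf <- mfun(x)
    if (mf <= max(tol, 1e-8)) break
  }
  if (polish && mf > tol) {
    n <- length(x)
    for (it in 1:4) {
      g0 <- grf(x)
      hstep <- 1e-6
      H <- matrix(0, n, n)
      for (a in seq_len(n)) {
        xp <- x; xp[a] <- xp[a] + hstep
        xm <- x; xm[a] <- xm[a] - hstep
        H[, a] <- (grf(xp) - grf(xm)) / (2 * hstep)
      }
      H <- (H + t(H)) / 2
      dx <- tryCatch(solve(H + 1e-8 * mean(abs(diag(H))) * diag(n), -g0),
                     error = function(e) NULL)
      if (is.null(dx)) break
      if (mfun(x + dx) < mf) { x <- x + dx; mf <- mfun(x) } else break
      if (mf <= tol) break
    }
  }
  list(positions = matrix(x, nv, 2), steps = NA_integer_, energy = fn(x),
       energies = numeric(0), max_force = mf, converged = mf <= tol)
}

#' Relax a monolayer to mechanical equilibrium
#'
#' Evolves vertices down the energy gradient (`eta dr_k/dt` equal to the net
#' vertex force) until the largest vertex force resultant falls below `tol`.
#' Two integrators are available: `"descent"` is forward Euler with an
#' adaptive (Barzilai-Borwein) step and energy backtracking — the energy is
#' non-increasing across accepted steps and inverted cells cause step
#' rejection; `"minimise"` (the default, used for growth) minimises the same
#' energy by L-BFGS with a finite-difference Newton polish, reaching much
#' tighter force tolerances. Both are deterministic given the inputs.
#'
#' @param topo a `vm_topology`.
#' @param positions vertex coordinate matrix.
#' @param config a [sim_config()].
#' @param method `"minimise"` or `"descent"`.
#' @return list of class `vm_relax`: final `positions`, `energy`, `max_force`,
#'   `converged`, `steps` and (descent only) the accepted-step `energies`.
#' @export
relax <- function(topo, positions, config = sim_config(),
                  method = c("minimise", "descent")) {
  method <- match.arg(method)
  out <- switch(method,
    descent = relax_descent(topo, as.matrix(positions), config$params,
                            config$tol, config$max_steps, config$dt0),
    minimise = relax_minimise(topo, as.matrix(positions), config$params,
                              config$tol, config$max_steps))
  class(out) <- "vm_relax"
  out
}

## --- T1 neighbour exchange --------------------------------------------------

## topological T1 on cell lists; returns NULL when the move is not applicable.
## For an interior edge the standard reconnection is performed; when exactly
## one endpoint is peripheral the edge is handed to the outer cell and becomes
## a new stretch of the monolayer margin.
t1_lists <- function(cells, topo, j) {
  k1 <- topo$edge_tail[j]; k2 <- topo$edge_head[j]
  if (topo$edge_periph[j]) return(NULL)
  if (topo$vert_periph[k1] && topo$vert_periph[k2]) return(NULL)
  if (topo$vert_periph[k2]) { tmp <- k1; k1 <- k2; k2 <- tmp }
  sides <- which(topo$B[, j] != 0)
  trav <- function(i) {
    v <- cells[[i]]; n <- length(v)
    a <- match(k1, v)
    v[if (a == n) 1 else a + 1] == k2
  }
  i1 <- if (trav(sides[1])) sides[1] else sides[2]
  i2 <- setdiff(sides, i1)
  at <- function(k) which(vapply(cells, function(v) k %in% v, TRUE))
  i3 <- setdiff(at(k1), c(i1, i2))
  i4 <- setdiff(at(k2), c(i1, i2))
  if (length(i4) != 1 || length(i3) > 1) return(NULL)
  if (length(cells[[i1]]) <= 3 || length(cells[[i2]]) <= 3) return(NULL)
  ins_before <- function(v, ref, new) append(v, new, after = match(ref, v) - 1)
  cells[[i4]] <- ins_before(cells[[i4]], k2, k1)
  if (length(i3) == 1) cells[[i3]] <- ins_before(cells[[i3]], k1, k2)
  cells[[i1]] <- setdiff(cells[[i1]], k2)
  cells[[i2]] <- setdiff(cells[[i2]], k1)
  list(cells = cells, i1 = i1, i2 = i2, k1 = k1, k2 = k2)
}

#' T1 neighbour exchange on a short edge
#'
#' Reconnects the complex across internal edge `j`: the two cells sharing the
#' edge lose contact and the two end cells gain it; the edge is re-seeded
#' perpendicular to its old direction with length `1.5 * new_length`. All
#' internal vertices stay tricellular and the Euler characteristic is
#' preserved. Peripheral edges, edges whose both endpoints are peripheral,
#' and moves that would leave a cell with fewer than three edges are errors.
#'
#' @param topo a `vm_topology`.
#' @param positions vertex coordinates.
#' @param j edge index.
#' @param new_length half-separation of the reconnected vertices.
#' @return list with the updated `topology` and `positions`.
#' @export
t1_transition <- function(topo, positions, j, new_length = 0.02) {
  res <- t1_lists(topo$cells, topo, j)
  if (is.null(res))
    stop_bad_arg("T1 not applicable to edge ", j,
                 " (peripheral, doubly peripheral or triangle-adjacent)")
  pos <- as.matrix(positions)
  mid <- (pos[res$k1, ] + pos[res$k2, ]) / 2
  Rc <- as.matrix(topo$C %*% pos) / topo$Z
  dir <- Rc[res$i1, ] - Rc[res$i2, ]
  dir <- dir / sqrt(sum(dir^2))
  pos[res$k1, ] <- mid + new_length * dir
  pos[res$k2, ] <- mid - new_length * dir
  list(topology = build_complex(res$cells), positions = pos)
}

## apply T1s to all sub-threshold internal edges (shortest first)
sweep_t1 <- function(topo, pos, thr) {
  changed <- FALSE
  if (thr <= 0) return(list(topology = topo, positions = pos, changed = FALSE))
  repeat {
    g <- cell_AL(topo, pos)
    cand <- which(g$tlen < thr & !topo$edge_periph)
    if (!length(cand)) break
    applied <- FALSE
    for (j in cand[order(g$tlen[cand])]) {
      res <- tryCatch(t1_transition(topo, pos, j, new_length = 0.75 * thr),
                      error = function(e) NULL)
      if (!is.null(res)) {
        topo <- res$topology; pos <- res$positions
        changed <- TRUE; applied <- TRUE
        break
      }
    }
    if (!applied) break
  }
  list(topology = topo, positions = pos, changed = changed)
}

## --- growth by random division ----------------------------------------------

## division plane through the vertex centroid at angle th; returns NULL when
## the plane does not cut two distinct edges cleanly
divide_cell_geometric <- function(topo, pos, i, th) {
  v <- topo$cells[[i]]; n <- length(v)
  d <- c(cos(th), sin(th))
  Ri <- colMeans(pos[v, , drop = FALSE])
  hit_a <- integer(0); hit_p <- list()
  for (a in seq_len(n)) {
    pA <- pos[v[a], ]; pB <- pos[v[if (a == n) 1 else a + 1], ]
    e <- pB - pA
    den <- d[2] * e[1] - d[1] * e[2]
    if (abs(den) < 1e-12) next
    rhs <- pA - Ri
    w <- (d[1] * rhs[2] - d[2] * rhs[1]) / den
    if (w > 0.05 && w < 0.95) {
      hit_a <- c(hit_a, a); hit_p[[length(hit_p) + 1]] <- pA + w * e
    }
  }
  if (length(hit_a) != 2) return(NULL)
  lo <- min(hit_a); hi <- max(hit_a)
  if ((hi - lo) < 2 || (n - (hi - lo)) < 2) return(NULL)
  nv <- topo$n_vertices
  cells <- split_cell_lists(topo$cells, i, hit_a[1], hit_a[2], nv + 1L, nv + 2L)
  list(topology = build_complex(cells),
       positions = rbind(pos, hit_p[[1]], hit_p[[2]]))
}

## short-axis (Hertwig) division angle of a cell: the plane direction is the
## minor principal axis of the vertex scatter
short_axis_angle <- function(pos_cell) {
  q <- sweep(pos_cell, 2, colMeans(pos_cell))
  ev <- eigen(crossprod(q) / nrow(q), symmetric = TRUE)
  atan2(ev$vectors[2, 2], ev$vectors[1, 2])
}

## check a relaxed state is geometrically sound
state_ok <- function(topo, pos) {
  g <- cell_AL(topo, pos)
  if (any(g$A <= 0) || min(g$tlen) < 1e-4) return(FALSE)
  !inherits(try(assemble_geometry(topo, pos), silent = TRUE), "try-error")
}

relax_with_t1 <- function(topo, pos, config, tol, polish, max_rounds = 25) {
  for (round in seq_len(max_rounds)) {
    r <- relax_minimise(topo, pos, config$params, tol, config$max_steps,
                        polish = polish)
    pos <- r$positions
    tt <- sweep_t1(topo, pos, config$t1_threshold)
    if (!tt$changed)
      return(list(topo = topo, pos = pos, relax = r))
    topo <- tt$topology; pos <- tt$positions
  }
  list(topo = topo, pos = pos, relax = r)
}

#' Grow a monolayer by random cell division
#'
#' Starting from a single unit-area hexagonal cell, repeatedly divides a
#' randomly chosen cell (probability proportional to area, so cells that have
#' grown are the ones that divide) along a plane through its vertex centroid
#' oriented near the cell's short principal axis (Hertwig's rule, with a
#' +-0.2 rad jitter), relaxing to equilibrium after every division. Internal
#' edges that shrink below `config$t1_threshold` undergo T1 neighbour
#' exchanges during growth. A division whose relaxed state fails to converge
#' or degenerates is rolled back and a fresh division is drawn. The run is
#' fully reproducible from `config$seed`.
#'
#' @param n_cells target cell count.
#' @param config a [sim_config()]; `config$seed` seeds all randomness.
#' @return a [monolayer] object at equilibrium (final relaxation at
#'   `config$tol` with Newton polish).
#' @export
grow <- function(n_cells, config = sim_config()) {
  set.seed(config$seed)
  params <- config$params
  hx <- regular_hexagon(sqrt(2 / (3 * sqrt(3))))   # unit initial area
  topo <- hx$topology; pos <- hx$positions
  r <- relax_minimise(topo, pos, params, config$tol_interim,
                      config$max_steps, polish = FALSE)
  pos <- r$positions
  nfail <- 0L
  while (topo$n_cells < n_cells) {
    ar <- cell_AL(topo, pos)$A
    dv <- NULL
    for (att in 1:50) {
      i <- sample.int(topo$n_cells, 1, prob = ar)
      th <- short_axis_angle(pos[topo$cells[[i]], , drop = FALSE]) +
        stats::runif(1, -0.2, 0.2)
      dv <- divide_cell_geometric(topo, pos, i, th)
      if (!is.null(dv)) break
    }
    if (is.null(dv)) stop_bad_arg("no valid division plane found")
    st <- relax_with_t1(dv$topology, dv$positions, config,
                        config$tol_interim, polish = FALSE)
    if (st$relax$max_force <= 1e2 * config$tol_interim &&
        state_ok(st$topo, st$pos)) {
      topo <- st$topo; pos <- st$pos
    } else {
      nfail <- nfail + 1L
      if (nfail > 200L) stop_bad_arg("growth stalled: too many rejected divisions")
    }
  }
  st <- relax_with_t1(topo, pos, config, config$tol, polish = TRUE)
  monolayer(st$topo, st$pos, params,
            max_force = st$relax$max_force, config = config)
}
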