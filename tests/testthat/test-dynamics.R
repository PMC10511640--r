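test_that("gradient descent is monotone, rejects inversions, and stops at equilibrium", {
  cfg <- sim_config(tol = 1e-8)
  fl <- hex_patch(1, side = sqrt(2 / (3 * sqrt(3))))
  pos <- perturb(fl$topology, fl$positions, 0.05, seed = 13)
  r <- relax(fl$topology, pos, cfg, method = "descent")
  expect_true(r$converged)
  expect_lt(r$max_force, 1e-8)
  ## energy non-increasing across accepted steps
  expect_true(all(diff(r$energies) <= 1e-12 * abs(r$energies[-1]) + 1e-15))
  ## an already-equilibrated state takes no steps
  r2 <- relax(fl$topology, r$positions, cfg, method = "descent")
  expect_identical(r2$steps, 0L)
})

test_that("perturbed hexagon relaxes to the scalar-minimisation optimum", {
  p <- energy_params()
  obj <- function(rho) {
    A <- 3 * sqrt(3) / 2 * rho^2
    0.5 * (A - 1)^2 + 0.5 * p$Gamma * (6 * rho - p$L0)^2 + p$P_ext * A
  }
  rho_star <- optimize(obj, c(0.05, 2), tol = 1e-14)$minimum
  hx <- regular_hexagon(0.45)
  set.seed(8)
  pos <- hx$positions + matrix(rnorm(12, 0, 0.02), 6, 2)
  r <- relax(hx$topology, pos, sim_config(tol = 1e-11), method = "descent")
  ## a jittered hexagon relaxes back to a regular one of the optimal radius
  rho <- sqrt(rowSums(sweep(r$positions, 2, colMeans(r$positions))^2))
  expect_equal(mean(rho), rho_star, tolerance = 1e-6)
  expect_lt(stats::sd(rho), 1e-6)
})

test_that("growth is reproducible and yields valid jammed equilibria", {
  m1 <- grown12()
  m2 <- grow(12, sim_config(seed = 7))
  expect_identical(m1$geometry$positions, m2$geometry$positions)
  expect_identical(m1$topology$cells, m2$topology$cells)
  t <- m1$topology
  expect_equal(t$n_edges, t$n_cells + t$n_vertices - 1L)
  expect_length(validate_topology(t), 0)
  expect_lt(m1$max_force, 1e-9)
  ## the grown state passes the equilibrium mechanics suite
  mm <- analyse(m1)
  st <- mm$mech$stress
  expect_lt(mm$mech$forces$max_resultant, 1e-9)
  expect_lt(mx(st$antisym_c), 1e-8)
  tot <- apply(sweep(st$sigma_c, 1, m1$geometry$A, "*"), c(2, 3), sum)
  expect_lt(mx(tot - m1$params$P_ext * m1$geometry$total_area * diag(2)), 1e-8)
  ## jammed at the default parameters: no sub-threshold internal edge remains
  g <- cell_AL(t, m1$geometry$positions)
  expect_true(all(g$tlen[!t$edge_periph] >= m1$config$t1_threshold))
})

test_that("T1 transitions reconnect the expected cells and preserve invariants", {
  ## four cells around an internal edge: two side hexagons, two end cells
  pts <- rbind(
    c(0, 0.5), c(0, -0.5),                       # k1, k2 (the short edge)
    c(-1, 1), c(1, 1),                           # upper corners
    c(1, -1), c(-1, -1),                         # lower corners
    c(-2, 0), c(2, 0),                           # side apexes
    c(-1, 2.2), c(1, 2.2),                       # top cell outer corners
    c(1, -2.2), c(-1, -2.2))                     # bottom cell outer corners
  cells <- list(
    c(1, 3, 7, 6, 2),       # west (tail k1 -> k2 along the edge)
    c(2, 5, 8, 4, 1),       # east
    c(1, 4, 10, 9, 3),      # north (touches k1 only)
    c(2, 6, 12, 11, 5))     # south (touches k2 only)
  ## orient all cells counterclockwise
  cells <- lapply(cells, function(v) {
    if (shoelace(pts[v, , drop = FALSE]) < 0) rev(v) else v
  })
  topo <- build_complex(cells)
  j <- which(topo$edge_tail == 1 & topo$edge_head == 2)
  expect_false(topo$edge_periph[j])
  res <- t1_transition(topo, pts, j, new_length = 0.2)
  t2 <- res$topology
  expect_length(validate_topology(t2), 0)
  expect_equal(t2$n_cells - t2$n_edges + t2$n_vertices, 1L)
  expect_equal(c(t2$n_cells, t2$n_edges, t2$n_vertices),
               c(topo$n_cells, topo$n_edges, topo$n_vertices))
  ## the edge is now shared by the former end cells (north & south),
  ## and west/east are no longer neighbours across it
  j2 <- which(t2$edge_tail == 1 & t2$edge_head == 2)
  sides <- which(t2$B[, j2] != 0)
  has <- function(i, k) k %in% t2$cells[[i]]
  expect_setequal(sides, c(3L, 4L))
  ## each side cell keeps exactly one of the reconnected vertices; the end
  ## cells gain both
  expect_true(xor(has(1, 1), has(1, 2)))
  expect_true(xor(has(2, 1), has(2, 2)))
  expect_true(has(3, 1) && has(3, 2) && has(4, 1) && has(4, 2))
  ## peripheral edge refuses the move
  pj <- which(topo$edge_periph)[1]
  expect_error(t1_transition(topo, pts, pj), "not applicable")
  ## threshold 0 never fires
  sw <- sweep_t1(topo, pts, 0)
  expect_false(sw$changed)
})

test_that("jammed equilibria are stable to small perturbations", {
  m <- grown12()
  cfg <- m$config
  pos0 <- m$geometry$positions
  pos <- perturb(m$topology, pos0, 0.002, seed = 99)
  r <- relax(m$topology, pos, cfg)
  expect_true(r$converged)
  g0 <- cell_AL(m$topology, pos0)
  e0 <- energy_AL(g0$A, g0$L, cfg$params)$total
  expect_equal(r$energy, e0, tolerance = 1e-8)
})
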