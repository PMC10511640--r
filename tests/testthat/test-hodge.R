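test_that("eigenbases have the uniform zero mode, M-orthonormal modes, oracle-checked values", {
  O <- perturbed_ops()
  for (nm in c("L_V", "L_T", "L_F", "L_C")) {
    M <- if (nm %in% c("L_V", "L_T")) O$M_V else O$M_F
    b <- eigenbasis(O[[nm]], M)
    expect_lt(abs(b$values[1]), 1e-10)
    u <- b$modes[, 1]
    expect_lt(stats::sd(u) / abs(mean(u)), 1e-8)      # uniform mode
    Gram <- t(b$modes) %*% (Matrix::diag(M) * b$modes)
    expect_lt(mx(Gram - diag(nrow(Gram))), 1e-10)
    ## dense nonsymmetric eigensolve as an independent oracle
    expect_equal(b$values, eig_oracle(O[[nm]]), tolerance = 1e-8)
  }
  ## single hexagon: L_F is 1x1 and exactly zero (its only edge links are
  ## peripheral, all masked)
  hx <- regular_hexagon(1)
  Oh <- build_operators(assemble_geometry(hx$topology, hx$positions))
  expect_equal(dim(as.matrix(Oh$L_F)), c(1L, 1L))
  expect_lt(abs(as.matrix(Oh$L_F)[1, 1]), 1e-14)
  ## and equals the composition with the mask applied
  IbE <- Matrix::Diagonal(2 * 6, rep(Matrix::diag(Oh$I_b), each = 2))
  expect_lt(mx(Oh$L_F + Oh$div_c %*% IbE %*% Oh$tgrad_c), 1e-14)
  expect_error(eigenbasis(O$L_V, O$M_F), "dimension")
  wrongM <- Matrix::Diagonal(O$topology$n_vertices,
                             seq_len(O$topology$n_vertices))
  expect_error(eigenbasis(O$L_V, wrongM), "self-adjoint")
})

test_that("solve_poisson handles the kernel correctly", {
  O <- perturbed_ops()
  nv <- O$topology$n_vertices
  ## rhs = 0 -> 0
  x0 <- solve_poisson(O$L_V, O$M_V, rep(0, nv))
  expect_lt(mx(x0), 1e-14)
  ## forward-apply oracle: recover a zero-mean field
  set.seed(5)
  y <- rnorm(nv)
  d <- Matrix::diag(O$M_V)
  y <- y - sum(d * y) / sum(d)
  rhs <- as.vector(O$L_V %*% y)
  x <- solve_poisson(O$L_V, O$M_V, rhs)
  expect_lt(mx(x - y), 1e-9 * max(1, mx(y)))
  ## constant forcing violates solvability
  expect_error(solve_poisson(O$L_V, O$M_V, rep(1, nv)), "solvability")
})

test_that("Helmholtz decomposition reconstructs arbitrary per-edge fields exactly", {
  O <- perturbed_ops()
  ne <- O$topology$n_edges
  set.seed(9)
  for (rep in 1:3) {
    h <- rnorm(2 * ne)
    hp <- helmholtz_primal(O, h)
    expect_lt(hp$residual, 1e-8)
    expect_lt(mx(hp$h_par + hp$h_perp - h), 1e-8 * max(abs(h)))
    hd <- helmholtz_dual(O, h)
    expect_lt(hd$residual, 1e-8)
  }
  ## zero field -> all potentials zero
  h0 <- helmholtz_primal(O, rep(0, 2 * ne))
  expect_lt(mx(c(h0$psi_c, h0$Psi_c, h0$psi_v, h0$Psi_v)), 1e-12)
})

test_that("a pure gradient field is recovered in the psi_v potential alone", {
  O <- perturbed_ops()
  set.seed(4)
  phi <- rnorm(O$topology$n_vertices)
  d <- Matrix::diag(O$M_V)
  phi <- phi - sum(d * phi) / sum(d)
  h <- as.vector(O$grad_v %*% phi)
  hp <- helmholtz_primal(O, h)
  expect_lt(mx(hp$psi_v - phi), 1e-8 * max(1, mx(phi)))
  expect_lt(mx(hp$Psi_c), 1e-8)
  expect_lt(mx(hp$psi_c), 1e-8)
  expect_lt(mx(hp$Psi_v), 1e-8)
  ## a field perpendicular to every edge has no parallel part
  tvec <- O$geometry$t
  hperp <- as.vector(t(cbind(tvec[, 2], -tvec[, 1])))
  hperp_dec <- helmholtz_primal(O, hperp)
  expect_lt(mx(hperp_dec$h_par), 1e-8 * max(abs(hperp)))
})

test_that("spectral coefficients satisfy Parseval and one-hot identities", {
  O <- perturbed_ops()
  b <- eigenbasis(O$L_F, O$M_F)
  d <- Matrix::diag(O$M_F)
  ## uniform field -> only the zero-mode coefficient
  co <- spectrum(rep(2, length(d)), b)
  expect_lt(mx(co[-1]), 1e-10)
  ## single eigenmode in -> one-hot out
  co2 <- spectrum(b$modes[, 3], b)
  expect_equal(co2[3], 1, tolerance = 1e-10)
  expect_lt(mx(co2[-3]), 1e-10)
  ## Parseval
  set.seed(2)
  f <- rnorm(length(d))
  co3 <- spectrum(f, b)
  expect_equal(sum(co3^2), sum(d * f^2), tolerance = 1e-10)
  expect_error(spectrum(rep(1, length(d) + 1), b), "match")
})

test_that("grown-monolayer vertex and face Laplacian spectra pair closely", {
  mono <- grown50()
  O <- build_operators(mono$geometry)
  evV <- eigenbasis(O$L_V, O$M_V)$values
  evF <- eigenbasis(O$L_F, O$M_F)$values
  nmode <- min(21, length(evF))
  rel <- abs(evV[2:nmode] - evF[2:nmode]) / evF[2:nmode]
  expect_lt(max(rel), 0.25)   # loose sanity bound at this small size
})
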