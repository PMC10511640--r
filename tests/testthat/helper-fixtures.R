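# Shared fixtures, built once per test run and cached.

mx <- function(M) if (length(M)) max(abs(M)) else 0

.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

## a disordered but un-relaxed 2-ring honeycomb with jittered interior
perturbed_patch <- function() fixture("patch2", function() {
  fl <- hex_patch(2)
  pos <- perturb(fl$topology, fl$positions, 0.1, seed = 11)
  assemble_geometry(fl$topology, pos)
})

perturbed_ops <- function() fixture("patch2_ops", function() {
  build_operators(perturbed_patch())
})

## a grown 50-cell equilibrium monolayer under the default (jammed) parameters
grown50 <- function() fixture("grown50", function() {
  grow(50, sim_config(seed = 101))
})

grown50_analysed <- function() fixture("grown50_mech", function() {
  analyse(grown50())
})

## small grown monolayer for cheap equilibrium tests
grown12 <- function() fixture("grown12", function() {
  grow(12, sim_config(seed = 7))
})

## dense generalized-eigenvalue oracle: eigenvalues of M^-1 K for K = M L
eig_oracle <- function(L) sort(Re(eigen(as.matrix(L))$values))

## independent shoelace oracle for area checks
shoelace_area <- function(p) {
  n <- nrow(p); nxt <- c(2:n, 1)
  sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2]) / 2
}
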