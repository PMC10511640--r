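---
title: "Discrete calculus, stress potentials and couple stress in vertex-model monolayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete calculus, stress potentials and couple stress in vertex-model monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertexcalc)
```

## The model

A confluent planar epithelium is represented as a simply connected tiling of
polygonal cells. Cells are indexed by $i$, edges by $j$, vertices by $k$;
every interior vertex is a tricellular junction (exactly three cells and
three edges meet there). Two signed incidence matrices carry the whole
topology: $A_{jk} = \pm 1$ records which vertices an oriented edge runs
between, and $B_{ij} = \pm 1$ records which edges bound a cell and whether
the cell's counterclockwise traversal agrees with the edge orientation. The
identity $\mathsf{B}\mathsf{A} = 0$ — the boundary of a boundary is empty —
holds in exact integer arithmetic and is the backbone of every discrete
differential operator in the package.

Each cell carries the standard area–perimeter energy
$$U(A_i, L_i) = \tfrac12 (A_i - 1)^2 + \tfrac12\,\Gamma (L_i - L_0)^2,$$
with cell pressure $\mathcal{P}_i = A_i - 1$ and tension
$\mathcal{T}_i = \Gamma (L_i - L_0)$; the monolayer energy adds the work
term $P_\mathrm{ext}\mathcal{A}$ of a uniform external pressure acting on
the margin. The defaults $\Gamma = 0.2$, $L_0 = 0.75$,
$P_\mathrm{ext} = 0.2$ place the tissue in the jammed (solid) regime: cells
equilibrate near area $\approx 0.15$ with shape index $\approx 3.7$, below
the rigidity threshold, and equilibria are stable to small perturbations.
Vertices move by overdamped gradient descent,
$\eta\,\mathrm{d}\mathbf{r}_k/\mathrm{d}t = \sum_i C_{ik}\mathbf{f}_{ik}$,
where $\mathbf{f}_{ik} = -\partial(U_i + P_\mathrm{ext}A_i)/\partial\mathbf{r}_k$
is the force cell $i$ exerts on vertex $k$.

## Geometry of the primal and dual networks

From vertex positions the package builds edges $\mathbf{t}_j$, edge
centroids $\mathbf{c}_j$, cell centres $\mathbf{R}_i$ (plain vertex
centroids, not area centroids), and dual links $\mathbf{T}_j$ joining the
two cell centres across each edge — or, on the margin, joining a border-cell
centre to the peripheral edge centroid. The cross product
$F_j = \mathbf{t}_j \times \mathbf{T}_j$ is twice the area of the trapezium
spanned by an edge and its link and must be positive for every edge; with
counterclockwise cells (clockwise input is canonicalised) this holds
automatically, and a nonpositive $F_j$ is treated as a degenerate mesh and
rejected rather than silently reoriented.

Three tilings of the same tissue give the exact closure
$\sum_i A_i = \sum_j \tfrac12 F_j = \sum_k E_k$: cells, edge–link trapezia,
and the dual faces $E_k$. At an interior vertex the dual face is the
triangle of the three adjacent cell centres. At a peripheral vertex we take
the polygon $[\mathbf{r}_k, \mathbf{c}_{j_R}, \mathbf{R}_{i_c}, \dots,
\mathbf{R}_{i_1}, \mathbf{c}_{j_L}]$ bounded by the two half-edges at $k$
and the links of every edge incident to $k$. This construction was chosen
because each face side then lies on the line of an edge or link of $k$, so
flux and circulation sums over the face boundary are exact by the divergence
and Stokes theorems; in particular the identities
$\tfrac12\,\mathrm{div}^c\,\mathbf{m} = 1$ and
$\tfrac12\,\mathrm{div}^v\,\mathbf{m} = 1$, where $\mathbf{m}_j$ is the
intersection of the edge line with the link line, hold to machine precision
on every mesh — the package's substitute for boundary operator formulas that
are otherwise fixed only by the global identities they must satisfy.

## The sixteen operators and four Laplacians

Scalar fields live on vertices ($\mathcal{V}$), cells
($\mathcal{F} \simeq \mathcal{C}$), and per-edge 2-vectors live in
$\mathcal{E} \simeq \mathcal{L}$ (stored flat, components interleaved).
Eight primary operators (two gradients, two divergences, four curls) and
eight derived (tilde) operators are assembled as explicit sparse matrices;
the derived ones are the adjoints of the primary ones under the diagonal
inner products
$\mathsf{M}^\mathcal{V} = \mathrm{diag}(E_k)$,
$\mathsf{M}^\mathcal{F} = \mathrm{diag}(A_i)$,
$\mathsf{M}^\mathcal{E} = \mathrm{diag}(F_j)\otimes I_2$,
with divergence-type operators negative adjoints of gradients, as in the
continuum. These weights are pinned down by two requirements checked in the
test suite: the adjointness diagrams close to $10^{-10}$ on random fields,
and $[1, f]$ integrals reproduce area-weighted sums, so that
$[1,1] = \mathcal{A}$ on both networks.

Composing the operators yields four scalar Laplacians,
$$\mathsf{L}_\mathcal{V} = \mathsf{E}^{-1}\mathsf{A}^\top\mathsf{T}_e^{-1}\mathsf{A},\quad
  \mathsf{L}_\mathcal{T} = \mathsf{E}^{-1}\mathsf{A}^\top\mathsf{T}_l\mathsf{A},\quad
  \mathsf{L}_\mathcal{F} = \mathsf{H}^{-1}\mathsf{B}\,\mathsf{I}_b\,\mathsf{T}_e\mathsf{B}^\top,\quad
  \mathsf{L}_\mathcal{C} = \mathsf{H}^{-1}\mathsf{B}\,\mathsf{I}_b\,\mathsf{T}_l^{-1}\mathsf{B}^\top,$$
with $\mathsf{T}_e = \mathrm{diag}(t_j^2/F_j)$,
$\mathsf{T}_l = \mathrm{diag}(T_j^2/F_j)$. The mask $\mathsf{I}_b$ removes
peripheral links, which connect to only one cell centre; with it the cell
Laplacians are singular with a single uniform zero mode, matching the vertex
ones. Without it ($\mathsf{L}_\mathcal{F}^\mathrm{full}$,
$\mathsf{L}_\mathcal{C}^\mathrm{full}$) they are invertible and equal the
operator compositions $-\mathrm{div}^c\circ\widetilde{\mathrm{grad}}^c$ and
$-\widetilde{\mathrm{div}}^c\circ\mathrm{grad}^c$ exactly. Both forms are
exposed: the masked ones carry the spectra (eigenmodes shaped by the
monolayer outline at low order and localised around packing defects at high
order), the unmasked ones make the Helmholtz decomposition exactly solvable.
When edges and links are orthogonal ($F_j = t_j T_j$, e.g. an undeformed
honeycomb) the four Laplacians collapse pairwise to two.

## Helmholtz–Hodge decomposition

Any per-edge field $\mathbf{h}$ on a simply connected complex splits into
edge-parallel and edge-perpendicular parts generated by four scalar
potentials,
$$\mathbf{h} = \underbrace{\mathrm{grad}^v\psi^v + \widetilde{\mathrm{curl}}^c\Psi^c}_{\parallel}
 + \underbrace{\widetilde{\mathrm{grad}}^c\psi^c + \mathrm{curl}^v\Psi^v}_{\perp},$$
and analogously over the dual network with link-parallel/perpendicular
parts. A dimension count shows why the decomposition is exact here: the
vertex potentials each lose one constant (gauge, fixed as zero
$\mathsf{M}$-weighted mean) while the cell potentials are fully pinned by
the peripheral edges, leaving $2N_c + 2N_v - 2 = 2N_e$ free coefficients.
The package therefore solves the two cell problems with the invertible
Laplacians (no solvability condition, no gauge) and the two vertex problems
with the singular ones (right-hand sides are orthogonal to the kernel by
construction), and verifies reconstruction to $10^{-8}$ — the zero-mean
gauge applies to the vertex potentials only, which is a property of the
discrete boundary, not a numerical choice.

## Forces, the force potential, and stresses

At equilibrium the elastic forces $\mathbf{f}^\mathrm{el}_{ik} =
-\partial U_i/\partial\mathbf{r}_k$ balance at every interior vertex and
close around every cell, so their $\pi/2$-rotations tile the plane: the
tiling vertices define a per-edge vector potential $\mathbf{h}_j$ with
$\mathbf{f}^\mathrm{el}_{ik} = -\sum_j \boldsymbol{\epsilon}_i B_{ij}
\mathbf{h}_j A_{jk}$. The package integrates the rotated forces over a
spanning tree of the edge-adjacency graph and then verifies that every
independent cycle closes, refusing states that are not equilibria; the
additive constant is anchored so $\mathbf{h} + P_\mathrm{ext}\mathbf{m}$
has zero mean over peripheral edges, and every derived stress is
gauge-invariant.

Cell and junction stress tensors follow either as force moments or from
$\mathbf{h}$:
$$A_i\,\boldsymbol{\sigma}^c_i = \textstyle\sum_k C_{ik}\,\mathbf{r}_k\otimes\mathbf{f}^\mathrm{el}_{ik}
  = \sum_j B_{ij}(\mathbf{t}_j\otimes\mathbf{h}_j)\,\boldsymbol{\epsilon}_i,\qquad
  E_k\,\boldsymbol{\sigma}^v_k = \textstyle\sum_j A_{jk}(\mathbf{T}_j\otimes\mathbf{h}_j)\,\boldsymbol{\epsilon}_k,$$
the two routes agreeing to $10^{-8}$ per cell everywhere and per junction at
interior vertices (at peripheral vertices the elastic forces do not balance,
the moment is origin-dependent, and the gauge-invariant kite form from
$\mathbf{h}$ defines the stress). Effective pressures are half-traces,
equal to $-\tfrac12\,\mathrm{div}\,\mathbf{h}$ on each network.

**Sign convention.** The package uses a compression-positive convention:
stress is the moment of the forces cells *exert*, so at equilibrium
$\sum_i A_i\boldsymbol{\sigma}^c_i = +P_\mathrm{ext}\mathcal{A}\,\mathsf{I}$,
the area-weighted mean effective pressure equals $+P_\mathrm{ext}$, and the
affine (virtual-work) stress reads
$\boldsymbol{\varsigma}^c_i = -\bigl(\mathcal{P}_i\mathsf{I} +
(\mathcal{T}_iL_i/A_i)\mathsf{Q}_i\bigr)$ with the shape tensor
$L_i\mathsf{Q}_i = \sum_j \bar B_{ij}\,\mathbf{t}_j\otimes\hat{\mathbf{t}}_j$
(so $\mathrm{Tr}\,\mathsf{Q}_i = 1$). This is the one convention under which
the force-potential relations ($P_\mathrm{eff} = -\tfrac12\mathrm{div}\,
\mathbf{h}$, the $\breve{\mathbf{h}} = \mathbf{h} + P_\mathrm{ext}\mathbf{m}$
solvability construction, and the integral
$\sum_i A_i P_{\mathrm{eff},i} = \mathcal{A}P_\mathrm{ext}$) and the
virtual-work relations are simultaneously consistent; the common
tension-positive convention flips every stress sign at once.

## Stress potentials and couple stress

With zero couple on cells ($\mathrm{curl}^c\,\mathbf{h} = 0$ at equilibrium,
hence $\Psi^c \equiv 0$), the remaining seven potentials are computed from
Poisson problems. The divergence problems on the masked Laplacians use the
corrected field $\breve{\mathbf{h}}$, whose divergences have zero
area-weighted mean by the $\mathbf{m}$-identities — this is the discrete
solvability condition, and its residual is checked, not assumed. The two
dual cell problems use the invertible Laplacian (their right-hand sides
carry peripheral flux that the masked operator cannot represent). $\psi^c$
and $\check\psi^v$ are the discrete Airy functions — second "derivatives"
reproduce the pressure patterns $2P_\mathrm{eff} - 2P_\mathrm{ext}$ — and
$\Psi^v$, $\check\Psi^v$ are the Mindlin-type potentials of the couple
stress
$$\boldsymbol{\mu} = -\mathrm{curl}^v\,\Psi^v \in \mathcal{E}^\perp,\qquad
  \mathrm{div}^c\boldsymbol{\mu} = 0 \text{ (exact sequence)},\qquad
  \mathrm{CURL}^v\check{\boldsymbol{\mu}} = -\mathsf{L}_\mathcal{T}\check\Psi^v
  = -2\,\sigma^{v(a)},$$
linking the potentials to the measured junction torques
$\tfrac12\,\mathrm{CURL}^v\mathbf{h}$, which are nonzero on disordered
monolayers (largest near the margin) while cells individually carry none.
On grown monolayers edges and links are nearly orthogonal, so
$\check\Psi^v \approx -\Psi^v$; the package tests this as an approximate
(30% in norm) statement, not an identity.

The affine route attributes junction couples to pressure differences:
$\mathfrak{m}^c_i = \frac{\mathcal{P}_i + P_\mathrm{ext}}{12A_i}\sum_j t_j^2
\mathbf{n}_{ij}$ per cell, repartitioned onto edges as
$\mathfrak{m}_j = \frac{t_j^2}{6F_j}\sum_i(\mathcal{P}_i +
P_\mathrm{ext})\mathbf{n}_{ij}$ (an exact identity, tested), with junction
couple $\mathcal{C}_k = \mathrm{CURL}^v\mathfrak{m} =
-\frac{1}{6E_k}\sum_{i,j}\mathcal{P}_iB_{ij}t_j^2A_{jk}$ at interior
vertices. It vanishes for uniform pressures or uniform edge lengths and is
generically nonzero under disorder — but it is a different quantity from the
measured torque: on our equilibrium monolayers its scale is roughly a third
of the measured one, and the suite reports the ratio rather than forcing
agreement, since the affine (Cauchy–Born) assumption ignores the local
re-equilibration of vertices.

## The synthetic-monolayer generator

Monolayers are grown from a single unit-area hexagon by repeated division
and relaxation, under the default parameters above. Choices the package
makes where a protocol is not otherwise fixed:

* **Which cell divides.** Probability proportional to current area — cells
  divide once they have grown. Uniform choice lets chains of small cells
  elongate the tissue; size-dependent division keeps the monolayer compact,
  as real proliferating epithelia are.
* **Division plane.** Through the vertex centroid, perpendicular to the
  cell's long principal axis (Hertwig's rule) with a ±0.2 rad jitter;
  planes always bisect two edges (never pass through a vertex, keeping
  junctions tricellular) and must leave both daughters with at least two
  original vertices.
* **Neighbour exchanges.** Internal edges shorter than 0.03 undergo T1
  transitions during growth (including a boundary variant when one endpoint
  sits on the margin, where the edge is handed to the outer cell). Without
  them edges genuinely collapse around 40–60 cells. After growth the
  incidence matrices are held fixed; at the default parameters the final
  states are jammed and no sub-threshold edge remains.
* **Relaxation.** Between divisions, L-BFGS minimisation of the energy
  (exact gradients) to a force residual of $10^{-8}$; the final state gets a
  finite-difference Newton polish to $10^{-10}$, which the downstream
  $10^{-8}$ cycle-closure and torque checks require. A plain forward-Euler
  descent with adaptive (Barzilai–Borwein) steps and energy backtracking is
  kept as `relax(method = "descent")`; it is the literal overdamped dynamics
  and is what the monotone-energy tests exercise, but it stalls beyond
  ~50 cells, which is why growth uses the minimiser — only equilibria are
  analysed, so the path to them is immaterial.
* **Robustness.** A division whose relaxed state fails to converge or
  degenerates (inverted cell, vanishing trapezium) is rolled back and a
  fresh division drawn; runs are reproducible from the seed.

What the generator does *not* emulate: curved or multiply connected tissues,
fluctuating or motile vertices, cell death and extrusion, heterogeneous cell
mechanics, and viscous (rate-dependent) stresses. Passing tests on these
synthetic monolayers therefore validate the calculus and the equilibrium
stress analysis, not any claim about dynamic or heterogeneous real tissues.

## Numerical choices

Dense symmetric eigensolvers (on the $\mathsf{M}^{1/2}$-similarity
transform) are used throughout — the monolayers of interest have at most a
few hundred vertices. Poisson solves deflate the kernel with a relative
rank cutoff of $10^{-10}$ and report residuals; solvability violations are
errors carrying the offending integral. Geometry treats
$F_j \le 10^{-12}\,\overline{F}$ as degenerate and refuses. Problem sizes
in the tests and the acceptance script (112-cell monolayers for spectra,
50-cell for the pressure and torque checks, a 2-ring jittered honeycomb for
operator identities) were chosen as the smallest at which every phenomenon
of interest — disorder, boundary layers, nontrivial spectra — is present.

## A worked example

```{r example, eval = FALSE}
mono <- grow(50, sim_config(seed = 101))
mono <- analyse(mono)
summary(mono)
#> Monolayer of 50 cells, total area 6.3662
#>   area-weighted mean effective pressure: 0.2 (P_ext = 0.2 )
#>   cell torque (max |curl h| / 2): 5.33e-14
#>   junction torque (max |CURL h| / 2): 0.0799
plot(mono, "P_eff")
```

The mean effective pressure recovers the applied external pressure to
solver precision, cells carry no torque, and tricellular junctions do — the
central qualitative result the package exists to compute.

## Known limitations

The peripheral-kite operator variants are validated through the global
identities they satisfy (the $\mathbf{m}$-identities, the area-weighted
integrals, the exact dual tiling) rather than against a printed closed form;
they deliberately trade the $\mathsf{B}\mathsf{A}=0$ exact sequences at the
margin for exact boundary fluxes, so exact-sequence properties are stated
for the plain operator set. Multiply connected monolayers (holes) are out of
scope — the Helmholtz argument requires simple connectivity. The affine
couple is reported as a comparison quantity only.
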