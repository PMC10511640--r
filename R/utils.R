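# Shared geometric primitives and small helpers.

## The 2D Levi-Civita matrix used throughout: eps = [[0, 1], [-1, 0]], a
## clockwise pi/2 rotation. Cell faces carry orientation eps_i = -eps,
## triangles of the dual network eps_k = +eps; with counterclockwise cell
## traversal this makes all cell areas and trapezium areas F_j positive.
EPS_CW <- matrix(c(0, -1, 1, 0), 2, 2)

## rotate rows of a 2-column matrix clockwise / counterclockwise by pi/2
rot_cw <- function(v) cbind(v[, 2], -v[, 1])
rot_ccw <- function(v) cbind(-v[, 2], v[, 1])

## z-component of the cross product of row pairs
cross2 <- function(a, b) a[, 1] * b[, 2] - a[, 2] * b[, 1]

## signed polygon area (counterclockwise positive)
shoelace <- function(pts) {
  n <- nrow(pts)
  nxt <- c(seq_len(n)[-1], 1L)
  sum(pts[, 1] * pts[nxt, 2] - pts[nxt, 1] * pts[, 2]) / 2
}

## per-edge vector fields are stored flat with interleaved components
## (x_1, y_1, x_2, y_2, ...); these convert to/from an Ne x 2 matrix
as_edge_matrix <- function(b) {
  if (is.matrix(b) && ncol(b) == 2) return(b)
  matrix(b, ncol = 2, byrow = TRUE)
}
as_edge_flat <- function(b) {
  if (!is.matrix(b)) return(as.numeric(b))
  as.vector(t(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)
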