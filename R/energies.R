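#' Weeks-Chandler-Andersen (WCA) energy
#'
#' Purely repulsive excluded-volume interaction between any two beads:
#' \deqn{U(r) = 4 k_BT [(\sigma/r)^{12} - (\sigma/r)^6 + 1/4]} for
#' \eqn{r < 2^{1/6}\sigma}, and exactly 0 beyond. Continuous at the cutoff.
#'
#' @param r separation in sigma (vectorized, all > 0).
#' @return energy in kBT.
#' @export
wca_energy <- function(r) {
  if (any(r <= 0)) stop("wca_energy: separation must be positive")
  u <- numeric(length(r))
  inside <- r < 2^(1/6)
  ri6 <- (1 / r[inside])^6
  u[inside] <- 4 * (ri6^2 - ri6 + 0.25)
  u
}

# radial force magnitude -dU/dr (positive = repulsive)
wca_force <- function(r) {
  f <- numeric(length(r))
  inside <- r < 2^(1/6)
  ri <- 1 / r[inside]
  f[inside] <- 4 * (12 * ri^13 - 6 * ri^7)
  f
}

#' FENE backbone bond energy
#'
#' Finitely extensible non-linear elastic spring between consecutive chain
#' beads: \deqn{U(r) = -\tfrac{K_f R_0^2}{2}\ln[1-(r/R_0)^2].}
#' A separation at or beyond \eqn{R_0} means the bond has blown up, which is
#' a fatal diagnostic (usually a timestep problem), not a clampable value.
#'
#' @param r separation in sigma; must satisfy 0 <= r < r0.
#' @param k spring constant Kf (kBT/sigma^2).
#' @param r0 maximum extension R0 (sigma).
#' @return energy in kBT.
#' @export
fene_energy <- function(r, k = 30, r0 = 1.6) {
  if (any(r < 0)) stop("fene_energy: separation must be >= 0")
  if (any(r >= r0))
    stop("fene_energy: bond extension r >= R0 (bond blow-up; reduce the timestep)")
  -(k * r0^2 / 2) * log(1 - (r / r0)^2)
}

fene_force <- function(r, k = 30, r0 = 1.6) {
  # -dU/dr; attractive (negative) for r > 0
  -k * r / (1 - (r / r0)^2)
}

#' Kratky-Porod bending energy
#'
#' Stiffness of the chromatin fiber:
#' \deqn{U(\theta) = (l_p/\sigma)(1-\cos\theta)} with \eqn{\theta} the angle
#' between successive bond vectors (0 = straight chain).
#'
#' @param theta angle in radians, in `[0, pi]`.
#' @param lp persistence parameter in sigma.
#' @return energy in kBT.
#' @export
bending_energy <- function(theta, lp = 4) {
  if (any(theta < 0 | theta > pi))
    stop("bending_energy: theta must lie in [0, pi]")
  lp * (1 - cos(theta))
}

#' Normalization constant for the truncated-shifted Lennard-Jones potential
#'
#' Returns N such that the attractive potential, evaluated with unit well
#' depth and cutoff `rc`, reaches exactly -1 at its minimum. Computed by
#' bracketed 1-D numerical minimization (robust to any rc) and cached per rc.
#'
#' @param rc cutoff in sigma; must exceed 2^(1/6).
#' @return dimensionless normalization constant (>= 1, -> 1 as rc -> Inf).
#' @export
lj_normalization <- function(rc) {
  if (rc <= 2^(1/6))
    stop("lj_normalization: rc must exceed 2^(1/6) sigma (no attractive well)")
  key <- sprintf("%.12g", rc)
  cached <- .lj_norm_cache[[key]]
  if (!is.null(cached)) return(cached)
  shift <- (1 / rc)^12 - (1 / rc)^6
  raw <- function(d) { d6 <- (1 / d)^6; 4 * (d6^2 - d6 - shift) }
  opt <- stats::optimize(raw, interval = c(0.8, rc))
  n <- -1 / opt$objective
  assign(key, n, envir = .lj_norm_cache)
  n
}
.lj_norm_cache <- new.env(parent = emptyenv())

#' Protein-chromatin (and chromatin-chromatin) attraction energy
#'
#' Truncated and shifted Lennard-Jones potential with the normalization that
#' makes the well depth exactly `-eps` at the minimum \eqn{2^{1/6}\sigma}:
#' \deqn{U(d) = 4\epsilon N[(\sigma/d)^{12}-(\sigma/d)^6-(\sigma/r_c)^{12}+(\sigma/r_c)^6]}
#' for \eqn{d < r_c}, 0 beyond. The same single formula is used on the
#' repulsive branch below the minimum (no splice to WCA). With `eps = 0` the
#' interaction degenerates to zero, i.e. the steric-only limit is handled by
#' the WCA term instead.
#'
#' @param d separation in sigma (> 0).
#' @param eps well depth in kBT (>= 0).
#' @param rc cutoff in sigma.
#' @return energy in kBT.
#' @export
tf_chromatin_energy <- function(d, eps, rc = 1.8) {
  if (any(d <= 0)) stop("tf_chromatin_energy: separation must be positive")
  if (any(eps < 0)) stop("tf_chromatin_energy: eps must be >= 0")
  n <- lj_normalization(rc)
  u <- numeric(length(d))
  inside <- d < rc
  d6 <- (1 / d[inside])^6
  shift <- (1 / rc)^12 - (1 / rc)^6
  u[inside] <- 4 * eps * n * (d6^2 - d6 - shift)
  u
}

tf_chromatin_force <- function(d, eps, rc = 1.8) {
  n <- lj_normalization(rc)
  f <- numeric(length(d))
  inside <- d < rc
  di <- 1 / d[inside]
  f[inside] <- 4 * eps * n * (12 * di^13 - 6 * di^7)
  f
}

#' Loop-extruder bond energy
#'
#' The spring tying the two anchor beads of a loop extruder: a harmonic
#' spring plus short-range WCA repulsion,
#' \deqn{U(r) = U_{WCA}(r) + k_{extr}(r-r_0)^2.}
#'
#' @param r separation in sigma (> 0).
#' @param k spring constant (kBT/sigma^2).
#' @param r0 rest length (sigma).
#' @return energy in kBT.
#' @export
extruder_bond_energy <- function(r, k = 40, r0 = 1.5) {
  wca_energy(r) + k * (r - r0)^2
}

#' Crumple (heteromorphic) bond energy
#'
#' Harmonic spring linking next-to-nearest neighbour beads (i, i+2) in
#' regions without the H3K27ac mark, giving the fiber its locally compact
#' ("crumpled") form: \deqn{U(r) = k_h (r - r_0)^2.}
#'
#' @param r separation in sigma (>= 0).
#' @param k spring constant (kBT/sigma^2).
#' @param r0 rest length (sigma).
#' @return energy in kBT.
#' @export
crumple_bond_energy <- function(r, k = 200, r0 = 1.1) {
  if (any(r < 0)) stop("crumple_bond_energy: separation must be >= 0")
  k * (r - r0)^2
}
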