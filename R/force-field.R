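#' Shell interaction strength presets for the rigidity classes
#'
#' The nanoparticle's mechanical rigidity is set by the strength `eps_np` of
#' the orientation-weighted soft-core potential acting between its shell
#' beads. The presets were calibrated (short single-NP runs at kT = 0.23 eps)
#' so that the hard shell's gyration aspect ratio stays within 2% of its
#' initial value while the soft shell's aspect-ratio fluctuations exceed
#' 15%, reproducing the deformation taxonomy of the three classes: soft
#' shells deform excessively and irregularly, semi-elastic shells deform
#' into ellipsoids, hard shells stay spherical.
#'
#' Rigidity in this model is controlled jointly by the interaction strength
#' `eps_np` (cohesion) and the orientation weight `mu` (bending stiffness),
#' so each class preset fixes both.
#'
#' @return A data frame with one row per class (`soft`, `semi_elastic`,
#'   `hard`) and columns `np_eps`, `np_mu`.
#' @export
rigidity_presets <- function() {
  data.frame(row.names = c("soft", "semi_elastic", "hard"),
             np_eps = c(5, 6, 16),
             np_mu = c(1, 1.5, 3))
}

#' Interaction parameters for the network + nanoparticle system
#'
#' Collects every interaction constant: 12-6 Lennard-Jones pairs (cut and
#' shifted) for all bead pairs except shell-shell pairs, the
#' orientation-weighted soft-core potential between shell beads, harmonic
#' fiber bonds (constants live on the bonds themselves) and node tethers.
#'
#' Defaults, in reduced units with beads of radius sigma (so beads touch at
#' 2 sigma): polymer-polymer interactions are purely repulsive
#' (Weeks-Chandler-Andersen, cutoff `2^(1/6) sigma_lj`); polymer-shell pairs
#' attract with well depth `eps_polymer_np` (the adhesion dial, scanned over
#' 0.02-0.2 eps) and cutoff `2.5 sigma_lj`; shell-shell pairs use the
#' soft-core membrane potential with minimum at `np_rmin` (the shell bead
#' spacing), cutoff `np_rcut`, attraction sharpness `zeta`, orientation
#' weight `mu` and spontaneous curvature angle `theta0`.
#'
#' @param rigidity Rigidity class name used to pick `np_eps` and `np_mu`
#'   from [rigidity_presets()]; `"per_np"` to give every NP the preset of
#'   its own rigidity class (mixed-class systems); `NULL` to use `np_eps`
#'   and `np_mu` directly.
#' @param np_eps Shell bead-bead interaction strength (eps); the rigidity
#'   dial.
#' @param np_rmin Distance of the soft-core minimum (sigma).
#' @param np_rcut Shell pair cutoff (sigma); must exceed `np_rmin`.
#' @param np_zeta Attraction-well sharpness exponent (dimensionless).
#' @param np_mu Orientation-weight strength (dimensionless).
#' @param np_theta0 Spontaneous curvature angle (radians).
#' @param eps_polymer_np Polymer-shell LJ well depth (eps).
#' @param eps_polymer_polymer Polymer-polymer LJ strength (eps); repulsive
#'   only (WCA cutoff).
#' @param sigma_lj LJ length parameter for every pair (sigma); 2 for
#'   radius-sigma beads.
#' @param lj_cutoff Cutoff for attractive LJ pairs (sigma).
#' @param tether_k Node tether spring constant (eps/sigma^2).
#' @param skin Neighbor-list skin (sigma).
#' @return An object of class `force_field`.
#' @export
#' @examples
#' ff <- force_field(rigidity = "semi_elastic")
#' ff$np_eps
force_field <- function(rigidity = NULL, np_eps = 4, np_rmin = 2.33,
                        np_rcut = 4.15, np_zeta = 4, np_mu = 3,
                        np_theta0 = 0.233,
                        eps_polymer_np = 0.1, eps_polymer_polymer = 1,
                        sigma_lj = 2, lj_cutoff = 2.5 * sigma_lj,
                        tether_k = 10, skin = 0.8) {
  if (!is.null(rigidity) && rigidity != "per_np") {
    presets <- rigidity_presets()
    if (!rigidity %in% rownames(presets))
      stop("unknown rigidity class: ", rigidity)
    np_eps <- presets[rigidity, "np_eps"]
    np_mu <- presets[rigidity, "np_mu"]
  }
  if (np_rmin >= np_rcut) stop("need np_rmin < np_rcut")
  if (any(c(np_eps, eps_polymer_np, eps_polymer_polymer) < 0))
    stop("interaction strengths must be >= 0")
  if (lj_cutoff <= 0) stop("lj_cutoff must be positive")
  structure(
    list(np_eps = np_eps, np_rmin = np_rmin, np_rcut = np_rcut,
         np_zeta = np_zeta, np_mu = np_mu, np_theta0 = np_theta0,
         eps_polymer_np = eps_polymer_np,
         eps_polymer_polymer = eps_polymer_polymer,
         sigma_lj = sigma_lj, lj_cutoff = lj_cutoff,
         tether_k = tether_k, skin = skin,
         rigidity = rigidity %||% "custom"),
    class = "force_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.force_field <- function(x, ...) {
  cat("<force_field>\n")
  cat(sprintf("  shell: eps_np %.3g (class %s), rmin %.3g, rcut %.3g, zeta %g, mu %g\n",
              x$np_eps, x$rigidity, x$np_rmin, x$np_rcut, x$np_zeta, x$np_mu))
  cat(sprintf("  LJ: polymer-shell eps %.3g (cutoff %.3g), polymer-polymer WCA eps %.3g, sigma %.3g\n",
              x$eps_polymer_np, x$lj_cutoff, x$eps_polymer_polymer, x$sigma_lj))
  cat(sprintf("  tether_k %.3g\n", x$tether_k))
  invisible(x)
}

# 3x3 type-pair tables (polymer, node, np_bead) for the C++ core.
# Same-NP shell pairs use the membrane potential; shell beads of different
# NPs interact through plain WCA repulsion (distinct particles do not fuse),
# which is the [3, 3] LJ entry here.
as_cpp_params <- function(ff, system = NULL) {
  wca_cut <- 2^(1 / 6) * ff$sigma_lj
  eps <- matrix(ff$eps_polymer_polymer, 3, 3)
  eps[3, 1:2] <- eps[1:2, 3] <- ff$eps_polymer_np
  sig <- matrix(ff$sigma_lj, 3, 3)
  cut <- matrix(wca_cut, 3, 3)
  cut[3, 1:2] <- cut[1:2, 3] <- ff$lj_cutoff
  out <- list(lj_eps = eps, lj_sigma = sig, lj_cutoff = cut,
              np_eps = ff$np_eps, np_rmin = ff$np_rmin, np_rcut = ff$np_rcut,
              np_zeta = as.integer(ff$np_zeta), np_mu = ff$np_mu,
              np_theta0 = ff$np_theta0, tether_k = ff$tether_k,
              skin = ff$skin)
  if (identical(ff$rigidity, "per_np") && !is.null(system) &&
      length(system$np_models) > 0) {
    N <- nrow(system$positions)
    ev <- rep(ff$np_eps, N)
    mv <- rep(ff$np_mu, N)
    pres <- rigidity_presets()
    for (k in seq_along(system$np_models)) {
      cls <- system$np_models[[k]]$rigidity_class
      if (cls %in% rownames(pres)) {
        idx <- which(!is.na(system$np_id) & system$np_id == k)
        ev[idx] <- pres[cls, "np_eps"]
        mv[idx] <- pres[cls, "np_mu"]
      }
    }
    out$np_eps_bead <- ev
    out$np_mu_bead <- mv
  }
  out
}

max_cutoff <- function(ff) max(2^(1 / 6) * ff$sigma_lj, ff$lj_cutoff,
                               ff$np_rcut)

#' Harmonic bond energy and force
#'
#' Bond energy `k (r - r0)^2`; the returned force is `-dU/dr`
#' (`-2 k (r - r0)`), i.e. positive when the bond is compressed.
#'
#' @param r Current bond length (sigma), `> 0`.
#' @param k Spring constant (eps/sigma^2).
#' @param r0 Rest length (sigma).
#' @return List with `energy` (eps) and `force` (eps/sigma).
#' @export
harmonic_bond <- function(r, k, r0) {
  stopifnot(all(r > 0))
  list(energy = k * (r - r0)^2, force = -2 * k * (r - r0))
}

#' Cut-and-shifted 12-6 Lennard-Jones pair
#'
#' Standard 12-6 LJ with the energy shifted to zero at the cutoff; zero
#' beyond it. The returned force is `-dU/dr`.
#'
#' @param r Separation (sigma), `> 0`.
#' @param eps Well depth (eps).
#' @param sigma LJ length (sigma).
#' @param cutoff Cutoff distance (sigma); `Inf` gives the unshifted form.
#' @return List with `energy` and `force`.
#' @export
lj_pair <- function(r, eps, sigma, cutoff) {
  stopifnot(r > 0)
  lj_pair_cpp(r, eps, sigma, cutoff)
}

#' Orientation-weighted soft-core pair between two shell beads
#'
#' The one-particle-thick membrane interaction: a soft repulsive core
#' `u_R(r) = eps ((rmin/r)^4 - 2 (rmin/r)^2)` inside `rmin`, a cosine-shaped
#' attractive well `u_A(r) = -eps cos^(2 zeta)(pi (r - rmin) / (2 (rcut -
#' rmin)))` between `rmin` and `rcut`, and an orientation weight
#' `phi = 1 + mu (a - 1)` with
#' `a = (n_i x rhat) . (n_j x rhat) + sin(theta0) (n_j - n_i) . rhat -
#' sin^2(theta0)`. Below `rmin` the energy is `u_R + (1 - phi) eps`;
#' between `rmin` and `rcut` it is `u_A phi`; zero beyond `rcut`. Forces and the
#' generalized orientation forces (`-dU/dn`) are exact derivatives.
#'
#' @param r_vec Separation vector from bead i to bead j (sigma).
#' @param n_i,n_j Unit orientation vectors (checked to 1e-6).
#' @param params A [force_field()] (fields `np_eps`, `np_rmin`, `np_rcut`,
#'   `np_zeta`, `np_mu`, `np_theta0`).
#' @return List with `energy`, `force_i`, `force_j`, `gn_i`, `gn_j` (the
#'   generalized forces on the two orientation vectors).
#' @export
np_pair <- function(r_vec, n_i, n_j, params) {
  if (sqrt(sum(r_vec^2)) <= 0) stop("zero separation")
  if (abs(sqrt(sum(n_i^2)) - 1) > 1e-6 || abs(sqrt(sum(n_j^2)) - 1) > 1e-6)
    stop("orientation vectors must be unit length (tolerance 1e-6)")
  np_pair_cpp(r_vec, n_i, n_j, params$np_eps, params$np_rmin,
              params$np_rcut, as.integer(params$np_zeta), params$np_mu,
              params$np_theta0)
}

#' Evaluate all forces, orientation torques and the potential energy
#'
#' Assembles every term under the minimum-image convention using a
#' cell-binned Verlet list: harmonic fiber bonds, node tethers, LJ pairs for
#' all non-bonded pairs except shell-shell pairs, and the
#' orientation-weighted soft-core potential for shell-shell pairs (beads
#' inside the same rigid NP excluded; their geometry is fixed). Bonded
#' (1-2) pairs are excluded from the non-bonded terms.
#'
#' @param system A `bead_system`.
#' @param params A [force_field()].
#' @return A `force_result` list: `forces` (N x 3, eps/sigma),
#'   `normal_torques` (N x 3, generalized forces on orientation vectors),
#'   `potential_energy` (eps) and the per-term `breakdown`.
#' @export
compute_forces <- function(system, params) {
  stopifnot(inherits(system, "bead_system"), inherits(params, "force_field"))
  if (system$box_length < 2 * max_cutoff(params))
    stop("box smaller than twice the maximum interaction cutoff")
  res <- compute_forces_cpp(as_cpp_system(system),
                            as_cpp_params(params, system))
  structure(res, class = "force_result")
}

#' @export
print.force_result <- function(x, ...) {
  cat(sprintf("<force_result> potential energy %.6g eps\n",
              x$potential_energy))
  print(x$breakdown)
  invisible(x)
}
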