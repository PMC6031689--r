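#' Specify a regular cross-linked polymer network
#'
#' Geometry and spring constants for a cubic, periodic, regular network of
#' fibers running along all three axes, cross-linked at shared node beads.
#' All lengths are in reduced units of sigma (the bead radius).
#'
#' The number of mesh cells per axis is `n = round(box_length / mesh_size)`,
#' so the effective mesh is `box_length / n`; this keeps both the printed box
#' and the chain count attainable when the two are not commensurate (e.g. a
#' 98 sigma box with a nominal 16 sigma mesh gives n = 6 and an effective
#' mesh of ~16.33 sigma). The bead spacing along fibers is likewise snapped
#' so that an integer number of beads fits in each mesh cell.
#'
#' @param box_length Cubic box edge (sigma).
#' @param mesh_size Nominal distance between cross-linked fibers (sigma).
#' @param bead_spacing Target distance between consecutive fiber beads
#'   (sigma). Default 2, i.e. radius-sigma beads touching.
#' @param bond_k Harmonic spring constant between consecutive fiber beads
#'   (eps/sigma^2); bond energy is `k (r - r0)^2`.
#' @param tether_k Spring constant tethering each node bead to its initial
#'   position (eps/sigma^2).
#' @return An object of class `network_spec`.
#' @export
#' @examples
#' spec <- network_spec(box_length = 98, mesh_size = 16)
#' spec$n_cells      # 6
#' 3 * spec$n_cells^2  # 108 chains
network_spec <- function(box_length = 98, mesh_size = 16, bead_spacing = 2,
                         bond_k = 100, tether_k = 10) {
  stopifnot(is.numeric(box_length), is.numeric(mesh_size),
            is.numeric(bead_spacing))
  if (bead_spacing <= 0) stop("bead_spacing must be positive")
  if (!(box_length > mesh_size && mesh_size > bead_spacing))
    stop("need box_length > mesh_size > bead_spacing > 0")
  n <- round(box_length / mesh_size)
  if (n < 1) stop("box must contain at least one mesh cell")
  mesh_eff <- box_length / n
  m_div <- round(mesh_eff / bead_spacing)
  if (m_div < 1)
    stop("bead_spacing does not fit the effective mesh: ",
         "no bead interval divides ", signif(mesh_eff, 5), " sigma")
  structure(
    list(box_length = box_length, mesh_size = mesh_size,
         bead_spacing = bead_spacing, bond_k = bond_k, tether_k = tether_k,
         n_cells = as.integer(n), mesh_eff = mesh_eff,
         spacing_eff = mesh_eff / m_div, beads_per_cell = m_div),
    class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>\n")
  cat(sprintf("  box %.4g sigma, mesh %.4g sigma (effective %.4g, %d cells/axis)\n",
              x$box_length, x$mesh_size, x$mesh_eff, x$n_cells))
  cat(sprintf("  fiber bead spacing %.4g sigma (%d beads/cell), %d chains\n",
              x$spacing_eff, x$beads_per_cell, 3L * x$n_cells^2))
  invisible(x)
}

new_bead_system <- function(positions, velocities, normals, unwrapped,
                            bead_type, np_id, bonds, tether_index,
                            tether_anchor, box_length, masses,
                            rigid = logical(0), np_models = list(),
                            meta = list()) {
  structure(
    list(positions = positions, velocities = velocities, normals = normals,
         unwrapped = unwrapped, bead_type = bead_type, np_id = np_id,
         bonds = bonds, tether_index = tether_index,
         tether_anchor = tether_anchor, box_length = box_length,
         masses = masses, rigid = rigid, np_models = np_models, meta = meta),
    class = "bead_system")
}

#' @export
print.bead_system <- function(x, ...) {
  cat("<bead_system>\n")
  cat(sprintf("  %d beads (%d polymer, %d node, %d shell) in a %.4g sigma box\n",
              nrow(x$positions), sum(x$bead_type == "polymer"),
              sum(x$bead_type == "node"), sum(x$bead_type == "np_bead"),
              x$box_length))
  cat(sprintf("  %d bonds, %d tethered nodes, %d NPs (%d rigid)\n",
              nrow(x$bonds), length(x$tether_index),
              length(x$rigid), sum(x$rigid)))
  invisible(x)
}

wrap_coords <- function(x, box) x - box * floor(x / box)

#' Build the regular cross-linked polymer network
#'
#' Lays fibers parallel to each axis at every transverse grid line of the
#' mesh lattice. Each fiber spans the box and closes on itself through the
#' periodic boundary; a single shared node bead sits at each three-fiber
#' intersection and is tethered to its initial position. Consecutive beads
#' along a fiber are bonded harmonically at rest length equal to the
#' generated spacing. The chain count is `3 n^2` for `n` mesh cells per axis.
#'
#' @param spec A [network_spec()].
#' @return A `bead_system` containing polymer and node beads. The chain
#'   count, effective mesh and spacing are recorded in `$meta`.
#' @export
#' @examples
#' net <- build_network(network_spec(49, 16))
#' net$meta$chain_count  # 27
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  n <- spec$n_cells
  m <- spec$beads_per_cell
  s <- spec$spacing_eff
  mesh <- spec$mesh_eff
  box <- spec$box_length
  nb <- n * m                       # beads along one fiber

  # shared node beads at the lattice points, index a + n b + n^2 c + 1
  node_grid <- expand.grid(a = 0:(n - 1), b = 0:(n - 1), c = 0:(n - 1))
  node_pos <- as.matrix(node_grid) * mesh
  n_nodes <- nrow(node_pos)
  node_id <- function(a, b, c) a + n * b + n * n * c + 1L

  pos_list <- list(node_pos)
  next_id <- n_nodes + 1L
  bonds <- vector("list", 3L * n * n)
  fib <- 0L
  coords_line <- (0:(nb - 1)) * s
  is_node_slot <- (0:(nb - 1)) %% m == 0L
  cell_of <- (0:(nb - 1)) %/% m     # which mesh cell a node slot belongs to

  for (axis in 1:3) {
    for (jb in 0:(n - 1)) {
      for (kb in 0:(n - 1)) {
        fib <- fib + 1L
        ids <- integer(nb)
        # node slots reuse the shared node beads
        for (i in which(is_node_slot)) {
          cell <- cell_of[i]
          ids[i] <- switch(axis,
            node_id(cell, jb, kb), node_id(jb, cell, kb), node_id(jb, kb, cell))
        }
        free <- which(!is_node_slot)
        nfree <- length(free)
        if (nfree > 0) {
          ids[free] <- next_id:(next_id + nfree - 1L)
          next_id <- next_id + nfree
          along <- coords_line[free]
          p <- switch(axis,
            cbind(along, jb * mesh, kb * mesh),
            cbind(jb * mesh, along, kb * mesh),
            cbind(jb * mesh, kb * mesh, along))
          pos_list[[length(pos_list) + 1L]] <- p
        }
        bonds[[fib]] <- cbind(ids, c(ids[-1], ids[1]))
      }
    }
  }

  positions <- do.call(rbind, pos_list)
  dimnames(positions) <- NULL
  N <- nrow(positions)
  bonds <- do.call(rbind, bonds)
  bonds <- cbind(bonds, spec$bond_k, s)
  dimnames(bonds) <- NULL

  bead_type <- rep("polymer", N)
  bead_type[seq_len(n_nodes)] <- "node"

  new_bead_system(
    positions = wrap_coords(positions, box),
    velocities = matrix(0, N, 3),
    normals = matrix(NA_real_, N, 3),
    unwrapped = positions,
    bead_type = bead_type,
    np_id = rep(NA_integer_, N),
    bonds = bonds,
    tether_index = seq_len(n_nodes),
    tether_anchor = wrap_coords(node_pos, box),
    box_length = box,
    masses = rep(1, N),
    meta = list(spec = spec, chain_count = 3L * n * n,
                n_cells = n, mesh_eff = mesh, spacing_eff = s))
}

#' Number of polymer chains in a network
#'
#' @param x A `bead_system` built by [build_network()] (or a `network_spec`).
#' @return Integer chain count, `3 n^2`.
#' @export
chain_count <- function(x) {
  if (inherits(x, "network_spec")) return(3L * x$n_cells^2)
  stopifnot(inherits(x, "bead_system"))
  x$meta$chain_count
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

new_np_model <- function(bead_positions, bead_normals, nominal_diameter,
                         rigidity_class, aspect_ratio, target_spacing) {
  structure(
    list(bead_positions = bead_positions, bead_normals = bead_normals,
         nominal_diameter = nominal_diameter, rigidity_class = rigidity_class,
         aspect_ratio = aspect_ratio, target_spacing = target_spacing),
    class = "np_model")
}

#' @export
print.np_model <- function(x, ...) {
  cat(sprintf("<np_model> %s, %d beads, nominal diameter %.4g sigma, AR %.3g\n",
              x$rigidity_class, nrow(x$bead_positions),
              x$nominal_diameter, x$aspect_ratio))
  invisible(x)
}

#' Build a one-particle-thick spherical nanoparticle shell
#'
#' Beads are placed quasi-uniformly on the sphere surface using a
#' deterministic Fibonacci lattice; each bead carries an outward radial unit
#' orientation vector. The bead count is `round(pi d^2 / s^2)` so that each
#' bead tiles roughly `s^2` of surface area (the sphere area in these units
#' is `pi d^2` with `d` the diameter).
#'
#' @param diameter Shell diameter (sigma).
#' @param target_spacing Target inter-bead spacing on the surface (sigma).
#'   Default 2.5. The discretization sets the per-NP scale of the
#'   polymer-contact counts; 2.5 sigma (about 50 beads on a 10 sigma shell)
#'   reproduces the published per-NP bead-contact scale of the model.
#' @param rigidity_class One of `"soft"`, `"semi_elastic"`, `"hard"`,
#'   `"rigid_sphere"`. The class selects the shell interaction strength
#'   preset at the force-field stage; `rigid_sphere` is propagated as a
#'   rigid body.
#' @return An `np_model` (body-frame bead positions centered at the origin).
#' @export
#' @examples
#' shell <- build_np_shell(10)
#' nrow(shell$bead_positions)  # ~50
build_np_shell <- function(diameter = 10, target_spacing = 2.5,
                           rigidity_class = c("semi_elastic", "soft", "hard",
                                              "rigid_sphere")) {
  rigidity_class <- match.arg(rigidity_class)
  if (diameter <= 0) stop("diameter must be positive")
  if (target_spacing <= 0 || target_spacing >= diameter)
    stop("need 0 < target_spacing < diameter")
  n <- round(pi * diameter^2 / target_spacing^2)
  if (n < 12)
    stop("target_spacing too coarse: it yields fewer than 12 beads")
  u <- fibonacci_sphere(n)
  new_np_model(bead_positions = u * diameter / 2, bead_normals = u,
               nominal_diameter = diameter, rigidity_class = rigidity_class,
               aspect_ratio = 1, target_spacing = target_spacing)
}

#' Build a rigid prolate ellipsoid with the volume of a reference sphere
#'
#' Semi-axes `(a, b, b)` with `a/b` equal to the aspect ratio and volume
#' matching the reference sphere: `b = r AR^(-1/3)`, `a = r AR^(2/3)`.
#' Beads are obtained by axis-scaling the Fibonacci sphere lattice (so the
#' gyration aspect ratio of the bead set is exactly `AR`); orientation
#' vectors are the outward surface normals.
#'
#' @param reference_diameter Diameter of the equal-volume sphere (sigma).
#' @param aspect_ratio Prolate aspect ratio, `>= 1`.
#' @param target_spacing Target inter-bead spacing (sigma).
#' @return An `np_model` with `rigidity_class = "rigid_ellipsoid"`.
#' @export
build_rigid_ellipsoid <- function(reference_diameter = 10, aspect_ratio = 1,
                                  target_spacing = 2.5) {
  if (aspect_ratio < 1) stop("aspect_ratio must be >= 1")
  r <- reference_diameter / 2
  a <- r * aspect_ratio^(2 / 3)
  b <- r * aspect_ratio^(-1 / 3)
  n <- round(pi * reference_diameter^2 / target_spacing^2)
  if (n < 12) stop("target_spacing too coarse: fewer than 12 beads")
  u <- fibonacci_sphere(n)
  pos <- cbind(a * u[, 1], b * u[, 2], b * u[, 3])
  nrm <- cbind(pos[, 1] / a^2, pos[, 2] / b^2, pos[, 3] / b^2)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  new_np_model(bead_positions = pos, bead_normals = nrm,
               nominal_diameter = reference_diameter,
               rigidity_class = "rigid_ellipsoid",
               aspect_ratio = aspect_ratio, target_spacing = target_spacing)
}

random_rotation_matrix <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Insert nanoparticles at random positions and orientations
#'
#' Places `count` copies of an NP model at uniformly random positions with
#' uniformly random orientations (seeded quaternion sampling), rejecting any
#' placement in which an inserted bead lies within `min_clearance` of an
#' existing bead under the minimum-image convention. Velocities of the
#' inserted beads are drawn from the Maxwell-Boltzmann distribution at
#' `temperature`; if the host system is entirely at rest its beads are
#' initialized the same way, and the total linear momentum is zeroed.
#'
#' @param system A `bead_system` (typically from [build_network()]).
#' @param model An `np_model`.
#' @param count Number of copies to insert (`count = 0` returns the system
#'   unchanged).
#' @param min_clearance Minimum allowed center-center distance to any
#'   existing bead (sigma).
#' @param seed Integer seed for the placement RNG.
#' @param temperature Thermal energy kT (eps) for the velocity draw.
#' @param max_attempts Cap on rejected placements before erroring (signals
#'   over-dense packing).
#' @return The augmented `bead_system`.
#' @export
place_nps <- function(system, model, count, min_clearance = 2, seed = 1,
                      temperature = 0.23, max_attempts = 200 * max(count, 1)) {
  stopifnot(inherits(system, "bead_system"), inherits(model, "np_model"))
  if (count < 0) stop("count must be >= 0")
  if (min_clearance < 0) stop("min_clearance must be >= 0")
  if (count == 0) return(system)

  box <- system$box_length
  body <- model$bead_positions
  nb <- nrow(body)
  rigid_class <- model$rigidity_class %in% c("rigid_sphere", "rigid_ellipsoid")

  withr::with_seed(seed, {
    existing <- system$positions
    placed_pos <- vector("list", count)
    placed_nrm <- vector("list", count)
    attempts <- 0L
    for (k in seq_len(count)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop("place_nps: exceeded ", max_attempts,
               " attempts; packing too dense for min_clearance = ",
               min_clearance)
        R <- random_rotation_matrix()
        center <- runif(3) * box
        beads <- sweep(body %*% t(R), 2, center, "+")
        beads_w <- wrap_coords(beads, box)
        ok <- TRUE
        if (nrow(existing) > 0) {
          for (d in 1:3) {
            dd <- outer(beads_w[, d], existing[, d], "-")
            dd <- dd - box * round(dd / box)
            if (d == 1) r2 <- dd^2 else r2 <- r2 + dd^2
          }
          ok <- min(r2) >= min_clearance^2
        }
        if (ok) {
          placed_pos[[k]] <- beads
          placed_nrm[[k]] <- model$bead_normals %*% t(R)
          existing <- rbind(existing, beads_w)
          break
        }
      }
    }

    n_old <- nrow(system$positions)
    new_pos <- do.call(rbind, placed_pos)
    new_nrm <- do.call(rbind, placed_nrm)
    n_new <- nrow(new_pos)
    n_np0 <- length(system$rigid)

    vel_new <- matrix(rnorm(3 * n_new, sd = sqrt(temperature)), n_new, 3)
    vel_old <- system$velocities
    if (n_old > 0 && all(vel_old == 0)) {
      vel_old <- matrix(rnorm(3 * n_old, sd = sqrt(temperature)), n_old, 3)
    }
    vel <- rbind(vel_old, vel_new)
    vel <- sweep(vel, 2, colMeans(vel))   # zero total momentum (equal masses)

    out <- system
    out$positions <- rbind(system$positions, wrap_coords(new_pos, box))
    out$unwrapped <- rbind(system$unwrapped, new_pos)
    out$velocities <- vel
    out$normals <- rbind(system$normals, new_nrm)
    out$bead_type <- c(system$bead_type, rep("np_bead", n_new))
    out$np_id <- c(system$np_id, rep(n_np0 + seq_len(count), each = nb))
    out$masses <- c(system$masses, rep(1, n_new))
    out$rigid <- c(system$rigid, rep(rigid_class, count))
    out$np_models <- c(system$np_models, rep(list(model), count))
    out
  })
}

# integer encodings used by the C++ core
bead_type_code <- function(type) {
  unname(c(polymer = 1L, node = 2L, np_bead = 3L)[type])
}

as_cpp_system <- function(system) {
  npc <- system$np_id
  npc[is.na(npc)] <- 0L
  n_np <- max(0L, npc, length(system$rigid))
  rigid <- system$rigid
  if (length(rigid) < n_np) rigid <- c(rigid, rep(FALSE, n_np - length(rigid)))
  list(positions = system$positions,
       velocities = system$velocities,
       normals = system$normals,
       unwrapped = system$unwrapped,
       bead_type_code = bead_type_code(system$bead_type),
       np_id_code = as.integer(npc),
       masses = system$masses,
       bonds = if (nrow(system$bonds) > 0) system$bonds else
         matrix(0, 0, 4),
       tether_index = as.integer(system$tether_index),
       tether_anchor = if (length(system$tether_index) > 0)
         system$tether_anchor else matrix(0, 0, 3),
       box_length = system$box_length,
       n_np = n_np,
       rigid_code = as.integer(rigid))
}

#' Validate the structural invariants of a bead system
#'
#' Checks index ranges, tether bookkeeping, wrapped coordinates, unit
#' orientation vectors and disjoint per-NP bead sets. Called internally
#' before simulation; exported for direct use.
#'
#' @param system A `bead_system`.
#' @return Invisibly `TRUE`; errors describe the violated invariant.
#' @export
validate_bead_system <- function(system) {
  stopifnot(inherits(system, "bead_system"))
  N <- nrow(system$positions)
  b <- system$bonds
  if (nrow(b) > 0) {
    if (any(b[, 1] < 1 | b[, 1] > N | b[, 2] < 1 | b[, 2] > N))
      stop("bond indices out of range")
    if (any(b[, 1] == b[, 2])) stop("bond connects a bead to itself")
  }
  nodes <- which(system$bead_type == "node")
  if (!setequal(nodes, system$tether_index))
    stop("every node bead must have exactly one tether anchor")
  if (any(system$positions < 0 | system$positions >= system$box_length))
    stop("positions must be wrapped into [0, box_length)")
  is_np <- system$bead_type == "np_bead"
  if (any(is_np)) {
    nn <- sqrt(rowSums(system$normals[is_np, , drop = FALSE]^2))
    if (any(abs(nn - 1) > 1e-9)) stop("NP bead normals must be unit length")
    if (any(is.na(system$np_id[is_np]))) stop("NP beads need an np index")
  }
  if (any(!is.na(system$np_id) & !is_np))
    stop("only NP beads may carry an np index")
  invisible(TRUE)
}
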