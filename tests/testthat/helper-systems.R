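# shared fixtures: small systems and reference (brute-force) implementations

empty_system <- function(box = 49) {
  gelperm:::new_bead_system(
    positions = matrix(0, 0, 3), velocities = matrix(0, 0, 3),
    normals = matrix(NA_real_, 0, 3), unwrapped = matrix(0, 0, 3),
    bead_type = character(0), np_id = integer(0),
    bonds = matrix(0, 0, 4), tether_index = integer(0),
    tether_anchor = matrix(0, 0, 3), box_length = box,
    masses = numeric(0))
}

single_bead_system <- function(box = 50, pos = rep(box / 2, 3),
                               vel = c(0, 0, 0)) {
  gelperm:::new_bead_system(
    positions = matrix(pos, 1, 3), velocities = matrix(vel, 1, 3),
    normals = matrix(NA_real_, 1, 3), unwrapped = matrix(pos, 1, 3),
    bead_type = "polymer", np_id = NA_integer_,
    bonds = matrix(0, 0, 4), tether_index = integer(0),
    tether_anchor = matrix(0, 0, 3), box_length = box, masses = 1)
}

# n non-interacting beads (ideal gas) for thermostat statistics
ideal_gas_system <- function(n, box = 30, seed = 1) {
  withr::with_seed(seed, {
    pos <- matrix(runif(3 * n) * box, n, 3)
    gelperm:::new_bead_system(
      positions = pos, velocities = matrix(0, n, 3),
      normals = matrix(NA_real_, n, 3), unwrapped = pos,
      bead_type = rep("polymer", n), np_id = rep(NA_integer_, n),
      bonds = matrix(0, 0, 4), tether_index = integer(0),
      tether_anchor = matrix(0, 0, 3), box_length = box,
      masses = rep(1, n))
  })
}

# random mixed system (polymer + oriented shell beads) for oracle checks
random_mixed_system <- function(n_poly = 30, n_np = 20, box = 14,
                                seed = 1, with_bonds = TRUE) {
  withr::with_seed(seed, {
    n <- n_poly + n_np
    # sequential insertion with a minimum separation: overlapping beads give
    # astronomically large LJ terms whose roundoff would swamp the comparison
    pos <- matrix(0, n, 3)
    placed <- 0L
    while (placed < n) {
      cand <- runif(3) * box
      ok <- TRUE
      if (placed > 0) {
        d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, cand)
        d <- d - box * round(d / box)
        ok <- min(rowSums(d^2)) > 0.9^2
      }
      if (ok) {
        placed <- placed + 1L
        pos[placed, ] <- cand
      }
    }
    nrm <- matrix(NA_real_, n, 3)
    if (n_np > 0) {
      raw <- matrix(rnorm(3 * n_np), n_np, 3)
      nrm[n_poly + seq_len(n_np), ] <- raw / sqrt(rowSums(raw^2))
    }
    bonds <- matrix(0, 0, 4)
    if (with_bonds && n_poly >= 4) {
      i <- seq_len(n_poly - 1)
      keep <- sample(i, max(2, n_poly %/% 3))
      bonds <- cbind(keep, keep + 1, 50, 1.0)
    }
    gelperm:::new_bead_system(
      positions = pos, velocities = matrix(0, n, 3),
      normals = nrm, unwrapped = pos,
      bead_type = c(rep("polymer", n_poly), rep("np_bead", n_np)),
      np_id = c(rep(NA_integer_, n_poly), rep(1L, n_np)),
      bonds = bonds, tether_index = integer(0),
      tether_anchor = matrix(0, 0, 3), box_length = box,
      masses = rep(1, n), rigid = n_np > 0 && FALSE)
  })
}

# O(N^2) all-pairs reference for energies and forces
brute_forces <- function(sys, ff) {
  N <- nrow(sys$positions); box <- sys$box_length
  E <- 0; F <- matrix(0, N, 3)
  wca <- 2^(1 / 6) * ff$sigma_lj
  bkey <- if (nrow(sys$bonds) > 0)
    paste(pmin(sys$bonds[, 1], sys$bonds[, 2]),
          pmax(sys$bonds[, 1], sys$bonds[, 2])) else character(0)
  if (N >= 2) for (i in 1:(N - 1)) for (j in (i + 1):N) {
    d <- sys$positions[j, ] - sys$positions[i, ]
    d <- d - box * round(d / box)
    r <- sqrt(sum(d^2))
    np_i <- sys$bead_type[i] == "np_bead"
    np_j <- sys$bead_type[j] == "np_bead"
    if (np_i && np_j && sys$np_id[i] == sys$np_id[j]) {
      res <- np_pair(d, sys$normals[i, ], sys$normals[j, ], ff)
      E <- E + res$energy
      F[i, ] <- F[i, ] + res$force_i
      F[j, ] <- F[j, ] + res$force_j
    } else {
      if (paste(i, j) %in% bkey) next
      eps <- if (xor(np_i, np_j)) ff$eps_polymer_np else ff$eps_polymer_polymer
      cut <- if (xor(np_i, np_j)) ff$lj_cutoff else wca
      lj <- lj_pair(r, eps, ff$sigma_lj, cut)
      E <- E + lj$energy
      fv <- lj$force * d / r
      F[j, ] <- F[j, ] + fv
      F[i, ] <- F[i, ] - fv
    }
  }
  for (b in seq_len(nrow(sys$bonds))) {
    i <- sys$bonds[b, 1]; j <- sys$bonds[b, 2]
    d <- sys$positions[j, ] - sys$positions[i, ]
    d <- d - box * round(d / box)
    r <- sqrt(sum(d^2))
    hb <- harmonic_bond(r, sys$bonds[b, 3], sys$bonds[b, 4])
    E <- E + hb$energy
    fv <- hb$force * d / r
    F[j, ] <- F[j, ] + fv
    F[i, ] <- F[i, ] - fv
  }
  for (k in seq_along(sys$tether_index)) {
    i <- sys$tether_index[k]
    d <- sys$positions[i, ] - sys$tether_anchor[k, ]
    d <- d - box * round(d / box)
    E <- E + ff$tether_k * sum(d^2)
    F[i, ] <- F[i, ] - 2 * ff$tether_k * d
  }
  list(energy = unname(E), forces = unname(F))
}

# explicit two-loop MSD reference (multi-origin)
brute_msd <- function(x, lag_frames) {
  F <- dim(x)[1]; P <- dim(x)[2]
  vapply(lag_frames, function(l) {
    acc <- 0; cnt <- 0
    for (t0 in 1:(F - l)) for (p in 1:P) {
      acc <- acc + sum((x[t0 + l, p, ] - x[t0, p, ])^2)
      cnt <- cnt + 1
    }
    acc / cnt
  }, numeric(1))
}

# minimal trajectory object wrapping explicit frames, for analysis tests
manual_trajectory <- function(frames, bead_type, np_id, box,
                              times = seq_len(dim(frames)[1]) - 1) {
  structure(
    list(times = times, wrapped = frames, unwrapped = frames,
         normals = NULL, np_bead_index = which(!is.na(np_id)),
         np_centroids = NULL, energies = NULL,
         bead_type = bead_type, np_id = np_id,
         rigid = rep(FALSE, max(c(0, np_id), na.rm = TRUE)),
         box_length = box),
    class = "md_trajectory")
}
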