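# Desk-scale Langevin surrogate: a charged bead-spring chain integrated with
# the BAOAB splitting under the package's confinement/capsid potentials.
# Reduced units: length lambda_ox, energy k_BT (so the thermostat temperature
# is 1), mass 1, time tau. The surrogate validates potentials and trajectory
# observables; it carries no hydrogen bonding, stacking or sequence, so it
# never stands in for RNA folding behaviour.

#' Charged bead-spring chain
#'
#' @param positions n x 3 matrix in lambda_ox.
#' @param bond_length equilibrium bond length in lambda_ox.
#' @param bond_k harmonic bond stiffness in k_BT / lambda_ox^2.
#' @param bead_charge charge per bead in e (default -1: one phosphate).
#' @param excluded_sigma WCA excluded-volume diameter in lambda_ox (0 turns
#'   excluded volume off).
#' @param circular logical; closed chain?
#' @return an object of class \code{bead_chain}.
#' @export
bead_chain <- function(positions, bond_length = 1, bond_k = 100,
                       bead_charge = -1, excluded_sigma = 0.8,
                       circular = FALSE) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L, nrow(positions) >= 2L, bond_length > 0,
            bond_k >= 0, excluded_sigma >= 0)
  structure(list(positions = unname(positions), bond_length = bond_length,
                 bond_k = bond_k, bead_charge = bead_charge,
                 excluded_sigma = excluded_sigma, circular = isTRUE(circular)),
            class = "bead_chain")
}

#' Configuration for the toy Langevin integrator
#'
#' @param dt integration step in tau (default 3e-3, the CG engine's step
#'   convention).
#' @param gamma friction in tau^-1.
#' @param temperature temperature in K (sets the k_BT scale of the
#'   electrostatics; the reduced thermostat temperature is 1).
#' @param salt monovalent salt in mol/L; sets the Debye screening length of
#'   the bead-bead electrostatics.
#' @param seed RNG seed: equal seeds give byte-identical trajectories.
#' @param steps number of MD steps.
#' @param record_every recording stride in steps.
#' @return an object of class \code{toy_dynamics_config}.
#' @export
toy_dynamics_config <- function(dt = 3e-3, gamma = 1, temperature = 310,
                                salt = 0.5, seed = 1, steps = 1000L,
                                record_every = 10L) {
  stopifnot(dt > 0, gamma > 0, steps > 0, record_every >= 1)
  structure(list(dt = dt, gamma = gamma, temperature = temperature,
                 salt = salt, seed = as.integer(seed),
                 steps = as.integer(steps),
                 record_every = as.integer(record_every)),
            class = "toy_dynamics_config")
}

# Build the total force closure for a chain + external potential descriptors.
# x is n x 3 in lambda_ox; returns n x 3 forces in k_BT/lambda_ox.
make_force_fn <- function(chain, potentials, cfg) {
  n <- nrow(chain$positions)
  bonds_i <- seq_len(n - 1L); bonds_j <- bonds_i + 1L
  if (chain$circular) { bonds_i <- c(bonds_i, n); bonds_j <- c(bonds_j, 1L) }
  use_pairs <- (chain$excluded_sigma > 0 || chain$bead_charge != 0) && n > 2L
  if (use_pairs) {
    prs <- utils::combn(n, 2L)
    bonded <- paste(bonds_i, bonds_j) # i<j always except circular closure
    key <- paste(pmin(prs[1, ], prs[2, ]), pmax(prs[1, ], prs[2, ]))
    bkey <- paste(pmin(bonds_i, bonds_j), pmax(bonds_i, bonds_j))
    keep <- !(key %in% bkey)
    pi_ <- prs[1, keep]; pj_ <- prs[2, keep]
    lB <- bjerrum_length(cfg$temperature) / lambda_ox_nm       # lambda_ox
    kap <- debye_kappa(cfg$salt, cfg$temperature) * lambda_ox_nm # 1/lambda_ox
    q2 <- chain$bead_charge^2
  }
  caps <- Filter(function(p) inherits(p, c("yukawa_wca_params", "polyexp_params")), potentials)
  walls <- Filter(function(p) is.list(p) && identical(p$kind, "static_wall"), potentials)
  scheds <- Filter(function(p) inherits(p, "squeeze_schedule"), potentials)
  restraints <- Filter(function(p) inherits(p, "restraint_params"), potentials)

  function(x, step) {
    F <- matrix(0, n, 3)
    if (chain$bond_k > 0) {
      d <- x[bonds_j, , drop = FALSE] - x[bonds_i, , drop = FALSE]
      bl <- sqrt(rowSums(d^2))
      fmag <- -chain$bond_k * (bl - chain$bond_length) / pmax(bl, 1e-12)
      fb <- d * fmag
      # bonds_i and bonds_j are each duplicate-free, so vector indexing is safe
      F[bonds_j, ] <- F[bonds_j, ] + fb
      F[bonds_i, ] <- F[bonds_i, ] - fb
    }
    if (use_pairs && length(pi_)) {
      dp <- x[pj_, , drop = FALSE] - x[pi_, , drop = FALSE]
      r2 <- rowSums(dp^2)
      r <- sqrt(r2)
      fm <- numeric(length(r))
      if (chain$excluded_sigma > 0) {
        fm <- fm - wca_dUds(r, 1, chain$excluded_sigma)   # eps = 1 k_BT
      }
      if (chain$bead_charge != 0) {
        fm <- fm + lB * q2 * exp(-kap * r) * (1 / r2 + kap / r)
      }
      fp <- dp * (fm / pmax(r, 1e-12))
      for (k in seq_along(pi_)) {
        F[pj_[k], ] <- F[pj_[k], ] + fp[k, ]
        F[pi_[k], ] <- F[pi_[k], ] - fp[k, ]
      }
    }
    # radial external potentials about the origin
    if (length(walls) || length(scheds) || length(caps)) {
      r <- sqrt(rowSums(x^2))
      rhat <- x / pmax(r, 1e-12)
      fr <- numeric(n)
      for (w in walls) fr <- fr + static_wall(r, w$R0, w$omega)$force
      for (s in scheds) fr <- fr + squeeze_energy_force(r, step, s)$force
      for (cp in caps) {
        r_nm <- r * lambda_ox_nm
        if (inherits(cp, "yukawa_wca_params")) {
          # clamp just below the diverging WCA wall: beyond the clamp the
          # (already enormous) inward force is continued as a constant
          r_nm <- pmin(r_nm, cp$R_delta - 1e-3)
        } else {
          # the cavity form is only meant inside the shell; its exponential
          # blows up far outside, so continue the force constantly past R0
          r_nm <- pmin(r_nm, cp$R0 + 0.2)
        }
        ev <- eval_capsid_potential(r_nm, cp)
        fr <- fr + ev$force * lambda_ox_nm   # k_BT/nm -> k_BT/lambda_ox
      }
      F <- F + rhat * fr
    }
    for (rs in restraints) {
      er <- end_restraint(x[rs$i + 1L, ], x[rs$j + 1L, ], rs)
      F[rs$i + 1L, ] <- F[rs$i + 1L, ] + er$force_i
      F[rs$j + 1L, ] <- F[rs$j + 1L, ] + er$force_j
    }
    F
  }
}

#' Run BAOAB Langevin dynamics of a bead chain
#'
#' Integrates harmonic bonds, WCA excluded volume, Debye-Hueckel bead-bead
#' electrostatics and any supplied external radial potentials (static wall,
#' squeeze schedule, fitted capsid potentials, terminus restraints) with the
#' BAOAB splitting at reduced temperature 1. Trajectories are byte-identical
#' for equal seeds.
#'
#' @param chain a \code{\link{bead_chain}}.
#' @param potentials list of descriptors: \code{\link{squeeze_schedule}},
#'   \code{\link{restraint_params}}, \code{\link{yukawa_wca_params}},
#'   \code{\link{polyexp_params}} objects, or \code{list(kind = "static_wall",
#'   R0 =, omega =)}.
#' @param cfg a \code{\link{toy_dynamics_config}}.
#' @return an object of class \code{cg_trajectory}: list of recorded frames
#'   (n x 3 matrices, lambda_ox), their MD-step stamps, and the bead count.
#' @export
run_langevin <- function(chain, potentials = list(), cfg = toy_dynamics_config()) {
  stopifnot(inherits(chain, "bead_chain"), inherits(cfg, "toy_dynamics_config"))
  n <- nrow(chain$positions)
  force_fn <- make_force_fn(chain, potentials, cfg)
  dt <- cfg$dt
  c1 <- exp(-cfg$gamma * dt)
  c2 <- sqrt(1 - c1^2)     # reduced k_BT = 1, mass = 1
  x <- chain$positions
  nrec <- cfg$steps %/% cfg$record_every + 1L
  frames <- vector("list", nrec)
  times <- numeric(nrec)
  with_seed(cfg$seed, {
    v <- matrix(stats::rnorm(3 * n), n, 3)
    F <- force_fn(x, 0)
    frames[[1L]] <- x; times[1L] <- 0; ir <- 1L
    for (step in seq_len(cfg$steps)) {
      v <- v + (dt / 2) * F
      x <- x + (dt / 2) * v
      v <- c1 * v + c2 * matrix(stats::rnorm(3 * n), n, 3)
      x <- x + (dt / 2) * v
      F <- force_fn(x, step)
      v <- v + (dt / 2) * F
      if (step %% cfg$record_every == 0L) {
        if (!all(is.finite(x)))
          stop(sprintf("dynamics diverged: non-finite coordinate at step %d", step))
        ir <- ir + 1L
        frames[[ir]] <- x
        times[ir] <- step
      }
    }
  })
  structure(list(frames = frames[seq_len(ir)], times = times[seq_len(ir)],
                 n = n), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> %d beads, %d frames (steps %g..%g)\n",
              x$n, length(x$frames), x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Radius of gyration of one frame
#'
#' Root-mean-square distance of the beads from their centroid.
#'
#' @param frame n x 3 position matrix.
#' @return a length (same unit as the frame).
#' @export
radius_of_gyration <- function(frame) {
  frame <- as.matrix(frame)
  if (nrow(frame) == 1L) return(0)
  d <- sweep(frame, 2, colMeans(frame))
  sqrt(mean(rowSums(d^2)))
}

#' Radial number-density profile of a trajectory
#'
#' Frame-averaged bead counts per spherical shell divided by shell volume.
#' The quadrature identity sum(density * shell_volume) = bead count holds
#' exactly on the returned grid.
#'
#' @param traj a \code{cg_trajectory}.
#' @param center length-3 center.
#' @param bin_width radial bin width.
#' @return data.frame with \code{r} (bin midpoint), \code{density},
#'   \code{shell_volume}, \code{count} (mean beads per frame in the bin).
#' @export
radial_density <- function(traj, center = c(0, 0, 0), bin_width = 0.5) {
  stopifnot(inherits(traj, "cg_trajectory"), bin_width > 0)
  rall <- unlist(lapply(traj$frames, function(f) {
    sqrt(rowSums(sweep(f, 2, center)^2))
  }))
  r_max <- max(rall) + bin_width
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  idx <- findInterval(rall, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L) / length(traj$frames)
  vol <- (4 / 3) * pi * diff(edges^3)
  data.frame(r = (edges[-1] + edges[-length(edges)]) / 2,
             density = counts / vol, shell_volume = vol, count = counts)
}

#' Time-averaged wall pressure
#'
#' Magnitude of the total outward force the confining wall exerts, divided by
#' the instantaneous wall area 4 pi R(t)^2, averaged over frames.
#'
#' @param traj a \code{cg_trajectory}.
#' @param wall a \code{list(kind = "static_wall", R0 =, omega =)} descriptor
#'   or a \code{\link{squeeze_schedule}}.
#' @return pressure in k_BT / lambda_ox^3.
#' @export
wall_pressure <- function(traj, wall) {
  stopifnot(inherits(traj, "cg_trajectory"))
  p_frames <- mapply(function(f, t) {
    if (inherits(wall, "squeeze_schedule")) {
      R <- squeeze_radius(t, wall); omega <- wall$omega
    } else {
      R <- wall$R0; omega <- wall$omega
    }
    r <- sqrt(rowSums(f^2))
    Fout <- sum(omega * pmax(r - R, 0))
    Fout / (4 * pi * R^2)
  }, traj$frames, traj$times)
  mean(p_frames)
}
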