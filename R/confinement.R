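# The encapsidation protocol: a shrinking half-harmonic spherical wall
# ("squeezing"), its static counterpart at the cavity radius, and the
# harmonic restraint that keeps the chain termini a few nm apart.
#
# The squeezing wall is one-sided: zero inside the instantaneous radius R(t),
# (omega/2) (r - R(t))^2 outside, so it acts only on nucleotides at or beyond
# the enclosing surface. Schedule time is measured in MD steps (rates are
# printed per MD step), independent of any integrator's dt.

#' Time-dependent squeezing schedule
#'
#' Piecewise-linear shrinking program for the confining radius: starting at
#' \code{R_start}, each segment shrinks at its rate for its duration, and the
#' radius never undershoots \code{R_final}.
#'
#' @param omega wall stiffness in k_BT / lambda_ox^2.
#' @param R_start,R_final starting and final radii in lambda_ox.
#' @param rates per-segment shrinking rates in lambda_ox per MD step.
#' @param durations per-segment durations in MD steps (the last segment may be
#'   \code{Inf}).
#' @return an object of class \code{squeeze_schedule}.
#' @export
squeeze_schedule <- function(omega = 1, R_start, R_final,
                             rates = 5.6e-8, durations = Inf) {
  stopifnot(omega > 0, length(rates) == length(durations),
            all(rates >= 0), all(durations > 0), R_final <= R_start)
  structure(list(omega = omega, R_start = R_start, R_final = R_final,
                 rates = as.numeric(rates), durations = as.numeric(durations)),
            class = "squeeze_schedule")
}

#' Reference squeezing schedules for the two salt protocols
#'
#' The 0.5 M protocol shrinks at a single rate of 5.6e-8 lambda_ox per MD
#' step; the milder 0.15 M protocol halves the planned trajectory into a
#' first segment at that rate and a second at 1e-8 (the exact switch step is
#' a free parameter, defaulting to half the planned duration).
#'
#' @param salt 0.5 or 0.15 (mol/L), selecting the protocol.
#' @param R_start,R_final radii in lambda_ox.
#' @param omega wall stiffness in k_BT / lambda_ox^2.
#' @param total_steps planned trajectory length in MD steps (sets the switch
#'   point of the 0.15 M protocol).
#' @param switch_step optional explicit switch step for the 0.15 M protocol.
#' @return a \code{\link{squeeze_schedule}}.
#' @export
default_squeeze_schedule <- function(salt, R_start, R_final, omega = 1,
                                     total_steps = 1e8, switch_step = NULL) {
  if (isTRUE(all.equal(salt, 0.15))) {
    if (is.null(switch_step)) switch_step <- total_steps / 2
    squeeze_schedule(omega, R_start, R_final,
                     rates = c(5.6e-8, 1e-8),
                     durations = c(switch_step, Inf))
  } else {
    squeeze_schedule(omega, R_start, R_final, rates = 5.6e-8, durations = Inf)
  }
}

#' Instantaneous confining radius R(t)
#'
#' @param t MD step (vectorized, t >= 0).
#' @param sched a \code{\link{squeeze_schedule}}.
#' @return radius in lambda_ox: piecewise-linear, non-increasing, floored at
#'   \code{R_final}.
#' @export
squeeze_radius <- function(t, sched) {
  stopifnot(inherits(sched, "squeeze_schedule"), all(t >= 0))
  ends <- cumsum(sched$durations)
  starts <- c(0, ends[-length(ends)])
  drop <- vapply(t, function(ti) {
    consumed <- pmin(pmax(ti - starts, 0), sched$durations)
    sum(sched$rates * consumed)
  }, numeric(1))
  pmax(sched$R_final, sched$R_start - drop)
}

half_harmonic <- function(r, R, omega) {
  out <- r > R
  e <- ifelse(out, 0.5 * omega * (r - R)^2, 0)
  f <- ifelse(out, -omega * (r - R), 0)   # radial force, negative = inward
  list(energy = e, force = f)
}

#' Energy and force of the squeezing wall at step t
#'
#' One-sided harmonic: zero for r <= R(t), \eqn{(\omega/2)(r - R(t))^2} with
#' inward force \eqn{-\omega (r - R(t))} outside. C1-continuous at the
#' boundary.
#'
#' @param r radial distance in lambda_ox (vectorized).
#' @param t MD step.
#' @param sched a \code{\link{squeeze_schedule}}.
#' @return list with \code{energy} (k_BT) and \code{force} (k_BT/lambda_ox,
#'   radial component; negative values point inward).
#' @export
squeeze_energy_force <- function(r, t, sched) {
  stopifnot(all(r >= 0))
  half_harmonic(r, squeeze_radius(t, sched), sched$omega)
}

#' Static spherical wall at the cavity radius
#'
#' The time-independent counterpart of the squeezing wall, frozen at
#' \code{R0}: the excluded-volume term that keeps nucleotides inside the
#' capsid shell.
#'
#' @param r radial distance (vectorized).
#' @param R0 wall radius.
#' @param omega stiffness in k_BT per length^2.
#' @return list with \code{energy} and \code{force} as in
#'   \code{\link{squeeze_energy_force}}.
#' @export
static_wall <- function(r, R0, omega = 1) {
  stopifnot(all(r >= 0), R0 > 0, omega > 0)
  half_harmonic(r, R0, omega)
}

#' Harmonic restraint parameters for the chain termini
#'
#' Defaults are the terminus restraint of the encapsidation protocol:
#' stiffness 0.5 k_BT/lambda_ox^2 toward a rest distance of 5 lambda_ox
#' (about 4 nm).
#'
#' @param k stiffness in k_BT / lambda_ox^2.
#' @param d0 rest distance in lambda_ox.
#' @param i,j restrained nucleotide indices (0-based).
#' @return an object of class \code{restraint_params}.
#' @export
restraint_params <- function(k = 0.5, d0 = 5, i = 0L, j = NULL) {
  stopifnot(k >= 0, d0 >= 0)
  structure(list(k = k, d0 = d0, i = as.integer(i),
                 j = if (is.null(j)) NULL else as.integer(j)),
            class = "restraint_params")
}

#' Harmonic end-restraint energy and forces
#'
#' \eqn{U = (k/2)(|d| - d_0)^2} with \eqn{d} the vector from i to j; forces
#' are equal and opposite along the connecting line. A coincident pair with
#' d0 > 0 has no defined direction: zero forces are returned with
#' \code{degenerate = TRUE}.
#'
#' @param pos_i,pos_j length-3 positions.
#' @param p a \code{\link{restraint_params}}.
#' @return list with \code{energy}, \code{force_i}, \code{force_j},
#'   \code{degenerate}.
#' @export
end_restraint <- function(pos_i, pos_j, p = restraint_params()) {
  stopifnot(all(is.finite(pos_i)), all(is.finite(pos_j)))
  d <- pos_j - pos_i
  dist <- sqrt(sum(d^2))
  if (dist == 0 && p$d0 > 0) {
    return(list(energy = 0.5 * p$k * p$d0^2,
                force_i = c(0, 0, 0), force_j = c(0, 0, 0),
                degenerate = TRUE))
  }
  e <- 0.5 * p$k * (dist - p$d0)^2
  u <- if (dist > 0) d / dist else c(0, 0, 0)
  fj <- -p$k * (dist - p$d0) * u
  list(energy = e, force_i = -fj, force_j = fj, degenerate = FALSE)
}

#' Emit per-checkpoint static force files for a squeeze schedule
#'
#' For engines that cannot consume a time-dependent radius, samples R(t) at
#' the requested steps and writes one static-wall external-forces file per
#' checkpoint.
#'
#' @param sched a \code{\link{squeeze_schedule}}.
#' @param steps MD steps at which to freeze the wall.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return data.frame with columns \code{step}, \code{radius}, \code{path}.
#' @export
plan_squeeze_checkpoints <- function(sched, steps, dir, prefix = "wall") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  radii <- squeeze_radius(steps, sched)
  paths <- file.path(dir, sprintf("%s_step%012.0f.txt", prefix, steps))
  for (k in seq_along(steps)) {
    export_external_forces(list(list(kind = "static_wall", R0 = radii[k],
                                     omega = sched$omega)), paths[k])
  }
  data.frame(step = steps, radius = radii, path = paths,
             stringsAsFactors = FALSE)
}
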