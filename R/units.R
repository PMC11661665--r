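# Physical constants (SI) and the unit registry shared by all modules.
# Internal convention: lengths in nm at module boundaries that touch atomistic
# data, lengths in lambda_ox inside the CG/confinement modules, energies in
# k_BT at the configured temperature. Every conversion goes through here.

.kB   <- 1.380649e-23     # J/K
.qe   <- 1.602176634e-19  # C
.eps0 <- 8.8541878128e-12 # F/m
.Nav  <- 6.02214076e23    # 1/mol

#' oxDNA/oxRNA internal length unit in nanometers
#'
#' One simulation length unit of the oxDNA family of coarse-grained models,
#' \eqn{\lambda_{ox} = 0.8518} nm (so 5 \eqn{\lambda_{ox}} is about 4 nm).
#' @export
lambda_ox_nm <- 0.8518

#' Convert between nanometers and oxDNA length units
#'
#' @param x numeric vector of lengths.
#' @return numeric vector in the target unit.
#' @export
nm_to_lox <- function(x) x / lambda_ox_nm

#' @rdname nm_to_lox
#' @export
lox_to_nm <- function(x) x * lambda_ox_nm

#' Bjerrum length in nanometers
#'
#' \eqn{\ell_B = e^2 / (4\pi \epsilon_0 \epsilon_r k_B T)}: the distance at
#' which two elementary charges interact with thermal energy. All Coulomb
#' energies in the package are expressed as \eqn{\ell_B q_1 q_2 / r} in
#' \eqn{k_BT}.
#'
#' @param temperature temperature in K.
#' @param eps_r relative dielectric constant of the medium.
#' @return Bjerrum length in nm.
#' @export
bjerrum_length <- function(temperature = 310, eps_r = 78.5) {
  (.qe^2 / (4 * pi * .eps0 * eps_r)) / (.kB * temperature) * 1e9
}

#' Inverse Debye screening length for monovalent salt
#'
#' Standard 1:1 electrolyte formula
#' \eqn{\kappa^2 = 8 \pi \ell_B n} with \eqn{n} the number density of each
#' ionic species.
#'
#' @param salt molar concentration of monovalent salt (mol/L).
#' @param temperature temperature in K.
#' @param eps_r relative dielectric constant.
#' @return \eqn{\kappa} in nm^-1.
#' @export
debye_kappa <- function(salt, temperature = 310, eps_r = 78.5) {
  stopifnot(salt >= 0)
  n_nm3 <- salt * 1e3 * .Nav * 1e-27      # ions/nm^3 per species
  sqrt(8 * pi * bjerrum_length(temperature, eps_r) * n_nm3)
}

# Restore the caller's RNG state after running a seeded generator, so fixture
# creation never perturbs an enclosing simulation's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
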