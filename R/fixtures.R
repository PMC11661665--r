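# Seeded synthetic-fixture generators: every input class the framework
# consumes, with known ground truth, so all modules are testable without any
# external download. Charge fixtures use idealized geometry (spherical shell,
# interior tail layer, neutral ion pairs) rather than resampling a deposited
# capsid structure; the readers accept a real PQR whenever one is available.

#' Uniformly charged spherical shell fixture
#'
#' \code{n_points} points uniform on the sphere of radius R, each carrying
#' \code{Q_total / n_points}: the discrete stand-in for the thin charged
#' shell of the analytical capsid model.
#'
#' @param R shell radius in nm.
#' @param Q_total total charge in e.
#' @param n_points number of point charges.
#' @param seed RNG seed (fixed seed gives byte-identical output).
#' @return a \code{\link{charge_distribution}}.
#' @export
make_shell_charges <- function(R, Q_total, n_points, seed = 1) {
  stopifnot(n_points >= 1, R > 0)
  with_seed(seed, {
    g <- matrix(stats::rnorm(3 * n_points), n_points, 3)
    g <- g / sqrt(rowSums(g^2))
    charge_distribution(g * R, rep(Q_total / n_points, n_points),
                        labels = rep("SHL", n_points))
  })
}

#' Capsid-like charge fixture: anionic shell, cationic tails, ion cloud
#'
#' Emulates the interior electrostatic structure of an icosahedral plant-virus
#' capsid at a mean-field level: a negative-dominated protein shell just
#' outside the cavity radius \code{R0}, positively charged (arginine-rich
#' tail) charges spread through the layer \code{[R0 - tail_depth, R0]}, and
#' charge-neutral ion pairs whose placement is biased toward the oppositely
#' charged regions (a Boltzmann-like screening cloud). Total charge is
#' exactly \code{shell_Q + tail_Q}.
#'
#' @param R0 inner cavity radius in nm.
#' @param shell_Q net shell charge in e (typically negative).
#' @param tail_Q net tail charge in e (typically positive).
#' @param tail_depth radial extent of the tail layer in nm (< R0).
#' @param ion_pairs number of +/- ion pairs.
#' @param seed RNG seed.
#' @return a \code{\link{charge_distribution}}.
#' @export
make_capsid_like_charges <- function(R0 = 12, shell_Q = -300, tail_Q = 200,
                                     tail_depth = 3, ion_pairs = 500,
                                     seed = 1) {
  stopifnot(tail_depth < R0)
  with_seed(seed, {
    unit_sphere <- function(m) {
      g <- matrix(stats::rnorm(3 * m), m, 3)
      g / sqrt(rowSums(g^2))
    }
    n_shell <- 1200L
    shell_pos <- unit_sphere(n_shell) * (R0 + 1)
    shell_q <- rep(shell_Q / n_shell, n_shell)
    n_tail <- 600L
    tail_r <- stats::runif(n_tail, R0 - tail_depth, R0)
    tail_pos <- unit_sphere(n_tail) * tail_r
    tail_q <- rep(tail_Q / n_tail, n_tail)
    # cations crowd the anionic shell, anions the cationic tail layer
    cat_r <- R0 + 1 + stats::rnorm(ion_pairs, 0, 0.4)
    an_r <- (R0 - tail_depth / 2) + stats::rnorm(ion_pairs, 0, 0.6)
    cat_r <- pmin(pmax(abs(cat_r), 0.1), R0 + 2.5)
    an_r <- pmin(pmax(abs(an_r), 0.1), R0 + 2.5)
    ion_pos <- rbind(unit_sphere(ion_pairs) * cat_r,
                     unit_sphere(ion_pairs) * an_r)
    ion_q <- c(rep(1, ion_pairs), rep(-1, ion_pairs))
    charge_distribution(rbind(shell_pos, tail_pos, ion_pos),
                        c(shell_q, tail_q, ion_q),
                        labels = c(rep("SHL", n_shell), rep("TAIL", n_tail),
                                   rep("NA+", ion_pairs), rep("CL-", ion_pairs)))
  })
}

#' Linear or circular chain conformation fixture
#'
#' Linear: collinear beads along x with the given spacing. Circular: a
#' regular n-gon whose edge length equals the spacing.
#'
#' @param n number of beads (>= 2).
#' @param spacing bond length in lambda_ox.
#' @param circular closed chain?
#' @return a \code{\link{chain_conformation}} in lambda_ox units.
#' @export
make_chain <- function(n, spacing = 1, circular = FALSE) {
  stopifnot(n >= 2, spacing > 0)
  if (circular) {
    # edge of a regular n-gon with circumradius rho: 2 rho sin(pi/n)
    rho <- spacing / (2 * sin(pi / n))
    th <- 2 * pi * (seq_len(n) - 1) / n
    pos <- cbind(rho * cos(th), rho * sin(th), 0)
  } else {
    pos <- cbind((seq_len(n) - 1) * spacing, 0, 0)
  }
  chain_conformation(pos, circular = circular, unit = "lambda_ox")
}

#' Bernoulli contact-series fixture
#'
#' Each listed pair appears in each frame independently with its probability:
#' the counting oracle for persistence and stable-contact logic.
#'
#' @param n chain length.
#' @param pair_probs data.frame with columns \code{i}, \code{j} (0-based) and
#'   \code{prob}.
#' @param frames number of frames.
#' @param seed RNG seed.
#' @return a \code{\link{contact_series}}.
#' @export
make_contact_series <- function(n, pair_probs, frames, seed = 1) {
  stopifnot(all(pair_probs$prob >= 0), all(pair_probs$prob <= 1), frames >= 1)
  with_seed(seed, {
    maps <- lapply(seq_len(frames), function(f) {
      on <- stats::runif(nrow(pair_probs)) < pair_probs$prob
      contact_map(cbind(pair_probs$i[on], pair_probs$j[on]), n)
    })
    contact_series(maps, n)
  })
}

#' Synthetic potential curve from known analytic parameters
#'
#' Exact evaluation of an \code{\link{yukawa_wca_params}} or \code{\link{polyexp_params}}
#' form on a radial grid plus i.i.d. Gaussian noise: the parameter-recovery
#' oracle for the two fitters.
#'
#' @param params \code{yukawa_wca_params} or \code{polyexp_params}.
#' @param grid radii in nm (must lie in the form's domain).
#' @param noise_sd Gaussian noise s.d. in k_BT.
#' @param seed RNG seed.
#' @return a \code{\link{radial_potential_profile}} (zero-reference check
#'   relaxed when noise is added).
#' @export
make_potential_curve <- function(params, grid, noise_sd = 0, seed = 1) {
  if (inherits(params, "yukawa_wca_params") && any(grid >= params$R_delta))
    stop("grid points must lie strictly below R_delta")
  U <- eval_capsid_potential(grid, params)$energy
  if (noise_sd > 0)
    U <- U + with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  radial_potential_profile(grid, U, strict_zero = FALSE)
}

#' Seeded synthetic RNA sequence
#'
#' A deterministic random nucleotide sequence of the requested length. The
#' shipped file \code{inst/extdata/rna2_synthetic.fasta} is this generator's
#' output at the default arguments: a synthetic 2774-nt stand-in, with the
#' correct length but not the real sequence, for the RNA2 genome fragment.
#'
#' @param n sequence length (default 2774, the RNA2 fragment length).
#' @param seed RNG seed.
#' @return character vector of nucleotide letters.
#' @export
make_rna_sequence <- function(n = 2774, seed = 42) {
  with_seed(seed, sample(c("A", "C", "G", "U"), n, replace = TRUE))
}

#' Write a sequence as FASTA
#'
#' @param letters character vector of nucleotides.
#' @param path output path.
#' @param name record name.
#' @return the path, invisibly.
#' @export
write_fasta <- function(letters, path, name = "seq") {
  s <- paste(letters, collapse = "")
  chunks <- substring(s, seq(1, nchar(s), 70), pmin(seq(70, nchar(s) + 69, 70),
                                                    nchar(s)))
  writeLines(c(paste0(">", name), chunks), path)
  invisible(path)
}

#' Path to the shipped synthetic RNA2-length FASTA
#'
#' @return file path inside the installed package.
#' @export
rna2_synthetic_fasta <- function() {
  system.file("extdata", "rna2_synthetic.fasta", package = "capsidfield",
              mustWork = TRUE)
}
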