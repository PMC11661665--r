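# Core domain containers. Lightweight S3: each constructor validates the
# type's invariants and stamps a class; downstream code trusts the invariants.

#' Point-charge distribution
#'
#' The raw material of the structure-based capsid potential: one row per
#' atom/ion, Cartesian coordinates in nm and partial charges in elementary
#' charge units.
#'
#' @param positions numeric matrix with 3 columns (x, y, z in nm).
#' @param charges numeric vector, one elementary-charge value per row.
#' @param labels optional character vector of per-particle tags.
#' @return an object of class \code{charge_distribution}.
#' @export
charge_distribution <- function(positions, charges, labels = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("positions must have 3 columns")
  n <- nrow(positions)
  if (n < 1L) stop("a charge distribution needs at least one particle")
  if (length(charges) != n)
    stop(sprintf("positions (%d) and charges (%d) must have equal count", n, length(charges)))
  if (!all(is.finite(charges))) stop("charges must be finite")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (!is.null(labels) && length(labels) != n)
    stop("labels must match particle count")
  structure(list(positions = unname(positions), charges = as.numeric(charges),
                 labels = labels),
            class = "charge_distribution")
}

#' @export
print.charge_distribution <- function(x, ...) {
  cat(sprintf("<charge_distribution> %d particles, net charge %+.4g e\n",
              nrow(x$positions), sum(x$charges)))
  invisible(x)
}

#' Coarse-grained chain conformation
#'
#' Per-nucleotide bead positions with a unit tag, an optional sequence, and a
#' circular/linear flag.
#'
#' @param positions numeric matrix with 3 columns.
#' @param sequence optional character vector of nucleotide letters (A/C/G/U),
#'   one per bead, or a single string.
#' @param circular logical; is the chain closed?
#' @param unit length unit of \code{positions}: \code{"lambda_ox"} or \code{"nm"}.
#' @return an object of class \code{chain_conformation}.
#' @export
chain_conformation <- function(positions, sequence = NULL, circular = FALSE,
                               unit = c("lambda_ox", "nm")) {
  unit <- match.arg(unit)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must have 3 columns")
  if (!is.null(sequence)) {
    if (length(sequence) == 1L && nchar(sequence[1]) > 1L)
      sequence <- strsplit(sequence, "")[[1]]
    if (length(sequence) != nrow(positions))
      stop(sprintf("sequence length (%d) must equal position count (%d)",
                   length(sequence), nrow(positions)))
  }
  structure(list(positions = unname(positions), sequence = sequence,
                 circular = isTRUE(circular), unit = unit),
            class = "chain_conformation")
}

#' @export
print.chain_conformation <- function(x, ...) {
  cat(sprintf("<chain_conformation> %d nucleotides (%s, %s)\n",
              nrow(x$positions), if (x$circular) "circular" else "linear", x$unit))
  invisible(x)
}

# Normalize an m x 2 matrix of index pairs: 0-based, i < j, unique, sorted.
normalize_pairs <- function(pairs) {
  if (is.null(pairs) || length(pairs) == 0L)
    return(matrix(integer(0), ncol = 2L))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (any(pairs[, 1] == pairs[, 2]))
    stop("self-pair (i, i) is not a valid base pairing")
  lo <- pmin(pairs[, 1], pairs[, 2])
  hi <- pmax(pairs[, 1], pairs[, 2])
  m <- unique(cbind(lo, hi))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' Per-frame hydrogen-bond pair list
#'
#' @param frame_index integer frame stamp.
#' @param pairs m x 2 matrix of 0-based nucleotide index pairs (unordered;
#'   stored as i < j, duplicates collapsed).
#' @param n optional chain length; if given, indices are range-checked.
#' @return an object of class \code{hb_frame}.
#' @export
hb_frame <- function(frame_index, pairs, n = NULL) {
  pairs <- normalize_pairs(pairs)
  if (length(pairs) && any(pairs < 0L))
    stop("nucleotide indices are 0-based and must be non-negative")
  if (!is.null(n) && length(pairs) && any(pairs >= n))
    stop(sprintf("pair index %d out of range for chain length %d",
                 max(pairs), n))
  structure(list(frame_index = as.integer(frame_index), pairs = pairs),
            class = "hb_frame")
}

#' Rigid-body symmetry operator
#'
#' @param rotation 3 x 3 proper rotation matrix (orthogonal, det +1 within 1e-6).
#' @param translation length-3 translation vector in nm.
#' @return an object of class \code{symmetry_operator}.
#' @export
symmetry_operator <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation matrix is not orthogonal within 1e-6")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be proper (determinant +1 within 1e-6)")
  if (length(translation) != 3L) stop("translation must have length 3")
  structure(list(rotation = unname(rotation),
                 translation = as.numeric(translation)),
            class = "symmetry_operator")
}

#' Simulation protocol configuration for the external CG engine
#'
#' Collects the thermostat and run-length settings of the external
#' molecular-dynamics protocol into a validated record that
#' \code{\link{write_oxdna_input}} serializes in the engine's key = value
#' dialect.
#'
#' @param timestep MD timestep in internal time units tau.
#' @param thermostat \code{"bussi"} or \code{"langevin"}.
#' @param temperature temperature in K.
#' @param salt monovalent salt concentration in mol/L.
#' @param steps total number of MD steps.
#' @param bussi_correlation,bussi_frequency Bussi thermostat correlation time
#'   and timestep frequency (steps); defaults follow common engine practice.
#' @param langevin_diffusion,langevin_frequency Langevin thermostat diffusion
#'   coefficient (dimensionless) and timestep frequency (steps).
#' @return an object of class \code{oxdna_protocol_config}.
#' @export
oxdna_protocol_config <- function(timestep = 3e-3,
                                  thermostat = c("langevin", "bussi"),
                                  temperature = 310, salt = 0.5,
                                  steps = 1e8,
                                  bussi_correlation = 1000, bussi_frequency = 53,
                                  langevin_diffusion = 2.5, langevin_frequency = 103) {
  thermostat <- match.arg(thermostat)
  stopifnot(timestep > 0, steps > 0, salt > 0, temperature > 0)
  structure(list(timestep = timestep, thermostat = thermostat,
                 temperature = temperature, salt = salt, steps = steps,
                 bussi_correlation = bussi_correlation,
                 bussi_frequency = bussi_frequency,
                 langevin_diffusion = langevin_diffusion,
                 langevin_frequency = langevin_frequency),
            class = "oxdna_protocol_config")
}
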