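# Icosahedral symmetry expansion: replicate the trimeric asymmetric unit of a
# T=3 shell into the full 60-fold capsid.

rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' The 60 proper rotations of the icosahedral group
#'
#' Generated by closure from a five-fold rotation about an icosahedron vertex
#' axis and a two-fold rotation about a coordinate axis of the standard
#' (0, +/-1, +/-phi) vertex embedding. Translations are zero: capsid symmetry
#' operators act about the shell center.
#'
#' @return a list of 60 \code{\link{symmetry_operator}} objects; the first is
#'   the identity.
#' @export
icosahedral_operators <- function() {
  phi <- (1 + sqrt(5)) / 2
  gens <- list(rotation_about_axis(c(0, 1, phi), 2 * pi / 5),
               rotation_about_axis(c(0, 0, 1), pi))
  seen <- list(diag(3))
  key <- function(m) {
    v <- round(m, 6)
    v[v == 0] <- 0  # collapse -0
    paste(sprintf("%.4f", v), collapse = ",")
  }
  keys <- key(diag(3))
  repeat {
    added <- FALSE
    for (m in seen) for (g in gens) {
      cand <- g %*% m
      k <- key(cand)
      if (!(k %in% keys)) {
        seen[[length(seen) + 1L]] <- cand
        keys <- c(keys, k)
        added <- TRUE
      }
    }
    if (!added) break
  }
  stopifnot(length(seen) == 60L)
  lapply(seen, symmetry_operator)
}

#' Expand a charged asymmetric unit by a set of symmetry operators
#'
#' Applies each rigid-body operator to every particle of the unit and
#' concatenates the copies, replicating charges (and labels) unchanged. With
#' the 60 icosahedral operators this turns the trimeric capsomer unit into the
#' full icosahedral shell.
#'
#' @param unit a \code{\link{charge_distribution}}.
#' @param operators non-empty list of \code{\link{symmetry_operator}}s.
#' @return a \code{\link{charge_distribution}} with
#'   \code{nrow(unit$positions) * length(operators)} particles; total charge is
#'   exactly \code{length(operators)} times the unit's.
#' @export
expand_symmetry <- function(unit, operators) {
  stopifnot(inherits(unit, "charge_distribution"))
  if (length(operators) == 0L) stop("operators must be non-empty")
  copies <- lapply(operators, function(op) {
    if (!inherits(op, "symmetry_operator"))
      op <- symmetry_operator(op$rotation, op$translation)
    unit$positions %*% t(op$rotation) +
      matrix(op$translation, nrow(unit$positions), 3, byrow = TRUE)
  })
  charge_distribution(do.call(rbind, copies),
                      rep(unit$charges, times = length(operators)),
                      labels = if (!is.null(unit$labels))
                        rep(unit$labels, times = length(operators)))
}
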