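# Mean-field capsid electrostatics: the structure-based route (solid-angle
# averaged radial charge profile -> Gauss-theorem potential) and the
# analytical route (Debye-Hueckel thin charged shell), plus the two fitted
# analytic forms used to feed the potential into CG dynamics:
#   Yukawa+WCA: U(r) = alpha * exp(-(Rd - r)/lambda)/(Rd - r) + WCA(Rd - r)
#   polyexp:    U(r) = exp(A*(R0 - r)) * sum_{n=1..N} c_n (R0 - r)^n

#' Discretized radial potential profile
#'
#' The central exchange object between derivation, fitting and dynamics:
#' U(r) per unit test charge on a strictly increasing radial grid, in k_BT,
#' with the zero of energy at the outermost radius.
#'
#' @param r radii in nm, strictly increasing.
#' @param U energies in k_BT.
#' @param reference energy reference convention (only \code{"zero_at_rmax"}).
#' @param strict_zero enforce \code{U[length(U)] == 0} (shift tolerance 1e-9).
#' @return an object of class \code{radial_potential_profile}.
#' @export
radial_potential_profile <- function(r, U, reference = "zero_at_rmax",
                                     strict_zero = TRUE) {
  stopifnot(length(r) == length(U), length(r) >= 2L)
  if (any(diff(r) <= 0)) stop("r must be strictly increasing")
  if (!all(is.finite(U))) stop("U must be finite everywhere")
  if (strict_zero && abs(U[length(U)]) > 1e-9)
    stop("U must vanish at r_max under the zero_at_rmax reference")
  structure(list(r = as.numeric(r), U = as.numeric(U), reference = reference),
            class = "radial_potential_profile")
}

#' Solid-angle-averaged radial charge profile
#'
#' Bins every particle's full charge by its radial distance from \code{center},
#' emulating an average over the solid angle: the discretized input to the
#' Gauss-theorem potential. Total charge is conserved exactly.
#'
#' @param dist a \code{\link{charge_distribution}} (nm).
#' @param center length-3 center in nm, or \code{"com"} for the charge-
#'   weighted-by-nothing geometric centroid.
#' @param bin_width radial bin width in nm.
#' @param r_max outer radius; defaults to the outermost particle plus one bin.
#' @return object of class \code{radial_charge_profile} with fields
#'   \code{bin_edges}, \code{shell_charge}, \code{center}.
#' @export
radial_charge_profile <- function(dist, center = c(0, 0, 0), bin_width = 0.2,
                                  r_max = NULL) {
  stopifnot(inherits(dist, "charge_distribution"), bin_width > 0)
  if (identical(center, "com")) center <- colMeans(dist$positions)
  d <- sweep(dist$positions, 2, center)
  r <- sqrt(rowSums(d^2))
  if (is.null(r_max)) r_max <- max(r) + bin_width
  if (any(r > r_max)) {
    off <- which(r > r_max)[1]
    stop(sprintf("particle %d lies at r = %.4f nm beyond r_max = %.4f nm",
                 off, r[off], r_max))
  }
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  # right-open bins [e_k, e_{k+1}); the last bin closes at r_max
  idx <- findInterval(r, edges, rightmost.closed = TRUE)
  idx[idx > length(edges) - 1L] <- length(edges) - 1L
  shell <- vapply(seq_len(length(edges) - 1L),
                  function(k) sum(dist$charges[idx == k]), numeric(1))
  structure(list(bin_edges = edges, shell_charge = shell,
                 center = as.numeric(center)),
            class = "radial_charge_profile")
}

#' Gauss-theorem radial potential from a binned charge profile
#'
#' Under the spherical-symmetry approximation each radial bin's charge acts as
#' a thin shell at the bin midpoint, so the Gauss-law field
#' \eqn{E(r) = \ell_B q_{enc}(r)/r^2} integrates in closed form bin by bin:
#' the potential per unit test charge is the superposition of shell potentials
#' \eqn{\ell_B q_k (1/\max(r, m_k) - 1/r_{max})}, which is the exact integral
#' of the piecewise field (no quadrature error beyond the binning itself).
#' The zero of energy sits at the outer boundary of the charge data.
#'
#' @param profile a \code{radial_charge_profile}.
#' @param eps_r relative dielectric constant.
#' @param q_test test charge in e (default -1: one phosphate).
#' @param temperature temperature in K (sets the k_BT scale).
#' @return a \code{\link{radial_potential_profile}} on the bin midpoints plus
#'   the outer edge, where U = 0 exactly.
#' @export
gauss_potential <- function(profile, eps_r = 78.5, q_test = -1,
                            temperature = 310) {
  stopifnot(inherits(profile, "radial_charge_profile"), eps_r > 0)
  q <- profile$shell_charge
  if (length(q) < 2L) stop("profile needs at least two radial bins")
  edges <- profile$bin_edges
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  r_max <- edges[length(edges)]
  lB <- bjerrum_length(temperature, eps_r)
  # at r = m_j: shells below contribute q/r, shells at/above contribute q/m_k
  q_in <- cumsum(q)                       # includes own bin: 1/max(r, m_j) = 1/m_j
  outer_term <- rev(cumsum(rev(q / mids))) - q / mids   # sum_{k>j} q_k/m_k
  U_unit <- lB * (q_in / mids + outer_term - sum(q) / r_max)
  radial_potential_profile(c(mids, r_max), q_test * c(U_unit, 0))
}

#' Parameters of the Debye-Hueckel charged thin shell
#'
#' @param R_shell shell radius in nm.
#' @param Q_total total shell charge in e.
#' @param kappa inverse Debye length in nm^-1 (0 gives the bare Coulomb shell).
#' @param eps_r relative dielectric constant.
#' @return an object of class \code{dh_shell_params}.
#' @export
dh_shell_params <- function(R_shell, Q_total, kappa, eps_r = 78.5) {
  stopifnot(R_shell > 0, kappa >= 0, eps_r > 0)
  structure(list(R_shell = R_shell, Q_total = Q_total, kappa = kappa,
                 eps_r = eps_r), class = "dh_shell_params")
}

#' Analytical Debye-Hueckel potential of a charged spherical thin shell
#'
#' Linearized Poisson-Boltzmann solution for a uniformly charged thin shell
#' in a screening electrolyte: interior \eqn{\phi \propto \sinh(\kappa r)/r},
#' exterior \eqn{\phi \propto e^{-\kappa r}/r}, with the coefficients fixed by
#' continuity at the shell and the surface-charge jump condition. This is the
#' analytical ("empty capsid as a thin shell") route to the capsid-interior
#' potential.
#'
#' @param p a \code{\link{dh_shell_params}}.
#' @param temperature temperature in K.
#' @return a vectorized function r (nm) -> potential in k_BT per unit (+1e)
#'   test charge, finite at r = 0.
#' @export
dh_shell_potential <- function(p, temperature = 310) {
  stopifnot(inherits(p, "dh_shell_params"))
  lB <- bjerrum_length(temperature, p$eps_r)
  R <- p$R_shell; Q <- p$Q_total; kap <- p$kappa
  if (kap == 0) {
    return(function(r) ifelse(r <= R, lB * Q / R, lB * Q / r))
  }
  # A sinh(kr)/r inside, B exp(-kr)/r outside;
  # A = lB Q exp(-kR) / (kappa R), B = A sinh(kR) exp(kR)
  A <- lB * Q * exp(-kap * R) / (kap * R)
  B <- A * sinh(kap * R) * exp(kap * R)
  function(r) {
    r <- as.numeric(r)
    out <- numeric(length(r))
    inside <- r <= R
    x <- kap * r[inside]
    # sinh(x)/x via series below 1e-4 to stay finite at r = 0
    shx <- ifelse(x < 1e-4, 1 + x^2 / 6, sinh(x) / pmax(x, .Machine$double.xmin))
    out[inside] <- A * kap * shx
    out[!inside] <- B * exp(-kap * r[!inside]) / r[!inside]
    out
  }
}

wca_energy <- function(s, eps, sigma) {
  cut <- 2^(1 / 6) * sigma
  ifelse(s < cut & s > 0,
         4 * eps * ((sigma / s)^12 - (sigma / s)^6) + eps,
         0)
}

wca_dUds <- function(s, eps, sigma) {
  cut <- 2^(1 / 6) * sigma
  ifelse(s < cut & s > 0,
         4 * eps * (-12 * sigma^12 / s^13 + 6 * sigma^6 / s^7),
         0)
}

#' Parameters of the Yukawa + WCA capsid potential
#'
#' @param alpha Yukawa amplitude in k_BT nm (negative for attraction to the
#'   wall).
#' @param lam Yukawa decay length in nm.
#' @param eps WCA well depth in k_BT.
#' @param sigma WCA radius in nm.
#' @param R_delta wall radius in nm (slightly above the cavity radius); the
#'   potential diverges as r approaches it.
#' @return an object of class \code{yukawa_wca_params}.
#' @export
yukawa_wca_params <- function(alpha, lam, eps, sigma, R_delta) {
  stopifnot(lam > 0, sigma > 0, eps >= 0, R_delta > 0)
  structure(list(alpha = alpha, lam = lam, eps = eps, sigma = sigma,
                 R_delta = R_delta), class = "yukawa_wca_params")
}

#' Parameters of the exponential-polynomial cavity potential
#'
#' @param A exponential rate in nm^-1.
#' @param c polynomial coefficients c_1..c_N in k_BT nm^-n; the sum starts at
#'   n = 1 so the potential vanishes identically at r = R0.
#' @param R0 inner cavity radius in nm.
#' @return an object of class \code{polyexp_params}.
#' @export
polyexp_params <- function(A, c, R0) {
  stopifnot(R0 > 0, length(c) >= 1L)
  structure(list(A = A, c = as.numeric(c), N = length(c), R0 = R0),
            class = "polyexp_params")
}

#' Evaluate a fitted capsid potential and its radial force
#'
#' @param r radii in nm (vectorized). For \code{yukawa_wca_params} all radii must lie
#'   strictly below the wall radius \code{R_delta}.
#' @param params an \code{\link{yukawa_wca_params}} or \code{\link{polyexp_params}}.
#' @return list with \code{energy} (k_BT) and \code{force} (k_BT/nm), the
#'   analytic radial force \eqn{-dU/dr} (positive = outward).
#' @export
eval_capsid_potential <- function(r, params) {
  UseMethod("eval_capsid_potential", params)
}

#' @export
eval_capsid_potential.yukawa_wca_params <- function(r, params) {
  if (any(r >= params$R_delta))
    stop(sprintf("r must be below the WCA wall radius R_delta = %g nm",
                 params$R_delta))
  s <- params$R_delta - r
  U <- params$alpha * exp(-s / params$lam) / s + wca_energy(s, params$eps, params$sigma)
  dUds <- -params$alpha * exp(-s / params$lam) * (1 / (params$lam * s) + 1 / s^2) +
    wca_dUds(s, params$eps, params$sigma)
  list(energy = U, force = dUds)   # F = -dU/dr = +dU/ds
}

#' @export
eval_capsid_potential.polyexp_params <- function(r, params) {
  s <- params$R0 - r
  n <- seq_along(params$c)
  poly <- sapply(s, function(si) sum(params$c * si^n))
  dpoly <- sapply(s, function(si) sum(params$c * n * si^(n - 1)))
  U <- exp(params$A * s) * poly
  dUds <- exp(params$A * s) * (params$A * poly + dpoly)
  list(energy = U, force = dUds)   # F = -dU/dr = +dU/ds
}

#' Fit a radial profile with a Yukawa attraction plus a WCA wall
#'
#' Nonlinear least squares of
#' \eqn{U(r) = \alpha e^{-(R_\delta - r)/\lambda}/(R_\delta - r) +
#' U_{WCA}(R_\delta - r)} against the profile over \code{fit_window}, by
#' Levenberg-Marquardt with seeded random restarts (decay length and WCA
#' scales are fitted in log space to stay positive).
#'
#' @param profile a \code{\link{radial_potential_profile}}.
#' @param R_delta wall radius in nm; every fitted radius must lie below it.
#' @param fit_window length-2 radial interval in nm (default: whole profile).
#' @param n_starts number of random restarts.
#' @param seed RNG seed for the restarts.
#' @return list with \code{params} (\code{\link{yukawa_wca_params}}), \code{rms}
#'   residual, \code{converged} flag and \code{residuals}.
#' @export
fit_yukawa_wca <- function(profile, R_delta, fit_window = NULL,
                           n_starts = 10, seed = 1) {
  stopifnot(inherits(profile, "radial_potential_profile"))
  if (is.null(fit_window)) fit_window <- range(profile$r)
  sel <- profile$r >= fit_window[1] & profile$r <= fit_window[2]
  r <- profile$r[sel]; U <- profile$U[sel]
  if (any(r >= R_delta)) stop("all radii in fit_window must satisfy r < R_delta")
  s <- R_delta - r
  model <- function(th) {
    th[1] * exp(-s / exp(th[2])) / s + wca_energy(s, exp(th[3]), exp(th[4]))
  }
  scaleU <- max(abs(U), 1e-12)
  # data-driven start: away from the wall the Yukawa term dominates, so
  # log|U s| is linear in s with slope -1/lambda and intercept log|alpha|
  far <- s > stats::quantile(s, 0.5) & abs(U) > 1e-10 * scaleU
  th_guess <- c(-scaleU, log(0.15 * R_delta), log(0.5 * scaleU), log(0.5))
  if (sum(far) >= 3L) {
    y <- U[far] * s[far]
    sgn <- sign(y[which.max(abs(y))])
    ok <- sgn * y > 0
    if (sum(ok) >= 3L) {
      cf <- stats::coef(stats::lm(log(sgn * y[ok]) ~ s[far][ok]))
      if (is.finite(cf[2]) && cf[2] < 0)
        th_guess <- c(sgn * exp(cf[1]), log(-1 / cf[2]),
                      log(0.5 * scaleU), log(0.5))
    }
  }
  best <- NULL
  with_seed(seed, {
    for (k in seq_len(n_starts)) {
      th0 <- if (k == 1) th_guess else
        c(-scaleU * stats::runif(1, 0.1, 10) * sign(stats::runif(1) - 0.2),
          log(stats::runif(1, 0.05, 0.4) * R_delta),
          log(stats::runif(1, 0.1, 2) * max(scaleU, 1e-6)),
          log(stats::runif(1, 0.2, 1.5)))
      fit <- tryCatch(
        minpack.lm::nls.lm(par = th0, fn = function(th) model(th) - U,
                           control = minpack.lm::nls.lm.control(maxiter = 1000,
                                                                ftol = 1e-15,
                                                                ptol = 1e-15)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        ssr <- sum(fit$fvec^2)
        if (is.null(best) || ssr < best$ssr)
          best <- list(ssr = ssr, fit = fit)
      }
    }
  })
  if (is.null(best)) stop("Yukawa+WCA fit failed to run from any start")
  th <- best$fit$par
  rms <- sqrt(best$ssr / length(U))
  converged <- best$fit$info %in% 1:4
  res <- list(params = yukawa_wca_params(th[1], exp(th[2]), exp(th[3]), exp(th[4]),
                                  R_delta),
              rms = rms, converged = converged,
              residuals = best$fit$fvec)
  if (!converged && rms > 0.05 * max(diff(range(U)), 1e-12))
    stop(sprintf("Yukawa+WCA fit did not converge (best RMS %.3g); best-so-far parameters: alpha=%.4g lambda=%.4g",
                 rms, th[1], exp(th[2])))
  res
}

#' Fit a radial profile with the exponential-polynomial cavity form
#'
#' Least squares in the transformed variable \eqn{s = R_0 - r}: for each
#' candidate exponential rate A the coefficients c are the solution of a
#' linear problem (on a rescaled s for conditioning), and A itself is found
#' by a grid scan plus golden-section refinement. The fitted form vanishes at
#' r = R0 identically because the polynomial has no constant term.
#'
#' @param profile a \code{\link{radial_potential_profile}} covering (0, R0].
#' @param R0 inner cavity radius in nm.
#' @param N polynomial order (default 10).
#' @param a_range search interval for A in nm^-1.
#' @param cond_max condition-number threshold for the linear design.
#' @return list with \code{params} (\code{\link{polyexp_params}}), \code{rms},
#'   \code{condition} and \code{residuals}.
#' @export
fit_polyexp <- function(profile, R0, N = 10, a_range = c(-2, 2),
                        cond_max = 1e10) {
  stopifnot(inherits(profile, "radial_potential_profile"), R0 > 0, N >= 1)
  sel <- profile$r > 0 & profile$r <= R0
  r <- profile$r[sel]; U <- profile$U[sel]
  if (length(r) <= N + 1L)
    stop("profile must cover (0, R0] with more points than the polynomial order")
  s <- R0 - r
  smax <- max(s)
  u <- s / smax
  design <- function(A) exp(A * s) * outer(u, seq_len(N), `^`)
  solve_c <- function(A) {
    X <- design(A)
    qr.X <- qr(X)
    b <- qr.coef(qr.X, U)
    list(b = b, rss = sum((U - X %*% b)^2), X = X)
  }
  grid <- seq(a_range[1], a_range[2], length.out = 81)
  rss_grid <- vapply(grid, function(A) solve_c(A)$rss, numeric(1))
  k <- which.min(rss_grid)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  A_opt <- stats::optimize(function(A) solve_c(A)$rss, c(lo, hi),
                           tol = 1e-12)$minimum
  sol <- solve_c(A_opt)
  # joint Levenberg-Marquardt polish of (A, b): the 1-D profile over A can be
  # shallow when high-order terms dominate, and the polish removes the
  # resulting compensation error in the low-order coefficients
  pol <- tryCatch(
    minpack.lm::nls.lm(par = c(A_opt, sol$b),
                       fn = function(th) exp(th[1] * s) *
                         drop(outer(u, seq_len(N), `^`) %*% th[-1]) - U,
                       control = minpack.lm::nls.lm.control(maxiter = 200,
                                                            ftol = 1e-15,
                                                            ptol = 1e-15)),
    error = function(e) NULL)
  if (!is.null(pol) && sum(pol$fvec^2) <= sol$rss) {
    A_opt <- pol$par[1]
    sol <- list(b = pol$par[-1], rss = sum(pol$fvec^2), X = design(A_opt))
  }
  condn <- kappa(sol$X, exact = FALSE)
  if (condn > cond_max)
    stop(sprintf("ill-conditioned polynomial design (condition %.3g): lower N or rescale s",
                 condn))
  c_coef <- sol$b / smax^seq_len(N)
  list(params = polyexp_params(A_opt, c_coef, R0),
       rms = sqrt(sol$rss / length(U)), condition = condn,
       residuals = as.numeric(U - sol$X %*% sol$b))
}
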