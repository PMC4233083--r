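state_names <- as.vector(vapply(0:2, function(i)
  paste0(c("G", "M", "P", "Gs"), i), character(4)))

#' Build an ODE state vector
#'
#' The mass-action state has 4 components per gene `i`: free gene copies
#' `G_i`, mRNA `M_i`, protein `P_i`, singly-bound gene `Gs_i`. The
#' doubly-bound fraction is eliminated by conservation
#' `Gss_i = g_t - G_i - Gs_i`, leaving 12 equations.
#'
#' @param G,M,P,Gs Numeric vectors of length 3 (one entry per gene type).
#' @return Named numeric vector of length 12, ordered
#'   `G0, M0, P0, Gs0, G1, ..., Gs2`.
#' @examples
#' ode_state(G = rep(5, 3), M = rep(0, 3), P = rep(0, 3), Gs = rep(0, 3))
#' @export
ode_state <- function(G, M, P, Gs) {
  stopifnot(length(G) == 3, length(M) == 3, length(P) == 3, length(Gs) == 3)
  y <- as.vector(rbind(G, M, P, Gs))
  names(y) <- state_names
  y
}

check_ode_state <- function(y, g_t, tol) {
  G <- y[seq(1, 12, by = 4)]; Gs <- y[seq(4, 12, by = 4)]
  if (any(y < -tol)) return("negative component")
  if (any(G + Gs > g_t + tol)) return("bound fractions exceed g_t")
  NULL
}

#' Mass-action right-hand side of the repression ring
#'
#' Time derivative of the 12-component state under mass-action kinetics:
#' constitutive transcription of free genes, translation, first-order decay
#' of mRNA and protein, and cooperative repressor binding with the
#' doubly-bound gene fraction eliminated by conservation. Protein `i` binds
#' gene `(i + 1) mod 3`; gene `i` is bound by protein `(i + 2) mod 3`.
#'
#' @param state State vector from [ode_state()].
#' @param params A [kinetic_params()] object (mass-action mode).
#' @return Named derivative vector of length 12.
#' @examples
#' p <- param_preset("ode_standard")
#' y0 <- ode_state(rep(5, 3), rep(0, 3), rep(0, 3), rep(0, 3))
#' ode_rhs(y0, p)
#' @export
ode_rhs <- function(state, params) {
  stopifnot(length(state) == 12)
  dy <- numeric(12)
  for (i in 0:2) {
    ib <- repressed_by(i)   # protein bound to gene i
    j <- repressor_of(i)    # gene repressed by protein i
    G <- state[4 * i + 1]; M <- state[4 * i + 2]
    P <- state[4 * i + 3]; Gs <- state[4 * i + 4]
    Pib <- state[4 * ib + 3]
    Gj <- state[4 * j + 1]; Gsj <- state[4 * j + 4]
    dy[4 * i + 1] <- -params$k_on * G * Pib + params$k_off * Gs
    dy[4 * i + 2] <- params$alpha * G - M / params$tau_m
    dy[4 * i + 3] <- params$beta * M - P / params$tau_p -
      params$k_on * P * (Gj + Gsj) + params$k_off * Gsj +
      params$k_off2 * (params$g_t - Gj - Gsj)
    dy[4 * i + 4] <- params$k_on * Pib * (G - Gs) - params$k_off * Gs +
      params$k_off2 * (params$g_t - G - Gs)
  }
  names(dy) <- state_names
  dy
}

#' Integrate the mass-action ODE system
#'
#' Fixed-step classical Runge-Kutta (RK4) integration with `dt = 1` by
#' default, mirroring the convention that time is counted in integration
#' steps. The final state is checked against non-negativity and the bound
#' gene conservation `G_i + Gs_i <= g_t` within `1e-6 * g_t`; a violation
#' signals that `dt` is too large for the parameter set.
#'
#' @param params A [kinetic_params()] object.
#' @param y0 Initial state ([ode_state()]). Default: the symmetric steady
#'   state with `P_0` perturbed by +1 percent, which seeds the limit cycle
#'   in the oscillatory regime.
#' @param t_end Final time (steps).
#' @param dt Time step.
#' @param record_every Record every this many steps (thinning).
#' @return A tibble of class `ode_trajectory` with column `t` and the 12
#'   state components.
#' @examples
#' p <- param_preset("ode_standard", tau_p = 1e3)
#' traj <- integrate_ode(p, t_end = 1e4, record_every = 10)
#' @export
integrate_ode <- function(params, y0 = NULL, t_end, dt = 1,
                          record_every = 1) {
  if (dt <= 0) abort("`dt` must be positive.")
  if (is.null(y0)) {
    ss <- steady_state(params)
    y0 <- ss
    y0["P0"] <- y0["P0"] * 1.01
  }
  stopifnot(length(y0) == 12)
  res <- ode_rk4_cpp(as.numeric(y0), params$alpha, params$beta,
                     params$tau_m, params$tau_p, params$k_on, params$k_off,
                     params$k_off2, params$g_t, t_end, dt,
                     as.integer(record_every))
  bad <- check_ode_state(res$y[nrow(res$y), ], params$g_t,
                         tol = 1e-6 * params$g_t)
  if (!is.null(bad)) {
    abort(sprintf(
      "Trajectory left the invariant region (%s); reduce `dt`.", bad))
  }
  out <- as_tibble(as.data.frame(res$y))
  names(out) <- state_names
  out <- dplyr::bind_cols(tibble(t = res$t), out)
  attr(out, "params") <- params
  attr(out, "dt") <- dt
  class(out) <- c("ode_trajectory", class(out))
  out
}

#' Symmetric steady state of the repression ring
#'
#' With identical kinetic parameters for the three genes the fixed point is
#' symmetric (all species equal across gene types). The 12-equation system
#' then reduces to a scalar cubic in the protein level,
#' `P * (1 + a*P + q*P^2) = alpha*beta*tau_m*tau_p*g_t` with
#' `a = k_on/k_off` and `q = k_on^2/(k_off*k_off2)`, which has a unique
#' positive root (found by bisection and polished by Newton iteration).
#'
#' @param params A [kinetic_params()] object.
#' @param tol Residual tolerance on the full right-hand side, relative to
#'   `g_t`.
#' @return The symmetric fixed point as an [ode_state()] vector.
#' @examples
#' ss <- steady_state(param_preset("ode_standard"))
#' max(abs(ode_rhs(ss, param_preset("ode_standard"))))
#' @export
steady_state <- function(params, tol = 1e-10) {
  kap <- params$alpha * params$beta * params$tau_m * params$tau_p
  g_t <- params$g_t
  if (params$k_on == 0) {
    P <- kap * g_t
    y <- ode_state(rep(g_t, 3), rep(params$alpha * params$tau_m * g_t, 3),
                   rep(P, 3), rep(0, 3))
    return(y)
  }
  a <- params$k_on / params$k_off
  q <- params$k_on^2 / (params$k_off * params$k_off2)
  f <- function(P) P * (1 + a * P + q * P^2) - kap * g_t
  fp <- function(P) 1 + 2 * a * P + 3 * q * P^2
  upper <- kap * g_t
  P <- uniroot(f, c(0, upper), tol = 1e-12 * max(1, upper))$root
  for (k in 1:50) { # Newton polish to machine precision
    step <- f(P) / fp(P)
    P <- P - step
    if (abs(step) <= 1e-16 * max(1, P)) break
  }
  denom <- 1 + a * P + q * P^2
  G <- g_t / denom
  y <- ode_state(rep(G, 3), rep(params$alpha * params$tau_m * G, 3),
                 rep(P, 3), rep(a * G * P, 3))
  res <- max(abs(ode_rhs(y, params)))
  if (res > tol * g_t) {
    abort(sprintf("Steady-state solve did not converge (residual %g).", res))
  }
  y
}

#' Analytic Jacobian of the mass-action system
#'
#' @param state State vector ([ode_state()]).
#' @param params A [kinetic_params()] object.
#' @return A 12 x 12 matrix of partial derivatives of [ode_rhs()].
#' @examples
#' p <- param_preset("ode_standard")
#' J <- ode_jacobian(steady_state(p), p)
#' eigen(J, only.values = TRUE)$values[1]
#' @export
ode_jacobian <- function(state, params) {
  stopifnot(length(state) == 12)
  J <- matrix(0, 12, 12, dimnames = list(state_names, state_names))
  kon <- params$k_on; koff <- params$k_off; koff2 <- params$k_off2
  for (i in 0:2) {
    ib <- repressed_by(i); j <- repressor_of(i)
    iG <- 4 * i + 1; iM <- 4 * i + 2; iP <- 4 * i + 3; iS <- 4 * i + 4
    G <- state[iG]; P <- state[iP]; Gs <- state[iS]
    Pib <- state[4 * ib + 3]
    jG <- 4 * j + 1; jS <- 4 * j + 4
    Gj <- state[jG]; Gsj <- state[jS]
    # dG_i
    J[iG, iG] <- -kon * Pib
    J[iG, 4 * ib + 3] <- -kon * G
    J[iG, iS] <- koff
    # dM_i
    J[iM, iG] <- params$alpha
    J[iM, iM] <- -1 / params$tau_m
    # dP_i
    J[iP, iM] <- params$beta
    J[iP, iP] <- -1 / params$tau_p - kon * (Gj + Gsj)
    J[iP, jG] <- -kon * P - koff2
    J[iP, jS] <- -kon * P + koff - koff2
    # dGs_i
    J[iS, 4 * ib + 3] <- kon * (G - Gs)
    J[iS, iG] <- kon * Pib - koff2
    J[iS, iS] <- -kon * Pib - koff - koff2
  }
  J
}

leading_eigenvalue <- function(J) {
  ev <- eigen(J, only.values = TRUE)$values
  ev[which.max(Re(ev))]
}

#' Linear stability classification of a parameter point
#'
#' Computes the symmetric steady state at the given `(alpha, tau_p)`,
#' evaluates the Jacobian there and classifies the point from the leading
#' eigenvalue: `"oscillatory"` if the largest real part is positive and the
#' crossing eigenvalues form a complex pair (Hopf instability), else
#' `"stable"`.
#'
#' @param alpha Transcription rate.
#' @param tau_p Protein lifetime.
#' @param params Base [kinetic_params()] whose `alpha`/`tau_p` are replaced.
#' @return A one-row tibble: `alpha`, `tau_p`, `re_lambda`, `im_lambda`,
#'   `class`.
#' @examples
#' classify_point(0.1, 3e5, param_preset("ode_standard"))
#' @export
classify_point <- function(alpha, tau_p, params = param_preset("ode_standard")) {
  p <- params
  p$alpha <- alpha; p$tau_p <- tau_p
  ss <- steady_state(p)
  lam <- leading_eigenvalue(ode_jacobian(ss, p))
  cls <- if (Re(lam) > 0 && abs(Im(lam)) > 0) "oscillatory" else "stable"
  tibble(alpha = alpha, tau_p = tau_p,
         re_lambda = Re(lam), im_lambda = Im(lam), class = cls)
}

#' Hopf-bifurcation scan over the (alpha, tau_p) plane
#'
#' Classifies each grid point by linear stability of the symmetric steady
#' state, then locates, per `alpha`, the `tau_p` values where the leading
#' real part changes sign by bisection (relative tolerance `1e-3`). The sign
#' changes trace the two Hopf branches that enclose the oscillatory region.
#'
#' @param alpha_grid,taup_grid Numeric grids (log-spaced recommended,
#'   length `>= 2`).
#' @param params Base [kinetic_params()].
#' @param boundary_tol Relative bisection tolerance on the boundary
#'   `tau_p`; the default resolves the crossing essentially to machine
#'   precision so that the leading real part vanishes at the returned
#'   points.
#' @return A list of class `hopf_scan`: `grid` (per-point tibble, including
#'   a `failed` flag for points where the steady-state solve failed) and
#'   `boundary` (tibble `alpha`, `tau_p` of sign changes).
#' @examples
#' hopf_scan(c(0.05, 0.1), 10^seq(3, 6, length.out = 5),
#'           param_preset("ode_standard"))
#' @export
hopf_scan <- function(alpha_grid, taup_grid,
                      params = param_preset("ode_standard"),
                      boundary_tol = 1e-10) {
  stopifnot(length(alpha_grid) >= 2 || length(taup_grid) >= 2)
  pts <- tidyr::expand_grid(alpha = alpha_grid, tau_p = taup_grid)
  grid <- purrr::pmap(pts, function(alpha, tau_p) {
    tryCatch(
      dplyr::mutate(classify_point(alpha, tau_p, params), failed = FALSE),
      error = function(e) tibble(alpha = alpha, tau_p = tau_p,
                                 re_lambda = NA_real_, im_lambda = NA_real_,
                                 class = NA_character_, failed = TRUE))
  })
  grid <- dplyr::bind_rows(grid)

  re_at <- function(alpha, tau_p) {
    p <- params; p$alpha <- alpha; p$tau_p <- tau_p
    Re(leading_eigenvalue(ode_jacobian(steady_state(p), p)))
  }
  boundary <- purrr::map(unique(grid$alpha), function(a) {
    g <- dplyr::filter(grid, .data$alpha == a, !.data$failed)
    g <- dplyr::arrange(g, .data$tau_p)
    if (nrow(g) < 2) return(NULL)
    sgn <- sign(g$re_lambda)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (!length(idx)) return(NULL)
    tb <- purrr::map_dbl(idx, function(k) {
      lo <- g$tau_p[k]; hi <- g$tau_p[k + 1]
      flo <- g$re_lambda[k]
      while ((hi - lo) / hi > boundary_tol) {
        mid <- sqrt(lo * hi)
        fm <- re_at(a, mid)
        if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
      }
      sqrt(lo * hi)
    })
    tibble(alpha = a, tau_p = tb)
  })
  structure(list(grid = grid, boundary = dplyr::bind_rows(boundary)),
            class = "hopf_scan")
}

#' @export
print.hopf_scan <- function(x, ...) {
  n_osc <- sum(x$grid$class == "oscillatory", na.rm = TRUE)
  cat(sprintf("<hopf_scan> %d grid points (%d oscillatory), %d boundary points\n",
              nrow(x$grid), n_osc, nrow(x$boundary)))
  invisible(x)
}

#' Limit-cycle envelope of a trajectory
#'
#' Minimum and maximum of each protein over the trajectory tail, after
#' discarding the leading transient. On a stable fixed point the envelope
#' collapses (min close to max); on the limit cycle it spans the oscillation
#' amplitude.
#'
#' @param trajectory An `ode_trajectory` tibble from [integrate_ode()].
#' @param discard_fraction Leading fraction of the run treated as transient.
#' @return A tibble with one row per protein: `species`, `min`, `max`.
#' @examples
#' p <- param_preset("ode_standard", tau_p = 1e3)
#' limit_cycle_envelope(integrate_ode(p, t_end = 2e4, record_every = 10))
#' @export
limit_cycle_envelope <- function(trajectory, discard_fraction = 0.5) {
  stopifnot(is.data.frame(trajectory))
  keep <- trajectory$t >= discard_fraction * max(trajectory$t)
  if (!any(keep)) abort("No samples left after discarding the transient.")
  tail_tr <- trajectory[keep, ]
  purrr::map_dfr(0:2, function(i) {
    v <- tail_tr[[paste0("P", i)]]
    tibble(species = paste0("P", i), min = min(v), max = max(v))
  })
}

# Peak-to-peak amplitude of P0 over the trajectory tail, relative to the
# steady-state level: the integration oracle for "does it oscillate".
osc_amplitude <- function(trajectory, params, discard_fraction = 0.5) {
  env <- limit_cycle_envelope(trajectory, discard_fraction)
  ss <- steady_state(params)
  (env$max[1] - env$min[1]) / ss[["P0"]]
}
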