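#' Kinetic parameters of the three-gene repression ring
#'
#' Bundles all reaction rates of the circuit in which each gene is
#' constitutively transcribed, each mRNA is translated, both species decay
#' with fixed lifetimes, and each gene carries two repressor binding sites
#' with cooperative binding (much slower unbinding when doubly bound). The
#' same parameter set drives both the mass-action ODE system and the lattice
#' Monte-Carlo simulator; only the meaning of `k_on` differs between the two
#' (see `mode` in [validate_params()]).
#'
#' Time is measured in integration / Monte-Carlo steps throughout, so every
#' rate is a probability (or probability rate) per step.
#'
#' @param alpha Transcription probability rate per free gene copy per step.
#' @param beta Translation probability rate per surviving mRNA per step.
#'   Must satisfy `beta <= 1 - 1/tau_m` in lattice mode.
#' @param tau_m mRNA lifetime, steps (`>= 1`).
#' @param tau_p Protein lifetime, steps (`>= 1`).
#' @param k_on Binding rate. Mass-action mode: per molecule per step.
#'   Lattice mode: probability per protein/gene co-location event per step.
#' @param k_off Unbinding probability rate of a singly-bound gene, per step.
#' @param k_off2 Unbinding probability rate of a doubly-bound gene, per step.
#' @param g_t Gene copy number per gene type (integer `>= 1`).
#' @return An object of class `kinetic_params` (a named list).
#' @seealso [param_preset()] for the standard ODE and Monte-Carlo sets.
#' @examples
#' kinetic_params(alpha = 0.1, beta = 0.1, tau_m = 50, tau_p = 1e3,
#'                k_on = 1, k_off = 1e-3, k_off2 = 1e-5, g_t = 5)
#' @export
kinetic_params <- function(alpha, beta, tau_m, tau_p, k_on, k_off, k_off2,
                           g_t = 5) {
  p <- list(alpha = alpha, beta = beta, tau_m = tau_m, tau_p = tau_p,
            k_on = k_on, k_off = k_off, k_off2 = k_off2, g_t = g_t)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]])) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  alpha=%g beta=%g tau_m=%g tau_p=%g\n",
              x$alpha, x$beta, x$tau_m, x$tau_p))
  cat(sprintf("  k_on=%g k_off=%g k_off2=%g g_t=%d\n",
              x$k_on, x$k_off, x$k_off2, as.integer(x$g_t)))
  invisible(x)
}

#' Standard parameter presets
#'
#' Named parameter sets used throughout the package:
#' * `"ode_standard"`: mass-action set (`k_on = 1e-5`, `k_off = 1e-3`,
#'   `k_off2 = 1e-5`, `beta = 0.1`, `tau_m = 50`, `g_t = 5`); `alpha` and
#'   `tau_p` are the free bifurcation parameters and default to the
#'   oscillatory showcase point `alpha = 0.1`, `tau_p = 3e5`.
#' * `"mc_standard_2d"` / `"mc_standard_3d"`: individual-based set
#'   (`g_t = 5`, `tau_m = 50`, `tau_p = 1e3`, `alpha = beta = 0.1`,
#'   `k_on = 1`, `k_off = 1e-3`, `k_off2 = 1e-5`), with `p_move = 1` and a
#'   periodic lattice of 400 x 400 (2D) or 60 x 60 x 60 (3D) sites attached
#'   as attributes `p_move` and `lattice`.
#'
#' @param name Preset name.
#' @param ... Named overrides of individual fields (e.g. `tau_p = 3e5`).
#' @return A validated [kinetic_params()] object; the Monte-Carlo presets
#'   carry `p_move` and `lattice` attributes.
#' @examples
#' param_preset("mc_standard_2d")
#' param_preset("ode_standard", alpha = 0.05)
#' @export
param_preset <- function(name = c("ode_standard", "mc_standard_2d",
                                  "mc_standard_3d"), ...) {
  name <- match.arg(name)
  over <- list(...)
  if (name == "ode_standard") {
    base <- list(alpha = 0.1, beta = 0.1, tau_m = 50, tau_p = 3e5,
                 k_on = 1e-5, k_off = 1e-3, k_off2 = 1e-5, g_t = 5)
    mode <- "mass_action"
    p_move <- NULL
    lat <- NULL
  } else {
    base <- list(alpha = 0.1, beta = 0.1, tau_m = 50, tau_p = 1e3,
                 k_on = 1, k_off = 1e-3, k_off2 = 1e-5, g_t = 5)
    mode <- "lattice"
    p_move <- 1.0
    lat <- if (name == "mc_standard_2d") lattice_spec(dim = 2, R = 400)
           else lattice_spec(dim = 3, R = 60)
  }
  bad <- setdiff(names(over), c(names(base), "p_move"))
  if (length(bad)) abort(sprintf("Unknown parameter(s): %s",
                                 paste(bad, collapse = ", ")))
  if (!is.null(over$p_move)) {
    p_move <- over$p_move
    over$p_move <- NULL
  }
  base[names(over)] <- over
  p <- do.call(kinetic_params, base)
  p <- validate_params(p, mode = mode)
  attr(p, "p_move") <- p_move
  attr(p, "lattice") <- lat
  p
}

#' Validate a kinetic parameter set
#'
#' Checks positivity, lifetimes `>= 1`, the translation constraint
#' `beta <= 1 - 1/tau_m` (a surviving mRNA cannot translate more often than
#' it survives, lattice mode), and that every rate used as a per-step
#' probability in lattice mode lies in `[0, 1]`.
#'
#' @param params A [kinetic_params()] object.
#' @param mode `"mass_action"` or `"lattice"`. In lattice mode `alpha`,
#'   `beta`, `k_on`, `k_off`, `k_off2`, `1/tau_m`, `1/tau_p` are per-step
#'   probabilities and must be at most 1.
#' @param allow_zero Permit zero rates (useful for decoupled limits such as
#'   `k_on = 0`); by default all rates must be strictly positive.
#' @return `params`, unchanged, if valid; otherwise an error.
#' @examples
#' validate_params(param_preset("mc_standard_2d"), mode = "lattice")
#' @export
validate_params <- function(params, mode = c("mass_action", "lattice"),
                            allow_zero = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "kinetic_params"))
  rates <- c("alpha", "beta", "tau_m", "tau_p", "k_on", "k_off", "k_off2",
             "g_t")
  for (nm in rates) {
    v <- params[[nm]]
    if (v < 0 || (!allow_zero && v == 0)) {
      abort(sprintf("`%s` must be %s (got %g).", nm,
                    if (allow_zero) "non-negative" else "strictly positive",
                    v))
    }
  }
  if (params$tau_m < 1 || params$tau_p < 1) {
    abort("Lifetimes `tau_m` and `tau_p` must be at least 1 step.")
  }
  if (params$g_t < 1 || params$g_t != round(params$g_t)) {
    abort("`g_t` must be a positive integer.")
  }
  if (mode == "lattice") {
    if (params$beta > 1 - 1 / params$tau_m) {
      abort(sprintf(
        "Translation constraint violated: beta = %g > 1 - 1/tau_m = %g.",
        params$beta, 1 - 1 / params$tau_m))
    }
    probs <- c(alpha = params$alpha, beta = params$beta, k_on = params$k_on,
               k_off = params$k_off, k_off2 = params$k_off2)
    if (any(probs > 1)) {
      bad <- names(probs)[probs > 1][1]
      abort(sprintf("Lattice-mode probability `%s` = %g exceeds 1.",
                    bad, probs[[bad]]))
    }
  }
  params
}

#' Repression topology of the three-gene ring
#'
#' The circuit is a single directed 3-cycle: protein `i` represses gene
#' `(i + 1) mod 3`, equivalently gene `i` is bound by protein
#' `(i + 2) mod 3`. Gene and protein types are labelled 0, 1, 2 as is
#' conventional for this circuit. All other functions consume these helpers
#' rather than re-deriving indices.
#'
#' @param i Gene or protein type in `{0, 1, 2}` (vectorised).
#' @return `repressor_of(i)`: the gene type repressed by protein `i`.
#'   `repressed_by(i)`: the protein type that binds gene `i`.
#'   `repression_topology()`: a tibble with one row per gene listing its
#'   repressor protein and the gene its own protein represses.
#' @examples
#' repressor_of(0:2)
#' repressed_by(repressor_of(0:2)) # identity
#' @export
repressor_of <- function(i) {
  stopifnot(all(i %in% 0:2))
  (i + 1L) %% 3L
}

#' @rdname repressor_of
#' @export
repressed_by <- function(i) {
  stopifnot(all(i %in% 0:2))
  (i + 2L) %% 3L
}

#' @rdname repressor_of
#' @export
repression_topology <- function() {
  tibble(gene = 0:2,
         bound_by_protein = repressed_by(0:2),
         protein_represses_gene = repressor_of(0:2))
}

#' Dissociation constant in nanomolar
#'
#' Converts the per-cell equilibrium dissociation constant `k_off / k_on`
#' (in molecules per cell) to a molar concentration using the cell volume
#' and Avogadro's number, expressed in nM. With the standard mass-action
#' binding parameters and an *E. coli* volume of 3 fl this gives ~55 nM for
#' the free gene and ~0.55 nM for the singly-bound (cooperative) site.
#'
#' @param k_on Association rate, per molecule per step (`> 0`).
#' @param k_off Dissociation rate, per step (`> 0`).
#' @param volume Cell volume in litres; default 3 fl.
#' @return Dissociation constant in nM.
#' @examples
#' kd_nanomolar(1e-5, 1e-3) # ~55 nM
#' kd_nanomolar(1e-5, 1e-5) # ~0.55 nM
#' @export
kd_nanomolar <- function(k_on, k_off, volume = 3e-15) {
  if (any(c(k_on, k_off, volume) <= 0)) {
    abort("All arguments of kd_nanomolar() must be strictly positive.")
  }
  avogadro <- 6.02214076e23
  (k_off / k_on) / (avogadro * volume) * 1e9
}

#' Spatial range (Kuramoto length) of a diffusing, decaying molecule
#'
#' Root-mean-square displacement of a lattice random walker over one mean
#' lifetime, `sqrt(2 * dim * D * lifetime)` in lattice units. This is the
#' typical distance an mRNA or protein travels before degradation and sets
#' whether a repressor can reach a distant target gene. The shorthand
#' "lifetime times diffusion coefficient" often used for this range is not
#' itself a length; the RMS-displacement reading used here is this
#' package's convention and is monotone in the same product.
#'
#' @param lifetime Mean lifetime in steps (`> 0`).
#' @param D Diffusion coefficient in lattice-units^2 per step (`>= 0`).
#' @param dim Lattice dimension, 2 or 3.
#' @return Length in lattice units.
#' @examples
#' kuramoto_length(50, 0.25, dim = 2) # sqrt(50)
#' @export
kuramoto_length <- function(lifetime, D, dim = 2) {
  stopifnot(dim %in% c(2, 3))
  if (any(lifetime <= 0)) abort("`lifetime` must be positive.")
  if (any(D < 0)) abort("`D` must be non-negative.")
  sqrt(2 * dim * D * lifetime)
}

#' Diffusion coefficient of the lattice random walk
#'
#' A walker that moves with probability `p_move` per step to one of its
#' `2 * dim` nearest neighbours has diffusion coefficient
#' `D = p_move / (2 * dim)`: `p_move / 4` in 2D, `p_move / 6` in 3D
#' (lattice units squared per step).
#'
#' @param p_move Movement probability per step, in `[0, 1]`.
#' @param dim Lattice dimension, 2 or 3.
#' @return Diffusion coefficient in lattice-units^2 per step.
#' @examples
#' diffusion_coefficient(1, dim = 3) # 1/6 ~= 0.167
#' @export
diffusion_coefficient <- function(p_move, dim = 2) {
  if (!all(dim %in% c(2, 3))) abort("`dim` must be 2 or 3.")
  if (any(p_move < 0 | p_move > 1)) abort("`p_move` must lie in [0, 1].")
  p_move / (2 * dim)
}
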