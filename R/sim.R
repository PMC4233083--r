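#' One step of the periodic lattice random walk
#'
#' With probability `p_move` the walker moves to one of its `2 * dim`
#' nearest neighbours (chosen uniformly) with periodic wrap; otherwise it
#' stays. Exposed mainly for testing; the simulator applies the same rule
#' internally to every mRNA and free protein.
#'
#' @param position Integer vector of coordinates in `[0, R)`.
#' @param lattice A [lattice_spec()].
#' @param p_move Movement probability per step.
#' @return The new position (integer vector).
#' @examples
#' set.seed(1)
#' random_walk_step(c(0, 0), lattice_spec(2, 400), p_move = 1)
#' @export
random_walk_step <- function(position, lattice, p_move = 1) {
  stopifnot(inherits(lattice, "lattice_spec"),
            length(position) == lattice$dim,
            all(position >= 0 & position < lattice$R))
  if (runif(1) < p_move) {
    dir <- sample.int(2L * lattice$dim, 1L)
    axis <- (dir + 1L) %/% 2L
    sgn <- if (dir %% 2L == 1L) 1L else -1L
    position[axis] <- (position[axis] + sgn) %% lattice$R
  }
  position
}

#' Spatially explicit Monte-Carlo simulation of the repression ring
#'
#' Runs the individual-based simulator: immobile gene copies on a periodic
#' lattice, mRNAs and proteins performing nearest-neighbour random walks,
#' and per-step stochastic transcription, translation, degradation,
#' cooperative binding and unbinding. Each Monte-Carlo step executes, in
#' order: (1) every free gene emits an mRNA at its own site with probability
#' `alpha`; (2) every pre-existing mRNA is degraded with probability
#' `1/tau_m` or else attempts translation (probability `beta`, protein
#' deposited at the mRNA's current site) and then moves; (3) every
#' pre-existing free protein is degraded with probability `1/tau_p` or else
#' moves; (4) free proteins co-located with a free or singly-bound target
#' gene bind with probability `k_on` (candidates in uniformly random order,
#' at most two proteins per gene); (5) complexes formed before this step
#' unbind with probability `k_off` (singly bound) or `k_off2` (doubly
#' bound), releasing one protein at the gene's site. Newly created molecules
#' are inert until the next step. Only free proteins decay and only free
#' genes transcribe.
#'
#' Recorded totals count free plus gene-bound molecules. Runs are
#' bit-reproducible given `(layout, params, seed)`.
#'
#' @param layout A `gene_layout` tibble from [place_genes()].
#' @param params A [kinetic_params()] object (lattice mode).
#' @param n_steps Number of recorded steps (after burn-in).
#' @param burn_in Leading steps discarded before recording (transient).
#' @param p_move Movement probability; defaults to the preset's value.
#' @param seed Optional integer seed (caller's RNG state preserved).
#' @param record_stride Record every this many steps.
#' @param record_mrna Also record mRNA totals.
#' @param record_genes Also record free/singly/doubly-bound gene counts.
#' @param init_mrna,init_protein Initial molecules of each type placed at
#'   uniformly random sites (defaults 10 and 1e4).
#' @param init_occupancy Initial bound proteins per gene (0, 1 or 2);
#'   non-zero values are for targeted tests.
#' @param allow_zero Accept zero-valued rates (decoupled limits).
#' @return A tibble of class `species_ts` with columns `t`, `P0`, `P1`,
#'   `P2` (and optionally `M0..M2`, `G<i>_free/single/double`), plus
#'   attributes `params`, `lattice`, `p_move`, `seed`, `burn_in`, `stride`
#'   and `final_gene_state`.
#' @examples
#' lat <- lattice_spec(2, 50)
#' lay <- place_uniform(lat, g_t = 5, seed = 1)
#' p <- param_preset("mc_standard_2d", tau_p = 100)
#' ts <- simulate_circuit(lay, p, n_steps = 500, seed = 1,
#'                        init_protein = 100)
#' @export
simulate_circuit <- function(layout, params, n_steps, burn_in = 0,
                             p_move = NULL, seed = NULL, record_stride = 1,
                             record_mrna = FALSE, record_genes = FALSE,
                             init_mrna = 10, init_protein = 1e4,
                             init_occupancy = 0, allow_zero = FALSE) {
  lattice <- layout_lattice(layout)
  p_move <- p_move %||% attr(params, "p_move") %||% 1.0
  if (p_move < 0 || p_move > 1) abort("`p_move` must lie in [0, 1].")
  params <- validate_params(params, mode = "lattice", allow_zero = allow_zero)
  if (n_steps < 1) abort("`n_steps` must be at least 1.")
  if (!init_occupancy %in% 0:2) abort("`init_occupancy` must be 0, 1 or 2.")
  pos <- layout_positions(layout)
  if (any(pos < 0 | pos >= lattice$R)) abort("Gene positions out of range.")
  types <- as.integer(layout$type)
  counts <- table(factor(types, levels = 0:2))
  if (length(unique(counts)) != 1L) {
    abort("Layout must contain the same number of copies of each gene type.")
  }

  res <- with_rng(seed, {
    sim_run_cpp(pos, types, lattice$dim, lattice$R,
                params$alpha, params$beta, params$tau_m, params$tau_p,
                params$k_on, params$k_off, params$k_off2, p_move,
                as.numeric(n_steps), as.numeric(burn_in),
                as.integer(record_stride),
                as.integer(init_mrna), as.integer(init_protein),
                as.integer(init_occupancy), record_mrna, record_genes)
  })

  # hard invariant: per-type gene copies conserved across occupancy states
  per_type <- rowSums(res$final_gene_state)
  if (!all(per_type == as.integer(counts))) {
    abort("Gene-copy conservation violated (internal error).")
  }

  out <- tibble(t = res$t,
                P0 = res$P[, 1], P1 = res$P[, 2], P2 = res$P[, 3])
  if (record_mrna) {
    out$M0 <- res$M[, 1]; out$M1 <- res$M[, 2]; out$M2 <- res$M[, 3]
  }
  if (record_genes) {
    gcols <- as.data.frame(res$genes)
    names(gcols) <- as.vector(outer(c("free", "single", "double"), 0:2,
                                    function(s, ty) sprintf("G%d_%s", ty, s)))
    out <- dplyr::bind_cols(out, as_tibble(gcols))
  }
  attr(out, "params") <- params
  attr(out, "lattice") <- lattice
  attr(out, "p_move") <- p_move
  attr(out, "seed") <- seed
  attr(out, "burn_in") <- burn_in
  attr(out, "stride") <- record_stride
  attr(out, "layout_checksum") <- layout_checksum(layout)
  attr(out, "final_gene_state") <- res$final_gene_state
  class(out) <- c("species_ts", class(out))
  out
}

# FNV-1a hash of the layout's defining columns; identifies the layout in
# time-series headers so a run can be reproduced bit-exactly.
layout_checksum <- function(layout) {
  lat <- layout_lattice(layout)
  s <- paste(c(lat$dim, lat$R, as.matrix(layout[, c("gene_id", "type",
                                                    axis_names(lat$dim))])),
             collapse = ",")
  h <- 2166136261
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Mean squared displacement of free lattice tracers
#'
#' Simulates `n_walkers` independent random walkers (no reactions, unbounded
#' lattice) and returns their empirical mean squared displacement at every
#' step. For the nearest-neighbour walk the expectation is
#' `2 * dim * D * t` with `D = p_move / (2 * dim)`.
#'
#' @param n_walkers Number of walkers.
#' @param n_steps Number of steps.
#' @param dim Lattice dimension, 2 or 3.
#' @param p_move Movement probability per step.
#' @param seed Optional seed.
#' @return A tibble with columns `t`, `msd`, `expected`.
#' @examples
#' tracer_msd(1000, 100, dim = 2, seed = 1)
#' @export
tracer_msd <- function(n_walkers, n_steps, dim = 2, p_move = 1,
                       seed = NULL) {
  if (!dim %in% c(2, 3)) abort("`dim` must be 2 or 3.")
  msd <- with_rng(seed, tracer_msd_cpp(as.integer(n_walkers),
                                       as.integer(n_steps), as.integer(dim),
                                       p_move))
  t <- seq_len(n_steps)
  tibble(t = t, msd = msd,
         expected = 2 * dim * diffusion_coefficient(p_move, dim) * t)
}
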