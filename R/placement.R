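#' Periodic lattice specification
#'
#' A square (2D) or cubic (3D) lattice of linear size `R` with unit internode
#' distance and periodic boundaries. Site coordinates are integers in
#' `[0, R)` per axis.
#'
#' @param dim Dimension, 2 or 3.
#' @param R Linear size in lattice units (`>= 2`).
#' @return An object of class `lattice_spec`.
#' @examples
#' lattice_spec(2, 400)
#' @export
lattice_spec <- function(dim = 2, R = 400) {
  if (!dim %in% c(2, 3)) abort("`dim` must be 2 or 3.")
  if (!is.numeric(R) || length(R) != 1L || R < 1 || R != round(R)) {
    abort("`R` must be a positive integer.")
  }
  structure(list(dim = as.integer(dim), R = as.integer(R)),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %s periodic lattice, %s sites\n",
              paste(rep(x$R, x$dim), collapse = " x "),
              format(x$R^x$dim, big.mark = ",")))
  invisible(x)
}

axis_names <- function(dim) c("x", "y", "z")[seq_len(dim)]

new_layout <- function(lattice, type, pos, box_id) {
  colnames(pos) <- axis_names(lattice$dim)
  out <- tibble(gene_id = seq_along(type), type = as.integer(type))
  out <- dplyr::bind_cols(out, as_tibble(pos))
  out$box_id <- box_id
  out$occupancy <- rep("free", length(type))
  attr(out, "lattice") <- lattice
  class(out) <- c("gene_layout", class(out))
  out
}

#' Place disjoint boxes on the lattice
#'
#' Positions `n_boxes` axis-aligned hypercubes of side `r` uniformly at
#' random, entirely inside `[0, R)` on each axis (boxes never wrap across
#' the periodic boundary), with pairwise-disjoint interiors (touching faces
#' allowed). Placement is by rejection sampling over the joint configuration.
#'
#' @param lattice A [lattice_spec()].
#' @param n_boxes Number of boxes.
#' @param r Box side in lattice units, `1 <= r <= R`.
#' @param max_tries Rejection-sampling attempts before giving up.
#' @return Integer matrix of box origins (`n_boxes` rows, `dim` columns).
#' @examples
#' set.seed(1)
#' place_boxes(lattice_spec(2, 400), n_boxes = 5, r = 3)
#' @export
place_boxes <- function(lattice, n_boxes, r, max_tries = 1e4) {
  stopifnot(inherits(lattice, "lattice_spec"))
  R <- lattice$R; dim <- lattice$dim
  if (r < 1 || r > R) abort("`r` must satisfy 1 <= r <= R.")
  if (n_boxes * r^dim > R^dim) {
    abort(sprintf("Cannot fit %d boxes of side %d in a lattice of size %d.",
                  n_boxes, r, R))
  }
  n_origin <- R - r + 1L # origins with the box fully inside [0, R)
  for (try in seq_len(max_tries)) {
    org <- matrix(sample.int(n_origin, n_boxes * dim, replace = TRUE) - 1L,
                  nrow = n_boxes, ncol = dim)
    ok <- TRUE
    if (n_boxes > 1) {
      for (a in seq_len(n_boxes - 1)) {
        for (b in seq(a + 1, n_boxes)) {
          # disjoint iff separated along at least one axis
          if (all(abs(org[a, ] - org[b, ]) < r)) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) {
      colnames(org) <- axis_names(dim)
      return(org)
    }
  }
  abort(sprintf(
    "Failed to place %d disjoint boxes of side %d on a size-%d lattice after %d tries.",
    n_boxes, r, R, max_tries))
}

#' Gene placement scenarios
#'
#' Generate the immobile gene positions for the three spatial scenarios.
#' Each of the 3 gene types is present in `g_t` copies:
#' * `place_uniform()`: all `3 * g_t` copies at independent uniformly random
#'   sites (well-mixed reference). Site collisions between genes are allowed.
#' * `place_clustered()`: `g_t` disjoint boxes of side `r`, each holding one
#'   copy of each gene type at an independent uniform site inside its box
#'   (each repressor sits next to its target).
#' * `place_segregated()`: 3 disjoint boxes of side `r`; box `b` holds all
#'   `g_t` copies of type `b` (like genes together, unlike genes apart).
#'
#' The ratio `r/R` quantifies demixing: `r/R -> 1` recovers the uniform
#' configuration, `r/R -> 0` is strong demixing. Layouts are plain tibbles
#' (columns `gene_id`, `type`, coordinates, `box_id`, `occupancy`) and are
#' treated as immutable by the simulator (genes never move).
#'
#' @param lattice A [lattice_spec()].
#' @param g_t Copies per gene type.
#' @param r Box side (clustered/segregated only).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param max_tries Passed to [place_boxes()].
#' @return A `gene_layout` tibble with `3 * g_t` rows.
#' @examples
#' place_uniform(lattice_spec(2, 400), g_t = 5, seed = 1)
#' place_segregated(lattice_spec(2, 400), g_t = 5, r = 3, seed = 1)
#' @export
place_uniform <- function(lattice, g_t = 5, seed = NULL) {
  stopifnot(inherits(lattice, "lattice_spec"))
  with_rng(seed, {
    n <- 3L * g_t
    pos <- matrix(sample.int(lattice$R, n * lattice$dim, replace = TRUE) - 1L,
                  nrow = n, ncol = lattice$dim)
    new_layout(lattice, rep(0:2, each = g_t), pos, rep(NA_integer_, n))
  })
}

#' @rdname place_uniform
#' @export
place_clustered <- function(lattice, g_t = 5, r, seed = NULL,
                            max_tries = 1e4) {
  stopifnot(inherits(lattice, "lattice_spec"))
  with_rng(seed, {
    org <- place_boxes(lattice, n_boxes = g_t, r = r, max_tries = max_tries)
    # one copy of each type per box, uniform inside the box
    type <- rep(0:2, times = g_t)
    box <- rep(seq_len(g_t), each = 3L)
    pos <- org[box, , drop = FALSE] +
      matrix(sample.int(r, 3L * g_t * lattice$dim, replace = TRUE) - 1L,
             nrow = 3L * g_t, ncol = lattice$dim)
    out <- new_layout(lattice, type, pos, as.integer(box))
    attr(out, "box_origins") <- org
    attr(out, "r") <- as.integer(r)
    out
  })
}

#' @rdname place_uniform
#' @export
place_segregated <- function(lattice, g_t = 5, r, seed = NULL,
                             max_tries = 1e4) {
  stopifnot(inherits(lattice, "lattice_spec"))
  with_rng(seed, {
    org <- place_boxes(lattice, n_boxes = 3L, r = r, max_tries = max_tries)
    # box b holds all g_t copies of type b
    type <- rep(0:2, each = g_t)
    box <- rep(1:3, each = g_t)
    pos <- org[box, , drop = FALSE] +
      matrix(sample.int(r, 3L * g_t * lattice$dim, replace = TRUE) - 1L,
             nrow = 3L * g_t, ncol = lattice$dim)
    out <- new_layout(lattice, type, pos, as.integer(box))
    attr(out, "box_origins") <- org
    attr(out, "r") <- as.integer(r)
    out
  })
}

#' @rdname place_uniform
#' @param scenario One of `"uniform"`, `"clustered"`, `"segregated"`.
#' @export
place_genes <- function(lattice, scenario = c("uniform", "clustered",
                                              "segregated"),
                        g_t = 5, r = NULL, seed = NULL, max_tries = 1e4) {
  scenario <- match.arg(scenario)
  if (scenario == "uniform") return(place_uniform(lattice, g_t, seed))
  if (is.null(r)) abort("`r` is required for clustered/segregated placement.")
  switch(scenario,
         clustered = place_clustered(lattice, g_t, r, seed, max_tries),
         segregated = place_segregated(lattice, g_t, r, seed, max_tries))
}

layout_lattice <- function(layout) {
  lat <- attr(layout, "lattice")
  if (is.null(lat)) abort("Layout is missing its `lattice` attribute.")
  lat
}

layout_positions <- function(layout) {
  lat <- layout_lattice(layout)
  as.matrix(layout[, axis_names(lat$dim), drop = FALSE])
}
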