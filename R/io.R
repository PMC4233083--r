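format_header <- function(meta) {
  vapply(names(meta), function(k) sprintf("# %s: %s", k, format(meta[[k]])),
         character(1))
}

parse_header <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  setNames(as.list(vals), keys)
}

#' Write / read a species time series
#'
#' Tab-separated columns `t P0 P1 P2 [M0 M1 M2 ...]` preceded by `#`-prefixed
#' header lines carrying the full simulation parameters, the seed, the
#' recording stride and the layout checksum, so a run can be replayed from
#' the file alone. Counts are stored as integers and round-trip bit-exactly.
#'
#' @param series A `species_ts` tibble from [simulate_circuit()].
#' @param path Output file.
#' @return `write_series()` returns `path` invisibly; `read_series()`
#'   returns the tibble with header metadata re-attached (`params`,
#'   `stride`, `seed`, ...).
#' @export
write_series <- function(series, path) {
  stopifnot(is.data.frame(series))
  p <- attr(series, "params")
  lat <- attr(series, "lattice")
  meta <- list(format = "repressilator_series_v1")
  if (!is.null(p)) meta <- c(meta, unclass(p))
  if (!is.null(lat)) meta <- c(meta, list(dim = lat$dim, R = lat$R))
  meta$p_move <- attr(series, "p_move")
  meta$seed <- attr(series, "seed") %||% "none"
  meta$burn_in <- attr(series, "burn_in") %||% 0
  meta$stride <- attr(series, "stride") %||% 1
  meta$layout_checksum <- attr(series, "layout_checksum") %||% "none"
  meta <- meta[!vapply(meta, is.null, logical(1))]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_header(meta), con)
  writeLines(paste(names(series), collapse = "\t"), con)
  df <- as.data.frame(series)
  df$t <- format(df$t, scientific = FALSE, trim = TRUE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  n_hdr <- match(FALSE, hdr) - 1L
  if (is.na(n_hdr) || n_hdr == length(lines)) {
    abort(sprintf("Malformed series file '%s': no data after header.", path))
  }
  meta <- parse_header(lines[seq_len(n_hdr)])
  cols <- strsplit(lines[n_hdr + 1L], "\t")[[1]]
  body <- lines[-seq_len(n_hdr + 1L)]
  mat <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(mat) != length(cols))
  if (length(bad)) {
    abort(sprintf("Parse error in '%s' at line %d: expected %d columns.",
                  path, n_hdr + 1L + bad[1], length(cols)))
  }
  vals <- matrix(as.numeric(unlist(mat)), ncol = length(cols), byrow = TRUE)
  if (anyNA(vals)) {
    row <- which(apply(is.na(vals), 1, any))[1]
    abort(sprintf("Parse error in '%s' at line %d: non-numeric value.",
                  path, n_hdr + 1L + row))
  }
  count_cols <- setdiff(cols, "t")
  if (any(vals[, match(count_cols, cols)] %% 1 != 0)) {
    abort(sprintf("Count columns in '%s' must be integers.", path))
  }
  out <- as_tibble(as.data.frame(vals))
  names(out) <- cols
  for (ch in count_cols) out[[ch]] <- as.integer(out[[ch]])
  num <- function(k) if (!is.null(meta[[k]])) as.numeric(meta[[k]]) else NULL
  kin_keys <- c("alpha", "beta", "tau_m", "tau_p", "k_on", "k_off", "k_off2",
                "g_t")
  if (all(kin_keys %in% names(meta))) {
    attr(out, "params") <- do.call(kinetic_params,
                                   lapply(setNames(kin_keys, kin_keys), num))
  }
  if (!is.null(meta$dim)) {
    attr(out, "lattice") <- lattice_spec(num("dim"), num("R"))
  }
  attr(out, "p_move") <- num("p_move")
  attr(out, "stride") <- num("stride") %||% 1
  attr(out, "burn_in") <- num("burn_in") %||% 0
  if (!identical(meta$seed, "none")) attr(out, "seed") <- num("seed")
  attr(out, "layout_checksum") <- meta$layout_checksum
  class(out) <- c("species_ts", class(out))
  out
}

#' Write / read a gene layout
#'
#' Comma-separated columns `gene_id,type,x,y[,z],box_id,occupancy` with
#' `#`-prefixed header lines recording the lattice. A layout read back from
#' file reproduces a simulation bit-exactly (same positions, same checksum).
#'
#' @param layout A `gene_layout` tibble.
#' @param path File path.
#' @return `write_layout()` returns `path` invisibly; `read_layout()` the
#'   layout tibble.
#' @export
write_layout <- function(layout, path) {
  lat <- layout_lattice(layout)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_header(list(format = "repressilator_layout_v1",
                                dim = lat$dim, R = lat$R)), con)
  writeLines(paste(names(layout), collapse = ","), con)
  utils::write.table(as.data.frame(layout), con, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  n_hdr <- match(FALSE, hdr) - 1L
  meta <- parse_header(lines[seq_len(n_hdr)])
  if (!identical(meta$format, "repressilator_layout_v1")) {
    abort(sprintf("'%s' is not a layout file.", path))
  }
  lat <- lattice_spec(as.numeric(meta$dim), as.numeric(meta$R))
  df <- utils::read.csv(textConnection(lines[-seq_len(n_hdr)]))
  need <- c("gene_id", "type", axis_names(lat$dim), "occupancy")
  missing_c <- setdiff(need, names(df))
  if (length(missing_c)) {
    abort(sprintf("Layout file '%s' lacks column(s): %s", path,
                  paste(missing_c, collapse = ", ")))
  }
  out <- as_tibble(df)
  attr(out, "lattice") <- lat
  class(out) <- c("gene_layout", class(out))
  out
}

#' Load a simulation configuration file
#'
#' YAML key-value configuration with optional `preset` expansion: the named
#' preset is loaded first and the remaining keys override individual fields.
#' Unknown keys are errors (misspellings never pass silently). Recognised
#' keys are the [kinetic_params()] fields plus `preset`, `p_move`, `dim`,
#' `R`, `scenario`, `r`, `g_t`, `n_steps`, `burn_in`, `seed`,
#' `segment_length`, `threshold`.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `params` ([kinetic_params()]), `lattice`
#'   (or `NULL`), `p_move`, and `run` (the remaining run-control keys).
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort(sprintf("'%s' did not parse as a mapping.", path))
  kin_keys <- c("alpha", "beta", "tau_m", "tau_p", "k_on", "k_off", "k_off2",
                "g_t")
  run_keys <- c("scenario", "r", "n_steps", "burn_in", "seed",
                "segment_length", "threshold", "replicates", "record_stride")
  known <- c("preset", "p_move", "dim", "R", kin_keys, run_keys)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  for (k in intersect(names(cfg), c(kin_keys, "p_move", "dim", "R"))) {
    if (is.character(cfg[[k]]) && !is.na(suppressWarnings(as.numeric(cfg[[k]])))) {
      cfg[[k]] <- as.numeric(cfg[[k]]) # YAML 1.1 treats e.g. "3.0e5" as text
    }
    if (!is.numeric(cfg[[k]])) abort(sprintf("Key `%s` must be numeric.", k))
  }
  p_move <- cfg$p_move
  lattice <- NULL
  if (!is.null(cfg$preset)) {
    over <- cfg[intersect(names(cfg), kin_keys)]
    params <- do.call(param_preset, c(list(name = cfg$preset), over))
    p_move <- p_move %||% attr(params, "p_move")
    lattice <- attr(params, "lattice")
  } else {
    miss <- setdiff(setdiff(kin_keys, "g_t"), names(cfg))
    if (length(miss)) {
      abort(sprintf("No preset given and missing kinetic key(s): %s",
                    paste(miss, collapse = ", ")))
    }
    params <- do.call(kinetic_params, cfg[intersect(names(cfg), kin_keys)])
  }
  if (!is.null(cfg$dim) || !is.null(cfg$R)) {
    if (is.null(cfg$dim) || is.null(cfg$R)) {
      abort("`dim` and `R` must be given together.")
    }
    lattice <- lattice_spec(cfg$dim, cfg$R)
  }
  list(params = params, lattice = lattice, p_move = p_move,
       run = cfg[intersect(names(cfg), run_keys)])
}

#' Run manifest
#'
#' Collects everything needed to replay a run: package version, resolved
#' parameters, seeds and input-file checksums, with a timestamp.
#'
#' @param params A [kinetic_params()] object.
#' @param lattice A [lattice_spec()] or `NULL`.
#' @param seed Seed(s) used.
#' @param files Named character vector of input files to checksum.
#' @param extra Named list of additional fields.
#' @return A list of class `run_manifest`; write with [yaml::write_yaml()].
#' @export
run_manifest <- function(params = NULL, lattice = NULL, seed = NULL,
                         files = character(), extra = list()) {
  checks <- lapply(files, function(f) {
    if (!file.exists(f)) return("missing")
    h <- 2166136261
    for (ch in as.integer(readBin(f, "raw", file.size(f)))) {
      h <- (h * 31 + ch) %% 2147483647
    }
    sprintf("%08x", h)
  })
  structure(c(list(
    tool = "repressilator",
    version = as.character(utils::packageVersion("repressilator")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = if (!is.null(params)) unclass(params),
    lattice = if (!is.null(lattice)) unclass(lattice),
    seed = seed,
    input_checksums = checks), extra),
    class = "run_manifest")
}
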