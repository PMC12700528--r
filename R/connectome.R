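#' Construct a structural connectome
#'
#' A structural connectome holds the non-negative inter-regional coupling
#' weights (typically streamline counts from diffusion tractography, here
#' dimensionless), optional inter-regional distances in millimetres, and
#' region labels. The weight diagonal is forced to zero: the network coupling
#' sums in every model are afferent input from *other* regions.
#'
#' @param weights square numeric matrix of non-negative, finite weights.
#' @param distances optional square symmetric matrix of distances (mm) with a
#'   zero diagonal.
#' @param labels optional character vector of region names.
#' @param normalized logical; `TRUE` when `max(weights) == 1` by construction.
#' @return an object of class `connectome`.
#' @export
connectome <- function(weights, distances = NULL, labels = NULL,
                       normalized = FALSE) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("connectome weights must be square, got ", nrow(weights), "x", ncol(weights))
  if (any(!is.finite(weights)))
    stop("connectome weights contain NaN or Inf entries")
  if (any(weights < 0))
    stop("connectome weights must be non-negative")
  if (any(diag(weights) != 0)) {
    warning("nonzero weight diagonal forced to zero (self-connections are not modeled)")
    diag(weights) <- 0
  }
  n <- nrow(weights)
  if (!is.null(distances)) {
    distances <- as.matrix(distances)
    if (!identical(dim(distances), dim(weights)))
      stop("distances must match weights dimensions")
    if (any(!is.finite(distances)) || any(distances < 0))
      stop("distances must be finite and non-negative")
    if (max(abs(distances - t(distances))) > 1e-8 * max(1, max(distances)))
      stop("distances must be symmetric")
    if (any(diag(distances) != 0))
      stop("distances must have a zero diagonal")
  }
  if (is.null(labels)) labels <- sprintf("region_%03d", seq_len(n))
  if (length(labels) != n) stop("labels must have length ", n)
  structure(
    list(weights = weights, distances = distances, labels = labels,
         normalized = isTRUE(normalized)),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  nz <- sum(x$weights[upper.tri(x$weights) | lower.tri(x$weights)] > 0)
  cat(sprintf(
    "<connectome> %d regions, %d nonzero edges (density %.2f), %s, distances: %s\n",
    n, nz, nz / (n * (n - 1)),
    if (x$normalized) "normalized" else "unnormalized",
    if (is.null(x$distances)) "absent" else "present"
  ))
  invisible(x)
}

#' Number of regions in a connectome
#' @param sc a `connectome`.
#' @return integer region count.
#' @export
n_regions <- function(sc) nrow(sc$weights)

#' Load a structural connectome from disk
#'
#' @param path file path. Delimited text holds the weight matrix only
#'   (whitespace- or comma-separated); NPZ archives use keys `weights` and
#'   optionally `distances`; RDS files hold a saved `connectome`.
#' @param format one of `"delimited"`, `"npz"`, `"rds"`; default guesses from
#'   the file extension.
#' @return a validated `connectome` with `normalized = FALSE` (RDS keeps its
#'   stored flag).
#' @export
load_connectome <- function(path, format = c("auto", "delimited", "npz", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      "npz" = "npz", "rds" = "rds", "delimited")
  }
  if (format == "rds") {
    sc <- readRDS(path)
    if (!inherits(sc, "connectome")) stop("RDS file does not contain a connectome")
    return(connectome(sc$weights, sc$distances, sc$labels, sc$normalized))
  }
  if (format == "npz") {
    arrays <- read_npz(path)
    if (is.null(arrays$weights)) stop("NPZ archive lacks a 'weights' entry")
    return(connectome(arrays$weights, distances = arrays$distances))
  }
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(m) <- NULL
  if (!is.numeric(m)) stop("connectome file is not numeric: ", path)
  connectome(m)
}

#' Write a connectome to disk
#'
#' @param sc a `connectome`.
#' @param path output path; format from extension (`.npz`, `.rds`, else
#'   whitespace-delimited text holding the weights).
#' @return `path`, invisibly.
#' @export
write_connectome <- function(sc, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "npz") {
    if (is.null(sc$distances)) write_npz(path, weights = sc$weights)
    else write_npz(path, weights = sc$weights, distances = sc$distances)
  } else if (ext == "rds") {
    saveRDS(sc, path)
  } else {
    # full precision so the round-trip is bit-exact
    lines <- apply(sc$weights, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " "))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Normalize connectome weights by their global maximum
#'
#' Dividing by the global maximum preserves the relative weight structure and
#' keeps the coupling-strength priors of the network models on their stated
#' scales. Idempotent.
#'
#' @param sc a `connectome`.
#' @return the connectome with `max(weights) == 1` and `normalized = TRUE`.
#' @export
normalize_connectome <- function(sc) {
  stopifnot(inherits(sc, "connectome"))
  m <- max(sc$weights)
  if (m <= 0) stop("cannot normalize an all-zero connectome")
  connectome(sc$weights / m, sc$distances, sc$labels, normalized = TRUE)
}

#' Inter-regional conduction delay matrix
#'
#' Delays are distances divided by an average conduction velocity,
#' `T_jk = d_jk / v`, with distances in millimetres converted to metres.
#'
#' @param sc a `connectome` carrying distances (mm).
#' @param velocity average conduction velocity in m/s; must be positive.
#' @return matrix of delays in seconds with zero diagonal.
#' @export
delay_matrix <- function(sc, velocity) {
  stopifnot(inherits(sc, "connectome"))
  if (is.null(sc$distances))
    stop("connectome has no distances; delays need an inter-regional distance matrix")
  if (!is.numeric(velocity) || length(velocity) != 1 || velocity <= 0)
    stop("velocity must be a single positive number (m/s)")
  (sc$distances / 1000) / velocity
}

#' Generate a synthetic structural connectome
#'
#' Produces a symmetric non-negative weight matrix with log-normal magnitudes
#' (heavy-tailed, like empirical streamline counts), zero diagonal, and a
#' requested edge density, together with Euclidean distances between region
#' centroids placed uniformly in a cube. A stand-in for a tractography-derived
#' connectome in fully synthetic studies.
#'
#' @param n number of regions (>= 2).
#' @param density fraction of off-diagonal pairs connected, in (0, 1].
#' @param seed integer seed; the same `(n, density, seed)` always yields the
#'   same connectome.
#' @param meanlog,sdlog log-normal parameters of the weight magnitudes.
#' @param cube_mm side length (mm) of the cube containing region centroids.
#' @return a `connectome` with weights and distances.
#' @export
generate_synthetic_connectome <- function(n, density = 0.3, seed = 1,
                                          meanlog = 0, sdlog = 1,
                                          cube_mm = 150) {
  if (n < 2) stop("a connectome needs at least 2 regions")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  with_seed(seed, {
    centroids <- matrix(stats::runif(n * 3, 0, cube_mm), n, 3)
    distances <- as.matrix(stats::dist(centroids))
    dimnames(distances) <- NULL
    n_pairs <- n * (n - 1) / 2
    n_edges <- max(1L, round(density * n_pairs))
    picked <- sample.int(n_pairs, n_edges)
    w_upper <- numeric(n_pairs)
    w_upper[picked] <- stats::rlnorm(n_edges, meanlog, sdlog)
    weights <- matrix(0, n, n)
    weights[upper.tri(weights)] <- w_upper
    weights <- weights + t(weights)
  })
  connectome(weights, distances = distances)
}

# Evaluate `expr` under a locally-set RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible 31-bit sub-seed from a master seed and an index.
derive_seed <- function(seed, index) {
  x <- (as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 12345) %% 2147483647
  x <- (x * 69621) %% 2147483647
  as.integer(x)
}
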