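#' Protein universe
#'
#' The ordered set of proteins shared by every layer of a multiplex biological
#' network. Positions in the returned object define the node indexing used by
#' all matrix and tensor code in the package.
#'
#' @param ids Character vector of protein identifiers. Whitespace is trimmed;
#'   duplicates are an error. Identifiers are case-sensitive.
#' @return An object of class \code{protein_universe}: a character vector of
#'   unique ids with an \code{n} attribute.
#' @export
protein_universe <- function(ids) {
  ids <- trimws(as.character(ids))
  if (length(ids) < 1L) stop("universe must contain at least one protein")
  if (anyDuplicated(ids)) stop("duplicate protein identifiers in universe")
  if (any(ids == "")) stop("empty protein identifier")
  structure(ids, n = length(ids), class = "protein_universe")
}

#' @export
print.protein_universe <- function(x, ...) {
  cat("protein_universe with", attr(x, "n"), "proteins\n")
  invisible(x)
}

#' Map protein ids to universe indices
#'
#' @param universe A \code{protein_universe}.
#' @param ids Character vector of ids.
#' @return Integer positions (NA for ids outside the universe).
#' @export
universe_index <- function(universe, ids) {
  match(trimws(as.character(ids)), as.character(universe))
}

n_proteins <- function(universe) attr(universe, "n")

#' Protein interaction network
#'
#' An undirected, unweighted protein-protein interaction (PPI) graph.
#' Self-interactions and repeated interactions are removed at construction,
#' mirroring the standard hygiene applied to curated PPI datasets; the numbers
#' dropped are kept as attributes for logging.
#'
#' @param edges Two-column character matrix or data.frame of interacting
#'   protein pairs (undirected).
#' @param universe Optional \code{protein_universe}. Defaults to the sorted
#'   unique set of endpoint ids. Must contain every endpoint if supplied.
#' @return An object of class \code{pin_graph} with fields \code{universe} and
#'   \code{edges} (two-column integer matrix of universe indices, i < j,
#'   lexicographically ordered).
#' @export
pin_graph <- function(edges, universe = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have exactly two columns")
  storage.mode(edges) <- "character"
  a <- trimws(edges[, 1L]); b <- trimws(edges[, 2L])
  keep <- a != b
  n_self <- sum(!keep)
  a <- a[keep]; b <- b[keep]
  if (is.null(universe)) {
    universe <- protein_universe(sort(unique(c(a, b))))
  } else {
    stopifnot(inherits(universe, "protein_universe"))
    if (anyNA(universe_index(universe, c(a, b))))
      stop("PIN edge endpoint not present in the supplied universe")
  }
  i <- universe_index(universe, a)
  j <- universe_index(universe, b)
  lo <- pmin(i, j); hi <- pmax(i, j)
  dup <- duplicated(cbind(lo, hi))
  n_dup <- sum(dup)
  lo <- lo[!dup]; hi <- hi[!dup]
  ord <- order(lo, hi)
  structure(
    list(universe = universe,
         edges = cbind(i = lo[ord], j = hi[ord])),
    dropped_self = n_self, dropped_dup = n_dup,
    class = "pin_graph")
}

#' @export
print.pin_graph <- function(x, ...) {
  cat("pin_graph:", n_proteins(x$universe), "proteins,",
      nrow(x$edges), "interactions\n")
  invisible(x)
}

#' Sparse adjacency matrix of a PIN
#'
#' @param pin A \code{pin_graph}.
#' @return Symmetric 0/1 \code{dgCMatrix} (no diagonal).
#' @keywords internal
pin_adjacency <- function(pin) {
  n <- n_proteins(pin$universe)
  e <- pin$edges
  Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                       x = 1, dims = c(n, n))
}

#' Protein-domain membership map
#'
#' Stores which protein contains which structural domain, together with the
#' per-domain protein counts NP_j used by the inverse-frequency domain score:
#' rare domains carry more weight.
#'
#' @param memberships Two-column data.frame or matrix (protein, domain_id).
#'   Duplicate memberships are collapsed.
#' @return Object of class \code{domain_map} with fields \code{protein},
#'   \code{domain} (parallel character vectors) and \code{domain_counts}
#'   (named integer vector, NP_j per domain).
#' @export
domain_map <- function(memberships) {
  m <- as.matrix(memberships)
  if (ncol(m) != 2L) stop("memberships must have two columns: protein, domain")
  storage.mode(m) <- "character"
  p <- trimws(m[, 1L]); d <- trimws(m[, 2L])
  dup <- duplicated(cbind(p, d))
  p <- p[!dup]; d <- d[!dup]
  counts <- table(d)
  structure(list(protein = p, domain = d,
                 domain_counts = stats::setNames(as.integer(counts), names(counts))),
            class = "domain_map")
}

#' Gene expression profile
#'
#' Time-course expression values, one row per gene. All rows share the same
#' number of time points; proteins absent from the profile are simply missing
#' (lookup returns NULL) and contribute no co-expression edges.
#'
#' @param values Numeric matrix, rownames = gene/protein ids, one column per
#'   time point (at least 2).
#' @return Object of class \code{expression_profile}.
#' @export
expression_profile <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression matrix must have gene ids as rownames")
  if (ncol(values) < 2L) stop("expression profile needs at least 2 time points")
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids in expression profile")
  rownames(values) <- trimws(rownames(values))
  structure(list(values = values, n_timepoints = ncol(values)),
            class = "expression_profile")
}

#' Ortholog count table
#'
#' N(p_i): the number of reference organisms in which a homolog of protein p_i
#' exists. Proteins missing from the table count 0.
#'
#' @param counts Named nonnegative integer vector, or two-column data.frame
#'   (protein, count).
#' @return Object of class \code{ortholog_table} (named integer vector).
#' @export
ortholog_table <- function(counts) {
  if (is.data.frame(counts) || is.matrix(counts)) {
    m <- as.matrix(counts)
    cnt <- suppressWarnings(as.numeric(m[, 2L]))
    if (anyNA(cnt)) stop("non-numeric ortholog count")
    counts <- stats::setNames(cnt, trimws(as.character(m[, 1L])))
  }
  if (is.null(names(counts))) stop("ortholog counts must be named by protein")
  if (any(counts < 0)) stop("negative ortholog count")
  if (anyDuplicated(names(counts))) stop("duplicate protein in ortholog table")
  structure(stats::setNames(as.integer(round(counts)), trimws(names(counts))),
            class = "ortholog_table")
}

#' Look up ortholog counts for a universe (missing proteins count 0)
#' @keywords internal
ortholog_counts_for <- function(universe, orth) {
  idx <- match(as.character(universe), names(orth))
  out <- ifelse(is.na(idx), 0L, unclass(orth)[idx])
  stats::setNames(as.integer(out), as.character(universe))
}

#' Weighted network layer
#'
#' One undirected weighted graph over the shared protein universe. Weights lie
#' in (0, 1]; zero-weight edges are never stored, so absence and weight zero
#' are interchangeable downstream.
#'
#' @param universe A \code{protein_universe}.
#' @param i,j Integer universe indices of edge endpoints (any orientation;
#'   stored with i < j).
#' @param w Numeric weights in (0, 1]. Entries with w == 0 are dropped.
#' @param name Layer name.
#' @return Object of class \code{weighted_layer} with fields \code{universe},
#'   \code{edges} (data.frame i, j, w) and \code{name}.
#' @export
weighted_layer <- function(universe, i = integer(), j = integer(),
                           w = numeric(), name = "layer") {
  stopifnot(inherits(universe, "protein_universe"))
  i <- as.integer(i); j <- as.integer(j); w <- as.numeric(w)
  stopifnot(length(i) == length(j), length(j) == length(w))
  keep <- w != 0
  i <- i[keep]; j <- j[keep]; w <- w[keep]
  if (any(i == j)) stop("self-pairs are not allowed in a layer")
  n <- n_proteins(universe)
  if (length(i) && (min(i, j) < 1L || max(i, j) > n))
    stop("edge endpoint outside the universe")
  if (any(w < 0 | w > 1)) stop("layer weights must lie in (0, 1]")
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (anyDuplicated(cbind(lo, hi))) stop("duplicate edge in layer")
  ord <- order(lo, hi)
  structure(list(universe = universe,
                 edges = data.frame(i = lo[ord], j = hi[ord], w = w[ord]),
                 name = name),
            class = "weighted_layer")
}

#' @export
print.weighted_layer <- function(x, ...) {
  cat("weighted_layer '", x$name, "': ", nrow(x$edges), " edges over ",
      n_proteins(x$universe), " proteins\n", sep = "")
  invisible(x)
}

#' Symmetric sparse weight matrix of a layer
#' @keywords internal
layer_matrix <- function(layer) {
  n <- n_proteins(layer$universe)
  e <- layer$edges
  Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i), x = c(e$w, e$w),
                       dims = c(n, n))
}

#' Assemble layers into a multiplex network
#'
#' Orders the given layers into a multiplex network G = (G^1, ..., G^L) over
#' one shared protein universe. For the full essentiality pipeline the order is
#' co-neighbor, co-structure, co-expression.
#'
#' @param layers List of \code{weighted_layer} objects sharing one universe.
#' @return Object of class \code{multiplex_network} with fields
#'   \code{universe} and \code{layers}.
#' @export
assemble_multiplex <- function(layers) {
  if (!length(layers)) stop("need at least one layer")
  if (!all(vapply(layers, inherits, logical(1), "weighted_layer")))
    stop("all elements must be weighted_layer objects")
  u <- layers[[1L]]$universe
  same <- vapply(layers, function(l) identical(as.character(l$universe),
                                              as.character(u)), logical(1))
  if (!all(same)) stop("layers do not share the same protein universe")
  structure(list(universe = u, layers = layers), class = "multiplex_network")
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat("multiplex_network: L =", length(x$layers), "layers over",
      n_proteins(x$universe), "proteins\n")
  for (l in x$layers)
    cat("  ", l$name, ": ", nrow(l$edges), " edges\n", sep = "")
  invisible(x)
}
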