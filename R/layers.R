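#' Build the co-neighbor layer
#'
#' Weights each PIN edge (p_i, p_j) by the squared count of common neighbors
#' normalized by degrees:
#' \deqn{e^1(i,j) = |N_i \cap N_j|^2 / ((|N_i| - 1)(|N_j| - 1))}
#' where N_i is the direct-neighbor set of p_i in the PIN. Interacting pairs
#' with no common neighbor get weight 0 and are absent from the layer. Because
#' a common neighbor of two interacting proteins is counted in both degrees but
#' is neither endpoint, \eqn{|N_i \cap N_j| \le \min(|N_i|, |N_j|) - 1}, so all
#' stored weights lie in (0, 1].
#'
#' @param pin A \code{pin_graph}.
#' @return A \code{weighted_layer} named "co_neighbor".
#' @export
build_co_neighbor <- function(pin) {
  stopifnot(inherits(pin, "pin_graph"))
  u <- pin$universe
  e <- pin$edges
  if (!nrow(e)) return(weighted_layer(u, name = "co_neighbor"))
  A <- pin_adjacency(pin)
  deg <- Matrix::colSums(A)
  # (A %*% A)[i, j] counts paths of length 2, i.e. common neighbors of i and j
  CN <- A %*% A
  cn <- CN[cbind(e[, "i"], e[, "j"])]
  keep <- cn > 0
  i <- e[keep, "i"]; j <- e[keep, "j"]; cn <- cn[keep]
  w <- cn^2 / ((deg[i] - 1) * (deg[j] - 1))
  weighted_layer(u, i, j, w, name = "co_neighbor")
}

#' Raw domain score of one protein
#'
#' Sum of inverse domain frequencies over the protein's domains:
#' \deqn{P_D(p_i) = \sum_j t_{ij} / NP_j}
#' where NP_j is the number of proteins containing domain d_j and t_{ij}
#' indicates membership. Proteins with rare domains score high; a protein with
#' no annotated domain scores 0.
#'
#' @param protein Protein id.
#' @param domains A \code{domain_map}.
#' @return Nonnegative numeric score.
#' @export
domain_score_raw <- function(protein, domains) {
  stopifnot(inherits(domains, "domain_map"))
  protein <- trimws(protein)
  d <- domains$domain[domains$protein == protein]
  if (!length(d)) return(0)
  sum(1 / domains$domain_counts[d])
}

#' Min-max normalized domain scores over a universe
#'
#' Raw inverse-frequency domain scores are min-max normalized over all
#' proteins in the universe; proteins without annotations enter with a raw
#' score of 0. In the degenerate case max = min (including a single-protein
#' universe) every normalized score is 0: a constant score carries no ranking
#' information and 0 avoids the 0/0.
#'
#' @param universe A \code{protein_universe}.
#' @param domains A \code{domain_map}.
#' @return Named numeric vector in [0, 1], one entry per universe protein.
#' @export
domain_scores_normalized <- function(universe, domains) {
  stopifnot(inherits(universe, "protein_universe"),
            inherits(domains, "domain_map"))
  ids <- as.character(universe)
  raw <- stats::setNames(numeric(length(ids)), ids)
  inside <- domains$protein %in% ids
  if (any(inside)) {
    per <- tapply(1 / domains$domain_counts[domains$domain[inside]],
                  domains$protein[inside], sum)
    raw[names(per)] <- as.numeric(per)
  }
  rng <- range(raw)
  if (rng[1L] == rng[2L]) return(raw * 0)
  (raw - rng[1L]) / (rng[2L] - rng[1L])
}

#' Build the co-structure layer
#'
#' Weights each PIN edge by the product of the endpoints' normalized domain
#' scores, \eqn{e^2(i,j) = P_D(p_i) \times P_D(p_j)}. The edge set is
#' restricted to PIN edges, consistent with the other two layers; products of
#' 0 are not stored.
#'
#' @param pin A \code{pin_graph}.
#' @param domains A \code{domain_map}.
#' @return A \code{weighted_layer} named "co_structure".
#' @export
build_co_structure <- function(pin, domains) {
  stopifnot(inherits(pin, "pin_graph"))
  pd <- domain_scores_normalized(pin$universe, domains)
  e <- pin$edges
  w <- pd[e[, "i"]] * pd[e[, "j"]]
  weighted_layer(pin$universe, e[, "i"], e[, "j"], w, name = "co_structure")
}

#' Pearson correlation with degenerate-variance guard
#'
#' Standard sample Pearson correlation of two equal-length vectors. Returns
#' \code{NA} ("undefined") when either vector has zero variance.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in [-1, 1], or NA when undefined.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Build the co-expression layer
#'
#' Two proteins are co-expressed if they interact in the PIN and the Pearson
#' correlation of their expression time courses is defined and nonzero; the
#' edge weight is |PCC|. PIN edges with an endpoint missing from the profile,
#' a zero-variance profile, or PCC exactly 0 are absent.
#'
#' @param pin A \code{pin_graph}.
#' @param expr An \code{expression_profile}.
#' @return A \code{weighted_layer} named "co_expression".
#' @export
build_co_expression <- function(pin, expr) {
  stopifnot(inherits(pin, "pin_graph"), inherits(expr, "expression_profile"))
  ids <- as.character(pin$universe)
  e <- pin$edges
  ri <- match(ids[e[, "i"]], rownames(expr$values))
  rj <- match(ids[e[, "j"]], rownames(expr$values))
  keep <- !is.na(ri) & !is.na(rj)
  w <- numeric(sum(keep))
  ii <- e[keep, "i"]; jj <- e[keep, "j"]
  ri <- ri[keep]; rj <- rj[keep]
  for (k in seq_along(w)) {
    r <- pearson_correlation(expr$values[ri[k], ], expr$values[rj[k], ])
    w[k] <- if (is.na(r)) 0 else abs(r)
  }
  weighted_layer(pin$universe, ii, jj, w, name = "co_expression")
}

#' Build the standard three-layer multiplex network
#'
#' Convenience wrapper assembling the co-neighbor, co-structure and
#' co-expression layers (in that fixed order) from the three raw inputs.
#'
#' @param pin A \code{pin_graph}.
#' @param domains A \code{domain_map}.
#' @param expr An \code{expression_profile}.
#' @return A \code{multiplex_network} with L = 3.
#' @export
build_multiplex <- function(pin, domains, expr) {
  assemble_multiplex(list(build_co_neighbor(pin),
                          build_co_structure(pin, domains),
                          build_co_expression(pin, expr)))
}

#' Coverage rate of one dataset in another, in percent
#'
#' @param n_covered Number of covered items (0 <= n_covered <= n_total).
#' @param n_total Total number of items (> 0).
#' @return Percentage, rounded to two decimals.
#' @export
coverage_rate <- function(n_covered, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_covered < 0 || n_covered > n_total) stop("need 0 <= n_covered <= n_total")
  round(100 * n_covered / n_total, 2)
}
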