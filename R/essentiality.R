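#' Conservative (orthology) scores
#'
#' Max-normalized ortholog counts over a protein universe:
#' \deqn{C_S(p_i) = N(p_i) / \max_j N(p_j)}
#' where N(p_i) is the number of reference organisms containing a homolog of
#' p_i. Proteins missing from the table count 0; if every count is 0 all
#' scores are 0.
#'
#' @param universe A \code{protein_universe}.
#' @param orth An \code{ortholog_table}.
#' @return Named numeric vector in [0, 1] over the universe.
#' @export
conservative_scores <- function(universe, orth) {
  stopifnot(inherits(universe, "protein_universe"),
            inherits(orth, "ortholog_table"))
  cnt <- ortholog_counts_for(universe, orth)
  mx <- max(cnt)
  if (mx == 0) return(cnt * 0)
  cnt / mx
}

#' Restart vector from conservative and modular scores
#'
#' Convex combination \eqn{dr(p_i) = \beta C_S(p_i) + (1-\beta) M_S(p_i)},
#' then normalized to sum 1 so that the walk's mass-conservation property
#' holds (pure rescaling leaves the ranking unchanged). An all-zero
#' combination falls back to the uniform distribution.
#'
#' @param cs Named conservative scores in [0, 1] over the universe.
#' @param ms Named modular scores in [0, 1] over the same proteins (same
#'   order). Modular scores arrive pre-normalized from an external module
#'   detector; when unavailable use a neutral constant (see
#'   \code{\link{mon_rank}}).
#' @param beta Mixing weight in (0, 1).
#' @return Object of class \code{restart_vector}: named probability vector
#'   with attributes \code{beta}, \code{cs}, \code{ms}.
#' @export
build_restart_vector <- function(cs, ms, beta) {
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0, 1)")
  if (length(cs) != length(ms)) stop("cs and ms must have equal length")
  if (any(ms < 0 | ms > 1)) stop("modular scores must lie in [0, 1]")
  if (any(cs < 0 | cs > 1)) stop("conservative scores must lie in [0, 1]")
  dr <- beta * cs + (1 - beta) * ms
  tot <- sum(dr)
  rv <- if (tot == 0) rep(1 / length(dr), length(dr)) else dr / tot
  structure(stats::setNames(as.numeric(rv), names(cs)),
            beta = beta, cs = cs, ms = ms, class = "restart_vector")
}

#' Rank proteins for essentiality on a multiplex biological network
#'
#' The full pipeline: builds the three-layer multiplex network (co-neighbor,
#' co-structure, co-expression), the restart vector from orthology and modular
#' scores, runs the coupled random walk with restart, and returns the proteins
#' sorted by converged score (descending, ties broken by protein id
#' ascending), truncated to the top K.
#'
#' @param pin A \code{pin_graph}.
#' @param domains A \code{domain_map}.
#' @param expr An \code{expression_profile}.
#' @param orth An \code{ortholog_table}.
#' @param ms Optional named modular scores in [0, 1]. Missing proteins (or
#'   \code{ms = NULL}) default to the neutral value 0.5.
#' @param alpha Walk probability, default 0.3.
#' @param beta Conservative/modular mixing weight, default 0.5.
#' @param K Number of top proteins to return; default the full universe.
#' @param threshold,max_iter Convergence controls passed to
#'   \code{\link{run_rwr}}.
#' @return Object of class \code{ranked_list}: a data.frame with columns
#'   \code{rank}, \code{protein}, \code{score}, plus attributes \code{walk}
#'   (the full \code{walk_result}) and \code{universe}.
#' @export
mon_rank <- function(pin, domains, expr, orth, ms = NULL,
                     alpha = 0.3, beta = 0.5, K = NULL,
                     threshold = 1e-9, max_iter = 1000L) {
  stopifnot(inherits(pin, "pin_graph"))
  u <- pin$universe
  n <- n_proteins(u)
  if (is.null(K)) K <- n
  if (K < 1 || K > n) stop("K must lie in 1..n")
  net <- build_multiplex(pin, domains, expr)
  cs <- conservative_scores(u, orth)
  ms_full <- stats::setNames(rep(0.5, n), as.character(u))
  if (!is.null(ms)) {
    idx <- match(as.character(u), names(ms))
    ms_full[!is.na(idx)] <- as.numeric(ms)[idx[!is.na(idx)]]
  }
  rv <- build_restart_vector(cs, ms_full, beta)
  wr <- run_rwr(net, as.numeric(rv), alpha = alpha,
                threshold = threshold, max_iter = max_iter)
  rl <- ranked_list(wr$x, u, walk = wr)
  if (K < n) {
    top <- as.data.frame(rl)[seq_len(K), , drop = FALSE]
    rl <- structure(top, walk = wr, universe = u,
                    class = c("ranked_list", "data.frame"))
  }
  rl
}

#' Ranked protein list with deterministic tie-breaking
#'
#' @param scores Named numeric scores over the universe.
#' @param universe A \code{protein_universe}.
#' @param walk Optional \code{walk_result} to attach.
#' @return A \code{ranked_list} data.frame (rank, protein, score), sorted by
#'   score descending then protein id ascending.
#' @export
ranked_list <- function(scores, universe, walk = NULL) {
  ids <- as.character(universe)
  if (length(scores) != length(ids)) stop("one score per universe protein required")
  if (!is.null(names(scores))) scores <- scores[ids]
  ord <- order(-scores, ids)
  out <- data.frame(rank = seq_along(ids), protein = ids[ord],
                    score = as.numeric(scores)[ord],
                    stringsAsFactors = FALSE)
  structure(out, walk = walk, universe = universe,
            class = c("ranked_list", "data.frame"))
}

#' Degree-centrality ranking (baseline)
#'
#' Ranks proteins by PIN degree, the classical topology-only baseline, with
#' the same deterministic tie-breaking as \code{\link{mon_rank}}.
#'
#' @param pin A \code{pin_graph}.
#' @return A \code{ranked_list}.
#' @export
degree_rank <- function(pin) {
  A <- pin_adjacency(pin)
  ranked_list(stats::setNames(Matrix::colSums(A), as.character(pin$universe)),
              pin$universe)
}
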