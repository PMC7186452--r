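#' Benchmark essential-protein set
#'
#' Restricts a list of known essential proteins to a universe. Ids outside the
#' universe are dropped with a warning: evaluation happens within each
#' network's protein set, and dropped ids are excluded from recall
#' denominators.
#'
#' @param essential Character vector of essential protein ids.
#' @param universe A \code{protein_universe}.
#' @return Object of class \code{benchmark}: list with \code{essential}
#'   (character, inside the universe) and \code{universe}.
#' @export
benchmark_set <- function(essential, universe) {
  stopifnot(inherits(universe, "protein_universe"))
  essential <- unique(trimws(as.character(essential)))
  inside <- essential %in% as.character(universe)
  if (any(!inside))
    warning(sum(!inside), " benchmark protein(s) outside the universe dropped")
  structure(list(essential = essential[inside], universe = universe),
            class = "benchmark")
}

rl_proteins <- function(rl) {
  stopifnot(inherits(rl, "ranked_list"))
  rl$protein
}

#' Top-K precision of a ranking
#'
#' Fraction of true essential proteins among the top K ranked proteins.
#'
#' @param rl A \code{ranked_list}.
#' @param bench A \code{benchmark}.
#' @param K Cutoff, 1 <= K <= length of the ranking.
#' @return Fraction in [0, 1].
#' @export
topk_precision <- function(rl, bench, K) {
  p <- rl_proteins(rl)
  if (K < 1 || K > length(p)) stop("K must lie in 1..n")
  sum(p[seq_len(K)] %in% bench$essential) / K
}

#' Precision-recall curve over all cutoffs
#'
#' For each cutoff K = 1..n the top-K proteins form the positive set;
#' precision = TP/K and recall = TP/|essential|.
#'
#' @param rl A \code{ranked_list} (full ranking).
#' @param bench A non-empty \code{benchmark}.
#' @return data.frame with columns K, precision, recall, in K order.
#' @export
pr_curve <- function(rl, bench) {
  if (!length(bench$essential)) stop("benchmark set is empty")
  hits <- cumsum(rl_proteins(rl) %in% bench$essential)
  K <- seq_along(hits)
  data.frame(K = K, precision = hits / K, recall = hits / length(bench$essential))
}

#' Jackknife curve of a ranking
#'
#' Cumulative count of true essential proteins encountered while moving down
#' the ranking, plus its area (trapezoidal rule over the rank axis) for
#' method comparison. Also reports the fraction-of-benchmark normalization.
#'
#' @param rl A \code{ranked_list} (full ranking).
#' @param bench A \code{benchmark}.
#' @return List with \code{curve} (integer cumulative counts per rank),
#'   \code{fraction} (curve / |essential|, NaN-free only for non-empty
#'   benchmarks), and \code{area}.
#' @export
jackknife_curve <- function(rl, bench) {
  hits <- cumsum(rl_proteins(rl) %in% bench$essential)
  n <- length(hits)
  area <- if (n >= 2) sum((hits[-1] + hits[-n]) / 2) else 0
  list(curve = as.integer(hits),
       fraction = if (length(bench$essential)) hits / length(bench$essential)
                  else hits * NA_real_,
       area = area)
}

#' Uniformly random ranking (baseline)
#'
#' Deterministic per seed; used as the random-assortment baseline against
#' which jackknife curves are compared. The global RNG state is left
#' untouched.
#'
#' @param universe A \code{protein_universe}.
#' @param seed Integer seed.
#' @return A \code{ranked_list} whose scores are the (negated) random ranks.
#' @export
random_assortment <- function(universe, seed) {
  ids <- as.character(universe)
  perm <- with_local_seed(seed, sample.int(length(ids)))
  # score = n - position so the permutation order is reproduced exactly
  scores <- stats::setNames(numeric(length(ids)), ids)
  scores[perm] <- rev(seq_along(ids))
  ranked_list(scores, universe)
}

#' Run code under a temporary RNG seed
#' @keywords internal
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Overlap statistics between two rankings
#'
#' Compares the top-K sets of two rankings over the same universe: the
#' intersection size, the set differences, and the essential fraction within
#' each difference.
#'
#' @param rl_a,rl_b Two \code{ranked_list}s over the same universe.
#' @param bench A \code{benchmark}.
#' @param K Cutoff.
#' @return List with \code{overlap} (|A intersect B| in the top K),
#'   \code{only_a}, \code{only_b} (character vectors), and
#'   \code{essential_frac_only_a} / \code{essential_frac_only_b}
#'   (NaN when the difference is empty).
#' @export
overlap_stats <- function(rl_a, rl_b, bench, K) {
  ua <- as.character(attr(rl_a, "universe"))
  ub <- as.character(attr(rl_b, "universe"))
  if (!identical(ua, ub)) stop("rankings are over different universes")
  a <- rl_proteins(rl_a)[seq_len(K)]
  b <- rl_proteins(rl_b)[seq_len(K)]
  only_a <- setdiff(a, b); only_b <- setdiff(b, a)
  list(overlap = length(intersect(a, b)),
       only_a = only_a, only_b = only_b,
       essential_frac_only_a = mean(only_a %in% bench$essential),
       essential_frac_only_b = mean(only_b %in% bench$essential))
}
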