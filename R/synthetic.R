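#' Configuration for the synthetic-data generator
#'
#' Describes a synthetic yeast-like world in which essentiality is correlated
#' with the four signals the ranking pipeline exploits: network degree, rare
#' domains, co-expression clustering, and ortholog conservation. Defaults give
#' a desk-scale fixture (n = 200, 6 modules) that runs the full pipeline in
#' seconds.
#'
#' @param n_proteins Number of proteins (default 200).
#' @param n_essential Number of essential proteins (default 40, roughly the
#'   essential fraction seen in curated yeast PPI networks).
#' @param n_modules Number of protein modules (default 6). Essentials are
#'   concentrated in the lowest-index modules ("essential modules").
#' @param n_domains Number of distinct domains (default 60).
#' @param n_timepoints Expression time points (default 36, the length of the
#'   standard yeast metabolic-cycle time course).
#' @param density_within Within-module edge probability (default 0.30).
#' @param density_background Background (Erdos-Renyi) edge probability
#'   (default 0.01).
#' @param degree_boost Expected number of extra random partners attached to
#'   each essential protein (default 4).
#' @param domain_rarity_bias Probability that a domain drawn for an essential
#'   protein comes from the rare half of the domain pool (default 0.8;
#'   non-essentials draw rare domains with the complementary probability).
#' @param rho Expected within-module expression correlation in [0, 1)
#'   (default 0.6).
#' @param ortholog_rate Mean ortholog count of non-essential proteins
#'   (default 5; Poisson).
#' @param ortholog_ratio Essential/non-essential rate ratio (default 4).
#' @param expression_coverage Fraction of proteins present in the expression
#'   profile (default 0.98, matching the near-complete coverage of real
#'   time-course compendia).
#' @param seed Integer seed; the entire bundle is reproducible from it.
#' @return Object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_proteins = 200L, n_essential = 40L,
                             n_modules = 6L, n_domains = 60L,
                             n_timepoints = 36L,
                             density_within = 0.30,
                             density_background = 0.01,
                             degree_boost = 4,
                             domain_rarity_bias = 0.8,
                             rho = 0.6,
                             ortholog_rate = 5,
                             ortholog_ratio = 4,
                             expression_coverage = 0.98,
                             seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_essential = as.integer(n_essential),
              n_modules = as.integer(n_modules),
              n_domains = as.integer(n_domains),
              n_timepoints = as.integer(n_timepoints),
              density_within = density_within,
              density_background = density_background,
              degree_boost = degree_boost,
              domain_rarity_bias = domain_rarity_bias,
              rho = rho,
              ortholog_rate = ortholog_rate,
              ortholog_ratio = ortholog_ratio,
              expression_coverage = expression_coverage,
              seed = as.integer(seed))
  if (cfg$n_essential > cfg$n_proteins) stop("n_essential must not exceed n_proteins")
  if (cfg$rho < 0 || cfg$rho >= 1) stop("rho must lie in [0, 1)")
  if (cfg$density_within < 0 || cfg$density_within > 1 ||
      cfg$density_background < 0 || cfg$density_background > 1)
    stop("densities must lie in [0, 1]")
  if (cfg$n_modules < 1L || cfg$n_proteins < 1L || cfg$n_domains < 1L ||
      cfg$n_timepoints < 2L)
    stop("counts must be positive (and n_timepoints >= 2)")
  if (cfg$density_within > 0 && cfg$n_proteins < 2L * cfg$n_modules)
    stop("modules of size < 2 cannot carry within-module edges")
  structure(cfg, class = "synthetic_config")
}

#' Generate a coherent synthetic input bundle
#'
#' Produces all six pipeline inputs from one seed:
#' \enumerate{
#'   \item proteins partitioned into modules; essentials fill the lowest-index
#'     modules;
#'   \item a PIN with dense within-module edges, sparse background edges, and
#'     extra random partners for essentials (degree boost);
#'   \item domain annotations in which essentials preferentially draw rare
#'     (low-NP) domains;
#'   \item a latent-factor expression profile: module members share a common
#'     standard-normal time course mixed with independent noise so that the
#'     expected within-module correlation is exactly rho
#'     (g = sqrt(rho) f_module + sqrt(1-rho) noise);
#'   \item Poisson ortholog counts with a higher rate for essentials;
#'   \item modular scores in [0, 1] correlated with membership in essential
#'     modules, plus noise.
#' }
#'
#' @param cfg A \code{synthetic_config}.
#' @return List (class \code{synthetic_bundle}) with elements \code{pin},
#'   \code{domains}, \code{expr}, \code{orth}, \code{ms} (named numeric),
#'   \code{essential} (character vector), \code{module} (named integer
#'   module assignment), and \code{config}.
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_local_seed(cfg$seed, generate_synthetic_impl(cfg))
}

generate_synthetic_impl <- function(cfg) {
  n <- cfg$n_proteins
  ids <- sprintf("P%04d", seq_len(n))
  module <- stats::setNames(sort(rep(seq_len(cfg$n_modules), length.out = n)), ids)
  # essentials fill the lowest-index modules in order
  essential <- ids[seq_len(cfg$n_essential)]

  # --- PIN: within-module + background + essential degree boost -------------
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (m in seq_len(cfg$n_modules)) {
    members <- which(module == m)
    if (length(members) >= 2L) {
      cmb <- utils::combn(members, 2L)
      keep <- stats::runif(ncol(cmb)) < cfg$density_within
      pairs_i <- c(pairs_i, cmb[1L, keep]); pairs_j <- c(pairs_j, cmb[2L, keep])
    }
  }
  # background edges: sample from all pairs via geometric skipping would be
  # overkill at this scale; a Bernoulli sweep over all pairs is fine for n<=1000
  allp <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(allp)) < cfg$density_background
  pairs_i <- c(pairs_i, allp[1L, keep]); pairs_j <- c(pairs_j, allp[2L, keep])
  ess_idx <- seq_len(cfg$n_essential)
  if (cfg$degree_boost > 0 && n > 1L) {
    for (e in ess_idx) {
      k <- stats::rpois(1L, cfg$degree_boost)
      if (k > 0) {
        partners <- sample(setdiff(seq_len(n), e), min(k, n - 1L))
        pairs_i <- c(pairs_i, rep(e, length(partners)))
        pairs_j <- c(pairs_j, partners)
      }
    }
  }
  universe <- protein_universe(ids)
  pin <- pin_graph(cbind(ids[pairs_i], ids[pairs_j]), universe = universe)

  # --- domains: essentials biased toward the rare half ----------------------
  # first half of the domain pool is "rare" (drawn less often overall)
  rare <- seq_len(max(1L, cfg$n_domains %/% 2L))
  common <- setdiff(seq_len(cfg$n_domains), rare)
  if (!length(common)) common <- rare
  dprot <- character(0); ddom <- character(0)
  for (v in seq_len(n)) {
    ndom <- 1L + stats::rpois(1L, 1)
    p_rare <- if (v %in% ess_idx) cfg$domain_rarity_bias else 1 - cfg$domain_rarity_bias
    from_rare <- stats::runif(ndom) < p_rare
    doms <- integer(ndom)
    if (any(from_rare)) doms[from_rare] <- sample(rare, sum(from_rare), replace = TRUE)
    if (any(!from_rare)) doms[!from_rare] <- sample(common, sum(!from_rare), replace = TRUE)
    doms <- unique(doms)
    dprot <- c(dprot, rep(ids[v], length(doms)))
    ddom <- c(ddom, sprintf("D%03d", doms))
  }
  domains <- domain_map(cbind(dprot, ddom))

  # --- expression: latent module factor + noise -----------------------------
  tp <- cfg$n_timepoints
  fac <- matrix(stats::rnorm(cfg$n_modules * tp), cfg$n_modules, tp)
  noise <- matrix(stats::rnorm(n * tp), n, tp)
  vals <- sqrt(cfg$rho) * fac[module, , drop = FALSE] +
    sqrt(1 - cfg$rho) * noise
  rownames(vals) <- ids
  colnames(vals) <- sprintf("t%02d", seq_len(tp))
  covered <- sort(sample(n, max(2L, round(cfg$expression_coverage * n))))
  expr <- expression_profile(vals[covered, , drop = FALSE])

  # --- orthologs: Poisson, higher rate for essentials -----------------------
  rate <- ifelse(seq_len(n) %in% ess_idx,
                 cfg$ortholog_rate * cfg$ortholog_ratio, cfg$ortholog_rate)
  orth <- ortholog_table(stats::setNames(stats::rpois(n, rate), ids))

  # --- modular scores: high inside essential modules, noisy -----------------
  ess_modules <- unique(module[essential])
  base <- ifelse(module %in% ess_modules, 0.75, 0.25)
  ms <- pmin(1, pmax(0, base + stats::rnorm(n, sd = 0.1)))
  names(ms) <- ids

  structure(list(pin = pin, domains = domains, expr = expr, orth = orth,
                 ms = ms, essential = essential, module = module,
                 config = cfg),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle:", n_proteins(x$pin$universe), "proteins,",
      nrow(x$pin$edges), "interactions,", length(x$essential),
      "planted essentials, seed", x$config$seed, "\n")
  invisible(x)
}
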