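#' Load a PPI edge list
#'
#' Reads a two-column TSV of interacting protein pairs, drops
#' self-interactions and repeated interactions (counts reported via
#' \code{message}), and returns the deduplicated undirected graph. The PIN
#' defines the protein universe for the whole pipeline.
#'
#' @param path Path to a two-column TSV (protein_a, protein_b).
#' @param header Does the file carry a header line? Default FALSE.
#' @return A \code{pin_graph}.
#' @export
load_ppi <- function(path, header = FALSE) {
  tab <- read_tsv_checked(path, header = header, what = "PPI")
  if (ncol(tab) != 2L)
    stop("PPI file must have exactly two columns: ", path)
  pin <- pin_graph(tab)
  ds <- attr(pin, "dropped_self"); dd <- attr(pin, "dropped_dup")
  if (ds + dd > 0)
    message("load_ppi: dropped ", ds, " self-interaction(s) and ",
            dd, " repeated interaction(s)")
  pin
}

#' Load protein-domain memberships
#' @param path Two-column TSV (protein, domain_id), one membership per line.
#' @param header Header line present? Default FALSE.
#' @return A \code{domain_map}.
#' @export
load_domains <- function(path, header = FALSE) {
  tab <- read_tsv_checked(path, header = header, what = "domain")
  if (ncol(tab) != 2L) stop("domain file must have exactly two columns: ", path)
  domain_map(tab)
}

#' Load a gene expression profile
#'
#' First column: gene id; remaining columns: numeric expression values, one
#' per time point. Non-numeric cells and ragged rows are errors naming the
#' offending location.
#'
#' @param path TSV path.
#' @param header Header line present? Default TRUE.
#' @return An \code{expression_profile}.
#' @export
load_expression <- function(path, header = TRUE) {
  tab <- read_tsv_checked(path, header = header, what = "expression")
  if (ncol(tab) < 3L) stop("expression file needs id column plus >= 2 time points: ", path)
  ids <- trimws(as.character(tab[[1L]]))
  num <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(num) <- "double")
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric expression value at data row ", bad[1L],
         ", time point column ", bad[2L], " of ", path)
  }
  rownames(num) <- ids
  expression_profile(num)
}

#' Load ortholog counts
#' @param path Two-column TSV (protein, count).
#' @param header Header line present? Default FALSE.
#' @return An \code{ortholog_table}.
#' @export
load_orthologs <- function(path, header = FALSE) {
  tab <- read_tsv_checked(path, header = header, what = "ortholog")
  if (ncol(tab) != 2L) stop("ortholog file must have exactly two columns: ", path)
  cnt <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(cnt)) stop("non-numeric ortholog count at line ",
                       which(is.na(cnt))[1L] + as.integer(attr(tab, "had_header")),
                       " of ", path)
  if (any(cnt < 0)) stop("negative ortholog count at line ",
                         which(cnt < 0)[1L], " of ", path)
  ortholog_table(stats::setNames(cnt, trimws(as.character(tab[[1L]]))))
}

#' Load per-protein scores (e.g. modular scores)
#' @param path Two-column TSV (protein, score).
#' @param header Header line present? Default FALSE.
#' @return Named numeric vector.
#' @export
load_scores <- function(path, header = FALSE) {
  tab <- read_tsv_checked(path, header = header, what = "score")
  if (ncol(tab) != 2L) stop("score file must have exactly two columns: ", path)
  s <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(s)) stop("non-numeric score at line ", which(is.na(s))[1L], " of ", path)
  stats::setNames(s, trimws(as.character(tab[[1L]])))
}

#' Load a benchmark essential-protein list (one id per line)
#' @param path File path.
#' @return Character vector of unique ids.
#' @export
load_essential <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  if (!length(lines)) stop("empty essential-protein list: ", path)
  unique(lines)
}

read_tsv_checked <- function(path, header, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  if (file.size(path) == 0) stop("empty ", what, " file: ", path)
  tab <- tryCatch(
    utils::read.table(path, header = header, sep = "\t",
                      colClasses = "character", quote = "",
                      comment.char = "", stringsAsFactors = FALSE),
    error = function(e) stop("malformed ", what, " file ", path, ": ",
                             conditionMessage(e)))
  if (!nrow(tab)) stop("empty ", what, " file: ", path)
  attr(tab, "had_header") <- header
  tab
}

#' Write a weighted layer as a three-column TSV
#'
#' Weights are printed with 12 significant digits so layers round-trip
#' exactly enough to preserve rankings across platforms.
#'
#' @param layer A \code{weighted_layer}.
#' @param path Output path.
#' @export
write_layer <- function(layer, path) {
  ids <- as.character(layer$universe)
  df <- data.frame(a = ids[layer$edges$i], b = ids[layer$edges$j],
                   w = formatC(layer$edges$w, digits = 12, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a weighted layer TSV back
#' @param path Three-column TSV (protein_a, protein_b, weight).
#' @param universe The shared \code{protein_universe}.
#' @param name Layer name.
#' @return A \code{weighted_layer}.
#' @export
read_layer <- function(path, universe, name = "layer") {
  tab <- read_tsv_checked(path, header = FALSE, what = "layer")
  i <- universe_index(universe, tab[[1L]])
  j <- universe_index(universe, tab[[2L]])
  if (anyNA(i) || anyNA(j)) stop("layer endpoint outside universe in ", path)
  weighted_layer(universe, i, j, as.numeric(tab[[3L]]), name = name)
}

#' Write a ranking as TSV, with an optional JSON walk sidecar
#'
#' Emits (protein, score) sorted descending with the package's deterministic
#' tie-breaking, scores at 12 significant digits. If the ranking carries a
#' walk result, a JSON sidecar records the layer importances y, alpha,
#' iteration count and final residual.
#'
#' @param rl A \code{ranked_list}.
#' @param path Output TSV path.
#' @param sidecar Optional JSON path; default \code{paste0(path, ".json")}
#'   when a walk result is attached, none otherwise.
#' @param alpha Optional alpha to record in the sidecar.
#' @export
write_ranking <- function(rl, path, sidecar = NULL, alpha = NULL) {
  df <- data.frame(protein = rl$protein,
                   score = formatC(rl$score, digits = 12, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  wr <- attr(rl, "walk")
  if (!is.null(wr)) {
    if (is.null(sidecar)) sidecar <- paste0(path, ".json")
    jsonlite::write_json(
      list(layer_importance = wr$y, alpha = alpha,
           iterations = wr$iterations, converged = wr$converged,
           final_residual = wr$residual_trace[length(wr$residual_trace)]),
      sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a ranking TSV back as a ranked_list
#' @param path Two-column TSV (protein, score), descending.
#' @param universe Optional universe; defaults to the file's protein order.
#' @return A \code{ranked_list}.
#' @export
read_ranking <- function(path, universe = NULL) {
  tab <- read_tsv_checked(path, header = FALSE, what = "ranking")
  ids <- trimws(as.character(tab[[1L]]))
  sc <- as.numeric(tab[[2L]])
  if (is.null(universe)) universe <- protein_universe(ids)
  ranked_list(stats::setNames(sc, ids), universe)
}

#' Write a synthetic bundle to a directory
#'
#' Writes the six input files in exactly the formats the loaders consume:
#' ppi.tsv, domains.tsv, expression.tsv, orthologs.tsv, modular_scores.tsv,
#' essential.txt.
#'
#' @param bundle A \code{synthetic_bundle}.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the paths written.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- as.character(bundle$pin$universe)
  paths <- c(ppi = file.path(dir, "ppi.tsv"),
             domains = file.path(dir, "domains.tsv"),
             expression = file.path(dir, "expression.tsv"),
             orthologs = file.path(dir, "orthologs.tsv"),
             modular_scores = file.path(dir, "modular_scores.tsv"),
             essential = file.path(dir, "essential.txt"))
  e <- bundle$pin$edges
  utils::write.table(data.frame(a = ids[e[, "i"]], b = ids[e[, "j"]]),
                     paths["ppi"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(p = bundle$domains$protein,
                                d = bundle$domains$domain),
                     paths["domains"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ex <- bundle$expr$values
  utils::write.table(
    data.frame(gene = rownames(ex),
               formatC(ex, digits = 12, format = "g"),
               check.names = FALSE),
    paths["expression"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = c("gene", colnames(ex)))
  utils::write.table(data.frame(p = names(bundle$orth), n = as.integer(bundle$orth)),
                     paths["orthologs"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(p = names(bundle$ms),
                                s = formatC(bundle$ms, digits = 12, format = "g")),
                     paths["modular_scores"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(bundle$essential, paths["essential"])
  invisible(paths)
}
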