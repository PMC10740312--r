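# Co-expression network construction and utilities.

as_adjacency <- function(x) {
  if (inherits(x, "coexpression_network")) return(x$adjacency)
  stopifnot(is.matrix(x))
  x
}

#' Binarize a correlation matrix
#'
#' Entries at or above the threshold become edges; everything below —
#' including all negative correlations — does not (signed convention; use
#' `absolute = TRUE` to threshold |r| instead). The diagonal is always 0.
#'
#' @param C symmetric correlation matrix with dimnames.
#' @param threshold threshold in (0, 1).
#' @param absolute threshold |r| instead of r.
#' @return Binary symmetric hollow adjacency matrix.
#' @export
binarize <- function(C, threshold, absolute = FALSE) {
  stopifnot(threshold > 0, threshold < 1)
  v <- if (absolute) abs(C) else C
  A <- (v >= threshold) * 1
  diag(A) <- 0
  A
}

#' Scale-free topology fit of a degree distribution
#'
#' Bins positive node degrees into logarithmically spaced bins, regresses
#' `log10 p(k)` on `log10 k` over nonempty bins (k = the bin's geometric
#' mean), and returns the regression R-squared. A scale-free network
#' (power-law degree distribution) gives values near 1. Fewer than 3
#' nonempty bins (e.g. a k-regular graph) returns 0 with a warning.
#'
#' @param adjacency binary adjacency matrix or `coexpression_network`.
#' @param n_bins number of log bins (default 10).
#' @return R-squared in \[0, 1\].
#' @export
scale_free_r2 <- function(adjacency, n_bins = 10) {
  A <- as_adjacency(adjacency)
  k <- rowSums(A)
  k <- k[k > 0]
  if (!length(k)) { warning("no connected nodes; R^2 = 0"); return(0) }
  if (min(k) == max(k)) {
    warning("degenerate degree distribution (single degree); R^2 = 0")
    return(0)
  }
  brks <- exp(seq(log(min(k)), log(max(k)), length.out = n_bins + 1))
  brks[1] <- brks[1] * (1 - 1e-9); brks[n_bins + 1] <- brks[n_bins + 1] * (1 + 1e-9)
  bin <- cut(k, brks, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  kg <- tapply(k, bin, function(x) exp(mean(log(x))))
  ok <- !is.na(pk) & pk > 0
  if (sum(ok) < 3) {
    warning("fewer than 3 nonempty degree bins; R^2 = 0")
    return(0)
  }
  # simple linear regression: R^2 is the squared correlation
  stats::cor(log10(kg[ok]), log10(pk[ok]))^2
}

#' Mean connectivity (average degree)
#'
#' `2 * edges / nodes`, isolated nodes included.
#'
#' @param adjacency binary adjacency matrix or `coexpression_network`.
#' @return Nonnegative number.
#' @export
mean_connectivity <- function(adjacency) {
  A <- as_adjacency(adjacency)
  if (!nrow(A)) stop("empty node set")
  mean(rowSums(A))
}

#' Count near-disconnected components
#'
#' Number of connected components with at least `min_size` nodes (default
#' 2, so isolated genes are not counted as clusters). With
#' `method = "spectral"` the count is instead the number of graph-Laplacian
#' eigenvalues below `1e-8` among non-singleton nodes.
#'
#' @param adjacency binary adjacency matrix or `coexpression_network`.
#' @param min_size minimum component size counted.
#' @param method `"components"` (default) or `"spectral"`.
#' @return Integer count.
#' @export
count_components <- function(adjacency, min_size = 2,
                             method = c("components", "spectral")) {
  method <- match.arg(method)
  A <- as_adjacency(adjacency)
  keep <- rowSums(A) > 0
  if (!any(keep)) return(0L)
  A2 <- A[keep, keep, drop = FALSE]
  if (method == "spectral") {
    L <- diag(rowSums(A2)) - A2
    return(sum(eigen(L, symmetric = TRUE, only.values = TRUE)$values < 1e-8))
  }
  g <- igraph::graph_from_adjacency_matrix(A2, mode = "undirected")
  comp <- igraph::components(g)
  sum(comp$csize >= min_size)
}

#' Network summary statistics
#'
#' @param adjacency binary adjacency matrix or `coexpression_network`.
#' @return A list: `nodes`, `edges`, `average_degree`, and
#'   `degree_distribution` (a tibble of degree, count).
#' @export
network_stats <- function(adjacency) {
  A <- as_adjacency(adjacency)
  k <- rowSums(A)
  tab <- table(k)
  list(nodes = nrow(A),
       edges = sum(A) / 2,
       average_degree = if (nrow(A)) mean(k) else 0,
       degree_distribution = tibble::tibble(
         degree = as.integer(names(tab)), count = as.integer(tab)))
}

#' Select the binarization threshold
#'
#' Scans a grid of candidate thresholds; for each, records the scale-free
#' fit R-squared, mean connectivity, component count and edge count. Among
#' candidates meeting the scale-free criterion (R-squared >= `r2_min`,
#' default 0.5) the one maximizing the component count wins; ties go to the
#' smallest threshold (retaining more edges). If no candidate qualifies,
#' the maximal-R-squared candidate is returned with a prominent warning.
#'
#' @param expr cleaned expression table (first column gene id; >= 3
#'   conditions).
#' @param grid ascending candidate thresholds in (0, 1).
#' @param r2_min scale-free qualification bound.
#' @param absolute passed to [binarize()].
#' @return A `coexpression_network`: list with `genes`, `adjacency`,
#'   `threshold` and the per-candidate `diagnostics` tibble
#'   (threshold, r2, mean_connectivity, n_components, n_edges).
#' @export
select_threshold <- function(expr, grid = seq(0.50, 0.99, by = 0.01),
                             r2_min = 0.5, absolute = FALSE) {
  if (!length(grid)) stop("empty threshold grid")
  stopifnot(all(grid > 0 & grid < 1), !is.unsorted(grid))
  if (ncol(expr) - 1L < 3L) stop("threshold selection requires >= 3 conditions")
  C <- correlation_matrix(expr)
  diag <- purrr::map_dfr(grid, function(t) {
    A <- binarize(C, t, absolute = absolute)
    tibble::tibble(
      threshold = t,
      r2 = suppressWarnings(scale_free_r2(A)),
      mean_connectivity = mean_connectivity(A),
      n_components = count_components(A),
      n_edges = sum(A) / 2)
  })
  ok <- diag$r2 >= r2_min
  if (any(ok)) {
    cand <- diag[ok, ]
    best <- cand$threshold[which.max(cand$n_components)] # which.max = first = smallest t
  } else {
    warning("no candidate threshold reaches scale-free R^2 >= ", r2_min,
            "; falling back to the maximal-R^2 candidate", immediate. = TRUE)
    best <- diag$threshold[which.max(diag$r2)]
  }
  A <- binarize(C, best, absolute = absolute)
  structure(list(genes = rownames(A), adjacency = A, threshold = best,
                 diagnostics = diag),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  st <- network_stats(x)
  cat("<coexpression_network> ", st$nodes, " genes, ", st$edges,
      " edges (avg degree ", round(st$average_degree, 4), ")\n", sep = "")
  if (!is.null(x$threshold)) cat("  threshold: ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Randomly rewire a fraction of edges
#'
#' Removes `round(fraction * E)` randomly chosen edges and inserts the same
#' number uniformly among current non-edges (no self-loops, no duplicates),
#' so node and edge counts are conserved exactly. Deterministic given
#' `seed`.
#'
#' @param network `coexpression_network` or adjacency matrix.
#' @param fraction fraction of edges to rewire, in \[0, 1\].
#' @param seed RNG seed.
#' @return A `coexpression_network` with the rewired adjacency.
#' @export
rewire_random <- function(network, fraction, seed = 0) {
  stopifnot(fraction >= 0, fraction <= 1)
  A <- as_adjacency(network)
  n <- nrow(A)
  edges <- which(upper.tri(A) & A != 0)
  n_rewire <- round(fraction * length(edges))
  if (n_rewire > 0) {
    set.seed(seed)
    # replacements are drawn among the ORIGINAL graph's non-edges, so no
    # removed edge can come back: exactly E - n_rewire originals survive
    free <- which(upper.tri(A) & A == 0)
    drop <- sample(edges, n_rewire)
    A[drop] <- 0
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    if (length(free) < n_rewire) {
      stop("graph too dense to place ", n_rewire, " replacement edges")
    }
    add <- sample(free, n_rewire)
    A[add] <- 1
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
  }
  structure(list(genes = rownames(A), adjacency = A, threshold = NULL,
                 diagnostics = NULL),
            class = "coexpression_network")
}

#' Import a STRING protein-links network
#'
#' Reads the STRING `protein1 protein2 combined_score` whitespace-separated
#' format, keeps interactions with `combined_score` strictly greater than
#' `score_cut` (default 900, the high-confidence band), maps protein ids to
#' model gene ids, and deduplicates reciprocal lines into one undirected
#' edge. Unmapped proteins and malformed lines are counted and dropped.
#'
#' @param path links file path (a header line is auto-detected).
#' @param id_map named character vector: protein id -> gene id; `NULL`
#'   keeps protein ids.
#' @param score_cut strict lower bound on `combined_score`.
#' @return A `coexpression_network` over the mapped genes; attribute
#'   `import_log` records dropped counts.
#' @export
import_string_ppi <- function(path, id_map = NULL, score_cut = 900) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("protein1", lines[1], fixed = TRUE)) {
    lines <- lines[-1]
  }
  n_bad <- 0L; n_unmapped <- 0L; n_low <- 0L
  from <- character(0); to <- character(0)
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    sc <- suppressWarnings(as.numeric(f[3]))
    if (length(f) < 3L || is.na(sc)) { n_bad <- n_bad + 1L; next }
    if (!(sc > score_cut)) { n_low <- n_low + 1L; next }
    a <- f[1]; b <- f[2]
    if (!is.null(id_map)) {
      if (!a %in% names(id_map) || !b %in% names(id_map)) {
        n_unmapped <- n_unmapped + 1L; next
      }
      a <- id_map[[a]]; b <- id_map[[b]]
    }
    if (a == b) next
    from <- c(from, min(a, b)); to <- c(to, max(a, b))
  }
  if (n_bad) warning(n_bad, " malformed line(s) skipped")
  keep <- !duplicated(paste(from, to))
  from <- from[keep]; to <- to[keep]
  genes <- sort_c(unique(c(from, to)))
  if (!length(genes)) warning("zero edges survive the score cut")
  A <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (e in seq_along(from)) {
    A[from[e], to[e]] <- 1; A[to[e], from[e]] <- 1
  }
  out <- structure(list(genes = genes, adjacency = A, threshold = NULL,
                        diagnostics = NULL),
                   class = "coexpression_network")
  attr(out, "import_log") <- tibble::tibble(
    dropped_malformed = n_bad, dropped_low_score = n_low,
    dropped_unmapped = n_unmapped)
  out
}

#' Topological overlap similarity
#'
#' `TOM[i,j] = (l[i,j] + a[i,j]) / (min(k_i, k_j) + 1 - a[i,j])` with
#' `l[i,j]` the number of shared neighbors and `k` the degree; the diagonal
#' is 1 and 0/0 cells are 0. Values lie in \[0, 1\]; high overlap means the
#' two genes share most of their network neighborhood.
#'
#' @param adjacency binary hollow adjacency matrix or
#'   `coexpression_network`.
#' @return Symmetric TOM matrix.
#' @export
tom_similarity <- function(adjacency) {
  A <- as_adjacency(adjacency)
  l <- A %*% A
  k <- rowSums(A)
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (l + A) / denom
  tom[denom == 0 | (l + A) == 0] <- 0
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity
#' `1 - TOM`, cut to a requested number of modules (or at a static height).
#' Modules are labelled `ME1, ME2, ...` in decreasing size order;
#' deterministic.
#'
#' @param tom TOM similarity matrix from [tom_similarity()].
#' @param n_modules number of modules to cut (mutually exclusive with
#'   `cut_height`).
#' @param cut_height static tree-cut height in \[0, 1\].
#' @return Named character vector gene -> module label.
#' @export
detect_modules <- function(tom, n_modules = NULL, cut_height = NULL) {
  stopifnot(xor(is.null(n_modules), is.null(cut_height)))
  if (!is.null(n_modules) && n_modules > nrow(tom)) {
    stop("requested ", n_modules, " modules from ", nrow(tom), " genes")
  }
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  cl <- if (!is.null(n_modules)) stats::cutree(hc, k = n_modules)
        else stats::cutree(hc, h = cut_height)
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- stats::setNames(paste0("ME", seq_along(sizes)), names(sizes))
  out <- relabel[as.character(cl)]
  names(out) <- rownames(tom)
  out
}
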