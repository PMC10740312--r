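test_that("cleaning removes missing genes, averages duplicates, winsorizes", {
  raw <- tibble::tibble(
    gene = c("a", "b", "b", "c", "d"),
    c1 = c(1, 2, 4, NA, 5),
    c2 = c(2, 3, 5, 1, 5),
    c3 = c(3, 4, 6, 2, 5),
    c4 = c(4, 5, 7, 3, 100)) # d has an extreme outlier
  cleaned <- clean_expression(raw)
  log <- attr(cleaned, "cleaning_log")
  expect_false("c" %in% cleaned$gene) # NA row removed
  expect_true("removed_missing" %in% log$action)
  b <- as.numeric(cleaned[cleaned$gene == "b", -1])
  expect_equal(b, c(3, 4, 5, 6)) # duplicates averaged
  # winsorization fence recomputed by an independent one-pass oracle
  d_orig <- c(5, 5, 5, 100)
  fence <- median(d_orig) + 5 * mad(d_orig)
  d <- as.numeric(cleaned[cleaned$gene == "d", -1])
  expect_equal(d, pmin(d_orig, fence))
  expect_true("winsorized" %in% log$action)
  expect_error(clean_expression(raw[, 1:2]), "conditions")
})

test_that("correlation matrix matches the textbook formula", {
  expr <- tibble::tibble(gene = c("a", "b", "c"),
                         c1 = c(1, 2, 9), c2 = c(2, 4, 4),
                         c3 = c(3, 6, 2), c4 = c(4, 8, 7))
  C <- correlation_matrix(expr)
  expect_equal(unname(C["a", "b"]), 1) # b = 2a
  # direct sum-formula oracle for (a, c)
  x <- c(1, 2, 3, 4); y <- c(9, 4, 2, 7)
  n <- 4
  r <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(unname(C["a", "c"]), r)
  neg <- tibble::tibble(gene = c("a", "b"),
                        c1 = c(1, 9), c2 = c(2, 8), c3 = c(3, 7))
  expect_equal(unname(correlation_matrix(neg)["a", "b"]), -1)
  const <- tibble::tibble(gene = c("a", "b"),
                          c1 = c(1, 5), c2 = c(2, 5), c3 = c(3, 5))
  expect_warning(Cc <- correlation_matrix(const), "constant")
  expect_equal(unname(Cc["a", "b"]), 0)
})

test_that("binarization conventions: sign, boundary, hollow diagonal", {
  C <- matrix(c(1, 0.95, -0.99, 0.95, 1, 0.91, -0.99, 0.91, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  A <- binarize(C, 0.91)
  expect_equal(unname(A["a", "b"]), 1) # 0.95 >= 0.91
  expect_equal(unname(A["a", "c"]), 0) # negative never an edge (signed)
  expect_equal(unname(A["b", "c"]), 1) # boundary: r == t is an edge
  expect_equal(unname(diag(A)), rep(0, 3))
  Aabs <- binarize(C, 0.91, absolute = TRUE)
  expect_equal(unname(Aabs["a", "c"]), 1)
})

test_that("scale-free fit is 1 on an exact power law, 0 when degenerate", {
  # degrees 1,2,4,8 with counts 8,4,2,1: log p(k) is exactly linear in
  # log k, each log-bin holds one degree value -> collinear points
  deg <- rep(c(1, 2, 4, 8), times = c(8, 4, 2, 1))
  g <- igraph::realize_degseq(deg)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  dimnames(A) <- list(paste0("n", 1:15), paste0("n", 1:15))
  expect_equal(scale_free_r2(A), 1, tolerance = 1e-12)
  # k-regular graph: single degree value
  ring <- as.matrix(igraph::as_adjacency_matrix(igraph::make_ring(6)))
  expect_warning(r2 <- scale_free_r2(ring), "degenerate|bins")
  expect_equal(r2, 0)
})

test_that("scale-free fit equals an independent regression on a PA graph", {
  set.seed(21)
  g <- igraph::sample_pa(50, directed = FALSE)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  got <- scale_free_r2(A, n_bins = 10)
  # independent implementation: same binning contract, R^2 via cor()^2
  k <- rowSums(A); k <- k[k > 0]
  brks <- exp(seq(log(min(k)), log(max(k)), length.out = 11))
  brks[1] <- brks[1] * (1 - 1e-9); brks[11] <- brks[11] * (1 + 1e-9)
  bin <- cut(k, brks, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  kg <- tapply(k, bin, function(x) exp(mean(log(x))))
  ok <- !is.na(pk)
  want <- cor(log10(kg[ok]), log10(pk[ok]))^2
  expect_equal(got, unname(want), tolerance = 1e-10)
})

test_that("mean connectivity and network stats agree with hand counts", {
  star <- adjacency_from_edges(paste0("n", 1:4),
                               list(c("n1", "n2"), c("n1", "n3"), c("n1", "n4")))
  st <- network_stats(star)
  expect_equal(st$nodes, 4)
  expect_equal(st$edges, 3)
  expect_equal(st$average_degree, 1.5)
  expect_equal(st$degree_distribution$count[st$degree_distribution$degree == 1], 3)
  expect_equal(st$degree_distribution$count[st$degree_distribution$degree == 3], 1)
  expect_equal(sum(st$degree_distribution$count), 4)
  pair <- adjacency_from_edges(c("a", "b"), list(c("a", "b")))
  expect_equal(mean_connectivity(pair), 1)
  empty <- matrix(0, 5, 5, dimnames = list(paste0("n", 1:5), paste0("n", 1:5)))
  st0 <- network_stats(empty)
  expect_equal(st0$edges, 0)
  expect_equal(st0$average_degree, 0)
  expect_error(mean_connectivity(empty[0, 0]), "empty")
})

test_that("component counting excludes singletons and matches union-find", {
  genes <- paste0("n", 1:9)
  A <- adjacency_from_edges(genes, list(
    c("n1", "n2"), c("n2", "n3"), c("n1", "n3"), # triangle
    c("n4", "n5"), c("n5", "n6"), c("n4", "n6"))) # triangle; n7..n9 isolated
  expect_equal(count_components(A), 2)
  expect_equal(count_components(A * 0), 0)

  # path graph vs an independent union-find oracle
  path <- adjacency_from_edges(genes, lapply(1:8, function(i)
    c(paste0("n", i), paste0("n", i + 1))))
  uf <- seq_len(9)
  find <- function(i) { while (uf[i] != i) i <- uf[i]; i }
  for (i in 1:8) uf[find(i)] <- find(i + 1)
  expect_equal(count_components(path),
               length(unique(vapply(1:9, find, numeric(1)))))
  expect_equal(count_components(path), 1)

  # invariance under node relabeling
  set.seed(3)
  perm <- sample(9)
  expect_equal(count_components(A[perm, perm]), count_components(A))
  # spectral variant agrees on clean components
  expect_equal(count_components(A, method = "spectral"), 2)
})

test_that("threshold selection maximizes components under the R^2 gate", {
  # three tight blocks of correlated genes + mild noise
  spec <- toy_spec(n_conditions = 12, block_correlation = 0.95, seed = 9)
  genes <- paste0("g", 1:15)
  blocks <- setNames(rep(c("b1", "b2", "b3"), each = 5), genes)
  expr <- gen_expression(spec, genes, blocks)
  grid <- seq(0.5, 0.95, by = 0.05)
  suppressWarnings(net <- select_threshold(expr, grid))
  d <- net$diagnostics
  expect_equal(nrow(d), length(grid))
  # edge count is non-increasing in the threshold
  expect_true(all(diff(d$n_edges) <= 0))
  # independent recomputation of the diagnostics for each candidate
  C <- correlation_matrix(expr)
  for (k in sample(seq_along(grid), 4)) {
    A <- (C >= grid[k]) * 1; diag(A) <- 0
    expect_equal(d$n_edges[k], sum(A) / 2)
    expect_equal(d$mean_connectivity[k], mean(rowSums(A)))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    cs <- igraph::components(g)$csize
    expect_equal(d$n_components[k], sum(cs >= 2))
  }
  # the selection rule applied to the diagnostics table reproduces the pick
  ok <- d$r2 >= 0.5
  if (any(ok)) {
    want <- d$threshold[ok][which.max(d$n_components[ok])]
  } else {
    want <- d$threshold[which.max(d$r2)]
  }
  expect_equal(net$threshold, want)
  expect_error(select_threshold(expr, numeric(0)), "empty")
})

test_that("rewiring conserves nodes and edges at every fraction", {
  set.seed(5)
  genes <- paste0("n", 1:20)
  g <- igraph::sample_gnm(20, 40)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  dimnames(A) <- list(genes, genes)
  for (f in c(0, 0.25, 0.5, 0.75, 1)) {
    rw <- rewire_random(A, f, seed = 7)
    expect_equal(dim(rw$adjacency), dim(A))
    expect_equal(sum(rw$adjacency) / 2, sum(A) / 2)
    expect_true(isSymmetric(rw$adjacency))
    expect_equal(unname(diag(rw$adjacency)), rep(0, 20))
  }
  expect_equal(rewire_random(A, 0, seed = 1)$adjacency, A)
  # full rewire changes the edge set (w.h.p. on a sparse graph)
  rw1 <- rewire_random(A, 1, seed = 7)
  expect_false(identical(rw1$adjacency, A))
  # determinism
  expect_equal(rewire_random(A, 0.5, seed = 3)$adjacency,
               rewire_random(A, 0.5, seed = 3)$adjacency)
})

test_that("rewiring half of a 16-edge graph keeps exactly 8 original edges", {
  genes <- paste0("n", 1:12)
  set.seed(8)
  g <- igraph::sample_gnm(12, 16)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  dimnames(A) <- list(genes, genes)
  rw <- rewire_random(A, 0.5, seed = 2)$adjacency
  orig <- which(upper.tri(A) & A == 1)
  new <- which(upper.tri(rw) & rw == 1)
  expect_equal(length(intersect(orig, new)), 8) # set-difference oracle
  expect_equal(length(new), 16)
})

test_that("STRING import applies the strict score cut and deduplicates", {
  f <- tempfile()
  writeLines(c(
    "protein1 protein2 combined_score",
    "p1 p2 901",
    "p2 p1 901",  # reciprocal duplicate
    "p1 p3 900",  # at the cut: dropped (strict >)
    "p3 p4 950",
    "p5 p6 999",  # p5 unmappable
    "junk_line"
  ), f)
  idmap <- c(p1 = "gA", p2 = "gB", p3 = "gC", p4 = "gD", p6 = "gF")
  expect_warning(net <- import_string_ppi(f, idmap), "malformed")
  A <- net$adjacency
  expect_equal(sum(A) / 2, 2) # gA-gB once, gC-gD
  expect_equal(unname(A["gA", "gB"]), 1)
  expect_false("gC" %in% rownames(A) && A["gA", "gC"] == 1)
  log <- attr(net, "import_log")
  expect_equal(log$dropped_low_score, 1)
  expect_equal(log$dropped_unmapped, 1)
})

test_that("topological overlap: triangle, shared neighborhoods, components", {
  tri <- adjacency_from_edges(letters[1:3],
                              list(c("a", "b"), c("b", "c"), c("a", "c")))
  tom <- tom_similarity(tri)
  # hand computation: l = 1, a = 1, min k = 2 -> (1+1)/(2+1-1) = 1
  expect_equal(unname(tom[upper.tri(tom)]), rep(1, 3))
  expect_equal(unname(diag(tom)), rep(1, 3))

  # two adjacent hubs sharing every other neighbor
  genes <- c("h1", "h2", paste0("x", 1:4))
  edges <- c(list(c("h1", "h2")),
             lapply(paste0("x", 1:4), function(x) c("h1", x)),
             lapply(paste0("x", 1:4), function(x) c("h2", x)))
  A <- adjacency_from_edges(genes, edges)
  expect_equal(unname(tom_similarity(A)["h1", "h2"]), 1)

  # different components share nothing
  two <- adjacency_from_edges(c("a", "b", "c", "d"),
                              list(c("a", "b"), c("c", "d")))
  t2 <- tom_similarity(two)
  expect_equal(unname(t2["a", "c"]), 0)
  expect_true(all(t2 >= 0 & t2 <= 1))
})

test_that("module detection recovers separable structure deterministically", {
  c1 <- expand.grid(a = paste0("p", 1:4), b = paste0("p", 1:4))
  c2 <- expand.grid(a = paste0("q", 1:4), b = paste0("q", 1:4))
  genes <- c(paste0("p", 1:4), paste0("q", 1:4))
  edges <- c(
    apply(subset(c1, a != b), 1, function(r) c(r[1], r[2]), simplify = FALSE),
    apply(subset(c2, a != b), 1, function(r) c(r[1], r[2]), simplify = FALSE))
  A <- adjacency_from_edges(genes, edges)
  tom <- tom_similarity(A)
  mods <- detect_modules(tom, n_modules = 2)
  expect_equal(length(unique(mods[paste0("p", 1:4)])), 1)
  expect_equal(length(unique(mods[paste0("q", 1:4)])), 1)
  expect_setequal(unique(mods), c("ME1", "ME2"))
  expect_equal(unique(unname(detect_modules(tom, n_modules = 1))), "ME1")
  expect_error(detect_modules(tom, n_modules = 99), "modules")

  # 3-block synthetic TOM with inter-block noise: exact block recovery
  set.seed(13)
  truth <- rep(1:3, each = 4)
  Tm <- matrix(runif(144, 0, 0.05), 12, 12)
  for (b in 1:3) {
    i <- which(truth == b)
    Tm[i, i] <- runif(16, 0.8, 1)
  }
  Tm <- (Tm + t(Tm)) / 2; diag(Tm) <- 1
  dimnames(Tm) <- list(paste0("g", 1:12), paste0("g", 1:12))
  got <- detect_modules(Tm, n_modules = 3)
  expect_equal(mclust::adjustedRandIndex(got, truth), 1)
})
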