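# Independent recursive GPR evaluator used as an oracle (kept deliberately
# separate from the package implementation).
oracle_eval <- function(tree, expr) {
  if (is.null(tree)) return(NA_real_)
  if (!is.null(tree$gene)) {
    if (tree$gene %in% names(expr)) return(expr[[tree$gene]]) else return(NA)
  }
  vals <- Filter(Negate(is.na), lapply(tree$args, oracle_eval, expr = expr))
  if (!length(vals)) return(NA_real_)
  vals <- unlist(vals)
  if (tree$op == "and") min(vals) else sum(vals)
}

test_that("GPR grammar: precedence, parentheses, empty and malformed rules", {
  tr <- parse_gpr("(g1 and g2) or g3")
  expect_equal(tr$op, "or")
  expect_equal(tr$args[[1]]$op, "and")
  expect_equal(tr$args[[2]]$gene, "g3")
  # and binds tighter than or
  tr2 <- parse_gpr("g1 and g2 or g3")
  expect_equal(tr2$op, "or")
  expect_null(parse_gpr(""))
  expect_null(parse_gpr("   "))
  expect_error(parse_gpr("g1 and (g2 or"), "parse error")
  expect_error(parse_gpr("g1 or or g2"), "parse error")
  expect_error(parse_gpr("(g1 and g2))"), "parse error")
  expect_equal(sort(gpr_genes(parse_gpr("(a and b) or (a and c)"))),
               c("a", "b", "c"))
})

test_that("bound evaluation: and -> min, or -> sum, nested vs oracle", {
  ex <- c(g1 = 3, g2 = 5, g3 = 2)
  expect_equal(eval_gpr_bound(parse_gpr("g1 and g2"), ex, T = 100), 3)
  expect_equal(eval_gpr_bound(parse_gpr("g1 or g2"), ex, T = 100), 8)
  expect_equal(eval_gpr_bound(parse_gpr("(g1 and g2) or g3"), ex, T = 100), 5)
  expect_equal(eval_gpr_bound(parse_gpr("(g1 and g2) or g3"), ex, T = 100,
                              or_rule = "max"), 3)
  # randomized nested rules against the independent oracle
  rules <- c("(g1 or g2) and g3", "g1 or (g2 and g3) or g1",
             "((g1 and g2) or (g2 and g3)) and g1")
  set.seed(7)
  for (r in rules) {
    for (i in 1:10) {
      e <- c(g1 = runif(1, 0, 10), g2 = runif(1, 0, 10), g3 = runif(1, 0, 10))
      expect_equal(eval_gpr_bound(parse_gpr(r), e, T = 100),
                   oracle_eval(parse_gpr(r), as.list(e)))
    }
  }
})

test_that("unmeasured genes are dropped; fully unmeasured rules hit T", {
  ex <- c(g1 = 3)
  expect_equal(eval_gpr_bound(parse_gpr("g1 and gX"), ex, T = 100), 3)
  expect_equal(eval_gpr_bound(parse_gpr("g1 or gX"), ex, T = 100), 3)
  expect_equal(eval_gpr_bound(parse_gpr("gX and gY"), ex, T = 100), 100)
  expect_equal(eval_gpr_bound(NULL, ex, T = 100), 100)
  expect_error(eval_gpr_bound(parse_gpr("g1"), c(g1 = -1), T = 100),
               "negative")
})

test_that("raising a leaf's expression never decreases the bound", {
  rules <- c("g1 and g2", "g1 or g2", "(g1 and g2) or (g1 and g3)",
             "g1 and (g2 or g3)")
  set.seed(11)
  for (r in rules) {
    tree <- parse_gpr(r)
    for (i in 1:20) {
      e <- c(g1 = runif(1, 0, 5), g2 = runif(1, 0, 5), g3 = runif(1, 0, 5))
      g <- sample(names(e), 1)
      e2 <- e
      e2[g] <- e[g] + runif(1, 0, 5)
      expect_gte(eval_gpr_bound(tree, e2, T = 100),
                 eval_gpr_bound(tree, e, T = 100))
    }
  }
})

test_that("per-condition bounds: f at the condition, M over all conditions", {
  m <- chain_fixture()
  tpl <- build_template(m, "DC", carbon_source = "EX_glc", T = 1000)
  expr <- tibble::tibble(gene = c("gs1", "gs2", "gb"),
                         c1 = c(2, 7, 9), c2 = c(6, 3, 9), c3 = c(4, 5, 9))
  b2 <- reaction_bounds(tpl, expr, "c2")
  s1 <- which(b2$reaction == "S1")
  expect_equal(b2$f[s1], 6)
  expect_equal(b2$M[s1], 6) # max over (2, 6, 4)
  b1 <- reaction_bounds(tpl, expr, "c1")
  expect_equal(b1$f[s1], 2)
  expect_equal(b1$M[s1], 6)
  # empty-GPR exchange columns are unmapped at bound T
  ex_cols <- which(b1$reaction == "EX_glc")
  expect_true(all(!b1$mapped[ex_cols]))
  expect_true(all(b1$f[ex_cols] == 1000))
  expect_error(reaction_bounds(tpl, expr, "c9"), "not found")
})

test_that("reversible siblings share f and M", {
  fx <- branch_fixture(toy_spec(seed = 5))
  tpl <- build_template(fx$model, "DC", carbon_source = "EX_glc",
                        T = default_T(fx$expr))
  bnd <- reaction_bounds(tpl, fx$expr, "C1")
  for (r in seq_len(nrow(tpl$rev_pairs))) {
    fw <- tpl$rev_pairs[r, 1]; bw <- tpl$rev_pairs[r, 2]
    expect_equal(bnd$f[fw], bnd$f[bw])
    expect_equal(bnd$M[fw], bnd$M[bw])
  }
})

test_that("pair lifting follows edges, drops self-pairs and Rev pairs", {
  m <- chain_fixture() # genes gs1 (S1), gs2 (S2), gb (BIO)
  tpl <- build_template(m, "DC", carbon_source = "EX_glc", T = 1000)
  bnd <- reaction_bounds(tpl, chain_expr(), "C1")
  A <- adjacency_from_edges(c("gs1", "gs2", "gb"),
                            list(c("gs1", "gs2")))
  R <- build_pair_set(as_network(A), tpl, bnd)
  s1 <- which(tpl$columns$reaction == "S1")
  s2 <- which(tpl$columns$reaction == "S2")
  expect_equal(nrow(R), 1)
  expect_equal(sort(c(R$i, R$j)), sort(c(s1, s2)))

  # both genes of an edge on the same single reaction -> self-pair dropped
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "#objective b", "#formula g=CH2O", "#formula x=R",
    "reaction\tequation\tlower\tupper\tgpr\tsubsystem",
    "EX\tg ->\t-10\t10\t\t",
    "r1\tg -> x\t0\t10\tga and gb\t",
    "b\tx ->\t0\t10\t\t"
  ), tsv)
  m2 <- read_model_tsv(tsv)
  tpl2 <- build_template(m2, "DC", carbon_source = "EX", T = 100)
  expr2 <- tibble::tibble(gene = c("ga", "gb"), c1 = c(1, 2), c2 = c(2, 1))
  bnd2 <- reaction_bounds(tpl2, expr2, "c1")
  A2 <- adjacency_from_edges(c("ga", "gb"), list(c("ga", "gb")))
  R2 <- build_pair_set(as_network(A2), tpl2, bnd2)
  expect_equal(nrow(R2), 0)
})

test_that("pair set matches brute-force enumeration on a 5-gene toy", {
  # one reversible reaction with two genes; an edge linking them must not
  # produce the forward/backward Rev pair
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "#objective b", "#formula g=CH2O", "#formula z=R",
    "reaction\tequation\tlower\tupper\tgpr\tsubsystem",
    "EX\tg ->\t-10\t10\t\t",
    "r1\tg -> x\t0\t10\tg1\t",
    "r2\tx <=> y\t-10\t10\tg2 or g3\t",
    "r3\ty -> z\t0\t10\tg4 and g5\t",
    "b\tz ->\t0\t10\t\t"
  ), tsv)
  m <- read_model_tsv(tsv)
  tpl <- build_template(m, "DC", carbon_source = "EX", T = 100)
  genes <- paste0("g", 1:5)
  expr <- tibble::tibble(gene = genes, c1 = 1:5, c2 = 5:1, c3 = c(2, 2, 2, 2, 2))
  bnd <- reaction_bounds(tpl, expr, "c1")
  edges <- list(c("g1", "g2"), c("g2", "g3"), c("g4", "g5"), c("g1", "g4"))
  A <- adjacency_from_edges(genes, edges)
  R <- build_pair_set(as_network(A), tpl, bnd)

  # oracle: exhaustive enumeration over all column pairs
  col_genes <- lapply(tpl$columns$gpr, function(g) gpr_genes(parse_gpr(g)))
  rev_keys <- apply(tpl$rev_pairs, 1,
                    function(p) paste(min(p), max(p)))
  want <- character(0)
  nc <- nrow(tpl$columns)
  for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
    hit <- any(vapply(edges, function(e) {
      (e[1] %in% col_genes[[i]] && e[2] %in% col_genes[[j]]) ||
        (e[2] %in% col_genes[[i]] && e[1] %in% col_genes[[j]])
    }, logical(1)))
    if (hit && !(paste(i, j) %in% rev_keys)) want <- c(want, paste(i, j))
  }
  got <- paste(R$i, R$j)
  expect_setequal(got, want)
  # invariants: no self-pairs, disjoint from Rev
  expect_true(all(R$i != R$j))
  expect_false(any(got %in% rev_keys))
})

test_that("no gene overlap yields an empty pair set with a warning", {
  m <- chain_fixture()
  tpl <- build_template(m, "DC", carbon_source = "EX_glc", T = 1000)
  bnd <- reaction_bounds(tpl, chain_expr(), "C1")
  A <- adjacency_from_edges(c("zz1", "zz2"), list(c("zz1", "zz2")))
  expect_warning(R <- build_pair_set(as_network(A), tpl, bnd), "no overlap")
  expect_equal(nrow(R), 0)
})
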