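# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Tiny 3-metabolite / 4-reaction model as tabular text.
tiny_model_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "#objective r_bio",
    "#formula glc=C6H12O6",
    "#formula nh4=NH4",
    "#formula b=R",
    "reaction\tequation\tlower\tupper\tgpr\tsubsystem",
    "EX_glc\tglc ->\t-10\t10\t\tExchange",
    "r1\tglc -> a\t0\t10\t(G1 AND G2) OR G3\tCore",
    "r2\ta <=> b\t-10\t10\tg4\tCore",
    "r_bio\tb ->\t0\t10\tg5\tBiomass"
  ), path)
  path
}

tiny_model <- function() read_model_tsv(tiny_model_tsv())

# Linear chain EX -> A -> B -> biomass; per-reaction genes so expression
# bounds are controllable. Capacities set through the expression table.
chain_fixture <- function() {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "#objective BIO",
    "#formula glc=C6H12O6",
    "#formula b=R",
    "reaction\tequation\tlower\tupper\tgpr\tsubsystem",
    "EX_glc\tglc ->\t-1000\t1000\t\tExchange",
    "S1\tglc -> a\t0\t1000\tgs1\tChain",
    "S2\ta -> b\t0\t1000\tgs2\tChain",
    "BIO\tb ->\t0\t1000\tgb\tBiomass"
  ), tsv)
  read_model_tsv(tsv)
}

chain_expr <- function(gs1 = 2, gs2 = 7, gb = 1000) {
  tibble::tibble(gene = c("gs1", "gs2", "gb"),
                 C1 = c(gs1, gs2, gb),
                 C2 = c(gs1, gs2, gb) * 1.5,
                 C3 = c(gs1, gs2, gb) * 0.5)
}

# Two parallel routes with capacities 3 and 4 feeding biomass.
parallel_fixture <- function() {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "#objective BIO",
    "#formula glc=C6H12O6",
    "#formula x=R",
    "reaction\tequation\tlower\tupper\tgpr\tsubsystem",
    "EX_glc\tglc ->\t-1000\t1000\t\tExchange",
    "RA\tglc -> x\t0\t1000\tga\tRoutes",
    "RB\tglc -> x\t0\t1000\tgb2\tRoutes",
    "BIO\tx ->\t0\t1000\tgbio\tBiomass"
  ), tsv)
  read_model_tsv(tsv)
}

parallel_expr <- function(ga = 3, gb2 = 4, gbio = 1000) {
  tibble::tibble(gene = c("ga", "gb2", "gbio"),
                 C1 = c(ga, gb2, gbio),
                 C2 = c(ga, gb2, gbio) * 2,
                 C3 = c(ga, gb2, gbio) * 0.9)
}

# Wrap a bare adjacency matrix into a network object.
as_network <- function(A) {
  structure(list(genes = rownames(A), adjacency = A, threshold = NULL,
                 diagnostics = NULL), class = "coexpression_network")
}

adjacency_from_edges <- function(genes, edges) {
  A <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (e in edges) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  A
}

# Feasibility checks every solution must satisfy (mass balance, bounds,
# complementarity, q-range, biomass pinning).
expect_feasible <- function(sol, alpha = 1) {
  prob <- sol$problem
  tpl <- prob$template
  v <- sol$v_bar
  resid <- max(abs(tpl$S_bar %*% v))
  expect_lte(resid, 1e-6 * (1 + max(abs(v))))
  expect_true(all(v >= -1e-9))
  expect_true(all(v <= prob$bounds$f + 1e-9))
  if (nrow(tpl$rev_pairs)) {
    comp <- apply(tpl$rev_pairs, 1, function(p) min(v[p[1]], v[p[2]]))
    expect_lte(max(comp), 1e-6)
  }
  mapped <- prob$bounds$mapped & prob$bounds$M > 0
  expect_true(all(sol$q[mapped] >= 1 - 1e-9))
  expect_true(all(sol$q[mapped] <= 2 + 1e-9))
  if (alpha == 1) {
    expect_lte(abs(sol$biomass - sol$z_star), 1e-6 * (1 + sol$z_star))
  } else {
    expect_gte(sol$biomass, alpha * sol$z_star - 1e-6 * (1 + sol$z_star))
  }
}
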