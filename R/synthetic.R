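# Self-contained synthetic fixtures: toy metabolic models with per-reaction
# genes, and block-correlated expression matrices emulating groups of
# co-regulated genes observed across multiple conditions.

#' Specify a synthetic toy system
#'
#' @param n_pathways number of parallel linear pathways from the carbon
#'   source to the biomass precursor.
#' @param pathway_length reactions per pathway.
#' @param n_conditions number of expression conditions N (>= 3 for network
#'   construction; N = 2 is allowed and degenerate — every non-constant
#'   gene pair has |r| = 1).
#' @param block_correlation target within-block Pearson correlation in
#'   (0, 1); sets the default noise level.
#' @param noise_sd Gaussian noise standard deviation on the latent scale;
#'   default derived from `block_correlation` (two genes sharing a latent
#'   profile with additive noise sd `s` correlate at `1/(1+s^2)` in
#'   expectation).
#' @param seed RNG seed; every stochastic step in the generators derives
#'   from it.
#' @return An object of class `toy_spec`.
#' @export
toy_spec <- function(n_pathways = 2, pathway_length = 2, n_conditions = 8,
                     block_correlation = 0.9, noise_sd = NULL, seed = 1) {
  stopifnot(n_pathways >= 1, pathway_length >= 1, n_conditions >= 2,
            block_correlation > 0, block_correlation < 1)
  if (is.null(noise_sd)) {
    noise_sd <- 0.9 * sqrt(1 / block_correlation - 1)
  }
  structure(list(n_pathways = n_pathways, pathway_length = pathway_length,
                 n_conditions = n_conditions,
                 block_correlation = block_correlation,
                 noise_sd = noise_sd, seed = seed),
            class = "toy_spec")
}

#' Generate a toy metabolic model
#'
#' Builds a glucose-uptake exchange, `n_pathways` parallel linear pathways
#' of `pathway_length` reactions converging on a biomass precursor `X`, and
#' an irreversible biomass sink. Every internal reaction carries a unique
#' gene (`g_A1`, `g_A2`, ..., biomass `g_bio`); the second step of pathway
#' A (or its only step) is reversible, so the split template always has
#' exactly one reversible pair beyond the exchange. Construction is
#' deterministic.
#'
#' @param spec a [toy_spec()].
#' @param dir optional directory; when given, the model is also written as
#'   `toy_model.xml` (SBML L3+FBC) and `toy_model.tsv` (tabular fixture
#'   format).
#' @return A [metabolic_model()]; written file paths in attribute `files`.
#' @export
gen_toy_model <- function(spec, dir = NULL) {
  letters_p <- LETTERS[seq_len(spec$n_pathways)]
  L <- spec$pathway_length
  rows <- list()
  add <- function(id, eq, lo, hi, gpr, subsystem) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      reaction = id, equation = eq, lower = lo, upper = hi,
      gpr = gpr, subsystem = subsystem)
  }
  add("EX_glc", "glc_e ->", -1000, 1000, "", "Exchange")
  for (p in letters_p) {
    for (s in seq_len(L)) {
      from <- if (s == 1) "glc_e" else paste0("M_", p, s - 1)
      to <- if (s == L) "X" else paste0("M_", p, s)
      rev <- p == "A" && s == min(2L, L)
      add(paste0("P_", p, s), paste(from, if (rev) "<=>" else "->", to),
          if (rev) -1000 else 0, 1000,
          paste0("g_", p, s), paste("Pathway", p))
    }
  }
  add("BIOMASS", "X ->", 0, 1000, "g_bio", "Biomass")
  tab <- dplyr::bind_rows(rows)
  parsed <- lapply(tab$equation, parse_equation)
  mets <- sort_c(unique(unlist(lapply(parsed, names))))
  S <- matrix(0, length(mets), nrow(tab), dimnames = list(mets, tab$reaction))
  for (j in seq_along(parsed)) S[names(parsed[[j]]), j] <- parsed[[j]]
  model <- metabolic_model(S, tab$lower, tab$upper, tab$gpr, tab$subsystem,
                           objective = "BIOMASS",
                           metabolite_formulas = c(glc_e = "C6H12O6", X = "R"))
  files <- character(0)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    xml <- file.path(dir, "toy_model.xml")
    tsv <- file.path(dir, "toy_model.tsv")
    write_sbml(model, xml)
    writeLines(c("#objective BIOMASS", "#formula glc_e=C6H12O6",
                 "#formula X=R",
                 paste(names(tab), collapse = "\t"),
                 apply(tab, 1, paste, collapse = "\t")), tsv)
    files <- c(sbml = xml, tsv = tsv)
  }
  attr(model, "files") <- files
  model
}

#' Gene ids of a toy model
#' @param model a toy [metabolic_model()].
#' @return Character vector of gene ids in reaction order.
#' @export
toy_genes <- function(model) {
  unique(unlist(lapply(model$reactions$gpr,
                       function(g) gpr_genes(parse_gpr(g)))))
}

#' Generate a block-correlated expression matrix
#'
#' Each block of genes shares one latent condition profile; a gene's values
#' are an affine transform of its block's latent plus Gaussian noise, and
#' the whole matrix is shifted to nonnegativity (a shift leaves Pearson
#' correlations untouched). With `noise_sd = 0`, within-block correlations
#' are exactly 1; independent latents keep between-block correlations low.
#'
#' @param spec a [toy_spec()] (supplies `n_conditions`, `noise_sd`,
#'   `seed`).
#' @param genes character vector of gene ids.
#' @param blocks block assignment: named vector/list gene -> block label;
#'   blocks must partition `genes`.
#' @param gene_scale optional named multipliers applied to individual
#'   genes' rows (shifting a gene's dynamic range without changing its
#'   correlations' sign structure).
#' @return A tibble: `gene` column plus condition columns `C1..CN`.
#' @export
gen_expression <- function(spec, genes, blocks, gene_scale = NULL) {
  N <- spec$n_conditions
  if (N < 2) stop("need at least 2 conditions")
  blocks <- unlist(blocks)
  if (!setequal(names(blocks), genes)) {
    stop("blocks must assign every gene exactly once")
  }
  set.seed(spec$seed)
  labels <- unique(blocks)
  latents <- lapply(stats::setNames(labels, labels),
                    function(b) stats::rnorm(N, mean = 0, sd = 1))
  vals <- matrix(0, length(genes), N,
                 dimnames = list(genes, paste0("C", seq_len(N))))
  for (g in genes) {
    a <- stats::runif(1, 0.8, 1.2)
    b <- stats::runif(1, -0.5, 0.5)
    vals[g, ] <- a * latents[[blocks[[g]]]] + b +
      stats::rnorm(N, 0, spec$noise_sd)
  }
  vals <- vals - min(vals) + 1 # shift to strictly positive expression
  vals <- vals * 5             # plausible transcript-abundance scale
  if (!is.null(gene_scale)) {
    for (g in intersect(names(gene_scale), genes)) {
      vals[g, ] <- vals[g, ] * gene_scale[[g]]
    }
  }
  tibble::as_tibble(cbind(tibble::tibble(gene = genes),
                          tibble::as_tibble(vals)))
}

#' The two-pathway branch fixture
#'
#' The package's parameter-recovery fixture: two parallel pathways of equal
#' capacity feed biomass, so mass balance alone cannot decide the split;
#' the co-expression signal can. Pathway A's genes share a block with the
#' biomass gene, pathway B's genes form their own block. The biomass gene's
#' expression is halved so the biomass demand — not pathway capacity — is
#' the bottleneck, leaving the split between pathways free for the network
#' to resolve. The ground-truth flux pattern routes everything through
#' pathway A.
#'
#' @param spec a [toy_spec()]; `n_pathways` is forced to 2.
#' @return A list: `model`, `expr` (expression tibble), `blocks`, and
#'   `truth` (named ground-truth net-flux pattern, biomass-normalized).
#' @export
branch_fixture <- function(spec = toy_spec()) {
  spec$n_pathways <- 2
  model <- gen_toy_model(spec)
  genes <- toy_genes(model)
  blocks <- stats::setNames(
    ifelse(grepl("^g_B", genes), "blockB", "blockA"), genes)
  expr <- gen_expression(spec, genes, blocks,
                         gene_scale = c(g_bio = 0.5))
  truth <- stats::setNames(numeric(nrow(model$reactions)),
                           model$reactions$id)
  truth["EX_glc"] <- -1
  truth[grep("^P_A", names(truth))] <- 1
  truth["BIOMASS"] <- 1
  list(model = model, expr = expr, blocks = blocks, truth = truth)
}

#' Accuracy of the pipeline versus the number of expression conditions
#'
#' Condition-count robustness experiment on the branch fixture: for each
#' number of conditions `N`, co-expression networks are built from `n_reps`
#' replicate expression draws, the pipeline is run, and the prediction is
#' scored against the fixture's ground-truth flux pattern with the
#' uncentered Pearson correlation. Averaging over replicate draws mirrors
#' assembling networks from different dataset combinations of the same
#' size; a Pearson network built from very few conditions is noisy (at
#' N = 2 it is fully connected and uninformative), so mean accuracy is
#' expected to rise with N.
#'
#' @param n_conditions integer vector of condition counts to test.
#' @param n_reps replicate expression draws per condition count (the
#'   default 50 keeps the Monte Carlo error of each mean well below the
#'   accuracy differences between adjacent condition counts).
#' @param seed base seed; replicate seeds derive from it deterministically.
#' @param spec base [toy_spec()] for the fixture (its `n_conditions` and
#'   `seed` are overridden per replicate).
#' @param threshold,n_starts passed to [run_toy_pipeline()].
#' @return A tibble (n_conditions, rep, accuracy) with the per-N means in
#'   attribute `summary`.
#' @export
robustness_curve <- function(n_conditions = c(3, 5, 10, 20), n_reps = 50,
                             seed = 0, spec = toy_spec(),
                             threshold = 0.7, n_starts = 4) {
  n_conditions <- sort(n_conditions)
  N_max <- max(n_conditions)
  rows <- list()
  for (r in seq_len(n_reps)) {
    # one master dataset per replicate; each N uses its first N conditions,
    # mirroring networks assembled from subsets of one expression compendium
    sp <- spec
    sp$n_conditions <- N_max
    sp$seed <- (seed + 104729L * r) %% .Machine$integer.max
    fx <- branch_fixture(sp)
    for (N in n_conditions) {
      fxN <- fx
      fxN$expr <- fx$expr[, c(1, 1 + seq_len(N))]
      sol <- suppressWarnings(
        run_toy_pipeline(fxN, threshold = threshold, n_starts = n_starts,
                         seed = sp$seed))
      acc <- uncentered_pearson(unname(sol$net_flux[names(fx$truth)]),
                                fx$truth)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_conditions = N, rep = r, accuracy = acc)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "summary") <- dplyr::summarise(
    dplyr::group_by(out, .data$n_conditions),
    mean_accuracy = mean(.data$accuracy), .groups = "drop")
  out
}

#' Run the full pipeline on a toy fixture
#'
#' Convenience wrapper chaining template construction, expression bounds,
#' network binarization (at a fixed threshold — toy gene sets are far too
#' small for scale-free threshold selection), pair lifting and the
#' co-activation solve for one condition.
#'
#' @param fixture a list with `model` and `expr` (e.g. [branch_fixture()]).
#' @param condition condition label (default the first).
#' @param threshold correlation threshold for the toy network.
#' @param mode,alpha,n_starts,seed passed through.
#' @return The `icon_solution`, with the problem reachable via
#'   `$problem`.
#' @export
run_toy_pipeline <- function(fixture, condition = "C1", threshold = 0.7,
                             mode = "DC", alpha = 1, n_starts = 10,
                             seed = 0) {
  tpl <- build_template(fixture$model, mode = mode,
                        carbon_source = "EX_glc",
                        T = default_T(fixture$expr))
  bnd <- reaction_bounds(tpl, fixture$expr, condition)
  C <- correlation_matrix(fixture$expr)
  A <- binarize(C, threshold)
  net <- structure(list(genes = rownames(A), adjacency = A,
                        threshold = threshold, diagnostics = NULL),
                   class = "coexpression_network")
  pairs <- build_pair_set(net, tpl, bnd)
  prob <- icon_problem(tpl, bnd, pairs, alpha = alpha)
  solve_icon(prob, n_starts = n_starts, seed = seed)
}
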