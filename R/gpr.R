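#' Parse a gene-protein-reaction rule
#'
#' Recursive-descent parser for boolean GPR strings over gene identifiers
#' with `and`, `or` (case-insensitive) and parentheses. `and` binds tighter
#' than `or`, matching the convention of constraint-based modeling tools.
#'
#' @param gpr the rule string; `""` (no gene association) returns `NULL`.
#' @return A tree of nested lists: internal nodes `list(op = "and"|"or",
#'   args = list(...))`, leaves `list(gene = "<id>")`; or `NULL` for the
#'   empty rule.
#' @export
parse_gpr <- function(gpr) {
  gpr <- trimws(gpr)
  if (!nzchar(gpr) || is.na(gpr)) return(NULL)
  toks <- regmatches(gpr, gregexpr("\\(|\\)|[^()\\s]+", gpr, perl = TRUE))[[1]]
  pos <- 0L
  peek <- function() if (pos < length(toks)) toks[pos + 1L] else NA_character_
  advance <- function() { pos <<- pos + 1L; toks[pos] }
  fail <- function(msg) stop("GPR parse error at token ", pos + 1L, " ('",
                             peek(), "') in \"", gpr, "\": ", msg)

  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance(); args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance(); args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) fail("unexpected end of rule")
    if (t == "(") {
      advance()
      node <- parse_or()
      if (is.na(peek()) || peek() != ")") fail("expected ')'")
      advance()
      return(node)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) fail("expected a gene id")
    advance()
    list(gene = t)
  }
  tree <- parse_or()
  if (!is.na(peek())) fail("trailing input")
  tree
}

#' Genes referenced by a GPR tree
#' @param tree a tree from [parse_gpr()].
#' @return Character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (!is.null(tree$gene)) return(tree$gene)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Evaluate a GPR tree into an expression-derived flux bound
#'
#' E-flux style: an `and` node (enzyme complex) takes the minimum of its
#' children — capacity is limited by the scarcest subunit; an `or` node
#' (isoenzymes) takes the sum (or the maximum with `or_rule = "max"`). A
#' leaf contributes its gene's expression value, with the identity map
#' `f(g) = g`. Genes missing from `expr` are unmeasured and are dropped
#' from their parent node; a rule that is entirely unmeasured — or the empty
#' rule — evaluates to the unconstrained bound `T`.
#'
#' @param tree a tree from [parse_gpr()] (or `NULL`).
#' @param expr named numeric vector of nonnegative expression values.
#' @param T unconstrained-bound sentinel.
#' @param or_rule `"sum"` (default) or `"max"`.
#' @return A single nonnegative bound.
#' @export
eval_gpr_bound <- function(tree, expr, T, or_rule = c("sum", "max")) {
  or_rule <- match.arg(or_rule)
  if (any(expr < 0, na.rm = TRUE)) {
    stop("negative expression value; clean the expression table first")
  }
  v <- eval_gpr_rec(tree, expr, or_rule)
  if (is.na(v)) T else v
}

eval_gpr_rec <- function(tree, expr, or_rule) {
  if (is.null(tree)) return(NA_real_)
  if (!is.null(tree$gene)) {
    if (tree$gene %in% names(expr)) return(unname(expr[[tree$gene]]))
    return(NA_real_) # unmeasured leaf: dropped by the parent
  }
  vals <- vapply(tree$args, eval_gpr_rec, numeric(1), expr = expr,
                 or_rule = or_rule)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  if (tree$op == "and") min(vals)
  else if (or_rule == "sum") sum(vals) else max(vals)
}

#' Expression-derived flux bounds for one condition
#'
#' Evaluates every template column's GPR under the chosen condition to get
#' the E-flux upper bound `f`, and under every condition to get the
#' per-column maximum `M` used by the q-transform `q = 1 + v/M`. Forward and
#' backward siblings of a reversible reaction share `f` and `M`. Columns
#' with no (or fully unmeasured) GPR are unmapped and take the
#' unconstrained bound `T`.
#'
#' @param template an `icon_template` from [build_template()].
#' @param expr expression table: first column gene id, remaining columns one
#'   per condition.
#' @param condition condition label (a column name of `expr`).
#' @param or_rule passed to [eval_gpr_bound()].
#' @return An object of class `reaction_bounds`: a tibble (column, reaction,
#'   direction, f, M, mapped) with attributes `condition` and `T`.
#' @export
reaction_bounds <- function(template, expr, condition,
                            or_rule = c("sum", "max")) {
  or_rule <- match.arg(or_rule)
  conds <- setdiff(names(expr), names(expr)[1])
  if (!condition %in% conds) {
    stop("condition '", condition, "' not found; available: ",
         paste(conds, collapse = ", "))
  }
  T <- template$T
  genes <- expr[[1]]
  trees <- lapply(template$columns$gpr, parse_gpr)
  per_cond <- function(cond) {
    ev <- stats::setNames(as.numeric(expr[[cond]]), genes)
    vapply(trees, function(tr) {
      v <- eval_gpr_rec(tr, ev, or_rule)
      if (is.na(v)) NA_real_ else v
    }, numeric(1))
  }
  f_raw <- per_cond(condition)
  M_raw <- do.call(pmax, c(lapply(conds, per_cond), na.rm = TRUE))
  mapped <- !is.na(f_raw)
  out <- tibble::tibble(
    column = template$columns$column,
    reaction = template$columns$reaction,
    direction = template$columns$direction,
    f = ifelse(mapped, f_raw, T),
    M = ifelse(mapped, M_raw, T),
    mapped = mapped
  )
  structure(out, condition = condition, T = T,
            class = c("reaction_bounds", class(out)))
}

#' Lift co-expression edges to the reaction-pair set R
#'
#' Every gene-gene edge of the network becomes the set of unordered template
#' column pairs (i, j) where one endpoint's gene appears in column i's GPR
#' and the other endpoint's in column j's. Self-pairs, pairs of
#' forward/backward siblings of the same reversible reaction (the `Rev`
#' set), unmapped columns and columns with `M = 0` never enter R.
#'
#' @param network a `coexpression_network` (or a binary adjacency matrix
#'   with dimnames).
#' @param template an `icon_template`.
#' @param bounds a `reaction_bounds` table for any condition (supplies the
#'   mapped / `M > 0` filter, which is condition-independent).
#' @return An object of class `reaction_pairs`: tibble (i, j) of column
#'   index pairs with a `provenance` attribute tibble (gene_a, gene_b, i, j).
#' @export
build_pair_set <- function(network, template, bounds) {
  A <- as_adjacency(network)
  genes <- intersect(rownames(A), unique(unlist(
    lapply(template$columns$gpr, function(g) gpr_genes(parse_gpr(g))))))
  eligible <- bounds$column[bounds$mapped & bounds$M > 0]
  gene_cols <- lapply(stats::setNames(genes, genes), function(g) {
    hits <- which(vapply(template$columns$gpr, function(rule) {
      nzchar(rule) && g %in% gpr_genes(parse_gpr(rule))
    }, logical(1)))
    intersect(hits, eligible)
  })
  if (!length(genes)) {
    warning("no overlap between network genes and model genes; ",
            "R is empty and the solve degenerates to an E-flux-feasible point")
  }
  ut <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  rev_key <- character(0)
  if (nrow(template$rev_pairs)) {
    rev_key <- paste(pmin(template$rev_pairs[, 1], template$rev_pairs[, 2]),
                     pmax(template$rev_pairs[, 1], template$rev_pairs[, 2]))
  }
  prov <- list()
  for (e in seq_len(nrow(ut))) {
    ga <- rownames(A)[ut[e, 1]]; gb <- rownames(A)[ut[e, 2]]
    ca <- gene_cols[[ga]]; cb <- gene_cols[[gb]]
    if (is.null(ca) || is.null(cb) || !length(ca) || !length(cb)) next
    grid <- expand.grid(i = ca, j = cb)
    grid <- grid[grid$i != grid$j, , drop = FALSE]
    if (!nrow(grid)) next
    prov[[length(prov) + 1L]] <- tibble::tibble(
      gene_a = ga, gene_b = gb,
      i = pmin(grid$i, grid$j), j = pmax(grid$i, grid$j))
  }
  prov <- if (length(prov)) dplyr::bind_rows(prov) else
    tibble::tibble(gene_a = character(0), gene_b = character(0),
                   i = integer(0), j = integer(0))
  prov <- prov[!(paste(prov$i, prov$j) %in% rev_key), , drop = FALSE]
  pairs <- dplyr::distinct(prov[, c("i", "j")])
  structure(pairs, provenance = prov,
            class = c("reaction_pairs", class(pairs)))
}
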