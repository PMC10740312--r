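#' Construct a metabolic model object
#'
#' A `metabolic_model` is the package's in-memory form of a constraint-based
#' (stoichiometric) model: an m x n stoichiometric matrix `S`, per-reaction
#' flux bounds, gene-protein-reaction (GPR) rules, subsystem labels and a
#' designated objective (biomass) reaction. Reactions whose column touches a
#' single metabolite are flagged as boundary exchanges.
#'
#' @param S numeric matrix, metabolites x reactions, with dimnames.
#' @param lower,upper numeric vectors of flux bounds, one per reaction.
#' @param gpr character vector of GPR boolean strings (`""` = no genes).
#' @param subsystem character vector of subsystem labels (`""` allowed).
#' @param objective id of the objective (biomass) reaction.
#' @param metabolite_formulas named character vector of chemical formulas
#'   (names = metabolite ids); missing entries allowed.
#'
#' @return An object of class `metabolic_model` with components `S`,
#'   `reactions` (a tibble: id, lower, upper, gpr, subsystem, exchange),
#'   `metabolites` (a tibble: id, formula) and `objective`.
#' @export
metabolic_model <- function(S, lower, upper, gpr = NULL, subsystem = NULL,
                            objective, metabolite_formulas = NULL) {
  stopifnot(is.matrix(S), !is.null(rownames(S)), !is.null(colnames(S)))
  n <- ncol(S)
  m <- nrow(S)
  if (is.null(gpr)) gpr <- rep("", n)
  if (is.null(subsystem)) subsystem <- rep("", n)
  stopifnot(length(lower) == n, length(upper) == n,
            length(gpr) == n, length(subsystem) == n)
  if (any(lower > upper)) {
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(colnames(S)[lower > upper], collapse = ", "))
  }
  if (!objective %in% colnames(S)) {
    stop("objective reaction '", objective, "' is not in the model; ",
         "name one of: ", paste(utils::head(colnames(S), 5), collapse = ", "),
         " ...")
  }
  formulas <- rep(NA_character_, m)
  names(formulas) <- rownames(S)
  if (!is.null(metabolite_formulas)) {
    hit <- intersect(names(metabolite_formulas), rownames(S))
    formulas[hit] <- unname(metabolite_formulas[hit])
  }
  exchange <- colSums(S != 0) == 1L
  out <- structure(list(
    S = S,
    reactions = tibble::tibble(
      id = colnames(S), lower = as.numeric(lower), upper = as.numeric(upper),
      gpr = normalize_gpr(gpr), subsystem = subsystem,
      exchange = unname(exchange)
    ),
    metabolites = tibble::tibble(id = rownames(S), formula = unname(formulas)),
    objective = objective
  ), class = "metabolic_model")
  out
}

normalize_gpr <- function(x) {
  x <- ifelse(is.na(x), "", x)
  x <- gsub("\\bAND\\b", "and", x, ignore.case = TRUE)
  x <- gsub("\\bOR\\b", "or", x, ignore.case = TRUE)
  trimws(x)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$S), " metabolites x ", ncol(x$S),
      " reactions\n", sep = "")
  cat("  objective: ", x$objective, "\n", sep = "")
  cat("  exchanges: ", sum(x$reactions$exchange),
      ", reversible: ", sum(x$reactions$lower < 0 & x$reactions$upper > 0),
      "\n", sep = "")
  invisible(x)
}

#' Tabular view of a metabolic model's reactions
#'
#' @param x a `metabolic_model`.
#' @param ... unused.
#' @return A tibble with one row per reaction.
#' @export
tidy.metabolic_model <- function(x, ...) x$reactions

#' Read a model from the tabular fixture format
#'
#' A plain TSV with columns `reaction`, `equation`, `lower`, `upper`, `gpr`,
#' `subsystem`. Equations use ` + ` between terms, optional numeric
#' coefficients, and `<=>` (reversible) or `->` (irreversible) arrows; a
#' one-sided equation (e.g. `"glc_e ->"`) defines a boundary exchange.
#' Metabolite formulas may be declared in `#formula met=CH2O`-style header
#' comment lines.
#'
#' @param path file path.
#' @param objective objective reaction id; defaults to the reaction named
#'   in a `#objective` header line, else errors.
#' @return A [metabolic_model()].
#' @export
read_model_tsv <- function(path, objective = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  formulas <- character(0)
  for (h in grep("^#formula\\s", hdr, value = TRUE)) {
    kv <- strsplit(trimws(sub("^#formula\\s+", "", h)), "=")[[1]]
    formulas[kv[1]] <- kv[2]
  }
  obj_line <- grep("^#objective\\s", hdr, value = TRUE)
  if (is.null(objective) && length(obj_line)) {
    objective <- trimws(sub("^#objective\\s+", "", obj_line[1]))
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("reaction", "equation", "lower", "upper")
  if (!all(need %in% names(tab))) {
    stop("model TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$gpr)) tab$gpr <- ""
  if (is.null(tab$subsystem)) tab$subsystem <- ""
  parsed <- lapply(tab$equation, parse_equation)
  mets <- sort_c(unique(unlist(lapply(parsed, names))))
  S <- matrix(0, length(mets), nrow(tab),
              dimnames = list(mets, tab$reaction))
  for (j in seq_along(parsed)) S[names(parsed[[j]]), j] <- parsed[[j]]
  if (is.null(objective)) {
    stop("no objective reaction: add a '#objective <id>' header line or ",
         "pass `objective=`")
  }
  metabolic_model(S, tab$lower, tab$upper, tab$gpr, tab$subsystem,
                  objective, metabolite_formulas = formulas)
}

# "a + 2 b <=> c" -> named coefficient vector (reactants negative)
parse_equation <- function(eq) {
  arrow <- if (grepl("<=>|<->", eq)) "<=>|<->" else "->"
  sides <- strsplit(eq, arrow)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  coefs <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    out <- numeric(0)
    for (term in trimws(strsplit(side, "\\+")[[1]])) {
      if (!nzchar(term)) next
      toks <- strsplit(term, "\\s+")[[1]]
      if (length(toks) == 2L) {
        out[toks[2]] <- sign * as.numeric(toks[1])
      } else {
        out[toks[1]] <- sign * 1
      }
    }
    out
  }
  lhs <- coefs(sides[1], -1)
  rhs <- coefs(sides[2], +1)
  both <- intersect(names(lhs), names(rhs))
  for (b in both) { rhs[b] <- rhs[b] + lhs[b]; lhs <- lhs[setdiff(names(lhs), b)] }
  c(lhs, rhs)
}
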