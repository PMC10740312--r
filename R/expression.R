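#' Clean a raw expression table
#'
#' Prepares a gene x condition expression table for network construction:
#' rows of duplicated gene ids are averaged; genes with any missing value
#' are removed; extreme entries are winsorized per gene at
#' `median +/- 5 * MAD` (a conservative, deterministic outlier fence).
#' Every action is recorded in the `cleaning_log` attribute.
#'
#' @param raw a data frame whose first column is the gene id and remaining
#'   columns are numeric expression values (one per condition).
#' @param mad_mult multiplier of the MAD fence (default 5).
#' @return A tibble (gene + condition columns) with attribute
#'   `cleaning_log`, a tibble of (gene, action, detail) records.
#' @export
clean_expression <- function(raw, mad_mult = 5) {
  if (ncol(raw) < 3L) {
    stop("expression table needs a gene column plus >= 2 conditions")
  }
  gene_col <- names(raw)[1]
  log <- list()
  note <- function(gene, action, detail = "") {
    log[[length(log) + 1L]] <<- tibble::tibble(
      gene = gene, action = action, detail = detail)
  }
  tab <- tibble::as_tibble(raw)
  dup <- unique(tab[[1]][duplicated(tab[[1]])])
  if (length(dup)) {
    for (g in dup) note(g, "averaged_duplicates",
                        paste(sum(tab[[1]] == g), "rows"))
    tab <- dplyr::summarise(
      dplyr::group_by(tab, !!rlang::sym(gene_col)),
      dplyr::across(dplyr::everything(), ~ mean(.x, na.rm = FALSE)),
      .groups = "drop")
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  has_na <- rowSums(is.na(vals)) > 0
  for (g in tab[[1]][has_na]) note(g, "removed_missing")
  tab <- tab[!has_na, , drop = FALSE]
  vals <- vals[!has_na, , drop = FALSE]
  if (any(vals < 0)) {
    stop("negative expression values are not supported")
  }
  for (i in seq_len(nrow(vals))) {
    med <- stats::median(vals[i, ])
    fence <- mad_mult * stats::mad(vals[i, ])
    hi <- vals[i, ] > med + fence
    lo <- vals[i, ] < med - fence
    if (any(hi) || any(lo)) {
      note(tab[[1]][i], "winsorized",
           sprintf("%d value(s) clipped to median +/- %g*MAD",
                   sum(hi) + sum(lo), mad_mult))
      vals[i, hi] <- med + fence
      vals[i, lo] <- pmax(med - fence, 0)
    }
  }
  out <- tibble::as_tibble(cbind(tab[, 1, drop = FALSE],
                                 tibble::as_tibble(vals)))
  attr(out, "cleaning_log") <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(gene = character(0), action = character(0),
                   detail = character(0))
  out
}

#' Pearson correlation matrix across conditions
#'
#' Computes the gene-by-gene Pearson correlation over conditions. Rows with
#' zero variance have no defined correlation; their entries are set to 0
#' with a warning (a constant gene never supports an edge). With only two
#' conditions every non-constant pair has |r| = 1, which is flagged.
#'
#' @param expr cleaned expression table (first column gene id).
#' @return Symmetric correlation matrix with unit diagonal, gene ids as
#'   dimnames.
#' @export
correlation_matrix <- function(expr) {
  vals <- as.matrix(expr[, -1, drop = FALSE])
  rownames(vals) <- expr[[1]]
  if (ncol(vals) < 2L) stop("need at least 2 conditions")
  if (ncol(vals) == 2L) {
    warning("only 2 conditions: all non-constant gene pairs have |r| = 1; ",
            "co-expression carries no information")
  }
  constant <- apply(vals, 1, stats::sd) == 0
  C <- suppressWarnings(stats::cor(t(vals)))
  if (any(constant)) {
    warning(sum(constant), " constant gene(s): correlations set to 0")
    C[constant, ] <- 0
    C[, constant] <- 0
  }
  diag(C) <- 1
  C
}
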