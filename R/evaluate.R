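#' Read a measured-to-model flux mapping specification
#'
#' TSV with columns `measured_id`, `mode` (`chain` or `parallel`) and
#' `steps`, a semicolon-separated list of model reaction ids, each
#' optionally prefixed `-` to flip its orientation toward the measured
#' product.
#'
#' @param path file path.
#' @return A tibble (measured_id, mode, steps list-column of tibbles with
#'   `reaction` and `sign`).
#' @export
read_flux_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("measured_id", "mode", "steps")
  if (!all(need %in% names(tab))) {
    stop("mapping spec must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$measured_id)) {
    stop("duplicate measured_id entries in mapping spec")
  }
  if (!all(tab$mode %in% c("chain", "parallel"))) {
    stop("mode must be 'chain' or 'parallel'")
  }
  steps <- lapply(strsplit(tab$steps, ";"), function(s) {
    s <- trimws(s)
    if (!length(s) || !any(nzchar(s))) stop("empty step list in mapping spec")
    tibble::tibble(reaction = sub("^-", "", s),
                   sign = ifelse(grepl("^-", s), -1, 1))
  })
  tibble::tibble(measured_id = tab$measured_id, mode = tab$mode,
                 steps = steps)
}

#' Map predicted fluxes onto measured reactions
#'
#' Applies the two reconciliation cases between model reactions and a
#' measured (13C-MFA) reaction: a `chain` entry — the measured conversion
#' runs through several sequential model reactions — takes the minimum
#' absolute net flux along the chain (an AND relationship: the pathway
#' carries no more than its narrowest step); a `parallel` entry — several
#' model reactions accomplish the same conversion — sums the (oriented,
#' signed) net fluxes of the alternatives (an OR relationship).
#'
#' @param map a mapping tibble from [read_flux_map()] (or built directly).
#' @param fluxes named numeric vector of predicted net fluxes by reaction
#'   id, or a data frame with columns `reaction` and `net_flux`.
#' @return Named numeric vector of mapped predicted fluxes in the order of
#'   the mapping entries.
#' @export
map_fluxes <- function(map, fluxes) {
  if (is.data.frame(fluxes)) {
    fluxes <- stats::setNames(fluxes$net_flux, fluxes$reaction)
  }
  vapply(seq_len(nrow(map)), function(e) {
    st <- map$steps[[e]]
    missing <- setdiff(st$reaction, names(fluxes))
    if (length(missing)) {
      stop("mapping entry '", map$measured_id[e],
           "' references unknown reaction(s): ",
           paste(missing, collapse = ", "))
    }
    v <- fluxes[st$reaction]
    if (map$mode[e] == "chain") min(abs(v)) else sum(st$sign * v)
  }, numeric(1)) |> stats::setNames(map$measured_id)
}

#' Uncentered Pearson correlation
#'
#' `R = (x' y) / (||x|| ||y||)`: the cosine of the angle between the two
#' vectors. Unlike the centered Pearson correlation it does not subtract
#' means, so it is invariant to positive rescaling but not to shifts —
#' which makes it the appropriate agreement score between flux vectors
#' measured in different units.
#'
#' @param x,y equal-length numeric vectors, each with at least one nonzero
#'   entry.
#' @return A number in \[-1, 1\].
#' @export
uncentered_pearson <- function(x, y) {
  if (length(x) != length(y) || !length(x)) {
    stop("vectors must have equal positive length")
  }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop("uncentered correlation is undefined for a zero vector")
  }
  max(-1, min(1, sum(x * y) / (nx * ny)))
}

#' Score predictions against measured fluxes
#'
#' Maps the predicted fluxes through the reconciliation spec and scores
#' them against the measurements with the uncentered Pearson correlation.
#'
#' @param map mapping tibble ([read_flux_map()]).
#' @param fluxes predicted net fluxes (named vector or data frame).
#' @param measured named numeric vector of measured fluxes by
#'   `measured_id`, or a data frame with columns `measured_id`, `value`.
#' @return A list: `R` (the correlation), and `table` (tibble measured_id,
#'   predicted, measured).
#' @export
predictive_accuracy <- function(map, fluxes, measured) {
  if (is.data.frame(measured)) {
    measured <- stats::setNames(measured$value, measured$measured_id)
  }
  vp <- map_fluxes(map, fluxes)
  missing <- setdiff(names(vp), names(measured))
  if (length(missing)) {
    stop("no measured value for: ", paste(missing, collapse = ", "))
  }
  vm <- measured[names(vp)]
  list(R = uncentered_pearson(vp, vm),
       table = tibble::tibble(measured_id = names(vp),
                              predicted = unname(vp),
                              measured = unname(vm)))
}

#' Module-level concordance of expression and flux
#'
#' For each co-expression module and condition: the mean expression of the
#' module's genes, and the mean absolute net flux of the reactions whose
#' GPR references at least one module gene. Both matrices are row-wise
#' min-max normalized to \[0, 1\]; the per-module Pearson correlation
#' between the two row patterns is the concordance score.
#'
#' @param modules named character vector gene -> module label
#'   ([detect_modules()]).
#' @param expr cleaned expression table (first column gene id).
#' @param flux_list named list (condition -> named net-flux vector or
#'   data frame with `reaction`, `net_flux`).
#' @param model a [metabolic_model()] supplying GPR rules.
#' @return A list of tibbles: `expression` and `flux` (module x condition,
#'   normalized), and `concordance` (module, r).
#' @export
module_concordance <- function(modules, expr, flux_list, model) {
  conds <- names(flux_list)
  stopifnot(length(conds) >= 2)
  mods <- sort_c(unique(modules))
  gene_ids <- expr[[1]]
  rx_genes <- lapply(model$reactions$gpr, function(g) gpr_genes(parse_gpr(g)))

  expr_mat <- matrix(NA_real_, length(mods), length(conds),
                     dimnames = list(mods, conds))
  flux_mat <- expr_mat
  for (mi in seq_along(mods)) {
    genes <- names(modules)[modules == mods[mi]]
    rows <- which(gene_ids %in% genes)
    rx <- which(vapply(rx_genes, function(g) length(intersect(g, genes)) > 0,
                       logical(1)))
    if (!length(rx)) {
      warning("module ", mods[mi], " maps to no reactions; flux row is NA")
    }
    for (ci in seq_along(conds)) {
      expr_mat[mi, ci] <- mean(as.matrix(expr[rows, conds[ci]]))
      fl <- flux_list[[ci]]
      if (is.data.frame(fl)) fl <- stats::setNames(fl$net_flux, fl$reaction)
      if (length(rx)) {
        flux_mat[mi, ci] <- mean(abs(fl[model$reactions$id[rx]]))
      }
    }
  }

  norm_rows <- function(M) {
    t(apply(M, 1, function(r) {
      if (all(is.na(r))) return(r)
      rng <- range(r)
      if (diff(rng) == 0) {
        warning("constant row pattern; normalized to 0")
        return(r * 0)
      }
      (r - rng[1]) / diff(rng)
    }))
  }
  en <- norm_rows(expr_mat); fn <- norm_rows(flux_mat)
  conc <- vapply(seq_along(mods), function(mi) {
    if (all(is.na(fn[mi, ])) || stats::sd(en[mi, ]) == 0 ||
        stats::sd(fn[mi, ]) == 0) return(NA_real_)
    stats::cor(en[mi, ], fn[mi, ])
  }, numeric(1))
  as_tb <- function(M) tibble::as_tibble(cbind(
    tibble::tibble(module = rownames(M)), tibble::as_tibble(M)))
  list(expression = as_tb(en), flux = as_tb(fn),
       concordance = tibble::tibble(module = mods, r = conc))
}
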