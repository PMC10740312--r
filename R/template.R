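#' Template flux bounds
#'
#' Rescales a reaction's bounds to the unit-free template convention: the
#' lower bound becomes `0` if it was nonnegative and `-T` otherwise; the
#' upper bound becomes `T` if it was positive and `0` otherwise. Only the
#' sign pattern of the original bounds survives, so the template model keeps
#' stoichiometry and reversibility while discarding flux units.
#'
#' @param lower,upper numeric vectors of original bounds (recycled
#'   componentwise).
#' @param T the "largest number" bound, a single positive value.
#' @return A list with numeric vectors `lower` and `upper`.
#' @export
template_bounds <- function(lower, upper, T) {
  if (!is.numeric(T) || length(T) != 1L || T <= 0) {
    stop("T must be a single positive number")
  }
  stopifnot(length(lower) == length(upper))
  list(lower = ifelse(lower >= 0, 0, -T),
       upper = ifelse(upper > 0, T, 0))
}

# Tokenize a chemical formula into element counts; distinguishes "C" from
# two-letter elements such as Ca, Cl, Co, Cu.
formula_elements <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(numeric(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula))[[1]]
  out <- numeric(0)
  for (t in toks) {
    el <- sub("[0-9.].*$", "", t)
    ct <- sub("^[A-Za-z]+", "", t)
    ct <- if (nzchar(ct)) as.numeric(ct) else 1
    out[el] <- (if (el %in% names(out)) out[el] else 0) + ct
  }
  out
}

#' Identify carbon-source exchange reactions
#'
#' Returns the boundary exchange reactions whose exchanged metabolite
#' contains at least one carbon atom, by element-token parsing of the
#' chemical formula (so `Ca`, `Cl`, `Co` do not count as carbon). Exchanges
#' whose metabolite has no recorded formula are skipped with a warning.
#'
#' @param model a [metabolic_model()].
#' @return Character vector of reaction ids.
#' @export
identify_carbon_exchanges <- function(model) {
  ex <- which(model$reactions$exchange)
  out <- character(0)
  skipped <- character(0)
  formulas <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  for (j in ex) {
    met <- rownames(model$S)[which(model$S[, j] != 0)]
    f <- formulas[[met]]
    if (is.na(f) || !nzchar(f)) { skipped <- c(skipped, model$reactions$id[j]); next }
    counts <- formula_elements(f)
    if ("C" %in% names(counts) && counts[["C"]] >= 1) {
      out <- c(out, model$reactions$id[j])
    }
  }
  if (length(skipped)) {
    warning("skipping exchange reaction(s) with no metabolite formula: ",
            paste(skipped, collapse = ", "))
  }
  out
}

#' Build an irreversible template model
#'
#' Applies the template bound rescaling to every reaction, opens carbon
#' uptake according to the chosen mode, and splits reversible reactions into
#' paired forward/backward irreversible columns. In `"DC"` (determined
#' carbon source) mode only the named carbon exchange(s) may take up carbon
#' (lower bound `-T`; every other carbon exchange's lower bound is closed to
#' 0); in `"AC"` (all possible carbon sources) mode every carbon exchange is
#' opened at `-T`. Non-carbon exchanges keep their template bounds, so a
#' previously open nutrient uptake (oxygen, ammonium, ...) stays open.
#'
#' @param model a [metabolic_model()].
#' @param mode `"DC"` or `"AC"`.
#' @param carbon_source reaction id(s) of the carbon uptake exchange(s);
#'   required in DC mode.
#' @param T the largest-number bound; see [default_T()].
#' @return An object of class `icon_template`: the split stoichiometric
#'   matrix `S_bar`, a `columns` tibble (column, reaction, direction,
#'   gpr, subsystem), objective indicator `c_bar`, `rev_pairs` (two-column
#'   matrix of forward/backward column indices), template bounds and
#'   bookkeeping.
#' @export
build_template <- function(model, mode = c("DC", "AC"), carbon_source = NULL,
                           T = 1000) {
  mode <- match.arg(mode)
  tb <- template_bounds(model$reactions$lower, model$reactions$upper, T)
  L_hat <- tb$lower; U_hat <- tb$upper
  carbons <- identify_carbon_exchanges(model)
  ids <- model$reactions$id
  if (mode == "DC") {
    if (is.null(carbon_source)) {
      stop("DC mode requires `carbon_source` naming the uptake exchange(s)")
    }
    missing <- setdiff(carbon_source, ids)
    if (length(missing)) {
      stop("unknown carbon_source reaction(s): ", paste(missing, collapse = ", "))
    }
    L_hat[match(carbons, ids)] <- 0
    L_hat[match(carbon_source, ids)] <- -T
  } else {
    L_hat[match(carbons, ids)] <- -T
  }
  sp <- split_reversible(model$S, L_hat, U_hat, model$objective)
  structure(list(
    base = model, mode = mode, T = T,
    L_hat = L_hat, U_hat = U_hat,
    S_bar = sp$S_bar,
    columns = tibble::tibble(
      column = seq_len(ncol(sp$S_bar)),
      reaction = sp$origin$reaction,
      direction = sp$origin$direction,
      gpr = model$reactions$gpr[match(sp$origin$reaction, ids)],
      subsystem = model$reactions$subsystem[match(sp$origin$reaction, ids)]
    ),
    c_bar = sp$c_bar,
    rev_pairs = sp$rev_pairs,
    carbon_exchanges = carbons
  ), class = "icon_template")
}

#' Split reversible reactions into irreversible column pairs
#'
#' Given template bounds, each reversible reaction (`L < 0 < U`) contributes
#' a forward column (the original stoichiometry) and a backward column (its
#' negation), both bounded in `[0, T]`; backward-only reactions (`U <= 0`)
#' become a single negated column; forward-only reactions are unchanged.
#' Columns are ordered irreversible first, then reversible-forward, then
#' reversible-backward.
#'
#' @param S stoichiometric matrix.
#' @param lower,upper template bounds.
#' @param objective objective reaction id.
#' @return List with `S_bar`, `origin` (tibble: reaction, direction),
#'   `rev_pairs` (matrix with columns `forward`, `backward`), `c_bar`.
#' @export
split_reversible <- function(S, lower, upper, objective) {
  n <- ncol(S)
  rev <- which(lower < 0 & upper > 0)
  bwd_only <- which(upper <= 0 & lower < 0)
  irr <- setdiff(seq_len(n), rev)
  cols <- list(); origin_rx <- character(0); origin_dir <- character(0)
  for (j in irr) {
    sgn <- if (j %in% bwd_only) -1 else 1
    cols[[length(cols) + 1L]] <- sgn * S[, j]
    origin_rx <- c(origin_rx, colnames(S)[j])
    origin_dir <- c(origin_dir, if (sgn < 0) "backward" else "irreversible")
  }
  for (j in rev) {
    cols[[length(cols) + 1L]] <- S[, j]
    origin_rx <- c(origin_rx, colnames(S)[j]); origin_dir <- c(origin_dir, "forward")
  }
  for (j in rev) {
    cols[[length(cols) + 1L]] <- -S[, j]
    origin_rx <- c(origin_rx, colnames(S)[j]); origin_dir <- c(origin_dir, "backward")
  }
  S_bar <- do.call(cbind, cols)
  rownames(S_bar) <- rownames(S)
  colnames(S_bar) <- ifelse(origin_dir == "irreversible", origin_rx,
                            paste0(origin_rx, "_", substr(origin_dir, 1, 1)))
  p <- length(rev)
  rev_pairs <- cbind(forward = length(irr) + seq_len(p),
                     backward = length(irr) + p + seq_len(p))
  if (p == 0L) rev_pairs <- matrix(integer(0), 0, 2,
                                   dimnames = list(NULL, c("forward", "backward")))
  list(S_bar = S_bar,
       origin = tibble::tibble(reaction = origin_rx, direction = origin_dir),
       rev_pairs = rev_pairs,
       c_bar = as.numeric(origin_rx == objective))
}

# Per-column template upper bounds of the split model (all lowers are 0).
template_upper <- function(template) {
  ids <- template$base$reactions$id
  j <- match(template$columns$reaction, ids)
  ifelse(template$columns$direction == "backward",
         -template$L_hat[j], template$U_hat[j])
}

#' Fold a split-space flux vector back to original reactions
#'
#' For a reversible reaction the net flux is forward minus backward; a
#' backward-only column is reported negative; irreversible columns pass
#' through. The result follows the base model's reaction order.
#'
#' @param template an `icon_template`.
#' @param v_bar nonnegative flux vector over the template's columns.
#' @return Named numeric vector of net fluxes, one per original reaction.
#' @export
fold_solution <- function(template, v_bar) {
  if (length(v_bar) != nrow(template$columns)) {
    stop("v_bar has length ", length(v_bar), " but the template has ",
         nrow(template$columns), " columns")
  }
  ids <- template$base$reactions$id
  out <- stats::setNames(numeric(length(ids)), ids)
  sgn <- ifelse(template$columns$direction == "backward", -1, 1)
  for (k in seq_along(v_bar)) {
    rx <- template$columns$reaction[k]
    out[rx] <- out[rx] + sgn[k] * v_bar[k]
  }
  out
}

# Lift a net-flux vector of the bounded model into the nonnegative split
# space (one-sided: min(forward, backward) = 0 by construction).
unfold_solution <- function(template, v) {
  ids <- template$base$reactions$id
  v <- v[match(template$columns$reaction, ids)]
  ifelse(template$columns$direction == "backward", pmax(-v, 0),
         ifelse(template$columns$direction == "forward", pmax(v, 0), v))
}

#' @export
print.icon_template <- function(x, ...) {
  cat("<icon_template> mode ", x$mode, ", T = ", x$T, "\n", sep = "")
  cat("  ", ncol(x$S_bar), " columns (", nrow(x$rev_pairs),
      " reversible pairs) over ", length(x$base$reactions$id),
      " reactions\n", sep = "")
  cat("  carbon exchanges: ",
      paste(x$carbon_exchanges, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default largest-number bound
#'
#' The template bound `T` must dominate every expression-derived flux bound
#' so that no data-driven constraint is clipped. The default is ten times
#' the largest expression value seen (floor 1000), or 1000 when no
#' expression table is given.
#'
#' @param expr optional expression table (first column gene id, remaining
#'   columns numeric condition values).
#' @return A single positive number.
#' @export
default_T <- function(expr = NULL) {
  if (is.null(expr)) return(1000)
  vals <- as.matrix(expr[, -1, drop = FALSE])
  max(1000, 10 * max(vals, na.rm = TRUE))
}
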