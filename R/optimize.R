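# E-flux LP, the co-activation quadratic program, and FVA flexibility.
#
# The QP maximizes sum over co-expressed reaction pairs (i,j) of q_i q_j,
# q_j = 1 + v_j / M_j, subject to mass balance S_bar v = 0, expression
# bounds 0 <= v <= f, a biomass requirement c_bar' v >= alpha z*, and
# per-pair complementarity on split reversible reactions. The objective is
# an indefinite quadratic, so its maximum sits on the boundary of the LP
# polytope; we ascend with Frank-Wolfe steps (linearize, solve an LP for a
# vertex, exact line search on the segment) from multiple starts, then
# enforce complementarity by loop cancellation plus a direction-fixing
# polish. The folded E-flux optimizer is always one start, so the returned
# objective never falls below E-flux's.

# ---- quadratic objective machinery -----------------------------------------

pair_structure <- function(pairs, bounds) {
  M <- bounds$M
  active <- bounds$mapped & M > 0
  w <- 1 / ifelse(active, M, Inf) # dq/dv; 0 for frozen columns
  nb <- vector("list", nrow(bounds))
  for (e in seq_len(nrow(pairs))) {
    i <- pairs$i[e]; j <- pairs$j[e]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  list(pairs = pairs, nb = nb, w = w, active = active)
}

q_transform <- function(v, bounds) {
  ifelse(bounds$mapped & bounds$M > 0, 1 + v / bounds$M, 1)
}

icon_objective <- function(v, ps, bounds) {
  if (!nrow(ps$pairs)) return(0)
  q <- q_transform(v, bounds)
  sum(q[ps$pairs$i] * q[ps$pairs$j])
}

icon_gradient <- function(v, ps, bounds) {
  g <- numeric(length(v))
  if (!nrow(ps$pairs)) return(g)
  q <- q_transform(v, bounds)
  for (k in which(lengths(ps$nb) > 0)) {
    g[k] <- ps$w[k] * sum(q[ps$nb[[k]]])
  }
  g
}

icon_curvature <- function(s, ps) {
  if (!nrow(ps$pairs)) return(0)
  si <- s * ps$w
  sum(si[ps$pairs$i] * si[ps$pairs$j])
}

# Frank-Wolfe ascent of linear' v + quadratic pair objective over the
# polytope {S v = 0, 0 <= v <= ub, c_bar' v >= rhs}.
fw_ascent <- function(v0, linear, ps, bounds, S, ub, c_bar, rhs,
                      max_iter = 100, tol = 1e-12) {
  v <- v0
  A2 <- matrix(c_bar, 1); b2 <- rhs
  obj <- function(x) sum(linear * x) + icon_objective(x, ps, bounds)
  cur <- obj(v)
  for (it in seq_len(max_iter)) {
    g <- linear + icon_gradient(v, ps, bounds)
    lp <- lp_max(g, S, ub, A2 = A2, b2 = b2)
    if (!lp$solved) break
    s <- lp$x - v
    b <- sum(g * s)
    a <- icon_curvature(s, ps)
    t <- if (a < -1e-300) min(max(-b / (2 * a), 0), 1)
         else if (b + a > 0) 1 else 0
    if (a < 0 && obj(v + s) > obj(v + t * s)) t <- 1 # endpoint check
    cand <- v + t * s
    new <- obj(cand)
    if (new <= cur + tol * (1 + abs(cur))) break
    v <- cand; cur <- new
  }
  v
}

cancel_rev <- function(v, rev_pairs) {
  for (r in seq_len(nrow(rev_pairs))) {
    a <- rev_pairs[r, 1]; b <- rev_pairs[r, 2]
    m <- min(v[a], v[b])
    v[a] <- v[a] - m; v[b] <- v[b] - m
  }
  v
}

# ---- E-flux -----------------------------------------------------------------

#' Maximum biomass under expression bounds (E-flux)
#'
#' Solves the LP `maximize c_bar' v  s.t.  S_bar v = 0, 0 <= v <= f`: the
#' largest biomass flux the expression-derived bounds allow. Its optimum
#' `z*` anchors the biomass requirement of the co-activation program.
#'
#' @param template an `icon_template`.
#' @param bounds a `reaction_bounds` table from [reaction_bounds()].
#' @return List with `z_star`, the split-space optimizer `v_bar` (loop
#'   cancelled, so each reversible pair runs in one direction only) and the
#'   folded `net_flux`.
#' @export
solve_eflux <- function(template, bounds) {
  lp <- lp_max(template$c_bar, template$S_bar, bounds$f)
  if (!lp$solved) {
    stop("E-flux LP did not solve (status ", lp$status, "): the template ",
         "is misconfigured (check carbon source and expression bounds)")
  }
  v <- cancel_rev(pmin(pmax(lp$x, 0), bounds$f), template$rev_pairs)
  list(z_star = lp$value, v_bar = v,
       net_flux = fold_solution(template, v))
}

# ---- the co-activation program ---------------------------------------------

#' Assemble a co-activation flux problem
#'
#' Bundles the template, one condition's expression bounds, the
#' network-derived reaction pair set and the biomass requirement factor
#' `alpha` into a problem object; `z*` is computed by [solve_eflux()]
#' unless supplied.
#'
#' @param template an `icon_template`.
#' @param bounds a `reaction_bounds` table.
#' @param pairs a `reaction_pairs` set from [build_pair_set()] (may have
#'   zero rows).
#' @param alpha required fraction of the maximal biomass, in (0, 1\].
#' @param z_star optional precomputed E-flux optimum.
#' @return An object of class `icon_problem`.
#' @export
icon_problem <- function(template, bounds, pairs, alpha = 1, z_star = NULL) {
  stopifnot(alpha > 0, alpha <= 1)
  ef <- solve_eflux(template, bounds)
  if (is.null(z_star)) z_star <- ef$z_star
  structure(list(template = template, bounds = bounds, pairs = pairs,
                 alpha = alpha, z_star = z_star, eflux = ef),
            class = "icon_problem")
}

#' @export
print.icon_problem <- function(x, ...) {
  cat("<icon_problem> ", nrow(x$bounds), " columns, ", nrow(x$pairs),
      " co-expression reaction pairs\n", sep = "")
  cat("  condition: ", attr(x$bounds, "condition"),
      ", alpha = ", x$alpha, ", z* = ", format(x$z_star), "\n", sep = "")
  invisible(x)
}

biomass_rhs <- function(alpha, z_star) {
  alpha * z_star * (1 - 1e-9) - 1e-12
}

#' Solve the co-activation quadratic program
#'
#' Finds a flux distribution maximizing the summed co-activation
#' `sum q_i q_j` over the co-expressed reaction pairs, subject to mass
#' balance, expression bounds, the biomass requirement
#' `c_bar' v >= alpha z*` and one-directional flow on each split reversible
#' reaction. Solved by deterministic multistart Frank-Wolfe local ascent
#' (the program is a nonconvex QP); the folded E-flux optimizer is always
#' one start, so the result's objective is never below the E-flux
#' solution's. Status is `"optimal_lp"` when the pair set is empty (the
#' solve reduces to an LP), otherwise `"heuristic"`.
#'
#' @param problem an [icon_problem()].
#' @param n_starts number of multistart points (default 10).
#' @param seed RNG seed for the random starts.
#' @return An object of class `icon_solution`: split fluxes `v_bar`,
#'   transformed fluxes `q`, the `objective`, the attained `biomass`,
#'   `z_star`, `status` and the folded `net_flux`.
#' @export
solve_icon <- function(problem, n_starts = 10, seed = 0) {
  tpl <- problem$template; bnd <- problem$bounds
  S <- tpl$S_bar; ub <- bnd$f; c_bar <- tpl$c_bar
  rhs <- biomass_rhs(problem$alpha, problem$z_star)
  ps <- pair_structure(problem$pairs, bnd)

  finalize <- function(v, status) {
    v <- pmin(pmax(v, 0), ub)
    q <- q_transform(v, bnd)
    structure(list(
      v_bar = v, q = q,
      objective = icon_objective(v, ps, bnd),
      biomass = sum(c_bar * v),
      z_star = problem$z_star, alpha = problem$alpha,
      status = status,
      net_flux = fold_solution(tpl, v),
      problem = problem
    ), class = "icon_solution")
  }

  if (!nrow(problem$pairs)) {
    v <- cancel_rev(problem$eflux$v_bar, tpl$rev_pairs)
    sol <- finalize(v, "degenerate_no_pairs")
    return(sol)
  }

  zero_lin <- numeric(length(ub))
  starts <- list(cancel_rev(problem$eflux$v_bar, tpl$rev_pairs))
  set.seed(seed)
  for (k in seq_len(max(0, n_starts - 1))) {
    dir <- stats::rnorm(length(ub))
    lp <- lp_max(dir, S, ub, A2 = matrix(c_bar, 1), b2 = rhs)
    if (lp$solved) starts[[length(starts) + 1L]] <- lp$x
  }

  refine <- function(v0) {
    v <- fw_ascent(v0, zero_lin, ps, bnd, S, ub, c_bar, rhs)
    v <- cancel_rev(v, tpl$rev_pairs)
    # fix each reversible pair to its surviving direction and polish
    if (nrow(tpl$rev_pairs)) {
      ub2 <- ub
      for (r in seq_len(nrow(tpl$rev_pairs))) {
        a <- tpl$rev_pairs[r, 1]; b <- tpl$rev_pairs[r, 2]
        closed <- if (v[a] >= v[b]) b else a
        ub2[closed] <- 0
      }
      v <- pmin(v, ub2)
      v <- fw_ascent(v, zero_lin, ps, bnd, S, ub2, c_bar, rhs)
    }
    v
  }

  best <- NULL; best_obj <- -Inf
  for (v0 in starts) {
    v <- refine(v0)
    o <- icon_objective(v, ps, bnd)
    if (o > best_obj) { best <- v; best_obj <- o }
  }
  finalize(best, "heuristic")
}

#' @export
print.icon_solution <- function(x, ...) {
  cat("<icon_solution> status: ", x$status, "\n", sep = "")
  cat("  objective (sum q_i q_j): ", format(x$objective),
      "\n  biomass: ", format(x$biomass), " (z* = ", format(x$z_star),
      ", alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}

# ---- FVA flexibility --------------------------------------------------------

#' Flux-variability flexibility at the pinned objective
#'
#' Two-stage analysis: stage 1 is the co-activation solve (objective value
#' `Z*`); stage 2 maximizes and minimizes each original reaction's net flux
#' subject to the same constraints plus the objective pin
#' `sum q_i q_j >= Z* (1 - obj_tol)`. The flexibility of reaction i is
#' `F_i = |v_max_i - v_min_i|`. With an empty pair set the pin is vacuous
#' and each bound is an exact LP; otherwise stage 2 is solved by penalty
#' continuation over the quadratic pin (a conservative inner
#' approximation), with the stage-1 point always a candidate.
#'
#' @param problem an [icon_problem()].
#' @param solution optional stage-1 `icon_solution` (computed if missing).
#' @param obj_tol relative slack on the objective pin (default `1e-6`).
#' @param lambda_grid penalty weights for the continuation ladder.
#' @return An object of class `flexibility_report`: tibble (reaction,
#'   v_min, v_max, F, v_stage1, subsystem) with attribute `condition`.
#' @export
flexibility_fva <- function(problem, solution = NULL, obj_tol = 1e-6,
                            lambda_grid = 10^seq(-2, 4, by = 1)) {
  if (is.null(solution)) solution <- solve_icon(problem)
  tpl <- problem$template; bnd <- problem$bounds
  S <- tpl$S_bar; ub <- bnd$f; c_bar <- tpl$c_bar
  rhs <- biomass_rhs(problem$alpha, problem$z_star)
  ps <- pair_structure(problem$pairs, bnd)
  Z <- solution$objective
  pin <- Z * (1 - obj_tol) - 1e-9
  ids <- tpl$base$reactions$id
  sgn <- ifelse(tpl$columns$direction == "backward", -1, 1)

  dir_vec <- function(rx) {
    d <- numeric(length(ub))
    k <- which(tpl$columns$reaction == rx)
    d[k] <- sgn[k]
    d
  }

  bound_one <- function(d) { # returns c(min, max) of d' v under the pin
    if (!nrow(problem$pairs)) {
      hi <- lp_max(d, S, ub, A2 = matrix(c_bar, 1), b2 = rhs)
      lo <- lp_max(-d, S, ub, A2 = matrix(c_bar, 1), b2 = rhs)
      return(c(-lo$value, hi$value))
    }
    base_val <- sum(d * solution$v_bar)
    vals <- c(base_val, base_val)
    for (sense in c(1, -1)) {
      for (lam in lambda_grid) {
        v <- fw_ascent(solution$v_bar, sense * d / lam, ps, bnd, S, ub,
                       c_bar, rhs)
        v <- cancel_rev(v, tpl$rev_pairs)
        if (icon_objective(v, ps, bnd) >= pin) {
          val <- sum(d * v)
          if (sense > 0) vals[2] <- max(vals[2], val)
          else vals[1] <- min(vals[1], val)
        }
      }
    }
    vals
  }

  res <- purrr::map_dfr(ids, function(rx) {
    b <- bound_one(dir_vec(rx))
    tibble::tibble(reaction = rx, v_min = b[1], v_max = b[2],
                   F = abs(b[2] - b[1]))
  })
  res$v_stage1 <- solution$net_flux[res$reaction]
  res$subsystem <- tpl$base$reactions$subsystem[match(res$reaction, ids)]
  structure(res, condition = attr(bnd, "condition"),
            class = c("flexibility_report", class(res)))
}

#' Subsystem flexibility heatmap matrix
#'
#' Averages per-reaction flexibilities within each subsystem and
#' min-max-normalizes the resulting subsystem x condition matrix to
#' \[0, 1\] over all entries (a constant matrix normalizes to all zeros,
#' with a warning). Reactions without a subsystem label are skipped.
#'
#' @param reports a named list of `flexibility_report`s, one per condition
#'   (names = condition labels), or a single report.
#' @return A tibble with a `subsystem` column and one numeric column per
#'   condition; the raw (unnormalized) means are in attribute `raw_means`.
#' @export
subsystem_flexibility <- function(reports) {
  if (inherits(reports, "flexibility_report")) {
    nm <- attr(reports, "condition")
    reports <- stats::setNames(list(reports), if (is.null(nm)) "cond1" else nm)
  }
  means <- purrr::imap_dfr(reports, function(rep, cond) {
    rep <- rep[nzchar(rep$subsystem), , drop = FALSE]
    if (!nrow(rep)) {
      warning("no subsystem-labelled reactions in condition ", cond)
      return(tibble::tibble(subsystem = character(0), condition = character(0),
                            mean_F = numeric(0)))
    }
    dplyr::summarise(dplyr::group_by(rep, .data$subsystem),
                     mean_F = mean(.data$F), .groups = "drop") |>
      dplyr::mutate(condition = cond)
  })
  wide <- tidyr::pivot_wider(means, names_from = "condition",
                             values_from = "mean_F")
  vals <- as.matrix(wide[, -1, drop = FALSE])
  rng <- range(vals, na.rm = TRUE)
  if (diff(rng) == 0) {
    warning("all subsystem flexibilities equal; normalized matrix is all 0")
    norm <- vals * 0
  } else {
    norm <- (vals - rng[1]) / diff(rng)
  }
  out <- tibble::as_tibble(cbind(wide[, 1, drop = FALSE],
                                 tibble::as_tibble(norm)))
  attr(out, "raw_means") <- wide
  out
}
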