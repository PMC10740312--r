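# Internal linear-programming wrapper.
#
# All flux LPs in the package are solved in the nonnegative split space:
#   maximize  obj' v
#   s.t.      S v = 0,  0 <= v <= ub,  A2 v >= b2 (optional)
# boot::simplex wants x >= 0 natively, which matches the split space, so
# upper bounds become <= rows.

lp_max <- function(obj, S, ub, A2 = NULL, b2 = NULL, eps = 1e-10) {
  n <- length(obj)
  stopifnot(ncol(S) == n, length(ub) == n)
  if (max(ub) <= 0) { # fully clamped: the origin is the only feasible point
    return(list(value = 0, x = numeric(n), solved = TRUE, status = 1L))
  }
  # columns clamped to zero are fixed; solve the reduced problem
  keep_col <- ub > 0
  if (!all(keep_col)) {
    sub <- lp_max(obj[keep_col], S[, keep_col, drop = FALSE], ub[keep_col],
                  A2 = if (is.null(A2)) NULL else A2[, keep_col, drop = FALSE],
                  b2 = b2, eps = eps)
    x <- numeric(n); x[keep_col] <- sub$x
    return(list(value = sub$value, x = x, solved = sub$solved,
                status = sub$status))
  }
  # drop redundant all-zero mass-balance rows (boot::simplex dislikes them)
  keep <- rowSums(abs(S)) > 0
  S <- S[keep, , drop = FALSE]
  if (!is.null(A2)) {
    # a >= row with nonpositive rhs is vacuous for x >= 0, A2 >= 0
    ok <- b2 > 0
    A2 <- A2[ok, , drop = FALSE]; b2 <- b2[ok]
    if (!nrow(A2)) { A2 <- NULL; b2 <- NULL }
  }
  A1 <- diag(n)
  res <- boot::simplex(
    a = obj,
    A1 = A1, b1 = ub,
    A2 = A2, b2 = b2,
    A3 = if (nrow(S)) S else NULL, b3 = if (nrow(S)) rep(0, nrow(S)) else NULL,
    maxi = TRUE, eps = eps
  )
  list(
    value  = as.numeric(res$value),
    x      = as.numeric(res$soln),
    solved = res$solved == 1L,
    status = res$solved # 1 solved, 0 iteration limit, -1 infeasible
  )
}

# locale-independent (C-collation) sort, so emitted files are reproducible
sort_c <- function(x) sort(x, method = "radix")
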