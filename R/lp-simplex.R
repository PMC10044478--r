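#' Linear programming with dual values
#'
#' `lp_problem()` assembles a linear programme in the form
#' maximise (or minimise) \eqn{c'x} subject to \eqn{A x \{\le,\ge,=\} b},
#' \eqn{x \ge 0}; `solve_lp()` solves it with a dense two-phase primal
#' simplex and returns primal values, the objective, and one dual value per
#' constraint. Duals follow the convention of a maximisation problem: a
#' binding `<=` resource row has a non-negative dual equal to the marginal
#' objective value of one more unit of its right-hand side.
#'
#' The farm model built by [build_farm_model()] has a few hundred rows and
#' columns; a dense tableau is entirely adequate at that scale and keeps the
#' dual bookkeeping transparent.
#'
#' @param obj named numeric vector of objective coefficients.
#' @param A constraint matrix (rows = constraints, columns follow `obj`).
#' @param dir character vector of `"<="`, `">="`, `"="` per row.
#' @param rhs right-hand side vector.
#' @param maximize logical; `TRUE` maximises.
#' @param con_names optional row names; defaults to `rownames(A)`.
#' @param groups optional character vector tagging each row with a
#'   constraint-group label (land, feed pool, nutrition, ...), carried into
#'   the solution for shadow-price lookup and infeasibility reporting.
#' @return an object of class `lp_problem`.
#' @export
lp_problem <- function(obj, A, dir, rhs, maximize = TRUE,
                       con_names = NULL, groups = NULL) {
  A <- as.matrix(A)
  stopifnot(length(obj) == ncol(A), length(dir) == nrow(A),
            length(rhs) == nrow(A), all(dir %in% c("<=", ">=", "=")))
  if (is.null(con_names)) con_names <- rownames(A)
  if (is.null(con_names)) con_names <- paste0("con", seq_len(nrow(A)))
  if (is.null(groups)) groups <- con_names
  vn <- names(obj)
  if (is.null(vn)) vn <- paste0("x", seq_along(obj))
  structure(list(obj = stats::setNames(as.numeric(obj), vn),
                 A = A, dir = as.character(dir), rhs = as.numeric(rhs),
                 maximize = isTRUE(maximize),
                 con_names = con_names, groups = groups),
            class = "lp_problem")
}

#' @rdname lp_problem
#' @param problem an `lp_problem`.
#' @param tol feasibility/optimality tolerance.
#' @param maxit pivot limit (defaults to `200 * (m + n)`).
#' @return a list of class `lp_solution`: `status` ("optimal", "infeasible",
#'   "unbounded"), `objective`, `x` (named), `duals` (named by constraint),
#'   `constraints` (tibble: name, group, dir, rhs, activity, dual, binding)
#'   and, when infeasible, `violated_groups`.
#' @export
solve_lp <- function(problem, tol = 1e-9, maxit = NULL) {
  stopifnot(inherits(problem, "lp_problem"))
  m <- nrow(problem$A); n <- ncol(problem$A)
  if (is.null(maxit)) maxit <- 200L * (m + n)
  c0 <- if (problem$maximize) problem$obj else -problem$obj

  A <- problem$A; b <- problem$rhs; dir <- problem$dir
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  dir[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[flip]]

  # column layout: structural | slack/surplus (one per row) | artificial
  need_art <- dir != "<="
  n_art <- sum(need_art)
  ncol_t <- n + m + n_art
  Tb <- matrix(0, m, ncol_t)
  Tb[, seq_len(n)] <- A
  row_id_col <- integer(m)      # the +/- identity column of each row
  row_id_sign <- numeric(m)
  basis <- integer(m)
  ai <- 0L
  for (i in seq_len(m)) {
    sc <- n + i
    Tb[i, sc] <- if (dir[i] == ">=") -1 else 1  # surplus or slack ('=' gets
    if (dir[i] == "=") Tb[i, sc] <- 0           #  no slack column)
    row_id_col[i] <- sc
    row_id_sign[i] <- if (dir[i] == ">=") -1 else 1
    if (need_art[i]) {
      ai <- ai + 1L
      ac <- n + m + ai
      Tb[i, ac] <- 1
      basis[i] <- ac
      row_id_col[i] <- ac       # artificial is a cleaner identity column
      row_id_sign[i] <- 1
    } else {
      basis[i] <- sc
    }
  }
  art_cols <- if (n_art > 0) (n + m + 1L):ncol_t else integer(0)

  run_phase <- function(Tb, b, basis, cost, barred, maxit, tol) {
    m <- nrow(Tb)
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > maxit) return(list(status = "iteration_limit", Tb = Tb, b = b,
                                  basis = basis))
      cb <- cost[basis]
      red <- as.vector(crossprod(Tb, cb)) - cost   # z_j - c_j
      red[barred] <- Inf
      red[basis] <- Inf
      # Dantzig for speed, Bland after a while for anti-cycling
      if (it <= maxit %/% 2L) {
        j <- which.min(red)
        if (red[j] >= -tol) return(list(status = "optimal", Tb = Tb, b = b,
                                        basis = basis))
      } else {
        cand <- which(red < -tol)
        if (length(cand) == 0L) return(list(status = "optimal", Tb = Tb,
                                            b = b, basis = basis))
        j <- cand[1L]
      }
      col <- Tb[, j]
      pos <- which(col > tol)
      if (length(pos) == 0L) return(list(status = "unbounded", Tb = Tb,
                                         b = b, basis = basis))
      ratio <- b[pos] / col[pos]
      r <- pos[which.min(ratio + 1e-12 * basis[pos])]  # tie-break: low index
      # pivot on (r, j)
      piv <- Tb[r, j]
      Tb[r, ] <- Tb[r, ] / piv
      b[r] <- b[r] / piv
      other <- setdiff(seq_len(m), r)
      f <- Tb[other, j]
      Tb[other, ] <- Tb[other, , drop = FALSE] - outer(f, Tb[r, ])
      b[other] <- b[other] - f * b[r]
      basis[r] <- j
    }
  }

  # Phase 1: drive artificials out
  if (n_art > 0) {
    cost1 <- numeric(ncol_t)
    cost1[art_cols] <- -1       # maximise -sum(artificials)
    ph1 <- run_phase(Tb, b, basis, cost1, barred = integer(0),
                     maxit = maxit, tol = tol)
    if (ph1$status != "optimal")
      return(lp_result(problem, status = "infeasible"))
    Tb <- ph1$Tb; b <- ph1$b; basis <- ph1$basis
    if (sum(b[basis %in% art_cols]) > 1e-7)
      return(lp_result(problem, status = "infeasible",
                       infeas = b, basis = basis))
  }

  cost2 <- numeric(ncol_t)
  cost2[seq_len(n)] <- c0
  ph2 <- run_phase(Tb, b, basis, cost2, barred = art_cols,
                   maxit = maxit, tol = tol)
  if (ph2$status == "unbounded")
    return(lp_result(problem, status = "unbounded"))
  if (ph2$status == "iteration_limit")
    stop("simplex iteration limit reached (", maxit, " pivots)")
  Tb <- ph2$Tb; b <- ph2$b; basis <- ph2$basis

  x <- numeric(n)
  in_struct <- basis <= n
  x[basis[in_struct]] <- b[in_struct]
  obj_val <- sum(c0 * x)

  cb <- cost2[basis]
  zrow <- as.vector(crossprod(Tb, cb)) - cost2
  y <- zrow[row_id_col] * row_id_sign   # duals in the flipped system
  y[flip] <- -y[flip]
  if (!problem$maximize) y <- -y

  lp_result(problem, status = "optimal",
            objective = if (problem$maximize) obj_val else -obj_val,
            x = stats::setNames(x, names(problem$obj)),
            duals = stats::setNames(y, problem$con_names))
}

lp_result <- function(problem, status, objective = NA_real_, x = NULL,
                      duals = NULL, infeas = NULL, basis = NULL) {
  out <- list(status = status, objective = objective, x = x, duals = duals)
  if (status == "optimal") {
    act <- as.vector(problem$A %*% x)
    out$constraints <- tibble::tibble(
      name = problem$con_names, group = problem$groups,
      dir = problem$dir, rhs = problem$rhs, activity = act, dual = duals,
      binding = abs(act - problem$rhs) < 1e-7)
  } else if (status == "infeasible" && !is.null(infeas)) {
    # report groups whose artificials stayed positive
    bad <- which(basis > ncol(problem$A) + nrow(problem$A) & infeas > 1e-7)
    rows <- match(basis[bad], seq_len(nrow(problem$A)) +
                    ncol(problem$A) + nrow(problem$A))
    out$violated_groups <- unique(problem$groups[stats::na.omit(rows)])
  }
  class(out) <- "lp_solution"
  out
}

#' @export
print.lp_solution <- function(x, ...) {
  cat("<lp_solution> status:", x$status)
  if (x$status == "optimal") cat("  objective:", format(x$objective))
  cat("\n")
  invisible(x)
}

#' Enumerate the optimum of a small LP over basic feasible solutions
#'
#' Brute-force oracle used in tests: visits every vertex (basic solution) of
#' the feasible region of a small `lp_problem` and returns the best feasible
#' objective. Exponential in size; intended for problems with at most a
#' handful of variables.
#'
#' @param problem an `lp_problem` (at most ~8 structural variables).
#' @param tol feasibility tolerance.
#' @return list with `objective` and `x`, or status "infeasible".
#' @export
enumerate_lp_vertices <- function(problem, tol = 1e-7) {
  n <- ncol(problem$A)
  stopifnot(n <= 8)
  # standard form: add slack/surplus so every vertex solves a square system
  A <- problem$A; b <- problem$rhs; dir <- problem$dir
  ineq <- which(dir != "=")
  As <- cbind(A, matrix(0, nrow(A), length(ineq)))
  for (k in seq_along(ineq)) {
    As[ineq[k], n + k] <- if (dir[ineq[k]] == "<=") 1 else -1
  }
  ntot <- ncol(As); m <- nrow(As)
  best <- NULL
  sgn <- if (problem$maximize) 1 else -1
  cc <- c(problem$obj, rep(0, length(ineq)))
  for (idx in utils::combn(ntot, min(m, ntot), simplify = FALSE)) {
    B <- As[, idx, drop = FALSE]
    if (length(idx) < m || abs(det(B)) < 1e-10) next
    xb <- tryCatch(solve(B, b), error = function(e) NULL)
    if (is.null(xb) || any(xb < -tol)) next
    x <- numeric(ntot); x[idx] <- xb
    val <- sum(cc * x)
    if (is.null(best) || sgn * val > sgn * best$objective + 1e-12) {
      best <- list(objective = val, x = x[seq_len(n)])
    }
  }
  if (is.null(best)) return(list(status = "infeasible"))
  best$status <- "optimal"
  names(best$x) <- names(problem$obj)
  best
}
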