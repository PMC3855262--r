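# Thin interface to the GLPK command-line solver (glpsol).
#
# Problems are assembled as plain lists of dense objective/bound vectors plus
# sparse constraint triplets, written in CPLEX LP format and solved by glpsol.
# Every variable appears (with an explicit coefficient, possibly 0) in the
# objective row, which pins glpsol's column order to ours.

#' Locate the GLPK command-line solver
#'
#' Returns the path to the \code{glpsol} executable used for all linear and
#' mixed-integer programs in this package.
#'
#' @return Path to the solver binary.
#' @keywords internal
glpsol_path <- function() {
  p <- Sys.which("glpsol")
  if (!nzchar(p)) {
    stop("solver unavailable: 'glpsol' (GLPK) was not found on the PATH",
         call. = FALSE)
  }
  unname(p)
}

#' Create an empty linear/mixed-integer program
#'
#' @param n_var number of variables.
#' @param sense \code{"max"} or \code{"min"}.
#' @return A mutable problem environment; fill with [lp_set_objective()],
#'   [lp_set_bounds()], [lp_add_rows()], [lp_set_binary()].
#' @keywords internal
lp_new <- function(n_var, sense = c("max", "min")) {
  sense <- match.arg(sense)
  p <- new.env(parent = emptyenv())
  p$n <- as.integer(n_var)
  p$sense <- sense
  p$obj <- numeric(n_var)
  p$lb <- numeric(n_var)
  p$ub <- rep(Inf, n_var)
  p$binary <- logical(n_var)
  p$ri <- integer(0)   # row index per nonzero
  p$rj <- integer(0)   # column index per nonzero
  p$rx <- numeric(0)   # coefficient per nonzero
  p$rsense <- character(0)
  p$rrhs <- numeric(0)
  p$nrow <- 0L
  class(p) <- "glpk_problem"
  p
}

#' @keywords internal
lp_set_objective <- function(p, obj) {
  stopifnot(length(obj) == p$n)
  p$obj <- as.numeric(obj)
  invisible(p)
}

#' @keywords internal
lp_set_bounds <- function(p, lb = NULL, ub = NULL, idx = seq_len(p$n)) {
  if (!is.null(lb)) p$lb[idx] <- lb
  if (!is.null(ub)) p$ub[idx] <- ub
  invisible(p)
}

#' @keywords internal
lp_set_binary <- function(p, idx) {
  p$binary[idx] <- TRUE
  p$lb[idx] <- pmax(p$lb[idx], 0)
  p$ub[idx] <- pmin(p$ub[idx], 1)
  invisible(p)
}

#' Append constraint rows given as sparse triplets
#'
#' @param p problem from [lp_new()].
#' @param i,j,x row-local row index (1-based), column index and coefficient.
#' @param sense character vector per row: one of \code{"<="}, \code{">="},
#'   \code{"="}.
#' @param rhs numeric right-hand side per row.
#' @keywords internal
lp_add_rows <- function(p, i, j, x, sense, rhs) {
  nr <- length(rhs)
  stopifnot(length(sense) == nr, length(i) == length(j),
            length(j) == length(x))
  p$ri <- c(p$ri, p$nrow + as.integer(i))
  p$rj <- c(p$rj, as.integer(j))
  p$rx <- c(p$rx, as.numeric(x))
  p$rsense <- c(p$rsense, sense)
  p$rrhs <- c(p$rrhs, as.numeric(rhs))
  p$nrow <- p$nrow + as.integer(nr)
  invisible(p)
}

# Render one linear expression "c1 v1 + c2 v2 ..." from parallel vectors.
.lp_terms <- function(j, x) {
  sgn <- ifelse(x < 0, "-", "+")
  paste0(sgn, " ", sprintf("%.12g", abs(x)), " v", j, collapse = " ")
}

#' Write the problem in CPLEX LP format
#' @keywords internal
lp_format <- function(p) {
  out <- character(0)
  out <- c(out, if (p$sense == "max") "Maximize" else "Minimize")
  # full objective row fixes the column order v1..vn
  obj_terms <- paste0(ifelse(p$obj < 0, "-", "+"), " ",
                      sprintf("%.12g", abs(p$obj)), " v", seq_len(p$n))
  out <- c(out, paste(" obj:", paste(obj_terms, collapse = " ")))
  out <- c(out, "Subject To")
  if (p$nrow == 0L) out <- c(out, " c0: 0 v1 <= 1")
  if (p$nrow > 0L) {
    ord <- order(p$ri)
    ri <- p$ri[ord]; rj <- p$rj[ord]; rx <- p$rx[ord]
    keep <- rx != 0
    ri <- ri[keep]; rj <- rj[keep]; rx <- rx[keep]
    split_idx <- split(seq_along(ri), ri)
    for (r in seq_len(p$nrow)) {
      k <- split_idx[[as.character(r)]]
      lhs <- if (is.null(k)) "0 v1" else .lp_terms(rj[k], rx[k])
      out <- c(out, sprintf(" c%d: %s %s %.12g", r, lhs, p$rsense[r],
                            p$rrhs[r]))
    }
  }
  out <- c(out, "Bounds")
  lbs <- ifelse(is.finite(p$lb), sprintf("%.12g", p$lb), "-inf")
  ubs <- ifelse(is.finite(p$ub), sprintf("%.12g", p$ub), "+inf")
  fixed <- is.finite(p$lb) & is.finite(p$ub) & p$lb == p$ub
  bl <- ifelse(fixed,
               sprintf(" v%d = %.12g", seq_len(p$n), p$lb),
               sprintf(" %s <= v%d <= %s", lbs, seq_len(p$n), ubs))
  out <- c(out, bl)
  if (any(p$binary)) {
    out <- c(out, "Binary", paste0(" v", which(p$binary)))
  }
  c(out, "End")
}

#' Solve a linear or mixed-integer program with glpsol
#'
#' @param p problem built with [lp_new()] and friends.
#' @param time_limit seconds allowed for the solve (default 60).
#' @return List with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"} or \code{"failed"}), \code{objective} and the primal
#'   solution vector \code{x}.
#' @keywords internal
lp_solve <- function(p, time_limit = 60) {
  fin <- tempfile(fileext = ".lp")
  fout <- tempfile(fileext = ".sol")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(lp_format(p), fin)
  is_mip <- any(p$binary)
  args <- c("--lp", fin, "--write", fout,
            "--tmlim", sprintf("%d", as.integer(time_limit)))
  if (!is_mip) args <- c(args, "--nopresol")
  rc <- suppressWarnings(
    system2(glpsol_path(), args, stdout = FALSE, stderr = FALSE))
  if (!file.exists(fout)) {
    stop("solver failure: glpsol returned code ", rc,
         " and wrote no solution", call. = FALSE)
  }
  lines <- readLines(fout)
  sline <- strsplit(lines[startsWith(lines, "s ")][1], " +")[[1]]
  jlines <- lines[startsWith(lines, "j ")]
  jf <- strsplit(jlines, " +")
  x <- numeric(p$n)
  if (sline[2] == "mip") {
    status <- switch(sline[5], o = "optimal", f = "feasible",
                     n = "infeasible", "failed")
    objective <- as.numeric(sline[6])
    for (f in jf) x[as.integer(f[2])] <- as.numeric(f[3])
  } else {
    pstat <- sline[5]; dstat <- sline[6]
    status <- if (pstat == "f" && dstat == "f") "optimal"
      else if (pstat == "n") "infeasible"
      else if (dstat == "n") "unbounded"
      else "failed"
    objective <- as.numeric(sline[7])
    for (f in jf) x[as.integer(f[2])] <- as.numeric(f[4])
  }
  if (status %in% c("failed", "feasible")) {
    stop("solver did not reach a definitive optimum (status '", status,
         "'); consider raising the time limit", call. = FALSE)
  }
  list(status = status, objective = objective, x = x)
}

#' Test feasibility of a problem (zero objective solve)
#' @keywords internal
lp_feasible <- function(p, time_limit = 60) {
  q <- lp_new(p$n, "max")
  q$obj <- numeric(p$n)
  q$lb <- p$lb; q$ub <- p$ub; q$binary <- p$binary
  q$ri <- p$ri; q$rj <- p$rj; q$rx <- p$rx
  q$rsense <- p$rsense; q$rrhs <- p$rrhs; q$nrow <- p$nrow
  res <- lp_solve(q, time_limit = time_limit)
  res$status != "infeasible"
}
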