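#' @title Linear and mixed-integer programming layer
#'
#' @description
#' Thin interface between the gap-filling formulations and an external
#' solver. Problems are held as plain lists (sparse constraint matrix,
#' row/column bounds, variable types) and shipped to GLPK's `glpsol`
#' executable in CPLEX LP format; solutions are read back from the
#' machine-readable `-w` file. All bounds are finite by construction
#' (the flux cap replaces infinities upstream), so unboundedness never
#' arises in well-formed problems.
#'
#' @name solver-layer
#' @keywords internal
NULL

#' Construct a linear (or mixed-integer) program
#'
#' @param obj numeric objective coefficients, one per column.
#' @param A sparse constraint matrix (`dgCMatrix` or coercible), rows are
#'   constraints.
#' @param row_lb,row_ub numeric per-row bounds; an equality row has
#'   `row_lb == row_ub`. Ranged inequalities (finite, distinct bounds on
#'   both sides) are not supported.
#' @param lb,ub numeric per-column bounds.
#' @param sense `"min"` or `"max"`.
#' @param binary logical per-column flag; binary columns are solved as
#'   0/1 integers (their `lb`/`ub` are still honoured, so a fixed binary
#'   is expressed as `lb = ub`).
#' @param names character column names (used to name the solution).
#' @return an object of class `lp_problem`.
#' @keywords internal
lp_problem <- function(obj, A, row_lb, row_ub, lb, ub,
                       sense = c("min", "max"),
                       binary = NULL, names = NULL) {
  sense <- match.arg(sense)
  A <- methods::as(methods::as(methods::as(A, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  n <- ncol(A)
  m <- nrow(A)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(row_lb) == m, length(row_ub) == m)
  if (is.null(binary)) binary <- rep(FALSE, n)
  if (is.null(names)) names <- paste0("x", seq_len(n))
  if (any(lb > ub + 1e-12)) stop("lp_problem: lb > ub for some column")
  if (any(row_lb > row_ub + 1e-12)) stop("lp_problem: row_lb > row_ub")
  ranged <- is.finite(row_lb) & is.finite(row_ub) & (row_ub - row_lb > 1e-12)
  if (any(ranged)) stop("lp_problem: ranged rows are not supported")
  structure(list(obj = obj, A = A, row_lb = row_lb, row_ub = row_ub,
                 lb = lb, ub = ub, sense = sense, binary = binary,
                 names = names),
            class = "lp_problem")
}

# Format a coefficient for the LP file. %.15g keeps full double precision.
.lp_num <- function(x) sprintf("%.15g", x)

# Serialize an lp_problem to CPLEX LP format. Columns are written as
# generic names x<i> to stay within the format's identifier rules;
# the mapping back to user names happens when the solution is parsed.
write_lp_file <- function(prob, path) {
  n <- ncol(prob$A)
  vn <- paste0("x", seq_len(n))
  con <- file(path, open = "wt")
  on.exit(close(con))

  # every variable appears in the objective (zeros included): glpsol
  # numbers columns by first appearance in the file, and this pins its
  # column order to ours so the solution maps back by index
  objterms <- sprintf("%+.15g %s", prob$obj, vn)
  chunks <- split(objterms, (seq_len(n) - 1L) %/% 8L)
  writeLines(if (prob$sense == "min") "Minimize" else "Maximize", con)
  first <- TRUE
  for (ch in chunks) {
    writeLines(paste0(if (first) " obj: " else "      ",
                      paste(ch, collapse = " ")), con)
    first <- FALSE
  }
  writeLines("Subject To", con)

  At <- Matrix::t(prob$A)   # column-compressed over rows
  p <- At@p; idx <- At@i; val <- At@x
  for (r in seq_len(nrow(prob$A))) {
    k <- if (p[r + 1L] > p[r]) seq.int(p[r] + 1L, p[r + 1L]) else integer(0)
    if (length(k) == 0L) next   # empty row: vacuous given finite rhs checks
    terms <- paste(sprintf("%+.15g %s", val[k], vn[idx[k] + 1L]),
                   collapse = " ")
    lo <- prob$row_lb[r]; hi <- prob$row_ub[r]
    rel <- if (is.finite(lo) && is.finite(hi)) {
      paste0("= ", .lp_num(lo))
    } else if (is.finite(hi)) {
      paste0("<= ", .lp_num(hi))
    } else if (is.finite(lo)) {
      paste0(">= ", .lp_num(lo))
    } else {
      next
    }
    writeLines(sprintf(" r%d: %s %s", r, terms, rel), con)
  }

  writeLines("Bounds", con)
  for (j in seq_len(n)) {
    lo <- prob$lb[j]; hi <- prob$ub[j]
    line <- if (!is.finite(lo) && !is.finite(hi)) {
      sprintf(" %s free", vn[j])
    } else if (lo == hi) {
      sprintf(" %s = %s", vn[j], .lp_num(lo))
    } else {
      sprintf(" %s <= %s <= %s",
              if (is.finite(lo)) .lp_num(lo) else "-inf",
              vn[j],
              if (is.finite(hi)) .lp_num(hi) else "+inf")
    }
    writeLines(line, con)
  }

  if (any(prob$binary)) {
    writeLines("General", con)
    writeLines(paste0(" ", paste(vn[prob$binary], collapse = " ")), con)
  }
  writeLines("End", con)
  invisible(path)
}

#' Locate the GLPK executable
#'
#' @return path to `glpsol`, or `""` when not found.
#' @keywords internal
find_glpsol <- function() {
  p <- Sys.getenv("COMGAPFILL_GLPSOL", "")
  if (nzchar(p) && file.exists(p)) return(p)
  unname(Sys.which("glpsol"))
}

# Parse the machine-readable solution file written by glpsol -w,
# together with the captured stdout (needed to tell infeasible from
# unbounded: both stamp the solution file UNDEFINED).
.parse_glpk_solution <- function(sol_lines, out_lines, mip) {
  sline <- grep("^s ", sol_lines, value = TRUE)
  if (length(sline) == 0L) {
    return(list(status = "error", objective = NA_real_, x = NULL))
  }
  f <- strsplit(sline[1L], "\\s+")[[1L]]
  jlines <- grep("^j ", sol_lines, value = TRUE)
  jf <- strsplit(jlines, "\\s+")
  if (mip) {
    stat <- f[5L]; objv <- as.numeric(f[6L])
    xs <- vapply(jf, function(z) as.numeric(z[3L]), numeric(1))
  } else {
    stat <- f[5L]; objv <- as.numeric(f[7L])   # p_stat, obj
    xs <- vapply(jf, function(z) as.numeric(z[4L]), numeric(1))
  }
  jidx <- vapply(jf, function(z) as.integer(z[2L]), integer(1))
  x <- numeric(length(xs)); x[jidx] <- xs

  txt <- paste(out_lines, collapse = "\n")
  status <-
    if (mip && stat == "o") "optimal"
    else if (!mip && stat == "f") "optimal"
    else if (grepl("NO (PRIMAL )?FEASIBLE|HAS NO FEASIBLE|INTEGER EMPTY", txt) ||
             stat %in% c("n", "i")) "infeasible"
    else if (grepl("UNBOUNDED", txt)) "unbounded"
    else if (grepl("TIME LIMIT EXCEEDED", txt) && mip && stat == "f") "time_limit"
    else if (mip && stat == "f") "feasible"
    else "error"
  list(status = status, objective = objv, x = x)
}

#' Solve a linear or mixed-integer program
#'
#' @param prob an [lp_problem].
#' @param solver backend name; `"auto"` picks GLPK when `glpsol` is on the
#'   `PATH`. Only the GLPK backend is currently implemented.
#' @param time_limit seconds allowed for the solve (passed to the solver),
#'   `Inf` for none.
#' @param mip_gap relative MIP optimality gap; the default 0 requires a
#'   proven optimum.
#' @return list with `status` (`"optimal"`, `"feasible"`, `"infeasible"`,
#'   `"unbounded"`, `"time_limit"`, `"error"`), `objective`, and named
#'   numeric `x`.
#' @export
solve_lp <- function(prob, solver = "auto", time_limit = Inf, mip_gap = 0) {
  stopifnot(inherits(prob, "lp_problem"))
  if (solver == "auto") solver <- "glpk"
  if (solver != "glpk") {
    stop("unknown solver backend: ", solver, " (available: glpk)")
  }
  glpsol <- find_glpsol()
  if (!nzchar(glpsol)) {
    stop("glpsol executable not found; install GLPK or set COMGAPFILL_GLPSOL")
  }
  lpf <- tempfile(fileext = ".lp")
  slf <- tempfile(fileext = ".sol")
  on.exit(unlink(c(lpf, slf)))
  write_lp_file(prob, lpf)
  mip <- any(prob$binary)
  args <- c("--lp", lpf, "-w", slf)
  if (is.finite(time_limit)) args <- c(args, "--tmlim", as.integer(ceiling(time_limit)))
  if (mip && mip_gap > 0) args <- c(args, "--mipgap", .lp_num(mip_gap))
  out <- suppressWarnings(system2(glpsol, args, stdout = TRUE, stderr = TRUE))
  if (!file.exists(slf)) {
    return(list(status = "error", objective = NA_real_, x = NULL,
                log = out))
  }
  sol <- .parse_glpk_solution(readLines(slf), out, mip)
  if (!is.null(sol$x)) {
    if (length(sol$x) != ncol(prob$A)) sol$x <- rep(NA_real_, ncol(prob$A))
    names(sol$x) <- prob$names
  }
  sol
}

#' Is a MILP/LP solver available?
#'
#' @return `TRUE` when the GLPK backend can be used.
#' @export
solver_available <- function() nzchar(find_glpsol())
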