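# Thin linear-programming layer over boot::simplex. All problems in this
# package are small (tens of variables), well within the tableau solver's
# comfort zone. Variables carry finite lower bounds (shifted to x >= 0);
# upper bounds become inequality rows when finite.

solveLp <- function(obj, Aeq = NULL, beq = NULL, Aub = NULL, bub = NULL,
                    lb = rep(0, length(obj)), ub = rep(Inf, length(obj)),
                    maximize = FALSE) {
  nv <- length(obj)
  stopifnot(all(is.finite(lb)), length(lb) == nv, length(ub) == nv)
  if (any(ub < lb)) stop("upper bound below lower bound")

  # eliminate fixed variables (ub == lb): substitute them as constants
  fixed <- which(ub - lb <= 0)
  if (length(fixed)) {
    free <- setdiff(seq_len(nv), fixed)
    xFix <- lb[fixed]
    if (!is.null(Aeq)) {
      Aeq <- matrix(Aeq, ncol = nv)
      beq <- beq - as.numeric(Aeq[, fixed, drop = FALSE] %*% xFix)
      Aeq <- Aeq[, free, drop = FALSE]
    }
    if (!is.null(Aub)) {
      Aub <- matrix(Aub, ncol = nv)
      bub <- bub - as.numeric(Aub[, fixed, drop = FALSE] %*% xFix)
      Aub <- Aub[, free, drop = FALSE]
    }
    if (!length(free)) {
      if (!is.null(beq) && any(abs(beq) > 1e-8))
        stop("linear program infeasible")
      if (!is.null(bub) && any(bub < -1e-8))
        stop("linear program infeasible")
      return(list(solution = lb, objective = sum(obj * lb)))
    }
    inner <- solveLp(obj[free], Aeq = Aeq, beq = beq, Aub = Aub, bub = bub,
                     lb = lb[free], ub = ub[free], maximize = maximize)
    sol <- numeric(nv)
    sol[fixed] <- xFix
    sol[free] <- inner$solution
    return(list(solution = sol, objective = sum(obj * sol)))
  }
  # drop all-zero constraint rows (zero rhs: vacuous; nonzero: infeasible)
  if (!is.null(Aeq)) {
    Aeq <- matrix(Aeq, ncol = nv)
    zero <- rowSums(abs(Aeq)) == 0
    if (any(zero)) {
      if (any(abs(beq[zero]) > 1e-8)) stop("linear program infeasible")
      Aeq <- Aeq[!zero, , drop = FALSE]
      beq <- beq[!zero]
      if (!nrow(Aeq)) { Aeq <- NULL; beq <- NULL }
    }
  }
  if (!is.null(Aub)) {
    Aub <- matrix(Aub, ncol = nv)
    zero <- rowSums(abs(Aub)) == 0
    if (any(zero)) {
      if (any(bub[zero] < -1e-8)) stop("linear program infeasible")
      Aub <- Aub[!zero, , drop = FALSE]
      bub <- bub[!zero]
      if (!nrow(Aub)) { Aub <- NULL; bub <- NULL }
    }
  }

  # presolve: an equality row with zero shifted rhs and same-sign
  # coefficients forces its variables to their lower bounds (x >= 0 after
  # the shift); fixing them and recursing keeps the tableau well-posed for
  # boot::simplex (dead-end rows otherwise drive it to NaN pivots)
  if (!is.null(Aeq)) {
    Aeq <- matrix(Aeq, ncol = nv)
    shiftRhs <- beq - as.numeric(Aeq %*% lb)
    forced <- logical(nv)
    for (r in which(abs(shiftRhs) <= 1e-9)) {
      nz <- which(abs(Aeq[r, ]) > 1e-12)
      if (length(nz) && (all(Aeq[r, nz] > 0) || all(Aeq[r, nz] < 0)))
        forced[nz] <- TRUE
    }
    if (any(forced)) {
      ub2 <- ub
      ub2[forced] <- lb[forced]
      return(solveLp(obj, Aeq = Aeq, beq = beq, Aub = Aub, bub = bub,
                     lb = lb, ub = ub2, maximize = maximize))
    }
  }

  # shift x = v - lb
  A1 <- NULL; b1 <- numeric()   # <=
  A2 <- NULL; b2 <- numeric()   # >=
  A3 <- NULL; b3 <- numeric()   # ==
  addRow <- function(kind, row, rhs) {
    if (kind == "le" && rhs < 0) { kind <- "ge"; row <- -row; rhs <- -rhs }
    else if (kind == "ge" && rhs < 0) { kind <- "le"; row <- -row; rhs <- -rhs }
    else if (kind == "eq" && rhs < 0) { row <- -row; rhs <- -rhs }
    if (kind == "le") { A1 <<- rbind(A1, row); b1 <<- c(b1, rhs) }
    else if (kind == "ge") { A2 <<- rbind(A2, row); b2 <<- c(b2, rhs) }
    else { A3 <<- rbind(A3, row); b3 <<- c(b3, rhs) }
  }
  if (!is.null(Aeq)) {
    Aeq <- matrix(Aeq, ncol = nv)
    shift <- as.numeric(Aeq %*% lb)
    for (r in seq_len(nrow(Aeq))) addRow("eq", Aeq[r, ], beq[r] - shift[r])
  }
  if (!is.null(Aub)) {
    Aub <- matrix(Aub, ncol = nv)
    shift <- as.numeric(Aub %*% lb)
    for (r in seq_len(nrow(Aub))) addRow("le", Aub[r, ], bub[r] - shift[r])
  }
  for (i in which(is.finite(ub))) {
    row <- numeric(nv); row[i] <- 1
    addRow("le", row, ub[i] - lb[i])
  }
  nCons <- length(b1) + length(b2) + length(b3)
  if (nCons == 1L) {
    # boot::simplex mishandles single-constraint tableaus; a vacuous
    # inequality row (0'x <= 1) restores a well-formed problem
    A1 <- rbind(A1, rep(0, nv))
    b1 <- c(b1, 1)
    nCons <- 2L
  }
  res <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       A3 = A3, b3 = b3, maxi = maximize,
                       n.iter = max(200L, 50L * (nv + nCons)),
                       eps = 1e-10)
  if (res$solved == -1L)
    stop("linear program infeasible")
  if (res$solved == 0L)
    stop("linear program did not converge (possibly unbounded)")
  x <- as.numeric(res$soln)[seq_len(nv)]
  v <- x + lb
  list(solution = v, objective = sum(obj * v))
}
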