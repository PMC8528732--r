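# Independent LP oracle built on boot::simplex (pure-R, different pivoting
# code path from the package's compiled solver).  Variables are shifted to
# y = v - lb >= 0, upper bounds become <= rows, and equality rows are
# sign-normalised because boot::simplex requires non-negative right-hand
# sides.

oracleLP <- function(A, obj, lb, ub, maximize = TRUE) {
  n <- ncol(A)
  b3 <- as.vector(-A %*% lb)
  A3 <- A
  neg <- b3 < 0
  A3[neg, ] <- -A3[neg, , drop = FALSE]
  b3[neg] <- -b3[neg]
  s <- boot::simplex(a = obj, A1 = diag(n), b1 = ub - lb,
                     A3 = A3, b3 = b3, maxi = maximize)
  if (s$solved != 1) return(list(solved = s$solved))
  list(solved = 1, value = unname(s$value) + sum(obj * lb),
       x = unname(s$soln) + lb)
}

oracleFBA <- function(model, boundOverrides = NULL) {
  rxn <- reactions(model)
  lb <- setNames(rxn$lb, rxn$id)
  ub <- setNames(rxn$ub, rxn$id)
  for (rid in names(boundOverrides)) {
    lb[rid] <- boundOverrides[[rid]][1]
    ub[rid] <- boundOverrides[[rid]][2]
  }
  oracleLP(as.matrix(stoichiometry(model)), rxn$objective,
           unname(lb), unname(ub))
}

# brute-force blocked-reaction check: max/min each flux with exchanges open
oracleBlocked <- function(model, tol = 1e-6) {
  rxn <- reactions(model)
  lb <- rxn$lb; ub <- rxn$ub
  lb[rxn$exchange] <- -1000
  ub[rxn$exchange] <- 1000
  A <- as.matrix(stoichiometry(model))
  blocked <- character()
  for (j in seq_len(nrow(rxn))) {
    e <- rep(0, nrow(rxn)); e[j] <- 1
    hi <- oracleLP(A, e, lb, ub, maximize = TRUE)
    lo <- oracleLP(A, e, lb, ub, maximize = FALSE)
    if (hi$solved == 1 && lo$solved == 1 &&
        abs(hi$value) < tol && abs(lo$value) < tol)
      blocked <- c(blocked, rxn$id[j])
  }
  blocked
}
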