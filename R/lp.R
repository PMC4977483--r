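# Dense Mehrotra predictor-corrector interior-point solver, specialized to
# the non-negative L1 regression LP
#
#   stage 1:  min sum(t)   s.t.  X w - t <= y,  -X w - t <= -y,  w, t >= 0
#   stage 2:  min sum(w)   s.t.  the same rows plus  sum(t) <= f* (budget),
#
# i.e. least-absolute-deviations with non-negative coefficients, followed by
# a lexicographic minimum-norm tie-break among the L1 optima. A final
# active-set polish refits the support by least squares on the near-zero
# residual rows, which snaps consistent systems to machine precision.
#
# Only the m x k design matrix and m x m blocks are ever formed; the normal
# equations matrix is assembled from P = X Dw X', diagonal terms and (in
# stage 2) one bordered row for the budget constraint.

l1_linprog <- function(X, y, tol = 1e-9, max_iter = 100) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) abort("rhs length must match row count")
  # all-zero columns are free directions of the LP: their weights are 0 by
  # the minimum-norm rule, and carrying them along destabilizes the solves
  live <- colSums(X != 0) > 0
  if (!any(live)) {
    return(list(
      w = rep(0, ncol(X)), objective = sum(abs(y)),
      iterations = 0L, status = "degenerate"
    ))
  }
  if (!all(live)) {
    sub <- l1_linprog(X[, live, drop = FALSE], y, tol = tol, max_iter = max_iter)
    w <- rep(0, ncol(X))
    w[live] <- sub$w
    return(list(
      w = w, objective = sub$objective,
      iterations = sub$iterations, status = sub$status
    ))
  }
  s1 <- .l1_ip(X, y,
    cw = 0, ct = 1, budget = NULL,
    tol = tol, max_iter = max_iter
  )
  f_star <- sum(abs(as.vector(X %*% s1$w) - y))
  s2 <- .l1_ip(X, y,
    cw = 1, ct = 0, budget = f_star * (1 + 1e-9) + 1e-12,
    tol = tol, max_iter = max_iter
  )
  w <- if (s2$ok && sum(abs(as.vector(X %*% s2$w) - y)) <=
    f_star * (1 + 1e-7) + 1e-9) {
    s2$w
  } else {
    s1$w
  }
  w <- .l1_polish(X, y, w)
  obj <- sum(abs(as.vector(X %*% w) - y))
  # robustness net: a stalled interior point can return a poor iterate on
  # degenerate systems; the non-negative least-squares optimum is a valid
  # feasible point, so keep whichever attains the lower L1 objective
  nn <- tryCatch(pracma::lsqnonneg(X, y)$x, error = function(e) NULL)
  if (!is.null(nn)) {
    obj_nn <- sum(abs(as.vector(X %*% nn) - y))
    if (obj_nn < obj) {
      w <- .l1_polish(X, y, nn)
      obj <- sum(abs(as.vector(X %*% w) - y))
    }
  }
  list(
    w = w,
    objective = obj,
    iterations = c(s1$iterations, s2$iterations),
    status = s1$status
  )
}

# One interior-point solve of
#   min cw * sum(w) + ct * sum(t)
#   s.t. X w - t <= y, -X w - t <= -y, [sum(t) <= budget,] w, t >= 0
# Variables in standard form: x = (w, t, z1, z2[, z3]) with slacks z.
.l1_ip <- function(X, y, cw, ct, budget = NULL, tol = 1e-9, max_iter = 100) {
  m <- nrow(X)
  k <- ncol(X)
  has_b <- !is.null(budget)
  mc <- 2 * m + has_b # constraint count
  n <- k + m + mc # variable count (w, t, slacks)
  cc <- c(rep(cw, k), rep(ct, m), rep(0, mc))
  h <- c(y, -y, if (has_b) budget)
  iw <- seq_len(k)
  it_ <- k + seq_len(m)
  iz <- k + m + seq_len(mc)

  # A v for A = [[X,-I],[-X,-I],[0,1']] + slack identity
  Ax <- function(v) {
    xv <- as.vector(X %*% v[iw])
    c(
      xv - v[it_], -xv - v[it_],
      if (has_b) sum(v[it_])
    ) + v[iz]
  }
  At <- function(u) {
    u1 <- u[seq_len(m)]
    u2 <- u[m + seq_len(m)]
    ub <- if (has_b) u[2 * m + 1] else 0
    c(as.vector(crossprod(X, u1 - u2)), -(u1 + u2) + ub, u)
  }
  # normal-equations matrix A D A'
  assemble <- function(d) {
    dw <- d[iw]
    dt <- d[it_]
    dz <- d[iz]
    P <- X %*% (dw * t(X))
    M <- matrix(0, mc, mc)
    i1 <- seq_len(m)
    i2 <- m + i1
    M[i1, i1] <- P + diag(dt, m)
    M[i1, i2] <- -P + diag(dt, m)
    M[i2, i1] <- -P + diag(dt, m)
    M[i2, i2] <- P + diag(dt, m)
    if (has_b) {
      M[i1, mc] <- -dt
      M[i2, mc] <- -dt
      M[mc, i1] <- -dt
      M[mc, i2] <- -dt
      M[mc, mc] <- sum(dt)
    }
    diag(M) <- diag(M) + dz
    M
  }

  M0 <- assemble(rep(1, n))
  R <- chol(M0 + 1e-12 * mean(diag(M0)) * diag(mc))
  solve0 <- function(v) backsolve(R, forwardsolve(t(R), v))
  x <- At(solve0(h))
  yy <- as.vector(solve0(Ax(cc)))
  s <- cc - At(yy)
  x <- x + max(-1.5 * min(x), 0)
  s <- s + max(-1.5 * min(s), 0)
  xs <- sum(x * s)
  x <- x + 0.5 * xs / max(sum(s), 1e-8)
  s <- s + 0.5 * xs / max(sum(x), 1e-8)
  x <- pmax(x, 1e-8)
  s <- pmax(s, 1e-8)

  hnorm <- 1 + max(abs(h))
  cnorm <- 1 + max(abs(cc))
  best <- list(x = x, it = 0L)
  best_merit <- Inf
  status <- "maxiter"
  for (it in seq_len(max_iter)) {
    rb <- Ax(x) - h
    rc <- At(yy) + s - cc
    mu <- sum(x * s) / n
    merit <- max(max(abs(rb)) / hnorm, max(abs(rc)) / cnorm, mu)
    if (merit < best_merit) {
      best_merit <- merit
      best <- list(x = x, it = it)
    }
    if (max(abs(rb)) / hnorm < tol && max(abs(rc)) / cnorm < tol && mu < tol) {
      status <- "optimal"
      break
    }
    if (mu < 1e-14) break # complementarity floor; residuals will not improve
    d <- pmin(pmax(x / s, 1e-14), 1e14)
    M <- assemble(d)
    dreg <- 1e-13 * mean(diag(M))
    R <- tryCatch(chol(M + dreg * diag(mc)), error = function(e) NULL)
    while (is.null(R)) {
      dreg <- dreg * 100
      R <- tryCatch(chol(M + dreg * diag(mc)), error = function(e) NULL)
    }
    solveM <- function(v) {
      z <- backsolve(R, forwardsolve(t(R), v))
      z + backsolve(R, forwardsolve(t(R), v - as.vector(M %*% z)))
    }
    # affine (predictor) direction
    dy_a <- as.vector(solveM(-rb + Ax(x) - Ax(d * rc)))
    ds_a <- -rc - At(dy_a)
    dx_a <- -x - d * ds_a
    ap <- if (any(dx_a < 0)) min(1, min(-x[dx_a < 0] / dx_a[dx_a < 0])) else 1
    ad <- if (any(ds_a < 0)) min(1, min(-s[ds_a < 0] / ds_a[ds_a < 0])) else 1
    mu_aff <- sum((x + ap * dx_a) * (s + ad * ds_a)) / n
    sigma <- min(1, (mu_aff / mu)^3)
    # corrector
    rxs <- -x * s + sigma * mu - dx_a * ds_a
    dy <- as.vector(solveM(-rb - Ax(rxs / s) - Ax(d * rc)))
    ds <- -rc - At(dy)
    dx <- rxs / s - d * ds
    ap <- if (any(dx < 0)) min(1, 0.9995 * min(-x[dx < 0] / dx[dx < 0])) else 1
    ad <- if (any(ds < 0)) min(1, 0.9995 * min(-s[ds < 0] / ds[ds < 0])) else 1
    if (ap < 1e-10 && ad < 1e-10) break
    x <- x + ap * dx
    yy <- yy + ad * dy
    s <- s + ad * ds
  }
  if (status != "optimal" && best_merit < 1e-6) status <- "near-optimal"
  list(
    w = pmax(best$x[iw], 0), iterations = best$it, status = status,
    ok = status %in% c("optimal", "near-optimal")
  )
}

# Least-squares refit of the active support on near-zero residual rows;
# never accepted unless it improves (or matches) the L1 objective.
.l1_polish <- function(X, y, w) {
  r <- as.vector(X %*% w) - y
  obj <- sum(abs(r))
  scale_y <- max(abs(y), 1)
  S <- which(w > 1e-7 * max(w, 1))
  Z <- which(abs(r) <= 1e-6 * scale_y)
  if (length(S) == 0 || length(Z) < length(S)) {
    w[w < 1e-10 * max(w, 1)] <- 0
    return(w)
  }
  fit <- tryCatch(
    pracma::lsqnonneg(X[Z, S, drop = FALSE], y[Z]),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(w)
  }
  wp <- rep(0, length(w))
  wp[S] <- fit$x
  if (sum(abs(as.vector(X %*% wp) - y)) <= obj + 1e-9 * (1 + obj)) wp else w
}
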