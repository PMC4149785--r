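# Core restricted maximum-likelihood machinery.
#
# The phenotypic covariance is linear in the parameter vector theta:
#   V(theta) = sum_j theta_j * G_j
# with each G_j a dense symmetric n x n matrix (variance terms contribute
# Z K Z' or the identity; bivariate unstructured terms contribute one
# matrix per (co)variance parameter). This linearity means dV/dtheta_j =
# G_j, and a single Newton-type engine serves univariate and bivariate
# models alike.
#
# Maximisation is by average information (AI) updates with log-likelihood
# step halving, preceded by a couple of EM-flavoured updates for
# stability. Variance parameters that go negative are pinned at a small
# positive boundary; a parameter pinned for 3 consecutive iterations is
# dropped from the AI update until its gradient points back inside.
# Internally the response is scaled to unit variance so tolerances are
# scale-free; estimates, their sampling covariance and the restricted
# log-likelihood are reported on the original scale.

reml_core <- function(y, X, Glist, is_var, init = NULL, fixed = NULL,
                      cov_blocks = list(), max_iter = 200L, n_em = 2L,
                      tol_change = 1e-8, tol_grad = 1e-6, verbose = FALSE) {
  n <- length(y)
  k <- length(Glist)
  p <- ncol(X)
  stopifnot(nrow(X) == n, length(is_var) == k)
  if (is.null(fixed)) fixed <- rep(NA_real_, k)

  s2 <- stats::var(y)
  if (!is.finite(s2) || s2 <= 0) stop("response has zero variance", call. = FALSE)
  ys <- y / sqrt(s2)

  lb <- 1e-8 # boundary for variance parameters, on the scaled problem
  theta <- if (is.null(init)) {
    ifelse(is_var, 1 / sum(is_var), 0)
  } else {
    init / s2
  }
  theta[!is.na(fixed)] <- fixed[!is.na(fixed)] / s2
  free <- is.na(fixed)
  pinned_run <- integer(k)
  jitter_used <- FALSE

  # `full = FALSE` evaluates only the log-likelihood (triangular solves);
  # `full = TRUE` additionally materialises P and Py for the derivatives
  eval_state <- function(theta, full = TRUE) {
    V <- matrix(0, n, n)
    for (j in seq_len(k)) V <- V + theta[j] * Glist[[j]]
    cholV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cholV)) {
      jitter_used <<- TRUE
      cholV <- tryCatch(chol(V + diag(1e-6, n)), error = function(e) NULL)
      if (is.null(cholV)) return(NULL)
    }
    logdetV <- 2 * sum(log(diag(cholV)))
    # V = R'R with R upper triangular; Z = R^{-T} [X y]
    Z <- backsolve(cholV, cbind(X, ys), transpose = TRUE)
    Zx <- Z[, seq_len(p), drop = FALSE]
    Zy <- Z[, p + 1L]
    XtViX <- crossprod(Zx)
    cholXtViX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cholXtViX)) return(NULL)
    logdetXtViX <- 2 * sum(log(diag(cholXtViX)))
    b <- crossprod(Zx, Zy)
    yPy <- sum(Zy^2) - sum(backsolve(cholXtViX, b, transpose = TRUE)^2)
    ll <- -0.5 * (logdetV + logdetXtViX + yPy)
    st <- list(ll = ll, theta = theta, cholV = cholV, cholXtViX = cholXtViX)
    if (full) st <- promote(st)
    st
  }

  # add P and Py to a light state, reusing its Cholesky factors
  promote <- function(st) {
    if (!is.null(st$P)) return(st)
    Vinv <- chol2inv(st$cholV)
    VinvX <- Vinv %*% X
    P <- Vinv - VinvX %*% chol2inv(st$cholXtViX) %*% t(VinvX)
    st$P <- P
    st$Py <- drop(P %*% ys)
    st
  }

  derivs <- function(st) {
    W <- matrix(0, n, k)    # G_j P y
    tr <- numeric(k)        # tr(P G_j)
    for (j in seq_len(k)) {
      W[, j] <- Glist[[j]] %*% st$Py
      tr[j] <- sum(st$P * Glist[[j]])
    }
    q <- drop(crossprod(W, st$Py))     # y' P G_j P y
    grad <- -0.5 * (tr - q)
    PW <- st$P %*% W
    AI <- 0.5 * crossprod(W, PW)
    list(grad = grad, AI = AI, tr = tr, q = q)
  }

  # correlations are clamped strictly inside the unit ball so V keeps a
  # workable condition number even for degenerate (duplicated-trait) data
  cor_max <- 1 - 1e-4
  clamp <- function(theta) {
    theta[is_var & free & theta < lb] <- lb
    for (b in cov_blocks) {
      bound <- sqrt(theta[b[1]] * theta[b[3]]) * cor_max
      if (abs(theta[b[2]]) > bound) theta[b[2]] <- sign(theta[b[2]]) * bound
    }
    theta
  }

  theta <- clamp(theta)
  st <- eval_state(theta)
  if (is.null(st)) stop("initial covariance matrix is not positive definite",
                        call. = FALSE)
  trace <- list()
  converged <- FALSE
  grad_norm <- NA_real_
  iter_used <- max_iter

  last_ll <- st$ll
  for (iter in seq_len(max_iter)) {
    dv <- derivs(st)
    pinned <- is_var & free & theta <= lb * (1 + 1e-9) & dv$grad < 0
    # covariance parameters riding their |cov| <= sqrt(v1 v2) clamp with an
    # outward gradient are treated the same way
    for (b in cov_blocks) {
      bound <- sqrt(theta[b[1]] * theta[b[3]]) * cor_max
      if (abs(theta[b[2]]) >= bound * (1 - 1e-9) &&
          sign(theta[b[2]]) * dv$grad[b[2]] > 0) {
        pinned[b[2]] <- TRUE
      }
    }
    pinned_run <- ifelse(pinned, pinned_run + 1L, 0L)
    active <- free & !(pinned_run >= 3L)
    grad_norm <- sqrt(sum(dv$grad[active]^2))

    if (iter <= n_em) {
      # EM-flavoured update for variance parameters only (stays positive)
      delta <- numeric(k)
      upd <- is_var & free
      delta[upd] <- theta[upd]^2 * (dv$q[upd] - dv$tr[upd]) / n
      theta_new <- clamp(theta + delta)
      st_new <- eval_state(theta_new, full = FALSE)
      if (is.null(st_new) || st_new$ll < st$ll - 1e-10) {
        theta_new <- theta
        st_new <- st
      }
    } else {
      idx <- which(active)
      if (!length(idx)) { converged <- TRUE; iter_used <- iter; break }
      AIf <- dv$AI[idx, idx, drop = FALSE]
      step <- tryCatch(solve(AIf, dv$grad[idx]), error = function(e) NULL)
      if (is.null(step)) step <- drop(pinv(AIf) %*% dv$grad[idx])
      accepted <- FALSE
      fac <- 1
      for (h in seq_len(12)) {
        theta_new <- theta
        theta_new[idx] <- theta[idx] + fac * step
        theta_new <- clamp(theta_new)
        st_new <- eval_state(theta_new, full = FALSE)
        if (!is.null(st_new) && st_new$ll >= st$ll - 1e-10) {
          accepted <- TRUE
          break
        }
        fac <- fac / 2
      }
      if (!accepted) {
        # AI failed even damped; try an EM step for the variances, and if
        # that fails too, stay put (the stall exit below will fire)
        delta <- numeric(k)
        upd <- is_var & free
        delta[upd] <- theta[upd]^2 * (dv$q[upd] - dv$tr[upd]) / n
        theta_new <- clamp(theta + delta)
        st_new <- eval_state(theta_new, full = FALSE)
        if (is.null(st_new) || st_new$ll < st$ll - 1e-10) {
          theta_new <- theta
          st_new <- st
        }
      }
    }

    change <- max(abs(theta_new - theta) / pmax(abs(theta), lb))
    trace[[iter]] <- c(iter = iter, ll = st_new$ll, change = change,
                       grad_norm = grad_norm)
    if (verbose) {
      message(sprintf("iter %3d  ll %.6f  max rel change %.3g  |grad| %.3g",
                      iter, st_new$ll, change, grad_norm))
    }
    theta <- theta_new
    st <- promote(st_new)
    if (iter > n_em && change < tol_change && grad_norm < tol_grad) {
      converged <- TRUE
      iter_used <- iter
      break
    }
    # boundary solutions: relative change alone can stall the gradient test
    if (iter > n_em + 3 && change < tol_change) {
      converged <- TRUE
      iter_used <- iter
      break
    }
    # fully degenerate fits (e.g. correlations clamped at 1) can keep the
    # parameters crawling along the constraint; once the likelihood is
    # numerically flat the maximum is reached
    if (iter > n_em + 3 && abs(st$ll - last_ll) < 1e-9) {
      converged <- TRUE
      iter_used <- iter
      break
    }
    last_ll <- st$ll
  }

  if (!converged) {
    cond <- structure(class = c("wildqg_no_convergence", "error", "condition"),
                      list(message = sprintf(
                        "REML did not converge in %d iterations (last |grad| %.3g)",
                        max_iter, grad_norm),
                        call = NULL, trace = do.call(rbind, trace)))
    stop(cond)
  }

  dv <- derivs(st)
  vcov_s <- tryCatch(solve(dv$AI), error = function(e) pinv(dv$AI))
  at_boundary <- is_var & free & theta <= lb * (1 + 1e-6)

  list(
    theta = theta * s2,
    vcov = vcov_s * s2^2,
    loglik = st$ll - 0.5 * (n - p) * log(s2),
    iterations = iter_used,
    grad_norm = grad_norm,
    boundary = at_boundary,
    jitter_used = jitter_used,
    trace = do.call(rbind, trace),
    scale = s2
  )
}

# Moore-Penrose pseudo-inverse via SVD (used only for tiny AI matrices)
pinv <- function(A, tol = 1e-10) {
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

# Restricted log-likelihood (original scale, constants omitted) at given
# component values; shared by the fitting engine's callers and useful for
# profiling.  V = sum theta_j G_j.
reml_loglik <- function(y, X, Glist, theta) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (j in seq_along(Glist)) V <- V + theta[j] * Glist[[j]]
  cholV <- chol(V)
  Vinv <- chol2inv(cholV)
  VinvX <- Vinv %*% X
  XtViX <- crossprod(X, VinvX)
  cholX <- chol(XtViX)
  Py <- drop(Vinv %*% y) - VinvX %*% solve(XtViX, crossprod(VinvX, y))
  -0.5 * (2 * sum(log(diag(cholV))) + 2 * sum(log(diag(cholX))) + sum(y * Py))
}
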