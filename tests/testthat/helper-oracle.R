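# Independent oracles, deliberately implemented along different
# computational routes from the package code they check.

# Restricted log-likelihood evaluated naively from its definition:
# determinant() + solve(), no Cholesky shortcuts.
oracle_reml_ll <- function(theta, y, X, Glist) {
  V <- Reduce(`+`, Map(`*`, theta, Glist))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  ld1 <- determinant(V, logarithm = TRUE)$modulus
  ld2 <- determinant(XtViX, logarithm = TRUE)$modulus
  as.numeric(-0.5 * (ld1 + ld2 + t(y) %*% P %*% y))
}

# Brute-force restricted-likelihood maximisation: coarse grid over the
# component simplex followed by Nelder-Mead refinement on the log scale,
# from the best few grid points.
oracle_reml_fit <- function(y, X, Glist, lower = NULL) {
  k <- length(Glist)
  vp <- var(y)
  if (is.null(lower)) lower <- 1e-8 * vp
  grid_vals <- vp * c(0.02, 0.1, 0.25, 0.5, 0.75, 1)
  grid <- do.call(expand.grid, rep(list(grid_vals), k))
  ll <- apply(grid, 1, function(th) {
    tryCatch(oracle_reml_ll(as.numeric(th), y, X, Glist),
             error = function(e) -Inf)
  })
  starts <- grid[order(ll, decreasing = TRUE)[1:4], , drop = FALSE]
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    # optimise on log(theta) so the boundary maps to -Inf smoothly
    opt <- optim(log(pmax(as.numeric(starts[s, ]), lower)),
                 function(lt) -tryCatch(oracle_reml_ll(exp(lt), y, X, Glist),
                                        error = function(e) Inf),
                 method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    opt <- optim(opt$par,
                 function(lt) -tryCatch(oracle_reml_ll(exp(lt), y, X, Glist),
                                        error = function(e) Inf),
                 method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  list(theta = pmax(exp(best$par), lower), ll = -best$value)
}

# Gene-dropping kinship: drop unique founder alleles down the pedigree
# many times; kinship(i, j) = P(random allele from i IBD to random allele
# from j); the numerator relationship is twice that, and the diagonal is
# 1 + F with F = P(the two alleles of i are IBD).
oracle_genedrop_A <- function(ped, n_rep = 1e5, seed = 1) {
  withr::with_seed(seed, {
    n <- nrow(ped)
    ord_ped <- pedigree_order(ped)
    idx <- setNames(seq_len(n), ord_ped$id)
    dam_i <- ifelse(is.na(ord_ped$dam), 0L, idx[ord_ped$dam])
    sire_i <- ifelse(is.na(ord_ped$sire), 0L, idx[ord_ped$sire])
    a1 <- matrix(0L, n_rep, n)
    a2 <- matrix(0L, n_rep, n)
    next_allele <- 0L
    for (i in seq_len(n)) {
      if (dam_i[i] == 0L) {
        a1[, i] <- next_allele + 1L
        next_allele <- next_allele + 1L
      } else {
        pick <- runif(n_rep) < 0.5
        a1[, i] <- ifelse(pick, a1[, dam_i[i]], a2[, dam_i[i]])
      }
      if (sire_i[i] == 0L) {
        a2[, i] <- next_allele + 1L
        next_allele <- next_allele + 1L
      } else {
        pick <- runif(n_rep) < 0.5
        a2[, i] <- ifelse(pick, a1[, sire_i[i]], a2[, sire_i[i]])
      }
    }
    A <- matrix(0, n, n, dimnames = list(ord_ped$id, ord_ped$id))
    for (i in seq_len(n)) {
      A[i, i] <- 1 + mean(a1[, i] == a2[, i])
      for (j in seq_len(i - 1L)) {
        ind <- colMeans(cbind(a1[, i] == a1[, j], a1[, i] == a2[, j],
                              a2[, i] == a1[, j], a2[, i] == a2[, j]))
        A[i, j] <- A[j, i] <- 2 * mean(ind)   # 2 x kinship
      }
    }
    A[ped$id, ped$id]
  })
}

# HWE exact probabilities from first principles: exact rational-style
# computation of P(n_Aa | allele count) via products, no lgamma.
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  rare <- min(nA, 2 * n - nA)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  prob_one <- function(h) {
    nAA <- (nA - h) / 2
    naa <- n - nAA - h
    # n! 2^h / (nAA! h! naa!) / choose(2n, nA): build in log space via
    # cumulative sums of logs (different route from lfactorial)
    lf <- function(m) if (m < 2) 0 else sum(log(seq_len(m)))
    exp(lf(n) + h * log(2) - lf(nAA) - lf(h) - lf(naa) -
          (lf(2 * n) - lf(nA) - lf(2 * n - nA)))
  }
  pr <- vapply(hets, prob_one, numeric(1))
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}
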