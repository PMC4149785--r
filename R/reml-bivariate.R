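#' Fit a bivariate animal model and estimate the genetic correlation
#'
#' Records for the two traits are stacked with trait-specific fixed
#' effects (a separate intercept and coefficient set per trait). Every
#' random term carries an unstructured 2x2 (co)variance matrix across the
#' traits. The residual structure is selectable:
#'
#' * `"us"` — unstructured: trait-specific residual variances plus a
#'   residual covariance linking records of the two traits that share the
#'   same `residual_link` key (default the individual id; each individual
#'   may contribute at most one record per trait to the cross-link).
#' * `"idh"` — heterogeneous diagonal: trait-specific residual variances
#'   and zero residual covariance. With `fix_residual` one trait's
#'   residual variance can be fixed near zero, the device for pairing a
#'   repeated live measure with a single post-mortem measure: a
#'   permanent-environment [ran_group()] term on `id` then carries the
#'   non-genetic cross-trait covariance.
#'
#' The genetic correlation `r_G = cov_a(1,2) / sqrt(V_a1 V_a2)` is
#' reported for the first [ran_matrix()] term, with a delta-method
#' standard error from the inverse average-information matrix.
#'
#' @param phenotypes Long phenotype tibble (as for [fit_univariate()]).
#' @param traits Character vector of the two trait names.
#' @param spec A [model_spec()]; its `response` is ignored, its fixed
#'   formula is applied to both traits unless `fixed2` gives a separate
#'   formula for the second trait.
#' @param matrices Named list of [relmat()] objects.
#' @param residual `"us"` or `"idh"`.
#' @param fix_residual Length-2 numeric; non-`NA` entries fix that trait's
#'   residual variance (e.g. `c(NA, 1e-6)`).
#' @param residual_link Column matching records across traits for the
#'   residual covariance under `"us"`.
#' @param fixed2 Optional fixed-effect formula for the second trait.
#' @param ... Passed to the optimiser.
#' @return A `vc_biv_fit` with per-term 2x2 matrices, `r_G`, `se_r_G`,
#'   `vcov`, `loglik`, and convergence details.
#' @export
fit_bivariate <- function(phenotypes, traits, spec, matrices = list(),
                          residual = c("us", "idh"),
                          fix_residual = c(NA, NA), residual_link = "id",
                          fixed2 = NULL, ...) {
  residual <- match.arg(residual)
  stopifnot(length(traits) == 2)
  phenotypes <- tibble::as_tibble(phenotypes)

  mf1 <- build_model_frame(phenotypes, model_spec(traits[1], spec$fixed, spec$random),
                           matrices, check_confounded = FALSE)
  spec2 <- model_spec(traits[2], if (is.null(fixed2)) spec$fixed else fixed2,
                      spec$random)
  mf2 <- build_model_frame(phenotypes, spec2, matrices, check_confounded = FALSE)
  n1 <- mf1$n; n2 <- mf2$n; n <- n1 + n2
  if (length(intersect(mf1$data$id, mf2$data$id)) < 3) {
    stop("fewer than 3 individuals shared or linkable between the traits",
         call. = FALSE)
  }

  y <- c(mf1$y, mf2$y)
  X <- rbind(cbind(mf1$X, matrix(0, n1, ncol(mf2$X))),
             cbind(matrix(0, n2, ncol(mf1$X)), mf2$X))
  o1 <- c(rep(1, n1), rep(0, n2))
  o2 <- 1 - o1
  m11 <- tcrossprod(o1)          # masks selecting the within/cross blocks
  m22 <- tcrossprod(o2)
  m12 <- tcrossprod(o1, o2) + tcrossprod(o2, o1)

  data_all <- dplyr::bind_rows(mf1$data, mf2$data)
  Glist <- list()
  is_var <- logical(0)
  cov_blocks <- list()
  term_param <- list()
  for (nm in names(spec$random)) {
    r <- spec$random[[nm]]
    link <- as.character(data_all[[r$link]])
    Kfull <- if (r$type == "matrix") {
      matrices[[r$matrix]]$values[link, link, drop = FALSE]
    } else {
      (outer(link, link, "==")) * 1
    }
    dimnames(Kfull) <- NULL
    i0 <- length(Glist)
    Glist[[paste0(nm, "_11")]] <- Kfull * m11
    Glist[[paste0(nm, "_12")]] <- Kfull * m12
    Glist[[paste0(nm, "_22")]] <- Kfull * m22
    is_var <- c(is_var, TRUE, FALSE, TRUE)
    cov_blocks[[length(cov_blocks) + 1]] <- i0 + c(1L, 2L, 3L)
    term_param[[nm]] <- i0 + c(1L, 2L, 3L)
  }
  # residual structure
  i0 <- length(Glist)
  Glist[["residual_11"]] <- diag(o1)
  Glist[["residual_22"]] <- diag(o2)
  is_var <- c(is_var, TRUE, TRUE)
  fixed <- rep(NA_real_, length(Glist))
  fixed[i0 + 1L] <- fix_residual[1]
  fixed[i0 + 2L] <- fix_residual[2]
  term_param[["residual"]] <- c(i0 + 1L, NA, i0 + 2L)
  if (residual == "us") {
    key1 <- as.character(mf1$data[[residual_link]])
    key2 <- as.character(mf2$data[[residual_link]])
    if (anyDuplicated(key1) || anyDuplicated(key2)) {
      stop("residual = \"us\" needs a unique '", residual_link,
           "' per trait; use residual = \"idh\" for repeated measures",
           call. = FALSE)
    }
    E12 <- matrix(0, n, n)
    shared <- intersect(key1, key2)
    ii <- match(shared, key1)
    jj <- n1 + match(shared, key2)
    E12[cbind(ii, jj)] <- 1
    E12[cbind(jj, ii)] <- 1
    Glist[["residual_12"]] <- E12
    is_var <- c(is_var, FALSE)
    fixed <- c(fixed, NA_real_)
    cov_blocks[[length(cov_blocks) + 1]] <- c(i0 + 1L, i0 + 3L, i0 + 2L)
    term_param[["residual"]] <- c(i0 + 1L, i0 + 3L, i0 + 2L)
  }

  # moment-based initial values: univariate variance split per trait,
  # covariances started at a mild positive fraction of the bound
  v1 <- stats::var(mf1$y); v2 <- stats::var(mf2$y)
  k_terms <- length(spec$random) + 1L
  init <- numeric(length(Glist))
  for (nm in names(term_param)) {
    tp <- term_param[[nm]]
    init[tp[1]] <- v1 / k_terms
    if (!is.na(tp[2])) init[tp[2]] <- 0.3 * sqrt(init[tp[1]]) * sqrt(v2 / k_terms)
    init[tp[3]] <- v2 / k_terms
  }

  res <- reml_core(y, X, Glist, is_var = is_var, init = init, fixed = fixed,
                   cov_blocks = cov_blocks, ...)
  theta <- stats::setNames(res$theta, names(Glist))
  vcov <- res$vcov
  dimnames(vcov) <- list(names(Glist), names(Glist))

  term_mats <- lapply(term_param, function(tp) {
    cv <- if (is.na(tp[2])) 0 else theta[tp[2]]
    matrix(c(theta[tp[1]], cv, cv, theta[tp[3]]), 2, 2,
           dimnames = list(traits, traits))
  })

  gen_terms <- names(spec$random)[vapply(spec$random, function(r) r$type == "matrix",
                                         logical(1))]
  if (!length(gen_terms)) stop("no genetic (ran_matrix) term in the model",
                               call. = FALSE)
  gt <- gen_terms[1]
  tp <- term_param[[gt]]
  s11 <- theta[tp[1]]; s12 <- theta[tp[2]]; s22 <- theta[tp[3]]
  r_G <- s12 / sqrt(s11 * s22)
  g <- c(-r_G / (2 * s11), 1 / sqrt(s11 * s22), -r_G / (2 * s22))
  Vsub <- vcov[tp, tp]
  se_r_G <- sqrt(max(drop(t(g) %*% Vsub %*% g), 0))
  r_G <- max(-1, min(1, r_G))

  structure(list(
    traits = traits,
    term_matrices = term_mats,
    genetic_term = gt,
    genetic_covariance = unname(s12),
    r_G = unname(r_G),
    se_r_G = se_r_G,
    components = theta,
    vcov = vcov,
    loglik = res$loglik,
    residual_structure = residual,
    convergence = list(iterations = res$iterations, grad_norm = res$grad_norm,
                       boundary = stats::setNames(res$boundary, names(theta)),
                       jitter_used = res$jitter_used),
    n = c(n1 = n1, n2 = n2)
  ), class = "vc_biv_fit")
}

#' @export
print.vc_biv_fit <- function(x, ...) {
  cat(sprintf("# Bivariate animal model fit (REML): %s x %s, n = %d + %d\n",
              x$traits[1], x$traits[2], x$n[1], x$n[2]))
  cat(sprintf("#   logLik = %.3f; genetic covariance = %.4f\n", x$loglik,
              x$genetic_covariance))
  cat(sprintf("#   r_G (%s) = %.3f (SE %.3f)\n", x$genetic_term, x$r_G, x$se_r_G))
  invisible(x)
}
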