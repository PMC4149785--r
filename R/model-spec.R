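#' Specify an animal model
#'
#' A model specification names the response trait, a fixed-effect formula,
#' and an ordered list of random effects. Each random effect is either
#' [ran_matrix()] — a term whose levels are individuals and whose
#' covariance is a named relatedness matrix (additive genetic and maternal
#' genetic effects) — or [ran_group()] — an identity-covariance grouping
#' term (maternal environment, birth year, permanent environment, year of
#' capture). The residual is implicit.
#'
#' @param response Trait name; rows of the phenotype table are filtered to
#'   `trait == response`.
#' @param fixed One-sided formula of fixed effects, e.g.
#'   `~ sex + litter_size + factor(age)`.
#' @param random Named list of [ran_matrix()]/[ran_group()] terms, in the
#'   order they should be reported.
#' @return A `model_spec` object.
#' @examples
#' model_spec("weight", ~ sex + litter_size,
#'            random = list(additive = ran_matrix("id", "A"),
#'                          maternal_env = ran_group("dam"),
#'                          birth_year = ran_group("birth_year")))
#' @export
model_spec <- function(response, fixed = ~1, random = list()) {
  stopifnot(is.character(response), length(response) == 1,
            inherits(fixed, "formula"), is.list(random))
  if (length(random) < 1) {
    stop("at least one random term besides the residual is required",
         call. = FALSE)
  }
  if (is.null(names(random)) || any(names(random) == "")) {
    stop("random terms must be named", call. = FALSE)
  }
  ok <- vapply(random, inherits, logical(1), what = "ran_term")
  if (!all(ok)) stop("random terms must be ran_matrix() or ran_group()",
                     call. = FALSE)
  structure(list(response = response, fixed = fixed, random = random),
            class = "model_spec")
}

#' @rdname model_spec
#' @param link Column of the phenotype table mapping records to effect
#'   levels (e.g. `"id"` for direct genetic, `"dam"` for maternal terms).
#' @param matrix Name of the relatedness matrix in the `matrices` list
#'   passed to [fit_univariate()].
#' @export
ran_matrix <- function(link, matrix) {
  structure(list(type = "matrix", link = link, matrix = matrix),
            class = "ran_term")
}

#' @rdname model_spec
#' @export
ran_group <- function(link) {
  structure(list(type = "group", link = link), class = "ran_term")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("# Animal model spec\n")
  cat("#   response:", x$response, "\n")
  cat("#   fixed:   ", deparse(x$fixed), "\n")
  for (nm in names(x$random)) {
    r <- x$random[[nm]]
    cat(sprintf("#   random:   %s ~ %s on '%s'\n", nm,
                if (r$type == "matrix") paste0("matrix '", r$matrix, "'") else "identity",
                r$link))
  }
  invisible(x)
}

# -------------------------------------------------------------------------

# assemble y, X, per-term n x n covariance structures and bookkeeping from
# a phenotype table + spec; shared by univariate and bivariate fitting
build_model_frame <- function(phenotypes, spec, matrices,
                              check_confounded = TRUE) {
  stopifnot(is.data.frame(phenotypes), inherits(spec, "model_spec"))
  data <- dplyr::filter(tibble::as_tibble(phenotypes),
                        .data$trait == spec$response)
  if (!nrow(data)) stop("no records for trait '", spec$response, "'",
                        call. = FALSE)
  n0 <- nrow(data)

  vars <- unique(c("value", all.vars(spec$fixed),
                   vapply(spec$random, `[[`, character(1), "link")))
  vars <- intersect(vars, names(data))
  miss_fixed <- setdiff(c("value", all.vars(spec$fixed)), names(data))
  if (length(miss_fixed)) {
    stop("phenotype table lacks column(s): ", paste(miss_fixed, collapse = ", "),
         call. = FALSE)
  }
  for (r in spec$random) {
    if (!r$link %in% names(data)) {
      stop("random-term link column '", r$link, "' not in phenotype table",
           call. = FALSE)
    }
  }
  complete <- stats::complete.cases(data[, vars])
  data <- data[complete, ]

  # records whose link ids are absent from a referenced relatedness matrix
  for (nm in names(spec$random)) {
    r <- spec$random[[nm]]
    if (r$type == "matrix") {
      K <- matrices[[r$matrix]]
      if (is.null(K)) stop("relatedness matrix '", r$matrix, "' not supplied",
                           call. = FALSE)
      stopifnot(inherits(K, "relmat"))
      data <- data[data[[r$link]] %in% K$ids, ]
    }
  }
  n <- nrow(data)
  if (n < 3) stop("fewer than 3 usable records", call. = FALSE)
  n_dropped <- n0 - n
  if (n_dropped > 0) {
    message(n_dropped, " record(s) dropped (missing covariates or ids absent ",
            "from a relatedness matrix)")
  }

  y <- data$value
  X <- stats::model.matrix(spec$fixed, data = data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]

  Glist <- list()
  for (nm in names(spec$random)) {
    r <- spec$random[[nm]]
    link <- as.character(data[[r$link]])
    if (r$type == "matrix") {
      K <- matrices[[r$matrix]]
      Glist[[nm]] <- K$values[link, link, drop = FALSE]
    } else {
      Glist[[nm]] <- (outer(link, link, "==")) * 1
    }
    dimnames(Glist[[nm]]) <- NULL
  }
  Glist[["residual"]] <- diag(1, n)

  # confounded structures (e.g. an identity 'genetic' term with single
  # records per individual duplicates the residual); skipped for the
  # per-trait frames of a bivariate model, whose cross-trait blocks break
  # the within-trait aliasing
  if (check_confounded) {
    nms <- names(Glist)
    for (i in seq_along(Glist)) {
      for (j in seq_len(i - 1L)) {
        if (max(abs(Glist[[i]] - Glist[[j]])) < 1e-12) {
          stop("components not separable: random terms '", nms[j], "' and '",
               nms[i], "' imply identical covariance structures", call. = FALSE)
        }
      }
    }
  }
  list(data = data, y = y, X = X, Glist = Glist, n = n, n_dropped = n_dropped)
}

#' Fit a univariate animal model by AI-REML
#'
#' Maximises the restricted log-likelihood
#' `-1/2 (log|V| + log|X'V^-1 X| + y'Py)` over the variance components of
#' `V = sum_r sigma2_r Z_r K_r Z_r' + sigma2_e I` by average-information
#' REML with EM fallback steps. Sampling covariances of the estimates come
#' from the inverse average-information matrix; variance ratios (h2, m2,
#' ...) and their standard errors use the first-order delta method.
#' Estimates that would go negative are pinned at a small positive
#' boundary (1e-8 of the phenotypic variance) and flagged.
#'
#' @param phenotypes A phenotype tibble in long format with at least `id`,
#'   `trait`, `value` plus any fixed-effect and link columns the spec
#'   names. Records with missing model variables, or whose link ids are
#'   absent from a referenced relatedness matrix, are dropped with a
#'   message.
#' @param spec A [model_spec()].
#' @param matrices Named list of [relmat()] objects referenced by the
#'   spec's [ran_matrix()] terms.
#' @param ... Passed to the optimiser (e.g. `max_iter`, `verbose`).
#' @return A `vc_fit` object; see [tidy.vc_fit()] and [glance.vc_fit()].
#'   Components: `components` (named variances incl. `residual`), `vcov`,
#'   `ratios` (tibble with delta-method SEs), `loglik`, `convergence`,
#'   `boundary`, `n`, `n_dropped`.
#' @examples
#' \donttest{
#' sim <- sim_config(n_founders = 60, n_years = 6, n_markers = 200)
#' ped <- simulate_pedigree(sim, seed = 1)
#' A <- numerator_relatedness(ped)
#' phe <- simulate_phenotypes(ped, A, sim, seed = 2)$phenotypes
#' spec <- model_spec("weight", ~ sex, random = list(additive = ran_matrix("id", "A")))
#' fit <- fit_univariate(phe, spec, matrices = list(A = A))
#' tidy(fit)
#' }
#' @export
fit_univariate <- function(phenotypes, spec, matrices = list(), ...) {
  mf <- build_model_frame(phenotypes, spec, matrices)
  k <- length(mf$Glist)
  res <- reml_core(mf$y, mf$X, mf$Glist, is_var = rep(TRUE, k), ...)
  comp <- stats::setNames(res$theta, names(mf$Glist))
  vcov <- res$vcov
  dimnames(vcov) <- list(names(comp), names(comp))
  out <- structure(list(
    components = comp,
    vcov = vcov,
    loglik = res$loglik,
    convergence = list(iterations = res$iterations,
                       grad_norm = res$grad_norm,
                       boundary = stats::setNames(res$boundary, names(comp)),
                       jitter_used = res$jitter_used),
    boundary = stats::setNames(res$boundary, names(comp)),
    n = mf$n,
    n_dropped = mf$n_dropped,
    spec = spec,
    fixed_signature = fixed_signature(spec, mf),
    record_ids = mf$data$id,
    trace = res$trace
  ), class = "vc_fit")
  out$ratios <- variance_ratios(out)
  out
}

# identity of the fixed part + records, for REML LRT validity checks
fixed_signature <- function(spec, mf) {
  list(formula = deparse(spec$fixed), columns = colnames(mf$X), n = mf$n)
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("# Animal model fit (REML): trait '%s', n = %d, logLik = %.3f\n",
              x$spec$response, x$n, x$loglik))
  cat(sprintf("#   converged in %d iterations%s\n", x$convergence$iterations,
              if (any(x$boundary)) paste0("; at boundary: ",
                paste(names(x$boundary)[x$boundary], collapse = ", ")) else ""))
  print(x$ratios)
  invisible(x)
}

#' Variance-component ratios with delta-method standard errors
#'
#' Each fitted component (including the residual) divided by the total
#' phenotypic variance (the sum of all fitted components), the
#' heritability-style ratios of the animal model. Standard errors use the
#' first-order delta method with the full sampling covariance of the
#' estimates.
#'
#' @param result A `vc_fit` from [fit_univariate()].
#' @return A tibble: `term`, `variance`, `se_variance`, `ratio`,
#'   `se_ratio`, `boundary`.
#' @export
variance_ratios <- function(result) {
  stopifnot(inherits(result, "vc_fit"))
  th <- result$components
  S <- sum(th)
  if (S <= 0) stop("total fitted variance is zero", call. = FALSE)
  k <- length(th)
  ratios <- th / S
  se_var <- sqrt(pmax(diag(result$vcov), 0))
  se_ratio <- vapply(seq_len(k), function(r) {
    g <- -th[r] / S^2 + (seq_len(k) == r) / S   # d(theta_r/S)/d(theta_j)
    sqrt(max(drop(t(g) %*% result$vcov %*% g), 0))
  }, numeric(1))
  tibble::tibble(
    term = names(th),
    variance = unname(th),
    se_variance = unname(se_var),
    ratio = unname(ratios),
    se_ratio = se_ratio,
    boundary = unname(result$boundary)
  )
}

#' Likelihood-ratio test for a variance component
#'
#' `statistic = 2 (ll_full - ll_reduced)`, floored at zero, referred to a
#' chi-squared distribution with one degree of freedom (the conventional,
#' conservative choice for a variance component on the boundary; the
#' 50:50 mixture of a point mass at zero and chi-squared(1) is available
#' with `mixture = TRUE`). REML log-likelihoods are only comparable
#' between models with identical fixed-effect structure fitted to the same
#' records; when both arguments are `vc_fit` objects this is enforced.
#'
#' @param full,reduced Fitted `vc_fit` objects (nested: reduced drops one
#'   random term), or raw restricted log-likelihood values.
#' @param mixture Use the boundary mixture distribution for the p-value.
#' @return A tibble: `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced, mixture = FALSE) {
  if (inherits(full, "vc_fit") && inherits(reduced, "vc_fit")) {
    sf <- full$fixed_signature
    sr <- reduced$fixed_signature
    if (!identical(sf$formula, sr$formula) || !identical(sf$columns, sr$columns) ||
        !identical(sf$n, sr$n) || !identical(full$record_ids, reduced$record_ids)) {
      stop("REML LRT invalid across fixed-effect structures or data sets",
           call. = FALSE)
    }
    ll_full <- full$loglik
    ll_reduced <- reduced$loglik
  } else {
    ll_full <- as.numeric(full)
    ll_reduced <- as.numeric(reduced)
  }
  stat <- max(0, 2 * (ll_full - ll_reduced))
  p <- if (mixture) {
    if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  tibble::tibble(statistic = stat, df = 1, p_value = p)
}
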