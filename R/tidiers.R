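#' Tidy a univariate animal-model fit
#'
#' @param x A `vc_fit` from [fit_univariate()].
#' @param ... Unused.
#' @return One row per variance component: `term`, `estimate` (variance),
#'   `std.error`, `ratio` (proportion of phenotypic variance),
#'   `ratio.std.error`, `boundary`.
#' @method tidy vc_fit
#' @export
tidy.vc_fit <- function(x, ...) {
  dplyr::rename(x$ratios, estimate = "variance", std.error = "se_variance",
                ratio.std.error = "se_ratio")
}

#' @rdname tidy.vc_fit
#' @method glance vc_fit
#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    nobs = x$n,
    n_components = length(x$components),
    iterations = x$convergence$iterations,
    boundary_terms = sum(x$boundary),
    n_dropped = x$n_dropped
  )
}

#' Tidy a bivariate animal-model fit
#'
#' @param x A `vc_biv_fit` from [fit_bivariate()].
#' @param ... Unused.
#' @return One row per random term: trait variances, the cross-trait
#'   covariance and the implied correlation.
#' @method tidy vc_biv_fit
#' @export
tidy.vc_biv_fit <- function(x, ...) {
  purrr::imap_dfr(x$term_matrices, function(m, nm) {
    tibble::tibble(
      term = nm,
      var_trait1 = m[1, 1], var_trait2 = m[2, 2], covariance = m[1, 2],
      correlation = if (m[1, 1] > 0 && m[2, 2] > 0)
        m[1, 2] / sqrt(m[1, 1] * m[2, 2]) else NA_real_
    )
  })
}

#' @rdname tidy.vc_biv_fit
#' @method glance vc_biv_fit
#' @export
glance.vc_biv_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    nobs = sum(x$n),
    r_G = x$r_G,
    se_r_G = x$se_r_G,
    iterations = x$convergence$iterations
  )
}

#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) x$per_marker

#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input,
    n_removed_callrate = x$n_removed_callrate,
    n_removed_maf = x$n_removed_maf,
    n_removed_hwe = x$n_removed_hwe,
    n_retained = length(x$retained_markers)
  )
}

#' @method tidy ld_profile
#' @export
tidy.ld_profile <- function(x, ...) x$binned

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
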