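#' Assign phenotype records to age classes
#'
#' Splits a phenotype table into the four analysis age classes:
#'
#' * **neonate** — live capture within 5 days of birth (birth weight);
#' * **lamb** — August data at about 4 months, or post-mortem before 14
#'   months;
#' * **yearling** — August data at about 16 months, or post-mortem from 14
#'   to under 26 months;
#' * **adult** — August data at 28 months or older, or post-mortem at 26
#'   months or older.
#'
#' Live records falling between the August windows (e.g. 5-13 months)
#' match no rule; they are assigned `NA` and counted in a message.
#'
#' @param phenotypes Phenotype tibble with `age_months` and
#'   `measurement_type` (`"august-live"` or `"post-mortem"`).
#' @return The input with columns `age_class` and `age_rule` appended.
#' @export
classify_age <- function(phenotypes) {
  phe <- tibble::as_tibble(phenotypes)
  stopifnot(all(c("age_months", "measurement_type") %in% names(phe)))
  live <- phe$measurement_type == "august-live"
  pm <- phe$measurement_type == "post-mortem"
  age <- phe$age_months
  cls <- dplyr::case_when(
    live & age <= 5 / 30.44 ~ "neonate",
    live & age >= 3 & age < 5 ~ "lamb",
    live & age >= 15 & age < 17 ~ "yearling",
    live & age >= 28 ~ "adult",
    pm & age < 14 ~ "lamb",
    pm & age >= 14 & age < 26 ~ "yearling",
    pm & age >= 26 ~ "adult",
    TRUE ~ NA_character_
  )
  rule <- dplyr::case_when(
    is.na(cls) ~ NA_character_,
    cls == "neonate" ~ "live<=5d",
    live ~ paste0("august@", c(lamb = "4m", yearling = "16m",
                               adult = ">=28m")[cls]),
    TRUE ~ paste0("postmortem@", c(lamb = "<14m", yearling = "14-26m",
                                   adult = ">=26m")[cls])
  )
  n_un <- sum(is.na(cls))
  if (n_un > 0) {
    message(n_un, " record(s) matched no age-class rule and were left unclassified")
  }
  dplyr::mutate(phe, age_class = cls, age_rule = rule)
}

#' Run the univariate comparison grid
#'
#' Fits Model 1 (combined maternal effect) and/or Model 2 (maternal
#' effects split into genetic and environmental components) for every
#' combination of age class, trait and relatedness source, mirroring the
#' design in which two pedigrees of differing quality and a genomic
#' relatedness matrix are compared on the same phenotype data. For Model 2
#' the maternal genetic covariance always comes from the same source as
#' the direct genetic covariance. Permanent-environment and capture-year
#' terms are added for adult August traits (which carry repeated
#' measures). Cell-level failures (non-convergence, too little data) are
#' recorded and the grid continues.
#'
#' @param phenotypes Phenotype tibble; [classify_age()] is applied if an
#'   `age_class` column is absent.
#' @param sources Named list of [relmat()] objects, e.g.
#'   `list(ped1 = A1, ped2 = A2, grm = G)`.
#' @param traits Traits to analyse (default: all in the table).
#' @param age_classes Age classes to analyse (default: all present).
#' @param models `"M1"`, `"M2"` or both.
#' @param fixed Named list of fixed-effect formulas per age class;
#'   defaults follow the standard design (sex and litter size for
#'   juveniles, sex and age-class factors for adults).
#' @param lrt_terms Random terms to test by dropping one at a time against
#'   the full model (`NULL` for none, `"all"` for every random term).
#' @param keep_fits Keep the fitted `vc_fit` objects (attribute `fits`).
#' @param ... Passed to [fit_univariate()].
#' @return A `vc_grid` tibble: one row per cell per component with
#'   `estimate`, `se`, `ratio`, `ratio_se`, `lrt_p`, `n`,
#'   `n_maternities`, `status`.
#' @export
run_comparison <- function(phenotypes, sources, traits = NULL,
                           age_classes = NULL, models = c("M1", "M2"),
                           fixed = NULL, lrt_terms = NULL, keep_fits = FALSE,
                           ...) {
  phe <- tibble::as_tibble(phenotypes)
  if (!"age_class" %in% names(phe)) phe <- classify_age(phe)
  phe <- dplyr::filter(phe, !is.na(.data$age_class))
  if (is.null(traits)) traits <- unique(phe$trait)
  if (is.null(age_classes)) age_classes <- intersect(
    c("neonate", "lamb", "yearling", "adult"), unique(phe$age_class))
  models <- match.arg(models, several.ok = TRUE)
  stopifnot(is.list(sources), length(names(sources)) == length(sources))

  default_fixed <- list(
    neonate = ~ sex + litter_size,
    lamb = ~ sex + litter_size,
    yearling = ~ sex,
    adult = ~ sex + factor(age_months)
  )
  rows <- list()
  fits <- list()
  for (ac in age_classes) {
    fx <- if (!is.null(fixed) && !is.null(fixed[[ac]])) fixed[[ac]] else
      default_fixed[[ac]]
    dat <- dplyr::filter(phe, .data$age_class == ac)
    adult_rep <- ac == "adult" && any(dat$measurement_type == "august-live")
    for (tr in intersect(traits, unique(dat$trait))) {
      for (src in names(sources)) {
        for (model in models) {
          random <- list(additive = ran_matrix("id", src))
          if (model == "M1") {
            random$maternal <- ran_group("dam")
          } else {
            random$maternal_genetic <- ran_matrix("dam", src)
            random$maternal_env <- ran_group("dam")
          }
          random$birth_year <- ran_group("birth_year")
          if (adult_rep && tr %in% unique(
            dat$trait[dat$measurement_type == "august-live"])) {
            random$pe <- ran_group("id")
            random$capture_year <- ran_group("measurement_year")
          }
          spec <- model_spec(tr, fx, random)
          cell <- fit_cell(dat, spec, sources, lrt_terms, ...)
          cell$result <- dplyr::mutate(cell$result, age_class = ac, trait = tr,
                                       source = src, model = model,
                                       .before = 1)
          rows[[length(rows) + 1]] <- cell$result
          if (keep_fits && !is.null(cell$fit)) {
            fits[[paste(ac, tr, src, model, sep = ".")]] <- cell$fit
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("vc_grid", class(out))
  if (keep_fits) attr(out, "fits") <- fits
  out
}

# fit one grid cell, recording failure instead of propagating it
fit_cell <- function(dat, spec, sources, lrt_terms, ...) {
  n_mat <- length(unique(dat$dam[dat$trait == spec$response & !is.na(dat$dam)]))
  fit <- tryCatch(
    suppressMessages(fit_univariate(dat, spec, matrices = sources, ...)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(list(result = tibble::tibble(
      term = NA_character_, estimate = NA_real_, se = NA_real_,
      ratio = NA_real_, ratio_se = NA_real_, lrt_p = NA_real_,
      n = sum(dat$trait == spec$response), n_maternities = n_mat,
      status = paste0("failed: ", conditionMessage(fit))), fit = NULL))
  }
  lrt_p <- stats::setNames(rep(NA_real_, length(spec$random)), names(spec$random))
  if (!is.null(lrt_terms)) {
    terms <- if (identical(lrt_terms, "all")) names(spec$random) else
      intersect(lrt_terms, names(spec$random))
    for (tm in terms) {
      if (length(spec$random) < 2) next
      red_spec <- model_spec(spec$response, spec$fixed,
                             spec$random[setdiff(names(spec$random), tm)])
      red <- tryCatch(
        suppressMessages(fit_univariate(dat, red_spec, matrices = sources, ...)),
        error = function(e) NULL
      )
      if (!is.null(red)) {
        lrt_p[tm] <- likelihood_ratio_test(fit, red)$p_value
      }
    }
  }
  tab <- fit$ratios
  list(result = tibble::tibble(
    term = tab$term, estimate = tab$variance, se = tab$se_variance,
    ratio = tab$ratio, ratio_se = tab$se_ratio,
    lrt_p = unname(lrt_p[tab$term]),
    n = fit$n, n_maternities = n_mat, status = "ok"), fit = fit)
}

#' Refit the comparison grid on a pruned phenotype set
#'
#' Restricts the phenotype records to `keep_ids` and reruns
#' [run_comparison()]. The relatedness matrices are untouched: pedigree
#' links still flow information through unphenotyped relatives; only the
#' phenotyped set shrinks. Used to check whether differences between
#' relatedness sources are explained by sample composition.
#'
#' @param phenotypes,sources,... As for [run_comparison()].
#' @param keep_ids Ids whose records are retained.
#' @return A `vc_grid`.
#' @export
pruned_comparison <- function(phenotypes, sources, keep_ids, ...) {
  stopifnot(length(keep_ids) > 0)
  phe <- dplyr::filter(tibble::as_tibble(phenotypes), .data$id %in% keep_ids)
  if (!nrow(phe)) stop("no phenotype records match keep_ids", call. = FALSE)
  run_comparison(phe, sources, ...)
}

#' Marker-subsampling heritability curve
#'
#' Randomly samples fractions of the available markers without
#' replacement, rebuilds the genomic relatedness matrix from each subset,
#' refits the additive model and stores the heritability estimate —
#' mapping how much of the genetic variance is tagged as a function of
#' marker density. Subset sizes are `round(fraction * M)`. Replicate
#' seeds are derived deterministically from `(seed, fraction index,
#' replicate)`, so any single replicate is reproducible in isolation.
#'
#' @param genotypes Post-QC [geno_matrix()].
#' @param phenotypes Phenotype tibble (already restricted to the records
#'   to analyse, e.g. one adult trait).
#' @param spec A [model_spec()] whose first [ran_matrix()] term references
#'   the matrix name `"grm"`.
#' @param fractions Marker fractions to sample.
#' @param n_replicates Replicates per fraction.
#' @param seed Master seed.
#' @param extra_matrices Additional named matrices the spec references.
#' @param ... Passed to [fit_univariate()].
#' @return A `subsampling_curve` tibble: `fraction`, `replicate`,
#'   `n_markers`, `h2`, `status`, with a `summary` attribute (median and
#'   IQR per fraction).
#' @export
marker_subsampling <- function(genotypes, phenotypes, spec,
                               fractions = c(0.025, 0.05, 0.10, 0.30, 0.50,
                                             0.70, 0.90),
                               n_replicates = 50, seed = 1,
                               extra_matrices = list(), ...) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  M <- ncol(genotypes$dosage)
  gen_term <- spec$random[[which(vapply(spec$random, function(r)
    r$type == "matrix", logical(1)))[1]]]
  rows <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    m_sub <- if (f >= 1) M else round(f * M)
    if (m_sub < 50) stop("fraction ", f, " yields ", m_sub,
                         " markers (< 50)", call. = FALSE)
    for (rep_i in seq_len(n_replicates)) {
      rep_seed <- (seed %% 65536L) * 16384L + fi * 512L + rep_i
      h2 <- tryCatch({
        sub <- with_seed(rep_seed, sample.int(M, m_sub))
        g_sub <- geno_matrix(genotypes$dosage[, sort(sub), drop = FALSE],
                             genotypes$map[sort(sub), ])
        G <- genomic_relatedness(g_sub)
        mats <- c(stats::setNames(list(G), gen_term$matrix), extra_matrices)
        fit <- suppressMessages(fit_univariate(phenotypes, spec,
                                               matrices = mats, ...))
        fit$ratios$ratio[match(names(spec$random)[1], fit$ratios$term)]
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- tibble::tibble(
        fraction = f, replicate = rep_i, n_markers = m_sub, h2 = h2,
        status = if (is.na(h2)) "failed" else "ok")
    }
  }
  out <- dplyr::bind_rows(rows)
  summ <- out |>
    dplyr::filter(!is.na(.data$h2)) |>
    dplyr::group_by(.data$fraction, .data$n_markers) |>
    dplyr::summarise(median_h2 = stats::median(.data$h2),
                     iqr_h2 = stats::IQR(.data$h2),
                     n_ok = dplyr::n(), .groups = "drop")
  attr(out, "summary") <- summ
  class(out) <- c("subsampling_curve", class(out))
  out
}
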