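#' Simulation configuration
#'
#' Bundles every knob of the synthetic study-population generator. The
#' defaults emulate the statistical structure of an intensively monitored,
#' polygynous, overlapping-generation sheep population genotyped on a 50K
#' chip: a pedigree of roughly 5-7 thousand records with large paternal
#' sibships, ~37 thousand autosomal SNPs with median spacing near 50 Kb
#' and adjacent-marker LD r2 around 0.30, body-size phenotypes with
#' direct genetic, maternal genetic, maternal environment, birth-year,
#' permanent-environment, capture-year and residual components, and a
#' degraded-pedigree observation process with ~28% missing and ~4.4%
#' erroneous paternities and ~5.5% missing / ~2.7% erroneous maternities.
#'
#' @param n_founders Founder count (half female).
#' @param n_years Breeding seasons simulated.
#' @param p_breed Probability an adult female produces a litter in a year.
#' @param twin_rate Probability a litter has two lambs.
#' @param polygyny_shape Gamma shape of the per-male annual mating weights;
#'   smaller values give stronger reproductive skew (larger paternal
#'   sibships).
#' @param survival_juvenile,survival_adult Annual survival of lambs /
#'   older animals.
#' @param max_age Maximum age in years.
#' @param n_markers,n_chromosomes Marker panel size and autosome count.
#' @param mean_spacing_bp Mean adjacent-marker spacing (gamma distributed
#'   with shape `spacing_shape`, giving a median near 0.76 x mean).
#' @param spacing_shape Gamma shape of intermarker spacings.
#' @param cm_per_mb Genetic map density.
#' @param ld_target_r2 Target founder LD (r2) between adjacent markers at
#'   the median spacing; 0 gives independent loci.
#' @param maf_freq_autocorr Autocorrelation of allele frequencies along
#'   the chromosome (adjacent markers in strong LD have similar
#'   frequencies); marginally MAF ~ Uniform(0.01, 0.5).
#' @param geno_missing_rate Uniform random genotype missingness.
#' @param sigma2_a,sigma2_ma,sigma2_me,sigma2_by,sigma2_pe,sigma2_cy,sigma2_e
#'   True variance components: direct genetic, maternal genetic, maternal
#'   environment, birth year, permanent environment, capture year,
#'   residual. In trait units squared.
#' @param r_direct_maternal Correlation between direct and maternal
#'   genetic effects (default 0: not fitted in the standard models).
#' @param r_G Genetic correlation between the two traits when
#'   `n_traits = 2`.
#' @param n_traits 1 or 2.
#' @param mu Trait mean(s).
#' @param sex_effect Fixed effect of being male.
#' @param litter_size_effect Fixed effect per extra lamb in the litter.
#' @param age_effect Fixed effect per year of adult age.
#' @param capture_prob Probability an alive animal is captured in a given
#'   August (about two-thirds of residents).
#' @param maternity_missing,maternity_error,paternity_missing,paternity_error
#'   Pedigree degradation rates applied per non-founder link.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 450, n_years = 30,
                       p_breed = 0.9, twin_rate = 0.15,
                       polygyny_shape = 0.3,
                       survival_juvenile = 0.5, survival_adult = 0.72,
                       max_age = 12,
                       n_markers = 37037, n_chromosomes = 26,
                       mean_spacing_bp = 65900, spacing_shape = 1.4,
                       cm_per_mb = 1.3,
                       ld_target_r2 = 0.30, maf_freq_autocorr = 0.95,
                       geno_missing_rate = 0.005,
                       sigma2_a = 0.2, sigma2_ma = 0.1, sigma2_me = 0.1,
                       sigma2_by = 0.1, sigma2_pe = 0.1, sigma2_cy = 0.05,
                       sigma2_e = 0.45,
                       r_direct_maternal = 0, r_G = 0.6, n_traits = 1,
                       mu = 20, sex_effect = 1.5, litter_size_effect = -1,
                       age_effect = 0.2, capture_prob = 2 / 3,
                       maternity_missing = 0.055, maternity_error = 0.027,
                       paternity_missing = 0.28, paternity_error = 0.044) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_founders >= 4, cfg$n_years >= 0,
            all(unlist(cfg[grep("^sigma2_", names(cfg))]) >= 0),
            cfg$ld_target_r2 >= 0, cfg$ld_target_r2 < 1,
            all(unlist(cfg[c("maternity_missing", "maternity_error",
                             "paternity_missing", "paternity_error")]) >= 0),
            all(unlist(cfg[c("maternity_missing", "maternity_error",
                             "paternity_missing", "paternity_error")]) <= 1))
  structure(cfg, class = "sim_config")
}

# run code under a local RNG stream without disturbing the caller's
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulate a polygynous overlapping-generation pedigree
#'
#' Year-structured demography: adult females each produce a litter with
#' probability `p_breed` (twinning with probability `twin_rate`); the sire
#' of each litter is drawn from adult males with gamma-distributed annual
#' mating weights, producing strong reproductive skew and hence larger
#' paternal than maternal sibships. Survival is age-structured. The
#' returned pedigree is topologically ordered and carries a `life` table
#' (`id`, `birth`, `death`) used by [simulate_phenotypes()].
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `ped_tbl` with attribute `life`.
#' @export
simulate_pedigree <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    nf <- config$n_founders
    id <- sprintf("F%04d", seq_len(nf))
    sex <- rep(c("F", "M"), length.out = nf)
    dam <- rep(NA_character_, nf)
    sire <- rep(NA_character_, nf)
    cohort <- rep(0L, nf)
    alive <- rep(TRUE, nf)
    death <- rep(NA_integer_, nf)
    counter <- 0L
    for (t in seq_len(config$n_years)) {
      fem <- which(alive & sex == "F" & cohort < t)
      mal <- which(alive & sex == "M" & cohort < t)
      if (!length(fem) || !length(mal)) {
        stop("population went extinct in year ", t,
             "; increase survival or founder count", call. = FALSE)
      }
      breeds <- fem[stats::runif(length(fem)) < config$p_breed]
      if (length(breeds)) {
        w <- stats::rgamma(length(mal), shape = config$polygyny_shape, rate = 1)
        if (all(w == 0)) w <- rep(1, length(mal))
        litter_sire <- mal[sample.int(length(mal), length(breeds), replace = TRUE,
                                      prob = w)]
        litter_n <- 1L + (stats::runif(length(breeds)) < config$twin_rate)
        n_new <- sum(litter_n)
        new_id <- sprintf("I%06d", counter + seq_len(n_new))
        counter <- counter + n_new
        id <- c(id, new_id)
        dam <- c(dam, rep(id[breeds], litter_n))
        sire <- c(sire, rep(id[litter_sire], litter_n))
        sex <- c(sex, sample(c("F", "M"), n_new, replace = TRUE))
        cohort <- c(cohort, rep(t, n_new))
        alive <- c(alive, rep(TRUE, n_new))
        death <- c(death, rep(NA_integer_, n_new))
      }
      # survival to the next year
      age <- t - cohort
      p_surv <- ifelse(age < 1, config$survival_juvenile, config$survival_adult)
      p_surv[age >= config$max_age] <- 0
      died <- alive & (stats::runif(length(alive)) >= p_surv)
      alive[died] <- FALSE
      death[died] <- t
    }
    death[is.na(death)] <- config$n_years + 1L
    ped <- as_pedigree(tibble::tibble(id = id, dam = dam, sire = sire,
                                      cohort = cohort, sex = sex))
    attr(ped, "life") <- tibble::tibble(id = id, birth = cohort, death = death)
    ped
  })
}

#' Gene-drop genotypes down a pedigree
#'
#' Builds a marker map (gamma-distributed spacings across
#' `n_chromosomes`), draws founder haplotypes from a stationary
#' first-order Markov chain whose adjacent-locus allelic correlation
#' decays with distance and is tuned so that adjacent-marker r2 at the
#' median spacing matches `ld_target_r2`, then transmits haplotypes down
#' the pedigree with Haldane (Poisson crossover) recombination on the
#' genetic map. Allele frequencies are marginally Uniform(0.01, 0.5) with
#' autocorrelation along the chromosome, so that strong local LD remains
#' attainable. The counted allele is the founder-minor allele `"B"`.
#'
#' @param pedigree A topologically ordered `ped_tbl` (e.g. from
#'   [simulate_pedigree()]); any individual with missing parents receives
#'   fresh founder haplotypes.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param unlinked If `TRUE`, every locus segregates independently
#'   (founder LD off, free recombination); used for calibration studies.
#' @return A [geno_matrix()].
#' @export
gene_drop <- function(pedigree, config, seed = 1, unlinked = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  ped <- pedigree_order(pedigree)
  n <- nrow(ped)
  M <- config$n_markers
  n_chr <- config$n_chromosomes
  if (M < n_chr) stop("marker map inconsistent: fewer markers than chromosomes",
                      call. = FALSE)
  with_seed(seed, {
    per_chr <- diff(round(seq(0, M, length.out = n_chr + 1)))
    chrom <- rep(seq_len(n_chr), per_chr)
    gaps <- stats::rgamma(M, shape = config$spacing_shape,
                          scale = config$mean_spacing_bp / config$spacing_shape)
    pos <- unlist(lapply(split(gaps, chrom), cumsum), use.names = FALSE)
    pos <- as.integer(round(pos))
    cm <- pos * config$cm_per_mb / 1e6
    map <- tibble::tibble(marker = sprintf("snp%05d", seq_len(M)),
                          chrom = as.character(chrom), pos = pos, cm = cm,
                          counted = "B", other = "A")

    # allele frequencies: autocorrelated along the chromosome, marginally
    # Uniform(0.01, 0.5)
    phi <- if (unlinked) 0 else config$maf_freq_autocorr
    z <- numeric(M)
    for (c_idx in split(seq_len(M), chrom)) {
      z[c_idx[1]] <- stats::rnorm(1)
      if (length(c_idx) > 1) {
        e <- stats::rnorm(length(c_idx) - 1, sd = sqrt(1 - phi^2))
        for (k in seq_along(e)) z[c_idx[k + 1]] <- phi * z[c_idx[k]] + e[k]
      }
    }
    p <- 0.01 + 0.49 * stats::pnorm(z)

    # per-adjacent-pair target haplotype correlation; the attainable
    # correlation between two binary markers is capped by their allele
    # frequencies, so the requested decay curve is inflated (by analytic
    # root-finding on the generated frequency sequence) until the mean
    # realised adjacent r2 near the median spacing hits the target
    rho <- numeric(M) # rho[i] links locus i-1 -> i within a chromosome
    if (!unlinked && config$ld_target_r2 > 0) {
      med_gap <- stats::median(gaps)
      d_ld <- -med_gap / log(sqrt(config$ld_target_r2))
      first <- !duplicated(chrom)
      rho_base <- exp(-gaps / d_ld)
      rho_base[first] <- 0
      pa <- c(1, p[-M])  # frequency of the left member of each pair
      rho_max <- pmin(sqrt(pa * (1 - p) / ((1 - pa) * p)),
                      sqrt(p * (1 - pa) / ((1 - p) * pa)))
      near <- !first & gaps >= 0.5 * med_gap & gaps <= 1.5 * med_gap
      if (any(near)) {
        fmean <- function(cc) {
          mean(pmin(cc * rho_base[near], rho_max[near])^2) -
            config$ld_target_r2
        }
        cc <- if (fmean(1) >= 0) 1 else {
          upper <- 4
          while (fmean(upper) < 0 && upper < 64) upper <- upper * 2
          if (fmean(upper) < 0) upper else
            stats::uniroot(fmean, c(1, upper))$root
        }
      } else {
        cc <- 1
      }
      rho <- pmin(cc * rho_base, rho_max * (1 - 1e-9))
      rho[first] <- 0
    }

    idx <- stats::setNames(seq_len(n), ped$id)
    dam_i <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
    sire_i <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])

    H1 <- matrix(0L, n, M)
    H2 <- matrix(0L, n, M)
    founder <- which(dam_i == 0L | sire_i == 0L)
    nonf <- which(dam_i > 0L & sire_i > 0L)

    # founder haplotypes: first-order Markov chain across loci
    nh <- 2L * length(founder)
    hap <- matrix(0L, nh, M)
    for (c_idx in split(seq_len(M), chrom)) {
      j0 <- c_idx[1]
      hap[, j0] <- (stats::runif(nh) < p[j0]) * 1L
      for (j in c_idx[-1]) {
        pj <- p[j]; pprev <- p[j - 1]
        cv <- rho[j] * sqrt(pprev * (1 - pprev) * pj * (1 - pj))
        p1 <- pmin(1, pmax(0, pj + cv / pprev))
        p0 <- pmin(1, pmax(0, pj - cv / (1 - pprev)))
        pr <- ifelse(hap[, j - 1] == 1L, p1, p0)
        hap[, j] <- (stats::runif(nh) < pr) * 1L
      }
    }
    H1[founder, ] <- hap[seq_along(founder), ]
    H2[founder, ] <- hap[length(founder) + seq_along(founder), ]

    chr_split <- split(seq_len(M), chrom)
    chr_len_m <- vapply(chr_split, function(ix) (max(cm[ix]) - min(cm[ix])) / 100,
                        numeric(1))
    gamete <- function(h1, h2) {
      if (unlinked) {
        pick <- stats::runif(M) < 0.5
        return(ifelse(pick, h1, h2))
      }
      out <- integer(M)
      for (ci in seq_along(chr_split)) {
        ix <- chr_split[[ci]]
        nx <- stats::rpois(1, chr_len_m[ci])
        phase <- stats::runif(1) < 0.5
        if (nx == 0) {
          out[ix] <- if (phase) h1[ix] else h2[ix]
        } else {
          br <- sort(stats::runif(nx, min(cm[ix]), max(cm[ix])))
          seg <- findInterval(cm[ix], br)
          use1 <- (seg %% 2 == 0) == phase
          out[ix] <- ifelse(use1, h1[ix], h2[ix])
        }
      }
      out
    }
    for (i in nonf) {
      H1[i, ] <- gamete(H1[dam_i[i], ], H2[dam_i[i], ])
      H2[i, ] <- gamete(H1[sire_i[i], ], H2[sire_i[i], ])
    }
    d <- H1 + H2
    if (config$geno_missing_rate > 0) {
      nmiss <- stats::rbinom(1, length(d), config$geno_missing_rate)
      if (nmiss > 0) d[sample.int(length(d), nmiss)] <- NA_integer_
    }
    rownames(d) <- ped$id
    # return individuals in the caller's row order
    orig <- as_pedigree(pedigree)$id
    geno_matrix(d[orig, , drop = FALSE], map)
  })
}

#' Simulate phenotypes with known variance components
#'
#' Generates a long phenotype table from the model
#' `y = fixed effects + a + ma(dam) + me(dam) + birth-year +
#' (pe + capture-year, for repeated adult records) + e`,
#' with every realised draw stored in a truth bundle so that the
#' phenotypes can be reconstructed exactly and estimators can be validated
#' against the generating values.
#'
#' Genetic values come in two modes. In *pedigree mode* breeding values
#' follow the pedigree recursion `a_i = (a_dam + a_sire)/2 + m_i` with
#' Mendelian-sampling deviation `m_i ~ N(0, sigma2_a (1 - (F_dam +
#' F_sire)/2) / 2)` (a missing parent contributes a fresh founder-scale
#' draw). In *causal-locus mode* a supplied genotype matrix provides
#' `n_causal` loci with effects `beta_i ~ N(0, sigma2_a / (n_causal 2 p_i
#' q_i))`, and `a = sum_i (x_i - 2 p_i) beta_i`. Maternal genetic values
#' are generated analogously (pedigree recursion) and enter the phenotype
#' through the dam.
#'
#' @param pedigree A `ped_tbl`, ideally from [simulate_pedigree()] (its
#'   `life` attribute drives the capture schedule; without it every
#'   individual gets single lamb-age records).
#' @param relatedness Either a pedigree-A [relmat()] (its diagonal supplies
#'   inbreeding for the Mendelian-sampling variance; computed internally if
#'   `NULL`) or a [geno_matrix()] to trigger causal-locus mode.
#' @param config A [sim_config()]; variance components, fixed effects and
#'   `n_traits` are read from it.
#' @param seed Integer seed.
#' @param scheme `"age_classes"` (birth, lamb, yearling and repeated adult
#'   August live records, following the capture schedule implied by the
#'   pedigree's `life` table) or `"single"` (one lamb-age record per
#'   individual).
#' @param n_causal Number of causal loci in causal-locus mode.
#' @return A list with `phenotypes` (tibble: `id`, `trait`, `value`,
#'   `age_months`, `measurement_year`, `birth_year`, `sex`, `litter_size`,
#'   `dam`, `measurement_type`) and `truth` (list of all realised draws).
#' @export
simulate_phenotypes <- function(pedigree, relatedness = NULL, config,
                                seed = 1, scheme = c("age_classes", "single"),
                                n_causal = 1000) {
  stopifnot(inherits(config, "sim_config"))
  scheme <- match.arg(scheme)
  ped <- as_pedigree(pedigree)
  life <- attr(pedigree, "life")
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  maternal_on <- config$sigma2_ma > 0 || config$sigma2_me > 0
  n_traits <- config$n_traits
  causal_mode <- inherits(relatedness, "geno_matrix")

  with_seed(seed, {
    # --- genetic values -------------------------------------------------
    s2a <- rep_len(config$sigma2_a, n_traits)
    if (causal_mode) {
      d <- relatedness$dosage
      if (!all(ped$id %in% rownames(d))) {
        stop("genotypes missing for some pedigree ids", call. = FALSE)
      }
      d <- d[ped$id, , drop = FALSE]
      pfreq <- colMeans(d, na.rm = TRUE) / 2
      poly <- which(pfreq > 0 & pfreq < 1)
      if (length(poly) < n_causal) n_causal <- length(poly)
      cls <- sort(sample(poly, n_causal))
      xc <- d[, cls, drop = FALSE]
      pc <- pfreq[cls]
      xc <- sweep(xc, 2, 2 * pc, "-")
      xc[is.na(xc)] <- 0
      beta1 <- stats::rnorm(n_causal, sd = sqrt(s2a[1] / (n_causal * 2 * pc * (1 - pc))))
      a <- matrix(0, n, n_traits)
      a[, 1] <- drop(xc %*% beta1)
      if (n_traits == 2) {
        beta2 <- config$r_G * beta1 * sqrt(s2a[2] / s2a[1]) +
          sqrt(1 - config$r_G^2) *
            stats::rnorm(n_causal, sd = sqrt(s2a[2] / (n_causal * 2 * pc * (1 - pc))))
        a[, 2] <- drop(xc %*% beta2)
      }
      causal <- list(loci = colnames(d)[cls], beta = cbind(beta1))
    } else {
      Fcoef <- if (inherits(relatedness, "relmat")) {
        diag(relatedness$values)[ped$id] - 1
      } else {
        diag(numerator_relatedness(ped)$values)[ped$id] - 1
      }
      corr <- if (n_traits == 2) config$r_G else NULL
      a <- pedigree_trait(ped, idx, s2a, Fcoef, corr)
      causal <- NULL
    }

    # maternal genetic values: always pedigree-mode on the true pedigree;
    # optionally correlated with the direct effects (single-trait,
    # pedigree-mode only)
    dm_corr <- config$r_direct_maternal
    if (!causal_mode && n_traits == 1 && config$sigma2_ma > 0 && dm_corr != 0) {
      both <- pedigree_trait(ped, idx, c(s2a[1], config$sigma2_ma),
                             if (is.null(Fcoef)) rep(0, n) else Fcoef,
                             corr = dm_corr)
      a[, 1] <- both[, 1]
      ma <- both[, 2]
      names(ma) <- ped$id
    } else {
      ma <- NULL
    }
    if (is.null(ma)) ma <- if (config$sigma2_ma > 0) {
      Fc <- if (causal_mode) rep(0, n) else NULL
      if (is.null(Fc)) {
        Fc <- if (inherits(relatedness, "relmat")) {
          diag(relatedness$values)[ped$id] - 1
        } else diag(numerator_relatedness(ped)$values)[ped$id] - 1
      }
      drop(pedigree_trait(ped, idx, config$sigma2_ma, Fc, NULL))
    } else {
      numeric(n)
    }
    me <- stats::rnorm(n, sd = sqrt(config$sigma2_me))   # one draw per dam id
    names(me) <- ped$id
    pe <- stats::rnorm(n, sd = sqrt(config$sigma2_pe))
    names(pe) <- ped$id

    # --- measurement schedule ------------------------------------------
    if (is.null(life)) {
      life <- tibble::tibble(id = ped$id, birth = ped$cohort,
                             death = ped$cohort + 3L)
      life$birth[is.na(life$birth)] <- 0L
      life$death[is.na(life$death)] <- 3L
    }
    birth <- stats::setNames(life$birth, life$id)[ped$id]
    death <- stats::setNames(life$death, life$id)[ped$id]
    litter <- table(paste(ped$dam, ped$cohort))
    litter_size <- ifelse(is.na(ped$dam), 1L,
                          as.integer(litter[paste(ped$dam, ped$cohort)]))

    keep <- if (maternal_on) which(!is.na(ped$dam)) else seq_len(n)
    if (maternal_on && !length(keep)) {
      stop("maternal components requested but no individual has a known dam",
           call. = FALSE)
    }
    recs <- list()
    add_rec <- function(i, age_months, year, type) {
      tibble::tibble(row = i, age_months = age_months, year = year, type = type)
    }
    if (scheme == "single") {
      recs[[1]] <- add_rec(keep, 4, birth[keep], "august-live")
    } else {
      recs[[1]] <- add_rec(keep, 0.07, birth[keep], "august-live") # birth capture
      lamb_ok <- keep[death[keep] > birth[keep]]
      lamb_ok <- lamb_ok[stats::runif(length(lamb_ok)) < config$capture_prob]
      recs[[2]] <- add_rec(lamb_ok, 4, birth[lamb_ok], "august-live")
      yr_ok <- keep[death[keep] > birth[keep] + 1]
      yr_ok <- yr_ok[stats::runif(length(yr_ok)) < config$capture_prob]
      recs[[3]] <- add_rec(yr_ok, 16, birth[yr_ok] + 1L, "august-live")
      # repeated adult August captures while alive (ages 28, 40, ... months)
      for (i in keep) {
        if (death[i] < birth[i] + 2L) next
        yrs <- (birth[i] + 2L):death[i]
        yrs <- yrs[stats::runif(length(yrs)) < config$capture_prob]
        if (length(yrs)) {
          recs[[length(recs) + 1]] <- add_rec(rep(i, length(yrs)),
                                              (yrs - birth[i]) * 12 + 4,
                                              yrs, "august-live")
        }
      }
    }
    rec <- dplyr::bind_rows(recs)

    by_levels <- sort(unique(birth))
    by_eff <- stats::setNames(stats::rnorm(length(by_levels),
                                           sd = sqrt(config$sigma2_by)),
                              by_levels)
    cy_levels <- sort(unique(rec$year))
    cy_eff <- stats::setNames(stats::rnorm(length(cy_levels),
                                           sd = sqrt(config$sigma2_cy)),
                              cy_levels)

    traits <- if (n_traits == 2) c("weight", "hindleg") else "weight"
    mu <- rep_len(config$mu, n_traits)
    out <- list()
    e_store <- list()
    for (tt in seq_len(n_traits)) {
      i <- rec$row
      dam_i <- ped$dam[i]
      adult <- rec$age_months >= 28
      e <- stats::rnorm(nrow(rec), sd = sqrt(config$sigma2_e))
      value <- mu[tt] +
        config$sex_effect * (ped$sex[i] == "M") +
        config$litter_size_effect * (litter_size[i] - 1L) +
        config$age_effect * adult * (rec$age_months / 12) +
        a[i, tt] +
        ifelse(is.na(dam_i), 0, ma[idx[dam_i]]) +
        ifelse(is.na(dam_i), 0, me[dam_i]) +
        by_eff[as.character(birth[i])] +
        adult * (pe[ped$id[i]] + cy_eff[as.character(rec$year)]) +
        e
      out[[tt]] <- tibble::tibble(
        id = ped$id[i], trait = traits[tt], value = unname(value),
        age_months = rec$age_months, measurement_year = rec$year,
        birth_year = birth[i], sex = ped$sex[i],
        litter_size = litter_size[i], dam = dam_i,
        measurement_type = rec$type
      )
      e_store[[tt]] <- e
    }
    phenotypes <- dplyr::bind_rows(out)
    truth <- list(a = a, ma = ma, me = me, pe = pe, by = by_eff, cy = cy_eff,
                  e = e_store, causal = causal, pedigree = ped,
                  litter_size = litter_size, config = config)
    rownames(truth$a) <- ped$id
    list(phenotypes = phenotypes, truth = truth)
  })
}

# breeding-value recursion down a (topologically orderable) pedigree;
# returns an n x T matrix, traits correlated via `corr` when T = 2
pedigree_trait <- function(ped, idx, s2, Fcoef, corr = NULL) {
  n <- nrow(ped)
  Tt <- length(s2)
  ord <- topo_order(ped)
  a <- matrix(0, n, Tt)
  R <- if (Tt == 2) matrix(c(1, corr, corr, 1), 2) else matrix(1)
  cR <- chol(R)
  sds <- sqrt(s2)
  for (i in ord) {
    d <- ped$dam[i]; s <- ped$sire[i]
    di <- if (is.na(d)) 0L else idx[[d]]
    si <- if (is.na(s)) 0L else idx[[s]]
    mid <- numeric(Tt)
    # Mendelian-sampling variance scales: both parents 1/2, one parent 3/4,
    # none 1 (founder), reduced by parental inbreeding where known
    if (di > 0L && si > 0L) {
      vscale <- 0.5 * (1 - (Fcoef[di] + Fcoef[si]) / 2)
      mid <- 0.5 * (a[di, ] + a[si, ])
    } else if (di > 0L) {
      vscale <- 0.75 - Fcoef[di] / 4
      mid <- 0.5 * a[di, ]
    } else if (si > 0L) {
      vscale <- 0.75 - Fcoef[si] / 4
      mid <- 0.5 * a[si, ]
    } else {
      vscale <- 1
    }
    z <- drop(crossprod(cR, stats::rnorm(Tt)))
    a[i, ] <- mid + z * sds * sqrt(max(vscale, 0))
  }
  a
}

#' Degrade a pedigree to emulate field parentage assignment
#'
#' Independently for each non-founder: the sire link is dropped with
#' probability `paternity_missing`, and otherwise replaced with a random
#' cohort-eligible male (born before the offspring) with probability
#' `paternity_error`; analogously for dams. Rates of zero return the
#' pedigree unchanged. A change log is attached as attribute `changes`.
#'
#' @param pedigree A `ped_tbl`.
#' @param config A [sim_config()] carrying the four degradation rates.
#' @param seed Integer seed.
#' @return A `ped_tbl` with attribute `changes` (tibble: `id`, `link`,
#'   `action`, `old`, `new`).
#' @export
degrade_pedigree <- function(pedigree, config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  ped <- as_pedigree(pedigree)
  with_seed(seed, {
    changes <- list()
    for (lk in c("dam", "sire")) {
      p_miss <- if (lk == "dam") config$maternity_missing else config$paternity_missing
      p_err <- if (lk == "dam") config$maternity_error else config$paternity_error
      sex_needed <- if (lk == "dam") "F" else "M"
      has <- which(!is.na(ped[[lk]]))
      if (!length(has)) next
      u <- stats::runif(length(has))
      drop_i <- has[u < p_miss]
      u2 <- stats::runif(length(has))
      err_i <- setdiff(has[u2 < p_err], drop_i)
      if (length(drop_i)) {
        dropped_old <- ped[[lk]][drop_i]
        changes[[length(changes) + 1]] <- tibble::tibble(
          id = ped$id[drop_i], link = lk, action = "dropped",
          old = dropped_old, new = NA_character_)
        ped[[lk]][drop_i] <- NA_character_
      }
      for (i in err_i) {
        old_p <- ped[[lk]][i]
        elig <- ped$id[!is.na(ped$sex) & ped$sex == sex_needed &
                         !is.na(ped$cohort) & !is.na(ped$cohort[i]) &
                         ped$cohort < ped$cohort[i] & ped$id != old_p]
        if (!length(elig)) next
        new_p <- sample(elig, 1)
        changes[[length(changes) + 1]] <- tibble::tibble(
          id = ped$id[i], link = lk, action = "replaced",
          old = old_p, new = new_p)
        ped[[lk]][i] <- new_p
      }
    }
    out <- as_pedigree(ped)
    attr(out, "changes") <- if (length(changes)) dplyr::bind_rows(changes) else
      tibble::tibble(id = character(), link = character(), action = character(),
                     old = character(), new = character())
    attr(out, "life") <- attr(pedigree, "life")
    out
  })
}
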