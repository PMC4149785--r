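small_cfg <- function(...) {
  sim_config(n_founders = 60, n_years = 8, n_markers = 400,
             n_chromosomes = 4, geno_missing_rate = 0, ...)
}

test_that("simulated pedigrees respect demography and reproductive skew", {
  cfg <- small_cfg()
  # no breeding seasons: founders only
  ped0 <- simulate_pedigree(sim_config(n_founders = 20, n_years = 0), seed = 1)
  expect_equal(nrow(ped0), 20)
  expect_true(all(is.na(ped0$dam)))

  ped <- simulate_pedigree(cfg, seed = 2)
  expect_s3_class(ped, "ped_tbl")
  expect_gt(nrow(ped), 100)
  # topologically ordered: parents precede offspring
  pos <- setNames(seq_len(nrow(ped)), ped$id)
  ok <- mapply(function(d, i) is.na(d) || pos[d] < i, ped$dam,
               seq_len(nrow(ped)))
  expect_true(all(ok))
  # parents are of the recorded sex
  sex <- setNames(ped$sex, ped$id)
  expect_true(all(sex[ped$dam[!is.na(ped$dam)]] == "F"))
  expect_true(all(sex[ped$sire[!is.na(ped$sire)]] == "M"))

  # polygyny: paternal sibships exceed maternal sibships on average
  st <- pedigree_statistics(ped, numerator_relatedness(ped))
  expect_gt(st$mean_paternal_sibship, st$mean_maternal_sibship)

  # in the extreme-skew limit the top sire fathers most of each cohort
  cfg_skew <- small_cfg(polygyny_shape = 1e-4)
  ped_skew <- simulate_pedigree(cfg_skew, seed = 3)
  top_share <- dplyr::summarise(
    dplyr::filter(tibble::as_tibble(ped_skew), !is.na(sire)),
    share = max(table(sire)) / dplyr::n(), .by = cohort)
  expect_gt(mean(top_share$share), 0.8)

  # determinism
  expect_identical(simulate_pedigree(cfg, seed = 2), ped)
})

test_that("gene drop transmits Mendelianly and hits the founder LD target", {
  cfg <- small_cfg()
  ped <- simulate_pedigree(cfg, seed = 4)
  g <- gene_drop(ped, cfg, seed = 5)
  expect_equal(rownames(g$dosage), ped$id)

  # offspring share >= 1 allele IBS with each known parent at every locus
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  kids <- which(!is.na(ped$dam))[1:25]
  for (i in kids) {
    for (par in c(ped$dam[i], ped$sire[i])) {
      x <- g$dosage[i, ]; y <- g$dosage[idx[par], ]
      incompatible <- (x == 2 & y == 0) | (x == 0 & y == 2)
      expect_false(any(incompatible, na.rm = TRUE))
    }
  }

  # founder-only population, LD parameter 0: adjacent r2 near zero
  cfg0 <- sim_config(n_founders = 3000, n_years = 0, n_markers = 200,
                     n_chromosomes = 2, ld_target_r2 = 0,
                     geno_missing_rate = 0)
  ped0 <- simulate_pedigree(cfg0, seed = 6)
  g0 <- gene_drop(ped0, cfg0, seed = 7)
  prof0 <- ld_decay(g0, max_rank_distance = 2)
  expect_lt(mean(prof0$pairs$r2), 0.01)

  # LD target: founder adjacent-marker r2 near the configured 0.30
  cfg_ld <- sim_config(n_founders = 1500, n_years = 0, n_markers = 600,
                       n_chromosomes = 3, ld_target_r2 = 0.30,
                       geno_missing_rate = 0)
  ped_ld <- simulate_pedigree(cfg_ld, seed = 8)
  g_ld <- gene_drop(ped_ld, cfg_ld, seed = 9)
  # no MAF screen, offset-1 only: true adjacent pairs near the median gap
  prof <- ld_decay(g_ld, maf_min = 0, max_rank_distance = 2)
  med_gap <- median(diff(g_ld$map$pos))
  near <- dplyr::filter(prof$pairs, dist_bp >= 0.5 * med_gap,
                        dist_bp <= 1.5 * med_gap)
  expect_lt(abs(mean(near$r2) - 0.30), 0.05)

  # MAF distribution roughly uniform on (0.01, 0.5): mean near 0.25
  maf <- marker_stats(g_ld)$maf
  expect_lt(abs(mean(maf) - 0.25), 0.03)

  expect_identical(gene_drop(ped, cfg, seed = 5)$dosage, g$dosage)
})

test_that("simulated phenotypes decompose exactly into their stored truth", {
  cfg <- small_cfg(sigma2_a = 0.3, sigma2_ma = 0.15, sigma2_me = 0.1,
                   sigma2_by = 0.05, sigma2_pe = 0.1, sigma2_cy = 0.05,
                   sigma2_e = 0.4)
  ped <- simulate_pedigree(cfg, seed = 10)
  A <- numerator_relatedness(ped)
  sim <- simulate_phenotypes(ped, A, cfg, seed = 11)
  phe <- sim$phenotypes
  tr <- sim$truth
  expect_gt(nrow(phe), nrow(ped) * 0.5)
  # maternal effects present -> all records have a known dam
  expect_true(all(!is.na(phe$dam)))

  # reconstruct each record from the stored draws
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  adult <- phe$age_months >= 28
  recon <- cfg$mu + cfg$sex_effect * (phe$sex == "M") +
    cfg$litter_size_effect * (phe$litter_size - 1) +
    cfg$age_effect * adult * (phe$age_months / 12) +
    tr$a[idx[phe$id], 1] +
    tr$ma[idx[phe$dam]] + tr$me[phe$dam] +
    tr$by[as.character(phe$birth_year)] +
    adult * (tr$pe[phe$id] + tr$cy[as.character(phe$measurement_year)]) +
    tr$e[[1]]
  expect_equal(phe$value, unname(recon))

  # residual-only model: phenotypic variance tracks sigma2_e
  cfg_e <- sim_config(n_founders = 400, n_years = 6, sigma2_a = 0,
                      sigma2_ma = 0, sigma2_me = 0, sigma2_by = 0,
                      sigma2_pe = 0, sigma2_cy = 0, sigma2_e = 2,
                      sex_effect = 0, litter_size_effect = 0, age_effect = 0)
  ped_e <- simulate_pedigree(cfg_e, seed = 12)
  sim_e <- simulate_phenotypes(ped_e, NULL, cfg_e, seed = 13,
                               scheme = "single")
  expect_gt(nrow(sim_e$phenotypes), 1000)
  expect_equal(var(sim_e$phenotypes$value), 2, tolerance = 0.1)
})

test_that("pedigree-mode breeding values have the theoretical moments", {
  cfg <- sim_config(n_founders = 2000, n_years = 1, sigma2_a = 1)
  ped <- simulate_pedigree(cfg, seed = 14)
  A <- numerator_relatedness(ped)
  sim <- simulate_phenotypes(ped, A, cfg, seed = 15, scheme = "single")
  a <- sim$truth$a[, 1]
  founders <- is.na(ped$dam) & is.na(ped$sire)
  expect_equal(var(a[founders]), 1, tolerance = 0.1)
  kids <- which(!is.na(ped$dam))
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  expect_equal(cov(a[kids], a[idx[ped$dam[kids]]]), 0.5, tolerance = 0.2)
})

test_that("causal-locus mode produces genetic variance tied to the markers", {
  cfg <- small_cfg(sigma2_a = 1, sigma2_ma = 0, sigma2_me = 0, sigma2_by = 0,
                   sigma2_pe = 0, sigma2_cy = 0, sigma2_e = 1)
  ped <- simulate_pedigree(cfg, seed = 16)
  g <- gene_drop(ped, cfg, seed = 17)
  sim <- simulate_phenotypes(ped, g, cfg, seed = 18, scheme = "single",
                             n_causal = 200)
  # realised genetic variance fluctuates with the (LD-correlated) causal
  # draw; require the right scale rather than a tight match
  expect_gt(var(sim$truth$a[, 1]), 0.5)
  expect_lt(var(sim$truth$a[, 1]), 1.7)
  expect_equal(length(sim$truth$causal$loci), 200)
})

test_that("degrade_pedigree hits its target rates and logs changes", {
  cfg <- sim_config(n_founders = 200, n_years = 12)
  ped <- simulate_pedigree(cfg, seed = 19)

  # identity at zero rates
  cfg0 <- sim_config(maternity_missing = 0, maternity_error = 0,
                     paternity_missing = 0, paternity_error = 0)
  same <- degrade_pedigree(ped, cfg0, seed = 20)
  expect_equal(tibble::as_tibble(same), tibble::as_tibble(ped),
               ignore_attr = TRUE)
  expect_equal(nrow(attr(same, "changes")), 0)

  # total paternity loss
  cfg1 <- sim_config(paternity_missing = 1, maternity_missing = 0,
                     maternity_error = 0, paternity_error = 0)
  none <- degrade_pedigree(ped, cfg1, seed = 21)
  expect_true(all(is.na(none$sire)))

  # default rates realised within binomial error
  deg <- degrade_pedigree(ped, sim_config(), seed = 22)
  n_pat <- sum(!is.na(ped$sire))
  changes <- attr(deg, "changes")
  p_drop <- sum(changes$link == "sire" & changes$action == "dropped") / n_pat
  p_err <- sum(changes$link == "sire" & changes$action == "replaced") /
    sum(!is.na(deg$sire))
  se <- function(p, n) sqrt(p * (1 - p) / n)
  expect_lt(abs(p_drop - 0.28), 3 * se(0.28, n_pat))
  expect_lt(abs(p_err - 0.044), 3 * se(0.044, n_pat) + 0.01)
  # replacements are cohort-eligible males
  rep_rows <- changes[changes$action == "replaced" & changes$link == "sire", ]
  sex <- setNames(ped$sex, ped$id)
  coh <- setNames(ped$cohort, ped$id)
  expect_true(all(sex[rep_rows$new] == "M"))
  expect_true(all(coh[rep_rows$new] < coh[rep_rows$id]))
})

test_that("direct-maternal genetic correlation is honoured in pedigree mode", {
  cfg <- sim_config(n_founders = 1200, n_years = 2, sigma2_a = 1,
                    sigma2_ma = 1, r_direct_maternal = 0.5)
  ped <- simulate_pedigree(cfg, seed = 23)
  A <- numerator_relatedness(ped)
  sim <- simulate_phenotypes(ped, A, cfg, seed = 24, scheme = "single")
  expect_equal(cor(sim$truth$a[, 1], sim$truth$ma), 0.5, tolerance = 0.15)
  # and the default remains uncorrelated
  cfg0 <- sim_config(n_founders = 1200, n_years = 2, sigma2_a = 1,
                     sigma2_ma = 1)
  sim0 <- simulate_phenotypes(ped, A, cfg0, seed = 25, scheme = "single")
  expect_lt(abs(cor(sim0$truth$a[, 1], sim0$truth$ma)), 0.1)
})
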