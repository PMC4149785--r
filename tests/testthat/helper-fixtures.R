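# Shared fixtures, all generated in code under fixed seeds.

# minimal trio: two unrelated founders and their offspring
trio_pedigree <- function() {
  as_pedigree(data.frame(id = c("A", "B", "C"),
                         dam = c(NA, NA, "A"),
                         sire = c(NA, NA, "B")))
}

# random valid pedigree: founders plus generations of random matings
random_pedigree <- function(n_founders = 10, n_gen = 3, per_gen = 10,
                            seed = 1) {
  withr::with_seed(seed, {
    id <- sprintf("P%03d", seq_len(n_founders))
    sex <- rep(c("F", "M"), length.out = n_founders)
    dam <- rep(NA_character_, n_founders)
    sire <- rep(NA_character_, n_founders)
    for (g in seq_len(n_gen)) {
      fem <- id[sex == "F"]
      mal <- id[sex == "M"]
      new_id <- sprintf("P%03d", length(id) + seq_len(per_gen))
      id <- c(id, new_id)
      dam <- c(dam, sample(fem, per_gen, replace = TRUE))
      sire <- c(sire, sample(mal, per_gen, replace = TRUE))
      sex <- c(sex, sample(c("F", "M"), per_gen, replace = TRUE))
    }
    as_pedigree(data.frame(id = id, dam = dam, sire = sire, sex = sex))
  })
}

# small genotype matrix with controlled allele frequencies
random_genotypes <- function(n = 50, m = 20, seed = 1, maf = NULL,
                             missing_rate = 0) {
  withr::with_seed(seed, {
    p <- if (is.null(maf)) runif(m, 0.05, 0.5) else rep_len(maf, m)
    d <- sapply(p, function(pp) rbinom(n, 2, pp))
    if (missing_rate > 0) d[runif(length(d)) < missing_rate] <- NA
    rownames(d) <- sprintf("i%03d", seq_len(n))
    geno_matrix(d, data.frame(marker = sprintf("m%03d", seq_len(m)),
                              chrom = "1", pos = seq_len(m) * 1000L,
                              counted = "B", other = "A"))
  })
}

# simple phenotype table on a pedigree: y = a + e drawn from given h2
simple_phenotypes <- function(ped, A, h2 = 0.4, vp = 1, seed = 1,
                              trait = "weight") {
  withr::with_seed(seed, {
    n <- nrow(ped)
    L <- chol(A$values + diag(1e-8, n))
    a <- drop(crossprod(L, rnorm(n))) * sqrt(h2 * vp)
    e <- rnorm(n, sd = sqrt((1 - h2) * vp))
    tibble::tibble(id = ped$id, trait = trait, value = a + e)
  })
}

# small model-fitting fixtures: n <= 30, 2-3 components, built on random
# pedigrees so the additive structure is informative
make_fixture <- function(seed, n_components = 2) {
  withr::with_seed(seed, {
    ped <- random_pedigree(n_founders = 8, n_gen = 2, per_gen = 11,
                           seed = seed)
    A <- numerator_relatedness(ped)
    n <- nrow(ped)
    L <- chol(A$values + diag(1e-8, n))
    a <- drop(crossprod(L, rnorm(n))) * sqrt(0.5)
    dam <- ped$dam
    dam[is.na(dam)] <- paste0("self", seq_len(sum(is.na(dam))))
    me_lev <- unique(dam)
    me <- setNames(rnorm(length(me_lev), sd = sqrt(0.4)), me_lev)
    y <- a + rnorm(n, sd = sqrt(0.6)) + if (n_components == 3) me[dam] else 0
    sex <- rep(c("F", "M"), length.out = n)
    phe <- tibble::tibble(id = ped$id, trait = "w", value = y, sex = sex,
                          dam2 = dam)
    random <- list(additive = ran_matrix("id", "A"))
    if (n_components == 3) random$maternal_env <- ran_group("dam2")
    spec <- model_spec("w", ~sex, random)
    list(phe = phe, spec = spec, A = A)
  })
}

glist_from_fixture <- function(fx) {
  # reconstruct the dense covariance structures the model implies
  link <- fx$phe$id
  G1 <- fx$A$values[link, link]
  out <- list(G1)
  if (length(fx$spec$random) == 2) {
    d <- fx$phe$dam2
    out <- c(out, list(outer(d, d, "==") * 1))
  }
  c(out, list(diag(length(link))))
}

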