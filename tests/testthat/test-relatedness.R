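test_that("tabular A reproduces textbook relationships", {
  A <- numerator_relatedness(trio_pedigree())$values
  expect_equal(A["C", "A"], 0.5)
  expect_equal(A["C", "B"], 0.5)
  expect_equal(diag(A), c(A = 1, B = 1, C = 1))

  # full sibs mated: offspring inbred F = 0.25, diagonal 1.25
  ped <- as_pedigree(data.frame(
    id = c("A", "B", "C", "D", "E"),
    dam = c(NA, NA, "A", "A", "C"),
    sire = c(NA, NA, "B", "B", "D")))
  A2 <- numerator_relatedness(ped)$values
  expect_equal(A2["C", "D"], 0.5)     # full sibs
  expect_equal(A2["E", "E"], 1.25)    # 1 + A_CD / 2
})

test_that("tabular A equals 2x gene-dropping kinship on random pedigrees", {
  for (seed in c(2, 9)) {
    ped <- random_pedigree(n_founders = 12, n_gen = 4, per_gen = 10,
                           seed = seed)
    A <- numerator_relatedness(ped)$values
    Adrop <- oracle_genedrop_A(ped, n_rep = 1e5, seed = seed + 100)
    expect_lt(max(abs(A - Adrop)), 0.01)
  }
})

test_that("pedigree A is positive semidefinite and invariant properties hold", {
  ped <- random_pedigree(n_founders = 10, n_gen = 5, per_gen = 15, seed = 5)
  A <- numerator_relatedness(ped)
  ev <- eigen(A$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_true(all(diag(A$values) >= 1 - 1e-12))
})

test_that("GRM matches the 2pq estimator by hand and is allele-label invariant", {
  # single locus at sample frequency p = 0.5; individuals a, b carry
  # dosage 2: off-diagonal (2-1)(2-1)/0.5 = 2, diagonal
  # 1 + (4 - 2*2 + 0.5)/0.5 = 2
  d <- matrix(c(2L, 2L, 0L, 0L), 4, 1,
              dimnames = list(c("a", "b", "c", "d"), "s1"))
  g <- geno_matrix(d, data.frame(marker = "s1", chrom = "1", pos = 1L))
  G <- genomic_relatedness(g)
  expect_equal(unname(G$values["a", "b"]), 2)
  expect_equal(unname(diag(G$values)[c("a", "b")]), c(2, 2))
  # and dosage-0 individuals mirror them: (0-1)(0-1)/0.5 = 2
  expect_equal(unname(G$values["c", "d"]), 2)
  expect_equal(unname(G$values["a", "c"]), -2)

  # a heterozygote contributes 0 to off-diagonals at p = 0.5
  d3 <- rbind(a = c(1L, 1L), b = c(1L, 1L))
  colnames(d3) <- c("s1", "s2")
  g3 <- geno_matrix(d3, data.frame(marker = c("s1", "s2"), chrom = "1",
                                   pos = c(1L, 2L)))
  G3 <- genomic_relatedness(g3)
  expect_equal(unname(G3$values["a", "b"]), 0)

  # swapping the counted allele (x -> 2 - x) leaves G unchanged
  g4 <- random_genotypes(n = 40, m = 100, seed = 7, missing_rate = 0.02)
  G4 <- genomic_relatedness(g4)
  flip <- g4
  flip$dosage <- 2L - flip$dosage
  G5 <- genomic_relatedness(flip)
  expect_lt(max(abs(G4$values - G5$values)), 1e-12)
})

test_that("GRM of gene-dropped unlinked loci converges to pedigree A", {
  # shallow pedigree: with sample allele frequencies the GRM is centred
  # on the genotyped sample, so G tracks A faithfully only when mean
  # sample relatedness is small
  cfg <- sim_config(n_founders = 120, n_years = 2, n_markers = 6000,
                    n_chromosomes = 6, ld_target_r2 = 0,
                    geno_missing_rate = 0)
  ped <- simulate_pedigree(cfg, seed = 31)
  A <- numerator_relatedness(ped)
  err <- sapply(c(500, 6000), function(m) {
    cfg_m <- cfg
    cfg_m$n_markers <- m
    g <- gene_drop(ped, cfg_m, seed = 32, unlinked = TRUE)
    G <- genomic_relatedness(g)
    mean(abs(G$values - A$values[G$ids, G$ids]))
  })
  expect_lt(err[2], err[1])  # error shrinks with marker count

  # parent-offspring entries track their pedigree expectation (0.5 plus
  # any contribution of parental relatedness/inbreeding)
  cfg$n_markers <- 6000
  g <- gene_drop(ped, cfg, seed = 33, unlinked = TRUE)
  G <- genomic_relatedness(g)$values
  po <- dplyr::filter(tibble::as_tibble(ped), !is.na(dam))
  po_vals <- mapply(function(i, d) G[i, d], po$id, po$dam)
  po_exp <- mapply(function(i, d) A$values[i, d], po$id, po$dam)
  expect_lt(abs(mean(po_vals) - mean(po_exp)), 0.02)
  expect_equal(mean(po_exp), 0.5, tolerance = 0.1)
})

test_that("pedigree_statistics counts sibships, links and inbreeding", {
  # one sibship of 3 full sibs
  ped <- as_pedigree(data.frame(id = c("O1", "O2", "O3"),
                                dam = "A", sire = "B"))
  st <- pedigree_statistics(ped, numerator_relatedness(ped))
  expect_equal(st$full_sibs, 3)
  expect_equal(st$maternities, 3)
  expect_equal(st$paternities, 3)
  expect_equal(st$maternal_sibs, 3)
  expect_equal(st$maternal_half_sibs, 0)
  expect_equal(st$founders, 2)

  # 3 offspring of one dam by 3 sires
  ped2 <- as_pedigree(data.frame(id = c("O1", "O2", "O3"),
                                 dam = "A", sire = c("S1", "S2", "S3")))
  st2 <- pedigree_statistics(ped2, numerator_relatedness(ped2))
  expect_equal(st2$maternal_sibs, 3)
  expect_equal(st2$full_sibs, 0)
  expect_equal(st2$maternal_half_sibs, 3)
  expect_equal(st2$paternal_sibs, 0)

  # sib identities hold exactly on a random pedigree, against brute-force
  # pair enumeration
  ped3 <- random_pedigree(n_founders = 10, n_gen = 3, per_gen = 20, seed = 8)
  st3 <- pedigree_statistics(ped3, numerator_relatedness(ped3))
  expect_equal(st3$maternal_sibs, st3$full_sibs + st3$maternal_half_sibs)
  expect_equal(st3$paternal_sibs, st3$full_sibs + st3$paternal_half_sibs)
  pairs <- t(combn(nrow(ped3), 2))
  same <- function(x, y) !is.na(x) & !is.na(y) & x == y
  dam_p <- ped3$dam[pairs[, 1]]; dam_q <- ped3$dam[pairs[, 2]]
  sire_p <- ped3$sire[pairs[, 1]]; sire_q <- ped3$sire[pairs[, 2]]
  expect_equal(st3$maternal_sibs, sum(same(dam_p, dam_q)))
  expect_equal(st3$paternal_sibs, sum(same(sire_p, sire_q)))
  expect_equal(st3$full_sibs, sum(same(dam_p, dam_q) & same(sire_p, sire_q)))

  # depth: founders at 0
  expect_equal(pedigree_statistics(
    trio_pedigree(), numerator_relatedness(trio_pedigree()))$max_depth, 1)
})

test_that("compare_relatedness recovers affine relationships and slope ~ 1 vs G", {
  g <- random_genotypes(n = 30, m = 300, seed = 13)
  G <- genomic_relatedness(g)
  self <- compare_relatedness(G, G)
  expect_equal(self$slope, 1)
  expect_equal(self$intercept, 0, tolerance = 1e-12)
  expect_equal(self$r_squared, 1)

  Gb <- G
  Gb$values <- 2 * G$values + 0.1
  aff <- compare_relatedness(G, Gb)
  expect_equal(aff$slope, 2)
  expect_equal(aff$intercept, 0.1)
  expect_equal(aff$r_squared, 1)

  expect_error(compare_relatedness(
    relmat(diag(2), "genomic-G", ids = c("x", "y")),
    relmat(diag(2), "genomic-G", ids = c("z", "w"))), "shared")

  # regression of gene-dropped G on pedigree A has slope close to 1
  cfg <- sim_config(n_founders = 50, n_years = 6, n_markers = 5000,
                    n_chromosomes = 5, ld_target_r2 = 0,
                    geno_missing_rate = 0)
  ped <- simulate_pedigree(cfg, seed = 41)
  A <- numerator_relatedness(ped)
  G2 <- genomic_relatedness(gene_drop(ped, cfg, seed = 42, unlinked = TRUE))
  cmp <- compare_relatedness(A, G2)
  expect_lt(abs(cmp$slope - 1), 0.1)
})
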