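#' Numerator relationship matrix from a pedigree
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' method, processing individuals in topological order. For individual `i`
#' with parents `d` and `s`, `A[i, i] = 1 + A[d, s] / 2` (a missing parent
#' contributes 0, so founders have diagonal 1) and for any earlier
#' individual `j`, `A[i, j] = (A[j, d] + A[j, s]) / 2`. The diagonal is
#' `1 + F` with `F` the inbreeding coefficient, and the matrix is positive
#' semidefinite.
#'
#' @param pedigree A [as_pedigree()] table (acyclic; validated on entry).
#' @return A [relmat()] of kind `"pedigree-A"` with ids in the pedigree's
#'   original row order.
#' @examples
#' ped <- as_pedigree(data.frame(id = c("A", "B", "C"),
#'                               dam = c(NA, NA, "A"), sire = c(NA, NA, "B")))
#' numerator_relatedness(ped)$values
#' @export
numerator_relatedness <- function(pedigree) {
  ped <- as_pedigree(pedigree)
  ord <- topo_order(ped)
  if (is.null(ord)) stop("cycle detected in pedigree", call. = FALSE)
  po <- ped[ord, ]
  n <- nrow(po)
  idx <- stats::setNames(seq_len(n), po$id)
  dam_i <- ifelse(is.na(po$dam), 0L, idx[po$dam])
  sire_i <- ifelse(is.na(po$sire), 0L, idx[po$sire])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- dam_i[i]; s <- sire_i[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- numeric(i - 1L)
      if (d > 0L) aj <- aj + A[j, d]
      if (s > 0L) aj <- aj + A[j, s]
      aj <- aj / 2
      A[j, i] <- aj
      A[i, j] <- aj
    }
    A[i, i] <- 1 + if (d > 0L && s > 0L) A[d, s] / 2 else 0
  }
  dimnames(A) <- list(po$id, po$id)
  # return in the original pedigree order
  A <- A[ped$id, ped$id]
  relmat(A, kind = "pedigree-A", provenance = "tabular method")
}

#' Genomic relatedness matrix (2pq-scaled IBS)
#'
#' Computes the GCTA-style genomic relatedness matrix from post-QC dosages.
#' At each locus with counted-allele frequency `p` (estimated from all
#' non-missing dosages), the contribution for a pair (j, k) is
#' `(x_j - 2p)(x_k - 2p) / (2p(1-p))` and for the diagonal
#' `1 + (x^2 - (1+2p)x + 2p^2) / (2p(1-p))`; entries are means over the
#' loci non-missing in both individuals (pairwise-complete). Monomorphic
#' loci are excluded. The estimator is invariant to which allele is
#' counted.
#'
#' @param genotypes A [geno_matrix()].
#' @return A [relmat()] of kind `"genomic-G"` carrying per-pair locus
#'   counts in `nsnps`.
#' @export
genomic_relatedness <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  d <- genotypes$dosage
  n_obs <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  keep <- n_obs > 0 & p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic loci", call. = FALSE)
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  het <- 2 * p * (1 - p)
  obs <- !is.na(d)
  if (any(rowSums(obs) == 0)) {
    stop("individual(s) with zero non-missing loci: ",
         paste(utils::head(rownames(d)[rowSums(obs) == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  # centred, scaled scores with missing set to 0 so cross products skip them
  w <- sweep(d, 2, 2 * p, "-")
  w <- sweep(w, 2, sqrt(het), "/")
  w[!obs] <- 0
  num <- tcrossprod(w)
  cnt <- tcrossprod(obs * 1)
  if (any(cnt[upper.tri(cnt)] == 0)) {
    warning("some pairs share no non-missing loci; their G entries are NA")
  }
  G <- num / ifelse(cnt > 0, cnt, NA)
  # diagonal uses the homozygosity-based estimator, not the plain square
  x <- d; x[!obs] <- 0
  diag_num <- (x * x - sweep(x, 2, 1 + 2 * p, "*")) %*% (1 / het) +
    obs %*% (2 * p^2 / het + 1)
  diag(G) <- diag_num / diag(cnt)
  relmat(G, kind = "genomic-G", nsnps = cnt,
         provenance = sprintf("GCTA 2pq estimator, %d loci", ncol(d)))
}

#' Pedigree summary statistics
#'
#' Computes the standard pedigree-quality summary table: record, link and
#' sibship counts, grandparental links, depth, inbreeding counts from the
#' A-matrix diagonal, and the distribution of pairwise relatedness.
#' "Maternal sibs" share a known dam (full sibs included); "maternal
#' half-sibs" share a known dam but are not confirmed full sibs (a pair
#' with either sire unknown counts as a half-sib pair), so maternal sibs =
#' full sibs + maternal half-sibs by construction, and likewise on the
#' paternal side. Pairwise-relatedness thresholds are evaluated as
#' proportions of off-diagonal pairs.
#'
#' @param pedigree A [as_pedigree()] table.
#' @param A The [numerator_relatedness()] matrix of the same pedigree.
#' @return A one-row tibble of statistics.
#' @export
pedigree_statistics <- function(pedigree, A) {
  ped <- as_pedigree(pedigree)
  stopifnot(inherits(A, "relmat"))
  if (!setequal(ped$id, A$ids)) {
    stop("pedigree and relatedness matrix ids do not match", call. = FALSE)
  }
  n <- nrow(ped)
  pairs2 <- function(k) k * (k - 1) / 2
  sib_pairs <- function(parent) {
    tab <- table(parent[!is.na(parent)])
    sum(pairs2(as.numeric(tab)))
  }
  full_key <- ifelse(is.na(ped$dam) | is.na(ped$sire), NA,
                     paste(ped$dam, ped$sire, sep = "\r"))
  full_sibs <- sib_pairs(full_key)
  mat_sibs <- sib_pairs(ped$dam)
  pat_sibs <- sib_pairs(ped$sire)

  idx <- stats::setNames(seq_len(n), ped$id)
  dam_of <- function(ids) ifelse(is.na(ids), NA, ped$dam[idx[ids]])
  sire_of <- function(ids) ifelse(is.na(ids), NA, ped$sire[idx[ids]])

  # pedigree depth: founders at 0
  ord <- topo_order(ped)
  depth <- stats::setNames(integer(n), ped$id)
  for (i in ord) {
    pd <- c(ped$dam[i], ped$sire[i])
    pd <- pd[!is.na(pd)]
    depth[ped$id[i]] <- if (length(pd)) 1L + max(depth[pd]) else 0L
  }

  Fvals <- diag(A$values)[ped$id] - 1
  off <- A$values[upper.tri(A$values)]
  mean_sibship <- function(parent) {
    tab <- table(parent[!is.na(parent)])
    if (!length(tab)) NA_real_ else mean(as.numeric(tab))
  }

  tibble::tibble(
    records = n,
    maternities = sum(!is.na(ped$dam)),
    paternities = sum(!is.na(ped$sire)),
    full_sibs = full_sibs,
    maternal_sibs = mat_sibs,
    maternal_half_sibs = mat_sibs - full_sibs,
    paternal_sibs = pat_sibs,
    paternal_half_sibs = pat_sibs - full_sibs,
    maternal_grandmothers = sum(!is.na(dam_of(ped$dam))),
    maternal_grandfathers = sum(!is.na(sire_of(ped$dam))),
    paternal_grandmothers = sum(!is.na(dam_of(ped$sire))),
    paternal_grandfathers = sum(!is.na(sire_of(ped$sire))),
    max_depth = max(depth),
    founders = sum(is.na(ped$dam) & is.na(ped$sire)),
    mean_maternal_sibship = mean_sibship(ped$dam),
    mean_paternal_sibship = mean_sibship(ped$sire),
    n_nonzero_F = sum(Fvals > 1e-12),
    n_F_gt_0.125 = sum(Fvals > 0.125),
    mean_pairwise_relatedness = mean(off),
    prop_rel_ge_0.125 = mean(off >= 0.125),
    prop_rel_ge_0.25 = mean(off >= 0.25),
    prop_rel_ge_0.5 = mean(off >= 0.5)
  )
}

#' Compare two relatedness matrices
#'
#' Ordinary least-squares regression of the off-diagonal pairwise
#' relatedness in `b` on the corresponding pairs in `a`, over the ids
#' shared by both matrices, plus per-matrix means and variances of the
#' off-diagonal relatedness.
#'
#' @param a,b [relmat()] objects with at least 3 shared ids.
#' @return A one-row tibble: `intercept`, `slope`, `r_squared`, `mean_a`,
#'   `mean_b`, `var_a`, `var_b`, `n_ids`, `n_pairs`.
#' @export
compare_relatedness <- function(a, b) {
  stopifnot(inherits(a, "relmat"), inherits(b, "relmat"))
  shared <- intersect(a$ids, b$ids)
  if (length(shared) < 3) stop("fewer than 3 shared ids", call. = FALSE)
  va <- a$values[shared, shared]
  vb <- b$values[shared, shared]
  ut <- upper.tri(va)
  xa <- va[ut]; xb <- vb[ut]
  ok <- is.finite(xa) & is.finite(xb)
  xa <- xa[ok]; xb <- xb[ok]
  fit <- stats::lm.fit(cbind(1, xa), xb)
  ssr <- sum(fit$residuals^2)
  sst <- sum((xb - mean(xb))^2)
  tibble::tibble(
    intercept = fit$coefficients[[1]],
    slope = fit$coefficients[[2]],
    r_squared = 1 - ssr / sst,
    mean_a = mean(xa), mean_b = mean(xb),
    var_a = stats::var(xa), var_b = stats::var(xb),
    n_ids = length(shared), n_pairs = length(xa)
  )
}
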