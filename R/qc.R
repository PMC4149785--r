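#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on genotype counts: conditional on the observed
#' allele counts, the probability of each possible heterozygote count is
#' computed from the standard hypergeometric-type distribution
#' `P(n_Aa | n_A, n) = n! 2^n_Aa / (n_AA! n_Aa! n_aa!) / C(2n, n_A)`,
#' and the p-value is the sum of the probabilities of all outcomes no more
#' probable than the observed one (the convention of PLINK's SNP-HWE).
#' A monomorphic marker has only one possible outcome, so p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, at least one
#'   individual in total).
#' @return The exact p-value.
#' @examples
#' hwe_exact_p(0, 0, 10)   # monomorphic: 1
#' hwe_exact_p(0, 10, 0)   # all heterozygous
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero", call. = FALSE)
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_A, 2 * n - n_A)
  if (rare == 0) return(1)
  # possible heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  log_p <- lfactorial(n) + hets * log(2) -
    lfactorial((n_A - hets) / 2) - lfactorial(hets) -
    lfactorial((2 * n - n_A - hets) / 2)
  log_p <- log_p - max(log_p)
  pr <- exp(log_p)
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

#' Marker quality control
#'
#' Filters markers in the fixed order call rate, then minor allele
#' frequency, then Hardy-Weinberg equilibrium, retaining markers with call
#' rate strictly above `callrate_min`, MAF strictly above `maf_min` and
#' exact-test HWE p strictly above `hwe_alpha`. A marker failing several
#' criteria is counted once, at the first failing stage, so the removal
#' counts are disjoint and sum with the retained count to the input count.
#'
#' @param genotypes A [geno_matrix()].
#' @param callrate_min Minimum call rate (retain if strictly greater).
#' @param maf_min Minimum minor allele frequency (strictly greater).
#' @param hwe_alpha HWE significance floor (retain if p strictly greater).
#' @return A list with `genotypes` (filtered [geno_matrix()]) and `report`
#'   (a `qc_report`: removal counts plus a per-marker tibble with
#'   `call_rate`, `maf`, `hwe_p` and the `stage` at which each marker was
#'   removed, `"retained"` otherwise).
#' @export
qc_filter <- function(genotypes, callrate_min = 0.99, maf_min = 0.01,
                      hwe_alpha = 1e-5) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  stats <- marker_stats(genotypes)
  d <- genotypes$dosage
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hwe_exact_p(sum(x == 2), sum(x == 1), sum(x == 0))
  }, numeric(1))
  stage <- rep("retained", ncol(d))
  stage[!is.na(hwe_p) & hwe_p <= hwe_alpha] <- "hwe"
  stage[is.na(stats$maf) | stats$maf <= maf_min] <- "maf"
  stage[stats$call_rate <= callrate_min] <- "callrate"
  keep <- stage == "retained"
  if (!any(keep)) stop("no markers survive QC", call. = FALSE)
  per_marker <- dplyr::mutate(stats, hwe_p = hwe_p, stage = stage)
  report <- structure(list(
    n_input = ncol(d),
    n_removed_callrate = sum(stage == "callrate"),
    n_removed_maf = sum(stage == "maf"),
    n_removed_hwe = sum(stage == "hwe"),
    retained_markers = genotypes$map$marker[keep],
    per_marker = per_marker
  ), class = "qc_report")
  filtered <- geno_matrix(genotypes$dosage[, keep, drop = FALSE],
                          genotypes$map[keep, ])
  list(genotypes = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("# SNP QC: %d markers in; removed %d (call rate), ",
                     "%d (MAF), %d (HWE); %d retained\n"),
              x$n_input, x$n_removed_callrate, x$n_removed_maf,
              x$n_removed_hwe, length(x$retained_markers)))
  invisible(x)
}

#' Linkage disequilibrium decay profile
#'
#' For each focal marker with MAF above `maf_min`, computes the squared
#' Pearson correlation of dosages (complete pairs) against every
#' downstream marker on the same chromosome that also passes the MAF
#' screen, is fewer than `max_rank_distance` such markers away, and lies
#' within `max_bp_distance`. Rank distance is counted among the markers
#' passing the MAF screen. Pair distances are also summarised as the mean
#' r-squared within distance bins of `bin_width` bp.
#'
#' @param genotypes A [geno_matrix()]; the map must be sorted (it is, for
#'   any [geno_matrix()]).
#' @param maf_min MAF screen for both members of a pair.
#' @param max_rank_distance Pairs must be fewer than this many (screened)
#'   markers apart.
#' @param max_bp_distance Pairs must be closer than this many bp.
#' @param bin_width Width of the distance bins for the summary, bp.
#' @return An `ld_profile`: list with `pairs` (tibble: `marker_i`,
#'   `marker_j`, `dist_bp`, `r2`) and `binned` (tibble: `bin_start`,
#'   `bin_mid`, `mean_r2`, `n_pairs`).
#' @export
ld_decay <- function(genotypes, maf_min = 0.05, max_rank_distance = 50,
                     max_bp_distance = 1e6, bin_width = 1e4) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  stats <- marker_stats(genotypes)
  if (is.unsorted(order(factor(stats$chrom, levels = unique(stats$chrom)),
                        stats$pos))) {
    stop("marker map is not sorted", call. = FALSE)
  }
  keep <- which(!is.na(stats$maf) & stats$maf > maf_min)
  out <- vector("list", 0)
  for (chr in unique(stats$chrom[keep])) {
    sel <- keep[stats$chrom[keep] == chr]
    if (length(sel) < 2) next
    x <- genotypes$dosage[, sel, drop = FALSE]
    pos <- stats$pos[sel]
    m <- length(sel)
    for (off in seq_len(min(max_rank_distance - 1L, m - 1L))) {
      i <- seq_len(m - off)
      j <- i + off
      dist <- pos[j] - pos[i]
      ok <- dist < max_bp_distance
      if (!any(ok)) next
      r2 <- pairwise_r2(x[, i[ok], drop = FALSE], x[, j[ok], drop = FALSE])
      out[[length(out) + 1]] <- tibble::tibble(
        marker_i = stats$marker[sel][i[ok]],
        marker_j = stats$marker[sel][j[ok]],
        dist_bp = dist[ok],
        r2 = r2
      )
    }
  }
  pairs <- if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(marker_i = character(), marker_j = character(),
                   dist_bp = integer(), r2 = numeric())
  }
  binned <- pairs |>
    dplyr::filter(is.finite(.data$r2)) |>
    dplyr::mutate(bin_start = floor(.data$dist_bp / bin_width) * bin_width) |>
    dplyr::group_by(.data$bin_start) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(bin_mid = .data$bin_start + bin_width / 2, .after = "bin_start") |>
    dplyr::arrange(.data$bin_start)
  structure(list(pairs = pairs, binned = binned), class = "ld_profile")
}

# squared correlation between matched columns of two dosage matrices,
# complete pairs only, vectorised over columns
pairwise_r2 <- function(xa, xb) {
  ok <- (!is.na(xa)) & (!is.na(xb))
  xa0 <- ifelse(ok, xa, 0)
  xb0 <- ifelse(ok, xb, 0)
  n <- colSums(ok)
  sa <- colSums(xa0); sb <- colSums(xb0)
  saa <- colSums(xa0^2); sbb <- colSums(xb0^2); sab <- colSums(xa0 * xb0)
  cov <- sab - sa * sb / n
  vara <- saa - sa^2 / n
  varb <- sbb - sb^2 / n
  r2 <- cov^2 / (vara * varb)
  r2[n < 2 | vara <= 0 | varb <= 0] <- NA_real_
  unname(pmin(r2, 1))
}

#' @export
print.ld_profile <- function(x, ...) {
  cat(sprintf("# LD profile: %d marker pairs in %d distance bins\n",
              nrow(x$pairs), nrow(x$binned)))
  if (nrow(x$binned)) {
    cat(sprintf("#   mean r2 in first bin (%g-%g bp): %.3f\n",
                x$binned$bin_start[1],
                x$binned$bin_start[1] + 2 * (x$binned$bin_mid[1] - x$binned$bin_start[1]),
                x$binned$mean_r2[1]))
  }
  invisible(x)
}
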