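#' SNP genotype matrices
#'
#' A `geno_matrix` bundles an individuals-by-markers dosage matrix with its
#' marker map. Dosages count copies of the *counted allele* (the minor
#' allele as determined at first read, then frozen in the map) and are
#' integers in `{0, 1, 2}` with `NA` for missing genotypes.
#'
#' @param dosage Integer matrix, individuals in rows (rownames = ids),
#'   markers in columns.
#' @param map A data frame with columns `marker`, `chrom`, `pos` (1-based
#'   bp) and optionally `cm`, `counted`, `other` (allele labels).
#' @return A `geno_matrix` object: list with elements `dosage` (matrix) and
#'   `map` (tibble), ordered by chromosome then position.
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L, 1L), 2,
#'                         dimnames = list(c("a", "b"), c("s1", "s2"))),
#'                  data.frame(marker = c("s1", "s2"), chrom = 1, pos = c(100, 200)))
#' g$map
#' @export
geno_matrix <- function(dosage, map) {
  stopifnot(is.matrix(dosage))
  map <- tibble::as_tibble(map)
  if (!all(c("marker", "chrom", "pos") %in% names(map))) {
    stop("map needs columns marker, chrom, pos", call. = FALSE)
  }
  if (ncol(dosage) != nrow(map)) {
    stop("dosage has ", ncol(dosage), " markers but map has ", nrow(map),
         call. = FALSE)
  }
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (!"cm" %in% names(map)) map$cm <- 0
  if (!"counted" %in% names(map)) map$counted <- NA_character_
  if (!"other" %in% names(map)) map$other <- NA_character_
  if (any(map$pos < 0, na.rm = TRUE)) stop("negative bp position", call. = FALSE)
  if (is.null(rownames(dosage))) {
    stop("dosage matrix needs individual ids as rownames", call. = FALSE)
  }
  colnames(dosage) <- map$marker
  storage.mode(dosage) <- "integer"
  bad <- dosage[!is.na(dosage) & (dosage < 0L | dosage > 2L)]
  if (length(bad)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  # sort by chromosome (order of first appearance) then position
  chrom_f <- factor(map$chrom, levels = unique(map$chrom))
  ord <- order(chrom_f, map$pos)
  structure(list(dosage = dosage[, ord, drop = FALSE], map = map[ord, ]),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("# Genotypes: %d individuals x %d markers on %d chromosome(s), %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Per-marker summaries
#'
#' Counted-allele frequency, minor allele frequency and call rate per
#' marker, computed from non-missing dosages.
#'
#' @param genotypes A [geno_matrix()].
#' @return A tibble with columns `marker`, `chrom`, `pos`, `call_rate`,
#'   `freq` (counted-allele frequency) and `maf`.
#' @export
marker_stats <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  d <- genotypes$dosage
  n_obs <- colSums(!is.na(d))
  freq <- colSums(d, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  freq[n_obs == 0] <- NA_real_
  tibble::tibble(
    marker = genotypes$map$marker,
    chrom = genotypes$map$chrom,
    pos = genotypes$map$pos,
    call_rate = n_obs / nrow(d),
    freq = freq,
    maf = pmin(freq, 1 - freq)
  )
}

#' Read PLINK text genotypes
#'
#' Reads the PLINK `.ped`/`.map` text dialect: six leading columns
#' (family, individual, father, mother, sex, phenotype) followed by two
#' allele columns per SNP; `0` encodes a missing allele. The counted allele
#' for each SNP is the minor allele in the input sample (ties broken by
#' sorting the allele labels), recorded in the map so that dosage coding is
#' stable across read/write round trips.
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @return A [geno_matrix()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  map_raw <- data.table::fread(map_path, header = FALSE, data.table = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) != 4) stop(".map must have 4 columns (chrom, name, cM, bp)",
                               call. = FALSE)
  names(map_raw) <- c("chrom", "marker", "cm", "pos")
  m <- nrow(map_raw)

  ped_raw <- data.table::fread(ped_path, header = FALSE, data.table = FALSE,
                               colClasses = "character")
  if (ncol(ped_raw) != 6 + 2 * m) {
    stop(".ped has ", ncol(ped_raw) - 6, " allele columns but .map lists ",
         m, " SNPs (expected ", 2 * m, " columns)", call. = FALSE)
  }
  ids <- ped_raw[[2]]
  a1 <- as.matrix(ped_raw[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped_raw[, 6 + 2 * seq_len(m), drop = FALSE])
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  # a genotype with one missing allele is treated as wholly missing
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA
  a2[half] <- NA

  counted <- character(m)
  other <- character(m)
  dosage <- matrix(NA_integer_, nrow(ped_raw), m, dimnames = list(ids, map_raw$marker))
  for (j in seq_len(m)) {
    als <- c(a1[, j], a2[, j])
    tab <- sort(table(als[!is.na(als)]))
    if (length(tab) > 2) {
      stop("more than 2 alleles at SNP ", map_raw$marker[j], ": ",
           paste(names(tab), collapse = ","), call. = FALSE)
    }
    if (length(tab) == 0) {
      counted[j] <- NA_character_
      other[j] <- NA_character_
      next
    }
    # minor allele = least frequent; tie -> lexicographically first
    if (length(tab) == 2 && tab[[1]] == tab[[2]]) {
      tab <- tab[order(names(tab))]
    }
    counted[j] <- names(tab)[1]
    other[j] <- if (length(tab) == 2) names(tab)[2] else NA_character_
    dosage[, j] <- (a1[, j] == counted[j]) + (a2[, j] == counted[j])
  }
  map <- tibble::tibble(
    marker = map_raw$marker, chrom = map_raw$chrom,
    pos = as.integer(map_raw$pos), cm = as.numeric(map_raw$cm),
    counted = counted, other = other
  )
  geno_matrix(dosage, map)
}

#' @rdname read_plink_text
#' @param genotypes A [geno_matrix()] with counted/other alleles in its map
#'   (synthetic data uses `"B"`/`"A"`).
#' @param prefix Output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @export
write_plink_text <- function(genotypes, prefix) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  map <- genotypes$map
  counted <- ifelse(is.na(map$counted), "B", map$counted)
  other <- ifelse(is.na(map$other), "A", map$other)
  d <- genotypes$dosage
  n <- nrow(d); m <- ncol(d)
  # allele pair per genotype; dosage counts the counted allele
  al1 <- matrix(rep(other, each = n), n, m)
  al2 <- matrix(rep(other, each = n), n, m)
  al1[!is.na(d) & d >= 1L] <- matrix(rep(counted, each = n), n, m)[!is.na(d) & d >= 1L]
  al2[!is.na(d) & d == 2L] <- matrix(rep(counted, each = n), n, m)[!is.na(d) & d == 2L]
  al1[is.na(d)] <- "0"
  al2[is.na(d)] <- "0"
  inter <- matrix("", n, 2 * m)
  inter[, 2 * seq_len(m) - 1] <- al1
  inter[, 2 * seq_len(m)] <- al2
  ids <- rownames(d)
  lead <- cbind(ids, ids, "0", "0", "0", "-9")
  data.table::fwrite(data.table::as.data.table(cbind(lead, inter)),
                     paste0(prefix, ".ped"), sep = " ", col.names = FALSE,
                     quote = FALSE)
  data.table::fwrite(data.table::data.table(map$chrom, map$marker,
                                            format(map$cm, trim = TRUE),
                                            map$pos),
                     paste0(prefix, ".map"), sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(prefix)
}
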