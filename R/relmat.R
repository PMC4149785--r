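#' Relatedness matrices
#'
#' A `relmat` wraps a symmetric relatedness matrix (pedigree numerator
#' relationship matrix A or genomic relatedness matrix G) with its
#' individual id index, the kind of matrix, and optionally a per-pair count
#' of markers used (for the GRM file's nsnps column).
#'
#' @param values Symmetric numeric matrix with ids as dimnames (or supply
#'   `ids`).
#' @param kind `"pedigree-A"` or `"genomic-G"`.
#' @param ids Character vector of individual ids (defaults to rownames).
#' @param nsnps Optional matrix of per-pair marker counts, same shape as
#'   `values`.
#' @param provenance Free-text description of the source.
#' @return A `relmat` object (list with `ids`, `values`, `kind`, `nsnps`,
#'   `provenance`).
#' @export
relmat <- function(values, kind = c("pedigree-A", "genomic-G"), ids = NULL,
                   nsnps = NULL, provenance = "") {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) stop("relatedness matrix needs ids", call. = FALSE)
  ids <- as.character(ids)
  stopifnot(length(ids) == nrow(values))
  asym <- max(abs(values - t(values)))
  if (asym > 1e-8) {
    stop("relatedness matrix is not symmetric (max |a_ij - a_ji| = ",
         format(asym), ")", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, kind = kind, nsnps = nsnps,
                 provenance = provenance),
            class = "relmat")
}

#' @export
print.relmat <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("# Relatedness matrix (%s): %d individuals\n", x$kind, length(x$ids)))
  cat(sprintf("#   mean diagonal %.4f, mean off-diagonal %.5f, var off-diagonal %.3g\n",
              mean(diag(x$values)), mean(off), stats::var(off)))
  invisible(x)
}

#' @export
dim.relmat <- function(x) dim(x$values)

# submatrix for a set of ids, in the given order
relmat_subset <- function(x, ids) {
  stopifnot(inherits(x, "relmat"))
  miss <- setdiff(ids, x$ids)
  if (length(miss)) {
    stop("ids absent from relatedness matrix: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  x$values[ids, ids, drop = FALSE]
}

#' Write and read GCTA-dialect GRM files
#'
#' Writes the text GRM dialect used by GCTA: `<prefix>.grm.gz` with one row
#' per lower-triangle element (`i j nsnps a_ij`, 1-based indices, diagonal
#' included) and `<prefix>.grm.id` with family and within-family id columns.
#' Values are written with 6 decimals, so a write/read round trip
#' reproduces the matrix to 1e-6.
#'
#' @param matrix A [relmat()].
#' @param prefix Output path prefix.
#' @param nsnps Default marker count written when the matrix carries no
#'   per-pair counts.
#' @return [write_grm_gcta()] returns `prefix` invisibly; [read_grm_gcta()]
#'   returns a [relmat()].
#' @export
write_grm_gcta <- function(matrix, prefix, nsnps = 1L) {
  stopifnot(inherits(matrix, "relmat"))
  v <- matrix$values
  n <- nrow(v)
  ii <- rep(seq_len(n), times = seq_len(n))   # row index of lower triangle,
  jj <- unlist(lapply(seq_len(n), seq_len))   # by row: (1,1),(2,1),(2,2),...
  vals <- v[cbind(ii, jj)]
  cnt <- if (!is.null(matrix$nsnps)) matrix$nsnps[cbind(ii, jj)] else rep(nsnps, length(ii))
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("%d\t%d\t%d\t%.6f", ii, jj, as.integer(round(cnt)), vals), con)
  readr::write_tsv(tibble::tibble(fid = matrix$ids, iid = matrix$ids),
                   paste0(prefix, ".grm.id"), col_names = FALSE, progress = FALSE)
  invisible(prefix)
}

#' @rdname write_grm_gcta
#' @param kind Kind recorded on the matrix read back.
#' @export
read_grm_gcta <- function(prefix, kind = "genomic-G") {
  idf <- readr::read_tsv(paste0(prefix, ".grm.id"), col_names = c("fid", "iid"),
                         col_types = "cc", progress = FALSE)
  ids <- idf$iid
  n <- length(ids)
  tri <- utils::read.table(gzfile(paste0(prefix, ".grm.gz")), header = FALSE,
                           colClasses = c("integer", "integer", "integer", "numeric"))
  names(tri) <- c("i", "j", "nsnps", "value")
  v <- matrix(0, n, n)
  v[cbind(tri$i, tri$j)] <- tri$value
  v[cbind(tri$j, tri$i)] <- tri$value
  cnt <- matrix(0, n, n)
  cnt[cbind(tri$i, tri$j)] <- tri$nsnps
  cnt[cbind(tri$j, tri$i)] <- tri$nsnps
  relmat(v, kind = kind, ids = ids, nsnps = cnt,
         provenance = paste0("read from ", prefix, ".grm.gz"))
}
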