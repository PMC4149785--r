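#' Pedigree tables
#'
#' A pedigree is an ordinary tibble with columns `id`, `dam`, `sire` and
#' optionally `cohort` (integer birth year) and `sex` (`"F"`, `"M"` or `NA`),
#' carrying the class `ped_tbl`. [as_pedigree()] validates a data frame and
#' [read_pedigree()] reads one from CSV. Validation enforces unique ids,
#' resolvable parents (after closure), and acyclicity; a topological order
#' with parents before offspring always exists for a valid pedigree.
#'
#' Missing parents may be encoded as `NA`, the empty string or `"0"` on
#' input; internally they are `NA_character_`, and [write_pedigree()] writes
#' them as `"0"` (the PLINK convention).
#'
#' @param x A data frame with columns `id`, `dam`, `sire` and optionally
#'   `cohort`, `sex`.
#' @return A `ped_tbl` tibble with columns `id`, `dam`, `sire`, `cohort`,
#'   `sex`, in an order where every parent row precedes its offspring rows
#'   is *not* guaranteed; use [pedigree_order()] for that.
#' @examples
#' ped <- as_pedigree(data.frame(id = c("A", "B", "C"),
#'                               dam = c(NA, NA, "A"),
#'                               sire = c(NA, NA, "B")))
#' pedigree_order(ped)
#' @export
as_pedigree <- function(x) {
  stopifnot(is.data.frame(x))
  if (!all(c("id", "dam", "sire") %in% names(x))) {
    stop("pedigree needs columns id, dam, sire", call. = FALSE)
  }
  ped <- tibble::as_tibble(x)
  ped$id <- as.character(ped$id)
  ped$dam <- normalise_parent(ped$dam)
  ped$sire <- normalise_parent(ped$sire)
  if (!"cohort" %in% names(ped)) ped$cohort <- NA_integer_
  ped$cohort <- as.integer(ped$cohort)
  if (!"sex" %in% names(ped)) ped$sex <- NA_character_
  ped$sex <- normalise_sex(ped$sex)
  ped <- ped[, c("id", "dam", "sire", "cohort", "sex")]

  if (anyDuplicated(ped$id)) {
    dup <- unique(ped$id[duplicated(ped$id)])
    stop("duplicate pedigree id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(ped$id) & ped$id == "")) stop("empty id in pedigree", call. = FALSE)

  ped <- close_pedigree(ped)
  check_acyclic(ped)
  class(ped) <- c("ped_tbl", class(tibble::tibble()))
  ped
}

# parents appearing only in dam/sire columns become founder records (closure)
close_pedigree <- function(ped) {
  parents <- unique(c(ped$dam, ped$sire))
  parents <- parents[!is.na(parents)]
  missing_dams <- setdiff(unique(ped$dam[!is.na(ped$dam)]), ped$id)
  missing_sires <- setdiff(unique(ped$sire[!is.na(ped$sire)]), ped$id)
  extra <- union(missing_dams, missing_sires)
  if (!length(extra)) return(ped)
  add <- tibble::tibble(
    id = extra,
    dam = NA_character_,
    sire = NA_character_,
    cohort = NA_integer_,
    sex = dplyr::case_when(
      extra %in% missing_dams & !extra %in% missing_sires ~ "F",
      extra %in% missing_sires & !extra %in% missing_dams ~ "M",
      TRUE ~ NA_character_
    )
  )
  dplyr::bind_rows(add, ped)
}

normalise_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "0" | x == "NA")] <- NA_character_
  x
}

normalise_sex <- function(x) {
  x <- toupper(as.character(x))
  x[!is.na(x) & x %in% c("1", "M", "MALE")] <- "M"
  x[!is.na(x) & x %in% c("2", "F", "FEMALE")] <- "F"
  x[!is.na(x) & !x %in% c("M", "F")] <- NA_character_
  x
}

# Kahn's algorithm; on failure reports one offending id chain
check_acyclic <- function(ped) {
  ord <- topo_order(ped)
  if (!is.null(ord)) return(invisible(TRUE))
  # find a cycle for the error message by walking parent links
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  for (start in seq_len(nrow(ped))) {
    seen <- character()
    i <- start
    repeat {
      id <- ped$id[i]
      if (id %in% seen) {
        chain <- c(seen[which(seen == id):length(seen)], id)
        stop("cycle detected in pedigree: ", paste(chain, collapse = " -> "),
             call. = FALSE)
      }
      seen <- c(seen, id)
      nxt <- ped$dam[i]
      if (is.na(nxt)) nxt <- ped$sire[i]
      if (is.na(nxt)) break
      i <- idx[[nxt]]
    }
  }
  stop("cycle detected in pedigree", call. = FALSE)
}

# returns a permutation of row indices with parents before offspring,
# or NULL if the parent graph has a cycle
topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  dam_i <- ifelse(is.na(ped$dam), NA_integer_, idx[ped$dam])
  sire_i <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(dam_i[i], sire_i[i])) {
      if (!is.na(p) && p != i) {
        children[[p]] <- c(children[[p]], i)
        indeg[i] <- indeg[i] + 1L
      } else if (!is.na(p) && p == i) {
        return(NULL) # self-parent
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[[1]]
    queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) NULL else out
}

#' @describeIn as_pedigree Reorder rows so every parent precedes its
#'   offspring (stable within ties).
#' @param ped A `ped_tbl`.
#' @export
pedigree_order <- function(ped) {
  ped <- as_pedigree(ped)
  ord <- topo_order(ped)
  if (is.null(ord)) stop("cycle detected in pedigree", call. = FALSE)
  out <- ped[ord, ]
  class(out) <- class(ped)
  out
}

#' Read and write pedigree CSV files
#'
#' The file must have a header with at least `id,dam,sire`; `cohort` and
#' `sex` columns are used when present. Missing parents may be written as
#' an empty field, `0` or `NA`. Parents that appear only in the `dam`/`sire`
#' columns are appended as founder records ("closure"), so reading a written
#' closed pedigree adds no records.
#'
#' @param path Path to a CSV file.
#' @return [read_pedigree()] returns a validated `ped_tbl`;
#'   [write_pedigree()] returns `path` invisibly.
#' @export
read_pedigree <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  names(raw) <- tolower(names(raw))
  as_pedigree(raw)
}

#' @rdname read_pedigree
#' @param ped A `ped_tbl` (or coercible data frame).
#' @export
write_pedigree <- function(ped, path) {
  ped <- as_pedigree(ped)
  out <- ped
  out$dam[is.na(out$dam)] <- "0"
  out$sire[is.na(out$sire)] <- "0"
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.ped_tbl <- function(x, ...) {
  founders <- sum(is.na(x$dam) & is.na(x$sire))
  cat(sprintf("# Pedigree: %d records (%d founders, %d maternities, %d paternities)\n",
              nrow(x), founders, sum(!is.na(x$dam)), sum(!is.na(x$sire))))
  NextMethod()
}
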