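#' Read a phenotype table
#'
#' Reads the long-format phenotype CSV used throughout the package: one
#' trait value per row, with columns `id`, `trait`, `value` and any of
#' `age_months`, `measurement_year`, `birth_year`, `sex`, `litter_size`,
#' `dam`, `measurement_type` (`"august-live"` or `"post-mortem"`).
#' Repeated measures within an age class are only expected for adult
#' August records.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  phe <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("id", "trait", "value")
  miss <- setdiff(need, names(phe))
  if (length(miss)) {
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  phe$id <- as.character(phe$id)
  phe$trait <- as.character(phe$trait)
  phe$value <- as.numeric(phe$value)
  if ("dam" %in% names(phe)) phe$dam <- normalise_parent(phe$dam)
  if ("sex" %in% names(phe)) phe$sex <- normalise_sex(phe$sex)
  if ("measurement_type" %in% names(phe)) {
    bad <- setdiff(unique(phe$measurement_type),
                   c("august-live", "post-mortem", NA))
    if (length(bad)) stop("unknown measurement_type: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  phe
}

#' @rdname read_phenotypes
#' @param phenotypes Phenotype tibble.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_csv(tibble::as_tibble(phenotypes), path, progress = FALSE)
  invisible(path)
}
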