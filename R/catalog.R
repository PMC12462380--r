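## Catalog of model records: filtering and plain-text persistence.
## The catalog query surface mirrors a model database: filter by matrix kind,
## taxonomic group, publication year and authors, and sort by any one field.

.recordField <- function(r, field) {
  switch(field,
         name = modelName(r),
         kind = r@kind,
         taxonomic_group = r@taxonomicGroup,
         year = r@year,
         authors = r@authors,
         reference = r@reference,
         comments = r@comments,
         .stopf("unknown catalog field '%s'", field))
}

#' Filter and sort a list of model records
#'
#' Returns exactly the records satisfying every constraint, preserving input
#' order (or sorted by one field when \code{sortBy} is given). Constraints are
#' named entries of \code{criteria}: \code{name}, \code{kind},
#' \code{taxonomic_group} and \code{authors} select by equality (for
#' \code{authors}, by substring), \code{year} by equality, and
#' \code{year_min}/\code{year_max} by bounds. An unknown criterion name is a
#' usage error. Applying two criteria sets in sequence is equivalent to
#' applying their union at once.
#'
#' @param records list of \linkS4class{ModelRecord}.
#' @param criteria named list of constraints (empty: keep everything).
#' @param sortBy optional single field name to sort the result by.
#' @return The filtered (and possibly sorted) list of records.
#' @export
#' @examples
#' m <- RateModel(matrix(c(0, 1, 1, 0), 2), alphabet = c("a", "b"), name = "toy")
#' recs <- list(ModelRecord(m, taxonomicGroup = "viral", year = 2011),
#'              ModelRecord(m, taxonomicGroup = "mitochondrial", year = 1996))
#' length(filterRecords(recs, list(taxonomic_group = "viral")))
filterRecords <- function(records, criteria = list(), sortBy = NULL) {
  known <- c("name", "kind", "taxonomic_group", "year", "year_min", "year_max",
             "authors")
  bad <- setdiff(names(criteria), known)
  if (length(bad))
    .stopf("unknown filter criterion: %s (known: %s)",
           paste(bad, collapse = ", "), paste(known, collapse = ", "))
  keep <- vapply(records, function(r) {
    for (fld in names(criteria)) {
      want <- criteria[[fld]]
      ok <- switch(fld,
        year_min = r@year >= want,
        year_max = r@year <= want,
        authors = grepl(want, r@authors, fixed = TRUE),
        .recordField(r, fld) == want)
      if (!ok) return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- records[keep]
  if (!is.null(sortBy)) {
    sortable <- c("name", "kind", "taxonomic_group", "year", "authors")
    if (!sortBy %in% sortable)
      .stopf("cannot sort by '%s' (one of: %s)", sortBy, paste(sortable, collapse = ", "))
    vals <- sapply(out, .recordField, field = sortBy)
    out <- out[order(vals)]
  }
  out
}

#' Write a model catalog to a directory
#'
#' Persists the catalog as one model file per record (PAML format for rate
#' models, labeled score format for score models) plus a tab-separated
#' \code{metadata.tsv} with columns name, kind, taxonomic_group, year,
#' authors, reference, comments, file.
#'
#' @param records list of \linkS4class{ModelRecord}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the metadata data.frame.
#' @seealso \code{\link{readModelCatalog}}
#' @export
writeModelCatalog <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(
    name = vapply(records, modelName, ""),
    kind = vapply(records, function(r) r@kind, ""),
    taxonomic_group = vapply(records, function(r) r@taxonomicGroup, ""),
    year = vapply(records, function(r) r@year, 1L),
    authors = vapply(records, function(r) r@authors, ""),
    reference = vapply(records, function(r) r@reference, ""),
    comments = vapply(records, function(r) r@comments, ""),
    stringsAsFactors = FALSE)
  if (anyDuplicated(meta$name)) .stopf("record names must be unique within a catalog")
  meta$file <- paste0(meta$name, ifelse(meta$kind == "rate", ".dat", ".score"))
  for (i in seq_along(records)) {
    path <- file.path(dir, meta$file[i])
    if (meta$kind[i] == "rate") writePaml(records[[i]]@model, path)
    else writeScore(records[[i]]@model, path)
  }
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(meta)
}

#' Read a model catalog from a directory
#'
#' @param dir directory holding \code{metadata.tsv} and the model files
#'   written by \code{\link{writeModelCatalog}}.
#' @param alphabet symbol order for the model files.
#' @return List of \linkS4class{ModelRecord}.
#' @export
readModelCatalog <- function(dir, alphabet = aminoAcids()) {
  meta <- read.delim(file.path(dir, "metadata.tsv"), stringsAsFactors = FALSE,
                     colClasses = "character")
  lapply(seq_len(nrow(meta)), function(i) {
    path <- file.path(dir, meta$file[i])
    model <- if (meta$kind[i] == "rate")
      parsePaml(path, alphabet = alphabet, name = meta$name[i])
    else parseScore(path, alphabet = alphabet, name = meta$name[i])
    ModelRecord(model, kind = meta$kind[i],
                taxonomicGroup = meta$taxonomic_group[i],
                year = as.integer(meta$year[i]), authors = meta$authors[i],
                reference = meta$reference[i], comments = meta$comments[i])
  })
}
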