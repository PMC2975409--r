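#' Read and write the pipeline's tabular formats
#'
#' All tabular artifacts are tab-separated text. An intensity table has the
#' feature identifier in the first column and one numeric column per
#' sample; the group map and peptide map are two-column TSVs; a biomarker
#' set is one identifier per line with the set name in a `# name:` header
#' comment; pathway annotations use the GMT format (set name, description,
#' then member identifiers, tab-separated).
#'
#' @param data,path,x Table to write / file path / object to write.
#' @return Readers return tibbles (or the package's objects); writers
#'   return the path invisibly.
#' @name permpanel-io
NULL

#' @rdname permpanel-io
#' @export
write_intensity_tsv <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' @rdname permpanel-io
#' @export
read_intensity_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' @rdname permpanel-io
#' @export
write_group_map <- function(data, path) {
  readr::write_tsv(data[, c("sample_id", "group")], path)
  invisible(path)
}

#' @rdname permpanel-io
#' @export
read_group_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname permpanel-io
#' @export
write_peptide_map <- function(data, path) {
  readr::write_tsv(data[, c("peptide_id", "protein_id")], path)
  invisible(path)
}

#' @rdname permpanel-io
#' @export
read_peptide_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname permpanel-io
#' @export
write_biomarker_set <- function(x, path) {
  x <- as_biomarker_set(x)
  writeLines(c(sprintf("# name: %s", x$name), x$members), path)
  invisible(path)
}

#' @rdname permpanel-io
#' @export
read_biomarker_set <- function(path) {
  lines <- readLines(path)
  name_line <- grep("^#\\s*name:", lines, value = TRUE)
  name <- if (length(name_line) > 0) {
    trimws(sub("^#\\s*name:\\s*", "", name_line[1]))
  } else {
    tools::file_path_sans_ext(basename(path))
  }
  members <- trimws(lines[!grepl("^#", lines)])
  biomarker_set(name, members[nzchar(members)])
}

#' Read a GMT gene-set file as a pathway annotation
#'
#' @param path GMT file: one set per line, fields `name`, `description`,
#'   then member identifiers, tab-separated.
#' @param universe Optional background universe; defaults to the union of
#'   all members.
#' @return A [pathway_annotation()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 2
  if (any(bad)) abort(sprintf("Malformed GMT line(s): %s",
                              paste(head(which(bad), 3), collapse = ", ")))
  sets <- purrr::map(fields, ~ unique(.x[-(1:2)]))
  names(sets) <- purrr::map_chr(fields, 1)
  pathway_annotation(sets, universe = universe)
}

#' Write a pathway annotation as a GMT file
#'
#' @param annotation A [pathway_annotation()].
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to `"na"`).
#' @return The path, invisibly.
#' @export
write_gmt <- function(annotation, path, descriptions = NULL) {
  check_annotation(annotation)
  n <- length(annotation$sets)
  if (is.null(descriptions)) descriptions <- rep("na", n)
  lines <- purrr::imap_chr(annotation$sets, function(m, nm) {
    i <- match(nm, names(annotation$sets))
    paste(c(nm, descriptions[i], m), collapse = "\t")
  })
  writeLines(unname(lines), path)
  invisible(path)
}
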