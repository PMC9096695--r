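#' Read and write pipeline file formats
#'
#' Plain-text readers/writers for every artifact the pipeline exchanges:
#' CNV calls as BED-like 6-column TSV (`sample_id`, `chrom`, `start`,
#' `end`, `type`, `platform`; 0-based half-open coordinates), the gene
#' annotation TSV, cohort and brain-volume CSVs, pathogenic regions as a
#' 4-column BED (`chrom`, `start`, `end`, `type`), and normative reference
#' curves as TSV with the study offset in a `# offset:` header line.
#'
#' @param x Object to write.
#' @param path File path.
#' @return Readers return tibbles (the reference reader returns a
#'   `normative_reference`); writers return `path` invisibly.
#' @name cnvrisk_io
NULL

#' @rdname cnvrisk_io
#' @export
write_cnv_calls <- function(x, path) {
  readr::write_tsv(x[c("sample_id", "chrom", "start", "end", "type", "platform")],
                   path)
  invisible(path)
}

#' @rdname cnvrisk_io
#' @export
read_cnv_calls <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         sample_id = "c", chrom = "c", start = "d",
                         end = "d", type = "c", platform = "c"
                       ))
  x$qc_pass <- TRUE
  x
}

#' @rdname cnvrisk_io
#' @export
write_gene_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname cnvrisk_io
#' @export
read_gene_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname cnvrisk_io
#' @export
write_cohort <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname cnvrisk_io
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname cnvrisk_io
#' @export
write_brain <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname cnvrisk_io
#' @export
read_brain <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname cnvrisk_io
#' @export
read_pathogenic_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "type"),
                  comment = "#", show_col_types = FALSE)
}

#' @rdname cnvrisk_io
#' @export
write_pathogenic_bed <- function(x, path) {
  readr::write_tsv(x[c("chrom", "start", "end", "type")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname cnvrisk_io
#' @export
write_normative_reference <- function(x, path) {
  con <- file(path, "w")
  writeLines(sprintf("# offset: %.10g", attr(x, "offset") %||% 0), con)
  close(con)
  readr::write_tsv(as_tibble(x), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname cnvrisk_io
#' @export
read_normative_reference <- function(path) {
  if (!file.exists(path)) {
    abort(paste("Normative reference file not found:", path),
          class = "cnvrisk_io_error")
  }
  first <- readLines(path, n = 1)
  offset <- if (grepl("^# offset:", first)) {
    as.numeric(sub("^# offset:\\s*", "", first))
  } else {
    0
  }
  curves <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  new_normative_reference(curves, offset)
}

#' @rdname cnvrisk_io
#' @export
write_run_config <- function(x, path) {
  scalars <- purrr::keep(x, ~ is.atomic(.x) && length(.x) == 1L)
  lines <- purrr::imap_chr(scalars, ~ paste0(.y, " = ", format(.x, digits = 15)))
  complex <- setdiff(names(unclass(x)), names(scalars))
  for (nm in complex) {
    lines <- c(lines, paste0(nm, " = ",
                             jsonlite::toJSON(x[[nm]], auto_unbox = TRUE,
                                              digits = NA)))
  }
  writeLines(lines, path)
  invisible(path)
}
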