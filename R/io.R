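#' Read and write sample-level association matrices
#'
#' On disk a sample-level matrix is a TSV with a header row, the first two
#' columns `sample` and `host`, and one column of integer read counts per OTU;
#' one file per site. `read_sample_table()` attaches the site identifier and
#' returns the long canonical form.
#'
#' @param file Path to the TSV file.
#' @param site Site identifier for the rows of `file`; defaults to the file
#'   name without extension.
#' @return A long sample-level tibble (see [validate_sample_table()]).
#' @export
read_sample_table <- function(file, site = NULL) {
  site <- site %||% sub("\\.[^.]*$", "", basename(file))
  wide <- readr::read_tsv(file, show_col_types = FALSE)
  if (!all(c("sample", "host") %in% names(wide))) {
    abort(paste0("file ", file, " lacks 'sample'/'host' columns"))
  }
  out <- wide |>
    dplyr::mutate(site = site, .before = 1) |>
    tidyr::pivot_longer(-c("site", "sample", "host"),
                        names_to = "otu", values_to = "reads") |>
    dplyr::mutate(reads = as.integer(.data$reads)) |>
    dplyr::filter(.data$reads > 0)
  validate_sample_table(out)
  out
}

#' @rdname read_sample_table
#' @param x Sample-level tibble covering a single site.
#' @export
write_sample_table <- function(x, file) {
  validate_sample_table(x)
  if (dplyr::n_distinct(x$site) != 1) {
    abort("write_sample_table() writes one site per file")
  }
  wide <- x |>
    dplyr::arrange(.data$sample, .data$otu) |>
    tidyr::pivot_wider(id_cols = c("sample", "host"), names_from = "otu",
                       values_from = "reads", values_fill = 0L)
  readr::write_tsv(wide, file)
  invisible(file)
}

#' Read and write species-level association matrices
#'
#' On disk a species-level matrix is a TSV with rows = plant taxa (first
#' column `plant`) and one column per OTU, cells counting the root samples
#' supporting the association; one file per site.
#'
#' @param file Path to the TSV file.
#' @param site Site identifier; defaults to the file name without extension.
#' @return Long species-level tibble (see [validate_species_table()]).
#' @export
read_species_table <- function(file, site = NULL) {
  site <- site %||% sub("\\.[^.]*$", "", basename(file))
  wide <- readr::read_tsv(file, show_col_types = FALSE)
  if (!"plant" %in% names(wide)) {
    abort(paste0("file ", file, " lacks a 'plant' column"))
  }
  out <- wide |>
    dplyr::mutate(site = site, .before = 1) |>
    tidyr::pivot_longer(-c("site", "plant"),
                        names_to = "otu", values_to = "n_samples") |>
    dplyr::mutate(n_samples = as.integer(.data$n_samples)) |>
    dplyr::filter(.data$n_samples > 0)
  validate_species_table(out)
  out
}

#' @rdname read_species_table
#' @param x Species-level tibble covering a single site.
#' @export
write_species_table <- function(x, file) {
  validate_species_table(x)
  if (dplyr::n_distinct(x$site) != 1) {
    abort("write_species_table() writes one site per file")
  }
  wide <- x |>
    dplyr::arrange(.data$plant, .data$otu) |>
    tidyr::pivot_wider(id_cols = "plant", names_from = "otu",
                       values_from = "n_samples", values_fill = 0L)
  readr::write_tsv(wide, file)
  invisible(file)
}

#' Import sample-level matrices from a spreadsheet
#'
#' Convenience reader for workbooks with one sheet per site, each sheet laid
#' out like the TSV format of [read_sample_table()] (`sample`, `host`, then
#' OTU columns). The result is identical to reading per-site TSV exports of
#' the same sheets.
#'
#' @param file Path to the `.xlsx` workbook.
#' @param sheets Sheet names to read; default all, each sheet name becoming
#'   the site id.
#' @return Long sample-level tibble covering all requested sheets.
#' @export
read_sample_xlsx <- function(file, sheets = NULL) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    abort("package 'readxl' is required for spreadsheet import")
  }
  sheets <- sheets %||% readxl::excel_sheets(file)
  purrr::map(sheets, function(sh) {
    wide <- readxl::read_excel(file, sheet = sh)
    wide |>
      dplyr::mutate(site = sh, .before = 1) |>
      tidyr::pivot_longer(-c("site", "sample", "host"),
                          names_to = "otu", values_to = "reads") |>
      dplyr::mutate(reads = as.integer(.data$reads)) |>
      dplyr::filter(.data$reads > 0)
  }) |>
    dplyr::bind_rows() |>
    validate_sample_table()
}

#' Export an association graph
#'
#' Writes the bipartite graph either as an edge-list TSV (`plant`, `fungus`,
#' `weight`) or as GraphML with a `partition` node attribute
#' (`"plant"`/`"fungus"`).
#'
#' @param g An `assoc_graph` (see [build_local_network()]).
#' @param file Output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `file`, invisibly.
#' @export
write_graph_file <- function(g, file, format = c("edgelist", "graphml")) {
  stopifnot(inherits(g, "assoc_graph"))
  format <- match.arg(format)
  if (format == "edgelist") {
    readr::write_tsv(tidy(g), file)
  } else {
    ig <- g$graph
    igraph::V(ig)$partition <- igraph::V(ig)$type_label
    igraph::write_graph(ig, file, format = "graphml")
  }
  invisible(file)
}

#' Write a result object as JSON
#'
#' @param x A list or one-row data frame of scalar results.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_result_json <- function(x, file) {
  jsonlite::write_json(as.list(x), file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
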