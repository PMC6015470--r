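#' Sample-level association tables
#'
#' The package's canonical input is a *sample-level association table*: a long
#' tibble with one row per (sample, OTU) read count and the columns
#'
#' * `site`   — forest/locality identifier,
#' * `sample` — root-sample identifier (unique within a site),
#' * `host`   — the host plant taxon of the sample (exactly one per sample;
#'   taxa that could not be resolved to species are kept as opaque labels),
#' * `otu`    — fungal OTU identifier,
#' * `reads`  — non-negative integer sequencing-read count.
#'
#' Zero-read rows may be present but carry no information; all functions treat
#' a missing (sample, otu) pair as zero reads.
#'
#' @param x A data frame to validate.
#' @return `x` invisibly, after validation.
#' @examples
#' tbl <- tibble::tibble(
#'   site = "s1", sample = c("a", "a", "b"), host = "Quercus",
#'   otu = c("F1", "F2", "F1"), reads = c(900L, 100L, 1000L)
#' )
#' validate_sample_table(tbl)
#' @export
validate_sample_table <- function(x) {
  required <- c("site", "sample", "host", "otu", "reads")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "sample table lacks column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(x) == 0) abort("sample table is empty")
  if (any(is.na(x$reads)) || any(x$reads < 0) ||
      any(x$reads != round(x$reads))) {
    abort("read counts must be non-negative integers")
  }
  hosts <- dplyr::distinct(x, .data$site, .data$sample, .data$host)
  dup <- dplyr::count(hosts, .data$site, .data$sample) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "sample(s) with more than one host label: ",
      paste(utils::head(dup$sample, 5), collapse = ", ")
    ))
  }
  dup_cell <- dplyr::count(x, .data$site, .data$sample, .data$otu) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_cell) > 0) {
    abort("duplicated (site, sample, otu) rows in sample table")
  }
  invisible(x)
}

#' Validate a species-level association table
#'
#' A *species-level association table* is a long tibble with columns `site`,
#' `plant`, `otu`, `n_samples`: one row per plant-taxon/OTU association,
#' `n_samples` counting the root samples in which the association was observed.
#' Zero cells are omitted, so every plant and OTU present has at least one
#' positive association.
#'
#' @param x A data frame to validate.
#' @return `x` invisibly.
#' @export
validate_species_table <- function(x) {
  required <- c("site", "plant", "otu", "n_samples")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "species table lacks column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(x) == 0) abort("species table is empty")
  if (any(x$n_samples < 1) || any(x$n_samples != round(x$n_samples))) {
    abort("n_samples must be positive integers")
  }
  invisible(x)
}

#' Remove rare within-sample associations
#'
#' Drops plant–fungus associations whose read count represents less than
#' `threshold` (default 0.1%) of the focal sample's total read count, a
#' standard guard against PCR/sequencing carry-over. The inequality is strict:
#' a cell exactly at the threshold is kept. Sample membership is unchanged;
#' only cells are zeroed (i.e., dropped from the long table).
#'
#' @param x Sample-level association table (see [validate_sample_table()]).
#' @param threshold Fraction of the per-sample total below which a count is
#'   removed; must be in (0, 1).
#' @return Filtered sample-level tibble.
#' @examples
#' tbl <- tibble::tibble(
#'   site = "s1", sample = "a", host = "Quercus",
#'   otu = c("F1", "F2"), reads = c(19981L, 19L)
#' )
#' filter_rare_associations(tbl) # F2 is 0.095% of the sample: removed
#' @export
filter_rare_associations <- function(x, threshold = 0.001) {
  validate_sample_table(x)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single number in (0, 1)")
  }
  x |>
    dplyr::group_by(.data$site, .data$sample) |>
    dplyr::filter(.data$reads >= threshold * sum(.data$reads) |
                    sum(.data$reads) == 0) |>
    dplyr::ungroup()
}

#' Rarefy samples to a common sequencing depth
#'
#' Subsamples each sample's reads without replacement down to `depth` reads
#' (each individual read equally likely to be kept), so that every retained
#' sample row-sum equals `depth` exactly and each OTU's retained count is
#' hypergeometric. Samples whose total read count is below `depth` cannot be
#' subsampled and are dropped with a warning. Supplying the same `seed`
#' reproduces the output bit-for-bit.
#'
#' @param x Sample-level association table.
#' @param depth Target reads per sample (positive integer), default 1000.
#' @param seed Integer seed controlling the subsample.
#' @return Rarefied sample-level tibble (zero cells dropped).
#' @export
rarefy_samples <- function(x, depth = 1000, seed = 1) {
  validate_sample_table(x)
  if (!is.numeric(depth) || length(depth) != 1 || depth < 1) {
    abort("`depth` must be a positive integer")
  }
  depth <- as.integer(depth)
  totals <- x |>
    dplyr::group_by(.data$site, .data$sample) |>
    dplyr::summarise(total = sum(.data$reads), .groups = "drop")
  shallow <- dplyr::filter(totals, .data$total < depth)
  if (nrow(shallow) > 0) {
    warn(paste0(
      nrow(shallow), " sample(s) below rarefaction depth ", depth,
      " dropped: ",
      paste(utils::head(paste0(shallow$site, "/", shallow$sample), 5),
            collapse = ", "),
      if (nrow(shallow) > 5) ", ..." else ""
    ))
  }
  keep <- dplyr::anti_join(x, shallow, by = c("site", "sample")) |>
    dplyr::filter(.data$reads > 0) |>
    dplyr::arrange(.data$site, .data$sample, .data$otu)
  if (nrow(keep) == 0) abort("no sample reaches the rarefaction depth")

  set.seed(seed)
  keep |>
    dplyr::group_by(.data$site, .data$sample, .data$host) |>
    dplyr::reframe(otu = .data$otu,
                   reads = subsample_reads(.data$reads, depth)) |>
    dplyr::filter(.data$reads > 0)
}

# draw `depth` of sum(x) reads without replacement; returns per-OTU kept counts
subsample_reads <- function(x, depth) {
  total <- sum(x)
  if (total == depth) return(as.integer(x))
  kept <- sample.int(total, depth)
  upper <- cumsum(x)
  tabulate(findInterval(kept - 1L, c(0L, upper[-length(upper)])),
           nbins = length(x))
}

#' Convert a sample-level table to a species-level table
#'
#' Collapses root samples onto their host plant taxa: the resulting cell for
#' (plant, OTU) counts the samples of that plant in which the OTU was present.
#' Only presence/absence of the OTU in each sample is used — read magnitudes
#' beyond presence do not affect the result. Plants or OTUs without any
#' positive cell do not appear.
#'
#' @param x Sample-level association table.
#' @return Species-level tibble with columns `site`, `plant`, `otu`,
#'   `n_samples` (see [validate_species_table()]).
#' @examples
#' tbl <- tibble::tibble(
#'   site = "s1", sample = c("a", "b"), host = "Alnus",
#'   otu = "F1", reads = c(500L, 1L)
#' )
#' as_species_table(tbl) # both samples count once: n_samples = 2
#' @export
as_species_table <- function(x) {
  validate_sample_table(x)
  pos <- dplyr::filter(x, .data$reads > 0)
  if (nrow(pos) == 0) abort("sample table has no positive read counts")
  pos |>
    dplyr::distinct(.data$site, .data$sample, .data$host, .data$otu) |>
    dplyr::count(.data$site, .data$host, .data$otu, name = "n_samples") |>
    dplyr::rename(plant = "host") |>
    dplyr::arrange(.data$site, .data$plant, .data$otu)
}

#' Preprocess sample-level data for network construction
#'
#' Chains the rare-association filter and rarefaction in the stated order.
#' The default applies the 0.1% filter to the raw per-sample totals *before*
#' rarefaction: at a depth of 1000 reads the threshold corresponds to a single
#' read, so a post-rarefaction filter would be vacuous.
#'
#' @param x Sample-level association table.
#' @param threshold Rare-association threshold, see
#'   [filter_rare_associations()]. `NULL` skips the filter.
#' @param depth Rarefaction depth, see [rarefy_samples()]. `NULL` skips
#'   rarefaction.
#' @param seed Integer seed for the rarefaction subsample.
#' @param order `"filter_first"` (default) or `"rarefy_first"`.
#' @return Preprocessed sample-level tibble.
#' @export
preprocess_samples <- function(x, threshold = 0.001, depth = 1000, seed = 1,
                               order = c("filter_first", "rarefy_first")) {
  order <- match.arg(order)
  steps <- list(
    filter = function(tb) {
      if (is.null(threshold)) tb else filter_rare_associations(tb, threshold)
    },
    rarefy = function(tb) {
      if (is.null(depth)) tb else rarefy_samples(tb, depth, seed = seed)
    }
  )
  if (order == "filter_first") {
    steps$rarefy(steps$filter(x))
  } else {
    steps$filter(steps$rarefy(x))
  }
}
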