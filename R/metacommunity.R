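#' Min-max standardize betweenness scores of fungal OTUs
#'
#' Rescales raw betweenness so that scores vary from 0 to 1 within one
#' network: `B'_i = (B_i - min(B)) / (max(B) - min(B))`, where the minimum and
#' maximum are taken over the *fungal* OTUs of that network only (plant nodes
#' are excluded from the range). The OTU with the highest raw betweenness
#' therefore always maps to exactly 1. Since the raw minimum is 0 in practice,
#' the standardization is invariant to any positive rescaling of the raw
#' scores, so normalization conventions of the underlying betweenness routine
#' cannot change results. If all raw scores are equal every score maps to 0,
#' with a warning.
#'
#' @param b Numeric vector of raw betweenness scores (one per fungal OTU).
#' @return Numeric vector of standardized scores in `[0, 1]`.
#' @examples
#' standardize_betweenness(c(a = 0, b = 2, c = 8))
#' @export
standardize_betweenness <- function(b) {
  if (length(b) == 0 || !is.numeric(b)) {
    abort("`b` must be a non-empty numeric vector")
  }
  rng <- range(b)
  if (diff(rng) == 0) {
    warn("all raw betweenness scores are equal; standardized scores set to 0")
    return(setNames(rep(0, length(b)), names(b)))
  }
  (b - rng[1]) / (rng[2] - rng[1])
}

#' Per-site standardized local betweenness of fungal OTUs
#'
#' Computes raw Freeman betweenness in each site's local network and
#' standardizes it within the site (fungal OTUs only, see
#' [standardize_betweenness()]).
#'
#' @param x Species-level association table (one or more sites).
#' @param weighted Use sample-frequency link weights (see
#'   [node_betweenness()]).
#' @return Tibble with `site`, `otu`, `betweenness` (raw), `b_local`
#'   (standardized within site).
#' @export
local_betweenness <- function(x, weighted = FALSE) {
  validate_species_table(x)
  purrr::map(unique(x$site), function(s) {
    g <- build_local_network(x, site = s)
    node_betweenness(g, weighted = weighted) |>
      dplyr::filter(.data$type == "fungus") |>
      dplyr::transmute(site = s, otu = .data$node, .data$betweenness,
                       b_local = standardize_betweenness(.data$betweenness))
  }) |>
    dplyr::bind_rows()
}

#' Mean standardized local betweenness across occupied sites
#'
#' Averages each OTU's standardized local betweenness over the sites where it
#' occurs; localities from which an OTU is absent are omitted from its mean
#' (they contribute neither a zero nor anything else).
#'
#' @param local_scores Tibble from [local_betweenness()] (columns `site`,
#'   `otu`, `b_local`), containing only occupied (site, otu) pairs.
#' @return Tibble with `otu`, `n_sites` (occupancy count), `mean_b_local`.
#' @export
mean_local_betweenness <- function(local_scores) {
  required <- c("site", "otu", "b_local")
  if (!all(required %in% names(local_scores))) {
    abort("`local_scores` needs columns site, otu, b_local")
  }
  if (nrow(local_scores) == 0) abort("`local_scores` is empty")
  local_scores |>
    dplyr::group_by(.data$otu) |>
    dplyr::summarise(n_sites = dplyr::n_distinct(.data$site),
                     mean_b_local = mean(.data$b_local), .groups = "drop")
}

#' Classify OTUs into the four metacommunity categories
#'
#' Places each OTU in one quadrant of the (mean standardized local
#' betweenness, standardized metacommunity betweenness) plane:
#'
#' * `metacommunity_hub`: high in both (`mean_local >= threshold` and
#'   `meta >= threshold`) — broad host range locally *and* broad geographic
#'   reach;
#' * `metacommunity_connector`: `mean_local < threshold <= meta` — broad
#'   geographic range but low local betweenness;
#' * `local_hub`: `mean_local >= threshold > meta` — central in local networks
#'   but not across the metacommunity;
#' * `peripheral`: low in both.
#'
#' Boundary values equal to the threshold fall on the "high" side.
#'
#' @param mean_local,meta Numeric vectors in `[0, 1]` (recycled if length 1).
#' @param threshold Classification threshold, default 0.5; the value can be
#'   adapted to the purpose of a study.
#' @return Factor with levels `metacommunity_hub`, `metacommunity_connector`,
#'   `local_hub`, `peripheral`.
#' @examples
#' classify_otus(c(0.6, 0.2, 0.7, 0.2), c(0.7, 0.7, 0.2, 0.2))
#' @export
classify_otus <- function(mean_local, meta, threshold = 0.5) {
  if (length(mean_local) == 1) mean_local <- rep(mean_local, length(meta))
  if (length(meta) == 1) meta <- rep(meta, length(mean_local))
  if (length(mean_local) != length(meta)) {
    abort("`mean_local` and `meta` must have the same length")
  }
  bad <- !is.finite(mean_local) | !is.finite(meta) |
    mean_local < 0 | mean_local > 1 | meta < 0 | meta > 1
  if (any(bad)) abort("scores must lie in [0, 1]")
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1) {
    abort("`threshold` must be a single number in [0, 1]")
  }
  hi_local <- mean_local >= threshold
  hi_meta <- meta >= threshold
  out <- dplyr::case_when(
    hi_local & hi_meta ~ "metacommunity_hub",
    !hi_local & hi_meta ~ "metacommunity_connector",
    hi_local & !hi_meta ~ "local_hub",
    .default = "peripheral"
  )
  factor(out, levels = c("metacommunity_hub", "metacommunity_connector",
                         "local_hub", "peripheral"))
}

#' Metacommunity hub classification of fungal OTUs
#'
#' The package's core pipeline stage: from the species-level tables of two or
#' more localities it
#'
#' 1. computes each site's local-network betweenness and standardizes it
#'    within the site,
#' 2. averages the standardized local scores over each OTU's occupied sites,
#' 3. builds the metacommunity-scale network (plant populations site-tagged,
#'    fungal OTUs shared; [build_metacommunity_network()]), computes and
#'    standardizes metacommunity betweenness, and
#' 4. classifies every OTU into the four categories of [classify_otus()].
#'
#' @param x Species-level association table with >= 2 sites.
#' @param threshold Classification threshold, default 0.5.
#' @param weighted Use sample-frequency link weights in both local and
#'   metacommunity betweenness (default `FALSE`, the binary topology).
#' @return A `hub_classification` tibble with one row per OTU: `otu`,
#'   `n_sites`, `mean_b_local`, `b_meta`, `category`; the threshold, site set
#'   and weighting are stored as attributes. `glance()` summarises category
#'   counts; `autoplot()` draws the classification plane.
#' @examples
#' sp <- tibble::tibble(
#'   site = rep(c("s1", "s2"), each = 4),
#'   plant = c("A", "A", "B", "C", "D", "D", "E", "F"),
#'   otu = c("F1", "F2", "F1", "F3", "F1", "F4", "F1", "F4"),
#'   n_samples = 1L
#' )
#' hub_classification(sp)
#' @export
hub_classification <- function(x, threshold = 0.5, weighted = FALSE) {
  validate_species_table(x)
  loc <- local_betweenness(x, weighted = weighted)
  mean_loc <- mean_local_betweenness(loc)

  meta_g <- build_metacommunity_network(x)
  meta_b <- node_betweenness(meta_g, weighted = weighted) |>
    dplyr::filter(.data$type == "fungus")
  meta_b$b_meta <- standardize_betweenness(meta_b$betweenness)

  out <- mean_loc |>
    dplyr::inner_join(dplyr::select(meta_b, otu = "node", "b_meta"),
                      by = "otu") |>
    dplyr::mutate(
      category = classify_otus(.data$mean_b_local, .data$b_meta, threshold)
    ) |>
    dplyr::arrange(dplyr::desc(.data$b_meta), .data$otu)
  attr(out, "threshold") <- threshold
  attr(out, "sites") <- unique(x$site)
  attr(out, "weighted") <- weighted
  class(out) <- c("hub_classification", class(out))
  out
}

#' @exportS3Method generics::glance
glance.hub_classification <- function(x, ...) {
  counts <- table(x$category)
  tibble(
    n_otus = nrow(x),
    n_metacommunity_hubs = unname(counts["metacommunity_hub"]),
    n_metacommunity_connectors = unname(counts["metacommunity_connector"]),
    n_local_hubs = unname(counts["local_hub"]),
    n_peripherals = unname(counts["peripheral"]),
    threshold = attr(x, "threshold"),
    n_sites = length(attr(x, "sites")),
    weighted = attr(x, "weighted")
  )
}

#' Restrict species-level tables to a regional subset of sites
#'
#' Returns the rows of the requested sites, preserving input order, so that
#' the whole pipeline can be rerun unchanged on a region (e.g. the northern
#' or southern half of a transect, or the subtropical sites only).
#'
#' @param x Species-level association table.
#' @param sites Non-empty character/integer vector of site ids to keep; every
#'   requested site must be present in `x`.
#' @return Species-level tibble restricted to `sites`.
#' @export
regional_subset <- function(x, sites) {
  validate_species_table(x)
  if (length(sites) == 0) abort("`sites` must name at least one site")
  unknown <- setdiff(as.character(sites), as.character(unique(x$site)))
  if (length(unknown) > 0) {
    abort(paste0("unknown site id(s): ", paste(unknown, collapse = ", ")))
  }
  dplyr::filter(x, .data$site %in% sites)
}
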