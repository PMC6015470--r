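#' Build a local plant-fungus association network
#'
#' Constructs the bipartite graph of one locality from its species-level
#' table: one node per plant taxon and per fungal OTU, one undirected edge per
#' positive cell, the edge weight being the number of root samples supporting
#' the association. The graph is strictly bipartite by construction.
#'
#' @param x Species-level association table (single site, or pass `site`).
#' @param site Optional site id selecting one site from a multi-site table.
#' @return An `assoc_graph` object: a list with the `igraph` graph, the site
#'   id(s) and a `scale` flag; `tidy()` returns the edge list.
#' @examples
#' sp <- tibble::tibble(
#'   site = "s1", plant = c("A", "A", "B"),
#'   otu = c("F1", "F2", "F1"), n_samples = c(5L, 1L, 2L)
#' )
#' g <- build_local_network(sp)
#' tidy(g)
#' @export
build_local_network <- function(x, site = NULL) {
  validate_species_table(x)
  if (!is.null(site)) {
    if (!site %in% x$site) abort(paste0("unknown site: ", site))
    x <- dplyr::filter(x, .data$site == !!site)
  }
  if (dplyr::n_distinct(x$site) != 1) {
    abort("local network requires a single site; use build_metacommunity_network() for several")
  }
  new_assoc_graph(
    edges = dplyr::transmute(x, plant = .data$plant, fungus = .data$otu,
                             weight = .data$n_samples),
    sites = unique(x$site), scale = "local"
  )
}

#' Build the metacommunity-scale association network
#'
#' Merges the species-level tables of two or more localities into one graph.
#' Plant taxa observed in different localities are treated as *different*
#' nodes (node id `site::plant`), so local populations stay distinct, while
#' each fungal OTU is a single node regardless of how many sites it occupies —
#' OTUs occurring in two or more localities are what interconnect the local
#' sub-networks.
#'
#' @param x Species-level association table with at least two distinct sites.
#' @return An `assoc_graph` with `scale = "metacommunity"`; plant vertices
#'   carry their site in the `site` vertex attribute.
#' @export
build_metacommunity_network <- function(x) {
  validate_species_table(x)
  sites <- unique(x$site)
  if (length(sites) < 2) {
    abort("metacommunity network requires >= 2 sites")
  }
  edges <- dplyr::transmute(
    x,
    plant = paste(.data$site, .data$plant, sep = "::"),
    fungus = .data$otu, weight = .data$n_samples
  )
  if (anyDuplicated(paste(edges$plant, edges$fungus))) {
    abort("duplicate (site, plant, otu) cells: site ids must be distinct")
  }
  new_assoc_graph(edges = edges, sites = sites, scale = "metacommunity")
}

new_assoc_graph <- function(edges, sites, scale) {
  plants <- sort(unique(edges$plant))
  fungi <- sort(unique(edges$fungus))
  overlap <- intersect(plants, fungi)
  if (length(overlap) > 0) {
    abort(paste0("labels used for both plants and OTUs: ",
                 paste(utils::head(overlap, 3), collapse = ", ")))
  }
  verts <- tibble(
    name = c(plants, fungi),
    type = c(rep(FALSE, length(plants)), rep(TRUE, length(fungi))),
    type_label = c(rep("plant", length(plants)), rep("fungus", length(fungi)))
  )
  # edge attribute deliberately named n_samples, not "weight": igraph treats a
  # "weight" attribute as distances by default, which must stay opt-in here
  g <- igraph::graph_from_data_frame(
    dplyr::rename(edges, n_samples = "weight"),
    directed = FALSE, vertices = verts
  )
  structure(list(graph = g, sites = sites, scale = scale),
            class = "assoc_graph")
}

#' @export
print.assoc_graph <- function(x, ...) {
  g <- x$graph
  cat(sprintf(
    "<assoc_graph: %s | %d plant node(s), %d fungal node(s), %d edge(s), %d site(s)>\n",
    x$scale, sum(!igraph::V(g)$type), sum(igraph::V(g)$type),
    igraph::ecount(g), length(x$sites)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.assoc_graph <- function(x, ...) {
  el <- igraph::as_data_frame(x$graph, what = "edges")
  tibble(plant = el$from, fungus = el$to, weight = as.integer(el$n_samples))
}

#' @exportS3Method generics::glance
glance.assoc_graph <- function(x, ...) {
  g <- x$graph
  tibble(
    scale = x$scale, n_sites = length(x$sites),
    n_plants = sum(!igraph::V(g)$type), n_fungi = sum(igraph::V(g)$type),
    n_edges = igraph::ecount(g),
    n_components = igraph::count_components(g)
  )
}

#' Betweenness centrality of every node
#'
#' Freeman shortest-path betweenness, unnormalized, over the whole (possibly
#' disconnected) graph; the contribution of each node pair is split equally
#' among all tied shortest paths. By default the binary topology is used.
#' With `weighted = TRUE` the association frequencies enter as link strengths:
#' an edge supported by `w` samples has traversal cost `1/w`, so stronger
#' associations shorten paths. When all weights are equal the two variants
#' coincide.
#'
#' @param g An `assoc_graph`.
#' @param weighted Use sample-frequency link weights (default `FALSE`).
#' @return Tibble with `node`, `type` (`"plant"`/`"fungus"`), `betweenness`.
#' @export
node_betweenness <- function(g, weighted = FALSE) {
  stopifnot(inherits(g, "assoc_graph"))
  ig <- g$graph
  w <- if (weighted) 1 / igraph::E(ig)$n_samples else NULL
  b <- igraph::betweenness(ig, directed = FALSE, weights = w,
                           normalized = FALSE)
  tibble(node = igraph::V(ig)$name, type = igraph::V(ig)$type_label,
         betweenness = unname(b))
}

#' Degree, closeness and eigenvector centrality of every node
#'
#' Degree is the number of incident edges. Closeness on a possibly
#' disconnected graph is component-restricted with the reachable-fraction
#' scaling: for a node reaching `r` other nodes at total geodesic distance
#' `s`, closeness is `(r / (n - 1)) * (r / s)` (0 for isolated nodes).
#' Eigenvector centrality is the principal eigenvector of the binary adjacency
#' matrix of the largest connected component, computed by power iteration from
#' a uniform start vector to tolerance 1e-10, scaled to unit Euclidean norm;
#' nodes outside the largest component score 0.
#'
#' @param g An `assoc_graph`.
#' @return Tibble with `node`, `type`, `degree`, `closeness`, `eigenvector`.
#' @export
centrality_suite <- function(g) {
  stopifnot(inherits(g, "assoc_graph"))
  ig <- g$graph
  n <- igraph::vcount(ig)
  deg <- igraph::degree(ig)

  dmat <- igraph::distances(ig, weights = NA)
  clos <- vapply(seq_len(n), function(i) {
    d <- dmat[i, -i]
    d <- d[is.finite(d)]
    r <- length(d)
    if (r == 0 || n == 1) return(0)
    (r / (n - 1)) * (r / sum(d))
  }, numeric(1))

  eig <- rep(0, n)
  if (igraph::ecount(ig) == 0) {
    warn("graph has no edges: eigenvector centrality is zero everywhere")
  } else {
    comp <- igraph::components(ig)
    big <- which.max(comp$csize)
    idx <- which(comp$membership == big)
    a <- igraph::as_adjacency_matrix(
      igraph::induced_subgraph(ig, idx), sparse = TRUE
    )
    a <- (a > 0) * 1
    eig[idx] <- power_iteration(a)
  }

  tibble(node = igraph::V(ig)$name, type = igraph::V(ig)$type_label,
         degree = unname(deg), closeness = clos, eigenvector = eig)
}

power_iteration <- function(a, tol = 1e-10, max_iter = 10000L) {
  n <- nrow(a)
  v <- rep(1 / sqrt(n), n)
  # iterate on A + I: a bipartite adjacency has a symmetric spectrum (+/-
  # lambda_max), so plain power iteration oscillates; the +I shift makes the
  # principal eigenvalue strictly dominant without changing the eigenvectors
  for (i in seq_len(max_iter)) {
    v_new <- as.numeric(a %*% v) + v
    nrm <- sqrt(sum(v_new^2))
    if (nrm == 0) return(rep(0, n))
    v_new <- v_new / nrm
    if (max(abs(v_new - v)) < tol) return(abs(v_new))
    v <- v_new
  }
  warn("power iteration did not converge; returning last iterate")
  abs(v)
}

#' Per-site centrality records for fungal OTUs
#'
#' Runs each site's local network through the full centrality suite and the
#' d' specificity index, returning one row per (site, OTU): the
#' `CentralityRecord` surface used for ranking and downstream hub
#' classification.
#'
#' @param x Species-level association table (any number of sites).
#' @return Tibble with `site`, `otu`, `degree`, `closeness`, `eigenvector`,
#'   `betweenness`, `weighted_betweenness`, `dprime`.
#' @export
centrality_table <- function(x) {
  validate_species_table(x)
  purrr::map(unique(x$site), function(s) {
    g <- build_local_network(x, site = s)
    suite <- centrality_suite(g)
    bin <- node_betweenness(g, weighted = FALSE)
    wtd <- node_betweenness(g, weighted = TRUE)
    dp <- dprime_scores(dplyr::filter(x, .data$site == s))
    suite |>
      dplyr::filter(.data$type == "fungus") |>
      dplyr::transmute(site = s, otu = .data$node, .data$degree,
                       .data$closeness, .data$eigenvector) |>
      dplyr::left_join(dplyr::select(bin, otu = "node", "betweenness"),
                       by = "otu") |>
      dplyr::left_join(
        dplyr::select(wtd, otu = "node", weighted_betweenness = "betweenness"),
        by = "otu"
      ) |>
      dplyr::left_join(dplyr::select(dp, "otu", "dprime"), by = "otu")
  }) |>
    dplyr::bind_rows()
}

#' Pearson correlation between two centrality scores
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return The Pearson product-moment correlation coefficient.
#' @export
centrality_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("x and y must have equal length >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation is undefined for a constant vector")
  }
  cor(x, y, method = "pearson")
}

#' Top-k nodes by a centrality score
#'
#' Ranks records in descending score order, ties broken by OTU id
#' (lexicographic) so that rankings are reproducible, and keeps the first
#' `min(k, n)` rows. If the table has a `site` column the ranking is done
#' within each site.
#'
#' @param records Tibble of centrality records (e.g. [centrality_table()]).
#' @param k Number of rows to keep per site (default 20).
#' @param by Name of the score column to rank by (default `"betweenness"`).
#' @return Ranked tibble with a `rank` column.
#' @export
top_k_table <- function(records, k = 20, by = "betweenness") {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    abort("`k` must be a positive integer")
  }
  if (!by %in% names(records) || !is.numeric(records[[by]])) {
    abort(paste0("unknown or non-numeric score column: ", by))
  }
  grouped <- if ("site" %in% names(records)) {
    dplyr::group_by(records, .data$site)
  } else {
    records
  }
  grouped |>
    dplyr::arrange(dplyr::desc(.data[[by]]), .data$otu,
                   .by_group = "site" %in% names(records)) |>
    dplyr::slice_head(n = as.integer(k)) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1) |>
    dplyr::ungroup()
}
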