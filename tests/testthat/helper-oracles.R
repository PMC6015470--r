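# Independent brute-force oracles used to check the package's implementations.
# These deliberately share no code with the implementation: betweenness is
# obtained by enumerating every simple path, d' extremes by enumerating every
# feasible integer allocation, PERMANOVA sums of squares by explicit double
# loops over the definition.

# --- exhaustive shortest-path betweenness --------------------------------

# all simple paths from s to t in an adjacency list, as vectors of node ids
enumerate_paths <- function(adj, s, t) {
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      out[[length(out) + 1]] <<- path
      return()
    }
    for (nb in adj[[last]]) {
      if (!nb %in% path) walk(c(path, nb))
    }
  }
  walk(s)
  out
}

# Freeman betweenness by enumeration: for each unordered pair, keep the
# shortest paths and split the pair's unit contribution equally among them
oracle_betweenness <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges[[1]][k]
    b <- edges[[2]][k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  score <- setNames(numeric(length(nodes)), nodes)
  pairs <- utils::combn(nodes, 2, simplify = FALSE)
  for (pr in pairs) {
    paths <- enumerate_paths(adj, pr[1], pr[2])
    if (length(paths) == 0) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    for (p in shortest) {
      inner <- setdiff(p, pr)
      score[inner] <- score[inner] + 1 / length(shortest)
    }
  }
  score
}

# random connected-ish bipartite edge set with np plants, nf fungi
random_bipartite_edges <- function(np, nf, p_edge = 0.4) {
  plants <- paste0("p", seq_len(np))
  fungi <- paste0("f", seq_len(nf))
  grid <- expand.grid(plant = plants, fungus = fungi,
                      stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < p_edge
  # guarantee every node has at least one edge
  for (pl in plants) {
    if (!any(keep & grid$plant == pl)) {
      keep[sample(which(grid$plant == pl), 1)] <- TRUE
    }
  }
  for (fu in fungi) {
    if (!any(keep & grid$fungus == fu)) {
      keep[sample(which(grid$fungus == fu), 1)] <- TRUE
    }
  }
  grid[keep, ]
}

# species-level table from a bipartite edge set (single site)
edges_to_species <- function(edges, site = "s1", weights = NULL) {
  tibble::tibble(
    site = site, plant = edges$plant, otu = edges$fungus,
    n_samples = as.integer(weights %||% rep(1L, nrow(edges)))
  )
}

# --- exhaustive d' allocation oracle -------------------------------------

# all non-negative integer vectors of length k summing to t with a_j <= cap_j
enumerate_allocations <- function(t, cap) {
  if (length(cap) == 1) {
    if (t <= cap) return(list(t)) else return(list())
  }
  out <- list()
  for (a1 in 0:min(t, cap[1])) {
    for (rest in enumerate_allocations(t - a1, cap[-1])) {
      out[[length(out) + 1]] <- c(a1, rest)
    }
  }
  out
}

oracle_kl <- function(alloc, q) {
  p <- alloc / sum(alloc)
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep]))
}

# d, d_min, d_max, d' for column `otu` of plant x OTU count matrix m
oracle_dprime <- function(m, otu) {
  q <- rowSums(m) / sum(m)
  cap <- rowSums(m)
  alloc <- m[, otu]
  allocs <- enumerate_allocations(sum(alloc), cap)
  ds <- vapply(allocs, oracle_kl, numeric(1), q = q)
  d <- oracle_kl(alloc, q)
  d_min <- min(ds)
  d_max <- max(ds)
  list(d = d, d_min = d_min, d_max = d_max,
       dprime = if (d_max - d_min < 1e-12) 0 else (d - d_min) / (d_max - d_min))
}

# --- PERMANOVA sums-of-squares oracle ------------------------------------

# F and R2 straight from the definition, by explicit double loops
oracle_permanova <- function(dmat, groups) {
  n <- nrow(dmat)
  g <- as.factor(groups)
  ss_total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) ss_total <- ss_total + dmat[i, j]^2
  }
  ss_total <- ss_total / n
  ss_within <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    acc <- 0
    if (length(idx) > 1) {
      for (i in seq_len(length(idx) - 1)) {
        for (j in (i + 1):length(idx)) {
          acc <- acc + dmat[idx[i], idx[j]]^2
        }
      }
    }
    ss_within <- ss_within + acc / length(idx)
  }
  ss_among <- ss_total - ss_within
  a <- nlevels(g)
  list(
    f = (ss_among / (a - 1)) / (ss_within / (n - a)),
    r2 = ss_among / ss_total
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
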