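#' Interaction-specificity index d' for fungal OTUs
#'
#' The d' index measures how strongly an OTU's observed association
#' distribution over plant taxa deviates from the taxa's overall availability,
#' as a standardized Kullback–Leibler divergence. For OTU `i` with
#' associations `a_j` over plants `j` (total `t`):
#'
#' * `p'_j = a_j / t` is the OTU's proportional use of plant `j`,
#' * `q_j` is plant `j`'s share of *all* associations in the matrix,
#' * `d_i = sum_{p'_j > 0} p'_j * log(p'_j / q_j)`,
#' * `d'_i = (d_i - d_min) / (d_max - d_min)`, in `[0, 1]`.
#'
#' `d_min` and `d_max` are the extremes of `d` attainable by reallocating the
#' OTU's total `t` over the plants, holding `q` and each plant's marginal
#' total (its capacity) fixed. `d_max` is found by searching capacity-
#' constrained extreme allocations: the greedy fill of plants in ascending
#' order of availability `q`, plus, for each plant, the allocation that
#' concentrates as much as possible on that plant before falling back to the
#' ascending-`q` fill (pure ascending-`q` filling alone can be beaten when
#' capacities force splitting). The observed allocation is always included in
#' the candidate set, so `d' <= 1` holds exactly. `d_min` is a proportional
#' fill (`a_j ~ t * q_j`) with the integer remainder placed one unit at a time
#' wherever it increases `d` least, again clamped by the observed value, so
#' `d' >= 0` holds exactly. When `d_max = d_min` (e.g. a single plant taxon)
#' d' is defined as 0.
#'
#' A generalist whose use is exactly proportional to availability scores
#' `d' = 0`; an OTU concentrating all associations on the least-available
#' plant taxon scores `d' = 1`.
#'
#' @param x Species-level association table for a single site (or any single
#'   association matrix).
#' @param otus OTU ids to score; default all OTUs in the matrix.
#' @return Tibble with `site`, `otu`, `d`, `d_min`, `d_max`, `dprime`.
#' @examples
#' sp <- tibble::tibble(
#'   site = "s1",
#'   plant = c("A", "A", "B", "B", "C"),
#'   otu = c("F1", "F2", "F1", "F2", "F1"),
#'   n_samples = c(4L, 1L, 2L, 1L, 1L)
#' )
#' dprime_scores(sp)
#' @export
dprime_scores <- function(x, otus = NULL) {
  validate_species_table(x)
  if (dplyr::n_distinct(x$site) != 1) {
    abort("dprime_scores() operates on one association matrix (single site)")
  }
  mat <- x |>
    tidyr::pivot_wider(id_cols = "plant", names_from = "otu",
                       values_from = "n_samples", values_fill = 0L)
  m <- as.matrix(mat[, -1, drop = FALSE])
  rownames(m) <- mat$plant
  otus <- otus %||% colnames(m)
  unknown <- setdiff(otus, colnames(m))
  if (length(unknown) > 0) {
    abort(paste0("OTU(s) absent from matrix: ",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  q <- rowSums(m) / sum(m)
  capacity <- rowSums(m)
  purrr::map(otus, function(f) {
    res <- dprime_one(m[, f], q, capacity)
    tibble(site = x$site[1], otu = f, d = res$d, d_min = res$d_min,
           d_max = res$d_max, dprime = res$dprime)
  }) |>
    dplyr::bind_rows()
}

# KL divergence of an allocation against availability q
kl_d <- function(alloc, q) {
  t <- sum(alloc)
  if (t == 0) return(0)
  p <- alloc / t
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep]))
}

# greedy fill of total t into capacities cap, visiting partners in `ord`
fill_in_order <- function(t, cap, ord) {
  alloc <- numeric(length(cap))
  left <- t
  for (j in ord) {
    take <- min(left, cap[j])
    alloc[j] <- take
    left <- left - take
    if (left == 0) break
  }
  alloc
}

dprime_one <- function(alloc, q, capacity) {
  t <- sum(alloc)
  if (t == 0) abort("OTU has no associations")
  d_obs <- kl_d(alloc, q)

  # candidate extreme allocations for d_max
  asc <- order(q, seq_along(q)) # ascending availability, stable
  cands <- list(alloc, fill_in_order(t, capacity, asc))
  for (j in seq_along(q)) {
    cands[[length(cands) + 1]] <-
      fill_in_order(t, capacity, c(j, setdiff(asc, j)))
  }
  d_max <- max(vapply(cands, kl_d, numeric(1), q = q))

  # proportional fill for d_min, integer remainder placed greedily
  base <- floor(t * q)
  base <- pmin(base, capacity)
  left <- t - sum(base)
  while (left > 0) {
    gain <- vapply(seq_along(q), function(j) {
      if (base[j] + 1 > capacity[j]) return(Inf)
      trial <- base
      trial[j] <- trial[j] + 1
      kl_d(trial, q)
    }, numeric(1))
    j_best <- which.min(gain)
    base[j_best] <- base[j_best] + 1
    left <- left - 1
  }
  d_min <- min(kl_d(base, q), d_obs)

  dprime <- if (d_max - d_min < 1e-12) 0 else (d_obs - d_min) / (d_max - d_min)
  list(d = d_obs, d_min = d_min, d_max = d_max,
       dprime = min(max(dprime, 0), 1))
}
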