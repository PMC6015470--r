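#' Aggregate OTU columns by a taxonomic or functional annotation
#'
#' Sums read counts within annotation groups (e.g. fungal orders, or FUNGuild
#' functional groups consumed as input annotations), turning a sample x OTU
#' table into a sample x group table. OTUs without a mapping entry are pooled
#' into `"unidentified"`. The mapping may be partial or empty.
#'
#' @param x Sample-level association table.
#' @param mapping Either a named character vector (`names` = OTU ids, values =
#'   group labels) or a data frame with columns `otu` and `group`.
#' @return Sample-level tibble whose `otu` column holds group labels.
#' @examples
#' tbl <- tibble::tibble(
#'   site = "s1", sample = "a", host = "Acer",
#'   otu = c("F1", "F2", "F3"), reads = c(3L, 4L, 5L)
#' )
#' aggregate_by_annotation(tbl, c(F1 = "Helotiales", F2 = "Helotiales",
#'                                F3 = "Russulales"))
#' @export
aggregate_by_annotation <- function(x, mapping) {
  validate_sample_table(x)
  if (is.data.frame(mapping)) {
    if (!all(c("otu", "group") %in% names(mapping))) {
      abort("`mapping` data frame needs columns otu and group")
    }
    map_vec <- setNames(as.character(mapping$group), mapping$otu)
  } else {
    map_vec <- mapping
  }
  grp <- unname(map_vec[x$otu])
  grp[is.na(grp)] <- "unidentified"
  x |>
    dplyr::mutate(otu = grp) |>
    dplyr::group_by(.data$site, .data$sample, .data$host, .data$otu) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop")
}

#' Per-site composition of annotation groups
#'
#' Proportions of read counts per annotation group within each site, the
#' tabular analogue of stacked-bar composition figures.
#'
#' @inheritParams aggregate_by_annotation
#' @return Tibble with `site`, `group`, `reads`, `proportion` (summing to 1
#'   within each site).
#' @export
composition_table <- function(x, mapping) {
  aggregate_by_annotation(x, mapping) |>
    dplyr::group_by(.data$site, group = .data$otu) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop_last") |>
    dplyr::mutate(proportion = .data$reads / sum(.data$reads)) |>
    dplyr::ungroup()
}

#' Bray-Curtis dissimilarity between samples
#'
#' Computes, from its definition, `d(x, y) = sum|x_k - y_k| / sum(x_k + y_k)`
#' for every pair of samples' read-count vectors. Values lie in `[0, 1]`:
#' 0 for identical vectors, 1 for disjoint support.
#'
#' @param x Sample-level association table; every sample must have a positive
#'   total read count.
#' @return A [stats::dist] object labelled `site/sample`.
#' @examples
#' tbl <- tibble::tibble(
#'   site = "s1", sample = rep(c("a", "b"), each = 2), host = "Acer",
#'   otu = rep(c("F1", "F2"), 2), reads = c(2L, 2L, 1L, 3L)
#' )
#' bray_curtis(tbl) # (|2-1| + |2-3|) / 8 = 0.25
#' @export
bray_curtis <- function(x) {
  validate_sample_table(x)
  wide <- x |>
    dplyr::arrange(.data$site, .data$sample) |>
    tidyr::pivot_wider(id_cols = c("site", "sample"), names_from = "otu",
                       values_from = "reads", values_fill = 0L,
                       values_fn = sum)
  m <- as.matrix(wide[, -(1:2), drop = FALSE])
  rownames(m) <- paste(wide$site, wide$sample, sep = "/")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort(paste0("sample(s) with zero total reads: ",
                 paste(utils::head(rownames(m)[rs == 0], 5), collapse = ", ")))
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    # sum |x-y| = sum(x+y) - 2 sum(min(x,y))
    shared <- colSums(pmin(t(m[rest, , drop = FALSE]), m[i, ]))
    d[rest, i] <- d[i, rest] <- 1 - 2 * shared / (rs[i] + rs[rest])
  }
  stats::as.dist(d)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the squared dissimilarities of a distance matrix into among- and
#' within-group components (one-way design), computed directly from the
#' definition:
#' `SS_total = (1/N) * sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) * sum_{i<j in g} d_ij^2`,
#' `SS_among = SS_total - SS_within`,
#' `F = (SS_among / (a - 1)) / (SS_within / (N - a))`,
#' `R^2 = SS_among / SS_total`.
#' The p-value is obtained by freely permuting whole sample labels:
#' `p = (1 + #[F_perm >= F_obs]) / (n_perm + 1)`.
#'
#' @param d A [stats::dist] object or symmetric matrix of dissimilarities.
#' @param groups Group labels: either a vector aligned with the rows of `d`
#'   or a named vector keyed by the labels of `d`. At least two groups, each
#'   with at least two members.
#' @param n_perm Number of permutations, default 999.
#' @param seed Optional integer seed for the permutations.
#' @return An object of class `mh_permanova`; see [tidy()] and [glance()]
#'   methods for tabular views.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  prep <- prep_dist_groups(d, groups)
  if (!is.null(seed)) set.seed(seed)
  d2 <- prep$d2
  g <- prep$g
  n <- nrow(d2)
  a <- nlevels(g)

  obs <- permanova_stat(d2, g)
  f_perm <- replicate(n_perm, permanova_stat(d2, g[sample.int(n)])$f)
  p <- (1 + sum(f_perm >= obs$f)) / (n_perm + 1)

  structure(
    list(statistic = "PERMANOVA pseudo-F", f = obs$f, r2 = obs$r2, p = p,
         df_among = a - 1, df_within = n - a,
         ss_among = obs$ss_among, ss_within = obs$ss_within,
         ss_total = obs$ss_total,
         n = n, n_groups = a, n_perm = n_perm, seed = seed),
    class = "mh_permanova"
  )
}

permanova_stat <- function(d2, g) {
  n <- nrow(d2)
  a <- nlevels(g)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    ss_within <- ss_within +
      sum(d2[idx, idx, drop = FALSE]) / (2 * length(idx))
  }
  ss_among <- ss_total - ss_within
  f <- (ss_among / (a - 1)) / (ss_within / (n - a))
  list(f = f, r2 = ss_among / ss_total, ss_among = ss_among,
       ss_within = ss_within, ss_total = ss_total)
}

#' Permutational test of multivariate dispersion homogeneity (PERMDISP)
#'
#' Embeds the distance matrix by principal-coordinates analysis, keeping the
#' axes of negative eigenvalues as imaginary coordinates; the distance of a
#' sample to its group centroid is then
#' `z^2 = (distance on real axes)^2 - (distance on imaginary axes)^2`,
#' truncated at 0. The statistic is the one-way ANOVA F of those distances
#' across groups; its p-value comes from permuting group labels over the
#' fixed embedding. Group centres are centroids (means), not spatial medians.
#'
#' @inheritParams permanova
#' @return An object of class `mh_permdisp` carrying `f`, `p`, and the
#'   per-sample distances to centroids; see [tidy()] and [glance()].
#' @export
permdisp <- function(d, groups, n_perm = 999, seed = NULL) {
  prep <- prep_dist_groups(d, groups)
  if (!is.null(seed)) set.seed(seed)
  g <- prep$g
  n <- nrow(prep$d2)

  # Gower-centred double-centring of -d^2/2, eigen-decomposed
  a_mat <- -prep$d2 / 2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g_mat <- ctr %*% a_mat %*% ctr
  e <- eigen((g_mat + t(g_mat)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * sqrt(.Machine$double.eps)
  pos <- e$values > tol
  neg <- e$values < -tol
  x_real <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  x_imag <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), sum(neg))

  dist_to_centroid <- function(gl) {
    z2 <- numeric(n)
    for (lev in levels(gl)) {
      idx <- which(gl == lev)
      cr <- colMeans(x_real[idx, , drop = FALSE])
      ci <- colMeans(x_imag[idx, , drop = FALSE])
      dr2 <- rowSums(sweep(x_real[idx, , drop = FALSE], 2, cr)^2)
      di2 <- if (ncol(x_imag) > 0) {
        rowSums(sweep(x_imag[idx, , drop = FALSE], 2, ci)^2)
      } else {
        0
      }
      z2[idx] <- pmax(dr2 - di2, 0)
    }
    sqrt(z2)
  }
  anova_f <- function(z, gl) {
    grand <- mean(z)
    means <- tapply(z, gl, mean)
    ns <- tabulate(gl)
    ss_b <- sum(ns * (means - grand)^2)
    ss_w <- sum((z - means[gl])^2)
    if (ss_w == 0) return(if (ss_b == 0) 0 else Inf)
    (ss_b / (nlevels(gl) - 1)) / (ss_w / (length(z) - nlevels(gl)))
  }

  z_obs <- dist_to_centroid(g)
  f_obs <- anova_f(z_obs, g)
  f_perm <- replicate(n_perm, {
    gp <- g[sample.int(n)]
    anova_f(dist_to_centroid(gp), gp)
  })
  p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)

  structure(
    list(statistic = "PERMDISP F", f = f_obs, p = p,
         distances = tibble(id = prep$ids, group = g, distance = z_obs),
         df_among = nlevels(g) - 1, df_within = n - nlevels(g),
         n = n, n_groups = nlevels(g), n_perm = n_perm, seed = seed),
    class = "mh_permdisp"
  )
}

prep_dist_groups <- function(d, groups) {
  if (inherits(d, "dist")) {
    dm <- as.matrix(d)
  } else if (is.matrix(d)) {
    if (!isSymmetric(unname(d)) || any(diag(d) != 0)) {
      abort("`d` must be a symmetric dissimilarity matrix with zero diagonal")
    }
    dm <- d
  } else {
    abort("`d` must be a dist object or symmetric matrix")
  }
  ids <- rownames(dm) %||% as.character(seq_len(nrow(dm)))
  if (!is.null(names(groups))) {
    missing_ids <- setdiff(ids, names(groups))
    if (length(missing_ids) > 0) {
      abort(paste0("no group label for: ",
                   paste(utils::head(missing_ids, 5), collapse = ", ")))
    }
    groups <- groups[ids]
  }
  if (length(groups) != nrow(dm)) {
    abort("`groups` must match the size of `d`")
  }
  g <- droplevels(as.factor(unname(groups)))
  if (nlevels(g) < 2) abort("need at least two groups")
  if (any(table(g) < 2)) abort("every group needs at least two members")
  list(d2 = dm^2, g = g, ids = ids)
}

#' @export
print.mh_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (one-way, %d permutations): F = %.4g, R2 = %.4g, p = %.4g\n",
    x$n_perm, x$f, x$r2, x$p
  ))
  invisible(x)
}

#' @export
print.mh_permdisp <- function(x, ...) {
  cat(sprintf(
    "PERMDISP (centroids, %d permutations): F = %.4g, p = %.4g\n",
    x$n_perm, x$f, x$p
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mh_permanova <- function(x, ...) {
  tibble(
    term = c("among groups", "within groups", "total"),
    df = c(x$df_among, x$df_within, x$df_among + x$df_within),
    sum_of_squares = c(x$ss_among, x$ss_within, x$ss_total),
    statistic = c(x$f, NA, NA),
    r.squared = c(x$r2, NA, NA),
    p.value = c(x$p, NA, NA)
  )
}

#' @exportS3Method generics::glance
glance.mh_permanova <- function(x, ...) {
  tibble(statistic = x$f, r.squared = x$r2, p.value = x$p,
         n = x$n, n_groups = x$n_groups, n_perm = x$n_perm)
}

#' @exportS3Method generics::tidy
tidy.mh_permdisp <- function(x, ...) {
  x$distances |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_distance = mean(.data$distance),
                     sd_distance = sd(.data$distance), .groups = "drop")
}

#' @exportS3Method generics::glance
glance.mh_permdisp <- function(x, ...) {
  tibble(statistic = x$f, p.value = x$p,
         n = x$n, n_groups = x$n_groups, n_perm = x$n_perm)
}
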