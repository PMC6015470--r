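test_that("annotation aggregation sums columns within groups and pools unmapped OTUs", {
  tbl <- tibble::tibble(
    site = "s1", sample = "a", host = "A",
    otu = c("F1", "F2", "F3"), reads = c(3L, 4L, 5L)
  )
  mapping <- c(F1 = "Helotiales", F2 = "Helotiales", F3 = "Russulales")
  out <- aggregate_by_annotation(tbl, mapping)
  expect_equal(out$reads[out$otu == "Helotiales"], 7L)
  expect_equal(out$reads[out$otu == "Russulales"], 5L)
  # empty mapping: everything pooled into "unidentified" at the row total
  pooled <- aggregate_by_annotation(tbl, character(0))
  expect_equal(pooled$otu, "unidentified")
  expect_equal(pooled$reads, 12L)
  # mapping as a data frame and per-site proportions summing to 1
  comp <- composition_table(tbl, data.frame(otu = c("F1", "F2", "F3"),
                                            group = mapping))
  expect_equal(sum(comp$proportion), 1)
})

test_that("Bray-Curtis reproduces direct-formula values and its bounds", {
  disjoint <- tibble::tibble(
    site = "s", sample = rep(c("a", "b"), each = 1),
    host = "A", otu = c("F1", "F2"), reads = 1L
  )
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)

  same <- tibble::tibble(
    site = "s", sample = rep(c("a", "b"), each = 2), host = "A",
    otu = rep(c("F1", "F2"), 2), reads = c(4L, 6L, 4L, 6L)
  )
  expect_equal(as.numeric(bray_curtis(same)), 0)

  toy <- tibble::tibble(
    site = "s", sample = rep(c("a", "b"), each = 2), host = "A",
    otu = rep(c("F1", "F2"), 2), reads = c(2L, 2L, 1L, 3L)
  )
  expect_equal(as.numeric(bray_curtis(toy)), 0.25)

  zero <- tibble::tibble(site = "s", sample = c("a", "b"), host = "A",
                         otu = "F1", reads = c(5L, 0L))
  expect_error(bray_curtis(zero), "zero total")
})

test_that("Bray-Curtis agrees with vegan and is zero iff vectors are equal", {
  set.seed(2)
  x <- random_samples(n_sites = 2, n_samp = 7, n_otus = 15)
  d <- bray_curtis(x)
  wide <- tidyr::pivot_wider(x, id_cols = c("site", "sample"),
                             names_from = "otu", values_from = "reads",
                             values_fill = 0L) |>
    dplyr::arrange(site, sample)
  ref <- vegan::vegdist(as.matrix(wide[, -(1:2)]), method = "bray")
  expect_equal(as.numeric(d), as.numeric(ref), tolerance = 1e-12)
  dm <- as.matrix(d)
  expect_true(isSymmetric(dm))
  expect_true(all(dm >= 0 & dm <= 1))
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm[upper.tri(dm)] > 0)) # all samples distinct here
})

euclid_toy <- function() {
  # two tight, well-separated triplets in the plane
  coords <- rbind(
    c(0, 0), c(0.2, 0), c(0, 0.2),
    c(10, 10), c(10.2, 10), c(10, 10.2)
  )
  rownames(coords) <- paste0("x", 1:6)
  list(coords = coords, d = dist(coords),
       groups = setNames(rep(c("g1", "g2"), each = 3), rownames(coords)))
}

test_that("PERMANOVA F and R2 equal the double-loop oracle and vegan::adonis2", {
  toy <- euclid_toy()
  res <- permanova(toy$d, toy$groups, n_perm = 199, seed = 5)
  want <- oracle_permanova(as.matrix(toy$d), toy$groups)
  expect_equal(res$f, want$f, tolerance = 1e-12)
  expect_equal(res$r2, want$r2, tolerance = 1e-12)

  ref <- vegan::adonis2(toy$d ~ g, data = data.frame(g = toy$groups),
                        permutations = 49)
  expect_equal(res$f, ref$F[1], tolerance = 1e-10)
  expect_equal(res$r2, ref$R2[1], tolerance = 1e-10)
  # full separation, 3+3 design: only the 2 of choose(6,3) = 20 relabelings
  # reproducing the split reach the observed F, so p is near 0.1
  expect_lt(res$p, 0.2)
  expect_true(res$p >= 1 / 200 && res$p <= 1)
})

test_that("PERMANOVA on Euclidean distances equals the coordinate-space pseudo-F", {
  set.seed(6)
  coords <- rbind(matrix(rnorm(12), 6, 2),
                  matrix(rnorm(12, mean = 1.5), 6, 2))
  groups <- rep(c("a", "b"), each = 6)
  res <- permanova(dist(coords), groups, n_perm = 99, seed = 1)
  # classical one-way trace pseudo-F from centroids
  grand <- colMeans(coords)
  ss_tot <- sum(sweep(coords, 2, grand)^2)
  ss_w <- 0
  for (g in unique(groups)) {
    sub <- coords[groups == g, , drop = FALSE]
    ss_w <- ss_w + sum(sweep(sub, 2, colMeans(sub))^2)
  }
  f_classic <- ((ss_tot - ss_w) / 1) / (ss_w / 10)
  expect_equal(res$f, f_classic, tolerance = 1e-10)
})

test_that("PERMANOVA is invariant to input order and near-null on mirrored groups", {
  toy <- euclid_toy()
  perm <- c(4, 1, 6, 2, 3, 5)
  dmat <- as.matrix(toy$d)[perm, perm]
  res1 <- permanova(toy$d, toy$groups, n_perm = 49, seed = 2)
  res2 <- permanova(stats::as.dist(dmat), toy$groups[perm], n_perm = 49,
                    seed = 2)
  expect_equal(res1$f, res2$f, tolerance = 1e-12)
  expect_equal(res1$r2, res2$r2, tolerance = 1e-12)

  # mirror-image point clouds: no among-group separation
  coords <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                  c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  groups <- rep(c("a", "b"), each = 4)
  res <- permanova(dist(coords), groups, n_perm = 199, seed = 3)
  expect_lt(res$r2, 0.05)
  expect_gt(res$p, 0.5)
})

test_that("PERMANOVA validates its design", {
  toy <- euclid_toy()
  singleton <- setNames(c("a", "a", "a", "a", "a", "b"),
                        rownames(as.matrix(toy$d)))
  expect_error(permanova(toy$d, singleton), "at least two members")
  expect_error(permanova(toy$d, rep("a", 6)), "two groups")
})

test_that("PERMDISP distances equal direct coordinate computation on Euclidean data", {
  toy <- euclid_toy()
  res <- permdisp(toy$d, toy$groups, n_perm = 99, seed = 4)
  direct <- numeric(6)
  for (g in c("g1", "g2")) {
    idx <- which(toy$groups == g)
    cen <- colMeans(toy$coords[idx, ])
    direct[idx] <- sqrt(rowSums(sweep(toy$coords[idx, ], 2, cen)^2))
  }
  expect_equal(res$distances$distance, direct, tolerance = 1e-8)
  expect_true(all(res$distances$distance >= 0))

  ref <- vegan::betadisper(toy$d, toy$groups, type = "centroid")
  expect_equal(res$distances$distance, unname(ref$distances),
               tolerance = 1e-8)
  f_ref <- stats::anova(ref)$`F value`[1]
  expect_equal(res$f, f_ref, tolerance = 1e-8)
})

test_that("PERMDISP is near-zero when groups have identical dispersion by construction", {
  # each group is a cross with distances {1, 1, 2, 2} to its centroid; the
  # groups are congruent, so within-group spread is real but mean dispersion
  # is exactly equal between groups
  cross <- rbind(c(1, 0), c(-1, 0), c(0, 2), c(0, -2))
  coords <- rbind(cross, sweep(cross, 2, c(50, 50), `+`))
  groups <- rep(c("a", "b"), each = 4)
  res <- permdisp(dist(coords), groups, n_perm = 99, seed = 9)
  expect_equal(res$distances$distance, rep(c(1, 1, 2, 2), 2),
               tolerance = 1e-8)
  expect_lt(res$f, 1e-12)
  expect_gt(res$p, 0.5)
})

test_that("permutation p-values respect their attainable bounds", {
  toy <- euclid_toy()
  for (np in c(19, 99)) {
    res <- permanova(toy$d, toy$groups, n_perm = np, seed = 1)
    expect_gte(res$p, 1 / (np + 1))
    expect_lte(res$p, 1)
    res2 <- permdisp(toy$d, toy$groups, n_perm = np, seed = 1)
    expect_gte(res2$p, 1 / (np + 1))
    expect_lte(res2$p, 1)
  }
})

test_that("tidy and glance views expose the statistics", {
  toy <- euclid_toy()
  res <- permanova(toy$d, toy$groups, n_perm = 49, seed = 1)
  td <- tidy(res)
  expect_equal(td$term, c("among groups", "within groups", "total"))
  expect_equal(td$sum_of_squares[3],
               td$sum_of_squares[1] + td$sum_of_squares[2])
  gl <- glance(res)
  expect_equal(gl$statistic, res$f)
  res2 <- permdisp(toy$d, toy$groups, n_perm = 49, seed = 1)
  expect_equal(nrow(tidy(res2)), 2)
  expect_equal(glance(res2)$p.value, res2$p)
})
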