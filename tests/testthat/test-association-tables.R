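test_that("rare-association filter removes strictly-below-threshold cells only", {
  base <- tibble::tibble(site = "s1", sample = "a", host = "A",
                         otu = c("F1", "F2"), reads = c(995L, 5L))
  expect_equal(filter_rare_associations(base), base) # 0.5% of the sample

  big <- tibble::tibble(site = "s1", sample = "a", host = "A",
                        otu = c("F1", "F2"), reads = c(19981L, 19L))
  out <- filter_rare_associations(big)
  expect_equal(out$otu, "F1") # 19/20000 = 0.095% < 0.1%

  # a cell exactly at the threshold is kept (strict inequality)
  at <- tibble::tibble(site = "s1", sample = "a", host = "A",
                       otu = c("F1", "F2"), reads = c(1998L, 2L))
  expect_equal(nrow(filter_rare_associations(at)), 2)

  # an all-zero sample passes through unchanged, no error
  zero <- tibble::tibble(site = "s1", sample = c("a", "z"), host = "A",
                         otu = "F1", reads = c(1000L, 0L))
  expect_equal(filter_rare_associations(zero), zero)
})

test_that("filter never increases a cell and preserves the sample set", {
  set.seed(42)
  x <- random_samples(n_sites = 2, n_samp = 5, n_otus = 10, depth = 2000)
  y <- filter_rare_associations(x, 0.01)
  joined <- dplyr::left_join(
    x, y, by = c("site", "sample", "host", "otu"), suffix = c("_pre", "_post")
  )
  expect_true(all(is.na(joined$reads_post) |
                    joined$reads_post <= joined$reads_pre))
  expect_setequal(unique(paste(y$site, y$sample)),
                  unique(paste(x$site, x$sample)))
})

test_that("filter rejects invalid counts and thresholds", {
  bad <- tibble::tibble(site = "s1", sample = "a", host = "A",
                        otu = "F1", reads = -1)
  expect_error(filter_rare_associations(bad), "non-negative")
  ok <- tibble::tibble(site = "s1", sample = "a", host = "A",
                       otu = "F1", reads = 10L)
  expect_error(filter_rare_associations(ok, threshold = 0), "threshold")
})

test_that("rarefaction returns exact row sums, drops shallow samples, is seed-deterministic", {
  x <- tibble::tibble(
    site = "s1", sample = rep(c("deep", "exact", "shallow"), each = 2),
    host = "A", otu = rep(c("F1", "F2"), 3),
    reads = c(900L, 300L, 600L, 400L, 100L, 50L)
  )
  expect_warning(out <- rarefy_samples(x, depth = 1000, seed = 3), "below")
  sums <- out |>
    dplyr::group_by(sample) |>
    dplyr::summarise(total = sum(reads))
  expect_setequal(sums$sample, c("deep", "exact"))
  expect_true(all(sums$total == 1000))
  # a sample already exactly at depth is returned unchanged
  expect_equal(
    dplyr::filter(out, sample == "exact") |> dplyr::arrange(otu) |>
      dplyr::pull(reads),
    c(600L, 400L)
  )
  expect_identical(
    suppressWarnings(rarefy_samples(x, depth = 1000, seed = 3)),
    suppressWarnings(rarefy_samples(x, depth = 1000, seed = 3))
  )
  expect_error(rarefy_samples(x, depth = 0), "positive")
})

test_that("rarefied counts follow the hypergeometric expectation", {
  # subsampling 100 of 1000 reads (900 F1 / 100 F2): E[F2] = n*K/N = 10
  x <- tibble::tibble(site = "s1", sample = "a", host = "A",
                      otu = c("F1", "F2"), reads = c(900L, 100L))
  draws <- vapply(seq_len(1000), function(s) {
    out <- rarefy_samples(x, depth = 100, seed = s)
    sum(out$reads[out$otu == "F2"])
  }, numeric(1))
  n <- 100; k_succ <- 100; n_tot <- 1000
  expectation <- n * k_succ / n_tot
  v <- n * (k_succ / n_tot) * (1 - k_succ / n_tot) * (n_tot - n) / (n_tot - 1)
  se <- sqrt(v / length(draws))
  expect_lt(abs(mean(draws) - expectation), 3 * se)
})

test_that("species-level conversion counts presences, ignoring read magnitude", {
  x <- tibble::tibble(
    site = "s1", sample = c("a", "b", "b"), host = "A",
    otu = c("F1", "F1", "F2"), reads = c(500L, 1L, 3L)
  )
  sp <- as_species_table(x)
  expect_equal(sp$n_samples[sp$otu == "F1"], 2L)
  # identical to the all-ones version of the same presences
  ones <- dplyr::mutate(x, reads = 1L)
  expect_equal(sp, as_species_table(ones))
  # zero counts contribute nothing, absent plants/OTUs are dropped
  with_zero <- dplyr::add_row(x, site = "s1", sample = "a", host = "A",
                              otu = "F9", reads = 0L)
  expect_false("F9" %in% as_species_table(with_zero)$otu)
  empty <- dplyr::mutate(x, reads = 0L)
  expect_error(as_species_table(empty), "positive")
})

test_that("species-matrix column sums equal the number of samples containing each OTU", {
  set.seed(11)
  x <- random_samples(n_sites = 2, n_samp = 8, n_otus = 12)
  sp <- as_species_table(x)
  per_otu <- sp |>
    dplyr::group_by(otu) |>
    dplyr::summarise(total = sum(n_samples))
  direct <- x |>
    dplyr::filter(reads > 0) |>
    dplyr::distinct(site, sample, otu) |>
    dplyr::count(otu, name = "total")
  expect_equal(per_otu, direct)
})

test_that("preprocessing is idempotent: a second pass changes nothing", {
  set.seed(5)
  x <- random_samples(n_sites = 2, n_samp = 6, n_otus = 10, depth = 500)
  once <- preprocess_samples(x, threshold = 0.001, depth = 300, seed = 9)
  twice <- preprocess_samples(once, threshold = 0.001, depth = 300, seed = 9)
  expect_equal(
    dplyr::arrange(once, site, sample, otu),
    dplyr::arrange(twice, site, sample, otu)
  )
  expect_equal(as_species_table(once), as_species_table(twice))
})

test_that("sample- and species-level TSVs round-trip", {
  x <- fixture_samples() |> dplyr::filter(site == "s1")
  f <- tempfile(fileext = ".tsv")
  write_sample_table(x, f)
  back <- read_sample_table(f, site = "s1")
  expect_equal(
    dplyr::arrange(back, sample, otu),
    dplyr::arrange(x, sample, otu)
  )

  sp <- as_species_table(x)
  f2 <- tempfile(fileext = ".tsv")
  write_species_table(sp, f2)
  back2 <- read_species_table(f2, site = "s1")
  expect_equal(dplyr::arrange(back2, plant, otu),
               dplyr::arrange(sp, plant, otu))
})

test_that("validators catch malformed tables", {
  expect_error(validate_sample_table(data.frame(a = 1)), "lacks column")
  two_hosts <- tibble::tibble(site = "s1", sample = "a",
                              host = c("A", "B"), otu = c("F1", "F2"),
                              reads = 1L)
  expect_error(validate_sample_table(two_hosts), "more than one host")
  expect_error(
    validate_species_table(tibble::tibble(site = "s", plant = "A",
                                          otu = "F", n_samples = 0L)),
    "positive"
  )
})
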