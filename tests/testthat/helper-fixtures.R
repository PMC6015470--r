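# Shared small fixtures built in code.

# two-site sample-level table with known structure
fixture_samples <- function() {
  tibble::tibble(
    site = rep(c("s1", "s2"), c(6, 4)),
    sample = c("a", "a", "b", "b", "c", "c", "d", "d", "e", "e"),
    host = rep(c("A", "A", "B", "C", "C"), each = 2),
    otu = c("F1", "F2", "F1", "F3", "F2", "F3",
            "F1", "F4", "F4", "F5"),
    reads = c(900L, 100L, 950L, 50L, 400L, 600L,
              700L, 300L, 500L, 500L)
  )
}

# random sample-level table (single or multi site)
random_samples <- function(n_sites = 2, n_samp = 6, n_otus = 8,
                           depth = 100) {
  rows <- list()
  for (s in seq_len(n_sites)) {
    for (j in seq_len(n_samp)) {
      reads <- as.integer(rmultinom(1, depth, runif(n_otus, 0.1, 1)))
      pos <- which(reads > 0)
      rows[[length(rows) + 1]] <- tibble::tibble(
        site = paste0("s", s), sample = paste0("s", s, "_", j),
        host = sample(c("A", "B", "C"), 1),
        otu = paste0("F", pos), reads = reads[pos]
      )
    }
  }
  dplyr::bind_rows(rows)
}

# small strong-signal simulation config used by recovery checks: planted hubs
# occupy every site as abundant generalists; the background is single-site
# and strongly host-specialized
strong_signal_config <- function(seed = 101) {
  sim_config(
    n_sites = 5, samples_per_site = 30, depth = 200,
    n_plant_pool = 40, plants_per_site = 10, plant_sharing = 0.3,
    n_otus = 150, range_exponent = 6, host_concentration = 0.05,
    n_planted_hubs = 5, hub_sites = 5, hub_concentration = 100,
    abundance_sdlog = 0.5, hub_abundance_factor = 5, seed = seed
  )
}
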