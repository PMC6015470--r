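#' Configuration for the synthetic metacommunity generator
#'
#' Bundles and validates the parameters of [simulate_metacommunity()]. The
#' defaults emulate the sampling design the pipeline targets: 8 forest sites
#' along an environmental gradient, 240 root samples per site at a fixed
#' sequencing depth of 1000 reads, a regional pool of 150 plant taxa of which
#' each site hosts a partially shared subset, and a fungal OTU pool whose
#' members vary both in geographic range (number of sites occupied, a
#' truncated power law) and in host specificity (a Dirichlet concentration:
#' low = specialist, high = generalist). A configurable number of *planted
#' hubs* — abundant generalists occupying many sites — provides ground truth
#' for recovery experiments.
#'
#' @param n_sites Number of localities.
#' @param samples_per_site Root samples per locality.
#' @param depth Sequencing reads per sample (fixed depth; set
#'   `variable_depth = TRUE` to draw depths uniformly from
#'   `depth_range` instead, e.g. to exercise [rarefy_samples()]).
#' @param n_plant_pool Size of the regional plant-taxon pool.
#' @param plants_per_site Plant taxa present per site.
#' @param plant_sharing Fraction of each site's plant list drawn from a common
#'   core shared by all sites, in `[0, 1]`.
#' @param n_otus Size of the fungal OTU pool.
#' @param range_exponent Exponent of the truncated power law
#'   `P(k) ~ k^-range_exponent` over sites occupied `k = 1..n_sites`.
#' @param host_concentration Symmetric Dirichlet concentration of background
#'   OTUs' host-preference vectors (low = host specialist).
#' @param n_planted_hubs Number of planted hub OTUs.
#' @param hub_sites Sites occupied by each planted hub; at least
#'   `ceiling(n_sites / 2)`, default all sites.
#' @param hub_concentration Dirichlet concentration for planted hubs (high =
#'   generalist); must be >= `host_concentration`.
#' @param abundance_sdlog Log-normal sd of per-OTU abundance weights.
#' @param hub_abundance_factor Multiplier on planted hubs' abundance weights.
#' @param variable_depth,depth_range Optional variable-depth mode.
#' @param seed Master seed; replicate seeds are derived by fixed increments.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_sites = 8, samples_per_site = 240, depth = 1000,
                       n_plant_pool = 150, plants_per_site = 25,
                       plant_sharing = 0.3, n_otus = 2000,
                       range_exponent = 2.5, host_concentration = 0.3,
                       n_planted_hubs = 10, hub_sites = n_sites,
                       hub_concentration = 50, abundance_sdlog = 1,
                       hub_abundance_factor = 5,
                       variable_depth = FALSE,
                       depth_range = c(depth %/% 2, 2 * depth),
                       seed = 1) {
  cfg <- list(
    n_sites = n_sites, samples_per_site = samples_per_site, depth = depth,
    n_plant_pool = n_plant_pool, plants_per_site = plants_per_site,
    plant_sharing = plant_sharing, n_otus = n_otus,
    range_exponent = range_exponent,
    host_concentration = host_concentration,
    n_planted_hubs = n_planted_hubs, hub_sites = hub_sites,
    hub_concentration = hub_concentration,
    abundance_sdlog = abundance_sdlog,
    hub_abundance_factor = hub_abundance_factor,
    variable_depth = variable_depth, depth_range = depth_range,
    seed = seed
  )
  counts <- c("n_sites", "samples_per_site", "depth", "n_plant_pool",
              "plants_per_site", "n_otus")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 1) {
      abort(paste0("`", nm, "` must be a positive count"))
    }
  }
  if (plant_sharing < 0 || plant_sharing > 1) {
    abort("`plant_sharing` must lie in [0, 1]")
  }
  if (plants_per_site > n_plant_pool) {
    abort("per-site plant richness exceeds the plant pool")
  }
  if (n_planted_hubs < 0 || n_planted_hubs > n_otus) {
    abort("`n_planted_hubs` must lie in [0, n_otus]")
  }
  if (n_planted_hubs > 0 && hub_sites < ceiling(n_sites / 2)) {
    abort("planted hubs must occupy at least ceiling(n_sites / 2) sites")
  }
  if (hub_concentration < host_concentration) {
    abort("planted hubs must be at least as generalist as the background")
  }
  structure(cfg, class = "sim_config")
}

rdirichlet_one <- function(k, alpha) {
  g <- rgamma(k, shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(k, 1)] <- 1 # guard against underflow
  g / sum(g)
}

#' Simulate a multi-site plant-fungus metacommunity
#'
#' Draws a synthetic metacommunity under `cfg` (see [sim_config()]):
#'
#' 1. each site's plant list combines a shared core with site-specific taxa,
#'    with log-normal within-site plant abundances;
#' 2. each OTU occupies `k` sites (`k` power-law distributed; planted hubs
#'    occupy `hub_sites` sites) and carries a host-preference vector drawn
#'    once from a symmetric Dirichlet over the plant pool and restricted to
#'    each site's plant list;
#' 3. each sample draws its host plant from the site's plant abundances and
#'    its read vector from a multinomial over the OTUs present at the site,
#'    with weights `occupancy x host preference x OTU abundance`.
#'
#' The same `cfg$seed` reproduces the output exactly; every sample's reads
#' sum to `cfg$depth` (unless `variable_depth`).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `metahub_sim`: `samples` (long sample-level
#'   tibble), `truth` (list with per-OTU tibble `otus` — occupancy, planted
#'   flag, concentration — and per-site `plants` abundance tibble), and `cfg`.
#' @export
simulate_metacommunity <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  site_ids <- sprintf("site%d", seq_len(cfg$n_sites))
  plant_ids <- sprintf("P%03d", seq_len(cfg$n_plant_pool))
  otu_ids <- sprintf("F%04d", seq_len(cfg$n_otus))

  # per-site plant pools: shared core + site-specific draw
  n_core <- round(cfg$plant_sharing * cfg$plants_per_site)
  core <- plant_ids[seq_len(n_core)]
  site_plants <- lapply(seq_len(cfg$n_sites), function(s) {
    extra <- sample(setdiff(plant_ids, core), cfg$plants_per_site - n_core)
    plants <- c(core, extra)
    ab <- rlnorm(length(plants), 0, 1)
    tibble(site = site_ids[s], plant = plants, abundance = ab / sum(ab))
  })

  # OTU geographic ranges: truncated power law, hubs forced wide
  k_range <- seq_len(cfg$n_sites)
  pk <- k_range^(-cfg$range_exponent)
  pk <- pk / sum(pk)
  is_hub <- seq_len(cfg$n_otus) <= cfg$n_planted_hubs
  k_occ <- ifelse(is_hub, cfg$hub_sites,
                  sample(k_range, cfg$n_otus, replace = TRUE, prob = pk))
  occ_sites <- lapply(seq_len(cfg$n_otus), function(i) {
    sort(sample.int(cfg$n_sites, k_occ[i]))
  })
  occ <- matrix(FALSE, cfg$n_otus, cfg$n_sites)
  for (i in seq_len(cfg$n_otus)) occ[i, occ_sites[[i]]] <- TRUE

  conc <- ifelse(is_hub, cfg$hub_concentration, cfg$host_concentration)
  pref <- t(vapply(conc, function(a) rdirichlet_one(cfg$n_plant_pool, a),
                   numeric(cfg$n_plant_pool)))
  colnames(pref) <- plant_ids
  abundance <- rlnorm(cfg$n_otus, 0, cfg$abundance_sdlog) *
    ifelse(is_hub, cfg$hub_abundance_factor, 1)

  samples <- vector("list", cfg$n_sites)
  for (s in seq_len(cfg$n_sites)) {
    sp <- site_plants[[s]]
    present <- which(occ[, s])
    if (length(present) == 0) {
      abort("a site has no occupying OTU; increase n_otus or range exponent")
    }
    hosts <- sample(sp$plant, cfg$samples_per_site, replace = TRUE,
                    prob = sp$abundance)
    depths <- if (cfg$variable_depth) {
      sample(seq(cfg$depth_range[1], cfg$depth_range[2]),
             cfg$samples_per_site, replace = TRUE)
    } else {
      rep(cfg$depth, cfg$samples_per_site)
    }
    rows <- vector("list", cfg$samples_per_site)
    for (j in seq_len(cfg$samples_per_site)) {
      w <- pref[present, hosts[j]] * abundance[present]
      if (sum(w) == 0) w <- rep(1, length(present))
      reads <- as.integer(rmultinom(1, depths[j], w))
      pos <- reads > 0
      rows[[j]] <- tibble(
        site = site_ids[s], sample = sprintf("s%d_%03d", s, j),
        host = hosts[j], otu = otu_ids[present][pos], reads = reads[pos]
      )
    }
    samples[[s]] <- dplyr::bind_rows(rows)
  }

  truth_otus <- tibble(
    otu = otu_ids,
    n_sites = k_occ,
    sites = purrr::map(occ_sites, ~ site_ids[.x]),
    planted_hub = is_hub,
    concentration = conc,
    abundance = abundance
  )
  structure(
    list(samples = dplyr::bind_rows(samples),
         truth = list(otus = truth_otus,
                      plants = dplyr::bind_rows(site_plants)),
         cfg = cfg),
    class = "metahub_sim"
  )
}

#' @export
print.metahub_sim <- function(x, ...) {
  cat(sprintf(
    "<metahub_sim: %d site(s) x %d sample(s), %d OTU(s) in pool, %d planted hub(s), seed %d>\n",
    x$cfg$n_sites, x$cfg$samples_per_site, x$cfg$n_otus,
    x$cfg$n_planted_hubs, x$cfg$seed
  ))
  invisible(x)
}

#' Planted-hub recovery experiment
#'
#' Runs the full pipeline (rare-association filter, species-level conversion,
#' local and metacommunity betweenness, hub classification) on `n_reps`
#' independently simulated metacommunities and scores how well the
#' classification recovers the planted hubs:
#'
#' * `sensitivity` — planted hubs classified `metacommunity_hub` / planted
#'   hubs present in the realized matrices;
#' * `precision` — planted hubs among all OTUs classified `metacommunity_hub`;
#' * `rho` — Spearman rank correlation between an OTU's true number of
#'   occupied sites and its standardized metacommunity betweenness.
#'
#' Replicate `r` uses seed `cfg$seed + r - 1`.
#'
#' @param cfg A [sim_config()].
#' @param n_reps Number of replicates (>= 1), default 20.
#' @param threshold Classification threshold, default 0.5.
#' @param filter_threshold Rare-association threshold applied before
#'   conversion (`NULL` to skip), default 0.001.
#' @return A `recovery_report` tibble with one row per replicate; `glance()`
#'   averages over replicates.
#' @export
recovery_experiment <- function(cfg, n_reps = 20, threshold = 0.5,
                                filter_threshold = 0.001) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.numeric(n_reps) || n_reps < 1) abort("`n_reps` must be >= 1")
  reps <- purrr::map(seq_len(n_reps), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1
    sim <- simulate_metacommunity(cfg_r)
    tbl <- sim$samples
    if (!is.null(filter_threshold)) {
      tbl <- filter_rare_associations(tbl, filter_threshold)
    }
    cls <- hub_classification(as_species_table(tbl), threshold = threshold)
    truth <- sim$truth$otus
    joined <- dplyr::inner_join(cls, truth[, c("otu", "n_sites", "planted_hub")],
                                by = "otu", suffix = c("", "_true"))
    predicted <- joined$category == "metacommunity_hub"
    planted <- joined$planted_hub
    tibble(
      rep = r, seed = cfg_r$seed,
      n_classified = nrow(joined),
      n_planted_present = sum(planted),
      sensitivity = if (sum(planted) > 0) {
        sum(predicted & planted) / sum(planted)
      } else {
        NA_real_
      },
      precision = if (sum(predicted) > 0) {
        sum(predicted & planted) / sum(predicted)
      } else {
        NA_real_
      },
      rho = suppressWarnings(
        cor(joined$n_sites_true, joined$b_meta, method = "spearman")
      )
    )
  })
  out <- dplyr::bind_rows(reps)
  class(out) <- c("recovery_report", class(out))
  out
}

#' @exportS3Method generics::glance
glance.recovery_report <- function(x, ...) {
  tibble(
    n_reps = nrow(x),
    mean_sensitivity = mean(x$sensitivity, na.rm = TRUE),
    mean_precision = mean(x$precision, na.rm = TRUE),
    mean_rho = mean(x$rho, na.rm = TRUE)
  )
}
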