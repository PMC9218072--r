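#' Virtual grassland: species pool, communities and the two survey protocols
#'
#' The simulator generates the latent truth the pipeline is validated
#' against: a regional pool of species with Gaussian precipitation response
#' curves (compositional turnover along the gradient), site communities
#' whose expected richness follows a rise-then-saturate quadratic in mean
#' annual precipitation, and "virtual ecologist" observations of each
#' community under both protocols -- 16 waypoint photographs per site (with
#' small-stature species invisible from 2 m) and 3 ground quadrats of
#' 0.25 m^2 (which do see small-stature species but sample a much smaller
#' footprint).
#'
#' All randomness flows from a single seed through named sub-streams
#' (pool, sites, communities, uav, quadrat), so each stage is reproducible
#' independently.
#'
#' @name simulate
NULL

#' Simulation configuration
#'
#' Defaults emulate an alpine-grassland monitoring campaign: 37 sites over a
#' 250-720 mm precipitation gradient, a regional pool of 111 species of
#' which 4 are small-stature (invisible to aerial photographs), 16 photos
#' per site, and 3 quadrats at 13 of the sites. Expected site richness is
#' r0 + r1*P + r2*P^2 with r2 < 0: about 8 species at 250 mm rising to a
#' plateau of about 35 near 600 mm. The quadratic's curvature was fixed by a
#' design power analysis so the curvature is detectable from 37 sites.
#'
#' @param seed integer master seed.
#' @param n_sites number of sites (default 37).
#' @param precip_range precipitation range in mm (default c(250, 720)).
#' @param n_pool regional species-pool size (default 111).
#' @param n_small_stature number of pool species too low-growing to be seen
#'   in aerial photos (default 4).
#' @param richness_coef quadratic coefficients (r0, r1, r2) of expected
#'   richness vs precipitation, r2 < 0.
#' @param turnover_width_mm width (sd, mm) of the Gaussian species response
#'   curves along precipitation; smaller = faster compositional turnover.
#' @param occupancy_k photo occupancy steepness: a species of relative
#'   abundance a occurs in a photo with probability 1 - (1 - a)^k, i.e. k
#'   acts as the number of rooted units distinguishable in one footprint.
#'   The default (200) makes photo detection of all but the rarest species
#'   near-certain over 16 photos while the area-scaled quadrat exponent
#'   (k * quadrat/photo area ratio, about 7) leaves quadrats missing many
#'   rare species -- the sampling-effort contrast between the protocols.
#' @param photo_area_m2 ground footprint of one photo (about 7 m^2 at 2 m
#'   flight height with an 83 degree field of view).
#' @param quadrat_area_m2 quadrat area (0.5 m x 0.5 m = 0.25 m^2).
#' @param uav_miss_prob probability that a small-stature species present at
#'   a site is missed entirely by the photo protocol (default 1).
#' @param dominance_thresholds within-photo abundance shares above which a
#'   detected species may be labelled dominant / subdominant (at most two
#'   of each per photo).
#' @param geometric_k parameter of the geometric rank-abundance series.
#' @param logseries_x parameter of the log-series regional commonness
#'   weights.
#' @param biomass_scale_g median clipped dry biomass (g per quadrat) of a
#'   hypothetical species with abundance share 1.
#' @param biomass_sdlog lognormal biomass noise on the log scale.
#' @param density_rate expected shoot count per quadrat for abundance
#'   share 1 (density is 1 + Poisson, so detected species have >= 1 shoot).
#' @param n_quadrat_sites how many sites also get the ground protocol
#'   (default 13).
#' @param n_photos photographs per site (default 16).
#' @param n_quadrats quadrats per ground-sampled site (default 3).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_sites = 37L,
                       precip_range = c(250, 720),
                       n_pool = 111L,
                       n_small_stature = 4L,
                       richness_coef = c(r0 = -44.3469387755102,
                                         r1 = 0.264489795918367,
                                         r2 = -0.000220408163265306),
                       turnover_width_mm = 150,
                       occupancy_k = 200,
                       photo_area_m2 = 7,
                       quadrat_area_m2 = 0.25,
                       uav_miss_prob = 1,
                       dominance_thresholds = c(dominant = 0.30,
                                                subdominant = 0.15),
                       geometric_k = 0.15,
                       logseries_x = 0.98,
                       biomass_scale_g = 40,
                       biomass_sdlog = 0.6,
                       density_rate = 150,
                       n_quadrat_sites = 13L,
                       n_photos = 16L,
                       n_quadrats = 3L) {
  cfg <- list(seed = as.integer(seed), n_sites = as.integer(n_sites),
              precip_range = as.numeric(precip_range),
              n_pool = as.integer(n_pool),
              n_small_stature = as.integer(n_small_stature),
              richness_coef = unname(as.numeric(richness_coef)),
              turnover_width_mm = turnover_width_mm,
              occupancy_k = occupancy_k, photo_area_m2 = photo_area_m2,
              quadrat_area_m2 = quadrat_area_m2,
              uav_miss_prob = uav_miss_prob,
              dominance_thresholds = dominance_thresholds,
              geometric_k = geometric_k, logseries_x = logseries_x,
              biomass_scale_g = biomass_scale_g,
              biomass_sdlog = biomass_sdlog, density_rate = density_rate,
              n_quadrat_sites = as.integer(n_quadrat_sites),
              n_photos = as.integer(n_photos),
              n_quadrats = as.integer(n_quadrats))
  if (length(cfg$precip_range) != 2 || diff(cfg$precip_range) <= 0) {
    abort("precip_range must be an increasing pair (mm)")
  }
  if (length(cfg$richness_coef) != 3) {
    abort("richness_coef must be (r0, r1, r2)")
  }
  if (cfg$uav_miss_prob < 0 || cfg$uav_miss_prob > 1) {
    abort("uav_miss_prob must be in [0, 1]")
  }
  if (cfg$n_small_stature > cfg$n_pool) {
    abort("more small-stature species than pool species")
  }
  if (cfg$n_quadrat_sites > cfg$n_sites) {
    abort("n_quadrat_sites cannot exceed n_sites")
  }
  if (cfg$n_photos < 1 || cfg$n_photos > 16) {
    abort("n_photos must be in 1-16 (the waypoint grid)")
  }
  mu <- expected_richness(cfg, seq(cfg$precip_range[1], cfg$precip_range[2],
                                   length.out = 101))
  if (any(mu < 1)) {
    abort("expected richness drops below 1 inside the precipitation range")
  }
  if (max(mu) > cfg$n_pool) {
    abort("expected richness exceeds the species-pool size")
  }
  class(cfg) <- "sim_config"
  cfg
}

expected_richness <- function(config, precip) {
  r <- config$richness_coef
  r[1] + r[2] * precip + r[3] * precip^2
}

#' Generate the regional species pool
#'
#' Each of the `n_pool` taxa gets a precipitation optimum (uniform over the
#' site range extended by one turnover width on each side), a Gaussian
#' response width, a log-series regional commonness weight, and a
#' small-stature flag for `n_small_stature` randomly chosen taxa.
#'
#' @param config a [sim_config].
#' @return tibble: `species`, `optimum_mm`, `width_mm`, `commonness`,
#'   `small_stature`.
#' @export
generate_pool <- function(config) {
  withr::with_seed(stream_seed(config$seed, "pool"), {
    n <- config$n_pool
    lo <- config$precip_range[1] - config$turnover_width_mm
    hi <- config$precip_range[2] + config$turnover_width_mm
    ranks <- seq_len(n)
    x <- config$logseries_x
    pool <- tibble::tibble(
      species = sprintf("Species_%03d", ranks),
      optimum_mm = runif(n, lo, hi),
      width_mm = config$turnover_width_mm,
      commonness = x^ranks / ranks,
      small_stature = FALSE
    )
    pool$commonness <- pool$commonness / sum(pool$commonness)
    if (config$n_small_stature > 0) {
      pool$small_stature[sample.int(n, config$n_small_stature)] <- TRUE
    }
    pool
  })
}

#' Assemble the true community of one site
#'
#' Target richness is Poisson around the quadratic mean (truncated to
#' [1, pool size]); species are drawn without replacement with probability
#' proportional to commonness times the Gaussian response at this
#' precipitation; relative abundances follow a geometric rank-abundance
#' series down the suitability ranking.
#'
#' @param pool output of [generate_pool].
#' @param precip site mean annual precipitation (mm).
#' @param config a [sim_config].
#' @param seed site-level seed (derive with `stream_seed`).
#' @return tibble: `species`, `abundance` (sums to 1), `small_stature`.
#' @export
assemble_community <- function(pool, precip, config, seed) {
  withr::with_seed(seed, {
    mu <- max(1, expected_richness(config, precip))
    n_target <- min(config$n_pool, max(1L, rpois(1, mu)))
    suit <- pool$commonness *
      exp(-0.5 * ((precip - pool$optimum_mm) / pool$width_mm)^2)
    suit <- pmax(suit, 1e-12)
    idx <- sample.int(config$n_pool, n_target, prob = suit)
    chosen <- pool[idx, , drop = FALSE]
    ord <- order(suit[idx], decreasing = TRUE)
    k <- config$geometric_k
    ab <- k * (1 - k)^(seq_len(n_target) - 1)
    tibble::tibble(
      species = chosen$species[ord],
      abundance = ab / sum(ab),
      small_stature = chosen$small_stature[ord]
    )
  })
}

label_dominance <- function(shares, thresholds) {
  # at most two 'dominant' and two 'subdominant' labels per photo, assigned
  # down the abundance ranking when the share clears the class threshold
  lab <- rep("present", length(shares))
  ord <- order(shares, decreasing = TRUE)
  n_dom <- 0L
  n_sub <- 0L
  for (i in ord) {
    if (n_dom < 2L && shares[i] > thresholds[["dominant"]]) {
      lab[i] <- "dominant"
      n_dom <- n_dom + 1L
    } else if (n_sub < 2L && shares[i] > thresholds[["subdominant"]]) {
      lab[i] <- "subdominant"
      n_sub <- n_sub + 1L
    }
  }
  lab
}

#' Simulate the photo protocol at one site
#'
#' Species i (abundance a_i) appears in each photograph independently with
#' occupancy 1 - (1 - a_i)^k. Small-stature species are missed entirely
#' with probability `uav_miss_prob`. Within each photo the detected species
#' whose abundance share clears the configured thresholds are labelled
#' dominant (top 2) or subdominant (next 2).
#'
#' @param community output of [assemble_community].
#' @param site_id site label.
#' @param config a [sim_config].
#' @param seed site-level seed.
#' @return tibble in [photo_survey] column layout (possibly zero rows).
#' @export
simulate_uav_survey <- function(community, site_id, config, seed) {
  withr::with_seed(seed, {
    visible <- !community$small_stature |
      runif(nrow(community)) >= config$uav_miss_prob
    com <- community[visible, , drop = FALSE]
    out <- list()
    for (wp in seq_len(config$n_photos)) {
      occ <- 1 - (1 - com$abundance)^config$occupancy_k
      hit <- runif(nrow(com)) < occ
      if (!any(hit)) next
      ab <- com$abundance[hit]
      shares <- ab / sum(ab)
      out[[length(out) + 1]] <- tibble::tibble(
        site_id = site_id,
        waypoint = wp,
        species = com$species[hit],
        dominance_class = label_dominance(shares,
                                          config$dominance_thresholds)
      )
    }
    if (length(out) == 0) {
      tibble::tibble(site_id = character(), waypoint = integer(),
                     species = character(), dominance_class = character())
    } else {
      dplyr::bind_rows(out)
    }
  })
}

#' Simulate the ground-quadrat protocol at one site
#'
#' Quadrats sample a footprint `quadrat_area_m2 / photo_area_m2` times the
#' photo's, so per-quadrat occupancy is 1 - (1 - a_i)^(k * area ratio).
#' Detected species get lognormal biomass with median proportional to
#' abundance and shifted-Poisson shoot density. Small-stature species are
#' fully detectable on the ground.
#'
#' @inheritParams simulate_uav_survey
#' @return tibble in [quadrat_survey] column layout (possibly zero rows).
#' @export
simulate_quadrat_survey <- function(community, site_id, config, seed) {
  withr::with_seed(seed, {
    area_ratio <- config$quadrat_area_m2 / config$photo_area_m2
    k_q <- config$occupancy_k * area_ratio
    out <- list()
    for (q in seq_len(config$n_quadrats)) {
      occ <- 1 - (1 - community$abundance)^k_q
      hit <- runif(nrow(community)) < occ
      if (!any(hit)) next
      ab <- community$abundance[hit]
      out[[length(out) + 1]] <- tibble::tibble(
        site_id = site_id,
        quadrat_id = q,
        species = community$species[hit],
        biomass_g = rlnorm(length(ab),
                           meanlog = log(config$biomass_scale_g * ab),
                           sdlog = config$biomass_sdlog),
        density_count = 1 + rpois(length(ab), config$density_rate * ab)
      )
    }
    if (length(out) == 0) {
      tibble::tibble(site_id = character(), quadrat_id = integer(),
                     species = character(), biomass_g = numeric(),
                     density_count = numeric())
    } else {
      dplyr::bind_rows(out)
    }
  })
}

#' Simulate a whole survey region under both protocols
#'
#' Draws `n_sites` sites with precipitation uniform over the configured
#' range, assembles each site's true community, photographs every site, and
#' additionally ground-samples a random subset of `n_quadrat_sites` sites.
#'
#' @param config a [sim_config].
#' @return list with elements `photo` ([photo_survey]), `quadrat`
#'   ([quadrat_survey]), `covariates` ([site_covariates]), `truth` (tibble
#'   `site_id`, `species`, `true_abundance`, `small_stature`, `precip_mm`),
#'   and `config`.
#' @export
simulate_region <- function(config = sim_config()) {
  pool <- generate_pool(config)
  site_ids <- sprintf("S%02d", seq_len(config$n_sites))
  sites <- withr::with_seed(stream_seed(config$seed, "sites"), {
    precip <- sort(round(runif(config$n_sites, config$precip_range[1],
                               config$precip_range[2]), 1))
    quadrat_sites <- sort(sample(site_ids, config$n_quadrat_sites))
    list(precip = precip, quadrat_sites = quadrat_sites)
  })
  communities <- lapply(seq_len(config$n_sites), function(i) {
    assemble_community(pool, sites$precip[i], config,
                       stream_seed(config$seed, "communities", i))
  })
  photo_rows <- lapply(seq_len(config$n_sites), function(i) {
    simulate_uav_survey(communities[[i]], site_ids[i], config,
                        stream_seed(config$seed, "uav", i))
  })
  quadrat_rows <- lapply(which(site_ids %in% sites$quadrat_sites), function(i) {
    simulate_quadrat_survey(communities[[i]], site_ids[i], config,
                            stream_seed(config$seed, "quadrat", i))
  })
  truth <- dplyr::bind_rows(lapply(seq_len(config$n_sites), function(i) {
    tibble::tibble(site_id = site_ids[i],
                   species = communities[[i]]$species,
                   true_abundance = communities[[i]]$abundance,
                   small_stature = communities[[i]]$small_stature,
                   precip_mm = sites$precip[i])
  }))
  list(
    photo = suppressWarnings(photo_survey(dplyr::bind_rows(photo_rows))),
    quadrat = suppressWarnings(quadrat_survey(dplyr::bind_rows(quadrat_rows))),
    covariates = site_covariates(
      tibble::tibble(site_id = site_ids, precip_mm = sites$precip)),
    truth = truth,
    config = config
  )
}
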