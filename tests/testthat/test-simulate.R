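test_that("the default pool has 111 taxa with 4 small-stature flags and is seed-stable", {
  cfg <- sim_config(seed = 5)
  pool <- generate_pool(cfg)
  expect_equal(nrow(pool), 111)
  expect_equal(sum(pool$small_stature), 4)
  expect_equal(anyDuplicated(pool$species), 0)
  expect_true(all(pool$commonness > 0))
  expect_equal(sum(pool$commonness), 1, tolerance = 1e-12)
  expect_identical(pool, generate_pool(sim_config(seed = 5)))
  expect_false(identical(pool$optimum_mm,
                         generate_pool(sim_config(seed = 6))$optimum_mm))

  none <- generate_pool(sim_config(seed = 5, n_small_stature = 0))
  expect_equal(sum(none$small_stature), 0)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(uav_miss_prob = 2), "miss_prob")
  expect_error(sim_config(n_quadrat_sites = 40), "exceed")
  expect_error(sim_config(n_small_stature = 200), "small-stature")
  expect_error(sim_config(richness_coef = c(0, 0.002, 0)),
               "drops below 1")
  expect_error(sim_config(richness_coef = c(500, 0, -1e-9)),
               "exceeds the species-pool")
})

test_that("communities are normalized, pool-drawn, and precipitation-sized", {
  cfg <- sim_config(seed = 9)
  pool <- generate_pool(cfg)
  com <- assemble_community(pool, 500, cfg, seed = 1234)
  expect_equal(sum(com$abundance), 1, tolerance = 1e-12)
  expect_true(all(com$abundance > 0))
  expect_true(all(com$species %in% pool$species))
  expect_equal(anyDuplicated(com$species), 0)
  expect_identical(com, assemble_community(pool, 500, cfg, seed = 1234))

  # richness tracks the quadratic mean: wet-plateau sites hold more species
  rich_at <- function(precip) {
    mean(vapply(1:40, function(i) {
      nrow(assemble_community(pool, precip, cfg, seed = 5000 + i))
    }, numeric(1)))
  }
  expect_gt(rich_at(600), rich_at(260) + 10)

  # flat truth: richness independent of precipitation
  flat <- sim_config(seed = 9, richness_coef = c(20, 0, 0))
  flat_pool <- generate_pool(flat)
  flat_rich <- function(precip) {
    mean(vapply(1:60, function(i) {
      nrow(assemble_community(flat_pool, precip, flat, seed = 7000 + i))
    }, numeric(1)))
  }
  expect_lt(abs(flat_rich(600) - flat_rich(300)), 3)
})

test_that("turnover: nearby sites share more species than sites 300 mm apart", {
  cfg <- sim_config(seed = 21)
  pool <- generate_pool(cfg)
  sor <- function(p1, p2, i) {
    a <- assemble_community(pool, p1, cfg, seed = 100 + i)
    b <- assemble_community(pool, p2, cfg, seed = 9000 + i)
    beta_pair(a$species, b$species)$sorensen
  }
  near <- vapply(1:60, function(i) sor(400, 400, i), numeric(1))
  far <- vapply(1:60, function(i) sor(400, 700, i), numeric(1))
  expect_gt(mean(near), mean(far) + 0.05)
})

test_that("photo simulation honors visibility, occupancy and the dominance bound", {
  cfg <- sim_config(seed = 13)
  pool <- generate_pool(cfg)
  com <- assemble_community(pool, 550, cfg, seed = 77)

  # small-stature species never reach the photo table under full miss
  com_small <- com
  com_small$small_stature[1:3] <- TRUE
  photos <- simulate_uav_survey(com_small, "S1", cfg, seed = 5)
  expect_false(any(photos$species %in% com_small$species[1:3]))
  expect_true(all(photos$waypoint %in% 1:16))

  # miss probability zero restores them (they are abundant ranks here)
  cfg_keep <- sim_config(seed = 13, uav_miss_prob = 0)
  photos_keep <- simulate_uav_survey(com_small, "S1", cfg_keep, seed = 5)
  expect_true(any(photos_keep$species %in% com_small$species[1:3]))

  # saturated occupancy puts every (photo-visible) species in all photos,
  # so presence frequencies are uniform
  cfg_sat <- sim_config(seed = 13, occupancy_k = 1e9)
  com_vis <- com
  com_vis$small_stature <- FALSE
  sat <- simulate_uav_survey(com_vis, "S1", cfg_sat, seed = 5)
  expect_equal(nrow(sat), nrow(com) * 16)
  p <- presence_proportions(suppressWarnings(photo_survey(sat)))
  expect_true(all(abs(p - 1 / nrow(com)) < 1e-12))

  # dominance labels never exceed two per class in any photo
  many <- dplyr::bind_rows(lapply(1:60, function(i) {
    simulate_uav_survey(assemble_community(pool, 300 + 5 * i, cfg,
                                           seed = 800 + i),
                        paste0("S", i), cfg, seed = 900 + i)
  }))
  labelled <- many[many$dominance_class != "present", ]
  per_photo <- table(paste(labelled$site_id, labelled$waypoint,
                           labelled$dominance_class))
  expect_true(all(per_photo <= 2))
  expect_s3_class(suppressWarnings(photo_survey(many)), "photo_survey")
})

test_that("quadrat simulation sees small-stature species but a smaller footprint", {
  cfg <- sim_config(seed = 31)
  pool <- generate_pool(cfg)
  com <- assemble_community(pool, 550, cfg, seed = 3)
  com$small_stature[1] <- TRUE

  quad <- simulate_quadrat_survey(com, "S1", cfg, seed = 8)
  expect_true(all(quad$biomass_g > 0))
  expect_true(all(quad$density_count >= 1))
  expect_s3_class(quadrat_survey(quad), "quadrat_survey")
  # the top-ranked (small-stature) species is on the ground table but
  # never on the photo table
  expect_true(com$species[1] %in% quad$species)
  photos <- simulate_uav_survey(com, "S1", cfg, seed = 8)
  expect_false(com$species[1] %in% photos$species)

  # a vanishing footprint detects (almost) nothing
  cfg_tiny <- sim_config(seed = 31, quadrat_area_m2 = 1e-6)
  tiny <- simulate_quadrat_survey(com, "S1", cfg_tiny, seed = 8)
  expect_lt(nrow(tiny), 3)

  # photos out-detect quadrats per site on average
  rich <- vapply(1:40, function(i) {
    ci <- assemble_community(pool, 300 + 10 * i %% 400, cfg, seed = 40 + i)
    c(uav = length(unique(
        simulate_uav_survey(ci, "X", cfg, seed = 50 + i)$species)),
      quad = length(unique(
        simulate_quadrat_survey(ci, "X", cfg, seed = 60 + i)$species)))
  }, numeric(2))
  expect_gt(mean(rich["uav", ]), mean(rich["quad", ]))
})

test_that("simulate_region reproduces the study design and is deterministic", {
  cfg <- sim_config(seed = 101)
  region <- simulate_region(cfg)
  expect_equal(nrow(region$covariates), 37)
  expect_equal(length(unique(region$photo$site_id)), 37)
  expect_equal(length(unique(region$quadrat$site_id)), 13)
  expect_true(all(region$covariates$precip_mm >= 250 &
                    region$covariates$precip_mm <= 720))
  expect_s3_class(region$photo, "photo_survey")
  expect_s3_class(region$quadrat, "quadrat_survey")

  again <- simulate_region(sim_config(seed = 101))
  expect_identical(tibble::as_tibble(region$photo),
                   tibble::as_tibble(again$photo))
  expect_identical(tibble::as_tibble(region$quadrat),
                   tibble::as_tibble(again$quadrat))
  expect_identical(region$truth, again$truth)

  # gamma of the photo tables is bounded by the pool and dominates the
  # richest single site
  sets <- species_sets(region$photo)
  g <- gamma_richness(sets)
  expect_lte(g, 111)
  expect_gte(g, max(lengths(sets)))

  # byte-identical files on re-simulation
  d1 <- withr::local_tempdir()
  write_photo_survey(region$photo, file.path(d1, "a.csv"))
  write_photo_survey(again$photo, file.path(d1, "b.csv"))
  expect_identical(readLines(file.path(d1, "a.csv")),
                   readLines(file.path(d1, "b.csv")))
})
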