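one_site_photos <- function(...) {
  # build a photo_survey from per-photo species lists, e.g.
  # one_site_photos(c(A = "dominant", B = "present"), c(B = "present"))
  photos <- list(...)
  rows <- lapply(seq_along(photos), function(wp) {
    tibble::tibble(site_id = "S1", waypoint = wp,
                   species = names(photos[[wp]]),
                   dominance_class = unname(photos[[wp]]))
  })
  suppressWarnings(photo_survey(dplyr::bind_rows(rows)))
}

test_that("richness is the distinct-species union across subplots", {
  expect_equal(site_richness(c("A", "B", "B", "C")), 3)
  expect_equal(site_richness(rep("A", 3)), 1)
  expect_equal(site_richness(character()), 0)
  tab <- one_site_photos(c(A = "present", B = "present"),
                         c(B = "present", C = "present"))
  expect_equal(site_richness(tab$species), 3)
})

test_that("presence-frequency proportions follow photo counts and sum to 1", {
  tab <- one_site_photos(c(A = "present", B = "present"),
                         c(A = "present", B = "present"),
                         c(A = "present"),
                         c(A = "present"))
  p <- presence_proportions(tab)
  expect_setequal_named(p, c(A = 4 / 6, B = 2 / 6))
  single <- one_site_photos(c(A = "present"), c(A = "present"))
  expect_equal(unname(unclass(presence_proportions(single))), 1)
})

test_that("dominance weighting uses 3/2/1 and collapses to presence when unlabeled", {
  one <- one_site_photos(c(A = "dominant", B = "subdominant", C = "present"))
  expect_setequal_named(dominance_proportions(one),
                        c(A = 3 / 6, B = 2 / 6, C = 1 / 6))

  # photo 1: A dominant alone; photo 2: A and B present
  two <- one_site_photos(c(A = "dominant"), c(A = "present", B = "present"))
  expect_setequal_named(dominance_proportions(two), c(A = 4 / 5, B = 1 / 5))

  for (seed in 1:20) {
    tab <- random_photo_table(seed)
    tab$dominance_class <- "present"
    expect_equal(dominance_proportions(tab), presence_proportions(tab))
  }
})

test_that("quadrat proportions average biomass and density across quadrats first", {
  single <- quadrat_survey(tibble::tibble(
    site_id = "S1", quadrat_id = 1L, species = c("A", "B"),
    biomass_g = c(10, 10), density_count = c(5, 15)))
  expect_setequal_named(quadrat_proportions(single),
                        c(A = 0.375, B = 0.625))

  # A only in q1 (biomass 6), B biomass 3 in both: mean biomasses equal,
  # and mean densities equal too (8 in one quadrat vs 4 in both)
  two <- quadrat_survey(tibble::tibble(
    site_id = "S1", quadrat_id = c(1L, 1L, 2L),
    species = c("A", "B", "B"),
    biomass_g = c(6, 3, 3), density_count = c(8, 4, 4)))
  expect_setequal_named(quadrat_proportions(two), c(A = 0.5, B = 0.5))

  lone <- quadrat_survey(tibble::tibble(
    site_id = "S1", quadrat_id = 1L, species = "A",
    biomass_g = 3, density_count = 2))
  expect_equal(unname(unclass(quadrat_proportions(lone))), 1)
})

test_that("Shannon, Simpson and Pielou match their closed forms", {
  expect_equal(shannon(proportion_vector(setNames(rep(1, 4), letters[1:4]))),
               log(4), tolerance = 1e-12)
  expect_equal(shannon(proportion_vector(c(a = 1))), 0)
  expect_equal(shannon(proportion_vector(c(a = 0.5, b = 0.25, c = 0.25))),
               1.039721, tolerance = 1e-6)
  expect_equal(simpson(proportion_vector(c(a = 1))), 0)
  expect_equal(simpson(proportion_vector(c(a = 1, b = 1))), 0.5)
  expect_equal(simpson(proportion_vector(c(a = 0.375, b = 0.625))), 0.46875,
               tolerance = 1e-12)
  expect_equal(pielou(log(7), 7), 1, tolerance = 1e-12)
  expect_true(is.na(pielou(0, 1)))
  expect_error(pielou(0.5, 0), "at least one species")
  expect_equal(pielou(1.039721, 3), 0.946395, tolerance = 1e-6)
})

test_that("index values agree with vegan on random proportion vectors", {
  skip_if_not_installed("vegan")
  for (seed in 1:25) {
    p <- withr::with_seed(seed, {
      v <- runif(sample(2:12, 1))
      proportion_vector(setNames(v, paste0("sp", seq_along(v))))
    })
    expect_equal(shannon(p), unname(vegan::diversity(unclass(p), "shannon")),
                 tolerance = 1e-12)
    expect_equal(simpson(p), unname(vegan::diversity(unclass(p), "simpson")),
                 tolerance = 1e-12)
  }
})

test_that("all three proportion pathways produce unit-sum vectors with entropy and Simpson bounds", {
  for (seed in 1:40) {
    ptab <- random_photo_table(seed)
    qtab <- random_quadrat_table(seed + 1000)
    for (p in list(presence_proportions(ptab), dominance_proportions(ptab),
                   quadrat_proportions(qtab))) {
      n <- length(p)
      expect_lt(abs(sum(p) - 1), 1e-9)
      expect_true(all(p > 0))
      expect_lte(shannon(p), log(n) + 1e-9)
      expect_gte(simpson(p), 0)
      expect_lte(simpson(p), 1 - 1 / n + 1e-12)
    }
  }
  # entropy attains ln N exactly at the uniform vector
  u <- proportion_vector(setNames(rep(2, 6), paste0("s", 1:6)))
  expect_equal(shannon(u), log(6), tolerance = 1e-12)
})

test_that("alpha profiles equal the scalar-loop oracle on random fixtures", {
  for (seed in 1:30) {
    ptab <- random_photo_table(seed)
    prof_b <- alpha_profile(photo = ptab, method = "UAV_B")
    p_or <- oracle_presence_props(ptab)
    expect_equal(prof_b$richness, length(p_or))
    expect_equal(prof_b$shannon, oracle_shannon(p_or), tolerance = 1e-12)
    expect_equal(prof_b$simpson, oracle_simpson(p_or), tolerance = 1e-12)
    expect_equal(prof_b$pielou, oracle_pielou(prof_b$shannon, prof_b$richness),
                 tolerance = 1e-12)

    prof_bd <- alpha_profile(photo = ptab, method = "UAV_BD")
    d_or <- oracle_dominance_props(ptab)
    expect_equal(prof_bd$shannon, oracle_shannon(d_or), tolerance = 1e-12)
    expect_equal(prof_bd$simpson, oracle_simpson(d_or), tolerance = 1e-12)

    qtab <- random_quadrat_table(seed + 500)
    prof_q <- alpha_profile(quadrat = qtab, method = "TSM_Q")
    q_or <- oracle_quadrat_props(qtab)
    expect_equal(prof_q$shannon, oracle_shannon(q_or), tolerance = 1e-12)
    expect_equal(prof_q$simpson, oracle_simpson(q_or), tolerance = 1e-12)
  }
})

test_that("a single-species site profiles as N=1, H=0, D=0, undefined Pielou", {
  tab <- one_site_photos(c(A = "present"), c(A = "present"))
  prof <- alpha_profile(photo = tab, method = "UAV_B")
  expect_equal(prof$richness, 1)
  expect_equal(prof$shannon, 0)
  expect_equal(prof$simpson, 0)
  expect_true(is.na(prof$pielou))
})

test_that("adding a photo never decreases richness", {
  for (seed in 1:15) {
    tab <- random_photo_table(seed)
    n_before <- site_richness(tab$species)
    extra <- tibble::tibble(site_id = "S1",
                            waypoint = max(tab$waypoint),
                            species = "brand_new_sp",
                            dominance_class = "present")
    grown <- suppressWarnings(photo_survey(dplyr::bind_rows(
      tibble::as_tibble(tab), extra)))
    expect_gte(site_richness(grown$species), n_before)
  }
})

test_that("unknown methods and empty inputs raise clear errors", {
  tab <- one_site_photos(c(A = "present"))
  expect_error(alpha_profile(photo = tab, method = "UAV_X"), "unknown method")
  expect_error(alpha_profile(method = "TSM_Q"), "quadrat")
  empty <- tab[0, ]
  expect_error(presence_proportions(empty), "no species")
  expect_error(dominance_proportions(empty), "no species")
})
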