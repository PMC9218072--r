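# Scalar-loop oracles and random-fixture builders. The oracles are written
# as plain element-by-element loops, deliberately independent of the
# package's vectorized implementations.

oracle_shannon <- function(p) {
  h <- 0
  for (i in seq_along(p)) h <- h - p[[i]] * log(p[[i]])
  h
}

oracle_simpson <- function(p) {
  s <- 0
  for (i in seq_along(p)) s <- s + p[[i]]^2
  1 - s
}

oracle_pielou <- function(h, n) if (n == 1) NA_real_ else h / log(n)

# presence-frequency proportions by explicit photo-by-photo counting
oracle_presence_props <- function(photos) {
  counts <- list()
  for (wp in unique(photos$waypoint)) {
    in_photo <- unique(photos$species[photos$waypoint == wp])
    for (sp in in_photo) counts[[sp]] <- (counts[[sp]] %||% 0) + 1
  }
  v <- unlist(counts)
  v / sum(v)
}

oracle_dominance_props <- function(photos) {
  w <- c(dominant = 3, subdominant = 2, present = 1)
  totals <- list()
  for (r in seq_len(nrow(photos))) {
    sp <- photos$species[r]
    totals[[sp]] <- (totals[[sp]] %||% 0) + w[[photos$dominance_class[r]]]
  }
  v <- unlist(totals)
  v / sum(v)
}

oracle_quadrat_props <- function(quadrats) {
  n_q <- length(unique(quadrats$quadrat_id))
  species <- unique(quadrats$species)
  mb <- md <- setNames(numeric(length(species)), species)
  for (r in seq_len(nrow(quadrats))) {
    sp <- quadrats$species[r]
    mb[sp] <- mb[sp] + quadrats$biomass_g[r] / n_q
    md[sp] <- md[sp] + quadrats$density_count[r] / n_q
  }
  p <- setNames(numeric(length(species)), species)
  for (sp in species) {
    p[sp] <- (mb[sp] / sum(mb) + md[sp] / sum(md)) / 2
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random one-site photo table: n_photos photos, species drawn from a small
# alphabet, dominance labels honoring the 0-2/0-2 bound
random_photo_table <- function(seed, site = "S1") {
  withr::with_seed(seed, {
    n_photos <- sample(2:16, 1)
    alphabet <- paste0("sp", 1:12)
    rows <- lapply(seq_len(n_photos), function(wp) {
      sp <- sample(alphabet, sample(1:8, 1))
      dom <- rep("present", length(sp))
      n_dom <- sample(0:min(2, length(sp)), 1)
      left <- length(sp) - n_dom
      n_sub <- if (left > 0) sample(0:min(2, left), 1) else 0
      if (n_dom > 0) dom[seq_len(n_dom)] <- "dominant"
      if (n_sub > 0) dom[n_dom + seq_len(n_sub)] <- "subdominant"
      tibble::tibble(site_id = site, waypoint = wp, species = sp,
                     dominance_class = dom)
    })
    suppressWarnings(photo_survey(dplyr::bind_rows(rows)))
  })
}

random_quadrat_table <- function(seed, site = "S1") {
  withr::with_seed(seed, {
    alphabet <- paste0("sp", 1:10)
    rows <- lapply(1:3, function(q) {
      sp <- sample(alphabet, sample(1:6, 1))
      tibble::tibble(site_id = site, quadrat_id = q, species = sp,
                     biomass_g = round(rlnorm(length(sp), 1, 1), 3),
                     density_count = rpois(length(sp), 8) + 1)
    })
    quadrat_survey(dplyr::bind_rows(rows))
  })
}

random_composition <- function(seed, pool = paste0("sp", 1:30)) {
  withr::with_seed(seed, sample(pool, sample(1:20, 1)))
}

expect_setequal_named <- function(got, want, tol = 1e-12) {
  expect_setequal(names(got), names(want))
  expect_equal(unclass(got)[names(want)], want, tolerance = tol,
               ignore_attr = TRUE)
}
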