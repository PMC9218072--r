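#' Per-site alpha diversity under three species-proportion definitions
#'
#' Richness N, Shannon H (nats), Simpson D and Pielou J are computed per site
#' from a species relative-dominance vector p. The three survey methods
#' differ only in how p is formed:
#'
#' * `TSM_Q` (ground quadrats): per species, biomass and density are averaged
#'   across the site's quadrats (absent = 0), and
#'   p_i = (biomass share + density share) / 2 over those means.
#' * `UAV_B` (photo presence): p_i proportional to the number of photographs
#'   in which species i occurs.
#' * `UAV_BD` (photo dominance): each occurrence is weighted 3 (dominant),
#'   2 (subdominant) or 1 (present) and p_i is the species' share of the
#'   total weight. With no dominance labels this collapses exactly to
#'   `UAV_B`.
#'
#' @name alpha-diversity
NULL

ALPHA_METHODS <- c("TSM_Q", "UAV_B", "UAV_BD")
DOMINANCE_WEIGHTS <- c(dominant = 3, subdominant = 2, present = 1)

#' Build a species-proportion vector
#'
#' @param x named non-negative numeric; zero entries are dropped.
#' @return named numeric summing to 1 (class `proportion_vector`).
#' @export
proportion_vector <- function(x) {
  if (is.null(names(x)) || any(names(x) == "")) {
    abort("proportions must be named by species")
  }
  x <- x[x > 0]
  if (length(x) == 0) {
    abort("undefined proportions: no species with positive weight")
  }
  if (anyDuplicated(names(x))) abort("duplicate species in proportion vector")
  p <- x / sum(x)
  structure(p, class = "proportion_vector")
}

check_proportions <- function(p) {
  if (abs(sum(p) - 1) > 1e-9 || any(p <= 0)) {
    abort("invalid proportion vector: entries must be positive and sum to 1")
  }
  invisible(p)
}

#' Species richness of one sampling unit
#'
#' The number of distinct species across a site's sampling unit (union over
#' its photographs, or over its quadrats).
#'
#' @param species character vector of species observations (repeats allowed).
#' @return integer count (0 for no observations).
#' @export
site_richness <- function(species) {
  length(unique(species[!is.na(species) & species != ""]))
}

#' Presence-frequency proportions from a site's photographs (UAV_B)
#'
#' p_i = (photos containing species i) / (sum over species of photos
#' containing that species), so the vector sums to 1.
#'
#' @param photos a [photo_survey] restricted to one site.
#' @return a [proportion_vector].
#' @export
presence_proportions <- function(photos) {
  if (nrow(photos) == 0) abort("undefined proportions: no species observed")
  counts <- table(photos$species)
  proportion_vector(setNames(as.numeric(counts), names(counts)))
}

#' Dominance-weighted proportions from a site's photographs (UAV_BD)
#'
#' Each per-photo occurrence contributes weight 3 (dominant), 2 (subdominant)
#' or 1 (present); p_i is species i's share of the summed weights.
#'
#' @inheritParams presence_proportions
#' @return a [proportion_vector].
#' @export
dominance_proportions <- function(photos) {
  if (nrow(photos) == 0) abort("undefined proportions: no species observed")
  bad <- setdiff(unique(photos$dominance_class), names(DOMINANCE_WEIGHTS))
  if (length(bad) > 0) {
    abort(sprintf("invalid dominance class: %s", paste(bad, collapse = ", ")))
  }
  w <- DOMINANCE_WEIGHTS[photos$dominance_class]
  totals <- tapply(w, photos$species, sum)
  proportion_vector(setNames(as.numeric(totals), names(totals)))
}

#' Biomass/density proportions from a site's quadrats (TSM_Q)
#'
#' Biomass and density are first averaged per species across the site's
#' quadrats (a species absent from a quadrat contributes zero), then
#' p_i = (mean-biomass share + mean-density share) / 2.
#'
#' @param quadrats a [quadrat_survey] restricted to one site.
#' @return a [proportion_vector].
#' @export
quadrat_proportions <- function(quadrats) {
  if (nrow(quadrats) == 0) abort("undefined proportions: no species observed")
  n_q <- length(unique(quadrats$quadrat_id))
  mean_b <- tapply(quadrats$biomass_g, quadrats$species, sum) / n_q
  mean_d <- tapply(quadrats$density_count, quadrats$species, sum) / n_q
  if (sum(mean_b) == 0 && sum(mean_d) == 0) {
    abort("undefined proportions: all biomass and density are zero")
  }
  share <- function(v) if (sum(v) > 0) v / sum(v) else v * 0
  p <- (share(mean_b) + share(mean_d)) / 2
  proportion_vector(setNames(as.numeric(p), names(p)))
}

#' Shannon diversity H = -sum p_i ln p_i (nats)
#'
#' @param p a [proportion_vector].
#' @return H in nats; 0 for a single species.
#' @export
shannon <- function(p) {
  check_proportions(p)
  -sum(p * log(p))
}

#' Simpson diversity D = 1 - sum p_i^2
#'
#' @param p a [proportion_vector].
#' @return D in [0, 1 - 1/N].
#' @export
simpson <- function(p) {
  check_proportions(p)
  1 - sum(p^2)
}

#' Pielou evenness J = H / ln N
#'
#' Undefined (NA) for a single species, since ln 1 = 0; such values are
#' excluded from downstream regressions.
#'
#' @param H Shannon diversity in nats.
#' @param N species richness (>= 1).
#' @return J in [0, 1], or `NA_real_` when N = 1.
#' @export
pielou <- function(H, N) {
  if (N < 1) abort("Pielou evenness needs at least one species")
  if (N == 1) return(NA_real_)
  H / log(N)
}

site_proportions <- function(photos = NULL, quadrats = NULL, method) {
  switch(method,
    UAV_B = presence_proportions(photos),
    UAV_BD = dominance_proportions(photos),
    TSM_Q = quadrat_proportions(quadrats),
    abort(sprintf("unknown method '%s' (expected %s)", method,
                  paste(ALPHA_METHODS, collapse = "/")))
  )
}

#' Alpha-diversity profile of every site under one method
#'
#' @param photo a [photo_survey] (required for `UAV_B` / `UAV_BD`).
#' @param quadrat a [quadrat_survey] (required for `TSM_Q`).
#' @param method one of `"TSM_Q"`, `"UAV_B"`, `"UAV_BD"`.
#' @return tibble with one row per site: `site_id`, `method`, `richness`,
#'   `shannon`, `simpson`, `pielou` (NA when undefined).
#' @export
alpha_profile <- function(photo = NULL, quadrat = NULL, method) {
  if (!method %in% ALPHA_METHODS) {
    abort(sprintf("unknown method '%s' (expected %s)", method,
                  paste(ALPHA_METHODS, collapse = "/")))
  }
  src <- if (method == "TSM_Q") quadrat else photo
  if (is.null(src)) {
    abort(sprintf("method %s needs a %s table", method,
                  if (method == "TSM_Q") "quadrat" else "photo"))
  }
  sites <- sort(unique(src$site_id))
  rows <- lapply(sites, function(s) {
    sub <- src[src$site_id == s, , drop = FALSE]
    p <- if (method == "TSM_Q") {
      site_proportions(quadrats = sub, method = method)
    } else {
      site_proportions(photos = sub, method = method)
    }
    N <- site_richness(sub$species)
    H <- shannon(p)
    tibble::tibble(site_id = s, method = method, richness = N, shannon = H,
                   simpson = simpson(p), pielou = pielou(H, N))
  })
  dplyr::bind_rows(rows)
}
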