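#' Beta diversity along a precipitation gradient, and gamma richness
#'
#' Between two composition lists with `a` and `b` species and `c` shared,
#' the Sorensen similarity is S = 2c / (a + b) and the Cody turnover is
#' C = (a + b - 2c) / 2, i.e. half the species gained plus lost along the
#' gradient. Sites are grouped into half-open precipitation bins
#' (50 mm by default) and beta indices are computed between adjacent bins,
#' either between the bins' pooled species lists (default) or as the mean
#' over all cross-bin site pairs.
#'
#' @name beta-gamma
NULL

#' Sorensen and Cody indices between two composition lists
#'
#' Direction: `gains` counts species of B absent from A and `losses` species
#' of A absent from B (along increasing gradient A to B); Cody turnover is
#' symmetric in the two.
#'
#' @param a_species,b_species character vectors (presence lists) of the two
#'   sampling units; both must be non-empty.
#' @param unit_a,unit_b optional unit labels carried into the result.
#' @return one-row tibble: `unit_a`, `unit_b`, `a`, `b`, `c`, `sorensen`,
#'   `cody`, `gains`, `losses`.
#' @export
beta_pair <- function(a_species, b_species, unit_a = "A", unit_b = "B") {
  A <- unique(a_species)
  B <- unique(b_species)
  if (length(A) == 0 || length(B) == 0) {
    abort("beta diversity is undefined for an empty composition list")
  }
  a <- length(A)
  b <- length(B)
  c_ <- length(intersect(A, B))
  tibble::tibble(
    unit_a = unit_a, unit_b = unit_b,
    a = a, b = b, c = c_,
    sorensen = 2 * c_ / (a + b),
    cody = (a + b - 2 * c_) / 2,
    gains = length(setdiff(B, A)),
    losses = length(setdiff(A, B))
  )
}

#' Group sites into fixed-width precipitation bins
#'
#' Bins are half-open intervals `[k*interval, (k+1)*interval)` anchored at
#' `origin` (so a site at exactly 450 mm falls in the upper bin); empty bins
#' are dropped and groups are returned in gradient order.
#'
#' @param covariates a [site_covariates] table.
#' @param interval_mm bin width in mm (default 50).
#' @param origin bin origin in mm (default 0).
#' @return tibble with one row per non-empty bin: `bin`, `lo_mm`, `hi_mm`,
#'   `sites` (list column), `n_sites`, `mean_precip_mm`.
#' @export
precipitation_bins <- function(covariates, interval_mm = 50, origin = 0) {
  if (interval_mm <= 0) abort("interval_mm must be positive")
  k <- floor((covariates$precip_mm - origin) / interval_mm)
  split_sites <- split(covariates$site_id, k)
  split_precip <- split(covariates$precip_mm, k)
  bins <- sort(as.numeric(names(split_sites)))
  tibble::tibble(
    bin = as.integer(bins),
    lo_mm = origin + bins * interval_mm,
    hi_mm = origin + (bins + 1) * interval_mm,
    sites = unname(split_sites[as.character(bins)]),
    n_sites = vapply(split_sites[as.character(bins)], length, integer(1),
                     USE.NAMES = FALSE),
    mean_precip_mm = vapply(split_precip[as.character(bins)], mean, numeric(1),
                            USE.NAMES = FALSE)
  )
}

#' Species lists per site from a survey table
#'
#' @param survey a [photo_survey] or [quadrat_survey].
#' @return named list mapping site_id to its character species set.
#' @export
species_sets <- function(survey) {
  lapply(split(survey$species, survey$site_id), unique)
}

#' Pooled composition of a site group
#'
#' @param site_ids character vector of member sites.
#' @param sets named list of per-site species sets (see [species_sets]).
#' @return character vector: the union of the members' species lists.
#' @export
group_composition <- function(site_ids, sets) {
  missing <- setdiff(site_ids, names(sets))
  if (length(missing) > 0) {
    abort(sprintf("no composition data for site%s %s",
                  if (length(missing) > 1) "s" else "",
                  paste(missing, collapse = ", ")))
  }
  unique(unlist(sets[site_ids], use.names = FALSE))
}

#' Beta diversity between adjacent precipitation bins
#'
#' For each consecutive pair of bins, computes Sorensen and Cody either
#' between the bins' pooled species lists (`mode = "pooled"`) or as the mean
#' over all cross-bin site pairs (`mode = "mean-pairwise"`). Each pair is
#' annotated with the midpoint of the two bins' mean precipitation, the
#' abscissa for gradient regression.
#'
#' @param bins output of [precipitation_bins].
#' @param sets named list of per-site species sets (see [species_sets]);
#'   bins are restricted to sites with composition data and dropped if none
#'   remain.
#' @param mode `"pooled"` or `"mean-pairwise"`.
#' @return tibble with one row per adjacent pair: `pair_index`,
#'   `group_lo_mm`, `group_hi_mm` (of the lower and upper bin), `midpoint_mm`,
#'   `a`, `b`, `c`, `sorensen`, `cody`, `mode`. Zero rows (with a warning)
#'   when fewer than two bins are available.
#' @export
adjacent_group_beta <- function(bins, sets, mode = c("pooled", "mean-pairwise")) {
  mode <- match.arg(mode)
  keep <- lapply(bins$sites, intersect, y = names(sets))
  has_data <- vapply(keep, length, integer(1)) > 0
  bins <- bins[has_data, , drop = FALSE]
  bins$sites <- keep[has_data]
  empty <- tibble::tibble(
    pair_index = integer(), group_lo_mm = numeric(), group_hi_mm = numeric(),
    midpoint_mm = numeric(), a = numeric(), b = numeric(), c = numeric(),
    sorensen = numeric(), cody = numeric(), mode = character())
  if (nrow(bins) < 2) {
    warn("fewer than 2 precipitation groups: no adjacent beta series")
    return(empty)
  }
  rows <- lapply(seq_len(nrow(bins) - 1), function(i) {
    lower <- bins[i, ]
    upper <- bins[i + 1, ]
    midpoint <- (lower$mean_precip_mm + upper$mean_precip_mm) / 2
    if (mode == "pooled") {
      bp <- beta_pair(group_composition(lower$sites[[1]], sets),
                      group_composition(upper$sites[[1]], sets))
      tibble::tibble(pair_index = i, group_lo_mm = lower$lo_mm,
                     group_hi_mm = upper$hi_mm, midpoint_mm = midpoint,
                     a = as.numeric(bp$a), b = as.numeric(bp$b),
                     c = as.numeric(bp$c), sorensen = bp$sorensen,
                     cody = bp$cody, mode = mode)
    } else {
      pairs <- expand.grid(x = lower$sites[[1]], y = upper$sites[[1]],
                           stringsAsFactors = FALSE)
      bp <- dplyr::bind_rows(Map(function(x, y) {
        beta_pair(sets[[x]], sets[[y]], x, y)
      }, pairs$x, pairs$y))
      tibble::tibble(pair_index = i, group_lo_mm = lower$lo_mm,
                     group_hi_mm = upper$hi_mm, midpoint_mm = midpoint,
                     a = mean(bp$a), b = mean(bp$b), c = mean(bp$c),
                     sorensen = mean(bp$sorensen), cody = mean(bp$cody),
                     mode = mode)
    }
  })
  dplyr::bind_rows(rows)
}

#' Gamma richness: total distinct species across composition lists
#'
#' @param sets list of character species vectors (any grouping level).
#' @return integer count; 0 for empty input.
#' @export
gamma_richness <- function(sets) {
  length(unique(unlist(sets, use.names = FALSE)))
}
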