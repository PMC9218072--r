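#' Survey tables: constructors, readers, writers and joint validation
#'
#' The pipeline starts from three delimited-text tables: a photo survey
#' (one row per site x waypoint-photo x species, with an optional dominance
#' class), a quadrat survey (one row per site x quadrat x species with dry
#' biomass and shoot density), and site covariates (mean annual
#' precipitation). Files are comma-separated UTF-8 with a header row.
#'
#' @name survey-io
NULL

DOMINANCE_LEVELS <- c("dominant", "subdominant", "present")

#' Construct and validate a photo survey table
#'
#' A photo survey records which species were identified in each of up to 16
#' waypoint photographs per site, optionally with a visual dominance class.
#' Per photograph at most two species may be labelled `dominant` and at most
#' two `subdominant`; all other recorded species are `present`.
#'
#' @param df data frame with columns `site_id`, `waypoint`, `species`,
#'   `dominance_class` (the last may be missing or blank, meaning `present`).
#' @param source label used in error messages (defaults to "photo survey").
#' @return a tibble of class `photo_survey` with normalized columns.
#' @export
photo_survey <- function(df, source = "photo survey") {
  check_columns(df, c("site_id", "waypoint", "species"), source)
  if (!"dominance_class" %in% names(df)) df$dominance_class <- "present"
  out <- tibble::tibble(
    site_id = trim_ws(as.character(df$site_id)),
    waypoint = as.integer(df$waypoint),
    species = trim_ws(as.character(df$species)),
    dominance_class = trim_ws(tolower(as.character(df$dominance_class)))
  )
  out$dominance_class[is.na(out$dominance_class) | out$dominance_class == ""] <-
    "present"

  if (nrow(out) == 0) {
    warn(sprintf("%s: no observations", source))
  } else {
    bad_dom <- which(!out$dominance_class %in% DOMINANCE_LEVELS)
    if (length(bad_dom) > 0) {
      row_error(source, head(bad_dom, 5),
                sprintf("dominance_class must be one of %s",
                        paste(DOMINANCE_LEVELS, collapse = "/")))
    }
    bad_wp <- which(is.na(out$waypoint) | out$waypoint < 1L | out$waypoint > 16L)
    if (length(bad_wp) > 0) {
      row_error(source, head(bad_wp, 5), "waypoint must be an integer in 1-16")
    }
    bad_sp <- which(out$species == "" | is.na(out$species))
    if (length(bad_sp) > 0) {
      row_error(source, head(bad_sp, 5), "species name is empty")
    }
    dup <- duplicated(out[c("site_id", "waypoint", "species")])
    if (any(dup)) {
      row_error(source, head(which(dup), 5),
                "duplicate (site, waypoint, species) observation")
    }
    # the visual-dominance protocol allows 0-2 dominant and 0-2 subdominant
    # species per photograph
    per_photo <- dplyr::count(
      dplyr::filter(out, .data$dominance_class != "present"),
      .data$site_id, .data$waypoint, .data$dominance_class
    )
    over <- dplyr::filter(per_photo, .data$n > 2L)
    if (nrow(over) > 0) {
      abort(sprintf(
        "%s: more than 2 %s species in photo %s/waypoint %d (found %d)",
        source, over$dominance_class[1], over$site_id[1], over$waypoint[1],
        over$n[1]))
    }
    n_photos <- dplyr::summarise(
      dplyr::group_by(out, .data$site_id),
      n = dplyr::n_distinct(.data$waypoint), .groups = "drop")
    short <- dplyr::filter(n_photos, .data$n < 16L)
    if (nrow(short) > 0) {
      warn(sprintf(
        "%s: site%s with fewer than 16 photos: %s (frequencies use the observed photo count)",
        source, if (nrow(short) > 1) "s" else "",
        paste(short$site_id, collapse = ", ")))
    }
  }
  class(out) <- c("photo_survey", class(tibble::tibble()))
  out
}

#' Construct and validate a quadrat survey table
#'
#' Ground quadrats (0.5 m x 0.5 m, up to three per site) record each species'
#' oven-dry biomass (g) and shoot/individual count. Both measures must be
#' non-negative and a recorded species may not have both equal to zero.
#'
#' @param df data frame with columns `site_id`, `quadrat_id`, `species`,
#'   `biomass_g`, `density_count`.
#' @param source label used in error messages.
#' @return a tibble of class `quadrat_survey`.
#' @export
quadrat_survey <- function(df, source = "quadrat survey") {
  check_columns(df, c("site_id", "quadrat_id", "species", "biomass_g",
                      "density_count"), source)
  out <- tibble::tibble(
    site_id = trim_ws(as.character(df$site_id)),
    quadrat_id = as.integer(df$quadrat_id),
    species = trim_ws(as.character(df$species)),
    biomass_g = as.numeric(df$biomass_g),
    density_count = as.numeric(df$density_count)
  )
  if (nrow(out) == 0) {
    warn(sprintf("%s: no observations", source))
  } else {
    bad_num <- which(is.na(out$biomass_g) | is.na(out$density_count))
    if (length(bad_num) > 0) {
      row_error(source, head(bad_num, 5), "non-numeric biomass or density")
    }
    neg <- which(out$biomass_g < 0 | out$density_count < 0)
    if (length(neg) > 0) {
      row_error(source, head(neg, 5), "negative biomass or density")
    }
    zz <- which(out$biomass_g == 0 & out$density_count == 0)
    if (length(zz) > 0) {
      row_error(source, head(zz, 5),
                "recorded species has both biomass and density zero")
    }
    bad_q <- which(is.na(out$quadrat_id) | out$quadrat_id < 1L)
    if (length(bad_q) > 0) {
      row_error(source, head(bad_q, 5), "quadrat_id must be a positive integer")
    }
    bad_sp <- which(out$species == "" | is.na(out$species))
    if (length(bad_sp) > 0) {
      row_error(source, head(bad_sp, 5), "species name is empty")
    }
    dup <- duplicated(out[c("site_id", "quadrat_id", "species")])
    if (any(dup)) {
      row_error(source, head(which(dup), 5),
                "duplicate (site, quadrat, species) observation")
    }
  }
  class(out) <- c("quadrat_survey", class(tibble::tibble()))
  out
}

#' Construct and validate a site covariate table
#'
#' @param df data frame with columns `site_id` and `precip_mm` (mean annual
#'   precipitation, mm).
#' @return a tibble of class `site_covariates`, one row per site.
#' @export
site_covariates <- function(df, source = "site covariates") {
  check_columns(df, c("site_id", "precip_mm"), source)
  out <- tibble::tibble(
    site_id = trim_ws(as.character(df$site_id)),
    precip_mm = as.numeric(df$precip_mm)
  )
  bad <- which(is.na(out$precip_mm) | out$precip_mm <= 0)
  if (length(bad) > 0) {
    row_error(source, head(bad, 5), "precipitation must be a positive number")
  }
  if (anyDuplicated(out$site_id)) {
    row_error(source, head(which(duplicated(out$site_id)), 5),
              "duplicate site_id")
  }
  class(out) <- c("site_covariates", class(tibble::tibble()))
  out
}

read_survey_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Read a photo survey from a CSV file
#'
#' Expects columns `site_id,waypoint,species,dominance_class`; blank or
#' absent dominance means `present`.
#'
#' @param path path to a comma-separated UTF-8 file with a header row.
#' @return a validated [photo_survey] tibble.
#' @export
read_photo_survey <- function(path) {
  photo_survey(read_survey_csv(path), source = path)
}

#' Read a quadrat survey from a CSV file
#'
#' Expects columns `site_id,quadrat_id,species,biomass_g,density_count`.
#'
#' @inheritParams read_photo_survey
#' @return a validated [quadrat_survey] tibble.
#' @export
read_quadrat_survey <- function(path) {
  df <- read_survey_csv(path)
  check_columns(df, c("biomass_g", "density_count"), path)
  for (col in c("biomass_g", "density_count")) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(parsed))
    if (length(bad) > 0) {
      # +1 for the header line so the message points at the file line
      row_error(path, head(bad + 1L, 5),
                sprintf("cannot parse %s as a number ('%s')", col,
                        df[[col]][bad[1]]))
    }
    df[[col]] <- parsed
  }
  quadrat_survey(df, source = path)
}

#' Read site covariates from a CSV file
#'
#' Expects columns `site_id,precip_mm`.
#'
#' @inheritParams read_photo_survey
#' @return a validated [site_covariates] tibble.
#' @export
read_site_covariates <- function(path) {
  site_covariates(read_survey_csv(path), source = path)
}

#' Write survey tables back to the CSV dialects they are read from
#'
#' Round-trips exactly: writing then reading a valid table reproduces it
#' field for field.
#'
#' @param x a survey table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_photo_survey <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname write_photo_survey
#' @export
write_quadrat_survey <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname write_photo_survey
#' @export
write_site_covariates <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Cross-check the photo survey, quadrat survey and covariates
#'
#' Produces a report (never an error) listing sites present in only one of
#' the two survey protocols, sites lacking a precipitation covariate, and
#' species names that collide after case-folding (possible spelling
#' near-misses; names are matched case-sensitively everywhere else).
#'
#' @param photo a [photo_survey] (or `NULL`).
#' @param quadrat a [quadrat_survey] (or `NULL`).
#' @param covariates a [site_covariates] (or `NULL`).
#' @return a `validation_report`: a tibble of issues with columns `issue`,
#'   `detail`; zero rows means no problems found.
#' @export
validate_joint <- function(photo = NULL, quadrat = NULL, covariates = NULL) {
  issues <- list()
  add <- function(issue, detail) {
    issues[[length(issues) + 1]] <<- tibble::tibble(issue = issue, detail = detail)
  }
  photo_sites <- if (!is.null(photo)) unique(photo$site_id) else character()
  quad_sites <- if (!is.null(quadrat)) unique(quadrat$site_id) else character()
  cov_sites <- if (!is.null(covariates)) unique(covariates$site_id) else character()

  if (!is.null(photo) && !is.null(quadrat)) {
    for (s in setdiff(photo_sites, quad_sites)) {
      add("photo_only_site", s)
    }
    for (s in setdiff(quad_sites, photo_sites)) {
      add("quadrat_only_site", s)
    }
  }
  if (!is.null(covariates)) {
    for (s in setdiff(union(photo_sites, quad_sites), cov_sites)) {
      add("missing_covariate", s)
    }
  }
  all_species <- unique(c(
    if (!is.null(photo)) photo$species else character(),
    if (!is.null(quadrat)) quadrat$species else character()
  ))
  folded <- tolower(all_species)
  for (f in unique(folded[duplicated(folded)])) {
    add("species_case_near_miss",
        paste(sort(all_species[folded == f]), collapse = " ~ "))
  }
  out <- if (length(issues) > 0) {
    dplyr::bind_rows(issues)
  } else {
    tibble::tibble(issue = character(), detail = character())
  }
  class(out) <- c("validation_report", class(tibble::tibble()))
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("validation report: no issues\n")
  } else {
    cat(sprintf("validation report: %d issue%s\n", nrow(x),
                if (nrow(x) > 1) "s" else ""))
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  - [%s] %s\n", x$issue[i], x$detail[i]))
    }
  }
  invisible(x)
}

#' Serialize a validation report as JSON
#'
#' @param x a `validation_report`.
#' @return a JSON string (array of issue objects).
#' @export
report_json <- function(x) {
  jsonlite::toJSON(tibble::as_tibble(x), dataframe = "rows", pretty = TRUE)
}
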