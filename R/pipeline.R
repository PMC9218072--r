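#' Run the full multiscale diversity pipeline
#'
#' Stages: joint validation -> per-site alpha diversity under every
#' applicable method -> precipitation binning, adjacent-bin beta series and
#' gamma richness -> method-agreement regression on sites sampled by both
#' protocols -> linear-vs-quadratic precipitation-response selection for
#' every index. Each stage writes its CSV into `out_dir`, and a JSON summary
#' joins the headline quantities; every number in the summary is a copy of a
#' stage-output cell.
#'
#' @param photo a [photo_survey], or `NULL` for a quadrat-only run.
#' @param quadrat a [quadrat_survey], or `NULL` for a photo-only run.
#' @param covariates a [site_covariates] table (required).
#' @param out_dir output directory (created if absent); `NULL` to skip
#'   writing files.
#' @param interval_mm precipitation bin width (default 50).
#' @param group_mode `"pooled"` or `"mean-pairwise"` adjacent-bin beta.
#' @param alpha_level selection level of the likelihood-ratio test.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list: `validation`, `alpha`, `beta`, `gamma`,
#'   `agreement`, `gradient_alpha`, `gradient_beta`, `normality`, `summary`.
#' @export
run_pipeline <- function(photo = NULL, quadrat = NULL, covariates,
                         out_dir = NULL, interval_mm = 50,
                         group_mode = c("pooled", "mean-pairwise"),
                         alpha_level = 0.05, quiet = FALSE) {
  group_mode <- match.arg(group_mode)
  if (is.null(photo) && is.null(quadrat)) {
    abort("at least one survey table is required")
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  written <- character()
  emit <- function(obj, name, writer = readr::write_csv) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      path <- file.path(out_dir, name)
      writer(obj, path)
      written <<- c(written, path)
    }
  }
  on_error_cleanup <- function(e) {
    unlink(written)
    abort(sprintf("pipeline aborted: %s", conditionMessage(e)))
  }

  tryCatch({
    say("validate: cross-checking surveys and covariates")
    validation <- validate_joint(photo, quadrat, covariates)
    if (!quiet && nrow(validation) > 0) print(validation)
    emit(validation, "validation.json",
         function(x, p) writeLines(report_json(x), p))

    methods <- c(if (!is.null(quadrat)) "TSM_Q",
                 if (!is.null(photo)) c("UAV_B", "UAV_BD"))
    if (is.null(quadrat)) say("alpha: no quadrat table, TSM_Q skipped")
    if (is.null(photo)) say("alpha: no photo table, UAV methods skipped")
    say("alpha: computing per-site indices (%s)",
        paste(methods, collapse = ", "))
    alpha <- dplyr::bind_rows(lapply(methods, function(m) {
      alpha_profile(photo = photo, quadrat = quadrat, method = m)
    }))
    emit(alpha, "alpha.csv")

    normality <- dplyr::bind_rows(lapply(methods, function(m) {
      sub <- alpha[alpha$method == m, ]
      dplyr::bind_rows(lapply(c("richness", "shannon", "simpson", "pielou"),
        function(idx) {
          v <- sub[[idx]][!is.na(sub[[idx]])]
          if (length(v) < 3 || length(unique(v)) < 2) return(NULL)
          s <- shapiro_normality(v)
          tibble::tibble(method = m, index = idx, shapiro_w = s$statistic,
                         shapiro_p = s$p_value)
        }))
    }))
    if (nrow(normality) > 0) {
      for (i in seq_len(nrow(normality))) {
        say("normality: %s %s W = %.3f, p = %.3g", normality$method[i],
            normality$index[i], normality$shapiro_w[i], normality$shapiro_p[i])
      }
      emit(normality, "normality.csv")
    }

    say("beta/gamma: %g-mm bins, %s adjacent-group mode", interval_mm,
        group_mode)
    comp_sources <- list()
    if (!is.null(photo)) comp_sources$UAV_B <- species_sets(photo)
    if (!is.null(quadrat)) comp_sources$TSM_Q <- species_sets(quadrat)
    bins <- precipitation_bins(covariates, interval_mm = interval_mm)
    beta <- dplyr::bind_rows(lapply(names(comp_sources), function(m) {
      series <- withCallingHandlers(
        adjacent_group_beta(bins, comp_sources[[m]], mode = group_mode),
        warning = function(w) {
          say("beta (%s): %s", m, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      if (nrow(series) > 0) series$method <- m
      series
    }))
    emit(beta, "beta.csv")
    gamma <- tibble::tibble(
      method = names(comp_sources),
      n_species = vapply(comp_sources, gamma_richness, integer(1),
                         USE.NAMES = FALSE))
    if (length(comp_sources) > 1) {
      gamma <- dplyr::bind_rows(gamma, tibble::tibble(
        method = "all",
        n_species = gamma_richness(unlist(comp_sources, recursive = FALSE))))
    }
    emit(gamma, "gamma.json",
         function(x, p) jsonlite::write_json(x, p, dataframe = "rows",
                                             pretty = TRUE))

    agreement <- NULL
    if (!is.null(photo) && !is.null(quadrat)) {
      say("agreement: TSM_Q vs UAV methods on jointly sampled sites")
      agreement <- method_agreement_table(alpha, beta)
      emit(agreement, "agreement.csv")
    } else {
      say("agreement: skipped (needs both protocols)")
    }

    say("gradient: linear-vs-quadratic selection at alpha = %g", alpha_level)
    alpha_cov <- dplyr::inner_join(alpha, tibble::as_tibble(covariates),
                                   by = "site_id")
    gradient_alpha <- dplyr::bind_rows(lapply(methods, function(m) {
      sub <- alpha_cov[alpha_cov$method == m, ]
      idx <- c("richness", "shannon", "simpson", "pielou")
      defined <- idx[vapply(idx, function(i) any(!is.na(sub[[i]])), logical(1))]
      for (i in setdiff(idx, defined)) {
        say("gradient (%s): index %s has no defined values; skipped", m, i)
      }
      g <- gradient_response(sub, x = "precip_mm", indices = defined,
                             alpha = alpha_level)
      g$method <- m
      g
    }))
    gradient_beta <- dplyr::bind_rows(lapply(unique(beta$method), function(m) {
      sub <- beta[beta$method == m, ]
      if (nrow(sub) < 5) {
        say("gradient (beta, %s): only %d adjacent pairs, need 5; skipped",
            m, nrow(sub))
        return(NULL)
      }
      g <- gradient_response(sub, x = "midpoint_mm",
                             indices = c("sorensen", "cody"),
                             alpha = alpha_level)
      g$method <- m
      g
    }))
    gradient <- dplyr::bind_rows(gradient_alpha, gradient_beta)
    emit(gradient, "gradient.csv")

    summary <- list(
      n_sites = length(unique(covariates$site_id)),
      methods = methods,
      gamma = setNames(as.list(gamma$n_species), gamma$method),
      chosen_degree = if (nrow(gradient) > 0) {
        setNames(as.list(gradient$chosen_degree),
                 paste(gradient$method, gradient$index, sep = "."))
      } else NULL,
      agreement_r2 = if (!is.null(agreement) && nrow(agreement) > 0) {
        setNames(as.list(agreement$r2),
                 paste(agreement$method_y, agreement$index, sep = "."))
      } else NULL,
      settings = list(interval_mm = interval_mm, group_mode = group_mode,
                      alpha_level = alpha_level,
                      bin_convention = "half-open [lo, lo+interval)")
    )
    emit(summary, "summary.json",
         function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                             pretty = TRUE, digits = NA))
    say("done%s", if (is.null(out_dir)) "" else paste0(": outputs in ", out_dir))
    invisible(list(validation = validation, alpha = alpha, beta = beta,
                   gamma = gamma, agreement = agreement,
                   gradient_alpha = gradient_alpha,
                   gradient_beta = gradient_beta,
                   normality = normality, summary = summary))
  }, error = on_error_cleanup)
}

# Pairwise agreement of every index between TSM_Q (x) and each UAV method
# (y), alpha indices paired by site and beta indices by adjacent-bin pair.
method_agreement_table <- function(alpha, beta) {
  rows <- list()
  add_row <- function(index, mx, my, xv, yv) {
    ok <- !is.na(xv) & !is.na(yv)
    if (sum(ok) < 3) return()
    ag <- method_agreement(xv[ok], yv[ok])
    rows[[length(rows) + 1]] <<- tibble::tibble(
      index = index, method_x = mx, method_y = my, n = ag$fit$n,
      slope = ag$fit$coefficients[2], intercept = ag$fit$coefficients[1],
      r2 = ag$fit$r_squared, p_value = ag$fit$p_value,
      mean_1to1_deviation = ag$mean_deviation)
  }
  wide <- tidyr::pivot_wider(alpha, id_cols = "site_id",
                             names_from = "method",
                             values_from = c("richness", "shannon", "simpson",
                                             "pielou"))
  for (m in intersect(c("UAV_B", "UAV_BD"), unique(alpha$method))) {
    for (idx in c("richness", "shannon", "simpson", "pielou")) {
      xcol <- paste(idx, "TSM_Q", sep = "_")
      ycol <- paste(idx, m, sep = "_")
      if (all(c(xcol, ycol) %in% names(wide))) {
        add_row(idx, "TSM_Q", m, wide[[xcol]], wide[[ycol]])
      }
    }
  }
  if (!is.null(beta) && nrow(beta) > 0 &&
      all(c("TSM_Q", "UAV_B") %in% unique(beta$method))) {
    bw <- tidyr::pivot_wider(beta, id_cols = "pair_index",
                             names_from = "method",
                             values_from = c("sorensen", "cody"))
    for (idx in c("sorensen", "cody")) {
      xcol <- paste(idx, "TSM_Q", sep = "_")
      ycol <- paste(idx, "UAV_B", sep = "_")
      if (all(c(xcol, ycol) %in% names(bw))) {
        add_row(idx, "TSM_Q", "UAV_B", bw[[xcol]], bw[[ycol]])
      }
    }
  }
  if (length(rows) == 0) {
    tibble::tibble(index = character(), method_x = character(),
                   method_y = character(), n = integer(), slope = numeric(),
                   intercept = numeric(), r2 = numeric(), p_value = numeric(),
                   mean_1to1_deviation = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
}
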