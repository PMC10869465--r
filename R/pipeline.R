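#' Run a configured phenotyping analysis end to end
#'
#' Drives the full analysis from a single YAML configuration: load (or
#' simulate) a cultivar panel, reduce the raw traces to traits, scan trait
#' against reflectance (correlation spectrum) and against every NDI
#' wavelength pair (correlation heatmap), extract significant regions, and
#' run the cultivar comparison statistics. All result tables are written as
#' CSV under the configured output directory, plus heatmap/spectrum figures
#' when `figures: true`.
#'
#' The config file has two top-level sections:
#' \preformatted{
#' input:
#'   simulate: true        # or spectra/induction/heat/drought CSV paths
#'   seed: 1
#' analysis:
#'   traits: [dw, dti, t_dec]   # which target traits to correlate
#'   alpha: 0.05
#'   min_run: 2
#'   min_area: 4
#'   steady_window: 120
#'   baseline_window: 120
#'   out_dir: results
#'   figures: false
#' }
#'
#' @param config_path Path to the YAML configuration.
#' @return Invisibly, a list with the computed objects (`traits`,
#'   `spectrum_scans`, `heatmap_scans`, `group_stats`) and the output
#'   directory.
#' @export
run_pipeline <- function(config_path) {
  if (!file.exists(config_path)) {
    abort(sprintf("Config file not found: '%s'.", config_path))
  }
  cfg <- yaml::read_yaml(config_path)
  input <- cfg$input %||% list()
  an <- cfg$analysis %||% list()
  alpha <- an$alpha %||% 0.05
  min_run <- an$min_run %||% 2L
  min_area <- an$min_area %||% 4L
  steady_window <- an$steady_window %||% 120
  baseline_window <- an$baseline_window %||% 120
  traits_wanted <- an$traits %||% c("dw", "dti", "t_dec")
  out_dir <- an$out_dir %||% "results"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (isTRUE(input$simulate)) {
    panel <- generate_panel(panel_config(), seed = input$seed %||% 1L)
    spectra <- panel$spectra
    induction <- panel$induction
    heat <- panel$heat
    drought <- panel$drought
  } else {
    spectra <- if (!is.null(input$spectra)) {
      df <- read_spectra(input$spectra)
      if (!"cultivar" %in% names(df)) df$cultivar <- df$sample_id
      df
    }
    induction <- if (!is.null(input$induction)) {
      df <- read_induction(input$induction)
      if (!"cultivar" %in% names(df)) df$cultivar <- sub("_.*$", "", df$sample_id)
      df
    }
    heat <- if (!is.null(input$heat)) {
      df <- read_heat_ramp(input$heat)
      if (!"cultivar" %in% names(df)) df$cultivar <- sub("_.*$", "", df$sample_id)
      df
    }
    drought <- if (!is.null(input$drought)) {
      read_checked(input$drought, c("cultivar", "dw_control", "dw_drought"))
    }
    if (is.null(spectra)) abort("Config provides neither `simulate: true` nor a spectra table.")
  }

  # --- traits per cultivar ---------------------------------------------
  traits <- tibble(cultivar = unique(spectra$cultivar))
  if (!is.null(induction)) {
    feats <- chlf_features(induction, steady_window = steady_window) %>%
      left_join(dplyr::distinct(induction, .data$sample_id, .data$cultivar),
                by = "sample_id") %>%
      group_by(.data$cultivar) %>%
      summarise(across(c("fv_fm", "phi_psii_ef", "t_half_phi",
                         "npq_max", "t_npq_max", "npq_s"), mean),
                .groups = "drop")
    traits <- left_join(traits, feats, by = "cultivar")
  }
  if (!is.null(heat)) {
    ht <- heat_tolerance(heat, baseline_window = baseline_window) %>%
      left_join(dplyr::distinct(heat, .data$sample_id, .data$cultivar),
                by = "sample_id") %>%
      group_by(.data$cultivar) %>%
      summarise(t_dec = mean(.data$t_dec),
                phi_psii_resid = mean(.data$phi_psii_resid),
                .groups = "drop")
    traits <- left_join(traits, ht, by = "cultivar")
  }
  if (!is.null(drought)) {
    dr <- drought %>%
      mutate(dti = dti(.data$dw_drought, .data$dw_control)) %>%
      group_by(.data$cultivar) %>%
      summarise(dw = mean(.data$dw_control), dti = mean(.data$dti),
                .groups = "drop")
    traits <- left_join(traits, dr, by = "cultivar")
  }
  write_panel_csv(traits, file.path(out_dir, "traits.csv"))

  # --- correlation scans -----------------------------------------------
  cult_spec <- mean_spectra(spectra, by = "cultivar")
  ndis <- lapply(split(spectra, spectra$cultivar), function(df) {
    mean_ndi_matrix(ndi_matrices(df))
  })

  spectrum_scans <- list()
  heatmap_scans <- list()
  for (tr in intersect(traits_wanted, names(traits))) {
    y <- setNames(traits[[tr]], traits$cultivar)
    y <- y[!is.na(y)]
    if (length(y) < 3L || sd(y) == 0) next
    cs <- correlation_spectrum(cult_spec[cult_spec$sample_id %in% names(y), ],
                               y, alpha = alpha, min_run = min_run)
    hm <- ndi_correlation_heatmap(ndis[names(y)], y, alpha = alpha,
                                  min_area = min_area)
    spectrum_scans[[tr]] <- cs
    heatmap_scans[[tr]] <- hm
    write_panel_csv(as_tibble(cs),
                    file.path(out_dir, sprintf("corr_spectrum_%s.csv", tr)))
    write_panel_csv(attr(cs, "runs"),
                    file.path(out_dir, sprintf("corr_spectrum_runs_%s.csv", tr)))
    write_panel_csv(tidy(hm),
                    file.path(out_dir, sprintf("corr_heatmap_%s.csv", tr)))
    write_panel_csv(hm$regions,
                    file.path(out_dir, sprintf("corr_regions_%s.csv", tr)))
    if (isTRUE(an$figures)) {
      ggplot2::ggsave(file.path(out_dir, sprintf("corr_spectrum_%s.png", tr)),
                      ggplot2::autoplot(cs), width = 7, height = 4, dpi = 150)
      ggplot2::ggsave(file.path(out_dir, sprintf("corr_heatmap_%s.png", tr)),
                      ggplot2::autoplot(hm), width = 6.5, height = 5.5, dpi = 150)
    }
  }

  # --- cultivar comparison statistics ----------------------------------
  group_stats <- NULL
  if (!is.null(drought)) {
    dd <- drought %>% mutate(dti = dti(.data$dw_drought, .data$dw_control))
    group_stats <- anova_tukey_cld(dd, "cultivar", "dti", alpha = alpha)
    write_panel_csv(group_stats$letters,
                    file.path(out_dir, "groupstats_dti.csv"))
  }

  summary_path <- file.path(out_dir, "summary.txt")
  lines_out <- c(
    sprintf("specphen pipeline: %d cultivars", nrow(traits)),
    purrr::imap_chr(heatmap_scans, function(hm, tr) {
      sprintf("trait %s: %d significant region(s)%s", tr, nrow(hm$regions),
              if (nrow(hm$regions) > 0L) {
                sprintf(", peak |r| = %.2f", max(abs(hm$regions$peak_r)))
              } else "")
    })
  )
  writeLines(lines_out, summary_path)

  invisible(list(
    traits = traits, spectrum_scans = spectrum_scans,
    heatmap_scans = heatmap_scans, group_stats = group_stats,
    out_dir = out_dir
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
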