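## Orchestration: image pipeline (register -> fit -> VOI metrics) producing a
## cohort table, and the cohort-level statistical analysis producing a
## structured study report (group summaries, paired and unpaired tests, ROC
## analyses of dADC / dVOL / FLDA, DeLong comparisons, per-group Pearson
## correlation).

#' Run the image pipeline over a cohort of studies
#'
#' Each animal entry names a baseline and a follow-up session; a session is
#' either on-disk data (`image` + `bvalues` + `mask` NIfTI/sidecar paths,
#' optionally a separate `t2_mask` for volumetry) or a simulated phantom
#' (`phantom = ` a [phantom_config()]). Per session the series is registered
#' along the b-value dimension, the ADC map is fitted inside the mask, and
#' the median tumor ADC and mask volume are extracted. Failures are
#' collected per animal in a manifest and do not abort the remaining
#' animals.
#'
#' @param config List with `animals` (list of `list(id, group, baseline,
#'   followup)`) and optional `register` (default `TRUE`) and `adc_max`.
#' @return A list with `cohort` (a [cohort_table()] of the successfully
#'   processed animals) and `failures` (data frame `animal_id`, `session`,
#'   `message`).
#' @export
run_image_pipeline <- function(config) {
  register <- !isFALSE(config$register)
  adc_max <- if (is.null(config$adc_max)) 10 else config$adc_max
  rows <- list(); fails <- list()
  for (an in config$animals) {
    res <- list()
    ok <- TRUE
    for (ses in c("baseline", "followup")) {
      out <- tryCatch(process_session(an[[ses]], register, adc_max),
                      error = function(e) e)
      if (inherits(out, "error")) {
        fails[[length(fails) + 1L]] <-
          data.frame(animal_id = an$id, session = ses,
                     message = conditionMessage(out))
        ok <- FALSE
        break
      }
      res[[ses]] <- out
    }
    if (!ok) next
    rows[[length(rows) + 1L]] <-
      data.frame(animal_id = an$id, group = an$group,
                 adc_b = res$baseline$median_adc,
                 adc_f = res$followup$median_adc,
                 vol_b = res$baseline$volume,
                 vol_f = res$followup$volume)
  }
  if (!length(rows))
    stop_validation("no animal processed successfully")
  df <- do.call(rbind, rows)
  list(cohort = build_records(df$animal_id, df$group, df$adc_b, df$adc_f,
                              df$vol_b, df$vol_f,
                              provenance = "image_pipeline"),
       failures = if (length(fails)) do.call(rbind, fails)
                  else data.frame(animal_id = character(),
                                  session = character(),
                                  message = character()))
}

process_session <- function(ses, register, adc_max) {
  if (!is.null(ses$phantom)) {
    ph <- generate_phantom(ses$phantom)
    study <- ph$study; mask <- ph$mask; vol_mask <- ph$mask
  } else {
    if (is.null(ses$image) || !file.exists(ses$image))
      stop_format("missing image file: %s",
                  if (is.null(ses$image)) "<unset>" else ses$image)
    study <- read_dwi_study(ses$image, ses$bvalues)
    mask <- read_voi_mask(ses$mask)
    vol_mask <- if (!is.null(ses$t2_mask)) read_voi_mask(ses$t2_mask) else mask
  }
  if (register)
    study <- register_series(study)$study
  map <- compute_adc_map(study, mask = mask, adc_max = adc_max)
  list(median_adc = median_adc(map, mask), volume = mask_volume(vol_mask))
}

group_summaries <- function(cohort) {
  metrics <- c("adc_b", "adc_f", "d_adc", "vol_b", "vol_f", "d_vol_pct")
  out <- list()
  for (g in c("therapy", "control")) {
    sub <- cohort[cohort$group == g, ]
    out[[g]] <- lapply(stats::setNames(metrics, metrics), function(m)
      list(median = stats::median(sub[[m]]), sd = stats::sd(sub[[m]]),
           n = nrow(sub)))
  }
  out
}

#' Full statistical analysis of a two-group cohort
#'
#' Computes the complete response-analysis report from a per-animal cohort
#' table: per-group median +/- SD summaries; paired Wilcoxon tests of
#' baseline vs follow-up (ADC and volume, within each group); Mann-Whitney
#' intergroup comparisons of dADC, dVOL and the follow-up values; ROC curves
#' with Youden-optimal operating points for dADC (higher change indicates
#' therapy), dVOL (lower growth indicates therapy) and the fitted FLDA score
#' (therapy below threshold); pairwise DeLong AUC comparisons; and per-group
#' Pearson correlation between dADC and dVOL. Degenerate statistics are
#' reported as flagged condition messages rather than silently omitted.
#'
#' @param cohort A [cohort_table()] with >= 2 animals per group.
#' @return A list of class `study_report`.
#' @export
run_cohort_analysis <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  for (g in c("therapy", "control"))
    if (sum(cohort$group == g) < 2)
      stop_validation("group '%s' needs at least 2 animals", g)
  th <- cohort[cohort$group == "therapy", ]
  co <- cohort[cohort$group == "control", ]
  guarded <- function(expr) tryCatch(expr, dwi_degenerate_error = function(e)
    list(statistic = NA_real_, p_value = NA_real_, degenerate = TRUE,
         message = conditionMessage(e)))

  paired <- list(
    therapy_adc = guarded(wilcoxon_signed_rank(th$adc_f, th$adc_b)),
    control_adc = guarded(wilcoxon_signed_rank(co$adc_f, co$adc_b)),
    therapy_vol = guarded(wilcoxon_signed_rank(th$vol_f, th$vol_b)),
    control_vol = guarded(wilcoxon_signed_rank(co$vol_f, co$vol_b)))
  intergroup <- list(
    d_adc = guarded(mann_whitney_u(th$d_adc, co$d_adc)),
    d_vol_pct = guarded(mann_whitney_u(th$d_vol_pct, co$d_vol_pct)),
    adc_f = guarded(mann_whitney_u(th$adc_f, co$adc_f)),
    vol_f = guarded(mann_whitney_u(th$vol_f, co$vol_f)))

  flda <- fit_flda(cbind(cohort$d_vol_pct, cohort$d_adc), cohort$group)
  flda_scores <- project_flda(flda, cbind(cohort$d_vol_pct, cohort$d_adc))
  rocs <- list(
    d_adc = roc_curve(cohort$d_adc, cohort$group, "greater_is_positive"),
    d_vol_pct = roc_curve(cohort$d_vol_pct, cohort$group,
                          "less_is_positive"),
    flda = flda$roc)
  optimal <- lapply(rocs, optimal_threshold)

  delong <- list(
    flda_vs_d_adc = guarded(delong_test(
      flda_scores, cohort$d_adc, cohort$group,
      directions = c("less_is_positive", "greater_is_positive"))),
    flda_vs_d_vol = guarded(delong_test(
      flda_scores, cohort$d_vol_pct, cohort$group,
      directions = c("less_is_positive", "less_is_positive"))),
    d_adc_vs_d_vol = guarded(delong_test(
      cohort$d_adc, cohort$d_vol_pct, cohort$group,
      directions = c("greater_is_positive", "less_is_positive"))))

  pearson <- list(
    therapy = guarded(pearson_correlation(th$d_adc, th$d_vol_pct)),
    control = guarded(pearson_correlation(co$d_adc, co$d_vol_pct)))

  structure(list(summaries = group_summaries(cohort), paired = paired,
                 intergroup = intergroup, rocs = rocs, optimal = optimal,
                 flda = flda, flda_scores = flda_scores, delong = delong,
                 pearson = pearson, cohort = cohort),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  fmt_ms <- function(s, d = 2)
    sprintf("%.*f+/-%.*f", d, s$median, d, s$sd)
  cat("Two-group DWI therapy-response report\n")
  cat(sprintf("  therapy n = %d, control n = %d\n",
              x$summaries$therapy$adc_b$n, x$summaries$control$adc_b$n))
  cat("  Tumor ADC (1e-3 mm^2/s), median +/- SD:\n")
  for (g in c("therapy", "control"))
    cat(sprintf("    %-7s ADC_B %s  ADC_F %s  dADC %s\n", g,
                fmt_ms(x$summaries[[g]]$adc_b),
                fmt_ms(x$summaries[[g]]$adc_f),
                fmt_ms(x$summaries[[g]]$d_adc)))
  cat("  Tumor volume (mm^3), median +/- SD:\n")
  for (g in c("therapy", "control"))
    cat(sprintf("    %-7s VOL_B %s  VOL_F %s  dVOL%% %s\n", g,
                fmt_ms(x$summaries[[g]]$vol_b, 1),
                fmt_ms(x$summaries[[g]]$vol_f, 1),
                fmt_ms(x$summaries[[g]]$d_vol_pct, 1)))
  cat(sprintf("  Intergroup dADC p = %.4g, dVOL p = %.4g\n",
              x$intergroup$d_adc$p_value, x$intergroup$d_vol_pct$p_value))
  cat("  ROC:\n")
  for (nm in names(x$rocs))
    cat(sprintf("    %-9s AUC %.3f  thr %.4g  sens %.1f%%  spec %.1f%%  acc %.1f%%\n",
                nm, x$rocs[[nm]]$auc, x$optimal[[nm]]$threshold,
                100 * x$optimal[[nm]]$sens, 100 * x$optimal[[nm]]$spec,
                100 * x$optimal[[nm]]$accuracy))
  cat(sprintf("  DeLong FLDA vs dADC p = %.4g, FLDA vs dVOL p = %.4g, dADC vs dVOL p = %.4g\n",
              x$delong$flda_vs_d_adc$p_value, x$delong$flda_vs_d_vol$p_value,
              x$delong$d_adc_vs_d_vol$p_value))
  cat(sprintf("  Pearson r(dADC, dVOL): therapy %.2f (p = %.3g), control %.2f (p = %.3g)\n",
              x$pearson$therapy$statistic, x$pearson$therapy$p_value,
              x$pearson$control$statistic, x$pearson$control$p_value))
  invisible(x)
}

#' Serialize a study report
#'
#' `report_to_json()` writes the full-precision machine-readable report;
#' `report_to_markdown()` renders the human-readable tables (display
#' rounding only).
#'
#' @param report A `study_report`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
report_to_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "roc_result"))
      return(list(auc = x$auc, direction = x$direction,
                  thresholds = x$thresholds, sens = x$sens, spec = x$spec))
    if (inherits(x, "flda_model"))
      return(list(w_dvol = x$w_dvol, w_dadc = x$w_dadc, scaling = x$scaling,
                  threshold = x$threshold, orientation = x$orientation))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  out <- strip(report[c("summaries", "paired", "intergroup", "rocs",
                        "optimal", "flda", "delong", "pearson")])
  out$cohort <- as.data.frame(report$cohort)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_to_markdown <- function(report, path) {
  s <- report$summaries
  ln <- c("# DWI therapy-response report", "",
          sprintf("Cohort: %d therapy, %d control animals.",
                  s$therapy$adc_b$n, s$control$adc_b$n), "",
          "## Tumor ADC (median +/- SD, 1e-3 mm^2/s)", "",
          "| Group | ADC_B | ADC_F | dADC |",
          "|---|---|---|---|")
  for (g in c("therapy", "control"))
    ln <- c(ln, sprintf("| %s | %.2f+/-%.2f | %.2f+/-%.2f | %+.2f+/-%.2f |",
                        g, s[[g]]$adc_b$median, s[[g]]$adc_b$sd,
                        s[[g]]$adc_f$median, s[[g]]$adc_f$sd,
                        s[[g]]$d_adc$median, s[[g]]$d_adc$sd))
  ln <- c(ln, "", "## Tumor volume (median +/- SD, mm^3; dVOL in %)", "",
          "| Group | VOL_B | VOL_F | dVOL |",
          "|---|---|---|---|")
  for (g in c("therapy", "control"))
    ln <- c(ln, sprintf("| %s | %.1f+/-%.1f | %.1f+/-%.1f | %.2f+/-%.2f |",
                        g, s[[g]]$vol_b$median, s[[g]]$vol_b$sd,
                        s[[g]]$vol_f$median, s[[g]]$vol_f$sd,
                        s[[g]]$d_vol_pct$median, s[[g]]$d_vol_pct$sd))
  ln <- c(ln, "", "## ROC analyses", "",
          "| Classifier | AUC | Threshold | Sensitivity | Specificity | Accuracy |",
          "|---|---|---|---|---|---|")
  for (nm in names(report$rocs))
    ln <- c(ln, sprintf("| %s | %.3f | %.4g | %.1f%% | %.1f%% | %.1f%% |",
                        nm, report$rocs[[nm]]$auc,
                        report$optimal[[nm]]$threshold,
                        100 * report$optimal[[nm]]$sens,
                        100 * report$optimal[[nm]]$spec,
                        100 * report$optimal[[nm]]$accuracy))
  ln <- c(ln, "",
          sprintf("FLDA score = %.4f x dVOL[%%] %+.4f x dADC[1e-3 mm^2/s] (%s).",
                  report$flda$w_dvol, report$flda$w_dadc,
                  report$flda$scaling),
          "",
          sprintf("DeLong: FLDA vs dADC p = %.3g; FLDA vs dVOL p = %.3g; dADC vs dVOL p = %.3g.",
                  report$delong$flda_vs_d_adc$p_value,
                  report$delong$flda_vs_d_vol$p_value,
                  report$delong$d_adc_vs_d_vol$p_value))
  writeLines(ln, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return The configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}
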