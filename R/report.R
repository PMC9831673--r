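# Validation report container, rendering, broom-style tidiers and plots.

#' Assemble a validation report
#'
#' Bundles the analytical-validation results and enforces the ordering
#' invariant `lob <= lod <= loq` (checked for the cutoffs that were
#' established).
#'
#' @param lob One-row tibble from [estimate_lob()], or a bare percent.
#' @param lod One-row tibble from [establish_lod()] (optional).
#' @param loq One-row tibble from [determine_loq()] (optional).
#' @param performance Tibble from [performance()] (optional).
#' @param level_stats Stacked [level_stats()] rows (optional).
#' @param detection Tibble from [detection_rate()] (optional).
#' @param meta Named list of provenance (seed, config hash, ...).
#' @return A `duplexlb_report` object.
#' @export
validation_report <- function(lob, lod = NULL, loq = NULL, performance = NULL,
                              level_stats = NULL, detection = NULL,
                              meta = list()) {
  if (is.numeric(lob)) lob <- tibble(lob = lob, raw_estimate = lob,
                                     method = "assay_default", n_positions = NA_integer_)
  lob_v <- lob$lob[1]
  lod_v <- if (!is.null(lod) && isTRUE(lod$established[1])) lod$lod[1] else NA_real_
  loq_v <- if (!is.null(loq) && isTRUE(loq$established[1])) loq$loq[1] else NA_real_
  if (!is.na(lod_v) && lob_v > lod_v) abort("invariant violated: LOB must not exceed LOD")
  if (!is.na(lod_v) && !is.na(loq_v) && lod_v > loq_v) {
    abort("invariant violated: LOD must not exceed LOQ")
  }
  structure(
    list(lob = lob, lod = lod, loq = loq, performance = performance,
         level_stats = level_stats, detection = detection, meta = meta),
    class = "duplexlb_report"
  )
}

#' @noRd
fmt_pct <- function(x) ifelse(is.na(x), "n/a", sprintf("%.1f", x))

#' Render a validation report as JSON and text
#'
#' Field order is deterministic; percentages are reported at one decimal
#' and counts verbatim, so a fixed-seed rerun renders byte-identically.
#'
#' @param report A [validation_report()].
#' @param json_path,text_path Optional output paths.
#' @return (Invisibly) a list with `data` (the report as plain lists),
#'   `json` (the JSON string) and `text` (the text lines).
#' @export
render_report <- function(report, json_path = NULL, text_path = NULL) {
  stopifnot(inherits(report, "duplexlb_report"))
  r1 <- function(x) if (is.null(x) || all(is.na(x))) NULL else round(x, 1)
  lod <- report$lod; loq <- report$loq
  data <- list(
    tool = list(name = "duplexlb", version = duplexlb_version()),
    meta = report$meta,
    lob = list(
      vaf_pct = report$lob$lob[1],
      method = report$lob$method[1],
      n_positions = report$lob$n_positions[1]
    ),
    lod = if (is.null(lod)) NULL else list(
      vaf_pct = lod$lod[1],
      achieved_confidence_pct = r1(lod$achieved_confidence[1]),
      detected = lod$detected[1], total = lod$total[1],
      established = lod$established[1]
    ),
    loq = if (is.null(loq)) NULL else list(
      vaf_pct = loq$loq[1], established = loq$established[1]
    ),
    performance = if (is.null(report$performance)) NULL else
      purrr::pmap(report$performance, function(region_set, class, tp, fn, fp,
                                               sensitivity, ppv, ...) {
        list(region_set = region_set, class = class, tp = tp, fn = fn, fp = fp,
             sensitivity_pct = sensitivity, ppv_pct = ppv)
      }),
    detection_rates = if (is.null(report$detection)) NULL else
      purrr::pmap(report$detection, function(class, level, detected, total, rate, ...) {
        list(class = class, level_pct = level, detected = detected,
             total = total, rate_pct = rate)
      }),
    level_stats = if (is.null(report$level_stats)) NULL else
      purrr::pmap(report$level_stats, function(nominal_vaf, n_variants,
                                               mean_relative_bias, trueness,
                                               pooled_sd, cv, repeatability,
                                               total_error, ...) {
        list(nominal_vaf_pct = nominal_vaf, n_variants = n_variants,
             trueness_pct = round(trueness, 1),
             repeatability_pct = round(repeatability, 1),
             total_error_pct = round(total_error, 1))
      })
  )
  data <- data[!vapply(data, is.null, logical(1))]
  json <- jsonlite::toJSON(data, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")

  text <- c(
    sprintf("duplexlb validation report (v%s)", duplexlb_version()),
    sprintf("LOB: %s%% VAF (%s, %s positions)", format(report$lob$lob[1]),
            report$lob$method[1],
            ifelse(is.na(report$lob$n_positions[1]), "n/a", report$lob$n_positions[1])),
    if (!is.null(lod)) sprintf(
      "LOD: %s%% VAF at %s%% confidence (%d/%d)",
      ifelse(lod$established[1], format(lod$lod[1]), "not established"),
      fmt_pct(lod$achieved_confidence[1]), lod$detected[1], lod$total[1]
    ) else "LOD: n/a",
    if (!is.null(loq)) sprintf(
      "LOQ: %s%% VAF",
      ifelse(loq$established[1], format(loq$loq[1]), "not established")
    ) else "LOQ: n/a",
    if (!is.null(report$performance)) c(
      "Sensitivity / PPV:",
      sprintf("  %-11s %-6s TP=%-4d FN=%-3d FP=%-3d sens=%s%% ppv=%s%%",
              report$performance$region_set, report$performance$class,
              report$performance$tp, report$performance$fn, report$performance$fp,
              fmt_pct(report$performance$sensitivity), fmt_pct(report$performance$ppv))
    ) else NULL,
    if (!is.null(report$detection)) c(
      "Detection rates:",
      sprintf("  %-6s %5s%%: %d/%d (%s%%)",
              report$detection$class, format(report$detection$level, trim = TRUE),
              report$detection$detected, report$detection$total,
              ifelse(is.na(report$detection$rate), "n/a", report$detection$rate))
    ) else NULL,
    if (!is.null(report$level_stats)) c(
      "Quantification:",
      sprintf("  %5s%%: trueness %s%%, repeatability %s%%, total error %s%%",
              format(report$level_stats$nominal_vaf, trim = TRUE),
              fmt_pct(report$level_stats$trueness),
              fmt_pct(report$level_stats$repeatability),
              fmt_pct(report$level_stats$total_error))
    ) else NULL
  )
  if (!is.null(json_path)) readr::write_lines(json, json_path)
  if (!is.null(text_path)) readr::write_lines(text, text_path)
  invisible(list(data = data, json = as.character(json), text = text))
}

#' @export
print.duplexlb_report <- function(x, ...) {
  cat(render_report(x)$text, sep = "\n")
  invisible(x)
}

#' Tidy a validation report into a long metric table
#'
#' @param x A `duplexlb_report`.
#' @param ... Unused.
#' @return Tibble `metric`, `group`, `value`.
#' @export
tidy.duplexlb_report <- function(x, ...) {
  rows <- list(tibble(metric = "lob_vaf_pct", group = NA_character_, value = x$lob$lob[1]))
  if (!is.null(x$lod)) {
    rows <- c(rows, list(tibble(
      metric = c("lod_vaf_pct", "lod_confidence_pct"), group = NA_character_,
      value = c(x$lod$lod[1], x$lod$achieved_confidence[1])
    )))
  }
  if (!is.null(x$loq)) {
    rows <- c(rows, list(tibble(metric = "loq_vaf_pct", group = NA_character_,
                                value = x$loq$loq[1])))
  }
  if (!is.null(x$performance)) {
    p <- x$performance
    rows <- c(rows, list(
      tibble(metric = "sensitivity_pct", group = paste(p$region_set, p$class),
             value = p$sensitivity),
      tibble(metric = "ppv_pct", group = paste(p$region_set, p$class), value = p$ppv)
    ))
  }
  if (!is.null(x$detection)) {
    d <- x$detection
    rows <- c(rows, list(tibble(
      metric = "detection_rate_pct",
      group = sprintf("%s %s%%", d$class, format(d$level, trim = TRUE)),
      value = as.numeric(d$rate)
    )))
  }
  if (!is.null(x$level_stats)) {
    s <- x$level_stats
    grp <- sprintf("%s%%", format(s$nominal_vaf, trim = TRUE))
    rows <- c(rows, list(
      tibble(metric = "trueness_pct", group = grp, value = s$trueness),
      tibble(metric = "repeatability_pct", group = grp, value = s$repeatability),
      tibble(metric = "total_error_pct", group = grp, value = s$total_error)
    ))
  }
  bind_rows(rows)
}

#' One-row summary of a validation report
#'
#' @inheritParams tidy.duplexlb_report
#' @return One-row tibble with the three cutoffs and their status.
#' @export
glance.duplexlb_report <- function(x, ...) {
  tibble(
    lob_vaf_pct = x$lob$lob[1],
    lod_vaf_pct = if (!is.null(x$lod)) x$lod$lod[1] else NA_real_,
    lod_established = if (!is.null(x$lod)) x$lod$established[1] else NA,
    loq_vaf_pct = if (!is.null(x$loq)) x$loq$loq[1] else NA_real_,
    loq_established = if (!is.null(x$loq)) x$loq$established[1] else NA,
    n_level_stats = if (!is.null(x$level_stats)) nrow(x$level_stats) else 0L
  )
}

#' Plot detection rates by class and level
#'
#' @param detection Tibble from [detection_rate()].
#' @return A ggplot.
#' @export
plot_detection_rates <- function(detection) {
  ggplot2::ggplot(detection, ggplot2::aes(
    x = factor(.data$level), y = .data$rate_raw, fill = .data$class
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 90, linetype = "dashed") +
    ggplot2::labs(x = "nominal VAF (%)", y = "detection rate (%)", fill = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot measured versus nominal VAF across the validation series
#'
#' @param measured Tibble with `level` (nominal percent) and `vaf`
#'   (measured percent), e.g. the `measured` element of
#'   [run_validation_pipeline()].
#' @return A ggplot.
#' @export
plot_vaf_recovery <- function(measured) {
  ggplot2::ggplot(measured, ggplot2::aes(
    x = .data$level, y = .data$vaf, colour = .data$class
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_jitter(width = 0.02, height = 0, alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "nominal VAF (%)", y = "measured VAF (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_detection_rates
#' @param object A `duplexlb_report`.
#' @param ... Unused.
#' @export
autoplot.duplexlb_report <- function(object, ...) {
  if (is.null(object$detection)) abort("report carries no detection-rate table")
  plot_detection_rates(object$detection)
}
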