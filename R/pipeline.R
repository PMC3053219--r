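#' Configuration for the end-to-end reporting pipeline
#'
#' @param input path to an ODM XML document or a records CSV (alternative
#'   to `simulate`).
#' @param simulate optional [cohort_spec()]: generate the input cohort
#'   instead of reading one.
#' @param mapping_file optional JSON/YAML status-mapping file overriding
#'   the document's code lists.
#' @param origin `"therapy"` or `"diagnosis"` time origin.
#' @param endpoints non-empty subset of `c("os", "efs")`.
#' @param group_col optional record column used for grouped analysis and
#'   the log-rank test (e.g. `"department"`, `"study"`, `"group"`).
#' @param conf_level confidence level in (0, 1).
#' @param risk_times times (years) for the numbers-at-risk table; defaults
#'   to an even grid over the observed range.
#' @param study_end optional study end date enabling person-time
#'   completeness.
#' @param out_dir output directory (created if needed).
#' @param seed optional integer seed (used when `simulate` is given).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            mapping_file = NULL,
                            origin = c("therapy", "diagnosis"),
                            endpoints = c("os", "efs"), group_col = NULL,
                            conf_level = 0.95, risk_times = NULL,
                            study_end = NULL, out_dir = ".", seed = NULL) {
  origin <- match.arg(origin)
  endpoints <- unique(as.character(endpoints))
  if (length(endpoints) == 0L || !all(endpoints %in% c("os", "efs")))
    stop("endpoints must be a non-empty subset of {os, efs}; got: ",
         paste(endpoints, collapse = ", "), call. = FALSE)
  if (!(conf_level > 0 && conf_level < 1))
    stop("conf_level must be in (0, 1)", call. = FALSE)
  if (is.null(input) && is.null(simulate))
    stop("either input or simulate must be given", call. = FALSE)
  structure(list(input = input, simulate = simulate,
                 mapping_file = mapping_file, origin = origin,
                 endpoints = endpoints, group_col = group_col,
                 conf_level = conf_level, risk_times = risk_times,
                 study_end = study_end, out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

log_stage <- function(stage, ...) message("[", stage, "] ", ...)

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full follow-up reporting pipeline
#'
#' simulate/parse -> harmonize -> analyze -> quality -> report. Produces
#' in `out_dir`: the analysis records (`records.csv`), a curve table per
#' endpoint (`km_<endpoint>.csv`), the completeness table
#' (`completeness.csv`), a PDF report (`report.pdf`) with one
#' Kaplan-Meier panel per endpoint (confidence band and numbers at risk;
#' grouped with the log-rank p-value when a group column is configured)
#' plus a data-quality page, and a machine-readable run summary
#' (`summary.json`). Stage-tagged progress goes to `stderr`; excluded
#' patients are counted in the summary, never dropped silently.
#'
#' @param config a [pipeline_config()].
#' @return the run summary, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  run_summary <- list(stages = list())

  records <- NULL
  doc <- with_stage("parse", {
    if (!is.null(config$simulate)) {
      spec <- config$simulate
      if (!is.null(config$seed)) spec$seed <- as.integer(config$seed)
      log_stage("parse", "simulating cohort of ", spec$n_patients,
                " patients (seed ", spec$seed, ")")
      simulate_cohort(spec)
    } else if (grepl("\\.csv$", config$input)) {
      log_stage("parse", "reading records CSV ", config$input)
      records <- read_records_csv(config$input)
      NULL
    } else {
      log_stage("parse", "parsing ODM document ", config$input)
      parse_odm(config$input)
    }
  })
  mapping <- if (!is.null(config$mapping_file))
    with_stage("parse", read_mapping(config$mapping_file))
  else if (!is.null(doc)) doc$mapping else default_status_mappings()

  current <- NULL
  if (!is.null(doc)) {
    harmonized <- with_stage("harmonize", {
      dd <- deduplicate_forms(doc)
      rec <- build_records(doc, mapping, origin = config$origin)
      list(dd = dd, rec = rec)
    })
    current <- harmonized$dd$current
    records <- harmonized$rec
    excluded <- attr(records, "excluded")
    run_summary$stages$parsed_forms <- nrow(doc$forms)
    run_summary$stages$patients <- nrow(current)
    run_summary$stages$analyzed <- nrow(records)
    run_summary$stages$excluded <- nrow(excluded)
    run_summary$exclusions <- as.list(table(excluded$reason))
    log_stage("harmonize", nrow(doc$forms), " forms -> ", nrow(current),
              " patients; ", nrow(records), " analyzable, ",
              nrow(excluded), " excluded")
  } else {
    run_summary$stages$patients <- run_summary$stages$analyzed <- nrow(records)
    run_summary$stages$excluded <- 0L
  }
  if (!is.null(config$group_col)) {
    if (!config$group_col %in% names(records))
      stop("[harmonize] unknown group column '", config$group_col, "'",
           call. = FALSE)
    records$group <- records[[config$group_col]]
  }
  export_csv(records, out("records.csv"))

  fits <- list(); tests <- list()
  for (ep in config$endpoints) {
    res <- with_stage("analyze", {
      fit <- km_fit(records, endpoint = ep, conf_level = config$conf_level)
      km_table(fit, out(paste0("km_", ep, ".csv")))
      med <- median_survival(fit)
      log_stage("analyze", toupper(ep), ": n = ", fit$n, ", events = ",
                sum(fit$n_event), ", median = ",
                if (is.na(med)) "not reached" else format(med, digits = 4))
      lr <- NULL
      if (!is.null(config$group_col) &&
          length(unique(stats::na.omit(records$group))) >= 2L) {
        lr <- logrank_test(records, group_col = "group", endpoint = ep)
        log_stage("analyze", toupper(ep), ": log-rank p = ",
                  format.pval(lr$p_value, digits = 3))
      }
      list(fit = fit, lr = lr, median = med)
    })
    fits[[ep]] <- res$fit
    tests[[ep]] <- res$lr
    run_summary[[ep]] <- list(
      n = res$fit$n, events = sum(res$fit$n_event),
      median_years = if (is.na(res$median)) "not reached" else res$median)
    if (!is.null(res$lr)) run_summary[[ep]]$logrank_p <- res$lr$p_value
  }

  quality <- with_stage("quality", {
    q <- if (!is.null(current))
      quality_report(current,
                     records = if (!is.null(config$study_end)) records,
                     study_end = config$study_end,
                     path = out("completeness.csv"))
    else list(items = NULL)
    q
  })
  if (!is.null(quality$items)) {
    tot <- quality$items[quality$items$stratum == "total" &
                           quality$items$item == "all_three", ]
    run_summary$completeness_all_three_pct <- tot$percentage
    log_stage("quality", "all-three item completeness: ",
              tot$percentage, "%")
  }
  if (!is.null(quality$clark_c)) run_summary$clark_c_pct <- quality$clark_c

  with_stage("report", {
    grDevices::pdf(out("report.pdf"), width = 8, height = 6, onefile = TRUE)
    tryCatch({
    for (ep in config$endpoints) {
      fit <- fits[[ep]]
      if (!is.null(config$group_col) && !is.null(tests[[ep]])) {
        grp_fits <- lapply(split(records, records$group), km_fit,
                           endpoint = ep, conf_level = config$conf_level)
        render_km_plot(grp_fits, risk_times = config$risk_times,
                       main = paste("Kaplan-Meier:", toupper(ep)),
                       p_value = tests[[ep]]$p_value)
      } else {
        render_km_plot(fit, risk_times = config$risk_times,
                       main = paste("Kaplan-Meier:", toupper(ep)))
      }
    }
    if (!is.null(quality$items)) quality_page(quality)
    }, finally = grDevices::dev.off())
    log_stage("report", "report written to ", out("report.pdf"))
  })

  jsonlite::write_json(run_summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(run_summary)
}

# step-function coordinates of a KM curve, starting at (0, 1)
km_steps <- function(t, s) {
  list(x = c(0, rep(t, each = 2)),
       y = c(1, 1, rep(s, each = 2))[seq_len(2 * length(t) + 1)])
}

fill_forward <- function(x, first = 1) {
  for (i in seq_along(x))
    x[i] <- if (is.na(x[i])) (if (i == 1) first else x[i - 1]) else x[i]
  x
}

#' Draw a Kaplan-Meier plot with confidence band and numbers at risk
#'
#' Step-function survival curves with a shaded pointwise confidence band
#' (single curve) or one line per group, and a numbers-at-risk table
#' aligned beneath the time axis. Structural content only — appearance is
#' base-graphics default.
#'
#' @param fits a `km_fit` or a named list of them (one per group).
#' @param risk_times times at which numbers at risk are tabulated;
#'   `NULL` for an even grid over the observed range.
#' @param main plot title.
#' @param p_value optional log-rank p-value annotated on the plot.
#' @param xlab,ylab axis labels.
#' @param cols line colours, recycled over groups.
#' @return invisibly, the matrix of risk counts (groups x times).
#' @export
render_km_plot <- function(fits, risk_times = NULL, main = "",
                           p_value = NULL, xlab = "Years",
                           ylab = "Survival probability",
                           cols = c("#00468B", "#ED0000", "#42B540",
                                    "#0099B4", "#925E9F")) {
  if (inherits(fits, "km_fit")) fits <- list(all = fits)
  if (!length(fits)) stop("at least one curve is required", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, TRUE, "km_fit")))
  tmax <- max(c(0, unlist(lapply(fits, `[[`, "times"))))
  if (is.null(risk_times))
    risk_times <- pretty(c(0, tmax), n = 6)
  risk_times <- risk_times[risk_times >= 0]
  cols <- rep_len(cols, length(fits))

  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  graphics::layout(matrix(1:2), heights = c(4, 1 + 0.35 * length(fits)))
  graphics::par(mar = c(2.5, 4, 3, 1))
  graphics::plot(NULL, xlim = range(c(0, tmax, risk_times)), ylim = c(0, 1),
                 xlab = "", ylab = ylab, main = main)
  for (k in seq_along(fits)) {
    fit <- fits[[k]]
    st <- km_steps(fit$times, fit$survival)
    if (length(fits) == 1L) {
      lo <- km_steps(fit$times, fill_forward(fit$ci_low))
      hi <- km_steps(fit$times, fill_forward(fit$ci_high))
      graphics::polygon(c(lo$x, rev(hi$x)), c(lo$y, rev(hi$y)),
                        col = grDevices::adjustcolor(cols[k], 0.2),
                        border = NA)
    }
    graphics::lines(st$x, st$y, col = cols[k], lwd = 2)
    cens <- fit$times[fit$n_censor > 0]
    if (length(cens))
      graphics::points(cens, survival_at(fit, cens)$survival,
                       pch = 3, cex = 0.6, col = cols[k])
  }
  if (length(fits) > 1L)
    graphics::legend("bottomleft", legend = names(fits), col = cols,
                     lwd = 2, bty = "n")
  if (!is.null(p_value))
    graphics::mtext(paste0("log-rank p = ", format.pval(p_value, digits = 3)),
                    side = 3, line = -1.5, adj = 0.98, cex = 0.9)

  counts <- matrix(unlist(lapply(fits, numbers_at_risk, at_times = risk_times)),
                   nrow = length(fits), byrow = TRUE,
                   dimnames = list(names(fits), NULL))
  graphics::par(mar = c(2.5, 4, 0.5, 1))
  graphics::plot(NULL, xlim = range(c(0, tmax, risk_times)),
                 ylim = c(0, length(fits) + 1), axes = FALSE,
                 xlab = xlab, ylab = "")
  graphics::mtext("Numbers at risk", side = 2, las = 1, line = 3, cex = 0.7,
                  at = length(fits) + 0.8)
  for (k in seq_along(fits)) {
    y <- length(fits) - k + 0.5
    graphics::text(risk_times, y, counts[k, ], cex = 0.8, col = cols[k])
    if (length(fits) > 1L)
      graphics::mtext(names(fits)[k], side = 2, las = 1, line = 3,
                      at = y, cex = 0.7, col = cols[k])
  }
  graphics::axis(1, at = risk_times)
  invisible(counts)
}

# textual data-quality page of the PDF report
quality_page <- function(quality) {
  graphics::par(mar = c(1, 1, 3, 1))
  graphics::plot.new()
  graphics::title("Data quality: completeness of survival items")
  items <- as.data.frame(quality$items)
  lines <- c(sprintf("%-14s %6s %-18s %9s %10s", "stratum", "cases", "item",
                     "available", "percent"),
             sprintf("%-14s %6d %-18s %9d %9.1f%%",
                     items$stratum, items$cases, items$item,
                     items$available, items$percentage))
  if (!is.null(quality$form))
    lines <- c(lines, "", sprintf(
      "form completeness: %d of %d eligible patients (%.1f%%)",
      quality$form$with_form, quality$form$eligible,
      quality$form$percentage))
  if (!is.null(quality$clark_c))
    lines <- c(lines, sprintf(
      "person-time follow-up completeness C: %.1f%%", quality$clark_c))
  graphics::text(0, seq(0.95, by = -0.045, length.out = length(lines)),
                 lines, adj = 0, family = "mono", cex = 0.75)
}
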