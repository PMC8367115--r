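# One-command orchestration of the desk-scale study: generate the synthetic
# dataset, segment every image, measure colour differences against the
# reference condition, train and evaluate the surrogate classifier, run the
# repeated-measures statistics, and bundle everything into a report object.

#' Experiment configuration
#'
#' @param seed master seed; every random draw in the experiment flows from
#'   it.
#' @param n_per_cell images per (pill, condition) cell (default 2).
#' @param canvas canvas side in pixels (default 96).
#' @param render a [render_params()] list.
#' @param roi a [roi_params()] list.
#' @param k top-k cutoffs to evaluate (default `c(1, 5)`).
#' @param white reference white for the Lab conversion (`"anchored"` or
#'   `"d65"`).
#' @param out_dir output directory; `NULL` uses a session temporary
#'   directory.
#' @return A named list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1, n_per_cell = 2, canvas = 96,
                              render = render_params(), roi = roi_params(),
                              k = c(1, 5), white = "anchored",
                              out_dir = NULL) {
  if (n_per_cell < 1) {
    pc_stop("pillchroma_config_error", "n_per_cell must be >= 1")
  }
  if (canvas < 64) {
    pc_stop("pillchroma_config_error", "canvas must be at least 64 pixels")
  }
  structure(list(seed = seed, n_per_cell = n_per_cell, canvas = canvas,
                 render = render, roi = roi, k = k, white = white,
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' Recognised keys mirror the arguments of [experiment_config()]; `render`
#' and `roi` may be nested maps of [render_params()] / [roi_params()]
#' arguments.
#'
#' @param path path to a YAML file.
#' @return An `experiment_config` list.
#' @export
load_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("render", "roi"))]
  if (!is.null(y$render)) args$render <- do.call(render_params, y$render)
  if (!is.null(y$roi)) args$roi <- do.call(roi_params, y$roi)
  do.call(experiment_config, args)
}

#' Run the full imaging-condition experiment
#'
#' Executes the pipeline generate -> segment -> colour-difference ->
#' classify -> analyse at the configured scale: renders the 19-pill catalog
#' under the reference condition and the 12 real-world conditions, extracts
#' every ROI (when both segmentation strategies fail the ground-truth mask
#' is substituted and flagged `"oracle"` in the segmentation log, keeping the
#' repeated-measures crossing complete), measures per-pill Delta E against
#' the reference, trains the surrogate classifier on reference images only,
#' evaluates top-k accuracy per condition, and runs the three-way and
#' EV-stratified repeated-measures ANOVAs plus the accuracy-vs-Delta E
#' association.  All tables are also written as CSV/JSON under the output
#' directory together with a provenance record.
#'
#' @param config an [experiment_config()].
#' @return An object of class `pill_experiment`: `condition_table`
#'   (condition, top1, top5, mean/sd Delta E), `delta_e` (per pill and
#'   condition), `anova`, `strata`, `association`, `segmentation_log`,
#'   `config`, `dir`.
#' @export
run_pill_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  out_dir <- config$out_dir %||% file.path(tempdir(), sprintf("pillchroma_%d", config$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  catalog <- pill_catalog(seed = config$seed)
  ds <- generate_pill_dataset(
    file.path(out_dir, "dataset"), catalog = catalog,
    conditions = all_conditions(), n_per_cell = config$n_per_cell,
    seed = config$seed, canvas = config$canvas, params = config$render
  )
  manifest <- ds$manifest
  truth <- ds$truth

  n <- nrow(manifest)
  feats <- matrix(NA_real_, n, 8)
  lab_cols <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("L", "a", "b")))
  stage <- character(n)
  fallback <- logical(n)
  for (i in seq_len(n)) {
    img <- read_pill_image(file.path(ds$dir, manifest$path[i]))
    res <- tryCatch(extract_roi(img, config$roi), error = identity)
    if (inherits(res, "error")) {
      # keep the factorial design complete: fall back to the ground-truth
      # mask, flagged as an oracle substitution in the log
      tm <- read_pill_mask(file.path(ds$dir, truth$mask_path[i]))
      crop <- mask_and_crop(img, tm, config$roi$pad)
      res <- list(roi = crop$roi, mask = tm, roi_mask = crop$roi_mask,
                  bbox = crop$bbox, fallback = TRUE, stage = "oracle")
    }
    stage[i] <- res$stage
    fallback[i] <- res$fallback
    fv <- featurize_roi(res$roi, res$roi_mask, white = config$white)
    feats[i, ] <- fv
    if (i == 1L) colnames(feats) <- names(fv)
    lab_cols[i, ] <- rgb_to_lab(roi_mean_color(res$roi, res$roi_mask),
                                white = config$white)
  }
  seg_log <- data.frame(manifest, stage = stage, fallback = fallback,
                        stringsAsFactors = FALSE)

  meas <- data.frame(label = manifest$label, condition = manifest$condition,
                     lab_cols, stringsAsFactors = FALSE)
  is_ref <- meas$condition == "REF"
  de <- condition_delta_e(meas[is_ref, ], meas[!is_ref, ])
  de_sum <- delta_e_summary(de)

  model <- pill_classifier(feats[is_ref, , drop = FALSE],
                           manifest$label[is_ref])
  acc <- topk_accuracy(model, feats[!is_ref, , drop = FALSE],
                       manifest$label[!is_ref],
                       manifest$condition[!is_ref], k = config$k)

  conds <- condition_grid()
  de_long <- merge(de, conds[, c("name", "background", "flash", "ev")],
                   by.x = "condition", by.y = "name")
  anova_tab <- delta_e_rm_anova(de_long)
  strata <- ev_strata_anova(de_long)
  assoc <- accuracy_delta_e_association(acc, de_sum)

  wide_acc <- function(kk) {
    a <- acc[acc$k == kk, c("condition", "accuracy")]
    setNames(a$accuracy[match(conds$name, a$condition)], conds$name)
  }
  cond_table <- data.frame(
    condition = conds$name,
    top1 = wide_acc(1),
    top5 = if (5 %in% config$k) wide_acc(5) else NA_real_,
    mean_delta_e = de_sum$mean_delta_e[match(conds$name, de_sum$condition)],
    sd_delta_e = de_sum$sd_delta_e[match(conds$name, de_sum$condition)],
    stringsAsFactors = FALSE, row.names = NULL
  )

  write.csv(cond_table, file.path(out_dir, "condition_table.csv"),
            row.names = FALSE)
  write.csv(de, file.path(out_dir, "delta_e.csv"), row.names = FALSE)
  write.csv(as.data.frame(anova_tab), file.path(out_dir, "anova.csv"),
            row.names = FALSE)
  write.csv(strata$anova, file.path(out_dir, "strata_anova.csv"),
            row.names = FALSE)
  write.csv(strata$pairwise, file.path(out_dir, "strata_pairwise.csv"),
            row.names = FALSE)
  write.csv(seg_log, file.path(out_dir, "segmentation_log.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(correlations = assoc$correlations, flagged = assoc$flagged),
    file.path(out_dir, "association.json"), digits = NA, dataframe = "rows"
  )
  write_classifier(model, file.path(out_dir, "classifier.json"))
  jsonlite::write_json(
    list(package = "pillchroma",
         version = as.character(utils::packageVersion("pillchroma")),
         r_version = R.version.string,
         seed = config$seed, n_per_cell = config$n_per_cell,
         canvas = config$canvas,
         render = unclass(config$render), roi = unclass(config$roi)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA
  )

  structure(list(
    condition_table = cond_table, delta_e = de, delta_e_summary = de_sum,
    accuracy = acc, anova = anova_tab, strata = strata, association = assoc,
    segmentation_log = seg_log, model = model, config = config,
    dir = out_dir
  ), class = "pill_experiment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pill_experiment <- function(x, ...) {
  cat("Pill imaging-condition experiment\n")
  cat(sprintf("  seed %d, %d images/cell, canvas %dpx\n",
              x$config$seed, x$config$n_per_cell, x$config$canvas))
  cat(sprintf("  segmentation: %d contour-fill, %d threshold fallback, %d oracle\n",
              sum(x$segmentation_log$stage == "contour_fill"),
              sum(x$segmentation_log$stage == "threshold"),
              sum(x$segmentation_log$stage == "oracle")))
  cat("\nPer-condition accuracy and colour difference:\n")
  tab <- x$condition_table
  tab$top1 <- round(tab$top1, 3)
  tab$top5 <- round(tab$top5, 3)
  tab$mean_delta_e <- round(tab$mean_delta_e, 2)
  tab$sd_delta_e <- round(tab$sd_delta_e, 2)
  print(tab, row.names = FALSE)
  rho <- x$association$correlations
  cat(sprintf("\nSpearman rho(mean Delta E, accuracy): %s\n",
              paste(sprintf("top-%d %.3f", rho$k, rho$spearman),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.pill_experiment <- function(object, ...) {
  print(object)
  cat("\nThree-way repeated-measures ANOVA:\n")
  print(object$anova)
  cat("\nEV effect per background x flash stratum:\n")
  print(object$strata$anova, row.names = FALSE)
  cat("\nBonferroni-adjusted EV pairwise comparisons:\n")
  print(object$strata$pairwise, row.names = FALSE)
  invisible(object)
}

#' Two-panel condition plot
#'
#' Panel A: top-1/top-5 accuracy bars per condition; panel B: mean Delta E
#' with SD whiskers per condition.
#'
#' @param x a `pill_experiment`.
#' @param ... unused.
#' @export
plot.pill_experiment <- function(x, ...) {
  tab <- x$condition_table
  old <- par(mfrow = c(2, 1), mar = c(6, 4, 2, 1))
  on.exit(par(old))
  bars <- rbind(top1 = tab$top1, top5 = tab$top5)
  barplot(bars, beside = TRUE, names.arg = tab$condition, las = 2,
          ylim = c(0, 1), ylab = "accuracy",
          legend.text = c("top-1", "top-5"),
          args.legend = list(x = "topright", bty = "n"),
          main = "A: recognition accuracy per condition")
  bp <- barplot(tab$mean_delta_e, names.arg = tab$condition, las = 2,
                ylab = expression(Delta * E),
                ylim = c(0, max(tab$mean_delta_e + tab$sd_delta_e,
                                na.rm = TRUE) * 1.1),
                main = "B: colour difference per condition (mean +/- SD)")
  ok <- !is.na(tab$sd_delta_e) & tab$sd_delta_e > 0
  if (any(ok)) {
    arrows(bp[ok], tab$mean_delta_e[ok] - tab$sd_delta_e[ok],
           bp[ok], tab$mean_delta_e[ok] + tab$sd_delta_e[ok],
           angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}

#' Write the experiment report
#'
#' Renders the two-panel figure as PNG and a markdown summary table.  Purely
#' presentational: every number comes from the tables already computed by
#' [run_pill_experiment()].
#'
#' @param x a `pill_experiment`.
#' @param dir output directory (defaults to the experiment's own directory).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(x, dir = x$dir) {
  stopifnot(inherits(x, "pill_experiment"))
  if (is.null(x$condition_table) || nrow(x$condition_table) == 0) {
    pc_stop("pillchroma_report_error", "experiment bundle has no condition table")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fig <- file.path(dir, "conditions.png")
  grDevices::png(fig, width = 900, height = 700)
  plot(x)
  dev.off()

  tab <- x$condition_table
  md <- c(
    "# Imaging-condition experiment report",
    "",
    sprintf("Seed %d; %d image(s) per cell; canvas %d px.",
            x$config$seed, x$config$n_per_cell, x$config$canvas),
    "",
    "| condition | top-1 | top-5 | mean dE | sd dE |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.3f | %.3f | %.2f | %.2f |", tab$condition, tab$top1,
            tab$top5, tab$mean_delta_e, tab$sd_delta_e),
    "",
    sprintf("Spearman rho between mean Delta E and accuracy: %s.",
            paste(sprintf("top-%d %.3f", x$association$correlations$k,
                          x$association$correlations$spearman),
                  collapse = ", ")),
    "",
    sprintf("Segmentation: %d contour-fill, %d threshold fallback, %d oracle substitution(s).",
            sum(x$segmentation_log$stage == "contour_fill"),
            sum(x$segmentation_log$stage == "threshold"),
            sum(x$segmentation_log$stage == "oracle")),
    "",
    "![conditions](conditions.png)"
  )
  md_path <- file.path(dir, "report.md")
  writeLines(md, md_path)
  invisible(c(fig, md_path))
}
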