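#' Compute the metric table for a whole cohort
#'
#' Runs [metrics_by_zone()] on every eye of a cohort, either from
#' in-memory label maps or from a manifest of image files. A per-eye
#' failure (unreadable image, missing file) is recorded and the run
#' continues; failures are summarized in a warning and attached as
#' `attr(, "failures")`.
#'
#' @param x Either a named list of `vessel_label_map`s or a manifest
#'   data.frame (see [load_cohort_manifest()]).
#' @param zones Optional precomputed `zone_partition` list keyed by
#'   laterality; by default zones are built per eye from its metadata.
#' @param config A [metric_config()].
#' @return data.frame of metric records (eye x zone x class), with a
#'   `failures` attribute (data.frame eye_id, error) when any eye failed.
#' @export
run_metrics <- function(x, zones = NULL, config = metric_config()) {
  if (is.data.frame(x)) {
    manifest <- x
    getmap <- function(i) read_label_map(
      manifest$path[i], pixel_pitch_mm = manifest$pixel_pitch_mm[i],
      laterality = manifest$laterality[i], eye_id = manifest$eye_id[i])
    ids <- manifest$eye_id
    n <- nrow(manifest)
  } else if (is.list(x)) {
    getmap <- function(i) x[[i]]
    ids <- names(x)
    n <- length(x)
  } else stop("x must be a manifest data.frame or a list of label maps")
  zcache <- list()
  rows <- list(); fails <- list()
  for (i in seq_len(n)) {
    res <- tryCatch({
      map <- getmap(i)
      key <- paste(map$laterality, nrow(map$classes), ncol(map$classes),
                   signif(map$pixel_pitch_mm, 10))
      if (is.null(zcache[[key]]))
        zcache[[key]] <- build_zones(dim(map$classes), map$pixel_pitch_mm,
                                     laterality = map$laterality)
      metrics_by_zone(map, zones = zcache[[key]], config = config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1]] <-
        data.frame(eye_id = ids[i], error = conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  if (length(rows) == 0) stop("no eye could be processed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(fails) > 0) {
    fl <- do.call(rbind, fails)
    warning(nrow(fl), " of ", n, " eyes failed: ",
            paste(utils::head(fl$eye_id, 5), collapse = ", "))
    attr(out, "failures") <- fl
  }
  out
}

#' Compare all metric cells across cohort groups
#'
#' Thin orchestration over [compare_metric_across_groups()]: joins the
#' grouping, runs the full decision protocol per metric cell, and
#' optionally writes the results (and post hoc pairs) as CSV.
#'
#' @param metric_tbl Output of [run_metrics()].
#' @param grouping data.frame with `eye_id` and `group` (e.g. a cohort
#'   manifest), or a named vector.
#' @param out_dir Optional output directory for `comparisons.csv` /
#'   `posthoc.csv`.
#' @param ... Passed to [compare_metric_across_groups()].
#' @return The comparison data.frame (invisible `posthoc` attribute).
#' @export
run_compare <- function(metric_tbl, grouping, out_dir = NULL, ...) {
  res <- compare_metric_across_groups(metric_tbl, grouping, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    ph <- attr(res, "posthoc")
    if (!is.null(ph))
      utils::write.csv(ph, file.path(out_dir, "posthoc.csv"),
                       row.names = FALSE)
  }
  res
}

#' Reconstruct published-style baseline comparisons from summary tables
#'
#' Given demographic summaries (per-group n/mean/sd for continuous
#' variables; per-group level counts for categorical ones), recomputes
#' the between-group tests exactly as such tables are built: one-way
#' ANOVA from summaries for continuous variables (a pooled two-group test
#' when only two groups report the variable) and Pearson chi-square for
#' counts. Continuous variables use person counts; laterality uses eye
#' counts (each eye contributes a row).
#'
#' @param summary_tbl data.frame with columns `table`, `variable`,
#'   `group`, `n_persons`, `n_eyes`, `mean`, `sd`.
#' @param counts_tbl data.frame with columns `table`, `variable`,
#'   `group`, `level`, `count`.
#' @return data.frame: `table`, `variable`, `test`, `statistic`, `p`.
#' @export
baseline_statistics <- function(summary_tbl, counts_tbl) {
  rows <- list()
  for (tb in unique(summary_tbl$table)) {
    st <- summary_tbl[summary_tbl$table == tb, ]
    for (v in unique(st$variable)) {
      sv <- st[st$variable == v, ]
      if (nrow(sv) < 2) next
      res <- anova_from_summary(sv$n_persons, sv$mean, sv$sd)
      rows[[length(rows) + 1]] <- data.frame(
        table = tb, variable = v,
        test = if (nrow(sv) == 2) "anova_2group" else "anova",
        statistic = res$statistic, p = res$p)
    }
  }
  for (tb in unique(counts_tbl$table)) {
    ct <- counts_tbl[counts_tbl$table == tb, ]
    for (v in unique(ct$variable)) {
      cv <- ct[ct$variable == v, ]
      tab <- stats::xtabs(count ~ group + level, data = cv)
      res <- chi_square_table(tab)
      rows[[length(rows) + 1]] <- data.frame(
        table = tb, variable = v, test = "chi_square",
        statistic = res$statistic, p = res$p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Baseline demographic summaries bundled with the package
#'
#' Loads the demographic summary tables of a published three-group
#' T1DM OCTA cohort (healthy controls, diabetics without retinopathy,
#' and non-proliferative retinopathy; the NDR group additionally split
#' by disease duration at 5 years). These printed summaries are the
#' worked-example inputs for [baseline_statistics()].
#'
#' @return List with `summary` and `counts` data.frames.
#' @export
baseline_example_data <- function() {
  dir <- system.file("extdata", package = "vesselmetrics")
  list(summary = utils::read.csv(file.path(dir, "t1dm_baseline_summary.csv")),
       counts = utils::read.csv(file.path(dir, "t1dm_baseline_counts.csv")))
}

#' End-to-end worked example
#'
#' Generates a three-group phantom cohort (emulating control / diabetic
#' no-retinopathy / retinopathy groups) with one injected arterial
#' density deficit, computes the full metric table, runs the group
#' comparison protocol, recomputes the bundled baseline worked examples,
#' and writes everything under `out_dir`.
#'
#' @param seed Integer seed controlling the whole run.
#' @param out_dir Output directory.
#' @param eyes_per_group Cohort size per group.
#' @return Invisible list with `cohort`, `metrics`, `comparisons`,
#'   `baseline`.
#' @export
run_demo <- function(seed = 1, out_dir = "demo_outputs",
                     eyes_per_group = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cs <- cohort_spec(
    eyes_per_group = eyes_per_group,
    effects = data.frame(group = "NPDR", zone = "para_I",
                         class = "artery", delta_vd = -0.018),
    seed = seed)
  cohort <- generate_cohort(cs, out_dir = file.path(out_dir, "cohort"))
  metrics <- run_metrics(cohort$maps)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  comparisons <- run_compare(metrics, cohort$manifest, out_dir = out_dir)
  bl <- baseline_example_data()
  baseline <- baseline_statistics(bl$summary, bl$counts)
  utils::write.csv(baseline, file.path(out_dir, "baseline_statistics.csv"),
                   row.names = FALSE)
  invisible(list(cohort = cohort, metrics = metrics,
                 comparisons = comparisons, baseline = baseline))
}
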