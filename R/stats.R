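#' Kolmogorov–Smirnov normality test
#'
#' One-sample K-S test against a normal distribution with mean and SD
#' estimated from the data. Because the parameters are estimated, the
#' default applies the Lilliefors correction; `method = "ks"` gives the
#' uncorrected test (the common statistics-package default) for fidelity
#' comparisons.
#'
#' @param x Numeric vector (n >= 4 for `"lilliefors"`, n >= 3 for
#'   `"ks"`).
#' @param method `"lilliefors"` (default) or `"ks"`.
#' @return p-value.
#' @export
ks_normality <- function(x, method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("normality testing needs at least 3 values")
  if (stats::sd(x) == 0) stop("constant sample: normality undefined")
  if (method == "lilliefors") {
    if (length(x) < 4) stop("the Lilliefors test needs at least 4 values")
    nortest::lillie.test(x)$p.value
  } else {
    suppressWarnings(
      stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x))$p.value)
  }
}

#' One-way ANOVA on raw samples
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @return List with `statistic` (F), `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs at least 2 values")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (all(vapply(groups, stats::sd, 1) == 0) &&
      length(unique(vapply(groups, mean, 1))) == 1)
    return(list(statistic = 0, df1 = length(groups) - 1,
                df2 = length(y) - length(groups), p = 1))
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = unname(ft$p.value))
}

#' One-way ANOVA from group summaries
#'
#' Reconstructs the F test from per-group `n`, `mean`, `sd` alone:
#' `SSB = sum n_i (m_i - m)^2`, `SSW = sum (n_i - 1) sd_i^2`,
#' `F = (SSB / (k - 1)) / (SSW / (N - k))`. This is how published
#' between-group comparisons (reported as mean +/- SD with group sizes)
#' are re-derived; with two groups it equals the pooled two-sample t test
#' (`F = t^2`).
#'
#' @param n,mean,sd Numeric vectors, one entry per group (all n >= 2).
#' @return List with `statistic` (F), `df1`, `df2`, `p`.
#' @export
anova_from_summary <- function(n, mean, sd) {
  stopifnot(length(n) == length(mean), length(n) == length(sd),
            length(n) >= 2)
  if (any(n < 2)) stop("every group needs n >= 2")
  k <- length(n); N <- sum(n)
  gm <- sum(n * mean) / N
  ssb <- sum(n * (mean - gm)^2)
  ssw <- sum((n - 1) * sd^2)
  if (ssw == 0 && ssb == 0)
    return(list(statistic = 0, df1 = k - 1, df2 = N - k, p = 1))
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(statistic = F, df1 = k - 1, df2 = N - k,
       p = stats::pf(F, k - 1, N - k, lower.tail = FALSE))
}

#' Levene variance-homogeneity test
#'
#' Levene's test on absolute deviations from the group means (the
#' mean-centered form), used as the gate between the LSD and Tamhane T2
#' post hoc procedures.
#'
#' @param groups List of numeric vectors.
#' @param center `"mean"` (default) or `"median"` (Brown–Forsythe).
#' @return List with `statistic`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs at least 2 values")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  cfun <- if (center == "mean") mean else stats::median
  dev <- unlist(lapply(groups, function(v) abs(v - cfun(v))))
  if (stats::sd(dev) == 0)
    return(list(statistic = 0, df1 = length(groups) - 1,
                df2 = length(y) - length(groups), p = 1))
  lt <- car::leveneTest(y ~ g, center = cfun)
  list(statistic = lt$`F value`[1], df1 = lt$Df[1], df2 = lt$Df[2],
       p = lt$`Pr(>F)`[1])
}

#' LSD post hoc pairwise comparisons
#'
#' Fisher's least-significant-difference procedure: pairwise t tests with
#' the pooled within-group mean square of the full ANOVA (`df = N - k`)
#' and no multiplicity adjustment — the classical follow-up when variances
#' are homogeneous.
#'
#' @param groups Named list of numeric vectors.
#' @return data.frame with `group1`, `group2`, `statistic`, `df`, `p`.
#' @export
posthoc_lsd <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs at least 2 values")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  N <- sum(ns)
  msw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1)) / (N - k)
  out <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(msw * (1 / ns[i] + 1 / ns[j]))
    tstat <- if (se == 0) 0 else (mean(groups[[i]]) - mean(groups[[j]])) / se
    p <- if (se == 0) 1 else
      2 * stats::pt(abs(tstat), df = N - k, lower.tail = FALSE)
    out[[length(out) + 1]] <- data.frame(
      group1 = nm[i], group2 = nm[j], statistic = tstat, df = N - k,
      p_unadjusted = p, p = p)
  }
  do.call(rbind, out)
}

#' Tamhane T2 post hoc pairwise comparisons
#'
#' Pairwise Welch t tests (separate variances, Welch–Satterthwaite df)
#' with a Sidak-style conservative adjustment over the `k(k-1)/2` pairs
#' (`p_adj = 1 - (1 - p)^m`) — the heteroscedasticity-robust follow-up
#' used when the variance-homogeneity gate fails.
#'
#' @param groups Named list of numeric vectors.
#' @return data.frame with `group1`, `group2`, `statistic`, `df`,
#'   `p_unadjusted`, `p` (adjusted).
#' @export
posthoc_tamhane_t2 <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs at least 2 values")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  k <- length(groups)
  m <- k * (k - 1) / 2
  out <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    a <- groups[[i]]; b <- groups[[j]]
    va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
    se <- sqrt(va + vb)
    if (se == 0) {
      tstat <- 0; df <- length(a) + length(b) - 2; p <- 1
    } else {
      tstat <- (mean(a) - mean(b)) / se
      df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
      p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
    }
    out[[length(out) + 1]] <- data.frame(
      group1 = nm[i], group2 = nm[j], statistic = tstat, df = df,
      p_unadjusted = p, p = 1 - (1 - p)^m)
  }
  do.call(rbind, out)
}

#' Kruskal–Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' `k - 1` degrees of freedom; the nonparametric fallback when a group
#' fails the normality gate.
#'
#' @param groups List of numeric vectors.
#' @return List with `statistic` (H), `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  y <- unlist(groups)
  if (length(unique(y)) == 1) stop("all values tied: test undefined")
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  kt <- stats::kruskal.test(y, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction, `df = (r - 1)(c - 1)` — the comparison
#' used for count data (sex, laterality) across groups.
#'
#' @param tab Integer matrix of counts (at least 2 x 2).
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_table <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least a 2 x 2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column sum: expected counts undefined")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Group comparison protocol for one set of samples
#'
#' The full decision cascade applied to each metric cell: test every
#' group for normality (K-S gate); if all pass, one-way ANOVA with a
#' Levene gate choosing LSD (homogeneous) or Tamhane T2 (heterogeneous)
#' post hoc pairs; otherwise Kruskal–Wallis. Two-tailed p, significance
#' at `alpha`.
#'
#' @param groups Named list of numeric vectors (NAs dropped).
#' @param alpha Significance level for the gates and the flag.
#' @param normality `"lilliefors"` or `"ks"` for the normality gate.
#' @param min_n Minimum usable values per group.
#' @return List: `test` ("anova" or "kruskal"), `statistic`, `p`,
#'   `normality_p` (per group), `levene_p`, `posthoc_method`, `posthoc`
#'   (data.frame or NULL), `significant`, `n`, `mean`, `sd`.
#' @export
compare_groups <- function(groups, alpha = 0.05,
                           normality = c("lilliefors", "ks"), min_n = 3) {
  normality <- match.arg(normality)
  groups <- lapply(groups, function(v) v[!is.na(v)])
  groups <- groups[vapply(groups, length, 1L) >= min_n]
  if (length(groups) < 2)
    stop("need at least 2 groups with >= ", min_n, " usable values")
  ns <- vapply(groups, length, 1L)
  mns <- vapply(groups, mean, 1)
  sds <- vapply(groups, stats::sd, 1)
  norm_p <- vapply(groups, function(v) {
    tryCatch(ks_normality(v, method = normality), error = function(e) 0)
  }, numeric(1))
  all_normal <- all(norm_p > alpha)
  posthoc <- NULL; posthoc_method <- NA_character_; levene_p <- NA_real_
  if (all_normal) {
    om <- one_way_anova(groups)
    lev <- tryCatch(levene_test(groups), error = function(e) list(p = NA))
    levene_p <- lev$p
    test <- "anova"
    if (length(groups) >= 3) {
      if (!is.na(levene_p) && levene_p <= alpha) {
        posthoc <- posthoc_tamhane_t2(groups); posthoc_method <- "tamhane_t2"
      } else {
        posthoc <- posthoc_lsd(groups); posthoc_method <- "lsd"
      }
    }
  } else {
    om <- kruskal_wallis(groups)
    test <- "kruskal"
  }
  list(test = test, statistic = om$statistic, p = om$p,
       normality_p = norm_p, levene_p = levene_p,
       posthoc_method = posthoc_method, posthoc = posthoc,
       significant = om$p < alpha, n = ns, mean = mns, sd = sds)
}

#' Compare every metric cell across groups
#'
#' Applies [compare_groups()] to each metric x zone x vessel-class cell
#' of a metric table. Missing metric values are dropped cell-wise; cells
#' without at least two groups of `min_n` usable values are reported with
#' a reason rather than silently skipped.
#'
#' @param metric_tbl data.frame from [metrics_by_zone()] / [run_metrics()]
#'   (rows: eye x zone x class; metric columns).
#' @param grouping Named character vector `eye_id -> group`, or a
#'   data.frame with `eye_id` and `group` columns.
#' @param metrics Character vector of metric column names to test.
#' @param alpha Significance level.
#' @param normality Normality gate variant.
#' @param min_n Minimum usable values per group and cell.
#' @param mtc `"none"` (default: raw p-values, as is conventional for
#'   these zone-wise reports) or `"BH"` for Benjamini–Hochberg across all
#'   tested cells.
#' @return data.frame, one row per tested cell, with the gates, test
#'   used, statistic, p (and `p_adj` if `mtc != "none"`), significance
#'   flag, and per-group n/mean/sd; pairwise post hoc rows are in
#'   `attr(, "posthoc")`.
#' @export
compare_metric_across_groups <- function(metric_tbl, grouping,
                                         metrics = c("vd", "vdi_um", "vlf",
                                                     "fd", "mdac", "lc_mm",
                                                     "tsc_lx", "tsc_lc"),
                                         alpha = 0.05,
                                         normality = c("lilliefors", "ks"),
                                         min_n = 3,
                                         mtc = c("none", "BH")) {
  normality <- match.arg(normality)
  mtc <- match.arg(mtc)
  if (is.data.frame(grouping))
    grouping <- stats::setNames(as.character(grouping$group),
                                grouping$eye_id)
  miss <- setdiff(unique(metric_tbl$eye_id), names(grouping))
  if (length(miss) > 0)
    stop("grouping does not cover eye(s): ", paste(miss, collapse = ", "))
  metrics <- intersect(metrics, names(metric_tbl))
  gnames <- unique(unname(grouping[unique(metric_tbl$eye_id)]))
  rows <- list(); ph <- list()
  cells <- unique(metric_tbl[, c("zone", "vessel_class")])
  for (ci in seq_len(nrow(cells))) {
    zn <- cells$zone[ci]; cls <- cells$vessel_class[ci]
    sub <- metric_tbl[metric_tbl$zone == zn &
                        metric_tbl$vessel_class == cls, ]
    for (m in metrics) {
      vals <- split(sub[[m]], factor(unname(grouping[sub$eye_id]),
                                     levels = gnames))
      res <- tryCatch(
        compare_groups(vals, alpha = alpha, normality = normality,
                       min_n = min_n),
        error = function(e) e)
      base <- data.frame(metric = m, zone = zn, vessel_class = cls)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1]] <- cbind(base, data.frame(
          test = NA_character_, statistic = NA_real_, p = NA_real_,
          levene_p = NA_real_, posthoc_method = NA_character_,
          significant = NA, note = conditionMessage(res)))
        next
      }
      grp_cols <- list()
      for (g in gnames) {
        i <- match(g, names(res$n))
        grp_cols[[paste0("n_", g)]] <- if (is.na(i)) NA_integer_ else res$n[i]
        grp_cols[[paste0("mean_", g)]] <- if (is.na(i)) NA_real_ else res$mean[i]
        grp_cols[[paste0("sd_", g)]] <- if (is.na(i)) NA_real_ else res$sd[i]
      }
      rows[[length(rows) + 1]] <- cbind(base, data.frame(
        test = res$test, statistic = res$statistic, p = res$p,
        levene_p = res$levene_p, posthoc_method = res$posthoc_method,
        significant = res$significant, note = NA_character_),
        as.data.frame(grp_cols))
      if (!is.null(res$posthoc))
        ph[[length(ph) + 1]] <- cbind(base, res$posthoc)
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    miss_cols <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (mc in miss_cols) r[[mc]] <- NA
    r
  }))
  rownames(out) <- NULL
  if (mtc == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  }
  attr(out, "posthoc") <- if (length(ph) > 0) do.call(rbind, ph) else NULL
  out
}
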