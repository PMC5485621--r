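## Paired statistics on synCT-vs-planCT metric differences and the report
## tables/figure. Differences are always synCT minus planCT. The
## between-group test is the rank-sum (Mann-Whitney) test, since it compares
## independent PTV groups defined by size and location. No multiple-testing
## correction is applied (noted in the report footer). Confidence intervals
## use t quantiles.

#' One-sample paired t-test on metric differences
#'
#' @param differences numeric vector (synCT - planCT per plan), n >= 2.
#' @return list with `t`, `p`, `mean`, `n` and `degenerate` (TRUE when the
#'   differences have zero variance, in which case t/p are NA).
#' @export
paired_t_test <- function(differences) {
  differences <- as.numeric(differences)
  n <- length(differences)
  if (n < 2) stop("need at least 2 paired differences")
  if (sd(differences) == 0) {
    return(list(t = NA_real_, p = NA_real_, mean = mean(differences), n = n,
                degenerate = TRUE))
  }
  ht <- t.test(differences)
  list(t = unname(ht$statistic), p = ht$p.value, mean = mean(differences),
       n = n, degenerate = FALSE)
}

#' Mean and 95% confidence half-width of differences
#'
#' Half-width = `t(0.975, n-1) * SE`; zero-variance input gives half-width 0.
#'
#' @param differences numeric vector, n >= 2.
#' @return list with `mean` and `half_width`.
#' @export
mean_ci95 <- function(differences) {
  differences <- as.numeric(differences)
  n <- length(differences)
  if (n < 2) stop("need at least 2 differences")
  se <- sd(differences) / sqrt(n)
  list(mean = mean(differences), half_width = qt(0.975, n - 1) * se)
}

#' Wilcoxon rank-sum (Mann-Whitney U) test between two groups
#'
#' Exact for small samples (both groups <= 12, no ties), normal
#' approximation with tie correction otherwise.
#'
#' @param group_a,group_b numeric vectors of per-plan metric differences.
#' @return list with `U` (for `group_a`) and `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 12 && length(b) <= 12 && !ties
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Long paired metric table
#'
#' One row per plan and metric with the synCT value, planCT value and their
#' difference (synCT - planCT).
#'
#' @param plan_id,size_class,location per-plan identifiers (recycled across
#'   metrics).
#' @param syn,plan `dvh_metric_set`s (or named numeric vectors) of the same
#'   metrics.
#' @return data.frame.
#' @export
paired_metric_table <- function(plan_id, size_class, location, syn, plan) {
  stopifnot(identical(names(syn), names(plan)))
  data.frame(plan_id = plan_id, size_class = size_class, location = location,
             metric = names(syn), synCT = as.numeric(syn),
             planCT = as.numeric(plan),
             difference = as.numeric(syn) - as.numeric(plan),
             stringsAsFactors = FALSE)
}

group_difference_table <- function(metrics) {
  groups <- c(lapply(unique(metrics$size_class), function(s)
    list(name = s, rows = metrics$size_class == s)),
    lapply(unique(metrics$location), function(l)
      list(name = l, rows = metrics$location == l)),
    list(list(name = "All", rows = rep(TRUE, nrow(metrics)))))
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- metrics[g$rows, , drop = FALSE]
    do.call(rbind, lapply(unique(sub$metric), function(mn) {
      d <- sub$difference[sub$metric == mn]
      ci <- if (length(d) >= 2) mean_ci95(d) else
        list(mean = mean(d), half_width = NA_real_)
      pt <- if (length(d) >= 2) paired_t_test(d) else
        list(p = NA_real_, degenerate = TRUE)
      data.frame(group = g$name, metric = mn, n = length(d),
                 mean_diff = ci$mean, ci95_half_width = ci$half_width,
                 p_paired_t = pt$p,
                 flag = if (isTRUE(pt$degenerate)) "degenerate" else "",
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Build the report bundle
#'
#' Writes CSV tables (organ mean HU, per-plan metrics, metric differences by
#' group, gamma pass rates by group) and a whisker plot of the metric
#' distributions to `out_dir`. Missing pieces are flagged and skipped rather
#' than fatal.
#'
#' @param metrics [paired_metric_table()]-style data.frame.
#' @param gamma_results per-plan gamma data.frame (see [pass_rate_table()]);
#'   may be `NULL` or empty (then the gamma table is omitted with a notice).
#' @param organ_hu optional [organ_mean_hu()] table.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written (class `synct_report`).
#' @export
build_report <- function(metrics, gamma_results = NULL, organ_hu = NULL,
                         out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths[[length(paths) + 1]] <<- p
  }
  if (!is.null(organ_hu)) wr(organ_hu, "organ_mean_hu.csv")
  wr(metrics, "plan_metrics.csv")
  wr(group_difference_table(metrics), "metric_differences_by_group.csv")
  if (!is.null(gamma_results) && nrow(gamma_results) > 0) {
    wr(gamma_results, "gamma_pass_rates_per_plan.csv")
    wr(pass_rate_table(gamma_results), "gamma_pass_rates_by_group.csv")
  } else {
    message("no gamma results supplied; gamma tables omitted")
  }
  fig <- file.path(out_dir, "metric_differences_whisker.png")
  grDevices::png(fig, width = 1200, height = 600)
  op <- graphics::par(mar = c(8, 5, 2, 1))
  graphics::boxplot(difference ~ metric, data = metrics, las = 2,
                    ylab = "synCT - planCT", xlab = "",
                    main = "Dose-volume metric differences")
  graphics::abline(h = 0, lty = 2)
  graphics::par(op)
  grDevices::dev.off()
  paths <- c(paths, fig)
  footer <- file.path(out_dir, "README.txt")
  writeLines(c("synctdose report bundle.",
               "Differences are synCT - planCT.",
               "No multiple-testing correction is applied."), footer)
  invisible(structure(c(paths, footer), class = "synct_report"))
}
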