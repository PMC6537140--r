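#' Summarize a strain's image-wise lifetime distribution
#'
#' Box-plot style summary of the QC-passing image-wise lifetimes pooled for
#' one strain: median and quartiles by linear interpolation, interquartile
#' range, and the 95% confidence interval of the median by the box-plot
#' notch convention `median +/- 1.57 * IQR / sqrt(n)` (the normal-assumption
#' formula behind notched box plots).
#'
#' @param lifetimes_ns Numeric vector of image-wise lifetimes (ns).
#' @param strain_id,group_id,role Identifiers carried into the summary.
#' @return A one-row data frame of class `strain_summary` with columns
#'   `strain_id`, `group_id`, `role`, `n_fov`, `median_ns`, `q1_ns`,
#'   `q3_ns`, `iqr_ns`, `ci95_low_ns`, `ci95_high_ns`, `ci_defined`, plus
#'   the pooled lifetimes in `attr(, "lifetimes_ns")`.
#' @export
summarize_strain <- function(lifetimes_ns, strain_id = "strain",
                             group_id = "g1", role = "query") {
  lifetimes_ns <- lifetimes_ns[is.finite(lifetimes_ns)]
  n <- length(lifetimes_ns)
  if (!n) stop("no lifetimes to summarize for strain ", strain_id)
  qs <- stats::quantile(lifetimes_ns, c(0.25, 0.5, 0.75), type = 7,
                        names = FALSE)
  iqr <- qs[3] - qs[1]
  ci_ok <- n >= 3
  half <- if (ci_ok) 1.57 * iqr / sqrt(n) else NA_real_
  out <- data.frame(
    strain_id = strain_id, group_id = group_id, role = role,
    n_fov = n, median_ns = qs[2], q1_ns = qs[1], q3_ns = qs[3],
    iqr_ns = iqr,
    ci95_low_ns = if (ci_ok) qs[2] - half else NA_real_,
    ci95_high_ns = if (ci_ok) qs[2] + half else NA_real_,
    ci_defined = ci_ok,
    stringsAsFactors = FALSE
  )
  attr(out, "lifetimes_ns") <- lifetimes_ns
  class(out) <- c("strain_summary", class(out))
  out
}

# Two-sided rank-sum p-value: exact null distribution when both samples
# have n <= 10 and there are no ties, tie-corrected normal approximation
# with continuity correction otherwise.
rank_sum_p <- function(x, y, exact_max_n = 10) {
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) <= exact_max_n && length(y) <= exact_max_n
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = TRUE)$p.value
  )
}

#' Compare the query strains of a group to its negative control
#'
#' Each query strain's pooled image-wise lifetimes are compared to the
#' group's negative control with a two-sided Wilcoxon rank-sum test at
#' significance level `alpha = 0.05`. When a group has more than one query
#' strain, a Bonferroni correction divides `alpha` by the number of query
#' strains `m`. Positive controls are tested the same way but never counted
#' in `m`. Comparisons are strictly within-group.
#'
#' @param summaries List of [summarize_strain()] results (with their pooled
#'   lifetimes attached) belonging to one group; exactly one must have role
#'   `negative_control`.
#' @param alpha Family significance level (default 0.05).
#' @return Data frame with one row per tested strain: `query_strain`,
#'   `control_strain`, `role`, `n_query`, `n_control`, `p_value`,
#'   `alpha_corrected`, `n_comparisons_in_group`, `significant`,
#'   `delta_median_ps`.
#' @export
compare_group <- function(summaries, alpha = 0.05) {
  roles <- vapply(summaries, function(s) s$role, character(1))
  ctrl_i <- which(roles == "negative_control")
  if (length(ctrl_i) != 1L) {
    stop("group must contain exactly one negative_control strain (found ",
         length(ctrl_i), ")")
  }
  ctrl <- summaries[[ctrl_i]]
  ctrl_life <- attr(ctrl, "lifetimes_ns")
  m <- sum(roles == "query")
  alpha_corr <- alpha / max(m, 1)
  rows <- lapply(summaries[-ctrl_i], function(s) {
    x <- attr(s, "lifetimes_ns")
    p <- rank_sum_p(x, ctrl_life)
    data.frame(
      query_strain = s$strain_id, control_strain = ctrl$strain_id,
      role = s$role, n_query = s$n_fov, n_control = ctrl$n_fov,
      p_value = p, alpha_corrected = alpha_corr,
      n_comparisons_in_group = m,
      significant = p < alpha_corr,
      delta_median_ps = (s$median_ns - ctrl$median_ns) * 1000,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Box-plot quantities in the plotting convention: whiskers at the most
# extreme points within 1.5 x IQR of the box, everything beyond an outlier.
boxplot_stats <- function(lifetimes_ns) {
  qs <- stats::quantile(lifetimes_ns, c(0.25, 0.5, 0.75), type = 7,
                        names = FALSE)
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - 1.5 * iqr
  hi_fence <- qs[3] + 1.5 * iqr
  inside <- lifetimes_ns[lifetimes_ns >= lo_fence & lifetimes_ns <= hi_fence]
  list(
    q1 = qs[1], median = qs[2], q3 = qs[3], iqr = iqr,
    whisker_low = min(inside), whisker_high = max(inside),
    notch_low = qs[2] - 1.57 * iqr / sqrt(length(lifetimes_ns)),
    notch_high = qs[2] + 1.57 * iqr / sqrt(length(lifetimes_ns)),
    outliers = lifetimes_ns[lifetimes_ns < lo_fence |
                              lifetimes_ns > hi_fence]
  )
}

#' Build the per-strain report from FOV results
#'
#' Pools QC-passing image-wise lifetimes across runs by strain, summarizes
#' each strain, runs the within-group comparisons against the negative
#' controls, and (optionally) writes the per-strain table, the comparison
#' table and a JSON run report to `out_dir`. Strains with zero QC-passing
#' FOVs are excluded with a warning.
#'
#' @param fov_results Data frame(s) from [analyze_fovs()]; multiple runs may
#'   be concatenated with `rbind` before calling (pooling across
#'   experiments).
#' @param layout A [plate_layout()] assigning strains to groups and roles.
#' @param out_dir Optional output directory for `strains.csv`,
#'   `comparisons.csv` and `report.json`.
#' @param alpha Family significance level (default 0.05).
#' @param meta Optional named list echoed into the JSON report (config,
#'   seeds, ...).
#' @return List with `strains` (summary table), `comparisons`, `boxplots`
#'   (named list of box-plot quantities per strain) and `qc` (counts of
#'   passing/failing FOVs per strain).
#' @export
build_report <- function(fov_results, layout, out_dir = NULL, alpha = 0.05,
                         meta = list()) {
  stopifnot(is.data.frame(fov_results), is_plate_layout(layout))
  wl <- unique(layout$wells[, c("strain_id", "group_id", "role")])
  qc_tab <- stats::aggregate(qc_pass ~ strain_id, fov_results,
                             function(x) c(pass = sum(x), fail = sum(!x)))
  passing <- fov_results[fov_results$qc_pass & is.finite(fov_results$tau_ns), ]

  summaries <- list()
  for (i in seq_len(nrow(wl))) {
    sid <- wl$strain_id[i]
    lt <- passing$tau_ns[passing$strain_id == sid]
    if (!length(lt)) {
      warning("strain ", sid, " has no QC-passing FOVs and is excluded")
      next
    }
    summaries[[sid]] <- summarize_strain(lt, sid, wl$group_id[i], wl$role[i])
  }
  if (!length(summaries)) stop("no strain has QC-passing FOVs")
  strain_tab <- do.call(rbind, lapply(summaries, function(s) {
    d <- as.data.frame(s)
    attr(d, "lifetimes_ns") <- NULL
    d
  }))
  rownames(strain_tab) <- NULL

  comps <- list()
  for (g in unique(strain_tab$group_id)) {
    grp <- summaries[names(summaries) %in%
                       strain_tab$strain_id[strain_tab$group_id == g]]
    if (sum(vapply(grp, function(s) s$role, character(1)) ==
              "negative_control") == 1L && length(grp) > 1L) {
      comps[[g]] <- compare_group(grp, alpha)
    }
  }
  comparisons <- if (length(comps)) do.call(rbind, comps) else NULL
  if (!is.null(comparisons)) rownames(comparisons) <- NULL

  boxes <- lapply(summaries, function(s) boxplot_stats(attr(s, "lifetimes_ns")))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(strain_tab, file.path(out_dir, "strains.csv"),
                     row.names = FALSE)
    if (!is.null(comparisons)) {
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(fov_results, file.path(out_dir, "fov_results.csv"),
                     row.names = FALSE)
    report <- list(
      meta = meta,
      n_fov = nrow(fov_results),
      n_fov_qc_pass = sum(fov_results$qc_pass),
      strains = strain_tab,
      comparisons = comparisons
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  list(strains = strain_tab, comparisons = comparisons, boxplots = boxes,
       qc = qc_tab)
}

#' Notched box plot of per-strain lifetimes
#'
#' @param report A [build_report()] result.
#' @param file Optional PNG path; plots to the active device when `NULL`.
#' @return Invisibly, the matrix of plotted values.
#' @export
plot_strain_boxes <- function(report, file = NULL) {
  vals <- lapply(report$boxplots, function(b) {
    c(b$whisker_low, b$q1, b$median, b$q3, b$whisker_high)
  })
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 480)
    on.exit(grDevices::dev.off())
  }
  bx <- list(
    stats = matrix(unlist(vals), nrow = 5),
    n = report$strains$n_fov,
    conf = rbind(report$strains$ci95_low_ns, report$strains$ci95_high_ns),
    out = numeric(0), group = numeric(0),
    names = report$strains$strain_id
  )
  graphics::bxp(bx, notch = TRUE, ylab = "donor lifetime (ns)",
                main = "image-wise donor lifetimes")
  invisible(bx$stats)
}
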