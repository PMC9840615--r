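.outcomes <- c("mean_err", "mean_rt_correct")

#' Run the full validation analysis over one or more datasets
#'
#' Reproduces the three validation stages on joined feature/behavior tables:
#' \enumerate{
#'   \item Pearson correlation of each of the 15 visual properties with the
#'     dot ratio, per dataset;
#'   \item explained variance (R-squared) of each of the 16 properties (dot
#'     ratio + 15 visual) on mean error rate and on mean correct-trial RT,
#'     per dataset;
#'   \item the incremental R-squared of dot ratio entered after each visual
#'     property, per dataset and pooled across datasets with dataset dummy
#'     indicators.
#' }
#' Bonferroni families: in paper mode the printed sizes 75 (correlations),
#' 80 (single regressions, one outcome at a time) and 75 (hierarchical
#' regressions) are used; otherwise the family is the grid actually run.
#'
#' @param features named list of feature tables (one per dataset), or a
#'   single table.
#' @param behavior named list of per-stimulus behavior tables matching
#'   `features`, or a single table.
#' @param out_dir if non-`NULL`: writes `correlations.csv`, `r2_grid.csv`,
#'   `delta_r2_grid.csv`, heatmap PNGs and `run_log.txt` there.
#' @param paper_mode use the fixed family sizes 75/80/75.
#' @param family_alpha family-wise alpha (default 0.05).
#' @return A list of class `validation_report`: `correlations`, `r2_grid`,
#'   `delta_r2_grid` (all long data frames with significance flags),
#'   `pooled_delta_r2`, and `family_sizes`.
#' @export
run_validation <- function(features, behavior, out_dir = NULL,
                           paper_mode = TRUE, family_alpha = 0.05) {
  if (is.data.frame(features)) features <- list(pooled = features)
  if (is.data.frame(behavior)) behavior <- list(pooled = behavior)
  stopifnot(identical(names(features), names(behavior)))
  dsets <- names(features)
  joined <- lapply(dsets, function(d) {
    j <- merge(features[[d]], behavior[[d]], by = "STIMID")
    miss <- setdiff(features[[d]]$STIMID, behavior[[d]]$STIMID)
    if (length(miss))
      warning(sprintf("%s: %d stimuli without behavior rows (e.g. %s)",
                      d, length(miss), miss[1]))
    j
  })
  names(joined) <- dsets
  props15 <- c(.visual_indices, .hash_indices)
  props16 <- c("dot_ratio", props15)

  m_corr <- if (paper_mode) 75 else length(props15) * length(dsets)
  m_r2 <- if (paper_mode) 80 else length(props16) * length(dsets)
  m_delta <- if (paper_mode) 75 else length(props15) * length(dsets)
  a_corr <- bonferroni_alpha(family_alpha, m_corr)
  a_r2 <- bonferroni_alpha(family_alpha, m_r2)
  a_delta <- bonferroni_alpha(family_alpha, m_delta)

  correlations <- do.call(rbind, lapply(dsets, function(d) {
    ct <- correlate_with_ratio(joined[[d]], alpha = a_corr)
    cbind(dataset = d, ct)
  }))

  cell <- function(fun) {
    rows <- list()
    for (d in dsets) for (oc in .outcomes) for (pn in fun$props) {
      res <- tryCatch(fun$f(joined[[d]], pn, oc),
                      error = function(e) NULL, warning = function(w) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        dataset = d, property = pn, outcome = oc,
        value = if (is.null(res)) NA_real_ else res$value,
        p = if (is.null(res)) NA_real_ else res$p,
        n = if (is.null(res)) NA_integer_ else res$n)
    }
    do.call(rbind, rows)
  }
  r2_grid <- cell(list(props = props16, f = function(j, pn, oc) {
    r <- r2_single(j[[pn]], j[[oc]])
    list(value = r$r2, p = r$p, n = r$n)
  }))
  r2_grid$significant <- !is.na(r2_grid$p) & r2_grid$p < a_r2

  delta_grid <- cell(list(props = props15, f = function(j, pn, oc) {
    r <- delta_r2(j[[pn]], j$dot_ratio, j[[oc]])
    list(value = r$delta_r2, p = r$p, n = r$n)
  }))
  delta_grid$significant <- !is.na(delta_grid$p) & delta_grid$p < a_delta

  pooled <- NULL
  if (length(dsets) > 1) {
    all_j <- do.call(rbind, lapply(dsets, function(d)
      cbind(joined[[d]][, c("STIMID", "dot_ratio", props15, .outcomes)],
            dataset = d)))
    pooled <- do.call(rbind, lapply(.outcomes, function(oc) {
      do.call(rbind, lapply(props15, function(pn) {
        res <- tryCatch(
          delta_r2(all_j[[pn]], all_j$dot_ratio, all_j[[oc]],
                   dataset = all_j$dataset),
          error = function(e) NULL, warning = function(w) NULL)
        data.frame(property = pn, outcome = oc,
                   delta_r2 = if (is.null(res)) NA_real_ else res$delta_r2,
                   p = if (is.null(res)) NA_real_ else res$p,
                   n = if (is.null(res)) NA_integer_ else res$n)
      }))
    }))
    pooled$significant <- !is.na(pooled$p) & pooled$p < a_delta
  }

  report <- structure(
    list(correlations = correlations, r2_grid = r2_grid,
         delta_r2_grid = delta_grid, pooled_delta_r2 = pooled,
         family_sizes = c(correlations = as.numeric(m_corr),
                          r2 = as.numeric(m_r2),
                          delta_r2 = as.numeric(m_delta)),
         alphas = c(correlations = a_corr, r2 = a_r2, delta_r2 = a_delta)),
    class = "validation_report")
  if (!is.null(out_dir)) .write_validation(report, out_dir)
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  Bonferroni families: %d correlations (alpha %.2g), %d R2",
              x$family_sizes["correlations"], x$alphas["correlations"],
              x$family_sizes["r2"]))
  cat(sprintf(" (alpha %.2g), %d delta-R2 (alpha %.2g)\n",
              x$alphas["r2"], x$family_sizes["delta_r2"],
              x$alphas["delta_r2"]))
  cat(sprintf("  %d correlation rows, %d R2 cells, %d delta-R2 cells\n",
              nrow(x$correlations), nrow(x$r2_grid),
              nrow(x$delta_r2_grid)))
  invisible(x)
}

.grid_to_matrix <- function(grid, oc, value_col = "value") {
  g <- grid[grid$outcome == oc, ]
  props <- unique(g$property); dsets <- unique(g$dataset)
  m <- matrix(NA_real_, length(props), length(dsets),
              dimnames = list(props, dsets))
  m[cbind(match(g$property, props), match(g$dataset, dsets))] <-
    g[[value_col]]
  m
}

.heatmap_file <- function(mat, path, main) {
  mat <- mat[rowSums(!is.na(mat)) > 0, , drop = FALSE]
  if (!nrow(mat) || !ncol(mat)) return(invisible(NULL))
  mat[is.na(mat)] <- 0
  tryCatch(
    pheatmap::pheatmap(100 * mat, cluster_rows = FALSE, cluster_cols = FALSE,
                       display_numbers = TRUE, number_format = "%.1f",
                       main = main, filename = path, width = 6,
                       height = 0.45 * nrow(mat) + 2),
    error = function(e) warning("heatmap not written: ", conditionMessage(e)))
  invisible(path)
}

.write_validation <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$correlations,
                   file.path(out_dir, "correlations.csv"), row.names = FALSE)
  utils::write.csv(report$r2_grid, file.path(out_dir, "r2_grid.csv"),
                   row.names = FALSE)
  utils::write.csv(report$delta_r2_grid,
                   file.path(out_dir, "delta_r2_grid.csv"), row.names = FALSE)
  if (!is.null(report$pooled_delta_r2))
    utils::write.csv(report$pooled_delta_r2,
                     file.path(out_dir, "pooled_delta_r2.csv"),
                     row.names = FALSE)
  for (oc in .outcomes) {
    .heatmap_file(.grid_to_matrix(report$r2_grid, oc),
                  file.path(out_dir, sprintf("r2_%s.png", oc)),
                  sprintf("Explained variance (%%) on %s", oc))
    .heatmap_file(.grid_to_matrix(report$delta_r2_grid, oc),
                  file.path(out_dir, sprintf("delta_r2_%s.png", oc)),
                  sprintf("Unique dot-ratio contribution (%%) on %s", oc))
  }
  log <- c(
    sprintf("family sizes: correlations=%d r2=%d delta_r2=%d",
            report$family_sizes["correlations"], report$family_sizes["r2"],
            report$family_sizes["delta_r2"]),
    sprintf("per-test alphas: correlations=%.6f r2=%.6f delta_r2=%.6f",
            report$alphas["correlations"], report$alphas["r2"],
            report$alphas["delta_r2"]))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
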