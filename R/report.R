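# Results-report generator. The permutation test evaluates exchangeability of
# the condition labels, so a significant outcome is phrased as a difference
# between conditions; the cluster's location and extent are reported as a
# description of the data, never as the object of the inference. The exact
# phrase "significant cluster" is therefore never emitted.

#' Render a results report
#'
#' Produces structured prose: (a) the test-outcome statement phrased as a
#' condition difference with the corrected Monte Carlo p-value; (b) a
#' descriptive account of each cluster's topographic and temporal extent;
#' (c) the effect sizes, with the maximum-within-cluster value as an
#' upper-bound-style estimate and the rectangle value (with its exact
#' channels and interval) as a lower-bound-style estimate; (d) a caveat block
#' on what the test does and does not license. Pure: identical inputs give
#' identical text.
#'
#' @param result a `cluster_perm_test` or a `cluster_result_file`.
#' @param es an `effect_size_report` for the same result (optional).
#' @return A character vector of markdown lines, class `erp_report`.
#' @export
render_report <- function(result, es = NULL) {
  conds <- if (inherits(result, "cluster_perm_test")) result$conditions
           else result$config$conditions
  cfg <- if (inherits(result, "cluster_perm_test"))
    list(alpha = result$alpha, n_randomizations = result$n_randomizations,
         tails = result$tails, mode = result$mode, seed = result$seed)
  else result$config
  clusters <- result$clusters
  sig <- Filter(function(cl) isTRUE(cl$significant), clusters)
  B <- cfg$n_randomizations
  lines <- c("# Cluster-based permutation test report", "")
  lines <- c(lines, "## Test outcome", "")
  if (length(sig)) {
    pmin_ <- min(vapply(sig, `[[`, numeric(1), "p_corrected"))
    lines <- c(lines, sprintf(
      paste0("There is a significant difference between condition %s and ",
             "condition %s (max-cluster permutation test, %s, B = %d, ",
             "corrected %s, alpha = %g)."),
      conds[1], conds[2], cfg$mode, B, format_p(pmin_, B, cfg$tails),
      cfg$alpha))
    lines <- c(lines, "", "## Descriptive extent of the condition difference", "")
    for (cl in sig) {
      dirword <- if (cl$polarity == "positive") "more positive" else "more negative"
      lines <- c(lines, sprintf(
        paste0("- The data show a %s amplitude for %s than for %s roughly ",
               "between %.0f and %.0f ms, over channels %s (cluster mass ",
               "%.1f over %d samples, corrected %s). This describes the ",
               "observed data; the precise cluster boundary is not itself ",
               "the tested hypothesis."),
        dirword, conds[1], conds[2],
        cl$time_range[1] * 1000, cl$time_range[2] * 1000,
        paste(cl$channels, collapse = ", "), cl$mass, cl$size,
        format_p(cl$p_corrected, B, cfg$tails)))
    }
  } else {
    lines <- c(lines, sprintf(
      paste0("The test provides no evidence against exchangeability of ",
             "conditions %s and %s (no corrected p-value below alpha = %g; ",
             "%s, B = %d)."),
      conds[1], conds[2], cfg$alpha, cfg$mode, B))
  }
  if (!is.null(es) && nrow(es)) {
    lines <- c(lines, "", "## Effect sizes (paired Cohen's d)", "")
    fps <- attr(es, "footprints")
    for (i in seq_len(nrow(es))) {
      r <- es[i, ]
      rect <- fps[[i]]$rectangle
      lines <- c(lines, sprintf(
        paste0("- %s effect: maximum within the cluster d = %.3f at %s, ",
               "%.0f ms (upper-bound-style estimate); rectangle (%s) ",
               "d = %.3f from %.0f to %.0f ms over channels %s ",
               "(lower-bound-style estimate); average over the cluster ",
               "d = %.3f."),
        r$polarity, r$d_max, r$d_max_channel, r$d_max_latency * 1000,
        rect$variant, r$d_rectangle, r$rect_t_start * 1000,
        r$rect_t_end * 1000, paste(rect$channels, collapse = ", "),
        r$d_average))
    }
  }
  lines <- c(lines, "", "## Interpretation caveats", "",
             paste0("- The permutation test evaluates exchangeability of the ",
                    "condition labels; a significant result supports a ",
                    "difference between the conditions, not an inference on ",
                    "precisely where or when the effect occurs."),
             paste0("- Cluster shape depends on the data and on analysis ",
                    "parameters (cluster-forming threshold, neighbour ",
                    "definition, smoothing); extents above are descriptive."),
             paste0("- Peak effect sizes are positively biased; rectangle ",
                    "summaries dilute the effect. Together they bracket the ",
                    "underlying effect size."))
  if (!is.null(cfg$seed))
    lines <- c(lines, "",
               sprintf("Reproducibility: seed %s, %d randomizations (%s).",
                       cfg$seed, B, cfg$mode))
  class(lines) <- "erp_report"
  lines
}

#' @export
print.erp_report <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}
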