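#' Construct an expression panel
#'
#' Genes x timepoints non-negative expression values for one condition,
#' sampled on a regular grid (default t0, t20, ..., t180 at 20-min
#' spacing) with a designated reference timepoint for normalization.
#'
#' @param values Numeric genes x timepoints matrix (non-negative).
#' @param genes Gene ids (defaults to rownames).
#' @param timepoints Ordered timepoint labels (defaults to colnames).
#' @param condition Condition label, e.g. `"control"` or `"miR_high"`.
#' @param reference_timepoint Label of the normalization reference column.
#' @return An `expression_panel` object.
#' @export
expression_panel <- function(values, genes = rownames(values),
                             timepoints = colnames(values),
                             condition = "control",
                             reference_timepoint = timepoints[1L]) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(values)))
  if (is.null(timepoints)) {
    stop("timepoints must be supplied or present as colnames")
  }
  stopifnot(length(genes) == nrow(values),
            length(timepoints) == ncol(values))
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  if (!reference_timepoint %in% timepoints) {
    stop("reference timepoint ", reference_timepoint, " not in panel")
  }
  dimnames(values) <- list(genes, timepoints)
  structure(
    list(values = values, genes = genes, timepoints = timepoints,
         condition = condition,
         reference_timepoint = reference_timepoint,
         normalized = FALSE),
    class = "expression_panel"
  )
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("<expression_panel> %d genes x %d timepoints (%s%s)\n",
              nrow(x$values), ncol(x$values), x$condition,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Normalize a panel to its reference timepoint
#'
#' Divides each gene's row by its expression at the reference timepoint
#' (time zero by default), so every gene starts at 1 and later values are
#' fold changes relative to its own baseline.
#'
#' @param panel An [expression_panel()].
#' @return The normalized panel.
#' @export
normalize_to_reference <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  ref <- panel$values[, panel$reference_timepoint]
  bad <- which(!(ref > 0))
  if (length(bad)) {
    stop("non-positive reference expression for gene(s): ",
         paste(panel$genes[bad], collapse = ", "))
  }
  panel$values <- panel$values / ref
  panel$normalized <- TRUE
  panel
}

#' Sample standard deviation (n - 1 denominator)
#'
#' The transcript-noise statistic: `sqrt(sum((x - mean(x))^2) / (n - 1))`.
#'
#' @param xs Numeric vector of length >= 2.
#' @return The sample standard deviation.
#' @export
sample_sd <- function(xs) {
  if (length(xs) < 2L) stop("need at least 2 values")
  stats::sd(xs)
}

#' Pooled per-timepoint summaries of a normalized panel
#'
#' Pools normalized expression across genes at each timepoint and reports
#' box-plot statistics (median, quartiles, whiskers), the maximum, and the
#' sample standard deviation.
#'
#' @param panel A normalized [expression_panel()].
#' @return Data frame with one row per timepoint: `timepoint`, `median`,
#'   `q1`, `q3`, `whisker_low`, `whisker_high`, `max`, `sd`, `n`.
#' @export
pooled_timepoint_stats <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  if (!panel$normalized) {
    warning("panel is not normalized; statistics are on raw values")
  }
  if (!nrow(panel$values)) stop("empty panel")
  rows <- lapply(panel$timepoints, function(tp) {
    x <- panel$values[, tp]
    bp <- grDevices::boxplot.stats(x)$stats
    data.frame(timepoint = tp, median = bp[3L], q1 = bp[2L], q3 = bp[4L],
               whisker_low = bp[1L], whisker_high = bp[5L],
               max = max(x), sd = sample_sd(x), n = length(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percent reduction of the upper limit of transcript variability
#'
#' Compares the pooled upper-limit statistic (maximum of normalized
#' expression by default; 97.5th percentile as a robust alternative) of a
#' treated panel against a control panel at one timepoint:
#' `100 * (1 - U_treated / U_control)`.  Positive values mean buffering;
#' negative values (flagged) mean the treated upper limit exceeds the
#' control (amplification).
#'
#' @param control,treated Normalized [expression_panel()] objects over the
#'   same gene set.
#' @param timepoint Timepoint label at which to compare.
#' @param statistic `"max"` or `"q97.5"`.
#' @return Percent reduction (numeric scalar).
#' @export
upper_limit_reduction <- function(control, treated, timepoint,
                                  statistic = c("max", "q97.5")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(control, "expression_panel"),
            inherits(treated, "expression_panel"))
  if (!setequal(control$genes, treated$genes)) {
    stop("control and treated panels cover different gene sets")
  }
  u <- function(panel) {
    x <- panel$values[, timepoint]
    if (statistic == "max") max(x) else
      unname(stats::quantile(x, 0.975, names = FALSE))
  }
  uc <- u(control); ut <- u(treated)
  if (uc == 0) stop("control upper limit is zero at ", timepoint)
  out <- 100 * (1 - ut / uc)
  if (out < 0) {
    message("note: treated upper limit exceeds control at ", timepoint,
            " (amplification)")
  }
  out
}
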