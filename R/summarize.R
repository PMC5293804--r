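#' Round half away from zero
#'
#' Reporting convention for the summary tables: one decimal, ties
#' rounded up (47.38 -> 47.4, 0.25 -> 0.3), unlike R's banker's
#' rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

CELL_LABELS <- c("I_Action", "You_Action", "He_Action",
                 "I_Interaction", "You_Interaction", "He_Interaction")

PARAMETER_LABELS <- c(
  reach_time_ms = "Reach time",
  vpeak_mm_s = "Velocity peak amplitude",
  t_vpeak_ms = "Time to velocity peak",
  pct_t_vpeak = "% Time to velocity peak",
  grasp_time_ms = "Grasp time",
  max_aperture_mm = "Maximal finger aperture",
  t_max_aperture_ms = "Time to maximal aperture",
  pct_t_max_aperture = "% Time to maximal aperture"
)

#' Condition-mean summary table
#'
#' Collapses subject condition means into the classical summary layout:
#' one row per kinematic parameter, one column per pronoun x verb-type
#' cell, values rounded to one decimal (half up).
#'
#' @param means Long table from [condition_means()].
#' @return Data frame with a `parameter` column and the six cell columns.
#' @export
summary_table <- function(means) {
  params <- intersect(names(PARAMETER_LABELS), unique(means$parameter))
  if (!length(params)) {
    return(data.frame(parameter = character(0)))
  }
  rows <- lapply(params, function(p) {
    mat <- means_matrix(means, p)
    cellm <- colMeans(mat)
    out <- as.data.frame(as.list(round_half_up(cellm, 1)))
    names(out) <- CELL_LABELS
    cbind(data.frame(parameter = PARAMETER_LABELS[[p]],
                     stringsAsFactors = FALSE), out)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Assemble the full inference report for one or more parameters
#'
#' Runs [rm_anova()], [planned_ttests()] and (optionally)
#' [jzs_bf_anova()] for each requested parameter and collects the
#' results together with the condition-mean [summary_table()].
#'
#' @param means Long table from [condition_means()].
#' @param parameters Parameters to analyze (default: all present).
#' @param ttest_parameters Parameters for which planned comparisons are
#'   run (default: same as `parameters`).
#' @param bayes Logical; compute JZS Bayes factors.
#' @param bf_samples,seed Monte Carlo settings for [jzs_bf_anova()].
#' @param ... Passed to [planned_ttests()] (alpha, correction, ...).
#' @return A list of class `reachgrasp_report` with elements `means`,
#'   `anova`, `ttests`, `bayes`.
#' @export
summarize_results <- function(means, parameters = unique(means$parameter),
                              ttest_parameters = parameters, bayes = TRUE,
                              bf_samples = 10000L, seed = 1L, ...) {
  anova_tab <- do.call(rbind, lapply(parameters, function(p) rm_anova(means, p)))
  tt_tab <- do.call(rbind, lapply(ttest_parameters, function(p)
    planned_ttests(means, p, ...)))
  bf_tab <- if (bayes) {
    do.call(rbind, lapply(parameters, function(p)
      jzs_bf_anova(means, p, n_mc_samples = bf_samples, seed = seed)))
  } else {
    NULL
  }
  structure(list(means = summary_table(means), anova = anova_tab,
                 ttests = tt_tab, bayes = bf_tab),
            class = "reachgrasp_report")
}

#' @export
print.reachgrasp_report <- function(x, ...) {
  cat("Condition means:\n")
  print(x$means, row.names = FALSE)
  cat("\nRepeated-measures ANOVA:\n")
  print(x$anova, row.names = FALSE, digits = 4)
  if (!is.null(x$ttests)) {
    cat("\nPlanned comparisons:\n")
    print(x$ttests, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$bayes)) {
    cat("\nJZS Bayes factors:\n")
    print(x$bayes, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write the report tables as TSV files
#'
#' Writes `means.tsv`, `anova.tsv`, `ttests.tsv` and `bayes.tsv` (when
#' present) into `dir`.
#'
#' @param report A `reachgrasp_report` from [summarize_results()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(report, dir) {
  stopifnot(inherits(report, "reachgrasp_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(tab, name) {
    if (!is.null(tab)) {
      utils::write.table(tab, file.path(dir, name), sep = "\t", quote = FALSE,
                         row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
    }
  }
  wt(report$means, "means.tsv")
  wt(report$anova, "anova.tsv")
  wt(report$ttests, "ttests.tsv")
  wt(report$bayes, "bayes.tsv")
  invisible(dir)
}
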