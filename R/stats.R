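#' Per-subject condition means
#'
#' Averages each kinematic parameter over the valid critical trials of
#' every subject x (pronoun, verb type) cell, producing the complete
#' 2 x 3 within-subject table that all inference operates on. Subjects
#' with an empty cell for a parameter cannot enter a repeated-measures
#' analysis and are dropped, with an entry in the `dropped` attribute.
#'
#' @param params QC-flagged per-trial table (see [apply_qc()]); only
#'   rows with `valid == TRUE` are used.
#' @param parameters Character vector of parameter columns to average.
#' @return Long data frame `subject_id, pronoun, verb_type, parameter,
#'   mean`, with attribute `dropped` naming subjects removed per
#'   parameter.
#' @export
condition_means <- function(params,
                            parameters = intersect(KINEMATIC_PARAMETERS,
                                                   names(params))) {
  stopifnot(is.data.frame(params))
  if (is.null(params$valid)) params <- apply_qc(params)
  use <- params[params$valid & !isTRUE_vec(params$is_catch), , drop = FALSE]
  if (!nrow(use)) stop("no valid critical trials to average", call. = FALSE)
  out <- list()
  dropped <- list()
  for (p in parameters) {
    vals <- use[!is.na(use[[p]]), c("subject_id", "pronoun", "verb_type", p)]
    if (!nrow(vals)) next
    agg <- stats::aggregate(vals[[p]],
                            by = list(subject_id = vals$subject_id,
                                      pronoun = vals$pronoun,
                                      verb_type = vals$verb_type),
                            FUN = mean)
    names(agg)[4L] <- "mean"
    n_cells <- table(agg$subject_id)
    incomplete <- names(n_cells)[n_cells < 6L]
    if (length(incomplete)) {
      dropped[[p]] <- incomplete
      agg <- agg[!(agg$subject_id %in% incomplete), , drop = FALSE]
    }
    if (nrow(agg)) {
      agg$parameter <- p
      out[[p]] <- agg
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[, c("subject_id", "pronoun", "verb_type", "parameter", "mean")]
  attr(res, "dropped") <- dropped
  res
}

KINEMATIC_PARAMETERS <- c("reach_time_ms", "vpeak_mm_s", "t_vpeak_ms",
                          "pct_t_vpeak", "grasp_time_ms", "max_aperture_mm",
                          "t_max_aperture_ms", "pct_t_max_aperture")

# complete subject x cell matrix (subjects in rows, 6 cells in columns)
means_matrix <- function(means, parameter) {
  m <- means[means$parameter == parameter, , drop = FALSE]
  if (!nrow(m)) stop("no condition means for parameter ", parameter, call. = FALSE)
  cells <- cell_key(m$pronoun, m$verb_type)
  wide <- stats::xtabs(mean ~ subject_id + cells, data = cbind(m, cells = cells))
  if (any(table(m$subject_id) != 6L)) {
    stop("incomplete condition cells for parameter ", parameter, call. = FALSE)
  }
  ord <- cell_key(rep(PRONOUNS, times = 2), rep(VERB_TYPES, each = 3))
  mat <- matrix(wide, nrow(wide), 6L,
                dimnames = list(rownames(wide), colnames(wide)))[, ord, drop = FALSE]
  mat
}

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`, the effect-size measure
#' `SS_effect / (SS_effect + SS_error)` re-expressed through the
#' reported F ratio and degrees of freedom.
#'
#' @param f F statistic.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta squared in `[0, 1)`.
#' @examples
#' eta_p2(6.48, 2, 22)
#' @export
eta_p2 <- function(f, df1, df2) f * df1 / (f * df1 + df2)

#' Repeated-measures ANOVA on subject condition means
#'
#' Classical 2 (verb type) x 3 (pronoun) within-subject decomposition:
#' each effect is tested against its own subject-by-effect error
#' stratum, with exact p values from the F distribution and partial eta
#' squared per effect. No sphericity correction is applied by default
#' (`gg = TRUE` applies Greenhouse-Geisser correction to the p values).
#'
#' @param means Long table from [condition_means()].
#' @param parameter Which parameter to analyze.
#' @param gg Apply Greenhouse-Geisser epsilon correction to the
#'   p values (the F and df columns stay uncorrected).
#' @return Data frame with one row per effect (`Verb`, `Pronoun`,
#'   `Verb x Pronoun`): `F`, `df1`, `df2`, `MSE`, `p`, `eta_p2`.
#' @export
rm_anova <- function(means, parameter = "pct_t_vpeak", gg = FALSE) {
  mat <- means_matrix(means, parameter)
  n <- nrow(mat)
  if (n < 2L) stop("repeated-measures ANOVA needs at least 2 subjects", call. = FALSE)
  d <- data.frame(
    value = as.vector(mat),
    subject = factor(rep(rownames(mat), 6L)),
    pronoun = factor(rep(rep(PRONOUNS, times = 2), each = n), levels = PRONOUNS),
    verb = factor(rep(rep(VERB_TYPES, each = 3), each = n), levels = VERB_TYPES)
  )
  fit <- stats::aov(value ~ verb * pronoun + Error(subject / (verb * pronoun)),
                    data = d)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[paste0("Error: ", stratum)]][[1L]]
    rn <- trimws(rownames(tab))
    i <- match(term, rn)
    r <- match("Residuals", rn)
    data.frame(effect = effect_label(term),
               F = tab[i, "F value"], df1 = tab[i, "Df"], df2 = tab[r, "Df"],
               MSE = tab[r, "Mean Sq"], p = tab[i, "Pr(>F)"],
               stringsAsFactors = FALSE)
  }
  out <- rbind(pull("subject:verb", "verb"),
               pull("subject:pronoun", "pronoun"),
               pull("subject:verb:pronoun", "verb:pronoun"))
  out$eta_p2 <- eta_p2(out$F, out$df1, out$df2)
  if (gg) {
    eps <- c(1, gg_epsilon(mat, "pronoun"), gg_epsilon(mat, "interaction"))
    out$p <- stats::pf(out$F, out$df1 * eps, out$df2 * eps, lower.tail = FALSE)
    out$gg_epsilon <- eps
  }
  out$parameter <- parameter
  rownames(out) <- NULL
  out
}

effect_label <- function(term) {
  switch(term, verb = "Verb", pronoun = "Pronoun",
         "verb:pronoun" = "Verb x Pronoun", term)
}

# Greenhouse-Geisser epsilon for the pronoun (3-level) and interaction
# effects, computed from the covariance of the orthonormal contrast
# scores (the verb effect has 1 df; epsilon is identically 1).
gg_epsilon <- function(mat, which = c("pronoun", "interaction")) {
  which <- match.arg(which)
  # columns ordered I.AV YOU.AV HE.AV I.IV YOU.IV HE.IV
  C3 <- matrix(c(1, -1, 0, 1, 0, -1), 3L, 2L) # pronoun contrasts
  M <- if (which == "pronoun") {
    rbind(C3, C3) / 2
  } else {
    rbind(C3, -C3) / 2
  }
  M <- qr.Q(qr(M)) # orthonormal basis of the effect subspace
  scores <- mat %*% M
  S <- stats::cov(scores)
  d <- ncol(S)
  sum(diag(S))^2 / (d * sum(S * S))
}

#' Planned paired comparisons between verb types within pronouns
#'
#' Paired t tests on subject-wise differences between two condition
#' cells, by default action vs. interaction verbs within each pronoun.
#' One-sided p values are reported by default; because the direction of
#' a verb-type effect can differ across pronouns, the default
#' `direction = "observed"` takes the tail on the side of the observed
#' difference and records which side was used (set `direction` to
#' `"greater"`/`"less"` for an a-priori one-sided test of A > B / A < B,
#' or `sided = "two"` for two-sided tests).
#'
#' @param means Long table from [condition_means()].
#' @param parameter Which parameter to test.
#' @param comparisons List of `c(pronoun_A, verb_A, pronoun_B, verb_B)`
#'   cell pairs; default AV vs IV within I, YOU, HE.
#' @param alpha Nominal significance level before correction.
#' @param correction `"bonferroni"` (alpha / number of comparisons),
#'   `"fixed"` (use `alpha_fixed` as the corrected level, e.g. a
#'   pre-registered 0.01), or `"none"`.
#' @param alpha_fixed Corrected level used when `correction = "fixed"`.
#' @param sided `"one"` or `"two"`.
#' @param direction For one-sided tests: `"observed"`, `"greater"` or
#'   `"less"` (A minus B).
#' @return Data frame with one row per comparison: `t`, `df`, `p`,
#'   `mean_diff`, `sided`, `direction`, `alpha_corrected`, `significant`.
#' @export
planned_ttests <- function(means, parameter = "pct_t_vpeak",
                           comparisons = NULL, alpha = 0.05,
                           correction = c("bonferroni", "fixed", "none"),
                           alpha_fixed = 0.01,
                           sided = c("one", "two"),
                           direction = c("observed", "greater", "less")) {
  correction <- match.arg(correction)
  sided <- match.arg(sided)
  direction <- match.arg(direction)
  mat <- means_matrix(means, parameter)
  if (is.null(comparisons)) {
    comparisons <- lapply(PRONOUNS, function(p) c(p, "AV", p, "IV"))
  }
  k <- length(comparisons)
  alpha_corrected <- switch(correction,
                            bonferroni = alpha / k,
                            fixed = alpha_fixed,
                            none = alpha)
  rows <- lapply(comparisons, function(cmp) {
    a <- mat[, cell_key(cmp[1L], cmp[2L])]
    b <- mat[, cell_key(cmp[3L], cmp[4L])]
    dif <- a - b
    n <- length(dif)
    se <- stats::sd(dif) / sqrt(n)
    degenerate <- !is.finite(se) || se == 0
    tval <- if (degenerate) 0 else mean(dif) / se
    df <- n - 1L
    used <- direction
    p <- if (sided == "two") {
      2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    } else {
      if (direction == "observed") used <- if (tval >= 0) "greater" else "less"
      if (used == "greater") stats::pt(tval, df, lower.tail = FALSE)
      else stats::pt(tval, df, lower.tail = TRUE)
    }
    data.frame(
      comparison = sprintf("%s.%s - %s.%s", cmp[1L], cmp[2L], cmp[3L], cmp[4L]),
      t = tval, df = df, p = p, mean_diff = mean(dif),
      sided = sided, direction = if (sided == "two") "two.sided" else used,
      alpha_corrected = alpha_corrected,
      significant = p < alpha_corrected,
      degenerate = degenerate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$parameter <- parameter
  out
}
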