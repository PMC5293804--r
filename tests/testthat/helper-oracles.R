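# Brute-force reference implementations used to cross-check the package:
# plain-loop transliterations of the segmentation rules and a direct
# sums-of-squares ANOVA. Deliberately slow and simple.

# Reach onset/offset by per-axis displacement thresholds: scan frames one
# by one. `xyz` is an n x 3 matrix, already filtered.
oracle_reach_displacement <- function(xyz, t_ms, speed, grasp_end_ms, thr = 0.3) {
  n <- nrow(xyz)
  onset <- NA_integer_
  for (k in 2:n) {
    d <- abs(xyz[k, ] - xyz[k - 1L, ])
    if (d[1] > thr && d[2] > thr && d[3] > thr) { onset <- k; break }
  }
  if (is.na(onset)) return(NULL)
  peak <- which.max(speed)
  cand <- rep(NA_integer_, 3L)
  for (ax in 1:3) {
    for (k in (peak + 1L):n) {
      if (abs(xyz[k, ax] - xyz[k - 1L, ax]) < thr) { cand[ax] <- k; break }
    }
  }
  if (all(is.na(cand))) return(NULL)
  best <- NA_integer_; bestd <- Inf
  for (ax in 1:3) {
    if (is.na(cand[ax])) next
    d <- abs(t_ms[cand[ax]] - grasp_end_ms)
    if (d < bestd || (d == bestd && t_ms[cand[ax]] < t_ms[best])) {
      best <- cand[ax]; bestd <- d
    }
  }
  list(onset = onset, offset = best)
}

# Reach onset/offset as first and last frame with speed above threshold.
oracle_reach_velocity <- function(speed, thr = 1) {
  onset <- offset <- NA_integer_
  for (k in seq_along(speed)) if (speed[k] > thr) { onset <- k; break }
  if (is.na(onset)) return(NULL)
  for (k in rev(seq_along(speed))) if (speed[k] > thr) { offset <- k; break }
  list(onset = onset, offset = offset)
}

# Grasp window: departure from / return to the initial aperture.
oracle_grasp <- function(aperture, thr = 0.3) {
  n <- length(aperture)
  onset <- NA_integer_
  for (k in seq_len(n)) {
    if (abs(aperture[k] - aperture[1L]) > thr) { onset <- k; break }
  }
  if (is.na(onset)) return(NULL)
  mx <- which.max(aperture)
  offset <- NA_integer_
  if (mx < n) {
    for (k in (mx + 1L):n) {
      if (abs(aperture[k] - aperture[1L]) < thr) { offset <- k; break }
    }
  }
  if (is.na(offset)) return(NULL)
  list(onset = onset, offset = offset, max = mx)
}

# Two-way within-subject ANOVA from explicit sums of squares over the
# subject x cell mean table (rows = subjects, columns in the order
# I.AV, YOU.AV, HE.AV, I.IV, YOU.IV, HE.IV).
oracle_rm_anova <- function(mat) {
  n <- nrow(mat)
  verb <- rep(1:2, each = 3)
  pron <- rep(1:3, times = 2)
  grand <- mean(mat)
  subj_m <- rowMeans(mat)
  verb_m <- vapply(1:2, function(v) mean(mat[, verb == v]), 0)
  pron_m <- vapply(1:3, function(p) mean(mat[, pron == p]), 0)
  cell_m <- colMeans(mat)

  ss_verb <- n * 3 * sum((verb_m - grand)^2)
  ss_pron <- n * 2 * sum((pron_m - grand)^2)
  inter <- cell_m - verb_m[verb] - pron_m[pron] + grand
  ss_inter <- n * sum(inter^2)

  sv_m <- t(vapply(seq_len(n), function(i)
    vapply(1:2, function(v) mean(mat[i, verb == v]), 0), numeric(2)))
  ss_sv <- 3 * sum((sv_m - outer(subj_m, rep(1, 2)) -
                      outer(rep(1, n), verb_m) + grand)^2)
  sp_m <- t(vapply(seq_len(n), function(i)
    vapply(1:3, function(p) mean(mat[i, pron == p]), 0), numeric(3)))
  ss_sp <- 2 * sum((sp_m - outer(subj_m, rep(1, 3)) -
                      outer(rep(1, n), pron_m) + grand)^2)
  # subject-by-interaction residual: total SS minus all accounted strata
  ss_total <- sum((mat - grand)^2)
  ss_subj <- 6 * sum((subj_m - grand)^2)
  ss_svp <- ss_total - ss_subj - ss_verb - ss_pron - ss_inter - ss_sv - ss_sp

  f_of <- function(ss_eff, df1, ss_err, df2) {
    f <- (ss_eff / df1) / (ss_err / df2)
    list(F = f, df1 = df1, df2 = df2, MSE = ss_err / df2,
         p = stats::pf(f, df1, df2, lower.tail = FALSE),
         eta_p2 = ss_eff / (ss_eff + ss_err))
  }
  list(verb = f_of(ss_verb, 1, ss_sv, n - 1),
       pronoun = f_of(ss_pron, 2, ss_sp, 2 * (n - 1)),
       interaction = f_of(ss_inter, 2, ss_svp, 2 * (n - 1)))
}

# random small kinematic fixture: piecewise motion with randomized ramps
random_motion_fixture <- function(seed) {
  set.seed(seed)
  n <- sample(40:80, 1)
  rate <- sample(c(60, 100, 200), 1)
  t_ms <- (seq_len(n) - 1) * 1000 / rate
  v <- c(rep(0, sample(3:8, 1)),
         stats::runif(1, 100, 900) * sin(seq(0, pi, length.out = sample(20:40, 1)))^2)
  v <- c(v, rep(0, max(0, n - length(v))))[1:n]
  v <- v + stats::rnorm(n, sd = 5)
  v[v < 0] <- 0
  dirs <- matrix(stats::runif(3, 0.2, 1), 1)
  dirs <- dirs / sqrt(sum(dirs^2))
  s <- cumsum(v) * (1000 / rate) / 1000
  xyz <- outer(s, dirs[1, ]) + matrix(stats::rnorm(3 * n, sd = 0.02), n)
  list(t_ms = t_ms, xyz = xyz, rate = rate)
}

# long condition-means table from a subject x cell matrix
synthetic_means <- function(mat) {
  n <- nrow(mat)
  data.frame(
    subject_id = rep(sprintf("S%02d", seq_len(n)), 6),
    pronoun = rep(rep(c("I", "YOU", "HE"), times = 2), each = n),
    verb_type = rep(rep(c("AV", "IV"), each = 3), each = n),
    parameter = "pct_t_vpeak",
    mean = as.vector(mat),
    stringsAsFactors = FALSE
  )
}

random_means_matrix <- function(n, seed) {
  set.seed(seed)
  base <- rnorm(n, 50, 3)
  mat <- outer(base, rep(1, 6)) + matrix(rnorm(6 * n, 0, 2), n, 6)
  colnames(mat) <- paste(rep(c("I", "YOU", "HE"), 2),
                         rep(c("AV", "IV"), each = 3), sep = ".")
  mat
}

# subject x cell table with an interaction-patterned effect of given size
bf_means <- function(n, effect = 0, seed = 1) {
  set.seed(seed)
  base <- rnorm(n, 50, 2)
  cell_eff <- effect * c(-1.5, 2.1, -0.7, 1.5, -2.1, 0.7)
  mat <- outer(base, rep(1, 6)) + outer(rep(1, n), cell_eff) +
    matrix(rnorm(6 * n, 0, 1.5), n, 6)
  colnames(mat) <- paste(rep(c("I", "YOU", "HE"), 2),
                         rep(c("AV", "IV"), each = 3), sep = ".")
  synthetic_means(mat)
}
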