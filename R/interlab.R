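#' Interlaboratory study statistics (ISO 5725-2 style)
#'
#' The interlaboratory functions operate on a long-format table with one
#' row per reported replicate: columns `lab` (laboratory identifier),
#' `replicate` (index within the lab) and `value_nm` (reported median of a
#' minimal Feret diameter distribution). Outlier screening flags
#' laboratories (or single replicates) as *stragglers* at the 5 % level
#' and *outliers* at the 1 % level; precision estimates are computed on
#' the retained data by one-way ANOVA with laboratory as the factor.
#'
#' @name interlab
NULL

check_interlab <- function(tbl) {
  stopifnot(all(c("lab", "value_nm") %in% names(tbl)))
  if (length(unique(tbl$lab)) < 3) stop("at least 3 laboratories required")
  invisible(tbl)
}

classify_flag <- function(stat, c5, c1, lower = FALSE) {
  if (lower) {
    if (stat < c1) "outlier" else if (stat < c5) "straggler" else "ok"
  } else {
    if (stat > c1) "outlier" else if (stat > c5) "straggler" else "ok"
  }
}

#' Critical value of Cochran's variance-homogeneity test
#'
#' Exact critical value from the F-distribution relation: with `L` labs of
#' `nu` degrees of freedom each, `C_crit = 1 / (1 + (L - 1) /
#' qf(1 - alpha / L, nu, (L - 1) nu))`.
#'
#' @param alpha significance level.
#' @param n_labs number of laboratories L.
#' @param nu within-lab degrees of freedom (replicates - 1).
#' @return Critical value in (0, 1).
#' @export
cochran_critical <- function(alpha, n_labs, nu) {
  1 / (1 + (n_labs - 1) /
         stats::qf(1 - alpha / n_labs, nu, (n_labs - 1) * nu))
}

#' Cochran test for an anomalously large laboratory variance
#'
#' Compares the largest within-laboratory variance with the sum of all
#' within-laboratory variances: `C = max(s_i^2) / sum(s_i^2)`. Only the
#' laboratory with the largest variance is tested (a lab with zero
#' variance is never flagged).
#'
#' @param tbl interlaboratory table (see [interlab]).
#' @param alpha the straggler and outlier levels, default `c(0.05, 0.01)`.
#' @return Data frame flag: `lab`, `test`, `statistic`, `critical_5pct`,
#'   `critical_1pct`, `classification`.
#' @export
cochran_test <- function(tbl, alpha = c(0.05, 0.01)) {
  check_interlab(tbl)
  counts <- table(tbl$lab)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("labs with < 2 replicates skipped in Cochran test: ",
            paste(small, collapse = ", "))
    tbl <- tbl[!tbl$lab %in% small, , drop = FALSE]
  }
  v <- tapply(tbl$value_nm, tbl$lab, stats::var)
  if (sum(v) == 0) return(empty_flags())
  stat <- max(v) / sum(v)
  lab <- names(v)[which.max(v)]
  nu <- round(mean(table(tbl$lab))) - 1
  c5 <- cochran_critical(alpha[1], length(v), nu)
  c1 <- cochran_critical(alpha[2], length(v), nu)
  data.frame(lab = lab, replicate = NA_integer_, test = "cochran",
             statistic = stat, critical_5pct = c5, critical_1pct = c1,
             classification = classify_flag(stat, c5, c1))
}

empty_flags <- function() {
  data.frame(lab = character(), replicate = integer(), test = character(),
             statistic = numeric(), critical_5pct = numeric(),
             critical_1pct = numeric(), classification = character())
}

#' Critical value of the (single) Grubbs test
#'
#' Closed form from the t-distribution:
#' `G_crit = (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha / (2 n), n - 2)`.
#'
#' @param alpha significance level (two-sided).
#' @param n sample size.
#' @return Critical value.
#' @export
grubbs_critical <- function(alpha, n) {
  t <- stats::qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

grubbs_stat <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(list(stat = 0, which = NA_integer_))
  d <- abs(x - mean(x)) / s
  list(stat = max(d), which = which.max(d))
}

#' Double-Grubbs critical value (two outliers on the same side)
#'
#' The double-Grubbs statistic for the two highest values is
#' `G = SS_without / SS_full`, the residual sum of squares after removing
#' the pair divided by the full sum of squares; small values are
#' significant. Critical values are estimated once per `(n, alpha)` by
#' Monte Carlo under the normal null (fixed internal seed, memoized).
#'
#' @param alpha significance level.
#' @param n sample size (>= 5).
#' @param n_sim Monte Carlo draws.
#' @return Lower critical value.
#' @export
double_grubbs_critical <- function(alpha, n, n_sim = 40000L) {
  key <- sprintf("n%d_a%g_s%d", n, alpha, n_sim)
  if (!is.null(.dg_cache[[key]])) return(.dg_cache[[key]])
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(20260101L + n)
  stats <- replicate(n_sim, {
    x <- sort(stats::rnorm(n))
    double_grubbs_stat_sorted(x)
  })
  cv <- stats::quantile(stats, alpha, names = FALSE)
  .dg_cache[[key]] <- cv
  cv
}

.dg_cache <- new.env(parent = emptyenv())

# statistic for the two highest of a sorted sample
double_grubbs_stat_sorted <- function(x) {
  n <- length(x)
  ss0 <- sum((x - mean(x))^2)
  if (ss0 == 0) return(1)
  xr <- x[1:(n - 2)]
  sum((xr - mean(xr))^2) / ss0
}

#' Grubbs outlier tests on laboratory means and within-lab replicates
#'
#' Three variants, as used for interlaboratory screening:
#' `grubbs_mean` tests the most extreme laboratory mean against all lab
#' means; `grubbs_double` tests the two highest and the two lowest lab
#' means jointly; `grubbs_internal` tests the most extreme replicate
#' within each laboratory.
#'
#' @inheritParams cochran_test
#' @return Data frame of flags (possibly zero rows), same columns as
#'   [cochran_test()].
#' @export
grubbs_tests <- function(tbl, alpha = c(0.05, 0.01)) {
  check_interlab(tbl)
  flags <- empty_flags()
  means <- tapply(tbl$value_nm, tbl$lab, mean)
  n <- length(means)
  if (n >= 3) {
    g <- grubbs_stat(as.vector(means))
    if (!is.na(g$which)) {
      c5 <- grubbs_critical(alpha[1], n)
      c1 <- grubbs_critical(alpha[2], n)
      flags <- rbind(flags, data.frame(
        lab = names(means)[g$which], replicate = NA_integer_,
        test = "grubbs_mean", statistic = g$stat,
        critical_5pct = c5, critical_1pct = c1,
        classification = classify_flag(g$stat, c5, c1)))
    }
  }
  if (n >= 5) {
    x <- sort(as.vector(means))
    ss0 <- sum((x - mean(x))^2)
    if (ss0 > 0) {
      c5 <- double_grubbs_critical(alpha[1], n)
      c1 <- double_grubbs_critical(alpha[2], n)
      hi <- double_grubbs_stat_sorted(x)
      lo <- double_grubbs_stat_sorted(rev(-x))
      ord <- order(as.vector(means))
      hi_labs <- names(means)[ord[c(n - 1, n)]]
      lo_labs <- names(means)[ord[c(1, 2)]]
      for (side in list(list(stat = hi, labs = hi_labs),
                        list(stat = lo, labs = lo_labs))) {
        cls <- classify_flag(side$stat, c5, c1, lower = TRUE)
        if (cls != "ok") {
          flags <- rbind(flags, data.frame(
            lab = side$labs, replicate = NA_integer_, test = "grubbs_double",
            statistic = side$stat, critical_5pct = c5, critical_1pct = c1,
            classification = cls))
        }
      }
    }
  }
  # internal: within-lab replicates
  for (lab in unique(tbl$lab)) {
    x <- tbl$value_nm[tbl$lab == lab]
    if (length(x) < 3) next
    g <- grubbs_stat(x)
    if (is.na(g$which)) next
    c5 <- grubbs_critical(alpha[1], length(x))
    c1 <- grubbs_critical(alpha[2], length(x))
    cls <- classify_flag(g$stat, c5, c1)
    if (cls != "ok") {
      rep_idx <- if ("replicate" %in% names(tbl))
        tbl$replicate[tbl$lab == lab][g$which] else g$which
      flags <- rbind(flags, data.frame(
        lab = lab, replicate = as.integer(rep_idx), test = "grubbs_internal",
        statistic = g$stat, critical_5pct = c5, critical_1pct = c1,
        classification = cls))
    }
  }
  flags
}

#' Iterative outlier screening workflow
#'
#' Applies, in order, Cochran, Grubbs-internal, Grubbs on lab means and
#' double Grubbs; 1 %-level outliers are excluded (whole laboratory for
#' Cochran/Grubbs-mean/double-Grubbs, the single replicate for
#' Grubbs-internal) and the tests re-run on the cleaned table until no
#' new outlier appears. Stragglers (5 % level) are logged but retained.
#' Following common interlaboratory practice, no more than 2/9 of the
#' original laboratories are excluded; remaining flags are logged as
#' unapplied.
#'
#' @inheritParams cochran_test
#' @param max_removed_fraction cap on the fraction of labs excluded.
#' @return List: `cleaned` (table), `log` (all flags with an `applied`
#'   column), `excluded_labs`, `excluded_replicates`.
#' @export
outlier_workflow <- function(tbl, alpha = c(0.05, 0.01),
                             max_removed_fraction = 2 / 9) {
  check_interlab(tbl)
  n_labs0 <- length(unique(tbl$lab))
  max_excl <- floor(n_labs0 * max_removed_fraction)
  cur <- tbl
  log <- empty_flags()
  log$applied <- logical(0)
  excluded_labs <- character(0)
  excluded_reps <- data.frame(lab = character(), replicate = integer())
  repeat {
    flags <- rbind(cochran_test(cur, alpha), grubbs_tests(cur, alpha))
    flags <- flags[order(match(flags$test, c("cochran", "grubbs_internal",
                                             "grubbs_mean", "grubbs_double"))), ]
    new <- FALSE
    for (i in seq_len(nrow(flags))) {
      f <- flags[i, ]
      applied <- FALSE
      if (f$classification == "outlier") {
        if (f$test == "grubbs_internal") {
          sel <- cur$lab == f$lab & cur$replicate == f$replicate
          if (any(sel)) {
            cur <- cur[!sel, , drop = FALSE]
            excluded_reps <- rbind(excluded_reps,
                                   data.frame(lab = f$lab,
                                              replicate = f$replicate))
            applied <- TRUE
          }
        } else if (length(excluded_labs) < max_excl) {
          cur <- cur[cur$lab != f$lab, , drop = FALSE]
          excluded_labs <- c(excluded_labs, f$lab)
          applied <- TRUE
        }
      }
      f$applied <- applied
      log <- rbind(log, f)
      if (applied) { new <- TRUE; break }  # re-test on the cleaned table
    }
    if (!new) break
    if (length(unique(cur$lab)) < 3)
      stop("fewer than 3 laboratories remain after outlier exclusion")
  }
  list(cleaned = cur, log = log, excluded_labs = excluded_labs,
       excluded_replicates = excluded_reps)
}

#' ISO 5725-2 precision summary of a (cleaned) interlaboratory table
#'
#' One-way ANOVA with laboratory as factor on the retained values.
#' Repeatability variance `S_r^2` is the pooled within-lab variance; the
#' between-lab component uses the effective replicate count
#' `n_bar = (N - sum(n_i^2) / N) / (p - 1)` to handle unbalanced tables,
#' and `S_R^2 = S_r^2 + S_L^2` is floored at `S_r^2`. Repeatability and
#' reproducibility limits are `r = 2.8 S_r` and `R = 2.8 S_R`.
#'
#' @inheritParams cochran_test
#' @return Object of class `interlab_summary`: list with `X_obs`, `S_r`,
#'   `r`, `RSD_r`, `S_R`, `R`, `RSD_R`, `n_labs`, `n_values`.
#' @export
iso_summary <- function(tbl) {
  check_interlab(tbl)
  labs <- split(tbl$value_nm, tbl$lab)
  labs <- labs[vapply(labs, length, 1L) >= 1]
  p <- length(labs)
  ni <- vapply(labs, length, 1L)
  N <- sum(ni)
  x_obs <- mean(tbl$value_nm)
  mi <- vapply(labs, mean, 0)
  with_df <- sum(ni - 1)
  s_r2 <- if (with_df > 0)
    sum(vapply(labs, function(x) sum((x - mean(x))^2), 0)) / with_df else 0
  s_d2 <- sum(ni * (mi - x_obs)^2) / (p - 1)
  n_bar <- (N - sum(ni^2) / N) / (p - 1)
  s_l2 <- max((s_d2 - s_r2) / n_bar, 0)
  s_r <- sqrt(s_r2)
  s_R <- sqrt(s_r2 + s_l2)
  structure(list(X_obs = x_obs, S_r = s_r, r = 2.8 * s_r,
                 RSD_r = 100 * s_r / x_obs, S_R = s_R, R = 2.8 * s_R,
                 RSD_R = 100 * s_R / x_obs, n_labs = p, n_values = N),
            class = "interlab_summary")
}

#' @export
print.interlab_summary <- function(x, ...) {
  cat(sprintf(
    "%d labs, %d values: X_obs = %.2f nm; S_r = %.2f nm (r = %.1f, RSD_r = %.1f%%); S_R = %.2f nm (R = %.1f, RSD_R = %.1f%%)\n",
    x$n_labs, x$n_values, x$X_obs, x$S_r, x$r, x$RSD_r, x$S_R, x$R, x$RSD_R))
  invisible(x)
}

#' Complete interlaboratory evaluation
#'
#' Outlier workflow followed by the ISO precision summary on the retained
#' data.
#'
#' @inheritParams cochran_test
#' @return List: `summary` (an [iso_summary()]), `outliers` (the workflow
#'   result).
#' @export
interlab_evaluation <- function(tbl, alpha = c(0.05, 0.01)) {
  wf <- outlier_workflow(tbl, alpha)
  list(summary = iso_summary(wf$cleaned), outliers = wf)
}
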