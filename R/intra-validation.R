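#' One-way ANOVA decomposition of a day x replicate design
#'
#' Decomposes the balanced day-by-replicate matrix of specimen medians
#' (one row per measurement day, one column per replicate specimen) into
#' within-day and between-day mean squares, the basis of the top-down
#' uncertainty budget.
#'
#' @param medians numeric matrix, `n_days x n_r`, complete (no `NA`).
#' @return Object of class `anova_decomposition`: list with `C_m` (grand
#'   mean), `sd` (standard deviation of all medians), `MS_within`,
#'   `MS_between`, `df_within` (= `n_days * (n_r - 1)`), `df_between`,
#'   `n_days`, `n_r`.
#' @export
anova_decompose <- function(medians) {
  medians <- as.matrix(medians)
  if (anyNA(medians)) stop("balanced complete design required (no missing cells)")
  n_days <- nrow(medians); n_r <- ncol(medians)
  if (n_days < 2 || n_r < 2) stop("need at least 2 days and 2 replicates per day")
  grand <- mean(medians)
  dm <- rowMeans(medians)
  ss_b <- n_r * sum((dm - grand)^2)
  ss_w <- sum((medians - dm)^2)
  df_b <- n_days - 1L
  df_w <- n_days * (n_r - 1L)
  structure(list(C_m = grand, sd = stats::sd(as.vector(medians)),
                 MS_within = ss_w / df_w, MS_between = ss_b / df_b,
                 df_within = df_w, df_between = df_b,
                 n_days = n_days, n_r = n_r),
            class = "anova_decomposition")
}

#' Relative precision components from an ANOVA decomposition
#'
#' Repeatability: `u_r = 100 * sqrt(MS_within) / C_m`. Day-to-day
#' component: when `MS_between > MS_within`,
#' `u_day = 100 * sqrt((MS_between - MS_within) / n_r) / C_m`; otherwise
#' the day effect is not resolvable and the degenerate branch
#' `u_day = 100 * sqrt(MS_within / n_r) * (2 / df_within)^(1/4) / C_m`
#' bounds it by the uncertainty of the within estimate itself. `u_day` is
#' therefore always real and non-negative.
#'
#' @param decomp an [anova_decompose()] result.
#' @return List with `u_r`, `u_day` (relative %), the signed raw variance
#'   components `s2_within` and `s2_day_signed = (MS_between -
#'   MS_within)/n_r` (nm^2, useful for unbiased component recovery), and
#'   `degenerate` (`TRUE` when the fallback branch was taken).
#' @export
variance_components <- function(decomp) {
  stopifnot(inherits(decomp, "anova_decomposition"))
  if (decomp$C_m <= 0) stop("grand mean must be positive")
  u_r <- 100 * sqrt(decomp$MS_within) / decomp$C_m
  degenerate <- decomp$MS_between <= decomp$MS_within
  u_day <- if (!degenerate) {
    100 * sqrt((decomp$MS_between - decomp$MS_within) / decomp$n_r) / decomp$C_m
  } else {
    100 * sqrt(decomp$MS_within / decomp$n_r) *
      (2 / decomp$df_within)^(1 / 4) / decomp$C_m
  }
  list(u_r = u_r, u_day = u_day,
       s2_within = decomp$MS_within,
       s2_day_signed = (decomp$MS_between - decomp$MS_within) / decomp$n_r,
       degenerate = degenerate)
}

#' Reference value of a certified reference material
#'
#' @param value_nm certified (or indicative) modal ECD value, nm.
#' @param u_nm its standard uncertainty (k = 1), nm.
#' @param u_t_rel_pct relative trueness component fed into the budget;
#'   defaults to `100 * u_nm / value_nm`.
#' @return Object of class `crm_reference`.
#' @export
crm_reference <- function(value_nm, u_nm, u_t_rel_pct = 100 * u_nm / value_nm) {
  stopifnot(value_nm > 0, u_nm >= 0)
  structure(list(value_nm = value_nm, u_nm = u_nm, u_t_rel_pct = u_t_rel_pct),
            class = "crm_reference")
}

#' Combine the measurement-uncertainty budget
#'
#' Quadrature chain of the top-down budget, all components as relative
#' percentages: intermediate precision `u_IP = sqrt(u_r^2 + u_day^2)`;
#' trueness `u_t = sqrt(u_t_crm^2 + u_IP^2)`; combined
#' `u_c = sqrt(u_IP^2 + u_t^2 + u_cal^2)`; expanded `Ucx = 2 * u_c`
#' (coverage factor 2, ~95 % confidence).
#'
#' @param u_r,u_day repeatability and day-to-day components (%).
#' @param u_cal calibration uncertainty (%); a per-magnification constant,
#'   see [u_cal_default()].
#' @param u_t_crm relative trueness component of the reference material
#'   (%); either a number or a [crm_reference()].
#' @return Object of class `uncertainty_budget`: list `u_r`, `u_day`,
#'   `u_IP`, `u_cal`, `u_t`, `u_c`, `Ucx` (all %).
#' @export
combine_budget <- function(u_r, u_day, u_cal, u_t_crm) {
  if (inherits(u_t_crm, "crm_reference")) u_t_crm <- u_t_crm$u_t_rel_pct
  stopifnot(u_r >= 0, u_day >= 0, u_cal >= 0, u_t_crm >= 0)
  u_ip <- sqrt(u_r^2 + u_day^2)
  u_t <- sqrt(u_t_crm^2 + u_ip^2)
  u_c <- sqrt(u_ip^2 + u_t^2 + u_cal^2)
  structure(list(u_r = u_r, u_day = u_day, u_IP = u_ip, u_cal = u_cal,
                 u_t = u_t, u_c = u_c, Ucx = 2 * u_c),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  v <- unlist(x[c("u_r", "u_day", "u_IP", "u_cal", "u_t", "u_c", "Ucx")])
  cat(paste(sprintf("%s = %.1f%%", names(v), v), collapse = ", "), "\n")
  invisible(x)
}

#' Default calibration uncertainty per magnification
#'
#' Relative standard uncertainty of the pixel calibration for the
#' magnifications used in the validation campaigns (cross-grating at low,
#' image-shift at intermediate magnifications). Calibration itself is out
#' of scope; these enter the budget as supplied constants.
#'
#' @param magnification nominal magnification (e.g. 18500).
#' @return u_cal in %.
#' @export
u_cal_default <- function(magnification) {
  tab <- c(`9300` = 0.8, `18500` = 1.0, `30000` = 0.1, `68000` = 0.2)
  key <- as.character(magnification)
  if (!key %in% names(tab))
    stop("no default u_cal for magnification ", magnification,
         "; supply u_cal explicitly")
  unname(tab[key])
}

#' Trueness assessment against a certified reference value
#'
#' Compares the mean measured value with the certified value: the absolute
#' bias `Delta_m = |C_m - C_CRM|` is judged against the expanded combined
#' uncertainty `U_Delta = 2 * sqrt(u_c^2 + u_CRM^2)` (all in nm). No
#' significant bias is concluded when `Delta_m <= U_Delta`.
#'
#' @param C_m mean measured value, nm.
#' @param u_c_nm combined measurement uncertainty of `C_m`, in absolute nm.
#' @param crm a [crm_reference()].
#' @return List: `delta_m_nm`, `u_delta_nm`, `U_delta_nm`,
#'   `no_significant_bias`.
#' @export
trueness <- function(C_m, u_c_nm, crm) {
  stopifnot(inherits(crm, "crm_reference"))
  delta <- abs(C_m - crm$value_nm)
  u_delta <- sqrt(u_c_nm^2 + crm$u_nm^2)
  list(delta_m_nm = delta, u_delta_nm = u_delta, U_delta_nm = 2 * u_delta,
       no_significant_bias = delta <= 2 * u_delta)
}

#' Full intra-laboratory budget from a day x replicate median matrix
#'
#' Convenience chain: [anova_decompose()], [variance_components()],
#' [combine_budget()], and (when a CRM is supplied) [trueness()] with the
#' combined uncertainty converted to absolute nm.
#'
#' @param medians `n_days x n_r` matrix of specimen medians (nm).
#' @param u_cal calibration uncertainty (%).
#' @param u_t_crm relative trueness component (%); or a [crm_reference()],
#'   in which case the trueness verdict is also computed.
#' @return List `decomposition`, `components`, `budget`, `u_c_nm`, and
#'   optionally `trueness`.
#' @export
intra_budget <- function(medians, u_cal, u_t_crm) {
  dec <- anova_decompose(medians)
  comp <- variance_components(dec)
  bud <- combine_budget(comp$u_r, comp$u_day, u_cal, u_t_crm)
  out <- list(decomposition = dec, components = comp, budget = bud,
              u_c_nm = bud$u_c / 100 * dec$C_m)
  if (inherits(u_t_crm, "crm_reference"))
    out$trueness <- trueness(dec$C_m, out$u_c_nm, u_t_crm)
  out
}

#' Ruggedness of the intermediate precision versus particle count
#'
#' Subsamples each specimen pool to `N` particles (without replacement,
#' `n_boot` times), recomputes the specimen medians and the intermediate
#' precision `u_IP` through the ANOVA chain, and averages over the
#' resamples. A piecewise log10-log10 linear regression (single
#' breakpoint, chosen by least total residual) and the overall log-log
#' slope summarize the scaling; the smallest `N` whose mean `u_IP` falls
#' below `target_pct` is reported.
#'
#' @param pools data frame with columns `day`, `replicate`, `value_nm`:
#'   the per-particle pool of every specimen.
#' @param n_grid increasing vector of subsample sizes.
#' @param n_boot resamples per grid point.
#' @param seed RNG seed.
#' @param target_pct precision target in % (default 5).
#' @return List: `curve` (data frame `N`, `u_ip_mean`, `u_ip_sd`),
#'   `slope` (overall log-log slope), `piecewise` (breakpoint and the two
#'   segment slopes), `n_for_target`.
#' @export
ruggedness_curve <- function(pools, n_grid, n_boot = 30, seed = 1L,
                             target_pct = 5) {
  stopifnot(all(c("day", "replicate", "value_nm") %in% names(pools)))
  set.seed(seed)
  spl <- split(pools$value_nm, list(pools$day, pools$replicate), drop = FALSE)
  days <- sort(unique(pools$day)); reps <- sort(unique(pools$replicate))
  n_days <- length(days); n_r <- length(reps)
  pool_min <- min(vapply(spl, length, 1L))
  if (max(n_grid) > pool_min)
    stop("subsample size exceeds the smallest specimen pool (", pool_min, ")")
  u_ip_one <- function(N) {
    M <- matrix(0, n_days, n_r)
    for (i in seq_len(n_days)) for (j in seq_len(n_r)) {
      v <- spl[[paste(days[i], reps[j], sep = ".")]]
      M[i, j] <- stats::median(sample(v, N))
    }
    comp <- variance_components(anova_decompose(M))
    sqrt(comp$u_r^2 + comp$u_day^2)
  }
  curve <- do.call(rbind, lapply(n_grid, function(N) {
    u <- replicate(n_boot, u_ip_one(N))
    data.frame(N = N, u_ip_mean = mean(u), u_ip_sd = stats::sd(u))
  }))
  lx <- log10(curve$N); ly <- log10(curve$u_ip_mean)
  slope <- unname(stats::coef(stats::lm(ly ~ lx))[2])
  piecewise <- fit_piecewise_loglog(lx, ly)
  below <- curve$N[curve$u_ip_mean < target_pct]
  list(curve = curve, slope = slope, piecewise = piecewise,
       n_for_target = if (length(below)) min(below) else NA_integer_)
}

fit_piecewise_loglog <- function(lx, ly) {
  n <- length(lx)
  if (n < 5) {
    return(list(breakpoint = NA_real_,
                slope_left = unname(stats::coef(stats::lm(ly ~ lx))[2]),
                slope_right = NA_real_))
  }
  best <- NULL; best_sse <- Inf
  for (k in 2:(n - 2)) {
    f1 <- stats::lm(ly[1:k] ~ lx[1:k])
    f2 <- stats::lm(ly[(k + 1):n] ~ lx[(k + 1):n])
    sse <- sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- list(breakpoint = 10^mean(lx[k:(k + 1)]),
                   slope_left = unname(stats::coef(f1)[2]),
                   slope_right = unname(stats::coef(f2)[2]))
    }
  }
  best
}

#' Robustness of the median against the analysis mode
#'
#' Analyzes one micrograph with each of the four segmentation modes and
#' tabulates the per-mode median minimal Feret diameter plus all pairwise
#' absolute differences.
#'
#' @param m a [micrograph()].
#' @param params_by_mode named list of [detection_params()], one per mode;
#'   by default the same baseline settings re-used in all four modes.
#' @param limits optional [quantification_limits()].
#' @return List: `medians` (named vector, nm), `n` (particles retained per
#'   mode), `pairwise_diff_nm` (matrix of absolute differences).
#' @export
mode_robustness <- function(m, params_by_mode = NULL, limits = NULL) {
  modes <- c("default", "irregular_watershed", "ellipse_fitting",
             "single_particle")
  if (is.null(params_by_mode)) {
    params_by_mode <- lapply(modes, function(md) detection_params(mode = md))
    names(params_by_mode) <- modes
  }
  res <- lapply(modes, function(md) {
    a <- analyze_micrograph(m, params_by_mode[[md]], limits = limits,
                            image_id = md)
    if (nrow(a$retained) == 0) return(list(median = NA_real_, n = 0L))
    list(median = median_min_feret(a$retained$min_feret_nm),
         n = nrow(a$retained))
  })
  med <- vapply(res, `[[`, 0, "median")
  names(med) <- modes
  d <- abs(outer(med, med, "-"))
  list(medians = med, n = vapply(res, `[[`, 0L, "n"), pairwise_diff_nm = d)
}
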