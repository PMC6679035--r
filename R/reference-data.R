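#' Reference tables from the multi-partner validation campaigns
#'
#' Small CSV tables shipped with the package: the imaging specifications
#' and working-range limits per material/magnification
#' (`"imaging_specs"`), the per-partner intra-laboratory uncertainty
#' budgets (`"intralab_budget"`), the modal-ECD trueness assessment
#' against the silica reference materials (`"trueness"`), and the
#' interlaboratory precision summary (`"interlab"`). Values are reported
#' at the precision they were published at; the closure checks below
#' verify that the package's formulas reproduce them.
#'
#' @param name which table.
#' @return Data frame.
#' @export
validation_reference <- function(name = c("imaging_specs", "intralab_budget",
                                          "trueness", "interlab")) {
  name <- match.arg(name)
  file <- c(imaging_specs = "imaging_specs.csv",
            intralab_budget = "intralab_budget.csv",
            trueness = "trueness_reference.csv",
            interlab = "interlab_performance.csv")[[name]]
  path <- system.file("extdata", file, package = "temsizer")
  if (path == "") stop("reference table not found: ", file)
  utils::read.csv(path, check.names = FALSE)
}

# a printed value x rounded to `digits` is compatible with a recomputed
# interval [lo, hi] when the rounding intervals overlap
interval_compatible <- function(printed, lo, hi, digits = 1) {
  half <- 0.5 * 10^(-digits)
  printed >= lo - half - 1e-12 & printed <= hi + half + 1e-12
}

# recompute an increasing function of rounded inputs over their rounding
# intervals; returns cbind(lo, hi)
interval_apply <- function(f, ..., digits = 1) {
  half <- 0.5 * 10^(-digits)
  args <- list(...)
  lo <- do.call(f, lapply(args, function(a) pmax(a - half, 0)))
  hi <- do.call(f, lapply(args, function(a) a + half))
  cbind(lo = lo, hi = hi)
}

#' Closure of the published working-range limits
#'
#' Recomputes LOD, LLOQ and ULOQ for every material/magnification row of
#' the imaging-specification table from the field of view and camera size
#' alone, and compares with the published values after rounding to the
#' published precision (two decimals for LOD, one for LLOQ/ULOQ).
#'
#' @return Data frame with recomputed values and logical `*_ok` columns.
#' @export
working_range_closure <- function() {
  tab <- validation_reference("imaging_specs")
  lim <- lapply(seq_len(nrow(tab)), function(i)
    quantification_limits(tab$fov_nm[i], tab$n_pixels[i]))
  lod <- vapply(lim, `[[`, 0, "lod_nm")
  lloq <- vapply(lim, `[[`, 0, "lloq_nm")
  uloq <- vapply(lim, `[[`, 0, "uloq_nm")
  data.frame(tab[c("material", "magnification")],
             lod_recomputed = round(lod, 2),
             lloq_recomputed = round(lloq, 1),
             uloq_recomputed = round(uloq, 1),
             lod_ok = round(lod, 2) == tab$lod_nm,
             lloq_ok = round(lloq, 1) == tab$lloq_nm,
             uloq_ok = round(uloq, 1) == tab$uloq_nm)
}

#' Closure of the published uncertainty budgets
#'
#' For every partner/material column of the intra-laboratory budget table,
#' recomputes the quadrature chain from the published components --
#' `u_IP` from (`u_r`, `u_day`), `u_c` from (`u_IP`, `u_t`, `u_cal`),
#' `Ucx = 2 u_c` -- and checks compatibility with the published value.
#' Because the published inputs are themselves rounded to one decimal,
#' compatibility is assessed on the interval the chain can reach over the
#' input rounding intervals.
#'
#' @return Data frame with one row per budget column: recomputed central
#'   values, deviations, and `uip_ok`, `uc_ok`, `ucx_ok`.
#' @export
budget_closure <- function() {
  tab <- validation_reference("intralab_budget")
  q2 <- function(a, b) sqrt(a^2 + b^2)
  q3 <- function(a, b, c) sqrt(a^2 + b^2 + c^2)
  uip <- q2(tab$u_r_pct, tab$u_day_pct)
  uip_iv <- interval_apply(q2, tab$u_r_pct, tab$u_day_pct)
  uc <- q3(tab$u_IP_pct, tab$u_t_pct, tab$u_cal_pct)
  uc_iv <- interval_apply(q3, tab$u_IP_pct, tab$u_t_pct, tab$u_cal_pct)
  ucx <- 2 * tab$u_c_pct
  ucx_iv <- interval_apply(function(x) 2 * x, tab$u_c_pct)
  data.frame(tab[c("material", "magnification", "partner")],
             uip_recomputed = uip, uip_dev = uip - tab$u_IP_pct,
             uc_recomputed = uc, uc_dev = uc - tab$u_c_pct,
             ucx_recomputed = ucx, ucx_dev = ucx - tab$Ucx_pct,
             uip_ok = interval_compatible(tab$u_IP_pct, uip_iv[, 1], uip_iv[, 2]),
             uc_ok = interval_compatible(tab$u_c_pct, uc_iv[, 1], uc_iv[, 2]),
             ucx_ok = interval_compatible(tab$Ucx_pct, ucx_iv[, 1], ucx_iv[, 2]))
}

#' Closure of the published trueness assessment
#'
#' Recomputes `Delta_m`, `u_Delta` and `U_Delta` for the four reference
#' rows from the published means and uncertainties via [trueness()], and
#' evaluates the bias verdict.
#'
#' @return Data frame with recomputed values, `*_ok` columns and the
#'   `no_significant_bias` verdict per row.
#' @export
trueness_closure <- function() {
  tab <- validation_reference("trueness")
  res <- lapply(seq_len(nrow(tab)), function(i)
    trueness(tab$C_m_nm[i], tab$u_c_nm[i],
             crm_reference(tab$C_crm_nm[i], tab$u_crm_nm[i])))
  dm <- vapply(res, `[[`, 0, "delta_m_nm")
  ud <- vapply(res, `[[`, 0, "u_delta_nm")
  Ud <- vapply(res, `[[`, 0, "U_delta_nm")
  data.frame(tab[c("material", "magnification")],
             delta_recomputed = round(dm, 1), u_delta_recomputed = round(ud, 1),
             U_delta_recomputed = round(Ud, 1),
             delta_ok = round(dm, 1) == tab$delta_m_nm,
             u_delta_ok = round(ud, 1) == tab$u_delta_nm,
             U_delta_ok = round(Ud, 1) == tab$U_delta_nm,
             no_significant_bias = vapply(res, `[[`, TRUE,
                                          "no_significant_bias"))
}

#' Closure of the published interlaboratory precision limits
#'
#' Checks `r = 2.8 S_r`, `R = 2.8 S_R`, `RSD_r = 100 S_r / X_obs` and
#' `RSD_R = 100 S_R / X_obs` against the published cells, over the
#' rounding intervals of the published inputs.
#'
#' @return Data frame with recomputed central values and `*_ok` columns.
#' @export
interlab_closure <- function() {
  tab <- validation_reference("interlab")
  dig_s <- ifelse(tab$material == "Gold nanorods", 2, 1)  # X_obs printed finer there
  lim <- function(s) 2.8 * s
  rsd <- function(s, x) 100 * s / x
  half1 <- 0.05
  r_iv <- interval_apply(lim, tab$S_r_nm)
  R_iv <- interval_apply(lim, tab$S_R_nm)
  rsdr_lo <- rsd(tab$S_r_nm - half1, tab$X_obs_nm + 0.5 * 10^(-dig_s))
  rsdr_hi <- rsd(tab$S_r_nm + half1, tab$X_obs_nm - 0.5 * 10^(-dig_s))
  rsdR_lo <- rsd(tab$S_R_nm - half1, tab$X_obs_nm + 0.5 * 10^(-dig_s))
  rsdR_hi <- rsd(tab$S_R_nm + half1, tab$X_obs_nm - 0.5 * 10^(-dig_s))
  data.frame(tab["material"],
             r_recomputed = lim(tab$S_r_nm), R_recomputed = lim(tab$S_R_nm),
             rsdr_recomputed = rsd(tab$S_r_nm, tab$X_obs_nm),
             rsdR_recomputed = rsd(tab$S_R_nm, tab$X_obs_nm),
             r_ok = interval_compatible(tab$r_nm, r_iv[, 1], r_iv[, 2]),
             R_ok = interval_compatible(tab$R_nm, R_iv[, 1], R_iv[, 2]),
             rsdr_ok = interval_compatible(tab$RSD_r_pct, rsdr_lo, rsdr_hi),
             rsdR_ok = interval_compatible(tab$RSD_R_pct, rsdR_lo, rsdR_hi))
}
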