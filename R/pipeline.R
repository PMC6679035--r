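#' Simulate a complete intra-laboratory validation dataset
#'
#' Generates the nested design of a validation campaign: `n_days`
#' measurement days, `n_r` replicate specimens per day, `n_images` images
#' per specimen, all drawn from the same scene specification with
#' per-image seeds derived from `seed`. An optional relative day effect
#' perturbs the size law median between days (emulating day-to-day
#' preparation variability).
#'
#' @param spec a [scene_spec()] describing one image.
#' @param n_days,n_r,n_images design dimensions.
#' @param day_effect_sd relative standard deviation of the day-level size
#'   shift (0 = none).
#' @param seed master seed.
#' @return List of records `list(micrograph, truth, day, replicate,
#'   image)`.
#' @export
simulate_validation_dataset <- function(spec, n_days = 5, n_r = 3,
                                        n_images = 2, day_effect_sd = 0,
                                        seed = 1L) {
  set.seed(seed)
  day_shift <- stats::rnorm(n_days, 0, day_effect_sd)
  out <- list()
  k <- 0L
  for (d in seq_len(n_days)) for (r in seq_len(n_r)) for (i in seq_len(n_images)) {
    k <- k + 1L
    sp <- spec
    if (day_effect_sd > 0) {
      if (sp$size_law$family == "constant")
        sp$size_law$value <- sp$size_law$value * (1 + day_shift[d])
      else if (sp$size_law$family == "lognormal")
        sp$size_law$median <- sp$size_law$median * (1 + day_shift[d])
      else sp$size_law$mean <- sp$size_law$mean * (1 + day_shift[d])
    }
    sp$seed <- as.integer((seed * 10000L + d * 1000L + r * 100L + i) %% .Machine$integer.max)
    sc <- simulate_scene(sp)
    out[[k]] <- list(micrograph = sc$micrograph, truth = sc$truth,
                     day = d, replicate = r, image = i)
  }
  out
}

#' Run the intra-laboratory sizing pipeline on a dataset
#'
#' Per-image detection and measurement, per-specimen pooling (all images
#' of one day/replicate), the day x replicate median matrix, and the full
#' uncertainty budget. The dataset is either in memory (a list as
#' returned by [simulate_validation_dataset()], or any list of records
#' with `micrograph`, `day`, `replicate`) or a directory with layout
#' `dayD/repR/*.tif` under `image_dir` (with `pixel_size_nm` supplied).
#'
#' @param dataset in-memory dataset, or `NULL` when `image_dir` is given.
#' @param params a [detection_params()].
#' @param u_cal calibration uncertainty (%).
#' @param crm optional [crm_reference()]; enables the trueness verdict.
#' @param u_t_crm relative trueness component (%); defaults to the CRM's
#'   own, and must be given when no CRM is supplied.
#' @param image_dir directory of TIFF images laid out as `dayD/repR/`.
#' @param pixel_size_nm calibration for images read from `image_dir`.
#' @return List: `specimens` (per-specimen summary data frame), `medians`
#'   (day x replicate matrix), `validation` (see [intra_budget()]),
#'   `filter_log` (summed rejection counts), `params`.
#' @export
run_pipeline <- function(dataset = NULL, params = detection_params(),
                         u_cal = 1.0, crm = NULL, u_t_crm = NULL,
                         image_dir = NULL, pixel_size_nm = NULL) {
  if (is.null(dataset)) {
    if (is.null(image_dir) || is.null(pixel_size_nm))
      stop("give either an in-memory dataset or image_dir + pixel_size_nm")
    dataset <- read_image_tree(image_dir, pixel_size_nm)
  }
  key <- vapply(dataset, function(d) paste(d$day, d$replicate, sep = "/"), "")
  groups <- split(dataset, key)
  filter_log <- NULL
  specimens <- list()
  for (g in names(groups)) {
    recs <- list()
    for (d in groups[[g]]) {
      a <- analyze_micrograph(d$micrograph, params,
                              image_id = paste(g, d$image %||% "", sep = "/"))
      recs[[length(recs) + 1L]] <- a$retained
      filter_log <- if (is.null(filter_log)) a$log else filter_log + a$log
    }
    pooled <- do.call(rbind, recs)
    dr <- groups[[g]][[1]]
    if (is.null(pooled) || nrow(pooled) == 0)
      stop("no particles survive filters for specimen day ", dr$day,
           " replicate ", dr$replicate)
    specimens[[g]] <- summarize_specimen(pooled, day = dr$day,
                                         replicate = dr$replicate)
  }
  spec_df <- do.call(rbind, specimens)
  spec_df <- spec_df[order(spec_df$day, spec_df$replicate), ]
  days <- sort(unique(spec_df$day)); reps <- sort(unique(spec_df$replicate))
  M <- matrix(NA_real_, length(days), length(reps),
              dimnames = list(paste0("day", days), paste0("rep", reps)))
  for (i in seq_len(nrow(spec_df)))
    M[match(spec_df$day[i], days), match(spec_df$replicate[i], reps)] <-
      spec_df$median_min_feret_nm[i]
  if (is.null(u_t_crm)) {
    if (is.null(crm)) stop("supply u_t_crm (or a crm) for the budget")
    u_t_crm <- crm
  }
  validation <- intra_budget(M, u_cal, if (!is.null(crm)) crm else u_t_crm)
  list(specimens = spec_df, medians = M, validation = validation,
       filter_log = filter_log, params = params)
}

read_image_tree <- function(image_dir, pixel_size_nm) {
  days <- list.dirs(image_dir, recursive = FALSE)
  out <- list()
  for (dd in days) {
    d <- as.integer(gsub("\\D", "", basename(dd)))
    reps <- list.dirs(dd, recursive = FALSE)
    if (is.na(d) || !length(reps))
      stop("expected layout dayD/repR/*.tif under ", image_dir)
    for (rr in reps) {
      r <- as.integer(gsub("\\D", "", basename(rr)))
      files <- list.files(rr, pattern = "\\.(tif|tiff|png)$", full.names = TRUE)
      for (i in seq_along(files)) {
        out[[length(out) + 1L]] <- list(
          micrograph = read_micrograph(files[i], pixel_size_nm = pixel_size_nm),
          day = d, replicate = r, image = i)
      }
    }
  }
  if (!length(out)) stop("no images found under ", image_dir)
  out
}

#' Export a validation report as JSON (plus a readable summary)
#'
#' Stable field names; raw values are preserved, display rounding is left
#' to the reader. Empty optional sections are omitted.
#'
#' @param result a [run_pipeline()] result (or any list of the same
#'   shape).
#' @param path output JSON path; `NULL` returns the report list only.
#' @return Invisibly, the report list.
#' @export
export_report <- function(result, path = NULL) {
  v <- result$validation
  rep <- list(
    specimens = result$specimens,
    medians_nm = result$validation$decomposition$C_m,
    budget = unclass(v$budget),
    u_c_nm = v$u_c_nm,
    anova = list(C_m = v$decomposition$C_m, sd = v$decomposition$sd,
                 MS_within = v$decomposition$MS_within,
                 MS_between = v$decomposition$MS_between,
                 df_within = v$decomposition$df_within)
  )
  if (!is.null(v$trueness)) rep$trueness <- v$trueness
  if (!is.null(result$filter_log)) rep$filter_log <- as.list(result$filter_log)
  rep <- rep[!vapply(rep, is.null, TRUE)]
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(rep)
}
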