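make_table <- function(values_by_lab, reps = NULL) {
  do.call(rbind, lapply(seq_along(values_by_lab), function(i) {
    v <- values_by_lab[[i]]
    data.frame(lab = sprintf("L%02d", i), replicate = seq_along(v), value_nm = v)
  }))
}

test_that("Cochran critical values match the published 5 % table point", {
  # 5 labs, 3 replicates each (nu = 2): tabulated value 0.6838
  expect_equal(cochran_critical(0.05, 5, 2), 0.6838, tolerance = 1e-4)
})

test_that("the Cochran statistic and classification behave as specified", {
  # identical variances: C = 1/5, comfortably ok
  tbl <- make_table(lapply(1:5, function(i) c(0, 1) + i * 10))
  f <- cochran_test(tbl)
  expect_equal(f$statistic, 0.2)
  expect_equal(f$classification, "ok")

  # one lab with variance 100 among eight with variance 1
  set.seed(2)
  vals <- lapply(1:9, function(i) {
    s <- if (i == 5) 10 else 1
    c(-s, s) / sqrt(2) + 20   # sample variance exactly s^2
  })
  f2 <- cochran_test(make_table(vals))
  expect_equal(f2$statistic, 100 / 108, tolerance = 1e-12)
  expect_equal(f2$lab, "L05")
  expect_equal(f2$classification, "outlier")

  # a zero-variance lab is never the Cochran maximum
  vals3 <- lapply(1:6, function(i) if (i == 1) c(20, 20) else 20 + c(-1, 1) * i / 10)
  f3 <- cochran_test(make_table(vals3))
  expect_false(f3$lab == "L01")
})

test_that("the single Grubbs test matches hand computation and the t-based critical value", {
  expect_equal(grubbs_critical(0.01, 5), 1.764, tolerance = 1e-3)
  tbl <- make_table(lapply(c(10, 10, 10, 10, 100), function(v) c(v, v)))
  f <- grubbs_tests(tbl)
  gm <- f[f$test == "grubbs_mean", ]
  expect_equal(gm$statistic, (100 - 28) / stats::sd(c(10, 10, 10, 10, 100)),
               tolerance = 1e-12)
  expect_equal(gm$statistic, 1.789, tolerance = 1e-3)
  expect_equal(gm$classification, "outlier")
  expect_equal(gm$lab, "L05")

  # symmetric small set: G = 1, unflagged
  tbl2 <- make_table(lapply(c(1, 2, 3), function(v) c(v, v)))
  f2 <- grubbs_tests(tbl2)
  expect_equal(f2[f2$test == "grubbs_mean", "statistic"], 1)
  expect_equal(f2[f2$test == "grubbs_mean", "classification"], "ok")
})

test_that("the internal Grubbs test flags a single gross replicate only", {
  set.seed(4)
  vals <- lapply(1:8, function(i) 20 + stats::rnorm(15, 0, 0.3))
  vals[[3]][7] <- 35
  f <- grubbs_tests(make_table(vals))
  gi <- f[f$test == "grubbs_internal" & f$classification == "outlier", ]
  expect_equal(nrow(gi), 1)
  expect_equal(gi$lab, "L03")
  expect_equal(gi$replicate, 7L)
})

test_that("double-Grubbs critical values and flags behave sensibly", {
  c1 <- double_grubbs_critical(0.01, 10)
  c5 <- double_grubbs_critical(0.05, 10)
  expect_lt(c1, c5)       # smaller statistic = more extreme pair
  expect_gt(c1, 0); expect_lt(c5, 1)
  # two coincident far-out labs escape the single test but not the double
  vals <- lapply(c(10, 10.2, 9.9, 10.1, 10, 9.8, 30, 30), function(v) v + c(-0.05, 0.05))
  f <- grubbs_tests(make_table(vals))
  dg <- f[f$test == "grubbs_double" & f$classification == "outlier", ]
  expect_setequal(dg$lab, c("L07", "L08"))
})

test_that("the outlier workflow is the identity on homogeneous tables", {
  set.seed(6)
  vals <- lapply(1:10, function(i) 20 + stats::rnorm(5, 0, 0.5))
  tbl <- make_table(vals)
  wf <- outlier_workflow(tbl)
  expect_identical(wf$cleaned, tbl)
  expect_length(wf$excluded_labs, 0)
  expect_equal(nrow(wf$excluded_replicates), 0)
})

test_that("the workflow excludes a variance outlier and a shifted-mean lab", {
  set.seed(7)
  vals <- lapply(1:12, function(i) 20 + stats::rnorm(5, 0, 0.3))
  vals[[2]] <- 20 + stats::rnorm(5, 0, 6)   # inflated variance (Cochran)
  vals[[9]] <- 28 + stats::rnorm(5, 0, 0.3) # shifted mean (Grubbs)
  wf <- outlier_workflow(make_table(vals))
  expect_setequal(wf$excluded_labs, c("L02", "L09"))
  expect_true(all(c("cochran", "grubbs_mean") %in%
                    wf$log$test[wf$log$applied]))
})

test_that("a 19-lab study with two constructed outliers retains 17 laboratories", {
  set.seed(8)
  vals <- lapply(1:19, function(i) 17.4 + stats::rnorm(15, 0, 0.3))
  vals[[1]] <- 19.5 + stats::rnorm(15, 0, 0.3)   # mean outlier
  vals[[17]] <- 17.4 + stats::rnorm(15, 0, 3)    # variance outlier
  ev <- interlab_evaluation(make_table(vals))
  expect_equal(ev$summary$n_labs, 17)
  expect_setequal(ev$outliers$excluded_labs, c("L01", "L17"))
  expect_equal(ev$summary$X_obs, 17.4, tolerance = 0.05)
})

test_that("ISO precision summary closes on published cells and degenerate input", {
  # published NM-100 cells: S_r = 4.7 nm, X_obs = 97.4 nm
  expect_equal(round(2.8 * 4.7, 1), 13.2)
  expect_equal(round(100 * 4.7 / 97.4, 1), 4.8)
  ic <- interlab_closure()
  expect_true(all(ic$r_ok))
  expect_true(all(ic$R_ok))
  expect_true(all(ic$rsdr_ok))
  expect_true(all(ic$rsdR_ok))

  tbl <- make_table(lapply(1:5, function(i) rep(20, 4)))
  s <- iso_summary(tbl)
  expect_equal(s$S_r, 0)
  expect_equal(s$S_R, 0)
  expect_equal(s$RSD_r, 0)
})

test_that("the limit factors r/S_r and R/S_R are exactly 2.8", {
  set.seed(9)
  tbl <- make_table(lapply(1:8, function(i) 20 + i / 5 + stats::rnorm(4, 0, 0.4)))
  s <- iso_summary(tbl)
  expect_equal(s$r / s$S_r, 2.8)
  expect_equal(s$R / s$S_R, 2.8)
  expect_gte(s$S_R, s$S_r)
})

test_that("variance components are recovered from a simulated interlab study", {
  set.seed(10)
  n_sim <- 300
  sr <- sR <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    lab_eff <- stats::rnorm(15, 0, 2)
    vals <- lapply(1:15, function(l) 20 + lab_eff[l] + stats::rnorm(15, 0, 1))
    s <- iso_summary(make_table(vals))
    sr[i] <- s$S_r^2; sR[i] <- s$S_R^2
  }
  expect_lt(abs(mean(sr) - 1), 3 * stats::sd(sr) / sqrt(n_sim))
  expect_lt(abs(mean(sR) - 5), 3 * stats::sd(sR) / sqrt(n_sim))
})

test_that("removing a flagged outlier does not increase the reproducibility spread", {
  set.seed(11)
  vals <- lapply(1:10, function(i) 20 + stats::rnorm(5, 0, 0.3))
  vals[[4]] <- 26 + stats::rnorm(5, 0, 0.3)
  tbl <- make_table(vals)
  before <- iso_summary(tbl)$S_R
  wf <- outlier_workflow(tbl)
  after <- iso_summary(wf$cleaned)$S_R
  expect_lte(after, before)
})

test_that("tables with too few laboratories are rejected", {
  tbl <- make_table(list(c(1, 2), c(2, 3)))
  expect_error(iso_summary(tbl), "at least 3")
})
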