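meta_std <- acq_meta(0.5, 0.11, 10)

test_that("QC applies the intensity windows and channel ordering", {
  cells <- list(stub_qc_cell("a", 150, 300),   # pass
                stub_qc_cell("b", 250, 300),   # green out of range
                stub_qc_cell("c", 190, 180),   # red out of range and <= green
                stub_qc_cell("d", 150, 201),   # pass
                stub_qc_cell("e", 139.9, 250)) # green out of range
  qc <- qc_filter(cells)
  expect_equal(vapply(qc$passing, function(c) c$cell_id, character(1)),
               c("a", "d"))
  expect_equal(qc$failing$cell_id, c("b", "c", "e"))
  expect_match(qc$failing$reason[1], "green i0 out of range")
  expect_match(qc$failing$reason[2], "red i0 out of range")
  expect_match(qc$failing$reason[2], "red i0 <= green")
  # the ordering requirement can be dropped
  qc2 <- qc_filter(list(stub_qc_cell("f", 190, 200)),
                   red_range = c(150, 400), require_red_gt_green = FALSE)
  expect_equal(length(qc2$passing), 1)
})

test_that("final-FMR clustering forms contiguous rank quartiles", {
  mk <- function(id, final) stub_curve_cell(id, meta_std,
                                            c(rep(0, 10), seq(0, final, length.out = 10)))
  cells <- lapply(1:8, function(i) mk(letters[i], i / 10))
  cl <- cluster_by_final_fmr(cells, "green", 4)
  expect_equal(cl$assignments$cluster, rep(1:4, each = 2))
  expect_equal(cl$assignments$cell_id[1:2], c("h", "g"))  # top final FMR
  expect_equal(cl$ranges$n, rep(2L, 4))
  # remainder rule: 10 cells -> sizes 3,3,2,2
  cells10 <- lapply(1:10, function(i) mk(paste0("c", i), i / 11))
  cl10 <- cluster_by_final_fmr(cells10, "green", 4)
  expect_equal(cl10$ranges$n, c(3L, 3L, 2L, 2L))
  # ranges partition the observed values without overlap
  r <- cl10$ranges
  expect_true(all(r$fmr_min[-4] >= r$fmr_max[-1]))
  expect_error(cluster_by_final_fmr(cells[1:3], "green", 4), "at least k")
})

test_that("heatmap ordering sorts by windowed mean FMR, stable on ties", {
  mk <- function(id, lvl) stub_curve_cell(id, meta_std, rep(lvl, 160))
  cells <- list(mk("lo", 0.1), mk("hi", 0.9), mk("mid", 0.5))
  expect_equal(heatmap_order(cells, "green", c(15, 150)), c(2, 3, 1))
  short <- list(mk("a", 0.4), mk("b", 0.4))
  short <- lapply(short, function(c) {
    c$green$curve$fmr <- c$green$curve$fmr[1:100]
    c$green$curve$time_s <- c$green$curve$time_s[1:100]
    c
  })
  expect_warning(ord <- heatmap_order(short, "green", c(15, 150)), "clamped")
  expect_equal(ord, c(1, 2))  # equal means keep input order
})

test_that("linear fits agree with the normal-equations oracle", {
  x <- 1:10
  f <- fit_linear(x, 2 * x + 1)
  expect_equal(f$slope, 2); expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  expect_equal(fit_linear(x, rep(3, 10))$r_squared, 0)
  expect_error(fit_linear(rep(1, 5), 1:5), "constant")
  expect_error(fit_linear(1:2, 1:2), "at least 3")
  set.seed(13)
  for (i in 1:10) {
    x <- stats::rnorm(50); y <- stats::rnorm(50, sd = 2) + 0.5 * x
    got <- fit_linear(x, y); want <- oracle_ols(x, y)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
  }
})

test_that("scatter analyses fit planted relations and exclude undefined cells", {
  set.seed(17)
  n <- 30
  cells <- lapply(seq_len(n), function(i) {
    i0 <- stats::runif(1, 140, 200)
    # plant t50 linear in i0 by shaping the FMR ramp
    t50 <- 0.05 * i0
    ramp <- pmin(1, pmax(0, (seq(0, 74.5, by = 0.5) + 0.25) / (2 * t50)))
    stub_curve_cell(paste0("c", i), meta_std, c(rep(0, 10), ramp),
                    i0_green = i0, i0_red = 300 + i,
                    area = 2000 + 10 * i)
  })
  sc <- intensity_kinetics_scatter(cells, "green", "t50")
  expect_gt(sc$fit$r_squared, 0.95)
  expect_equal(sc$n_excluded, 0)
  # nuclear size here is collinear with nothing: planted null
  ns <- nuclear_size_scatter(cells, "green", "final_fmr")
  expect_equal(ns$fit$r_squared, 0)  # final FMR constant 1 -> R^2 defined 0
  # undefined t50 cells are dropped and counted
  cells[[1]]$green$curve$t50 <- NA_real_
  sc2 <- intensity_kinetics_scatter(cells, "green", "t50")
  expect_equal(sc2$n_excluded, 1)
  expect_equal(nrow(sc2$points), n - 1)
  expect_error(intensity_kinetics_scatter(cells[2:3], "green"), "too few")
})

test_that("cross-channel scatter detects planted dependence and null", {
  set.seed(19)
  cells <- lapply(1:25, function(i) {
    i0g <- stats::runif(1, 140, 200)
    t50r <- 0.1 * i0g
    ramp <- pmin(1, pmax(0, (seq(0, 74.5, by = 0.5) + 0.25) / (2 * t50r)))
    stub_curve_cell(paste0("c", i), meta_std,
                    fmr_green = c(rep(0, 10), rep(1, 150)),
                    fmr_red = c(rep(0, 10), ramp), i0_green = i0g)
  })
  scx <- cross_correlation_scatter(cells, "green", "red", "t50")
  expect_gt(scx$fit$r_squared, 0.95)
})

test_that("FMR ratio masks early frames and averages across cells", {
  cells <- list(stub_curve_cell("a", acq_meta(0.5, 0.11, 1),
                                fmr_green = c(0, 0.5, 1),
                                fmr_red = c(0, 0.25, 1)))
  rt <- fmr_ratio(cells, "red", "green", start = 1, delta = 0.05)
  expect_equal(rt$ratio[1, ], c(NA, 0.5, 1))
  expect_equal(rt$n, c(0, 1, 1))
  # a channel against itself is exactly 1 wherever defined
  set.seed(23)
  cells2 <- lapply(1:5, function(i)
    stub_curve_cell(paste0("c", i), meta_std,
                    c(rep(0, 10), pmin(1, seq(0.01, 1.5, length.out = 150)))))
  self <- fmr_ratio(cells2, "green", "green")
  expect_true(all(self$ratio[!is.na(self$ratio)] == 1))
  expect_true(all(self$mean[self$n > 0] == 1))
  # denominator below delta everywhere
  tiny <- list(stub_curve_cell("z", acq_meta(0.5, 0.11, 1),
                               fmr_green = c(0, 0.01, 0.02),
                               fmr_red = c(0, 0.5, 1)))
  expect_error(fmr_ratio(tiny, "red", "green"), "no unmasked")
})

test_that("mean/SEM curves match the direct formula", {
  mk <- function(id, v) stub_curve_cell(id, acq_meta(0.5, 0.11, 1), v)
  same <- lapply(1:4, function(i) mk(paste0("s", i), c(0, 0.5, 1)))
  ms <- mean_sem_curves(same, "green", "fmr")
  expect_equal(ms$sem, rep(0, 3))
  two <- list(mk("a", c(0, 0, 0)), mk("b", c(2, 2, 2)))
  ms2 <- mean_sem_curves(two, "green", "fmr")
  expect_equal(ms2$mean, rep(1, 3))
  expect_equal(ms2$sem, rep(1, 3))  # sd = sqrt(2), n = 2
  set.seed(29)
  vals <- matrix(stats::rnorm(50 * 20), 50, 20)
  cells <- lapply(1:50, function(i) mk(paste0("r", i), vals[i, ]))
  ms3 <- mean_sem_curves(cells, "green", "fmr")
  expect_equal(ms3$mean, colMeans(vals), tolerance = 1e-12)
  expect_equal(ms3$sem, apply(vals, 2, stats::sd) / sqrt(50), tolerance = 1e-12)
})

test_that("t50 pairs exclude cells missing either channel", {
  mk <- function(id, fg, fr) stub_curve_cell(id, acq_meta(0.5, 0.11, 1), fg, fr)
  cells <- list(mk("a", c(0, 0.6, 1), c(0, 0.4, 1)),
                mk("b", c(0, 0.6, 1), c(0, 0.1, 0.2)),  # red never recruits
                mk("c", c(0, 0.7, 1), c(0, 0.9, 1)))
  tp <- t50_scatter(cells)
  expect_equal(tp$cell_id, c("a", "c"))
  expect_equal(attr(tp, "n_excluded"), 1)
  expect_equal(nrow(t50_scatter(list())), 0)
})
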