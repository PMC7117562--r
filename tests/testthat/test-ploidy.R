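test_that("modal IOD: constants, scale equivariance, ties to the lower bin", {
  expect_equal(modal_iod(rep(120, 30)), 120)
  # mode of {0.9, 1, 1, 1, 1.1} * c is 1 * c at any slide calibration c
  for (c in c(1, 7, 120)) {
    expect_equal(suppressWarnings(
      modal_iod(c(0.9, 1, 1, 1, 1.1) * c, bin_width = 0.05 * c)), 1 * c)
  }
  # two equally heavy bins: the lower center wins
  expect_equal(suppressWarnings(
    modal_iod(c(1.0, 1.0, 1.3, 1.3), bin_width = 0.1)), 1.0)
  expect_error(modal_iod(numeric(0)), "empty")
})

test_that("modal IOD lands on the heavier component of a mixture", {
  # two-component normal mixture, heavier component centered at 100; the
  # oracle evaluates the mixture density on a dense grid
  dens <- function(x) 0.7 * dnorm(x, 100, 5) + 0.3 * dnorm(x, 200, 5)
  grid <- seq(50, 250, by = 0.01)
  true_mode <- grid[which.max(dens(grid))]
  expect_equal(true_mode, 100, tolerance = 1e-3)
  set.seed(41)
  n <- 1000
  comp <- runif(n) < 0.7
  draws <- ifelse(comp, rnorm(n, 100, 5), rnorm(n, 200, 5))
  w <- 0.05 * median(draws)
  expect_lt(abs(modal_iod(draws) - true_mode), w + 1e-9)
})

test_that("DI normalization is exact and invariant to global rescaling", {
  expect_identical(compute_di(123.456, 123.456), 1)
  expect_equal(compute_di(c(100, 200, 250), 100), c(1, 2, 2.5))
  set.seed(42)
  ctrl <- rnorm(30, 400, 12)
  epi <- rnorm(100, 520, 40)
  di1 <- compute_di(epi, suppressWarnings(modal_iod(ctrl)))
  for (c in c(0.2, 3, 1e3)) {
    di2 <- compute_di(epi * c, suppressWarnings(modal_iod(ctrl * c)))
    expect_equal(di2, di1, tolerance = 1e-12)
  }
  expect_error(compute_di(1, 0), "positive")
})

test_that("DI histogram conserves counts and bins half-open", {
  h <- build_histogram(rep(0.97, 150), bin_width = 0.05)
  expect_equal(sum(h$counts), 150L)
  expect_equal(h$bin_centers[which.max(h$counts)], 0.95)
  # a value exactly on an interior edge joins the upper bin:
  # 0.975 sits on the edge between bins centered 0.95 and 1.00
  h2 <- build_histogram(0.975, bin_width = 0.05)
  expect_equal(h2$bin_centers[h2$counts == 1L], 1.00)
  # counting oracle: assign every value by explicit edge comparison
  set.seed(43)
  vals <- runif(500, 0.2, 2.8)
  h3 <- build_histogram(vals, bin_width = 0.05)
  want <- integer(length(h3$counts))
  for (v in vals) {
    k <- which(v >= h3$bin_edges[-length(h3$bin_edges)] &
                 v < h3$bin_edges[-1])
    want[k] <- want[k] + 1L
  }
  expect_equal(h3$counts, want)
  expect_equal(sum(h3$counts), 500L)
  expect_error(build_histogram(1, bin_width = 0), "positive")
})

test_that("histogram range always covers 2N through 4N", {
  h <- build_histogram(c(0.9, 1.0, 1.1))
  expect_gte(max(h$bin_centers), 3)
  h2 <- build_histogram(c(0.9, 4.2))
  expect_gte(max(h2$bin_centers), 4.2 - 0.05)
})

test_that("peak DI finds the histogram maximum, ties toward lower DI", {
  h <- build_histogram(c(rep(0.95, 80), rep(1.2, 40)))
  expect_equal(peak_di(h), 0.95)
  h_tie <- build_histogram(c(rep(0.9, 50), rep(1.3, 50)))
  expect_equal(peak_di(h_tie), 0.9)
  # mode recovery from a stated unimodal density, against a grid oracle
  grid <- seq(0.5, 2.5, by = 1e-3)
  true_mode <- grid[which.max(dnorm(grid, 1.2, 0.1))]
  set.seed(44)
  draws <- rnorm(10000, 1.2, 0.1)
  pk <- peak_di(build_histogram(draws, bin_width = 0.05))
  expect_lt(abs(pk - true_mode), 0.05 + 1e-9)
  expect_error(peak_di(structure(list(counts = c(0L, 0L)),
                                 class = "di_histogram")), "zero")
})

test_that("ploidy classification matches published calls and is monotone", {
  expect_equal(classify_ploidy(0.95), "diploid")
  expect_equal(classify_ploidy(1.22), "mild")
  expect_equal(classify_ploidy(1.46), "moderate")
  # DI > 1.1 is strict: 1.10 itself stays diploid
  expect_equal(classify_ploidy(1.10), "diploid")
  expect_equal(classify_ploidy(1.10 + 1e-12), "mild")
  # raising peak DI never moves the class back toward diploid
  lev <- c(diploid = 1L, mild = 2L, moderate = 3L)
  cls <- lev[vapply(seq(0.5, 2.5, by = 0.01), classify_ploidy, "")]
  expect_true(all(diff(cls) >= 0L))
  expect_error(ploidy_thresholds(1.5, 1.2), "mild < moderate")
})

test_that("analyze_sample composes the pipeline and self-normalizes", {
  set.seed(45)
  ctrl_iod <- rnorm(30, 400, 10)
  meas <- data.frame(
    roi_id = sprintf("r%02d", 1:60),
    cell_class = rep(c("control", "epithelial"), each = 30),
    area_px = 80L,
    iod = c(ctrl_iod, ctrl_iod),   # epithelium duplicates the control set
    mean_od = 1)
  res <- analyze_sample(meas, sample_id = "self", condition = "X")
  expect_s3_class(res, "sample_result")
  expect_equal(res$peak_di, 1)
  expect_equal(res$ploidy_class, "diploid")
  expect_false(res$aneuploid)
  expect_equal(sum(res$histogram$counts), res$n_epithelial)
  # deterministic given inputs
  expect_identical(res, analyze_sample(meas, "self", "X"))
  expect_error(analyze_sample(meas[meas$cell_class == "control", ]),
               "epithelial")
})

test_that("sample results serialize to JSON and read back consistently", {
  set.seed(46)
  meas <- data.frame(
    roi_id = sprintf("r%02d", 1:80),
    cell_class = rep(c("control", "epithelial"), c(30, 50)),
    area_px = 80L,
    iod = c(rnorm(30, 400, 10), rnorm(50, 480, 30)),
    mean_od = 1)
  res <- analyze_sample(meas, "s1", "TA")
  path <- withr::local_tempfile(fileext = ".json")
  write_sample_result(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$peak_di, res$peak_di)
  expect_equal(back$modal_control_iod, res$modal_control_iod)
  expect_equal(sum(back$histogram$counts), res$n_epithelial)
})
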