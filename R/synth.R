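#' Nucleus population specification
#'
#' One ploidy population within a sample's epithelium: a fraction of cells
#' at a given DNA multiple (1.0 = 2N diploid, 2.0 = 4N tetraploid, other
#' values aneuploid) with per-cell biological scatter.
#'
#' @param label population name.
#' @param fraction fraction of epithelial cells drawn from this population.
#' @param ploidy_multiple DNA content relative to 2N (positive).
#' @param cv coefficient of variation of per-cell DNA content (>= 0).
#' @return list of class `population_spec`.
#' @export
population_spec <- function(label, fraction = 1, ploidy_multiple = 1, cv = 0.05) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (ploidy_multiple <= 0) stop("ploidy_multiple must be positive")
  if (cv < 0) stop("cv must be >= 0")
  structure(list(label = label, fraction = fraction,
                 ploidy_multiple = ploidy_multiple, cv = cv),
            class = "population_spec")
}

#' Synthetic Feulgen scene specification
#'
#' Describes one synthetic slide: dark elliptical nuclei on a light
#' background, each nucleus's total absorbance proportional to its DNA
#' content (Beer-Lambert), plus Gaussian intensity noise and bit-depth
#' quantization. Absorbance is expressed directly in the pipeline's OD
#' units (ten times decadic absorbance), so transmitted intensity is
#' `background_level * white * 10^(-A_pixel / 10)` and the measured IOD of
#' a noiseless nucleus equals its true total absorbance.
#'
#' @param image_size `(rows, cols)` (default 512 x 512).
#' @param bit_depth 8 or 16 (default 16).
#' @param background_level background transmission as a fraction of white
#'   (default 1.0).
#' @param noise_sd additive Gaussian intensity noise, as a fraction of the
#'   white level (default 0.01).
#' @param n_controls number of lymphocyte control nuclei (default 30, the
#'   measurement protocol's count).
#' @param n_epithelial number of epithelial nuclei (default 175, inside the
#'   protocol's 150-200 band).
#' @param control_radius,epithelial_radius semi-axis ranges in pixels;
#'   lymphocytes are the smaller, rounder nuclei.
#' @param control_cv CV of control (diploid) DNA content (default 0.03).
#' @param absorbance_per_2N total absorbance of a 2N nucleus in OD*pixel
#'   units (default 400; keeps 4N dome peaks far above the quantization
#'   floor at 16-bit).
#' @param populations list of [population_spec] for the epithelium;
#'   fractions must sum to 1. Default: one pure 2N population.
#' @param seed integer seed; all randomness in [render_scene()] flows
#'   from it.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(512L, 512L), bit_depth = 16L,
                       background_level = 1.0, noise_sd = 0.01,
                       n_controls = 30L, n_epithelial = 175L,
                       control_radius = c(4, 6), epithelial_radius = c(6, 10),
                       control_cv = 0.03, absorbance_per_2N = 400,
                       populations = list(population_spec("2N")),
                       seed = 1L) {
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (background_level <= 0 || background_level > 1)
    stop("background_level must be in (0, 1]")
  fr <- vapply(populations, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop("population fractions must sum to 1")
  if (absorbance_per_2N <= 0) stop("absorbance_per_2N must be positive")
  structure(list(image_size = as.integer(image_size), bit_depth = as.integer(bit_depth),
                 background_level = background_level, noise_sd = noise_sd,
                 n_controls = as.integer(n_controls),
                 n_epithelial = as.integer(n_epithelial),
                 control_radius = control_radius,
                 epithelial_radius = epithelial_radius,
                 control_cv = control_cv, absorbance_per_2N = absorbance_per_2N,
                 populations = populations, seed = as.integer(seed)),
            class = "scene_spec")
}

# Nonoverlap via dart-throwing on bounding circles: a candidate is accepted
# when its center clears every accepted center by the sum of bounding radii
# plus a one-pixel guard, which guarantees disjoint rasterizations.
.place_nuclei <- function(n, bound_r, shape, max_tries = 400L * n) {
  cx <- numeric(n); cy <- numeric(n); placed <- 0L; tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("nucleus placement infeasible after ", max_tries,
           " tries; enlarge the image or reduce counts")
    i <- placed + 1L
    x <- stats::runif(1, bound_r[i] + 1, shape[2] - bound_r[i] - 1)
    y <- stats::runif(1, bound_r[i] + 1, shape[1] - bound_r[i] - 1)
    if (placed > 0L) {
      d2 <- (cx[1:placed] - x)^2 + (cy[1:placed] - y)^2
      lim <- (bound_r[1:placed] + bound_r[i] + 1)^2
      if (any(d2 < lim)) next
    }
    cx[i] <- x; cy[i] <- y; placed <- i
  }
  cbind(x = cx, y = cy)
}

# 64-gon approximation of a rotated ellipse; the exported polygon, whose
# rasterization is the nucleus's authoritative pixel set.
.ellipse_polygon <- function(cx, cy, a, b, phi, nv = 64L) {
  th <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  x <- cx + a * cos(th) * cos(phi) - b * sin(th) * sin(phi)
  y <- cy + a * cos(th) * sin(phi) + b * sin(th) * cos(phi)
  cbind(x, y)
}

#' Render one synthetic Feulgen slide
#'
#' Nuclei are elliptical regions with a smooth radial absorbance dome (peak
#' at the center, falling toward the boundary) scaled so the discrete
#' per-pixel absorbance field integrates exactly to the nucleus's true
#' total absorbance `A = absorbance_per_2N * DNA multiple`. Transmitted
#' intensity follows Beer-Lambert with additive Gaussian noise, clipping
#' and quantization to the bit depth. Bit-identical for a given spec.
#'
#' @param spec a [scene_spec].
#' @return list with:
#'   * `image`: the rendered [image_plane];
#'   * `rois`: list of [nucleus_roi] (polygon geometry, classes tagged);
#'   * `truth`: data.frame `roi_id, cell_class, population, dna_multiple,
#'     true_A, area_px, center_x, center_y`;
#'   * `masks`: list (by roi_id) of the authoritative rasterized pixel sets.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  shape <- spec$image_size
  n_c <- spec$n_controls; n_e <- spec$n_epithelial; n <- n_c + n_e

  # population assignment for epithelial nuclei (largest-remainder rounding)
  fr <- vapply(spec$populations, `[[`, numeric(1), "fraction")
  cnt <- floor(fr * n_e)
  rem <- n_e - sum(cnt)
  if (rem > 0) {
    o <- order(fr * n_e - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1L
  }
  pop_idx <- rep.int(seq_along(spec$populations), cnt)

  cls <- c(rep("control", n_c), rep("epithelial", n_e))
  pop_lab <- c(rep("control", n_c),
               vapply(spec$populations[pop_idx], `[[`, "", "label"))
  ploidy <- c(rep(1, n_c),
              vapply(spec$populations[pop_idx], `[[`, numeric(1), "ploidy_multiple"))
  cv <- c(rep(spec$control_cv, n_c),
          vapply(spec$populations[pop_idx], `[[`, numeric(1), "cv"))
  dna <- ploidy * pmax(1 + cv * stats::rnorm(n), 0.2)

  rr <- rbind(matrix(spec$control_radius, n_c, 2, byrow = TRUE),
              matrix(spec$epithelial_radius, n_e, 2, byrow = TRUE))
  a <- stats::runif(n, rr[, 1], rr[, 2])
  b <- stats::runif(n, rr[, 1], rr[, 2])
  phi <- stats::runif(n, 0, pi)
  centers <- .place_nuclei(n, pmax(a, b), shape)

  ids <- c(sprintf("ctrl_%02d", seq_len(n_c)), sprintf("epi_%03d", seq_len(n_e)))
  A_img <- matrix(0, shape[1], shape[2])
  rois <- vector("list", n)
  masks <- vector("list", n)
  area <- integer(n)
  A_true <- spec$absorbance_per_2N * dna
  for (i in seq_len(n)) {
    poly <- .ellipse_polygon(centers[i, 1], centers[i, 2], a[i], b[i], phi[i])
    roi <- nucleus_roi(ids[i], cls[i], polygon = poly)
    px <- rasterize_roi(roi, shape)
    dx <- px[, 2] + 0.5 - centers[i, 1]
    dy <- px[, 1] + 0.5 - centers[i, 2]
    u <- ((dx * cos(phi[i]) + dy * sin(phi[i])) / a[i])^2 +
         ((-dx * sin(phi[i]) + dy * cos(phi[i])) / b[i])^2
    dome <- pmax(1 - u, 0.02)           # dome floor keeps edge pixels stained
    absorb <- dome * (A_true[i] / sum(dome))
    idx <- px[, 1] + 1L + px[, 2] * shape[1]
    A_img[idx] <- A_img[idx] + absorb
    rois[[i]] <- roi
    masks[[i]] <- px
    area[i] <- nrow(px)
  }
  names(masks) <- ids

  white <- 2^spec$bit_depth - 1
  intensity <- spec$background_level * white * 10^(-A_img / 10)
  if (spec$noise_sd > 0)
    intensity <- intensity + stats::rnorm(length(intensity), 0,
                                          spec$noise_sd * white)
  pixels <- matrix(as.integer(round(pmin(pmax(intensity, 0), white))),
                   shape[1], shape[2])
  truth <- data.frame(roi_id = ids, cell_class = cls, population = pop_lab,
                      dna_multiple = dna, true_A = A_true, area_px = area,
                      center_x = centers[, 1], center_y = centers[, 2],
                      stringsAsFactors = FALSE)
  list(image = image_plane(pixels, bit_depth = spec$bit_depth),
       rois = rois, truth = truth, masks = masks)
}

#' Default five-arm study design
#'
#' One row per condition in progression order (NCT, L-HP, L-SA, TA, AC)
#' with the study's arm sizes (10, 9, 12, 8, 10) and per-sample target
#' peak-DI distributions: Normal(mean, SD) truncated to each condition's
#' observed DI range. `cell_cv` is the within-sample per-cell DNA scatter,
#' widening along the progression (carcinomas are the most heterogeneous).
#'
#' @return data.frame `condition, n_samples, di_mean, di_sd, di_min, di_max,
#'   cell_cv`.
#' @export
default_study_design <- function() {
  data.frame(
    condition = c("NCT", "L-HP", "L-SA", "TA", "AC"),
    n_samples = c(10L, 9L, 12L, 8L, 10L),
    di_mean = c(0.95, 1.08, 1.11, 1.22, 1.46),
    di_sd = c(0.08, 0.14, 0.15, 0.17, 0.27),
    di_min = c(0.81, 0.81, 0.95, 1.02, 1.20),
    di_max = c(1.05, 1.30, 1.42, 1.52, 2.04),
    cell_cv = c(0.05, 0.07, 0.08, 0.09, 0.13),
    stringsAsFactors = FALSE)
}

# Truncated-normal draw by rejection with a deterministic clamp fallback.
.rtruncnorm1 <- function(mean, sd, lo, hi, max_tries = 200L) {
  for (k in seq_len(max_tries)) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' Generate a synthetic study cohort on disk
#'
#' For each sample: draws a target peak DI from its condition's truncated
#' normal, an epithelial count uniform in the protocol band (150-200),
#' renders the scene, and writes a 16-bit TIFF image, a polygon ROI JSON
#' and truth rows. A study layout CSV and a ground-truth CSV
#' (`sample_id, roi_id, cell_class, dna_multiple, true_A`) tie everything
#' together. All randomness derives from `seed`; per-sample sub-seeds are
#' drawn deterministically from it.
#'
#' @param design data.frame as [default_study_design()].
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @param scene_args named list of overrides passed to [scene_spec()]
#'   (e.g. a smaller `image_size`).
#' @return The study layout data.frame (as written), invisibly with
#'   attribute `targets`: per-sample intended peak DI.
#' @export
generate_cohort <- function(design = default_study_design(), seed = 1L,
                            out_dir, scene_args = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  n_total <- sum(design$n_samples)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  lay <- list(); truth <- list(); targets <- numeric(0)
  k <- 0L
  for (g in seq_len(nrow(design))) {
    for (s in seq_len(design$n_samples[g])) {
      k <- k + 1L
      sid <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", design$condition[g]), s)
      target <- .rtruncnorm1(design$di_mean[g], design$di_sd[g],
                             design$di_min[g], design$di_max[g])
      n_epi <- sample(150:200, 1L)
      args <- utils::modifyList(list(
        n_epithelial = n_epi,
        populations = list(population_spec(design$condition[g],
                                           fraction = 1,
                                           ploidy_multiple = target,
                                           cv = design$cell_cv[g])),
        seed = sub_seeds[k]), scene_args)
      scene <- render_scene(do.call(scene_spec, args))
      img_file <- file.path(out_dir, paste0(sid, ".tif"))
      roi_file <- file.path(out_dir, paste0(sid, "_rois.json"))
      write_image(scene$image, img_file)
      write_rois(scene$rois, roi_file)
      lay[[k]] <- data.frame(sample_id = sid, condition = design$condition[g],
                             image_path = basename(img_file),
                             roi_path = basename(roi_file),
                             stringsAsFactors = FALSE)
      tr <- scene$truth[, c("roi_id", "cell_class", "dna_multiple", "true_A")]
      tr <- cbind(sample_id = sid, tr)
      truth[[k]] <- tr
      targets[k] <- target
    }
  }
  layout <- do.call(rbind, lay)
  utils::write.csv(layout, file.path(out_dir, "layout.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, truth), file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  attr(layout, "targets") <- targets
  invisible(layout)
}
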