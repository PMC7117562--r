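# Independent oracles used across the suite. These deliberately use
# different algorithms from the package code paths they check.

# Even-odd membership by per-pixel ray casting (package uses scanline
# interval fill): pixel (r, c) center (c + 0.5, r + 0.5), 0-based; inside
# iff an odd number of polygon edges cross the horizontal ray to the right.
oracle_rasterize <- function(poly, shape) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1L), 1]; y2 <- poly[c(2:n, 1L), 2]
  out <- NULL
  for (r in 0:(shape[1] - 1L)) {
    for (c in 0:(shape[2] - 1L)) {
      px <- c + 0.5; py <- r + 0.5
      crossings <- 0L
      for (e in seq_len(n)) {
        if ((y1[e] <= py) != (y2[e] <= py)) {
          xc <- x1[e] + (py - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
          if (xc > px) crossings <- crossings + 1L
        }
      }
      if (crossings %% 2L == 1L) out <- rbind(out, c(r, c))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# Brute-force IOD: plain scalar accumulation over an explicit pixel list.
oracle_iod <- function(od, pixels) {
  s <- 0
  for (i in seq_len(nrow(pixels)))
    s <- s + od[pixels[i, 1] + 1L, pixels[i, 2] + 1L]
  s
}

# Random simple polygon: jittered equally spaced angles keep every edge in
# its own angular wedge around the center, which guarantees simplicity.
random_polygon <- function(shape, nv = 8L) {
  cx <- runif(1, 8, shape[2] - 8)
  cy <- runif(1, 8, shape[1] - 8)
  step <- 2 * pi / nv
  th <- (0:(nv - 1)) * step + runif(nv, 0, 0.8 * step)
  r <- runif(nv, 3, 6)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Upper-tail t probability by quadrature of the density (package uses pt).
oracle_p_upper <- function(t, df) {
  stats::integrate(function(x) stats::dt(x, df), t, Inf,
                   rel.tol = 1e-10)$value
}

# Exact permutation p for mean(b) - mean(a) under the "b greater" alternative.
oracle_perm_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  obs <- mean(b) - mean(a)
  splits <- utils::combn(length(pool), na)
  stat <- apply(splits, 2, function(ix) mean(pool[-ix]) - mean(pool[ix]))
  mean(stat >= obs - 1e-12)
}

# Small, fast synthetic scene for unit tests (protocol-scale counts kept
# only where a test needs them).
tiny_scene_spec <- function(seed = 1L, n_controls = 12L, n_epithelial = 30L,
                            noise_sd = 0, ...) {
  scene_spec(image_size = c(192L, 192L), n_controls = n_controls,
             n_epithelial = n_epithelial, noise_sd = noise_sd,
             control_radius = c(3, 4), epithelial_radius = c(4, 6),
             seed = seed, ...)
}

tiny_design <- function() {
  data.frame(condition = c("low", "high"), n_samples = c(2L, 2L),
             di_mean = c(1.0, 1.5), di_sd = c(0.05, 0.1),
             di_min = c(0.9, 1.3), di_max = c(1.1, 1.8),
             cell_cv = c(0.05, 0.1), stringsAsFactors = FALSE)
}

tiny_cohort <- function(dir, seed = 5L) {
  generate_cohort(tiny_design(), seed = seed, out_dir = dir,
                  scene_args = list(image_size = c(192L, 192L),
                                    n_controls = 12L, n_epithelial = 30L,
                                    control_radius = c(3, 4),
                                    epithelial_radius = c(4, 6)))
}

measure_quiet <- function(...) suppressWarnings(measure_sample(...))
analyze_quiet <- function(...) suppressWarnings(analyze_sample(...))
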