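# Shared fixtures: a compact phantom geometry that keeps test volumes
# small, plus independent oracles for the segmentation tests.

# coarse but wall-resolving phantom (grids ~ 40 x 40 x 55 voxels)
small_spec <- function(noise_sd_hu = 0, spacing_mm = 0.15, seed = 1L,
                       true_ef = 0.36, infarct_fraction = 0.25, ...) {
  sp <- phantom_spec(
    lv_cavity_semiaxes_dia_mm = c(1.6, 1.6, 2.6),
    wall_thickness_mm = 0.9,
    true_ef = true_ef,
    noise_sd_hu = noise_sd_hu,
    spacing_mm = spacing_mm,
    seed = seed, ...)
  sp$infarct_wedge <- infarct_wedge_for_fraction(
    sp$lv_cavity_semiaxes_dia_mm, sp$wall_thickness_mm, infarct_fraction)
  sp
}

# logical array from a label code, keeping dimensions
label_eq <- function(mask_obj, code) {
  array(mask_obj$labels == code, dim = dim(mask_obj$labels))
}

label_in <- function(mask_obj, codes) {
  array(mask_obj$labels %in% codes, dim = dim(mask_obj$labels))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Brute-force scalar flood fill: an intentionally naive queue-based BFS,
# independent of the package's vectorized propagation.
flood_fill_oracle <- function(allowed, seeds, connectivity = 6L) {
  d <- dim(allowed)
  offs <- if (connectivity == 6L) {
    list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    g <- expand.grid(-1:1, -1:1, -1:1)
    g <- g[rowSums(abs(g)) > 0, ]
    lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
  }
  visited <- array(FALSE, dim = d)
  queue <- list()
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ]
    if (allowed[s[1], s[2], s[3]] && !visited[s[1], s[2], s[3]]) {
      visited[s[1], s[2], s[3]] <- TRUE
      queue[[length(queue) + 1L]] <- s
    }
  }
  while (length(queue)) {
    v <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (o in offs) {
      w <- v + o
      if (all(w >= 1) && all(w <= d) &&
          allowed[w[1], w[2], w[3]] && !visited[w[1], w[2], w[3]]) {
        visited[w[1], w[2], w[3]] <- TRUE
        queue[[length(queue) + 1L]] <- w
      }
    }
  }
  visited
}

# squared Pearson correlation straight from its definition
r2_definition <- function(x, y) {
  n <- length(x)
  cxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  cxy^2 / (var(x) * var(y))
}
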