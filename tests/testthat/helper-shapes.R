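# Rasterized analytic shapes and brute-force pixel oracles used across the
# morphometry tests.

raster_disk <- function(r = 20, pad = 10) {
  n <- 2L * (r + pad)
  cx <- n / 2 + 0.5
  m <- matrix(FALSE, n, n)
  idx <- which(outer(seq_len(n), seq_len(n),
                     function(i, j) (i - cx)^2 + (j - cx)^2 <= r^2))
  m[idx] <- TRUE
  m
}

raster_bar <- function(len = 200, wid = 4, pad = 10) {
  m <- matrix(FALSE, wid + 2 * pad, len + 2 * pad)
  m[pad + seq_len(wid), pad + seq_len(len)] <- TRUE
  m
}

raster_square <- function(side = 20, pad = 10) {
  m <- matrix(FALSE, side + 2 * pad, side + 2 * pad)
  m[pad + seq_len(side), pad + seq_len(side)] <- TRUE
  m
}

raster_L <- function(arm = 40, thick = 6, pad = 10) {
  n <- arm + 2 * pad
  m <- matrix(FALSE, n, n)
  m[pad + seq_len(arm), pad + seq_len(thick)] <- TRUE
  m[pad + arm - seq_len(thick) + 1, pad + seq_len(arm)] <- TRUE
  m
}

# independent oracles ---------------------------------------------------

oracle_feret <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  max(stats::dist(pts))
}

oracle_radius_gyration <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  sqrt(mean((pts[, 1] - mean(pts[, 1]))^2 +
              (pts[, 2] - mean(pts[, 2]))^2))
}

oracle_box_count <- function(pts, sizes) {
  vapply(sizes, function(s) {
    nrow(unique(cbind(floor((pts[, 1] - min(pts[, 1])) / s),
                      floor((pts[, 2] - min(pts[, 2])) / s))))
  }, numeric(1))
}

# naive step-by-step greedy filter used as an oracle for greedycut
oracle_greedycut <- function(fail, max_frac) {
  rs <- seq_len(nrow(fail)); cs <- seq_len(ncol(fail))
  repeat {
    sub <- fail[rs, cs, drop = FALSE]
    if (!length(rs) || !length(cs)) break
    rf <- rowMeans(sub); cf <- colMeans(sub)
    if (max(rf) <= max_frac && max(cf) <= max_frac) break
    if (max(rf) >= max(cf)) rs <- rs[-which.max(rf)] else
      cs <- cs[-which.max(cf)]
  }
  list(rows = rs, cols = cs)
}

poisson_bounds99 <- function(lambda) {
  c(qpois(0.005, lambda), qpois(0.995, lambda))
}

# shared fast fiber tile, memoised across test files
local_tile_cache <- new.env()
get_loose_tile <- function(seed = 42) {
  key <- paste0("tile", seed)
  if (is.null(local_tile_cache[[key]])) {
    p <- fiber_preset("loose_plexus", seed = seed)
    local_tile_cache[[key]] <- simulate_fiber_roi(p)
  }
  local_tile_cache[[key]]
}

truth_mask <- function(sim) {
  m <- matrix(FALSE, nrow(sim$od_truth), ncol(sim$od_truth))
  m[unlist(sim$fibers$pixels)] <- TRUE
  m
}
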