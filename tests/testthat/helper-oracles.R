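# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain arithmetic on raw matrices.

# exact two-sided signed-rank p-value by full enumeration of the 2^n sign
# patterns of the null distribution
enum_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- as.vector(signs %*% r)
  p_ge <- mean(w >= v_obs)
  p_le <- mean(w <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# brute-force recount of a thresholded area from a raw raster (um^2)
recount_area_um2 <- function(raster, threshold, pixel_size) {
  length(which(as.numeric(raster) - threshold > 0)) * pixel_size^2
}

# brute-force biovolume recount of a z-stack from its raw rasters given the
# per-slice thresholds a pipeline report recorded
recount_stack_um3 <- function(stack, thresholds, channel, pixel_size) {
  areas <- vapply(seq_along(stack$slices), function(i)
    recount_area_um2(stack$slices[[i]][[channel]], thresholds[i], pixel_size),
    numeric(1))
  sum(areas) * stack$interslice_um
}

# random logical mask fixture
random_mask <- function(nr, nc, p = 0.3) {
  biofilmph:::new_mask(matrix(runif(nr * nc) < p, nr, nc),
                       provenance = "cell", pixel_size = 1)
}

make_raster <- function(values, pixel_size = 1, channel = "green") {
  intensity_raster(values, pixel_size = pixel_size, channel = channel)
}
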