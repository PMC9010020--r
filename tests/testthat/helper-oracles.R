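# Independent brute-force oracles for the statistic kernels.

# two-sample KS D by direct ECDF evaluation over the pooled values
ks_oracle_D <- function(a, b) {
  pooled <- sort(unique(c(a, b)))
  max(abs(vapply(pooled, function(v) mean(a <= v) - mean(b <= v), 0)))
}

# Peacock/Fasano-Franceschini D by explicit origin loops and quadrant
# counting; origins = pooled coordinate grid (full_grid) or pooled points
peacock_oracle_D <- function(a, b, full_grid = TRUE) {
  gx <- sort(unique(c(a[, 1], b[, 1])))
  gy <- sort(unique(c(a[, 2], b[, 2])))
  na <- nrow(a); nb <- nrow(b)
  best <- 0
  quad_diff <- function(ox, oy) {
    ax <- a[, 1] <= ox; ay <- a[, 2] <= oy
    bx <- b[, 1] <= ox; by <- b[, 2] <= oy
    d <- abs(sum(ax & ay) / na - sum(bx & by) / nb)
    d <- max(d, abs(sum(ax & !ay) / na - sum(bx & !by) / nb))
    d <- max(d, abs(sum(!ax & ay) / na - sum(!bx & by) / nb))
    max(d, abs(sum(!ax & !ay) / na - sum(!bx & !by) / nb))
  }
  if (full_grid) {
    for (ox in gx) for (oy in gy) best <- max(best, quad_diff(ox, oy))
  } else {
    pts <- rbind(a, b)
    for (k in seq_len(nrow(pts))) {
      best <- max(best, quad_diff(pts[k, 1], pts[k, 2]))
    }
  }
  best
}
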