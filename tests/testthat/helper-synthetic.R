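# Small session specs reused across tests. Rendering uses 6 px/cm (a
# 160 x 255 px arena crop) to keep frame stacks light.
quick_spec <- function(seed = 1, duration_s = 60, n_bouts = 4, ...) {
  session_spec(duration_s = duration_s, fps = 25, n_bouts = n_bouts,
               px_per_cm = 6, seed = seed, ...)
}

# Brute-force run-length bout oracle: maximal runs of TRUE, merge gaps,
# drop short runs — written against the definition, independently of
# segment_bouts' internals.
oracle_bouts <- function(mask, fps, min_bout_s = 1, max_gap_s = 0) {
  n <- length(mask)
  runs <- list()
  i <- 1
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i - 1, j - 1)  # 0-based inclusive
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs)) return(data.frame(start_frame = integer(0),
                                       end_frame = integer(0)))
  m <- do.call(rbind, runs)
  # merge
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) {
    for (k in 2:nrow(m)) {
      gap <- m[k, 1] - out[nrow(out), 2] - 1
      if (gap <= max_gap_s * fps) out[nrow(out), 2] <- m[k, 2]
      else out <- rbind(out, m[k, ])
    }
  }
  len <- out[, 2] - out[, 1] + 1
  out <- out[len >= min_bout_s * fps, , drop = FALSE]
  data.frame(start_frame = as.integer(out[, 1]),
             end_frame = as.integer(out[, 2] + 1))
}

# Axial orientation error in degrees.
axial_err_deg <- function(a, b) {
  d <- abs(((a - b + pi / 2) %% pi) - pi / 2)
  d * 180 / pi
}
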