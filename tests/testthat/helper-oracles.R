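# Independent oracles used across the suite. These deliberately avoid the
# package's own recursions: likelihoods by exhaustive path enumeration,
# integrals by direct summation of the generative model.

# Exhaustive-path log-likelihood of a compound-window HMM: sums over every
# promoter path (w - 1 pre-observation bits + T observed bits), with the
# earliest bit drawn from the stationary distribution. Feasible for
# T + w - 1 <= ~16.
brute_force_loglik <- function(f, model) {
  w <- model$w
  A <- model$A
  p <- A[1, 2]; q <- A[2, 1]
  pi0 <- if (p + q == 0) c(0.5, 0.5) else c(q, p) / (p + q)
  T_ <- length(f)
  nbits <- T_ + w - 1
  total <- 0
  for (m in 0:(2^nbits - 1)) {
    bits <- as.integer(intToBits(m))[1:nbits] # bits[1] = earliest
    pr <- pi0[bits[1] + 1]
    if (nbits > 1) {
      for (i in 2:nbits) pr <- pr * A[bits[i - 1] + 1, bits[i] + 1]
    }
    for (t in 1:T_) {
      cnt <- sum(bits[t:(t + w - 1)])
      pr <- pr * dnorm(f[t], model$nu * cnt + model$b, model$sigma)
    }
    total <- total + pr
  }
  log(total)
}

# Direct sum of a 3D Gaussian over a voxel region (the same grid the
# integrator sees), as the numeric oracle for spot integration.
gaussian_region_sum <- function(dim_zyx, x0, y0, z0, amp, sxy, sz, r_xy) {
  total <- 0
  for (z in seq_len(dim_zyx[1])) {
    gz <- exp(-(z - z0)^2 / (2 * sz^2))
    for (y in seq_len(dim_zyx[2])) {
      for (x in seq_len(dim_zyx[3])) {
        if ((y - y0)^2 + (x - x0)^2 <= r_xy^2) {
          total <- total + amp * gz *
            exp(-((y - y0)^2 + (x - x0)^2) / (2 * sxy^2))
        }
      }
    }
  }
  total
}

# simple flat two-channel cohort builder for pulse-pipeline unit tests
flat_cohort <- function(n_cells, n_frames, yap = 100, mcp = 100,
                        dt_min = 10) {
  purrr::map_dfr(seq_len(n_cells), function(i) {
    tibble::tibble(cell_id = sprintf("c%02d", i),
                   frame = seq_len(n_frames) - 1L,
                   t_s = (seq_len(n_frames) - 1L) * dt_min * 60,
                   yap_au = rep_len(yap, n_frames),
                   mcp_au = rep_len(mcp, n_frames))
  })
}
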