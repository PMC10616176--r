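# MS2 transcription-spot quantification: blob candidates on the maximum
# z-projection, 2D + 1D Gaussian fit verification, annulus background
# subtraction, and a second-order-polynomial correction for coat-protein
# (MCP) expression differences between nuclei.
#
# Coordinates are 1-based (R convention): a candidate at (y, x) indexes
# stack[z, y, x]; sub-pixel centers are continuous in the same units.

log_kernel <- function(sigma) {
  half <- ceiling(3 * sigma)
  g <- seq(-half, half)
  gg <- outer(g, g, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  gg <- gg / sum(gg)
  lap <- (outer(g, g, function(a, b) (a^2 + b^2 - 2 * sigma^2) / sigma^4)) * gg
  lap - mean(lap)
}

#' Detect spot candidates on a maximum z-projection
#'
#' Laplacian-of-Gaussian blob response on the maximum projection; local
#' maxima of the (negated) response above a threshold are returned as
#' integer candidates.
#'
#' @param stack Numeric array `[z, y, x]`.
#' @param sigma Expected spot width in px (default 1.5).
#' @param threshold Response threshold; `NULL` (default) uses
#'   `5 * mad(response)`.
#' @return Tibble: `y`, `x` (1-based integers), `response`.
#' @export
detect_candidates <- function(stack, sigma = 1.5, threshold = NULL) {
  if (length(stack) == 0) abort_param("empty stack")
  if (length(dim(stack)) != 3) abort_param("stack must be a 3D [z, y, x] array")
  proj <- apply(stack, c(2, 3), max)
  resp <- -EBImage::filter2(proj, log_kernel(sigma), boundary = "replicate")
  if (is.null(threshold)) {
    # epsilon floor so numerically flat stacks yield no candidates
    threshold <- max(5 * stats::mad(resp), 1e-8 * (1 + max(abs(proj))))
  }
  ny <- nrow(resp); nx <- ncol(resp)
  cand <- which(resp > threshold, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(tibble::tibble(y = integer(), x = integer(), response = numeric()))
  }
  is_max <- apply(cand, 1, function(ix) {
    yy <- max(1, ix[1] - 1):min(ny, ix[1] + 1)
    xx <- max(1, ix[2] - 1):min(nx, ix[2] + 1)
    resp[ix[1], ix[2]] >= max(resp[yy, xx])
  })
  cand <- cand[is_max, , drop = FALSE]
  tibble::tibble(y = as.integer(cand[, 1]), x = as.integer(cand[, 2]),
                 response = resp[cand])
}

#' Fit and verify a spot candidate
#'
#' Least-squares 2D Gaussian (amplitude, sub-pixel center, widths, offset)
#' on a local window of the maximum projection, followed by a 1D Gaussian
#' along z of the 3x3-summed column at the fitted center. The fit is
#' accepted iff both widths lie within `width_bounds`, the amplitude
#' exceeds `amp_k` times the local background SD, and the z-peak is
#' interior to the stack. Non-convergence yields a rejected fit (reason
#' `fit_failed`), not an error.
#'
#' @param stack Numeric array `[z, y, x]`.
#' @param candidate One-row data frame or list with `y`, `x`.
#' @param window Half-size of the fit window in px (default 5).
#' @param width_bounds Acceptable Gaussian widths in px (default
#'   `c(0.5, 4)`).
#' @param amp_k Amplitude acceptance threshold in background SDs
#'   (default 3).
#' @return A `spot_fit` tibble row: `x0`, `y0`, `sigma_x`, `sigma_y`,
#'   `amplitude`, `offset`, `z0`, `sigma_z`, `accepted`, `reason`.
#' @export
fit_spot <- function(stack, candidate, window = 5, width_bounds = c(0.5, 4),
                     amp_k = 3) {
  proj <- apply(stack, c(2, 3), max)
  ny <- nrow(proj); nx <- ncol(proj); nz <- dim(stack)[1]
  cy <- candidate$y[1]; cx <- candidate$x[1]
  yy <- max(1, cy - window):min(ny, cy + window)
  xx <- max(1, cx - window):min(nx, cx + window)
  patch <- proj[yy, xx]
  df <- data.frame(
    y = rep(yy, times = length(xx)),
    x = rep(xx, each = length(yy)),
    v = as.vector(patch)
  )
  reject <- function(reason) {
    tibble::tibble(x0 = NA_real_, y0 = NA_real_, sigma_x = NA_real_,
                   sigma_y = NA_real_, amplitude = NA_real_,
                   offset = NA_real_, z0 = NA_real_, sigma_z = NA_real_,
                   sum_intensity = NA_real_, accepted = FALSE, reason = reason)
  }
  fit2d <- tryCatch(
    minpack.lm::nlsLM(
      v ~ off + amp * exp(-((x - x0)^2 / (2 * sx^2) + (y - y0)^2 / (2 * sy^2))),
      data = df,
      start = list(off = min(df$v), amp = max(df$v) - min(df$v),
                   x0 = cx, y0 = cy, sx = 1.5, sy = 1.5),
      lower = c(off = -Inf, amp = 0, x0 = min(xx) - 1, y0 = min(yy) - 1,
                sx = 0.1, sy = 0.1),
      upper = c(off = Inf, amp = Inf, x0 = max(xx) + 1, y0 = max(yy) + 1,
                sx = 10, sy = 10),
      control = minpack.lm::nls.lm.control(maxiter = 100)
    ),
    error = function(e) NULL
  )
  if (is.null(fit2d)) return(reject("fit_failed"))
  p <- as.list(coef(fit2d))
  bg_sd <- stats::sd(stats::residuals(fit2d))
  if (p$sx < width_bounds[1] || p$sx > width_bounds[2] ||
      p$sy < width_bounds[1] || p$sy > width_bounds[2]) {
    return(reject("width_out_of_bounds"))
  }
  if (!is.finite(bg_sd) || bg_sd == 0) bg_sd <- 1e-12
  if (p$amp < amp_k * bg_sd) return(reject("low_amplitude"))

  # 1D Gaussian along z of the 3x3-summed column at the fitted center
  iy <- round(p$y0); ix <- round(p$x0)
  yy3 <- max(1, iy - 1):min(ny, iy + 1)
  xx3 <- max(1, ix - 1):min(nx, ix + 1)
  zprof <- vapply(seq_len(nz), function(z) sum(stack[z, yy3, xx3]), numeric(1))
  dfz <- data.frame(z = seq_len(nz), v = zprof)
  fitz <- tryCatch(
    minpack.lm::nlsLM(
      v ~ off + amp * exp(-(z - z0)^2 / (2 * sz^2)),
      data = dfz,
      start = list(off = min(zprof), amp = max(zprof) - min(zprof),
                   z0 = which.max(zprof), sz = 2),
      lower = c(off = -Inf, amp = 0, z0 = 0, sz = 0.2),
      upper = c(off = Inf, amp = Inf, z0 = nz + 1, sz = nz),
      control = minpack.lm::nls.lm.control(maxiter = 100)
    ),
    error = function(e) NULL
  )
  if (is.null(fitz)) return(reject("fit_failed"))
  pz <- as.list(coef(fitz))
  # interior means at least one slice of margin on both sides
  if (pz$z0 < 2 || pz$z0 > nz - 1) return(reject("z_boundary"))

  tibble::tibble(
    x0 = p$x0, y0 = p$y0, sigma_x = p$sx, sigma_y = p$sy,
    amplitude = p$amp, offset = p$off, z0 = pz$z0, sigma_z = pz$sz,
    sum_intensity = NA_real_, accepted = TRUE, reason = "ok"
  )
}

#' Background-subtracted summed spot intensity
#'
#' Local background is the per-slice mean in an annulus around the spot
#' center; the spot is summed over voxels within
#' `2 * max(sigma_x, sigma_y)` of the center on every slice, minus
#' background times voxel count, clipped at zero.
#'
#' @param stack Numeric array `[z, y, x]`.
#' @param fit Accepted row from [fit_spot()].
#' @param annulus Inner and outer annulus radii in px (default `c(4, 8)`).
#' @return Single non-negative intensity (a.u.).
#' @export
integrate_spot <- function(stack, fit, annulus = c(4, 8)) {
  if (!isTRUE(fit$accepted[1])) abort_param("fit must be accepted")
  nz <- dim(stack)[1]; ny <- dim(stack)[2]; nx <- dim(stack)[3]
  r_int <- 2 * max(fit$sigma_x[1], fit$sigma_y[1])
  d2 <- outer(seq_len(ny) - fit$y0[1], seq_len(nx) - fit$x0[1],
              function(a, b) a^2 + b^2)
  in_spot <- d2 <= r_int^2
  in_ann <- d2 > annulus[1]^2 & d2 <= annulus[2]^2
  # fall back to the slice median if the annulus leaves the image
  ann_clipped <- fit$y0[1] - annulus[2] < 1 | fit$y0[1] + annulus[2] > ny |
    fit$x0[1] - annulus[2] < 1 | fit$x0[1] + annulus[2] > nx
  if (ann_clipped && sum(in_ann) == 0) {
    warning("annulus outside image; using whole-slice median background")
  }
  total <- 0
  for (z in seq_len(nz)) {
    slice <- stack[z, , ]
    bg <- if (sum(in_ann) > 0) mean(slice[in_ann]) else median(slice)
    total <- total + sum(slice[in_spot]) - bg * sum(in_spot)
  }
  max(total, 0)
}

#' Fit the coat-protein (MCP) intensity correction
#'
#' Second-order polynomial of mean spot intensity vs nuclear MCP level,
#' fitted over nuclei inside the valid (non-saturating) MCP band. The
#' correction rescales intensities multiplicatively to a reference MCP
#' level: `corrected = raw * poly(m_ref) / poly(m)`.
#'
#' @param per_nucleus Table with `mcp_au` and `mean_spot_intensity`.
#' @param valid_band Usable MCP interval in a.u. (default `c(50, 200)`).
#' @param m_ref Reference level (default band midpoint).
#' @return An `mcp_correction` list: coefficients `c0..c2`, `valid_band`,
#'   `m_ref`, `correct(raw, m)` function (NA outside the band).
#' @export
build_mcp_correction <- function(per_nucleus, valid_band = c(50, 200),
                                 m_ref = mean(valid_band)) {
  stopifnot(all(c("mcp_au", "mean_spot_intensity") %in% names(per_nucleus)))
  inside <- per_nucleus$mcp_au >= valid_band[1] &
    per_nucleus$mcp_au <= valid_band[2]
  if (sum(inside) < 6) {
    abort_param("need >= 6 nuclei inside the valid MCP band")
  }
  d <- per_nucleus[inside, ]
  if (stats::sd(d$mcp_au) < 1e-9) {
    # no MCP spread: the correction degenerates to the identity
    cf <- c(mean(d$mean_spot_intensity), 0, 0)
  } else {
    fit <- lm(mean_spot_intensity ~ poly(mcp_au, 2, raw = TRUE), data = d)
    cf <- unname(coef(fit))
    cf[is.na(cf)] <- 0
  }
  poly_eval <- function(m) cf[1] + cf[2] * m + cf[3] * m^2
  band_grid <- seq(valid_band[1], valid_band[2], length.out = 101)
  if (any(poly_eval(band_grid) <= 0)) {
    abort_param("fitted polynomial non-positive inside the valid band; unusable fit")
  }
  ref_val <- poly_eval(m_ref)
  structure(
    list(c0 = cf[1], c1 = cf[2], c2 = cf[3],
         valid_band = valid_band, m_ref = m_ref,
         correct = function(raw, m) {
           out <- raw * ref_val / poly_eval(m)
           out[m < valid_band[1] | m > valid_band[2]] <- NA_real_
           out
         }),
    class = "mcp_correction"
  )
}

#' Assemble per-nucleus MS2 intensity traces from spot fits
#'
#' Multiple accepted spots in one nucleus/frame are summed; frames with no
#' detectable spot get intensity zero; nuclei outside the MCP valid band
#' are excluded. Output follows the long trace schema.
#'
#' @param spot_rows Table with one row per accepted spot: `nucleus_id`,
#'   `frame`, `sum_intensity`, `mcp_au`.
#' @param correction An [build_mcp_correction()] object, or `NULL` to skip
#'   correction.
#' @param frames Full frame vector to fill (default: observed range).
#' @param dt Seconds per frame (for the `t_s` column; default `NA`).
#' @return Tibble: `cell_id`, `frame`, `t_s`, `ms2_au`.
#' @export
assemble_ms2_traces <- function(spot_rows, correction = NULL, frames = NULL,
                                dt = NA_real_) {
  stopifnot(all(c("nucleus_id", "frame", "sum_intensity") %in% names(spot_rows)))
  if (is.null(frames)) {
    frames <- seq(min(spot_rows$frame), max(spot_rows$frame))
  }
  rows <- spot_rows
  if (!is.null(correction)) {
    stopifnot("mcp_au" %in% names(rows))
    rows$sum_intensity <- correction$correct(rows$sum_intensity, rows$mcp_au)
    rows <- rows[!is.na(rows$sum_intensity), ]
  }
  per_frame <- rows |>
    dplyr::group_by(.data$nucleus_id, .data$frame) |>
    dplyr::summarise(ms2_au = sum(.data$sum_intensity), .groups = "drop")
  tidyr::expand_grid(nucleus_id = unique(spot_rows$nucleus_id),
                     frame = frames) |>
    dplyr::left_join(per_frame, by = c("nucleus_id", "frame")) |>
    dplyr::mutate(ms2_au = dplyr::coalesce(.data$ms2_au, 0),
                  t_s = .data$frame * dt) |>
    dplyr::rename(cell_id = "nucleus_id") |>
    dplyr::select("cell_id", "frame", "t_s", "ms2_au") |>
    dplyr::arrange(.data$cell_id, .data$frame)
}

#' Validate a long trace table (one value per cell and frame)
#' @param traces Long trace table.
#' @return The table, invisibly; errors on duplicate `(cell_id, frame)`.
#' @export
validate_trace_table <- function(traces) {
  dup <- traces |>
    dplyr::count(.data$cell_id, .data$frame) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_param(sprintf("duplicate (cell_id, frame) entries, e.g. %s / %d",
                        dup$cell_id[1], dup$frame[1]))
  }
  invisible(traces)
}
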