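# Synthetic 3D image stacks with Gaussian transcription spots over a
# nuclear (MCP) background, for exercising the spot-quantification pipeline
# without microscopy data. Stacks are numeric arrays with axis order
# (z, y, x) and 1-based coordinates; they round-trip through 16-bit TIFF.

#' Scene description for the spot-stack generator
#'
#' @param stack_shape Integer vector `c(z, y, x)` in voxels.
#' @param spots A data frame with columns `x0`, `y0`, `z0` (1-based centers,
#'   may be fractional), `amplitude`, `sigma_xy`, `sigma_z`. May have zero
#'   rows.
#' @param mcp_level Uniform nuclear background level (a.u.).
#' @param noise_sd Additive Gaussian noise SD (a.u.).
#' @return An object of class `spot_scene`.
#' @export
spot_scene <- function(stack_shape, spots = NULL, mcp_level = 100,
                       noise_sd = 0) {
  stopifnot(length(stack_shape) == 3, all(stack_shape >= 1))
  if (is.null(spots)) {
    spots <- tibble::tibble(x0 = numeric(), y0 = numeric(), z0 = numeric(),
                            amplitude = numeric(), sigma_xy = numeric(),
                            sigma_z = numeric())
  }
  spots <- tibble::as_tibble(spots)
  if (nrow(spots) > 0) {
    if (any(spots$sigma_xy <= 0) || any(spots$sigma_z <= 0)) {
      abort_param("spot sigmas must be > 0")
    }
    inside <- spots$x0 >= 1 & spots$x0 <= stack_shape[3] &
      spots$y0 >= 1 & spots$y0 <= stack_shape[2] &
      spots$z0 >= 1 & spots$z0 <= stack_shape[1]
    if (!all(inside)) abort_param("spot centers must lie inside the stack")
  }
  structure(list(stack_shape = as.integer(stack_shape), spots = spots,
                 mcp_level = mcp_level, noise_sd = noise_sd),
            class = "spot_scene")
}

#' Simulate a 3D spot image stack
#'
#' Voxel value = `mcp_level + sum of 3D Gaussians + N(0, noise_sd)`.
#'
#' @param scene A [spot_scene()] object.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return List with `stack` (numeric array `[z, y, x]`) and `ground_truth`
#'   (the scene).
#' @export
simulate_spot_stack <- function(scene, seed = 1) {
  stopifnot(inherits(scene, "spot_scene"))
  nz <- scene$stack_shape[1]; ny <- scene$stack_shape[2]; nx <- scene$stack_shape[3]
  stack <- array(scene$mcp_level, dim = c(nz, ny, nx))
  if (nrow(scene$spots) > 0) {
    zi <- seq_len(nz); yi <- seq_len(ny); xi <- seq_len(nx)
    for (k in seq_len(nrow(scene$spots))) {
      sp <- scene$spots[k, ]
      gz <- exp(-(zi - sp$z0)^2 / (2 * sp$sigma_z^2))
      gy <- exp(-(yi - sp$y0)^2 / (2 * sp$sigma_xy^2))
      gx <- exp(-(xi - sp$x0)^2 / (2 * sp$sigma_xy^2))
      stack <- stack + sp$amplitude * (gz %o% gy %o% gx)
    }
  }
  if (scene$noise_sd > 0) {
    stack <- stack + with_seed(seed, array(rnorm(length(stack), 0, scene$noise_sd),
                                           dim = dim(stack)))
  }
  list(stack = stack, ground_truth = scene)
}

#' Write / read an image stack as multi-page 16-bit TIFF
#'
#' Values are stored as 16-bit unsigned integers; `scale` maps array units
#' to the stored range (`stored = round(value / scale)`, clipped to
#' `[0, 65535]`). The reader applies the inverse.
#'
#' @param stack Numeric array `[z, y, x]`.
#' @param path Output file.
#' @param scale Units per integer step (default 1).
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, scale = 1) {
  pages <- lapply(seq_len(dim(stack)[1]), function(z) {
    m <- pmin(pmax(round(stack[z, , ] / scale), 0), 65535)
    m / 65535 # tiff package expects [0, 1]
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  stack <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) stack[z, , ] <- round(pages[[z]] * 65535) * scale
  stack
}
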