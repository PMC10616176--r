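# Synthetic dose-response populations: per-cell nuclear YAP "doses" drawn
# from a lognormal, pluripotency-marker readouts from ground-truth Hill
# repression curves, plus lineage-marker columns for gating and cutoff
# classification tests.

#' Evaluate a four-parameter Hill (repression) curve
#'
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^n)`. At `x = 0` the curve
#' is at `top`; it decays to `bottom` as `x -> Inf`; `x = ic50` gives the
#' midpoint.
#'
#' @param x Dose values (>= 0).
#' @param top,bottom Plateaus (`top > bottom` for repression).
#' @param ic50 Dose at half repression (> 0).
#' @param n Hill exponent.
#' @return Numeric response values.
#' @export
hill_response <- function(x, top, bottom, ic50, n) {
  bottom + (top - bottom) / (1 + (x / ic50)^n)
}

#' Ground-truth Hill curve container
#' @param top,bottom,ic50,n Curve parameters (see [hill_response()]).
#' @return A named list of class `hill_curve`.
#' @export
hill_curve <- function(top, bottom, ic50, n) {
  if (ic50 <= 0) abort_param("ic50 must be > 0")
  if (top <= bottom) abort_param("top must exceed bottom for a repression curve")
  structure(list(top = top, bottom = bottom, ic50 = ic50, n = n),
            class = "hill_curve")
}

#' Parameters for the dose-response population generator
#'
#' Defaults emulate the wild-type reporter population: switch-like Oct4
#' repression (exponent 1.6) with the Nanog threshold offset below the Oct4
#' threshold so intermediate doses repress Nanog preferentially.
#'
#' @param n_cells Number of cells.
#' @param yap_meanlog,yap_sdlog Lognormal parameters of the nuclear YAP dose.
#' @param oct4_curve,nanog_curve [hill_curve()] ground truths.
#' @param noise_cv Per-cell multiplicative readout noise CV.
#' @param lineage_probs Named probabilities for ectoderm/mesoderm/endoderm/
#'   none used to populate lineage-marker columns.
#' @return An object of class `dose_pop_params`.
#' @export
dose_pop_params <- function(n_cells = 2000,
                            yap_meanlog = log(100), yap_sdlog = 1.0,
                            oct4_curve = hill_curve(1, 0.05, 100, 1.6),
                            nanog_curve = hill_curve(1, 0.05, 50, 1.6),
                            noise_cv = 0.1,
                            lineage_probs = c(ecto = 0.25, meso = 0.25,
                                              endo = 0.15, none = 0.35)) {
  if (n_cells < 1) abort_param("n_cells must be >= 1")
  structure(
    list(n_cells = n_cells, yap_meanlog = yap_meanlog, yap_sdlog = yap_sdlog,
         oct4_curve = oct4_curve, nanog_curve = nanog_curve,
         noise_cv = noise_cv, lineage_probs = lineage_probs),
    class = "dose_pop_params"
  )
}

#' Simulate a snapshot dose-response cell population
#'
#' Per-cell YAP dose ~ lognormal; Oct4/Nanog = Hill(dose) * (1 + noise).
#' Lineage markers (Sox1/Tbra/FoxA2) are lognormal with a high component for
#' the cell's true lineage (~3 SD above background in log space); Otx2
#' decreases with dose. The true lineage label is carried in the table and
#' in the ground truth for recovery tests.
#'
#' @param params A [dose_pop_params()] object.
#' @param seed Integer seed.
#' @param condition,replicate Labels stored in the table.
#' @return List with `cells` (tibble) and `ground_truth`.
#' @export
simulate_dose_population <- function(params, seed, condition = "dark",
                                     replicate = 1L) {
  stopifnot(inherits(params, "dose_pop_params"))
  with_seed(seed, {
    n <- params$n_cells
    yap <- rlnorm(n, params$yap_meanlog, params$yap_sdlog)
    noise <- function() 1 + rnorm(n, 0, params$noise_cv)
    oct4 <- do.call(hill_response, c(list(x = yap), unclass(params$oct4_curve))) * noise()
    nanog <- do.call(hill_response, c(list(x = yap), unclass(params$nanog_curve))) * noise()
    lineage <- sample(names(params$lineage_probs), n, replace = TRUE,
                      prob = params$lineage_probs)
    marker <- function(high_for) {
      # background ~N(100, 20) a.u. (truncated at 1); positive cells sit
      # 4 background-SDs higher, the contrast typical of clean IF staining
      mu <- ifelse(lineage == high_for, 180, 100)
      pmax(rnorm(n, mu, 20), 1)
    }
    otx2 <- hill_response(yap, top = 500, bottom = 50, ic50 = 150, n = 1.5) * noise()
    cells <- tibble::tibble(
      cell_id = sprintf("cell_%05d", seq_len(n)),
      yap_au = yap,
      oct4_au = oct4,
      nanog_au = nanog,
      sox1_au = marker("ecto"),
      tbra_au = marker("meso"),
      foxa2_au = marker("endo"),
      otx2_au = otx2,
      lineage_true = lineage,
      condition = condition,
      replicate = as.integer(replicate)
    )
    list(
      cells = cells,
      ground_truth = list(params = rapply(unclass(params), unclass, how = "replace"))
    )
  })
}
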