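# Cross-replicate scaling, IC-quantile gating, lineage-marker cutoff
# classification and dose binning for snapshot cell populations.

#' Scale and pool dose-response replicates
#'
#' Per replicate, both marker curves (default Oct4 and Nanog) are fitted;
#' the dose axis is divided by the midpoint of the two IC50s and
#' multiplied by the grand mean of the midpoints (so dose units are
#' preserved); each marker's response is min-max normalized using its
#' replicate fit's plateaus: `(y - bottom) / (top - bottom)`. Cells below
#' the detection floor are dropped (the no-detectable-expression bin).
#' Replicates whose fits fail are excluded with a warning.
#'
#' @param cells Snapshot table with `replicate`, `yap_au` and the marker
#'   columns.
#' @param markers Marker columns to fit and normalize (default
#'   `c("oct4_au", "nanog_au")`).
#' @param dose_column Dose column (default `yap_au`).
#' @param detection_floor Doses `<= detection_floor` are dropped
#'   (default 0).
#' @return List: `cells` (pooled, scaled table with normalized marker
#'   columns), `fits` (per replicate per marker), `midpoints`.
#' @export
scale_replicates <- function(cells, markers = c("oct4_au", "nanog_au"),
                             dose_column = "yap_au", detection_floor = 0) {
  reps <- sort(unique(cells$replicate))
  fits <- list()
  mids <- numeric(0)
  used <- integer(0)
  for (r in reps) {
    d <- cells[cells$replicate == r, ]
    fr <- tryCatch(
      purrr::map(setNames(markers, markers),
                 function(m) fit_hill(d[[dose_column]], d[[m]])),
      error = function(e) NULL
    )
    if (is.null(fr)) {
      warning(sprintf("replicate %s excluded: curve fit failed", r))
      next
    }
    fits[[as.character(r)]] <- fr
    mids <- c(mids, mean(purrr::map_dbl(fr, "ic50")))
    used <- c(used, r)
  }
  if (length(used) == 0) abort_param("all replicates failed to fit")
  grand <- mean(mids)
  out <- purrr::map_dfr(seq_along(used), function(i) {
    r <- used[i]
    d <- cells[cells$replicate == r & cells[[dose_column]] > detection_floor, ]
    d[[dose_column]] <- d[[dose_column]] / mids[i] * grand
    for (m in markers) {
      f <- fits[[as.character(r)]][[m]]
      d[[m]] <- (d[[m]] - f$bottom) / (f$top - f$bottom)
    }
    d
  })
  list(cells = out, fits = fits,
       midpoints = setNames(mids, as.character(used)))
}

#' Gated median effect and delta versus the dark control
#'
#' The gate threshold is the ICq of the reference (dark-control) fit; per
#' condition the median effect over gated cells is divided by the median
#' effect of low-expressing dark-control cells (doses below the IC
#' `low_q`), and the difference to the dark condition is reported.
#'
#' @param cells Snapshot table with `condition`, the dose and effect
#'   columns.
#' @param reference_fit [fit_hill()] of the dark control.
#' @param q Gate quantile in percent (50 or 5 in practice).
#' @param effect_column Column summarized (e.g. `oct4_au`).
#' @param dose_column Dose column (default `yap_au`).
#' @param dark_label Condition label of the dark control.
#' @param low_q IC quantile defining dark low-expressors (default 5).
#' @return Tibble per condition: `n_gated`, `median_effect`, `normalized`,
#'   `delta`.
#' @export
gate_and_delta <- function(cells, reference_fit, q, effect_column,
                           dose_column = "yap_au", dark_label = "dark",
                           low_q = 5) {
  thr <- icq(reference_fit, q)
  low_thr <- icq(reference_fit, low_q)
  dark <- cells[cells$condition == dark_label, ]
  if (nrow(dark) == 0) abort_param("reference (dark) condition missing")
  low_ref <- median(dark[[effect_column]][dark[[dose_column]] < low_thr])
  if (!is.finite(low_ref) || low_ref == 0) {
    abort_param("dark low-expressor reference is empty or zero")
  }
  out <- cells |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_gated = sum(.data[[dose_column]] >= thr),
      median_effect = median(.data[[effect_column]][.data[[dose_column]] >= thr]),
      .groups = "drop"
    )
  if (any(out$n_gated == 0)) {
    occ <- paste(sprintf("%s: %d", out$condition, out$n_gated), collapse = ", ")
    abort_param(paste0("empty gate for at least one condition (", occ, ")"))
  }
  out$normalized <- out$median_effect / low_ref
  dark_norm <- out$normalized[out$condition == dark_label]
  out$delta <- out$normalized - dark_norm
  out
}

#' Opposing-fate cutoff rule
#'
#' For a target marker, cells in the top `gate_quantile` of the opposing
#' marker define the background gate; the cutoff is the median + 2 SD of
#' the target marker inside that gate; positives exceed the cutoff.
#'
#' @param target,opposing Marker column names.
#' @param gate_quantile Top fraction of the opposing marker (default 0.10).
#' @return A `cutoff_rule` list.
#' @export
cutoff_rule <- function(target, opposing, gate_quantile = 0.10) {
  structure(list(target = target, opposing = opposing,
                 gate_quantile = gate_quantile),
            class = "cutoff_rule")
}

#' Classify lineages by opposing-fate cutoffs
#'
#' Applies each [cutoff_rule()]: the cutoff is recomputed per dataset from
#' the opposing-high gate, cells above it are positive for the target
#' marker. Cells positive for several markers are labelled by their
#' brightest (relative to cutoff); cells positive for none get `"none"`.
#'
#' @param cells Snapshot table with all marker columns.
#' @param rules Named list of [cutoff_rule()]s; names are lineage labels.
#' @return List: `cells` (with `lineage` column and per-marker logicals),
#'   `cutoffs`, `fractions` (per lineage), `co_positive` (cells positive
#'   for > 1 marker).
#' @export
classify_lineage <- function(cells, rules) {
  stopifnot(length(names(rules)) == length(rules))
  cutoffs <- purrr::map_dbl(rules, function(rl) {
    if (!all(c(rl$target, rl$opposing) %in% names(cells))) {
      abort_param(sprintf("marker columns %s/%s missing", rl$target, rl$opposing))
    }
    gate <- cells[[rl$opposing]] >=
      quantile(cells[[rl$opposing]], 1 - rl$gate_quantile)
    if (sum(gate) == 0) abort_param("opposing gate is empty")
    median(cells[[rl$target]][gate]) + 2 * sd(cells[[rl$target]][gate])
  })
  pos <- purrr::imap_dfc(rules, function(rl, nm) {
    tibble::tibble(!!paste0(nm, "_pos") := cells[[rl$target]] > cutoffs[[nm]])
  })
  score <- purrr::imap_dfc(rules, function(rl, nm) {
    tibble::tibble(!!nm := cells[[rl$target]] / cutoffs[[nm]])
  })
  lineage <- apply(as.matrix(score), 1, function(s) {
    if (all(s <= 1)) "none" else names(rules)[which.max(s)]
  })
  out <- dplyr::bind_cols(cells, pos)
  out$lineage <- lineage
  fractions <- purrr::map_dbl(setNames(names(rules), names(rules)),
                              function(nm) mean(pos[[paste0(nm, "_pos")]]))
  list(cells = out, cutoffs = cutoffs, fractions = fractions,
       co_positive = mean(rowSums(as.matrix(pos)) > 1))
}

#' Bin cells by dose and summarize a value column
#'
#' Values are normalized to the lowest bin's median; per bin the mean
#' normalized value and the cell count are reported. Empty bins are kept
#' as `NA` rows. An optional dose floor is applied before counting.
#'
#' @param cells Snapshot table.
#' @param dose_column,value_column Column names.
#' @param bins Number of (quantile) bins, or explicit numeric breaks.
#' @param dose_floor Optional: drop cells with dose below this before
#'   binning.
#' @return Tibble per bin: `bin`, `dose_lo`, `dose_hi`, `n`, `mean_value`
#'   (normalized to the lowest bin's median).
#' @export
bin_and_summarize <- function(cells, dose_column, value_column, bins = 5,
                              dose_floor = NULL) {
  d <- cells
  if (!is.null(dose_floor)) d <- d[d[[dose_column]] >= dose_floor, ]
  breaks <- if (length(bins) == 1) {
    unique(quantile(d[[dose_column]], seq(0, 1, length.out = bins + 1)))
  } else {
    bins
  }
  if (length(breaks) < 3) abort_param("need >= 2 bins")
  bin <- cut(d[[dose_column]], breaks, include.lowest = TRUE)
  lowest_median <- median(d[[value_column]][bin == levels(bin)[1]])
  tibble::tibble(bin = levels(bin),
                 dose_lo = head(breaks, -1), dose_hi = tail(breaks, -1)) |>
    dplyr::left_join(
      tibble::tibble(bin = as.character(bin),
                     value = d[[value_column]] / lowest_median) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(n = dplyr::n(), mean_value = mean(.data$value),
                         .groups = "drop"),
      by = "bin"
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}
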