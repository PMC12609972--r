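#' Background-correct a spot table
#'
#' Subtracts the local background from the foreground in each channel
#' (`s_c = fg_c - bg_c`). Spots where either corrected signal is
#' non-positive are flagged `BAD` (reason `nonpositive`) rather than
#' dropped, so the audit trail survives until [filter_spots()].
#'
#' @param scan A spot-record tibble (one or more arrays).
#' @return The same tibble with columns `s1`, `s2` added and flags updated;
#'   a `reason` column records why a spot was flagged.
#' @export
correct_background <- function(scan) {
  out <- scan %>%
    dplyr::mutate(
      s1 = .data$fg1 - .data$bg1,
      s2 = .data$fg2 - .data$bg2
    )
  nonpos <- out$s1 <= 0 | out$s2 <= 0
  out$reason <- dplyr::if_else(out$flag == "BAD", "flagged", NA_character_)
  out$reason[nonpos & is.na(out$reason)] <- "nonpositive"
  out$flag[nonpos] <- "BAD"
  out
}

#' Filter low-quality spots
#'
#' Removes `BAD`-flagged spots and spots whose signal-to-noise ratio
#' `min(fg1/max(bg1, 1), fg2/max(bg2, 1))` falls below `min_snr`
#' (default 1.5). Attaches per-reason removal counts as the
#' `"filter_report"` attribute.
#'
#' @param scan A background-corrected spot tibble (from
#'   [correct_background()]).
#' @param min_snr Minimum per-channel foreground/background ratio.
#' @param drop_flagged Remove `BAD`-flagged spots (default `TRUE`).
#' @return The filtered tibble; `attr(, "filter_report")` is a tibble with
#'   columns `reason`, `n` plus the totals `n_total` and `n_retained`.
#' @export
filter_spots <- function(scan, min_snr = 1.5, drop_flagged = TRUE) {
  if (!all(c("s1", "s2") %in% names(scan))) {
    abort("`scan` must be background-corrected first (see correct_background())")
  }
  snr <- pmin(scan$fg1 / pmax(scan$bg1, 1), scan$fg2 / pmax(scan$bg2, 1))
  low_snr <- snr < min_snr
  flagged <- scan$flag == "BAD"
  drop <- (drop_flagged & flagged) | (low_snr & !flagged)
  reason <- dplyr::case_when(
    drop_flagged & flagged ~ dplyr::coalesce(scan$reason, "flagged"),
    low_snr ~ "low_snr",
    TRUE ~ NA_character_
  )
  report <- dplyr::count(tibble::tibble(reason = reason[drop]), .data$reason, name = "n")
  out <- scan[!drop, , drop = FALSE]
  if (nrow(out) == 0) abort("all spots removed by filtering")
  attr(out, "filter_report") <- list(
    by_reason = report,
    n_total = nrow(scan),
    n_retained = nrow(out)
  )
  out
}

#' Compute per-spot MA coordinates
#'
#' For each retained spot, `M = log2(s2) - log2(s1)` (treated minus
#' control) and `A = (log2(s1) + log2(s2)) / 2`. For arrays recorded with
#' `dye_orientation == "swapped"` the channels were physically exchanged,
#' so M is negated to keep the treated-minus-control orientation.
#'
#' @param scan A filtered, background-corrected spot tibble.
#' @return A tibble `array_id`, `spot_id`, `gene`, `A`, `M`.
#' @export
compute_ratios <- function(scan) {
  if (!all(c("s1", "s2") %in% names(scan))) {
    abort("`scan` must be background-corrected first (see correct_background())")
  }
  if (any(scan$s1 <= 0 | scan$s2 <= 0)) {
    abort("internal contract violation: non-positive signal reached compute_ratios()")
  }
  scan %>%
    dplyr::mutate(
      M = (log2(.data$s2) - log2(.data$s1)) *
        dplyr::if_else(.data$dye_orientation == "swapped", -1, 1),
      A = (log2(.data$s1) + log2(.data$s2)) / 2
    ) %>%
    dplyr::select("array_id", "spot_id", "gene", "A", "M")
}

#' LOWESS dye-bias normalization in MA coordinates
#'
#' Fits a locally weighted regression of M on A (tricube weights, span
#' `span`, 3 robustness iterations — classic Cleveland LOWESS) separately
#' for each array and subtracts the fit: `M' = M - f(A)`. This removes the
#' intensity-dependent dye bias that bends the MA cloud. Below
#' `min_records` points the fit is unreliable and the function falls back
#' to median-centering with a warning.
#'
#' @param records A ratio tibble from [compute_ratios()].
#' @param span LOWESS span (fraction of points in each local fit).
#' @param min_records Minimum points per array for a LOWESS fit.
#' @return The tibble with `M` replaced by the normalized value and a
#'   `fit` column holding the subtracted curve evaluation (for MA plots).
#' @export
lowess_normalize <- function(records, span = 0.3, min_records = 50) {
  records %>%
    dplyr::group_by(.data$array_id) %>%
    dplyr::group_modify(function(df, key) {
      if (length(unique(df$A)) == 1) {
        abort("degenerate fit: A is constant across records")
      }
      if (nrow(df) < min_records) {
        warn(sprintf("array %s: only %d records; falling back to median-centering",
                     key$array_id, nrow(df)))
        fit <- rep(stats::median(df$M), nrow(df))
      } else {
        lw <- stats::lowess(df$A, df$M, f = span, iter = 3)
        fit <- stats::approx(lw$x, lw$y, xout = df$A, ties = mean, rule = 2)$y
      }
      df$fit <- fit
      df$M <- df$M - fit
      df
    }) %>%
    dplyr::ungroup()
}

#' Average duplicate spots and biological replicate arrays
#'
#' Per gene: normalized log-ratios of duplicate spots are averaged within
#' each array first, then the per-array means are averaged (unweighted)
#' across arrays. Genes observed in fewer than `min_arrays` arrays are
#' dropped and reported in the `"dropped_genes"` attribute.
#'
#' @param records Normalized ratio records (all arrays in one tibble).
#' @param min_arrays Minimum number of arrays a gene must appear in.
#' @return A tibble `gene`, `A`, `R`, `n_spots`, `n_arrays` where `R` is the
#'   final averaged normalized log2 ratio and `A` the mean average
#'   intensity.
#' @export
average_replicates <- function(records, min_arrays = 1) {
  per_array <- records %>%
    dplyr::group_by(.data$gene, .data$array_id) %>%
    dplyr::summarise(
      A = mean(.data$A), M = mean(.data$M), n_spots = dplyr::n(),
      .groups = "drop"
    )
  out <- per_array %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      A = mean(.data$A), R = mean(.data$M),
      n_spots = sum(.data$n_spots), n_arrays = dplyr::n(),
      .groups = "drop"
    )
  dropped <- out$gene[out$n_arrays < min_arrays]
  out <- out[out$n_arrays >= min_arrays, , drop = FALSE]
  if (nrow(out) == 0) abort("no genes survive replicate averaging")
  attr(out, "dropped_genes") <- dropped
  out
}

#' Quality-control report for a replicate experiment
#'
#' Computes the spot-pass fraction per array (from the [filter_spots()]
#' report when supplied), pairwise Pearson correlations of gene-level
#' normalized log-ratios between arrays, and verdicts against the
#' conventional thresholds: replicate consistency r > 0.85, array-to-array
#' reproducibility r > 0.90, and > 95% of spots passing filters.
#'
#' @param records Normalized ratio records for all arrays.
#' @param filter_reports Optional named list (by array_id) of
#'   `"filter_report"` attributes from [filter_spots()].
#' @param r_replicate,r_array,pass_fraction QC thresholds.
#' @return A list of class `"qc_report"` with elements `pass_fraction`
#'   (tibble per array), `correlations` (tibble of array pairs), and
#'   `verdicts` (named logical vector).
#' @export
qc_report <- function(records, filter_reports = NULL,
                      r_replicate = 0.85, r_array = 0.90,
                      pass_fraction = 0.95) {
  gene_level <- records %>%
    dplyr::group_by(.data$array_id, .data$gene) %>%
    dplyr::summarise(M = mean(.data$M), .groups = "drop")
  arrays <- unique(gene_level$array_id)
  cors <- NULL
  if (length(arrays) >= 2) {
    pairs <- utils::combn(arrays, 2)
    cors <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- gene_level[gene_level$array_id == pairs[1, j], c("gene", "M")]
      b <- gene_level[gene_level$array_id == pairs[2, j], c("gene", "M")]
      shared <- dplyr::inner_join(a, b, by = "gene", suffix = c("_a", "_b"))
      tibble::tibble(
        array_a = pairs[1, j], array_b = pairs[2, j],
        n_genes = nrow(shared),
        r = stats::cor(shared$M_a, shared$M_b)
      )
    })
  }
  pass <- NULL
  if (!is.null(filter_reports)) {
    pass <- purrr::imap_dfr(filter_reports, function(rep, id) {
      tibble::tibble(array_id = id,
                     pass_fraction = rep$n_retained / rep$n_total)
    })
  }
  verdicts <- c(
    replicate_consistency = if (is.null(cors)) NA else all(cors$r > r_replicate),
    array_reproducibility = if (is.null(cors)) NA else all(cors$r > r_array),
    spot_pass = if (is.null(pass)) NA else all(pass$pass_fraction > pass_fraction)
  )
  structure(
    list(pass_fraction = pass, correlations = cors, verdicts = verdicts,
         thresholds = c(r_replicate = r_replicate, r_array = r_array,
                        pass_fraction = pass_fraction)),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  if (!is.null(x$pass_fraction)) {
    cat("Spot pass fractions:\n")
    print(x$pass_fraction)
  }
  if (!is.null(x$correlations)) {
    cat("Between-array correlations (gene-level M):\n")
    print(x$correlations)
  } else {
    cat("Between-array correlations: not applicable (< 2 arrays)\n")
  }
  cat("Verdicts:\n")
  print(x$verdicts)
  invisible(x)
}

#' Run the full preprocessing chain on simulated or imported scans
#'
#' Convenience wrapper: background correction, spot filtering, MA-ratio
#' computation, per-array LOWESS normalization, and replicate averaging.
#'
#' @param scans Spot-record tibble covering one or more arrays.
#' @param min_snr,span,min_arrays Passed to the component steps.
#' @return A tibble of gene-level records (`gene`, `A`, `R`, `n_spots`,
#'   `n_arrays`); the per-array filter reports are attached as the
#'   `"filter_reports"` attribute and the normalized per-spot records as
#'   `"spot_records"`.
#' @export
preprocess_experiment <- function(scans, min_snr = 1.5, span = 0.3, min_arrays = 1) {
  corrected <- correct_background(scans)
  split_arrays <- split(corrected, corrected$array_id)
  filtered <- purrr::map(split_arrays, filter_spots, min_snr = min_snr)
  reports <- purrr::map(filtered, attr, "filter_report")
  ratios <- purrr::map_dfr(filtered, compute_ratios)
  normalized <- lowess_normalize(ratios, span = span)
  gene_level <- average_replicates(normalized, min_arrays = min_arrays)
  attr(gene_level, "filter_reports") <- reports
  attr(gene_level, "spot_records") <- normalized
  gene_level
}
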