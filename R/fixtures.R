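#' Bundled case-study tables
#'
#' `case_study_zscores()` returns the published per-gene intensity-dependent
#' Z-scores of the cisplatin rat-brain case study the package was built
#' around: the top 25 upregulated and the printed downregulated genes (56
#' rows in total). Feeding the `zscore` column to [call_genes()]-style
#' thresholds (inclusive Z >= 2 / Z <= -2) reproduces the study's headline
#' counts for this table.
#'
#' `case_study_literature()` returns the bundled slice of the curated
#' literature-comparison database: the genes the case study explicitly
#' names as previously reported upregulated, downregulated, or stably
#' expressed (SEG). Only explicitly named genes are included; the full
#' curated database is not redistributed.
#'
#' @return A tibble (`gene`, `zscore`) or (`symbol`, `label`,
#'   `provenance`).
#' @export
case_study_zscores <- function() {
  path <- system.file("extdata", "case_study_zscores.tsv", package = "arrayz",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = "cd", progress = FALSE)
}

#' @rdname case_study_zscores
#' @export
case_study_literature <- function() {
  path <- system.file("extdata", "case_study_literature.tsv", package = "arrayz",
                      mustWork = TRUE)
  read_literature_table(path)
}

#' Call differential expression directly from a Z-score table
#'
#' Applies the inclusive UP/DOWN/STABLE thresholds to a plain table of
#' per-gene Z-scores (no window statistics required), e.g. the bundled
#' [case_study_zscores()].
#'
#' @param zscores A tibble with columns `gene` and `zscore`.
#' @param thresholds A [de_thresholds()] object.
#' @return A tibble `gene`, `z`, `call`.
#' @export
call_from_zscores <- function(zscores, thresholds = de_thresholds()) {
  z <- zscores$zscore
  call <- dplyr::case_when(
    is.na(z) ~ "NONE",
    z >= thresholds$up_threshold ~ "UP",
    z <= thresholds$down_threshold ~ "DOWN",
    abs(z) <= thresholds$seg_band ~ "STABLE",
    TRUE ~ "NONE"
  )
  tibble::tibble(
    gene = zscores$gene,
    z = z,
    call = factor(call, levels = c("UP", "DOWN", "STABLE", "NONE"))
  )
}
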