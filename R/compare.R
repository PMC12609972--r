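#' Standardize gene symbols
#'
#' Trims whitespace, upper-cases, and optionally applies an alias table
#' (columns `alias`, `canonical`) so study and literature symbols can be
#' compared. Aliases are matched after case-folding; unresolved symbols
#' pass through unchanged. Idempotent.
#'
#' @param symbols Character vector.
#' @param alias_table Optional tibble/data frame with columns `alias`,
#'   `canonical`.
#' @return A character vector of canonical symbols, with the attribute
#'   `"mapping"` holding a tibble `input`, `output` for the symbols that
#'   changed.
#' @export
standardize_symbols <- function(symbols, alias_table = NULL) {
  if (length(symbols) == 0) abort("`symbols` must be nonempty")
  out <- toupper(stringr::str_trim(symbols))
  if (!is.null(alias_table)) {
    stopifnot(all(c("alias", "canonical") %in% names(alias_table)))
    key <- toupper(stringr::str_trim(alias_table$alias))
    val <- toupper(stringr::str_trim(alias_table$canonical))
    hit <- match(out, key)
    out[!is.na(hit)] <- val[hit[!is.na(hit)]]
  }
  changed <- symbols != out
  attr(out, "mapping") <- tibble::tibble(input = symbols[changed], output = out[changed])
  out
}

#' Classify study calls against a literature database
#'
#' Cross-tabulates the study's UP/DOWN calls with literature labels into
#' the categories behind a study-versus-literature concordance figure:
#'
#' * `concordant_up` / `concordant_down`: same direction both sides;
#' * `discordant_down_vs_litUP`: study DOWN, literature UP;
#' * `discordant_up_vs_litDOWN`: study UP, literature DOWN;
#' * `study_only_up` / `study_only_down`: no directional literature report
#'   (absent from the database, or listed there as SEG);
#' * `lit_seg_not_de`: literature stably-expressed genes that the study did
#'   not call differentially expressed;
#' * `stable_overlap_up` / `stable_overlap_down`: study DEGs that also
#'   appear in `stable_genes` (a caller-supplied set of genes deemed stably
#'   expressed under basal conditions, e.g. from a control-vs-control
#'   contrast).
#'
#' The first six categories partition the study DEG list; the last three
#' are supplementary intersections and may overlap the partition.
#'
#' @param calls A `de_calls` object or its [tidy()] tibble (columns `gene`,
#'   `call`).
#' @param lit A literature tibble (`symbol`, `label`).
#' @param stable_genes Optional character vector of stably expressed genes
#'   for the `stable_overlap_*` categories.
#' @return A list of class `"overlap_report"`: `categories` (named list of
#'   gene vectors) and `counts` (tibble `category`, `n`).
#' @export
classify_overlap <- function(calls, lit, stable_genes = NULL) {
  if (inherits(calls, "de_calls")) calls <- tidy(calls)
  if (anyDuplicated(lit$symbol)) {
    abort("invariant violation: a symbol carries two literature labels")
  }
  up <- calls$gene[calls$call == "UP"]
  down <- calls$gene[calls$call == "DOWN"]
  lit_up <- lit$symbol[lit$label == "UP"]
  lit_down <- lit$symbol[lit$label == "DOWN"]
  lit_seg <- lit$symbol[lit$label == "SEG"]

  categories <- list(
    concordant_up = intersect(up, lit_up),
    concordant_down = intersect(down, lit_down),
    discordant_down_vs_litUP = intersect(down, lit_up),
    discordant_up_vs_litDOWN = intersect(up, lit_down),
    study_only_up = setdiff(up, c(lit_up, lit_down)),
    study_only_down = setdiff(down, c(lit_up, lit_down)),
    lit_seg_not_de = setdiff(lit_seg, c(up, down)),
    stable_overlap_up = intersect(up, stable_genes %||% character(0)),
    stable_overlap_down = intersect(down, stable_genes %||% character(0))
  )
  structure(
    list(
      categories = categories,
      counts = tibble::tibble(
        category = names(categories),
        n = unname(purrr::map_int(categories, length))
      )
    ),
    class = "overlap_report"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
tidy.overlap_report <- function(x, ...) {
  purrr::imap_dfr(x$categories, function(genes, cat) {
    if (length(genes) == 0) return(NULL)
    tibble::tibble(category = cat, gene = genes)
  })
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Study-versus-literature overlap\n")
  print(x$counts)
  invisible(x)
}

#' Venn region counts for two or three named gene sets
#'
#' Counts every exclusive region of the 2- or 3-set Venn partition, with
#' percentages relative to the union of all sets.
#'
#' @param sets A named list of 2 or 3 character vectors.
#' @return A tibble `region`, `n`, `pct` where `region` names the sets the
#'   region belongs to, separated by `&` (e.g. `"A&B"` for the exclusive
#'   intersection of A and B only).
#' @export
venn_counts <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list")
  }
  k <- length(sets)
  if (k < 2 || k > 3) abort("unsupported arity: venn_counts() handles 2 or 3 sets")
  sets <- purrr::map(sets, unique)
  universe <- unique(unlist(sets))
  membership <- purrr::map(sets, ~ universe %in% .x)
  mat <- do.call(cbind, membership)
  pattern <- apply(mat, 1, function(row) paste(names(sets)[row], collapse = "&"))
  all_patterns <- unlist(purrr::map(seq_len(k), function(m) {
    utils::combn(names(sets), m, paste, collapse = "&")
  }))
  counts <- table(factor(pattern, levels = all_patterns))
  tibble::tibble(
    region = names(counts),
    n = as.integer(counts),
    pct = if (length(universe) > 0) 100 * as.integer(counts) / length(universe) else 0
  )
}
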