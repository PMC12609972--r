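#' Read and write spot-level two-channel quantification tables
#'
#' The native dialect is a plain TSV with columns `spot_id`, `gene`, `fg1`,
#' `bg1`, `fg2`, `bg2`, `flag` (channel 1 = control, channel 2 = treated).
#' Scanner exports with other headers (e.g. GenePix-style "F635 Mean") are
#' supported through `col_map`, a named character vector mapping native
#' names to the file's header names. Flags are normalized to `OK`/`BAD`
#' through `bad_flags`: any flag value listed there (or, for numeric
#' GenePix-style flag columns, any negative value) becomes `BAD`.
#'
#' @param path File path.
#' @param array_id Identifier for the scan; defaults to the file name.
#' @param dye_orientation `"standard"` (channel 2 = treated) or `"swapped"`.
#' @param col_map Optional named character vector, e.g.
#'   `c(fg2 = "F635 Mean", bg2 = "B635 Mean", fg1 = "F532 Mean",
#'      bg1 = "B532 Mean", gene = "Name", spot_id = "ID", flag = "Flags")`.
#' @param bad_flags Character vector of flag values to normalize to `BAD`.
#' @return A tibble of spot records with columns `array_id`,
#'   `dye_orientation`, `spot_id`, `gene`, `fg1`, `bg1`, `fg2`, `bg2`,
#'   `flag`.
#' @export
read_spot_table <- function(path, array_id = basename(path),
                            dye_orientation = c("standard", "swapped"),
                            col_map = NULL, bad_flags = c("BAD", "bad")) {
  dye_orientation <- match.arg(dye_orientation)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("spot_id", "gene", "fg1", "bg1", "fg2", "bg2", "flag")
  header <- stats::setNames(needed, needed)
  if (!is.null(col_map)) header[names(col_map)] <- col_map
  missing <- header[!header %in% names(raw)]
  if (length(missing) > 0) {
    abort(sprintf("format error: missing column(s) %s (expected header(s) %s)",
                  paste(names(missing), collapse = ", "),
                  paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    array_id = array_id,
    dye_orientation = dye_orientation,
    spot_id = raw[[header["spot_id"]]],
    gene = raw[[header["gene"]]],
    fg1 = suppressWarnings(as.numeric(raw[[header["fg1"]]])),
    bg1 = suppressWarnings(as.numeric(raw[[header["bg1"]]])),
    fg2 = suppressWarnings(as.numeric(raw[[header["fg2"]]])),
    bg2 = suppressWarnings(as.numeric(raw[[header["bg2"]]])),
    flag = raw[[header["flag"]]]
  )
  bad_rows <- which(is.na(out$fg1) | is.na(out$bg1) | is.na(out$fg2) | is.na(out$bg2))
  if (length(bad_rows) > 0) {
    abort(sprintf("validation error: non-numeric intensity in row(s) %s",
                  paste(utils::head(bad_rows, 10), collapse = ", ")))
  }
  neg <- which(out$fg1 < 0 | out$bg1 < 0 | out$fg2 < 0 | out$bg2 < 0)
  if (length(neg) > 0) {
    abort(sprintf("validation error: negative intensity in row(s) %s",
                  paste(utils::head(neg, 10), collapse = ", ")))
  }
  if (any(out$gene == "" | is.na(out$gene))) {
    abort("validation error: empty gene symbol")
  }
  if (anyDuplicated(out$spot_id)) {
    abort("validation error: duplicate spot_id within array")
  }
  # normalize flags: numeric GenePix-style flags are BAD when negative
  num_flag <- suppressWarnings(as.numeric(out$flag))
  is_bad <- out$flag %in% bad_flags | (!is.na(num_flag) & num_flag < 0)
  out$flag <- ifelse(is_bad, "BAD", "OK")
  out
}

#' @rdname read_spot_table
#' @param scan A spot-record tibble as returned by [read_spot_table()] or
#'   [simulate_experiment()] (one array).
#' @export
write_spot_table <- function(scan, path) {
  readr::write_tsv(scan[, c("spot_id", "gene", "fg1", "bg1", "fg2", "bg2", "flag")],
                   path, progress = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' GMT is the tab-separated format `term_id<TAB>description<TAB>member...`,
#' one term per line. Duplicate members within a term are collapsed with a
#' warning; lines with fewer than three fields are a format error.
#'
#' @param path File path.
#' @return A long tibble with columns `term_id`, `term_name`, `gene`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  out <- purrr::imap_dfr(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("format error: line %d has fewer than 3 fields", i))
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warn(sprintf("term %s: duplicate members collapsed", fields[1]))
      members <- unique(members)
    }
    tibble::tibble(term_id = fields[1], term_name = fields[2], gene = members)
  })
  if (anyDuplicated(unique(out[, c("term_id", "term_name")])$term_id)) {
    abort("format error: duplicated term_id in collection")
  }
  out
}

#' @rdname read_gmt
#' @param collection A long tibble `term_id`, `term_name`, `gene`.
#' @export
write_gmt <- function(collection, path) {
  lines <- collection %>%
    dplyr::group_by(.data$term_id, .data$term_name) %>%
    dplyr::summarise(members = paste(.data$gene, collapse = "\t"), .groups = "drop") %>%
    dplyr::arrange(.data$term_id) %>%
    dplyr::mutate(line = paste(.data$term_id, .data$term_name, .data$members, sep = "\t"))
  readr::write_lines(lines$line, path)
  invisible(path)
}

#' Read and write scored interaction edge lists
#'
#' Three-column TSV `node1<TAB>node2<TAB>score` with scores in [0, 1].
#' Edges are undirected: pairs are canonicalized, duplicate pairs keep the
#' maximum score, and self-loops are dropped with a warning.
#'
#' @param path File path.
#' @return A tibble `node1`, `node2`, `score` with `node1 < node2`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_names = c("node1", "node2", "score"),
                         col_types = "ccd", progress = FALSE)
  if (any(is.na(raw$score) | raw$score < 0 | raw$score > 1)) {
    abort("validation error: scores must lie in [0, 1]")
  }
  loops <- raw$node1 == raw$node2
  if (any(loops)) {
    warn(sprintf("%d self-loop(s) dropped", sum(loops)))
    raw <- raw[!loops, , drop = FALSE]
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(node1 = character(), node2 = character(), score = double()))
  }
  raw %>%
    dplyr::mutate(a = pmin(.data$node1, .data$node2),
                  b = pmax(.data$node1, .data$node2)) %>%
    dplyr::group_by(.data$a, .data$b) %>%
    dplyr::summarise(score = max(.data$score), .groups = "drop") %>%
    dplyr::transmute(node1 = .data$a, node2 = .data$b, score = .data$score)
}

#' @rdname read_edge_list
#' @param edges A tibble `node1`, `node2`, `score`.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(edges[, c("node1", "node2", "score")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a curated literature table of reported expression changes
#'
#' Expects columns `symbol`, `label`, `provenance` (TSV or CSV, sniffed
#' from the file). Labels must be `UP`, `DOWN`, or `SEG` (stably expressed
#' gene); a symbol listed twice with conflicting labels is an error.
#'
#' @param path File path.
#' @return A tibble `symbol`, `label`, `provenance`.
#' @export
read_literature_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readr::read_lines(path, n_max = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  needed <- c("symbol", "label")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("format error: missing column(s) %s", paste(missing, collapse = ", ")))
  }
  if (!"provenance" %in% names(raw)) raw$provenance <- NA_character_
  bad <- which(!raw$label %in% c("UP", "DOWN", "SEG"))
  if (length(bad) > 0) {
    abort(sprintf("validation error: unknown label in row(s) %s",
                  paste(bad, collapse = ", ")))
  }
  conf <- raw %>%
    dplyr::distinct(.data$symbol, .data$label) %>%
    dplyr::count(.data$symbol) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(conf) > 0) {
    abort(sprintf("validation error: conflicting labels for symbol(s) %s",
                  paste(conf$symbol, collapse = ", ")))
  }
  raw %>%
    dplyr::distinct(.data$symbol, .keep_all = TRUE) %>%
    dplyr::select("symbol", "label", "provenance")
}

#' Read and write clinical cohort tables
#'
#' TSV with columns `subject`, `time`, `event` (0 censored / 1 event) and
#' one numeric column per gene.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("subject", "time", "event"), names(out))
  if (length(missing) > 0) {
    abort(sprintf("format error: missing column(s) %s", paste(missing, collapse = ", ")))
  }
  if (any(out$time <= 0)) abort("validation error: follow-up times must be positive")
  if (!all(out$event %in% c(0, 1))) abort("validation error: event must be 0 or 1")
  out
}

#' @rdname read_cohort_table
#' @param cohort A cohort tibble.
#' @export
write_cohort_table <- function(cohort, path) {
  readr::write_tsv(cohort, path, progress = FALSE)
  invisible(path)
}
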