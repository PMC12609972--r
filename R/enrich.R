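#' Hypergeometric over-representation analysis
#'
#' Tests each term of a gene-set collection for over-representation in a
#' query gene list against a background universe, using the one-sided
#' hypergeometric upper tail: with `N` background genes, `K` of them in the
#' term, and a query of size `n` hitting the term `k` times,
#' `p = P[X >= k]` for `X ~ Hypergeometric(N, K, n)`. Fold enrichment is
#' `FE = (k/n) / (K/N)`. Terms are intersected with the background before
#' testing and only terms with `k >= 1` are reported. Benjamini-Hochberg
#' FDR is applied across the reported terms of the collection.
#'
#' @param query Character vector of query genes (must lie in `background`).
#' @param collection Long gene-set tibble (`term_id`, `term_name`, `gene`),
#'   e.g. from [read_gmt()].
#' @param background Character vector: the gene universe (for a spotted
#'   array, every probe on the platform).
#' @return An object of class `"enrich_result"`; [tidy()] returns the
#'   per-term tibble (`term_id`, `term_name`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment`, `p`, `fdr`, `tier`), [glance()] the tier counts.
#' @export
hypergeom_enrich <- function(query, collection, background) {
  query <- unique(query)
  background <- unique(background)
  if (length(query) == 0 || length(background) == 0) {
    abort("`query` and `background` must be nonempty")
  }
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    abort(sprintf("query genes not in background: %s",
                  paste(utils::head(outside, 10), collapse = ", ")))
  }
  N <- length(background)
  n <- length(query)
  terms <- collection %>%
    dplyr::filter(.data$gene %in% background) %>%
    dplyr::distinct(.data$term_id, .data$term_name, .data$gene) %>%
    dplyr::group_by(.data$term_id, .data$term_name) %>%
    dplyr::summarise(
      K = dplyr::n(),
      k = sum(.data$gene %in% query),
      members = list(intersect(.data$gene, query)),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$k >= 1)
  if (nrow(terms) == 0) {
    records <- tibble::tibble(
      term_id = character(), term_name = character(),
      k = integer(), n = integer(), K = integer(), N = integer(),
      fold_enrichment = double(), p = double(), fdr = double(),
      tier = character()
    )
    return(structure(list(records = records, members = list(),
                          query = query, background = background),
                     class = "enrich_result"))
  }
  records <- terms %>%
    dplyr::mutate(
      n = n, N = N,
      fold_enrichment = (.data$k / n) / (.data$K / N),
      p = stats::phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE)
    )
  records$fdr <- adjust_bh(records$p)
  members <- stats::setNames(records$members, records$term_id)
  records <- records %>%
    dplyr::select("term_id", "term_name", "k", "n", "K", "N",
                  "fold_enrichment", "p", "fdr") %>%
    dplyr::arrange(.data$p)
  res <- structure(list(records = records, members = members,
                        query = query, background = background),
                   class = "enrich_result")
  tier_enrichment(res)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' and capping at 1 (delegates to [stats::p.adjust()] after validating the
#' input range).
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted values, same length and order.
#' @export
adjust_bh <- function(pvals) {
  if (any(is.na(pvals) | pvals <= 0 | pvals > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Assign significance tiers and apply the fold-enrichment filter
#'
#' Tiers: `significant` at `fdr <= fdr_sig` (default 0.05), `suggestive` at
#' `fdr_sig < fdr <= fdr_sugg` (default 0.10), else `none`. When
#' `apply_fe` is `TRUE`, records failing `fold_enrichment >= fe_min`
#' (default 5) are demoted to `none` regardless of FDR; the raw record is
#' retained so filtering is reportable.
#'
#' @param result An `"enrich_result"`.
#' @param fdr_sig,fdr_sugg,fe_min,apply_fe Tiering parameters.
#' @return The `"enrich_result"` with the `tier` column set.
#' @export
tier_enrichment <- function(result, fdr_sig = 0.05, fdr_sugg = 0.10,
                            fe_min = 5, apply_fe = TRUE) {
  stopifnot(inherits(result, "enrich_result"))
  rec <- result$records
  tier <- dplyr::case_when(
    rec$fdr <= fdr_sig ~ "significant",
    rec$fdr <= fdr_sugg ~ "suggestive",
    TRUE ~ "none"
  )
  if (apply_fe) {
    tier[rec$fold_enrichment < fe_min] <- "none"
  }
  rec$tier <- factor(tier, levels = c("significant", "suggestive", "none"))
  result$records <- rec
  result
}

#' @export
tidy.enrich_result <- function(x, ...) x$records

#' @export
glance.enrich_result <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x$records),
    n_significant = sum(x$records$tier == "significant"),
    n_suggestive = sum(x$records$tier == "suggestive")
  )
}

#' @export
print.enrich_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Over-representation: %d terms tested | %d significant, %d suggestive\n",
              g$n_terms, g$n_significant, g$n_suggestive))
  print(utils::head(x$records, 10))
  invisible(x)
}

#' @export
autoplot.enrich_result <- function(object, max_terms = 20, ...) {
  df <- utils::head(dplyr::arrange(object$records, .data$fdr), max_terms)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_enrichment,
                                   y = stats::reorder(.data$term_name, -.data$fdr),
                                   size = .data$k,
                                   colour = -log10(.data$fdr))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fold enrichment", y = NULL, size = "genes",
                  colour = expression(-log[10] * "(FDR)")) +
    ggplot2::theme_minimal()
}

#' Term-overlap network of tiered enrichment results
#'
#' Builds the network whose nodes are retained (significant/suggestive)
#' terms — node size attribute `k`, color attribute `-log10(fdr)` — and
#' whose edges join term pairs sharing query genes: edge weight is the
#' shared-gene count and an edge is drawn when the Jaccard similarity of
#' the query-restricted member sets reaches `min_similarity`.
#'
#' @param result A tiered `"enrich_result"`.
#' @param min_similarity Jaccard threshold for drawing an edge.
#' @param tiers Tiers to retain as nodes.
#' @return A list of class `"term_network"` with tibbles `nodes` (`term_id`,
#'   `term_name`, `k`, `fdr`, `neg_log10_fdr`) and `edges` (`term_a`,
#'   `term_b`, `shared`, `similarity`).
#' @export
build_term_network <- function(result, min_similarity = 0.2,
                               tiers = c("significant", "suggestive")) {
  stopifnot(inherits(result, "enrich_result"))
  rec <- dplyr::filter(result$records, .data$tier %in% tiers)
  nodes <- rec %>%
    dplyr::transmute(
      term_id = .data$term_id, term_name = .data$term_name,
      k = .data$k, fdr = .data$fdr,
      neg_log10_fdr = -log10(.data$fdr)
    )
  edges <- tibble::tibble(term_a = character(), term_b = character(),
                          shared = integer(), similarity = double())
  if (nrow(nodes) >= 2) {
    pairs <- utils::combn(nodes$term_id, 2)
    edges <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- result$members[[pairs[1, j]]]
      b <- result$members[[pairs[2, j]]]
      shared <- length(intersect(a, b))
      uni <- length(union(a, b))
      sim <- if (uni == 0) 0 else shared / uni
      tibble::tibble(term_a = pairs[1, j], term_b = pairs[2, j],
                     shared = shared, similarity = sim)
    }) %>%
      dplyr::filter(.data$similarity >= min_similarity)
  }
  structure(list(nodes = nodes, edges = edges), class = "term_network")
}

#' @export
print.term_network <- function(x, ...) {
  cat(sprintf("Term network: %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
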