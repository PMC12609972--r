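#' Dosing regimen helpers
#'
#' A dose regimen describes a multi-cycle schedule of repeated injections:
#' `dose_per_injection` (mg/kg), `injections_per_cycle`, and `n_cycles`.
#' [cumulative_dose()] returns the total administered dose in mg/kg. The
#' default regimen (2 mg/kg per injection, two injections per cycle, five
#' cycles) is the cumulative cisplatin schedule the simulated experiment
#' emulates, totalling 20 mg/kg.
#'
#' @param dose_per_injection Dose of a single injection, mg/kg.
#' @param injections_per_cycle Number of injections in one cycle.
#' @param n_cycles Number of cycles.
#' @return `dose_regimen()` returns a list of class `"dose_regimen"`;
#'   `cumulative_dose()` returns a single number (mg/kg).
#' @examples
#' cumulative_dose(dose_regimen(2, 2, 5))  # 20 mg/kg
#' @export
dose_regimen <- function(dose_per_injection = 2, injections_per_cycle = 2, n_cycles = 5) {
  stop_if_not_positive(dose_per_injection, "dose_per_injection")
  stop_if_not_count(injections_per_cycle, "injections_per_cycle")
  stop_if_not_count(n_cycles, "n_cycles")
  structure(
    list(
      dose_per_injection = dose_per_injection,
      injections_per_cycle = as.integer(injections_per_cycle),
      n_cycles = as.integer(n_cycles)
    ),
    class = "dose_regimen"
  )
}

#' @rdname dose_regimen
#' @param regimen A `dose_regimen` object.
#' @export
cumulative_dose <- function(regimen) {
  stopifnot(inherits(regimen, "dose_regimen"))
  regimen$dose_per_injection * regimen$injections_per_cycle * regimen$n_cycles
}

#' Simulation configuration for a two-color array experiment
#'
#' Bundles every knob of the spot-level simulator. The defaults are the
#' study conditions the package's tests and acceptance checks run under:
#' a 5000-probe array printed in duplicate, two biological replicate
#' hybridizations, 6% of genes truly differentially expressed at
#' |log2 fold change| = 2, log-normal spot intensities, an additive
#' background, a cubic intensity-dependent dye-bias curve, and ratio noise
#' whose SD shrinks log-linearly from 0.4 at low average intensity to 0.15
#' at high average intensity (low-intensity spots are noisier, which is
#' what motivates the intensity-dependent Z-score downstream).
#'
#' @param n_genes Number of gene-specific probes.
#' @param n_duplicate_spots Spots printed per gene per array.
#' @param n_arrays Number of biological replicate hybridizations.
#' @param prop_de Fraction of genes truly differentially expressed.
#' @param de_log2fc_magnitude Absolute true log2 fold change of DE genes.
#' @param base_intensity_log_mean,base_intensity_log_sd Mean and SD of the
#'   per-gene baseline log2 intensity.
#' @param dye_bias_coeffs Polynomial coefficients `c(c0, c1, c2, ...)` of the
#'   dye-bias curve evaluated at centered intensity
#'   `x = A - base_intensity_log_mean`: the bias added to M is
#'   `c0 + c1*x + c2*x^2 + ...`. Set to `0` for bias-free arrays.
#' @param background_level Mean additive background intensity per channel.
#' @param noise_sd_at_low_A,noise_sd_at_high_A Ratio-noise SD at the low and
#'   high ends of the intensity range; interpolated log-linearly in between.
#' @param dye_swap_arrays If `TRUE`, even-numbered arrays are simulated with
#'   swapped dye orientation.
#' @param seed Integer master seed; identical configurations produce
#'   identical output.
#' @param regimen A [dose_regimen()] recorded alongside the experiment.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 5000,
                       n_duplicate_spots = 2,
                       n_arrays = 2,
                       prop_de = 0.06,
                       de_log2fc_magnitude = 2,
                       base_intensity_log_mean = 10,
                       base_intensity_log_sd = 2,
                       dye_bias_coeffs = c(0.3, -0.06, 0.008, -0.0008),
                       background_level = 50,
                       noise_sd_at_low_A = 0.4,
                       noise_sd_at_high_A = 0.15,
                       dye_swap_arrays = FALSE,
                       seed = 1L,
                       regimen = dose_regimen()) {
  stop_if_not_count(n_genes, "n_genes")
  stop_if_not_count(n_duplicate_spots, "n_duplicate_spots")
  stop_if_not_count(n_arrays, "n_arrays")
  if (!is.numeric(prop_de) || prop_de < 0 || prop_de > 1) {
    abort("configuration error: `prop_de` must be in [0, 1]")
  }
  if (!is.numeric(de_log2fc_magnitude) || de_log2fc_magnitude < 0) {
    abort("configuration error: `de_log2fc_magnitude` must be >= 0")
  }
  stop_if_not_positive(base_intensity_log_sd, "base_intensity_log_sd")
  stop_if_not_positive(noise_sd_at_low_A, "noise_sd_at_low_A")
  stop_if_not_positive(noise_sd_at_high_A, "noise_sd_at_high_A")
  if (!is.numeric(background_level) || background_level < 0) {
    abort("configuration error: `background_level` must be >= 0")
  }
  if (!is.numeric(dye_bias_coeffs) || length(dye_bias_coeffs) < 1) {
    abort("configuration error: `dye_bias_coeffs` must be a numeric vector")
  }
  stopifnot(inherits(regimen, "dose_regimen"))
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_duplicate_spots = as.integer(n_duplicate_spots),
      n_arrays = as.integer(n_arrays),
      prop_de = prop_de,
      de_log2fc_magnitude = de_log2fc_magnitude,
      base_intensity_log_mean = base_intensity_log_mean,
      base_intensity_log_sd = base_intensity_log_sd,
      dye_bias_coeffs = dye_bias_coeffs,
      background_level = background_level,
      noise_sd_at_low_A = noise_sd_at_low_A,
      noise_sd_at_high_A = noise_sd_at_high_A,
      dye_swap_arrays = isTRUE(dye_swap_arrays),
      seed = as.integer(seed),
      regimen = regimen
    ),
    class = "sim_config"
  )
}

#' Evaluate the dye-bias polynomial of a simulation configuration
#'
#' Returns the bias added to the log-ratio M at average intensity `A`:
#' the polynomial in `config$dye_bias_coeffs` evaluated at
#' `A - config$base_intensity_log_mean`.
#'
#' @param config A [sim_config()].
#' @param A Numeric vector of average log2 intensities.
#' @return Numeric vector of biases.
#' @export
dye_bias_curve <- function(config, A) {
  x <- A - config$base_intensity_log_mean
  coef <- config$dye_bias_coeffs
  out <- numeric(length(x))
  for (j in seq_along(coef)) out <- out + coef[j] * x^(j - 1)
  out
}

noise_sd_at <- function(config, A) {
  # log-linear interpolation of the noise SD across the intensity range
  lo <- config$base_intensity_log_mean - 2 * config$base_intensity_log_sd
  hi <- config$base_intensity_log_mean + 2 * config$base_intensity_log_sd
  t <- pmin(pmax((A - lo) / (hi - lo), 0), 1)
  exp(log(config$noise_sd_at_low_A) +
        t * (log(config$noise_sd_at_high_A) - log(config$noise_sd_at_low_A)))
}

#' Simulate a two-color microarray experiment with planted truth
#'
#' Generates `config$n_arrays` biological replicate hybridizations of a
#' control (channel 1) versus treated (channel 2) sample on an array of
#' `config$n_genes` probes printed in `config$n_duplicate_spots` duplicate
#' spots, together with the ground-truth table of planted log2 fold
#' changes. Each spot's observed log-ratio is
#' `true_log2fc + bias(A) + noise(A)`, with an additive per-channel
#' background on top of the foreground signal, so the full preprocessing
#' chain (background correction, filtering, MA-plot LOWESS normalization,
#' replicate averaging) is exercised and its output can be compared with
#' the planted truth.
#'
#' @param config A [sim_config()].
#' @return A list with components `scans` (tibble of spot records across all
#'   arrays: `array_id`, `dye_orientation`, `spot_id`, `gene`, `fg1`, `bg1`,
#'   `fg2`, `bg2`, `flag`) and `truth` (tibble `gene`, `true_log2fc`,
#'   `is_de`).
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 100, seed = 1))
#' dplyr::count(sim$truth, is_de)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  genes <- sprintf("G%04d", seq_len(n))

  set.seed(derive_seed(config$seed, 0L))
  n_de <- round(config$prop_de * n)
  true_log2fc <- rep(0, n)
  if (n_de > 0) {
    de_idx <- sample.int(n, n_de)
    signs <- sample(c(-1, 1), n_de, replace = TRUE)
    true_log2fc[de_idx] <- signs * config$de_log2fc_magnitude
  }
  truth <- tibble::tibble(
    gene = genes,
    true_log2fc = true_log2fc,
    is_de = true_log2fc != 0
  )
  # gene baselines shared across arrays (biological identity of the probe)
  base <- stats::rnorm(n, config$base_intensity_log_mean, config$base_intensity_log_sd)

  scans <- purrr::map_dfr(seq_len(config$n_arrays), function(a) {
    set.seed(derive_seed(config$seed, a))
    swapped <- config$dye_swap_arrays && a %% 2L == 0L
    n_spots <- n * config$n_duplicate_spots
    gene_idx <- rep(seq_len(n), each = config$n_duplicate_spots)
    A <- base[gene_idx] + stats::rnorm(n_spots, 0, 0.1)
    M_true <- true_log2fc[gene_idx]
    M <- M_true + dye_bias_curve(config, A) +
      stats::rnorm(n_spots, 0, noise_sd_at(config, A))
    # invert MA coordinates into channel signals: treated = ch2, control = ch1
    s1 <- 2^(A - M / 2)
    s2 <- 2^(A + M / 2)
    if (swapped) {
      tmp <- s1; s1 <- s2; s2 <- tmp
    }
    bg1 <- if (config$background_level > 0) {
      pmax(stats::rnorm(n_spots, config$background_level, config$background_level / 10), 0)
    } else rep(0, n_spots)
    bg2 <- if (config$background_level > 0) {
      pmax(stats::rnorm(n_spots, config$background_level, config$background_level / 10), 0)
    } else rep(0, n_spots)
    tibble::tibble(
      array_id = sprintf("array%02d", a),
      dye_orientation = if (swapped) "swapped" else "standard",
      spot_id = sprintf("S%05d", seq_len(n_spots)),
      gene = genes[gene_idx],
      fg1 = s1 + bg1, bg1 = bg1,
      fg2 = s2 + bg2, bg2 = bg2,
      flag = "OK"
    )
  })

  list(scans = scans, truth = truth, config = config)
}

#' Simulate a curated literature database of reported expression changes
#'
#' Labels random, non-overlapping subsets of `genes` as previously reported
#' upregulated, downregulated, or stably expressed (SEG), with a synthetic
#' provenance string, to exercise the study-versus-literature overlap
#' classification.
#'
#' @param genes Character vector of unique gene symbols.
#' @param frac_up,frac_down,frac_seg Fractions of `genes` to label.
#' @param seed Integer seed.
#' @return A tibble `symbol`, `label` (`UP`/`DOWN`/`SEG`), `provenance`.
#' @export
simulate_literature_db <- function(genes, frac_up = 0.02, frac_down = 0.02,
                                   frac_seg = 0.02, seed = 1L) {
  if (length(genes) == 0) abort("`genes` must be nonempty")
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    abort(paste0("duplicate symbols: ", paste(dup, collapse = ", ")))
  }
  if (frac_up + frac_down + frac_seg > 1) {
    abort("label fractions must sum to at most 1")
  }
  set.seed(derive_seed(seed, 101L))
  n <- length(genes)
  counts <- c(UP = round(frac_up * n), DOWN = round(frac_down * n),
              SEG = round(frac_seg * n))
  picked <- sample(genes, sum(counts))
  label <- rep(names(counts), counts)
  tibble::tibble(
    symbol = picked,
    label = label,
    provenance = sprintf("sim:%s:%d", label, seq_along(picked))
  )
}

#' Simulate a gene-set collection with one planted enriched term
#'
#' Builds `n_terms` random gene sets plus a term `PLANTED` constructed to
#' share exactly `planted_overlap` members with `query`, so the
#' over-representation stage has a term of known hypergeometric
#' significance to recover.
#'
#' @param genes Background gene universe (character).
#' @param query Query gene set the planted term is built against.
#' @param n_terms Number of random background terms.
#' @param planted_term_size Size of the planted term.
#' @param planted_overlap Number of planted-term members drawn from `query`.
#' @param term_size_range Length-2 integer range of random term sizes.
#' @param seed Integer seed.
#' @return A tibble `term_id`, `term_name`, `gene` (long format, one row per
#'   member), writable with [write_gmt()].
#' @export
simulate_geneset_collection <- function(genes, query, n_terms = 50,
                                        planted_term_size = 20,
                                        planted_overlap = 10,
                                        term_size_range = c(10, 50),
                                        seed = 1L) {
  stopifnot(all(query %in% genes))
  if (planted_overlap > planted_term_size) {
    abort("`planted_overlap` cannot exceed `planted_term_size`")
  }
  if (planted_overlap > length(query)) {
    abort("`planted_overlap` cannot exceed the query size")
  }
  if (planted_term_size > length(genes)) {
    abort("`planted_term_size` cannot exceed the universe size")
  }
  set.seed(derive_seed(seed, 202L))
  non_query <- setdiff(genes, query)
  n_out <- planted_term_size - planted_overlap
  if (n_out > length(non_query)) {
    abort("not enough non-query genes for the requested planted term")
  }
  planted <- c(sample(query, planted_overlap),
               if (n_out > 0) sample(non_query, n_out))
  rand <- purrr::map_dfr(seq_len(n_terms), function(i) {
    size <- sample(seq(term_size_range[1], term_size_range[2]), 1)
    tibble::tibble(
      term_id = sprintf("T%03d", i),
      term_name = sprintf("random term %d", i),
      gene = sample(genes, min(size, length(genes)))
    )
  })
  dplyr::bind_rows(
    tibble::tibble(term_id = "PLANTED", term_name = "planted term", gene = planted),
    rand
  )
}

#' Simulate a scored protein-interaction edge list with a planted hub
#'
#' Gives `hub_gene` exactly `hub_degree` high-confidence edges (scores in
#' [0.7, 1]) and adds `n_background_edges` random edges among the remaining
#' genes with scores spanning `score_range`, so hub detection after the
#' 0.700 confidence filter has a known answer.
#'
#' @param genes Character vector of node symbols.
#' @param hub_gene The planted hub (must be in `genes`).
#' @param hub_degree Degree of the hub after score filtering at 0.700.
#' @param n_background_edges Number of random non-hub edges.
#' @param score_range Length-2 numeric range of background edge scores.
#' @param seed Integer seed.
#' @return A tibble `node1`, `node2`, `score`.
#' @export
simulate_ppi_edges <- function(genes, hub_gene, hub_degree,
                               n_background_edges = 100,
                               score_range = c(0.15, 0.95), seed = 1L) {
  stopifnot(hub_gene %in% genes)
  others <- setdiff(genes, hub_gene)
  if (hub_degree >= length(genes)) {
    abort("`hub_degree` must be smaller than the number of genes")
  }
  set.seed(derive_seed(seed, 303L))
  partners <- sample(others, hub_degree)
  hub_edges <- tibble::tibble(
    node1 = hub_gene,
    node2 = partners,
    score = stats::runif(hub_degree, 0.7, 1)
  )
  bg <- NULL
  if (n_background_edges > 0) {
    pool <- others
    n1 <- sample(pool, n_background_edges, replace = TRUE)
    n2 <- sample(pool, n_background_edges, replace = TRUE)
    keep <- n1 != n2
    bg <- tibble::tibble(
      node1 = n1[keep], node2 = n2[keep],
      score = stats::runif(sum(keep), score_range[1], score_range[2])
    )
  }
  edges <- dplyr::bind_rows(hub_edges, bg)
  # canonical undirected representation, duplicates keep the max score
  edges <- edges %>%
    dplyr::mutate(
      a = pmin(.data$node1, .data$node2),
      b = pmax(.data$node1, .data$node2)
    ) %>%
    dplyr::group_by(.data$a, .data$b) %>%
    dplyr::summarise(score = max(.data$score), .groups = "drop") %>%
    dplyr::transmute(node1 = .data$a, node2 = .data$b, score = .data$score)
  edges
}

#' Simulate a clinical cohort with planted survival and correlation effects
#'
#' Generates per-subject expression for `signature_genes` (standard normal),
#' event times that are exponential with log-hazard
#' `planted_log_hr * I(signature score above its median)` — the planted
#' effect acts on the median-dichotomized standardized signature score, so
#' `exp(planted_log_hr)` is exactly the high-versus-low hazard ratio that a
#' median-split log-rank analysis estimates — independent exponential
#' censoring tuned to `censor_rate`, and an immune-infiltration column
#' rank-coupled to the first signature gene so that the population Spearman
#' correlation equals `planted_rho` (Gaussian copula with Pearson parameter
#' `2*sin(pi*rho/6)`; at `rho = +/-1` the coupling is exactly monotone).
#'
#' @param n_subjects Number of subjects (>= 20).
#' @param signature_genes Character vector of gene symbols to simulate.
#' @param planted_log_hr True log hazard ratio per SD of signature score.
#' @param planted_rho Target Spearman correlation of the infiltration column
#'   with the first signature gene; `|planted_rho| <= 1`.
#' @param censor_rate Approximate fraction of censored subjects.
#' @param seed Integer seed.
#' @return A list with `cohort` (tibble: `subject`, `time`, `event`, one
#'   column per gene) and `infiltration` (tibble: `subject`, `infiltration`).
#' @export
simulate_clinical_cohort <- function(n_subjects, signature_genes,
                                     planted_log_hr = 0, planted_rho = 0,
                                     censor_rate = 0.2, seed = 1L) {
  if (n_subjects < 20) abort("`n_subjects` must be at least 20")
  if (!is.numeric(planted_rho) || abs(planted_rho) > 1) {
    abort("`planted_rho` must lie in [-1, 1]")
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    abort("`censor_rate` must be in [0, 1)")
  }
  set.seed(derive_seed(seed, 404L))
  expr <- matrix(stats::rnorm(n_subjects * length(signature_genes)),
                 nrow = n_subjects,
                 dimnames = list(NULL, signature_genes))
  score <- rowMeans(scale(expr))
  high <- score > stats::median(score)
  lambda <- exp(planted_log_hr * as.numeric(high))   # baseline hazard 1
  t_event <- stats::rexp(n_subjects, rate = lambda)
  if (censor_rate > 0) {
    rate_c <- censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(n_subjects, rate = rate_c)
  } else {
    t_cens <- rep(Inf, n_subjects)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  # Gaussian-copula rank coupling to the first signature gene
  g <- expr[, 1]
  u <- (rank(g, ties.method = "average") - 0.5) / n_subjects
  zg <- stats::qnorm(u)
  r <- 2 * sin(pi * planted_rho / 6)
  infil <- r * zg + sqrt(max(0, 1 - r^2)) * stats::rnorm(n_subjects)

  cohort <- dplyr::bind_cols(
    tibble::tibble(
      subject = sprintf("P%04d", seq_len(n_subjects)),
      time = time, event = event
    ),
    tibble::as_tibble(expr)
  )
  list(
    cohort = cohort,
    infiltration = tibble::tibble(subject = cohort$subject, infiltration = infil)
  )
}
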