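test_that("symbol standardization trims, folds case, applies aliases, and is idempotent", {
  expect_equal(as.character(standardize_symbols(" camk4 ")), "CAMK4")
  aliases <- tibble(alias = "Nrf2", canonical = "NFE2L2")
  out <- standardize_symbols(c("Nrf2", "gria4"), aliases)
  expect_equal(as.character(out), c("NFE2L2", "GRIA4"))
  twice <- standardize_symbols(as.character(out), aliases)
  expect_equal(as.character(twice), as.character(out))
  expect_equal(nrow(attr(out, "mapping")), 2)
})

test_that("the bundled case-study fixtures reproduce the discordance count", {
  zt <- case_study_zscores()
  calls <- call_from_zscores(zt)
  lit <- case_study_literature()
  rep <- classify_overlap(calls, lit)
  disc <- rep$categories$discordant_down_vs_litUP
  expect_setequal(disc, c("PRKCZ", "GRPR", "PLA2G2A", "PLCB4", "SARDH", "GABRR1"))
  expect_equal(rep$counts$n[rep$counts$category == "discordant_down_vs_litUP"], 6L)
  # named stably-expressed genes are not among the study DEGs
  expect_true(all(c("UBB", "BCL2", "FAS") %in% rep$categories$lit_seg_not_de))
})

test_that("overlap classification with an empty literature DB puts all DEGs in study_only", {
  calls <- tibble(gene = c("A", "B", "C"),
                  call = factor(c("UP", "DOWN", "STABLE"),
                                levels = c("UP", "DOWN", "STABLE", "NONE")))
  lit <- tibble(symbol = character(), label = character(), provenance = character())
  rep <- classify_overlap(calls, lit)
  expect_equal(rep$categories$study_only_up, "A")
  expect_equal(rep$categories$study_only_down, "B")
})

test_that("category counts equal brute-force cross-tabulation on random labels", {
  set.seed(11)
  for (trial in 1:20) {
    genes <- sprintf("G%02d", 1:40)
    call <- sample(c("UP", "DOWN", "STABLE", "NONE"), 40, replace = TRUE)
    calls <- tibble(gene = genes,
                    call = factor(call, levels = c("UP", "DOWN", "STABLE", "NONE")))
    lit_genes <- sample(genes, 20)
    lit <- tibble(symbol = lit_genes,
                  label = sample(c("UP", "DOWN", "SEG"), 20, replace = TRUE),
                  provenance = "t")
    rep <- classify_overlap(calls, lit)
    lab <- setNames(lit$label, lit$symbol)
    brute <- table(study = call, lit = lab[genes], useNA = "always")
    expect_equal(length(rep$categories$concordant_up),
                 sum(call == "UP" & !is.na(lab[genes]) & lab[genes] == "UP"))
    expect_equal(length(rep$categories$discordant_down_vs_litUP),
                 sum(call == "DOWN" & !is.na(lab[genes]) & lab[genes] == "UP"))
    expect_equal(length(rep$categories$study_only_up),
                 sum(call == "UP" & (is.na(lab[genes]) | lab[genes] == "SEG")))
    # partition property: study-side categories partition the DEG list
    study_side <- unlist(rep$categories[c("concordant_up", "concordant_down",
                                          "discordant_down_vs_litUP",
                                          "discordant_up_vs_litDOWN",
                                          "study_only_up", "study_only_down")])
    expect_equal(anyDuplicated(study_side), 0L)
    expect_setequal(study_side, genes[call %in% c("UP", "DOWN")])
  }
})

test_that("classification is invariant to input order", {
  calls <- tibble(gene = c("A", "B", "C", "D"),
                  call = factor(c("UP", "DOWN", "UP", "NONE"),
                                levels = c("UP", "DOWN", "STABLE", "NONE")))
  lit <- tibble(symbol = c("A", "D"), label = c("UP", "SEG"), provenance = "x")
  a <- classify_overlap(calls, lit)
  b <- classify_overlap(calls[c(3, 1, 4, 2), ], lit[c(2, 1), ])
  expect_equal(lapply(a$categories, sort), lapply(b$categories, sort))
})

test_that("stable-overlap categories intersect DEGs with the supplied stable set", {
  calls <- tibble(gene = c("A", "B", "C"),
                  call = factor(c("UP", "DOWN", "UP"),
                                levels = c("UP", "DOWN", "STABLE", "NONE")))
  lit <- tibble(symbol = character(), label = character(), provenance = character())
  rep <- classify_overlap(calls, lit, stable_genes = c("A", "B", "Z"))
  expect_equal(rep$categories$stable_overlap_up, "A")
  expect_equal(rep$categories$stable_overlap_down, "B")
})

test_that("venn regions partition the union and match a membership tally", {
  out <- venn_counts(list(A = c("x", "y"), B = c("y", "z")))
  expect_equal(out$n[out$region == "A"], 1L)
  expect_equal(out$n[out$region == "B"], 1L)
  expect_equal(out$n[out$region == "A&B"], 1L)
  expect_equal(sum(out$pct), 100)

  disjoint <- venn_counts(list(A = "x", B = "y"))
  expect_equal(disjoint$n[disjoint$region == "A&B"], 0L)

  set.seed(3)
  sets <- list(A = sample(letters, 10), B = sample(letters, 12), C = sample(letters, 8))
  out3 <- venn_counts(sets)
  expect_equal(sum(out3$n), length(unique(unlist(sets))))
  # exhaustive membership-vector tally
  uni <- unique(unlist(sets))
  vec <- sapply(uni, function(g) paste(names(sets)[sapply(sets, function(s) g %in% s)],
                                       collapse = "&"))
  expect_equal(out3$n[match(names(table(vec)), out3$region)],
               as.integer(table(vec)))

  expect_error(venn_counts(list(A = "x", B = "y", C = "z", D = "w")), "arity")
})
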