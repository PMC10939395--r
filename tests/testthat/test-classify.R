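tax_basic <- make_taxonomy(
  dino = dino_lineage("Heterocapsa", "rotundata"),
  crypto = crypto_lineage("Teleaulax"),
  cil = ciliate_lineage("Strombidium"),
  fungus = "Eukaryota;Opisthokonta;Fungi;Metschnikowia;Metschnikowia sp."
)

test_that("excluded-group and singleton ASVs are removed, others untouched", {
  counts <- make_counts(list(
    "WP_2021-03-15_plus_1" = c(dino = 400L, crypto = 100L, cil = 1L,
                               fungus = 500L),
    "WP_2021-03-15_minus_1" = c(dino = 300L, crypto = 200L, cil = 0L,
                                fungus = 100L)
  ))
  out <- filter_asvs(counts, tax_basic)
  expect_false("fungus" %in% out$asv_id)   # excluded group, 600 reads
  expect_false("cil" %in% out$asv_id)      # total count 1 across experiment
  kept <- dplyr::arrange(dplyr::filter(counts, asv_id %in% c("dino", "crypto")),
                         asv_id, treatment)
  expect_equal(as.data.frame(dplyr::arrange(out, asv_id, treatment)),
               as.data.frame(kept))
})

test_that("a table with nothing to filter is returned unchanged", {
  counts <- make_counts(list(
    "WP_2021-03-15_plus_1" = c(dino = 10L, crypto = 5L),
    "WP_2021-03-15_minus_1" = c(dino = 8L, crypto = 7L)
  ))
  out <- filter_asvs(counts, tax_basic)
  expect_equal(
    as.data.frame(dplyr::arrange(out, asv_id, treatment)),
    as.data.frame(dplyr::arrange(counts, asv_id, treatment))
  )
})

test_that("the alternative singleton rule drops single-sample ASVs", {
  counts <- make_counts(list(
    "WP_2021-03-15_plus_1" = c(dino = 50L, crypto = 40L),
    "WP_2021-03-15_minus_1" = c(dino = 30L, crypto = 0L)
  ))
  out <- filter_asvs(counts, tax_basic,
                     cm_config(singleton_rule = "one_sample"))
  expect_false("crypto" %in% out$asv_id)  # present in one sample only
  out2 <- filter_asvs(counts, tax_basic)  # default rule: total reads == 1
  expect_true("crypto" %in% out2$asv_id)
})

test_that("uncovered ASVs are retained with a warning", {
  counts <- make_counts(list(
    "WP_2021-03-15_plus_1" = c(dino = 50L, mystery = 40L),
    "WP_2021-03-15_minus_1" = c(dino = 30L, mystery = 20L)
  ))
  expect_warning(out <- filter_asvs(counts, tax_basic), "no taxonomy")
  expect_true("mystery" %in% out$asv_id)
  cls <- suppressWarnings(classify_experiments(counts, tax_basic))
  expect_false(cls$has_plastid[cls$asv_id == "mystery"])
})

test_that("filtering everything yields an empty result, not an error", {
  counts <- make_counts(list(
    "WP_2021-03-15_plus_1" = c(fungus = 100L),
    "WP_2021-03-15_minus_1" = c(fungus = 50L)
  ))
  out <- filter_asvs(counts, tax_basic)
  expect_equal(nrow(out), 0)
  cls <- classify_experiments(counts, tax_basic)
  expect_s3_class(cls, "cm_classification")
  expect_equal(nrow(cls), 0)
})

test_that("relative abundances renormalize each sample to 100", {
  counts <- make_counts(list(
    "WP_2021-03-15_plus_1" = c(a = 2L, b = 2L),
    "WP_2021-03-15_minus_1" = c(a = 1L, b = 3L, c = 6L)
  ))
  rel <- to_relative(counts)
  expect_equal(rel$pct[rel$treatment == "plus"], c(50, 50))
  expect_equal(rel$pct[rel$treatment == "minus"], c(10, 30, 60))
})

test_that("relative abundances match a direct renormalization oracle on random tables", {
  sim <- simulate_brdu_experiment(n_asvs = 60, depth = 3000, seed = 21)
  rel <- to_relative(sim$counts)
  sums <- rel %>%
    dplyr::group_by(treatment, replicate) %>%
    dplyr::summarise(s = sum(pct), .groups = "drop")
  expect_true(all(abs(sums$s - 100) < 1e-9 * 100))
  # brute-force oracle, computed sample by sample from the raw counts
  oracle <- sim$counts %>%
    dplyr::group_by(treatment, replicate) %>%
    dplyr::mutate(pct_oracle = 100 * count / sum(count)) %>%
    dplyr::ungroup()
  joined <- dplyr::inner_join(
    rel, oracle,
    by = c("station", "date", "treatment", "replicate", "asv_id", "count")
  )
  expect_equal(joined$pct, joined$pct_oracle)
})

test_that("a zero-total sample is a value error naming the sample", {
  counts <- make_counts(list(
    "WP_2021-03-15_plus_1" = c(a = 0L, b = 0L),
    "WP_2021-03-15_minus_1" = c(a = 1L, b = 3L)
  ))
  expect_error(to_relative(counts), "WP_2021-03-15_plus_1",
               class = "cmtracer_value_error")
})

test_that("treatment means average replicates with zero fill for absent ASVs", {
  counts <- make_counts(list(
    "WP_2021-03-15_plus_1" = c(a = 1L, b = 99L),
    "WP_2021-03-15_plus_2" = c(a = 2L, b = 98L),
    "WP_2021-03-15_plus_3" = c(a = 3L, b = 97L),
    "WP_2021-03-15_minus_1" = c(b = 10L)
  ))
  m <- treatment_means(to_relative(counts))
  expect_equal(m$mean_pct[m$treatment == "plus" & m$asv_id == "a"], 2)
  # ASV a absent from the minus sample: contributes 0%
  expect_equal(m$mean_pct[m$treatment == "minus" & m$asv_id == "a"], 0)
  expect_equal(m$mean_pct[m$treatment == "minus" & m$asv_id == "b"], 100)
})

test_that("treatment means equal a column-mean oracle on a seeded table", {
  sim <- simulate_brdu_experiment(n_asvs = 30, depth = 2000, seed = 8)
  m <- treatment_means(to_relative(sim$counts))
  # oracle: wide percentage matrix, plain rowMeans per treatment
  rel <- to_relative(sim$counts)
  for (tr in c("plus", "minus")) {
    wide <- rel %>%
      dplyr::filter(treatment == tr) %>%
      tidyr::pivot_wider(id_cols = "asv_id", names_from = "replicate",
                         values_from = "pct", values_fill = 0)
    oracle <- rowMeans(as.matrix(wide[, -1]))
    got <- m$mean_pct[m$treatment == tr][match(wide$asv_id,
                                               m$asv_id[m$treatment == tr])]
    expect_equal(got, unname(oracle))
  }
})

test_that("differential subtraction handles identity and one-sided presence", {
  counts <- make_counts(list(
    "WP_2021-03-15_plus_1" = c(a = 10L, b = 990L),
    "WP_2021-03-15_minus_1" = c(a = 10L, b = 987L, c = 3L)
  ))
  d <- differential(treatment_means(to_relative(counts)))
  expect_equal(d$diff_pct[d$asv_id == "c"], -0.3)
  expect_equal(d$diff_pct[d$asv_id == "a"], 0)
  expect_equal(sum(d$diff_pct), 0, tolerance = 1e-12)
})

test_that("compositional mass is conserved: differences sum to zero", {
  for (seed in c(2, 3)) {
    sim <- simulate_brdu_experiment(n_asvs = 80, depth = 4000, seed = seed)
    d <- differential(treatment_means(to_relative(sim$counts)))
    expect_equal(sum(d$diff_pct), 0, tolerance = 1e-9)
  }
})

test_that("an experiment missing a treatment is a value error", {
  counts <- make_counts(list("WP_2021-03-15_plus_1" = c(a = 5L, b = 5L)))
  expect_error(differential(treatment_means(to_relative(counts))),
               class = "cmtracer_value_error")
})

test_that("bacterivore calls are strict at both boundaries", {
  rec <- make_records(c(-0.5, 0, 0.05, 0.1, 0.1000001, 2))
  out <- call_bacterivores(rec, cm_config())
  expect_equal(out$is_bacterivore,
               c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("noise-free planted enrichment is recovered exactly", {
  diff <- rep(0, 50)
  planted <- c(4, 8, 15, 16, 23, 42, 3, 9, 27, 31)
  diff[planted] <- 0.5
  out <- call_bacterivores(make_records(diff), cm_config())
  expect_setequal(which(out$is_bacterivore), planted)
})

test_that("CM calls require both a bacterivore call and a plastid lineage", {
  counts <- make_counts(list(
    "WP_2021-03-15_plus_1" = c(dino = 300L, cil = 300L, crypto = 400L),
    "WP_2021-03-15_minus_1" = c(dino = 100L, cil = 100L, crypto = 800L)
  ))
  cls <- classify_experiments(counts, tax_basic)
  expect_true(cls$is_bacterivore[cls$asv_id == "cil"])
  expect_false(cls$is_cm[cls$asv_id == "cil"])    # heterotrophic ciliate
  expect_true(cls$is_cm[cls$asv_id == "dino"])    # dinoflagellate bacterivore
  expect_false(cls$is_cm[cls$asv_id == "crypto"]) # depleted, not bacterivore
})

test_that("no bacterivores yields an empty CM set", {
  counts <- make_counts(list(
    "WP_2021-03-15_plus_1" = c(dino = 100L, crypto = 100L),
    "WP_2021-03-15_minus_1" = c(dino = 100L, crypto = 100L)
  ))
  cls <- classify_experiments(counts, tax_basic)
  expect_false(any(cls$is_cm))
})

test_that("CM set is nested in bacterivore set and threshold raising is monotone", {
  for (seed in 4:6) {
    sim <- simulate_brdu_experiment(n_asvs = 120, depth = 5000, seed = seed)
    cls <- classify_experiments(sim$counts, sim$taxonomy)
    expect_true(all(cls$asv_id[cls$is_cm] %in% cls$asv_id[cls$is_bacterivore]))
    low <- call_bacterivores(cls, cm_config(bacterivore_min_diff_pct = 0.1))
    high <- call_bacterivores(cls, cm_config(bacterivore_min_diff_pct = 0.5))
    expect_true(all(cls$asv_id[high$is_bacterivore] %in%
                      cls$asv_id[low$is_bacterivore]))
  }
})

test_that("planted bacterivores are recovered with few false positives", {
  tax <- simulate_brdu_experiment(n_asvs = 400, depth = 20000, seed = 1)$taxonomy
  sens <- fpr <- numeric(10)
  for (i in 1:10) {
    sim <- simulate_brdu_experiment(n_asvs = 400, depth = 20000,
                                    n_planted = 10, taxonomy = tax,
                                    seed = 100 + i)
    cls <- classify_experiments(sim$counts, sim$taxonomy)
    planted <- sim$truth$asv_id[sim$truth$planted]
    called <- cls$asv_id[cls$is_bacterivore]
    sens[i] <- mean(planted %in% called)
    fpr[i] <- length(setdiff(called, planted)) /
      (nrow(sim$truth) - length(planted))
  }
  expect_gte(mean(sens), 0.95)
  expect_lte(mean(fpr), 0.05)
})

test_that("classification round-trips through its TSV representation", {
  sim <- simulate_brdu_experiment(n_asvs = 50, depth = 3000, seed = 13)
  cls <- classify_experiments(sim$counts, sim$taxonomy)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_classification(cls, path)
  expect_equal(as.data.frame(read_classification(path)), as.data.frame(cls))
})
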