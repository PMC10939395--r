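# the genus/species labels of the matched-ASV fixture
matched_asv_labels <- c(
  "Gymnodinium aureolum", "Gymnodinium nolleri", "Gymnodinium dorsalisulcum",
  "Gymnodinium palustre", "Gymnodinium sp. GSSW10",
  "Gymnodinium uncultured eukaryote", "Gymnodinium uncultured marine eukaryote",
  "Gyrodinium uncultured eukaryote", "Gyrodinium instriatum",
  "Gyrodinium uncultured alveolate", "Gyrodinium uncultured dinoflagellate",
  "Gyrodinium uncultured marine eukaryote",
  "Heterocapsa rotundata", "Heterocapsa niei", "Heterocapsa triquetra",
  "Heterocapsa uncultured dinoflagellate", "Heterocapsa uncultured eukaryote",
  "Karlodinium uncultured marine dinoflagellate",
  "Scrippsiella sp. NY012", "Scrippsiella uncultured marine alveolate",
  "Teleaulax uncultured eukaryote", "Teleaulax uncultured marine eukaryote"
)

test_that("22 matched ASV labels collapse to exactly six genera", {
  expect_length(matched_asv_labels, 22)
  genera <- sort(unique(extract_genus(matched_asv_labels)))
  expect_equal(genera, c("Gymnodinium", "Gyrodinium", "Heterocapsa",
                         "Karlodinium", "Scrippsiella", "Teleaulax"))
})

make_classification <- function(cm_genera_by_exp) {
  purrr::imap_dfr(cm_genera_by_exp, function(genera, key) {
    parts <- stringr::str_split_1(key, "\\|")
    if (length(genera) == 0) {
      return(tibble::tibble(
        station = parts[1], date = parts[2], asv_id = character(0),
        mean_plus_pct = double(0), mean_minus_pct = double(0),
        diff_pct = double(0), is_bacterivore = logical(0),
        genus = character(0), has_plastid = logical(0), is_cm = logical(0)
      ))
    }
    tibble::tibble(
      station = parts[1], date = parts[2],
      asv_id = paste0(key, "_", seq_along(genera)),
      mean_plus_pct = 1, mean_minus_pct = 0.2, diff_pct = 0.8,
      is_bacterivore = TRUE, genus = genera, has_plastid = TRUE,
      is_cm = TRUE
    )
  })
}

test_that("active genera collapse CM ASVs to a genus set per experiment", {
  cls <- tibble::tibble(
    station = "WP", date = "2021-03-15",
    asv_id = c("a1", "a2", "a3", "a4"),
    mean_plus_pct = 1, mean_minus_pct = 0, diff_pct = 1,
    is_bacterivore = c(TRUE, TRUE, TRUE, FALSE),
    genus = c("Gymnodinium", "Gymnodinium", NA, "Teleaulax"),
    has_plastid = c(TRUE, TRUE, TRUE, TRUE),
    is_cm = c(TRUE, TRUE, TRUE, FALSE)
  )
  act <- active_genus_table(cls)
  expect_equal(act$genus, "Gymnodinium")  # species collapse, NA dropped
  empty <- active_genus_table(dplyr::mutate(cls, is_cm = FALSE))
  expect_equal(nrow(empty), 0)
})

test_that("potential genera are the per-station union over dates", {
  cls <- make_classification(list(
    "WP|2021-03-15" = "Gymnodinium",
    "WP|2021-06-15" = "Teleaulax",
    "GP|2021-03-15" = "Heterocapsa"
  ))
  pot <- potential_genus_table(active_genus_table(cls))
  expect_setequal(pot$genus[pot$station == "WP"],
                  c("Gymnodinium", "Teleaulax"))
  expect_equal(pot$genus[pot$station == "GP"], "Heterocapsa")

  # single date: potential equals that date's active set
  one <- make_classification(list("WP|2021-03-15" = c("Gymnodinium", "Teleaulax")))
  expect_setequal(potential_genus_table(active_genus_table(one))$genus,
                  c("Gymnodinium", "Teleaulax"))
})

test_that("potential genera match a brute-force union oracle on seeded fixtures", {
  withr::with_seed(99, {
    genera_pool <- c("Gymnodinium", "Teleaulax", "Heterocapsa", "Scrippsiella",
                     "Karlodinium", "Gyrodinium", "Cryptomonas")
    sets <- lapply(1:6, function(i) sample(genera_pool, sample(0:4, 1)))
    names(sets) <- paste0("WP|2021-0", 1:6, "-01")
    cls <- make_classification(sets)
    pot <- potential_genus_table(active_genus_table(cls))
    expect_setequal(pot$genus, unique(unlist(sets)))
    # union monotonicity: adding a date never shrinks the potential set
    cls2 <- dplyr::bind_rows(cls, make_classification(
      list("WP|2021-07-01" = "Rhodomonas")))
    pot2 <- potential_genus_table(active_genus_table(cls2))
    expect_true(all(pot$genus %in% pot2$genus))
  })
})

test_that("abundance estimates sum matched plastid taxa and divide by the phototroph total", {
  cls <- make_classification(list("WP|2021-03-15" = "Gymnodinium"))
  mic <- make_microscopy(list(
    mic_row("WP", "2021-03-15", "Gymnodinium aureolum", 25),
    mic_row("WP", "2021-03-15", "Skeletonema spp.", 75),
    mic_row("WP", "2021-03-15", "Strombidium sp.", 40, plastid = FALSE)
  ))
  est <- estimate_cms(cls, mic)
  expect_equal(est$total_phototroph_abundance, 100)
  expect_equal(est$active_abundance, 25)
  expect_equal(est$active_proportion, 0.25)
  expect_equal(est$potential_abundance, 25)
  expect_equal(est$active_genera, "Gymnodinium")
})

test_that("an empty active set gives zero abundance and proportion", {
  cls <- make_classification(list("WP|2021-03-15" = character(0)))
  mic <- make_microscopy(list(
    mic_row("WP", "2021-03-15", "Teleaulax sp.", 50),
    mic_row("WP", "2021-03-15", "Skeletonema spp.", 50)
  ))
  est <- estimate_cms(cls, mic)
  expect_equal(est$active_abundance, 0)
  expect_equal(est$active_proportion, 0)
  expect_equal(est$potential_abundance, 0)
})

test_that("a genus active on another date counts as potential but not active", {
  # Teleaulax present all year, only grazing in autumn
  cls <- make_classification(list(
    "WP|2021-03-15" = "Gymnodinium",
    "WP|2021-10-15" = "Teleaulax"
  ))
  mic <- make_microscopy(list(
    mic_row("WP", "2021-03-15", "Teleaulax sp.", 30),
    mic_row("WP", "2021-03-15", "Gymnodinium aureolum", 20),
    mic_row("WP", "2021-03-15", "Skeletonema spp.", 50),
    mic_row("WP", "2021-10-15", "Teleaulax sp.", 60),
    mic_row("WP", "2021-10-15", "Skeletonema spp.", 40)
  ))
  est <- estimate_cms(cls, mic)
  spring <- est[est$date == "2021-03-15", ]
  expect_equal(spring$active_abundance, 20)         # Gymnodinium only
  expect_equal(spring$potential_abundance, 50)      # + ever-active Teleaulax
  autumn <- est[est$date == "2021-10-15", ]
  expect_equal(autumn$active_abundance, 60)
  expect_equal(autumn$potential_abundance, 60)
})

test_that("a zero phototroph total is a value error", {
  cls <- make_classification(list("WP|2021-03-15" = "Gymnodinium"))
  mic <- make_microscopy(list(
    mic_row("WP", "2021-03-15", "Strombidium sp.", 40, plastid = FALSE)
  ))
  expect_error(estimate_cms(cls, mic), class = "cmtracer_value_error")
})

test_that("estimates obey subset ordering and match a flat join-and-sum oracle", {
  study <- simulate_study(n_dates = 6, n_asvs = 150, depth = 8000, seed = 17)
  cls <- classify_experiments(study$counts, study$taxonomy)
  est <- estimate_cms(cls, study$microscopy)
  expect_true(all(est$active_abundance >= 0))
  expect_true(all(est$active_abundance <= est$potential_abundance + 1e-9))
  expect_true(all(est$potential_abundance <=
                    est$total_phototroph_abundance + 1e-9))
  expect_true(all(est$active_proportion >= 0 & est$active_proportion <= 1))
  expect_true(all(est$potential_proportion >= 0 &
                    est$potential_proportion <= 1))

  # independent flat recomputation: explicit loops, no pipeline code
  act <- active_genus_table(cls)
  for (i in seq_len(nrow(est))) {
    st <- est$station[i]; dt <- est$date[i]
    mic <- study$microscopy[study$microscopy$station == st &
                              study$microscopy$date == dt, ]
    a_set <- tolower(act$genus[act$station == st & act$date == dt])
    p_set <- tolower(act$genus[act$station == st])
    g <- tolower(mic$genus)
    expect_equal(est$active_abundance[i],
                 sum(mic$cells_per_ml[mic$has_plastid & !is.na(g) &
                                        g %in% a_set]))
    expect_equal(est$potential_abundance[i],
                 sum(mic$cells_per_ml[mic$has_plastid & !is.na(g) &
                                        g %in% p_set]))
    expect_equal(est$active_proportion[i],
                 est$active_abundance[i] /
                   sum(mic$cells_per_ml[mic$has_plastid]))
  }
})

test_that("station summaries report mean, SE and ranges per metric", {
  cls <- make_classification(list(
    "WP|2021-03-15" = "Gymnodinium", "WP|2021-06-15" = "Gymnodinium"
  ))
  mic <- make_microscopy(list(
    mic_row("WP", "2021-03-15", "Gymnodinium aureolum", 100),
    mic_row("WP", "2021-03-15", "Skeletonema spp.", 900),
    mic_row("WP", "2021-06-15", "Gymnodinium aureolum", 300),
    mic_row("WP", "2021-06-15", "Skeletonema spp.", 700)
  ))
  s <- summarize_stations(estimate_cms(cls, mic))
  row <- s[s$metric == "active_abundance", ]
  expect_equal(row$mean, 200)
  expect_equal(row$se, 100)  # sd(100, 300)/sqrt(2)
  expect_equal(row$min, 100)
  expect_equal(row$max, 300)
  # single date: SE unavailable, mean still reported
  s1 <- summarize_stations(estimate_cms(
    make_classification(list("WP|2021-03-15" = "Gymnodinium")),
    make_microscopy(list(
      mic_row("WP", "2021-03-15", "Gymnodinium aureolum", 100),
      mic_row("WP", "2021-03-15", "Skeletonema spp.", 900)
    ))
  ))
  expect_true(all(is.na(s1$se)))
  expect_equal(s1$mean[s1$metric == "active_abundance"], 100)
})

test_that("set partitions satisfy the bookkeeping identity", {
  p <- set_partition(paste0("x", 1:106), paste0("x", 48:139))
  expect_equal(p$unique_a + p$unique_b + p$shared, p$total)
  expect_equal(p$unique_a, 47)
  expect_equal(p$unique_b, 33)

  # the 47 / 32 / 59 fixture totals 138
  a <- c(sprintf("wp%02d", 1:47), sprintf("sh%02d", 1:59))
  b <- c(sprintf("gp%02d", 1:32), sprintf("sh%02d", 1:59))
  p2 <- set_partition(a, b)
  expect_equal(unlist(p2), c(unique_a = 47, unique_b = 32, shared = 59,
                             total = 138))

  for (seed in 1:10) {
    withr::with_seed(seed, {
      a <- sample(paste0("asv", 1:200), sample(0:120, 1))
      b <- sample(paste0("asv", 1:200), sample(0:120, 1))
    })
    p3 <- set_partition(a, b)
    # brute-force set algebra oracle
    expect_equal(p3$shared, sum(unique(a) %in% unique(b)))
    expect_equal(p3$total, length(unique(c(a, b))))
    expect_equal(p3$unique_a + p3$unique_b + p3$shared, p3$total)
  }
})

test_that("the two-station ASV partition counts CM ASVs only", {
  cls <- dplyr::bind_rows(
    make_classification(list("WP|2021-03-15" = c("Gymnodinium", "Teleaulax"))),
    make_classification(list("GP|2021-03-15" = "Heterocapsa"))
  )
  cls$asv_id <- c("shared1", "wponly", "shared1")
  p <- asv_set_partition(cls, stations = c("WP", "GP"))
  expect_equal(p$unique_a, 1)
  expect_equal(p$unique_b, 0)
  expect_equal(p$shared, 1)
  expect_equal(p$total, 2)
  expect_error(asv_set_partition(dplyr::filter(cls, station == "WP")),
               class = "cmtracer_value_error")
})
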