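rdirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Default genus pool for synthetic taxonomies
#'
#' Genera spanning the major estuarine plankton groups, with the class used
#' to build Silva-style lineages and whether the lineage is
#' chloroplast-containing. Ciliates provide heterotrophic (non-plastid)
#' protists; metazoan, fungal and macroalgal entries exercise the
#' excluded-group filter.
#'
#' @return A tibble with columns `genus`, `clade`, `class`, `has_plastid`,
#'   `excluded`.
#' @export
default_genus_pool <- function() {
  tibble::tribble(
    ~genus,          ~clade,           ~class,              ~has_plastid, ~excluded,
    "Gymnodinium",   "Alveolata",      "Dinophyceae",       TRUE,  FALSE,
    "Gyrodinium",    "Alveolata",      "Dinophyceae",       TRUE,  FALSE,
    "Heterocapsa",   "Alveolata",      "Dinophyceae",       TRUE,  FALSE,
    "Karlodinium",   "Alveolata",      "Dinophyceae",       TRUE,  FALSE,
    "Scrippsiella",  "Alveolata",      "Dinophyceae",       TRUE,  FALSE,
    "Prorocentrum",  "Alveolata",      "Dinophyceae",       TRUE,  FALSE,
    "Akashiwo",      "Alveolata",      "Dinophyceae",       TRUE,  FALSE,
    "Teleaulax",     "Cryptista",      "Cryptophyceae",     TRUE,  FALSE,
    "Cryptomonas",   "Cryptista",      "Cryptophyceae",     TRUE,  FALSE,
    "Rhodomonas",    "Cryptista",      "Cryptophyceae",     TRUE,  FALSE,
    "Ochromonas",    "Stramenopiles",  "Chrysophyceae",     TRUE,  FALSE,
    "Dinobryon",     "Stramenopiles",  "Chrysophyceae",     TRUE,  FALSE,
    "Emiliania",     "Haptista",       "Haptophyta",        TRUE,  FALSE,
    "Chrysochromulina", "Haptista",    "Haptophyta",        TRUE,  FALSE,
    "Micromonas",    "Archaeplastida", "Chlorophyta",       TRUE,  FALSE,
    "Pyramimonas",   "Archaeplastida", "Chlorophyta",       TRUE,  FALSE,
    "Skeletonema",   "Stramenopiles",  "Bacillariophyta",   TRUE,  FALSE,
    "Chaetoceros",   "Stramenopiles",  "Bacillariophyta",   TRUE,  FALSE,
    "Thalassiosira", "Stramenopiles",  "Bacillariophyta",   TRUE,  FALSE,
    "Strombidium",   "Alveolata",      "Ciliophora",        FALSE, FALSE,
    "Tintinnopsis",  "Alveolata",      "Ciliophora",        FALSE, FALSE,
    "Didinium",      "Alveolata",      "Ciliophora",        FALSE, FALSE,
    "Acartia",       "Opisthokonta",   "Metazoa",           FALSE, TRUE,
    "Brachionus",    "Opisthokonta",   "Metazoa",           FALSE, TRUE,
    "Metschnikowia", "Opisthokonta",   "Fungi",             FALSE, TRUE,
    "Ulva",          "Archaeplastida", "Ulvophyceae",       FALSE, TRUE
  )
}

SPECIES_LABELS <- c("sp.", "spp.", "uncultured eukaryote",
                    "uncultured marine eukaryote", "rotundata", "aureolum",
                    "minor", "parva", "triquetra", "instriatum", "amphioxeia")

build_synthetic_taxonomy <- function(n_asvs, pool,
                                     frac_excluded = 0.08,
                                     frac_class_only = 0.20) {
  asv_id <- sprintf("asv%04d", seq_len(n_asvs))
  u <- runif(n_asvs)
  kind <- ifelse(u < frac_excluded, "excluded",
                 ifelse(u < frac_excluded + frac_class_only, "class_only",
                        "genus"))
  excl_pool <- pool[pool$excluded, , drop = FALSE]
  gen_pool <- pool[!pool$excluded, , drop = FALSE]
  class_pool <- unique(gen_pool[, c("clade", "class")])
  lineage <- character(n_asvs)
  for (i in seq_len(n_asvs)) {
    if (kind[i] == "excluded") {
      row <- excl_pool[sample.int(nrow(excl_pool), 1), ]
      lineage[i] <- paste("Eukaryota", row$clade, row$class, row$genus,
                          paste(row$genus, "sp."), sep = ";")
    } else if (kind[i] == "class_only") {
      row <- class_pool[sample.int(nrow(class_pool), 1), ]
      lineage[i] <- paste("Eukaryota", row$clade, row$class,
                          "uncultured eukaryote", sep = ";")
    } else {
      row <- gen_pool[sample.int(nrow(gen_pool), 1), ]
      sp <- sample(SPECIES_LABELS, 1)
      lineage[i] <- paste("Eukaryota", row$clade, row$class, row$genus,
                          paste(row$genus, sp), sep = ";")
    }
  }
  annotate_taxonomy(tibble::tibble(asv_id = asv_id, lineage = lineage))
}

#' Simulate one +/-BrdU labeled-prey amplicon experiment
#'
#' Generates the compositional structure the classifier assumes: a baseline
#' ASV composition drawn from a symmetric Dirichlet, a +BrdU composition in
#' which a planted minority of chloroplast-bearing ASVs has its proportion
#' multiplied by an enrichment factor and the whole composition
#' renormalized, replicate-level Dirichlet jitter emulating incubation
#' variability, and multinomial read sampling at fixed depth for triplicate
#' incubations of both treatments. Planted ASVs are pinned to a fixed
#' baseline relative abundance so their expected enrichment (computed in
#' closed form and returned in the truth table) is controlled.
#'
#' @param n_asvs Number of ASVs.
#' @param depth Reads per sample.
#' @param n_replicates Replicates per treatment.
#' @param n_planted Number of planted bacterivorous (enriched) ASVs, drawn
#'   from the plastid-bearing ASVs.
#' @param enrichment Multiplicative proportion boost of planted ASVs in the
#'   +BrdU composition (> 1).
#' @param planted_baseline_pct Baseline relative abundance (%) assigned to
#'   each planted ASV.
#' @param concentration Symmetric Dirichlet concentration of the baseline
#'   composition of unplanted ASVs.
#' @param jitter_precision Precision of the per-replicate Dirichlet jitter
#'   (counts are multinomial from `Dirichlet(jitter_precision * p)`);
#'   `Inf` disables jitter.
#' @param station,date Experiment key recorded in the count table.
#' @param pool Genus pool (see [default_genus_pool()]).
#' @param taxonomy Optional pre-built annotated taxonomy (so several
#'   experiments can share one ASV universe).
#' @param seed Optional integer seed (restores RNG state afterwards).
#' @return A list with `counts` (long tibble as from
#'   [read_feature_table()]), `taxonomy`, and `truth` (tibble with one row
#'   per ASV: `asv_id`, `baseline_pct`, `enrichment`, `expected_diff_pct`,
#'   `planted`) plus attribute-free `params` list.
#' @examples
#' sim <- simulate_brdu_experiment(n_asvs = 100, depth = 5000, seed = 42)
#' head(sim$truth[sim$truth$planted, ])
#' @export
simulate_brdu_experiment <- function(n_asvs = 1000, depth = 50000,
                                     n_replicates = 3, n_planted = 20,
                                     enrichment = 2,
                                     planted_baseline_pct = 0.75,
                                     concentration = 0.5,
                                     jitter_precision = 5000,
                                     station = "WP", date = "2021-03-15",
                                     pool = default_genus_pool(),
                                     taxonomy = NULL, seed = NULL) {
  if (n_planted > n_asvs) {
    abort("n_planted cannot exceed n_asvs", class = "cmtracer_value_error")
  }
  stopifnot(enrichment >= 1, depth >= 1, n_replicates >= 1)
  with_seed_if(seed, {
    if (is.null(taxonomy)) {
      taxonomy <- build_synthetic_taxonomy(n_asvs, pool)
    }
    stopifnot(nrow(taxonomy) == n_asvs)
    plastid_ids <- taxonomy$asv_id[taxonomy$has_plastid]
    if (n_planted > length(plastid_ids)) {
      abort("not enough plastid-bearing ASVs to plant bacterivores in",
            class = "cmtracer_value_error")
    }
    planted <- sample(plastid_ids, n_planted)
    is_planted <- taxonomy$asv_id %in% planted

    base <- rdirichlet(rep(concentration, n_asvs))
    if (n_planted > 0) {
      planted_mass <- n_planted * planted_baseline_pct / 100
      if (planted_mass >= 1) {
        abort("planted baseline mass must be below 100%",
              class = "cmtracer_value_error")
      }
      base[is_planted] <- planted_baseline_pct / 100
      rest <- sum(base[!is_planted])
      base[!is_planted] <- base[!is_planted] * (1 - planted_mass) / rest
    }
    f <- ifelse(is_planted, enrichment, 1)
    plus <- base * f
    plus <- plus / sum(plus)

    draw_sample <- function(p) {
      if (is.finite(jitter_precision)) {
        p <- rdirichlet(jitter_precision * p)
      }
      as.integer(rmultinom(1, depth, p))
    }
    rows <- list()
    for (tr in c("plus", "minus")) {
      p_tr <- if (tr == "plus") plus else base
      for (r in seq_len(n_replicates)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          station = station, date = date, treatment = tr,
          replicate = r, asv_id = taxonomy$asv_id,
          count = draw_sample(p_tr)
        )
      }
    }
    truth <- tibble::tibble(
      asv_id = taxonomy$asv_id,
      baseline_pct = 100 * base,
      enrichment = f,
      expected_diff_pct = 100 * (plus - base),
      planted = is_planted
    )
    list(
      counts = dplyr::bind_rows(rows),
      taxonomy = taxonomy,
      truth = truth,
      params = list(
        n_asvs = n_asvs, depth = depth, n_replicates = n_replicates,
        n_planted = n_planted, enrichment = enrichment,
        planted_baseline_pct = planted_baseline_pct,
        concentration = concentration, jitter_precision = jitter_precision,
        station = station, date = date, seed = seed
      )
    )
  })
}

#' Simulate a microscopy count series
#'
#' Draws per-date taxon cell concentrations log-normally around smooth
#' seasonal group profiles (sinusoids with group-specific phase, so
#' different groups peak in different seasons), and chooses the number of
#' Sedgewick-rafter grids counted so that at least `min_cells` cells are
#' counted per sample (the counting-effort convention behind the GLM
#' offset).
#'
#' @param stations Character vector of station ids.
#' @param dates Character vector of ISO-8601 sampling dates.
#' @param taxa Tibble with columns `taxon`, `group`, `has_plastid`,
#'   `mean_cells_per_ml`; defaults to a small estuarine community whose
#'   genera overlap [default_genus_pool()].
#' @param sdlog Log-normal noise on each taxon abundance.
#' @param seasonal_amplitude Relative amplitude of the seasonal sinusoid.
#' @param min_cells Minimum number of cells counted per sample.
#' @param grid_volume_ml Volume examined per grid (ml).
#' @param seed Optional integer seed.
#' @return A microscopy tibble as from [read_microscopy()].
#' @export
simulate_microscopy <- function(stations = c("WP", "GP"),
                                dates = iso_dates(24),
                                taxa = default_microscopy_taxa(),
                                sdlog = 0.4, seasonal_amplitude = 0.6,
                                min_cells = 300, grid_volume_ml = 0.001,
                                seed = NULL) {
  stopifnot(all(c("taxon", "group", "has_plastid", "mean_cells_per_ml")
                %in% names(taxa)))
  with_seed_if(seed, {
    groups <- unique(taxa$group)
    phase <- setNames(seq_along(groups) * 2 * pi / length(groups), groups)
    out <- list()
    for (st in stations) {
      for (k in seq_along(dates)) {
        frac <- (k - 1) / max(1, length(dates) - 1)
        season <- 1 + seasonal_amplitude *
          sin(2 * pi * frac + phase[taxa$group])
        mu <- taxa$mean_cells_per_ml * pmax(season, 0.05)
        cells <- rlnorm(nrow(taxa), meanlog = log(mu) - sdlog^2 / 2,
                        sdlog = sdlog)
        total <- sum(cells[taxa$has_plastid])
        grids <- max(1L, as.integer(ceiling(min_cells / (sum(cells) * grid_volume_ml))))
        out[[length(out) + 1]] <- tibble::tibble(
          station = st, date = dates[[k]], taxon = taxa$taxon,
          cells_per_ml = round(cells, 1), has_plastid = taxa$has_plastid,
          grids_counted = grids
        )
      }
    }
    res <- dplyr::bind_rows(out)
    res$genus <- extract_genus(res$taxon)
    res
  })
}

#' Default microscopy community for simulations
#'
#' @return A tibble with columns `taxon`, `group`, `has_plastid`,
#'   `mean_cells_per_ml`.
#' @export
default_microscopy_taxa <- function() {
  tibble::tribble(
    ~taxon,                         ~group,          ~has_plastid, ~mean_cells_per_ml,
    "Gymnodinium sp.",              "dinoflagellate", TRUE,  250,
    "Heterocapsa rotundata",        "dinoflagellate", TRUE,  400,
    "Scrippsiella sp.",             "dinoflagellate", TRUE,  120,
    "Gyrodinium sp.",               "dinoflagellate", TRUE,  80,
    "Prorocentrum minimum",         "dinoflagellate", TRUE,  150,
    "Teleaulax sp.",                "cryptophyte",    TRUE,  600,
    "Cryptomonas sp.",              "cryptophyte",    TRUE,  200,
    "Skeletonema spp.",             "diatom",         TRUE,  1500,
    "Chaetoceros spp.",             "diatom",         TRUE,  700,
    "Thalassiosira sp.",            "diatom",         TRUE,  300,
    "unidentified centric diatom",  "diatom",         TRUE,  350,
    "Emiliania huxleyi",            "haptophyte",     TRUE,  180,
    "Ochromonas sp.",               "chrysophyte",    TRUE,  90,
    "Strombidium sp.",              "ciliate",        FALSE, 60,
    "Tintinnopsis sp.",             "ciliate",        FALSE, 30
  )
}

#' Evenly spaced ISO dates over one year
#'
#' @param n Number of dates.
#' @param start First date (ISO-8601).
#' @return Character vector of ISO-8601 dates.
#' @export
iso_dates <- function(n, start = "2021-03-01") {
  format(seq(as.Date(start), by = paste(floor(365 / n), "days"),
             length.out = n))
}

#' Simulate an environmental covariate series with known GLM effects
#'
#' Generates correlated environmental covariates through a Gaussian copula
#' (correlated standard normals mapped to each covariate's mean and sd),
#' then draws a count response from a negative binomial whose mean-variance
#' relation matches a quasipoisson with dispersion `phi`
#' (`mean = exposure * exp(intercept + Z beta)`, `var = phi * mean`, `Z`
#' the standardized covariates) and a proportion response from a
#' beta-binomial matching quasibinomial overdispersion. The effect vector
#' `beta` is therefore expressed per standard deviation of each covariate;
#' standardize the covariates before refitting to recover it on the same
#' scale. Replicate rows share a date's covariates but re-draw the
#' response, mirroring triplicate counting.
#'
#' @param n_dates Number of sampling dates.
#' @param n_replicates Response replicates per date.
#' @param beta Named numeric vector of standardized effects; names must be
#'   environmental covariate names (missing covariates get 0).
#' @param intercept Intercept of the count model (log scale, per unit
#'   exposure) and of the proportion model (logit scale).
#' @param phi Dispersion (`>= 1`; 1 gives Poisson/binomial).
#' @param rho Common pairwise correlation of the covariates.
#' @param exposure Per-row exposure (grids counted); recycled.
#' @param n_trials Binomial denominator behind the proportion response.
#' @param station Station id recorded in the table.
#' @param seed Optional integer seed.
#' @return A list with `env` (tibble: station, date, replicate, covariate
#'   columns in natural units, `grids_counted`), `response` (tibble:
#'   station, date, replicate, `count`, `proportion`), and `truth`
#'   (list: `beta` full named vector, `intercept`, `phi`, `rho`,
#'   `z` standardized design matrix).
#' @export
simulate_env_series <- function(n_dates = 19, n_replicates = 3,
                                beta = c(temperature = 0.4, NOx = -0.4),
                                intercept = 1, phi = 2, rho = 0.3,
                                exposure = 50, n_trials = 500,
                                station = "WP", seed = NULL) {
  if (phi < 1) {
    abort("phi must be >= 1 for the negative-binomial/beta-binomial mechanism",
          class = "cmtracer_value_error")
  }
  covs <- setdiff(ENV_COVARIATES, "chl_a")
  bad <- setdiff(names(beta), covs)
  if (length(bad) > 0) {
    abort(sprintf("unknown covariate(s) in beta: %s", paste(bad, collapse = ", ")),
          class = "cmtracer_value_error")
  }
  b <- setNames(rep(0, length(covs)), covs)
  b[names(beta)] <- beta

  marg <- list(
    temperature = c(18, 7), salinity = c(12, 6), turbidity = c(10, 5),
    NH3 = c(5, 2), NOx = c(1.5, 0.8), PO4 = c(0.12, 0.05),
    SiO2 = c(7, 3), Kd = c(2.5, 1)
  )
  with_seed_if(seed, {
    k <- length(covs)
    R <- matrix(rho, k, k)
    diag(R) <- 1
    L <- chol(R)
    Z <- matrix(rnorm(n_dates * k), n_dates, k) %*% L
    colnames(Z) <- covs
    dates <- iso_dates(n_dates)
    exposure <- rep_len(exposure, n_dates)

    env_nat <- tibble::as_tibble(vapply(covs, function(v) {
      m <- marg[[v]]
      pmax(m[1] + m[2] * Z[, v], 0)
    }, double(n_dates)))

    idx <- rep(seq_len(n_dates), each = n_replicates)
    eta <- intercept + as.vector(Z %*% b)
    mu_count <- exposure * exp(eta)
    mu_prop <- stats::plogis(eta)
    rho_bb <- (phi - 1) / (n_trials - 1)

    draw_count <- function(mu) {
      if (phi == 1) return(stats::rpois(length(mu), mu))
      rnbinom(length(mu), size = mu / (phi - 1), mu = mu)
    }
    draw_prop <- function(mu) {
      if (rho_bb <= 0) return(rbinom(length(mu), n_trials, mu) / n_trials)
      a <- mu * (1 - rho_bb) / rho_bb
      bb <- (1 - mu) * (1 - rho_bb) / rho_bb
      p <- rbeta(length(mu), a, bb)
      rbinom(length(mu), n_trials, p) / n_trials
    }

    env <- dplyr::bind_cols(
      tibble::tibble(station = station, date = dates[idx],
                     replicate = rep(seq_len(n_replicates), n_dates)),
      env_nat[idx, ],
      tibble::tibble(grids_counted = as.integer(exposure[idx]))
    )
    response <- tibble::tibble(
      station = station, date = dates[idx],
      replicate = rep(seq_len(n_replicates), n_dates),
      count = draw_count(mu_count[idx]),
      proportion = draw_prop(mu_prop[idx])
    )
    list(
      env = env,
      response = response,
      truth = list(beta = b, intercept = intercept, phi = phi, rho = rho,
                   n_trials = n_trials, z = Z[idx, , drop = FALSE])
    )
  })
}

#' Simulate a full two-station study
#'
#' Builds every input of the end-to-end pipeline on one shared ASV
#' universe: a +/-BrdU experiment per station and date (each date samples
#' its planted CM ASVs from a per-station pool, so stations share some CM
#' ASVs and keep some unique), a microscopy series whose genera overlap
#' the amplicon taxonomy, and per-station environmental series. The
#' ground truth (planted sets per experiment, per-station pools, seed,
#' generator parameters) is returned and can be serialized with
#' [write_truth()].
#'
#' @param stations Two station ids.
#' @param n_dates Sampling dates per station.
#' @param n_asvs,depth,n_replicates,n_planted,enrichment,planted_baseline_pct,concentration,jitter_precision
#'   Passed to [simulate_brdu_experiment()].
#' @param station_pool_size Number of candidate CM ASVs in each station's
#'   pool.
#' @param shared_fraction Fraction of each station's pool shared with the
#'   other station.
#' @param seed Integer seed (the study is fully reproducible from it).
#' @return A list of class `"cm_study"`: `counts`, `taxonomy`,
#'   `microscopy`, `env`, `truth`.
#' @export
simulate_study <- function(stations = c("WP", "GP"), n_dates = 24,
                           n_asvs = 400, depth = 20000, n_replicates = 3,
                           n_planted = 12, enrichment = 2,
                           planted_baseline_pct = 0.75,
                           concentration = 0.5, jitter_precision = 5000,
                           station_pool_size = 40, shared_fraction = 0.5,
                           seed = 1) {
  stopifnot(length(stations) == 2)
  with_seed_if(seed, {
    taxonomy <- build_synthetic_taxonomy(n_asvs, default_genus_pool())
    plastid_ids <- taxonomy$asv_id[taxonomy$has_plastid]
    n_shared <- round(shared_fraction * station_pool_size)
    n_unique <- station_pool_size - n_shared
    if (length(plastid_ids) < n_shared + 2 * n_unique) {
      abort("not enough plastid ASVs for the requested station pools",
            class = "cmtracer_value_error")
    }
    shuffled <- sample(plastid_ids)
    shared_pool <- shuffled[seq_len(n_shared)]
    pool_a <- c(shared_pool, shuffled[n_shared + seq_len(n_unique)])
    pool_b <- c(shared_pool, shuffled[n_shared + n_unique + seq_len(n_unique)])
    pools <- setNames(list(pool_a, pool_b), stations)

    dates <- iso_dates(n_dates)
    counts <- list()
    planted_sets <- list()
    for (st in stations) {
      for (dt in dates) {
        planted <- sample(pools[[st]], min(n_planted, length(pools[[st]])))
        sim <- simulate_planted_experiment(
          taxonomy, planted, depth = depth, n_replicates = n_replicates,
          enrichment = enrichment,
          planted_baseline_pct = planted_baseline_pct,
          concentration = concentration,
          jitter_precision = jitter_precision, station = st, date = dt
        )
        counts[[length(counts) + 1]] <- sim$counts
        planted_sets[[paste(st, dt, sep = "_")]] <- planted
      }
    }
    microscopy <- simulate_microscopy(stations = stations, dates = dates)
    env <- dplyr::bind_rows(lapply(stations, function(st) {
      simulate_env_series(n_dates = n_dates, n_replicates = 1,
                          beta = c(temperature = 0.3, NOx = -0.3),
                          station = st)$env %>%
        dplyr::select(-"replicate", -"grids_counted") %>%
        dplyr::mutate(date = dates, chl_a = round(rlnorm(n_dates, log(10), 0.5), 2))
    }))

    structure(
      list(
        counts = dplyr::bind_rows(counts),
        taxonomy = taxonomy,
        microscopy = microscopy,
        env = env,
        truth = list(
          seed = seed,
          stations = stations,
          station_pools = pools,
          planted_sets = planted_sets,
          params = list(
            n_dates = n_dates, n_asvs = n_asvs, depth = depth,
            n_replicates = n_replicates, n_planted = n_planted,
            enrichment = enrichment,
            planted_baseline_pct = planted_baseline_pct,
            concentration = concentration,
            jitter_precision = jitter_precision,
            station_pool_size = station_pool_size,
            shared_fraction = shared_fraction
          )
        )
      ),
      class = "cm_study"
    )
  })
}

# one experiment with an externally chosen planted set on a shared taxonomy
simulate_planted_experiment <- function(taxonomy, planted, depth,
                                        n_replicates, enrichment,
                                        planted_baseline_pct, concentration,
                                        jitter_precision, station, date) {
  n_asvs <- nrow(taxonomy)
  is_planted <- taxonomy$asv_id %in% planted
  base <- rdirichlet(rep(concentration, n_asvs))
  planted_mass <- sum(is_planted) * planted_baseline_pct / 100
  base[is_planted] <- planted_baseline_pct / 100
  base[!is_planted] <- base[!is_planted] * (1 - planted_mass) /
    sum(base[!is_planted])
  f <- ifelse(is_planted, enrichment, 1)
  plus <- base * f / sum(base * f)
  rows <- list()
  for (tr in c("plus", "minus")) {
    p_tr <- if (tr == "plus") plus else base
    for (r in seq_len(n_replicates)) {
      p <- if (is.finite(jitter_precision)) rdirichlet(jitter_precision * p_tr) else p_tr
      rows[[length(rows) + 1]] <- tibble::tibble(
        station = station, date = date, treatment = tr, replicate = r,
        asv_id = taxonomy$asv_id, count = as.integer(rmultinom(1, depth, p))
      )
    }
  }
  list(counts = dplyr::bind_rows(rows))
}

#' Serialize study ground truth to JSON
#'
#' @param truth The `truth` element of a [simulate_study()] result.
#' @param path Output path (`truth.json`).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Reload study ground truth written by [write_truth()]
#'
#' @param path Path to `truth.json`.
#' @return The truth list.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$planted_sets <- lapply(tr$planted_sets, as.character)
  tr$station_pools <- lapply(tr$station_pools, as.character)
  tr
}

#' Write all inputs of a simulated study to a directory
#'
#' Writes the feature table, taxonomy, microscopy and environment tables in
#' the same plain-text formats the readers consume, plus `truth.json`.
#'
#' @param study A `"cm_study"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(study$counts, file.path(dir, "feature_table.tsv"))
  write_taxonomy(study$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_microscopy(study$microscopy, file.path(dir, "microscopy.csv"))
  write_env_table(study$env, file.path(dir, "environment.csv"))
  write_truth(study$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
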