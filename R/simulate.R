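#' Configuration for the synthetic-data generator
#'
#' The generator emulates the structure of the study panel: 31
#' provincial-level regions (12 eastern, 9 central, 10 western) observed
#' 2018-2022 on the 14-indicator schema, scored by 7 experts. Each
#' region's capacity is a latent scalar: its category's mean (category
#' means are `latent` plus `category_gap` times +1/0/-1 for
#' eastern/central/western) plus a Gaussian region effect. Indicator
#' values are monotone unit-scale transforms of latent + linear year trend
#' + Gaussian noise. All randomness flows from `seed`; global RNG state is
#' left untouched.
#'
#' @param seed integer seed (mandatory)
#' @param n_regions named integer triple of regions per category
#' @param years calendar years of the panel
#' @param latent baseline latent capacity, or a named triple of category
#'   means (then `category_gap` is ignored)
#' @param category_gap latent separation between adjacent categories
#' @param region_sd SD of the per-region latent effect
#' @param noise_sd SD of per-cell Gaussian noise on the latent scale
#' @param trend latent increase per year
#' @param missing_rate share of cells blanked at random (each
#'   region-indicator series keeps at least one observation)
#' @param n_experts number of simulated experts
#' @param expert_disagreement max integer jitter around the per-indicator
#'   consensus score (0 = identical experts)
#' @return a `sim_config` list
#' @export
sim_config <- function(seed,
                       n_regions = c(eastern = 12L, central = 9L, western = 10L),
                       years = 2018:2022,
                       latent = 0.5,
                       category_gap = 0.1,
                       region_sd = 0.05,
                       noise_sd = 0.05,
                       trend = 0.02,
                       missing_rate = 0.02,
                       n_experts = 7L,
                       expert_disagreement = 1L) {
  if (missing(seed)) stop_regcap("seed is mandatory for reproducibility")
  stopifnot(all(n_regions >= 1), length(years) >= 1,
            category_gap >= 0, region_sd >= 0, noise_sd >= 0,
            missing_rate >= 0, missing_rate < 1, n_experts >= 1,
            expert_disagreement >= 0)
  if (is.null(names(n_regions)) || !setequal(names(n_regions), region_categories))
    stop_regcap("n_regions must be named eastern/central/western")
  structure(list(seed = as.integer(seed), n_regions = n_regions,
                 years = as.integer(years), latent = latent,
                 category_gap = category_gap, region_sd = region_sd,
                 noise_sd = noise_sd, trend = trend,
                 missing_rate = missing_rate, n_experts = as.integer(n_experts),
                 expert_disagreement = as.integer(expert_disagreement)),
            class = "sim_config")
}

category_means <- function(config) {
  if (length(config$latent) == 3 && !is.null(names(config$latent)))
    return(config$latent[region_categories])
  config$latent + config$category_gap * c(eastern = 1, central = 0, western = -1)
}

# monotone unit-scale links; negative indicators reverse the signal so
# that larger latent capacity always means a *better* raw value
link_value <- function(s, unit, name, nature) {
  if (nature == "negative") s <- -s
  if (unit == "%") {
    if (grepl("qualified", name, ignore.case = TRUE))
      return(pmin(pmax(85 + 15 * stats::plogis(4 * (s - 0.5)), 85), 100))
    return(100 * stats::plogis(4 * (s - 0.5)))
  }
  if (unit %in% c("piece", "count", "number of times"))
    return(pmax(round(5000 * exp(s)), 0))
  if (unit == "ten thousand yuan") return(10000 * exp(s))
  s
}

#' Simulate a raw indicator panel with known latent structure
#'
#' @param config a [sim_config()]
#' @param schema an [indicator_schema()] (default: the bundled schema)
#' @return a `raw_panel`; attribute `"truth"` holds the latent region
#'   capacities (data.frame `region`, `category`, `latent`)
#' @export
simulate_panel <- function(config,
                           schema = read_schema(regcap_example("schema.yaml"))) {
  stopifnot(inherits(config, "sim_config"))
  with_rng(config$seed, {
    means <- category_means(config)
    regions <- unlist(lapply(region_categories, function(cat)
      sprintf("%s_%02d", cat, seq_len(config$n_regions[[cat]]))))
    cats <- rep(region_categories, times = config$n_regions[region_categories])
    latent <- means[cats] + stats::rnorm(length(regions), 0, config$region_sd)
    truth <- data.frame(region = regions, category = cats,
                        latent = as.numeric(latent), stringsAsFactors = FALSE)

    inds <- schema$indicators
    years <- config$years
    rows <- vector("list", length(regions))
    for (r in seq_along(regions)) {
      cells <- expand.grid(indicator = inds$id, year = years,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      t_idx <- match(cells$year, years) - 1L
      s <- latent[r] + config$trend * t_idx +
        stats::rnorm(nrow(cells), 0, config$noise_sd)
      irow <- match(cells$indicator, inds$id)
      val <- vapply(seq_len(nrow(cells)), function(i)
        link_value(s[i], inds$unit[irow[i]], inds$name[irow[i]],
                   inds$nature[irow[i]]), numeric(1))
      rows[[r]] <- data.frame(region = regions[r], category = cats[r],
                              year = cells$year, indicator = cells$indicator,
                              value = val, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    if (config$missing_rate > 0) {
      drop <- stats::runif(nrow(df)) < config$missing_rate
      df$value[drop] <- NA_real_
      # never blank out a whole (region, indicator) series
      key <- paste(df$region, df$indicator, sep = "\r")
      for (k in unique(key[drop])) {
        idx <- which(key == k)
        if (all(is.na(df$value[idx]))) {
          keep <- idx[ceiling(length(idx) / 2)]
          df$value[keep] <- vapply(keep, function(i) {
            j <- match(df$indicator[i], inds$id)
            link_value(latent[match(df$region[i], regions)] +
                         config$trend * (match(df$year[i], years) - 1L),
                       inds$unit[j], inds$name[j], inds$nature[j])
          }, numeric(1))
        }
      }
    }
    panel <- as_raw_panel(df, schema = schema)
    attr(panel, "truth") <- truth
    panel
  })
}

#' Simulate an expert importance-score table
#'
#' Scores are drawn as integer jitter around a fixed per-indicator
#' consensus (cycling through 2, 3, 4 in schema order), clipped to 1-5.
#'
#' @inheritParams simulate_panel
#' @return an `expert_scores` table
#' @export
simulate_expert_scores <- function(config,
                                   schema = read_schema(regcap_example("schema.yaml"))) {
  stopifnot(inherits(config, "sim_config"))
  with_rng(config$seed + 1L, {
    inds <- schema_indicators(schema)
    consensus <- 2 + (seq_along(inds) - 1L) %% 3
    d <- config$expert_disagreement
    rows <- lapply(seq_len(config$n_experts), function(e) {
      jitter <- if (d > 0) sample(seq(-d, d), length(inds), replace = TRUE) else 0
      data.frame(expert = sprintf("expert_%d", e), indicator = inds,
                 score = pmin(pmax(consensus + jitter, 1), 5),
                 stringsAsFactors = FALSE)
    })
    as_expert_scores(do.call(rbind, rows))
  })
}

#' Simulate a national pharmacovigilance series
#'
#' Yearly ADR totals grow geometrically with lognormal noise; the serious
#' share rises linearly; trial applications grow with approvals tracking a
#' rising pass rate. At zero noise every series is exactly monotone, and
#' the count invariants (serious <= total, approvals <= applications)
#' hold by construction.
#'
#' @param config a [sim_config()] (`noise_sd` scales the count noise)
#' @return a `vigilance_series`
#' @export
simulate_vigilance <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_rng(config$seed + 2L, {
    t_idx <- seq_along(config$years) - 1L
    wig <- function(n) exp(stats::rnorm(n, 0, config$noise_sd / 2))
    adr <- round(1.5e6 * 1.08^t_idx * wig(length(t_idx)))
    share <- pmin(0.10 + 0.01 * t_idx, 0.5)
    serious <- pmin(round(adr * share), adr)
    apps <- round(1100 * 1.15^t_idx * wig(length(t_idx)))
    rate <- pmin(0.78 + 0.02 * t_idx, 0.99)
    appr <- pmin(round(apps * rate), apps)
    as_vigilance_series(data.frame(
      year = config$years, adr_reports = adr, serious_reports = serious,
      trial_applications = apps, trial_approvals = appr))
  })
}
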