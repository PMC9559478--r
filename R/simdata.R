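#' Simulate a monthly meteorology series
#'
#' Generates a seeded monthly series of temperature, relative humidity,
#' cloud cover and rain for a single temperate maritime site (one station
#' standing in for the whole study region), plus the derived
#' temperature-humidity index (THI). Temperature follows a sinusoid
#' peaking in July; humidity and cloud cover are anti-phased (winter
#' maxima); rain is nearly aseasonal with a mild winter surplus.
#'
#' @param n_years number of years to simulate (>= 1).
#' @param seed integer RNG seed.
#' @param start_year calendar year of the first January (default 2011).
#' @param temp_mean annual mean temperature, degrees C (default 10).
#' @param temp_amplitude half-range of the seasonal temperature cycle,
#'   degrees C (default 7.5).
#' @param temp_noise_sd SD of month-to-month temperature noise (default 0.8).
#' @return data.frame with columns `year`, `month`, `temperature` (deg C),
#'   `humidity` (%), `cloud` (%), `rain` (mm), `thi`.
#' @seealso [compute_thi()], [generate_dataset()]
#' @examples
#' m <- simulate_meteo(2, seed = 1)
#' head(m)
#' @export
simulate_meteo <- function(n_years, seed, start_year = 2011,
                           temp_mean = 10, temp_amplitude = 7.5,
                           temp_noise_sd = 0.8) {
  n_years <- check_count(n_years, "n_years")
  n <- 12L * n_years
  year <- rep(start_year + seq_len(n_years) - 1L, each = 12L)
  month <- rep(1:12, times = n_years)
  season <- cos(2 * pi * (month - 7) / 12)  # +1 in July, -1 in January
  with_seed(seed, {
    temperature <- temp_mean + temp_amplitude * season +
      stats::rnorm(n, sd = temp_noise_sd)
    humidity <- pmin(100, pmax(0, 80 - 8 * season + stats::rnorm(n, sd = 1.5)))
    cloud <- pmin(100, pmax(0, 72 - 14 * season + stats::rnorm(n, sd = 4)))
    rain <- pmax(0, 72 - 8 * season + stats::rnorm(n, sd = 15))
    data.frame(year = year, month = month,
               temperature = temperature, humidity = humidity,
               cloud = cloud, rain = rain,
               thi = compute_thi(temperature, humidity))
  })
}

#' Latent grass fraction of the diet for one month
#'
#' Deterministic link from calendar month (and the month's THI) to the
#' latent fraction g in \[0, 1\] of grass in the herd's ration. Cows are
#' fully housed December through February (g = 0), are put to pasture
#' through a logistic spring ramp, hold a summer plateau near the farm's
#' `grass_amplitude` in June-August, and come back in through an autumn
#' ramp. Higher THI (warmer months) pushes the plateau up slightly,
#' emulating grass growth responding to heat.
#'
#' @param month integer vector in 1..12.
#' @param grass_amplitude peak grass fraction of the farm, in \[0, 1\].
#' @param thi temperature-humidity index of the month (default 58, the
#'   reference level at which THI modulation is neutral).
#' @param transition_width width of the spring/autumn logistic ramps in
#'   months (default 1.5: the ramp runs 12% to 88% of its range over 1.5
#'   months).
#' @param onset,offset month indices of the ramp midpoints (defaults 4.2
#'   and 9.8: turn-out through April, housing through late September).
#' @param thi_effect relative plateau change per 20 THI units (default 0.1).
#' @return numeric vector of grass fractions in \[0, 1\].
#' @examples
#' grass_fraction(1:12, grass_amplitude = 1)
#' @export
grass_fraction <- function(month, grass_amplitude, thi = 58,
                           transition_width = 1.5,
                           onset = 4.2, offset = 9.8, thi_effect = 0.1) {
  if (any(month < 1 | month > 12)) {
    stop("`month` must be in 1..12", call. = FALSE)
  }
  stopifnot(grass_amplitude >= 0, grass_amplitude <= 1)
  s <- transition_width / 4
  g <- grass_amplitude *
    stats::plogis((month - onset) / s) *
    stats::plogis((offset - month) / s)
  g <- g * (1 + thi_effect * (thi - 58) / 20)
  g[month %in% c(12L, 1L, 2L)] <- 0
  pmin(1, pmax(0, g))
}

#' Draw farm archetypes for a simulated cohort
#'
#' Assigns each farm one of four feeding archetypes and its parameters,
#' using a per-farm RNG substream (derived by hashing the farm id with the
#' root seed), so enlarging the cohort never changes existing farms.
#'
#' Archetypes:
#' \describe{
#'   \item{intensive}{high-concentrate ration, limited grazing
#'     (peak grass fraction 0.30-0.45).}
#'   \item{intermediate}{moderate grazing (0.65-0.80).}
#'   \item{extensive}{near-full summer grazing (0.92-1.00) and a winter
#'     ration richer in long-chain fatty acids (additive LCFA offset).}
#'   \item{skimmed}{farms whose submitted bulk-milk sample is skimmed
#'     (processed) milk: fat is stripped to about 0.25 g/100 g year-round,
#'     the fat-borne fatty-acid traits scale down accordingly, and the
#'     sample composition is decoupled from the herd's feeding season, so
#'     these records carry no grazing signal at all.}
#' }
#'
#' @param n_farms number of farms.
#' @param archetype_mix named numeric vector of proportions over
#'   `c("intensive", "intermediate", "extensive", "skimmed")`; must sum
#'   to 1. Missing names count as 0.
#' @param seed integer root seed.
#' @return data.frame with columns `farm_id`, `archetype`,
#'   `grass_amplitude`, `winter_lcfa_offset` (g/dL), `skimmed_flag`.
#' @export
farm_archetypes <- function(n_farms,
                            archetype_mix = c(intensive = 0.30,
                                              intermediate = 0.43,
                                              extensive = 0.25,
                                              skimmed = 0.02),
                            seed = 1) {
  n_farms <- check_count(n_farms, "n_farms")
  all_types <- c("intensive", "intermediate", "extensive", "skimmed")
  mix <- stats::setNames(numeric(4), all_types)
  mix[names(archetype_mix)] <- archetype_mix
  if (abs(sum(mix) - 1) > 1e-8) {
    stop("`archetype_mix` proportions must sum to 1", call. = FALSE)
  }
  cum <- cumsum(mix)
  out <- vector("list", n_farms)
  for (i in seq_len(n_farms)) {
    fid <- sprintf("farm_%04d", i)
    out[[i]] <- with_seed(farm_seed(seed, fid), {
      u <- stats::runif(1)
      type <- all_types[findInterval(u, cum, rightmost.closed = TRUE) + 1L]
      amp <- switch(type,
        intensive    = stats::runif(1, 0.30, 0.45),
        intermediate = stats::runif(1, 0.65, 0.80),
        extensive    = stats::runif(1, 0.92, 1.00),
        skimmed      = stats::runif(1, 0.65, 0.80))
      data.frame(farm_id = fid, archetype = type, grass_amplitude = amp,
                 winter_lcfa_offset = if (type == "extensive") 0.15 else 0,
                 skimmed_flag = type == "skimmed",
                 stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, out)
}

#' Generate a synthetic herd bulk-milk dataset
#'
#' Simulates one bulk-milk record per farm and month: each trait value is
#' `baseline_mean * (1 + (grass_multiplier - 1) * g)` plus Gaussian noise
#' of SD `noise_sd`, where g is the farm's latent grass fraction for that
#' month (see [grass_fraction()]). Fatty-acid traits share a common noise
#' factor per record (correlation `fa_correlation`), reflecting that they
#' are all predicted from the same spectrum. Extensive farms add their
#' winter LCFA offset scaled by (1 - g). Skimmed farms emit fat of about
#' 0.25 g/100 g year-round, with fat-borne FA traits (g/dL of milk) scaled
#' down proportionally and all trait means held at their no-grass baseline
#' (a processed sample does not track the herd's feeding season).
#'
#' The latent grass fraction is stored in column `latent_g` for simulation
#' oracles only; it is never available to real milk-recording data and
#' must not be fed to models.
#'
#' @param n_farms,n_years cohort size.
#' @param archetype_mix see [farm_archetypes()].
#' @param schema trait schema (default [default_trait_schema()]).
#' @param seed integer root seed.
#' @param meteo optional meteorology table from [simulate_meteo()]; by
#'   default one is simulated from `seed` for `n_years` starting at
#'   `start_year`.
#' @param start_year first calendar year (default 2011).
#' @param fa_correlation shared-noise correlation among fatty-acid traits
#'   (default 0.3).
#' @return data.frame with columns `farm_id`, `year`, `month`, the 48
#'   trait columns (schema units), and `latent_g`. The archetype table is
#'   attached as `attr(x, "archetypes")`.
#' @examples
#' d <- generate_dataset(5, 1, seed = 42)
#' dim(d)  # 60 rows, 52 columns
#' @export
generate_dataset <- function(n_farms, n_years,
                             archetype_mix = c(intensive = 0.30,
                                               intermediate = 0.43,
                                               extensive = 0.25,
                                               skimmed = 0.02),
                             schema = default_trait_schema(),
                             seed = 1, meteo = NULL, start_year = 2011,
                             fa_correlation = 0.3) {
  n_farms <- check_count(n_farms, "n_farms")
  n_years <- check_count(n_years, "n_years")
  if (is.null(schema) || nrow(schema) == 0L) {
    stop("empty trait schema", call. = FALSE)
  }
  validate_trait_schema(schema)
  stopifnot(fa_correlation >= 0, fa_correlation < 1)
  if (is.null(meteo)) {
    meteo <- simulate_meteo(n_years, seed = seed, start_year = start_year)
  }
  farms <- farm_archetypes(n_farms, archetype_mix, seed = seed)
  p <- nrow(schema)
  is_fa <- schema$unit == "g/dL milk"
  fat_row <- match("fat_pct", schema$name)
  lcfa_row <- match("lcfa", schema$name)
  fat_baseline <- schema$baseline_mean[fat_row]
  skim_fat <- 0.25  # g/100 g, skimmed bulk samples
  n_rec <- 12L * n_years
  key <- paste(meteo$year, meteo$month)
  rows <- vector("list", n_farms)
  for (i in seq_len(n_farms)) {
    fm <- farms[i, ]
    year <- rep(start_year + seq_len(n_years) - 1L, each = 12L)
    month <- rep(1:12, times = n_years)
    thi <- meteo$thi[match(paste(year, month), key)]
    g <- grass_fraction(month, fm$grass_amplitude, thi = thi)
    rows[[i]] <- with_seed(farm_seed(seed, fm$farm_id) + 1L, {
      # skimmed farms submit processed samples whose composition is
      # decoupled from the herd's feeding season
      g_sample <- if (fm$skimmed_flag) rep(0, n_rec) else g
      mu <- outer(g_sample, schema$grass_multiplier - 1) + 1
      mu <- sweep(mu, 2, schema$baseline_mean, "*")
      # extensive winter ration: LCFA-rich conserved forage
      mu[, lcfa_row] <- mu[, lcfa_row] + fm$winter_lcfa_offset * (1 - g_sample)
      z <- matrix(stats::rnorm(n_rec * p), n_rec, p)
      z_common <- stats::rnorm(n_rec)
      rho <- fa_correlation
      z[, is_fa] <- sqrt(1 - rho) * z[, is_fa] + sqrt(rho) * z_common
      vals <- mu + sweep(z, 2, schema$noise_sd, "*")
      if (fm$skimmed_flag) {
        scale_f <- skim_fat / fat_baseline
        vals[, is_fa] <- vals[, is_fa] * scale_f
        vals[, fat_row] <- skim_fat + stats::rnorm(n_rec, sd = 0.03)
      }
      vals <- pmax(vals, 0)  # composition traits cannot be negative
      colnames(vals) <- schema$name
      cbind(data.frame(farm_id = fm$farm_id, year = year, month = month,
                       stringsAsFactors = FALSE),
            as.data.frame(vals),
            data.frame(latent_g = g))
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "archetypes") <- farms
  attr(out, "meteo") <- meteo
  out
}

#' Fatty-acid traits rescaled to g/100 g of milk fat
#'
#' The simulator emits fatty-acid traits on the g/dL-of-milk scale (the
#' scale of the underlying prediction equations). Milk fat composition is
#' often more informative for diet assessment, so this helper derives the
#' g/100 g-of-fat scale by dividing each FA trait by the record's fat
#' content (g/100 g of milk, taken as numerically equal to g/dL).
#'
#' @param records data.frame from [generate_dataset()] (or the same
#'   columns read from CSV).
#' @param traits character vector of FA trait names to convert (default:
#'   all g/dL traits of the default schema).
#' @return data.frame of the converted traits, suffix `_fat`, aligned with
#'   `records` rows.
#' @export
fa_per_100g_fat <- function(records,
                            traits = trait_names()[
                              default_trait_schema()$unit == "g/dL milk"]) {
  missing <- setdiff(c("fat_pct", traits), names(records))
  if (length(missing)) {
    stop("records are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- as.data.frame(
    lapply(records[traits], function(v) 100 * v / records$fat_pct))
  names(out) <- paste0(traits, "_fat")
  out
}
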