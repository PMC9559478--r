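test_that("meteorology series covers the calendar and is seed-deterministic", {
  m <- simulate_meteo(1, seed = 7)
  expect_equal(nrow(m), 12L)
  expect_setequal(m$month, 1:12)
  expect_identical(m, simulate_meteo(1, seed = 7))
  expect_false(identical(m$temperature, simulate_meteo(1, seed = 8)$temperature))
  expect_true(all(m$humidity >= 0 & m$humidity <= 100))
  expect_true(all(m$cloud >= 0 & m$cloud <= 100))
  expect_true(all(m$rain >= 0))
  expect_equal(m$thi, compute_thi(m$temperature, m$humidity))
  expect_error(simulate_meteo(0, seed = 1), "n_years")
})

test_that("simulated summers are warmer than winters", {
  m <- simulate_meteo(3, seed = 1)
  jul <- mean(m$temperature[m$month == 7])
  jan <- mean(m$temperature[m$month == 1])
  # generator parameters: 10 +/- 7.5 sinusoid, noise SD 0.8 -> the
  # deterministic July-January gap is 15 degrees, far beyond the noise
  expect_gt(jul, jan)
  expect_gt(jul - jan, 10)
})

test_that("grass fraction obeys winter housing, summer plateau and ramps", {
  expect_equal(grass_fraction(1, grass_amplitude = 0.8), 0)
  expect_equal(grass_fraction(12, grass_amplitude = 1, thi = 70), 0)
  expect_gte(grass_fraction(7, grass_amplitude = 1, thi = 65), 0.95)
  expect_error(grass_fraction(13, 0.5), "month")
  # monthly sequence for a default farm under simulated meteorology
  m <- simulate_meteo(1, seed = 3)
  g <- grass_fraction(1:12, grass_amplitude = 0.8, thi = m$thi)
  expect_true(all(g >= 0 & g <= 1))
  expect_true(all(diff(g[3:7]) >= 0))   # March -> July nondecreasing
  expect_true(all(diff(g[8:11]) <= 0))  # August -> November nonincreasing
})

test_that("dataset has one record per farm-month and is byte-deterministic", {
  d <- generate_dataset(10, 2, seed = 11)
  expect_equal(nrow(d), 10 * 2 * 12)
  expect_equal(ncol(d), 3 + 48 + 1)
  expect_true(all(is.finite(as.matrix(d[trait_names()]))))
  expect_true(all(d$latent_g >= 0 & d$latent_g <= 1))
  expect_identical(d, generate_dataset(10, 2, seed = 11))
  expect_error(generate_dataset(2, 1, schema = data.frame()), "schema")
})

test_that("adding farms never perturbs the records of existing farms", {
  d10 <- generate_dataset(10, 2, seed = 11)
  d15 <- generate_dataset(15, 2, seed = 11)
  first10 <- d15[d15$farm_id %in% unique(d10$farm_id), ]
  rownames(first10) <- NULL
  attributes(d10)[c("archetypes", "meteo")] <- NULL
  attributes(first10)[c("archetypes", "meteo")] <- NULL
  expect_identical(d10, first10)
})

test_that("null schema makes summer and winter trait means indistinguishable", {
  d <- generate_dataset(24, 3, schema = null_trait_schema(), seed = 19)
  summer <- d$month %in% 6:8
  winter <- d$month %in% c(12, 1, 2)
  for (tr in trait_names()) {
    a <- d[[tr]][summer]
    b <- d[[tr]][winter]
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    expect_lt(abs(mean(a) - mean(b)) / se, 3)
  }
})

test_that("null schema makes GRASS and NOGRASS exchangeable (permutation test)", {
  d <- generate_dataset(56, 3, schema = null_trait_schema(), seed = 23)
  expect_gte(nrow(d), 2000)
  lab <- build_modeling_subset(label_records(d, 1))
  x <- lab$c18_3_cis9_cis12_cis15
  obs <- abs(mean(x[lab$y == 1]) - mean(x[lab$y == 0]))
  set.seed(1)
  perm <- replicate(999, {
    yp <- sample(lab$y)
    abs(mean(x[yp == 1]) - mean(x[yp == 0]))
  })
  p_value <- (1 + sum(perm >= obs)) / 1000
  expect_gt(p_value, 0.01)
})

test_that("full-grass milk shows the configured C18:3 enrichment", {
  d <- generate_dataset(80, 2, seed = 31)
  hi <- d$latent_g > 0.95
  lo <- d$latent_g == 0
  expect_gt(sum(hi), 20)
  ratio <- mean(d$c18_3_cis9_cis12_cis15[hi]) /
    mean(d$c18_3_cis9_cis12_cis15[lo])
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.5)
})

test_that("latent grass fraction drives C18:3 up and MCFA down", {
  d <- generate_dataset(40, 2, seed = 37)
  expect_gt(cor(d$latent_g, d$c18_3_cis9_cis12_cis15), 0)
  expect_lt(cor(d$latent_g, d$mcfa), 0)
})

test_that("skimmed farms emit near-zero fat, others normal fat", {
  d <- generate_dataset(60, 1, seed = 41,
                        archetype_mix = c(intensive = 0.3,
                                          intermediate = 0.3,
                                          extensive = 0.3, skimmed = 0.1))
  arch <- attr(d, "archetypes")
  skim_farms <- arch$farm_id[arch$archetype == "skimmed"]
  expect_gt(length(skim_farms), 0)
  skim <- d$farm_id %in% skim_farms
  expect_lt(mean(d$fat_pct[skim]), 1)
  expect_gt(mean(d$fat_pct[!skim]), 3.5)
  expect_lt(mean(d$fat_pct[!skim]), 4.5)
})

test_that("fatty-acid rescaling to g/100 g fat divides by the fat content", {
  d <- generate_dataset(4, 1, seed = 2)
  conv <- fa_per_100g_fat(d)
  expect_equal(conv$sfa_fat, 100 * d$sfa / d$fat_pct)
  expect_error(fa_per_100g_fat(d[, setdiff(names(d), "fat_pct")]), "fat_pct")
})

test_that("archetype mix must sum to one and schema must validate", {
  expect_error(farm_archetypes(5, c(intensive = 0.5)), "sum to 1")
  bad <- default_trait_schema()
  bad$noise_sd[1] <- 0
  expect_error(validate_trait_schema(bad), "noise_sd")
  bad <- default_trait_schema()[-1, ]
  expect_error(validate_trait_schema(bad), "48")
})
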