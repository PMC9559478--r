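#' Default 48-trait bulk-milk composition schema
#'
#' Returns the simulation schema for the 48 milk composition predictors
#' used throughout the package: the four traits read directly from the
#' FT-MIR spectrometer (fat, protein, urea, lactose), milk yield, 31
#' fatty-acid (FA) traits on the g/dL-of-milk scale, lactoferrin, six
#' protein fractions, and five minerals.
#'
#' Each row carries:
#' \describe{
#'   \item{name}{column-safe trait identifier.}
#'   \item{unit}{measurement unit of the simulated value.}
#'   \item{baseline_mean}{herd bulk-milk mean under a no-grass winter
#'     ration. The source survey publishes no herd means, so these are
#'     plausible values for Holstein-dominated Western-European bulk milk,
#'     documented in the methods vignette.}
#'   \item{noise_sd}{residual standard deviation of the simulated value.
#'     For the 44 equation-predicted traits this defaults to the published
#'     root-mean-squared error of the corresponding FT-MIR prediction
#'     equation, so the simulated predictive difficulty is realistic.}
#'   \item{grass_multiplier}{multiplicative shift of the trait mean at a
#'     full-grass diet (latent grass fraction g = 1). Defaults encode the
#'     relative effects reported for pasture milk: C18:3 x4, conjugated
#'     linoleic acid x2, fat and protein x1.05, milk yield x0.62,
#'     long-chain FAs up, short-/medium-chain FAs down, shifted Ca and P.}
#' }
#'
#' @return data.frame with 48 rows and columns `name`, `unit`,
#'   `baseline_mean`, `noise_sd`, `grass_multiplier`.
#' @seealso [generate_dataset()], [null_trait_schema()]
#' @examples
#' sch <- default_trait_schema()
#' nrow(sch)  # 48
#' @export
default_trait_schema <- function() {
  tr <- function(name, unit, mean, sd, mult) {
    data.frame(name = name, unit = unit, baseline_mean = mean,
               noise_sd = sd, grass_multiplier = mult,
               stringsAsFactors = FALSE)
  }
  fat <- 4.10  # g/100 g; FA baselines below are fractions of milk fat (g/dL)
  schema <- rbind(
    # -- 4 direct spectrometer traits -------------------------------------
    tr("fat_pct",     "g/100 g milk", fat,   0.250, 1.05),
    tr("protein_pct", "g/100 g milk", 3.45,  0.120, 1.05),
    tr("urea",        "mg/dL milk",   25.0,  4.00,  1.25),
    tr("lactose",     "g/100 g milk", 4.60,  0.080, 1.00),
    # -- milk yield -------------------------------------------------------
    tr("milk_yield",  "kg/day",       26.0,  3.48,  0.62),
    # -- 31 fatty-acid traits, g/dL of milk -------------------------------
    tr("c4_0",                  "g/dL milk", 0.145, 0.008, 1.00),
    tr("c6_0",                  "g/dL milk", 0.090, 0.006, 0.95),
    tr("c8_0",                  "g/dL milk", 0.053, 0.004, 0.92),
    tr("c10_0",                 "g/dL milk", 0.123, 0.010, 0.85),
    tr("c12_0",                 "g/dL milk", 0.143, 0.011, 0.85),
    tr("c14_0",                 "g/dL milk", 0.472, 0.030, 0.90),
    tr("c14_1_cis",             "g/dL milk", 0.041, 0.008, 0.95),
    tr("c16_0",                 "g/dL milk", 1.271, 0.091, 1.08),
    tr("c16_1_cis",             "g/dL milk", 0.062, 0.013, 1.10),
    tr("c17_0",                 "g/dL milk", 0.025, 0.003, 1.30),
    tr("c18_0",                 "g/dL milk", 0.390, 0.056, 1.20),
    tr("c18_1_total",           "g/dL milk", 0.902, 0.060, 1.30),
    tr("c18_1_trans",           "g/dL milk", 0.103, 0.025, 1.80),
    tr("c18_1_cis",             "g/dL milk", 0.800, 0.063, 1.25),
    tr("c18_1_cis9",            "g/dL milk", 0.738, 0.061, 1.25),
    tr("c18_2_total",           "g/dL milk", 0.103, 0.014, 1.30),
    tr("c18_2_cis9_cis12",      "g/dL milk", 0.062, 0.011, 1.10),
    tr("c18_2_cis9_trans11",    "g/dL milk", 0.018, 0.010, 2.00),
    tr("c18_3_cis9_cis12_cis15","g/dL milk", 0.016, 0.004, 4.00),
    tr("sfa",                   "g/dL milk", 2.870, 0.072, 0.95),
    tr("mufa",                  "g/dL milk", 1.025, 0.059, 1.20),
    tr("pufa",                  "g/dL milk", 0.143, 0.021, 1.50),
    tr("ufa",                   "g/dL milk", 1.170, 0.064, 1.25),
    tr("scfa",                  "g/dL milk", 0.410, 0.025, 0.85),
    tr("mcfa",                  "g/dL milk", 2.050, 0.104, 0.80),
    tr("lcfa",                  "g/dL milk", 1.640, 0.110, 1.25),
    tr("branched_fa",           "g/dL milk", 0.074, 0.013, 1.30),
    tr("omega3",                "g/dL milk", 0.021, 0.006, 2.50),
    tr("omega6",                "g/dL milk", 0.074, 0.014, 1.20),
    tr("odd_fa",                "g/dL milk", 0.090, 0.016, 1.30),
    tr("trans_fa",              "g/dL milk", 0.144, 0.029, 1.80),
    # -- lactoferrin and 6 protein fractions ------------------------------
    tr("lactoferrin",       "mg/L milk", 150.0, 139.01, 1.10),
    tr("casein_alpha_s1",   "g/L milk",  10.50, 0.58,   1.04),
    tr("casein_alpha_s2_k", "g/L milk",  6.00,  0.36,   1.04),
    tr("casein_beta",       "g/L milk",  9.80,  1.13,   1.04),
    tr("lactalbumin",       "g/L milk",  1.20,  0.15,   1.05),
    tr("lactoglobulin",     "g/L milk",  3.30,  0.25,   1.08),
    tr("casein_total",      "g/L milk",  26.50, 1.56,   1.04),
    # -- 5 minerals, mg/kg of milk ----------------------------------------
    tr("sodium",     "mg/kg milk", 400.0,  50.98, 1.00),
    tr("calcium",    "mg/kg milk", 1180.0, 53.38, 1.06),
    tr("phosphorus", "mg/kg milk", 950.0,  58.71, 0.94),
    tr("potassium",  "mg/kg milk", 1520.0, 88.14, 1.03),
    tr("magnesium",  "mg/kg milk", 115.0,  6.53,  1.06)
  )
  validate_trait_schema(schema)
  schema
}

#' Null-effect variant of the default trait schema
#'
#' All `grass_multiplier` values set to 1, so the simulated traits carry no
#' grazing signal. Used as a negative control: under this schema GRASS and
#' NOGRASS trait distributions are exchangeable and classifiers should
#' perform at chance.
#'
#' @return data.frame as [default_trait_schema()] with unit multipliers.
#' @export
null_trait_schema <- function() {
  schema <- default_trait_schema()
  schema$grass_multiplier <- rep(1, nrow(schema))
  schema
}

#' Validate a trait schema
#'
#' Checks the structural invariants of a simulation schema: exactly 48
#' predictor entries, unique names, strictly positive noise standard
#' deviations and grass multipliers.
#'
#' @param schema data.frame as returned by [default_trait_schema()].
#' @return `schema`, invisibly, or an error.
#' @export
validate_trait_schema <- function(schema) {
  required <- c("name", "unit", "baseline_mean", "noise_sd",
                "grass_multiplier")
  missing <- setdiff(required, names(schema))
  if (length(missing)) {
    stop("trait schema is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(schema) != 48L) {
    stop("trait schema must have exactly 48 predictor entries, got ",
         nrow(schema), call. = FALSE)
  }
  if (anyDuplicated(schema$name)) {
    stop("trait schema names must be unique", call. = FALSE)
  }
  if (any(!is.finite(schema$noise_sd)) || any(schema$noise_sd <= 0)) {
    stop("all noise_sd must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(schema$grass_multiplier)) ||
      any(schema$grass_multiplier <= 0)) {
    stop("all grass_multiplier must be finite and > 0", call. = FALSE)
  }
  invisible(schema)
}

#' Trait (predictor) names of a schema
#'
#' @param schema data.frame as returned by [default_trait_schema()].
#' @return character vector of the 48 predictor names.
#' @export
trait_names <- function(schema = default_trait_schema()) {
  schema$name
}
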