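# Model parameterization: environment-level constants and sampled values.

# Fixed physical constants of the arena.  The domain side length is the
# product of the maximum specific dispersal speed (36 um/s, an E. coli-
# scale flagellar speed) and the time step (1200 s, an E. coli-scale
# minimum doubling time): the fastest swimmer can cross the arena in
# exactly one step, and the fastest reproducer doubles at most once.
SECONDS_PER_STEP <- 1200
MAX_SPEED_UM_S   <- 36
DOMAIN_L         <- MAX_SPEED_UM_S * SECONDS_PER_STEP  # 43,200 um

# Resource particle geometry anchors: a particle of content 1000 mass
# units has diameter 4000 um; diameter scales with the cube root of
# content (volume-proportional).
REF_CONTENT  <- 1000
REF_DIAMETER <- 4000
CONTENT_MIN  <- 1000
CONTENT_MAX  <- 10000

# Cell geometry anchor: a cell at full relative quota (Q = 1) has
# diameter 1.25 um; volume is proportional to quota.
QUOTA_MAX_DIAMETER <- 1.25

# Resource type bookkeeping: supplied/metabolite types are 1..10
# (the maximum of the sampled resource-diversity range); type 11 is
# necromass, consumable by every species in scavenging regimes.
N_RESOURCE_TYPES <- 10L
NECROMASS_TYPE   <- 11L

# Gap-filling constants (no printed values exist for these; defaults
# are design choices, discussed in the methods vignette):
#   mass_to_quota    kappa  — relative quota gained per particle mass unit
#   growth_cost_coeff c_g   — fission cost = c_g * growth_rate * Q
#   dispersal_cost_coeff c_d— cost per step = mult * c_d * (dist/L) * Q
#   chemotaxis_cost_mult    — 2: chemotaxis twice as costly as run-and-tumble
#   crossfeed_yield  beta   — metabolite content per unit content consumed
#   dormancy_threshold_coeff theta_d — go dormant when Q <= theta_d * m_s
#   brownian_sigma   sigma_B— per-axis SD of passive Brownian motion, um/step
#   fragment_jitter  eps    — max per-axis offset of fragments, um (aggregation)
#   content_floor           — particles below this content are removed;
#                             1e-6 mass units is a ~4 um diameter crumb
#   particle_cap            — hard ceiling on the particle pool (the
#                             smallest crumbs are culled beyond it);
#                             total particle counts stay below 10,000
DEFAULT_CONSTANTS <- list(
  mass_to_quota        = 0.001,
  growth_cost_coeff    = 0.1,
  dispersal_cost_coeff = 0.05,
  chemotaxis_cost_mult = 2,
  crossfeed_yield      = 0.1,
  dormancy_threshold_coeff = 50,
  brownian_sigma       = 10,
  fragment_jitter      = 100,
  content_floor        = 1e-6,
  particle_cap         = 10000L,
  species_pool_size    = 100L
)

PARAM_FIELDS <- c(
  "supply_rate", "resource_diversity", "lock_key_prob", "necromass_value",
  "immigration_rate", "logseries_alpha", "lock_and_key_polyculture",
  "content_min", "content_max", "ref_content", "ref_diameter",
  "domain_length", "seconds_per_step", "quota_max_diameter", "rng_seed",
  names(DEFAULT_CONSTANTS))

#' Sample a randomized model parameterization
#'
#' Draws every ranged environment-level parameter uniformly within its
#' range: resource supply rate (probability per step, 0.1-1.0),
#' inflowing resource diversity (1-10 types), per-type lock-and-key
#' breakdown probabilities (0.01-1.0), necromass nutritional value
#' (1-100, read as a percent yield of the dead cell's quota),
#' immigration rate (probability per step, 0.01-0.1), and the
#' log-series shape parameter alpha (0.95-0.99) used to seed initial
#' communities.  Fixed constants (domain side 43,200 um, step 1200 s,
#' particle content 1000-10,000 mapping to 4000-8600 um diameters, max
#' cell diameter 1.25 um) and the gap-filling constants are attached
#' alongside.
#'
#' @param seed integer seed; the same seed reproduces the identical
#'   parameter set.
#' @param overrides named list of fields to set after sampling (e.g.
#'   `list(immigration_rate = 0)`).
#' @return An object of class `"model_params"`: a named list.
#' @examples
#' p <- sample_params(seed = 1)
#' p$supply_rate
#' @export
sample_params <- function(seed = NULL, overrides = list()) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- c(list(
    supply_rate        = runif(1, 0.1, 1.0),
    resource_diversity = sample.int(N_RESOURCE_TYPES, 1L),
    lock_key_prob      = runif(N_RESOURCE_TYPES, 0.01, 1.0),
    necromass_value    = runif(1, 1, 100),
    immigration_rate   = runif(1, 0.01, 0.1),
    logseries_alpha    = runif(1, 0.95, 0.99),
    # lock-and-key regimes combine recalcitrance with either a mono- or
    # polyculture supply; the choice is itself randomized
    lock_and_key_polyculture = runif(1) < 0.5,
    content_min  = CONTENT_MIN,
    content_max  = CONTENT_MAX,
    ref_content  = REF_CONTENT,
    ref_diameter = REF_DIAMETER,
    domain_length = DOMAIN_L,
    seconds_per_step = SECONDS_PER_STEP,
    quota_max_diameter = QUOTA_MAX_DIAMETER,
    rng_seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  ), DEFAULT_CONSTANTS)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad)) stop("unknown parameter override(s): ", paste(bad, collapse = ", "))
    p[names(overrides)] <- overrides
  }
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  supply_rate=%.3f diversity=%d immigration=%.3f alpha=%.3f necromass=%.1f\n",
              x$supply_rate, x$resource_diversity, x$immigration_rate,
              x$logseries_alpha, x$necromass_value))
  cat(sprintf("  L=%g um, step=%g s, S=%d, seed=%s\n",
              x$domain_length, x$seconds_per_step, x$species_pool_size,
              ifelse(is.na(x$rng_seed), "none", x$rng_seed)))
  invisible(x)
}

#' Read a flat text configuration file of parameter overrides
#'
#' The file is flat YAML whose keys are [sample_params()] field names
#' (e.g. `supply_rate: 0.4`); values override the sampled ones.  An
#' optional `seed` key supplies the sampling seed and an optional
#' `regime` key (index 1-72 or `"trophic/resource/dispersal/mixing"`)
#' selects the complexity regime.
#'
#' @param path path to the configuration file.
#' @return list with `overrides` (named list), `seed` (or `NULL`) and
#'   `regime` (a [regime()] or `NULL`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a mapping of key: value")
  seed <- cfg$seed
  reg <- cfg$regime
  if (!is.null(reg)) {
    reg <- if (is.character(reg) && grepl("/", reg)) {
      tok <- strsplit(reg, "/", fixed = TRUE)[[1]]
      if (length(tok) != 4) stop("regime needs 4 tokens or an index 1-72")
      regime(tok[1], tok[2], tok[3], tok[4])
    } else regime_from_index(reg)
  }
  overrides <- cfg[setdiff(names(cfg), c("seed", "regime"))]
  bad <- setdiff(names(overrides), PARAM_FIELDS)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  list(overrides = overrides, seed = seed, regime = reg)
}

# Resource types supplied from outside the system under a regime.
# Monoculture: one type.  Polyculture: the sampled inflowing diversity
# (at least two types, or it would not be a polyculture).  Lock-and-key
# combines recalcitrance with either, chosen by the sampled flag.
supplied_types <- function(regime, params) {
  poly <- switch(regime$resource,
                 monoculture_labile = FALSE,
                 polyculture_labile = TRUE,
                 lock_and_key       = isTRUE(params$lock_and_key_polyculture))
  if (poly) seq_len(max(2L, params$resource_diversity)) else 1L
}
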