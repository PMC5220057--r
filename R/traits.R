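# Species traits: per-species vital rates, resource use, and
# cross-feeding structure.

#' Sample species traits for a pool of S species
#'
#' Each species draws, uniformly within its range: specific maintenance
#' (quota units per step, 0.001-0.01), dispersal fraction (fraction of
#' the domain side per step, 0.01-1.0), growth rate (reproduction
#' probability scale, 0.1-1.0), resuscitation probability (per dormant
#' step, 0.001-0.01), and maintenance reduction (the divisor applied to
#' maintenance while dormant, 10-100).
#'
#' Resource use depends on the regime: under a monoculture all species
#' consume the single supplied type; under a polyculture each species
#' specializes on one randomly assigned supplied type.  Scavenging
#' regimes add the universal necromass type to every species.  Under
#' cross-feeding regimes each species additionally accepts one random
#' metabolite type and produces a metabolite type outside its own
#' consumable set; one-way cross-feeding avoids reciprocal
#' producer-consumer pairs, two-way allows them.
#'
#' @param S number of species in the pool (>= 1).
#' @param regime a [regime()] object.
#' @param params a [sample_params()] object.
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `"species_traits"`: a list with
#'   `$table` (data.frame of per-species rates), `$consumable`
#'   (S x 11 logical matrix over resource types; column 11 is
#'   necromass), and `$product` (integer vector of metabolite product
#'   types, `NA` when a species produces none).
#' @export
sample_species_traits <- function(S, regime, params, seed = NULL) {
  S <- as.integer(S)
  if (is.na(S) || S < 1L) stop("species pool size S must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))

  tab <- data.frame(
    species          = seq_len(S),
    maintenance      = runif(S, 0.001, 0.01),
    dispersal_frac   = runif(S, 0.01, 1.0),
    growth_rate      = runif(S, 0.1, 1.0),
    resuscitation    = runif(S, 0.001, 0.01),
    maint_reduction  = runif(S, 10, 100),
    # species-specific rate of consumption: the fraction of an
    # encountered particle's content a cell can strip in one step
    consumption_rate = runif(S, 0.1, 1.0)
  )

  types <- supplied_types(regime, params)
  consumable <- matrix(FALSE, nrow = S, ncol = NECROMASS_TYPE)
  if (length(types) == 1L) {
    consumable[, types] <- TRUE
  } else {
    # each supplied type usable only by its specialist subset
    specialist <- sample(types, S, replace = TRUE)
    consumable[cbind(seq_len(S), specialist)] <- TRUE
  }
  if (regime$trophic == "scavenging")
    consumable[, NECROMASS_TYPE] <- TRUE

  product <- rep(NA_integer_, S)
  if (regime$trophic %in% c("crossfeed_oneway", "crossfeed_twoway")) {
    # metabolite pool: at least two types so a producer always has a
    # type outside its own consumable set
    pool <- seq_len(max(2L, length(types)))
    accept <- sample(pool, S, replace = TRUE)
    consumable[cbind(seq_len(S), accept)] <- TRUE
    for (s in seq_len(S)) {
      allowed <- pool[!consumable[s, pool]]
      if (!length(allowed)) next  # consumes every pool type; produces none
      product[s] <- if (length(allowed) == 1L) allowed else sample(allowed, 1L)
    }
    if (regime$trophic == "crossfeed_oneway") {
      # one-way: repair any reciprocal producer-consumer pairs by
      # redrawing (or dropping) one side until none remain
      reciprocal <- function(s, t) {
        eaters <- which(consumable[, t])
        any(!is.na(product[eaters]) & consumable[s, product[eaters]])
      }
      for (iter in seq_len(6L * S)) {
        bad <- which(vapply(seq_len(S), function(s)
          !is.na(product[s]) && reciprocal(s, product[s]), logical(1)))
        if (!length(bad)) break
        s <- bad[1L]
        open <- if (iter <= 5L * S)
          Filter(function(t) !reciprocal(s, t),
                 setdiff(pool[!consumable[s, pool]], product[s]))
        else integer(0)  # converged slowly: drop the producer outright
        product[s] <- if (length(open))
          open[[if (length(open) == 1L) 1L else sample(length(open), 1L)]]
        else NA_integer_
      }
    }
  }

  structure(list(table = tab, consumable = consumable, product = product,
                 S = S),
            class = "species_traits")
}

#' Apply a dormancy scenario preset to a traits table
#'
#' Two presets contrast the capacity for dormancy across the whole
#' species pool.  `"strong_dormancy"` sets the maintenance-reduction
#' divisor to 100 and the resuscitation probability to 0.001 (cells
#' sleep deeply and wake rarely); `"weak_dormancy"` sets the divisor to
#' 10 and the resuscitation probability to 0.1 (shallow sleep, frequent
#' costly wake-ups; note 0.1 deliberately exceeds the sampled
#' resuscitation range).  All other trait values are untouched.
#'
#' @param traits a [sample_species_traits()] object.
#' @param name `"strong_dormancy"` or `"weak_dormancy"`.
#' @return The modified traits object.
#' @export
scenario_presets <- function(traits, name) {
  name <- match.arg(name, c("strong_dormancy", "weak_dormancy"))
  if (name == "strong_dormancy") {
    traits$table$maint_reduction <- 100
    traits$table$resuscitation  <- 0.001
  } else {
    traits$table$maint_reduction <- 10
    traits$table$resuscitation  <- 0.1
  }
  traits
}
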