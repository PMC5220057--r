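# Complexity regimes: the factorial design axes.

TROPHIC_LEVELS   <- c("consumer_resource", "scavenging", "crossfeed_oneway", "crossfeed_twoway")
RESOURCE_LEVELS  <- c("monoculture_labile", "polyculture_labile", "lock_and_key")
DISPERSAL_LEVELS <- c("passive", "run_tumble", "chemotaxis")
MIXING_LEVELS    <- c("well_mixed", "structured")

#' Construct a complexity regime
#'
#' A regime is one cell of the factorial design crossing trophic
#' complexity (4 levels), resource complexity (3), dispersal mode (3)
#' and spatial mixing (2).  Every combination is valid.
#'
#' @param trophic one of `"consumer_resource"`, `"scavenging"`,
#'   `"crossfeed_oneway"`, `"crossfeed_twoway"`.
#' @param resource one of `"monoculture_labile"`, `"polyculture_labile"`,
#'   `"lock_and_key"`.
#' @param dispersal one of `"passive"`, `"run_tumble"`, `"chemotaxis"`.
#' @param mixing one of `"well_mixed"`, `"structured"`.
#' @return An object of class `"complexity_regime"`: a named list with
#'   the four fields.
#' @examples
#' regime("consumer_resource", "monoculture_labile", "passive", "well_mixed")
#' @export
regime <- function(trophic = "consumer_resource",
                   resource = "monoculture_labile",
                   dispersal = "passive",
                   mixing = "well_mixed") {
  trophic   <- match.arg(trophic, TROPHIC_LEVELS)
  resource  <- match.arg(resource, RESOURCE_LEVELS)
  dispersal <- match.arg(dispersal, DISPERSAL_LEVELS)
  mixing    <- match.arg(mixing, MIXING_LEVELS)
  structure(list(trophic = trophic, resource = resource,
                 dispersal = dispersal, mixing = mixing),
            class = "complexity_regime")
}

#' @export
format.complexity_regime <- function(x, ...) {
  paste(x$trophic, x$resource, x$dispersal, x$mixing, sep = "/")
}

#' @export
print.complexity_regime <- function(x, ...) {
  cat("<complexity_regime>", format(x), "\n")
  invisible(x)
}

#' Enumerate all 72 complexity regimes
#'
#' Returns the full factorial (4 trophic x 3 resource x 3 dispersal x
#' 2 mixing = 72) in deterministic trophic-major lexicographic order:
#' mixing varies fastest, then dispersal, then resource, then trophic.
#' The first element is
#' `consumer_resource/monoculture_labile/passive/well_mixed`.
#'
#' @return A list of 72 [regime()] objects.
#' @examples
#' length(enumerate_regimes())
#' @export
enumerate_regimes <- function() {
  out <- vector("list", 72L)
  k <- 0L
  for (t in TROPHIC_LEVELS)
    for (r in RESOURCE_LEVELS)
      for (d in DISPERSAL_LEVELS)
        for (m in MIXING_LEVELS) {
          k <- k + 1L
          out[[k]] <- regime(t, r, d, m)
        }
  out
}

#' Look up a regime by its 1-based factorial index
#'
#' @param i integer in 1..72, indexing the order of [enumerate_regimes()].
#' @return A [regime()] object.
#' @export
regime_from_index <- function(i) {
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > 72L)
    stop("regime index must be in 1..72, got ", i)
  enumerate_regimes()[[i]]
}
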