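# Shared fixtures and independent oracles, built in code.

# A small default configuration for unit tests.
tiny_setup <- function(seed = 1, S = 20,
                       reg = regime("consumer_resource", "monoculture_labile",
                                    "run_tumble", "well_mixed"),
                       overrides = list()) {
  params <- sample_params(seed = seed, overrides = overrides)
  traits <- sample_species_traits(S, reg, params, seed = seed + 1000L)
  list(params = params, traits = traits, regime = reg)
}

# Brute-force all-pairs oracle for nearest / nearest-contacting
# consumable particle.  Independent of the package kernel.
oracle_nearest <- function(ix, iy, iz, irad, isp, parts, consumable) {
  n <- length(ix)
  near <- touch <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ok <- consumable[isp[i], parts$rtype]
    if (!any(ok)) next
    d <- sqrt((parts$x - ix[i])^2 + (parts$y - iy[i])^2 + (parts$z - iz[i])^2)
    dd <- d
    dd[!ok] <- Inf
    near[i] <- parts$id[which.min(dd)]
    reach <- irad[i] + diameter_from_content(parts$content) / 2
    tt <- d
    tt[!ok | d > reach] <- Inf
    if (any(is.finite(tt))) touch[i] <- parts$id[which.min(tt)]
  }
  list(near = near, touch = touch)
}

# Build a particle set from explicit fields (ids ascending).
build_particles <- function(rtype, content, x, y, z,
                            recalcitrant = FALSE, origin = 1L) {
  n <- length(content)
  list(id = seq_len(n), rtype = as.integer(rep_len(rtype, n)),
       content = content, x = x, y = y, z = z,
       recalcitrant = rep_len(recalcitrant, n),
       origin = as.integer(rep_len(origin, n)))
}

# Build a community from explicit fields.
build_individuals <- function(species, quota, x, y, z, active = TRUE) {
  n <- length(quota)
  h <- matrix(rep(c(1, 0, 0), each = n), ncol = 3)
  list(id = seq_len(n), species = as.integer(rep_len(species, n)),
       quota = quota, active = rep_len(active, n),
       x = x, y = y, z = z,
       hx = h[, 1], hy = h[, 2], hz = h[, 3],
       birth_step = rep(0L, n))
}
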