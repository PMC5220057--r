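# Resource particles: supply, size geometry, fragmentation,
# recalcitrance gating, and trophic by-products (necromass,
# metabolites).  Particles are held as a struct-of-vectors for speed;
# ids are assigned in strictly increasing order, so storage order is
# always ascending id (this is what makes "lowest id" tie-breaks equal
# to "first found").

PARTICLE_ORIGINS <- c("supplied", "fragment", "necromass", "metabolite")

#' Create an empty particle set
#'
#' @return A list of parallel vectors: `id`, `rtype` (resource type,
#'   1-10 supplied/metabolite types, 11 necromass), `content` (mass
#'   units), `x`,`y`,`z` (um), `recalcitrant` (logical), `origin`
#'   (integer code into `PARTICLE_ORIGINS`).
#' @export
new_particles <- function() {
  list(id = integer(0), rtype = integer(0), content = numeric(0),
       x = numeric(0), y = numeric(0), z = numeric(0),
       recalcitrant = logical(0), origin = integer(0))
}

#' Number of particles in a particle set
#' @param parts a particle set.
#' @return integer count.
#' @export
particle_count <- function(parts) length(parts$id)

particles_append <- function(parts, id, rtype, content, x, y, z,
                             recalcitrant, origin) {
  list(id = c(parts$id, as.integer(id)),
       rtype = c(parts$rtype, as.integer(rtype)),
       content = c(parts$content, content),
       x = c(parts$x, x), y = c(parts$y, y), z = c(parts$z, z),
       recalcitrant = c(parts$recalcitrant, recalcitrant),
       origin = c(parts$origin, as.integer(origin)))
}

particles_subset <- function(parts, keep) lapply(parts, `[`, keep)

#' Convert a particle set to a data.frame
#' @param parts a particle set.
#' @return data.frame with one row per particle and a `diameter` column.
#' @export
particles_as_df <- function(parts) {
  df <- as.data.frame(parts)
  if (nrow(df)) {
    df$origin <- PARTICLE_ORIGINS[df$origin]
    df$diameter <- diameter_from_content(df$content)
  }
  df
}

#' Particle diameter from resource content
#'
#' Volume-proportional (cube-root) scaling anchored at content 1000 ->
#' diameter 4000 um, so the supplied content range 1000-10,000 maps to
#' diameters 4000-8600 um (2 s.f.).
#'
#' @param content resource content, mass units (> 0).
#' @return diameter, um.
#' @examples
#' diameter_from_content(1000)   # 4000
#' diameter_from_content(10000)  # ~8617.7
#' @export
diameter_from_content <- function(content) {
  if (any(content <= 0)) stop("particle content must be > 0")
  REF_DIAMETER * (content / REF_CONTENT)^(1 / 3)
}

#' Supply step: stochastic arrival of one resource particle
#'
#' With probability `params$supply_rate` a single particle enters:
#' type uniform over the regime's supplied types, content uniform in
#' [1000, 10,000], position uniform in the domain; the recalcitrant
#' flag is set iff the regime is lock-and-key.
#'
#' @param parts particle set.
#' @param params model parameters.
#' @param regime complexity regime.
#' @param next_id next free particle id.
#' @return list `parts`, `next_id`, `supplied` (content added, 0 if none).
#' @export
supply_step <- function(parts, params, regime, next_id) {
  if (runif(1) >= params$supply_rate)
    return(list(parts = parts, next_id = next_id, supplied = 0))
  types <- supplied_types(regime, params)
  rtype <- if (length(types) == 1L) types else sample(types, 1L)
  content <- runif(1, params$content_min, params$content_max)
  pos <- runif(3, 0, params$domain_length)
  parts <- particles_append(parts, next_id, rtype, content,
                            pos[1], pos[2], pos[3],
                            regime$resource == "lock_and_key", 1L)
  list(parts = parts, next_id = next_id + 1L, supplied = content)
}

#' Split a particle's content into two fragments
#'
#' The remaining portion of an encountered particle is broken in two:
#' a uniform fraction u goes to one child and 1-u to the other, so
#' content is conserved exactly.  Children inherit the parent's type
#' and recalcitrance.  In structured environments children are placed
#' within `eps` of the parent per axis (fragments aggregate); in
#' well-mixed environments position is irrelevant because the next
#' mixing update re-randomizes it.  Children below the content floor
#' are removed (returned in `$floored`).
#'
#' This is the vectorized form: element i of the content/position
#' arguments describes one parent.
#'
#' @param content parent contents (mass units).
#' @param x,y,z parent coordinates (um).
#' @param rtype,recalcitrant parent type/flag vectors.
#' @param params model parameters.
#' @param structured logical: structured mixing regime?
#' @return list `children` (a particle fragment table without ids) and
#'   `floored` (total content removed below the floor).
#' @export
split_particles <- function(content, x, y, z, rtype, recalcitrant,
                            params, structured) {
  n <- length(content)
  if (n == 0L)
    return(list(children = NULL, floored = 0))
  u <- runif(n)
  cc <- c(content * u, content * (1 - u))
  cx <- c(x, x); cy <- c(y, y); cz <- c(z, z)
  if (structured) {
    eps <- params$fragment_jitter
    L <- params$domain_length
    cx <- reflect(cx + runif(2L * n, -eps, eps), L)
    cy <- reflect(cy + runif(2L * n, -eps, eps), L)
    cz <- reflect(cz + runif(2L * n, -eps, eps), L)
  }
  keep <- cc >= params$content_floor
  list(children = list(rtype = c(rtype, rtype)[keep],
                       content = cc[keep],
                       x = cx[keep], y = cy[keep], z = cz[keep],
                       recalcitrant = c(recalcitrant, recalcitrant)[keep]),
       floored = sum(cc[!keep]))
}

#' Attempt to break down a particle (recalcitrance gate)
#'
#' Labile particles are always broken down at no cost.  Recalcitrant
#' (lock-and-key) particles succeed with the per-type probability
#' `lock_key_prob`; the attempting individual pays a handling cost
#' whether or not the attempt succeeds (applied by the engine).
#' Vectorized over attempts.
#'
#' @param recalcitrant logical vector.
#' @param lock_key_prob per-attempt success probabilities (for the
#'   particle's type; ignored where labile).
#' @return logical vector of successes.
#' @export
attempt_breakdown <- function(recalcitrant, lock_key_prob) {
  n <- length(recalcitrant)
  out <- rep(TRUE, n)
  if (any(recalcitrant))
    out[recalcitrant] <- runif(sum(recalcitrant)) < lock_key_prob[recalcitrant]
  out
}

#' Necromass particle from a dead cell (scavenging regimes)
#'
#' The remains of a dead individual become a labile particle at the
#' death site, of the universal necromass type, with content equal to
#' `(necromass_value / 100)` of the dead cell's quota converted to mass
#' units (quota / kappa).  The 1-100 necromass value is thus a percent
#' yield: necromass never amplifies energy.  Returns `NULL` below the
#' content floor.
#'
#' @param quota dead cell quota(s).
#' @param x,y,z death coordinates (um).
#' @param params model parameters.
#' @return list of particle fields (no ids) or `NULL`.
#' @export
spawn_necromass <- function(quota, x, y, z, params) {
  content <- (params$necromass_value / 100) * quota / params$mass_to_quota
  keep <- content >= params$content_floor
  if (!any(keep)) return(NULL)
  list(rtype = rep(NECROMASS_TYPE, sum(keep)), content = content[keep],
       x = x[keep], y = y[keep], z = z[keep],
       recalcitrant = rep(FALSE, sum(keep)))
}

#' Metabolite particle from a consumption event (cross-feeding regimes)
#'
#' A producer that just gained `delta` quota releases a labile particle
#' of its species' metabolite product type at its own position, with
#' content `beta * delta / kappa` (a fixed by-product yield of the mass
#' consumed).  Returns `NULL` below the content floor or when the
#' species produces no metabolite.
#'
#' @param delta quota gained by the producer(s).
#' @param product_type metabolite type(s) (`NA` = none).
#' @param x,y,z producer coordinates (um).
#' @param params model parameters.
#' @return list of particle fields (no ids) or `NULL`.
#' @export
spawn_metabolite <- function(delta, product_type, x, y, z, params) {
  content <- params$crossfeed_yield * delta / params$mass_to_quota
  keep <- !is.na(product_type) & content >= params$content_floor
  if (!any(keep)) return(NULL)
  list(rtype = product_type[keep], content = content[keep],
       x = x[keep], y = y[keep], z = z[keep],
       recalcitrant = rep(FALSE, sum(keep)))
}
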