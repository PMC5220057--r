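# Individuals and their physiology.  A cell carries a relative quota
# Q in (0, 1] — its endogenous resource store as a fraction of the
# species maximum.  Volume is proportional to quota, so diameter
# follows a cube-root law anchored at 1.25 um for a full cell.

#' Create an empty community (struct-of-vectors)
#'
#' @return list of parallel vectors: `id`, `species`, `quota`,
#'   `active` (logical; FALSE = dormant), `x`,`y`,`z` (um),
#'   `hx`,`hy`,`hz` (unit heading), `birth_step`.
#' @export
new_individuals <- function() {
  list(id = integer(0), species = integer(0), quota = numeric(0),
       active = logical(0),
       x = numeric(0), y = numeric(0), z = numeric(0),
       hx = numeric(0), hy = numeric(0), hz = numeric(0),
       birth_step = integer(0))
}

#' Number of individuals in a community
#' @param inds a community.
#' @return integer count.
#' @export
individual_count <- function(inds) length(inds$id)

individuals_append <- function(inds, id, species, quota, active,
                               x, y, z, hx, hy, hz, birth_step) {
  list(id = c(inds$id, as.integer(id)),
       species = c(inds$species, as.integer(species)),
       quota = c(inds$quota, quota),
       active = c(inds$active, active),
       x = c(inds$x, x), y = c(inds$y, y), z = c(inds$z, z),
       hx = c(inds$hx, hx), hy = c(inds$hy, hy), hz = c(inds$hz, hz),
       birth_step = c(inds$birth_step, as.integer(birth_step)))
}

individuals_subset <- function(inds, keep) lapply(inds, `[`, keep)

#' Convert a community to a data.frame
#' @param inds a community.
#' @return data.frame with a `diameter` column (um).
#' @export
individuals_as_df <- function(inds) {
  df <- as.data.frame(inds)
  if (nrow(df)) df$diameter <- diameter_from_quota(df$quota)
  df
}

#' Cell diameter from relative quota
#'
#' Cell volume is proportional to quota, so diameter scales with the
#' cube root: `d = 1.25 * Q^(1/3)` um.  The immigration quota range
#' 0.5-1.0 maps to starting diameters of ~1 to 1.25 um.
#'
#' @param Q relative quota(s) in (0, 1].
#' @return diameter, um.
#' @examples
#' diameter_from_quota(1)    # 1.25
#' diameter_from_quota(0.5)  # ~0.992
#' @export
diameter_from_quota <- function(Q) {
  if (any(Q <= 0)) stop("quota must be > 0")
  QUOTA_MAX_DIAMETER * Q^(1 / 3)
}

# Engine-internal variant: a cell fully drained by maintenance holds
# quota 0 until the next death check; treat its diameter as 0.
cell_diam0 <- function(Q) QUOTA_MAX_DIAMETER * pmax(Q, 0)^(1 / 3)

#' Initialize a community of 100 individuals
#'
#' Species identities are drawn from a log-series distribution with
#' the sampled shape parameter alpha, truncated to the S-species pool
#' (the standard way to seed an ecological metacommunity with
#' realistic commonness and rarity); quotas are uniform in [0.5, 1.0];
#' positions uniform in the domain; everyone starts active.
#'
#' @param params model parameters.
#' @param traits species traits.
#' @param n number of founding individuals (default 100).
#' @return list `inds` (community), `next_id`, `quota_in` (total founding quota).
#' @export
initialize_community <- function(params, traits, n = 100L) {
  S <- traits$S
  pmf <- logseries_pmf(params$logseries_alpha, S)
  species <- sample.int(S, n, replace = TRUE, prob = pmf)
  quota <- runif(n, 0.5, 1.0)
  pos <- runif_positions(n, params$domain_length)
  h <- runif_headings(n)
  inds <- individuals_append(new_individuals(), seq_len(n), species, quota,
                             rep(TRUE, n), pos[, 1], pos[, 2], pos[, 3],
                             h[, 1], h[, 2], h[, 3], rep(0L, n))
  list(inds = inds, next_id = n + 1L, quota_in = sum(quota))
}

#' Immigration step: stochastic arrival of one individual
#'
#' With probability `params$immigration_rate` one active individual
#' enters at a uniform random point: species uniform over the pool,
#' quota uniform in [0.5, 1.0].
#'
#' @param inds community.
#' @param params model parameters.
#' @param traits species traits.
#' @param next_id next free individual id.
#' @param step current step index.
#' @return list `inds`, `next_id`, `quota_in`, `arrived` (0/1).
#' @export
immigrate <- function(inds, params, traits, next_id, step = 0L) {
  if (runif(1) >= params$immigration_rate)
    return(list(inds = inds, next_id = next_id, quota_in = 0, arrived = 0L))
  species <- sample.int(traits$S, 1L)
  quota <- runif(1, 0.5, 1.0)
  pos <- runif(3, 0, params$domain_length)
  h <- runif_headings(1L)
  inds <- individuals_append(inds, next_id, species, quota, TRUE,
                             pos[1], pos[2], pos[3],
                             h[1], h[2], h[3], step)
  list(inds = inds, next_id = next_id + 1L, quota_in = quota, arrived = 1L)
}

#' Consume from a particle (vectorized over consumer-particle pairs)
#'
#' Consumption transfers mass from particle to cell at the fixed
#' conversion kappa (relative quota per mass unit), capped by the
#' cell's remaining headroom 1 - Q (satiation) and by the consumer's
#' species-specific rate of consumption (the fraction of the
#' particle's content it can strip in one step):
#' `delta = min(rate * kappa * content, 1 - Q)`.
#' Conservation is exact: `kappa * Dcontent = delta`.
#'
#' @param quota consumer quotas.
#' @param content particle contents (mass units).
#' @param kappa mass-to-quota conversion.
#' @param rate per-encounter uptake fraction(s) in (0, 1] (default 1:
#'   uptake limited by satiation alone).
#' @return list `delta` (quota gained), `quota` (updated), `content`
#'   (updated; may reach 0).
#' @export
consume <- function(quota, content, kappa, rate = 1) {
  delta <- pmin(rate * kappa * content, 1 - quota)
  list(delta = delta, quota = quota + delta, content = content - delta / kappa)
}

#' Reproduction probabilities and fission bookkeeping
#'
#' Reproduction is clonal binary fission without mutation.  An active
#' cell divides with probability `g_s * Q` (growth rate times relative
#' quota, so p is in [0, 1]).  On division a growth cost `c_g * g_s *
#' Q` is deducted — larger, faster-growing cells pay more — and the
#' remaining quota is halved between mother and daughter.  The
#' daughter inherits the mother's species and coordinates.
#'
#' This helper computes the post-division quotas; the engine draws the
#' Bernoulli outcomes and appends daughters.
#'
#' @param quota mother quotas.
#' @param growth_rate species growth rates g_s.
#' @param c_g growth cost coefficient.
#' @return list `cost` (quota spent), `half` (quota of each of mother
#'   and daughter after fission).
#' @export
fission_split <- function(quota, growth_rate, c_g) {
  cost <- pmin(c_g * growth_rate * quota, quota)
  list(cost = cost, half = (quota - cost) / 2)
}

#' Maintenance deduction for one step
#'
#' Active cells pay their species-specific maintenance m_s per step;
#' dormant cells pay m_s divided by the species maintenance-reduction
#' factor f_s (10-100), the energetic benefit of dormancy.  Deductions
#' are capped at the current quota so quota never goes negative (a
#' cell driven to the floor dies at the next death check).
#'
#' @param quota current quotas.
#' @param active logical activity state.
#' @param maintenance species m_s per individual.
#' @param maint_reduction species f_s per individual.
#' @return list `quota` (updated), `paid` (deduction applied).
#' @export
maintenance_step <- function(quota, active, maintenance, maint_reduction) {
  due <- ifelse(active, maintenance, maintenance / maint_reduction)
  paid <- pmin(due, quota)
  list(quota = quota - paid, paid = paid)
}

#' Death check
#'
#' A cell dies when its quota is strictly below its species-specific
#' maintenance energy, whether active or dormant (`Q = m_s` exactly
#' survives).
#'
#' @param quota quotas.
#' @param maintenance species m_s per individual.
#' @return logical: TRUE = alive.
#' @export
check_death <- function(quota, maintenance) {
  quota >= maintenance
}

#' Dormancy transitions for one step
#'
#' Entry is deterministic on energetic depletion: an active cell whose
#' quota has fallen to `theta_d * m_s` or below goes dormant (theta_d
#' defaults to 50, i.e. dormancy begins with ~50 steps of active
#' maintenance left in reserve).  Exit is stochastic: a dormant cell
#' resuscitates with its species-specific per-step probability rho_s.
#'
#' @param active logical activity state.
#' @param quota quotas.
#' @param maintenance species m_s.
#' @param resuscitation species rho_s.
#' @param theta_d dormancy threshold coefficient.
#' @return updated logical activity vector.
#' @export
dormancy_transition <- function(active, quota, maintenance, resuscitation,
                                theta_d) {
  go_dormant <- active & quota <= theta_d * maintenance
  wake <- !active & (runif(length(active)) < resuscitation)
  out <- active
  out[go_dormant] <- FALSE
  out[wake] <- TRUE
  out
}
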