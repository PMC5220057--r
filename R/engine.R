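# The simulation engine: one discrete time step executes the life
# history and environment process blocks in a freshly shuffled order
# (shuffling prevents artifacts from any fixed ordering).  Within a
# block, operations are vectorized over individuals; where within-step
# order matters (several cells contacting the same particle) the
# winning pair is drawn by a uniform shuffle.

PROCESS_BLOCKS <- c("supply", "immigration", "mixing", "dispersal",
                    "consumption", "reproduction", "maintenance",
                    "death", "dormancy")

#' Build a fresh model state
#'
#' Seeds the RNG (if `seed` is given), initializes the 100-individual
#' founding community, an empty particle pool, zeroed tallies, and the
#' conservation ledgers.
#'
#' @param params model parameters ([sample_params()]).
#' @param traits species traits ([sample_species_traits()]).
#' @param regime complexity regime ([regime()]).
#' @param seed optional integer seed.
#' @param n_init founding community size (default 100).
#' @return An object of class `"model_state"`.
#' @export
make_state <- function(params, traits, regime, seed = NULL, n_init = 100L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  init <- initialize_community(params, traits, n_init)
  structure(list(
    step_index = 0L,
    inds = init$inds,
    parts = new_particles(),
    params = params,
    traits = traits,
    regime = regime,
    next_ind_id = init$next_id,
    next_part_id = 1L,
    tally = list(births = 0L, deaths = 0L, encounters = 0L,
                 immigrations = 0L),
    cum = list(supplied = 0, spawned = 0, consumed_mass = 0, floored = 0,
               q_init = init$quota_in, q_immig = 0, q_consumed = 0,
               q_maint = 0, q_growth = 0, q_disp = 0, q_hand = 0,
               q_dead = 0)
  ), class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("<model_state> step %d | %s\n  N=%d (%d active), particles=%d (R=%.0f)\n",
              x$step_index, format(x$regime),
              individual_count(x$inds), sum(x$inds$active),
              particle_count(x$parts), sum(x$parts$content)))
  invisible(x)
}

# Kernel wrapper: per-individual nearest consumable particle and/or
# nearest contacting consumable particle (indices into parts storage).
nearest_particles <- function(inds, parts, traits, which_ind = NULL,
                              L = DOMAIN_L, want_near = TRUE,
                              want_touch = TRUE) {
  if (is.null(which_ind)) which_ind <- seq_along(inds$id)
  if (!length(which_ind) || particle_count(parts) == 0L) {
    k <- length(which_ind)
    return(list(near_idx = rep(NA_integer_, k), near_dist = rep(NA_real_, k),
                touch_idx = rep(NA_integer_, k), touch_dist = rep(NA_real_, k)))
  }
  nearest_particles_cpp(
    inds$x[which_ind], inds$y[which_ind], inds$z[which_ind],
    cell_diam0(inds$quota[which_ind]) / 2,
    inds$species[which_ind],
    parts$x, parts$y, parts$z,
    diameter_from_content(parts$content) / 2,
    parts$rtype, parts$id, traits$consumable,
    L, want_near, want_touch)
}

#' Detect cell-particle encounters
#'
#' A contact exists when the centre-to-centre distance is at most the
#' sum of cell and particle radii and the particle's type is
#' consumable by the cell's species.  Each individual is paired with
#' at most its nearest contacting particle (ties to the lowest
#' particle id).  The result is exactly equivalent to a brute-force
#' all-pairs scan.
#'
#' @param inds community.
#' @param parts particle set.
#' @param traits species traits.
#' @param active_only restrict to active (foraging) individuals.
#' @return data.frame with columns `ind` and `part` (entity ids) and
#'   `dist` (um), one row per contact.
#' @export
detect_encounters <- function(inds, parts, traits, active_only = FALSE) {
  which_ind <- if (active_only) which(inds$active) else seq_along(inds$id)
  np <- nearest_particles(inds, parts, traits, which_ind,
                          want_near = FALSE, want_touch = TRUE)
  hit <- !is.na(np$touch_idx)
  data.frame(ind = inds$id[which_ind[hit]],
             part = parts$id[np$touch_idx[hit]],
             dist = np$touch_dist[hit])
}

#' Energetic cost of a dispersal move
#'
#' Passive drift is free; run-and-tumble costs `c_d * (distance / L) *
#' Q`; chemotaxis costs twice that (the price of sense perception).
#' Dormant cells never actively disperse and pay nothing.
#'
#' @param quota cell quotas.
#' @param distance distance actively moved, um.
#' @param mode `"passive"`, `"run_tumble"` or `"chemotaxis"`.
#' @param c_d dispersal cost coefficient.
#' @param L domain side, um.
#' @return Quota deduction (capped at the current quota).
#' @export
apply_dispersal_cost <- function(quota, distance, mode, c_d, L = DOMAIN_L) {
  mult <- switch(mode, passive = 0, run_tumble = 1, chemotaxis = 2,
                 stop("unknown dispersal mode: ", mode))
  pmin(mult * c_d * (distance / L) * quota, quota)
}

# ---- process blocks -------------------------------------------------

block_supply <- function(st) {
  res <- supply_step(st$parts, st$params, st$regime, st$next_part_id)
  st$parts <- res$parts
  st$next_part_id <- res$next_id
  st$cum$supplied <- st$cum$supplied + res$supplied
  st
}

block_immigration <- function(st) {
  res <- immigrate(st$inds, st$params, st$traits, st$next_ind_id,
                   st$step_index)
  st$inds <- res$inds
  st$next_ind_id <- res$next_id
  st$cum$q_immig <- st$cum$q_immig + res$quota_in
  st$tally$immigrations <- st$tally$immigrations + res$arrived
  st
}

block_mixing <- function(st) {
  L <- st$params$domain_length
  np <- particle_count(st$parts)
  ni <- individual_count(st$inds)
  if (st$regime$mixing == "well_mixed") {
    if (np) {
      pp <- relocate_well_mixed(np, L)
      st$parts$x <- pp[, 1]; st$parts$y <- pp[, 2]; st$parts$z <- pp[, 3]
    }
    if (ni) {
      ip <- relocate_well_mixed(ni, L)
      st$inds$x <- ip[, 1]; st$inds$y <- ip[, 2]; st$inds$z <- ip[, 3]
    }
  } else {
    sig <- st$params$brownian_sigma
    if (np) {
      pp <- brownian_step(cbind(st$parts$x, st$parts$y, st$parts$z), sig, L)
      st$parts$x <- pp[, 1]; st$parts$y <- pp[, 2]; st$parts$z <- pp[, 3]
    }
    # cells without active dispersal this step drift too: all of them
    # when the regime is passive, otherwise only the dormant ones
    drift <- if (st$regime$dispersal == "passive") seq_len(ni)
             else which(!st$inds$active)
    if (length(drift)) {
      ip <- brownian_step(cbind(st$inds$x[drift], st$inds$y[drift],
                                st$inds$z[drift]), sig, L)
      st$inds$x[drift] <- ip[, 1]; st$inds$y[drift] <- ip[, 2]
      st$inds$z[drift] <- ip[, 3]
    }
  }
  st
}

block_dispersal <- function(st) {
  mode <- st$regime$dispersal
  if (mode == "passive") return(st)
  act <- which(st$inds$active)
  if (!length(act)) return(st)
  L <- st$params$domain_length
  tr <- st$traits$table
  step_len <- tr$dispersal_frac[st$inds$species[act]] * L
  pos <- cbind(st$inds$x[act], st$inds$y[act], st$inds$z[act])
  hdg <- cbind(st$inds$hx[act], st$inds$hy[act], st$inds$hz[act])
  if (mode == "run_tumble") {
    mv <- run_tumble_step(pos, hdg, step_len, L)
    dist <- step_len
  } else {
    np <- nearest_particles(st$inds, st$parts, st$traits, act,
                            L = L, want_near = TRUE, want_touch = FALSE)
    has <- !is.na(np$near_idx)
    tpos <- matrix(NA_real_, length(act), 3L)
    trad <- rep(NA_real_, length(act))
    if (any(has)) {
      j <- np$near_idx[has]
      tpos[has, ] <- cbind(st$parts$x[j], st$parts$y[j], st$parts$z[j])
      trad[has] <- diameter_from_content(st$parts$content[j]) / 2
    }
    mv <- chemotaxis_step(pos, hdg, step_len,
                          cell_diam0(st$inds$quota[act]) / 2,
                          tpos, trad, L)
    dist <- mv$dist
  }
  st$inds$x[act] <- mv$pos[, 1]; st$inds$y[act] <- mv$pos[, 2]
  st$inds$z[act] <- mv$pos[, 3]
  st$inds$hx[act] <- mv$heading[, 1]; st$inds$hy[act] <- mv$heading[, 2]
  st$inds$hz[act] <- mv$heading[, 3]
  paid <- apply_dispersal_cost(st$inds$quota[act], dist, mode,
                               st$params$dispersal_cost_coeff, L)
  st$inds$quota[act] <- st$inds$quota[act] - paid
  st$cum$q_disp <- st$cum$q_disp + sum(paid)
  st
}

block_consumption <- function(st) {
  act <- which(st$inds$active)
  if (!length(act) || particle_count(st$parts) == 0L) return(st)
  np <- nearest_particles(st$inds, st$parts, st$traits, act,
                          L = st$params$domain_length,
                          want_near = FALSE, want_touch = TRUE)
  hit <- which(!is.na(np$touch_idx))
  if (!length(hit)) return(st)
  st$tally$encounters <- st$tally$encounters + length(hit)

  # one consumption event per individual (its nearest contact) and per
  # particle (winner drawn by uniform shuffle; losers wait a step)
  ord <- if (length(hit) > 1L) sample(length(hit)) else 1L
  sel <- hit[ord][!duplicated(np$touch_idx[hit][ord])]
  ii <- act[sel]                      # storage index of consumer
  jj <- np$touch_idx[sel]             # storage index of particle

  p <- st$params
  recal <- st$parts$recalcitrant[jj]
  # handling cost of working on a lock-and-key particle, success or not
  if (any(recal)) {
    hand <- pmin(p$growth_cost_coeff * st$inds$quota[ii][recal],
                 st$inds$quota[ii][recal])
    st$inds$quota[ii[recal]] <- st$inds$quota[ii[recal]] - hand
    st$cum$q_hand <- st$cum$q_hand + sum(hand)
  }
  lkp <- p$lock_key_prob[pmin(st$parts$rtype[jj], N_RESOURCE_TYPES)]
  success <- attempt_breakdown(recal, lkp)
  if (!any(success)) return(st)

  ii <- ii[success]; jj <- jj[success]
  cons <- consume(st$inds$quota[ii], st$parts$content[jj], p$mass_to_quota,
                  st$traits$table$consumption_rate[st$inds$species[ii]])
  st$inds$quota[ii] <- cons$quota
  st$cum$q_consumed <- st$cum$q_consumed + sum(cons$delta)
  st$cum$consumed_mass <- st$cum$consumed_mass + sum(cons$delta) / p$mass_to_quota

  # cross-feeding: consumption releases metabolite by-products
  if (st$regime$trophic %in% c("crossfeed_oneway", "crossfeed_twoway")) {
    made <- cons$delta > 0
    if (any(made)) {
      met <- spawn_metabolite(cons$delta[made],
                              st$traits$product[st$inds$species[ii][made]],
                              st$inds$x[ii][made], st$inds$y[ii][made],
                              st$inds$z[ii][made], p)
      if (!is.null(met)) {
        nmet <- length(met$content)
        st$parts <- particles_append(st$parts,
                                     st$next_part_id + seq_len(nmet) - 1L,
                                     met$rtype, met$content,
                                     met$x, met$y, met$z,
                                     met$recalcitrant, rep(4L, nmet))
        st$next_part_id <- st$next_part_id + nmet
        st$cum$spawned <- st$cum$spawned + sum(met$content)
      }
    }
  }

  # the remainder of each consumed particle is broken in two; the
  # parent row disappears, fragments (above the content floor) persist
  remainder <- cons$content
  keep_split <- remainder >= p$content_floor
  st$cum$floored <- st$cum$floored + sum(remainder[!keep_split])
  frag <- split_particles(remainder[keep_split],
                          st$parts$x[jj][keep_split],
                          st$parts$y[jj][keep_split],
                          st$parts$z[jj][keep_split],
                          st$parts$rtype[jj][keep_split],
                          st$parts$recalcitrant[jj][keep_split],
                          p, st$regime$mixing == "structured")
  st$cum$floored <- st$cum$floored + frag$floored
  st$parts <- particles_subset(st$parts, -jj)
  ch <- frag$children
  if (!is.null(ch) && length(ch$content)) {
    nch <- length(ch$content)
    st$parts <- particles_append(st$parts,
                                 st$next_part_id + seq_len(nch) - 1L,
                                 ch$rtype, ch$content, ch$x, ch$y, ch$z,
                                 ch$recalcitrant, rep(2L, nch))
    st$next_part_id <- st$next_part_id + nch
  }
  st
}

block_reproduction <- function(st) {
  act <- which(st$inds$active)
  if (!length(act)) return(st)
  tr <- st$traits$table
  g <- tr$growth_rate[st$inds$species[act]]
  p_rep <- g * st$inds$quota[act]
  who <- act[runif(length(act)) < p_rep]
  if (!length(who)) return(st)
  fs <- fission_split(st$inds$quota[who],
                      tr$growth_rate[st$inds$species[who]],
                      st$params$growth_cost_coeff)
  st$cum$q_growth <- st$cum$q_growth + sum(fs$cost)
  st$inds$quota[who] <- fs$half
  n <- length(who)
  h <- runif_headings(n)
  st$inds <- individuals_append(st$inds,
                                st$next_ind_id + seq_len(n) - 1L,
                                st$inds$species[who], fs$half,
                                rep(TRUE, n),
                                st$inds$x[who], st$inds$y[who], st$inds$z[who],
                                h[, 1], h[, 2], h[, 3],
                                rep(st$step_index, n))
  st$next_ind_id <- st$next_ind_id + n
  st$tally$births <- st$tally$births + n
  st
}

block_maintenance <- function(st) {
  n <- individual_count(st$inds)
  if (!n) return(st)
  tr <- st$traits$table
  ms <- maintenance_step(st$inds$quota, st$inds$active,
                         tr$maintenance[st$inds$species],
                         tr$maint_reduction[st$inds$species])
  st$inds$quota <- ms$quota
  st$cum$q_maint <- st$cum$q_maint + sum(ms$paid)
  st
}

block_death <- function(st) {
  n <- individual_count(st$inds)
  if (!n) return(st)
  alive <- check_death(st$inds$quota,
                       st$traits$table$maintenance[st$inds$species])
  if (all(alive)) return(st)
  dead <- which(!alive)
  st$tally$deaths <- st$tally$deaths + length(dead)
  st$cum$q_dead <- st$cum$q_dead + sum(st$inds$quota[dead])
  if (st$regime$trophic == "scavenging") {
    nec <- spawn_necromass(st$inds$quota[dead], st$inds$x[dead],
                           st$inds$y[dead], st$inds$z[dead], st$params)
    if (!is.null(nec)) {
      k <- length(nec$content)
      st$parts <- particles_append(st$parts,
                                   st$next_part_id + seq_len(k) - 1L,
                                   nec$rtype, nec$content,
                                   nec$x, nec$y, nec$z,
                                   nec$recalcitrant, rep(3L, k))
      st$next_part_id <- st$next_part_id + k
      st$cum$spawned <- st$cum$spawned + sum(nec$content)
    }
  }
  st$inds <- individuals_subset(st$inds, alive)
  st
}

block_dormancy <- function(st) {
  n <- individual_count(st$inds)
  if (!n) return(st)
  tr <- st$traits$table
  st$inds$active <- dormancy_transition(
    st$inds$active, st$inds$quota,
    tr$maintenance[st$inds$species],
    tr$resuscitation[st$inds$species],
    st$params$dormancy_threshold_coeff)
  st
}

#' Advance the model by one time step
#'
#' Executes the nine process blocks — resource supply, immigration,
#' mixing/Brownian update, individual dispersal (with energetic cost),
#' encounter/breakdown/consumption (with metabolite release and
#' lock-and-key handling costs), reproduction, maintenance, death
#' (with necromass release under scavenging), and dormancy transitions
#' — in a freshly shuffled order, then increments the step counter.
#' Per-step tallies (births, deaths, encounters, immigrations) are
#' reset at entry.
#'
#' @param st a [make_state()] object.
#' @return The updated state.
#' @export
step_model <- function(st) {
  st$tally <- list(births = 0L, deaths = 0L, encounters = 0L,
                   immigrations = 0L)
  st$last_order <- sample(PROCESS_BLOCKS)
  for (blk in st$last_order) {
    st <- switch(blk,
                 supply       = block_supply(st),
                 immigration  = block_immigration(st),
                 mixing       = block_mixing(st),
                 dispersal    = block_dispersal(st),
                 consumption  = block_consumption(st),
                 reproduction = block_reproduction(st),
                 maintenance  = block_maintenance(st),
                 death        = block_death(st),
                 dormancy     = block_dormancy(st))
  }
  # keep the particle pool below its ceiling: cull the smallest crumbs
  np <- particle_count(st$parts)
  if (np > st$params$particle_cap) {
    drop <- order(st$parts$content)[seq_len(np - st$params$particle_cap)]
    st$cum$floored <- st$cum$floored + sum(st$parts$content[drop])
    st$parts <- particles_subset(st$parts, -drop)
  }
  if (particle_count(st$parts) && any(st$parts$content < 0))
    stop("internal consistency failure: negative particle content")
  if (individual_count(st$inds) && any(st$inds$quota < 0))
    stop("internal consistency failure: negative cell quota")
  st$step_index <- st$step_index + 1L
  st
}

#' Audit the conservation ledgers of a state
#'
#' Checks, against the cumulative ledgers, that (1) total particle
#' content equals supplied + spawned - consumed - removed-below-floor,
#' and (2) total living quota equals founding + immigrated + consumed
#' - maintenance - growth costs - dispersal costs - handling costs -
#' quota removed at death.  Both balances are exact up to
#' floating-point accumulation.
#'
#' @param st a model state.
#' @return list with `content_error` and `quota_error` (absolute
#'   imbalance) plus the two expected totals.
#' @export
audit_state <- function(st) {
  cm <- st$cum
  content_expect <- cm$supplied + cm$spawned - cm$consumed_mass - cm$floored
  quota_expect <- cm$q_init + cm$q_immig + cm$q_consumed - cm$q_maint -
    cm$q_growth - cm$q_disp - cm$q_hand - cm$q_dead
  list(content_error = abs(sum(st$parts$content) - content_expect),
       quota_error = abs(sum(st$inds$quota) - quota_expect),
       content_expect = content_expect, quota_expect = quota_expect)
}
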