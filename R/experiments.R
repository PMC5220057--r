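# Desk-scale experiments reproducing the headline contrasts: each
# function fixes one study design (regimes, pairing, horizon) and
# varies only the seeds.  Run lengths are desk-scale ensembles of
# tens of runs, not the original >10,000-model sweep.

#' Chemotaxis vs passive dispersal in structured environments
#'
#' For each seed, one parameterization and trait table are drawn and
#' the same model is run twice in a spatially structured
#' consumer-resource monoculture: once with chemotactic dispersal and
#' once with fully passive dispersal.  The response is the total
#' number of cell-particle encounters over the run.
#'
#' @param seeds integer vector of paired-run seeds (default 1:10).
#' @param steps steps per run (default 1000; no burn-in is discarded
#'   because the response is cumulative, not stationary).
#' @param S species pool size.
#' @return list with `table` (per-seed encounter totals) and `fold`
#'   (ratio of ensemble mean chemotaxis encounters to ensemble mean
#'   passive encounters; if no passive encounter occurred at all, the
#'   fold is reported against a floor of one encounter).
#' @export
contrast_dispersal_encounters <- function(seeds = 1:10, steps = 1000L,
                                          S = 100L) {
  total_enc <- function(run) {
    if (!nrow(run$records)) return(0)
    sum(run$records$encounters_per_step) * 10
  }
  rows <- lapply(seeds, function(sd) {
    params <- sample_params(seed = as.integer(sd))
    reg_ch <- regime("consumer_resource", "monoculture_labile",
                     "chemotaxis", "structured")
    reg_pa <- regime("consumer_resource", "monoculture_labile",
                     "passive", "structured")
    tseed <- derive_seed(sd, 2L)
    rseed <- derive_seed(sd, 3L)
    traits <- sample_species_traits(S, reg_ch, params, seed = tseed)
    ch <- run_model(params, traits, reg_ch, seed = rseed, burnin_cap = 0L,
                    production_steps = steps, cadence = 10L)
    pa <- run_model(params, traits, reg_pa, seed = rseed, burnin_cap = 0L,
                    production_steps = steps, cadence = 10L)
    data.frame(seed = sd, enc_chemotaxis = total_enc(ch),
               enc_passive = total_enc(pa))
  })
  tab <- do.call(rbind, rows)
  denom <- max(mean(tab$enc_passive), 1 / length(seeds))
  list(table = tab, fold = mean(tab$enc_chemotaxis) / denom)
}

#' Emergent particle and cell sizes over a mixed-regime ensemble
#'
#' Runs one model per seed, each drawing its own parameterization and
#' one of the 72 complexity regimes, through burn-in and a recorded
#' production phase; averages the recorded mean breakdown-fragment
#' diameter and mean cell diameter over records, then over runs (runs
#' contributing no fragments are missing, not zero).
#'
#' @param seeds integer vector (default 1:20).
#' @param burnin_cap,production_steps run-length settings (desk-scale
#'   defaults 500 and 1500, i.e. ~2000 total steps per run).
#' @param S species pool size.
#' @return list with `summary` (per-run rows), `grand_fragment_diam`
#'   and `grand_cell_diam` (um).
#' @export
ensemble_emergent_sizes <- function(seeds = 1:20, burnin_cap = 500L,
                                    production_steps = 1500L, S = 100L) {
  ens <- run_ensemble(seeds, regimes = NULL, S = S,
                      burnin_cap = burnin_cap,
                      production_steps = production_steps)
  sm <- ens$summary
  list(summary = sm,
       grand_fragment_diam = mean(sm$mean_fragment_diam, na.rm = TRUE),
       grand_cell_diam = mean(sm$mean_cell_diam, na.rm = TRUE))
}

#' Extinction under strong vs weak dormancy (matched seeds)
#'
#' For each seed one parameterization is drawn with immigration shut
#' off (so extinction is absorbing), in a structured consumer-resource
#' monoculture whose dispersal mode cycles over passive, run-and-
#' tumble and chemotaxis across seeds.  The same model then runs under
#' the strong-dormancy preset (maintenance divided by 100,
#' resuscitation 0.001) and the weak-dormancy preset (divided by 10,
#' resuscitation 0.1), and extinction within the horizon is recorded.
#'
#' @param seeds integer vector (default 1:10).
#' @param horizon steps per run (default 2500).
#' @param S species pool size.
#' @return list with `table` (per-seed extinction flags),
#'   `freq_strong`, `freq_weak` (extinction frequencies).
#' @export
contrast_dormancy_presets <- function(seeds = 1:10, horizon = 2500L,
                                      S = 100L) {
  modes <- DISPERSAL_LEVELS
  rows <- lapply(seq_along(seeds), function(i) {
    sd <- seeds[i]
    params <- sample_params(seed = as.integer(sd),
                            overrides = list(immigration_rate = 0))
    reg <- regime("consumer_resource", "monoculture_labile",
                  modes[1L + (i - 1L) %% 3L], "structured")
    traits <- sample_species_traits(S, reg, params,
                                    seed = derive_seed(sd, 2L))
    rseed <- derive_seed(sd, 3L)
    run1 <- run_model(params, scenario_presets(traits, "strong_dormancy"),
                      reg, seed = rseed, burnin_cap = 0L,
                      production_steps = horizon, cadence = 10L)
    run2 <- run_model(params, scenario_presets(traits, "weak_dormancy"),
                      reg, seed = rseed, burnin_cap = 0L,
                      production_steps = horizon, cadence = 10L)
    data.frame(seed = sd, dispersal = reg$dispersal,
               extinct_strong = run1$status == "extinct",
               extinct_weak = run2$status == "extinct")
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       freq_strong = mean(tab$extinct_strong),
       freq_weak = mean(tab$extinct_weak))
}

#' Encounter rate vs seed bank size across an ensemble
#'
#' Runs a mixed-regime ensemble and correlates (Spearman) the per-run
#' mean encounters per step with the per-run mean percent dormancy:
#' communities that encounter resources more often should carry
#' smaller seed banks.
#'
#' @param seeds integer vector (default 1:30).
#' @param burnin_cap,production_steps run-length settings.
#' @param S species pool size.
#' @return list with `summary` (per-run rows) and `rho` (Spearman
#'   correlation).
#' @export
correlation_encounter_dormancy <- function(seeds = 1:30,
                                           burnin_cap = 500L,
                                           production_steps = 1500L,
                                           S = 100L) {
  ens <- run_ensemble(seeds, regimes = NULL, S = S,
                      burnin_cap = burnin_cap,
                      production_steps = production_steps)
  sm <- ens$summary
  ok <- is.finite(sm$mean_encounters) & is.finite(sm$mean_pct_dormant)
  rho <- cor(sm$mean_encounters[ok], sm$mean_pct_dormant[ok],
             method = "spearman")
  list(summary = sm, rho = rho)
}

#' Lock-and-key recalcitrance vs labile resources (matched seeds)
#'
#' For each seed the same structured-environment run-and-tumble
#' consumer-resource model is run with labile monoculture resources
#' and with lock-and-key resources (monoculture supply in both arms,
#' so only recalcitrance differs); the stabilizing influence of
#' recalcitrance is a structured-environment time-series result.
#' Reports per-run mean encounters per step and the temporal
#' coefficient of variation of encounters.
#'
#' @param seeds integer vector (default 1:10).
#' @param steps steps per run (default 1000).
#' @param S species pool size.
#' @return list with `table` and aggregate means `mean_enc_labile`,
#'   `mean_enc_lockkey`, `cv_labile`, `cv_lockkey`.
#' @export
contrast_lock_key_stability <- function(seeds = 1:10, steps = 1000L,
                                        S = 100L) {
  cv <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    sd(v) / mean(v)
  }
  rows <- lapply(seeds, function(sd) {
    params <- sample_params(seed = as.integer(sd),
                            overrides = list(lock_and_key_polyculture = FALSE))
    reg_la <- regime("consumer_resource", "monoculture_labile",
                     "run_tumble", "structured")
    reg_lk <- regime("consumer_resource", "lock_and_key",
                     "run_tumble", "structured")
    traits <- sample_species_traits(S, reg_la, params,
                                    seed = derive_seed(sd, 2L))
    rseed <- derive_seed(sd, 3L)
    la <- run_model(params, traits, reg_la, seed = rseed, burnin_cap = 0L,
                    production_steps = steps, cadence = 10L)
    lk <- run_model(params, traits, reg_lk, seed = rseed, burnin_cap = 0L,
                    production_steps = steps, cadence = 10L)
    data.frame(seed = sd,
               enc_labile = mean(la$records$encounters_per_step),
               enc_lockkey = mean(lk$records$encounters_per_step),
               cv_labile = cv(la$records$encounters_per_step),
               cv_lockkey = cv(lk$records$encounters_per_step))
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       mean_enc_labile = mean(tab$enc_labile),
       mean_enc_lockkey = mean(tab$enc_lockkey),
       cv_labile = mean(tab$cv_labile, na.rm = TRUE),
       cv_lockkey = mean(tab$cv_lockkey, na.rm = TRUE))
}
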