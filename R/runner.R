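# Workflow: burn-in detection by mean reversion, the sampled
# production run, and seeded ensembles.

#' Detect mean reversion in an abundance series
#'
#' The burn-in ends when total abundance fluctuates around a stable
#' value: the means of the two most recent non-overlapping windows of
#' length `window` must differ by at most `tol` times their pooled
#' standard deviation, and at least `min_steps` steps must have
#' elapsed.  A series shorter than `2 * window` is never converged.
#'
#' @param N_series numeric vector of per-step total abundances.
#' @param window window length (>= 10; default 100).
#' @param tol tolerance as a multiple of the pooled SD (default 0.1).
#' @param min_steps minimum series length before convergence can be
#'   declared (default 500).
#' @return logical: converged?
#' @export
detect_mean_reversion <- function(N_series, window = 100L, tol = 0.1,
                                  min_steps = 500L) {
  if (window < 10L) stop("window must be >= 10")
  n <- length(N_series)
  if (n < max(min_steps, 2L * window)) return(FALSE)
  w2 <- N_series[(n - window + 1L):n]
  w1 <- N_series[(n - 2L * window + 1L):(n - window)]
  pooled <- sqrt((var(w1) + var(w2)) / 2)
  if (pooled == 0) return(mean(w1) == mean(w2))
  abs(mean(w1) - mean(w2)) <= tol * pooled
}

#' Run one model: burn-in, then a sampled production phase
#'
#' The model is stepped until the total-abundance series mean-reverts
#' (checked every `check_every` steps via [detect_mean_reversion()]),
#' up to `burnin_cap` steps; runs hitting the cap are flagged, not
#' discarded.  The burn-in is then discarded and the model runs
#' `production_steps` further steps ("generations": one step is the
#' minimum doubling time, so the fastest species doubles at most once
#' per step), recording a metrics row every `cadence` steps with
#' tallies averaged over the interval.  If the community reaches N =
#' 0 with no immigration the run terminates with status `"extinct"`.
#'
#' @param params model parameters.
#' @param traits species traits.
#' @param regime complexity regime.
#' @param seed integer seed for the whole run.
#' @param burnin_cap maximum burn-in steps (default 10,000); 0 skips
#'   burn-in detection entirely.
#' @param production_steps recorded phase length (default 2000).
#' @param cadence record every `cadence`-th step (default 10).
#' @param window,tol,min_burnin,check_every mean-reversion settings.
#' @param n_init founding community size (default 100).
#' @return An object of class `"seedbank_run"`: list with `params`,
#'   `traits`, `regime`, `seed`, `burn_in_steps`, `records`
#'   (data.frame), `status` (`"completed"`, `"extinct"`, or completed
#'   with `burnin_capped = TRUE`), `extinction_step`, and the final
#'   `state`.
#' @export
run_model <- function(params, traits, regime, seed = NULL,
                      burnin_cap = 10000L, production_steps = 2000L,
                      cadence = 10L, window = 100L, tol = 0.1,
                      min_burnin = 500L, check_every = 25L,
                      n_init = 100L) {
  st <- make_state(params, traits, regime, seed = seed, n_init = n_init)
  no_rescue <- params$immigration_rate == 0

  finish <- function(status, records, burn_in, capped, ext_step) {
    structure(list(params = params, traits = traits, regime = regime,
                   seed = seed, burn_in_steps = burn_in,
                   records = records, status = status,
                   burnin_capped = capped, extinction_step = ext_step,
                   state = st),
              class = "seedbank_run")
  }

  # burn-in
  capped <- FALSE
  N_series <- numeric(0)
  if (burnin_cap > 0L) {
    repeat {
      st <- step_model(st)
      N_series <- c(N_series, individual_count(st$inds))
      if (no_rescue && individual_count(st$inds) == 0L)
        return(finish("extinct", empty_records(), st$step_index, FALSE,
                      st$step_index))
      if (st$step_index >= min_burnin &&
          st$step_index %% check_every == 0L &&
          detect_mean_reversion(N_series, window, tol, min_burnin)) break
      if (st$step_index >= burnin_cap) { capped <- TRUE; break }
    }
  }
  burn_in <- st$step_index

  # production: record every `cadence`-th step
  records <- vector("list", production_steps %/% cadence)
  acc <- list(births = 0L, encounters = 0L, immigrations = 0L)
  k <- 0L
  for (s in seq_len(production_steps)) {
    st <- step_model(st)
    acc$births <- acc$births + st$tally$births
    acc$encounters <- acc$encounters + st$tally$encounters
    acc$immigrations <- acc$immigrations + st$tally$immigrations
    if (no_rescue && individual_count(st$inds) == 0L) {
      rec <- if (k > 0L) do.call(rbind, records[seq_len(k)]) else empty_records()
      return(finish("extinct", rec, burn_in, capped, st$step_index))
    }
    if (s %% cadence == 0L) {
      k <- k + 1L
      records[[k]] <- record_metrics(st, cadence, acc$births,
                                     acc$encounters, acc$immigrations)
      acc <- list(births = 0L, encounters = 0L, immigrations = 0L)
    }
  }
  finish("completed", do.call(rbind, records[seq_len(k)]), burn_in,
         capped, NA_integer_)
}

empty_records <- function() {
  data.frame(step = integer(0), N = integer(0), N_active = integer(0),
             pct_dormant = numeric(0), productivity = numeric(0),
             immigrations = integer(0), encounters_per_step = numeric(0),
             R_total = numeric(0), n_particles = integer(0),
             mean_particle_diam = numeric(0),
             mean_fragment_diam = numeric(0), mean_cell_diam = numeric(0),
             sad = character(0), stringsAsFactors = FALSE)
}

#' @export
print.seedbank_run <- function(x, ...) {
  cat(sprintf("<seedbank_run> %s\n  seed=%s status=%s burn-in=%d records=%d%s\n",
              format(x$regime), ifelse(is.null(x$seed), "none", x$seed),
              x$status, x$burn_in_steps, nrow(x$records),
              if (isTRUE(x$burnin_capped)) " (burn-in capped)" else ""))
  invisible(x)
}

#' Summarize one run as a single row
#'
#' Per-run means of the recorded metrics, plus identity and status.
#'
#' @param run a [run_model()] result.
#' @return one-row data.frame.
#' @export
summarize_run <- function(run) {
  r <- run$records
  m <- function(v) if (length(v) && any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_
  data.frame(
    seed = ifelse(is.null(run$seed), NA_integer_, run$seed),
    regime = format(run$regime),
    status = run$status,
    burn_in_steps = run$burn_in_steps,
    n_records = nrow(r),
    mean_N = m(r$N), mean_N_active = m(r$N_active),
    mean_pct_dormant = m(r$pct_dormant),
    mean_productivity = m(r$productivity),
    mean_encounters = m(r$encounters_per_step),
    mean_R_total = m(r$R_total),
    mean_particle_diam = m(r$mean_particle_diam),
    mean_fragment_diam = m(r$mean_fragment_diam),
    mean_cell_diam = m(r$mean_cell_diam),
    extinction_step = run$extinction_step,
    stringsAsFactors = FALSE
  )
}

# Deterministic per-run seed derivation (no RNG involved).
derive_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) * 7919 + as.numeric(i) * 104729) %%
               2147483629)
}

#' Run a seeded ensemble of models
#'
#' Runs are mutually independent: each draws its own parameters,
#' traits, and (unless fixed) regime from its own seed, so results are
#' invariant to execution order.
#'
#' @param seeds integer vector of run seeds (must be distinct).
#' @param regimes either `NULL` (each run samples one of the 72
#'   regimes from its seed), a single [regime()] applied to all runs,
#'   or a list of regimes (recycled to `length(seeds)`).
#' @param overrides named list of parameter overrides applied after
#'   sampling (e.g. `list(immigration_rate = 0)`).
#' @param preset optional dormancy preset name for
#'   [scenario_presets()].
#' @param S species pool size.
#' @param ... further arguments passed to [run_model()]
#'   (e.g. `burnin_cap`, `production_steps`).
#' @return list with `runs` (list of [run_model()] results) and
#'   `summary` (one row per run, via [summarize_run()]).
#' @export
run_ensemble <- function(seeds, regimes = NULL, overrides = list(),
                         preset = NULL, S = 100L, ...) {
  if (anyDuplicated(seeds)) stop("ensemble seeds must be distinct")
  n <- length(seeds)
  if (inherits(regimes, "complexity_regime")) regimes <- list(regimes)
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    sd_i <- as.integer(seeds[i])
    params <- sample_params(seed = sd_i, overrides = overrides)
    reg <- if (is.null(regimes)) {
      regime_from_index(1L + (derive_seed(sd_i, 1L) %% 72L))
    } else regimes[[1L + (i - 1L) %% length(regimes)]]
    traits <- sample_species_traits(S, reg, params,
                                    seed = derive_seed(sd_i, 2L))
    if (!is.null(preset)) traits <- scenario_presets(traits, preset)
    runs[[i]] <- run_model(params, traits, reg,
                           seed = derive_seed(sd_i, 3L), ...)
  }
  list(runs = runs, summary = do.call(rbind, lapply(runs, summarize_run)))
}

#' Write a run's records (and config echo) to CSV
#'
#' @param run a [run_model()] result.
#' @param path output CSV path for the metrics records.
#' @param manifest optional path for a one-row manifest CSV echoing
#'   the configuration, regime, status and burn-in length.
#' @return `path`, invisibly.
#' @export
write_run_csv <- function(run, path, manifest = NULL) {
  write.csv(run$records, path, row.names = FALSE)
  if (!is.null(manifest)) {
    p <- run$params
    echo <- cbind(summarize_run(run),
                  supply_rate = p$supply_rate,
                  resource_diversity = p$resource_diversity,
                  immigration_rate = p$immigration_rate,
                  logseries_alpha = p$logseries_alpha,
                  necromass_value = p$necromass_value,
                  rng_seed = p$rng_seed)
    write.csv(echo, manifest, row.names = FALSE)
  }
  invisible(path)
}

#' Quick look at a run's time series
#'
#' Four base-graphics panels: total and active abundance, percent
#' dormancy, total resources, and encounters per step.
#'
#' @param x a [run_model()] result.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.seedbank_run <- function(x, ...) {
  r <- x$records
  if (!nrow(r)) { warning("no records to plot"); return(invisible(x)) }
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(r$step, r$N, type = "l", xlab = "step", ylab = "N",
       main = "abundance")
  graphics::lines(r$step, r$N_active, lty = 2)
  plot(r$step, r$pct_dormant, type = "l", xlab = "step",
       ylab = "% dormant", main = "seed bank")
  plot(r$step, r$R_total, type = "l", xlab = "step", ylab = "R total",
       main = "resources")
  plot(r$step, r$encounters_per_step, type = "l", xlab = "step",
       ylab = "encounters/step", main = "encounters")
  invisible(x)
}
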