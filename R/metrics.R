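# Community and resource metrics, species abundance distributions
# (SADs), and the Fisher log-series goodness-of-fit.

#' Summarize the current state into one metrics record
#'
#' Computes, from the state and from tallies accumulated since the
#' previous record: total abundance N, active abundance, percent
#' dormancy (the relative seed bank size), productivity (births per
#' step), immigrations, mean encounters per step, total resources
#' (summed particle content), particle count, mean particle diameter,
#' mean breakdown-fragment diameter, mean cell diameter, and the SAD.
#' Means over empty sets are recorded as missing (`NA`), not zero.
#'
#' @param st a model state.
#' @param steps_since_last steps covered by the accumulated tallies
#'   (>= 1).
#' @param births,encounters,immigrations tallies accumulated over the
#'   interval (default: the state's per-step tallies).
#' @return A one-row data.frame; the `sad` column is a compact
#'   `"species:abundance;..."` string.
#' @export
record_metrics <- function(st, steps_since_last = 1L,
                           births = st$tally$births,
                           encounters = st$tally$encounters,
                           immigrations = st$tally$immigrations) {
  if (steps_since_last < 1L) stop("steps_since_last must be >= 1")
  n <- individual_count(st$inds)
  n_act <- sum(st$inds$active)
  np <- particle_count(st$parts)
  frag <- st$parts$origin == 2L
  sad <- tabulate(st$inds$species, nbins = st$traits$S)
  nz <- which(sad > 0L)
  data.frame(
    step = st$step_index,
    N = n,
    N_active = n_act,
    pct_dormant = if (n > 0L) 100 * (n - n_act) / n else NA_real_,
    productivity = births / steps_since_last,
    immigrations = immigrations,
    encounters_per_step = encounters / steps_since_last,
    R_total = sum(st$parts$content),
    n_particles = np,
    mean_particle_diam = if (np > 0L)
      mean(diameter_from_content(st$parts$content)) else NA_real_,
    mean_fragment_diam = if (any(frag))
      mean(diameter_from_content(st$parts$content[frag])) else NA_real_,
    mean_cell_diam = if (n > 0L)
      mean(cell_diam0(st$inds$quota)) else NA_real_,
    sad = paste(nz, sad[nz], sep = ":", collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Parse a serialized SAD string back to an abundance vector
#' @param sad a `"species:abundance;..."` string from [record_metrics()].
#' @return named integer vector of positive abundances.
#' @export
parse_sad <- function(sad) {
  if (!nzchar(sad)) return(integer(0))
  kv <- do.call(rbind, strsplit(strsplit(sad, ";", fixed = TRUE)[[1]],
                                ":", fixed = TRUE))
  out <- as.integer(kv[, 2])
  names(out) <- kv[, 1]
  out
}

# Truncated log-series pmf over species indices 1..S: p_k proportional
# to alpha^k / k.  Used to seed founding communities.
logseries_pmf <- function(alpha, S) {
  k <- seq_len(S)
  p <- alpha^k / k
  p / sum(p)
}

# Solve the Fisher log-series shape x from observed richness S and
# total abundance N via S/N = ((1-x)/x) * (-log(1-x)).
fisher_x_from_SN <- function(S, N) {
  if (S >= N) return(1e-12)  # all (or nearly all) singletons
  f <- function(x) ((1 - x) / x) * (-log1p(-x)) - S / N
  uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

#' Expected log-series rank-abundance vector
#'
#' Given observed richness `S` and total abundance `N`, solves the
#' Fisher log-series shape parameter x (equivalently Fisher's alpha =
#' N (1 - x) / x) and returns the expected abundances of the S ranked
#' species, obtained by evaluating the log-series quantile function at
#' the rank midpoints (i - 0.5) / S and sorting in decreasing order.
#'
#' @param S species richness (>= 2).
#' @param N total abundance (> S recommended).
#' @return Numeric vector of length S, decreasing.
#' @export
rad_logseries <- function(S, N) {
  if (S < 2) stop("need at least 2 species")
  x <- fisher_x_from_SN(S, N)
  nmax <- max(N, 2L)
  n <- seq_len(nmax)
  p <- x^n / n
  cdf <- cumsum(p) / sum(p)
  q <- (seq_len(S) - 0.5) / S
  abund <- findInterval(q, cdf, left.open = TRUE) + 1L
  sort(abund, decreasing = TRUE)
}

#' Log-series goodness of fit (modified r-squared)
#'
#' Fits the Fisher log-series to an observed species abundance
#' distribution through its richness S and total abundance N, then
#' scores the rank-matched agreement on log abundances:
#' `r2 = 1 - sum((log obs - log pred)^2) / sum((log obs - mean log
#' obs)^2)`.  Values can be negative for poor fits and never exceed 1.
#'
#' @param sad numeric vector of positive species abundances (zeros are
#'   dropped); needs at least 2 species.
#' @param rank_order sort the observed abundances into rank order
#'   (decreasing) before matching (default).  With `FALSE` the vector
#'   is compared to the prediction as given, position by position —
#'   useful to quantify how badly a mis-ordered vector fits.
#' @return The modified coefficient of determination.
#' @export
logseries_r2 <- function(sad, rank_order = TRUE) {
  sad <- sad[sad > 0]
  if (length(sad) < 2) stop("log-series fit undefined for a single species")
  obs <- as.numeric(sad)
  if (rank_order) obs <- sort(obs, decreasing = TRUE)
  pred <- rad_logseries(length(obs), sum(obs))
  lo <- log(obs); lp <- log(pred)
  ss_tot <- sum((lo - mean(lo))^2)
  ss_res <- sum((lo - lp)^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else -Inf)
  1 - ss_res / ss_tot
}

#' Draw species abundances from a log-series distribution
#'
#' Samples `S` abundances from the Fisher log-series with shape
#' parameter `x` (P(n) proportional to x^n / n), truncated at `nmax`.
#' Used for self-consistency checks of the fit statistic.
#'
#' @param S number of species to draw.
#' @param x log-series shape in (0, 1).
#' @param nmax truncation for the inverse-CDF table.
#' @return Integer vector of abundances.
#' @export
rlogseries <- function(S, x, nmax = 100000L) {
  n <- seq_len(nmax)
  p <- exp(n * log(x) - log(n))
  cdf <- cumsum(p) / sum(p)
  findInterval(runif(S), cdf, left.open = TRUE) + 1L
}
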