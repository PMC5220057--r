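# Domain geometry and dispersal.  The arena is a cube of side L with
# reflecting boundaries: an entity "hitting the edge" is mirrored back
# inside (a periodic wrap would make edges undetectable, contradicting
# the turn-on-edge dispersal behaviour).

#' Reflect a coordinate into the domain
#'
#' Mirror-reflects about whichever boundary (0 or `L`) is violated,
#' repeatedly if the excursion exceeds `L`.  Vectorized.
#'
#' @param x numeric coordinate(s), um.
#' @param L domain side length, um.
#' @return Coordinate(s) in `[0, L]`.
#' @examples
#' reflect(43300, 43200)  # 43100
#' reflect(-50, 43200)    # 50
#' @export
reflect <- function(x, L = DOMAIN_L) {
  if (any(!is.finite(x))) stop("non-finite coordinate")
  # fold onto [0, 2L), then mirror the upper half
  y <- x %% (2 * L)
  ifelse(y > L, 2 * L - y, y)
}

# Uniform random positions in the cube, as an n x 3 matrix.
runif_positions <- function(n, L = DOMAIN_L) {
  matrix(runif(3L * n, 0, L), ncol = 3L)
}

# Random unit headings (uniform on the sphere), n x 3.
runif_headings <- function(n) {
  m <- matrix(rnorm(3L * n), ncol = 3L)
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Relocate entities uniformly (well-mixed update)
#'
#' In the well-mixed regime every organism and resource particle is
#' assigned a fresh independent uniform position each step, so
#' positions at step t+1 carry no memory of step t.
#'
#' @param n number of entities.
#' @param L domain side length, um.
#' @return An `n x 3` matrix of coordinates in `[0, L]`.
#' @export
relocate_well_mixed <- function(n, L = DOMAIN_L) {
  runif_positions(n, L)
}

#' Brownian displacement (structured regime)
#'
#' Each axis is displaced by a zero-mean Gaussian of standard deviation
#' `sigma` and reflected at the boundaries.  This is the only movement
#' of resource particles — and of passively dispersing or dormant cells
#' — in spatially structured environments.
#'
#' @param pos `n x 3` matrix of positions, um.
#' @param sigma per-axis standard deviation, um (>= 0).
#' @param L domain side length, um.
#' @return Updated `n x 3` position matrix.
#' @export
brownian_step <- function(pos, sigma, L = DOMAIN_L) {
  if (sigma < 0) stop("brownian sigma must be >= 0")
  if (nrow(pos) == 0L || sigma == 0) return(pos)
  matrix(reflect(pos + rnorm(length(pos), 0, sigma), L), ncol = 3L)
}

#' Run-and-tumble dispersal step
#'
#' Advances each entity along its persistent heading by its step
#' length; on boundary contact the entity stops at the wall, draws a
#' fresh uniform random heading (components flipped inward where
#' needed), and continues with the remaining path length.  Headings
#' persist between steps unless a wall is hit.
#'
#' @param pos `n x 3` positions, um.
#' @param heading `n x 3` unit headings.
#' @param step_length numeric vector of path lengths, um (>= 0).
#' @param L domain side length, um.
#' @return list with `pos` and `heading` matrices.
#' @export
run_tumble_step <- function(pos, heading, step_length, L = DOMAIN_L) {
  n <- nrow(pos)
  if (n == 0L) return(list(pos = pos, heading = heading))
  rem <- rep_len(step_length, n)
  eps <- 1e-9
  for (it in seq_len(200L)) {
    act <- which(rem > eps)
    if (!length(act)) break
    p <- pos[act, , drop = FALSE]
    h <- heading[act, , drop = FALSE]
    # distance to the nearest wall along the heading, per axis
    tb <- matrix(Inf, nrow = length(act), ncol = 3L)
    pos_h <- h > eps
    neg_h <- h < -eps
    tb[pos_h] <- (L - p[pos_h]) / h[pos_h]
    tb[neg_h] <- p[neg_h] / (-h[neg_h])
    tmin <- pmax(0, apply(tb, 1L, min))
    move <- pmin(rem[act], tmin)
    p <- p + h * move
    hit <- rem[act] - move > eps
    rem[act] <- rem[act] - move
    if (any(hit)) {
      hi <- which(hit)
      newh <- runif_headings(length(hi))
      ph <- p[hi, , drop = FALSE]
      # point the new heading inward off any wall we are touching
      on_hi <- ph >= L - eps
      on_lo <- ph <= eps
      newh[on_hi] <- -abs(newh[on_hi])
      newh[on_lo] <-  abs(newh[on_lo])
      h[hi, ] <- newh
    }
    pos[act, ] <- p
    heading[act, ] <- h
    rem[act][!hit] <- 0
  }
  pos[] <- pmin(pmax(pos, 0), L)
  list(pos = pos, heading = heading)
}

#' Chemotactic dispersal step
#'
#' Each cell senses the nearest resource particle of a type it can
#' consume (unlimited sensing range; ties broken by lowest particle
#' id) and moves straight toward its centre, travelling
#' `min(step_length, distance-to-contact)`.  Cells with no consumable
#' particle in the system fall back to run-and-tumble motion.
#'
#' @param pos `n x 3` cell positions, um.
#' @param heading `n x 3` unit headings (used by the fallback).
#' @param step_length path lengths, um.
#' @param cell_radius cell radii, um.
#' @param target_pos `n x 3` matrix of target particle centres
#'   (rows may be `NA` when no consumable particle exists).
#' @param target_radius target particle radii, um (`NA` allowed).
#' @param L domain side length, um.
#' @return list with `pos` and `heading`.
#' @export
chemotaxis_step <- function(pos, heading, step_length, cell_radius,
                            target_pos, target_radius, L = DOMAIN_L) {
  n <- nrow(pos)
  if (n == 0L) return(list(pos = pos, heading = heading, dist = numeric(0)))
  step_length <- rep_len(step_length, n)
  dist_moved <- numeric(n)
  has <- !is.na(target_radius)
  if (any(has)) {
    dvec <- target_pos[has, , drop = FALSE] - pos[has, , drop = FALSE]
    d <- sqrt(rowSums(dvec^2))
    gap <- pmax(0, d - (cell_radius[has] + target_radius[has]))
    travel <- pmin(step_length[has], gap)
    ok <- d > 0
    scale <- ifelse(ok, travel / pmax(d, 1e-300), 0)
    pos[has, ] <- pos[has, , drop = FALSE] + dvec * scale
    dist_moved[has] <- travel
  }
  if (any(!has)) {
    rt <- run_tumble_step(pos[!has, , drop = FALSE],
                          heading[!has, , drop = FALSE],
                          step_length[!has], L)
    pos[!has, ] <- rt$pos
    heading[!has, ] <- rt$heading
    dist_moved[!has] <- step_length[!has]
  }
  list(pos = pos, heading = heading, dist = dist_moved)
}

#' Nearest consumable particle (single individual)
#'
#' Returns the id of the particle, among those of a type the focal
#' species can consume, with the minimum centre-to-centre distance;
#' ties break to the lowest particle id.  `NA` when none exists.
#'
#' @param pos length-3 position of the individual, um.
#' @param species species index of the individual.
#' @param parts a particle set (see [new_particles()]).
#' @param consumable S x 11 logical matrix of consumable types.
#' @return Particle id, or `NA_integer_`.
#' @export
nearest_consumable <- function(pos, species, parts, consumable) {
  if (particle_count(parts) == 0L) return(NA_integer_)
  ok <- consumable[species, parts$rtype]
  if (!any(ok)) return(NA_integer_)
  dx <- parts$x[ok] - pos[1]; dy <- parts$y[ok] - pos[2]; dz <- parts$z[ok] - pos[3]
  d2 <- dx * dx + dy * dy + dz * dz
  ids <- parts$id[ok]
  # which.min takes the first minimum; storage order is ascending id
  ids[which.min(d2)]
}
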