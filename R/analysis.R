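#' Split an angle trace into oscillation cycles
#'
#' Cycles are delimited at successive upward crossings of the trace mean;
#' partial cycles at either end are discarded.  A constant (or
#' non-oscillating) trace yields an empty list.
#'
#' @param angle Numeric vector, deg.
#' @param time Matching time grid, ms.
#' @param min_amplitude Peak-to-peak amplitude (deg) below which the trace
#'   is treated as non-oscillating.
#' @return A list of cycle descriptors: \code{idx} (sample indices),
#'   \code{t_start}, \code{t_end}, \code{duration}, \code{amplitude}.
#' @export
extract_cycles <- function(angle, time, min_amplitude = 1) {
  stopifnot(length(angle) == length(time))
  if (length(angle) < 4) return(list())
  if (diff(range(angle)) < min_amplitude) return(list())
  m <- mean(angle)
  up <- which(angle[-length(angle)] < m & angle[-1] >= m)
  if (length(up) < 2) return(list())
  lapply(seq_len(length(up) - 1), function(i) {
    idx <- (up[i] + 1L):up[i + 1L]
    seg <- angle[idx]
    list(idx = idx, t_start = time[up[i] + 1L], t_end = time[up[i + 1L]],
         duration = time[up[i + 1L]] - time[up[i] + 1L],
         amplitude = diff(range(seg)))
  })
}

#' Cycle-averaged state-diagram loop
#'
#' Builds the closed (beta, gamma) loop of the limit cycle by segmenting
#' the trace into cycles (on beta), normalising each cycle to a common
#' phase grid and averaging pointwise across cycles.
#'
#' @param beta,gamma Angle vectors, deg.
#' @param time Time grid, ms.
#' @param n_phase Number of phase points of the averaged loop.
#' @param last If not NULL, average only over the last \code{last} full
#'   cycles (useful for post-recovery epochs where early cycles are still
#'   growing).
#' @return A two-column matrix (beta, gamma), or NULL if no full cycle is
#'   present.
#' @export
average_loop <- function(beta, gamma, time, n_phase = 200, last = NULL) {
  cyc <- extract_cycles(beta, time)
  if (!length(cyc)) return(NULL)
  if (!is.null(last) && length(cyc) > last)
    cyc <- cyc[(length(cyc) - last + 1L):length(cyc)]
  ph <- seq(0, 1, length.out = n_phase)
  bs <- gs <- matrix(NA_real_, nrow = length(cyc), ncol = n_phase)
  for (i in seq_along(cyc)) {
    idx <- cyc[[i]]$idx
    p <- seq(0, 1, length.out = length(idx))
    bs[i, ] <- stats::approx(p, beta[idx], ph)$y
    gs[i, ] <- stats::approx(p, gamma[idx], ph)$y
  }
  cbind(beta = colMeans(bs), gamma = colMeans(gs))
}

# perpendicular distance of points to the chord p1-p2
perp_dist <- function(pts, p1, p2) {
  v <- p2 - p1
  len <- sqrt(sum(v^2))
  if (len < .Machine$double.eps)
    return(sqrt(rowSums(sweep(pts, 2, p1)^2)))
  abs((pts[, 1] - p1[1]) * v[2] - (pts[, 2] - p1[2]) * v[1]) / len
}

# iterative Ramer-Douglas-Peucker on an open chain (returns kept indices)
rdp_chain <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2) return(seq_len(n))
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    mid <- (i + 1):(j - 1)
    d <- perp_dist(pts[mid, , drop = FALSE], pts[i, ], pts[j, ])
    k <- which.max(d)
    if (d[k] > tol) {
      keep[mid[k]] <- TRUE
      stack <- c(stack, list(c(i, mid[k])), list(c(mid[k], j)))
    }
  }
  which(keep)
}

# closed-loop polygon simplification: anchor at the two mutually most
# distant points, simplify the two chains, merge
rdp_closed <- function(pts, tol) {
  n <- nrow(pts)
  cen <- colMeans(pts)
  i1 <- which.max(rowSums(sweep(pts, 2, cen)^2))
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  a <- min(i1, i2); b <- max(i1, i2)
  chain1 <- a:b
  chain2 <- c(b:n, 1:a)
  k1 <- chain1[rdp_chain(pts[chain1, , drop = FALSE], tol)]
  k2 <- chain2[rdp_chain(pts[chain2, , drop = FALSE], tol)]
  keep <- unique(c(k1, k2))
  keep[order(match(keep, c(a:n, 1:(a - 1))))]
}

# drop polygon vertices that are not dominant: turning angle below
# `min_turn` degrees (gentle inflections of an edge), or neighbours closer
# than half the simplification tolerance
prune_vertices <- function(poly, tol, min_turn = 40) {
  turn_at <- function(poly, i) {
    n <- nrow(poly)
    p0 <- poly[if (i == 1) n else i - 1, ]
    p1 <- poly[i, ]
    p2 <- poly[if (i == n) 1 else i + 1, ]
    v1 <- p1 - p0; v2 <- p2 - p1
    l1 <- sqrt(sum(v1^2)); l2 <- sqrt(sum(v2^2))
    if (l1 < .Machine$double.eps || l2 < .Machine$double.eps) return(0)
    acos(pmin(1, pmax(-1, sum(v1 * v2) / (l1 * l2)))) * 180 / pi
  }
  repeat {
    n <- nrow(poly)
    if (n <= 3) return(poly)
    drop <- integer(0)
    for (i in seq_len(n)) {
      # a rounded corner is split by the simplifier into a close pair of
      # gentle vertices: merge such pairs, keeping the sharper member
      j <- if (i == n) 1 else i + 1
      l <- sqrt(sum((poly[j, ] - poly[i, ])^2))
      if (l < 2 * tol) {
        drop <- if (turn_at(poly, i) < turn_at(poly, j)) i else j
        break
      }
      # turning angle below the dominance threshold: not a corner
      if (turn_at(poly, i) < min_turn) { drop <- i; break }
    }
    if (!length(drop)) return(poly)
    poly <- poly[-drop, , drop = FALSE]
  }
}

#' Classify a state-diagram loop
#'
#' Operationalises the by-eye distinction between triangle-like and
#' quadrilateral-like beta-gamma loops: the loop is normalised (translation
#' and uniform scaling invariant), resampled by arc length, simplified
#' with a perpendicular-distance tolerance proportional to the loop
#' bounding-box diagonal, and labelled by the dominant-vertex count
#' (3 = triangular, 4 = quadrilateral).  If one angle's range collapses
#' below \code{degenerate_floor} the loop is a degenerate line; if both
#' collapse it is quiescent.  If the simplified polygon has more than four
#' vertices the tolerance is progressively increased until the count drops
#' to four or three; the confidence reported is the ratio of the nominal
#' to the required tolerance.
#'
#' @param loop Two-column matrix or data.frame of ordered (beta, gamma)
#'   points covering >= 1 full cycle.
#' @param tol Simplification tolerance as a fraction of the bounding-box
#'   diagonal.
#' @param degenerate_floor Angle range (deg) below which an axis is
#'   considered collapsed.
#' @return A list of class \code{loop_class}: \code{label} (one of
#'   "triangular", "quadrilateral", "degenerate-line", "quiescent"),
#'   \code{vertex_count}, \code{confidence}, \code{vertices}.
#' @examples
#' tri <- make_fixture("triangle-loop")
#' classify_loop(cbind(tri$beta_deg, tri$gamma_deg))$label
#' @export
classify_loop <- function(loop, tol = 0.05, degenerate_floor = 2) {
  loop <- as.matrix(loop)
  if (nrow(unique(round(loop, 10))) < 3)
    stop("loop needs at least 3 distinct points")
  # multi-cycle traces are collapsed to their cycle-averaged loop first
  if (nrow(loop) >= 50) {
    av <- average_loop(loop[, 1], loop[, 2], seq_len(nrow(loop)))
    if (!is.null(av) && !anyNA(av)) loop <- av
  }
  rb <- diff(range(loop[, 1]))
  rg <- diff(range(loop[, 2]))
  collapsed <- c(rb < degenerate_floor, rg < degenerate_floor)
  if (all(collapsed))
    return(structure(list(label = "quiescent", vertex_count = 0L,
                          confidence = 1, vertices = NULL),
                     class = "loop_class"))
  if (any(collapsed))
    return(structure(list(label = "degenerate-line", vertex_count = 2L,
                          confidence = 1, vertices = NULL),
                     class = "loop_class"))

  # normalise: translation + uniform scaling invariance
  cen <- colMeans(loop)
  sc <- sqrt(rb^2 + rg^2)
  pts <- sweep(loop, 2, cen) / sc

  # resample by arc length to even out sampling density
  d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2))
  s <- cumsum(c(0, d[-length(d)]))
  total <- s[length(s)] + d[length(d)]
  grid <- seq(0, total, length.out = 241)[-241]
  pts <- cbind(stats::approx(c(s, total), c(pts[, 1], pts[1, 1]), grid)$y,
               stats::approx(c(s, total), c(pts[, 2], pts[1, 2]), grid)$y)

  count_at <- function(tl) {
    keep <- rdp_closed(pts, tl)
    poly <- prune_vertices(pts[keep, , drop = FALSE], tl)
    poly
  }
  poly <- count_at(tol)
  conf <- 1
  tl <- tol
  while (nrow(poly) > 4 && tl < 0.4) {
    tl <- tl * 1.25
    poly <- count_at(tl)
    conf <- tol / tl
  }
  k <- nrow(poly)
  label <- if (k <= 2) "degenerate-line"
  else if (k == 3) "triangular"
  else "quadrilateral"
  structure(list(label = label, vertex_count = as.integer(k),
                 confidence = conf,
                 vertices = sweep(poly * sc, 2, cen, `+`)),
            class = "loop_class")
}

#' @export
print.loop_class <- function(x, ...) {
  cat("<loop_class>", x$label, "(", x$vertex_count, "vertices, confidence",
      round(x$confidence, 2), ")\n")
  invisible(x)
}

#' Detect quiescent (oscillation-cessation) intervals
#'
#' Flags intervals in which the sliding-window peak-to-peak amplitude of
#' the angle stays below \code{amplitude_floor} for at least
#' \code{min_duration} ms — the partial or complete stop of the beta or
#' gamma oscillation seen after obstacle removal.
#'
#' @param angle Numeric vector, deg.
#' @param time Uniform time grid, ms.
#' @param amplitude_floor Peak-to-peak floor, deg.
#' @param min_duration Minimum quiescent duration, ms.
#' @return A data.frame with columns \code{t_start}, \code{t_end},
#'   \code{duration} (one row per quiescent interval; zero rows if none).
#' @export
detect_cessation <- function(angle, time, amplitude_floor = 2,
                             min_duration = 500) {
  n <- length(angle)
  stopifnot(length(time) == n)
  if (n < 3)
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0)))
  dt <- stats::median(diff(time))
  w <- max(2L, round(min_duration / dt))
  if (w >= n) {
    if (diff(range(angle)) < amplitude_floor)
      return(data.frame(t_start = time[1], t_end = time[n],
                        duration = time[n] - time[1]))
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0)))
  }
  # windowed peak-to-peak via cumulative max/min over blocks
  starts <- seq_len(n - w)
  p2p <- vapply(starts, function(i) {
    seg <- angle[i:(i + w)]
    max(seg) - min(seg)
  }, numeric(1))
  quiet <- p2p < amplitude_floor
  if (!any(quiet))
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0)))
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  out <- data.frame(t_start = numeric(0), t_end = numeric(0),
                    duration = numeric(0))
  for (j in which(r$values)) {
    t0 <- time[starts[begins[j]]]
    t1 <- time[starts[ends[j]] + w]
    out <- rbind(out, data.frame(t_start = t0, t_end = t1,
                                 duration = t1 - t0))
  }
  out
}

# local extrema of a lightly smoothed trace
find_peaks <- function(angle, time, smooth_frac = 0.05) {
  n <- length(angle)
  cyc <- extract_cycles(angle, time)
  period <- if (length(cyc)) mean(vapply(cyc, `[[`, numeric(1), "duration"))
  else (time[n] - time[1]) / 4
  dt <- stats::median(diff(time))
  w <- max(1L, round(smooth_frac * period / dt))
  if (w > 1) {
    k <- rep(1 / w, w)
    sm <- stats::filter(angle, k, sides = 2)
    sm[is.na(sm)] <- angle[is.na(sm)]
    angle <- as.numeric(sm)
  }
  d <- diff(angle)
  s <- sign(d)
  s[s == 0] <- 1
  turn <- diff(s)
  imax <- which(turn < 0) + 1L
  imin <- which(turn > 0) + 1L
  # merge spurious wiggles: repeatedly remove the adjacent extremum pair
  # with the smallest height difference until all pairs clear 5% of the
  # trace range
  ext <- sort(c(imax, imin))
  prom <- 0.05 * diff(range(angle))
  while (length(ext) > 2) {
    dh <- abs(diff(angle[ext]))
    k <- which.min(dh)
    if (dh[k] >= prom) break
    ext <- ext[-c(k, k + 1L)]
  }
  list(imax = intersect(ext, imax), imin = intersect(ext, imin),
       smoothed = angle)
}

#' Alternation test on a sequence of cycle amplitudes
#'
#' Flags a sequence in which successive amplitudes alternate in the sign of
#' their difference for at least \code{min_pairs} consecutive pairs with a
#' relative difference above \code{rel_diff}.  The alternation depth is the
#' mean relative difference over the qualifying run.
#'
#' @param amps Numeric vector of successive cycle amplitudes.
#' @param min_pairs Minimum number of consecutive alternating pairs.
#' @param rel_diff Minimum relative amplitude difference.
#' @return List with \code{flag} (NA if fewer than 6 amplitudes) and
#'   \code{depth}.
#' @examples
#' alternation_from_amplitudes(c(10, 6, 10, 6, 10, 6))  # flag TRUE, depth 0.4
#' @export
alternation_from_amplitudes <- function(amps, min_pairs = 4, rel_diff = 0.1) {
  amps <- amps[is.finite(amps)]
  if (length(amps) < 6) return(list(flag = NA, depth = NA_real_))
  d <- diff(amps)
  rel <- abs(d) / pmax(amps[-1], amps[-length(amps)])
  sgn <- sign(d)
  good <- rel > rel_diff & sgn != 0
  alt <- c(FALSE, sgn[-1] == -sgn[-length(sgn)]) & good &
    c(FALSE, good[-length(good)])
  r <- rle(alt)
  best <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  flag <- best >= min_pairs
  depth <- if (flag) {
    j <- which(r$values & r$lengths >= min_pairs)[1]
    end <- cumsum(r$lengths)[j]
    beg <- end - r$lengths[j] + 1L
    mean(rel[beg:end])
  } else NA_real_
  list(flag = flag, depth = depth)
}

#' Detect alternating-amplitude oscillation
#'
#' After removal of the obstacle some regimes show a gamma oscillation in
#' which a large amplitude is followed by a smaller one, which is followed
#' by a larger one, and so on.  Cycle amplitudes are measured on a lightly
#' smoothed trace as the drop from each local maximum to the following
#' local minimum (robust to alternation expressed in the dip depths, the
#' typical case here, as well as in the peak heights); the alternation rule
#' is \code{\link{alternation_from_amplitudes}}.
#'
#' @param angle Numeric vector, deg.
#' @param time Time grid, ms.
#' @param min_pairs Minimum number of consecutive alternating pairs.
#' @param rel_diff Minimum relative amplitude difference.
#' @param smooth_frac Peak-detection smoothing window as a fraction of the
#'   oscillation period.
#' @return A list: \code{flag} (TRUE/FALSE, or NA if fewer than 6 peaks),
#'   \code{depth}, \code{amplitudes}.
#' @export
detect_alternating_amplitude <- function(angle, time, min_pairs = 4,
                                         rel_diff = 0.1,
                                         smooth_frac = 0.05) {
  pk <- find_peaks(angle, time, smooth_frac)
  imax <- pk$imax
  sm <- pk$smoothed
  if (length(imax) < 2)
    return(list(flag = NA, depth = NA_real_, amplitudes = numeric(0)))
  # drop from each maximum to the deepest point before the next maximum
  amps <- vapply(seq_len(length(imax) - 1L), function(i) {
    seg <- sm[imax[i]:imax[i + 1L]]
    sm[imax[i]] - min(seg)
  }, numeric(1))
  res <- alternation_from_amplitudes(amps, min_pairs, rel_diff)
  c(res, list(amplitudes = amps))
}

#' Oscillation statistics of a trace
#'
#' Ranges, mean period and per-cycle amplitudes for the three angles over
#' the post-transient window.
#'
#' @param trace A \code{leg_trace} (or data.frame with \code{time_ms},
#'   \code{alpha_deg}, \code{beta_deg}, \code{gamma_deg}).
#' @param transient Initial time discarded, ms.
#' @return A list with \code{ranges} (per angle), \code{period} (ms; NA if
#'   fewer than 2 cycles), \code{cycle_amplitudes}, \code{n_cycles}.
#' @export
oscillation_stats <- function(trace, transient = 0) {
  tr <- trace[trace$time_ms >= transient, ]
  angles <- list(alpha = tr$alpha_deg, beta = tr$beta_deg,
                 gamma = tr$gamma_deg)
  ranges <- lapply(angles, range)
  cyc <- extract_cycles(tr$beta_deg, tr$time_ms)
  period <- if (length(cyc) >= 2)
    mean(vapply(cyc, `[[`, numeric(1), "duration")) else NA_real_
  amp <- lapply(angles, function(a) {
    cc <- extract_cycles(a, tr$time_ms)
    vapply(cc, `[[`, numeric(1), "amplitude")
  })
  list(ranges = ranges, period = period, cycle_amplitudes = amp,
       n_cycles = length(cyc))
}
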