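#' Transition kernel between line-origin states over one map interval
#'
#' The maternal and paternal haplotypes recombine in independent meioses, so
#' the 4x4 transition matrix factorizes into two 2x2 single-haplotype
#' kernels with stay probability `1 - r` and switch probability `r`, where
#' `r` comes from [haldane_r()]. Distinct maternal and paternal distances are
#' accepted (sex-specific maps); by default both sexes share the map.
#'
#' @param d_maternal Distance (cM) of the interval on the maternal map.
#' @param d_paternal Distance on the paternal map; defaults to `d_maternal`.
#' @return A 4x4 row-stochastic matrix in the state order
#'   (1,1), (1,2), (2,1), (2,2).
#' @examples
#' transition_kernel(10)
#' @export
transition_kernel <- function(d_maternal, d_paternal = d_maternal) {
  rm_ <- haldane_r(d_maternal)
  rp_ <- haldane_r(d_paternal)
  Tm <- matrix(c(1 - rm_, rm_, rm_, 1 - rm_), 2, 2)
  Tp <- matrix(c(1 - rp_, rp_, rp_, 1 - rp_), 2, 2)
  K <- kronecker(Tm, Tp)
  dimnames(K) <- list(STATE_LABELS, STATE_LABELS)
  K
}

# Merge marker positions with test positions into one strictly increasing
# coordinate sequence. Positions closer than 1e-8 cM are treated as one
# shared coordinate (computed once). Returns positions, the merged index of
# every marker, and which merged positions are requested test positions.
.merge_positions <- function(map, test_positions) {
  if (length(test_positions) > 0) {
    L <- map_length(map)
    if (any(test_positions < 0) || any(test_positions > L)) {
      stop("test positions must lie within [0, length_cM]", call. = FALSE)
    }
  }
  key <- function(x) round(x * 1e8)
  all_keys <- sort(unique(c(key(map$position_cM), key(test_positions))))
  mk <- key(map$position_cM)
  tk <- key(test_positions)
  positions <- all_keys / 1e8
  mpos <- match(mk, all_keys)
  positions[mpos] <- map$position_cM  # keep exact marker coordinates
  list(
    positions = positions,
    marker_index = mpos,
    test_index = match(unique(tk), all_keys),
    is_test = all_keys %in% tk
  )
}

# Check/orient a per-individual emission matrix to markers x 4.
.check_emissions <- function(emissions, map) {
  emissions <- as.matrix(emissions)
  if (ncol(emissions) != 4) {
    stop("emissions must be a markers x 4 matrix in state order ",
         paste(STATE_LABELS, collapse = ", "), call. = FALSE)
  }
  if (nrow(emissions) != nrow(map)) {
    stop("emissions must have one row per map marker", call. = FALSE)
  }
  if (any(!is.finite(emissions)) || any(emissions < 0)) {
    stop("emissions must be finite and non-negative", call. = FALSE)
  }
  emissions
}

# Expand a markers x 4 emission matrix onto merged positions (all-compatible
# rows, i.e. 1s, at pure test positions).
.expand_emissions <- function(emissions, merged) {
  Em <- matrix(1, nrow = length(merged$positions), ncol = 4)
  Em[merged$marker_index, ] <- emissions
  Em
}

#' Forward and backward probability tables for one individual
#'
#' `forward_table()` runs the forward pass of the line-origin HMM: starting
#' from a uniform state distribution (1/4 each, the expected F2 line-origin
#' frequencies), it accumulates at each position the probability of the
#' state and all marker genotypes so far. `backward_table()` mirrors it from
#' the right end, starting from 1 for every state. Test positions are merged
#' into the marker sequence as pseudo-observations under which every state
#' is compatible (emission 1). Both tables are rescaled at every position to
#' avoid underflow — forward columns to sum 1, backward columns to max 1 —
#' with the cumulative log scale retained, so exact values are
#' `value * exp(log_scale)`.
#'
#' @param emissions Numeric matrix, map markers x 4 states in the order
#'   (1,1), (1,2), (2,1), (2,2).
#' @param map An `lo_map`.
#' @param test_positions Numeric vector of extra positions (cM) in
#'   `[0, length_cM]`.
#' @return A tibble with columns `position_cM`, `is_marker`, the four scaled
#'   state values (`a11`..`a22` / `b11`..`b22`) and `log_scale`.
#' @export
forward_table <- function(emissions, map, test_positions = numeric(0)) {
  emissions <- .check_emissions(emissions, map)
  merged <- .merge_positions(map, test_positions)
  Em <- .expand_emissions(emissions, merged)
  n <- length(merged$positions)
  r <- haldane_r(diff(merged$positions))
  A <- matrix(0, n, 4)
  ls <- numeric(n)
  a <- 0.25 * Em[1, ]
  s <- sum(a)
  A[1, ] <- a / s
  ls[1] <- log(s)
  for (p in seq_len(n - 1)) {
    K <- transition_kernel(merged$positions[p + 1] - merged$positions[p])
    a <- as.vector(A[p, ] %*% K) * Em[p + 1, ]
    s <- sum(a)
    if (s <= 0) stop("forward probabilities vanished; use a positive error floor", call. = FALSE)
    A[p + 1, ] <- a / s
    ls[p + 1] <- ls[p] + log(s)
  }
  out <- tibble::tibble(
    position_cM = merged$positions,
    is_marker = seq_len(n) %in% merged$marker_index,
    a11 = A[, 1], a12 = A[, 2], a21 = A[, 3], a22 = A[, 4],
    log_scale = ls
  )
  out
}

#' @rdname forward_table
#' @export
backward_table <- function(emissions, map, test_positions = numeric(0)) {
  emissions <- .check_emissions(emissions, map)
  merged <- .merge_positions(map, test_positions)
  Em <- .expand_emissions(emissions, merged)
  n <- length(merged$positions)
  B <- matrix(0, n, 4)
  ls <- numeric(n)
  B[n, ] <- 1
  ls[n] <- 0
  if (n > 1) {
    for (p in (n - 1):1) {
      K <- transition_kernel(merged$positions[p + 1] - merged$positions[p])
      b <- as.vector(K %*% (B[p + 1, ] * Em[p + 1, ]))
      s <- max(b)
      if (s <= 0) stop("backward probabilities vanished; use a positive error floor", call. = FALSE)
      B[p, ] <- b / s
      ls[p] <- ls[p + 1] + log(s)
    }
  }
  tibble::tibble(
    position_cM = merged$positions,
    is_marker = seq_len(n) %in% merged$marker_index,
    b11 = B[, 1], b12 = B[, 2], b21 = B[, 3], b22 = B[, 4],
    log_scale = ls
  )
}

#' Combine forward and backward tables into posterior probabilities
#'
#' At every position the posterior of state (i,j) is
#' `alpha(i,j) * beta(i,j)` normalized over the four states; the scale
#' factors cancel in the normalization.
#'
#' @param forward,backward Tables from [forward_table()] and
#'   [backward_table()] over identical position sequences.
#' @return A tibble with `position_cM`, `is_marker`, `p11`..`p22`,
#'   `p1_maternal`, `p1_paternal`.
#' @export
posterior_from_tables <- function(forward, backward) {
  if (nrow(forward) != nrow(backward) ||
      any(abs(forward$position_cM - backward$position_cM) > 1e-9)) {
    stop("forward and backward tables cover different positions", call. = FALSE)
  }
  A <- as.matrix(forward[c("a11", "a12", "a21", "a22")])
  B <- as.matrix(backward[c("b11", "b12", "b21", "b22")])
  P <- A * B
  tot <- rowSums(P)
  if (any(tot <= 0)) stop("all-zero posterior; emissions degenerate", call. = FALSE)
  P <- P / tot
  tibble::tibble(
    position_cM = forward$position_cM,
    is_marker = forward$is_marker,
    p11 = P[, 1], p12 = P[, 2], p21 = P[, 3], p22 = P[, 4],
    p1_maternal = P[, 1] + P[, 2],
    p1_paternal = P[, 1] + P[, 3]
  )
}

#' Exhaustive enumeration reference for the line-origin posterior
#'
#' Enumerates all `4^n` state sequences over the merged marker/test
#' positions, scoring each by initial x transition x emission products, and
#' normalizes — the brute-force computation the forward-backward recursion
#' collapses. Exact but exponential; refuses more than 10 total positions.
#' Used to verify that the dynamic-programming posterior is identical to
#' direct enumeration.
#'
#' @inheritParams forward_table
#' @return Same shape as [posterior_from_tables()].
#' @export
enumerate_oracle <- function(emissions, map, test_positions = numeric(0)) {
  emissions <- .check_emissions(emissions, map)
  merged <- .merge_positions(map, test_positions)
  Em <- .expand_emissions(emissions, merged)
  n <- length(merged$positions)
  if (n > 10) {
    stop("enumeration oracle limited to 10 positions (4^n state sequences)",
         call. = FALSE)
  }
  seqs <- as.matrix(expand.grid(rep(list(1:4), n)))
  w <- rep(0.25, nrow(seqs))
  for (p in seq_len(n)) w <- w * Em[p, ][seqs[, p]]
  for (p in seq_len(n - 1)) {
    K <- transition_kernel(merged$positions[p + 1] - merged$positions[p])
    w <- w * K[cbind(seqs[, p], seqs[, p + 1])]
  }
  tot <- sum(w)
  P <- vapply(seq_len(n), function(p) {
    vapply(1:4, function(s) sum(w[seqs[, p] == s]), numeric(1))
  }, numeric(4))
  P <- t(P) / tot
  tibble::tibble(
    position_cM = merged$positions,
    is_marker = seq_len(n) %in% merged$marker_index,
    p11 = P[, 1], p12 = P[, 2], p21 = P[, 3], p22 = P[, 4],
    p1_maternal = P[, 1] + P[, 2],
    p1_paternal = P[, 1] + P[, 3]
  )
}

# Vectorized scaled forward-backward over all individuals at once.
# E: array (4 states, n positions, n individuals); r: recombination
# fractions between adjacent positions (length n - 1), shared by both
# meioses. Returns the posterior array with the same dimensions.
.fb_posterior_cube <- function(E, r) {
  dims <- dim(E)
  n <- dims[2]
  ni <- dims[3]
  slab <- function(p) matrix(E[, p, ], nrow = 4)
  kernels <- lapply(r, function(ri) {
    Tm <- matrix(c(1 - ri, ri, ri, 1 - ri), 2, 2)
    kronecker(Tm, Tm)
  })
  A <- array(0, dims)
  a <- 0.25 * slab(1)
  a <- a / rep(colSums(a), each = 4)
  A[, 1, ] <- a
  for (p in seq_len(n - 1)) {
    a <- (kernels[[p]] %*% a) * slab(p + 1)  # kernels are symmetric
    cs <- colSums(a)
    if (any(cs <= 0)) stop("forward probabilities vanished", call. = FALSE)
    a <- a / rep(cs, each = 4)
    A[, p + 1, ] <- a
  }
  P <- array(0, dims)
  b <- matrix(1, 4, ni)
  P[, n, ] <- A[, n, ] * b
  if (n > 1) {
    for (p in (n - 1):1) {
      b <- kernels[[p]] %*% (b * slab(p + 1))
      b <- b / rep(apply(b, 2, max), each = 4)
      P[, p, ] <- matrix(A[, p, ], nrow = 4) * b
    }
  }
  tot <- colSums(P)  # 2-d apply over (position, individual)
  P / rep(tot, each = 4)
}

#' Infer line-origin posterior probabilities for every F2 individual
#'
#' Runs the scaled forward-backward algorithm over the four line-origin
#' states for each F2 individual, evaluating posteriors on a regular grid of
#' test positions (default every 1 cM from 0 to the chromosome length) and
#' optionally at the markers themselves. Emissions come from Mendelian
#' compatibility of the observed genotypes with the F1 parents'
#' transmissible alleles ([build_emission_table()]); transitions follow
#' Haldane's map function. Each individual is independent, so results do not
#' depend on input row order.
#'
#' @param genotypes An `lo_geno` tibble (founders, F1, F2).
#' @param pedigree An `lo_pedigree`.
#' @param map An `lo_map`.
#' @param grid_step_cM Spacing of test positions in cM (default 1).
#' @param error_floor Emission for Mendelian-incompatible states (default
#'   0.01); must be in (0, 0.5).
#' @param weighted Use frequency-weighted emissions (see [emission()]).
#' @param parental_phase Optional parental phase, see
#'   [build_emission_table()].
#' @param at_markers Also report posteriors at marker positions.
#' @return A tibble of class `lo_posterior`, one row per F2 individual and
#'   test position: `individual`, `position_cM`, `p11`, `p12`, `p21`, `p22`
#'   (state order (1,1), (1,2), (2,1), (2,2) with (i,j) = maternal from line
#'   i, paternal from line j), and the per-haplotype line-1 probabilities
#'   `p1_maternal = p11 + p12`, `p1_paternal = p11 + p21`.
#' @examples
#' sim <- simulate_cross(sim_map(length_cM = 50, spacing_cM = 5),
#'                       sim_pedigree(1, 2, 4), seed = 1)
#' infer_line_origin(sim$genotypes, sim$pedigree, sim$map, grid_step_cM = 10)
#' @export
infer_line_origin <- function(genotypes, pedigree, map, grid_step_cM = 1,
                              error_floor = 0.01, weighted = FALSE,
                              parental_phase = NULL, at_markers = FALSE) {
  stopifnot(grid_step_cM > 0)
  emis <- build_emission_table(genotypes, pedigree, map,
                               error_floor = error_floor, weighted = weighted,
                               parental_phase = parental_phase)
  grid <- seq(0, map_length(map), by = grid_step_cM)
  merged <- .merge_positions(map, grid)
  n <- length(merged$positions)
  ni <- length(emis$individuals)
  E <- array(1, dim = c(4L, n, ni))
  E[, merged$marker_index, ] <- emis$E
  r <- haldane_r(diff(merged$positions))
  P <- .fb_posterior_cube(E, r)
  keep <- if (at_markers) sort(unique(c(merged$test_index, merged$marker_index)))
          else merged$test_index
  pos <- merged$positions[keep]
  is_marker <- keep %in% merged$marker_index
  blocks <- lapply(seq_len(ni), function(k) {
    Pi <- matrix(P[, keep, k], nrow = 4)
    tibble::tibble(
      individual = emis$individuals[k],
      position_cM = pos,
      is_marker = is_marker,
      p11 = Pi[1, ], p12 = Pi[2, ], p21 = Pi[3, ], p22 = Pi[4, ],
      p1_maternal = Pi[1, ] + Pi[2, ],
      p1_paternal = Pi[1, ] + Pi[3, ]
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(blocks), .data$individual,
                        .data$position_cM)
  attr(out, "grid_step_cM") <- grid_step_cM
  attr(out, "error_floor") <- error_floor
  attr(out, "length_cM") <- map_length(map)
  class(out) <- c("lo_posterior", class(out))
  out
}

#' Glance at a posterior grid
#'
#' @param x An `lo_posterior` tibble.
#' @param ... Unused.
#' @return One-row tibble: number of individuals, positions per individual,
#'   grid step, error floor, and the largest deviation of the four-state sum
#'   from 1.
#' @method glance lo_posterior
#' @export
glance.lo_posterior <- function(x, ...) {
  tibble::tibble(
    n_individuals = dplyr::n_distinct(x$individual),
    n_positions = dplyr::n_distinct(x$position_cM),
    grid_step_cM = attr(x, "grid_step_cM") %||% NA_real_,
    error_floor = attr(x, "error_floor") %||% NA_real_,
    max_sum_deviation = max(abs(x$p11 + x$p12 + x$p21 + x$p22 - 1))
  )
}

#' Plot haplotype line-origin probability curves
#'
#' Draws the per-haplotype probability of line-1 origin along the chromosome
#' for a subset of individuals, the standard visual check for inferred
#' recombination switches.
#'
#' @param object An `lo_posterior` tibble.
#' @param individuals Which individuals to show (default: first 4).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lo_posterior
#' @export
autoplot.lo_posterior <- function(object, individuals = NULL, ...) {
  if (is.null(individuals)) {
    individuals <- utils::head(unique(object$individual), 4)
  }
  df <- object |>
    dplyr::filter(.data$individual %in% individuals) |>
    tidyr::pivot_longer(c("p1_maternal", "p1_paternal"),
                        names_to = "haplotype", values_to = "p1",
                        names_prefix = "p1_")
  ggplot2::ggplot(df, ggplot2::aes(.data$position_cM, .data$p1,
                                   colour = .data$haplotype)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~individual) +
    ggplot2::labs(x = "position (cM)", y = "P(line 1 origin)",
                  colour = "haplotype") +
    ggplot2::ylim(0, 1)
}
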