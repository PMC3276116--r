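#' Line-origin error of a probability series against the simulated truth
#'
#' For one haplotype, the error at position `i` is `1 - p1(i)` where the
#' true origin is line 1 and `p1(i)` where it is line 2, so 0 is a perfect
#' call and 1 a maximally confident wrong call.
#'
#' @param p1 Probabilities of line-1 origin, in `[0, 1]`.
#' @param true_line Integer vector of true origins (1 or 2), same length.
#' @return Numeric error vector in `[0, 1]`.
#' @examples
#' origin_error(c(1, 0.7, 0.2), c(1, 2, 1))
#' @export
origin_error <- function(p1, true_line) {
  if (length(p1) != length(true_line)) stop("length mismatch", call. = FALSE)
  if (any(p1 < 0 | p1 > 1, na.rm = TRUE)) {
    stop("p1 outside [0, 1]", call. = FALSE)
  }
  if (!all(true_line %in% 1:2)) stop("true_line must be 1 or 2", call. = FALSE)
  ifelse(true_line == 1L, 1 - p1, p1)
}

#' Per-position line-origin error for all haplotypes
#'
#' Joins the inferred per-haplotype line-1 probabilities with the simulated
#' truth and applies [origin_error()].
#'
#' @param posteriors An `lo_posterior` tibble from [infer_line_origin()].
#' @param truth Truth tibble from [simulate_cross()].
#' @return A tibble: `individual`, `haplotype`, `position_cM`, `p1`,
#'   `true_line`, `error`.
#' @export
line_origin_error <- function(posteriors, truth) {
  long <- posteriors |>
    dplyr::select("individual", "position_cM", "p1_maternal", "p1_paternal") |>
    tidyr::pivot_longer(c("p1_maternal", "p1_paternal"),
                        names_to = "haplotype", values_to = "p1",
                        names_prefix = "p1_")
  tr <- truth_origin(truth, sort(unique(posteriors$position_cM)))
  out <- dplyr::inner_join(long, tr,
                           by = c("individual", "haplotype", "position_cM"))
  if (nrow(out) != nrow(long)) {
    stop("truth does not cover all individuals/haplotypes in the posteriors",
         call. = FALSE)
  }
  out$error <- origin_error(out$p1, out$true_line)
  out
}

#' Summarize line-origin errors over haplotypes and individuals
#'
#' Averages the error at each position over both haplotypes of all
#' individuals, with the sample (n-1) standard deviation, plus the grand
#' mean over every position/haplotype/individual value.
#'
#' @param errors Tibble from [line_origin_error()] (needs `position_cM` and
#'   `error`).
#' @return A tibble of class `lo_error_summary` with `position_cM`, `n`,
#'   `mean_error`, `sd_error`, and attribute `grand_mean`.
#' @export
summarize_error <- function(errors) {
  out <- errors |>
    dplyr::group_by(.data$position_cM) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_error = mean(.data$error),
                     sd_error = stats::sd(.data$error),
                     .groups = "drop")
  attr(out, "grand_mean") <- mean(errors$error)
  class(out) <- c("lo_error_summary", class(out))
  out
}

#' @rdname summarize_error
#' @param x An `lo_error_summary`.
#' @param ... Unused.
#' @method glance lo_error_summary
#' @export
glance.lo_error_summary <- function(x, ...) {
  tibble::tibble(
    grand_mean_error = attr(x, "grand_mean"),
    mean_sd = mean(x$sd_error, na.rm = TRUE),
    n_positions = nrow(x),
    worst_position_cM = x$position_cM[which.max(x$mean_error)],
    worst_mean_error = max(x$mean_error)
  )
}

#' @rdname summarize_error
#' @param object An `lo_error_summary`.
#' @method autoplot lo_error_summary
#' @export
autoplot.lo_error_summary <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("mean_error", "sd_error"),
                            names_to = "statistic", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$position_cM, .data$value)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~statistic, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (cM)", y = NULL,
                  title = "Line-origin error along the chromosome")
}

# Scan one p1 series for switches. Returns tibble(direction, start_cM,
# end_cM, cross_cM, imprecision_cM), possibly empty.
.switch_scan <- function(p1, positions, upper = 0.975, lower = 0.025) {
  n <- length(p1)
  empty <- tibble::tibble(direction = character(), start_cM = numeric(),
                          end_cM = numeric(), cross_cM = numeric(),
                          imprecision_cM = numeric())
  if (n < 2) return(empty)
  s <- sign(p1 - 0.5)
  nz <- which(s != 0)
  if (length(nz) < 2) return(empty)
  recs <- list()
  for (k in seq_len(length(nz) - 1)) {
    i <- nz[k]; j <- nz[k + 1]
    if (s[i] == s[j]) next
    falling <- s[i] > 0
    # cross position: central 0.5 plateau if present, else linear interpolation
    cross <- if (j > i + 1) {
      mean(positions[(i + 1):(j - 1)])
    } else {
      positions[i] + (p1[i] - 0.5) / (p1[i] - p1[j]) * (positions[j] - positions[i])
    }
    # scan outward for the threshold attainments, stopping at any other
    # 0.5-crossing (sign change or exact 0.5)
    left <- NA_real_
    for (q in i:1) {
      if (s[q] != s[i]) break
      if ((falling && p1[q] >= upper) || (!falling && p1[q] <= lower)) {
        left <- positions[q]; break
      }
    }
    right <- NA_real_
    for (q in j:n) {
      if (s[q] != s[j]) break
      if ((falling && p1[q] <= lower) || (!falling && p1[q] >= upper)) {
        right <- positions[q]; break
      }
    }
    if (is.na(left) || is.na(right)) next
    recs[[length(recs) + 1]] <- tibble::tibble(
      direction = if (falling) "1to2" else "2to1",
      start_cM = left, end_cM = right, cross_cM = cross,
      imprecision_cM = right - left
    )
  }
  if (length(recs) == 0) empty else dplyr::bind_rows(recs)
}

#' Detect line-origin switches in posterior probability series
#'
#' A switch is an inferred parental recombination: the haplotype's line-1
#' probability traverses from one confident extreme to the other. Only
#' traversals covering the full `lower`-`upper` probability range count; the
#' nearest positions attaining the thresholds on either side of the
#' 0.5-crossing (before any other crossing) are the switch end points, their
#' distance the imprecision. The crossing position is interpolated linearly
#' between the flanking grid points, or taken as the centre of a run of
#' exact-0.5 values.
#'
#' @param posteriors An `lo_posterior` tibble, or any tibble with columns
#'   `individual`, `position_cM`, `p1_maternal`, `p1_paternal`.
#' @param upper,lower Threshold probabilities defining the switch end points
#'   (defaults 0.975 and 0.025).
#' @return A tibble: `individual`, `haplotype`, `direction` (`1to2` when the
#'   line-1 probability falls), `start_cM`, `end_cM`, `cross_cM`,
#'   `imprecision_cM`.
#' @export
detect_switches <- function(posteriors, upper = 0.975, lower = 0.025) {
  stopifnot(lower < 0.5, upper > 0.5)
  long <- posteriors |>
    dplyr::select("individual", "position_cM", "p1_maternal", "p1_paternal") |>
    tidyr::pivot_longer(c("p1_maternal", "p1_paternal"),
                        names_to = "haplotype", values_to = "p1",
                        names_prefix = "p1_") |>
    dplyr::arrange(.data$individual, .data$haplotype, .data$position_cM)
  out <- long |>
    dplyr::group_by(.data$individual, .data$haplotype) |>
    dplyr::reframe(.switch_scan(.data$p1, .data$position_cM, upper, lower))
  tibble::as_tibble(out)
}

#' Match detected switches to true crossovers
#'
#' Pairs each detected switch with a simulated crossover of the same
#' haplotype and direction by greedy nearest-distance matching (each side
#' matched at most once). Matched switches get the true position and the
#' inaccuracy — the distance between the true crossover and the inferred
#' 0.5-crossing. Unmatched true crossovers count as undetected.
#'
#' @param switches Tibble from [detect_switches()].
#' @param truth Truth tibble from [simulate_cross()].
#' @return A tibble of class `lo_switch_match`: the switch rows with
#'   `matched_truth` and `inaccuracy_cM` (NA when unmatched), plus
#'   attributes `n_true`, `n_matched` and `detection_fraction`.
#' @export
match_switches <- function(switches, truth) {
  true_xo <- truth |>
    dplyr::filter(lengths(.data$crossovers) > 0) |>
    dplyr::reframe(
      position = unlist(.data$crossovers),
      direction = {
        # line just before the k-th crossover is the start line toggled k-1 times
        lab <- mapply(function(xo, st) {
          before <- ifelse((seq_along(xo) - 1L) %% 2L == 0L, st, 3L - st)
          ifelse(before == 1L, "1to2", "2to1")
        }, .data$crossovers, .data$start_line, SIMPLIFY = FALSE)
        unlist(lab)
      },
      .by = c("individual", "haplotype")
    )
  sw <- switches
  sw$matched_truth <- NA_real_
  sw$inaccuracy_cM <- NA_real_
  n_matched <- 0L
  if (nrow(sw) > 0 && nrow(true_xo) > 0) {
    keys <- dplyr::distinct(sw[c("individual", "haplotype", "direction")])
    for (r in seq_len(nrow(keys))) {
      si <- which(sw$individual == keys$individual[r] &
                  sw$haplotype == keys$haplotype[r] &
                  sw$direction == keys$direction[r])
      ti <- which(true_xo$individual == keys$individual[r] &
                  true_xo$haplotype == keys$haplotype[r] &
                  true_xo$direction == keys$direction[r])
      if (length(ti) == 0) next
      d <- abs(outer(sw$cross_cM[si], true_xo$position[ti], "-"))
      ord <- order(d)
      used_s <- logical(length(si))
      used_t <- logical(length(ti))
      for (o in ord) {
        a <- (o - 1) %% length(si) + 1
        b <- (o - 1) %/% length(si) + 1
        if (used_s[a] || used_t[b]) next
        used_s[a] <- used_t[b] <- TRUE
        sw$matched_truth[si[a]] <- true_xo$position[ti[b]]
        sw$inaccuracy_cM[si[a]] <- d[a, b]
        n_matched <- n_matched + 1L
      }
    }
  }
  attr(sw, "n_true") <- nrow(true_xo)
  attr(sw, "n_matched") <- n_matched
  attr(sw, "detection_fraction") <-
    if (nrow(true_xo) > 0) n_matched / nrow(true_xo) else NA_real_
  class(sw) <- c("lo_switch_match", class(sw))
  sw
}

#' @rdname match_switches
#' @param x An `lo_switch_match`.
#' @param ... Unused.
#' @method glance lo_switch_match
#' @export
glance.lo_switch_match <- function(x, ...) {
  tibble::tibble(
    n_true = attr(x, "n_true"),
    n_switches = nrow(x),
    n_matched = attr(x, "n_matched"),
    detection_fraction = attr(x, "detection_fraction"),
    mean_imprecision_cM = mean(x$imprecision_cM),
    mean_inaccuracy_cM = mean(x$inaccuracy_cM, na.rm = TRUE)
  )
}

#' @rdname match_switches
#' @param object An `lo_switch_match` (or plain switch tibble).
#' @method autoplot lo_switch_match
#' @export
autoplot.lo_switch_match <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- tidyr::pivot_longer(df, c("imprecision_cM", "inaccuracy_cM"),
                            names_to = "measure", values_to = "cM")
  ggplot2::ggplot(dplyr::filter(df, !is.na(.data$cM)),
                  ggplot2::aes(.data$cM)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = "cM", y = "switches",
                  title = "Recombination-position estimation quality")
}
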