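# Line-origin states are indexed 1..4 in the fixed order
# (mat=1,pat=1), (mat=1,pat=2), (mat=2,pat=1), (mat=2,pat=2).
STATE_MAT <- c(1L, 1L, 2L, 2L)
STATE_PAT <- c(1L, 2L, 1L, 2L)
STATE_LABELS <- c("p11", "p12", "p21", "p22")

# Allele sets are encoded as 2-bit masks: 1 = {0}, 2 = {1}, 3 = {0,1}.
.mask_from_alleles <- function(alleles) {
  sum(unique(alleles) + 1L)
}
.alleles_from_mask <- function(mask) {
  c(0L, 1L)[c(bitwAnd(mask, 1L) > 0, bitwAnd(mask, 2L) > 0)]
}

# Vectorized transmissible-allele masks over markers for one F1 parent.
# pd, g1d, g2d: dosages of the parent, its line-1 founder parent and its
# line-2 founder parent (NA = ungenotyped, imposing no constraint).
# Returns list(line1, line2, consistent): integer masks and a logical flag
# that is FALSE where the parent genotype is Mendelian-inconsistent with both
# allele assignments (sets then fall back to the parent's own alleles).
.transmissible_masks <- function(pd, g1d, g2d) {
  n <- length(pd)
  m1 <- integer(n)
  m2 <- integer(n)
  gp_allows <- function(x, d) is.na(d) | (if (x == 0L) d <= 1L else d >= 1L)
  for (x in 0:1) {
    for (y in 0:1) {
      ok <- (is.na(pd) | pd == x + y) & gp_allows(x, g1d) & gp_allows(y, g2d)
      m1 <- ifelse(ok, bitwOr(m1, x + 1L), m1)
      m2 <- ifelse(ok, bitwOr(m2, y + 1L), m2)
    }
  }
  consistent <- m1 > 0L
  if (any(!consistent)) {
    parent_mask <- c(1L, 3L, 2L)[pd + 1L]
    parent_mask[is.na(pd)] <- 3L
    m1[!consistent] <- parent_mask[!consistent]
    m2[!consistent] <- parent_mask[!consistent]
  }
  list(line1 = m1, line2 = m2, consistent = consistent)
}

#' Alleles an F1 parent can transmit on each line-origin haplotype
#'
#' For one marker, determines which alleles the F1 parent could carry on its
#' line-1-derived and line-2-derived haplotype, by enumerating the two
#' assignments of its alleles to (from line-1 founder, from line-2 founder)
#' and keeping those Mendelian-consistent with the founder genotypes. A
#' missing genotype imposes no constraint. If neither assignment is
#' consistent (a genotyping error), the sets fall back to the parent's own
#' alleles and the result is flagged.
#'
#' @param parent_genotype,grandparent_line1_genotype,grandparent_line2_genotype
#'   Unordered allele pairs as integer vectors like `c(0, 1)`, or `NA` for an
#'   ungenotyped individual.
#' @return A list with sorted integer allele vectors `line1` and `line2` and
#'   logical `consistent`.
#' @examples
#' transmissible_alleles(c(0, 1), c(0, 0), c(1, 1))
#' transmissible_alleles(c(0, 1), c(0, 1), c(0, 0))
#' @export
transmissible_alleles <- function(parent_genotype, grandparent_line1_genotype,
                                  grandparent_line2_genotype) {
  dose <- function(g) {
    if (length(g) == 1 && is.na(g)) return(NA_integer_)
    if (length(g) != 2 || !all(g %in% 0:1)) {
      stop("genotypes must be biallelic pairs of 0/1 alleles or NA", call. = FALSE)
    }
    as.integer(sum(g))
  }
  m <- .transmissible_masks(dose(parent_genotype),
                            dose(grandparent_line1_genotype),
                            dose(grandparent_line2_genotype))
  list(line1 = .alleles_from_mask(m$line1),
       line2 = .alleles_from_mask(m$line2),
       consistent = m$consistent)
}

# Compatibility lookup over (maternal mask, paternal mask, F2 dosage + 1):
# TRUE when the observed unordered genotype can be composed from one allele
# of each set.
.compat_lookup <- function() {
  L <- array(FALSE, dim = c(3, 3, 3))
  for (mm in 1:3) {
    for (fm in 1:3) {
      m0 <- bitwAnd(mm, 1L) > 0; m1 <- bitwAnd(mm, 2L) > 0
      f0 <- bitwAnd(fm, 1L) > 0; f1 <- bitwAnd(fm, 2L) > 0
      L[mm, fm, 1] <- m0 && f0
      L[mm, fm, 2] <- (m0 && f1) || (m1 && f0)
      L[mm, fm, 3] <- m1 && f1
    }
  }
  L
}

# Frequency-weighted lookup: P(F2 genotype | one allele drawn uniformly from
# each set).
.weighted_lookup <- function() {
  W <- array(0, dim = c(3, 3, 3))
  for (mm in 1:3) {
    for (fm in 1:3) {
      ms <- .alleles_from_mask(mm); fs <- .alleles_from_mask(fm)
      pm1 <- mean(ms); pf1 <- mean(fs)
      W[mm, fm, 1] <- (1 - pm1) * (1 - pf1)
      W[mm, fm, 2] <- (1 - pm1) * pf1 + pm1 * (1 - pf1)
      W[mm, fm, 3] <- pm1 * pf1
    }
  }
  W
}

#' Emission probability of an F2 genotype under one line-origin state
#'
#' Compatibility-based emission: 1 when the observed unordered genotype can
#' be composed from one allele of the mother's transmissible set for the
#' state's maternal origin and one of the father's set for its paternal
#' origin; otherwise the error floor, which keeps incompatible states
#' reachable so a genotyping error cannot zero out the truth. A missing F2
#' genotype emits 1 under every state.
#'
#' @param f2_genotype Unordered allele pair `c(x, y)` with alleles in 0/1, or
#'   `NA`.
#' @param mother_sets,father_sets Transmissible-allele sets for the F1 dam and
#'   sire, as returned by [transmissible_alleles()].
#' @param state Integer pair `c(maternal_origin, paternal_origin)`, each 1 or 2.
#' @param error_floor Emission for incompatible states, in (0, 0.5).
#' @param weighted If `TRUE`, use the frequency-weighted emission
#'   P(genotype | state) with alleles drawn uniformly from the transmissible
#'   sets (floored at `error_floor`); default is pure compatibility.
#' @return A single emission value.
#' @examples
#' sets <- transmissible_alleles(c(0, 1), c(0, 0), c(1, 1))
#' emission(c(0, 0), sets, sets, c(1, 1))
#' emission(c(0, 0), sets, sets, c(2, 2))
#' @export
emission <- function(f2_genotype, mother_sets, father_sets, state,
                     error_floor = 0.01, weighted = FALSE) {
  stopifnot(length(state) == 2, all(state %in% 1:2))
  stopifnot(error_floor > 0, error_floor < 0.5)
  if (length(f2_genotype) == 1 && is.na(f2_genotype)) return(1)
  if (length(f2_genotype) != 2 || !all(f2_genotype %in% 0:1)) {
    stop("F2 genotype must be a pair of 0/1 alleles or NA", call. = FALSE)
  }
  g <- sum(f2_genotype)
  mm <- .mask_from_alleles(mother_sets[[paste0("line", state[1])]])
  fm <- .mask_from_alleles(father_sets[[paste0("line", state[2])]])
  if (weighted) {
    max(.weighted_lookup()[mm, fm, g + 1L], error_floor)
  } else {
    if (.compat_lookup()[mm, fm, g + 1L]) 1 else error_floor
  }
}

#' Build the emission table for all F2 individuals
#'
#' Computes, for every F2 individual, marker and line-origin state, the
#' emission probability of the observed genotype. Transmissible-allele sets
#' are computed once per F1 parent from its founder parents' genotypes;
#' supplying parental phase (e.g. from [phase_parent()] or simulator truth)
#' collapses the sets to singletons at phased heterozygous markers, which can
#' only tighten the constraints.
#'
#' @param genotypes An `lo_geno` tibble covering founders, F1s and F2s
#'   (ungenotyped individuals may simply be absent: their genotypes are
#'   treated as missing).
#' @param pedigree An `lo_pedigree`.
#' @param map An `lo_map`; markers define the table rows.
#' @param error_floor,weighted See [emission()].
#' @param parental_phase Optional tibble with columns `id`, `marker_id`,
#'   `line1_allele`, `line2_allele` (NA where unresolved), as produced by
#'   [phase_parent()] or [simulate_cross()].
#' @return An object of class `lo_emission`: a list with the emission array
#'   `E` (4 states x markers x F2 individuals), the marker ids, F2 ids, and a
#'   tibble `inconsistent` flagging parent/marker pairs whose genotypes are
#'   Mendelian-incompatible with the founders (their constraints are relaxed,
#'   not fatal).
#' @export
build_emission_table <- function(genotypes, pedigree, map,
                                 error_floor = 0.01, weighted = FALSE,
                                 parental_phase = NULL) {
  stopifnot(error_floor > 0, error_floor < 0.5)
  dm <- dosage_matrix(genotypes)
  markers <- map$marker_id
  if (!all(markers %in% colnames(dm))) {
    stop("genotype table does not cover all map markers", call. = FALSE)
  }
  dm <- dm[, markers, drop = FALSE]
  dose_of <- function(id) {
    if (id %in% rownames(dm)) dm[id, ] else rep(NA_integer_, length(markers))
  }
  ped_idx <- stats::setNames(seq_len(nrow(pedigree)), pedigree$id)

  f1_ids <- pedigree$id[pedigree$generation == "F1"]
  inconsistent <- list()
  f1_masks <- lapply(f1_ids, function(p) {
    i <- ped_idx[[p]]
    par_ids <- c(pedigree$sire[i], pedigree$dam[i])
    par_lines <- pedigree$line[ped_idx[par_ids]]
    gp1 <- par_ids[par_lines == 1L]
    gp2 <- par_ids[par_lines == 2L]
    m <- .transmissible_masks(dose_of(p), dose_of(gp1), dose_of(gp2))
    if (any(!m$consistent)) {
      inconsistent[[p]] <<- tibble::tibble(id = p, marker_id = markers[!m$consistent])
    }
    if (!is.null(parental_phase)) {
      ph <- parental_phase[parental_phase$id == p, , drop = FALSE]
      ph <- ph[!is.na(ph$line1_allele) & !is.na(ph$line2_allele), , drop = FALSE]
      j <- match(ph$marker_id, markers)
      keep <- !is.na(j)
      m$line1[j[keep]] <- ph$line1_allele[keep] + 1L
      m$line2[j[keep]] <- ph$line2_allele[keep] + 1L
    }
    m
  })
  names(f1_masks) <- f1_ids

  f2_ids <- pedigree$id[pedigree$generation == "F2"]
  if (length(f2_ids) == 0) stop("pedigree contains no F2 individuals", call. = FALSE)
  lookup <- if (weighted) .weighted_lookup() else NULL
  compat <- .compat_lookup()
  nm <- length(markers)
  E <- array(1, dim = c(4L, nm, length(f2_ids)),
             dimnames = list(STATE_LABELS, NULL, f2_ids))
  for (k in seq_along(f2_ids)) {
    i <- ped_idx[[f2_ids[k]]]
    mom <- f1_masks[[pedigree$dam[i]]]
    dad <- f1_masks[[pedigree$sire[i]]]
    g <- dose_of(f2_ids[k])
    obs <- which(!is.na(g))
    if (length(obs) == 0) next
    for (s in 1:4) {
      mmask <- (if (STATE_MAT[s] == 1L) mom$line1 else mom$line2)[obs]
      fmask <- (if (STATE_PAT[s] == 1L) dad$line1 else dad$line2)[obs]
      idx <- cbind(mmask, fmask, g[obs] + 1L)
      E[s, obs, k] <- if (weighted) {
        pmax(lookup[idx], error_floor)
      } else {
        ifelse(compat[idx], 1, error_floor)
      }
    }
  }
  structure(list(
    E = E, marker_id = markers, individuals = f2_ids,
    states = STATE_LABELS, error_floor = error_floor,
    inconsistent = if (length(inconsistent)) dplyr::bind_rows(inconsistent)
                   else tibble::tibble(id = character(), marker_id = character())
  ), class = "lo_emission")
}

#' @export
print.lo_emission <- function(x, ...) {
  cat("<lo_emission> ", length(x$individuals), " F2 individuals x ",
      length(x$marker_id), " markers x 4 line-origin states\n", sep = "")
  if (nrow(x$inconsistent) > 0) {
    cat("  ", nrow(x$inconsistent),
        " Mendelian-inconsistent parent/marker pairs (constraints relaxed)\n",
        sep = "")
  }
  invisible(x)
}

#' Tidy an emission table into a long tibble
#'
#' @param x An `lo_emission` object.
#' @param ... Unused.
#' @return A tibble with columns `individual`, `marker_id`, `state`,
#'   `emission`.
#' @method tidy lo_emission
#' @export
tidy.lo_emission <- function(x, ...) {
  tibble::tibble(
    individual = rep(x$individuals, each = 4L * length(x$marker_id)),
    marker_id = rep(rep(x$marker_id, each = 4L), times = length(x$individuals)),
    state = rep(x$states, times = length(x$marker_id) * length(x$individuals)),
    emission = as.vector(x$E)
  )
}
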