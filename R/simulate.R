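#' Default marker map for simulated intercrosses
#'
#' A single chromosome with markers at a regular spacing, emulating a dense
#' SNP-chip map: by default 0.3 cM spacing over 451 cM, i.e. about 1500
#' markers.
#'
#' @param length_cM Chromosome length in cM.
#' @param spacing_cM Inter-marker spacing in cM.
#' @param chromosome Chromosome label.
#' @return An `lo_map`.
#' @export
sim_map <- function(length_cM = 451, spacing_cM = 0.3, chromosome = "1") {
  pos <- seq(0, length_cM, by = spacing_cM)
  genetic_map(sprintf("M%04d", seq_along(pos)), pos, chromosome,
              length_cM = length_cM)
}

#' Default three-generation intercross pedigree
#'
#' One line-1 grandsire and three line-2 granddams produce the F1
#' generation; F1 sires and dams are intermated to give the F2 mapping
#' population. Defaults reproduce a large poultry-style intercross design:
#' 4 F1 sires, 37 F1 dams, 773 F2 individuals, with F2s assigned to
#' sire x dam pairs round-robin.
#'
#' @param n_sires,n_dams Numbers of F1 males and females.
#' @param n_f2 Number of F2 individuals.
#' @param n_granddams Number of line-2 founder dams shared among the F1s.
#' @return An `lo_pedigree`.
#' @export
sim_pedigree <- function(n_sires = 4, n_dams = 37, n_f2 = 773,
                         n_granddams = 3) {
  gs <- "GS1"
  gd <- sprintf("GD%d", seq_len(n_granddams))
  f1_ids <- c(sprintf("S%d", seq_len(n_sires)), sprintf("D%d", seq_len(n_dams)))
  f1_sex <- c(rep("male", n_sires), rep("female", n_dams))
  f1_dam <- gd[(seq_along(f1_ids) - 1L) %% n_granddams + 1L]
  f2_ids <- sprintf("F2_%03d", seq_len(n_f2))
  f2_sire <- sprintf("S%d", (seq_len(n_f2) - 1L) %% n_sires + 1L)
  f2_dam <- sprintf("D%d", (seq_len(n_f2) - 1L) %% n_dams + 1L)
  as_pedigree(tibble::tibble(
    id = c(gs, gd, f1_ids, f2_ids),
    sire = c(NA, rep(NA, n_granddams), rep(gs, length(f1_ids)), f2_sire),
    dam = c(NA, rep(NA, n_granddams), f1_dam, f2_dam),
    sex = c("male", rep("female", n_granddams), f1_sex, rep("unknown", n_f2)),
    line = c(1L, rep(2L, n_granddams), rep(NA, length(f1_ids)), rep(NA, n_f2))
  ))
}

#' Simulate founder haplotypes
#'
#' Each founder receives two haplotypes whose alleles are drawn
#' independently per marker from its line's allele-1 frequency. By default
#' the per-marker, per-line frequencies themselves are drawn uniformly on
#' (0, 1), which produces the realistic mixture of fully informative,
#' partially informative, and uninformative markers that arises when the
#' same alleles segregate in both lines; there is no within-line linkage
#' disequilibrium under this model.
#'
#' @param map An `lo_map`.
#' @param pedigree An `lo_pedigree` (its founders get haplotypes).
#' @param freq Optional numeric matrix, markers x 2 columns (`line1`,
#'   `line2`), of allele-1 frequencies; default draws them U(0,1).
#' @return A list with `haplotypes` (named list: per founder a 2 x n_markers
#'   0/1 matrix) and the `freq` matrix used. Deterministic given the current
#'   RNG state; seed it with [set.seed()] or use [simulate_cross()].
#' @export
simulate_founders <- function(map, pedigree, freq = NULL) {
  nm <- nrow(map)
  if (is.null(freq)) {
    freq <- cbind(line1 = stats::runif(nm), line2 = stats::runif(nm))
  }
  stopifnot(nrow(freq) == nm, ncol(freq) == 2,
            all(freq >= 0), all(freq <= 1))
  founders <- pedigree[pedigree$generation == "founder", ]
  haps <- lapply(seq_len(nrow(founders)), function(i) {
    q <- freq[, founders$line[i]]
    matrix(as.integer(stats::runif(2L * nm) < rep(q, each = 2L)),
           nrow = 2L, ncol = nm)
  })
  names(haps) <- founders$id
  list(haplotypes = haps, freq = freq)
}

#' Drop one gamete through meiosis
#'
#' Samples a crossover count from Poisson(length in Morgans), places the
#' crossovers independently and uniformly along the chromosome (no
#' interference, matching the Haldane model assumed in inference), picks a
#' starting haplotype at random, and copies alleles from the current
#' haplotype, switching at every crossover.
#'
#' @param parent_haplotypes 2 x n_markers 0/1 matrix (rows = the parent's
#'   two haplotypes).
#' @param map An `lo_map`.
#' @return A list: `gamete` (allele vector over markers), `start_haplotype`
#'   (1 or 2), `crossovers` (sorted positions in cM), and `source`
#'   (which parental haplotype each marker allele came from).
#' @export
drop_gamete <- function(parent_haplotypes, map) {
  stopifnot(nrow(parent_haplotypes) == 2, ncol(parent_haplotypes) == nrow(map))
  L <- map_length(map)
  n_xo <- if (L > 0) stats::rpois(1, L / 100) else 0L
  xo <- if (n_xo > 0) sort(stats::runif(n_xo, 0, L)) else numeric(0)
  start <- sample(1:2, 1)
  source <- hap_at(xo, start, map$position_cM)
  list(
    gamete = parent_haplotypes[cbind(source, seq_len(ncol(parent_haplotypes)))],
    start_haplotype = start,
    crossovers = xo,
    source = source
  )
}

#' Which haplotype (or line) is carried at given positions
#'
#' Given a starting label and sorted crossover positions, returns the label
#' at each query position: the start label where an even number of
#' crossovers lies at or before the position, the other label where odd.
#' Labels alternate between 1 and 2 exactly at the crossovers.
#'
#' @param crossovers Sorted crossover positions (cM).
#' @param start Starting label, 1 or 2.
#' @param positions Query positions (cM).
#' @return Integer vector of labels (1/2) at each query position.
#' @export
hap_at <- function(crossovers, start, positions) {
  n_before <- findInterval(positions, crossovers)
  ifelse(n_before %% 2 == 0, start, 3L - start)
}

#' Simulate a complete three-generation intercross with known truth
#'
#' Generates founder haplotypes, drops gametes founders -> F1 -> F2, and
#' records the ground truth needed for evaluation: for every F2 haplotype,
#' the line origin along the chromosome (the F1 parent's haplotypes carry
#' known line labels, so the meiosis crossovers translate directly into
#' line-origin switch points) and the true parental phase. Optionally
#' injects genotyping errors (random allele flips) and missingness to
#' exercise the inference error floor.
#'
#' @param map An `lo_map`; default [sim_map()].
#' @param pedigree An `lo_pedigree`; default [sim_pedigree()].
#' @param seed Integer seed; required, so every simulated dataset is
#'   reproducible.
#' @param freq Optional markers x 2 allele-frequency matrix, see
#'   [simulate_founders()].
#' @param error_rate Per-allele flip probability (default 0).
#' @param missing_rate Per-genotype missing probability (default 0).
#' @return A list of class `lo_sim`: `genotypes` (`lo_geno`, all
#'   generations), `pedigree`, `map`, `truth` (tibble: `individual`,
#'   `haplotype` = maternal/paternal, `start_line`, list-column `crossovers`
#'   — line origin flips at each crossover), `parental_phase` (true F1 phase
#'   by line origin: `id`, `marker_id`, `line1_allele`, `line2_allele`),
#'   `freq`, and `seed`.
#' @export
simulate_cross <- function(map = sim_map(), pedigree = sim_pedigree(), seed,
                           freq = NULL, error_rate = 0, missing_rate = 0) {
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  set.seed(seed)
  nm <- nrow(map)
  founders <- simulate_founders(map, pedigree, freq)
  haps <- founders$haplotypes
  ped_idx <- stats::setNames(seq_len(nrow(pedigree)), pedigree$id)

  # founder -> F1: each F1 haplotype is a founder gamete; because founders
  # are pure-line, the haplotype's line origin equals that founder's line
  f1_ids <- pedigree$id[pedigree$generation == "F1"]
  f1_hap_line <- list()
  for (id in f1_ids) {
    i <- ped_idx[[id]]
    pat <- drop_gamete(haps[[pedigree$sire[i]]], map)
    mat <- drop_gamete(haps[[pedigree$dam[i]]], map)
    haps[[id]] <- rbind(pat$gamete, mat$gamete)
    f1_hap_line[[id]] <- c(
      pedigree$line[ped_idx[[pedigree$sire[i]]]],
      pedigree$line[ped_idx[[pedigree$dam[i]]]]
    )
  }

  # F1 -> F2: record truth per meiosis
  f2_ids <- pedigree$id[pedigree$generation == "F2"]
  truth <- vector("list", 2L * length(f2_ids))
  for (k in seq_along(f2_ids)) {
    id <- f2_ids[k]
    i <- ped_idx[[id]]
    for (side in c("paternal", "maternal")) {
      parent <- if (side == "paternal") pedigree$sire[i] else pedigree$dam[i]
      g <- drop_gamete(haps[[parent]], map)
      hl <- f1_hap_line[[parent]]
      row <- if (side == "paternal") 1L else 2L
      if (is.null(haps[[id]])) haps[[id]] <- matrix(NA_integer_, 2, nm)
      haps[[id]][row, ] <- g$gamete
      truth[[2L * (k - 1L) + (side == "maternal") + 1L]] <- tibble::tibble(
        individual = id, haplotype = side,
        start_line = hl[g$start_haplotype],
        crossovers = list(g$crossovers)
      )
    }
  }
  truth <- dplyr::bind_rows(truth)

  # true parental phase: F1 haplotype rows reordered by line label
  parental_phase <- dplyr::bind_rows(lapply(f1_ids, function(pid) {
    hl <- f1_hap_line[[pid]]
    tibble::tibble(
      id = pid, marker_id = map$marker_id,
      line1_allele = haps[[pid]][which(hl == 1L), ],
      line2_allele = haps[[pid]][which(hl == 2L), ]
    )
  }))

  dm <- t(vapply(pedigree$id, function(id) as.integer(colSums(haps[[id]])),
                 integer(nm)))
  if (error_rate > 0) {
    # flip one of the two alleles: dosage +1/-1 where possible
    flip <- matrix(stats::runif(length(dm)) < error_rate, nrow(dm))
    up <- flip & dm < 2L & (dm == 0L | stats::runif(length(dm)) < 0.5)
    down <- flip & !up & dm > 0L
    dm[up] <- dm[up] + 1L
    dm[down] <- dm[down] - 1L
  }
  if (missing_rate > 0) {
    dm[matrix(stats::runif(length(dm)) < missing_rate, nrow(dm))] <- NA_integer_
  }
  geno <- tibble::as_tibble(cbind(
    tibble::tibble(id = pedigree$id),
    stats::setNames(as.data.frame(dm), map$marker_id)
  ))
  class(geno) <- c("lo_geno", class(geno))

  structure(list(
    genotypes = geno, pedigree = pedigree, map = map, truth = truth,
    parental_phase = parental_phase, freq = founders$freq, seed = seed
  ), class = "lo_sim")
}

#' @export
print.lo_sim <- function(x, ...) {
  cat("<lo_sim> seed ", x$seed, ": ",
      sum(x$pedigree$generation == "F2"), " F2 x ", nrow(x$map),
      " markers over ", map_length(x$map), " cM; ",
      sum(lengths(x$truth$crossovers)), " F2-meiosis crossovers\n", sep = "")
  invisible(x)
}

#' True line origin of simulated F2 haplotypes at given positions
#'
#' Expands the crossover-based truth tracks from [simulate_cross()] into the
#' line origin at arbitrary positions (piecewise constant, flipping at each
#' crossover of the F1 meiosis).
#'
#' @param truth The `truth` tibble of an `lo_sim`.
#' @param positions Numeric positions (cM).
#' @return A tibble: `individual`, `haplotype`, `position_cM`, `true_line`.
#' @export
truth_origin <- function(truth, positions) {
  blocks <- purrr::pmap(truth, function(individual, haplotype, start_line,
                                        crossovers) {
    tibble::tibble(
      individual = individual, haplotype = haplotype,
      position_cM = positions,
      true_line = hap_at(crossovers, start_line, positions)
    )
  })
  dplyr::bind_rows(blocks)
}

#' Write / read simulator truth tracks
#'
#' Tab-separated columns `individual  haplotype  start_line  crossovers`
#' with crossover positions comma-joined (empty string for none).
#'
#' @param truth Truth tibble from [simulate_cross()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  out <- tibble::tibble(
    individual = truth$individual,
    haplotype = truth$haplotype,
    start_line = truth$start_line,
    crossovers = vapply(truth$crossovers,
                        function(x) paste(sprintf("%.15g", x), collapse = ","),
                        character(1))
  )
  out <- out[order(out$individual, out$haplotype), , drop = FALSE]
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    individual = readr::col_character(), haplotype = readr::col_character(),
    start_line = readr::col_integer(), crossovers = readr::col_character()
  ))
  df$crossovers <- lapply(df$crossovers, function(s) {
    if (is.na(s) || s == "") numeric(0) else as.numeric(strsplit(s, ",")[[1]])
  })
  df
}

#' Phase an F1 parent by grandparental (line) origin
#'
#' Reconstructs which allele of a heterozygous F1 parent sits on its line-1
#' and line-2 haplotype. Step 1 resolves the straightforward markers —
#' homozygous in the parent, or heterozygous with a founder genotype forcing
#' the assignment (singleton transmissible sets). Step 2 takes each
#' remaining heterozygous marker and pairs it with the nearest resolved
#' heterozygous marker: for either candidate phase it counts offspring whose
#' two-marker genotypes cannot be explained without a recombination between
#' the pair, and keeps the phase implying fewer such double-recombinant
#' configurations; ties stay unresolved.
#'
#' @param parent_id Id of an F1 individual.
#' @param genotypes An `lo_geno` covering the parent, its founder parents and
#'   its offspring.
#' @param pedigree An `lo_pedigree`.
#' @param map An `lo_map`.
#' @return A tibble `id`, `marker_id`, `line1_allele`, `line2_allele`,
#'   `resolved_by` (`"homozygous"`, `"mendelian"`, `"linkage"`, or
#'   `"unresolved"`, with NA alleles when unresolved).
#' @export
phase_parent <- function(parent_id, genotypes, pedigree, map) {
  ped_idx <- stats::setNames(seq_len(nrow(pedigree)), pedigree$id)
  if (!parent_id %in% pedigree$id ||
      pedigree$generation[ped_idx[[parent_id]]] != "F1") {
    stop(parent_id, " is not an F1 individual", call. = FALSE)
  }
  dm <- dosage_matrix(genotypes)[, map$marker_id, drop = FALSE]
  dose_of <- function(id) {
    if (id %in% rownames(dm)) dm[id, ] else rep(NA_integer_, nrow(map))
  }
  i <- ped_idx[[parent_id]]
  par_ids <- c(pedigree$sire[i], pedigree$dam[i])
  par_lines <- pedigree$line[ped_idx[par_ids]]
  pd <- dose_of(parent_id)
  masks <- .transmissible_masks(pd, dose_of(par_ids[par_lines == 1L]),
                                dose_of(par_ids[par_lines == 2L]))

  nm <- nrow(map)
  a1 <- rep(NA_integer_, nm)
  a2 <- rep(NA_integer_, nm)
  how <- rep("unresolved", nm)
  hom <- !is.na(pd) & pd != 1L
  a1[hom] <- a2[hom] <- pd[hom] %/% 2L
  how[hom] <- "homozygous"
  het <- !is.na(pd) & pd == 1L
  forced <- het & masks$line1 %in% c(1L, 2L) & masks$line2 %in% c(1L, 2L) &
    masks$consistent
  a1[forced] <- masks$line1[forced] - 1L
  a2[forced] <- masks$line2[forced] - 1L
  how[forced] <- "mendelian"

  # offspring of this parent and the other-parent transmissible alleles
  is_off <- (pedigree$sire == parent_id | pedigree$dam == parent_id) &
    pedigree$generation == "F2"
  off_ids <- pedigree$id[which(is_off)]
  off_ids <- off_ids[off_ids %in% rownames(dm)]
  if (length(off_ids) == 0) {
    warning("no genotyped offspring for ", parent_id,
            "; ambiguous heterozygous markers left unresolved")
    unres <- het & !forced
  } else {
    other_parent <- vapply(off_ids, function(o) {
      j <- ped_idx[[o]]
      if (pedigree$sire[j] == parent_id) pedigree$dam[j] else pedigree$sire[j]
    }, character(1))
    # other parent's possible transmitted alleles as masks (from genotype)
    other_mask <- vapply(other_parent, function(q) {
      d <- dose_of(q)
      mk <- c(1L, 3L, 2L)[d + 1L]
      mk[is.na(d)] <- 3L
      mk
    }, integer(nm))  # markers x offspring
    offg <- t(dm[off_ids, , drop = FALSE])  # markers x offspring

    resolved_het <- function() which(het & !is.na(a1))
    todo <- which(het & is.na(a1))
    # visit ambiguous markers nearest-first to a resolved anchor; newly
    # resolved markers become anchors for the rest
    for (u in todo[order(vapply(todo, function(u) {
      rh <- resolved_het()
      if (length(rh) == 0) Inf else min(abs(map$position_cM[rh] - map$position_cM[u]))
    }, numeric(1)))]) {
      rh <- resolved_het()
      if (length(rh) == 0) break
      v <- rh[which.min(abs(map$position_cM[rh] - map$position_cM[u]))]
      # candidate cis phase: allele a1[v]'s co-inherited allele at u is x
      bad <- vapply(0:1, function(x) {
        # parent haplotypes under this candidate: (x at u with a1[v] at v) on
        # line 1 side; count offspring incompatible without recombination
        h <- rbind(c(x, a1[v]), c(1L - x, a2[v]))
        n_bad <- 0L
        for (o in seq_along(off_ids)) {
          gu <- offg[u, o]; gv <- offg[v, o]
          if (is.na(gu) || is.na(gv)) next
          qmu <- other_mask[u, o]; qmv <- other_mask[v, o]
          ok <- FALSE
          for (hh in 1:2) {
            for (qu in .alleles_from_mask(qmu)) {
              for (qv in .alleles_from_mask(qmv)) {
                if (h[hh, 1] + qu == gu && h[hh, 2] + qv == gv) ok <- TRUE
              }
            }
          }
          if (!ok) n_bad <- n_bad + 1L
        }
        n_bad
      }, integer(1))
      if (bad[1] == bad[2]) next  # tie: leave unresolved
      x <- which.min(bad) - 1L
      a1[u] <- x
      a2[u] <- 1L - x
      how[u] <- "linkage"
    }
  }
  tibble::tibble(id = parent_id, marker_id = map$marker_id,
                 line1_allele = a1, line2_allele = a2, resolved_by = how)
}
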