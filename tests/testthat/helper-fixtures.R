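# Shared fixture builders: everything is generated in code at test time.

# map with auto-named markers at given positions
make_map <- function(positions, length_cM = NULL) {
  genetic_map(sprintf("m%d", seq_along(positions)), positions,
              length_cM = length_cM)
}

# minimal valid three-generation pedigree: two founders per line, two F1s,
# n_f2 offspring of the F1 pair
tiny_pedigree <- function(n_f2 = 1) {
  as_pedigree(tibble::tibble(
    id = c("gs1", "gd1", "gs2", "gd2", "p1", "p2",
           sprintf("x%d", seq_len(n_f2))),
    sire = c(NA, NA, NA, NA, "gs1", "gs2", rep("p1", n_f2)),
    dam = c(NA, NA, NA, NA, "gd1", "gd2", rep("p2", n_f2)),
    sex = c("male", "female", "male", "female", "male", "female",
            rep("unknown", n_f2)),
    line = c(1, 2, 1, 2, NA, NA, rep(NA, n_f2))
  ))
}

# genotype tibble from a named list of dosage vectors
geno_from_dosage <- function(dosages, map) {
  df <- tibble::as_tibble(c(
    list(id = names(dosages)),
    stats::setNames(
      lapply(seq_len(nrow(map)), function(j) {
        vapply(dosages, function(d) d[j], numeric(1))
      }),
      map$marker_id
    )
  ))
  as_genotypes(df, map)
}

# allele-frequency matrix making every marker fully informative
# (line 1 fixed for allele 0, line 2 for allele 1)
informative_freq <- function(map) {
  cbind(line1 = rep(0, nrow(map)), line2 = rep(1, nrow(map)))
}

# random small HMM instance for oracle comparisons: random inter-marker
# distances and a random emission pattern per marker (uninformative, or a
# random non-empty compatible subset with the rest at the error floor)
random_instance <- function(n_markers, eps, rng_distances = c(0.1, 20)) {
  d <- stats::runif(n_markers - 1, rng_distances[1], rng_distances[2])
  map <- make_map(cumsum(c(0, d)))
  E <- matrix(1, n_markers, 4)
  for (p in seq_len(n_markers)) {
    if (stats::runif(1) < 0.25) next  # uninformative position
    compat <- sample(c(TRUE, FALSE), 4, replace = TRUE)
    if (!any(compat)) compat[sample(4, 1)] <- TRUE
    E[p, ] <- ifelse(compat, 1, eps)
  }
  list(map = map, E = E)
}

# hard 0/1 posterior tibble from simulator truth on a grid
hard_posteriors <- function(truth, grid) {
  tr <- truth_origin(truth, grid)
  wide <- tidyr::pivot_wider(tr, names_from = "haplotype",
                             values_from = "true_line")
  tibble::tibble(
    individual = wide$individual,
    position_cM = wide$position_cM,
    p1_maternal = as.numeric(wide$maternal == 1),
    p1_paternal = as.numeric(wide$paternal == 1)
  )
}
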