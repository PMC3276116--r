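eps <- 0.01

test_that("forward table: uniform propagation and single-marker cases", {
  map1 <- make_map(0, length_cM = 20)
  # no informative markers anywhere
  fw <- forward_table(matrix(1, 1, 4), map1, test_positions = c(5, 10, 20))
  expect_true(all(abs(as.matrix(fw[c("a11", "a12", "a21", "a22")]) - 0.25) < 1e-12))
  # single marker with emission (1, e, e, e)
  fw <- forward_table(matrix(c(1, eps, eps, eps), 1, 4), map1)
  e <- c(1, eps, eps, eps)
  expect_equal(unlist(fw[1, c("a11", "a12", "a21", "a22")], use.names = FALSE),
               e / sum(e))
})

test_that("two-marker forward pass matches the hand expansion", {
  map <- make_map(c(0, 10))
  E <- matrix(c(1, eps, eps, eps), 2, 4, byrow = TRUE)
  fw <- forward_table(E, map)
  r <- 0.5 * (1 - exp(-2 * 10 / 100))
  # per-haplotype stay/switch probabilities; state order 11,12,21,22
  t1 <- c(1, eps, eps, eps) / 4            # alpha_1 before scaling
  stay <- 1 - r
  tr <- function(i, j) {  # kernel entry between composite states
    im <- c(1, 1, 2, 2); ip <- c(1, 2, 1, 2)
    (if (im[i] == im[j]) stay else r) * (if (ip[i] == ip[j]) stay else r)
  }
  a2 <- vapply(1:4, function(j) {
    sum(vapply(1:4, function(i) t1[i] * tr(i, j), numeric(1))) *
      c(1, eps, eps, eps)[j]
  }, numeric(1))
  expect_equal(unlist(fw[2, c("a11", "a12", "a21", "a22")], use.names = FALSE),
               a2 / sum(a2), tolerance = 1e-12)
  # unscaled alpha recoverable through log_scale
  expect_equal(fw$a11[2] * exp(fw$log_scale[2]), a2[1], tolerance = 1e-12)
})

test_that("backward table: terminal ones, hand expansion, reversal symmetry", {
  map <- make_map(c(0, 10))
  E <- matrix(c(1, eps, eps, eps), 2, 4, byrow = TRUE)
  bw <- backward_table(E, map)
  expect_equal(unlist(bw[2, c("b11", "b12", "b21", "b22")], use.names = FALSE),
               rep(1, 4))
  r <- 0.5 * (1 - exp(-2 * 10 / 100))
  stay <- 1 - r
  tr <- function(i, j) {
    im <- c(1, 1, 2, 2); ip <- c(1, 2, 1, 2)
    (if (im[i] == im[j]) stay else r) * (if (ip[i] == ip[j]) stay else r)
  }
  b1 <- vapply(1:4, function(i) {
    sum(vapply(1:4, function(j) tr(i, j) * c(1, eps, eps, eps)[j], numeric(1)))
  }, numeric(1))
  expect_equal(unlist(bw[1, c("b11", "b12", "b21", "b22")], use.names = FALSE),
               b1 / max(b1), tolerance = 1e-12)
  # backward on the reversed chromosome equals forward on the original
  set.seed(17)
  inst <- random_instance(6, eps)
  L <- map_length(inst$map)
  rev_map <- make_map(rev(L - inst$map$position_cM))
  rev_E <- inst$E[6:1, ]
  fw <- forward_table(inst$E, inst$map)
  bw_rev <- backward_table(rev_E, rev_map)
  post1 <- posterior_from_tables(fw, backward_table(inst$E, inst$map))
  post2 <- posterior_from_tables(forward_table(rev_E, rev_map), bw_rev)
  expect_equal(as.matrix(post1[c("p11", "p12", "p21", "p22")]),
               as.matrix(post2[6:1, c("p11", "p12", "p21", "p22")]),
               tolerance = 1e-12)
})

test_that("posteriors normalize, and degenerate emissions pin the state", {
  map <- make_map(c(0, 10))
  # uniform emissions everywhere
  E <- matrix(1, 2, 4)
  post <- posterior_from_tables(forward_table(E, map, 5), backward_table(E, map, 5))
  expect_true(all(abs(as.matrix(post[c("p11", "p12", "p21", "p22")]) - 0.25) < 1e-12))
  # error floor 0: posterior exactly 1 for the compatible state at the marker
  E0 <- matrix(c(1, 0, 0, 0), 2, 4, byrow = TRUE)
  post <- posterior_from_tables(forward_table(E0, map, 5), backward_table(E0, map, 5))
  expect_equal(post$p11[post$is_marker], c(1, 1))
  # midpoint between two markers indicating (1,1), 2 cM apart: oracle-exact
  map2 <- make_map(c(0, 2))
  Ei <- matrix(c(1, eps, eps, eps), 2, 4, byrow = TRUE)
  post <- posterior_from_tables(forward_table(Ei, map2, 1), backward_table(Ei, map2, 1))
  oracle <- enumerate_oracle(Ei, map2, 1)
  expect_equal(post$p11, oracle$p11, tolerance = 1e-12)
})

test_that("forward-backward equals exhaustive enumeration on random instances", {
  set.seed(101)
  worst <- 0
  for (k in 1:60) {
    n <- sample(2:8, 1)
    e_floor <- sample(c(0, 0.01, 0.1), 1)
    inst <- random_instance(n, e_floor)
    tp <- sort(runif(2, 0, map_length(inst$map)))
    fb <- posterior_from_tables(forward_table(inst$E, inst$map, tp),
                                backward_table(inst$E, inst$map, tp))
    or <- enumerate_oracle(inst$E, inst$map, tp)
    worst <- max(worst, max(abs(as.matrix(fb[c("p11", "p12", "p21", "p22")]) -
                                as.matrix(or[c("p11", "p12", "p21", "p22")]))))
  }
  expect_lt(worst, 1e-10)
})

test_that("oracle handles trivial cases and refuses big instances", {
  map1 <- make_map(0)
  o <- enumerate_oracle(matrix(c(1, eps, eps, eps), 1, 4), map1)
  e <- c(1, eps, eps, eps)
  expect_equal(unlist(o[1, c("p11", "p12", "p21", "p22")], use.names = FALSE),
               e / sum(e))
  o <- enumerate_oracle(matrix(1, 1, 4), map1)
  expect_equal(o$p11, 0.25)
  big <- make_map(seq(0, 110, by = 10))
  expect_error(enumerate_oracle(matrix(1, 12, 4), big), "limited")
})

test_that("inserting an all-compatible pseudo-marker changes no posterior", {
  set.seed(23)
  for (k in 1:10) {
    inst <- random_instance(6, 0.01)
    tp <- c(3, 11)
    base <- posterior_from_tables(forward_table(inst$E, inst$map, tp),
                                  backward_table(inst$E, inst$map, tp))
    # insert a pseudo-marker at an arbitrary interior coordinate
    at <- runif(1, 0.01, map_length(inst$map) - 0.01)
    pos2 <- sort(c(inst$map$position_cM, at))
    map2 <- make_map(pos2)
    E2 <- matrix(1, 7, 4)
    E2[match(round(inst$map$position_cM, 8), round(pos2, 8)), ] <- inst$E
    aug <- posterior_from_tables(forward_table(E2, map2, tp),
                                 backward_table(E2, map2, tp))
    shared <- match(round(base$position_cM, 8), round(aug$position_cM, 8))
    expect_equal(as.matrix(base[c("p11", "p12", "p21", "p22")]),
                 as.matrix(aug[shared, c("p11", "p12", "p21", "p22")]),
                 tolerance = 1e-12)
  }
})

test_that("swapping line labels permutes posteriors exactly", {
  set.seed(29)
  inst <- random_instance(7, 0.01)
  post <- posterior_from_tables(forward_table(inst$E, inst$map, 5),
                                backward_table(inst$E, inst$map, 5))
  swapped <- posterior_from_tables(forward_table(inst$E[, 4:1], inst$map, 5),
                                   backward_table(inst$E[, 4:1], inst$map, 5))
  expect_equal(as.matrix(post[c("p11", "p12", "p21", "p22")]),
               as.matrix(swapped[c("p22", "p21", "p12", "p11")]),
               ignore_attr = TRUE, tolerance = 1e-14)
})

test_that("with zero floor, certainty at informative markers bounds interior positions", {
  map <- make_map(c(0, 10))
  E0 <- matrix(c(1, 0, 0, 0), 2, 4, byrow = TRUE)
  post <- posterior_from_tables(forward_table(E0, map, seq(0, 10)),
                                backward_table(E0, map, seq(0, 10)))
  at_markers <- post$p11[post$is_marker]
  between <- post$p11[!post$is_marker]
  expect_true(all(min(at_markers) >= between - 1e-15))
})

test_that("scaled recursion stays normalized over long chains", {
  # 10,000 positions with mixed informativeness: scaling must not drift
  set.seed(37)
  n <- 10000
  map <- make_map(cumsum(c(0, runif(n - 1, 0.05, 0.2))))
  E <- matrix(1, n, 4)
  informative <- sample(n, n / 2)
  E[informative, ] <- ifelse(matrix(runif(length(informative) * 4) < 0.5,
                                    ncol = 4), 1, 0.01)
  E[cbind(informative, sample(1:4, length(informative), replace = TRUE))] <- 1
  fw <- forward_table(E, map)
  bw <- backward_table(E, map)
  post <- posterior_from_tables(fw, bw)
  sums <- post$p11 + post$p12 + post$p21 + post$p22
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(is.finite(fw$log_scale)))
})

test_that("infer_line_origin: grid convention, order invariance, per-individual consistency", {
  sim <- simulate_cross(make_map(seq(0, 333, by = 4), length_cM = 333),
                        tiny_pedigree(3), seed = 9)
  post <- infer_line_origin(sim$genotypes, sim$pedigree, sim$map)
  # 1-cM grid on a 333 cM chromosome: 334 test positions
  expect_equal(dplyr::n_distinct(post$position_cM), 334)
  expect_true(all(abs(post$p11 + post$p12 + post$p21 + post$p22 - 1) < 1e-9))
  # shuffling genotype rows changes nothing
  g2 <- sim$genotypes[sample(nrow(sim$genotypes)), ]
  class(g2) <- class(sim$genotypes)
  post2 <- infer_line_origin(g2, sim$pedigree, sim$map)
  expect_equal(as.data.frame(post), as.data.frame(post2))
  # identical to composing the single-individual pipeline
  emis <- build_emission_table(sim$genotypes, sim$pedigree, sim$map)
  k <- 2
  Ek <- t(matrix(emis$E[, , k], nrow = 4))
  grid <- seq(0, 333)
  single <- posterior_from_tables(forward_table(Ek, sim$map, grid),
                                  backward_table(Ek, sim$map, grid))
  single <- single[!single$is_marker | single$position_cM %in% grid, ]
  mine <- post[post$individual == emis$individuals[k], ]
  shared <- match(round(mine$position_cM, 8), round(single$position_cM, 8))
  expect_equal(mine$p11, single$p11[shared], tolerance = 1e-12)
  expect_equal(mine$p1_paternal, single$p1_paternal[shared], tolerance = 1e-12)
})

test_that("work grows linearly with positions: one pass per position, constant state count", {
  set.seed(41)
  inst <- random_instance(5, 0.01)
  fw5 <- forward_table(inst$E, inst$map)
  expect_equal(nrow(fw5), 5)
  # doubling the positions doubles the table rows; the per-row state space
  # is fixed at 4, so total operations are proportional to rows
  tp <- seq(0.5, map_length(inst$map) - 0.5, length.out = 5)
  fw10 <- forward_table(inst$E, inst$map, tp)
  expect_equal(nrow(fw10), 10)
  expect_equal(ncol(fw5), ncol(fw10))
})
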