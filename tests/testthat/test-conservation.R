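test_that("default similarity matrix is a valid unit-diagonal similarity", {
  S <- similarity_matrix()
  expect_equal(dim(S), c(20L, 20L))
  expect_true(all(S >= 0 & S <= 1))
  expect_equal(unname(diag(S)), rep(1, 20))
  expect_equal(S, t(S))
  # similar residues score higher than dissimilar ones
  expect_gt(S["I", "V"], S["I", "D"])
})

test_that("sequence weights follow the evolutionary-distance definition", {
  sim <- similarity_matrix()
  # identical sequences: all distances zero -> uniform fallback
  a <- alignment(c(s1 = "MKVL", s2 = "MKVL", s3 = "MKVL"))
  expect_equal(unname(sequence_weights(a, sim)), rep(1 / 3, 3))

  # maximally dissimilar pair under the identity matrix: both weights 1
  b <- alignment(c(s1 = "AAAA", s2 = "CCCC"))
  expect_equal(unname(sequence_weights(b, identity_sim())), c(1, 1))

  # 3-sequence toy against brute-force pairwise means
  toy <- alignment(c(s1 = "MKV-A", s2 = "MRVLA", s3 = "-KVCA"))
  expect_equal(unname(sequence_weights(toy, sim)), brute_weights(toy, sim),
               tolerance = 1e-12)
  expect_error(sequence_weights(alignment(c(only = "MKV")), sim),
               "at least two")
})

test_that("Valdar score matches hand limits and the brute-force oracle", {
  sim <- similarity_matrix()
  cons <- alignment(c(s1 = "WWW", s2 = "WWW", s3 = "WWW", s4 = "WWW"))
  expect_equal(valdar_score(cons, sim)$values, rep(1, 3))

  # every pair has similarity 0 under the identity matrix
  dis <- alignment(c(s1 = "A", s2 = "C", s3 = "D"))
  expect_equal(valdar_score(dis, identity_sim())$values, 0)

  toy <- random_alignment(4, 6, seed = 21)
  expect_equal(valdar_score(toy, sim)$values, brute_valdar(toy, sim),
               tolerance = 1e-12)
  # and with externally fixed (unweighted) weights
  expect_equal(valdar_score(toy, sim, weights = rep(1, 4))$values,
               brute_valdar(toy, sim, weights = rep(1, 4)),
               tolerance = 1e-12)
})

test_that("Valdar oracle equivalence holds on random gapped alignments", {
  sim <- similarity_matrix()
  for (seed in 1:5) {
    a <- random_alignment(sample(3:8, 1), sample(10:50, 1),
                          gap_prob = 0.15, seed = seed)
    expect_equal(valdar_score(a, sim)$values, brute_valdar(a, sim),
                 tolerance = 1e-10)
  }
})

test_that("majority substitution never decreases the Valdar score", {
  sim <- similarity_matrix()
  set.seed(77)
  for (rep in 1:10) {
    a <- random_alignment(6, 8)
    w <- rep(1, 6)
    v0 <- valdar_score(a, sim, weights = w)$values
    x <- sample(8, 1)
    col <- a$mat[, x]
    maj <- names(which.max(table(col)))
    i <- sample(6, 1)
    b <- a
    b$mat[i, x] <- maj
    v1 <- valdar_score(b, sim, weights = w)$values
    expect_gte(v1[x] + 1e-12, v0[x])
  }
})

test_that("JSD score matches closed forms and respects gap weighting", {
  # column distribution equal to uniform background -> 0 (no smoothing)
  all20 <- stats::setNames(AA20, paste0("s", 1:20))
  a <- alignment(all20)
  expect_equal(jsd_score(a, window_weight = 0)$values, 0, tolerance = 1e-12)

  # all-gap column is zeroed by the residue-fraction multiplier
  g <- alignment(c(s1 = "-A", s2 = "-A", s3 = "-C"))
  expect_equal(jsd_score(g, window_weight = 0)$values[1], 0)

  # point mass vs uniform background: closed-form divergence
  pm <- alignment(c(s1 = "W", s2 = "W", s3 = "W", s4 = "W"))
  m_w <- (1 + 1 / 20) / 2
  m_o <- (0 + 1 / 20) / 2
  kl_p <- log2(1 / m_w)
  kl_q <- (1 / 20) * log2((1 / 20) / m_w) + (19 / 20) * log2((1 / 20) / m_o)
  expected <- 0.5 * kl_p + 0.5 * kl_q
  expect_equal(jsd_score(pm, window_weight = 0)$values, expected,
               tolerance = 1e-12)

  # window smoothing: hand-blend of own and flank means
  b <- alignment(c(s1 = "WAC", s2 = "WCD", s3 = "WDE"))
  raw <- jsd_score(b, window_weight = 0)$values
  sm <- jsd_score(b, window = 1, window_weight = 0.5)$values
  expect_equal(sm[2], 0.5 * raw[2] + 0.5 * mean(raw[c(1, 3)]),
               tolerance = 1e-12)
  expect_equal(sm[1], 0.5 * raw[1] + 0.5 * raw[2], tolerance = 1e-12)

  expect_error(jsd_score(pm, background = rep(1, 20)), "summing to 1")
})

test_that("electrostatic score reproduces the charge-table worked cases", {
  his <- alignment(stats::setNames(rep("H", 10), paste0("s", 1:10)))
  expect_equal(electrostatic_score(his)$values, 0.5)
  asp <- alignment(stats::setNames(rep("D", 10), paste0("s", 1:10)))
  expect_equal(electrostatic_score(asp)$values, -1)
  mix <- alignment(c(s1 = "R", s2 = "R", s3 = "D", s4 = "G"))
  expect_equal(electrostatic_score(mix)$values, 0.25)
  # gaps dilute via the total-sequence denominator
  gappy <- alignment(c(s1 = "K", s2 = "K", s3 = "-", s4 = "-"))
  expect_equal(electrostatic_score(gappy)$values, 0.5)
})

test_that("hydrophobicity score averages the bundled scale over all rows", {
  hs <- hydrophobicity_scale()
  expect_equal(max(hs), 5.39)
  expect_equal(min(hs), -2.20)
  top <- names(which.max(hs))
  full <- alignment(stats::setNames(rep(top, 6), paste0("s", 1:6)))
  expect_equal(hydrophobicity_score(full)$values, 5.39)
  allgap <- alignment(c(s1 = "-A", s2 = "-A"))
  expect_equal(hydrophobicity_score(allgap)$values[1], 0)
  half <- alignment(stats::setNames(c(top, top, "-", "-"), paste0("s", 1:4)))
  expect_equal(hydrophobicity_score(half)$values, 5.39 / 2)
})

test_that("RNA-binding tracks are threaded through gaps and averaged", {
  a1 <- alignment(c(s1 = "MKVLA"))
  tr <- list(s1 = c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(rna_binding_conservation(a1, tr)$values, tr$s1)

  a2 <- alignment(c(s1 = "MKVLA", s2 = "MKVLA"))
  tr2 <- list(s1 = rep(0.2, 5), s2 = rep(0.8, 5))
  expect_equal(rna_binding_conservation(a2, tr2)$values, rep(0.5, 5))

  # gapped toy: hand-computed per-column means over contributing rows
  a3 <- alignment(c(s1 = "MK-A", s2 = "M-VA", s3 = "----"))
  tr3 <- list(s1 = c(1, 2, 4), s2 = c(10, 30, 40), s3 = numeric(0))
  got <- rna_binding_conservation(a3, tr3)$values
  expect_equal(got, c(mean(c(1, 10)), 2, 30, mean(c(4, 40))))

  # no contributing sequence -> undefined marker, excluded by region_mean
  a4 <- alignment(c(s1 = "M-A", s2 = "M-A"))
  tr4 <- list(s1 = c(1, 3), s2 = c(1, 5))
  p4 <- rna_binding_conservation(a4, tr4)
  expect_true(is.na(p4$values[2]))
  expect_equal(p4$values, c(1, NA, 4))
  expect_equal(region_mean(p4, region("all", 1:3)), 2.5)
  expect_error(rna_binding_conservation(a1, list(s1 = c(0.1, 0.2))),
               "length mismatch")
})

test_that("secondary-structure agreement is the modal-state frequency", {
  a <- alignment(c(s1 = "MKV", s2 = "MKV"))
  expect_equal(ss_agreement(a, c(s1 = "HHH", s2 = "HHH"))$values, rep(1, 3))
  p <- ss_agreement(a, c(s1 = "HEC", s2 = "EEC"))
  expect_equal(p$values, c(0.5, 1, 1))
  expect_equal(attr(p, "modal_state"), c("H", "E", "C"))  # tie breaks H < E

  # 5-sequence toy with gaps against a hand count
  b <- alignment(c(s1 = "MK", s2 = "MK", s3 = "M-", s4 = "MK", s5 = "MK"))
  ssb <- c(s1 = "HE", s2 = "HE", s3 = "C", s4 = "HC", s5 = "EE")
  pb <- ss_agreement(b, ssb)
  expect_equal(pb$values, c(3 / 5, 3 / 4))
  expect_error(ss_agreement(a, c(s1 = "HH", s2 = "HHH")), "length mismatch")
  expect_error(ss_agreement(a, c(s1 = "HHZ", s2 = "HHH")), "H/E/C")
})

test_that("bootstrap mean with draws equal to group size is exact", {
  gen <- make_alignment(conservation_spec(12, group_sizes = c(big = 6, small = 3),
                                          seed = 4))
  sim <- similarity_matrix()
  direct <- valdar_score(partition_alignment(gen$alignment, gen$labeling, "big"),
                         sim = sim)
  boot <- bootstrap_group_score(gen$alignment, gen$labeling, "big",
                                n_draws = 6, n_iterations = 5, seed = 1,
                                sim = sim)
  expect_equal(boot$values, direct$values, tolerance = 1e-12)
})

test_that("bootstrap is reproducible and matches exhaustive enumeration", {
  gen <- make_alignment(conservation_spec(
    10, group_sizes = c(big = 6, small = 3),
    conserved_columns = list(list(col = 2, residue = "W", sub_prob = 0.1)),
    seed = 8))
  sim <- similarity_matrix()
  b1 <- bootstrap_group_score(gen$alignment, gen$labeling, "big",
                              n_draws = 3, n_iterations = 1, seed = 99,
                              sim = sim)
  b2 <- bootstrap_group_score(gen$alignment, gen$labeling, "big",
                              n_draws = 3, n_iterations = 1, seed = 99,
                              sim = sim)
  expect_identical(b1$values, b2$values)

  # exhaustive average over all 6-choose-3 sub-alignments
  big <- partition_alignment(gen$alignment, gen$labeling, "big")
  subsets <- utils::combn(aln_ids(big), 3)
  exact <- rowMeans(apply(subsets, 2, function(ids) {
    sa <- big
    sa$mat <- big$mat[ids, , drop = FALSE]
    valdar_score(sa, sim = sim)$values
  }))
  boot <- bootstrap_group_score(gen$alignment, gen$labeling, "big",
                                n_draws = 3, n_iterations = 2000, seed = 5,
                                sim = sim)
  # per-column Monte-Carlo error: sd of the 20 subset scores / sqrt(iters)
  per_subset <- apply(subsets, 2, function(ids) {
    sa <- big
    sa$mat <- big$mat[ids, , drop = FALSE]
    valdar_score(sa, sim = sim)$values
  })
  mc_sd <- apply(per_subset, 1, stats::sd) / sqrt(2000)
  expect_true(all(abs(boot$values - exact) <= pmax(4 * mc_sd, 1e-3)))
  expect_error(bootstrap_group_score(gen$alignment, gen$labeling, "big",
                                     n_draws = 7, n_iterations = 1),
               "exceeds group size")
})

test_that("conservation bias follows the log-ratio definition", {
  b <- conservation_bias(c(0.7, 0.5, 1.0), c(0.7, 0.8, 0.3))
  expect_equal(b$values[1], 1)
  expect_equal(b$values[2], log(0.5) / log(0.8), tolerance = 1e-12)
  expect_equal(b$values[2], 3.106, tolerance = 1e-3)
  # V = 1 is clamped, not divergent
  expect_true(is.finite(b$values[3]) && b$values[3] > 0)
  expect_error(conservation_bias(c(0.5), c(0.5, 0.6)), "length mismatch")
})

test_that("conservation bias is antisymmetric after clamping", {
  set.seed(12)
  a <- runif(50)
  b <- runif(50)
  f <- conservation_bias(a, b)$values
  r <- conservation_bias(b, a)$values
  expect_equal(f * r, rep(1, 50), tolerance = 1e-12)
})

test_that("region means average defined scores over region columns", {
  p <- cons_profile("valdar", c(0.2, 0.4, 0.6, NA, 1.0), c(0, 1))
  expect_equal(region_mean(p, region("one", 3)), 0.6)
  expect_equal(region_mean(p, region("toy", c(1, 2, 3))), 0.4)
  expect_equal(region_mean(p, region("skip", c(3, 4, 5))), 0.8)  # NA excluded
  const <- cons_profile("jsd", rep(0.3, 4), c(0, 1))
  expect_equal(region_mean(const, region("all", 1:4)), 0.3)
  expect_error(region_mean(p, region("empty", integer(0))), "empty region")
  expect_error(region_mean(p, region("undef", 4)), "no defined scores")
  expect_error(region_mean(p, region("oob", 9)), "outside")
})

test_that("profiles are invariant under row reordering", {
  a <- random_alignment(6, 15, gap_prob = 0.1, seed = 31)
  perm <- sample(aln_ids(a))
  b <- a
  b$mat <- a$mat[perm, , drop = FALSE]
  sim <- similarity_matrix()
  expect_equal(valdar_score(b, sim)$values, valdar_score(a, sim)$values,
               tolerance = 1e-12)
  expect_equal(jsd_score(b)$values, jsd_score(a)$values, tolerance = 1e-12)
  expect_equal(electrostatic_score(b)$values, electrostatic_score(a)$values)
  expect_equal(hydrophobicity_score(b)$values, hydrophobicity_score(a)$values)
})

test_that("clade_bias composes bootstrap, direct scoring and the ratio", {
  gen <- make_alignment(conservation_spec(
    20, group_sizes = c(holo = 8, hemi = 4),
    conserved_columns = list(list(col = 3, residue = "W",
                                  sub_prob = c(holo = 0.8, hemi = 0.0))),
    seed = 14))
  res <- clade_bias(gen$alignment, gen$labeling, "holo", "hemi",
                    n_iterations = 50, seed = 2)
  expect_s3_class(res$bias, "cons_profile")
  expect_equal(res$n_draws, 4L)
  expect_length(res$bootstrap_mean_group_score, 20L)
  # hemi fully conserved at col 3, holo mostly substituted: bias >> 1
  expect_gt(res$bias$values[3], 1)
})
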