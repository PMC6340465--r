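test_that("window_dxy matches closed forms and the averaged-Hamming oracle", {
  # identical fixed groups -> 0
  A <- cbind(matrix(1L, 5, 4), matrix(1L, 5, 4))
  h <- toy_hap(A)
  w <- list(start = 0, end = 1000)
  expect_equal(window_dxy(h, h$hap_ids[1:4], h$hap_ids[5:8], w), 0)
  # one fixed difference in 1000 bp -> 0.001
  A2 <- rbind(c(rep(1L, 4), rep(0L, 4)))
  h2 <- toy_hap(A2, pos = 10)
  expect_equal(window_dxy(h2, h2$hap_ids[1:4], h2$hap_ids[5:8], w), 0.001)
  expect_error(window_dxy(h2, character(0), h2$hap_ids[1:4], w), "empty")
  set.seed(303)
  for (i in 1:30) {
    hr <- random_hap(40, 20, miss = 0.1)
    wr <- list(start = 0, end = max(hr$pos))
    ga <- hr$hap_ids[1:10]
    gb <- hr$hap_ids[11:20]
    expect_equal(window_dxy(hr, ga, gb, wr), oracle_dxy(hr, ga, gb, wr),
                 tolerance = 1e-12)
  }
})

test_that("dxy rank test separates introgression from deep coalescence", {
  # identical distributions -> introgression_consistent with p about 0.5
  set.seed(5)
  x <- rnorm(40, 0.02, 0.002)
  r <- ils_vs_introgression_test(x, x)
  expect_equal(r$classification, "introgression_consistent")
  expect_gt(r$p_value, 0.3)
  # clearly elevated SDR divergence -> ils_consistent
  r2 <- ils_vs_introgression_test(x + 0.01, x)
  expect_equal(r2$classification, "ils_consistent")
  expect_lt(r2$p_value, 1e-6)
  expect_equal(r2$mean_difference, 0.01, tolerance = 1e-9)
  expect_error(ils_vs_introgression_test(x[1:3], x), "5 windows")
})

test_that("NG86 handles the canonical single-codon cases", {
  r0 <- ng86_pairwise("TTT", "TTT")
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  expect_equal(r0$N_sites + r0$S_sites, 3)
  # TTT -> TTC: synonymous Phe change
  r1 <- ng86_pairwise("TTT", "TTC")
  expect_equal(r1$Sd, 1)
  expect_equal(r1$Nd, 0)
  expect_equal(r1$S_sites, 1 / 3, tolerance = 1e-12)
  # TTT -> GTT: nonsynonymous Phe -> Val
  r2 <- ng86_pairwise("TTT", "GTT")
  expect_equal(r2$Sd, 0)
  expect_equal(r2$Nd, 1)
  # two-hit codon averaged over both pathways
  r3 <- ng86_pairwise("TTT", "GTC")
  expect_equal(r3$Sd + r3$Nd, 2)
  expect_error(ng86_pairwise("TTT", "TTTAAA"), "mismatch")
  expect_error(ng86_pairwise("TTTA", "TTTA"), "multiple of 3")
})

test_that("NG86 is symmetric and equals the pathway-enumeration oracle", {
  set.seed(404)
  for (i in 1:12) {
    a <- random_cds(40)
    b <- mutate_cds(a, sample(3:15, 1))
    got <- ng86_pairwise(a, b)
    rev <- ng86_pairwise(b, a)
    expect_equal(got$Sd, rev$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, rev$Nd, tolerance = 1e-12)
    expect_equal(got$S_sites, rev$S_sites, tolerance = 1e-12)
    want <- oracle_ng86(a, b)
    expect_equal(got$S_sites, want$S_sites, tolerance = 1e-12)
    expect_equal(got$N_sites, want$N_sites, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
    if (!is.na(want$dS)) expect_equal(got$dS, want$dS, tolerance = 1e-12)
    # sites identity: every codon contributes exactly 3 sites
    expect_equal(got$N_sites + got$S_sites, 3 * got$n_codons_used,
                 tolerance = 1e-12)
  }
})

test_that("private substitutions partition derived variants by group", {
  # groups of 2 haplotypes each; ancestral state all 0
  A <- rbind(
    c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L), # fixed derived in g1 only -> private g1
    c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), # derived in g1 and g2 -> private none
    c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L), # freq 0.5 in g1 -> substitution g1
    c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), # no derived anywhere
    c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L)) # derived everywhere
  ids <- paste0("h", 1:8)
  colnames(A) <- ids
  h <- toy_hap(A, pos = c(10, 20, 30, 40, 50), samples = ids)
  grp <- list(g1 = ids[1:2], g2 = ids[3:4], g3 = ids[5:6], g4 = ids[7:8])
  r <- private_substitutions(h, grp)
  expect_setequal(r$private$g1, c(10, 30))
  expect_length(r$private$g2, 0)
  expect_setequal(r$substitutions$g1, c(10, 20, 30, 50))
  expect_setequal(r$substitutions$g2, c(20, 50))
  # substitutions always contain the private set
  for (g in names(grp)) {
    expect_true(all(r$private[[g]] %in% r$substitutions[[g]]))
  }
})

test_that("simulated mutations are classified consistently with the truth", {
  cfg <- small_config(auto_length = 0, seed = 37)
  sim <- simulate_scenario(cfg)
  md <- sim$metadata
  focal <- sim$hap$chrXII
  ym <- sim$truth$y_map
  ytips <- paste0(names(ym), "_", ym)
  grp <- list(
    tym = resolve_group(focal, md, "tymensis"),
    sin = resolve_group(focal, md, "sinensis"),
    punX = setdiff(resolve_group(focal, md, "pungitius"), ytips),
    punY = ytips)
  w <- sim$windows[sim$windows$label == "SDR", ][1, ]
  r <- private_substitutions(focal, grp, w)
  pos_y <- r$private$punY
  expect_gt(length(pos_y), 0)
  sites <- match(pos_y, focal$pos)
  # the derived allele is absent from every X haplotype and carried by at
  # least half the Y haplotypes (private substitutions need not be fixed)
  X <- focal$alleles[sites, grp$punX, drop = FALSE]
  Y <- focal$alleles[sites, grp$punY, drop = FALSE]
  expect_true(all(X == 0L))
  expect_true(all(rowMeans(Y) >= 0.5))
  # a male whose Y carries the derived allele is heterozygous there
  m <- names(ym)[1]
  a <- focal$alleles[sites, paste0(m, "_A")]
  b <- focal$alleles[sites, paste0(m, "_B")]
  carries <- focal$alleles[sites, paste0(m, "_", ym[m])] == 1L
  expect_true(all((a != b)[carries]))
  # private sets are disjoint between groups
  all_priv <- unlist(r$private)
  expect_equal(anyDuplicated(all_priv), 0L)
  # group consensus at private punY sites never shows derived X alleles
  cons_x <- group_consensus(focal, grp$punX)[sites]
  expect_true(all(cons_x == 0L))
})
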