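test_that("JC distances follow the closed form and matrix properties", {
  # identical haplotypes -> 0; p = 0.0748 -> d = 0.0788
  n <- 10000
  A <- matrix(0L, n, 3)
  k <- round(0.0748 * n)
  A[seq_len(k), 2] <- 1L
  h <- toy_hap(A, samples = c("a", "b", "c"))
  d <- jc_distance_matrix(h)
  expect_equal(d[1, 3], 0)
  expect_equal(d[1, 2], -0.75 * log(1 - 4 * (k / n) / 3), tolerance = 1e-12)
  expect_equal(round(d[1, 2], 4), 0.0788)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 3), colnames(d)))
  # saturated pair capped and flagged
  B <- cbind(rep(0L, 10), rep(1L, 10))
  h2 <- toy_hap(B, samples = c("a", "b"))
  d2 <- jc_distance_matrix(h2, cap = 5)
  expect_equal(d2[1, 2], 5)
  expect_equal(attr(d2, "capped_pairs"), 1)
  # per-bp mode counts monomorphic sequence as identical
  d3 <- jc_distance_matrix(h2, bp = 1000)
  expect_equal(d3[1, 2], -0.75 * log(1 - 4 * 0.01 / 3), tolerance = 1e-12)
})

test_that("NJ recovers additive trees and is order-invariant", {
  # additive distances from a known 4-tip topology ((a,b),(c,d))
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.2          # 0.1 + 0.1
  d["c", "d"] <- d["d", "c"] <- 0.4          # 0.2 + 0.2
  d["a", "c"] <- d["c", "a"] <- 0.1 + 0.3 + 0.2
  d["a", "d"] <- d["d", "a"] <- 0.1 + 0.3 + 0.2
  d["b", "c"] <- d["c", "b"] <- 0.1 + 0.3 + 0.2
  d["b", "d"] <- d["d", "b"] <- 0.1 + 0.3 + 0.2
  tr <- nj_tree(d, outgroup = "d")
  expect_true(ape::is.monophyletic(tr, c("a", "b")))
  # permuted input -> identical topology
  perm <- c(3, 1, 4, 2)
  tr2 <- nj_tree(d[perm, perm], outgroup = "d")
  expect_equal(phangorn::RF.dist(tr, tr2), 0)
  # 3 tips: unique topology, closed-form branch lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- suppressMessages(nj_tree(d3))
  # closed-form pendant lengths 0 / 2 / 3; midpoint rooting splits the
  # longest pendant at the path midpoint (2.5 from each end)
  expect_equal(sort(tr3$edge.length), c(0, 0.5, 2, 2.5), tolerance = 1e-9)
  expect_error(nj_tree(d3[1:2, 1:2]), "3 tips")
  d3[1, 2] <- d3[2, 1] <- Inf
  expect_error(nj_tree(d3), "finite")
})

test_that("xy_consistent detects the male-clade signature with its rules", {
  md <- data.frame(sample_id = c(paste0("m", 1:3), "f1"),
                   species = "pungitius",
                   sex = c("male", "male", "male", "female"))
  t1 <- ape::read.tree(text = "((m1_A,m2_A,m3_A),(m1_B,m2_B,m3_B,f1_A,f1_B));")
  r1 <- xy_consistent(t1, md, "pungitius")
  expect_true(r1$is_consistent)
  expect_setequal(r1$clade_tips, c("m1_A", "m2_A", "m3_A"))
  # both haplotypes of m1 inside the candidate clade -> rule (b) fails
  t2 <- ape::read.tree(text = "((m1_A,m1_B,m2_A,m3_A),(m2_B,m3_B,f1_A,f1_B));")
  expect_false(xy_consistent(t2, md, "pungitius")$is_consistent)
  # clade covering 2 of 3 males passes only when q is relaxed
  t3 <- ape::read.tree(text = "((m1_A,m2_A),((m3_A,f1_A),(m1_B,m2_B,m3_B,f1_B)));")
  expect_false(xy_consistent(t3, md, "pungitius", q = 1)$is_consistent)
  expect_true(xy_consistent(t3, md, "pungitius", q = 0.5)$is_consistent)
  expect_error(xy_consistent(ape::unroot(t1), md, "pungitius"), "rooted")
})

test_that("random within-species coalescent trees are never XY-consistent", {
  md <- data.frame(sample_id = c(paste0("m", 1:5), paste0("f", 1:5)),
                   species = "pungitius",
                   sex = rep(c("male", "female"), each = 5))
  set.seed(2024)
  hits <- 0
  for (i in 1:200) {
    tr <- ape::rcoal(20, tip.label = sample(paste0(md$sample_id,
                                                   rep(c("_A", "_B"), each = 10))))
    if (xy_consistent(tr, md, "pungitius")$is_consistent) hits <- hits + 1
  }
  expect_equal(hits, 0)
})

test_that("topology weights: sorted tree, normalisation, exhaustive = truth", {
  txt <- "(((x1:1,x2:1):1,(y1:1,y2:1):1):1,((s1:1,s2:1):1,(t1:1,t2:1):1):1);"
  tr <- ape::read.tree(text = txt)
  grp <- list(punX = c("x1", "x2"), punY = c("y1", "y2"),
              sin = c("s1", "s2"), tym = c("t1", "t2"))
  tw <- topology_weights(tr, grp)
  expect_true(tw$exhaustive)
  expect_equal(tw$weights, c(1, 0, 0))
  expect_equal(sum(tw$weights), 1, tolerance = 1e-12)
  expect_error(topology_weights(tr, list(c("x1"), c("x1"), c("s1"), c("t1"))),
               "disjoint")
})

test_that("topology weights agree with the ape quartet-pruning oracle", {
  set.seed(31)
  for (rep in 1:5) {
    tr <- ape::rcoal(16, tip.label = paste0("h", 1:16))
    grp <- split(sample(tr$tip.label), rep(1:4, each = 4))
    names(grp) <- c("a", "b", "c", "d")
    tw <- topology_weights(tr, grp)
    expect_true(tw$exhaustive)
    counts <- c(0, 0, 0)
    for (a in grp[[1]]) for (b in grp[[2]]) for (cc in grp[[3]]) {
      for (dd in grp[[4]]) {
        t <- oracle_quartet(tr, a, b, cc, dd)
        if (t > 0) counts[t] <- counts[t] + 1
      }
    }
    expect_equal(tw$weights, counts / sum(counts), tolerance = 1e-12)
  }
})

test_that("Monte-Carlo weights converge to the exhaustive weights", {
  set.seed(55)
  tr <- ape::rcoal(20, tip.label = paste0("h", 1:20))
  grp <- split(tr$tip.label, rep(1:4, each = 5))
  names(grp) <- letters[1:4]
  ex <- topology_weights(tr, grp)
  mc <- topology_weights(tr, grp, max_exhaustive = 1, n_mc = 20000, seed = 8)
  expect_false(mc$exhaustive)
  se <- sqrt(ex$weights * (1 - ex$weights) / 20000)
  expect_true(all(abs(mc$weights - ex$weights) <= 3 * se + 1e-9))
})

test_that("classify_direction recognises both donor topologies", {
  grp <- list(punX = c("X1", "X2"), punY = c("Y1", "Y2"),
              sin = c("sin1", "sin2"), tym = c("tym1", "tym2"))
  # sinensis paraphyletic, Y nested inside
  ta <- ape::read.tree(
    text = "((((sin1,(sin2,(Y1,Y2))),(tym1,tym2)),(X1,X2)),out);")
  expect_equal(classify_direction(ta, grp), "donor_sinensis")
  # pungitius paraphyletic, sinensis nested with the Y
  tb <- ape::read.tree(
    text = "(((((Y1,Y2),(sin1,sin2)),(X1,X2)),(tym1,tym2)),out);")
  expect_equal(classify_direction(tb, grp), "donor_pungitius")
  # intermingled groups -> ambiguous
  tc <- ape::read.tree(text = "(((X1,sin1),(Y1,tym1),(X2,sin2),(Y2,tym2)),out);")
  expect_equal(classify_direction(tc, grp), "ambiguous")
  expect_error(classify_direction(ta, grp[1:3]), "groups")
})
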