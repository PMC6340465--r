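md_phase <- data.frame(
  sample_id = c(paste0("m", 1:4), paste0("f", 1:3), "out"),
  species = c(rep("pungitius", 7), "outgroup"),
  sex = c(rep("male", 4), rep("female", 3), "unknown"))

test_that("window scoring returns Y haplotypes from qualifying male clades", {
  # perfect SDR tree: one haplotype per male in a male-only clade
  t1 <- ape::read.tree(text = paste0(
    "((m1_A,m2_A,m3_A,m4_A),(m1_B,m2_B,m3_B,m4_B,",
    "f1_A,f1_B,f2_A,f2_B,f3_A,f3_B),out_A);"))
  t1 <- ape::root(t1, outgroup = "out_A", resolve.root = TRUE)
  got <- score_window_y_haplotypes(t1, md_phase, "pungitius")
  expect_setequal(got, c("m1_A", "m2_A", "m3_A", "m4_A"))
  # PAR-like tree, X and Y interleaved with females -> empty
  t2 <- ape::read.tree(text = paste0(
    "((m1_A,f1_A),(m2_A,f2_A),(m1_B,f1_B),(m2_B,f2_B),",
    "(m3_A,m3_B),(m4_A,(m4_B,(f3_A,f3_B))),out_A);"))
  t2 <- ape::root(t2, outgroup = "out_A", resolve.root = TRUE)
  expect_length(score_window_y_haplotypes(t2, md_phase, "pungitius"), 0)
  # m3 haplotypes both outside the male clade -> m3 absent, others scored
  t3 <- ape::read.tree(text = paste0(
    "((m1_A,m2_A,m4_A),((m3_A,m3_B),(m1_B,m2_B,m4_B,",
    "f1_A,f1_B,f2_A,f2_B,f3_A,f3_B)),out_A);"))
  t3 <- ape::root(t3, outgroup = "out_A", resolve.root = TRUE)
  got3 <- score_window_y_haplotypes(t3, md_phase, "pungitius", q_min = 0.5)
  expect_setequal(got3, c("m1_A", "m2_A", "m4_A"))
})

test_that("tied disjoint male clades skip the window", {
  t4 <- ape::read.tree(text = paste0(
    "((m1_A,m2_A),((m3_A,m4_A),(m1_B,m2_B,m3_B,m4_B,",
    "f1_A,f1_B,f2_A,f2_B,f3_A,f3_B)),out_A);"))
  t4 <- ape::root(t4, outgroup = "out_A", resolve.root = TRUE)
  expect_length(score_window_y_haplotypes(t4, md_phase, "pungitius",
                                          q_min = 0.5), 0)
})

test_that("voting recovers truth exactly without phase errors", {
  # enlarged PAR so that some windows lie entirely outside the SDR
  cfg <- small_config(auto_length = 0, seed = 13, sdr_start = 2e5,
                      sdr_end = 4e5)
  sim <- simulate_scenario(cfg)
  focal <- sim$hap$chrXII
  asg <- suppressMessages(vote_assign(focal, sim$metadata,
                                      chrom_length = cfg$chrom_length))
  sdr_sites <- which(focal$pos > cfg$sdr_start & focal$pos <= cfg$sdr_end)
  acc <- phasing_accuracy(asg, truth_y_alleles(sim), sdr_sites)
  expect_gt(acc$n_decided, 0.9 * acc$n_het)
  expect_equal(acc$accuracy, 1.0)
  # a site covered by no qualifying window stays missing: het sites
  # covered only by pure-PAR windows receive no Y assignment
  par_sites <- which(focal$pos <= 1e5)
  par_dec <- phasing_accuracy(asg, truth_y_alleles(sim), par_sites)$n_decided
  expect_lt(par_dec / max(1, sum(asg$het[par_sites, ])), 0.05)
  # determinism
  asg2 <- suppressMessages(vote_assign(focal, sim$metadata,
                                       chrom_length = cfg$chrom_length))
  expect_identical(asg$y_allele, asg2$y_allele)
  expect_error(vote_assign(focal, sim$metadata, window_size = 1e5,
                           step = 1e5), "overlap")
})

test_that("a single phase switch is outvoted by overlapping windows", {
  cfg <- small_config(auto_length = 0, seed = 17)
  sim <- simulate_scenario(cfg)
  focal <- sim$hap$chrXII
  # inject one switch in one male in the middle of the SDR by hand
  m <- "pungitius_m01"
  cols <- which(focal$samples == m)
  cut <- which(focal$pos > 9e5)
  A <- focal$alleles
  tmp <- A[cut, cols[1]]
  A[cut, cols[1]] <- A[cut, cols[2]]
  A[cut, cols[2]] <- tmp
  switched <- hap_matrix(focal$chrom, focal$pos, A, focal$hap_ids,
                         focal$samples, anc = focal$anc)
  asg <- suppressMessages(vote_assign(switched, sim$metadata,
                                      chrom_length = cfg$chrom_length))
  sdr_sites <- which(focal$pos > cfg$sdr_start & focal$pos <= cfg$sdr_end)
  acc <- phasing_accuracy(asg, truth_y_alleles(sim), sdr_sites)
  expect_gte(acc$accuracy, 0.999)
})

test_that("complementarity holds at every decided site of rebuilt haplotypes", {
  cfg <- small_config(auto_length = 0, seed = 19,
                      phase_switch_rate = 0.002)
  sim <- simulate_scenario(cfg)
  focal <- sim$hap$chrXII
  asg <- suppressMessages(vote_assign(focal, sim$metadata, window_size = 2e4,
                                      step = 4e3,
                                      chrom_length = cfg$chrom_length))
  reb <- build_xy_groups(focal, sim$metadata, asg)
  for (m in asg$males[1:5]) {
    cols <- which(focal$samples == m)
    a <- focal$alleles[, cols[1]]
    b <- focal$alleles[, cols[2]]
    het <- !is.na(a) & !is.na(b) & a != b
    x <- reb$alleles[, paste0(m, "_X")]
    y <- reb$alleles[, paste0(m, "_Y")]
    dec <- het & !is.na(y)
    # X and Y alleles are complementary and equal the male's two alleles
    expect_true(all(x[dec] + y[dec] == 1L))
    expect_true(all(x[dec] == a[dec] | x[dec] == b[dec]))
    # undecided het sites missing on both; hom sites carry the shared allele
    expect_true(all(is.na(x[het & is.na(y)])))
    hom <- !is.na(a) & !is.na(b) & a == b
    expect_true(all(y[hom] == a[hom]))
  }
  # rebuilt Y group resolves via hap_groups
  expect_length(resolve_group(reb, sim$metadata, "pungitius_Y"), 15)
  expect_length(resolve_group(reb, sim$metadata, "pungitius_X"), 45)
})
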