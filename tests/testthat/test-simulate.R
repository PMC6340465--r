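test_that("scenario config validates its time ordering and rates", {
  expect_error(scenario_config(t_intro = 0.9, t_st = 0.5), "t_intro")
  expect_error(scenario_config(phase_switch_rate = 1), "phase_switch_rate")
  expect_error(scenario_config(scenario = "bogus"))
  cfg <- scenario_config()
  md <- scenario_samples(cfg)
  expect_equal(sum(md$species == "pungitius"), 30)
  expect_equal(sum(md$species == "sinensis"), 20)
  expect_equal(sum(md$species == "tymensis"), 23)
  expect_equal(sum(md$species == "outgroup"), 1)
})

test_that("window genealogies realise the scenario structure", {
  cfg <- small_config()
  md <- scenario_samples(cfg)
  sin <- paste0(rep(md$sample_id[md$species == "sinensis"], each = 2),
                c("_A", "_B"))
  depth_of <- function(ph, tips) {
    nh <- ape::node.depth.edgelength(ph)
    max(nh[seq_len(ape::Ntip(ph))]) - nh[ape::getMRCA(ph, tips)]
  }
  set.seed(1)
  # introgression: MRCA(Y + sinensis) younger than the species split
  gen <- simulate_window_genealogy(cfg, "SDR")
  ph <- genealogy_phylo(gen)
  y <- attr(gen, "y_tips")
  expect_length(y, 15)
  expect_true(ape::is.monophyletic(ph, y))
  expect_lt(depth_of(ph, c(y, sin)), cfg$t_st)
  # ils: MRCA(Y + sinensis) older than the pungitius split
  cfg_ils <- small_config(scenario = "ils")
  gen2 <- simulate_window_genealogy(cfg_ils, "SDR")
  ph2 <- genealogy_phylo(gen2)
  expect_gt(depth_of(ph2, c(attr(gen2, "y_tips"), sin)), cfg$t_pun)
  # autosome window at negligible jitter: every species monophyletic
  cfg0 <- small_config(coal_rate = 1e4)
  gen3 <- simulate_window_genealogy(cfg0, "autosome")
  ph3 <- genealogy_phylo(gen3)
  for (spp in c("pungitius", "sinensis", "tymensis")) {
    tips <- paste0(rep(md$sample_id[md$species == spp], each = 2),
                   c("_A", "_B"))
    expect_true(ape::is.monophyletic(ph3, tips))
  }
  expect_error(simulate_window_genealogy(cfg, "nonsense"), "window_label")
})

test_that("mutation dropping honours rates and infinite sites", {
  cfg <- small_config()
  set.seed(4)
  gen <- simulate_window_genealogy(cfg, "autosome")
  # mu = 0 -> no segregating sites
  h0 <- drop_mutations(gen, 0, 1e4)
  expect_equal(nrow(h0$alleles), 0)
  # all positions unique, ancestral all zero
  h <- drop_mutations(gen, 0.005, 1e4)
  expect_false(anyDuplicated(h$pos) > 0)
  expect_true(all(h$anc == 0))
  # infinite-sites guard
  expect_error(drop_mutations(gen, 5, 100), "infinite-sites")
})

test_that("pairwise divergence matches the branch-length expectation", {
  # two tips separated by total path 2 * t; mean pairwise difference per
  # site over replicates must match within 3 SE (Poisson counts)
  t_div <- 0.4
  mu <- 0.01
  L <- 10000
  two_tip <- list(h = t_div, kids = list(list(h = 0, label = "a_A"),
                                         list(h = 0, label = "b_A")))
  set.seed(11)
  diffs <- replicate(60, {
    h <- drop_mutations(two_tip, mu, L)
    sum(h$alleles[, "a_A"] != h$alleles[, "b_A"]) / L
  })
  expected <- 2 * t_div * mu
  se <- sqrt(expected / L / 60) # Poisson SE of the mean
  expect_lt(abs(mean(diffs) - expected), 3 * se)
})

test_that("default calibration brackets the observed species divergences", {
  cfg <- small_config(seed = 21)
  sim <- simulate_scenario(cfg)
  md <- sim$metadata
  auto <- sim$hap$chrI
  w <- list(start = 0, end = cfg$auto_length)
  d_st <- window_dxy(auto, resolve_group(auto, md, "sinensis"),
                     resolve_group(auto, md, "tymensis"), w)
  d_sp <- window_dxy(auto, resolve_group(auto, md, "sinensis"),
                     resolve_group(auto, md, "pungitius"), w)
  d_out <- window_dxy(auto, resolve_group(auto, md, "pungitius"),
                      resolve_group(auto, md, "outgroup"), w)
  expect_equal(d_st, 0.018, tolerance = 0.15)
  expect_equal(d_sp, 0.025, tolerance = 0.15)
  expect_equal(d_out, 0.126, tolerance = 0.1)
  expect_gt(d_sp, d_st)
})

test_that("phase-error injection is a per-male Markov switch process", {
  md <- data.frame(sample_id = c("m1", "f1"), species = "pungitius",
                   sex = c("male", "female"))
  A <- cbind(m1_A = c(0L, 0L), m1_B = c(1L, 1L), f1_A = c(0L, 1L),
             f1_B = c(1L, 0L))
  h <- toy_hap(A)
  # rate 0 -> identity
  expect_identical(inject_phase_errors(h, 0, md)$alleles, h$alleles)
  # rate ~1 on 2 sites -> alternating assignment, deterministic under seed
  set.seed(1)
  h2 <- inject_phase_errors(h, 0.999999, md)
  expect_equal(unname(h2$alleles[, "m1_A"]), c(1L, 0L))
  expect_equal(unname(h2$alleles[, "m1_B"]), c(0L, 1L))
  # females untouched
  expect_identical(h2$alleles[, c("f1_A", "f1_B")],
                   h$alleles[, c("f1_A", "f1_B")])
  # switch count ~ Binomial(n, rate)
  set.seed(2)
  n <- 1000
  B <- cbind(m1_A = rep(0L, n), m1_B = rep(1L, n), f1_A = rep(0L, n),
             f1_B = rep(1L, n))
  hb <- toy_hap(B)
  counts <- replicate(40, {
    hs <- inject_phase_errors(hb, 0.02, md)
    sum(diff(hs$alleles[, "m1_A"]) != 0) # state changes along the column
  })
  expect_equal(mean(counts), n * 0.02, tolerance = 0.25)
})

test_that("simulated datasets are deterministic and correctly shaped", {
  cfg <- small_config(seed = 31)
  d1 <- tempfile()
  d2 <- tempfile()
  suppressMessages(simulate_dataset(cfg, d1))
  suppressMessages(simulate_dataset(cfg, d2))
  for (f in c("genotypes.vcf", "metadata.tsv", "truth_windows.tsv",
              "truth_y.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  sim <- simulate_scenario(cfg)
  # 2 x (30 + 20 + 23) diploid haplotypes + 1 outgroup haplotype
  expect_equal(ncol(sim$hap$chrXII$alleles), 2 * 73 + 1)
  expect_equal(names(sim$truth$y_map),
               sim$metadata$sample_id[sim$metadata$species == "pungitius" &
                                        sim$metadata$sex == "male"])
  expect_true(all(sim$truth$y_map %in% c("A", "B")))
})
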