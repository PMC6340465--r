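#' Scenario configuration for the coalescent window simulator
#'
#' Defines the study conditions emulated by the generator: three species with
#' topology ((sinensis, tymensis), pungitius), an outgroup carrying the
#' ancestral allele, and a focal (sex) chromosome whose SDR windows follow one
#' of four genealogy scenarios. Times are in coalescent units; the per-site
#' mutation rate is scaled so that autosomal divergences bracket the observed
#' synonymous divergences between the species pairs (about 0.018 for
#' sinensis-tymensis and 0.025 for sinensis-pungitius, and about 0.126 to the
#' outgroup).
#'
#' Scenarios:
#' * `introgression` - the Y lineage is a sinensis lineage that joins the
#'   sinensis coalescent at `t_intro` (Y nested inside sinensis).
#' * `introgression_reverse` - the donated direction is flipped: the sinensis
#'   chromosome derives from the pungitius Y (sinensis nests inside
#'   pungitius).
#' * `ils` - discordance by deep coalescence: the Y lineage coalesces only
#'   above the common ancestor of the whole sample, so its divergence from
#'   every species exceeds the genomic average.
#' * `xy_ancestral` - X and Y diverged before the species splits: the Y
#'   lineage coalesces at the fixed deeper time `t_xy`.
#' * `no_sdr` - every window, including the nominal SDR interval, follows the
#'   species tree (negative control).
#'
#' @param scenario one of "introgression", "introgression_reverse", "ils",
#'   "xy_ancestral", "no_sdr".
#' @param n_pun_m,n_pun_f,n_sin_m,n_sin_f,n_tym_m,n_tym_f diploid sample
#'   counts per species and sex (defaults: the study design of 15/15
#'   pungitius, 11/9 sinensis, 13/10 tymensis).
#' @param chrom_length focal (sex) chromosome length in bp.
#' @param auto_length autosome length in bp (0 = no autosome).
#' @param window_size analysis window size in bp.
#' @param sdr_start,sdr_end SDR interval, default the 3.5-18.9 Mb inversion
#'   breakpoints of a 21-Mb chromosome rescaled to `chrom_length`.
#' @param t_intro time the Y lineage joins the donor lineage.
#' @param t_st sinensis-tymensis split time.
#' @param t_pun pungitius split time from the (sinensis, tymensis) ancestor.
#' @param t_xy X-Y divergence time under `xy_ancestral`.
#' @param t_out time the outgroup tip attaches.
#' @param coal_rate within-population pairwise coalescent rate; its inverse
#'   sets the intraspecific diversity scale (jitter) of the trees.
#' @param coal_rate_y pairwise coalescent rate among Y lineages (large: the Y
#'   is young and of single origin).
#' @param mu mutations per site per coalescent time unit.
#' @param phase_switch_rate per-site haplotype switch probability applied to
#'   every male (simulated phasing error).
#' @param seed integer seed; all window genealogies and mutations derive from
#'   it deterministically.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = "introgression",
                            n_pun_m = 15, n_pun_f = 15,
                            n_sin_m = 11, n_sin_f = 9,
                            n_tym_m = 13, n_tym_f = 10,
                            chrom_length = 2e6, auto_length = 2e6,
                            window_size = 1e5,
                            sdr_start = round(3.5e6 / 21e6 * chrom_length),
                            sdr_end = round(18.9e6 / 21e6 * chrom_length),
                            t_intro = 0.05, t_st = 0.87, t_pun = 1.27,
                            t_xy = 2.5, t_out = 7,
                            coal_rate = 10, coal_rate_y = 100,
                            mu = 0.009, phase_switch_rate = 0,
                            seed = 1) {
  scenario <- match.arg(scenario, c("introgression", "introgression_reverse",
                                    "ils", "xy_ancestral", "no_sdr"))
  stopifnot(t_intro > 0, t_intro < t_st, t_st < t_pun, t_pun < t_out,
            t_xy > t_pun, mu >= 0, coal_rate > 0, coal_rate_y > 0,
            phase_switch_rate >= 0, phase_switch_rate < 1,
            sdr_start >= 0, sdr_end <= chrom_length, sdr_start < sdr_end)
  structure(as.list(environment()), class = "scenario_config")
}

#' Sample metadata implied by a scenario configuration
#' @param config a [scenario_config()].
#' @return metadata data.frame (sample_id, species, sex) including the
#'   haploid outgroup sample `out`.
#' @export
scenario_samples <- function(config) {
  mk <- function(prefix, n, sex) {
    if (n == 0) return(NULL)
    data.frame(sample_id = sprintf("%s%02d", prefix, seq_len(n)),
               species = sub("_.*", "", prefix), sex = sex,
               stringsAsFactors = FALSE)
  }
  md <- rbind(mk("pungitius_m", config$n_pun_m, "male"),
              mk("pungitius_f", config$n_pun_f, "female"),
              mk("sinensis_m", config$n_sin_m, "male"),
              mk("sinensis_f", config$n_sin_f, "female"),
              mk("tymensis_m", config$n_tym_m, "male"),
              mk("tymensis_f", config$n_tym_f, "female"),
              data.frame(sample_id = "out", species = "outgroup",
                         sex = "unknown", stringsAsFactors = FALSE))
  rownames(md) <- NULL
  md
}

# --- genealogy machinery -----------------------------------------------------

.tip <- function(label) list(h = 0, label = label)

.node <- function(h, kids) list(h = h, kids = kids)

# Kingman coalescent on a pool of lineages: pairwise rate `rate`, running from
# t0 until t_end or until a single lineage remains. Returns the surviving pool.
.coalesce <- function(pool, rate, t0, t_end = Inf) {
  t <- t0
  while (length(pool) >= 2L) {
    k <- length(pool)
    w <- stats::rexp(1, rate * k * (k - 1) / 2)
    if (t + w > t_end) return(pool)
    t <- t + w
    pair <- sample.int(k, 2)
    merged <- .node(t, pool[pair])
    pool <- c(pool[-pair], list(merged))
  }
  pool
}

# force-merge a pool into a single lineage at time t (polytomy if > 2)
.merge_at <- function(pool, t) {
  if (length(pool) == 1L) pool[[1]] else .node(t, pool)
}

.genealogy_tips <- function(node) {
  if (!is.null(node$label)) return(node$label)
  unlist(lapply(node$kids, .genealogy_tips), use.names = FALSE)
}

# list of branches: each a list(tips = descendant tip labels, len = length)
.genealogy_branches <- function(root) {
  out <- list()
  walk <- function(node, parent_h) {
    tips <- .genealogy_tips(node)
    if (!is.null(parent_h)) {
      out[[length(out) + 1L]] <<- list(tips = tips, len = parent_h - node$h)
    }
    if (is.null(node$label)) for (k in node$kids) walk(k, node$h)
  }
  walk(root, NULL)
  out
}

#' Convert a simulated genealogy to an ape phylo tree
#' @param gen genealogy returned by [simulate_window_genealogy()].
#' @return a rooted `phylo` object with branch lengths in coalescent units.
#' @export
genealogy_phylo <- function(gen) {
  nwk <- function(node, parent_h) {
    if (!is.null(node$label)) {
      sprintf("%s:%.10f", node$label, parent_h - node$h)
    } else {
      inner <- paste(vapply(node$kids, nwk, "", parent_h = node$h),
                     collapse = ",")
      if (is.null(parent_h)) sprintf("(%s);", inner)
      else sprintf("(%s):%.10f", inner, parent_h - node$h)
    }
  }
  ape::read.tree(text = nwk(gen, NULL))
}

#' Simulate one window genealogy
#'
#' Realises the scenario genealogy for a window: autosome/PAR windows follow
#' the species tree ((sinensis, tymensis), pungitius); SDR windows place the
#' male Y lineages according to the scenario (see [scenario_config()]). The Y
#' lineages always form a single young clade; under `introgression` that clade
#' attaches to a held-out sinensis lineage at `t_intro`, guaranteeing Y
#' haplotypes coalesce inside the sinensis clade.
#'
#' Uses the current RNG state; callers wanting reproducibility should
#' `set.seed()` first (as [simulate_scenario()] does per window).
#'
#' @param config a [scenario_config()].
#' @param window_label "autosome", "PAR" or "SDR".
#' @param y_map named character vector mapping each pungitius male sample id
#'   to "A" or "B" (which haplotype is the Y). Default: "A" for every male.
#' @return a genealogy (nested node list) with tip labels `<sample>_A/_B` and
#'   the haploid outgroup tip `out_A`; attribute `y_tips` gives the Y tip ids
#'   used (SDR scenarios only).
#' @export
simulate_window_genealogy <- function(config, window_label, y_map = NULL) {
  md <- scenario_samples(config)
  haps_of <- function(species) {
    ids <- md$sample_id[md$species == species]
    c(paste0(ids, "_A"), paste0(ids, "_B"))
  }
  pun_haps <- haps_of("pungitius")
  sin_haps <- haps_of("sinensis")
  tym_haps <- haps_of("tymensis")
  males <- md$sample_id[md$species == "pungitius" & md$sex == "male"]
  if (is.null(y_map)) y_map <- stats::setNames(rep("A", length(males)), males)
  scen <- config$scenario
  eff_label <- if (scen == "no_sdr") "autosome" else window_label
  r <- config$coal_rate
  y_tips <- character(0)
  if (eff_label %in% c("autosome", "PAR")) {
    pun_pool <- .coalesce(lapply(pun_haps, .tip), r, 0, config$t_pun)
    sin_pool <- .coalesce(lapply(sin_haps, .tip), r, 0, config$t_st)
    tym_pool <- .coalesce(lapply(tym_haps, .tip), r, 0, config$t_st)
    st_pool <- .coalesce(c(sin_pool, tym_pool), r, config$t_st, config$t_pun)
    all_pool <- .coalesce(c(st_pool, pun_pool), r, config$t_pun,
                          config$t_out * 0.99)
    ingroup <- .merge_at(all_pool, config$t_out * 0.99)
  } else if (eff_label == "SDR") {
    y_tips <- paste0(males, "_", y_map[males])
    x_haps <- setdiff(pun_haps, y_tips)
    y_pool <- .coalesce(lapply(y_tips, .tip), config$coal_rate_y, 0,
                        config$t_intro * 0.999)
    y_lineage <- .merge_at(y_pool, config$t_intro * 0.999)
    if (scen == "introgression") {
      donor <- .tip(sin_haps[1])
      sin_rest <- .coalesce(lapply(sin_haps[-1], .tip), r, 0, config$t_intro)
      yd <- .node(config$t_intro, list(y_lineage, donor))
      sin_pool <- .coalesce(c(sin_rest, list(yd)), r, config$t_intro,
                            config$t_st)
      tym_pool <- .coalesce(lapply(tym_haps, .tip), r, 0, config$t_st)
      pun_pool <- .coalesce(lapply(x_haps, .tip), r, 0, config$t_pun)
      st_pool <- .coalesce(c(sin_pool, tym_pool), r, config$t_st, config$t_pun)
      all_pool <- .coalesce(c(st_pool, pun_pool), r, config$t_pun,
                            config$t_out * 0.99)
    } else if (scen == "introgression_reverse") {
      sin_pool <- .coalesce(lapply(sin_haps, .tip), r, 0,
                            config$t_intro * 0.999)
      sin_lineage <- .merge_at(sin_pool, config$t_intro * 0.999)
      ys <- .node(config$t_intro, list(y_lineage, sin_lineage))
      punx_pool <- .coalesce(lapply(x_haps, .tip), r, 0, config$t_intro)
      pun_pool <- .coalesce(c(punx_pool, list(ys)), r, config$t_intro,
                            config$t_pun)
      tym_pool <- .coalesce(lapply(tym_haps, .tip), r, 0, config$t_pun)
      all_pool <- .coalesce(c(pun_pool, tym_pool), r, config$t_pun,
                            config$t_out * 0.99)
    } else { # ils / xy_ancestral
      pun_pool <- .coalesce(lapply(x_haps, .tip), r, 0, config$t_pun)
      sin_pool <- .coalesce(lapply(sin_haps, .tip), r, 0, config$t_st)
      tym_pool <- .coalesce(lapply(tym_haps, .tip), r, 0, config$t_st)
      st_pool <- .coalesce(c(sin_pool, tym_pool), r, config$t_st, config$t_pun)
      if (scen == "ils") {
        # deep coalescence: the Y lineage fails to coalesce with anything
        # until the whole ancestral sample has found its common ancestor, so
        # Y-versus-anything divergence exceeds the genomic average - the
        # lineage-sorting prediction
        anc_pool <- .coalesce(c(st_pool, pun_pool), r, config$t_pun,
                              config$t_out * 0.95)
        anc <- .merge_at(anc_pool, config$t_out * 0.95)
        all_pool <- .coalesce(list(anc, y_lineage), r, anc$h,
                              config$t_out * 0.99)
      } else {
        anc_pool <- .coalesce(c(st_pool, pun_pool), r, config$t_pun,
                              config$t_xy)
        all_pool <- .coalesce(c(anc_pool, list(y_lineage)), r, config$t_xy,
                              config$t_out * 0.99)
      }
    }
    ingroup <- .merge_at(all_pool, config$t_out * 0.99)
  } else {
    stop("window_label must be autosome, PAR or SDR")
  }
  root <- .node(config$t_out, list(ingroup, .tip("out_A")))
  attr(root, "y_tips") <- y_tips
  root
}

#' Drop mutations on a genealogy (infinite sites within a window)
#'
#' Each branch receives Poisson(`mu` * `length` * branch length) mutations;
#' every mutation occupies a unique position drawn uniformly in the window,
#' and flips the branch's descendant tips to the derived allele. The true
#' ancestral state is 0 at every site.
#'
#' @param gen genealogy from [simulate_window_genealogy()].
#' @param mu mutations per site per coalescent unit.
#' @param length window length in bp.
#' @param window_start 0-based window start (positions are offset by it).
#' @param chrom chromosome name for the result.
#' @return a [hap_matrix()] over the genealogy's tips (zero rows if no
#'   mutation fell in the window).
#' @export
drop_mutations <- function(gen, mu, length, window_start = 0,
                           chrom = "chr") {
  branches <- .genealogy_branches(gen)
  blen <- vapply(branches, function(b) b$len, 0)
  if (any(!is.finite(blen)) || any(blen < 0)) stop("non-finite or negative branch length")
  expected <- mu * length * sum(blen)
  if (expected > length / 2) {
    stop(sprintf("expected mutation count %.0f exceeds half the window length (infinite-sites violated)", expected))
  }
  n_mut <- stats::rpois(base::length(branches), mu * length * blen)
  total <- sum(n_mut)
  tip_labels <- .genealogy_tips(gen)
  samples <- .sample_of_hap(tip_labels)
  if (total == 0L) {
    return(hap_matrix(chrom, integer(0),
                      matrix(integer(0), 0, base::length(tip_labels)),
                      tip_labels, samples))
  }
  offs <- sort(sample.int(length, total)) # distinct 1..length
  # assign positions to branches: branch j owns a random subset of rows
  branch_of <- rep.int(seq_along(branches), n_mut)[sample.int(total)]
  A <- matrix(0L, total, base::length(tip_labels))
  colnames(A) <- tip_labels
  for (j in which(n_mut > 0L)) {
    rows <- which(branch_of == j)
    A[rows, branches[[j]]$tips] <- 1L
  }
  hap_matrix(chrom, window_start + offs, A, tip_labels, samples,
             anc = rep(0L, total))
}

#' Inject haplotype phase-switch errors
#'
#' For each male sample independently, a Markov switch process runs along the
#' site axis: at every site the switch state flips with probability `rate`,
#' and wherever the state is "switched" the two haplotype columns exchange
#' alleles. This emulates statistical-phasing switch errors; the ground truth
#' (which chromosome is the Y) refers to the original, pre-switch columns.
#'
#' @param hap a [hap_matrix()].
#' @param rate per-site switch probability in `[0, 1)`.
#' @param metadata sample metadata identifying the males.
#' @return a [hap_matrix()] with switched male haplotypes.
#' @export
inject_phase_errors <- function(hap, rate, metadata) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(hap)
  males <- metadata$sample_id[metadata$sex == "male"]
  A <- hap$alleles
  n <- nrow(A)
  if (n == 0L) return(hap)
  for (m in males) {
    cols <- which(hap$samples == m)
    if (length(cols) != 2L) next
    state <- cumsum(stats::rbinom(n, 1L, rate)) %% 2L == 1L
    if (!any(state)) next
    tmp <- A[state, cols[1]]
    A[state, cols[1]] <- A[state, cols[2]]
    A[state, cols[2]] <- tmp
  }
  hap$alleles <- A
  hap
}

.window_seed <- function(seed, chrom_tag, index) {
  as.integer((as.numeric(seed) * 1000003 + index * 7919 +
                chrom_tag * 104729) %% 2147483629)
}

#' Simulate a full scenario dataset in memory
#'
#' Windows are simulated independently (no recombination within a window,
#' free recombination between windows, matching the windowed analyses):
#' the focal chromosome `chrXII` with PAR/SDR structure and, if
#' `auto_length > 0`, an autosome `chrI`. Each pungitius male is assigned a
#' Y haplotype (A or B) once, constant along the chromosome. Deterministic
#' under the config seed.
#'
#' @param config a [scenario_config()].
#' @return list with `hap` (named list of [hap_matrix()], post phase-switch),
#'   `hap_original` (pre-switch), `metadata`, `windows` (with truth labels),
#'   `truth` (list: `y_map`, per-window class), `config`.
#' @export
simulate_scenario <- function(config) {
  md <- scenario_samples(config)
  set.seed(config$seed)
  males <- md$sample_id[md$species == "pungitius" & md$sex == "male"]
  y_map <- stats::setNames(sample(c("A", "B"), length(males), replace = TRUE),
                           males)
  chrom_plan <- list()
  if (config$auto_length > 0) {
    w <- make_windows(config$auto_length, config$window_size, chrom = "chrI")
    chrom_plan$chrI <- label_windows(w)
  }
  wX <- make_windows(config$chrom_length, config$window_size, chrom = "chrXII")
  wX <- label_windows(wX, config$sdr_start, config$sdr_end)
  if (config$scenario == "no_sdr") wX$label <- "autosome"
  chrom_plan$chrXII <- wX
  haps <- list()
  for (ci in seq_along(chrom_plan)) {
    wins <- chrom_plan[[ci]]
    chrom <- names(chrom_plan)[ci]
    parts <- vector("list", nrow(wins))
    for (i in seq_len(nrow(wins))) {
      set.seed(.window_seed(config$seed, ci, i))
      gen <- simulate_window_genealogy(config, wins$label[i], y_map)
      parts[[i]] <- drop_mutations(gen, config$mu,
                                   wins$end[i] - wins$start[i],
                                   window_start = wins$start[i],
                                   chrom = chrom)
    }
    pos <- unlist(lapply(parts, function(p) p$pos))
    A <- do.call(rbind, lapply(parts, function(p) {
      p$alleles[, parts[[1]]$hap_ids, drop = FALSE]
    }))
    haps[[chrom]] <- hap_matrix(chrom, pos, A, parts[[1]]$hap_ids,
                                parts[[1]]$samples,
                                anc = rep(0L, length(pos)))
  }
  windows <- do.call(rbind, chrom_plan)
  rownames(windows) <- NULL
  hap_original <- haps
  if (config$phase_switch_rate > 0) {
    for (chrom in names(haps)) {
      set.seed(.window_seed(config$seed, 997, match(chrom, names(haps))))
      haps[[chrom]] <- inject_phase_errors(haps[[chrom]],
                                           config$phase_switch_rate, md)
    }
  }
  list(hap = haps, hap_original = hap_original, metadata = md,
       windows = windows,
       truth = list(y_map = y_map, window_class = windows$label),
       config = config)
}

#' Simulate a scenario and write it to disk
#'
#' Writes `genotypes.vcf` (phased, both chromosomes), `metadata.tsv`,
#' `truth_windows.tsv` (window truth classes) and `truth_y.tsv` (per-male Y
#' haplotype assignment). Byte-identical for identical configs.
#'
#' @param config a [scenario_config()].
#' @param dir output directory (created if needed).
#' @return the in-memory dataset from [simulate_scenario()], invisibly.
#' @export
simulate_dataset <- function(config, dir) {
  sim <- simulate_scenario(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(sim$hap, file.path(dir, "genotypes.vcf"))
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  utils::write.table(sim$windows, file.path(dir, "truth_windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(sim$truth$y_map), y_hap = sim$truth$y_map),
    file.path(dir, "truth_y.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(sim)
}

#' True Y allele per (male, site) from a simulated dataset
#'
#' Looks up the allele carried by each male's true Y chromosome in the
#' pre-switch matrix; this is the reference against which phasing accuracy is
#' measured.
#'
#' @param sim result of [simulate_scenario()].
#' @param chrom chromosome (default the focal chromosome).
#' @return integer matrix (sites x males), colnames = male sample ids.
#' @export
truth_y_alleles <- function(sim, chrom = "chrXII") {
  hap <- sim$hap_original[[chrom]]
  males <- names(sim$truth$y_map)
  cols <- match(paste0(males, "_", sim$truth$y_map), hap$hap_ids)
  m <- hap$alleles[, cols, drop = FALSE]
  colnames(m) <- males
  m
}
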