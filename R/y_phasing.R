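#' Score Y-linked haplotypes from one window's gene tree
#'
#' Male haplotypes are scored as Y-linked when they occur in an exclusively
#' male clade (one haplotype per male, covering at least a fraction `q_min`
#' of the males in the tree), as expected of a single-origin Y. When several
#' disjoint clades qualify the largest wins; a tie between disjoint maximal
#' clades skips the window (empty result).
#'
#' @param tree rooted `phylo` over one window.
#' @param metadata sample metadata.
#' @param focal_species the heterogametic species being phased.
#' @param q_min minimum fraction of males the clade must cover.
#' @return character vector of haplotype ids scored Y (possibly empty).
#' @export
score_window_y_haplotypes <- function(tree, metadata, focal_species,
                                      q_min = 0.5) {
  samp <- .sample_of_hap(tree$tip.label)
  sp <- metadata$species[match(samp, metadata$sample_id)]
  sx <- metadata$sex[match(samp, metadata$sample_id)]
  males <- unique(samp[!is.na(sp) & sp == focal_species & sx == "male"])
  if (length(males) < 2L) return(character(0))
  clades <- .male_clades(tree, metadata, focal_species)
  qual <- Filter(function(tips) {
    length(tips) >= 2L &&
      length(unique(.sample_of_hap(tips))) >= q_min * length(males)
  }, clades)
  if (length(qual) == 0L) return(character(0))
  # maximal qualifying clades (not nested inside another qualifying clade)
  maximal <- qual[!vapply(seq_along(qual), function(i) {
    any(vapply(seq_along(qual), function(j) {
      i != j && all(qual[[i]] %in% qual[[j]])
    }, TRUE))
  }, TRUE)]
  if (length(maximal) == 1L) return(maximal[[1]])
  sizes <- vapply(maximal, length, 0L)
  top <- which(sizes == max(sizes))
  if (length(top) > 1L) return(character(0)) # tie between disjoint clades
  maximal[[top]]
}

#' Assign Y alleles to male heterozygous sites by overlapping-window voting
#'
#' Gene trees are built in overlapping sliding windows (neighbor joining on
#' Jukes-Cantor distances over the focal species plus the outgroup, rooted on
#' the outgroup). In each window whose tree contains a qualifying exclusively
#' male clade, the member haplotypes are scored Y-linked and every
#' heterozygous site of a scored male inside that window receives one vote
#' for the allele carried by the scored haplotype. Because windows overlap,
#' each site is interrogated by several trees; the final Y allele per (male,
#' site) is the majority vote, with ties and unvoted sites left missing.
#' `min_margin` generalises the tie rule into a confidence threshold: a site
#' is decided only when the winning allele leads by at least that many votes
#' (1 = plain majority). Homozygous sites carry the shared allele as both X
#' and Y allele by definition.
#'
#' The window size should be matched to the expected phasing quality: large
#' windows give better-resolved trees, but a haplotype must be switch-free
#' across a window to be scored, so noisy phasing calls for smaller windows
#' (see the package vignette).
#'
#' @param hap a [hap_matrix()] for the focal chromosome.
#' @param metadata sample metadata.
#' @param focal_species species being phased.
#' @param outgroup_sample sample id of the outgroup.
#' @param window_size window size in bp.
#' @param step step between window starts (must be < `window_size`).
#' @param q_min clade male-coverage fraction for scoring.
#' @param min_snps minimum segregating sites (within the focal tip set) for a
#'   window tree to be built.
#' @param min_margin minimum lead of the winning allele for a heterozygous
#'   site to be decided; raise it (with denser window overlap) when phasing
#'   errors are expected.
#' @param region optional 0-based half-open interval restricting the scan.
#' @param chrom_length chromosome length (default: last site position).
#' @return object of class `y_assignment`: list with `positions`, `males`,
#'   `y_allele` (sites x males; 0/1/NA), `votes_y` (votes for the winning
#'   allele), `votes_total`, `n_windows_covering`, and the parameters used.
#' @export
vote_assign <- function(hap, metadata, focal_species = "pungitius",
                        outgroup_sample = "out",
                        window_size = 1e5, step = window_size / 5,
                        q_min = 0.5, min_snps = 10, min_margin = 1,
                        region = NULL, chrom_length = NULL) {
  if (step >= window_size) stop("step must be < window_size (windows must overlap)")
  focal_haps <- resolve_group(hap, metadata, focal_species)
  out_haps <- hap$hap_ids[hap$samples == outgroup_sample]
  if (length(out_haps) == 0L) stop("outgroup sample absent from matrix")
  out_tip <- out_haps[1]
  males <- metadata$sample_id[metadata$species == focal_species &
                                metadata$sex == "male"]
  if (is.null(chrom_length)) chrom_length <- max(hap$pos)
  windows <- make_windows(chrom_length, window_size, step, chrom = hap$chrom)
  if (!is.null(region)) {
    windows <- windows[windows$end > region$start & windows$start < region$end, ]
  }
  tipset <- c(focal_haps, out_tip)
  male_cols <- lapply(males, function(m) which(hap$samples == m))
  names(male_cols) <- males
  n_sites <- nrow(hap$alleles)
  v1 <- matrix(0L, n_sites, length(males), dimnames = list(NULL, males))
  vt <- matrix(0L, n_sites, length(males), dimnames = list(NULL, males))
  ncov <- rep(0L, n_sites)
  # het mask per male (both alleles present and different)
  het <- sapply(males, function(m) {
    cols <- male_cols[[m]]
    a <- hap$alleles[, cols[1]]
    b <- hap$alleles[, cols[2]]
    !is.na(a) & !is.na(b) & a != b
  })
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    sites <- window_sites(hap, w)
    if (length(sites) == 0L) next
    sub <- hap$alleles[sites, match(tipset, hap$hap_ids), drop = FALSE]
    n1 <- rowSums(sub == 1L, na.rm = TRUE)
    n0 <- rowSums(sub == 0L, na.rm = TRUE)
    seg <- which(n1 > 0L & n0 > 0L)
    if (length(seg) < min_snps) next
    d <- tryCatch(
      jc_distance_matrix(hap_subset(hap, sites = sites[seg]), tips = tipset,
                         bp = w$end - w$start - (length(sites) - length(seg))),
      error = function(e) NULL)
    if (is.null(d)) next
    tree <- nj_tree(d, outgroup = out_tip)
    scored <- score_window_y_haplotypes(tree, metadata, focal_species, q_min)
    if (length(scored) == 0L) next
    ncov[sites] <- ncov[sites] + 1L
    for (h in scored) {
      m <- .sample_of_hap(h)
      hs <- sites[het[sites, m]]
      if (length(hs) == 0L) next
      al <- hap$alleles[hs, match(h, hap$hap_ids)]
      v1[hs, m] <- v1[hs, m] + al
      vt[hs, m] <- vt[hs, m] + 1L
    }
  }
  v0 <- vt - v1
  y <- matrix(NA_integer_, n_sites, length(males),
              dimnames = list(NULL, males))
  y[v1 - v0 >= min_margin] <- 1L
  y[v0 - v1 >= min_margin] <- 0L
  # homozygous (or het-undecided) handling: shared allele at hom sites
  for (m in males) {
    cols <- male_cols[[m]]
    a <- hap$alleles[, cols[1]]
    b <- hap$alleles[, cols[2]]
    hom <- !is.na(a) & !is.na(b) & a == b
    y[hom, m] <- a[hom]
  }
  structure(list(positions = hap$pos, males = males, y_allele = y,
                 votes_y = pmax(v1, v0), votes_total = vt,
                 n_windows_covering = ncov, het = het,
                 window_size = window_size, step = step, q_min = q_min,
                 min_margin = min_margin),
            class = "y_assignment")
}

#' @export
#' @method print y_assignment
print.y_assignment <- function(x, ...) {
  dec <- sum(!is.na(x$y_allele) & x$het)
  tot <- sum(x$het)
  cat(sprintf("<y_assignment> %d males, %d sites; %d/%d het sites decided (%.1f%%)\n",
              length(x$males), length(x$positions), dec, tot,
              if (tot > 0) 100 * dec / tot else NA_real_))
  invisible(x)
}

#' Rebuild per-male X and Y haplotypes from a vote assignment
#'
#' For each focal male the Y haplotype carries the voted Y allele at decided
#' heterozygous sites and the shared allele at homozygous sites; the X
#' haplotype carries the complementary allele at decided heterozygous sites.
#' Undecided sites are missing on both. All other haplotypes (females, other
#' species, outgroup) are carried over unchanged. Gametolog group labels are
#' attached: rebuilt Y haplotypes are "Y"; male X and all focal female
#' haplotypes are "X".
#'
#' @param hap the [hap_matrix()] that was phased.
#' @param metadata sample metadata.
#' @param assignment result of [vote_assign()].
#' @param focal_species focal species.
#' @return a [hap_matrix()] with `<male>_X` / `<male>_Y` columns replacing
#'   each focal male's `_A`/`_B` columns, and `hap_groups` labels set.
#' @export
build_xy_groups <- function(hap, metadata, assignment,
                            focal_species = "pungitius") {
  males <- assignment$males
  stopifnot(identical(assignment$positions, hap$pos))
  keep <- !(hap$samples %in% males)
  ids <- hap$hap_ids[keep]
  samples <- hap$samples[keep]
  cols <- lapply(which(keep), function(j) hap$alleles[, j])
  groups <- rep(NA_character_, sum(keep))
  sp <- metadata$species[match(samples, metadata$sample_id)]
  sx <- metadata$sex[match(samples, metadata$sample_id)]
  groups[!is.na(sp) & sp == focal_species & sx == "female"] <- "X"
  for (m in males) {
    mc <- which(hap$samples == m)
    a <- hap$alleles[, mc[1]]
    b <- hap$alleles[, mc[2]]
    het <- !is.na(a) & !is.na(b) & a != b
    yv <- assignment$y_allele[, m]
    ycol <- yv # hom sites already filled with shared allele by vote_assign
    xcol <- yv
    xcol[het] <- 1L - yv[het] # complement at decided het sites (NA stays NA)
    cols <- c(cols, list(xcol, ycol))
    ids <- c(ids, paste0(m, "_X"), paste0(m, "_Y"))
    samples <- c(samples, m, m)
    groups <- c(groups, "X", "Y")
  }
  hap_matrix(hap$chrom, hap$pos, do.call(cbind, cols), ids, samples,
             anc = hap$anc, ref = hap$ref, alt = hap$alt,
             hap_groups = groups)
}

#' Phasing accuracy against simulation truth
#'
#' Fraction of decided heterozygous sites whose voted Y allele matches the
#' allele on the male's true Y chromosome.
#'
#' @param assignment result of [vote_assign()].
#' @param truth matrix from [truth_y_alleles()] (sites x males).
#' @param sites optional site-index subset (e.g. SDR sites only).
#' @return list: `accuracy`, `n_decided`, `n_het`.
#' @export
phasing_accuracy <- function(assignment, truth, sites = NULL) {
  stopifnot(identical(colnames(truth), assignment$males))
  y <- assignment$y_allele
  het <- assignment$het
  if (!is.null(sites)) {
    y <- y[sites, , drop = FALSE]
    het <- het[sites, , drop = FALSE]
    truth <- truth[sites, , drop = FALSE]
  }
  decided <- het & !is.na(y)
  list(accuracy = if (any(decided)) mean(y[decided] == truth[decided]) else NA_real_,
       n_decided = sum(decided), n_het = sum(het))
}
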