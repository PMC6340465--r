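#' Jukes-Cantor distance matrix over a window
#'
#' Pairwise p-distance corrected with `d = -3/4 * log(1 - 4p/3)`. By default
#' p is the mismatch fraction over shared non-missing SNP columns; when `bp`
#' is given (the window length in bp) the denominator is the comparable
#' sequence length instead, i.e. monomorphic positions count as identical -
#' the appropriate metric for window trees with a deeply diverged outgroup,
#' where SNP-only p-distances sit near the correction's saturation point.
#' Pairs with `p >= 0.75` (correction undefined) are capped at `cap` and
#' counted in the `capped_pairs` attribute. Every pair must share at least
#' one comparable site.
#'
#' @param hap a [hap_matrix()].
#' @param window 0-based half-open window, NULL = all sites.
#' @param tips haplotype ids to include.
#' @param cap distance assigned to saturated pairs.
#' @param bp optional window length in bp for per-bp distances.
#' @return symmetric numeric matrix with tip ids as dimnames.
#' @export
jc_distance_matrix <- function(hap, window = NULL, tips = hap$hap_ids,
                               cap = 5, bp = NULL) {
  if (length(tips) == 0L) stop("empty tip set")
  sites <- if (is.null(window)) seq_len(nrow(hap$alleles)) else window_sites(hap, window)
  A <- hap$alleles[sites, match(tips, hap$hap_ids), drop = FALSE]
  M <- !is.na(A)
  A0 <- A
  A0[!M] <- 0L
  storage.mode(A0) <- "double"
  storage.mode(M) <- "double"
  shared <- crossprod(M)
  ones <- A0
  zeros <- (1 - A0) * M
  diff <- crossprod(ones, zeros) + crossprod(zeros, ones)
  if (any(shared == 0)) stop("tip pair(s) share no comparable site")
  denom <- if (is.null(bp)) shared else bp - length(sites) + shared
  p <- diff / denom
  sat <- p >= 0.75
  d <- matrix(cap, nrow(p), ncol(p), dimnames = list(tips, tips))
  d[!sat] <- -0.75 * log(1 - 4 * p[!sat] / 3)
  diag(d) <- 0
  attr(d, "capped_pairs") <- sum(sat[upper.tri(sat)])
  d
}

#' Neighbor-joining gene tree from a distance matrix
#'
#' Tips are ordered lexicographically before agglomeration so the result is
#' deterministic under input permutation; negative NJ branch lengths are
#' clamped to zero. The tree is rooted on the outgroup tip when present,
#' otherwise midpoint-rooted (reported with a message).
#'
#' @param d distance matrix (>= 3 tips, finite entries).
#' @param outgroup outgroup tip label (NULL = midpoint root).
#' @return a rooted `phylo` object.
#' @export
nj_tree <- function(d, outgroup = NULL) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 tips")
  if (any(!is.finite(d))) stop("non-finite distances")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  if (!is.null(outgroup) && outgroup %in% tr$tip.label) {
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  } else {
    if (!is.null(outgroup)) message("nj_tree: outgroup absent, midpoint rooting")
    tr <- phangorn::midpoint(tr)
  }
  tr
}

# all clades (internal nodes) of a rooted tree as tip-label sets
.clade_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, (n_tip + 1):(n_tip + tree$Nnode),
                                type = "tips")
  lapply(desc, function(i) tree$tip.label[i])
}

# clades whose tips are exclusively focal-species male haplotypes, at most one
# haplotype per male; returns list of tip-label vectors
.male_clades <- function(tree, metadata, focal_species) {
  sp <- metadata$species[match(.sample_of_hap(tree$tip.label),
                               metadata$sample_id)]
  sx <- metadata$sex[match(.sample_of_hap(tree$tip.label),
                           metadata$sample_id)]
  is_fm <- !is.na(sp) & sp == focal_species & sx == "male"
  fm_tips <- tree$tip.label[is_fm]
  out <- list()
  for (tips in .clade_tips(tree)) {
    if (!all(tips %in% fm_tips)) next
    samp <- .sample_of_hap(tips)
    if (anyDuplicated(samp)) next
    out[[length(out) + 1L]] <- tips
  }
  out
}

#' Test a gene tree for an XY-consistent topology
#'
#' A rooted gene tree is XY-consistent when it contains a clade whose tips are
#' (a) exclusively focal-species male haplotypes, (b) at most one haplotype
#' per male, and (c) cover at least a fraction `q` of the males present in the
#' tree. With the default strict `q = 1` this is the classical signature of a
#' single-origin Y: one haplotype from every male forms a male-only clade.
#'
#' @param tree rooted `phylo` with haplotype-id tip labels.
#' @param metadata sample metadata.
#' @param focal_species species whose males are examined.
#' @param q minimum fraction of males the clade must cover.
#' @return list: `is_consistent` (logical), `clade_tips` (tips of the largest
#'   qualifying clade, or NULL), `n_males` (males represented in the tree).
#' @export
xy_consistent <- function(tree, metadata, focal_species, q = 1.0) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  samp <- .sample_of_hap(tree$tip.label)
  sp <- metadata$species[match(samp, metadata$sample_id)]
  sx <- metadata$sex[match(samp, metadata$sample_id)]
  males <- unique(samp[!is.na(sp) & sp == focal_species & sx == "male"])
  if (length(males) < 2L) stop("need >= 2 focal males in the tree")
  clades <- .male_clades(tree, metadata, focal_species)
  qual <- Filter(function(tips) {
    length(tips) >= 2L && length(unique(.sample_of_hap(tips))) >= q * length(males)
  }, clades)
  if (length(qual) == 0L) {
    return(list(is_consistent = FALSE, clade_tips = NULL,
                n_males = length(males)))
  }
  sizes <- vapply(qual, length, 0L)
  list(is_consistent = TRUE, clade_tips = qual[[which.max(sizes)]],
       n_males = length(males))
}

# per-tip ancestor chains (tip-to-root node id sequences)
.ancestor_chains <- function(tree) {
  n_tip <- length(tree$tip.label)
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n_tip + 1L
  lapply(seq_len(n_tip), function(tip) {
    chain <- integer(0)
    node <- tip
    while (node != 0L && node != root) {
      node <- parent[node]
      chain <- c(chain, node)
    }
    chain
  })
}

# first shared node of two tip-to-root chains
.chain_mrca <- function(ca, cb) {
  hit <- match(ca, cb)
  ca[which(!is.na(hit))[1]]
}

# quartet topology for tip indices (a, b, c, d) given ancestor chains:
# 1 = ab|cd, 2 = ac|bd, 3 = ad|bc
.quartet_topology <- function(chains, a, b, c, d) {
  ca <- chains[[a]]; cb <- chains[[b]]; cc <- chains[[c]]; cd <- chains[[d]]
  m_ab <- .chain_mrca(ca, cb)
  if (!(m_ab %in% cc) && !(m_ab %in% cd)) return(1L)
  m_cd <- .chain_mrca(cc, cd)
  if (!(m_cd %in% ca) && !(m_cd %in% cb)) return(1L)
  m_ac <- .chain_mrca(ca, cc)
  if (!(m_ac %in% cb) && !(m_ac %in% cd)) return(2L)
  m_bd <- .chain_mrca(cb, cd)
  if (!(m_bd %in% ca) && !(m_bd %in% cc)) return(2L)
  m_ad <- .chain_mrca(ca, cd)
  if (!(m_ad %in% cb) && !(m_ad %in% cc)) return(3L)
  m_bc <- .chain_mrca(cb, cc)
  if (!(m_bc %in% ca) && !(m_bc %in% cd)) return(3L)
  0L # unresolved (possible only with polytomies)
}

#' Quartet topology weights over four groups
#'
#' Samples one tip from each of four disjoint groups (ordered: pungitius X,
#' pungitius Y, sinensis, tymensis in the standard use) and classifies the
#' induced quartet into the three unrooted topologies
#' T1 = (punX,punY)|(sin,tym), T2 = (punX,sin)|(punY,tym),
#' T3 = (punX,tym)|(punY,sin). All combinations are enumerated when the
#' product of group sizes is at most `max_exhaustive`; otherwise `n_mc`
#' Monte-Carlo draws are used.
#'
#' @param tree a `phylo` tree containing all group tips.
#' @param groups list of 4 haplotype-id vectors (disjoint, non-empty).
#' @param max_exhaustive exhaustive-enumeration limit.
#' @param n_mc Monte-Carlo sample size.
#' @param seed optional seed for the Monte-Carlo path.
#' @return list: `weights` (length-3, sums to 1), `n_quartets`, `exhaustive`.
#' @export
topology_weights <- function(tree, groups, max_exhaustive = 10000,
                             n_mc = 1000, seed = NULL) {
  stopifnot(length(groups) == 4L)
  if (any(lengths(groups) == 0L)) stop("empty group")
  all_ids <- unlist(groups)
  if (anyDuplicated(all_ids)) stop("groups must be disjoint")
  idx <- lapply(groups, function(g) {
    i <- match(g, tree$tip.label)
    if (anyNA(i)) stop("group tip(s) absent from tree")
    i
  })
  chains <- .ancestor_chains(tree)
  counts <- c(0, 0, 0)
  n_comb <- prod(lengths(groups))
  exhaustive <- n_comb <= max_exhaustive
  if (exhaustive) {
    for (a in idx[[1]]) for (b in idx[[2]]) for (c in idx[[3]]) {
      for (d in idx[[4]]) {
        t <- .quartet_topology(chains, a, b, c, d)
        if (t > 0L) counts[t] <- counts[t] + 1
      }
    }
    n_used <- n_comb
  } else {
    if (!is.null(seed)) set.seed(seed)
    for (i in seq_len(n_mc)) {
      t <- .quartet_topology(chains,
                             idx[[1]][sample.int(length(idx[[1]]), 1)],
                             idx[[2]][sample.int(length(idx[[2]]), 1)],
                             idx[[3]][sample.int(length(idx[[3]]), 1)],
                             idx[[4]][sample.int(length(idx[[4]]), 1)])
      if (t > 0L) counts[t] <- counts[t] + 1
    }
    n_used <- n_mc
  }
  if (sum(counts) == 0) stop("no resolvable quartets")
  list(weights = counts / sum(counts), n_quartets = n_used,
       exhaustive = exhaustive)
}

#' Classify the direction of introgression from a rooted gene tree
#'
#' `donor_sinensis`: the pungitius Y haplotypes nest inside the sinensis
#' clade - the clade spanned by Y and sinensis tips contains no pungitius-X
#' or tymensis tips and its root is also the MRCA of sinensis alone
#' (sinensis paraphyletic with respect to the Y). `donor_pungitius`: the
#' sinensis haplotypes nest inside pungitius - the clade spanned by the
#' pungitius X and Y contains every sinensis tip, no tymensis tip, and equals
#' the MRCA of pungitius plus sinensis. Anything else is `ambiguous`.
#'
#' @param tree rooted `phylo` (root on the outgroup).
#' @param groups named list with elements `punX`, `punY`, `sin`, `tym` of
#'   haplotype ids present in the tree.
#' @return "donor_sinensis", "donor_pungitius" or "ambiguous".
#' @export
classify_direction <- function(tree, groups) {
  need <- c("punX", "punY", "sin", "tym")
  if (!all(need %in% names(groups))) {
    stop("groups must contain: ", paste(need, collapse = ", "))
  }
  if (any(lengths(groups[need]) == 0L)) stop("empty group")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tips_under <- function(node) {
    n_tip <- length(tree$tip.label)
    if (node <= n_tip) return(tree$tip.label[node])
    tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
  }
  mrca_of <- function(ids) {
    if (length(ids) == 1L) match(ids, tree$tip.label)
    else ape::getMRCA(tree, ids)
  }
  punX <- groups$punX; punY <- groups$punY
  sin <- groups$sin; tym <- groups$tym
  m_ys <- mrca_of(c(punY, sin))
  under_ys <- tips_under(m_ys)
  cond_a <- !any(punX %in% under_ys) && !any(tym %in% under_ys) &&
    identical(m_ys, mrca_of(sin))
  m_pun <- mrca_of(c(punX, punY))
  under_pun <- tips_under(m_pun)
  cond_b <- all(sin %in% under_pun) && !any(tym %in% under_pun) &&
    identical(m_pun, mrca_of(c(punX, punY, sin)))
  if (cond_a && cond_b) {
    # both nestings hold locally (Y inside the sinensis radiation, which in
    # turn sits inside pungitius); what is sister to the (Y, sin) clade
    # decides: tymensis under donor_sinensis, the pungitius X under
    # donor_pungitius
    under_yst <- tips_under(mrca_of(c(punY, sin, tym)))
    return(if (!any(punX %in% under_yst)) "donor_sinensis"
           else "donor_pungitius")
  }
  if (cond_a) return("donor_sinensis")
  if (cond_b) return("donor_pungitius")
  "ambiguous"
}
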