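#' Absolute divergence d_xy for one window
#'
#' `sum over sites of pA (1 - pB) + pB (1 - pA)` divided by the window length
#' in bp, where pA and pB are allele-1 frequencies among genotyped haplotypes
#' of each group. Sites need at least `min_n` genotyped haplotypes per group
#' to contribute.
#'
#' @param hap a [hap_matrix()].
#' @param group_a,group_b haplotype id vectors (non-empty).
#' @param window 0-based half-open window (required: defines the bp
#'   denominator).
#' @param min_n minimum genotyped haplotypes per group per site (default 1;
#'   a single haplotype carries a valid allele for divergence).
#' @return per-site divergence.
#' @export
window_dxy <- function(hap, group_a, group_b, window, min_n = 1) {
  if (length(group_a) == 0L || length(group_b) == 0L) stop("empty group")
  sites <- window_sites(hap, window)
  ca <- .site_counts(hap, match(group_a, hap$hap_ids), sites)
  cb <- .site_counts(hap, match(group_b, hap$hap_ids), sites)
  ok <- ca$n >= min_n & cb$n >= min_n
  pa <- ca$n1[ok] / ca$n[ok]
  pb <- cb$n1[ok] / cb$n[ok]
  sum(pa * (1 - pb) + pb * (1 - pa)) / (window$end - window$start)
}

#' Discriminate introgression from incomplete lineage sorting
#'
#' Under ILS the focal-region (Y-versus-donor) divergence should exceed the
#' genomic average, because the shared ancestry predates the species split;
#' under introgression it should not. A one-sided rank test (Wilcoxon) of
#' SDR > autosome decides: significant at `alpha` gives `ils_consistent`,
#' otherwise `introgression_consistent`.
#'
#' @param dxy_sdr per-window d_xy values for Y-vs-donor over SDR windows.
#' @param dxy_auto per-window d_xy values for the species pair over autosomal
#'   windows.
#' @param alpha significance level.
#' @return list: `classification`, `p_value` (one-sided), `mean_difference`
#'   (SDR mean minus autosomal mean).
#' @export
ils_vs_introgression_test <- function(dxy_sdr, dxy_auto, alpha = 0.05) {
  dxy_sdr <- dxy_sdr[!is.na(dxy_sdr)]
  dxy_auto <- dxy_auto[!is.na(dxy_auto)]
  if (length(dxy_sdr) < 5L || length(dxy_auto) < 5L) {
    stop("need at least 5 windows per set")
  }
  p <- stats::wilcox.test(dxy_sdr, dxy_auto, alternative = "greater",
                          exact = FALSE)$p.value
  list(classification = if (p < alpha) "ils_consistent" else "introgression_consistent",
       p_value = p,
       mean_difference = mean(dxy_sdr) - mean(dxy_auto))
}

# --- Nei-Gojobori (1986) pairwise dN/dS -------------------------------------

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

# fraction of synonymous sites per codon (changes to stop codons count as
# nonsynonymous, so every codon contributes exactly 3 sites)
.syn_sites_codon <- function(codon, code) {
  aa <- code[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (!is.na(code[alt]) && code[[alt]] == aa && code[[alt]] != "*") {
        s <- s + 1 / 3
      }
    }
  }
  s
}

# synonymous/nonsynonymous difference counts between two codons, averaged with
# equal weight over all minimal mutational pathways; pathways through stop
# codons are excluded (unless every pathway hits one, in which case all are
# used)
.codon_path_diffs <- function(ca, cb, code) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(S = 0, N = 0))
  perms <- if (k == 1L) list(pos) else
    if (k == 2L) list(pos, rev(pos)) else
      list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
           pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  score_path <- function(order) {
    cur <- ca
    s <- 0; n <- 0; hit_stop <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (code[[nxt]] == "*" && nxt != cb) hit_stop <- TRUE
      if (code[[cur]] == code[[nxt]] && code[[nxt]] != "*") s <- s + 1
      else n <- n + 1
      cur <- nxt
    }
    c(S = s, N = n, stop = as.numeric(hit_stop))
  }
  scores <- vapply(perms, score_path, c(S = 0, N = 0, stop = 0))
  ok <- scores["stop", ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(scores))
  c(S = mean(scores["S", ok]), N = mean(scores["N", ok]))
}

#' Nei-Gojobori (1986) pairwise dN/dS
#'
#' Synonymous and nonsynonymous site counts are averaged over the two
#' sequences; difference counts at multi-hit codons are averaged with equal
#' weight over all minimal mutational pathways (pathways through stop codons
#' excluded). Proportions are Jukes-Cantor corrected,
#' `d = -3/4 log(1 - 4p/3)`; a proportion at or beyond 3/4 yields NA with a
#' `saturated` flag. Codons containing gaps, ambiguity codes or stops are
#' skipped.
#'
#' @param cds_a,cds_b in-frame coding sequences (character strings of equal
#'   length, a multiple of 3).
#' @return list: `N_sites`, `S_sites`, `Nd`, `Sd`, `pN`, `pS`, `dN`, `dS`,
#'   `dNdS` (NA when `dS` is 0 or saturated), `n_codons_used`, `saturated`.
#' @export
ng86_pairwise <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a)
  cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) stop("sequence length mismatch")
  if (nchar(cds_a) %% 3 != 0) stop("length must be a multiple of 3")
  code <- .codon_table()
  n_codons <- nchar(cds_a) / 3
  S_sites <- 0; N_sites <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (i in seq_len(n_codons)) {
    ca <- substr(cds_a, 3 * i - 2, 3 * i)
    cb <- substr(cds_b, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    if (code[[ca]] == "*" || code[[cb]] == "*") next
    sa <- .syn_sites_codon(ca, code)
    sb <- .syn_sites_codon(cb, code)
    S_sites <- S_sites + (sa + sb) / 2
    N_sites <- N_sites + 3 - (sa + sb) / 2
    dd <- .codon_path_diffs(ca, cb, code)
    Sd <- Sd + dd[["S"]]
    Nd <- Nd + dd[["N"]]
    used <- used + 1
  }
  pS <- if (S_sites > 0) Sd / S_sites else NA_real_
  pN <- if (N_sites > 0) Nd / N_sites else NA_real_
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS)
  dN <- jc(pN)
  saturated <- (!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)
  list(N_sites = N_sites, S_sites = S_sites, Nd = Nd, Sd = Sd,
       pN = pN, pS = pS, dN = dN, dS = dS,
       dNdS = if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_,
       n_codons_used = used, saturated = saturated)
}

#' Per-group substitution and private-substitution site lists
#'
#' A site is a substitution for a group when the derived allele (relative to
#' the matrix's ancestral state) reaches frequency >= 0.5 among the group's
#' genotyped haplotypes; it is private to the group when, additionally, the
#' derived allele is entirely absent (frequency 0) from every other group.
#' Sites where any other group is completely ungenotyped cannot be judged
#' private and are excluded from the private lists.
#'
#' @param hap a [hap_matrix()].
#' @param groups named list of haplotype-id vectors (e.g. tym, sin, punX,
#'   punY).
#' @param window optional 0-based half-open window.
#' @return list with elements `substitutions` and `private`, each a named
#'   list of position vectors per group.
#' @export
private_substitutions <- function(hap, groups, window = NULL) {
  sites <- if (is.null(window)) seq_len(nrow(hap$alleles)) else window_sites(hap, window)
  freqs <- lapply(groups, function(g) {
    dc <- .derived_counts(hap, match(g, hap$hap_ids), sites)
    list(f = ifelse(dc$n > 0, dc$nd / dc$n, NA_real_), n = dc$n)
  })
  pos <- hap$pos[sites]
  subs <- lapply(freqs, function(fr) pos[!is.na(fr$f) & fr$f >= 0.5])
  priv <- lapply(seq_along(groups), function(i) {
    is_sub <- !is.na(freqs[[i]]$f) & freqs[[i]]$f >= 0.5
    others_zero <- rep(TRUE, length(pos))
    for (j in seq_along(groups)[-i]) {
      others_zero <- others_zero & !is.na(freqs[[j]]$f) & freqs[[j]]$f == 0
    }
    pos[is_sub & others_zero]
  })
  names(priv) <- names(groups)
  list(substitutions = subs, private = priv)
}

#' Majority-consensus sequence of a haplotype group
#'
#' Per site, the most frequent allele among genotyped haplotypes (ties broken
#' toward the ancestral state); used as the group representative in coding
#' comparisons.
#'
#' @param hap a [hap_matrix()].
#' @param group haplotype ids.
#' @return integer vector (0/1/NA) of length `nrow(hap$alleles)`.
#' @export
group_consensus <- function(hap, group) {
  cc <- .site_counts(hap, match(group, hap$hap_ids))
  out <- rep(NA_integer_, length(cc$n))
  has <- cc$n > 0
  p <- cc$n1[has] / cc$n[has]
  cons <- ifelse(p > 0.5, 1L, ifelse(p < 0.5, 0L, hap$anc[has]))
  out[has] <- cons
  out
}
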