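#' Per-site ABBA/BABA pattern components
#'
#' Given derived-allele frequencies `p1..p4` in the ordered populations
#' (P1, P2, P3, O):
#' `abba = (1-p1) p2 p3 (1-p4)`, `baba = p1 (1-p2) p3 (1-p4)`, and the
#' dynamic-donor denominators `abba_d`, `baba_d` obtained by replacing both
#' p2 and p3 with `p_d = max(p2, p3)`.
#'
#' @param p1,p2,p3,p4 derived-allele frequencies in `[0, 1]`.
#' @return list with `abba`, `baba`, `abba_d`, `baba_d`, `p_d` (vectorised).
#' @export
site_pattern <- function(p1, p2, p3, p4) {
  stopifnot(all(c(p1, p2, p3, p4) >= 0), all(c(p1, p2, p3, p4) <= 1))
  pd <- pmax(p2, p3)
  list(abba = (1 - p1) * p2 * p3 * (1 - p4),
       baba = p1 * (1 - p2) * p3 * (1 - p4),
       abba_d = (1 - p1) * pd * pd * (1 - p4),
       baba_d = p1 * (1 - pd) * pd * (1 - p4),
       p_d = pd)
}

# derived-allele frequencies for the four groups over window sites; sites are
# dropped when the outgroup is missing/polymorphic or any ingroup group has
# fewer than min_n genotyped haplotypes
.pattern_freqs <- function(hap, p1_ids, p2_ids, p3_ids, out_ids, window,
                           min_n = 2) {
  ids <- list(p1_ids, p2_ids, p3_ids)
  if (anyDuplicated(unlist(c(ids, list(out_ids))))) stop("groups overlap")
  sites <- if (is.null(window)) seq_len(nrow(hap$alleles)) else window_sites(hap, window)
  oc <- match(out_ids, hap$hap_ids)
  O <- hap$alleles[sites, oc, drop = FALSE]
  o_n <- rowSums(!is.na(O))
  o_1 <- rowSums(O == 1L, na.rm = TRUE)
  anc <- ifelse(o_n == 0L | (o_1 > 0L & o_1 < o_n), NA_integer_,
                as.integer(o_1 == o_n))
  freqs <- lapply(ids, function(g) {
    cc <- .site_counts(hap, match(g, hap$hap_ids), sites)
    p1_raw <- ifelse(cc$n > 0, cc$n1 / cc$n, NA_real_)
    list(p = p1_raw, n = cc$n)
  })
  ok <- !is.na(anc) &
    freqs[[1]]$n >= min_n & freqs[[2]]$n >= min_n & freqs[[3]]$n >= min_n
  # derived frequency: frequency of the non-ancestral allele
  pl <- lapply(freqs, function(f) {
    ifelse(anc[ok] == 1L, 1 - f$p[ok], f$p[ok])
  })
  list(p1 = pl[[1]], p2 = pl[[2]], p3 = pl[[3]],
       p4 = rep(0, sum(ok)), n_sites = sum(ok))
}

#' D and fd for one window
#'
#' `D = sum(abba - baba) / sum(abba + baba)`;
#' `fd = sum(abba - baba) / sum(abba_d - baba_d)` (the dynamic-donor
#' admixture-fraction estimator). fd is reported only for windows with
#' `D >= 0` - it estimates an excess of shared derived alleles and is
#' undefined for a deficit; such windows carry `fd = NA` with a reason code.
#' Windows with no ABBA/BABA imbalance at all (D = 0/0) but a positive fd
#' denominator report `fd = 0` and `D = NA`.
#'
#' @param hap a [hap_matrix()].
#' @param p1_ids,p2_ids,p3_ids,out_ids haplotype id vectors for the ordered
#'   populations (P1, P2, P3, O). Derived states are polarised by the
#'   outgroup haplotypes; sites with a missing or polymorphic outgroup are
#'   skipped.
#' @param window 0-based half-open window, NULL = all sites.
#' @param min_sites minimum usable sites for the window to be scored.
#' @param min_n minimum genotyped haplotypes per ingroup population per site.
#' @return one-row data.frame: `n_sites`, `D`, `fd`, `reason`.
#' @export
window_d_fd <- function(hap, p1_ids, p2_ids, p3_ids, out_ids, window = NULL,
                        min_sites = 20, min_n = 2) {
  fq <- .pattern_freqs(hap, p1_ids, p2_ids, p3_ids, out_ids, window, min_n)
  row <- data.frame(n_sites = fq$n_sites, D = NA_real_, fd = NA_real_,
                    reason = "", stringsAsFactors = FALSE)
  if (fq$n_sites < min_sites) {
    row$reason <- "too_few_sites"
    return(row)
  }
  sp <- site_pattern(fq$p1, fq$p2, fq$p3, fq$p4)
  num <- sum(sp$abba - sp$baba)
  den_d <- sum(sp$abba + sp$baba)
  den_f <- sum(sp$abba_d - sp$baba_d)
  if (den_d > 0) row$D <- num / den_d
  # fd estimates an excess of shared derived alleles: defined for D >= 0 and
  # for windows with no ABBA/BABA imbalance at all (D = 0/0, fd = 0)
  if (den_d > 0 && row$D < 0) {
    row$reason <- "negative_D"
  } else if (den_f == 0) {
    row$reason <- "zero_fd_denominator"
  } else {
    row$fd <- num / den_f
  }
  if (den_d == 0 && row$reason == "") row$reason <- "zero_D_denominator"
  row
}

#' Windowed fd scan in the species or sexed configuration
#'
#' `configuration = "species"` tests gene flow between sinensis and
#' pungitius relative to tymensis: P1 = tymensis, P2 = sinensis,
#' P3 = pungitius, O = outgroup. `configuration = "sexed"` tests an excess of
#' derived alleles shared between sinensis and pungitius males relative to
#' pungitius females: P1 = pungitius females, P2 = pungitius males,
#' P3 = sinensis, O = outgroup.
#'
#' @param hap a [hap_matrix()] (one chromosome).
#' @param metadata sample metadata.
#' @param windows window data.frame (rows on other chromosomes are returned
#'   with NA statistics); `label` column feeds the summary.
#' @param configuration "species" or "sexed".
#' @param min_sites,min_n as in [window_d_fd()].
#' @param max_missing site-level missingness filter.
#' @return data.frame, one row per window, with a `summary` attribute giving
#'   mean fd over SDR-labelled and autosome-labelled windows.
#' @export
genome_scan_fd <- function(hap, metadata, windows,
                           configuration = c("species", "sexed"),
                           min_sites = 20, min_n = 2, max_missing = 0.2) {
  configuration <- match.arg(configuration)
  hap <- filter_missing_sites(hap, max_missing)
  grp <- switch(configuration,
    species = list(resolve_group(hap, metadata, "tymensis"),
                   resolve_group(hap, metadata, "sinensis"),
                   resolve_group(hap, metadata, "pungitius")),
    sexed = list(resolve_group(hap, metadata, "pungitius&female"),
                 resolve_group(hap, metadata, "pungitius&male"),
                 resolve_group(hap, metadata, "sinensis")))
  out_ids <- resolve_group(hap, metadata, "outgroup")
  res <- windows
  res$n_sites <- NA_integer_
  res$D <- NA_real_
  res$fd <- NA_real_
  res$reason <- ""
  res$config <- configuration
  for (i in seq_len(nrow(res))) {
    if (res$chrom[i] != hap$chrom) next
    row <- window_d_fd(hap, grp[[1]], grp[[2]], grp[[3]], out_ids, res[i, ],
                       min_sites = min_sites, min_n = min_n)
    res$n_sites[i] <- row$n_sites
    res$D[i] <- row$D
    res$fd[i] <- row$fd
    res$reason[i] <- row$reason
  }
  attr(res, "summary") <- list(
    mean_fd_sdr = mean(res$fd[res$label == "SDR"], na.rm = TRUE),
    mean_fd_autosome = mean(res$fd[res$label == "autosome"], na.rm = TRUE))
  res
}
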