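#' Hudson's Fst for one window (ratio of sums)
#'
#' Per contributing site, with haplotype allele frequencies `pA`, `pB` and
#' genotyped haplotype counts `nA`, `nB`:
#' numerator `(pA - pB)^2 - pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1)`,
#' denominator `pA(1-pB) + pB(1-pA)`. The window estimate is the ratio of the
#' summed numerators to the summed denominators. Sites contribute only when
#' each group has at least `min_n` genotyped haplotypes. Negative values are
#' reported as-is (unbiased under the null), `NA` when no site contributes or
#' the summed denominator is 0.
#'
#' @param hap a [hap_matrix()].
#' @param group_a,group_b haplotype id vectors (non-overlapping, non-empty).
#' @param window 0-based half-open window (list/row with `start`, `end`);
#'   NULL = all sites.
#' @param min_n minimum genotyped haplotypes per group per site.
#' @return scalar Fst (possibly negative), or NA.
#' @export
window_fst <- function(hap, group_a, group_b, window = NULL, min_n = 4) {
  if (length(group_a) == 0L || length(group_b) == 0L) stop("empty group")
  sites <- if (is.null(window)) NULL else window_sites(hap, window)
  ca <- .site_counts(hap, match(group_a, hap$hap_ids), sites)
  cb <- .site_counts(hap, match(group_b, hap$hap_ids), sites)
  ok <- ca$n >= min_n & cb$n >= min_n
  if (!any(ok)) return(NA_real_)
  pa <- ca$n1[ok] / ca$n[ok]
  pb <- cb$n1[ok] / cb$n[ok]
  na <- ca$n[ok]
  nb <- cb$n[ok]
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  if (sum(den) == 0) return(NA_real_)
  sum(num) / sum(den)
}

#' Percentage of sex-limited SNPs in a window
#'
#' A site contributes when at least 80% of each sex's haplotypes are
#' genotyped; it counts as sex-limited when one sex's minor-allele frequency
#' exceeds `maf_threshold` while that same allele is entirely absent
#' (frequency exactly 0 among genotyped haplotypes) in the other sex.
#'
#' @param hap a [hap_matrix()].
#' @param males,females haplotype id vectors.
#' @param window 0-based half-open window, NULL = all sites.
#' @param maf_threshold minor-allele-frequency threshold in `[0, 0.5)`.
#' @param min_genotyped_frac per-sex genotyping completeness a site needs.
#' @return percentage in `[0, 100]`, or NA when no site contributes.
#' @export
sex_limited_fraction <- function(hap, males, females, window = NULL,
                                 maf_threshold = 0.1,
                                 min_genotyped_frac = 0.8) {
  if (maf_threshold < 0 || maf_threshold >= 0.5) {
    stop("maf_threshold must be in [0, 0.5)")
  }
  sites <- if (is.null(window)) NULL else window_sites(hap, window)
  cm <- .site_counts(hap, match(males, hap$hap_ids), sites)
  cf <- .site_counts(hap, match(females, hap$hap_ids), sites)
  ok <- cm$n >= min_genotyped_frac * length(males) &
    cf$n >= min_genotyped_frac * length(females)
  if (!any(ok)) return(NA_real_)
  pm <- cm$n1[ok] / cm$n[ok]
  pf <- cf$n1[ok] / cf$n[ok]
  # a minor allele (freq <= 0.5) above threshold in one sex, absent in the
  # other; checked for both alleles in both sexes
  qual <-
    (pm > maf_threshold & pm <= 0.5 & pf == 0) |
    (pf > maf_threshold & pf <= 0.5 & pm == 0) |
    ((1 - pm) > maf_threshold & (1 - pm) <= 0.5 & pf == 1) |
    ((1 - pf) > maf_threshold & (1 - pf) <= 0.5 & pm == 1)
  100 * sum(qual) / sum(ok)
}

#' Nucleotide diversity (pi) for one window
#'
#' Sums the unbiased per-site heterozygosity `(n/(n-1)) * 2 p (1-p)` over
#' contributing sites (>= 2 genotyped haplotypes) and divides by the window
#' length in bp (`denominator_mode = "window_bp"`, default) or by the number
#' of contributing SNPs (`"snp_only"`).
#'
#' @param hap a [hap_matrix()].
#' @param group haplotype ids.
#' @param window 0-based half-open window; required for `window_bp` mode.
#' @param denominator_mode "window_bp" or "snp_only".
#' @return per-site diversity, or NA when nothing contributes.
#' @export
window_pi <- function(hap, group, window = NULL,
                      denominator_mode = c("window_bp", "snp_only")) {
  denominator_mode <- match.arg(denominator_mode)
  sites <- if (is.null(window)) NULL else window_sites(hap, window)
  cc <- .site_counts(hap, match(group, hap$hap_ids), sites)
  ok <- cc$n >= 2
  p <- cc$n1[ok] / cc$n[ok]
  n <- cc$n[ok]
  tot <- sum(n / (n - 1) * 2 * p * (1 - p))
  if (denominator_mode == "window_bp") {
    if (is.null(window)) stop("window required for denominator_mode 'window_bp'")
    tot / (window$end - window$start)
  } else {
    if (!any(ok)) return(NA_real_)
    tot / sum(ok)
  }
}

#' log2 of a male:female ratio
#'
#' @param x_m,x_f non-negative values (e.g. male and female pi).
#' @return `log2(x_m / x_f)`; NA when either input is 0.
#' @export
log2_ratio <- function(x_m, x_f) {
  if (any(c(x_m, x_f) < 0, na.rm = TRUE)) stop("inputs must be >= 0")
  ifelse(is.na(x_m) | is.na(x_f) | x_m == 0 | x_f == 0, NA_real_,
         log2(x_m / x_f))
}

#' Male:female log2 coverage ratio for one window
#'
#' Depths are first normalised within each sample by that sample's mean depth
#' across all windows (its genome-wide mean), then averaged within each sex
#' for the requested window.
#'
#' @param depth_table data.frame with columns `sample_id`, `chrom`, `start`,
#'   `end`, `depth` (mean depth of that sample in that window).
#' @param metadata sample metadata giving each sample's sex.
#' @param window the window (matched on chrom/start/end).
#' @return `log2(mean male normalised depth / mean female normalised depth)`.
#' @export
coverage_log2_ratio <- function(depth_table, metadata, window) {
  gw <- tapply(depth_table$depth, depth_table$sample_id, mean)
  if (any(gw == 0)) {
    stop("sample(s) with zero genome-wide mean depth: ",
         paste(names(gw)[gw == 0], collapse = ", "))
  }
  depth_table$norm <- depth_table$depth / gw[depth_table$sample_id]
  rows <- depth_table$chrom == window$chrom &
    depth_table$start == window$start & depth_table$end == window$end
  dt <- depth_table[rows, ]
  sex <- metadata$sex[match(dt$sample_id, metadata$sample_id)]
  log2(mean(dt$norm[sex == "male"]) / mean(dt$norm[sex == "female"]))
}

#' Windowed male-female contrast scan for one species
#'
#' Computes, per window: SNP count, male-female Hudson Fst, sex-limited SNP
#' percentage, male and female pi, and the log2 male:female pi ratio
#' (plus the log2 coverage ratio when a depth table is supplied). Windows
#' with fewer than `min_snps` SNPs get NA statistics, never zeros.
#'
#' @param hap a [hap_matrix()] (one chromosome).
#' @param metadata sample metadata.
#' @param species focal species.
#' @param windows data.frame from [make_windows()] (rows on `hap$chrom` are
#'   scanned; others are returned with NA statistics).
#' @param depth_table optional per-sample per-window depth table.
#' @param min_snps minimum SNPs for a window to be scored.
#' @param max_missing site-level missingness filter (see
#'   [filter_missing_sites()]).
#' @return data.frame: one row per window with the statistics appended.
#' @export
scan_sexdiff <- function(hap, metadata, species, windows, depth_table = NULL,
                         min_snps = 5, max_missing = 0.2) {
  hap <- filter_missing_sites(hap, max_missing)
  males <- resolve_group(hap, metadata, paste0(species, "&male"))
  females <- resolve_group(hap, metadata, paste0(species, "&female"))
  res <- windows
  res$n_snps <- NA_integer_
  res$fst_mf <- NA_real_
  res$sex_limited_pct <- NA_real_
  res$pi_m <- NA_real_
  res$pi_f <- NA_real_
  res$log2_pi_ratio <- NA_real_
  res$log2_cov_ratio <- NA_real_
  for (i in seq_len(nrow(res))) {
    if (res$chrom[i] != hap$chrom) next
    w <- res[i, ]
    sites <- window_sites(hap, w)
    res$n_snps[i] <- length(sites)
    if (length(sites) < min_snps) next
    res$fst_mf[i] <- window_fst(hap, males, females, w)
    res$sex_limited_pct[i] <- sex_limited_fraction(hap, males, females, w)
    res$pi_m[i] <- window_pi(hap, males, w)
    res$pi_f[i] <- window_pi(hap, females, w)
    res$log2_pi_ratio[i] <- log2_ratio(res$pi_m[i], res$pi_f[i])
    if (!is.null(depth_table)) {
      res$log2_cov_ratio[i] <- coverage_log2_ratio(depth_table, metadata, w)
    }
  }
  attr(res, "fst_estimator") <- "hudson_ratio_of_sums"
  res
}
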