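#' Construct a phased haplotype matrix
#'
#' The core container for phased biallelic genotypes on one chromosome: an
#' integer matrix of 0/1 alleles (sites x haplotypes, `NA` = missing) with
#' strictly increasing 1-based positions. Each diploid sample contributes two
#' haplotype columns (`<sample>_A`, `<sample>_B`); a haploid outgroup
#' contributes one. Internal window arithmetic is 0-based half-open; only VCF
#' input/output uses 1-based coordinates.
#'
#' @param chrom chromosome name (scalar character).
#' @param pos integer vector of 1-based site positions, strictly increasing.
#' @param alleles integer matrix (sites x haplotypes) with entries 0, 1 or NA.
#' @param hap_ids character vector of haplotype column ids, unique.
#' @param samples character vector mapping each haplotype column to its sample.
#' @param anc per-site ancestral allele (0/1/NA). The outgroup allele when an
#'   outgroup is available, otherwise the reference allele (0).
#' @param ref,alt per-site REF/ALT bases, kept so VCF round-trips are exact.
#' @param hap_groups optional character vector (one per haplotype, NA allowed)
#'   of gametolog labels ("X"/"Y") attached by the Y-phasing stage.
#' @return an object of class `hap_matrix`.
#' @export
hap_matrix <- function(chrom, pos, alleles, hap_ids, samples,
                       anc = NULL, ref = NULL, alt = NULL, hap_groups = NULL) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n_sites <- nrow(alleles)
  n_haps <- ncol(alleles)
  pos <- as.integer(pos)
  if (length(pos) != n_sites) stop("length(pos) must equal nrow(alleles)")
  if (n_sites > 1L && any(diff(pos) <= 0L)) {
    stop("positions must be strictly increasing")
  }
  if (length(hap_ids) != n_haps) stop("need one hap_id per haplotype column")
  if (anyDuplicated(hap_ids)) stop("hap_ids must be unique")
  if (length(samples) != n_haps) stop("need one sample id per haplotype")
  bad <- !(alleles %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("alleles must be 0, 1 or NA")
  per_sample <- table(samples)
  if (any(per_sample > 2L)) stop("a sample may contribute at most 2 haplotypes")
  if (is.null(anc)) anc <- rep(0L, n_sites)
  anc <- as.integer(anc)
  if (length(anc) != n_sites) stop("need one ancestral state per site")
  if (is.null(ref)) ref <- rep("A", n_sites)
  if (is.null(alt)) alt <- rep("G", n_sites)
  if (!is.null(hap_groups) && length(hap_groups) != n_haps) {
    stop("hap_groups must have one entry per haplotype")
  }
  colnames(alleles) <- hap_ids
  structure(
    list(chrom = chrom, pos = pos, alleles = alleles, hap_ids = hap_ids,
         samples = samples, anc = anc, ref = as.character(ref),
         alt = as.character(alt), hap_groups = hap_groups),
    class = "hap_matrix"
  )
}

#' @export
#' @method print hap_matrix
print.hap_matrix <- function(x, ...) {
  cat(sprintf("<hap_matrix> %s: %d sites x %d haplotypes (%d samples)\n",
              x$chrom, nrow(x$alleles), ncol(x$alleles),
              length(unique(x$samples))))
  invisible(x)
}

#' @export
dim.hap_matrix <- function(x) dim(x$alleles)

#' Indices of sites falling in a window
#'
#' @param hap a [hap_matrix()].
#' @param window list or one-row data.frame with 0-based half-open `start`,
#'   `end`.
#' @return integer vector of site indices.
#' @export
window_sites <- function(hap, window) {
  which(hap$pos > window$start & hap$pos <= window$end)
}

#' Subset a haplotype matrix by sites and/or haplotypes
#'
#' @param hap a [hap_matrix()].
#' @param sites integer site indices (default all).
#' @param haps haplotype ids or column indices (default all).
#' @return a [hap_matrix()].
#' @export
hap_subset <- function(hap, sites = NULL, haps = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(hap$alleles))
  if (is.null(haps)) haps <- seq_len(ncol(hap$alleles))
  if (is.character(haps)) {
    idx <- match(haps, hap$hap_ids)
    if (anyNA(idx)) stop("unknown haplotype id(s): ",
                         paste(haps[is.na(idx)], collapse = ", "))
    haps <- idx
  }
  hap_matrix(hap$chrom, hap$pos[sites],
             hap$alleles[sites, haps, drop = FALSE],
             hap$hap_ids[haps], hap$samples[haps],
             anc = hap$anc[sites], ref = hap$ref[sites], alt = hap$alt[sites],
             hap_groups = if (!is.null(hap$hap_groups)) hap$hap_groups[haps])
}

#' Drop sites with too much missing data
#'
#' A single global site filter applied by every scan stage: sites where more
#' than `max_missing` of the haplotypes are ungenotyped are removed.
#'
#' @param hap a [hap_matrix()].
#' @param max_missing maximum tolerated missing fraction per site.
#' @return a filtered [hap_matrix()].
#' @export
filter_missing_sites <- function(hap, max_missing = 0.2) {
  miss <- rowMeans(is.na(hap$alleles))
  hap_subset(hap, sites = which(miss <= max_missing))
}

# allele-1 counts and genotyped counts per site over a set of hap columns
.site_counts <- function(hap, cols, sites = NULL) {
  A <- hap$alleles[, cols, drop = FALSE]
  if (!is.null(sites)) A <- A[sites, , drop = FALSE]
  list(n1 = rowSums(A == 1L, na.rm = TRUE), n = rowSums(!is.na(A)))
}

# derived-allele counts (relative to ancestral state) per site
.derived_counts <- function(hap, cols, sites = NULL) {
  A <- hap$alleles[, cols, drop = FALSE]
  anc <- hap$anc
  if (!is.null(sites)) {
    A <- A[sites, , drop = FALSE]
    anc <- anc[sites]
  }
  D <- A != anc
  list(nd = rowSums(D, na.rm = TRUE), n = rowSums(!is.na(D)))
}

.sample_of_hap <- function(hap_ids) sub("_(A|B|X|Y)$", "", hap_ids)

#' Resolve a group expression to haplotype ids
#'
#' Group expressions combine species, sex and gametolog tokens with `&`:
#' `"sinensis"`, `"pungitius&male"`, `"pungitius_Y"` (shorthand for
#' `"pungitius&Y"`). Gametolog tokens ("X"/"Y") require a matrix carrying
#' `hap_groups` labels from [build_xy_groups()]. The result is order-stable
#' (haplotype-column order of the matrix).
#'
#' @param hap a [hap_matrix()].
#' @param metadata sample metadata, see [read_metadata()].
#' @param spec group expression.
#' @return character vector of haplotype ids (never empty; empty is an error).
#' @export
resolve_group <- function(hap, metadata, spec) {
  species_levels <- c("pungitius", "sinensis", "tymensis", "outgroup")
  sex_levels <- c("male", "female", "unknown")
  midx <- match(hap$samples, metadata$sample_id)
  if (anyNA(midx)) {
    stop("haplotype sample(s) missing from metadata: ",
         paste(unique(hap$samples[is.na(midx)]), collapse = ", "))
  }
  sp <- metadata$species[midx]
  sx <- metadata$sex[midx]
  keep <- rep(TRUE, length(hap$hap_ids))
  for (tok in strsplit(spec, "&", fixed = TRUE)[[1]]) {
    if (grepl("_(X|Y)$", tok)) {
      g <- sub("^.*_", "", tok)
      tok2 <- sub("_(X|Y)$", "", tok)
      keep <- keep & .group_mask(hap, g)
      tok <- tok2
    }
    if (tok %in% species_levels) {
      keep <- keep & sp == tok
    } else if (tok %in% sex_levels) {
      keep <- keep & sx == tok
    } else if (tok %in% c("X", "Y")) {
      keep <- keep & .group_mask(hap, tok)
    } else {
      stop("unknown group token: '", tok, "'")
    }
  }
  ids <- hap$hap_ids[keep]
  if (length(ids) == 0L) stop("group expression '", spec,
                              "' resolves to no haplotypes")
  ids
}

.group_mask <- function(hap, g) {
  if (is.null(hap$hap_groups)) {
    stop("gametolog token '", g,
         "' requires hap_groups labels (see build_xy_groups)")
  }
  !is.na(hap$hap_groups) & hap$hap_groups == g
}
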