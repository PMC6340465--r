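#' Read a sample metadata table
#'
#' Tab-separated file with header `sample_id species sex`. Species must be one
#' of pungitius / sinensis / tymensis / outgroup; sex one of male / female /
#' unknown; sample ids unique.
#'
#' @param path file path.
#' @return data.frame with the three validated columns.
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_metadata(md)
}

#' Validate a sample metadata data.frame
#' @param md data.frame with columns sample_id, species, sex.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validate_metadata <- function(md) {
  need <- c("sample_id", "species", "sex")
  if (!all(need %in% names(md))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in metadata")
  bad_sp <- setdiff(md$species, c("pungitius", "sinensis", "tymensis", "outgroup"))
  if (length(bad_sp)) stop("unknown species label(s): ", paste(bad_sp, collapse = ", "))
  bad_sx <- setdiff(md$sex, c("male", "female", "unknown"))
  if (length(bad_sx)) stop("unknown sex label(s): ", paste(bad_sx, collapse = ", "))
  md
}

#' Write a sample metadata table
#' @param md metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phased genotypes from a VCF into a haplotype matrix
#'
#' Keeps biallelic SNP records only (others are skipped with a message giving
#' the count). Genotypes must be phased (`0|1`); unphased records are an error
#' unless `allow_unphased = TRUE`, in which case the written order is taken as
#' given and the affected sites are flagged in the `unphased_sites` attribute.
#' The ancestral state is the outgroup sample's allele when the metadata
#' contains an `outgroup` sample (sites where the outgroup is heterozygous get
#' NA), otherwise the REF allele; the choice is reported with a message.
#'
#' @param path VCF path (plain or bgzip/gzip).
#' @param metadata sample metadata; every sample listed must be in the VCF.
#' @param region optional window (list with `chrom`, `start`, `end`, 0-based
#'   half-open) to restrict to.
#' @param allow_unphased tolerate unphased diploid genotypes.
#' @return a [hap_matrix()] (multi-chromosome files: a named list of them).
#' @export
read_vcf <- function(path, metadata, region = NULL, allow_unphased = FALSE) {
  metadata <- validate_metadata(metadata)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0L) {
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)", n_skip))
  }
  gt_all <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_all))) {
    gt_all <- matrix(gt_all, nrow = 1, dimnames = list(NULL, names(gt_all)))
  }
  missing_samples <- setdiff(metadata$sample_id, colnames(gt_all))
  if (length(missing_samples)) {
    stop("sample(s) not in VCF header: ", paste(missing_samples, collapse = ", "))
  }
  chroms <- fix[snp, "CHROM"]
  pos <- as.integer(fix[snp, "POS"])
  ref <- ref[snp]
  alt <- alt[snp]
  gt_all <- gt_all[snp, metadata$sample_id, drop = FALSE]
  out_sample <- metadata$sample_id[metadata$species == "outgroup"]
  if (length(out_sample)) {
    message("read_vcf: ancestral state taken from outgroup sample '",
            out_sample[1], "'")
  } else {
    message("read_vcf: no outgroup sample; ancestral state = REF allele")
  }
  build_one <- function(idx, chrom) {
    cols <- list(); ids <- character(); samp <- character()
    unphased_sites <- integer()
    for (s in metadata$sample_id) {
      g <- gt_all[idx, s]
      g[is.na(g)] <- "."
      ploidy <- max(nchar(g), na.rm = TRUE)
      if (any(nchar(g) == 3 & substr(g, 2, 2) == "/")) {
        bad <- which(substr(g, 2, 2) == "/")
        if (!allow_unphased) {
          stop(sprintf("unphased genotype for sample %s at %s:%d", s,
                       chrom, pos[idx][bad[1]]))
        }
        unphased_sites <- union(unphased_sites, bad)
      }
      a1 <- substr(g, 1, 1)
      conv <- function(x) {
        out <- rep(NA_integer_, length(x))
        out[x == "0"] <- 0L
        out[x == "1"] <- 1L
        bad_tok <- !(x %in% c("0", "1", ".", "", NA))
        if (any(bad_tok)) {
          stop(sprintf("malformed GT for sample %s at %s:%d", s, chrom,
                       pos[idx][which(bad_tok)[1]]))
        }
        out
      }
      if (ploidy >= 3) {
        a2 <- substr(g, 3, 3)
        cols <- c(cols, list(conv(a1), conv(a2)))
        ids <- c(ids, paste0(s, "_A"), paste0(s, "_B"))
        samp <- c(samp, s, s)
      } else {
        cols <- c(cols, list(conv(a1)))
        ids <- c(ids, paste0(s, "_A"))
        samp <- c(samp, s)
      }
    }
    A <- do.call(cbind, cols)
    anc <- rep(0L, length(idx))
    if (length(out_sample)) {
      oc <- which(samp == out_sample[1])
      oa <- A[, oc, drop = FALSE]
      same <- apply(oa, 1, function(r) {
        r <- r[!is.na(r)]
        if (!length(r) || length(unique(r)) > 1L) NA_integer_ else r[1]
      })
      anc <- as.integer(same)
    }
    hm <- hap_matrix(chrom, pos[idx], A, ids, samp, anc = anc,
                     ref = ref[idx], alt = alt[idx])
    attr(hm, "unphased_sites") <- unphased_sites
    hm
  }
  if (!is.null(region)) {
    idx <- which(chroms == region$chrom & pos > region$start & pos <= region$end)
    return(build_one(idx, region$chrom))
  }
  uc <- unique(chroms)
  out <- lapply(uc, function(ch) build_one(which(chroms == ch), ch))
  names(out) <- uc
  attr(out, "n_skipped") <- n_skip
  if (length(out) == 1L) out[[1]] else out
}

#' Write a haplotype matrix (or list of them) as a phased VCF
#'
#' Inverse of [read_vcf()] on the files it accepts: genotype content, REF/ALT
#' and positions round-trip exactly. Diploid samples are written as `a|b`,
#' haploid samples (e.g. the outgroup) as a single allele.
#'
#' @param hap a [hap_matrix()] or list of them (one per chromosome).
#' @param path output path (plain text VCF).
#' @return the path, invisibly.
#' @export
write_vcf <- function(hap, path) {
  if (inherits(hap, "hap_matrix")) hap <- list(hap)
  samples <- unique(hap[[1]]$samples)
  writeLines(c("##fileformat=VCFv4.2",
               "##source=sdrscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), path)
  for (hm in hap) {
    gt_cols <- lapply(samples, function(s) {
      cols <- which(hm$samples == s)
      a <- hm$alleles[, cols[1]]
      a_chr <- ifelse(is.na(a), ".", as.character(a))
      if (length(cols) == 2L) {
        b <- hm$alleles[, cols[2]]
        b_chr <- ifelse(is.na(b), ".", as.character(b))
        paste0(a_chr, "|", b_chr)
      } else {
        a_chr
      }
    })
    dt <- data.table::data.table(
      CHROM = hm$chrom, POS = hm$pos, ID = ".", REF = hm$ref, ALT = hm$alt,
      QUAL = ".", FILTER = "PASS", INFO = ".", FORMAT = "GT")
    for (i in seq_along(samples)) data.table::set(dt, j = samples[i], value = gt_cols[[i]])
    data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
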