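# Independent brute-force oracles and small fixture builders. These are kept
# deliberately naive (explicit per-site loops, no shared code with the
# package internals) so they can serve as references for the vectorised
# implementations.

# build a hap_matrix from a plain 0/1/NA matrix (rows = sites)
toy_hap <- function(A, pos = seq_len(nrow(A)), chrom = "chr",
                    samples = NULL, anc = NULL, hap_groups = NULL) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (is.null(colnames(A))) {
    ids <- paste0("s", rep(seq_len(ceiling(n / 2)), each = 2)[1:n],
                  rep(c("_A", "_B"), length.out = n))
  } else {
    ids <- colnames(A)
  }
  if (is.null(samples)) samples <- sub("_(A|B|X|Y)$", "", ids)
  hap_matrix(chrom, pos, A, ids, samples, anc = anc, hap_groups = hap_groups)
}

# random hap_matrix with missingness
random_hap <- function(n_sites, n_haps, miss = 0.05, pos_max = n_sites * 10) {
  A <- matrix(rbinom(n_sites * n_haps, 1, runif(1, 0.2, 0.8)), n_sites)
  A[matrix(runif(n_sites * n_haps) < miss, n_sites)] <- NA
  toy_hap(A, pos = sort(sample.int(pos_max, n_sites)))
}

# ---- oracle: Hudson Fst, summed site by site -------------------------------
oracle_fst <- function(hap, ga, gb, window = NULL, min_n = 4) {
  ia <- match(ga, hap$hap_ids)
  ib <- match(gb, hap$hap_ids)
  num <- 0; den <- 0; any_site <- FALSE
  for (s in seq_along(hap$pos)) {
    if (!is.null(window) &&
        !(hap$pos[s] > window$start && hap$pos[s] <= window$end)) next
    a <- hap$alleles[s, ia]; a <- a[!is.na(a)]
    b <- hap$alleles[s, ib]; b <- b[!is.na(b)]
    if (length(a) < min_n || length(b) < min_n) next
    any_site <- TRUE
    pa <- mean(a); pb <- mean(b)
    num <- num + (pa - pb)^2 - pa * (1 - pa) / (length(a) - 1) -
      pb * (1 - pb) / (length(b) - 1)
    den <- den + pa * (1 - pb) + pb * (1 - pa)
  }
  if (!any_site || den == 0) NA_real_ else num / den
}

# ---- oracle: pi ------------------------------------------------------------
oracle_pi <- function(hap, g, window, mode = "window_bp") {
  ii <- match(g, hap$hap_ids)
  tot <- 0; nsnp <- 0
  for (s in seq_along(hap$pos)) {
    if (!(hap$pos[s] > window$start && hap$pos[s] <= window$end)) next
    a <- hap$alleles[s, ii]; a <- a[!is.na(a)]
    n <- length(a)
    if (n < 2) next
    p <- mean(a)
    tot <- tot + n / (n - 1) * 2 * p * (1 - p)
    nsnp <- nsnp + 1
  }
  if (mode == "window_bp") tot / (window$end - window$start)
  else if (nsnp == 0) NA_real_ else tot / nsnp
}

# ---- oracle: dxy -----------------------------------------------------------
oracle_dxy <- function(hap, ga, gb, window) {
  ia <- match(ga, hap$hap_ids)
  ib <- match(gb, hap$hap_ids)
  tot <- 0
  for (s in seq_along(hap$pos)) {
    if (!(hap$pos[s] > window$start && hap$pos[s] <= window$end)) next
    a <- hap$alleles[s, ia]; a <- a[!is.na(a)]
    b <- hap$alleles[s, ib]; b <- b[!is.na(b)]
    if (length(a) < 1 || length(b) < 1) next
    pa <- mean(a); pb <- mean(b)
    tot <- tot + pa * (1 - pb) + pb * (1 - pa)
  }
  tot / (window$end - window$start)
}

# ---- oracle: D and fd, site by site ----------------------------------------
oracle_d_fd <- function(hap, g1, g2, g3, go, window = NULL, min_n = 2) {
  i1 <- match(g1, hap$hap_ids); i2 <- match(g2, hap$hap_ids)
  i3 <- match(g3, hap$hap_ids); io <- match(go, hap$hap_ids)
  num <- 0; den <- 0; denf <- 0; n_used <- 0
  for (s in seq_along(hap$pos)) {
    if (!is.null(window) &&
        !(hap$pos[s] > window$start && hap$pos[s] <= window$end)) next
    o <- hap$alleles[s, io]; o <- o[!is.na(o)]
    if (length(o) == 0 || length(unique(o)) > 1) next
    anc <- o[1]
    fr <- function(ii) {
      a <- hap$alleles[s, ii]; a <- a[!is.na(a)]
      if (length(a) < min_n) return(NULL)
      mean(a != anc)
    }
    p1 <- fr(i1); p2 <- fr(i2); p3 <- fr(i3)
    if (is.null(p1) || is.null(p2) || is.null(p3)) next
    n_used <- n_used + 1
    pd <- max(p2, p3)
    num <- num + (1 - p1) * p2 * p3 - p1 * (1 - p2) * p3
    den <- den + (1 - p1) * p2 * p3 + p1 * (1 - p2) * p3
    denf <- denf + (1 - p1) * pd * pd - p1 * (1 - pd) * pd
  }
  list(D = if (den > 0) num / den else NA_real_,
       fd = if (denf != 0) num / denf else NA_real_, n_sites = n_used)
}

# ---- oracle: NG86 via independent path enumeration -------------------------
oracle_ng86 <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  translate1 <- function(codon) unname(code[codon])
  bases <- c("A", "C", "G", "T")
  syn_frac <- function(codon) {
    cnt <- 0
    for (p in 1:3) for (nb in bases) {
      if (nb == substr(codon, p, p)) next
      alt <- codon; substr(alt, p, p) <- nb
      if (translate1(alt) == translate1(codon) && translate1(alt) != "*") {
        cnt <- cnt + 1
      }
    }
    cnt / 3
  }
  all_paths <- function(pos) {
    if (length(pos) == 1) return(list(pos))
    out <- list()
    for (i in seq_along(pos)) {
      for (rest in all_paths(pos[-i])) out <- c(out, list(c(pos[i], rest)))
    }
    out
  }
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_len(nchar(a) / 3)) {
    ca <- substr(a, 3 * i - 2, 3 * i)
    cb <- substr(b, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", paste0(ca, cb))) next
    if (translate1(ca) == "*" || translate1(cb) == "*") next
    S <- S + (syn_frac(ca) + syn_frac(cb)) / 2
    N <- N + 3 - (syn_frac(ca) + syn_frac(cb)) / 2
    pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (length(pos) == 0) next
    path_scores <- list()
    for (path in all_paths(pos)) {
      cur <- ca; s <- 0; n <- 0; stopped <- FALSE
      for (p in path) {
        nxt <- cur; substr(nxt, p, p) <- substr(cb, p, p)
        if (translate1(nxt) == "*" && nxt != cb) stopped <- TRUE
        if (translate1(cur) == translate1(nxt) && translate1(nxt) != "*") {
          s <- s + 1
        } else n <- n + 1
        cur <- nxt
      }
      path_scores <- c(path_scores, list(c(s, n, stopped)))
    }
    valid <- Filter(function(x) !x[3], path_scores)
    if (length(valid) == 0) valid <- path_scores
    Sd <- Sd + mean(sapply(valid, `[`, 1))
    Nd <- Nd + mean(sapply(valid, `[`, 2))
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
       dS = jc(Sd / S), dN = jc(Nd / N))
}

# random in-frame CDS without stop codons
random_cds <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# mutate a CDS at k random positions avoiding stops
mutate_cds <- function(cds, k) {
  bases <- c("A", "C", "G", "T")
  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(k)) {
    repeat {
      p <- sample.int(nchar(cds), 1)
      alt <- cds
      substr(alt, p, p) <- sample(setdiff(bases, substr(cds, p, p)), 1)
      ci <- (p - 1) %/% 3
      codon <- substr(alt, ci * 3 + 1, ci * 3 + 3)
      if (code[codon] != "*") { cds <- alt; break }
    }
  }
  cds
}

# quartet-topology oracle: prune to 4 tips with ape and read off the split
oracle_quartet <- function(tree, a, b, c, d) {
  sub <- ape::keep.tip(tree, c(a, b, c, d))
  sub <- ape::unroot(sub)
  for (pair in list(c(a, b), c(a, c), c(a, d))) {
    other <- setdiff(c(a, b, c, d), pair)
    if (ape::is.monophyletic(sub, pair) || ape::is.monophyletic(sub, other)) {
      return(match(paste(sort(pair), collapse = "+"),
                   c(paste(sort(c(a, b)), collapse = "+"),
                     paste(sort(c(a, c)), collapse = "+"),
                     paste(sort(c(a, d)), collapse = "+"))))
    }
  }
  0L
}

# small scenario config for fast tests
small_config <- function(...) {
  args <- utils::modifyList(list(chrom_length = 4e5, auto_length = 4e5),
                            list(...))
  do.call(scenario_config, args)
}
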