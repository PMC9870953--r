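# Independent brute-force oracles: naive loops and pair enumeration, kept
# deliberately separate from the package's vectorised implementations.

naiveHamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- 0L
  for (i in seq_along(ca)) if (ca[i] != cb[i]) n <- n + 1L
  n
}

# mean pairwise difference over all C(n,2) expanded sequence pairs
oracleK <- function(seqs) {
  n <- length(seqs)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + naiveHamming(seqs[i], seqs[j])
  tot / choose(n, 2)
}

# proportion of unordered sequence pairs carrying different haplotypes
# (equals the unbiased haplotype-diversity estimator)
oracleHd <- function(seqs) {
  n <- length(seqs)
  diffpairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (seqs[i] != seqs[j]) diffpairs <- diffpairs + 1
  diffpairs / choose(n, 2)
}

# column scan for segregating sites
oracleS <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  s <- 0L
  for (j in seq_len(ncol(m))) if (length(unique(m[, j])) > 1L) s <- s + 1L
  s
}

# random alignment built from a handful of haplotypes sampled with
# replacement; returns the named sequence vector and a population map
randomAlignment <- function(n, L, nPops = 2L) {
  k <- sample(1:4, 1)
  ref <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  haps <- ref
  while (length(unique(haps)) < k) {
    ch <- strsplit(ref, "")[[1]]
    nm <- sample(1:3, 1)
    pos <- sample(L, nm)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    haps <- unique(c(haps, paste(ch, collapse = "")))
  }
  seqs <- sample(haps, n, replace = TRUE)
  seqs[seq_along(haps)] <- haps  # every haplotype observed
  ids <- sprintf("s%03d", seq_len(n))
  pops <- paste0("pop", sample(seq_len(nPops), n, replace = TRUE))
  list(seqs = stats::setNames(seqs, ids),
       partition = stats::setNames(pops, ids))
}

# collapsed fixture table, shared across tests
fixtureTable <- function(seed = 1, ...) {
  fx <- makePaperFixture(seed = seed, ...)
  cd <- completeDeletion(fx$seqs)
  list(fx = fx, table = collapseHaplotypes(cd$seqs, fx$partition))
}
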