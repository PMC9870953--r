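#' @include alignio.R
NULL

# character matrix (rows = sequences) from an AlignedSeqSet
.charMatrix <- function(seqs) {
  m <- do.call(rbind, strsplit(as.character(seqs), ""))
  rownames(m) <- sampleIds(seqs)
  m
}

#' Complete-deletion site filter
#'
#' Removes every alignment column that contains a gap or an ambiguity code in
#' any sequence, the default site handling of sequence-polymorphism software
#' such as DnaSP. All downstream statistics (distances, segregating sites,
#' per-site diversity) operate on the retained columns; their count is the
#' effective length `L_used`.
#'
#' @param seqs An [AlignedSeqSet-class].
#' @return A list: `seqs` (filtered [AlignedSeqSet-class]), `filter` (list
#'   with `retained_columns`, 1-based, and `n_excluded`).
#' @examples
#' aln <- AlignedSeqSet(c(a = "ACGT", b = "AC-T"))
#' completeDeletion(aln)$filter
#' @export
completeDeletion <- function(seqs) {
  stopifnot(is(seqs, "AlignedSeqSet"))
  m <- .charMatrix(seqs)
  keep <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(keep))
    stop("complete deletion removed every column; no analysable sites")
  out <- if (all(keep)) seqs else
    AlignedSeqSet(apply(m[, keep, drop = FALSE], 1L, paste, collapse = ""))
  list(seqs = out,
       filter = list(retained_columns = which(keep),
                     n_excluded = sum(!keep)))
}

#' Read a sample-to-population map
#'
#' Two-column TSV (`sample_id`, `population`), with or without a header row.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping sample id to population label.
#' @export
readPopulationMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("population map must have two columns")
  if (identical(tolower(df[1L, 1L]), "sample_id")) df <- df[-1L, , drop = FALSE]
  if (anyDuplicated(df[[1L]]))
    stop("sample mapped to more than one population: ",
         paste(unique(df[[1L]][duplicated(df[[1L]])]), collapse = ", "))
  stats::setNames(df[[2L]], df[[1L]])
}

#' Hamming distance between two equal-length sequences
#'
#' Number of columns at which the two sequences differ; the unit of
#' mutational distance used throughout the haplotype network.
#'
#' @param a,b Character scalars of equal length (sequences over retained
#'   columns).
#' @return Integer count of differing columns.
#' @examples
#' pairwiseDistance("ACGT", "ACTT")
#' @export
pairwiseDistance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences must have equal length (", nchar(a), " vs ", nchar(b), ")")
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

#' Count segregating sites
#'
#' Number of retained alignment columns at which more than one base is
#' observed among the sequences. Apply [completeDeletion()] first so that
#' gaps and ambiguity codes cannot masquerade as variation.
#'
#' @param seqs An [AlignedSeqSet-class] (post site filtering).
#' @return Integer, the segregating-site count S.
#' @export
segregatingSites <- function(seqs) {
  stopifnot(is(seqs, "AlignedSeqSet"))
  m <- .charMatrix(seqs)
  sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
}

#' Collapse an alignment into haplotypes
#'
#' Groups identical sequences (exact match over the retained columns) into
#' haplotypes, tabulates their counts per population and computes the full
#' pairwise Hamming-distance matrix. Haplotype ids `H1`, `H2`, ... are
#' assigned by descending total count, ties broken by first occurrence in
#' the input, so the labelling is reproducible and independent of record
#' order up to count ties.
#'
#' @param seqs An [AlignedSeqSet-class], already passed through
#'   [completeDeletion()].
#' @param partition Named character vector mapping every sample id in `seqs`
#'   to a population label (see [readPopulationMap()]).
#' @return A [HaplotypeTable-class].
#' @examples
#' aln <- AlignedSeqSet(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACTT"))
#' part <- c(s1 = "north", s2 = "north", s3 = "south")
#' collapseHaplotypes(aln, part)
#' @export
collapseHaplotypes <- function(seqs, partition) {
  stopifnot(is(seqs, "AlignedSeqSet"))
  ids <- sampleIds(seqs)
  missing <- setdiff(names(partition), ids)
  if (length(missing))
    stop("samples in partition absent from alignment: ",
         paste(missing, collapse = ", "))
  unmapped <- setdiff(ids, names(partition))
  if (length(unmapped))
    stop("samples without a population label: ",
         paste(unmapped, collapse = ", "))
  sq <- as.character(seqs)
  uniq <- unique(sq)                       # first-seen order
  idx <- match(sq, uniq)
  total <- tabulate(idx, nbins = length(uniq))
  ord <- order(-total, seq_along(uniq))    # count desc, then first seen
  uniq <- uniq[ord]
  total <- total[ord]
  hapOf <- match(sq, uniq)
  hapIds <- paste0("H", seq_along(uniq))
  pops <- unique(unname(partition[ids]))   # population order of appearance
  counts <- matrix(0L, nrow = length(uniq), ncol = length(pops),
                   dimnames = list(hapIds, pops))
  for (i in seq_along(ids)) {
    p <- partition[[ids[i]]]
    counts[hapOf[i], p] <- counts[hapOf[i], p] + 1L
  }
  chars <- strsplit(uniq, "")
  k <- length(uniq)
  d <- matrix(0L, k, k, dimnames = list(hapIds, hapIds))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      d[i, j] <- d[j, i] <- sum(chars[[i]] != chars[[j]])
    }
  }
  new("HaplotypeTable", haplotypes = stats::setNames(uniq, hapIds),
      counts = counts, dist = d, Lused = seqLength(seqs))
}

#' Export a haplotype table as TSV
#'
#' Writes the per-population count table (`<stem>_counts.tsv`) and the square
#' mutational-distance matrix (`<stem>_dist.tsv`).
#'
#' @param table A [HaplotypeTable-class].
#' @param stem Output path stem (no extension).
#' @return Invisibly, the two file paths written.
#' @export
writeHaplotypeTable <- function(table, stem) {
  stopifnot(is(table, "HaplotypeTable"))
  cf <- paste0(stem, "_counts.tsv")
  df <- data.frame(hap_id = hapIds(table), hapCounts(table),
                   check.names = FALSE)
  utils::write.table(df, cf, sep = "\t", quote = FALSE, row.names = FALSE)
  dfile <- paste0(stem, "_dist.tsv")
  utils::write.table(
    data.frame(hap_id = hapIds(table), hapDist(table), check.names = FALSE),
    dfile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(cf, dfile))
}
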