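#' @include haplotypes.R
NULL

#' Unbiased haplotype diversity
#'
#' Nei's small-sample estimator `Hd = n (1 - sum p_i^2) / (n - 1)` with
#' `p_i = count_i / n`: the probability that two sequences drawn without
#' replacement carry different haplotypes. This is the estimator reported by
#' DnaSP.
#'
#' @param counts Vector of positive haplotype counts (one population).
#' @return Numeric in `[0, 1]`.
#' @examples
#' haplotypeDiversity(c(7, 3, 1, 1))   # 0.636, a diverse population
#' haplotypeDiversity(c(25, 1))        # 0.077, one dominant haplotype
#' @export
haplotypeDiversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity undefined for fewer than 2 sequences")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Average number of pairwise nucleotide differences (K)
#'
#' Mean Hamming distance over all unordered pairs of sequences, computed from
#' haplotype counts and the haplotype distance matrix:
#' `K = sum_{i<j} n_i n_j d_ij / C(n, 2)` (within-haplotype pairs contribute
#' zero).
#'
#' @param counts Vector of haplotype counts.
#' @param dist Square distance matrix consistent with `counts`.
#' @return Numeric `K >= 0`; zero iff a single haplotype.
#' @examples
#' meanPairwiseDifferences(c(25, 1), matrix(c(0, 1, 1, 0), 2))  # 0.0769...
#' @export
meanPairwiseDifferences <- function(counts, dist) {
  dist <- as.matrix(dist)
  if (length(counts) != nrow(dist) || nrow(dist) != ncol(dist))
    stop("counts and dist dimensions disagree")
  n <- sum(counts)
  if (n < 2) stop("K undefined for fewer than 2 sequences")
  w <- outer(counts, counts)        # ordered pairs; distances symmetric
  sum(w * dist) / 2 / choose(n, 2)
}

#' Nucleotide diversity (pi)
#'
#' Per-site average pairwise difference: `pi = K / L_used`, where `L_used`
#' is the number of alignment columns retained by the site filter.
#'
#' @param K Average number of pairwise nucleotide differences.
#' @param Lused Number of analysed sites (>= 1).
#' @return Numeric in `[0, 1]`.
#' @export
nucleotideDiversity <- function(K, Lused) {
  if (Lused < 1) stop("Lused must be >= 1")
  K / Lused
}

#' Per-population diversity report
#'
#' Computes, for every population and for the pooled data (`All` row), the
#' classic barcoding diversity panel: N (sequences), K (mean pairwise
#' differences), S (segregating sites), pi (nucleotide diversity = K /
#' L_used), H (haplotypes) and Hd (unbiased haplotype diversity). S is
#' computed on the haplotypes actually present in each population. Hd is
#' `NA` for populations of a single sequence, where the unbiased estimator
#' is undefined.
#'
#' @param table A [HaplotypeTable-class].
#' @param Lused Number of analysed sites; defaults to the table's own
#'   [sitesUsed()].
#' @return A data.frame with columns `population`, `N`, `K`, `S`, `pi`, `H`,
#'   `Hd`, `L_used`, full precision (see [formatDiversityReport()] for
#'   display rounding).
#' @export
diversityReport <- function(table, Lused = sitesUsed(table)) {
  stopifnot(is(table, "HaplotypeTable"))
  cn <- hapCounts(table)
  if (any(colSums(cn) == 0))
    stop("empty population(s): ",
         paste(colnames(cn)[colSums(cn) == 0], collapse = ", "))
  d <- hapDist(table)
  seqsOf <- strsplit(hapSequences(table), "")
  oneRow <- function(label, counts) {
    present <- counts > 0
    n <- sum(counts)
    S <- if (sum(present) > 1L) {
      ch <- do.call(rbind, seqsOf[present])
      sum(apply(ch, 2L, function(col) length(unique(col)) > 1L))
    } else 0L
    K <- if (n >= 2) meanPairwiseDifferences(counts[present],
                                             d[present, present,
                                               drop = FALSE]) else 0
    data.frame(population = label, N = n, K = K, S = S,
               pi = nucleotideDiversity(K, Lused), H = sum(present),
               Hd = if (n >= 2) haplotypeDiversity(counts[present]) else NA_real_,
               L_used = Lused, stringsAsFactors = FALSE)
  }
  rows <- lapply(colnames(cn), function(p) oneRow(p, cn[, p]))
  rows <- c(rows, list(oneRow("All", rowSums(cn))))
  do.call(rbind, rows)
}

#' Render a diversity report for display or TSV export
#'
#' Rounds K and Hd to 3 decimal places and pi to 3 significant figures, the
#' conventional presentation for these statistics; the raw report keeps full
#' precision.
#'
#' @param report Output of [diversityReport()].
#' @param path Optional TSV path; when given the formatted table is written.
#' @return The formatted data.frame, invisibly when `path` is given.
#' @export
formatDiversityReport <- function(report, path = NULL) {
  out <- report
  out$K <- sprintf("%.3f", report$K)
  out$Hd <- ifelse(is.na(report$Hd), "NA", sprintf("%.3f", report$Hd))
  out$pi <- signif(report$pi, 3)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
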