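#' @include diversity.R
NULL

#' Probability that j observed differences are parsimonious
#'
#' Statistical-parsimony networks join haplotypes only while it is
#' sufficiently probable that the observed differences arose without
#' superimposed (multiple-hit) substitutions. This function computes that
#' probability for two sequences of `Lused` analysed sites differing at `j`
#' of them, under the finite-sites neutral model of the
#' Templeton--Crandall--Sing / Hudson lineage: per-site substitution counts
#' are independent Poisson with mean `lambda`, a site hit `k` times shows a
#' difference with the Jukes--Cantor visibility `3/4 (1 - (-1/3)^k)`, and
#' the per-site divergence is estimated from the pair itself
#' (`q = j / Lused`, `lambda = -3/4 log(1 - 4q/3)`). The probability of
#' parsimony is then the conditional probability that every differing site
#' was hit exactly once and every identical site not at all:
#' \deqn{P(j) = \left(\frac{\lambda e^{-\lambda}}{q}\right)^{j}
#'   \left(\frac{e^{-\lambda}}{1-q}\right)^{L-j}.}
#' `P(0) = 1`, `P` is strictly decreasing in `j` at fixed `Lused`, and
#' saturated pairs (`q >= 3/4`, beyond the Jukes--Cantor horizon) get
#' probability 0.
#'
#' @param j Number of observed differences (integer >= 0).
#' @param Lused Number of analysed sites (>= 1, `j <= Lused`).
#' @return Probability in `[0, 1]`.
#' @examples
#' parsimonyProbability(1, 658)   # > 0.95: single steps are safe
#' parsimonyProbability(20, 658)  # < 0.95: too many steps to trust
#' @export
parsimonyProbability <- function(j, Lused) {
  if (length(j) != 1L || j < 0 || j != round(j)) stop("j must be an integer >= 0")
  if (Lused < 1) stop("Lused must be >= 1")
  if (j > Lused) stop("j cannot exceed Lused")
  if (j == 0) return(1)
  m <- as.numeric(Lused)
  q <- j / m
  if (q >= 3 / 4) return(0)
  lambda <- -3 / 4 * log(1 - 4 * q / 3)
  lnP <- j * (log(lambda) - lambda - log(q)) +
    (m - j) * (-lambda - log1p(-q))
  exp(lnP)
}

#' Connection limit of a statistical-parsimony network
#'
#' The largest number of mutational steps whose probability of parsimony
#' ([parsimonyProbability()]) is at least `confidence`; haplotype pairs
#' farther apart than this are left unconnected. 0.95 is the method's
#' defining constant.
#'
#' @param Lused Number of analysed sites.
#' @param confidence Confidence level in (0, 1); default 0.95.
#' @return A [ParsimonyLimit-class].
#' @examples
#' connectionLimit(658)
#' @export
connectionLimit <- function(Lused, confidence = 0.95) {
  if (Lused < 1) stop("Lused must be >= 1")
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)")
  j <- 0L
  while (j < Lused && parsimonyProbability(j + 1L, Lused) >= confidence)
    j <- j + 1L
  new("ParsimonyLimit", limit = j, confidence = confidence,
      Lused = as.integer(Lused))
}

#' Build a statistical-parsimony haplotype network
#'
#' Agglomerative construction: candidate haplotype pairs are sorted by
#' ascending mutational distance (ties: larger combined count first, then
#' lexicographic id pair -- the "connect frequent haplotypes first"
#' heuristic made deterministic) and a pair is linked iff its distance is
#' within the connection limit and it spans two components. A link of
#' length `j` inserts `j - 1` inferred intermediate nodes (`mv1`, `mv2`,
#' ...) so every edge represents exactly one substitution. A candidate
#' whose endpoints are already connected is skipped, so the result is a
#' forest (no reticulation).
#'
#' @param table A [HaplotypeTable-class].
#' @param limit A [ParsimonyLimit-class] (from [connectionLimit()]) or a
#'   plain integer number of steps >= 1.
#' @return A [HaplotypeNetwork-class].
#' @examples
#' aln <- AlignedSeqSet(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACTA"))
#' tab <- collapseHaplotypes(aln, c(s1 = "A", s2 = "A", s3 = "B"))
#' buildNetwork(tab, connectionLimit(sitesUsed(tab)))
#' @export
buildNetwork <- function(table, limit) {
  stopifnot(is(table, "HaplotypeTable"))
  if (is(limit, "ParsimonyLimit")) {
    lim <- limit@limit
  } else {
    lim <- as.integer(limit)
    limit <- new("ParsimonyLimit", limit = lim, confidence = 0.95,
                 Lused = sitesUsed(table))
  }
  if (lim < 1L) stop("connection limit must be >= 1 to build a network")
  ids <- hapIds(table)
  d <- hapDist(table)
  cn <- hapCounts(table)
  total <- rowSums(cn)
  k <- length(ids)

  # candidate pairs within the limit, deterministic order
  cand <- which(upper.tri(d) & d <= lim & d >= 1L, arr.ind = TRUE)
  if (nrow(cand)) {
    cd <- d[cand]
    cc <- total[cand[, 1L]] + total[cand[, 2L]]
    pa <- pmin(ids[cand[, 1L]], ids[cand[, 2L]])
    pb <- pmax(ids[cand[, 1L]], ids[cand[, 2L]])
    ord <- order(cd, -cc, pa, pb)
    cand <- cand[ord, , drop = FALSE]
  }

  comp <- seq_len(k)                       # union-find over sampled nodes
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }

  edges <- character(0)                    # interleaved a,b pairs
  mv <- 0L
  mvNodes <- character(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    ri <- find(i); rj <- find(j)
    if (ri == rj) next                     # would close a loop: skip
    comp[ri] <- rj
    steps <- d[i, j]
    chain <- ids[i]
    if (steps > 1L) {
      newMv <- paste0("mv", mv + seq_len(steps - 1L))
      mv <- mv + steps - 1L
      mvNodes <- c(mvNodes, newMv)
      chain <- c(chain, newMv)
    }
    chain <- c(chain, ids[j])
    for (s in seq_len(length(chain) - 1L))
      edges <- c(edges, chain[s], chain[s + 1L])
  }

  allNodes <- c(ids, mvNodes)
  g <- igraph::make_empty_graph(n = length(allNodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = allNodes)
  g <- igraph::set_vertex_attr(g, "isInferred",
                               value = c(rep(FALSE, k),
                                         rep(TRUE, length(mvNodes))))
  g <- igraph::set_vertex_attr(g, "totalCount",
                               value = c(unname(total),
                                         rep(0L, length(mvNodes))))
  for (p in colnames(cn))
    g <- igraph::set_vertex_attr(g, paste0("count_", p),
                                 value = c(unname(cn[, p]),
                                           rep(0L, length(mvNodes))))
  if (length(edges)) g <- igraph::add_edges(g, edges)
  new("HaplotypeNetwork", graph = g, limit = limit)
}

#' Export a haplotype network
#'
#' Writes the network with its node attributes (`name`, `isInferred`,
#' `totalCount`, `count_<population>`) as GraphML or GML, or the bare edge
#' list as a two-column TSV (`node_a`, `node_b`).
#'
#' @param net A [HaplotypeNetwork-class].
#' @param path Output file path.
#' @param format `"graphml"`, `"gml"` or `"tsv-edgelist"`.
#' @return Invisibly, `path`.
#' @export
exportNetwork <- function(net, path,
                          format = c("graphml", "gml", "tsv-edgelist")) {
  stopifnot(is(net, "HaplotypeNetwork"))
  format <- match.arg(format)
  g <- networkGraph(net)
  if (format == "tsv-edgelist") {
    el <- igraph::as_edgelist(g)
    utils::write.table(
      data.frame(node_a = el[, 1L], node_b = el[, 2L]),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  # GraphML/GML writers do not carry R logicals; encode the flag as 0/1
  g <- igraph::set_vertex_attr(g, "isInferred",
                               value = as.integer(igraph::V(g)$isInferred))
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
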