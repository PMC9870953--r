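# plain transcription of the documented probability model, evaluated
# step-by-step with no shared code
transcribedParsProb <- function(j, m) {
  if (j == 0) return(1)
  q <- j / m
  if (q >= 0.75) return(0)
  lambda <- -0.75 * log(1 - (4 / 3) * q)
  pDiffSingle <- lambda * exp(-lambda)       # Poisson(1) and visible
  pSameZero <- exp(-lambda)                  # Poisson(0)
  pDiff <- 0.75 * (1 - exp(-(4 / 3) * lambda))  # JC visibility, any hits
  (pDiffSingle / pDiff)^j * (pSameZero / (1 - pDiff))^(m - j)
}

test_that("parsimony probability behaves like a probability of no multiple hits", {
  expect_equal(parsimonyProbability(0, 658), 1)
  expect_gt(parsimonyProbability(1, 658), 0.95)
  p <- vapply(1:15, parsimonyProbability, numeric(1), Lused = 658)
  expect_true(all(diff(p) < 0))          # strictly decreasing in j
  expect_true(all(p >= 0 & p <= 1))
  expect_error(parsimonyProbability(-1, 658), "integer")
  expect_error(parsimonyProbability(3, 0), "Lused")
  expect_error(parsimonyProbability(10, 5), "exceed")
  # saturated divergence is never parsimonious
  expect_equal(parsimonyProbability(80, 100), 0)
})

test_that("implementation matches an independent transcription of the model", {
  for (m in c(50, 200, 658, 1200)) for (j in c(0:5, 10, 20))
    expect_equal(parsimonyProbability(j, m), transcribedParsProb(j, m),
                 tolerance = 1e-12, info = paste(j, m))
})

test_that("the connection limit brackets the confidence level", {
  for (L in c(100, 350, 658, 1500)) {
    lim <- connectionLimit(L, 0.95)
    expect_gte(parsimonyProbability(lim@limit, L), 0.95)
    expect_lt(parsimonyProbability(lim@limit + 1L, L), 0.95)
  }
  expect_gte(connectionLimit(658, 0.95)@limit, 3)
  # stricter confidence can only lower the limit
  lims <- vapply(c(0.9, 0.95, 0.99, 0.999),
                 function(cf) connectionLimit(658, cf)@limit, integer(1))
  expect_true(all(diff(lims) <= 0))
  # longer alignments support longer connections
  byL <- vapply(c(100, 300, 658, 1500),
                function(L) connectionLimit(L, 0.95)@limit, integer(1))
  expect_true(all(diff(byL) >= 0))
})

test_that("simple networks link adjacent haplotypes without intermediates", {
  aln <- AlignedSeqSet(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGA"))
  tab <- collapseHaplotypes(aln, c(s1 = "p", s2 = "p", s3 = "p"))
  net <- buildNetwork(tab, 5L)
  g <- networkGraph(net)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(sum(igraph::V(g)$isInferred), 0L)
})

test_that("pairs beyond the connection limit stay in separate components", {
  aln <- AlignedSeqSet(c(s1 = "AAAAAAAA", s2 = "TTTTAAAA"))  # d = 4
  tab <- collapseHaplotypes(aln, c(s1 = "p", s2 = "p"))
  far <- buildNetwork(tab, 3L)
  expect_equal(igraph::count_components(networkGraph(far)), 2L)
  near <- buildNetwork(tab, 4L)
  expect_equal(igraph::count_components(networkGraph(near)), 1L)
  # a link of length 4 inserts exactly 3 intermediates
  expect_equal(sum(igraph::V(networkGraph(near))$isInferred), 3L)
})

test_that("the fixture network matches the published topology", {
  ft <- fixtureTable(seed = 1)
  tab <- ft$table
  net <- buildNetwork(tab, connectionLimit(sitesUsed(tab)))
  g <- networkGraph(net)
  expect_equal(igraph::count_components(g), 1L)

  tot <- rowSums(hapCounts(tab))
  h1 <- names(tot)[tot == 74]
  d <- hapDist(tab)
  h9 <- names(which(d[h1, ] == 3))
  path <- igraph::shortest_paths(g, h1, h9)$vpath[[1]]
  expect_equal(length(path) - 1L, 3L)       # three substitutions, three edges
  inner <- igraph::V(g)$isInferred[path[2:3]]
  expect_true(all(inner))                   # exactly 2 inferred intermediates
  expect_equal(sum(igraph::V(g)$isInferred), 2L)

  # node bookkeeping: sampled + sum(link length - 1); counts conserved
  expect_equal(igraph::vcount(g), 6L + 2L)
  expect_equal(sum(igraph::V(g)$totalCount), 119L)
  expect_true(all(igraph::degree(g)[igraph::V(g)$isInferred] >= 2))
  # every sampled pair sits within the limit's graph distance
  samp <- igraph::V(g)[!igraph::V(g)$isInferred]
  dg <- igraph::distances(g, samp, samp)
  expect_lte(max(dg), net@limit@limit)
})

test_that("additive fixtures balance path lengths against segregating sites", {
  # no homoplasy: total spanning path length from the central haplotype
  # equals the segregating-site count of the whole dataset
  ft <- fixtureTable(seed = 1)
  net <- buildNetwork(ft$table, connectionLimit(sitesUsed(ft$table)))
  g <- networkGraph(net)
  expect_equal(igraph::ecount(g),
               segregatingSites(completeDeletion(ft$fx$seqs)$seqs))
})

test_that("network construction is deterministic under record permutation", {
  set.seed(9)
  ra <- randomAlignment(30, 80)
  tab1 <- collapseHaplotypes(AlignedSeqSet(ra$seqs), ra$partition)
  perm <- sample(length(ra$seqs))
  tab2 <- collapseHaplotypes(AlignedSeqSet(ra$seqs[perm]), ra$partition)
  n1 <- buildNetwork(tab1, 10L)
  n2 <- buildNetwork(tab2, 10L)
  e1 <- igraph::as_edgelist(networkGraph(n1))
  e2 <- igraph::as_edgelist(networkGraph(n2))
  key <- function(e, tab) {
    seqOf <- function(v) ifelse(startsWith(v, "mv"), v,
                                unname(hapSequences(tab)[v]))
    sort(paste(pmin(seqOf(e[, 1]), seqOf(e[, 2])),
               pmax(seqOf(e[, 1]), seqOf(e[, 2]))))
  }
  expect_equal(key(e1, tab1), key(e2, tab2))
})

test_that("network export formats round-trip and carry attributes", {
  ft <- fixtureTable(seed = 1)
  net <- buildNetwork(ft$table, connectionLimit(sitesUsed(ft$table)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  exportNetwork(net, tsv, "tsv-edgelist")
  el <- read.delim(tsv)
  expect_equal(nrow(el), igraph::ecount(networkGraph(net)))

  gm <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(net, gm, "graphml")
  back <- igraph::read_graph(gm, format = "graphml")
  expect_true(igraph::isomorphic(back, networkGraph(net)))
  expect_equal(sum(igraph::V(back)$totalCount), 119)
  expect_equal(sum(igraph::V(back)$count_QLD), 12)

  gml <- withr::local_tempfile(fileext = ".gml")
  exportNetwork(net, gml, "gml")
  expect_true(file.size(gml) > 0)
  expect_error(exportNetwork(net, tsv, "dot"))
})
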