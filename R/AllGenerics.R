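#' @include AllClasses.R
NULL

#' Accessors for AlignedSeqSet
#'
#' `sampleIds()` returns the sample identifiers, `seqLength()` the number of
#' alignment columns, `sequences()` the underlying
#' [Biostrings::DNAStringSet].
#'
#' @param x An [AlignedSeqSet-class].
#' @return `sampleIds()`: character vector; `seqLength()`: integer;
#'   `sequences()`: a `DNAStringSet`.
#' @examples
#' aln <- AlignedSeqSet(c(s1 = "ACGT", s2 = "ACGA"))
#' sampleIds(aln)
#' seqLength(aln)
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))

#' @rdname sampleIds
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' Accessors for HaplotypeTable
#'
#' `hapIds()` returns haplotype identifiers, `hapSequences()` the collapsed
#' sequences (over retained columns), `hapCounts()` the haplotype x
#' population count matrix, `hapDist()` the pairwise mutational-distance
#' matrix, `populations()` the population labels and `sitesUsed()` the number
#' of retained alignment columns.
#'
#' @param x A [HaplotypeTable-class].
#' @return See description; matrices carry haplotype ids as dimnames.
#' @export
setGeneric("hapIds", function(x) standardGeneric("hapIds"))

#' @rdname hapIds
#' @export
setGeneric("hapSequences", function(x) standardGeneric("hapSequences"))

#' @rdname hapIds
#' @export
setGeneric("hapCounts", function(x) standardGeneric("hapCounts"))

#' @rdname hapIds
#' @export
setGeneric("hapDist", function(x) standardGeneric("hapDist"))

#' @rdname hapIds
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname hapIds
#' @export
setGeneric("sitesUsed", function(x) standardGeneric("sitesUsed"))

setMethod("sampleIds", "AlignedSeqSet", function(x) names(x@seqs))
setMethod("seqLength", "AlignedSeqSet",
          function(x) unique(Biostrings::width(x@seqs)))
setMethod("sequences", "AlignedSeqSet", function(x) x@seqs)

#' @describeIn sampleIds Number of sequences in the alignment.
#' @export
setMethod("length", "AlignedSeqSet", function(x) length(x@seqs))

#' @describeIn sampleIds Named character vector of the aligned sequences.
#' @export
setMethod("as.character", "AlignedSeqSet",
          function(x) as.character(x@seqs))

setMethod("show", "AlignedSeqSet", function(object) {
  cat(sprintf("AlignedSeqSet: %d sequences x %d columns\n",
              length(object@seqs), seqLength(object)))
  ids <- sampleIds(object)
  shown <- utils::head(ids, 4L)
  cat("  ids: ", paste(shown, collapse = ", "),
      if (length(ids) > 4L) ", ..." else "", "\n", sep = "")
})

setMethod("hapIds", "HaplotypeTable", function(x) names(x@haplotypes))
setMethod("hapSequences", "HaplotypeTable", function(x) x@haplotypes)
setMethod("hapCounts", "HaplotypeTable", function(x) x@counts)
setMethod("hapDist", "HaplotypeTable", function(x) x@dist)
setMethod("populations", "HaplotypeTable", function(x) colnames(x@counts))
setMethod("sitesUsed", "HaplotypeTable", function(x) x@Lused)

setMethod("show", "HaplotypeTable", function(object) {
  cat(sprintf(
    "HaplotypeTable: %d haplotypes, %d sequences, %d populations (L_used = %d)\n",
    length(object@haplotypes), sum(object@counts), ncol(object@counts),
    object@Lused))
  tot <- rowSums(object@counts)
  cat("  counts:", paste(sprintf("%s=%d", names(tot), tot), collapse = " "),
      "\n")
})

setMethod("show", "ParsimonyLimit", function(object) {
  cat(sprintf(
    "ParsimonyLimit: %d steps at %.0f%% confidence (L_used = %d)\n",
    object@limit, 100 * object@confidence, object@Lused))
})

setMethod("show", "HaplotypeNetwork", function(object) {
  g <- object@graph
  inf <- igraph::V(g)$isInferred
  cat(sprintf(
    "HaplotypeNetwork: %d sampled + %d inferred nodes, %d edges, %d component(s)\n",
    sum(!inf), sum(inf), igraph::ecount(g),
    igraph::count_components(g)))
})

setMethod("show", "ResponseFunction", function(object) {
  cat(sprintf(
    "ResponseFunction (%s): peak %.1f%% cover at %.1f degC, zero at >= %.1f degC\n",
    object@form, object@peakCover, object@tOpt, object@tMax))
})

setMethod("show", "CoverScenario", function(object) {
  cat(sprintf(
    "CoverScenario: %d x %d grid, lat [%.2f, %.2f], sea level -%.0f m, depth band %g-%g m\n",
    nrow(object@sst), ncol(object@sst), min(object@lat), max(object@lat),
    object@seaLevelOffset, object@depthBand[1L], object@depthBand[2L]))
})

#' Graph underlying a haplotype network
#'
#' @param x A [HaplotypeNetwork-class].
#' @return The [igraph::igraph] object with node attributes `name`,
#'   `isInferred`, `totalCount` and `count_<population>`.
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

setMethod("networkGraph", "HaplotypeNetwork", function(x) x@graph)
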