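#' @import methods
#' @importFrom Biostrings DNAStringSet width
NULL

# Alphabet accepted inside an alignment: the 15 IUPAC nucleotide codes plus
# the gap character. '+' and '.' (allowed by DNAString) are rejected.
.ALIGN_ALPHABET <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                     "V", "H", "D", "B", "N", "-")

#' AlignedSeqSet: an aligned set of equal-length DNA sequences
#'
#' Container for a multiple sequence alignment of DNA barcodes (typically a
#' ~658 bp COI fragment). Every record has the same number of columns; sample
#' identifiers are unique and non-empty; only IUPAC nucleotide symbols and the
#' gap character `-` are permitted.
#'
#' @slot seqs A named [Biostrings::DNAStringSet] of identical widths.
#'
#' @seealso [AlignedSeqSet()], [readAlignedFasta()], [seqLength()],
#'   [sampleIds()]
#' @exportClass AlignedSeqSet
setClass("AlignedSeqSet", representation(seqs = "DNAStringSet"))

setValidity("AlignedSeqSet", function(object) {
  s <- object@seqs
  if (length(s) == 0L)
    return("alignment must contain at least one sequence")
  w <- unique(Biostrings::width(s))
  if (length(w) != 1L)
    return(sprintf("sequences must have identical length; saw widths {%s}",
                   paste(w, collapse = ", ")))
  if (w < 1L)
    return("alignment length must be >= 1")
  ids <- names(s)
  if (is.null(ids) || any(!nzchar(ids)))
    return("all sequences must carry non-empty sample ids")
  if (anyDuplicated(ids))
    return(sprintf("duplicate sample ids: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  chars <- unique(strsplit(paste(as.character(s), collapse = ""), "")[[1L]])
  bad <- setdiff(chars, .ALIGN_ALPHABET)
  if (length(bad))
    return(sprintf("disallowed symbols in alignment: %s",
                   paste(bad, collapse = ", ")))
  TRUE
})

#' Distinct haplotypes with per-population counts and mutational distances
#'
#' Result of collapsing an alignment (after complete-deletion site filtering)
#' into its distinct sequences. Haplotype ids are assigned deterministically:
#' descending total count, ties broken by first occurrence in the input.
#'
#' @slot haplotypes Named character vector; each element is the haplotype
#'   sequence over the retained columns, names are haplotype ids.
#' @slot counts Integer matrix, haplotypes x populations; column sums are the
#'   population sample sizes.
#' @slot dist Symmetric integer matrix of pairwise Hamming distances between
#'   haplotype sequences.
#' @slot Lused Integer; number of alignment columns retained by the site
#'   filter (the effective sequence length used for distances and
#'   per-site statistics).
#'
#' @seealso [collapseHaplotypes()], [diversityReport()], [buildNetwork()]
#' @exportClass HaplotypeTable
setClass("HaplotypeTable", representation(
  haplotypes = "character", counts = "matrix", dist = "matrix",
  Lused = "integer"))

setValidity("HaplotypeTable", function(object) {
  h <- object@haplotypes
  if (length(h) == 0L) return("at least one haplotype required")
  if (anyDuplicated(h)) return("haplotype sequences must be pairwise distinct")
  if (is.null(names(h)) || anyDuplicated(names(h)))
    return("haplotype ids must be unique and non-empty")
  cn <- object@counts
  if (nrow(cn) != length(h) || !identical(rownames(cn), names(h)))
    return("counts rows must match haplotype ids")
  if (any(cn < 0) || any(cn != round(cn)))
    return("counts must be non-negative integers")
  if (any(rowSums(cn) == 0))
    return("every haplotype must be observed at least once")
  d <- object@dist
  if (!identical(dim(d), c(length(h), length(h))))
    return("dist must be square over the haplotypes")
  if (any(d != t(d)) || any(diag(d) != 0))
    return("dist must be symmetric with zero diagonal")
  if (length(h) > 1L && any(d[upper.tri(d)] < 1))
    return("off-diagonal distances must be >= 1 for distinct haplotypes")
  if (any(d > object@Lused))
    return("distances cannot exceed the number of retained columns")
  TRUE
})

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps `limit` for which the probability of
#' a parsimonious (no superimposed substitutions) connection between two
#' haplotypes is at least `confidence`, at effective alignment length `Lused`.
#'
#' @slot limit Integer number of steps (0 when even one step falls below the
#'   confidence level, which can happen for very short alignments).
#' @slot confidence Numeric in (0, 1); 0.95 is the method's defining constant.
#' @slot Lused Integer effective alignment length.
#'
#' @seealso [connectionLimit()], [parsimonyProbability()]
#' @exportClass ParsimonyLimit
setClass("ParsimonyLimit", representation(
  limit = "integer", confidence = "numeric", Lused = "integer"))

setValidity("ParsimonyLimit", function(object) {
  if (object@limit < 0L) return("limit must be >= 0")
  if (object@confidence <= 0 || object@confidence >= 1)
    return("confidence must be in (0, 1)")
  if (object@Lused < 1L) return("Lused must be >= 1")
  TRUE
})

#' Statistical-parsimony haplotype network
#'
#' An undirected graph whose nodes are the sampled haplotypes plus inferred
#' intermediates ("median vectors", ids `mv1`, `mv2`, ...) inserted so that
#' every edge represents exactly one substitution. Sampled nodes carry total
#' and per-population counts; intermediates have count zero and degree >= 2.
#'
#' @slot graph An [igraph::igraph] object with vertex attributes `name`,
#'   `isInferred`, `totalCount`, and one `count_<population>` attribute per
#'   population.
#' @slot limit The [ParsimonyLimit-class] used during construction.
#'
#' @seealso [buildNetwork()], [exportNetwork()]
#' @exportClass HaplotypeNetwork
setClass("HaplotypeNetwork", representation(
  graph = "ANY", limit = "ParsimonyLimit"))

setValidity("HaplotypeNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::any_loop(g)) return("self-loops are not allowed")
  if (igraph::any_multiple(g)) return("duplicate edges are not allowed")
  inf <- igraph::V(g)$isInferred
  if (any(inf) && any(igraph::degree(g)[inf] < 2))
    return("inferred intermediate nodes must have degree >= 2")
  TRUE
})

#' Thermal response curve linking kelp cover to sea surface temperature
#'
#' A continuous, unimodal cover--SST relationship. The built-in `"quadratic"`
#' form peaks at `tOpt` and declines symmetrically to zero at `tMax` (and at
#' the mirrored temperature below the optimum), staying zero beyond. A
#' `"custom"` form accepts any user function (e.g. a curve fitted to field
#' surveys or interpolated from a table); it is checked numerically at
#' construction for the peak/threshold/range conditions.
#'
#' @slot form `"quadratic"` or `"custom"`.
#' @slot tOpt Optimal mean annual SST in degrees C (default 23).
#' @slot tMax Upper thermal threshold in degrees C at and beyond which cover
#'   is zero (default 26).
#' @slot peakCover Cover (\%) attained at `tOpt`, in (0, 100].
#' @slot fun For `"custom"`: a vectorised function of SST returning cover.
#'
#' @seealso [responseFunction()], [responseCover()]
#' @exportClass ResponseFunction
setClass("ResponseFunction", representation(
  form = "character", tOpt = "numeric", tMax = "numeric",
  peakCover = "numeric", fun = "ANY"))

setValidity("ResponseFunction", function(object) {
  if (!object@form %in% c("quadratic", "custom"))
    return("form must be 'quadratic' or 'custom'")
  if (object@tMax <= object@tOpt) return("tMax must exceed tOpt")
  if (object@peakCover <= 0 || object@peakCover > 100)
    return("peakCover must be in (0, 100]")
  if (object@form == "custom") {
    f <- object@fun
    if (!is.function(f)) return("custom form requires a function in 'fun'")
    probe <- seq(object@tOpt - 2 * (object@tMax - object@tOpt),
                 object@tMax + 5, length.out = 201L)
    v <- f(probe)
    if (abs(f(object@tOpt) - object@peakCover) > 1e-8)
      return("custom curve must attain peakCover at tOpt")
    if (any(f(seq(object@tMax, object@tMax + 10, by = 0.5)) != 0))
      return("custom curve must be zero at and beyond tMax")
    if (any(v < -1e-12 | v > object@peakCover + 1e-8))
      return("custom curve must stay within [0, peakCover]")
  }
  TRUE
})

#' A hindcast scenario: SST, bathymetry, sea level, depth band
#'
#' Bundles the co-registered gridded inputs of one cover prediction. Grids
#' are latitude x longitude matrices on a regular grid; latitude decreases
#' southward (southern-hemisphere values are negative) and bathymetry is
#' present-day depth in metres, positive downward. `seaLevelOffset` is how
#' much lower sea level stands than today (0 for the present day, ~120 m for
#' the Last Glacial Maximum), and `depthBand` is the habitable depth range in
#' metres below the scenario's sea level (0--80 m for this kelp).
#'
#' @slot sst Numeric matrix of mean annual SST (degrees C), rows = latitudes.
#' @slot bathymetry Numeric matrix of present-day depth (m, positive down),
#'   same shape as `sst`.
#' @slot lat Numeric vector of row latitudes (degrees, negative south).
#' @slot lon Numeric vector of column longitudes (degrees east).
#' @slot seaLevelOffset Metres of sea-level lowering relative to present.
#' @slot depthBand Length-2 numeric, min < max, metres below scenario sea
#'   level.
#' @slot latRange Length-2 numeric (south, north) latitude window analysed.
#'
#' @seealso [coverScenario()], [depthMask()], [predictCoverGrid()]
#' @exportClass CoverScenario
setClass("CoverScenario", representation(
  sst = "matrix", bathymetry = "matrix", lat = "numeric", lon = "numeric",
  seaLevelOffset = "numeric", depthBand = "numeric", latRange = "numeric"))

setValidity("CoverScenario", function(object) {
  if (!identical(dim(object@sst), dim(object@bathymetry)))
    return("sst and bathymetry grids must be co-registered (same shape)")
  if (nrow(object@sst) != length(object@lat))
    return("lat must have one entry per grid row")
  if (ncol(object@sst) != length(object@lon))
    return("lon must have one entry per grid column")
  if (length(object@depthBand) != 2L ||
      object@depthBand[1L] >= object@depthBand[2L])
    return("depthBand must be (min, max) with min < max")
  if (length(object@latRange) != 2L ||
      object@latRange[1L] >= object@latRange[2L])
    return("latRange must be (south, north) with south < north")
  if (object@seaLevelOffset < 0)
    return("seaLevelOffset must be >= 0 m")
  TRUE
})
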