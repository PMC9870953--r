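#' @include paleocover.R
NULL

# run expr with a locally seeded RNG, restoring the caller's stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' COI barcoding primers Gaz F2 / Gaz R2
#'
#' The degenerate primer pair used to amplify the ~658 bp COI-5' barcode in
#' kelp: forward `CCAACCAYAAAGATATWGGTAC`, reverse `GGATGACCAAARAACCAAAA`
#' (both written 5'->3', the reverse on the opposite strand).
#'
#' @return Named character vector with elements `forward` and `reverse`.
#' @export
coiPrimers <- function() {
  c(forward = "CCAACCAYAAAGATATWGGTAC", reverse = "GGATGACCAAARAACCAAAA")
}

#' Deterministic stop-free coding reference sequence
#'
#' Draws `L %/% 3` codons uniformly from the 61 non-stop codons of the given
#' genetic code (plus leftover bases drawn from A/C/G/T), so the result has
#' no internal stop codon in reading frame 0. Fully determined by `seed`.
#'
#' @param L Sequence length in bp (default 658).
#' @param seed Integer seed.
#' @param geneticCode Code table id for the stop set (default `"1"`).
#' @return Character scalar of length `L`.
#' @export
referenceSequence <- function(L = 658L, seed = 1L, geneticCode = "1") {
  code <- Biostrings::getGeneticCode(geneticCode)
  sense <- names(code)[code != "*"]
  .withSeed(seed, {
    cod <- sample(sense, L %/% 3L, replace = TRUE)
    tail <- sample(c("A", "C", "G", "T"), L %% 3L, replace = TRUE)
    paste(c(cod, tail), collapse = "")
  })
}

# substitute column `col` with a base != ref that leaves frame 0 stop-free
.safeSubstitution <- function(refChars, col, geneticCode = "1") {
  code <- Biostrings::getGeneticCode(geneticCode)
  cstart <- col - (col - 1L) %% 3L          # first column of col's codon
  for (b in setdiff(c("G", "A", "T", "C"), refChars[col])) {
    trial <- refChars
    trial[col] <- b
    if (cstart + 2L > length(refChars)) return(b)  # incomplete tail codon
    codon <- paste(trial[cstart:(cstart + 2L)], collapse = "")
    if (is.na(code[codon]) || code[codon] != "*") return(b)
  }
  stop("no stop-free substitution available at column ", col)
}

#' Describe a synthetic haplotype structure
#'
#' A haplotype spec pins down everything [simulateAlignment()] needs: the
#' alignment length, each haplotype's substitutions relative to the
#' (seed-generated) reference, and the haplotype x population count matrix.
#' Substitution lists are data.frames with integer `column` (1-based) and
#' `base`; a haplotype with an empty list is the reference itself.
#'
#' @param L Alignment length in bp.
#' @param substitutions Named list (one element per haplotype) of
#'   data.frames with columns `column`, `base`.
#' @param counts Integer matrix haplotype x population; rownames must match
#'   `names(substitutions)`.
#' @param primerForward,primerReverse Optional concrete primer flanks to
#'   prepend/append (the reverse flank is given as it appears on the read,
#'   i.e. already reverse-complemented).
#' @return A validated list of class `HaplotypeSpec`.
#' @export
haplotypeSpec <- function(L, substitutions, counts, primerForward = NULL,
                          primerReverse = NULL) {
  stopifnot(L >= 1, is.list(substitutions), is.matrix(counts))
  if (!identical(sort(names(substitutions)), sort(rownames(counts))))
    stop("substitutions and counts must name the same haplotypes")
  keys <- vapply(substitutions, function(s) {
    if (nrow(s) == 0L) return("")
    if (anyDuplicated(s$column))
      stop("conflicting substitutions: duplicate column within a haplotype")
    if (any(s$column < 1L | s$column > L))
      stop("substitution column outside [1, L]")
    o <- order(s$column)
    paste(s$column[o], s$base[o], sep = ":", collapse = ";")
  }, character(1L))
  if (anyDuplicated(keys))
    stop("distinct haplotypes must have distinct substitution sets")
  if (any(counts < 0) || any(rowSums(counts) == 0))
    stop("counts must be non-negative with every haplotype observed")
  structure(list(L = as.integer(L), substitutions = substitutions,
                 counts = counts, primerForward = primerForward,
                 primerReverse = primerReverse),
            class = "HaplotypeSpec")
}

#' Expected pairwise distances of a haplotype spec
#'
#' Mutational distances implied directly by the substitution sets (ground
#' truth for parameter-recovery checks): two haplotypes differ at a column
#' iff their resolved bases there differ.
#'
#' @param spec A [haplotypeSpec()].
#' @return Symmetric integer matrix with haplotype dimnames.
#' @export
specDistanceMatrix <- function(spec) {
  stopifnot(inherits(spec, "HaplotypeSpec"))
  ids <- names(spec$substitutions)
  k <- length(ids)
  d <- matrix(0L, k, k, dimnames = list(ids, ids))
  baseAt <- function(s, col) {
    hit <- s$base[s$column == col]
    if (length(hit)) hit else NA_character_  # NA = reference base
  }
  if (k > 1L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    si <- spec$substitutions[[i]]; sj <- spec$substitutions[[j]]
    cols <- union(si$column, sj$column)
    diffs <- vapply(cols, function(cl) {
      a <- baseAt(si, cl); b <- baseAt(sj, cl)
      !identical(a, b)
    }, logical(1L))
    d[i, j] <- d[j, i] <- sum(diffs)
  }
  d
}

#' Sample-to-population partition implied by a spec
#'
#' Matches the deterministic sample ids produced by [simulateAlignment()].
#'
#' @param spec A [haplotypeSpec()].
#' @return Named character vector, sample id -> population.
#' @export
specPartition <- function(spec) {
  stopifnot(inherits(spec, "HaplotypeSpec"))
  ids <- character(0); pops <- character(0)
  for (p in colnames(spec$counts)) {
    n <- sum(spec$counts[, p])
    if (n == 0L) next
    ids <- c(ids, sprintf("%s_%03d", p, seq_len(n)))
    pops <- c(pops, rep(p, n))
  }
  stats::setNames(pops, ids)
}

#' Simulate an alignment from a haplotype spec
#'
#' Generates the stop-free reference with [referenceSequence()] (so the
#' whole alignment passes [translationQc()] in frame 0), applies each
#' haplotype's substitutions, and replicates haplotypes to their
#' per-population counts. Sample ids are `<population>_<i>` in column order
#' of the count matrix; the output is byte-identical for identical
#' `(spec, seed)`. Errors if a substitution equals the reference base there
#' (two "distinct" haplotypes would collapse together).
#'
#' @param spec A [haplotypeSpec()].
#' @param seed Integer seed for the reference sequence.
#' @return An [AlignedSeqSet-class]; see [specPartition()] for the matching
#'   population map.
#' @export
simulateAlignment <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "HaplotypeSpec"))
  refChars <- strsplit(referenceSequence(spec$L, seed), "")[[1L]]
  hapSeq <- vapply(names(spec$substitutions), function(h) {
    s <- spec$substitutions[[h]]
    chars <- refChars
    if (nrow(s)) {
      if (any(chars[s$column] == s$base))
        stop("substitution equals the reference base (haplotype ", h,
             "); choose a different base or seed")
      chars[s$column] <- s$base
    }
    paste(chars, collapse = "")
  }, character(1L))
  if (!is.null(spec$primerForward))
    hapSeq[] <- paste0(spec$primerForward, hapSeq)
  if (!is.null(spec$primerReverse))
    hapSeq[] <- paste0(hapSeq, spec$primerReverse)
  part <- specPartition(spec)
  seqs <- character(length(part))
  i <- 0L
  for (p in colnames(spec$counts)) for (h in rownames(spec$counts)) {
    cnt <- spec$counts[h, p]
    if (cnt > 0L) {
      seqs[i + seq_len(cnt)] <- hapSeq[h]
      i <- i + cnt
    }
  }
  AlignedSeqSet(stats::setNames(seqs, names(part)))
}

#' The deterministic study fixture: 119 COI sequences, 6 haplotypes
#'
#' Builds the alignment that mirrors the published south-west Pacific
#' dataset: 119 sequences of 658 bp in four regional populations
#' (SA/Vic/Tas n=63, NSW n=26, QLD n=12, LHI/NI/KI/NZ n=18) carrying six
#' haplotypes at the published counts -- H1 n=74, H12 n=35, H10 n=7, and
#' singletons H8, H9, H11 -- with H9 three substitutions from H1 and every
#' other haplotype one substitution from its parent. Substitution columns
#' are evenly spaced and chosen to keep frame 0 stop-free, so the fixture
#' is stable and passes translation QC. The SA/Vic/Tas H1 count (28) is the
#' arithmetic remainder 74 - 25 - 3 - 18 of the published totals; the
#' manifest records that derivation and every substitution.
#'
#' @param seed Integer seed for the reference sequence.
#' @param h11Parent `"H10"` (default) or `"H1"`: which haplotype H11 hangs
#'   off (both are one substitution away and both give QLD S = 5; published
#'   sources do not settle it).
#' @param withPrimers Prepend/append concrete Gaz F2/R2 primer flanks
#'   (22 + 20 bp), yielding 700 bp reads for trimming exercises.
#' @param dir Optional output directory; when given, writes
#'   `fixture.fasta`, `fixture_popmap.tsv` and `fixture_manifest.json`.
#' @return A list: `seqs` ([AlignedSeqSet-class]), `partition`, `spec`
#'   (the [haplotypeSpec()]), `manifest` (list), and `paths` when `dir` is
#'   given.
#' @examples
#' fx <- makePaperFixture(seed = 1)
#' length(fx$seqs)  # 119
#' @export
makePaperFixture <- function(seed = 1L, h11Parent = c("H10", "H1"),
                             withPrimers = FALSE, dir = NULL) {
  h11Parent <- match.arg(h11Parent)
  L <- 658L
  refChars <- strsplit(referenceSequence(L, seed), "")[[1L]]
  cols <- as.integer(round(L * (1:7) / 8))   # evenly spaced, non-overlapping
  sub1 <- function(cl) data.frame(
    column = cl, base = vapply(cl, function(x)
      .safeSubstitution(refChars, x), character(1L)),
    stringsAsFactors = FALSE)
  subs <- list(
    H1  = data.frame(column = integer(0), base = character(0)),
    H12 = sub1(cols[1L]),
    H8  = sub1(cols[2L]),
    H10 = sub1(cols[3L]),
    H9  = sub1(cols[4:6]))
  subs$H11 <- rbind(if (h11Parent == "H10") subs$H10 else subs$H1[0, ],
                    sub1(cols[7L]))
  counts <- matrix(0L, nrow = 6L, ncol = 4L,
                   dimnames = list(c("H1", "H12", "H8", "H10", "H9", "H11"),
                                   c("SA_Vic_Tas", "NSW", "QLD",
                                     "LHI_NI_KI_NZ")))
  counts["H12", "SA_Vic_Tas"] <- 35L
  counts["H1", "SA_Vic_Tas"] <- 28L         # 74 - 25 - 3 - 18
  counts["H1", "NSW"] <- 25L
  counts["H8", "NSW"] <- 1L
  counts["H1", "QLD"] <- 3L
  counts["H10", "QLD"] <- 7L
  counts["H11", "QLD"] <- 1L
  counts["H9", "QLD"] <- 1L
  counts["H1", "LHI_NI_KI_NZ"] <- 18L

  primers <- coiPrimers()
  fwdFlank <- "CCAACCACAAAGATATAGGTAC"      # Gaz F2 with Y->C, W->A
  revFlank <- "TTTTGGTTTTTTGGTCATCC"        # revcomp of Gaz R2 with R->A
  spec <- haplotypeSpec(L, subs[c("H1", "H12", "H8", "H10", "H9", "H11")],
                        counts,
                        primerForward = if (withPrimers) fwdFlank,
                        primerReverse = if (withPrimers) revFlank)
  seqs <- simulateAlignment(spec, seed)
  partition <- specPartition(spec)
  manifest <- list(
    seed = seed, L = L, h11_parent = h11Parent, with_primers = withPrimers,
    populations = as.list(colSums(counts)),
    haplotype_totals = as.list(rowSums(counts)),
    substitutions = lapply(spec$substitutions, function(s)
      if (nrow(s)) as.list(stats::setNames(s$base, s$column)) else list()),
    derivations = list(
      sa_vic_tas_H1 = "74 - 25 - 3 - 18 = 28 (arithmetic remainder of published totals)",
      implied_sa_vic_tas_Hd = round(haplotypeDiversity(c(28, 35)), 3),
      implied_all_Hd = round(haplotypeDiversity(rowSums(counts)), 3)),
    primers = as.list(primers))
  out <- list(seqs = seqs, partition = partition, spec = spec,
              manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "fixture.fasta")
    writeAlignedFasta(seqs, fa)
    pm <- file.path(dir, "fixture_popmap.tsv")
    utils::write.table(
      data.frame(sample_id = names(partition), population = partition),
      pm, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    mf <- file.path(dir, "fixture_manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
    out$paths <- c(fasta = fa, popmap = pm, manifest = mf)
  }
  out
}

#' Describe a synthetic SST / bathymetry grid
#'
#' The SST model is a latitudinally graded field,
#' `SST(lat) = sstBase + gradient * (lat - refLat) - cooling + noise`,
#' with `gradient` in degrees C per degree latitude (positive: warmer toward
#' the equator) and optional uniform glacial cooling; bathymetry is a
#' monotone cross-shelf ramp from 0 m at the coastal column to `maxDepth`
#' at the offshore edge, identical in every scenario. All randomness (the
#' Gaussian SST noise) is fixed by `seed`.
#'
#' @param latRange `(south, north)` latitudes; default `c(-38, -18)`.
#' @param lonRange Longitudes spanned; default `c(150, 154)`.
#' @param resolution Grid step in degrees; default 0.5.
#' @param sstBase Mean annual SST (degrees C) at `refLat`; default 14.
#' @param refLat Reference latitude for `sstBase`; default the southern edge.
#' @param gradient Degrees C per degree latitude; default 0.8.
#' @param cooling Uniform SST offset subtracted everywhere (degrees C), e.g.
#'   a glacial cooling; default 0.
#' @param noiseSd Gaussian noise standard deviation (degrees C); default
#'   0.25.
#' @param maxDepth Offshore depth of the bathymetry ramp (m); default 250.
#' @param seed Integer seed.
#' @return A validated list of class `GridSpec`.
#' @export
gridSpec <- function(latRange = c(-38, -18), lonRange = c(150, 154),
                     resolution = 0.5, sstBase = 14, refLat = latRange[1L],
                     gradient = 0.8, cooling = 0, noiseSd = 0.25,
                     maxDepth = 250, seed = 1L) {
  stopifnot(resolution > 0, noiseSd >= 0, maxDepth > 0,
            latRange[1L] < latRange[2L], lonRange[1L] < lonRange[2L])
  structure(list(latRange = latRange, lonRange = lonRange,
                 resolution = resolution, sstBase = sstBase, refLat = refLat,
                 gradient = gradient, cooling = cooling, noiseSd = noiseSd,
                 maxDepth = maxDepth, seed = as.integer(seed)),
            class = "GridSpec")
}

#' Simulate co-registered SST and bathymetry grids
#'
#' @param spec A [gridSpec()].
#' @return A list: `sst` and `bathymetry` matrices (rows = latitudes,
#'   north to south), `lat`, `lon`, and the `spec`.
#' @examples
#' g <- simulateGrids(gridSpec(noiseSd = 0))
#' range(g$sst)
#' @export
simulateGrids <- function(spec) {
  stopifnot(inherits(spec, "GridSpec"))
  lat <- seq(spec$latRange[2L], spec$latRange[1L], by = -spec$resolution)
  lon <- seq(spec$lonRange[1L], spec$lonRange[2L], by = spec$resolution)
  base <- spec$sstBase + spec$gradient * (lat - spec$refLat) - spec$cooling
  sst <- matrix(base, nrow = length(lat), ncol = length(lon))
  if (spec$noiseSd > 0)
    sst <- sst + .withSeed(spec$seed,
      matrix(stats::rnorm(length(sst), 0, spec$noiseSd),
             nrow = length(lat)))
  depth <- spec$maxDepth * (seq_along(lon) - 1L) / (length(lon) - 1L)
  bathy <- matrix(depth, nrow = length(lat), ncol = length(lon),
                  byrow = TRUE)
  list(sst = sst, bathymetry = bathy, lat = lat, lon = lon, spec = spec)
}
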