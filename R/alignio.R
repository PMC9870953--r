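#' @include AllGenerics.R
NULL

#' Construct an AlignedSeqSet
#'
#' Builds the package's alignment container from a named character vector or
#' a named [Biostrings::DNAStringSet]. Sequences are uppercased and RNA `U`
#' is mapped to `T`; all records must be equal length with unique, non-empty
#' names.
#'
#' @param x Named character vector of aligned sequences, or a named
#'   `DNAStringSet`.
#' @return An [AlignedSeqSet-class].
#' @examples
#' AlignedSeqSet(c(a = "ACGTAC", b = "ACGTAT"))
#' @export
AlignedSeqSet <- function(x) {
  if (is(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("x must be a named character or DNAStringSet")
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all sequences must be named with non-empty sample ids")
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  w <- nchar(x)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: sequences of differing length: ",
         paste(ids[w != as.integer(stats::median(w))], collapse = ", "))
  new("AlignedSeqSet", seqs = Biostrings::DNAStringSet(stats::setNames(x, ids)))
}

#' Read an aligned multi-FASTA file
#'
#' Reads a (wrapped or single-line) multi-record FASTA file and validates
#' that it forms a proper alignment: equal lengths, unique ids, IUPAC/gap
#' symbols only.
#'
#' @param path Path to a FASTA file.
#' @return An [AlignedSeqSet-class].
#' @seealso [writeAlignedFasta()], [writeNexus()]
#' @export
readAlignedFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("malformed FASTA (empty file): ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop(sprintf("malformed FASTA: line %d of '%s' is not a header", first,
                 path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))  # id = first whitespace-separated token
  if (anyDuplicated(ids))
    stop("duplicate sample ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    freq <- table(w)
    common <- as.integer(names(freq)[freq == max(freq)])
    modal <- w[w %in% common][1L]      # ties: first-seen width wins
    stop("not an alignment: unequal sequence lengths for ",
         paste(ids[w != modal], collapse = ", "))
  }
  AlignedSeqSet(stats::setNames(seqs, ids))
}

#' Write an alignment as FASTA
#'
#' @param seqs An [AlignedSeqSet-class].
#' @param path Output file path.
#' @param width Line-wrap width for the sequence lines.
#' @return Invisibly, `path`.
#' @export
writeAlignedFasta <- function(seqs, path, width = 70L) {
  stopifnot(is(seqs, "AlignedSeqSet"))
  Biostrings::writeXStringSet(sequences(seqs), filepath = path, width = width)
  invisible(path)
}

#' Export an alignment as a NEXUS DATA block
#'
#' Writes a standard non-interleaved NEXUS file (DIMENSIONS NTAX/NCHAR,
#' FORMAT DATATYPE=DNA, MATRIX), the interchange format used by haplotype
#' network tools such as PopART. `readNexus()` reads it back.
#'
#' @param seqs An [AlignedSeqSet-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeNexus <- function(seqs, path) {
  stopifnot(is(seqs, "AlignedSeqSet"))
  x <- strsplit(as.character(seqs), "")
  ape::write.nexus.data(x, file = path, format = "dna", interleaved = FALSE)
  # drop the writer's timestamp comment so identical inputs give identical files
  lines <- readLines(path)
  writeLines(lines[!grepl("^\\[Data written by", lines)], path)
  invisible(path)
}

#' @rdname writeNexus
#' @export
readNexus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- ape::read.nexus.data(path)
  AlignedSeqSet(vapply(x, paste, character(1L), collapse = ""))
}

# IUPAC degeneracy sets, gap excluded (a gap matches nothing).
.IUPAC_SETS <- strsplit(Biostrings::IUPAC_CODE_MAP, "")

#' Does an IUPAC symbol match a concrete base?
#'
#' `iupacMatch("Y", "C")` is `TRUE` because Y stands for C or T. Needed
#' because barcode primers such as Gaz F2/R2 carry degenerate positions
#' (Y, W, R).
#'
#' @param code IUPAC nucleotide symbol(s) (any of the 15 codes).
#' @param base Concrete base(s), one of A, C, G, T.
#' @return Logical vector: is `base` in the degeneracy set of `code`?
#' @examples
#' iupacMatch("Y", "C")  # TRUE
#' iupacMatch("W", "G")  # FALSE
#' @export
iupacMatch <- function(code, base) {
  code <- toupper(code); base <- toupper(base)
  if (any(!code %in% names(.IUPAC_SETS)))
    stop("unknown IUPAC symbol: ",
         paste(setdiff(code, names(.IUPAC_SETS)), collapse = ", "))
  if (any(!base %in% c("A", "C", "G", "T")))
    stop("base must be one of A, C, G, T")
  mapply(function(cd, b) b %in% .IUPAC_SETS[[cd]], code, base,
         USE.NAMES = FALSE)
}

# TRUE when the degeneracy sets of two IUPAC symbols intersect; a gap or
# unknown symbol never matches.
.iupacCompatible <- function(a, b) {
  sa <- .IUPAC_SETS[[a]]; sb <- .IUPAC_SETS[[b]]
  if (is.null(sa) || is.null(sb)) return(FALSE)
  any(sa %in% sb)
}

# Scan a window of a character matrix row for the best degenerate-primer
# match. Returns list(start, mismatches) or NULL when nothing is scanned.
.scanPrimer <- function(rowChars, primerChars, starts) {
  np <- length(primerChars)
  best <- NULL
  for (s in starts) {
    seg <- rowChars[s:(s + np - 1L)]
    mm <- sum(!vapply(seq_len(np),
                      function(i) .iupacCompatible(primerChars[i], seg[i]),
                      logical(1L)))
    if (is.null(best) || mm < best$mismatches)
      best <- list(start = s, mismatches = mm)
  }
  best
}

#' Trim amplification primers off an aligned barcode
#'
#' Searches for the forward primer in the leading window of the alignment and
#' for the reverse complement of the reverse primer in the trailing window
#' (windows span the primer length plus 10 columns). Degenerate IUPAC
#' positions match all their bases. Where a primer is found within
#' `maxMismatch` mismatches, the matched columns are removed from *all*
#' records, so the output is still an alignment; sequences in which the
#' primer was not found are logged but not treated as errors. When several
#' records match at different offsets the modal offset wins (ties go to the
#' earliest).
#'
#' @param seqs An [AlignedSeqSet-class].
#' @param forward,reverse Primer sequences, 5'->3', the reverse primer given
#'   on the opposite strand (as printed on an order sheet). IUPAC degeneracy
#'   codes allowed.
#' @param maxMismatch Maximum mismatches tolerated per primer (default 1).
#' @return A list with elements `seqs` (the trimmed [AlignedSeqSet-class]),
#'   `log` (data.frame: `sample_id`, `fwd_trimmed`, `rev_trimmed`,
#'   `mismatches`) and `trimmedColumns` (1-based indices of removed columns).
#' @examples
#' aln <- AlignedSeqSet(c(a = paste0("CCAACCACAAAGATATAGGTAC", "ATGGCT")))
#' trimPrimers(aln, forward = "CCAACCAYAAAGATATWGGTAC",
#'             reverse = "AGCCAT", maxMismatch = 0)$seqs
#' @export
trimPrimers <- function(seqs, forward, reverse, maxMismatch = 1L) {
  stopifnot(is(seqs, "AlignedSeqSet"))
  forward <- toupper(forward); reverse <- toupper(reverse)
  L <- seqLength(seqs)
  if (nchar(forward) >= L || nchar(reverse) >= L)
    stop("primers must be shorter than the alignment")
  revrc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(reverse)))
  fwdC <- strsplit(forward, "")[[1L]]
  revC <- strsplit(revrc, "")[[1L]]
  mat <- strsplit(as.character(seqs), "")
  ids <- sampleIds(seqs)
  n <- length(mat)

  scanAll <- function(primerChars, starts) {
    lapply(mat, .scanPrimer, primerChars = primerChars, starts = starts)
  }
  wf <- min(L, length(fwdC) + 10L)
  fwdHits <- scanAll(fwdC, seq_len(wf - length(fwdC) + 1L))
  wr <- min(L, length(revC) + 10L)
  revStarts <- seq.int(max(1L, L - wr + 1L), L - length(revC) + 1L)
  revHits <- scanAll(revC, revStarts)

  modalRange <- function(hits, plen) {
    ok <- vapply(hits, function(h) h$mismatches <= maxMismatch, logical(1L))
    if (!any(ok)) return(NULL)
    starts <- vapply(hits[ok], `[[`, numeric(1L), "start")
    tab <- sort(table(starts), decreasing = TRUE)
    s <- min(as.integer(names(tab)[tab == tab[1L]]))
    s:(s + plen - 1L)
  }
  fwdCols <- modalRange(fwdHits, length(fwdC))
  revCols <- modalRange(revHits, length(revC))
  drop <- union(fwdCols, revCols)

  log <- data.frame(
    sample_id = ids,
    fwd_trimmed = if (is.null(fwdCols)) rep(FALSE, n) else
      vapply(fwdHits, function(h) h$mismatches <= maxMismatch, logical(1L)),
    rev_trimmed = if (is.null(revCols)) rep(FALSE, n) else
      vapply(revHits, function(h) h$mismatches <= maxMismatch, logical(1L)),
    mismatches = vapply(fwdHits, `[[`, numeric(1L), "mismatches") +
      vapply(revHits, `[[`, numeric(1L), "mismatches"),
    stringsAsFactors = FALSE)

  out <- if (is.null(drop)) seqs else {
    keep <- setdiff(seq_len(L), drop)
    AlignedSeqSet(vapply(mat, function(ch) paste(ch[keep], collapse = ""),
                         character(1L)) |> stats::setNames(ids))
  }
  list(seqs = out, log = log,
       trimmedColumns = if (is.null(drop)) integer(0) else sort(drop))
}

#' Protein-translation quality check
#'
#' Translates every sequence in all three forward reading frames and keeps,
#' per sequence, the frame with the fewest internal stop codons; a clean
#' barcode of a protein-coding gene should have none. Codons containing a
#' gap or ambiguity code are skipped; a stop in the final (complete) codon
#' of the frame counts as terminal, not internal.
#'
#' @param seqs An [AlignedSeqSet-class] with at least 3 columns.
#' @param geneticCode Genetic code table id passed to
#'   [Biostrings::getGeneticCode()]; `"1"` (the standard code) by default,
#'   `"5"` for the invertebrate mitochondrial code, etc.
#' @param frame `NULL` (default) to pick, per sequence, the forward frame
#'   with the fewest internal stops, or a fixed frame 0, 1 or 2.
#' @return A data.frame with one row per sequence: `sample_id`, `frame_used`
#'   (0, 1 or 2), `internal_stop_count`, `passed`
#'   (`internal_stop_count == 0`).
#' @examples
#' aln <- AlignedSeqSet(c(good = "ATGGCTGCT", bad = "ATGTAAGCT"))
#' translationQc(aln, frame = 0)
#' @export
translationQc <- function(seqs, geneticCode = "1", frame = NULL) {
  stopifnot(is(seqs, "AlignedSeqSet"))
  if (seqLength(seqs) < 3L) stop("alignment too short to translate")
  if (!is.null(frame) && !frame %in% 0:2) stop("frame must be 0, 1 or 2")
  code <- Biostrings::getGeneticCode(geneticCode)
  stops <- names(code)[code == "*"]
  countInternal <- function(chars, frame) {
    usable <- chars[(frame + 1L):length(chars)]
    ncod <- length(usable) %/% 3L
    if (ncod < 2L) return(0L)
    codons <- vapply(seq_len(ncod), function(i)
      paste(usable[(3L * i - 2L):(3L * i)], collapse = ""), character(1L))
    internal <- codons[-ncod]  # a stop in the frame's final codon is terminal
    internal <- internal[grepl("^[ACGT]{3}$", internal)]  # skip gap/ambiguity
    sum(internal %in% stops)
  }
  mat <- strsplit(as.character(seqs), "")
  rows <- lapply(seq_along(mat), function(i) {
    if (is.null(frame)) {
      cnt <- vapply(0:2, countInternal, integer(1L), chars = mat[[i]])
      f <- which.min(cnt) - 1L
      nstop <- cnt[f + 1L]
    } else {
      f <- as.integer(frame)
      nstop <- countInternal(mat[[i]], f)
    }
    data.frame(sample_id = sampleIds(seqs)[i], frame_used = f,
               internal_stop_count = nstop,
               passed = nstop == 0L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
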