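#' @include network.R
NULL

#' Construct a thermal response curve
#'
#' The default `"quadratic"` form is the symmetric bump
#' `cover(T) = peakCover * max(0, 1 - ((T - tOpt) / (tMax - tOpt))^2)`:
#' maximal at the optimum, falling continuously to zero at the upper
#' thermal threshold (and at the mirrored temperature below the optimum),
#' zero beyond. Any other cover--SST relationship -- for example one fitted
#' to field surveys or interpolated from a published table -- can be
#' supplied as `fun` with `form = "custom"`; it must honour the same
#' peak/threshold/range conditions, which are checked at construction.
#'
#' @param tOpt Optimal mean annual SST (degrees C); default 23.
#' @param tMax Upper thermal threshold (degrees C); default 26.
#' @param peakCover Cover (\%) at the optimum; default 60.
#' @param form `"quadratic"` (default) or `"custom"`.
#' @param fun Vectorised cover function of SST, required for `"custom"`.
#' @return A [ResponseFunction-class].
#' @examples
#' rf <- responseFunction()
#' responseCover(c(20, 23, 26), rf)
#' @export
responseFunction <- function(tOpt = 23, tMax = 26, peakCover = 60,
                             form = c("quadratic", "custom"), fun = NULL) {
  form <- match.arg(form)
  new("ResponseFunction", form = form, tOpt = tOpt, tMax = tMax,
      peakCover = peakCover, fun = fun)
}

#' Predict kelp cover from sea surface temperature
#'
#' @param sst Numeric vector or matrix of mean annual SST (degrees C).
#' @param rf A [ResponseFunction-class].
#' @return Cover (\%) with the shape of `sst`, in `[0, peakCover]`.
#' @export
responseCover <- function(sst, rf) {
  stopifnot(is(rf, "ResponseFunction"))
  if (any(!is.finite(sst))) stop("sst must be finite")
  out <- if (rf@form == "quadratic") {
    z <- (sst - rf@tOpt) / (rf@tMax - rf@tOpt)
    rf@peakCover * pmax(0, 1 - z^2)
  } else {
    rf@fun(sst)
  }
  if (is.matrix(sst)) out <- matrix(out, nrow(sst), ncol(sst))
  out
}

#' Assemble a hindcast scenario
#'
#' @param sst Numeric matrix of mean annual SST (rows = latitudes).
#' @param bathymetry Numeric matrix of present-day depth (m, positive down),
#'   co-registered with `sst`.
#' @param lat,lon Coordinate vectors for rows/columns (degrees; southern
#'   latitudes negative).
#' @param seaLevelOffset Sea-level lowering in metres relative to today: 0
#'   for the present day, ~120 for the Last Glacial Maximum (sensitivity
#'   range roughly 65--125 m).
#' @param depthBand Habitable depth band (m below the scenario's sea level);
#'   default `c(0, 80)`, the maximum depth range this kelp occupies.
#' @param latRange Latitude window analysed, `(south, north)`; default
#'   `c(-38, -18)` (18--38 degrees S).
#' @return A [CoverScenario-class].
#' @export
coverScenario <- function(sst, bathymetry, lat, lon, seaLevelOffset = 0,
                          depthBand = c(0, 80), latRange = c(-38, -18)) {
  new("CoverScenario", sst = sst, bathymetry = bathymetry, lat = lat,
      lon = lon, seaLevelOffset = seaLevelOffset, depthBand = depthBand,
      latRange = latRange)
}

#' Depth-and-latitude habitat mask
#'
#' A cell is eligible when its depth below the scenario's sea level
#' (`bathymetry - seaLevelOffset`) lies within the habitable depth band and
#' its latitude falls inside the analysed window. With a 120 m glacial
#' offset and a 0--80 m band this selects shelf that is 120--200 m deep at
#' the present day. Warns when no cell qualifies (e.g. the whole shelf sat
#' above glacial sea level).
#'
#' @param scn A [CoverScenario-class].
#' @return Logical matrix, the shape of the scenario grids.
#' @export
depthMask <- function(scn) {
  stopifnot(is(scn, "CoverScenario"))
  depth <- scn@bathymetry - scn@seaLevelOffset
  inBand <- depth >= scn@depthBand[1L] & depth <= scn@depthBand[2L]
  inLat <- scn@lat >= scn@latRange[1L] & scn@lat <= scn@latRange[2L]
  mask <- inBand & matrix(inLat, nrow(inBand), ncol(inBand))
  if (!any(mask))
    warning("habitat mask is empty: no cell within the depth band ",
            "below scenario sea level")
  mask
}

#' Predict the cover grid of a scenario
#'
#' Cover is computed cell-wise from SST across the whole grid (full-shelf
#' maps aid visual interpretation); the habitat mask is returned alongside
#' and is what the latitudinal profile averages over.
#'
#' @param scn A [CoverScenario-class].
#' @param rf A [ResponseFunction-class].
#' @return A list: `cover` (matrix, \%), `mask` (logical matrix), `scenario`.
#' @export
predictCoverGrid <- function(scn, rf) {
  stopifnot(is(scn, "CoverScenario"))
  list(cover = responseCover(scn@sst, rf), mask = depthMask(scn),
       scenario = scn)
}

#' Latitudinal profile of mean cover
#'
#' Averages cover over the eligible (masked) cells in latitude bins of
#' `binWidth` degrees spanning the scenario's latitude window. Means are
#' unweighted cell averages; bins with no eligible cell are flagged `empty`
#' and carry `NA`, never zero.
#'
#' @param cover Cover matrix (\%) as from [predictCoverGrid()].
#' @param mask Logical eligibility matrix, same shape.
#' @param lat Latitude of each grid row (degrees).
#' @param binWidth Bin width in degrees; default 0.5.
#' @param latRange Optional `(south, north)` window; defaults to the span
#'   of `lat`.
#' @return A data.frame: `lat_bin` (bin centre), `mean_cover`, `n_cells`,
#'   `empty`.
#' @export
latitudinalProfile <- function(cover, mask, lat, binWidth = 0.5,
                               latRange = range(lat)) {
  if (!identical(dim(cover), dim(mask)))
    stop("cover and mask must be co-registered")
  if (nrow(cover) != length(lat)) stop("lat must match grid rows")
  breaks <- seq(latRange[1L], latRange[2L] + binWidth - 1e-9, by = binWidth)
  centres <- breaks[-length(breaks)] + binWidth / 2
  rowBin <- findInterval(lat, breaks, rightmost.closed = TRUE)
  meanC <- nC <- numeric(length(centres))
  for (b in seq_along(centres)) {
    cells <- cover[rowBin == b & mask]
    nC[b] <- length(cells)
    meanC[b] <- if (length(cells)) mean(cells) else NA_real_
  }
  data.frame(lat_bin = centres, mean_cover = meanC, n_cells = nC,
             empty = nC == 0L)
}

# latitude of a profile feature; profiles use signed latitudes
.profileFeature <- function(profile, metric, threshold = NULL) {
  ok <- !profile$empty
  lat <- profile$lat_bin[ok]
  cov <- profile$mean_cover[ok]
  if (!length(cov) || max(cov) <= 0 || diff(range(cov)) == 0)
    stop("profile feature undefined on a flat or empty profile")
  switch(metric,
    peak = mean(lat[cov == max(cov)]),
    centroid = sum(lat * cov) / sum(cov),
    threshold = {
      thr <- if (is.null(threshold)) max(cov) / 2 else threshold
      above <- lat[cov >= thr]
      if (!length(above)) stop("no bin reaches the threshold cover")
      # equatorward edge = latitude closest to the equator above threshold
      above[which.min(abs(above))]
    })
}

#' Latitudinal range shift between two scenarios
#'
#' Signed displacement, in degrees of latitude, of a profile feature between
#' a reference profile (`profileA`, e.g. present day) and a comparison
#' profile (`profileB`, e.g. the Last Glacial Maximum). Positive values are
#' equatorward (toward 0 degrees): the shift is `|feature_A| - |feature_B|`,
#' which works in either hemisphere provided both profiles sit in the same
#' one.
#'
#' @param profileA,profileB Profiles from [latitudinalProfile()] on the same
#'   binning.
#' @param metric `"peak"` (latitude of maximum cover; ties averaged),
#'   `"centroid"` (cover-weighted mean latitude) or `"threshold"`
#'   (equatorward-most bin at or above `threshold`, default half the
#'   profile's maximum).
#' @param threshold Cover threshold (\%) for the `"threshold"` metric.
#' @return Signed shift in degrees latitude.
#' @export
rangeShift <- function(profileA, profileB,
                       metric = c("peak", "centroid", "threshold"),
                       threshold = NULL) {
  metric <- match.arg(metric)
  if (!isTRUE(all.equal(profileA$lat_bin, profileB$lat_bin)))
    stop("profiles must share the same latitude binning")
  fa <- .profileFeature(profileA, metric, threshold)
  fb <- .profileFeature(profileB, metric, threshold)
  abs(fa) - abs(fb)
}

#' Read/write a grid as TSV
#'
#' Plain-text raster exchange: a tab-separated matrix with latitudes as row
#' names and longitudes as column names.
#'
#' @param grid Numeric matrix.
#' @param lat,lon Coordinate vectors.
#' @param path File path.
#' @return `writeGridTsv()`: invisibly `path`; `readGridTsv()`: a list
#'   `grid`, `lat`, `lon`.
#' @export
writeGridTsv <- function(grid, lat, lon, path) {
  m <- grid
  dimnames(m) <- list(lat, lon)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname writeGridTsv
#' @export
readGridTsv <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
  list(grid = unname(m), lat = as.numeric(rownames(m)),
       lon = as.numeric(colnames(m)))
}
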