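test_that("the thermal response curve honours optimum and threshold", {
  rf <- responseFunction()            # 23 / 26 degC, 60% peak
  expect_equal(responseCover(23, rf), 60)
  expect_equal(responseCover(26, rf), 0)
  expect_equal(responseCover(30, rf), 0)
  expect_equal(responseCover(20, rf), 0)   # mirrored lower zero
  # symmetry about the optimum and bounded range
  for (d in c(0.5, 1, 2))
    expect_equal(responseCover(23 + d, rf), responseCover(23 - d, rf))
  tt <- seq(10, 35, by = 0.1)
  cv <- responseCover(tt, rf)
  expect_true(all(cv >= 0 & cv <= 60))
  expect_error(responseCover(NA_real_, rf), "finite")
})

test_that("custom response curves are validated at construction", {
  tri <- function(t) 40 * pmax(0, 1 - abs(t - 23) / 3)
  rf <- responseFunction(peakCover = 40, form = "custom", fun = tri)
  expect_equal(responseCover(23, rf), 40)
  expect_equal(responseCover(26, rf), 0)
  expect_error(responseFunction(form = "custom", fun = function(t) t),
               "custom curve")
})

test_that("the depth mask selects the sea-level-adjusted band", {
  g <- simulateGrids(gridSpec(noiseSd = 0))
  present <- coverScenario(g$sst, g$bathymetry, g$lat, g$lon,
                           seaLevelOffset = 0)
  mp <- depthMask(present)
  expect_identical(unname(mp),
                   g$bathymetry >= 0 & g$bathymetry <= 80 &
                     matrix(g$lat >= -38 & g$lat <= -18, nrow(mp), ncol(mp)))

  lgm <- coverScenario(g$sst, g$bathymetry, g$lat, g$lon,
                       seaLevelOffset = 120)
  ml <- depthMask(lgm)
  expect_identical(unname(ml),
                   g$bathymetry >= 120 & g$bathymetry <= 200 &
                     matrix(g$lat >= -38 & g$lat <= -18, nrow(ml), ncol(ml)))
  expect_false(any(mp & ml))  # disjoint shelf bands

  # shelf entirely above glacial sea level: empty mask, warned
  shallow <- coverScenario(g$sst, matrix(50, nrow(g$sst), ncol(g$sst)),
                           g$lat, g$lon, seaLevelOffset = 120)
  expect_warning(m0 <- depthMask(shallow), "empty")
  expect_false(any(m0))
})

test_that("cover grids follow the SST field cell-wise", {
  g <- simulateGrids(gridSpec(noiseSd = 0))
  rf <- responseFunction()
  uni <- coverScenario(matrix(23, nrow(g$sst), ncol(g$sst)), g$bathymetry,
                       g$lat, g$lon)
  pu <- predictCoverGrid(uni, rf)
  expect_true(all(pu$cover == 60))

  scn <- coverScenario(g$sst, g$bathymetry, g$lat, g$lon)
  p <- predictCoverGrid(scn, rf)
  # peak row sits where SST crosses the optimum: lat = -38 + (23-14)/0.8
  peakLat <- g$lat[which.max(p$cover[, 1])]
  expect_equal(peakLat, -38 + (23 - 14) / 0.8, tolerance = 0.5)

  land <- coverScenario(g$sst, matrix(-5, nrow(g$sst), ncol(g$sst)),
                        g$lat, g$lon)
  expect_warning(pl <- predictCoverGrid(land, rf), "empty")
  expect_false(any(pl$mask))
})

test_that("latitudinal profiles are per-bin means of eligible cells", {
  g <- simulateGrids(gridSpec(noiseSd = 0))
  mask <- matrix(TRUE, nrow(g$sst), ncol(g$sst))
  uniform <- matrix(50, nrow(g$sst), ncol(g$sst))
  prof <- latitudinalProfile(uniform, mask, g$lat)
  expect_true(all(prof$mean_cover[!prof$empty] == 50))
  expect_false(any(prof$empty))
  expect_equal(sum(prof$n_cells), length(uniform))  # cells conserved

  # brute-force oracle on a graded field with a patchy mask
  set.seed(3)
  cover <- responseCover(g$sst, responseFunction())
  pmask <- matrix(sample(c(TRUE, FALSE), length(cover), TRUE), nrow(cover))
  prof2 <- latitudinalProfile(cover, pmask, g$lat, binWidth = 1)
  breaks <- seq(min(g$lat), max(g$lat) + 1 - 1e-9, by = 1)
  for (b in seq_len(nrow(prof2))) {
    rows <- which(findInterval(g$lat, breaks, rightmost.closed = TRUE) == b)
    cells <- c()
    for (r in rows) for (cc in seq_len(ncol(cover)))
      if (pmask[r, cc]) cells <- c(cells, cover[r, cc])
    if (length(cells)) expect_equal(prof2$mean_cover[b], mean(cells))
    else expect_true(prof2$empty[b])
  }

  expect_error(latitudinalProfile(cover, pmask[, -1], g$lat),
               "co-registered")
})

test_that("range shifts are translation-consistent and signed equatorward", {
  lat <- seq(-37.75, -18.25, by = 0.5)
  bump <- function(centre) 60 * pmax(0, 1 - ((lat - centre) / 4)^2)
  prof <- function(centre) data.frame(lat_bin = lat,
                                      mean_cover = bump(centre),
                                      n_cells = 1L, empty = FALSE)
  expect_equal(rangeShift(prof(-30), prof(-30), "peak"), 0)
  for (m in c("peak", "centroid", "threshold"))
    expect_equal(rangeShift(prof(-30), prof(-25), m), 5, tolerance = 0.26)
  # poleward displacement is negative
  expect_equal(rangeShift(prof(-28), prof(-33), "peak"), -5)
  flat <- data.frame(lat_bin = lat, mean_cover = 0, n_cells = 1L,
                     empty = FALSE)
  expect_error(rangeShift(prof(-30), flat, "peak"), "undefined")
  short <- prof(-30)[-1, ]
  expect_error(rangeShift(prof(-30), short, "peak"), "binning")
})

test_that("uniform cooling moves the cover peak equatorward monotonically", {
  rf <- responseFunction()
  peaks <- vapply(c(0, 1, 2, 3, 4), function(cool) {
    g <- simulateGrids(gridSpec(noiseSd = 0, cooling = cool))
    scn <- coverScenario(g$sst, g$bathymetry, g$lat, g$lon)
    p <- predictCoverGrid(scn, rf)
    prof <- latitudinalProfile(p$cover, p$mask, g$lat)
    with(prof[!prof$empty, ], mean(lat_bin[mean_cover == max(mean_cover)]))
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))  # toward 0 degrees in the south
})

test_that("grid TSV I/O round-trips", {
  g <- simulateGrids(gridSpec(noiseSd = 0.3, seed = 8))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGridTsv(g$sst, g$lat, g$lon, f)
  back <- readGridTsv(f)
  expect_equal(back$grid, g$sst, tolerance = 1e-9)
  expect_equal(back$lat, g$lat)
  expect_equal(back$lon, g$lon)
})
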