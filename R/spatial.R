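.markerMatch <- function(cells, spec) {
  # spec: character vector of marker column names, all of which must be
  # TRUE ("CD8a" & "PD1"), or a cell_class value prefixed "class:"
  if (length(spec) == 1L && startsWith(spec, "class:")) {
    if (is.null(cells$cell_class)) return(rep(FALSE, nrow(cells)))
    return(!is.na(cells$cell_class) &
             cells$cell_class == sub("^class:", "", spec))
  }
  missing <- setdiff(spec, names(cells))
  if (length(missing))
    stop("marker column(s) not in frame: ", paste(missing, collapse = ", "))
  ok <- rep(TRUE, nrow(cells))
  for (m in spec) ok <- ok & (cells[[m]] %in% TRUE)
  ok
}

# Uniform-grid spatial index: bins points into radius-sized square buckets
# so that all neighbors within `radius` of a point lie in its 3x3 bucket
# neighborhood.
.gridIndex <- function(x, y, cellSize) {
  ix <- floor(x / cellSize)
  iy <- floor(y / cellSize)
  key <- paste(ix, iy, sep = ",")
  list(ix = ix, iy = iy, buckets = split(seq_along(x), key))
}

.gridCandidates <- function(index, ix, iy) {
  keys <- as.vector(outer(ix + (-1:1), iy + (-1:1), paste, sep = ","))
  unlist(index$buckets[keys], use.names = FALSE)
}

#' Neighbor cells within a fixed radius
#'
#' For every query cell (matching `queryMarkers`), finds all target cells
#' (matching `targetMarkers`) whose center-to-center Euclidean distance is
#' at most `radiusUm` microns. The boundary is inclusive (a pair at
#' exactly the radius counts), and a cell carrying both marker sets never
#' pairs with itself. Search uses a uniform-grid spatial index whose
#' results are identical to brute-force all-pairs comparison.
#'
#' @param frame A [CellFrame].
#' @param queryMarkers,targetMarkers Character vectors of marker columns
#'   that must all be TRUE (e.g. `c("CD8a","PD1")`), or `"class:<label>"`
#'   to match `cell_class`.
#' @param radiusUm Search radius in microns (> 0); default 20.
#' @return Named list (query cell_id -> data.frame with `cell_id`,
#'   `distance` of its in-radius targets, sorted by distance). Queries
#'   with no in-radius target map to a zero-row data.frame.
#' @export
neighborsWithin <- function(frame, queryMarkers, targetMarkers,
                            radiusUm = 20) {
  stopifnot(is(frame, "CellFrame"))
  if (!is.numeric(radiusUm) || radiusUm <= 0)
    stop("radiusUm must be > 0")
  cl <- cells(frame)
  qi <- which(.markerMatch(cl, queryMarkers))
  ti <- which(.markerMatch(cl, targetMarkers))
  empty <- data.frame(cell_id = character(0), distance = numeric(0))
  if (!length(qi)) return(stats::setNames(list(), character(0)))
  if (!length(ti))
    return(stats::setNames(rep(list(empty), length(qi)), cl$cell_id[qi]))
  idx <- .gridIndex(cl$x[ti], cl$y[ti], radiusUm)
  out <- vector("list", length(qi))
  for (j in seq_along(qi)) {
    i <- qi[j]
    cand <- ti[.gridCandidates(idx, floor(cl$x[i] / radiusUm),
                               floor(cl$y[i] / radiusUm))]
    cand <- cand[cand != i]
    if (!length(cand)) { out[[j]] <- empty; next }
    d <- sqrt((cl$x[cand] - cl$x[i])^2 + (cl$y[cand] - cl$y[i])^2)
    keep <- d <= radiusUm
    if (!any(keep)) { out[[j]] <- empty; next }
    o <- order(d[keep], cl$cell_id[cand[keep]])
    out[[j]] <- data.frame(cell_id = cl$cell_id[cand[keep]][o],
                           distance = d[keep][o],
                           stringsAsFactors = FALSE)
  }
  names(out) <- cl$cell_id[qi]
  out
}

#' PD-1/PD-L1 engagement fraction
#'
#' Fraction of PD-L1+ cells with at least one PD-1+ cell within the
#' interaction radius (default 20 microns, boundary inclusive) — the
#' per-sample normalization of potential PD-1/PD-L1 interaction pairs by
#' total PD-L1+ cells. A frame with no PD-L1+ cell has an undefined
#' engagement: `NA` with a message, never 0. The per-pair interaction
#' count (total in-radius PD-1+ neighbors summed over PD-L1+ cells) is
#' also reported.
#'
#' @param frame A [CellFrame] with logical `PDL1` and `PD1` columns.
#' @param radiusUm Interaction radius in microns; default 20.
#' @return List: `n_pdl1`, `n_interactors`, `fraction`, `n_pairs`,
#'   `radius_um`.
#' @export
engagementFraction <- function(frame, radiusUm = 20) {
  cl <- cells(frame)
  nPdl1 <- sum(.markerMatch(cl, "PDL1"))
  if (nPdl1 == 0) {
    message("no PD-L1+ cells in frame ", sampleId(frame),
            ": engagement undefined")
    return(list(n_pdl1 = 0L, n_interactors = NA_integer_,
                fraction = NA_real_, n_pairs = NA_integer_,
                radius_um = radiusUm))
  }
  nb <- neighborsWithin(frame, "PDL1", "PD1", radiusUm = radiusUm)
  nNeighbors <- vapply(nb, nrow, integer(1))
  list(n_pdl1 = as.integer(nPdl1),
       n_interactors = as.integer(sum(nNeighbors > 0)),
       fraction = sum(nNeighbors > 0) / nPdl1,
       n_pairs = as.integer(sum(nNeighbors)),
       radius_um = radiusUm)
}

#' Nearest-neighbor distances between two cell populations
#'
#' For every cell matching `fromSpec` (default tumor cells, cytokeratin+),
#' the Euclidean distance to its nearest cell matching `toSpec` (default
#' CD8a+PD-1+ T cells), found by ring-expansion over a uniform-grid index
#' (identical to the brute-force minimum). From-cells in a frame with no
#' to-cell get missing distances and a warning. Edge effects are not
#' corrected; the fraction of from-cells within one search radius of the
#' frame's bounding box is reported as a note.
#'
#' @param frame A [CellFrame].
#' @param fromSpec,toSpec Marker specs as in [neighborsWithin()].
#' @return List: `distances` (data.frame `cell_id`, `distance`), `median`,
#'   `n_missing`, `edge_fraction`.
#' @export
nearestDistance <- function(frame, fromSpec = "CK",
                            toSpec = c("CD8a", "PD1")) {
  cl <- cells(frame)
  fi <- which(.markerMatch(cl, fromSpec))
  ti <- which(.markerMatch(cl, toSpec))
  if (!length(fi))
    stop("no cell matches fromSpec")
  if (!length(ti)) {
    warning("no cell matches toSpec: all distances missing")
    return(list(distances = data.frame(cell_id = cl$cell_id[fi],
                                       distance = NA_real_),
                median = NA_real_, n_missing = length(fi),
                edge_fraction = NA_real_))
  }
  extX <- max(cl$x[ti]) - min(cl$x[ti])
  extY <- max(cl$y[ti]) - min(cl$y[ti])
  cellSize <- max(sqrt(max(0, extX * extY) / length(ti)),
                  max(extX, extY) / 64, 1e-6)
  idx <- .gridIndex(cl$x[ti], cl$y[ti], cellSize)
  bruteMin <- function(i) {
    tset <- ti[ti != i]
    if (!length(tset)) return(NA_real_)
    min(sqrt((cl$x[tset] - cl$x[i])^2 + (cl$y[tset] - cl$y[i])^2))
  }
  dists <- vapply(fi, function(i) {
    if (length(ti) == 1L && ti == i) return(NA_real_)
    if (length(ti) <= 64L) return(bruteMin(i))  # grid not worth it
    tset <- ti[ti != i]
    if (!length(tset)) return(NA_real_)
    ix <- floor(cl$x[i] / cellSize); iy <- floor(cl$y[i] / cellSize)
    maxRing <- ceiling((max(extX, extY) +
                          max(abs(cl$x[i]), abs(cl$y[i]))) / cellSize) + 2
    best <- Inf
    ring <- 0L
    repeat {
      cand <- if (ring == 0L) .gridCandidates(idx, ix, iy) else {
        rng <- (-ring):ring
        keys <- c(paste(ix + rng, iy - ring, sep = ","),
                  paste(ix + rng, iy + ring, sep = ","),
                  paste(ix - ring, iy + rng[-c(1, length(rng))], sep = ","),
                  paste(ix + ring, iy + rng[-c(1, length(rng))], sep = ","))
        unlist(idx$buckets[keys], use.names = FALSE)
      }
      cand <- cand[!is.na(cand)]
      if (length(cand)) {
        cand <- ti[cand]
        cand <- cand[cand != i]
        if (length(cand)) {
          d <- sqrt((cl$x[cand] - cl$x[i])^2 + (cl$y[cand] - cl$y[i])^2)
          best <- min(best, min(d))
        }
      }
      # a hit at `best` is final once all buckets possibly holding a
      # closer point have been scanned: ring r covers distance >= (r-1)*s
      if (is.finite(best) && best <= ring * cellSize) break
      ring <- ring + 1L
      if (ring > maxRing) return(bruteMin(i))  # degenerate geometry
    }
    best
  }, numeric(1))
  bb <- c(min(cl$x), max(cl$x), min(cl$y), max(cl$y))
  edge <- mean(cl$x[fi] - bb[1] < 20 | bb[2] - cl$x[fi] < 20 |
                 cl$y[fi] - bb[3] < 20 | bb[4] - cl$y[fi] < 20)
  list(distances = data.frame(cell_id = cl$cell_id[fi], distance = dists,
                              stringsAsFactors = FALSE),
       median = stats::median(dists, na.rm = TRUE),
       n_missing = sum(is.na(dists)), edge_fraction = edge)
}

#' Cell density per class or marker combination
#'
#' @param frame A [CellFrame].
#' @param spec Marker spec as in [neighborsWithin()] (e.g.
#'   `"class:lymphocyte"` or `c("CD8a","PD1")`).
#' @return Density in cells/mm^2.
#' @examples
#' fr <- CellFrame(data.frame(cell_id = as.character(1:3), x = 1:3, y = 1:3,
#'                            CD8a = TRUE, PD1 = c(TRUE, FALSE, TRUE)),
#'                 tissueAreaMm2 = 0.5)
#' cellDensity(fr, c("CD8a", "PD1"))  # 4 cells/mm^2
#' @export
cellDensity <- function(frame, spec) {
  area <- tissueArea(frame)
  if (area <= 0) stop("tissue area must be > 0")
  sum(.markerMatch(cells(frame), spec)) / area
}

#' Per-sample spatial metric panel
#'
#' Computes the study's per-sample spatial summary: densities of the main
#' immune and tumor compartments, the PD-1/PD-L1 engagement fraction, and
#' the median tumor-to-CD8+PD-1+ nearest distance.
#'
#' @param frame A [CellFrame].
#' @param radiusUm Interaction radius for engagement; default 20.
#' @return One-row data.frame of metrics.
#' @export
spatialMetricPanel <- function(frame, radiusUm = 20) {
  cl <- cells(frame)
  dens <- function(spec) {
    ok <- tryCatch(.markerMatch(cl, spec), error = function(e) NULL)
    if (is.null(ok)) NA_real_ else sum(ok) / tissueArea(frame)
  }
  eng <- suppressMessages(engagementFraction(frame, radiusUm = radiusUm))
  nnd <- tryCatch(
    suppressWarnings(nearestDistance(frame))$median,
    error = function(e) NA_real_)
  data.frame(
    sample_id = sampleId(frame), timepoint = timepoint(frame),
    n_cells = nrow(cl),
    lymphocyte_per_mm2 = dens("class:lymphocyte"),
    macrophage_per_mm2 = dens("class:macrophage"),
    cd8_pd1_per_mm2 = dens(c("CD8a", "PD1")),
    pd1_per_mm2 = dens("PD1"), pdl1_per_mm2 = dens("PDL1"),
    engagement_fraction = eng$fraction,
    median_tumor_cd8pd1_dist_um = nnd,
    stringsAsFactors = FALSE)
}
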