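#' Read a SEG file of segmented copy-number profiles
#'
#' SEG is the tab-delimited segmented copy-number exchange format with a
#' header row and columns ID, chrom, loc.start, loc.end, num.mark,
#' seg.mean; coordinates are 1-based inclusive and are preserved as such.
#' Malformed rows (non-numeric seg.mean, start > end) are rejected with
#' their line numbers.
#'
#' @param path Path to a SEG file.
#' @return Named list: sample id -> segment data.frame (`chrom`, `start`,
#'   `end`, `log2_ratio`, `n_markers`).
#' @export
readSeg <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!nrow(raw)) return(stats::setNames(list(), character(0)))
  cn <- tolower(names(raw))
  idx <- function(what) {
    i <- match(what, cn)
    if (is.na(i)) stop("SEG file lacks column '", what, "'")
    i
  }
  id <- raw[[idx("id")]]
  segMean <- suppressWarnings(as.numeric(raw[[idx("seg.mean")]]))
  bad <- which(is.na(segMean) & !is.na(raw[[idx("seg.mean")]]))
  if (length(bad))
    stop("non-numeric seg.mean on line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header row
  start <- as.numeric(raw[[idx("loc.start")]])
  end <- as.numeric(raw[[idx("loc.end")]])
  bad <- which(start > end)
  if (length(bad))
    stop("start > end on line(s) ", paste(bad + 1L, collapse = ", "))
  df <- data.frame(chrom = as.character(raw[[idx("chrom")]]), start = start,
                   end = end, log2_ratio = segMean,
                   n_markers = as.integer(raw[[idx("num.mark")]]),
                   stringsAsFactors = FALSE)
  split(df, factor(id, levels = unique(id)))
}

#' Write segments to a SEG file
#'
#' @param segmentsBySample Named list: sample id -> segment data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSeg <- function(segmentsBySample, path) {
  rows <- do.call(rbind, lapply(names(segmentsBySample), function(id) {
    s <- segmentsBySample[[id]]
    data.frame(ID = id, chrom = s$chrom, loc.start = s$start,
               loc.end = s$end,
               num.mark = if (is.null(s$n_markers)) NA_integer_
                          else s$n_markers,
               seg.mean = s$log2_ratio, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BED interval file into a 1-based interval table
#'
#' BED is 0-based half-open on disk; intervals are converted to the
#' package's internal 1-based inclusive convention at this boundary.
#'
#' @param path Path to a BED file with a name in column 4.
#' @param nameColumn Column name for the feature label in the returned
#'   table (`"gene"` or `"arm"`).
#' @return data.frame with columns `chrom`, `start`, `end` and the name
#'   column.
#' @export
readBed <- function(path, nameColumn = "gene") {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  df[[nameColumn]] <- gr$name
  df
}

#' Bundled synthetic panel gene intervals
#'
#' A small interval table for the recurrently altered genes of the
#' acquired-resistance analysis, with approximate hg19 coordinates;
#' bundled as a synthetic reference for simulation and examples, not as
#' an assay definition.
#'
#' @return data.frame `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
defaultGeneIntervals <- function() {
  readBed(system.file("extdata", "panel_genes_synthetic.bed",
                      package = "ARpipe", mustWork = TRUE),
          nameColumn = "gene")
}

#' Bundled synthetic chromosome-arm intervals
#'
#' Autosomal p/q arm intervals with approximate hg19 centromere
#' boundaries; bundled as a synthetic reference for the arm-level caller.
#'
#' @return data.frame `arm`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
defaultArmIntervals <- function() {
  readBed(system.file("extdata", "chrom_arms_synthetic.bed",
                      package = "ARpipe", mustWork = TRUE),
          nameColumn = "arm")
}

#' Read a single-cell spatial table
#'
#' Requires columns `cell_id`, `x`, `y`; any other columns except
#' `cell_class` are coerced to logical marker flags. An optional
#' pixel-to-micron scale factor converts pixel-space coordinates.
#'
#' @param path CSV path.
#' @param tissueAreaMm2 Tissue area of the frame in mm^2.
#' @param scaleUmPerPx Multiplicative scale applied to x and y (default 1,
#'   coordinates already in microns).
#' @param sampleId,timepoint Frame annotations.
#' @return A [CellFrame].
#' @export
readCells <- function(path, tissueAreaMm2, scaleUmPerPx = 1,
                      sampleId = basename(path),
                      timepoint = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("cell table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id in ", path)
  df$x <- df$x * scaleUmPerPx
  df$y <- df$y * scaleUmPerPx
  for (m in setdiff(names(df), c("cell_id", "x", "y", "cell_class")))
    df[[m]] <- tolower(as.character(df[[m]])) %in% c("1", "true", "t", "yes")
  CellFrame(df, tissueAreaMm2 = tissueAreaMm2, sampleId = sampleId,
            timepoint = timepoint)
}

#' Write a CellFrame's cell table to CSV
#'
#' @param frame A [CellFrame].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeCells <- function(frame, path) {
  utils::write.csv(cells(frame), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a MAF-like variant TSV
#'
#' Expects columns `sample`, `gene`, `event_class`, `detail` and optional
#' `benign`, `chip`, `functional_class`.
#'
#' @param path TSV path.
#' @return Named list: sample id -> variant data.frame in the
#'   [SampleProfile()] layout.
#' @export
readVariants <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "event_class", "detail")
  if (!all(need %in% names(df)))
    stop("variant table needs columns: ", paste(need, collapse = ", "))
  lapply(split(df, factor(df$sample, levels = unique(df$sample))),
         function(s) s[, setdiff(names(s), "sample"), drop = FALSE])
}

#' Write per-sample variant tables to a MAF-like TSV
#'
#' @param variantsBySample Named list: sample id -> variant data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeVariants <- function(variantsBySample, path) {
  rows <- do.call(rbind, lapply(names(variantsBySample), function(id) {
    v <- variantsBySample[[id]]
    if (is.null(v) || !nrow(v)) return(NULL)
    cbind(sample = id, v[, setdiff(names(v), "event_key"), drop = FALSE])
  }))
  if (is.null(rows))
    rows <- data.frame(sample = character(0), gene = character(0),
                       event_class = character(0), detail = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample purity table
#'
#' @param path TSV with columns `sample`, `purity`.
#' @return Named numeric vector of purities.
#' @export
readPurity <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "purity") %in% names(df)))
    stop("purity table needs columns sample, purity")
  if (any(df$purity <= 0 | df$purity > 1))
    stop("purity values must lie in (0, 1]")
  stats::setNames(df$purity, df$sample)
}

#' Write a simulated cohort to a directory of standard files
#'
#' Emits the cohort as the file set the pipeline consumes: variants as a
#' MAF-like TSV, segments as SEG, per-sample cell tables as CSV, H-scores
#' and the paired-case manifest as TSV, and the ground truth as JSON.
#'
#' @param sim Output of [simulateCohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimOutputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  varBySample <- list()
  for (case in sim$cases) {
    varBySample[[sampleId(preSample(case))]] <- variants(preSample(case))
    varBySample[[sampleId(postSample(case))]] <- variants(postSample(case))
  }
  writeVariants(varBySample, file.path(dir, "variants.tsv"))
  writeSeg(sim$segments, file.path(dir, "segments.seg"))
  utils::write.table(sim$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$hscores, file.path(dir, "hscores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cellsDir <- file.path(dir, "cells")
  dir.create(cellsDir, showWarnings = FALSE)
  for (sid in names(sim$cellFrames))
    writeCells(sim$cellFrames[[sid]],
               file.path(cellsDir, paste0(sid, ".csv")))
  gt <- sim$groundTruth
  gt$trueAcn <- lapply(gt$trueAcn, as.list)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
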