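#' Simulate a segmented copy-number profile from planted absolute copy numbers
#'
#' Inverts the purity-corrected ACN relation to plant gene-level truths:
#' a gene with true absolute copy number ACN in a sample of purity p gets
#' segment log2 ratio
#' \deqn{l = \log_2(p \cdot ACN + 2(1-p)) - 1,}
#' so that the forward formula in [absoluteCopyNumber()] round-trips
#' exactly at zero noise. One segment spans each gene; the remainder of
#' each chromosome's covered span is filled with diploid (l for ACN 2,
#' i.e. 0) background segments. Gaussian noise of SD `noiseSd` is added to
#' every segment mean.
#'
#' @param trueAcnByGene Named numeric vector: gene -> true ACN (>= 0).
#'   Panel genes absent from the vector are planted at ACN 2.
#' @param purity Tumor purity in (0, 1].
#' @param noiseSd Log2-ratio noise SD (>= 0).
#' @param geneIntervals data.frame `gene`, `chrom`, `start`, `end`.
#' @param flank Background flank (bp) added around each chromosome's gene
#'   span.
#' @return Segment data.frame (`chrom`, `start`, `end`, `log2_ratio`,
#'   `n_markers`).
#' @export
simulateSegments <- function(trueAcnByGene, purity, noiseSd = 0,
                             geneIntervals = defaultGeneIntervals(),
                             flank = 1e6) {
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  if (any(trueAcnByGene < 0)) stop("true ACN must be >= 0")
  acn <- stats::setNames(rep(2, nrow(geneIntervals)),
                         toupper(geneIntervals$gene))
  known <- intersect(names(acn), toupper(names(trueAcnByGene)))
  acn[known] <- trueAcnByGene[match(known, toupper(names(trueAcnByGene)))]
  inner <- purity * acn + 2 * (1 - purity)
  if (any(inner <= 0))
    stop("infeasible configuration: p*ACN + 2(1-p) <= 0 for gene(s) ",
         paste(names(acn)[inner <= 0], collapse = ", "))
  l <- log2(inner) - 1
  segs <- lapply(split(seq_len(nrow(geneIntervals)), geneIntervals$chrom),
                 function(ii) {
    gi <- geneIntervals[ii, , drop = FALSE]
    gi <- gi[order(gi$start), , drop = FALSE]
    li <- unname(l[toupper(gi$gene)])
    n <- nrow(gi)
    # interleave background gaps (diploid, l = 0) with gene segments
    gapStart <- c(max(1, gi$start[1] - flank), gi$end[-n] + 1)
    gapEnd <- gi$start - 1
    keep <- gapStart <= gapEnd
    starts <- c(gapStart[keep], gi$start, gi$end[n] + 1)
    ends <- c(gapEnd[keep], gi$end, gi$end[n] + flank)
    l2 <- c(rep(0, sum(keep)), li, 0)
    o <- order(starts)
    data.frame(chrom = gi$chrom[1], start = starts[o], end = ends[o],
               log2_ratio = l2[o], stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs)
  rownames(segs) <- NULL
  if (noiseSd > 0)
    segs$log2_ratio <- segs$log2_ratio + stats::rnorm(nrow(segs), 0, noiseSd)
  segs$n_markers <- pmax(5L, as.integer(round((segs$end - segs$start + 1) / 5e4)))
  segs
}

.poissonCount <- function(density, areaMm2) stats::rpois(1, density * areaMm2)

.uniformXY <- function(n, side) {
  data.frame(x = stats::runif(n, 0, side), y = stats::runif(n, 0, side))
}

# place a point > minDist from every (px, py); rejection sampling
.placeAway <- function(side, px, py, minDist, maxTries = 1000L) {
  for (t in seq_len(maxTries)) {
    x <- stats::runif(1, 0, side); y <- stats::runif(1, 0, side)
    if (!length(px) || min((px - x)^2 + (py - y)^2) > minDist^2)
      return(c(x, y))
  }
  stop("infeasible spatial configuration: cannot place cell > ", minDist,
       " um from exclusion set (densities too high for the area)")
}

# place a point within (rMin, rMax] of (cx, cy), inside the frame and
# > minDist from every (px, py)
.placeNear <- function(cx, cy, side, px, py, rMin, rMax, minDist,
                       maxTries = 1000L) {
  for (t in seq_len(maxTries)) {
    r <- stats::runif(1, rMin, rMax)
    th <- stats::runif(1, 0, 2 * pi)
    x <- cx + r * cos(th); y <- cy + r * sin(th)
    if (x < 0 || x > side || y < 0 || y > side) next
    if (!length(px) || min((px - x)^2 + (py - y)^2) > minDist^2)
      return(c(x, y))
  }
  stop("infeasible spatial configuration: cannot place partner cell")
}

#' Simulate a single-cell spatial frame with a planted engagement fraction
#'
#' Cells of each class are placed by a homogeneous Poisson process over a
#' square frame of the configured area. To plant the PD-1/PD-L1
#' engagement, `k = round(targetEngagement * n_PDL1)` PD-L1+ cells are
#' designated interactors and each receives a PD-1+ partner within 20
#' microns, while every other PD-1+ cell is kept more than 20 microns away
#' from every non-interactor PD-L1+ cell; the achieved fraction
#' `k / n_PDL1` is returned alongside the frame (it equals the target
#' exactly whenever `target * n_PDL1` is an integer, in particular at 0
#' and 1). Coordinates are rounded to two decimals of a micron.
#'
#' @param spatial List with `areaMm2`, `density` (named cells/mm^2 over
#'   classes `lymphocyte`, `epithelial`, `macrophage` and markers `PD1`,
#'   `PDL1`), `targetEngagement` in \[0, 1\].
#' @param seed Integer seed.
#' @param sampleId,timepoint Frame annotations.
#' @return List: `frame` (a [CellFrame]), `achievedEngagement`,
#'   `plantedCounts` (named).
#' @export
simulateCells <- function(spatial, seed = 1L, sampleId = "sim",
                          timepoint = NA_character_) {
  if (spatial$areaMm2 <= 0) stop("area must be > 0")
  if (any(spatial$density < 0)) stop("densities must be >= 0")
  te <- spatial$targetEngagement
  if (te < 0 || te > 1) stop("targetEngagement must lie in [0, 1]")
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  side <- sqrt(spatial$areaMm2) * 1000  # microns
  dens <- spatial$density
  getD <- function(cls) if (cls %in% names(dens)) dens[[cls]] else 0

  nPdl1 <- .poissonCount(getD("PDL1"), spatial$areaMm2)
  nPd1 <- .poissonCount(getD("PD1"), spatial$areaMm2)
  k <- as.integer(round(te * nPdl1))

  # interactor PD-L1 placed first; non-interactors keep a 25 um berth from
  # interactors so that every interactor retains room for a partner that
  # clears all non-interactors
  intXY <- .uniformXY(k, side)
  nonInt <- do.call(rbind, lapply(seq_len(nPdl1 - k), function(j)
    .placeAway(side, intXY$x, intXY$y, minDist = 25)))
  nonIntX <- if (is.null(nonInt)) numeric(0) else nonInt[, 1]
  nonIntY <- if (is.null(nonInt)) numeric(0) else nonInt[, 2]
  pdl1 <- data.frame(x = c(intXY$x, nonIntX), y = c(intXY$y, nonIntY))
  isInteractor <- c(rep(TRUE, k), rep(FALSE, nPdl1 - k))

  # one PD-1+ partner per interactor, strictly inside the radius and clear
  # of all non-interactors (20.1 um buffer absorbs coordinate rounding)
  partners <- lapply(which(isInteractor), function(i)
    .placeNear(pdl1$x[i], pdl1$y[i], side, nonIntX, nonIntY,
               rMin = 1, rMax = 18, minDist = 20.1))
  nBg <- max(0L, nPd1 - k)
  background <- lapply(seq_len(nBg), function(j)
    .placeAway(side, nonIntX, nonIntY, minDist = 20.1))
  pd1 <- do.call(rbind, c(partners, background))
  pd1 <- if (is.null(pd1)) data.frame(x = numeric(0), y = numeric(0))
         else data.frame(x = pd1[, 1], y = pd1[, 2])

  others <- lapply(c("lymphocyte", "epithelial", "macrophage"), function(cls) {
    n <- .poissonCount(getD(cls), spatial$areaMm2)
    if (!n) return(NULL)
    cbind(.uniformXY(n, side), class = cls)
  })
  others <- do.call(rbind, others)

  mk <- function(n, x, y, cls, CK = FALSE, PD1 = FALSE, PDL1 = FALSE,
                 CD3e = FALSE, CD8a = FALSE, CD68 = FALSE) {
    if (!n) return(NULL)
    data.frame(x = x, y = y, cell_class = cls, CK = CK, PD1 = PD1,
               PDL1 = PDL1, CD3e = CD3e, CD8a = CD8a, CD68 = CD68,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    mk(nPdl1, pdl1$x, pdl1$y, "epithelial", CK = TRUE, PDL1 = TRUE),
    mk(nrow(pd1), pd1$x, pd1$y, "lymphocyte", PD1 = TRUE, CD3e = TRUE,
       CD8a = stats::runif(nrow(pd1)) < 0.5)
  )
  if (!is.null(others)) {
    for (cls in unique(others$class)) {
      o <- others[others$class == cls, , drop = FALSE]
      rows[[length(rows) + 1L]] <- switch(cls,
        lymphocyte = mk(nrow(o), o$x, o$y, "lymphocyte", CD3e = TRUE,
                        CD8a = stats::runif(nrow(o)) < 0.4),
        epithelial = mk(nrow(o), o$x, o$y, "epithelial", CK = TRUE),
        macrophage = mk(nrow(o), o$x, o$y, "macrophage", CD68 = TRUE))
    }
  }
  cellsDf <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(cellsDf))
    cellsDf <- data.frame(x = numeric(0), y = numeric(0),
                          cell_class = character(0), CK = logical(0),
                          PD1 = logical(0), PDL1 = logical(0),
                          CD3e = logical(0), CD8a = logical(0),
                          CD68 = logical(0))
  cellsDf$x <- round(cellsDf$x, 2)
  cellsDf$y <- round(cellsDf$y, 2)
  cellsDf <- cbind(cell_id = sprintf("%s_c%05d", sampleId,
                                     seq_len(nrow(cellsDf))),
                   cellsDf, stringsAsFactors = FALSE)
  frame <- CellFrame(cellsDf, tissueAreaMm2 = spatial$areaMm2,
                     sampleId = sampleId, timepoint = timepoint)
  list(frame = frame,
       achievedEngagement = if (nPdl1 > 0) k / nPdl1 else NA_real_,
       plantedCounts = c(PDL1 = nPdl1, PD1 = nrow(pd1),
                         interactors = k))
}

.simulateHscorePair <- function(shift) {
  pre <- min(300, max(0, round(stats::rnorm(1, 250, 40))))
  post <- min(300, max(0, round(pre + shift + stats::rnorm(1, 0, 20))))
  c(pre = pre, post = post)
}

#' Simulate a matched pre/post paired cohort with planted ground truth
#'
#' Generates `nPatients` [PairedCase]s emulating the statistical structure
#' of an acquired-resistance paired-biopsy study: baseline driver events
#' and patient-private passenger variants present in both biopsies,
#' acquired events planted independently per patient per event at the
#' configured probabilities in the post biopsy only (mutation events may
#' carry a concurrent acquired heterozygous loss with probability
#' `biallelicFreq`, planting biallelic inactivation), segmented
#' copy-number profiles consistent with the planted absolute copy numbers
#' at the drawn purity (equal pre/post), paired H-scores with the
#' configured mean shift, and — for the first `nSpatial` patients — paired
#' single-cell spatial frames with planted engagement fractions.
#'
#' Identical config (including seed) reproduces identical output.
#'
#' @param config A [SimConfig].
#' @param geneIntervals Gene interval table (default bundled panel).
#' @param nSpatial Number of patients receiving simulated cell frames
#'   (default 6, the scale of a typical paired mIF subset).
#' @return List with `cases` (list of [PairedCase]), `segments` (named
#'   list: sample id -> segment data.frame), `cellFrames` (named list of
#'   [CellFrame]), `hscores` (data.frame `patient_id`, `pre`, `post`),
#'   `manifest` (data.frame), and `groundTruth` (list: planted acquired
#'   event keys per patient, true ACN per sample, achieved engagement per
#'   sample, planted class densities, purity per patient).
#' @export
simulateCohort <- function(config, geneIntervals = defaultGeneIntervals(),
                           nSpatial = 6L) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  set.seed(config@seed)

  n <- config@nPatients
  aq <- config@acquiredEventFreqs
  bl <- config@baselineEventFreqs
  aqInfo <- if (length(aq)) .parseEventKey(names(aq)) else NULL
  therapy <- sample(names(config@therapyMix), n, replace = TRUE,
                    prob = config@therapyMix)
  response <- sample(c("CR", "PR", "SD"), n, replace = TRUE,
                     prob = c(0.024, 0.415, 0.561))
  timeToAR <- 3 + round(stats::rexp(n, rate = 1 / 8), 1)
  purity <- stats::runif(n, config@purityRange[1], config@purityRange[2])

  cases <- vector("list", n)
  segments <- list()
  trueAcn <- list()
  planted <- vector("list", n)
  hpre <- hpost <- numeric(n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    preId <- paste0(pid, "_pre"); postId <- paste0(pid, "_post")
    baseKeys <- names(bl)[stats::runif(length(bl)) < bl]
    privKeys <- if (config@nPrivateEvents > 0)
      eventKey(paste0("PRIV", i), "SNV",
               paste0("p.V", seq_len(config@nPrivateEvents), "M"))
      else character(0)
    acqHit <- if (length(aq)) stats::runif(length(aq)) < aq else logical(0)
    acqKeys <- names(aq)[acqHit]
    acqIsMut <- aqInfo$event_class[acqHit] %in% c("SNV", "small-indel")
    # biallelic planting: acquired LOF mutation + concurrent het loss
    mutIdx <- which(acqIsMut)
    biGenes <- aqInfo$gene[acqHit][mutIdx][
      stats::runif(length(mutIdx)) < config@biallelicFreq]

    # true ACN: pre diploid; post carries planted CNA events
    acnPre <- stats::setNames(rep(2, nrow(geneIntervals)),
                              toupper(geneIntervals$gene))
    acnPost <- acnPre
    cnaRows <- which(acqHit)[aqInfo$event_class[acqHit] == "gene-CNA"]
    for (r in cnaRows) {
      g <- aqInfo$gene[r]
      if (!g %in% names(acnPost)) next
      acnPost[g] <- switch(aqInfo$detail[r],
                           loss = 1, deletion = 0.1, amplification = 8,
                           acnPost[g])
    }
    for (g in intersect(biGenes, names(acnPost)))
      acnPost[g] <- min(acnPost[g], 1)

    segPre <- simulateSegments(acnPre, purity[i], config@segmentNoiseSd,
                               geneIntervals)
    segPost <- simulateSegments(acnPost, purity[i], config@segmentNoiseSd,
                                geneIntervals)
    segments[[preId]] <- segPre
    segments[[postId]] <- segPost
    trueAcn[[preId]] <- acnPre
    trueAcn[[postId]] <- acnPost

    keysToVariants <- function(keys, lofKeys = character(0)) {
      if (!length(keys)) return(NULL)
      info <- .parseEventKey(keys)
      mut <- info$event_class %in% c("SNV", "small-indel")
      if (!any(mut)) return(NULL)
      data.frame(gene = info$gene[mut], event_class = info$event_class[mut],
                 detail = info$detail[mut],
                 benign = FALSE, chip = FALSE,
                 functional_class = ifelse(keys[mut] %in% lofKeys,
                                           "LOF", "VUS"),
                 stringsAsFactors = FALSE)
    }
    preVar <- keysToVariants(c(baseKeys, privKeys))
    postVar <- keysToVariants(c(baseKeys, privKeys, acqKeys),
                              lofKeys = acqKeys)
    tmbVal <- round(stats::rlnorm(1, log(8), 0.5), 1)
    mkProfile <- function(sid, tp, vars, segs) {
      SampleProfile(sid, tp, variants = vars,
                    acnCalls = acnCallTable(segs, purity[i], geneIntervals),
                    tmb = tmbVal + round(stats::rnorm(1, 0, 0.5), 1),
                    purity = purity[i])
    }
    cases[[i]] <- PairedCase(pid,
      pre = mkProfile(preId, "pre", preVar, segPre),
      post = mkProfile(postId, "post", postVar, segPost),
      therapyCategory = therapy[i], bestResponse = response[i],
      timeToAR = timeToAR[i])
    plantedKeys <- acqKeys
    if (length(biGenes))
      plantedKeys <- union(plantedKeys,
                           eventKey(biGenes, "gene-CNA", "loss"))
    planted[[i]] <- plantedKeys
    names(planted)[i] <- pid

    hs <- .simulateHscorePair(config@hscoreShift)
    hpre[i] <- hs["pre"]; hpost[i] <- hs["post"]
  }

  cellFrames <- list()
  engagement <- numeric(0)
  spPost <- config@spatial
  spPost$targetEngagement <- config@spatial$targetEngagement / 2
  for (i in seq_len(min(nSpatial, n))) {
    pid <- sprintf("P%03d", i)
    for (tp in c("pre", "post")) {
      sid <- paste0(pid, "_", tp)
      sp <- if (tp == "pre") config@spatial else spPost
      sim <- simulateCells(sp, seed = .deriveSeed(config@seed,
                                                  2L * i + (tp == "post")),
                           sampleId = sid, timepoint = tp)
      cellFrames[[sid]] <- sim$frame
      engagement[sid] <- sim$achievedEngagement
    }
  }

  manifest <- data.frame(
    patient_id = vapply(cases, patientId, character(1)),
    pre_sample = paste0(vapply(cases, patientId, character(1)), "_pre"),
    post_sample = paste0(vapply(cases, patientId, character(1)), "_post"),
    therapy_category = therapy, best_response = response,
    time_to_ar_months = timeToAR, purity = round(purity, 3),
    stringsAsFactors = FALSE)

  list(cases = cases, segments = segments, cellFrames = cellFrames,
       hscores = data.frame(patient_id = manifest$patient_id, pre = hpre,
                            post = hpost, stringsAsFactors = FALSE),
       manifest = manifest,
       groundTruth = list(
         plantedAcquired = planted,
         trueAcn = trueAcn,
         achievedEngagement = engagement,
         plantedDensity = config@spatial$density,
         purity = stats::setNames(purity, manifest$patient_id),
         hscoreShift = config@hscoreShift,
         seed = config@seed))
}
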