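#' @importFrom GenomicRanges GRanges findOverlaps pintersect
#' @importFrom IRanges IRanges width
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Purity-corrected absolute copy number
#'
#' Converts a gene-level weighted mean segmented log2 ratio `l` and a tumor
#' purity `p` into an absolute copy number estimate:
#' \deqn{ACN = \frac{2^{l+1} - 2(1-p)}{p}}
#' At `l = 0` the purity cancels and ACN is exactly 2 for every `p` — a
#' diploid gene looks diploid regardless of stromal admixture. Raw values
#' can be negative when the observed ratio is lower than a pure-stroma
#' signal would allow (a diagnostic of purity overestimation); callers that
#' need a copy number clamp at 0 (see [acnCallTable()]).
#'
#' @param l Weighted mean segmented log2 ratio (vectorized).
#' @param p Tumor purity in (0, 1].
#' @return Numeric vector of raw ACN estimates (possibly negative).
#' @examples
#' absoluteCopyNumber(0, 0.4)   # 2: purity cancels at l = 0
#' absoluteCopyNumber(1, 0.5)   # 6
#' absoluteCopyNumber(-1, 0.8)  # 0.75
#' @export
absoluteCopyNumber <- function(l, p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("purity must lie in (0, 1]")
  (2^(l + 1) - 2 * (1 - p)) / p
}

#' Weighted mean segment log2 ratio over a gene
#'
#' Overlap-length-weighted average of segmented log2 ratios across a gene
#' interval: \eqn{l = \sum_k w_k \ell_k / \sum_k w_k} where \eqn{w_k} is the
#' number of bases of segment k overlapping the gene. Coordinates are
#' 1-based inclusive on both sides (SEG convention).
#'
#' @param segments data.frame of segments for one sample: columns `chrom`,
#'   `start`, `end`, `log2_ratio` (optional `n_markers`).
#' @param gene One-row data.frame or list with `chrom`, `start`, `end`.
#' @return The weighted mean log2 ratio, or `NA_real_` (with a message)
#'   when no segment overlaps the gene.
#' @examples
#' seg <- data.frame(chrom = "1", start = c(1, 2001), end = c(2000, 5000),
#'                   log2_ratio = c(1, 0))
#' weightedGeneLog2(seg, list(chrom = "1", start = 1001, end = 5000))  # 0.25
#' @export
weightedGeneLog2 <- function(segments, gene) {
  .checkSegments(segments)
  segChr <- segments[segments$chrom == gene$chrom, , drop = FALSE]
  if (!nrow(segChr)) {
    message("no segments on chromosome ", gene$chrom, "; gene uncallable")
    return(NA_real_)
  }
  gr <- GRanges(gene$chrom, IRanges(gene$start, gene$end))
  sg <- GRanges(segChr$chrom, IRanges(segChr$start, segChr$end))
  hits <- findOverlaps(gr, sg)
  if (!length(hits)) {
    message("no segment overlaps gene interval; gene uncallable")
    return(NA_real_)
  }
  ov <- pintersect(sg[subjectHits(hits)], gr[queryHits(hits)])
  w <- width(ov)
  l2 <- segChr$log2_ratio[subjectHits(hits)]
  sum(w * l2) / sum(w)
}

.checkSegments <- function(segments) {
  need <- c("chrom", "start", "end", "log2_ratio")
  if (!all(need %in% names(segments)))
    stop("segments need columns: ", paste(need, collapse = ", "))
  if (nrow(segments) && any(segments$start > segments$end))
    stop("segment start > end")
  invisible(segments)
}

.ACN_CATEGORIES <- c("homozygous-deletion", "heterozygous-deletion",
                     "neutral", "gain", "high-amplification")

#' Default ACN category thresholds
#'
#' Category cutpoints on the clamped ACN scale, chosen to mirror common
#' targeted-panel practice: homozygous deletion below 0.5 copies,
#' heterozygous deletion below 1.5, neutral through 2.5, gain through 6,
#' and high-level amplification above 6 copies. Boundary values fall in the
#' lower-severity class.
#'
#' @return Named numeric vector of upper bounds for the first four
#'   categories.
#' @export
defaultAcnThresholds <- function() {
  c("homozygous-deletion" = 0.5, "heterozygous-deletion" = 1.5,
    "neutral" = 2.5, "gain" = 6.0)
}

#' Classify an absolute copy number into a CNA category
#'
#' @param acn Clamped (nonnegative) absolute copy number, vectorized.
#' @param thresholds Named upper bounds as in [defaultAcnThresholds()];
#'   must be strictly increasing.
#' @return Character vector of categories.
#' @examples
#' classifyAcn(c(0.2, 2, 7.5))
#' @export
classifyAcn <- function(acn, thresholds = defaultAcnThresholds()) {
  if (length(thresholds) != 4L || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be 4 strictly increasing upper bounds")
  if (any(acn < 0, na.rm = TRUE)) stop("acn must be >= 0 (use the clamped value)")
  # boundaries inclusive on the lower-severity side:
  # hom-del < t1 <= het-del < t2 <= neutral <= t3 < gain <= t4 < high-amp
  out <- rep(NA_character_, length(acn))
  ok <- !is.na(acn)
  a <- acn[ok]
  cat <- ifelse(a < thresholds[1], "homozygous-deletion",
         ifelse(a < thresholds[2], "heterozygous-deletion",
         ifelse(a <= thresholds[3], "neutral",
         ifelse(a <= thresholds[4], "gain", "high-amplification"))))
  out[ok] <- cat
  out
}

#' Gene-level ACN call table for one sample
#'
#' Runs [weightedGeneLog2()] and [absoluteCopyNumber()] over a gene
#' interval table and classifies each gene. Both the raw (possibly
#' negative) and the clamped ACN are reported; the category uses the
#' clamped value.
#'
#' @param segments Segment data.frame for one sample (`chrom`, `start`,
#'   `end`, `log2_ratio`).
#' @param purity Tumor purity in (0, 1].
#' @param geneIntervals data.frame with columns `gene`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param thresholds Category thresholds, see [classifyAcn()].
#' @return data.frame with columns `gene`, `l`, `purity`, `acn_raw`, `acn`,
#'   `category` (`NA` rows for uncallable genes).
#' @export
acnCallTable <- function(segments, purity, geneIntervals,
                         thresholds = defaultAcnThresholds()) {
  .checkSegments(segments)
  ls <- rep(NA_real_, nrow(geneIntervals))
  if (nrow(segments)) {
    shared <- intersect(unique(geneIntervals$chrom), unique(segments$chrom))
    gi <- which(geneIntervals$chrom %in% shared)
    si <- which(segments$chrom %in% shared)
    if (length(gi) && length(si)) {
      gr <- GRanges(geneIntervals$chrom[gi],
                    IRanges(geneIntervals$start[gi], geneIntervals$end[gi]))
      sg <- GRanges(segments$chrom[si],
                    IRanges(segments$start[si], segments$end[si]))
      hits <- findOverlaps(gr, sg)
      if (length(hits)) {
        w <- width(pintersect(sg[subjectHits(hits)], gr[queryHits(hits)]))
        l2 <- segments$log2_ratio[si][subjectHits(hits)]
        num <- rowsum(w * l2, queryHits(hits))
        den <- rowsum(w, queryHits(hits))
        ls[gi[as.integer(rownames(num))]] <- num[, 1] / den[, 1]
      }
    }
  }
  raw <- ifelse(is.na(ls), NA_real_, absoluteCopyNumber(ls, purity))
  acn <- pmax(raw, 0)
  data.frame(gene = toupper(geneIntervals$gene), l = ls, purity = purity,
             acn_raw = raw, acn = acn,
             category = classifyAcn(acn, thresholds),
             stringsAsFactors = FALSE)
}

#' Arm-level aneuploidy calls and score
#'
#' A deliberately simplified arm-level somatic copy-number caller in the
#' spirit of coverage-weighted arm callers for targeted panels: an arm is
#' callable when at least `coverageThreshold` of its length is covered by
#' segments; a callable arm is called `gain` (resp. `loss`) when at least
#' `coverageThreshold` of its segment-covered length carries a log2 ratio
#' >= `amplitudeThreshold` (resp. <= `-amplitudeThreshold`), and `neutral`
#' otherwise. The aneuploidy score is the count of arms called gain or
#' loss. Output metadata records the simplification.
#'
#' @param segments Segment data.frame (`chrom`, `start`, `end`,
#'   `log2_ratio`).
#' @param armIntervals data.frame with columns `arm`, `chrom`, `start`,
#'   `end`.
#' @param amplitudeThreshold Log2-ratio amplitude cutoff (default 0.2).
#' @param coverageThreshold Fraction cutoff for both callability and call
#'   agreement (default 0.7).
#' @return List with `arm_calls` (data.frame `arm`, `covered_fraction`,
#'   `call`) and integer `score`; attribute `method` notes the simplified
#'   rule.
#' @export
aneuploidyScore <- function(segments, armIntervals,
                            amplitudeThreshold = 0.2,
                            coverageThreshold = 0.7) {
  if (!nrow(segments)) {
    warning("empty segment set: all arms uncalled, score 0")
    calls <- data.frame(arm = armIntervals$arm, covered_fraction = 0,
                        call = "uncalled", stringsAsFactors = FALSE)
    return(structure(list(arm_calls = calls, score = 0L),
                     method = "simplified amplitude+coverage arm caller"))
  }
  .checkSegments(segments)
  calls <- lapply(seq_len(nrow(armIntervals)), function(i) {
    arm <- armIntervals[i, ]
    armLen <- arm$end - arm$start + 1
    segChr <- segments[segments$chrom == arm$chrom, , drop = FALSE]
    if (!nrow(segChr))
      return(data.frame(arm = arm$arm, covered_fraction = 0,
                        call = "uncalled", stringsAsFactors = FALSE))
    sg <- GRanges(segChr$chrom, IRanges(segChr$start, segChr$end))
    ar <- GRanges(arm$chrom, IRanges(arm$start, arm$end))
    hits <- findOverlaps(ar, sg)
    if (!length(hits))
      return(data.frame(arm = arm$arm, covered_fraction = 0,
                        call = "uncalled", stringsAsFactors = FALSE))
    ov <- pintersect(sg[subjectHits(hits)], ar)
    w <- width(ov)
    l2 <- segChr$log2_ratio[subjectHits(hits)]
    covered <- sum(w) / armLen
    if (covered < coverageThreshold)
      return(data.frame(arm = arm$arm, covered_fraction = covered,
                        call = "uncalled", stringsAsFactors = FALSE))
    fGain <- sum(w[l2 >= amplitudeThreshold]) / sum(w)
    fLoss <- sum(w[l2 <= -amplitudeThreshold]) / sum(w)
    call <- if (fGain >= coverageThreshold) "gain"
            else if (fLoss >= coverageThreshold) "loss" else "neutral"
    data.frame(arm = arm$arm, covered_fraction = covered, call = call,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  structure(list(arm_calls = calls,
                 score = sum(calls$call %in% c("gain", "loss"))),
            method = "simplified amplitude+coverage arm caller")
}
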