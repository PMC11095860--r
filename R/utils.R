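.EVENT_CLASSES <- c("SNV", "small-indel", "gene-CNA", "structural-variant")

#' Canonical genomic event key
#'
#' Builds the canonical string identity of a genomic event: gene symbol
#' (upper-cased), event class, and a detail field — the protein change for
#' SNVs/indels, the direction (`loss`, `deletion`, `amplification`) for
#' gene-level CNAs, or a partner/breakpoint label for structural variants.
#' Two events are the same event iff their keys are equal.
#'
#' @param gene Gene symbol.
#' @param event_class One of `"SNV"`, `"small-indel"`, `"gene-CNA"`,
#'   `"structural-variant"`.
#' @param detail Canonical detail string (case-normalized to lower case
#'   except protein-change strings, which keep their case).
#' @return Character vector of canonical keys `GENE|class|detail`.
#' @examples
#' eventKey("stk11", "SNV", "p.K78fs")
#' eventKey("B2M", "gene-CNA", "Loss")
#' @export
eventKey <- function(gene, event_class, detail) {
  if (!all(event_class %in% .EVENT_CLASSES))
    stop("unknown event_class: ",
         paste(setdiff(event_class, .EVENT_CLASSES), collapse = ", "))
  detail <- ifelse(event_class == "gene-CNA", tolower(detail),
                   as.character(detail))
  paste(toupper(gene), event_class, detail, sep = "|")
}

.parseEventKey <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(
    gene = vapply(parts, `[`, "", 1L),
    event_class = vapply(parts, `[`, "", 2L),
    detail = vapply(parts, function(p) paste(p[-(1:2)], collapse = "|"), ""),
    stringsAsFactors = FALSE
  )
}

.emptyVariants <- function() {
  data.frame(gene = character(0), event_class = character(0),
             detail = character(0), event_key = character(0),
             benign = logical(0), chip = logical(0),
             functional_class = character(0), stringsAsFactors = FALSE)
}

.emptyAcnCalls <- function() {
  data.frame(gene = character(0), l = numeric(0), purity = numeric(0),
             acn_raw = numeric(0), acn = numeric(0), category = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a SampleProfile
#'
#' @param sampleId Sample identifier.
#' @param timepoint `"pre"` or `"post"`.
#' @param variants Variant data.frame with columns `gene`, `event_class`,
#'   `detail` and optional `benign`, `chip`, `functional_class`; an
#'   `event_key` column is derived. Absent flag columns are treated as
#'   all-FALSE (with a message).
#' @param acnCalls Gene-level ACN call data.frame (see [acnCallTable()]).
#' @param tmb,purity Optional scalars.
#' @return A [SampleProfile] object.
#' @export
SampleProfile <- function(sampleId, timepoint, variants = NULL,
                          acnCalls = NULL, tmb = NA_real_,
                          purity = NA_real_) {
  if (is.null(variants) || !nrow(variants)) {
    variants <- .emptyVariants()
  } else {
    variants <- as.data.frame(variants, stringsAsFactors = FALSE)
    for (fl in c("benign", "chip")) {
      if (is.null(variants[[fl]])) {
        message("variant flag column '", fl, "' absent; treating as FALSE")
        variants[[fl]] <- FALSE
      }
      variants[[fl]] <- as.logical(variants[[fl]]) %in% TRUE
    }
    if (is.null(variants$functional_class))
      variants$functional_class <- "VUS"
    variants$event_key <- eventKey(variants$gene, variants$event_class,
                                   variants$detail)
    variants$gene <- toupper(variants$gene)
    variants <- variants[, names(.emptyVariants())]
  }
  if (is.null(acnCalls)) acnCalls <- .emptyAcnCalls()
  new("SampleProfile", sampleId = as.character(sampleId),
      timepoint = timepoint, variants = variants,
      acnCalls = as.data.frame(acnCalls, stringsAsFactors = FALSE),
      tmb = as.numeric(tmb), purity = as.numeric(purity))
}

#' Construct a PairedCase
#'
#' @param patientId Patient identifier.
#' @param pre,post [SampleProfile]s; timepoints must be `"pre"`/`"post"`.
#' @param therapyCategory,bestResponse,timeToAR,biopsyIntervalMonths,pdl1TpsBin
#'   Clinical annotations; see [PairedCase-class].
#' @return A [PairedCase] object.
#' @export
PairedCase <- function(patientId, pre, post, therapyCategory = "ICI-mono",
                       bestResponse = "SD", timeToAR = 3,
                       biopsyIntervalMonths = NA_real_,
                       pdl1TpsBin = NA_character_) {
  new("PairedCase", patientId = as.character(patientId), pre = pre,
      post = post, therapyCategory = therapyCategory,
      bestResponse = bestResponse, timeToAR = as.numeric(timeToAR),
      biopsyIntervalMonths = as.numeric(biopsyIntervalMonths),
      pdl1TpsBin = as.character(pdl1TpsBin))
}

#' Construct a CellFrame
#'
#' @param cells data.frame with `cell_id`, `x`, `y` (microns), logical
#'   marker columns, optional `cell_class`.
#' @param tissueAreaMm2 Tissue area in mm^2.
#' @param sampleId,timepoint Identifiers.
#' @return A [CellFrame] object.
#' @export
CellFrame <- function(cells, tissueAreaMm2, sampleId = "sample",
                      timepoint = NA_character_) {
  new("CellFrame", cells = as.data.frame(cells, stringsAsFactors = FALSE),
      tissueAreaMm2 = as.numeric(tissueAreaMm2),
      sampleId = as.character(sampleId), timepoint = as.character(timepoint))
}

#' Construct a SimConfig
#'
#' Defaults emulate the cohort structure the analysis assumes: a mostly
#' PD-(L)1-treated cohort with acquired loss-of-function mutations and CNAs
#' planted at the frequencies reported for immunotherapy acquired
#' resistance, equal pre/post purity drawn uniformly from (0.3, 0.9), and a
#' spatial compartment with tumor and immune cell classes at realistic
#' densities. See the package vignette for the rationale behind each
#' default.
#'
#' @param nPatients Number of paired cases.
#' @param therapyMix Named proportions over therapy categories (sum to 1).
#' @param acquiredEventFreqs,baselineEventFreqs Named per-event planting
#'   probabilities (canonical event keys).
#' @param biallelicFreq Probability a planted acquired LOF mutation carries
#'   a concurrent acquired heterozygous loss of the same gene.
#' @param nPrivateEvents Patient-private passenger variants present in both
#'   samples of each pair.
#' @param purityRange Uniform sampling interval for purity, within (0, 1].
#' @param segmentNoiseSd Log2-ratio noise SD for simulated segments.
#' @param spatial List: `areaMm2`, `density` (named, cells/mm^2),
#'   `targetEngagement`.
#' @param hscoreShift Mean post-minus-pre H-score shift.
#' @param seed Integer seed.
#' @return A [SimConfig] object.
#' @export
SimConfig <- function(nPatients = 50L,
                      therapyMix = c("ICI-mono" = 0.561, "ICI+CTLA4" = 0.061,
                                     "chemo-ICI" = 0.378),
                      acquiredEventFreqs = defaultAcquiredEventFreqs(),
                      baselineEventFreqs = defaultBaselineEventFreqs(),
                      biallelicFreq = 0.3,
                      nPrivateEvents = 3L,
                      purityRange = c(0.3, 0.9),
                      segmentNoiseSd = 0.05,
                      spatial = list(areaMm2 = 1,
                                     density = c(lymphocyte = 150,
                                                 epithelial = 800,
                                                 macrophage = 100,
                                                 PD1 = 60, PDL1 = 80),
                                     targetEngagement = 0.25),
                      hscoreShift = -40,
                      seed = 1L) {
  if (!length(therapyMix) || is.null(names(therapyMix)))
    stop("therapyMix must be a non-empty named vector of proportions")
  new("SimConfig", nPatients = as.integer(nPatients), therapyMix = therapyMix,
      acquiredEventFreqs = acquiredEventFreqs,
      baselineEventFreqs = baselineEventFreqs,
      biallelicFreq = biallelicFreq, nPrivateEvents = as.integer(nPrivateEvents),
      purityRange = as.numeric(purityRange),
      segmentNoiseSd = as.numeric(segmentNoiseSd), spatial = spatial,
      hscoreShift = as.numeric(hscoreShift), seed = as.integer(seed))
}

#' Default planted acquired-event frequencies
#'
#' Per-patient probabilities for the recurrent acquired events reported at
#' resistance to PD-(L)1 blockade: loss-of-function mutations (e.g. STK11
#' 8.9%, B2M 6.3%, SMARCA4 6.3%, KEAP1 2.5%, JAK1 1.3%), acquired
#' heterozygous losses (B2M 22.8%, STK11 17.7%, KEAP1 16.5%), homozygous
#' deletions (CDKN2A 8.9%) and high-level amplifications (MDM2 5.1%, KRAS
#' 3.8%).
#'
#' @return Named numeric vector keyed by canonical event key.
#' @export
defaultAcquiredEventFreqs <- function() {
  c(
    structure(0.089, names = eventKey("STK11", "SNV", "p.K78fs")),
    structure(0.063, names = eventKey("B2M", "SNV", "p.E94*")),
    structure(0.063, names = eventKey("SMARCA4", "small-indel", "p.Q721fs")),
    structure(0.025, names = eventKey("KEAP1", "SNV", "p.R320Q")),
    structure(0.013, names = eventKey("JAK1", "SNV", "p.P733L")),
    structure(0.228, names = eventKey("B2M", "gene-CNA", "loss")),
    structure(0.177, names = eventKey("STK11", "gene-CNA", "loss")),
    structure(0.165, names = eventKey("KEAP1", "gene-CNA", "loss")),
    structure(0.089, names = eventKey("CDKN2A", "gene-CNA", "deletion")),
    structure(0.051, names = eventKey("MDM2", "gene-CNA", "amplification")),
    structure(0.038, names = eventKey("KRAS", "gene-CNA", "amplification"))
  )
}

#' Default baseline (shared pre/post) event frequencies
#'
#' Driver events present at baseline in both biopsies of a pair; KRAS
#' drivers at the cohort's reported 34.1% rate, TP53 at a typical NSCLC
#' rate.
#'
#' @return Named numeric vector keyed by canonical event key.
#' @export
defaultBaselineEventFreqs <- function() {
  c(
    structure(0.341, names = eventKey("KRAS", "SNV", "p.G12C")),
    structure(0.50, names = eventKey("TP53", "SNV", "p.R273H")),
    structure(0.12, names = eventKey("EGFR", "small-indel", "p.E746_A750del"))
  )
}

# Derive a module-level seed from the top-level seed; keeps all streams
# reproducible from one integer and below 2^31.
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

.roundPct <- function(x) round(x, 1)
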