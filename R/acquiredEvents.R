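#' Remove benign and clonal-hematopoiesis variants
#'
#' Variants predicted benign or attributed to clonal hematopoiesis of
#' indeterminate potential (CHIP, blood-derived) are excluded before any
#' acquired-event analysis. Absent flag columns are treated as all-FALSE
#' with a message; removal counts are reported via message.
#'
#' @param variants Variant data.frame with logical `benign` and `chip`
#'   columns (see [SampleProfile()]).
#' @return The filtered data.frame.
#' @export
filterVariants <- function(variants) {
  if (!nrow(variants)) return(variants)
  for (fl in c("benign", "chip")) {
    if (is.null(variants[[fl]])) {
      message("flag column '", fl, "' absent; treating as FALSE")
      variants[[fl]] <- FALSE
    }
  }
  drop <- variants$benign %in% TRUE | variants$chip %in% TRUE
  if (any(drop))
    message("filtered ", sum(variants$benign %in% TRUE), " benign and ",
            sum(variants$chip %in% TRUE & !(variants$benign %in% TRUE)),
            " CHIP variant(s); ", sum(!drop), " retained")
  variants[!drop, , drop = FALSE]
}

.CNA_SEVERITY <- c("neutral" = 0L,
                   "heterozygous-deletion" = 1L, "homozygous-deletion" = 2L,
                   "gain" = 1L, "high-amplification" = 2L)
.CNA_DIRECTION <- c("neutral" = "none",
                    "heterozygous-deletion" = "loss",
                    "homozygous-deletion" = "loss",
                    "gain" = "gain", "high-amplification" = "gain")

.cnaFindingType <- function(category) {
  c("heterozygous-deletion" = "heterozygous-loss",
    "homozygous-deletion" = "homozygous-deletion",
    "gain" = "amplification",
    "high-amplification" = "amplification")[category]
}

# An acquired CNA is a move away from the pre state toward (or further
# into) a non-neutral state: pre neutral -> any non-neutral, deeper
# same-direction change (het -> hom deletion, gain -> high-amplification),
# or a direction flip. Moves back toward neutral are reversions, reported
# separately.
.cnaAcquired <- function(preCat, postCat) {
  if (is.na(preCat) || is.na(postCat)) return(FALSE)
  if (postCat == "neutral" || postCat == preCat) return(FALSE)
  preDir <- .CNA_DIRECTION[preCat]; postDir <- .CNA_DIRECTION[postCat]
  if (preDir == "none") return(TRUE)
  if (preDir != postDir) return(TRUE)
  .CNA_SEVERITY[postCat] > .CNA_SEVERITY[preCat]
}

#' Call acquired genomic alterations in a matched pair
#'
#' Compares the filtered post-therapy profile against the pre-therapy
#' profile of one [PairedCase]: a mutation is acquired iff its canonical
#' event key is present post and absent pre (presence at any level in the
#' pre sample blocks the call); a gene CNA is acquired iff the post
#' category moved away from the pre category into or further into a
#' non-neutral state. A gene with both an acquired mutation and an
#' acquired copy loss in the same post sample is flagged biallelic
#' (biallelic inactivation). Events present pre but absent post are
#' returned separately as reversions.
#'
#' @param pair A [PairedCase]; pre/post patient ids must match.
#' @return List with `findings` (data.frame `gene`, `finding_type`,
#'   `biallelic`, `event`) and `lost` (reversion data.frame `gene`,
#'   `event`).
#' @export
callAcquired <- function(pair) {
  pre <- preSample(pair); post <- postSample(pair)
  preV <- filterVariants(variants(pre))
  postV <- filterVariants(variants(post))
  newMut <- postV[!postV$event_key %in% preV$event_key, , drop = FALSE]
  lostMut <- preV[!preV$event_key %in% postV$event_key, , drop = FALSE]

  preAcn <- acnCalls(pre); postAcn <- acnCalls(post)
  findings <- data.frame(gene = character(0), finding_type = character(0),
                         biallelic = logical(0), event = character(0),
                         stringsAsFactors = FALSE)
  if (nrow(newMut))
    findings <- rbind(findings, data.frame(
      gene = newMut$gene, finding_type = "mutation", biallelic = FALSE,
      event = newMut$event_key, stringsAsFactors = FALSE))
  if (nrow(postAcn)) {
    preCat <- preAcn$category[match(postAcn$gene, preAcn$gene)]
    preCat[is.na(preCat)] <- "neutral"  # gene uncalled pre: assume neutral
    acq <- vapply(seq_len(nrow(postAcn)), function(i)
      .cnaAcquired(preCat[i], postAcn$category[i]), logical(1))
    if (any(acq)) {
      g <- postAcn$gene[acq]
      findings <- rbind(findings, data.frame(
        gene = g, finding_type = .cnaFindingType(postAcn$category[acq]),
        biallelic = FALSE,
        event = eventKey(g, "gene-CNA",
                         ifelse(postAcn$category[acq] == "homozygous-deletion",
                                "deletion",
                         ifelse(.CNA_DIRECTION[postAcn$category[acq]] == "loss",
                                "loss", "amplification"))),
        stringsAsFactors = FALSE))
    }
  }
  if (nrow(findings)) {
    mutGenes <- unique(findings$gene[findings$finding_type == "mutation"])
    lossGenes <- unique(findings$gene[findings$finding_type %in%
                          c("heterozygous-loss", "homozygous-deletion")])
    bi <- intersect(mutGenes, lossGenes)
    findings$biallelic <- findings$gene %in% bi
    rownames(findings) <- NULL
  }
  lost <- data.frame(gene = lostMut$gene, event = lostMut$event_key,
                     stringsAsFactors = FALSE)
  list(findings = findings, lost = lost)
}

#' Summarize acquired alterations across a cohort
#'
#' Per-gene acquired-event frequencies and the headline cohort
#' percentages: fraction of pairs with at least one acquired mutation, at
#' least one acquired CNA, and at least one acquired change of any kind.
#' The denominator is always the number of pairs supplied (pairs with
#' genomic profiling); percentages are rounded to one decimal for report
#' parity and reported alongside their numerators and denominator. Within
#' each finding type a patient counts once per gene.
#'
#' @param cohort List of [PairedCase] objects.
#' @param genePanel Optional character vector restricting per-gene
#'   summaries; default: all genes observed in findings.
#' @return List with `overall` (data.frame `measure`, `numerator`,
#'   `denominator`, `pct`), `per_gene` (data.frame `gene`,
#'   `finding_type`, `n_patients`, `denominator`, `pct`), and
#'   `per_patient` (data.frame of per-pair indicator columns).
#' @export
summarizeCohort <- function(cohort, genePanel = NULL) {
  if (!length(cohort)) stop("empty cohort")
  perPatient <- lapply(cohort, function(pair) {
    res <- suppressMessages(callAcquired(pair))
    f <- res$findings
    data.frame(patient_id = patientId(pair),
               therapy_category = therapyCategory(pair),
               best_response = bestResponse(pair),
               time_to_ar = timeToAR(pair),
               pdl1_tps_bin = pair@pdl1TpsBin,
               any_mutation = any(f$finding_type == "mutation"),
               any_cna = any(f$finding_type != "mutation"),
               any_change = nrow(f) > 0,
               stringsAsFactors = FALSE)
  })
  perPatient <- do.call(rbind, perPatient)
  nPairs <- nrow(perPatient)
  overall <- data.frame(
    measure = c("acquired_mutation", "acquired_cna", "any_change"),
    numerator = c(sum(perPatient$any_mutation), sum(perPatient$any_cna),
                  sum(perPatient$any_change)),
    denominator = nPairs, stringsAsFactors = FALSE)
  overall$pct <- .roundPct(100 * overall$numerator / overall$denominator)

  allFindings <- do.call(rbind, lapply(cohort, function(pair) {
    f <- suppressMessages(callAcquired(pair))$findings
    if (!nrow(f)) return(NULL)
    f$patient_id <- patientId(pair)
    f
  }))
  if (is.null(allFindings) || !nrow(allFindings)) {
    perGene <- data.frame(gene = character(0), finding_type = character(0),
                          n_patients = integer(0), denominator = integer(0),
                          pct = numeric(0), stringsAsFactors = FALSE)
  } else {
    if (!is.null(genePanel))
      allFindings <- allFindings[allFindings$gene %in% toupper(genePanel), ,
                                 drop = FALSE]
    # one count per patient per gene per finding type
    key <- unique(allFindings[, c("gene", "finding_type", "patient_id")])
    agg <- stats::aggregate(patient_id ~ gene + finding_type, data = key,
                            FUN = length)
    names(agg)[3] <- "n_patients"
    agg$denominator <- nPairs
    agg$pct <- .roundPct(100 * agg$n_patients / nPairs)
    perGene <- agg[order(-agg$n_patients, agg$gene), ]
    rownames(perGene) <- NULL
  }
  list(overall = overall, per_gene = perGene, per_patient = perPatient)
}

#' Stratified acquired-event summaries with Fisher exact tests
#'
#' Splits the cohort on a clinical variable — time to acquired resistance
#' dichotomized at a cutoff (default 6 months), therapy category, best
#' response, or PD-L1 TPS bin — summarizes acquired-event rates per
#' stratum, and tests each category-level (and per-gene) 2x2 association
#' with the exact Fisher test. Pairs missing the stratification variable
#' are excluded with a message; empty strata are dropped with a warning.
#'
#' @param cohort List of [PairedCase] objects.
#' @param by One of `"time_to_ar"`, `"therapy_category"`,
#'   `"best_response"`, `"pdl1_tps_bin"`.
#' @param cutoffMonths Dichotomization cutoff for `by = "time_to_ar"`.
#' @return List with `strata` (per-stratum overall tables) and `tests`
#'   (data.frame `measure`, strata counts, `p_value`) for two-stratum
#'   splits; multi-stratum splits return summaries only, with tests `NULL`.
#' @export
stratifyCohort <- function(cohort, by = c("time_to_ar", "therapy_category",
                                          "best_response", "pdl1_tps_bin"),
                           cutoffMonths = 6) {
  by <- match.arg(by)
  summ <- summarizeCohort(cohort)$per_patient
  strat <- switch(by,
    time_to_ar = ifelse(is.na(summ$time_to_ar), NA_character_,
                        ifelse(summ$time_to_ar >= cutoffMonths,
                               paste0(">=", cutoffMonths, "mo"),
                               paste0("<", cutoffMonths, "mo"))),
    therapy_category = summ$therapy_category,
    best_response = summ$best_response,
    pdl1_tps_bin = summ$pdl1_tps_bin)
  keep <- !is.na(strat) & strat != "NA"
  if (any(!keep))
    message(sum(!keep), " pair(s) missing '", by, "'; excluded")
  summ <- summ[keep, , drop = FALSE]
  strat <- strat[keep]
  levs <- unique(strat)
  if (!length(levs)) stop("no pairs carry the stratification variable")
  strata <- lapply(split(summ, strat), function(s) {
    data.frame(
      measure = c("acquired_mutation", "acquired_cna", "any_change"),
      numerator = c(sum(s$any_mutation), sum(s$any_cna), sum(s$any_change)),
      denominator = nrow(s),
      pct = .roundPct(100 * c(sum(s$any_mutation), sum(s$any_cna),
                              sum(s$any_change)) / nrow(s)),
      stringsAsFactors = FALSE)
  })
  empty <- vapply(strata, function(s) s$denominator[1] == 0, logical(1))
  if (any(empty)) {
    warning("empty stratum omitted: ", paste(names(strata)[empty],
                                             collapse = ", "))
    strata <- strata[!empty]
  }
  tests <- NULL
  if (length(strata) == 2L) {
    s1 <- strata[[1]]; s2 <- strata[[2]]
    tests <- do.call(rbind, lapply(seq_len(nrow(s1)), function(i) {
      ft <- suppressWarnings(fisherExact(
        s1$numerator[i], s1$denominator[i] - s1$numerator[i],
        s2$numerator[i], s2$denominator[i] - s2$numerator[i]))
      data.frame(measure = s1$measure[i],
                 stratum1 = names(strata)[1], n1 = s1$numerator[i],
                 d1 = s1$denominator[i],
                 stratum2 = names(strata)[2], n2 = s2$numerator[i],
                 d2 = s2$denominator[i],
                 p_value = ft$p.value, stringsAsFactors = FALSE)
    }))
  }
  list(strata = strata, tests = tests)
}

#' Oncoprint-style acquired-alteration matrix
#'
#' Genes x patients character matrix of acquired findings
#' (`"mutation"`, `"heterozygous-loss"`, `"homozygous-deletion"`,
#' `"amplification"`, combinations joined with `";"`, `""` when none) —
#' the content of a cohort oncoprint of acquired events.
#'
#' @param cohort List of [PairedCase] objects.
#' @return Character matrix, rows = genes (by descending alteration
#'   count), columns = patient ids.
#' @export
acquiredMatrix <- function(cohort) {
  findings <- lapply(cohort, function(pair)
    suppressMessages(callAcquired(pair))$findings)
  names(findings) <- vapply(cohort, patientId, character(1))
  genes <- sort(unique(unlist(lapply(findings, `[[`, "gene"))))
  if (!length(genes))
    return(matrix(character(0), 0, length(cohort),
                  dimnames = list(NULL, names(findings))))
  m <- matrix("", length(genes), length(findings),
              dimnames = list(genes, names(findings)))
  for (p in names(findings)) {
    f <- findings[[p]]
    for (g in unique(f$gene))
      m[g, p] <- paste(sort(unique(f$finding_type[f$gene == g])),
                       collapse = ";")
  }
  m[order(-rowSums(m != "")), , drop = FALSE]
}
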