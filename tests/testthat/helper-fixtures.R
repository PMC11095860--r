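# Fixture builders shared across the suite. All fixtures are constructed in
# code; nothing is read from disk.

acnRow <- function(gene, category, purity = 0.5) {
  acn <- switch(category, "homozygous-deletion" = 0.2,
                "heterozygous-deletion" = 1, "neutral" = 2, "gain" = 4,
                "high-amplification" = 8)
  data.frame(gene = toupper(gene), l = log2((purity * acn + 2 * (1 - purity)) / 2),
             purity = purity, acn_raw = acn, acn = acn, category = category,
             stringsAsFactors = FALSE)
}

acnTable <- function(genes, categories, purity = 0.5) {
  if (!length(genes)) return(NULL)
  do.call(rbind, Map(acnRow, genes, categories, purity))
}

mutRow <- function(gene, detail = "p.X1Y", class = "SNV",
                   functional = "LOF") {
  data.frame(gene = gene, event_class = class, detail = detail,
             benign = FALSE, chip = FALSE, functional_class = functional,
             stringsAsFactors = FALSE)
}

# A paired case with chosen acquired events: mutations appear post-only;
# CNA genes are neutral pre and altered post.
toyPair <- function(pid, acqMut = character(0), acqMutDetail = NULL,
                    acqCna = character(0), acqCnaCat = "heterozygous-deletion",
                    baseMut = character(0), therapy = "ICI-mono",
                    response = "PR", timeToAR = 7) {
  if (is.null(acqMutDetail)) acqMutDetail <- paste0("p.A", seq_along(acqMut), "T")
  base <- if (length(baseMut))
    do.call(rbind, Map(mutRow, baseMut, paste0("p.B", seq_along(baseMut), "V")))
    else NULL
  postVar <- rbind(base, if (length(acqMut))
    do.call(rbind, Map(mutRow, acqMut, acqMutDetail)))
  genes <- unique(c(acqCna, "TP53"))
  preAcn <- acnTable(genes, rep("neutral", length(genes)))
  postAcn <- acnTable(genes, c(rep(acqCnaCat, length(acqCna)),
                               rep("neutral", length(genes) - length(acqCna))))
  PairedCase(pid,
    pre = SampleProfile(paste0(pid, "_pre"), "pre", variants = base,
                        acnCalls = preAcn, purity = 0.5),
    post = SampleProfile(paste0(pid, "_post"), "post", variants = postVar,
                         acnCalls = postAcn, purity = 0.5),
    therapyCategory = therapy, bestResponse = response, timeToAR = timeToAR)
}

# 79-pair cohort engineered to carry the acquired-event counts of a
# reference acquired-resistance cohort: 22 pairs with >=1 acquired
# mutation (5 of them B2M, 7 STK11), 39 with >=1 acquired CNA (12 of
# these also among the mutation carriers), 49 with any change.
toyCohort79 <- function() {
  cases <- vector("list", 79)
  for (i in 1:79) {
    pid <- sprintf("T%02d", i)
    mutGene <- if (i <= 5) "B2M" else if (i <= 12) "STK11"
               else if (i <= 22) "SMARCA4" else character(0)
    cnaGene <- if (i <= 12 || (i >= 23 && i <= 49)) "KEAP1" else character(0)
    cases[[i]] <- toyPair(pid, acqMut = mutGene, acqCna = cnaGene)
  }
  cases
}
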