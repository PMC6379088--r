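#' @include AllClasses.R
NULL

#' Extended-over-common 3'UTR isoform ratio
#'
#' Efficiency-based abundance ratio of a transcript's extended 3'UTR
#' isoform to its common region:
#' `ratio = E^(-Ct_ext) / E^(-Ct_comm) = E^(Ct_comm - Ct_ext)`.
#' Multiplicative in the cycle difference: adding delta-Ct values
#' multiplies the ratios.
#'
#' @param E amplification efficiency (per doubling E = 2), must exceed 1.
#' @param ctExt,ctComm detection cycle numbers of the extended and common
#'   amplicons; vectors are recycled.
#' @return numeric ratio(s).
#' @export
extComRatio <- function(E, ctExt, ctComm) {
  if (any(E <= 1)) stop("amplification efficiency must exceed 1")
  E^(ctComm - ctExt)
}

#' Normalized relative quantities from a qPCR Ct table
#'
#' Efficiency-corrected relative quantities `RQ = E^(Ct_mean(gene) - Ct)`
#' are normalized per sample by the geometric mean of the reference-gene
#' RQs, then rescaled so each gene's grand-mean NRQ is 1. NRQs are
#' invariant to adding a constant to all Ct values of a sample when all
#' efficiencies are equal (a global pipetting shift cancels). Genes whose
#' mean Ct exceeds 30 cycles are flagged unreliable, not dropped.
#'
#' @param table long-format data frame with columns `gene`, `sample`, `Ct`,
#'   `E` and logical `is_reference`; every sample must carry every
#'   reference gene.
#' @param ctReliableMax mean-Ct reliability cutoff (cycles).
#' @return data frame with `gene`, `sample`, `rq`, `nrq_raw` (before the
#'   grand-mean rescale), `nrq`, `log2_nrq`, `is_reference`, `unreliable`.
#' @export
normalizedRelativeQuantity <- function(table, ctReliableMax = 30) {
  need <- c("gene", "sample", "Ct", "E", "is_reference")
  if (!all(need %in% colnames(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  if (any(table$Ct <= 0)) stop("Ct values must be positive")
  if (any(table$E <= 1 | table$E > 2.2))
    stop("efficiencies must lie in (1, 2.2]")
  refs <- unique(table$gene[table$is_reference])
  if (length(refs) < 2)
    warning("fewer than two reference genes; normalization is fragile")
  samples <- unique(table$sample)
  for (r in refs) {
    missing <- setdiff(samples, table$sample[table$gene == r])
    if (length(missing))
      stop("reference gene ", r, " missing in sample(s) ",
           paste(missing, collapse = ", "))
  }
  ctMean <- tapply(table$Ct, table$gene, mean)
  out <- table[, c("gene", "sample", "is_reference")]
  out$rq <- as.numeric(table$E^(ctMean[table$gene] - table$Ct))
  nf <- tapply(seq_len(nrow(out)), table$sample, function(i) {
    ri <- i[table$is_reference[i]]
    exp(mean(log(out$rq[ri])))
  })
  out$nrq_raw <- out$rq / as.numeric(nf[as.character(table$sample)])
  gm <- tapply(out$nrq_raw, out$gene, mean)
  out$nrq <- out$nrq_raw / as.numeric(gm[as.character(out$gene)])
  out$log2_nrq <- log2(out$nrq)
  out$unreliable <- as.numeric(ctMean[out$gene]) > ctReliableMax
  rownames(out) <- NULL
  out
}
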