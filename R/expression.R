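#' Percent of soma area covered by transcript signal
#'
#' M-FISH quantification: the transcript channel is binarized (the same
#' threshold must be used across conditions) and the covered fraction of
#' the soma mask at its brightest focal plane is reported in percent.
#'
#' @param soma_mask logical matrix (soma at its brightest plane).
#' @param transcript plane matrix of transcript-channel intensities, or
#'   an already-binarized logical matrix.
#' @param method,value passed to [binarize()] when `transcript` is
#'   numeric (use a fixed value for cross-condition comparisons).
#' @return percent of soma area covered, in \[0, 100\].
#' @export
soma_transcript_coverage <- function(soma_mask, transcript,
                                     method = "fixed", value = NULL) {
  idx <- which(soma_mask)
  if (!length(idx)) stop("empty soma mask")
  m <- if (is.logical(transcript)) transcript
       else binarize(transcript, method, value)
  100 * sum(m[idx]) / length(idx)
}

#' Relative expression by multi-reference delta-delta-Ct
#'
#' Normalizes target Ct values to three biologically diverse reference
#' genes and a calibrator group:
#' `dCt = Ct_target - combine(Ct_refs)`, and the fold change per sample
#' is `2^-(dCt - mean dCt of the calibrator group)`. The default
#' reference combination is the arithmetic mean of the reference Cts
#' (equivalent to the geometric mean of reference expression);
#' `ref_combine = "expression_mean"` uses `-log2(mean(2^-Ct))` instead.
#' Technical replicates are averaged per sample and gene first. Samples
#' with incomplete reference measurements are excluded with a message.
#'
#' @param ct data.frame with columns `sample`, `group`, `gene`, `ct`
#'   (one row per replicate; replicates averaged).
#' @param target target gene name.
#' @param reference_genes reference gene names (default GAPDH,
#'   beta-Actin, HPRT roles).
#' @param calibrator calibrator group name.
#' @param ref_combine `"ct_mean"` (default) or `"expression_mean"`.
#' @return list with `samples` (per-sample `dct` and `fold`) and
#'   `groups` (group mean fold and SEM).
#' @export
relative_expression <- function(ct, target,
                                reference_genes = c("Gapdh", "Actb",
                                                    "Hprt"),
                                calibrator,
                                ref_combine = c("ct_mean",
                                                "expression_mean")) {
  ref_combine <- match.arg(ref_combine)
  if (any(ct$ct < 5 | ct$ct > 40)) {
    warning("Ct values outside the plausible 5-40 range")
  }
  agg <- stats::aggregate(ct ~ sample + group + gene, data = ct,
                          FUN = mean)
  out <- NULL
  for (s in unique(agg$sample)) {
    sub <- agg[agg$sample == s, ]
    tgt <- sub$ct[sub$gene == target]
    refs <- sub$ct[match(reference_genes, sub$gene)]
    if (length(tgt) != 1L || anyNA(refs) ||
        length(refs) != length(reference_genes)) {
      message("sample ", s, " excluded: incomplete target/reference Cts")
      next
    }
    ref_ct <- switch(ref_combine,
      ct_mean = mean(refs),
      expression_mean = -log2(mean(2^-refs)))
    out <- rbind(out, data.frame(sample = s, group = sub$group[1L],
                                 dct = tgt - ref_ct))
  }
  if (is.null(out)) stop("no usable samples")
  if (!calibrator %in% out$group) stop("calibrator group not present")
  cal <- mean(out$dct[out$group == calibrator])
  out$fold <- 2^-(out$dct - cal)
  grp <- do.call(rbind, lapply(split(out, out$group), function(g) {
    data.frame(group = g$group[1L], n = nrow(g),
               mean_fold = mean(g$fold),
               sem_fold = stats::sd(g$fold) / sqrt(nrow(g)))
  }))
  rownames(grp) <- NULL
  list(samples = out, groups = grp)
}
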