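#' Relative expression by the delta-delta-Ct method
#'
#' Technical-replicate Ct values are averaged on the Ct scale per
#' (condition, gene); `dCt = mean Ct(target) - mean Ct(reference)` within
#' each condition; `ddCt = dCt(condition) - dCt(calibrator)`; relative
#' expression `fold = 2^(-ddCt)` (amplification efficiency fixed at 2, the
#' classic assumption). The calibrator condition's fold is exactly 1 by
#' construction, and folds are invariant to any constant added to every Ct.
#'
#' If the table has a `replicate` column (biological replicates), folds are
#' computed per replicate and returned as mean with SD on the fold scale.
#'
#' @param ct Data.frame with columns `condition`, `gene`, `ct` (and
#'   optionally `replicate`); one row per technical-replicate measurement.
#' @param reference Reference (housekeeping) gene label, e.g. `"HPRT1"`.
#' @param calibrator Calibrator condition label, e.g. `"siCTL"`.
#' @return Data.frame: `condition`, `gene`, `fold`, `sd` (`NA` without
#'   biological replicates), for every non-reference gene.
#' @examples
#' ct <- data.frame(condition = rep(c("siCTL", "siKD"), each = 2),
#'                  gene = rep(c("HPRT1", "TARGET"), 2),
#'                  ct = c(20, 20, 20, 22))
#' ddct_relative_expression(ct)  # siKD TARGET fold 0.25
#' @export
ddct_relative_expression <- function(ct, reference = "HPRT1",
                                     calibrator = "siCTL") {
  stopifnot(all(c("condition", "gene", "ct") %in% names(ct)))
  if (any(!is.finite(ct$ct) | ct$ct <= 0))
    stop("ddct_relative_expression: Ct values must be finite and positive",
         call. = FALSE)
  if (!calibrator %in% ct$condition)
    stop("ddct_relative_expression: calibrator condition '", calibrator,
         "' not present", call. = FALSE)
  has_rep <- "replicate" %in% names(ct)
  reps <- if (has_rep) sort(unique(ct$replicate)) else 1L

  one_rep <- function(d) {
    for (cond in unique(d$condition))
      if (!reference %in% d$gene[d$condition == cond])
        stop("ddct_relative_expression: reference gene '", reference,
             "' missing in condition '", cond, "'", call. = FALSE)
    mct <- stats::aggregate(ct ~ condition + gene, data = d, FUN = mean)
    ref <- mct[mct$gene == reference, c("condition", "ct")]
    names(ref)[2] <- "ref_ct"
    tgt <- mct[mct$gene != reference, , drop = FALSE]
    tgt <- merge(tgt, ref, by = "condition")
    tgt$dct <- tgt$ct - tgt$ref_ct
    cal <- tgt[tgt$condition == calibrator, c("gene", "dct")]
    names(cal)[2] <- "dct_cal"
    tgt <- merge(tgt, cal, by = "gene")
    tgt$fold <- 2^(-(tgt$dct - tgt$dct_cal))
    tgt[, c("condition", "gene", "fold")]
  }

  per_rep <- lapply(reps, function(r) {
    d <- if (has_rep) ct[ct$replicate == r, , drop = FALSE] else ct
    one_rep(d)
  })
  all <- do.call(rbind, per_rep)
  agg <- stats::aggregate(fold ~ condition + gene, data = all,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  res <- data.frame(condition = agg$condition, gene = agg$gene,
                    fold = agg$fold[, "mean"], sd = agg$fold[, "sd"],
                    stringsAsFactors = FALSE)
  res <- res[order(res$condition, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Relative growth from nuclei counts
#'
#' Growth read out by counting DAPI-stained nuclei: each condition's mean
#' count divided by the control condition's mean, with SD propagated from
#' the replicate counts (SD of per-replicate counts on the control-mean
#' scale).
#'
#' @param counts Data.frame with columns `condition` and `count`, one row
#'   per replicate well/field.
#' @param control Control condition label.
#' @return Data.frame: `condition`, `rel_growth`, `sd`, `n`.
#' @examples
#' growth_from_counts(data.frame(condition = rep(c("siCTL", "siKD"), each = 2),
#'                               count = c(100, 100, 50, 50)))
#' @export
growth_from_counts <- function(counts, control = "siCTL") {
  stopifnot(all(c("condition", "count") %in% names(counts)))
  if (!control %in% counts$condition)
    stop("growth_from_counts: control condition '", control, "' not present",
         call. = FALSE)
  ctl_mean <- mean(counts$count[counts$condition == control])
  if (ctl_mean == 0)
    stop("growth_from_counts: zero control mean", call. = FALSE)
  conds <- unique(counts$condition)
  res <- do.call(rbind, lapply(conds, function(cond) {
    x <- counts$count[counts$condition == cond]
    data.frame(condition = cond,
               rel_growth = mean(x) / ctl_mean,
               sd = if (length(x) > 1) stats::sd(x) / ctl_mean else 0,
               n = length(x), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}
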