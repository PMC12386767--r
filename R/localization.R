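#' Normalize well metrics to negative-control wells
#'
#' Divides every well's metric by the mean metric of the siCTL wells of the
#' same biological replicate, so the siCTL-normalized mean is 1 per
#' replicate. Division (rather than subtraction) is used; the downstream
#' Z-score is location-scale invariant, so hit calls do not depend on this
#' choice.
#'
#' @param wells Well-record data.frame with columns `content`, `replicate`,
#'   `metric`.
#' @param control Negative-control label.
#' @return The input with `metric` replaced by the normalized value and the
#'   raw value kept in `metric_raw`.
#' @examples
#' w <- data.frame(content = c("siCTL", "siCTL", "KIN1"), replicate = 1,
#'                 metric = c(40, 40, 60))
#' normalize_to_controls(w)$metric  # 1, 1, 1.5
#' @export
normalize_to_controls <- function(wells, control = "siCTL") {
  stopifnot(all(c("content", "replicate", "metric") %in% names(wells)))
  out <- wells
  out$metric_raw <- wells$metric
  for (r in sort(unique(wells$replicate))) {
    sel <- wells$replicate == r
    ctl <- wells$metric[sel & wells$content == control]
    if (length(ctl) < 2L)
      stop("normalize_to_controls: fewer than 2 '", control,
           "' wells in replicate ", r, call. = FALSE)
    out$metric[sel] <- wells$metric[sel] / mean(ctl)
  }
  out
}

#' Screen-wide Z-scores per biological replicate
#'
#' Scores every well against the mean and SD of the library wells (controls
#' excluded) of the same replicate, the screen-wide scoring convention for
#' plate-based RNAi screens. Control wells are scored against the same
#' library distribution (`is_library = FALSE`) but excluded from ranks.
#' Positive Z corresponds to a cytoplasmic shift of YAP/TAZ.
#'
#' @param normalized Well-record data.frame (`content`, `replicate`,
#'   `metric`), typically from [normalize_to_controls()].
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Data.frame: `gene_id` (content label for controls), `replicate`,
#'   `z`, `rank` (1 = largest z, library wells only; ties broken by
#'   `gene_id`), `is_library`.
#' @examples
#' w <- data.frame(content = sprintf("G%d", 1:5), replicate = 1, metric = 1:5)
#' compute_zscores(w, sd_type = "population")$z
#' @export
compute_zscores <- function(normalized, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(all(c("content", "replicate", "metric") %in% names(normalized)))
  is_lib <- !(normalized$content %in% .non_library_labels)
  out <- vector("list", 0L)
  for (r in sort(unique(normalized$replicate))) {
    sel <- normalized$replicate == r
    lib_vals <- normalized$metric[sel & is_lib]
    if (length(lib_vals) < 2L)
      stop("compute_zscores: fewer than 2 library wells in replicate ", r,
           call. = FALSE)
    s <- stats::sd(lib_vals)
    if (sd_type == "population")
      s <- s * sqrt((length(lib_vals) - 1) / length(lib_vals))
    if (s == 0)
      stop("compute_zscores: zero SD among library wells in replicate ", r,
           call. = FALSE)
    z <- (normalized$metric[sel] - mean(lib_vals)) / s
    d <- data.frame(gene_id = normalized$content[sel], replicate = r,
                    z = z, rank = NA_integer_,
                    is_library = is_lib[sel], stringsAsFactors = FALSE)
    libd <- d$is_library
    d$rank[libd] <- order(order(-d$z[libd], d$gene_id[libd]))
    out[[length(out) + 1L]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Top-fraction gene sets per replicate
#'
#' Selects, independently for each replicate, the `ceiling(fraction * N)`
#' library genes with the largest Z-scores. Ties at the cutoff are broken
#' lexicographically by `gene_id` for determinism.
#'
#' @param zs Z-score data.frame from [compute_zscores()].
#' @param fraction Fraction of the library to keep, in `(0, 1]`; 0.25
#'   reproduces the top-25%-per-run rule.
#' @return Named list of character vectors, one per replicate.
#' @export
top_fraction <- function(zs, fraction = 0.25) {
  if (fraction <= 0 || fraction > 1)
    stop("top_fraction: 'fraction' must be in (0, 1]", call. = FALSE)
  lib <- if ("is_library" %in% names(zs))
    zs[zs$is_library, , drop = FALSE] else zs
  if (nrow(lib) == 0L)
    stop("top_fraction: empty Z-score table", call. = FALSE)
  reps <- sort(unique(lib$replicate))
  sets <- lapply(reps, function(r) {
    d <- lib[lib$replicate == r, , drop = FALSE]
    n_top <- as.integer(ceiling(fraction * nrow(d)))
    d$gene_id[order(-d$z, d$gene_id)][seq_len(n_top)]
  })
  names(sets) <- paste0("replicate_", reps)
  sets
}

#' Cytoplasmic-direction hits: replicate intersection of top sets
#'
#' Genes present in the top fraction of every biological replicate, the
#' replicate-concordance rule for cytoplasmic-translocation hits (Hippo
#' pathway inhibitors / YAP-TAZ activators).
#'
#' @param top_sets List of per-replicate gene sets from [top_fraction()].
#' @return Sorted character vector of gene ids.
#' @export
call_cytoplasmic_hits <- function(top_sets) {
  if (length(top_sets) < 2L)
    stop("call_cytoplasmic_hits: need at least 2 replicates", call. = FALSE)
  sort(Reduce(intersect, top_sets))
}

#' Nuclear-direction hits: Z below cutoff in every replicate
#'
#' @param zs Z-score data.frame from [compute_zscores()].
#' @param cutoff Z cutoff; genes with `z < cutoff` in every replicate are
#'   called (default -1.8, a permissive cutoff for the nuclear direction).
#' @return Sorted character vector of gene ids.
#' @export
call_nuclear_hits <- function(zs, cutoff = -1.8) {
  if (!is.finite(cutoff))
    stop("call_nuclear_hits: 'cutoff' must be finite", call. = FALSE)
  lib <- if (!is.null(zs$is_library)) zs[zs$is_library, , drop = FALSE] else zs
  reps <- sort(unique(lib$replicate))
  sets <- lapply(reps, function(r) {
    d <- lib[lib$replicate == r, , drop = FALSE]
    d$gene_id[d$z < cutoff]
  })
  if (length(sets) == 0L) return(character(0))
  sort(Reduce(intersect, sets))
}

#' Control frequency histogram and separation statistic
#'
#' Bins control-well Z-scores per control label, and computes an overlap
#' statistic: the fraction of positive-control values lying below the
#' maximum negative-control value. 0 means the positive-control
#' distribution is completely separated above the negative controls
#' (a well-performing screen); values near 1 mean complete overlap.
#'
#' @param control_zs Data.frame with columns `gene_id` (control label) and
#'   `z`, e.g. the `is_library = FALSE` rows of [compute_zscores()] output.
#' @param bin_width Histogram bin width (Z units).
#' @param negative,positive Control labels.
#' @return List: `breaks`, `counts` (matrix label x bin), `overlap`.
#' @export
control_histogram <- function(control_zs, bin_width = 0.5,
                              negative = "siCTL", positive = "siMARK4") {
  z_neg <- control_zs$z[control_zs$gene_id == negative]
  z_pos <- control_zs$z[control_zs$gene_id == positive]
  if (length(z_neg) < 1L || length(z_pos) < 1L)
    stop("control_histogram: need at least one well per control label",
         call. = FALSE)
  lo <- floor(min(z_neg, z_pos) / bin_width) * bin_width
  hi <- ceiling(max(z_neg, z_pos) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- rbind(
    table(cut(z_neg, breaks, include.lowest = TRUE)),
    table(cut(z_pos, breaks, include.lowest = TRUE)))
  rownames(counts) <- c(negative, positive)
  list(breaks = breaks, counts = counts,
       overlap = mean(z_pos < max(z_neg)))
}
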