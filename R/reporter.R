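#' Normalize firefly luciferase to beta-galactosidase
#'
#' `norm = firefly / bgal`; because both readings share the plate-level
#' transfection-efficiency factor, the ratio cancels it. Wells with
#' `bgal <= 0` are excluded (dropped) with a message.
#'
#' @param wells Reporter-well data.frame with columns `firefly`, `bgal`.
#' @return The included wells with an added `norm` column.
#' @examples
#' normalize_reporter(data.frame(plate_id = "P1", well = "A01",
#'                               content = "G1", firefly = 1000, bgal = 2))
#' @export
normalize_reporter <- function(wells) {
  stopifnot(all(c("firefly", "bgal") %in% names(wells)))
  bad <- !is.finite(wells$bgal) | wells$bgal <= 0
  if (any(bad))
    message("normalize_reporter: excluding ", sum(bad),
            " well(s) with non-positive beta-gal reading")
  out <- wells[!bad, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("normalize_reporter: all wells excluded", call. = FALSE)
  out$norm <- out$firefly / out$bgal
  rownames(out) <- NULL
  out
}

#' Fold change over the plate median
#'
#' Divides each well's normalized reporter signal by the median normalized
#' signal of the library wells on the same plate (controls excluded from
#' the median so control-heavy plates are not biased). The median of an
#' even count is the midpoint of the central pair; by construction the
#' median library-well fold is 1 on every plate.
#'
#' @param wells Data.frame with `plate_id`, `content`, `norm` (from
#'   [normalize_reporter()]).
#' @return The input with an added `fold` column.
#' @examples
#' w <- data.frame(plate_id = "P1", content = sprintf("G%d", 1:4),
#'                 norm = c(2, 4, 6, 8))
#' fold_over_plate_median(w)$fold  # 0.4 0.8 1.2 1.6
#' @export
fold_over_plate_median <- function(wells) {
  stopifnot(all(c("plate_id", "content", "norm") %in% names(wells)))
  is_lib <- !(wells$content %in% .non_library_labels)
  out <- wells
  out$fold <- NA_real_
  for (p in unique(wells$plate_id)) {
    sel <- wells$plate_id == p
    lib_vals <- wells$norm[sel & is_lib]
    if (length(lib_vals) < 1L)
      stop("fold_over_plate_median: no library wells on plate ", p,
           call. = FALSE)
    med <- stats::median(lib_vals)
    if (med == 0)
      stop("fold_over_plate_median: zero median on plate ", p, call. = FALSE)
    out$fold[sel] <- wells$norm[sel] / med
  }
  out
}

#' Call reporter-screen hits by fold-change cutoffs
#'
#' A library gene is an inhibitor hit when its fold over plate median is
#' strictly below `low` (its knockdown decreases TEAD-reporter activity,
#' i.e. the gene promotes YAP/TAZ activity) and an activator hit when
#' strictly above `high`. Boundary folds are non-hits.
#'
#' @param folds Data.frame with `content` and `fold` (from
#'   [fold_over_plate_median()]); control wells are ignored.
#' @param low,high Fold cutoffs, `0 < low < high`.
#' @return Data.frame: `gene_id`, `fold`, `inhibitor`, `activator`.
#' @examples
#' f <- data.frame(content = c("G1", "G2", "G3"), fold = c(0.49, 0.5, 2.01))
#' call_reporter_hits(f)
#' @export
call_reporter_hits <- function(folds, low = 0.5, high = 2.0) {
  if (!(low > 0 && low < high))
    stop("call_reporter_hits: need 0 < low < high", call. = FALSE)
  lib <- folds[!(folds$content %in% .non_library_labels), , drop = FALSE]
  res <- data.frame(gene_id = lib$content, fold = lib$fold,
                    inhibitor = lib$fold < low,
                    activator = lib$fold > high,
                    stringsAsFactors = FALSE)
  res <- res[order(res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
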