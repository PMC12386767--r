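#' Segment nuclei in a DAPI image
#'
#' Global Otsu thresholding of the DAPI channel followed by
#' distance-transform watershed to split touching nuclei; objects smaller
#' than `min_area` pixels are discarded and remaining labels renumbered
#' 1..K. An all-zero (or constant) image yields zero labels.
#'
#' @param dapi Integer/numeric matrix of DAPI intensities (counts).
#' @param min_area Minimum object area in pixels.
#' @param tolerance Watershed tolerance (intensity units of the distance
#'   map); larger values merge shallow splits.
#' @return Integer label matrix (0 = background, labels 1..K).
#' @examples
#' img <- render_well_image(random_cell_field(5, seed = 1))
#' max(segment_nuclei(img$dapi))  # 5
#' @export
segment_nuclei <- function(dapi, min_area = 20L, tolerance = 1) {
  stopifnot(is.matrix(dapi), nrow(dapi) > 0, ncol(dapi) > 0)
  img <- dapi / 65535
  if (diff(range(img)) == 0)
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  th <- EBImage::otsu(EBImage::Image(img))
  mask <- img > th
  if (!any(mask))
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  lab <- EBImage::watershed(EBImage::distmap(EBImage::Image(mask)),
                            tolerance = tolerance)
  lab <- EBImage::imageData(lab)
  keep <- as.integer(names(which(table(lab[lab > 0]) >= min_area)))
  relab <- integer(max(lab) + 1L)
  relab[keep + 1L] <- seq_along(keep)
  matrix(relab[lab + 1L], nrow(dapi), ncol(dapi))
}

#' Segment cytoplasm around labeled nuclei in the FITC channel
#'
#' For each nucleus, the cytoplasmic region is the FITC-foreground (global
#' Otsu) within a maximal ring of `ring_width` pixels around the nucleus,
#' excluding all nuclear pixels. Pixels reachable from several nuclei are
#' assigned to the nearest one (Voronoi-style propagation), so regions of
#' different cells are disjoint. Regions clipped by the image border are
#' retained.
#'
#' @param fitc Integer/numeric matrix of FITC intensities (counts).
#' @param nuclei Label matrix from [segment_nuclei()].
#' @param ring_width Maximal ring width around each nucleus, pixels.
#' @param fg_method FITC foreground rule: `"background"` (default; pixels
#'   brighter than the background estimate, median + 3 MAD of non-nuclear
#'   pixels — robust when cytoplasm intensities vary cell to cell) or
#'   `"otsu"` (global bimodal threshold of non-nuclear pixels).
#' @return Integer label matrix of cytoplasm regions, sharing labels with
#'   `nuclei`. Nuclei whose cytoplasm region is empty are listed in
#'   `attr(, "empty_cytoplasm")`.
#' @export
segment_cytoplasm <- function(fitc, nuclei, ring_width = 10L,
                              fg_method = c("background", "otsu")) {
  fg_method <- match.arg(fg_method)
  stopifnot(is.matrix(fitc), all(dim(fitc) == dim(nuclei)))
  labels <- sort(unique(nuclei[nuclei > 0]))
  if (length(labels) == 0L)
    stop("segment_cytoplasm: no nuclei labels", call. = FALSE)
  img <- fitc / 65535
  nucmask <- nuclei > 0
  # threshold from non-nuclear pixels only; nuclei would pull it too high
  outside <- img[!nucmask]
  th <- if (length(outside) == 0L || diff(range(outside)) == 0) {
    Inf
  } else if (fg_method == "otsu") {
    EBImage::otsu(EBImage::Image(matrix(outside, ncol = 1L)))
  } else {
    stats::median(outside) + 3 * stats::mad(outside)
  }
  fg <- img > th
  # distance of every non-nucleus pixel to the nearest nucleus pixel
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(!nucmask)))
  ring <- !nucmask & d <= ring_width & fg
  terr <- EBImage::propagate(EBImage::Image(img), EBImage::Image(nuclei),
                             mask = nucmask | ring, lambda = 1e10)
  cyto <- EBImage::imageData(terr)
  cyto[nucmask] <- 0L
  cyto <- matrix(as.integer(cyto), nrow(fitc), ncol(fitc))
  present <- unique(cyto[cyto > 0])
  attr(cyto, "empty_cytoplasm") <- setdiff(labels, present)
  cyto
}

#' Measure per-cell FITC distribution
#'
#' Computes, for each segmented cell, the arithmetic mean FITC intensity
#' over its nuclear and cytoplasmic masks, the cytoplasm/nucleus ratio (the
#' "FITC ratio"; low = nuclear-enriched YAP/TAZ), and the translocation
#' class. Cells with an empty cytoplasm region or zero nuclear mean are kept
#' in the table but flagged `included = FALSE` with the reason logged.
#'
#' @param pair List with matrices `dapi` and `fitc` (e.g. from
#'   [render_well_image()] or [read_image_pair()]).
#' @param nuclei,cytoplasm Label matrices from the segmentation steps.
#' @param t_nuclear,t_cytoplasmic Classification thresholds, see
#'   [classify_cells()].
#' @return Data.frame: `cell_id`, `nucleus_area`, `cytoplasm_area`,
#'   `fitc_nuc_mean`, `fitc_cyt_mean`, `ratio`, `cls`, `included`,
#'   `exclude_reason`.
#' @export
measure_cells <- function(pair, nuclei, cytoplasm,
                          t_nuclear = 0.4, t_cytoplasmic = 0.65) {
  fitc <- pair$fitc
  stopifnot(all(dim(fitc) == dim(nuclei)), all(dim(fitc) == dim(cytoplasm)))
  labels <- sort(unique(nuclei[nuclei > 0]))
  if (length(labels) == 0L)
    return(data.frame(cell_id = integer(0), nucleus_area = integer(0),
                      cytoplasm_area = integer(0), fitc_nuc_mean = numeric(0),
                      fitc_cyt_mean = numeric(0), ratio = numeric(0),
                      cls = character(0), included = logical(0),
                      exclude_reason = character(0),
                      stringsAsFactors = FALSE))
  nuc_sel <- nuclei > 0
  cyt_sel <- cytoplasm > 0
  nuc_area <- table(factor(nuclei[nuc_sel], levels = labels))
  cyt_area <- table(factor(cytoplasm[cyt_sel], levels = labels))
  nuc_mean <- tapply(fitc[nuc_sel], factor(nuclei[nuc_sel], levels = labels),
                     mean)
  cyt_mean <- tapply(fitc[cyt_sel],
                     factor(cytoplasm[cyt_sel], levels = labels), mean)
  res <- data.frame(cell_id = labels,
                    nucleus_area = as.integer(nuc_area),
                    cytoplasm_area = as.integer(cyt_area),
                    fitc_nuc_mean = as.numeric(nuc_mean),
                    fitc_cyt_mean = as.numeric(cyt_mean),
                    stringsAsFactors = FALSE)
  res$exclude_reason <- ""
  res$exclude_reason[res$cytoplasm_area == 0] <- "empty cytoplasm region"
  res$exclude_reason[!is.na(res$fitc_nuc_mean) & res$fitc_nuc_mean == 0] <-
    "zero nuclear FITC mean"
  res$included <- res$exclude_reason == ""
  res$ratio <- ifelse(res$included, res$fitc_cyt_mean / res$fitc_nuc_mean,
                      NA_real_)
  res$cls <- NA_character_
  res$cls[res$included] <- as.character(
    classify_cells(res$ratio[res$included], t_nuclear, t_cytoplasmic))
  res[, c("cell_id", "nucleus_area", "cytoplasm_area", "fitc_nuc_mean",
          "fitc_cyt_mean", "ratio", "cls", "included", "exclude_reason")]
}

#' Classify cells by FITC cytoplasm/nucleus ratio
#'
#' A cell is `nuclear` when `ratio <= t_nuclear`, `cytoplasmic` when
#' `ratio >= t_cytoplasmic`, otherwise `intermediate`; both boundaries are
#' inclusive toward their class. A low cytoplasm/nucleus ratio indicates
#' nuclear-enriched YAP/TAZ.
#'
#' @param ratio Numeric vector of non-negative ratios.
#' @param t_nuclear,t_cytoplasmic Thresholds, `t_nuclear < t_cytoplasmic`.
#' @return Factor with levels `nuclear`, `intermediate`, `cytoplasmic`.
#' @examples
#' classify_cells(c(0.4, 0.5, 0.65))
#' @export
classify_cells <- function(ratio, t_nuclear = 0.4, t_cytoplasmic = 0.65) {
  if (t_nuclear >= t_cytoplasmic)
    stop("classify_cells: need t_nuclear < t_cytoplasmic", call. = FALSE)
  if (any(!is.na(ratio) & ratio < 0))
    stop("classify_cells: negative ratio", call. = FALSE)
  cls <- ifelse(ratio <= t_nuclear, "nuclear",
                ifelse(ratio >= t_cytoplasmic, "cytoplasmic", "intermediate"))
  factor(cls, levels = c("nuclear", "intermediate", "cytoplasmic"))
}

#' Summarize a well's cell classes as percentages
#'
#' @param cells Measurement data.frame from [measure_cells()]; only rows
#'   with `included = TRUE` contribute.
#' @return One-row data.frame: `n_cells`, `pct_nuclear`, `pct_intermediate`,
#'   `pct_cytoplasmic` (percentages sum to 100; `NA` when `n_cells` is 0).
#' @examples
#' cells <- data.frame(ratio = c(0.3, 0.5, 0.7, 0.9), included = TRUE,
#'                     cls = as.character(classify_cells(c(0.3, 0.5, 0.7, 0.9))))
#' summarize_well(cells)
#' @export
summarize_well <- function(cells) {
  ok <- cells[cells$included %in% TRUE, , drop = FALSE]
  n <- nrow(ok)
  if (n == 0L)
    return(data.frame(n_cells = 0L, pct_nuclear = NA_real_,
                      pct_intermediate = NA_real_,
                      pct_cytoplasmic = NA_real_))
  counts <- table(factor(ok$cls,
                         levels = c("nuclear", "intermediate", "cytoplasmic")))
  data.frame(n_cells = n,
             pct_nuclear = 100 * counts[["nuclear"]] / n,
             pct_intermediate = 100 * counts[["intermediate"]] / n,
             pct_cytoplasmic = 100 * counts[["cytoplasmic"]] / n)
}

#' Manual-count style N>C / N=C / C>N categorization
#'
#' Mirrors manual scoring of YAP/TAZ localization: a cell is predominantly
#' nuclear (`N>C`) when its FITC ratio is below `1 - equal_band`,
#' predominantly cytoplasmic (`C>N`) above `1 + equal_band`, and balanced
#' (`N=C`) within the band. Fewer than 30 cells triggers a low-count
#' warning, the conventional minimum for this kind of manual quantification.
#'
#' @param cells Measurement data.frame (uses the `ratio` column) or a
#'   numeric vector of ratios.
#' @param equal_band Half-width of the `N=C` band around ratio 1.
#' @return One-row data.frame: `n_cells`, `pct_n_gt_c`, `pct_n_eq_c`,
#'   `pct_c_gt_n`.
#' @examples
#' categorize_manual(c(rep(0.5, 15), rep(1, 10), rep(2, 10)))
#' @export
categorize_manual <- function(cells, equal_band = 0.1) {
  ratio <- if (is.data.frame(cells)) cells$ratio else as.numeric(cells)
  ratio <- ratio[!is.na(ratio)]
  n <- length(ratio)
  if (n == 0L)
    stop("categorize_manual: no cells with a measured ratio", call. = FALSE)
  if (n < 30L)
    warning("categorize_manual: only ", n,
            " cells; a minimum of 30 cells per condition is recommended",
            call. = FALSE)
  cat3 <- ifelse(ratio < 1 - equal_band, "N>C",
                 ifelse(ratio > 1 + equal_band, "C>N", "N=C"))
  counts <- table(factor(cat3, levels = c("N>C", "N=C", "C>N")))
  data.frame(n_cells = n,
             pct_n_gt_c = 100 * counts[["N>C"]] / n,
             pct_n_eq_c = 100 * counts[["N=C"]] / n,
             pct_c_gt_n = 100 * counts[["C>N"]] / n)
}

#' Quantify one well image pair end to end
#'
#' Convenience wrapper: segment nuclei, segment cytoplasm, measure cells,
#' summarize the well.
#'
#' @inheritParams segment_nuclei
#' @inheritParams segment_cytoplasm
#' @inheritParams measure_cells
#' @param pair List with matrices `dapi` and `fitc`.
#' @return List with `cells` (per-cell table) and `summary` (one-row well
#'   summary).
#' @export
quantify_well_image <- function(pair, min_area = 20L, tolerance = 1,
                                ring_width = 10L,
                                t_nuclear = 0.4, t_cytoplasmic = 0.65) {
  nuclei <- segment_nuclei(pair$dapi, min_area = min_area,
                           tolerance = tolerance)
  if (max(nuclei) == 0L) {
    cells <- measure_cells(pair, nuclei, nuclei,
                           t_nuclear = t_nuclear,
                           t_cytoplasmic = t_cytoplasmic)
    return(list(cells = cells, summary = summarize_well(cells)))
  }
  cyto <- segment_cytoplasm(pair$fitc, nuclei, ring_width = ring_width)
  cells <- measure_cells(pair, nuclei, cyto, t_nuclear = t_nuclear,
                         t_cytoplasmic = t_cytoplasmic)
  list(cells = cells, summary = summarize_well(cells))
}
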