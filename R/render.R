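#' Render a synthetic two-channel well image
#'
#' Draws each cell as two concentric disks on a flat background: the DAPI
#' channel shows the nucleus (radius `nucleus_radius`, mean `dapi_nuc`), the
#' FITC channel shows the nucleus at `fitc_nuc` surrounded by a cytoplasmic
#' annulus (out to `cytoplasm_radius`) at `fitc_cyt`. Per-pixel Gaussian
#' noise of SD `noise$image_noise_sd` is added, intensities are clipped to
#' the 16-bit range and rounded to integer counts. The ground truth records
#' every cell's constructed cytoplasm/nucleus FITC ratio.
#'
#' @param cells Data.frame with columns `row`, `col` (center, pixels),
#'   `nucleus_radius`, `cytoplasm_radius` (`cytoplasm > nucleus > 0`),
#'   `fitc_nuc`, `fitc_cyt`, `dapi_nuc` (mean counts above background).
#'   May have zero rows.
#' @param shape Image size, `c(rows, cols)`.
#' @param noise A [noise_model()]; uses `image_background`,
#'   `image_noise_sd` and `seed`.
#' @param overlap_tolerance Pixels of nucleus-disk overlap tolerated before
#'   a warning is recorded (in the result, not raised as an error).
#' @return List with integer matrices `dapi` and `fitc` (counts, (row, col)
#'   convention, origin top-left), `ground_truth` (cell table plus
#'   `true_ratio`), and `warnings` (character vector).
#' @examples
#' cells <- data.frame(row = 32, col = 32, nucleus_radius = 8,
#'                     cytoplasm_radius = 14, fitc_nuc = 1000,
#'                     fitc_cyt = 400, dapi_nuc = 3000)
#' img <- render_well_image(cells, shape = c(64, 64))
#' img$ground_truth$true_ratio  # 0.4
#' @export
render_well_image <- function(cells, shape = c(256L, 256L),
                              noise = noise_model(),
                              overlap_tolerance = 0) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape > 0))
  n <- if (is.null(cells)) 0L else nrow(cells)
  warnings <- character(0)
  if (n > 0) {
    need <- c("row", "col", "nucleus_radius", "cytoplasm_radius",
              "fitc_nuc", "fitc_cyt", "dapi_nuc")
    missing <- setdiff(need, names(cells))
    if (length(missing))
      stop("render_well_image: cells lack column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (any(cells$nucleus_radius <= 0) ||
        any(cells$cytoplasm_radius <= cells$nucleus_radius))
      stop("render_well_image: need cytoplasm_radius > nucleus_radius > 0",
           call. = FALSE)
    if (any(cells$row - cells$cytoplasm_radius < 1) ||
        any(cells$row + cells$cytoplasm_radius > shape[1]) ||
        any(cells$col - cells$cytoplasm_radius < 1) ||
        any(cells$col + cells$cytoplasm_radius > shape[2]))
      stop("render_well_image: cells do not fit inside the image", call. = FALSE)
    if (n > 1) {
      d <- as.matrix(stats::dist(cells[, c("row", "col")]))
      rr <- outer(cells$nucleus_radius, cells$nucleus_radius, `+`)
      bad <- which(d < rr - overlap_tolerance & upper.tri(d), arr.ind = TRUE)
      if (nrow(bad))
        warnings <- sprintf("nuclei of cells %d and %d overlap",
                            bad[, 1], bad[, 2])
    }
  }

  bg <- noise$image_background
  dapi <- matrix(bg, shape[1], shape[2])
  fitc <- matrix(bg, shape[1], shape[2])
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  for (i in seq_len(n)) {
    d2 <- (rows - cells$row[i])^2 + (cols - cells$col[i])^2
    cyt <- d2 <= cells$cytoplasm_radius[i]^2
    nuc <- d2 <= cells$nucleus_radius[i]^2
    fitc[cyt & !nuc] <- bg + cells$fitc_cyt[i]
    fitc[nuc] <- bg + cells$fitc_nuc[i]
    dapi[nuc] <- bg + cells$dapi_nuc[i]
  }
  if (noise$image_noise_sd > 0) {
    set.seed(noise$seed)
    dapi <- dapi + stats::rnorm(length(dapi), 0, noise$image_noise_sd)
    fitc <- fitc + stats::rnorm(length(fitc), 0, noise$image_noise_sd)
  }
  clip16 <- function(m) matrix(as.integer(round(pmin(pmax(m, 0), 65535))),
                               nrow(m), ncol(m))
  gt <- if (n > 0) {
    cbind(data.frame(cell_id = seq_len(n)), cells,
          data.frame(true_ratio = cells$fitc_cyt / cells$fitc_nuc))
  } else {
    data.frame(cell_id = integer(0), row = numeric(0), col = numeric(0),
               nucleus_radius = numeric(0), cytoplasm_radius = numeric(0),
               fitc_nuc = numeric(0), fitc_cyt = numeric(0),
               dapi_nuc = numeric(0), true_ratio = numeric(0))
  }
  list(dapi = clip16(dapi), fitc = clip16(fitc),
       ground_truth = gt, warnings = warnings)
}

#' Place a field of non-overlapping synthetic cells
#'
#' Rejection-samples `n` cell positions whose cytoplasm disks do not overlap
#' and assigns each cell a constructed FITC cytoplasm/nucleus ratio.
#'
#' @param n Number of cells.
#' @param shape Image size `c(rows, cols)`.
#' @param ratios Per-cell true FITC ratios (recycled to length `n`).
#' @param nucleus_radius,cytoplasm_radius Disk radii (pixels).
#' @param fitc_nuc Nuclear FITC mean; the cytoplasmic mean is
#'   `ratio * fitc_nuc`.
#' @param dapi_nuc Nuclear DAPI mean.
#' @param seed Integer seed.
#' @return Cell data.frame suitable for [render_well_image()].
#' @examples
#' random_cell_field(10, ratios = c(0.3, 0.8), seed = 1)
#' @export
random_cell_field <- function(n, shape = c(256L, 256L), ratios = 0.5,
                              nucleus_radius = 6, cytoplasm_radius = 11,
                              fitc_nuc = 1000, dapi_nuc = 3000,
                              seed = 1L) {
  set.seed(as.integer(seed))
  ratios <- rep_len(ratios, n)
  margin <- cytoplasm_radius + 1
  pos <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(pos) < n) {
    cand <- c(stats::runif(1, margin, shape[1] - margin),
              stats::runif(1, margin, shape[2] - margin))
    ok <- nrow(pos) == 0 ||
      all(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2) >
            2 * cytoplasm_radius + 2)
    if (ok) pos <- rbind(pos, cand)
    tries <- tries + 1L
    if (tries > 20000L)
      stop("random_cell_field: could not place ", n,
           " non-overlapping cells in this image", call. = FALSE)
  }
  data.frame(row = round(pos[, 1]), col = round(pos[, 2]),
             nucleus_radius = nucleus_radius,
             cytoplasm_radius = cytoplasm_radius,
             fitc_nuc = fitc_nuc,
             fitc_cyt = round(ratios * fitc_nuc),
             dapi_nuc = dapi_nuc)
}

#' Write / read a DAPI+FITC image pair as 16-bit TIFF files
#'
#' Files are named `<plate>_<well>_dapi.tif` and `<plate>_<well>_fitc.tif`.
#'
#' @param pair List with integer matrices `dapi` and `fitc` (counts).
#' @param dir Output directory (created if needed).
#' @param plate,well Identifiers used in the file names.
#' @return `write_image_pair`: the two file paths, invisibly.
#' @export
write_image_pair <- function(pair, dir, plate, well) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%s_%s.tif", plate, well,
                                  c("dapi", "fitc")))
  tiff::writeTIFF(pair$dapi / 65535, paths[1], bits.per.sample = 16L)
  tiff::writeTIFF(pair$fitc / 65535, paths[2], bits.per.sample = 16L)
  invisible(paths)
}

#' @rdname write_image_pair
#' @param dapi_path,fitc_path Paths of the two channel TIFFs.
#' @return `read_image_pair`: list of integer matrices `dapi`, `fitc`.
#' @export
read_image_pair <- function(dapi_path, fitc_path) {
  rd <- function(p) {
    m <- tiff::readTIFF(p)
    matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  }
  list(dapi = rd(dapi_path), fitc = rd(fitc_path))
}
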