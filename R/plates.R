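#' Well addresses of a plate format
#'
#' @param format Plate format, 384 (16 x 24) or 96 (8 x 12).
#' @return Character vector of addresses (`"A01"` ... ), row-major.
#' @examples
#' head(well_addresses(96))
#' @export
well_addresses <- function(format) {
  format <- as.integer(format)
  dims <- switch(as.character(format),
                 "384" = c(16L, 24L),
                 "96"  = c(8L, 12L),
                 stop("well_addresses: unsupported plate format ", format,
                      call. = FALSE))
  as.vector(t(outer(LETTERS[seq_len(dims[1])], seq_len(dims[2]),
                    function(r, c) sprintf("%s%02d", r, c))))
}

#' Lay out a screening library and controls on plates
#'
#' Assigns every library gene to exactly one well and places control wells
#' either as totals spread evenly across plates (`per_plate = FALSE`, the
#' 384-well localization screen scheme) or as a fixed count on every plate
#' (`per_plate = TRUE`, the 96-well reporter screen scheme). Positions within
#' each plate are randomized deterministically from `seed`.
#'
#' @param library Library data.frame (from [build_kinome_library()]) or a
#'   character vector of gene ids; may be empty.
#' @param format Plate format, 384 or 96.
#' @param control_scheme Named integer vector, control label -> well count
#'   (e.g. `c(siCTL = 72, siMARK4 = 16)`). Counts are totals for the screen,
#'   or per plate when `per_plate = TRUE`.
#' @param per_plate Logical; interpret `control_scheme` counts as per plate.
#' @param plate_prefix Prefix for generated plate ids.
#' @param seed Integer seed for the within-plate position shuffle.
#' @return A data.frame with columns `plate_id`, `well`, `content`, with the
#'   plate format in `attr(, "format")`. Unoccupied wells are omitted.
#' @examples
#' lib <- build_kinome_library(720)
#' lay <- layout_plates(lib, 384, c(siCTL = 72, siMARK4 = 16), seed = 1)
#' table(lay$plate_id)
#' @export
layout_plates <- function(library, format = 384,
                          control_scheme = c(siCTL = 72, siMARK4 = 16),
                          per_plate = FALSE, plate_prefix = "P",
                          seed = 1L) {
  gene_ids <- if (is.data.frame(library)) library$gene_id else
    as.character(library)
  if (anyDuplicated(gene_ids))
    stop("layout_plates: duplicated gene_id in library", call. = FALSE)
  addresses <- well_addresses(format)
  format <- length(addresses)
  if (length(control_scheme) &&
      (is.null(names(control_scheme)) || any(!nzchar(names(control_scheme)))))
    stop("layout_plates: 'control_scheme' must be a named vector", call. = FALSE)
  control_scheme <- control_scheme[control_scheme > 0]
  storage.mode(control_scheme) <- "integer"
  n_genes <- length(gene_ids)
  n_ctrl <- sum(control_scheme)

  if (per_plate) {
    if (n_ctrl >= format && n_genes > 0)
      stop("layout_plates: control_scheme exceeds plate capacity", call. = FALSE)
    if (n_ctrl > format)
      stop("layout_plates: control_scheme exceeds plate capacity", call. = FALSE)
    lib_per_plate <- format - n_ctrl
    n_plates <- max(1L, as.integer(ceiling(n_genes / max(lib_per_plate, 1L))))
    ctrl_counts <- matrix(rep(control_scheme, n_plates),
                          nrow = n_plates, byrow = TRUE,
                          dimnames = list(NULL, names(control_scheme)))
  } else {
    n_plates <- max(1L, as.integer(ceiling((n_genes + n_ctrl) / format)))
    # spread each control label as evenly as possible across plates
    ctrl_counts <- vapply(control_scheme, function(k) {
      base <- k %/% n_plates
      extra <- k %% n_plates
      base + as.integer(seq_len(n_plates) <= extra)
    }, integer(n_plates))
    ctrl_counts <- matrix(ctrl_counts, nrow = n_plates,
                          dimnames = list(NULL, names(control_scheme)))
  }
  capacity <- format - rowSums(ctrl_counts)
  if (any(capacity < 0) || sum(capacity) < n_genes)
    stop("layout_plates: control_scheme exceeds plate capacity", call. = FALSE)

  set.seed(as.integer(seed))
  out <- vector("list", n_plates)
  gene_cursor <- 0L
  for (p in seq_len(n_plates)) {
    n_here <- min(capacity[p], n_genes - gene_cursor)
    contents <- c(if (n_here > 0) gene_ids[gene_cursor + seq_len(n_here)],
                  rep(colnames(ctrl_counts), ctrl_counts[p, ]))
    gene_cursor <- gene_cursor + n_here
    wells <- sample(addresses, length(contents))
    out[[p]] <- data.frame(plate_id = sprintf("%s%02d", plate_prefix, p),
                           well = wells, content = contents,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$plate_id, res$well), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "format") <- format
  res
}
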