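#' Intersect hit sets from the two screening modalities
#'
#' Genes called in both the localization screen (e.g. cytoplasmic-direction
#' hits) and the reporter screen (e.g. fold-change inhibitors) — the
#' higher-confidence Hippo pathway regulator class.
#'
#' @param loc_hits,rep_hits Character vectors of gene ids.
#' @return Sorted character vector.
#' @export
intersect_modalities <- function(loc_hits, rep_hits) {
  sort(intersect(as.character(loc_hits), as.character(rep_hits)))
}

#' Intersect hit sets across cell lines
#'
#' @param sets Named list (one gene set per cell line), length >= 2.
#' @return Sorted character vector of genes common to all lines.
#' @export
intersect_cell_lines <- function(sets) {
  if (length(sets) < 2L)
    stop("intersect_cell_lines: need at least 2 cell lines", call. = FALSE)
  sort(Reduce(intersect, lapply(sets, as.character)))
}

#' Venn region counts for 2 or 3 gene sets
#'
#' Computes the size of every exclusive region and every intersection;
#' exclusive regions partition the union.
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return List with `regions` (named integer vector of exclusive-region
#'   sizes, names like `"A"`, `"A&B"`), `intersections` (plain pairwise /
#'   triple intersection sizes), and `union_size`.
#' @examples
#' venn_counts(list(A = c("1", "2"), B = c("2", "3")))$regions
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 3L)
    stop("venn_counts: only 2 or 3 sets are supported", call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- LETTERS[seq_len(k)]
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  if (length(universe) == 0L) member <- matrix(logical(0), 0L, k,
                                               dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(patterns) <- names(sets)
  regions <- apply(patterns, 1L, function(p) {
    sum(apply(member, 1L, function(m) all(m == p)))
  })
  names(regions) <- apply(patterns, 1L, function(p)
    paste(names(sets)[as.logical(p)], collapse = "&"))
  inter <- c()
  combs <- utils::combn(names(sets), 2L, simplify = FALSE)
  if (k == 3L) combs <- c(combs, list(names(sets)))
  for (cb in combs) {
    inter[paste(cb, collapse = "&")] <-
      length(Reduce(intersect, sets[cb]))
  }
  list(regions = regions, intersections = inter,
       union_size = length(universe))
}

#' Build an integrated, ranked hit report
#'
#' One row per library gene with its per-replicate localization Z-scores,
#' reporter fold, every hit flag, and an evidence path describing which
#' screens support it. Rows are ordered by evidence tier (cross-line
#' dual-modality first), then mean Z descending, then `gene_id` — a total,
#' deterministic ordering.
#'
#' @param zs Z-score table from [compute_zscores()] (library rows used).
#' @param folds Reporter hit table from [call_reporter_hits()], or any
#'   data.frame with `gene_id` and `fold`.
#' @param loc_hits,nuc_hits,rep_inhibitors,rep_activators Character vectors
#'   of called genes (defaults: empty).
#' @param cross_line_hits Genes supported in every cell line (optional).
#' @return Data.frame with columns `gene_id`, `z_rep*`, `mean_z`, `fold`,
#'   the six flag columns, `evidence` and `tier` (3 = dual modality + cross
#'   line, 2 = dual modality, 1 = single modality, 0 = none).
#' @export
build_hit_report <- function(zs, folds,
                             loc_hits = character(0),
                             nuc_hits = character(0),
                             rep_inhibitors = character(0),
                             rep_activators = character(0),
                             cross_line_hits = character(0)) {
  lib <- if ("is_library" %in% names(zs)) zs[zs$is_library, , drop = FALSE]
         else zs
  z_wide <- stats::reshape(lib[, c("gene_id", "replicate", "z")],
                           idvar = "gene_id", timevar = "replicate",
                           direction = "wide")
  names(z_wide) <- sub("^z\\.", "z_rep", names(z_wide))
  zcols <- grep("^z_rep", names(z_wide), value = TRUE)
  z_wide$mean_z <- rowMeans(z_wide[, zcols, drop = FALSE])
  orphans_z <- setdiff(z_wide$gene_id, folds$gene_id)
  orphans_f <- setdiff(folds$gene_id, z_wide$gene_id)
  if (length(orphans_z) || length(orphans_f))
    stop("build_hit_report: gene ids present in only one modality: ",
         paste(utils::head(c(orphans_z, orphans_f), 10L), collapse = ", "),
         call. = FALSE)
  tbl <- merge(z_wide, folds[, c("gene_id", "fold")], by = "gene_id")
  tbl$loc_cyt_hit <- tbl$gene_id %in% loc_hits
  tbl$loc_nuc_hit <- tbl$gene_id %in% nuc_hits
  tbl$rep_inhibitor <- tbl$gene_id %in% rep_inhibitors
  tbl$rep_activator <- tbl$gene_id %in% rep_activators
  tbl$dual_inhibitor <- tbl$loc_cyt_hit & tbl$rep_inhibitor
  tbl$dual_activator <- tbl$loc_nuc_hit & tbl$rep_activator
  tbl$cross_line <- tbl$gene_id %in% cross_line_hits
  dual <- tbl$dual_inhibitor | tbl$dual_activator
  single <- tbl$loc_cyt_hit | tbl$loc_nuc_hit | tbl$rep_inhibitor |
    tbl$rep_activator
  tbl$tier <- ifelse(dual & tbl$cross_line, 3L,
                     ifelse(dual, 2L, ifelse(single, 1L, 0L)))
  ev <- function(i) {
    parts <- c(if (tbl$loc_cyt_hit[i]) "loc.cyt",
               if (tbl$loc_nuc_hit[i]) "loc.nuc",
               if (tbl$rep_inhibitor[i]) "rep.inh",
               if (tbl$rep_activator[i]) "rep.act",
               if (tbl$cross_line[i]) "lines")
    if (length(parts)) paste(parts, collapse = "+") else "none"
  }
  tbl$evidence <- vapply(seq_len(nrow(tbl)), ev, character(1))
  tbl <- tbl[order(-tbl$tier, -tbl$mean_z, tbl$gene_id), , drop = FALSE]
  rownames(tbl) <- NULL
  tbl
}
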