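#' Cell-line panel
#'
#' A panel fixes the set and order of cell lines shared by every profile
#' vector in a study. All methylation and expression profiles downstream are
#' aligned to a single harmonized panel.
#'
#' @param cell_lines character vector of unique cell-line names; the order
#'   is the canonical column order for all profile matrices.
#' @param subtype optional character vector of molecular-subtype labels
#'   (e.g. \code{"basal A"}, \code{"basal B"}, \code{"luminal"}), one per
#'   cell line; used only for stratified reporting.
#' @return An object of class \code{cell_panel}.
#' @export
cell_panel <- function(cell_lines, subtype = NULL) {
  cell_lines <- as.character(cell_lines)
  if (length(cell_lines) == 0L) stop("panel must contain at least one cell line")
  if (anyDuplicated(cell_lines))
    stop("duplicated cell-line names: ",
         paste(unique(cell_lines[duplicated(cell_lines)]), collapse = ", "))
  if (!is.null(subtype)) {
    if (length(subtype) != length(cell_lines))
      stop("subtype must have one label per cell line")
    subtype <- as.character(subtype)
    names(subtype) <- cell_lines
  }
  structure(list(cell_lines = cell_lines, subtype = subtype),
            class = "cell_panel")
}

#' @export
print.cell_panel <- function(x, ...) {
  cat("cell_panel with", length(x$cell_lines), "cell lines\n")
  cat(" ", paste(utils::head(x$cell_lines, 8), collapse = ", "),
      if (length(x$cell_lines) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
length.cell_panel <- function(x) length(x$cell_lines)

#' Harmonize two cell-line panels
#'
#' Methylation and expression assays are typically run on overlapping but
#' non-identical panels; only lines present in both can be analysed jointly.
#' The intersection is returned in deterministic (lexicographically sorted)
#' order, and all downstream profile matrices are subset and reordered to it.
#'
#' @param x,y \code{cell_panel} objects.
#' @return A \code{cell_panel} containing the sorted intersection. Subtype
#'   labels are carried over from \code{x} where available, else from
#'   \code{y}.
#' @export
harmonize_panels <- function(x, y) {
  stopifnot(inherits(x, "cell_panel"), inherits(y, "cell_panel"))
  common <- sort(intersect(x$cell_lines, y$cell_lines))
  if (length(common) == 0L)
    stop("panels share no cell lines; nothing to analyse")
  subtype <- NULL
  src <- c(x$subtype, y$subtype[setdiff(names(y$subtype), names(x$subtype))])
  if (!is.null(src) && any(common %in% names(src))) {
    subtype <- unname(src[common])
    subtype[is.na(subtype)] <- "unknown"
  }
  cell_panel(common, subtype)
}
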