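#' @name methrank-io
#' @title Tabular input and output
#'
#' @description
#' Methylation sites arrive as a tab-separated table with columns
#' \code{site_id}, \code{chromosome}, \code{position} followed by one column
#' of percent methylation (0--100) per cell line. Expression probe sets
#' arrive as a tab-separated table with columns \code{probeset_id},
#' \code{gene}, \code{chromosome}, \code{start}, \code{end} followed by one
#' log-scale expression column per cell line. All genomic coordinates are
#' 1-based and ranges are inclusive at both ends.
NULL

new_methylation_set <- function(sites, profiles, panel, dropped = 0L) {
  rownames(profiles) <- sites$site_id
  structure(list(sites = sites, profiles = profiles, panel = panel,
                 dropped = dropped),
            class = "methylation_set")
}

new_expression_set <- function(probesets, profiles, panel,
                               normalized = FALSE) {
  rownames(profiles) <- probesets$probeset_id
  structure(list(probesets = probesets, profiles = profiles, panel = panel,
                 normalized = normalized),
            class = "expression_set")
}

#' @export
print.methylation_set <- function(x, ...) {
  cat("methylation_set:", nrow(x$sites), "CpG sites x",
      length(x$panel), "cell lines\n")
  cat("  chromosomes:", paste(unique(x$sites$chromosome), collapse = ", "), "\n")
  if (x$dropped > 0) cat("  sites dropped on read:", x$dropped, "\n")
  invisible(x)
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set:", nrow(x$probesets), "probe sets (",
      length(unique(x$probesets$gene)), "genes ) x",
      length(x$panel), "cell lines\n")
  cat("  scale:", if (x$normalized) "normalized 0-100" else "log (as input)", "\n")
  invisible(x)
}

check_profile_columns <- function(cols, panel, path) {
  missing <- setdiff(panel$cell_lines, cols)
  extra <- setdiff(cols, panel$cell_lines)
  if (length(missing) || length(extra))
    stop("cell-line columns of '", path, "' do not match the panel",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")))
}

#' Read a methylation-site table
#'
#' Sites whose chromosome annotation is missing or empty are dropped and
#' counted (the count is kept in the returned object and reported via
#' \code{message}), mirroring the usual filtering of array sites without
#' valid chromosomal annotation. Returned sites are sorted by
#' (chromosome, position) and profile columns are reordered to the panel
#' order.
#'
#' @param path path to a tab-separated file with header
#'   \code{site_id, chromosome, position, <cell line 1>, ...}.
#' @param panel a \code{cell_panel}; \code{NULL} derives the panel from the
#'   file's own columns.
#' @return A \code{methylation_set}: \code{$sites} (data frame of
#'   \code{site_id}, \code{chromosome}, \code{position}), \code{$profiles}
#'   (sites x lines matrix of percentages), \code{$panel}, \code{$dropped}.
#' @export
read_methylation <- function(path, panel = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("site_id", "chromosome", "position")
  if (!identical(names(df)[1:3], need))
    stop("'", path, "' must start with columns ",
         paste(need, collapse = ", "))
  value_cols <- names(df)[-(1:3)]
  if (is.null(panel)) panel <- cell_panel(value_cols)
  check_profile_columns(value_cols, panel, path)

  pos <- suppressWarnings(as.numeric(df$position))
  bad <- which(is.na(pos) | pos < 1)
  if (length(bad))
    stop("malformed position on line ", bad[1] + 1L, " of '", path, "'")
  prof <- matrix(NA_real_, nrow(df), length(panel),
                 dimnames = list(NULL, panel$cell_lines))
  for (cl in panel$cell_lines) {
    v <- df[[cl]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & v != "NA" & is.na(num))
    if (length(bad))
      stop("non-numeric methylation value in column '", cl,
           "', line ", bad[1] + 1L, " of '", path, "'")
    out <- which(!is.na(num) & (num < 0 | num > 100))
    if (length(out))
      stop("methylation value outside [0, 100] in column '", cl,
           "', line ", out[1] + 1L, " of '", path, "'")
    prof[, cl] <- num
  }

  keep <- !is.na(df$chromosome) & df$chromosome != ""
  dropped <- sum(!keep)
  if (dropped > 0)
    message("read_methylation: dropped ", dropped,
            " site(s) without valid chromosome annotation")
  sites <- data.frame(site_id = df$site_id[keep],
                      chromosome = df$chromosome[keep],
                      position = pos[keep],
                      stringsAsFactors = FALSE)
  prof <- prof[keep, , drop = FALSE]
  ord <- order(sites$chromosome, sites$position, sites$site_id)
  new_methylation_set(sites[ord, , drop = FALSE][, need],
                      prof[ord, , drop = FALSE], panel, dropped)
}

#' Write a methylation-site table
#' @param x a \code{methylation_set}.
#' @param path output path (tab-separated, same layout as
#'   \code{\link{read_methylation}} expects).
#' @export
write_methylation <- function(x, path) {
  stopifnot(inherits(x, "methylation_set"))
  out <- cbind(x$sites, as.data.frame(x$profiles, check.names = FALSE))
  write_tsv(out, path)
  invisible(path)
}

#' Read an expression probe-set table
#'
#' Values are left on their input (log) scale; use
#' \code{\link{normalize_expression}} to bring them onto the 0--100
#' methylation scale. A gene may have multiple probe sets; all are retained.
#'
#' @param path path to a tab-separated file with header
#'   \code{probeset_id, gene, chromosome, start, end, <cell line 1>, ...}.
#' @param panel a \code{cell_panel}; \code{NULL} derives it from the file.
#' @return An \code{expression_set} sorted by (chromosome, start).
#' @export
read_expression <- function(path, panel = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("probeset_id", "gene", "chromosome", "start", "end")
  if (!identical(names(df)[1:5], need))
    stop("'", path, "' must start with columns ",
         paste(need, collapse = ", "))
  value_cols <- names(df)[-(1:5)]
  if (is.null(panel)) panel <- cell_panel(value_cols)
  check_profile_columns(value_cols, panel, path)
  if (nrow(df) == 0L) {
    warning("expression table '", path, "' is empty")
    return(new_expression_set(
      data.frame(probeset_id = character(), gene = character(),
                 chromosome = character(), start = numeric(),
                 end = numeric(), stringsAsFactors = FALSE),
      matrix(numeric(), 0, length(panel),
             dimnames = list(NULL, panel$cell_lines)),
      panel))
  }
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  bad <- which(is.na(start) | is.na(end) | start < 1)
  if (length(bad))
    stop("malformed coordinates on line ", bad[1] + 1L, " of '", path, "'")
  rev <- which(start > end)
  if (length(rev))
    stop("start > end on line ", rev[1] + 1L, " of '", path, "'")
  prof <- matrix(NA_real_, nrow(df), length(panel),
                 dimnames = list(NULL, panel$cell_lines))
  for (cl in panel$cell_lines) {
    v <- df[[cl]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & v != "NA" & is.na(num))
    if (length(bad))
      stop("non-numeric expression value in column '", cl,
           "', line ", bad[1] + 1L, " of '", path, "'")
    prof[, cl] <- num
  }
  probesets <- data.frame(probeset_id = df$probeset_id, gene = df$gene,
                          chromosome = df$chromosome,
                          start = start, end = end,
                          stringsAsFactors = FALSE)
  ord <- order(probesets$chromosome, probesets$start, probesets$probeset_id)
  new_expression_set(probesets[ord, , drop = FALSE],
                     prof[ord, , drop = FALSE], panel)
}

#' Write an expression probe-set table
#' @param x an \code{expression_set}.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_set"))
  out <- cbind(x$probesets, as.data.frame(x$profiles, check.names = FALSE))
  write_tsv(out, path)
  invisible(path)
}

#' Restrict a data set to a harmonized panel
#'
#' Subsets and reorders the profile columns of a \code{methylation_set} or
#' \code{expression_set} to the cell lines of \code{panel}.
#'
#' @param x a \code{methylation_set} or \code{expression_set}.
#' @param panel the target \code{cell_panel}; must be a subset of
#'   \code{x}'s panel.
#' @return \code{x} with profiles restricted to \code{panel}.
#' @export
subset_to_panel <- function(x, panel) {
  stopifnot(inherits(panel, "cell_panel"))
  missing <- setdiff(panel$cell_lines, colnames(x$profiles))
  if (length(missing))
    stop("panel lines absent from data: ", paste(missing, collapse = ", "))
  x$profiles <- x$profiles[, panel$cell_lines, drop = FALSE]
  x$panel <- panel
  x
}

#' Normalize expression onto the methylation scale
#'
#' Expression arrays report log-scale intensities while methylation is a
#' percentage, so the two are made commensurable by de-logging
#' (\code{log_base^x}) and min--max scaling to \eqn{[0, 100]} using the
#' global minimum and maximum over \emph{all} probe sets and cell lines
#' jointly: the global minimum maps to 0 and the global maximum to 100.
#'
#' @param x an \code{expression_set} on log scale.
#' @param log_base base of the input logarithm; defaults to 2, the
#'   convention for oligonucleotide expression arrays.
#' @return The \code{expression_set} with \code{$profiles} in
#'   \eqn{[0, 100]} and \code{$normalized = TRUE}.
#' @export
normalize_expression <- function(x, log_base = 2) {
  stopifnot(inherits(x, "expression_set"))
  if (x$normalized) stop("expression set is already normalized")
  vals <- x$profiles
  if (!all(is.finite(vals) | is.na(vals)))
    stop("expression values must be finite")
  dec <- log_base^vals
  rng <- range(dec, na.rm = TRUE)
  if (!is.finite(rng[1]) || !is.finite(rng[2]))
    stop("de-logged expression values overflow; check log_base")
  if (rng[2] == rng[1])
    stop("expression data set is constant; min-max normalization undefined")
  x$profiles <- 100 * (dec - rng[1]) / (rng[2] - rng[1])
  x$normalized <- TRUE
  x
}
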