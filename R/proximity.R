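#' Group CpG sites into regions by genomic proximity
#'
#' Within each chromosome, consecutive sites separated by at most \code{gap}
#' base pairs are aggregated into one region; a gap strictly greater than
#' \code{gap} starts a new region. The distance is measured between
#' successive site positions (not the region span), and a distance exactly
#' equal to \code{gap} merges. Regions partition the input: every site
#' belongs to exactly one region and regions never span chromosomes.
#'
#' @param sites a \code{methylation_set}, or a data frame with columns
#'   \code{site_id}, \code{chromosome}, \code{position}.
#' @param gap maximum merging distance in base pairs (default 2000).
#' @return A data frame with one row per region: \code{region_id},
#'   \code{chromosome}, \code{start}, \code{end}, \code{n_sites}, and a
#'   list column \code{member_sites} of site ids ordered by position.
#' @export
group_by_proximity <- function(sites, gap = 2000) {
  if (inherits(sites, "methylation_set")) sites <- sites$sites
  stopifnot(is.data.frame(sites), gap >= 0)
  empty <- data.frame(region_id = character(), chromosome = character(),
                      start = numeric(), end = numeric(),
                      n_sites = integer(), stringsAsFactors = FALSE)
  empty$member_sites <- list()
  if (nrow(sites) == 0L) return(empty)

  ord <- order(sites$chromosome, sites$position, sites$site_id)
  sites <- sites[ord, , drop = FALSE]
  n <- nrow(sites)
  new_region <- c(TRUE,
                  sites$chromosome[-1] != sites$chromosome[-n] |
                    (sites$position[-1] - sites$position[-n]) > gap)
  rid <- cumsum(new_region)

  idx <- split(seq_len(n), rid)
  per_chrom <- ave(rep(1L, length(idx)),
                   vapply(idx, function(i) sites$chromosome[i[1]],
                          character(1)),
                   FUN = seq_along)
  regions <- data.frame(
    region_id = vapply(seq_along(idx), function(j)
      sprintf("%s_r%04d", sites$chromosome[idx[[j]][1]], per_chrom[j]),
      character(1)),
    chromosome = vapply(idx, function(i) sites$chromosome[i[1]],
                        character(1)),
    start = vapply(idx, function(i) min(sites$position[i]), numeric(1)),
    end = vapply(idx, function(i) max(sites$position[i]), numeric(1)),
    n_sites = lengths(idx),
    stringsAsFactors = FALSE, row.names = NULL)
  regions$member_sites <- lapply(idx, function(i) sites$site_id[i])
  regions
}

#' Per-site region membership
#'
#' @param regions output of \code{\link{group_by_proximity}}.
#' @return Data frame \code{site_id}, \code{region_id}, one row per site.
#' @export
region_membership <- function(regions) {
  data.frame(
    site_id = unlist(regions$member_sites, use.names = FALSE),
    region_id = rep(regions$region_id, regions$n_sites),
    stringsAsFactors = FALSE)
}
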