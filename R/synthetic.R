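#' Generate a synthetic methylation-expression panel with known truth
#'
#' Emulates the structure the pipeline assumes, at a desk scale: CpG sites
#' fall in well-separated promoter clumps along a few chromosomes
#' (intra-clump spacing far below the 2,000 bp proximity rule, inter-clump
#' spacing far above it); each clump holds 2-3 sub-groups of sites sharing
#' a latent methylation profile plus i.i.d. noise, clipped to [0, 100];
#' cell lines are correlated through a shared line effect. Each gene owns
#' one clump, with its probe set placed within the 20,000 bp association
#' window downstream of the clump. A fraction of genes is "regulated":
#' their expression is a decreasing logistic of the promoter sub-group's
#' mean methylation (the sub-group nearest the probe set) plus Gaussian
#' noise; the rest are null genes with expression independent of
#' methylation. Expression is emitted on log2 scale, and one null-gene
#' value is pinned at each extreme of the decimal range so that global
#' min-max normalization is (numerically) the identity -- the zero-noise
#' panel then reaches a perfect sigmoid fit after the full pipeline.
#'
#' @param n_lines number of cell lines (default 45).
#' @param n_genes number of genes, one promoter clump each (default 60).
#' @param frac_regulated fraction of genes with planted epigenetic
#'   regulation (default 0.15).
#' @param sites_per_group CpG sites per latent sub-group (default 9).
#' @param noise_sd standard deviation of the site-level methylation noise
#'   and of the expression noise, both on the 0-100 scale (default 5).
#' @param seed integer seed; fully determines the output.
#' @param dir optional directory; when given, \code{methylation.tsv},
#'   \code{expression.tsv} and \code{truth.json} are written there.
#' @return A list: \code{methylation} (a \code{methylation_set}),
#'   \code{expression} (an \code{expression_set}, log2 scale),
#'   \code{truth} (regulated gene set, per-gene curve parameters, per-site
#'   clump/sub-group assignments, promoter sub-group means), and
#'   \code{paths} when \code{dir} was given.
#' @export
generate_panel <- function(n_lines = 45, n_genes = 60,
                           frac_regulated = 0.15, sites_per_group = 9,
                           noise_sd = 5, seed = 1, dir = NULL) {
  stopifnot(n_lines >= 4, n_genes >= 1,
            frac_regulated >= 0, frac_regulated <= 1, sites_per_group >= 1)
  with_seed(seed, {
    lines <- sprintf("CL%02d", seq_len(n_lines))
    panel <- cell_panel(lines)
    line_shift <- stats::rnorm(n_lines, 0, 12)
    n_chrom <- min(5L, n_genes)
    chroms <- sprintf("chr%d", ((seq_len(n_genes) - 1L) %% n_chrom) + 1L)
    n_reg <- round(frac_regulated * n_genes)
    regulated <- if (n_reg > 0) sort(sample(n_genes, n_reg)) else integer(0)

    cursor <- stats::setNames(rep(50000, n_chrom), sprintf("chr%d", 1:n_chrom))
    site_rows <- list(); site_prof <- list()
    ps_rows <- list(); expr_rows <- list()
    params <- data.frame(gene = character(), a = numeric(), b = numeric(),
                         c = numeric(), stringsAsFactors = FALSE)
    promoter_mean <- list()
    for (g in seq_len(n_genes)) {
      gene <- sprintf("GENE%03d", g)
      chr <- chroms[g]
      n_sub <- sample(2:3, 1)
      is_reg <- g %in% regulated
      # latent sub-group profiles; the promoter sub-group of a regulated
      # gene is spread across the whole methylation range so the sigmoid
      # relation is identifiable
      latent <- matrix(NA_real_, n_sub, n_lines)
      for (s in seq_len(n_sub)) {
        if (is_reg && s == n_sub) {
          latent[s, ] <- pmin(100, pmax(0,
            stats::runif(n_lines, 0, 100) * 0.8 + line_shift + 10))
        } else {
          mu <- stats::runif(1, 10, 90)
          latent[s, ] <- pmin(100, pmax(0,
            mu + line_shift + stats::rnorm(n_lines, 0, 18)))
        }
      }
      # lay out sites: sub-groups are consecutive blocks along the clump
      n_sites <- n_sub * sites_per_group
      spacing <- sample(30:250, n_sites, replace = TRUE)
      pos <- cursor[chr] + cumsum(spacing)
      sub_of_site <- rep(seq_len(n_sub), each = sites_per_group)
      prof <- latent[sub_of_site, , drop = FALSE] +
        matrix(stats::rnorm(n_sites * n_lines, 0, noise_sd),
               n_sites, n_lines)
      prof <- round(pmax(pmin(prof, 100), 0), 4)
      ids <- sprintf("%s_s%02d", gene, seq_len(n_sites))
      site_rows[[g]] <- data.frame(site_id = ids, chromosome = chr,
                                   position = pos, gene = gene,
                                   subgroup = sub_of_site,
                                   stringsAsFactors = FALSE)
      site_prof[[g]] <- prof

      # promoter sub-group = last block (nearest the probe set)
      pm <- colMeans(prof[sub_of_site == n_sub, , drop = FALSE])
      promoter_mean[[gene]] <- pm

      ps_start <- max(pos) + sample(2000:10000, 1)
      ps_end <- ps_start + sample(500:3000, 1)
      if (is_reg) {
        a <- stats::runif(1, 60, 100)
        b <- stats::runif(1, 0.08, 0.2)
        cc <- stats::runif(1, 30, 70)
        params <- rbind(params, data.frame(gene = gene, a = a, b = b,
                                           c = cc))
        e_dec <- a / (1 + exp(b * (pm - cc))) +
          stats::rnorm(n_lines, 0, noise_sd)
      } else {
        e_dec <- stats::runif(n_lines, 0, 100)
      }
      e_dec <- pmin(100, pmax(1e-6, e_dec))
      n_ps <- if (g %% 10 == 0) 2L else 1L # some genes have two probe sets
      for (p in seq_len(n_ps)) {
        ps_rows[[length(ps_rows) + 1L]] <- data.frame(
          probeset_id = sprintf("%s_at%d", gene, p), gene = gene,
          chromosome = chr,
          start = ps_start + (p - 1L) * 200,
          end = ps_end + (p - 1L) * 200, stringsAsFactors = FALSE)
        expr_rows[[length(expr_rows) + 1L]] <- e_dec
      }
      cursor[chr] <- ps_end + 60000 + sample(0:20000, 1)
    }

    sites <- do.call(rbind, site_rows)
    meth_prof <- do.call(rbind, site_prof)
    colnames(meth_prof) <- lines
    probesets <- do.call(rbind, ps_rows)
    expr_dec <- do.call(rbind, expr_rows)
    colnames(expr_dec) <- lines

    # pin the decimal extremes on null genes so min-max normalization is
    # numerically the identity (skipped when every gene is regulated)
    null_ps <- which(!(probesets$gene %in% sprintf("GENE%03d", regulated)))
    if (length(null_ps) >= 1) {
      expr_dec[null_ps[1], 1] <- 1e-6
      expr_dec[null_ps[length(null_ps)], n_lines] <- 100
    }
    expr_log <- round(log2(expr_dec), 6)

    ord <- order(sites$chromosome, sites$position, sites$site_id)
    meth <- new_methylation_set(
      sites[ord, c("site_id", "chromosome", "position")],
      meth_prof[ord, , drop = FALSE], panel)
    rownames(meth$sites) <- NULL
    pord <- order(probesets$chromosome, probesets$start,
                  probesets$probeset_id)
    expr <- new_expression_set(probesets[pord, , drop = FALSE],
                               expr_log[pord, , drop = FALSE], panel)
    rownames(expr$probesets) <- NULL

    truth <- list(seed = seed, n_lines = n_lines, n_genes = n_genes,
                  noise_sd = noise_sd,
                  regulated_genes = sprintf("GENE%03d", regulated),
                  curve_params = params,
                  sites = sites[ord, , drop = FALSE],
                  promoter_mean = promoter_mean)
    out <- list(methylation = meth, expression = expr, truth = truth)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      mp <- file.path(dir, "methylation.tsv")
      ep <- file.path(dir, "expression.tsv")
      tp <- file.path(dir, "truth.json")
      write_methylation(meth, mp)
      write_expression(expr, ep)
      truth_json <- truth
      truth_json$promoter_mean <- NULL
      jsonlite::write_json(truth_json, tp, auto_unbox = TRUE, digits = NA)
      out$paths <- c(methylation = mp, expression = ep, truth = tp)
    }
    out
  })
}

#' Generate labelled concentric-circle data
#'
#' The classic nonlinear-boundary benchmark for spectral clustering:
#' points equally distributed in angle around each ring (equal spacing
#' plus up to one spacing of uniform jitter, so no ring has a large
#' angular gap that would disconnect it in the affinity graph) with
#' radius drawn from \eqn{Normal(r_i, noise\_sd)}.
#'
#' @param n_per_ring points per ring (recycled; default 100).
#' @param radii strictly increasing ring radii (default \code{c(1, 3, 5)}).
#' @param noise_sd radial noise standard deviation (default 0.1).
#' @param seed integer seed.
#' @return A list with \code{points} (n x 2 matrix) and \code{labels}
#'   (ring index per point).
#' @export
generate_circles <- function(n_per_ring = 100, radii = c(1, 3, 5),
                             noise_sd = 0.1, seed = 1) {
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  if (length(radii) > 1 && any(diff(radii) < 4 * noise_sd))
    warning("rings may overlap at this noise level")
  n_per_ring <- rep_len(n_per_ring, length(radii))
  with_seed(seed, {
    pts <- list(); labs <- list()
    for (i in seq_along(radii)) {
      n_i <- n_per_ring[i]
      theta <- 2 * pi * (seq_len(n_i) - 1) / n_i +
        stats::runif(n_i, 0, 2 * pi / n_i)
      r <- stats::rnorm(n_i, radii[i], noise_sd)
      pts[[i]] <- cbind(x = r * cos(theta), y = r * sin(theta))
      labs[[i]] <- rep(i, n_per_ring[i])
    }
    list(points = do.call(rbind, pts),
         labels = unlist(labs, use.names = FALSE))
  })
}
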