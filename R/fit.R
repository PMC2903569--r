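#' @name sigmoid-fit
#' @title Constrained decreasing sigmoid regression of expression on
#'   methylation
#'
#' @description
#' Epigenetic silencing predicts a monotone-decreasing relationship between
#' promoter methylation and expression. Each association is scored by a
#' least-squares fit of the three-parameter logistic curve
#' \deqn{E_{fit}(M) = a / (1 + e^{b (M - c)})}
#' with \eqn{a \in [0, 200]}, \eqn{b \ge 0} (enforcing the decreasing
#' direction), \eqn{c \in [-50, 150]}. Fit quality is
#' \eqn{R = SSR / (SSR + SSE)} where
#' \eqn{SSR = \sum (E_{fit} - \bar E)^2} and
#' \eqn{SSE = \sum (E_{fit} - E)^2}; \eqn{R = 1} indicates a perfect fit
#' and \eqn{R = 0} is the degenerate (constant-fit) convention.
#' Significance comes from refitting on permutations of the methylation
#' values.
NULL

sigmoid_curve <- function(M, a, b, c) a / (1 + exp(pmin(700, pmax(-700, b * (M - c)))))

default_starts <- function(M) {
  list(b = c(0.05, 0.2, 1),
       c = unname(stats::quantile(M, c(0.25, 0.5, 0.75))))
}

#' Fit the decreasing sigmoid to one association
#'
#' Pairs with a missing value on either side are dropped (pairwise
#' deletion); at least 4 complete pairs are required (3 free parameters
#' plus one). The optimization is multi-start and fully deterministic: the
#' amplitude is profiled out in closed form and (b, c) are searched by
#' Nelder-Mead from starts at the methylation quartiles crossed with slopes
#' {0.05, 0.2, 1}, plus a coarse grid.
#'
#' @param M methylation percentages per cell line.
#' @param E normalized expression per cell line.
#' @return An object of class \code{sigmoid_fit}: \code{a}, \code{b},
#'   \code{c}, \code{E_fit} (fitted values for the complete pairs),
#'   \code{SSR}, \code{SSE}, \code{R}, \code{n_used}, \code{converged};
#'   or, with fewer than 4 complete pairs, \code{converged = FALSE} with a
#'   \code{reason}.
#' @export
fit_curve <- function(M, E) {
  stopifnot(length(M) == length(E))
  ok <- is.finite(M) & is.finite(E)
  if (sum(ok) < 4)
    return(structure(list(converged = FALSE, n_used = sum(ok),
                          reason = "fewer than 4 complete pairs"),
                     class = "sigmoid_fit"))
  m <- as.numeric(M[ok]); e <- as.numeric(E[ok])
  st <- default_starts(m)
  fit <- fit_sigmoid_cpp(m, e, st$b, st$c)
  E_fit <- sigmoid_curve(m, fit$a, fit$b, fit$c)
  structure(list(a = fit$a, b = fit$b, c = fit$c,
                 E_fit = E_fit, M_used = m, E_used = e,
                 SSR = fit$ssr, SSE = fit$sse, R = fit$R,
                 n_used = length(m), converged = TRUE),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("sigmoid_fit: not fitted (", x$reason, ")\n")
    return(invisible(x))
  }
  cat(sprintf("sigmoid_fit: a = %.3f, b = %.4f, c = %.2f | R = %.4f (n = %d)\n",
              x$a, x$b, x$c, x$R, x$n_used))
  invisible(x)
}

#' Goodness-of-fit score R
#'
#' \eqn{R = SSR / (SSR + SSE)}; when both sums are zero (constant data
#' fitted exactly) R is 0 by convention. R lies in \eqn{[0, 1]} and equals
#' 1 exactly when \eqn{SSE = 0} with \eqn{SSR > 0}.
#'
#' @param SSR sum of squares of fitted values about the expression mean.
#' @param SSE residual sum of squares.
#' @return The score R.
#' @export
compute_R <- function(SSR, SSE) {
  if (SSR < 0 || SSE < 0) stop("SSR and SSE must be nonnegative")
  tot <- SSR + SSE
  if (tot == 0) return(0)
  SSR / tot
}

#' Permutation p-value for an association
#'
#' The observed score is compared with \code{m_perm} scores obtained by
#' refitting the same curve (identical multi-start search) after uniformly
#' permuting the methylation values against the fixed expression values:
#' \eqn{p = \#\{m : R_m \ge R_{obs}\} / M_{perm}}. The plain count
#' convention (no add-one correction) is the default so a fit beating
#' every permutation reports exactly p = 0; set \code{add_one = TRUE} for
#' the (#+1)/(M+1) variant.
#'
#' @param M,E the association's methylation and expression profiles.
#' @param r_obs observed R; \code{NULL} computes it via
#'   \code{\link{fit_curve}}.
#' @param m_perm number of permutations (default 10000).
#' @param seed integer seed; the permutation stream is reproducible.
#' @param add_one use the add-one p-value convention.
#' @param keep_null return the vector of permutation scores.
#' @return A list: \code{p_value}, \code{n_exceed}, \code{m_perm},
#'   \code{r_obs}, and (if requested) \code{r_null}.
#' @export
permutation_pvalue <- function(M, E, r_obs = NULL, m_perm = 10000,
                               seed = 1, add_one = FALSE,
                               keep_null = FALSE) {
  if (m_perm < 1) stop("m_perm must be at least 1")
  ok <- is.finite(M) & is.finite(E)
  m <- as.numeric(M[ok]); e <- as.numeric(E[ok])
  if (length(m) < 4) stop("fewer than 4 complete pairs")
  if (is.null(r_obs)) r_obs <- fit_curve(m, e)$R
  st <- default_starts(m)
  res <- with_seed(seed,
                   perm_null_cpp(m, e, as.integer(m_perm), r_obs,
                                 st$b, st$c, keep_null))
  p <- if (add_one) (res$count + 1) / (m_perm + 1) else res$count / m_perm
  out <- list(p_value = p, n_exceed = res$count, m_perm = m_perm,
              r_obs = r_obs)
  if (keep_null) out$r_null <- res$r_null
  out
}
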