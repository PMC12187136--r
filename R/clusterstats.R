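# Label 4-connected components of a logical matrix. Returns an integer
# matrix (0 = background). Iterative flood fill; matrices here are small
# (tens of timepoints a side).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      cell <- queue[[1]]
      queue <- queue[-1]
      r <- (cell - 1L) %% nr + 1L
      cc <- (cell - 1L) %/% nr + 1L
      for (nb in c(if (r > 1) cell - 1L, if (r < nr) cell + 1L,
                   if (cc > 1) cell - nr, if (cc < nc) cell + nr)) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

# One-sample t statistics across the first (subject) dimension of an
# S x R x C array, returned as an R x C matrix. NA cells give NA.
subject_t_map <- function(values) {
  s <- dim(values)[1]
  m <- apply(values, c(2, 3), mean)
  v <- apply(values, c(2, 3), stats::var)
  m / sqrt(v / s)
}

#' Cluster-based sign-permutation test on subject-wise matrices
#'
#' Nonparametric family-wise test for contiguous effects in a
#' train-time x test-time (or any gridded) statistic map. Element-wise
#' one-sample t values are computed across subjects on baseline-subtracted
#' values; elements whose one-sided uncorrected t-test is significant in
#' the tested direction form 4-connected clusters; each cluster's summed
#' t value is compared with a null distribution of maximal cluster sums
#' obtained by randomly flipping the sign of entire subject maps. The
#' observed statistic is included in the null, so the smallest attainable
#' p is 1 / (n_perm + 1). Per the standard procedure, each cluster is
#' compared to the max-cluster null independently (no additional
#' correction over clusters).
#'
#' @param values subjects x rows x cols array of baseline-subtracted
#'   statistics (e.g. accuracy minus 50 for tests against chance, or
#'   off-diagonal minus diagonal accuracies for dynamic-coding tests).
#'   Cells that are NA for all subjects are excluded.
#' @param n_perm number of sign-flip permutations (default 1000).
#' @param alpha cluster significance level.
#' @param tail `"positive"` to test for values above baseline,
#'   `"negative"` for below.
#' @param cluster_p one-sided uncorrected p threshold forming clusters.
#' @param seed optional integer seed for the permutation draws.
#' @return an object of class `vwm_clusters`: `clusters` (list with cells,
#'   summed t `mass`, `p`), `element_t` (t map), `sig_mask` (logical map,
#'   union of clusters with p < alpha), `n_perm`, `tail`, `alpha`.
#' @export
cluster_sign_permutation_test <- function(values, n_perm = 1000,
                                          alpha = 0.05,
                                          tail = c("positive", "negative"),
                                          cluster_p = 0.05, seed = NULL) {
  tail <- match.arg(tail)
  d <- dim(values)
  if (length(d) != 3) stop("values must be a subjects x rows x cols array")
  s <- d[1]
  if (s < 2) stop("at least 2 subjects are required")
  if (n_perm < 100) warning("fewer than 100 permutations: p-values coarse")
  if (!is.null(seed)) set.seed(seed)

  sign_flip <- if (tail == "negative") -1 else 1
  tcrit <- stats::qt(1 - cluster_p, df = s - 1)

  x <- matrix(values, s, d[2] * d[3])           # subjects x cells
  ok <- colSums(is.na(x)) == 0
  sumsq <- colSums(x^2)

  t_from_sums <- function(sums) {
    m <- sums / s
    v <- pmax((sumsq - s * m^2) / (s - 1), 0)  # guard rounding at var ~ 0
    m / sqrt(v / s)
  }

  max_mass <- function(tvec) {
    u <- sign_flip * tvec
    u[!ok | !is.finite(u)] <- -Inf
    supra <- matrix(u > tcrit, d[2], d[3])
    if (!any(supra)) return(0)
    lab <- label_components(supra)
    max(vapply(seq_len(max(lab)),
               function(k) sum(u[lab == k]), numeric(1)))
  }

  t_obs <- t_from_sums(colSums(x))
  u_obs <- sign_flip * t_obs
  u_obs[!ok | !is.finite(u_obs)] <- -Inf
  supra <- matrix(u_obs > tcrit, d[2], d[3])
  lab <- label_components(supra)
  n_cl <- max(lab)

  null_max <- numeric(n_perm)
  if (n_cl > 0) {
    signs <- matrix(sample(c(-1, 1), n_perm * s, replace = TRUE), n_perm, s)
    perm_sums <- signs %*% x
    for (p in seq_len(n_perm))
      null_max[p] <- max_mass(t_from_sums(perm_sums[p, ]))
  }

  clusters <- lapply(seq_len(n_cl), function(k) {
    cells <- which(lab == k)
    mass <- sum(u_obs[cells])
    list(cells = cells,
         rows = (cells - 1L) %% d[2] + 1L,
         cols = (cells - 1L) %/% d[2] + 1L,
         mass = mass,
         p = (1 + sum(null_max >= mass)) / (1 + n_perm))
  })

  sig <- matrix(FALSE, d[2], d[3])
  for (cl in clusters) if (cl$p < alpha) sig[cl$cells] <- TRUE

  structure(list(
    clusters = clusters,
    element_t = matrix(t_obs, d[2], d[3]),
    sig_mask = sig,
    n_perm = n_perm, alpha = alpha, tail = tail, cluster_p = cluster_p
  ), class = "vwm_clusters")
}

#' @export
print.vwm_clusters <- function(x, ...) {
  cat(sprintf("Cluster sign-permutation test (%s tail, %d permutations)\n",
              x$tail, x$n_perm))
  if (length(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (i in seq_along(x$clusters)) {
      cl <- x$clusters[[i]]
      cat(sprintf("  cluster %d: %d cells, summed t = %.2f, p = %.4f%s\n",
                  i, length(cl$cells), cl$mass, cl$p,
                  if (cl$p < x$alpha) " *" else ""))
    }
  }
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjusted p-values controlling the FDR across a family of tests
#' (for example all pairwise time-bin subspace comparisons).
#'
#' @param pvals p-values in \[0, 1\].
#' @return adjusted q-values, in the original order.
#' @export
fdr_correct <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
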