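#' Binarize a continuous trait for LD score regression
#'
#' The largest 35% of values become cases (1), the smallest 35% become
#' controls (0), and the middle 30% of individuals are dropped. The case and
#' control counts are both \code{floor(0.35 n)}; ties are broken by stable
#' sort order (earlier observations first).
#'
#' @param values numeric vector, length >= 3.
#' @return List with \code{y} (binary vector over the kept individuals),
#'   \code{keep} (their indices into \code{values}).
#' @examples
#' binarize_trait(1:10)$y         # 3 controls, 3 cases
#' @export
binarize_trait <- function(values) {
  n <- length(values)
  if (n < 3) stop("need at least 3 individuals")
  if (max(values) - min(values) < .Machine$double.eps * 100)
    stop("all trait values identical: binary split is degenerate")
  k <- floor(0.35 * n)
  if (k < 1) stop("fewer than one case/control at 35%; increase n")
  ord <- order(values)              # stable for ties
  low <- ord[seq_len(k)]
  high <- ord[seq.int(n - k + 1, n)]
  keep <- sort(c(low, high))
  y <- as.integer(keep %in% high)
  list(y = y, keep = keep)
}

#' Per-marker LD scores
#'
#' The LD score of marker j is \code{l_j = sum_k r^2_jk} over all markers,
#' including the self term (\code{r^2_jj = 1}), where \code{r} is the sample
#' correlation of additive dosages. Monomorphic markers contribute 0 to every
#' sum, receive \code{NA} themselves, and are reported in the
#' \code{monomorphic} attribute.
#'
#' @param genotypes a \code{\link{genotype_table}} or a numeric dosage matrix
#'   (individuals x markers).
#' @return Named numeric vector of LD scores (>= 1 for polymorphic markers),
#'   with attribute \code{monomorphic}.
#' @export
ld_scores <- function(genotypes) {
  G <- if (inherits(genotypes, "genotype_table")) genotypes$geno else as.matrix(genotypes)
  if (ncol(G) < 2) stop("need at least two markers")
  v <- .colVars(G)
  mono <- v < 1e-12
  l <- rep(NA_real_, ncol(G))
  if (any(!mono)) {
    R <- stats::cor(G[, !mono, drop = FALSE])
    l[!mono] <- rowSums(R^2)
  }
  names(l) <- colnames(G)
  attr(l, "monomorphic") <- mono
  l
}

#' t test for an LD score regression intercept against 1
#'
#' A regression intercept significantly different from 1 indicates
#' population-structure inflation: \code{t = (intercept - 1) / SE}, with a
#' two-sided P value from a t distribution.
#'
#' @param intercept estimated regression intercept.
#' @param se its standard error.
#' @param df degrees of freedom (markers - 2).
#' @return List with \code{t} and \code{P}.
#' @examples
#' ldsc_intercept_test(-6.05, 3.22, 13)$t   # -2.19
#' @export
ldsc_intercept_test <- function(intercept, se, df) {
  if (se <= 0) stop("'se' must be positive")
  t <- (intercept - 1) / se
  list(t = t, P = 2 * stats::pt(-abs(t), df = df))
}

#' LD score regression on a binarized trait
#'
#' Computes a per-marker association chi-square against the binary trait as
#' the Armitage trend statistic \code{chi2_j = n * r^2(dosage_j, y)}, then
#' regresses \code{chi2_j} on the LD scores \code{l_j} by ordinary least
#' squares. The intercept is tested against 1 (\code{\link{ldsc_intercept_test}},
#' m - 2 df): a significant deviation flags population-structure inflation.
#' Continuous traits are binarized with \code{\link{binarize_trait}} first.
#'
#' @param genotypes a \code{\link{genotype_table}} or dosage matrix.
#' @param trait numeric trait vector (one value per individual). A vector
#'   containing only 0/1 is used as is; anything else is binarized (dropping
#'   the middle 30% of individuals).
#' @return Object of class \code{ldsc}: list with \code{scores} (per-marker
#'   table: marker, l, chi2), \code{intercept}, \code{slope}, \code{se_intercept},
#'   \code{se_slope}, \code{t}, \code{P}, \code{n_used}, \code{m}.
#' @export
ldsc <- function(genotypes, trait) {
  G <- if (inherits(genotypes, "genotype_table")) genotypes$geno else as.matrix(genotypes)
  if (is.null(colnames(G))) colnames(G) <- paste0("m", seq_len(ncol(G)))
  if (length(trait) != nrow(G)) stop("one trait value per individual required")
  if (all(trait %in% c(0, 1))) {
    y <- as.integer(trait); keep <- seq_len(nrow(G))
  } else {
    b <- binarize_trait(trait)
    y <- b$y; keep <- b$keep
  }
  G <- G[keep, , drop = FALSE]
  m <- ncol(G)
  if (m < 3) stop("LD score regression needs at least 3 markers")
  n_used <- length(y)
  l <- ld_scores(G)
  mono <- attr(l, "monomorphic")
  r <- suppressWarnings(stats::cor(G, y))
  chi2 <- n_used * as.numeric(r)^2
  ok <- !mono & is.finite(chi2) & is.finite(l)
  if (sum(ok) < 3) stop("fewer than 3 usable markers")
  fit <- stats::lm(chi2[ok] ~ l[ok])
  sm <- summary(fit)$coefficients
  tst <- ldsc_intercept_test(sm[1, 1], sm[1, 2], df = sum(ok) - 2)
  structure(list(
    scores = data.frame(marker = colnames(G), l = as.numeric(l),
                        chi2 = chi2, stringsAsFactors = FALSE),
    intercept = unname(sm[1, 1]), se_intercept = unname(sm[1, 2]),
    slope = unname(sm[2, 1]), se_slope = unname(sm[2, 2]),
    t = tst$t, P = tst$P, n_used = n_used, m = m),
    class = "ldsc")
}

#' @export
print.ldsc <- function(x, ...) {
  cat(sprintf("LD score regression: %d markers, %d individuals after binarization\n",
              x$m, x$n_used))
  cat(sprintf("  intercept %.3f (SE %.3f), slope %.4f (SE %.4f)\n",
              x$intercept, x$se_intercept, x$slope, x$se_slope))
  cat(sprintf("  H0 intercept = 1: t = %.3f, P = %.4g\n", x$t, x$P))
  invisible(x)
}

#' Write LD score regression output
#'
#' Per-marker table (marker, l, chi2) plus a one-line summary footer written
#' as a commented line.
#'
#' @param x an \code{\link{ldsc}} result.
#' @param path file path.
#' @export
write_ldsc <- function(x, path) {
  stopifnot(inherits(x, "ldsc"))
  utils::write.table(x$scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("# intercept=%.6g se=%.6g slope=%.6g t=%.6g P=%.6g\n",
              x$intercept, x$se_intercept, x$slope, x$t, x$P),
      file = path, append = TRUE)
  invisible(path)
}
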