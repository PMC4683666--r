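#' Construct an NCII mating design
#'
#' A North Carolina II (NCII) design crosses a roster of maternal lines with a
#' roster of paternal lines. A *partial* NCII design evaluates only a subset of
#' the \code{a * b} factorial. Maternal and paternal rosters are disjoint
#' namespaces: a label may appear in both rosters but then denotes two distinct
#' lines, and reciprocal crosses are distinct.
#'
#' @param maternal character vector of maternal line labels (no duplicates).
#' @param paternal character vector of paternal line labels (no duplicates).
#' @param crosses data frame with character columns \code{maternal} and
#'   \code{paternal}; one row per cross, no duplicate rows.
#' @param t crosses per maternal line (kept as metadata for schedules built by
#'   \code{\link{partial_ncii}}; \code{NA} for irregular schedules).
#' @return An object of class \code{ncii_design}: a list with elements
#'   \code{maternal}, \code{paternal}, \code{crosses}, \code{t}.
#' @seealso \code{\link{partial_ncii}}, \code{\link{f1_proportion}}
#' @export
ncii_design <- function(maternal, paternal, crosses, t = NA_integer_) {
  maternal <- as.character(maternal)
  paternal <- as.character(paternal)
  if (anyDuplicated(maternal)) stop("duplicated maternal line labels")
  if (anyDuplicated(paternal)) stop("duplicated paternal line labels")
  crosses <- as.data.frame(crosses)
  if (!all(c("maternal", "paternal") %in% names(crosses)))
    stop("'crosses' needs columns 'maternal' and 'paternal'")
  crosses$maternal <- as.character(crosses$maternal)
  crosses$paternal <- as.character(crosses$paternal)
  if (!all(crosses$maternal %in% maternal))
    stop("cross references an unlisted maternal line")
  if (!all(crosses$paternal %in% paternal))
    stop("cross references an unlisted paternal line")
  if (anyDuplicated(crosses[c("maternal", "paternal")]))
    stop("duplicate crosses in design")
  rownames(crosses) <- NULL
  structure(list(maternal = maternal, paternal = paternal,
                 crosses = crosses[c("maternal", "paternal")],
                 t = as.integer(t)),
            class = "ncii_design")
}

#' Build a partial NCII cross schedule
#'
#' Maternal line \code{i} (1-based) is crossed with paternal lines
#' \code{i, i+1, ..., i+t-1}, indices wrapped modulo \code{b}. \code{extra}
#' additional wrapped crosses are appended starting again from maternal line 1
#' and continuing the rotation (maternal line \code{e} gets paternal line
#' \code{e + t} wrapped), skipping any duplicate. The schedule therefore has
#' exactly \code{a * t + extra} crosses; with \code{t = b} it is the complete
#' factorial.
#'
#' @param a number of maternal lines.
#' @param b number of paternal lines.
#' @param t crosses per maternal line, \code{1 <= t <= b}.
#' @param extra number of padding crosses appended after the rotation
#'   (\code{>= 0}).
#' @param maternal,paternal optional label vectors (defaults \code{"M1"...},
#'   \code{"P1"...}).
#' @return An \code{\link{ncii_design}}.
#' @examples
#' d <- partial_ncii(26, 26, t = 7, extra = 6)
#' nrow(d$crosses)      # 188
#' f1_proportion(d)     # about 78.3
#' @export
partial_ncii <- function(a, b, t, extra = 0L,
                         maternal = paste0("M", seq_len(a)),
                         paternal = paste0("P", seq_len(b))) {
  a <- as.integer(a); b <- as.integer(b); t <- as.integer(t)
  extra <- as.integer(extra)
  if (a < 1L || b < 1L) stop("'a' and 'b' must be >= 1")
  if (t < 1L || t > b) stop("'t' must satisfy 1 <= t <= b")
  if (extra < 0L) stop("'extra' must be >= 0")
  if (a * t + extra > a * b)
    stop("a*t + extra exceeds the full factorial; impossible without duplicates")
  wrap <- function(j) ((j - 1L) %% b) + 1L
  mi <- rep(seq_len(a), each = t)
  pi <- wrap(rep(seq_len(a), each = t) + rep(seq_len(t) - 1L, times = a))
  if (extra > 0L) {
    # continue the rotation: one more paternal partner per maternal line,
    # restarting from maternal line 1, skipping duplicates
    em <- integer(0); ep <- integer(0)
    shift <- t
    while (length(em) < extra) {
      cand_m <- seq_len(a)
      cand_p <- wrap(cand_m + shift)
      keep <- !paste(cand_m, cand_p) %in% paste(mi, pi)
      cand_m <- cand_m[keep]; cand_p <- cand_p[keep]
      take <- min(extra - length(em), length(cand_m))
      em <- c(em, cand_m[seq_len(take)]); ep <- c(ep, cand_p[seq_len(take)])
      shift <- shift + 1L
      if (shift > t + b) stop("cannot place 'extra' crosses without duplicates")
    }
    mi <- c(mi, em); pi <- c(pi, ep)
  }
  ncii_design(maternal, paternal,
              data.frame(maternal = maternal[mi], paternal = paternal[pi],
                         stringsAsFactors = FALSE),
              t = t)
}

#' Proportion of F1 hybrids in the mapping population
#'
#' Returns \code{100 * n_crosses / (a + b + n_crosses)}: the percentage of F1
#' hybrids among all parental lines plus F1 hybrids.
#'
#' @param design an \code{\link{ncii_design}}.
#' @return A percentage (single numeric).
#' @export
f1_proportion <- function(design) {
  stopifnot(inherits(design, "ncii_design"))
  nc <- nrow(design$crosses)
  if (nc == 0L) stop("empty design: F1 proportion undefined")
  100 * nc / (length(design$maternal) + length(design$paternal) + nc)
}

#' @export
print.ncii_design <- function(x, ...) {
  cat(sprintf("NCII mating design: %d maternal x %d paternal lines, %d crosses",
              length(x$maternal), length(x$paternal), nrow(x$crosses)))
  if (!is.na(x$t)) cat(sprintf(" (t = %d per maternal line)", x$t))
  cat(sprintf("\nF1 proportion in mapping population: %.1f%%\n",
              f1_proportion(x)))
  invisible(x)
}

#' Read / write a cross schedule
#'
#' Cross schedules are stored as tab-delimited text with a header row and two
#' columns, \code{maternal} and \code{paternal}.
#'
#' @param path file path.
#' @param design an \code{\link{ncii_design}} (for writing).
#' @param maternal,paternal optional rosters for reading; defaults to the
#'   lines observed in the file (in order of first appearance).
#' @return \code{read_crosses} returns an \code{\link{ncii_design}};
#'   \code{write_crosses} returns \code{path} invisibly.
#' @export
read_crosses <- function(path, maternal = NULL, paternal = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("maternal", "paternal") %in% names(tab)))
    stop("cross schedule must have header columns 'maternal' and 'paternal'")
  tab$maternal <- as.character(tab$maternal)
  tab$paternal <- as.character(tab$paternal)
  if (is.null(maternal)) maternal <- unique(tab$maternal)
  if (is.null(paternal)) paternal <- unique(tab$paternal)
  ncii_design(maternal, paternal, tab)
}

#' @rdname read_crosses
#' @export
write_crosses <- function(design, path) {
  stopifnot(inherits(design, "ncii_design"))
  utils::write.table(design$crosses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
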