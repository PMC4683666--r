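#' Combining-ability decomposition of F1 phenotypes
#'
#' General combining ability (GCA) of a parent is the mean performance of its
#' F1 hybrids over the crosses it appears in, expressed as a deviation from
#' the grand mean of all F1 values in the design. Specific combining ability
#' (SCA) of a cross is the residual \code{s_ij = F_ij - grand_mean - g_i -
#' g_j}. For partial designs both means use only the observed crosses.
#' Maternal and paternal GCAs are kept as separate ledgers (the NCII design is
#' asymmetric).
#'
#' @param values numeric vector of F1 phenotypic values, one per cross,
#'   aligned with \code{design$crosses}.
#' @param design an \code{\link{ncii_design}}; every maternal and paternal
#'   line must appear in at least one cross.
#' @return An object of class \code{combining_ability}: list with
#'   \code{grand_mean}, \code{gca_maternal} and \code{gca_paternal} (named
#'   vectors of deviations), and \code{sca} (one value per cross, named by
#'   cross).
#' @examples
#' d <- partial_ncii(2, 2, t = 2)          # full 2 x 2 factorial
#' ca <- combining_ability(c(10, 12, 14, 16), d)
#' ca$gca_maternal   # -2, +2
#' ca$sca            # all 0: the table is purely additive
#' @export
combining_ability <- function(values, design) {
  stopifnot(inherits(design, "ncii_design"))
  cr <- design$crosses
  if (length(values) != nrow(cr))
    stop("'values' must have one entry per cross")
  if (anyNA(values) || any(!is.finite(values))) stop("non-finite F1 values")
  orphan_m <- setdiff(design$maternal, cr$maternal)
  orphan_p <- setdiff(design$paternal, cr$paternal)
  if (length(orphan_m) || length(orphan_p))
    stop("parent(s) with no crosses: ",
         paste(utils::head(c(orphan_m, orphan_p), 5), collapse = ", "))
  gm <- mean(values)
  mat_mean <- tapply(values, factor(cr$maternal, levels = design$maternal), mean)
  pat_mean <- tapply(values, factor(cr$paternal, levels = design$paternal), mean)
  g_m <- mat_mean - gm
  g_p <- pat_mean - gm
  sca <- values - gm - g_m[cr$maternal] - g_p[cr$paternal]
  names(sca) <- paste(cr$maternal, cr$paternal, sep = " x ")
  structure(list(grand_mean = gm,
                 gca_maternal = stats::setNames(as.numeric(g_m), names(g_m)),
                 gca_paternal = stats::setNames(as.numeric(g_p), names(g_p)),
                 sca = stats::setNames(as.numeric(sca), names(sca))),
            class = "combining_ability")
}

#' @export
print.combining_ability <- function(x, ...) {
  cat(sprintf("Combining-ability decomposition: grand mean %.4g\n", x$grand_mean))
  cat(sprintf("  %d maternal GCAs (sd %.3g), %d paternal GCAs (sd %.3g), %d SCAs (sd %.3g)\n",
              length(x$gca_maternal), stats::sd(x$gca_maternal),
              length(x$gca_paternal), stats::sd(x$gca_paternal),
              length(x$sca), stats::sd(x$sca)))
  invisible(x)
}

#' Mid-parent heterosis
#'
#' \code{100 * (F1 - MP) / MP} with mid-parent value
#' \code{MP = (maternal + paternal) / 2}. Undefined when \code{MP} is zero.
#'
#' @param f1 F1 hybrid phenotype(s).
#' @param maternal,paternal parental phenotypes (vectorized).
#' @return Percentage(s).
#' @examples
#' mph(11, 8, 12)   # 10
#' @export
mph <- function(f1, maternal, paternal) {
  mp <- (maternal + paternal) / 2
  if (any(abs(mp) < .Machine$double.eps * 100))
    stop("mid-parent value is zero: MPH undefined")
  100 * (f1 - mp) / mp
}

#' Assemble a dependent variable and its mapping population
#'
#' The four dependent variables of heterosis mapping pair a response with a
#' genotype roster: GCA is one value per parent (mapped on the parental
#' genotypes), while trait phenotype, SCA and MPH are one value per cross
#' (mapped on the F1 genotypes). GCA and SCA are computed from all crosses in
#' \code{design}; \code{subset} then restricts the per-cross responses to the
#' mapping crosses (e.g. a partial schedule drawn from a simulated full
#' factorial).
#'
#' @param kind one of \code{"trait"}, \code{"gca"}, \code{"sca"},
#'   \code{"mph"}.
#' @param f1_values numeric vector of F1 phenotypes aligned with
#'   \code{design$crosses}.
#' @param design an \code{\link{ncii_design}}.
#' @param parent_values named numeric vector of parental phenotypes (required
#'   for \code{kind = "mph"}); maternal labels are looked up as
#'   \code{"M:<label>"} first if present, else \code{"<label>"} (and
#'   paternal correspondingly), so disjoint rosters with shared labels can be
#'   disambiguated by prefixing.
#' @param subset integer or logical index of mapping crosses (default: all).
#'   Ignored for \code{kind = "gca"}.
#' @return List with \code{response} (named numeric), \code{population}
#'   (\code{"parents"} or \code{"f1"}), \code{ids} (parent labels, or indices
#'   of mapping crosses into \code{design$crosses}).
#' @export
dependent_variable <- function(kind = c("trait", "gca", "sca", "mph"),
                               f1_values, design, parent_values = NULL,
                               subset = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(design, "ncii_design"))
  cr <- design$crosses
  if (is.null(subset)) subset <- seq_len(nrow(cr))
  subset <- seq_len(nrow(cr))[subset]
  cross_ids <- paste(cr$maternal, cr$paternal, sep = " x ")
  if (kind == "gca") {
    ca <- combining_ability(f1_values, design)
    response <- c(ca$gca_maternal, ca$gca_paternal)
    names(response) <- c(names(ca$gca_maternal), names(ca$gca_paternal))
    return(list(response = response, population = "parents",
                ids = names(response)))
  }
  if (kind == "sca") {
    per_m <- table(cr$maternal); per_p <- table(cr$paternal)
    if (max(per_m) < 2 && max(per_p) < 2)
      stop("SCA is degenerate: every parent appears in a single cross")
    ca <- combining_ability(f1_values, design)
    response <- ca$sca[subset]
  } else if (kind == "mph") {
    if (is.null(parent_values))
      stop("MPH requires parental phenotypes ('parent_values')")
    look <- function(lab, side) {
      key <- paste0(side, ":", lab)
      ifelse(key %in% names(parent_values), key, lab)
    }
    pm <- parent_values[look(cr$maternal[subset], "M")]
    pp <- parent_values[look(cr$paternal[subset], "P")]
    if (anyNA(pm) || anyNA(pp))
      stop("missing parental phenotype for some crosses")
    response <- mph(f1_values[subset], as.numeric(pm), as.numeric(pp))
    names(response) <- cross_ids[subset]
  } else {
    response <- f1_values[subset]
    names(response) <- cross_ids[subset]
  }
  list(response = response, population = "f1", ids = subset)
}

#' Write a dependent-variable table
#'
#' Tab-delimited text with columns \code{unit_id}, \code{kind}, \code{value};
#' \code{unit_id} is the parent label for GCA and \code{"maternal x
#' paternal"} for the per-cross variables.
#'
#' @param dv result of \code{\link{dependent_variable}}.
#' @param kind the dependent-variable kind (stored in the table).
#' @param path file path.
#' @export
write_dependent_variable <- function(dv, kind, path) {
  utils::write.table(
    data.frame(unit_id = names(dv$response), kind = kind,
               value = as.numeric(dv$response), stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
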