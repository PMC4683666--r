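#' Equally spaced linkage map
#'
#' @param n_chr number of chromosomes.
#' @param length_cM chromosome length in centimorgans (recycled).
#' @param markers_per_chr markers per chromosome, placed at
#'   \code{0, s, 2s, ..., length_cM} with uniform spacing
#'   \code{s = length_cM / (markers_per_chr - 1)}.
#' @return A data frame of class \code{genome_map} with columns \code{chrom}
#'   (integer), \code{marker} (label \code{"M1"...} numbered across the whole
#'   map) and \code{pos} (cM within chromosome).
#' @examples
#' genome_map(3, 95, 20)   # the 60-marker map used by the simulation presets
#' @export
genome_map <- function(n_chr, length_cM, markers_per_chr) {
  length_cM <- rep_len(length_cM, n_chr)
  markers_per_chr <- rep_len(as.integer(markers_per_chr), n_chr)
  if (any(markers_per_chr < 1L)) stop("need at least one marker per chromosome")
  pos <- unlist(lapply(seq_len(n_chr), function(c) {
    k <- markers_per_chr[c]
    if (k == 1L) 0 else seq(0, length_cM[c], length.out = k)
  }))
  chrom <- rep(seq_len(n_chr), markers_per_chr)
  map <- data.frame(chrom = chrom,
                    marker = paste0("M", seq_along(pos)),
                    pos = pos, stringsAsFactors = FALSE)
  class(map) <- c("genome_map", "data.frame")
  map
}

#' Haldane map function
#'
#' Recombination fraction for a map distance \code{d} in cM:
#' \code{c = (1 - exp(-2 d / 100)) / 2}.
#'
#' @param d map distance in cM (vectorized).
#' @return Recombination fraction in \[0, 0.5).
#' @export
haldane <- function(d) (1 - exp(-2 * d / 100)) / 2

#' Genotype table
#'
#' Genotypes are stored as the dosage of the \code{Q} allele: \code{2} = QQ,
#' \code{1} = Qq, \code{0} = qq. Parents in an NCII design are inbred and must
#' be homozygous (dosage 0 or 2) at every marker.
#'
#' @param geno integer matrix, individuals in rows (rownames = labels),
#'   markers in columns (colnames = marker labels).
#' @param map a \code{\link{genome_map}} covering the columns of \code{geno}.
#' @param role character vector, one of \code{"parent"} or \code{"F1"} per
#'   individual (recycled).
#' @return An object of class \code{genotype_table}.
#' @export
genotype_table <- function(geno, map, role = "parent") {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno))) rownames(geno) <- paste0("I", seq_len(nrow(geno)))
  if (is.null(colnames(geno))) colnames(geno) <- map$marker
  if (!identical(colnames(geno), map$marker))
    stop("genotype columns must match map markers (same order)")
  if (any(!is.na(geno) & (geno < 0L | geno > 2L)))
    stop("genotype dosages must be 0, 1, 2 or NA")
  role <- rep_len(as.character(role), nrow(geno))
  if (!all(role %in% c("parent", "F1"))) stop("role must be 'parent' or 'F1'")
  pr <- which(role == "parent")
  if (length(pr)) {
    het <- rowSums(!is.na(geno[pr, , drop = FALSE]) &
                     geno[pr, , drop = FALSE] == 1L) > 0
    if (any(het))
      stop("heterozygous genotype in parent(s): ",
           paste(utils::head(rownames(geno)[pr][het], 5), collapse = ", "),
           " (inbred lines must be homozygous)")
  }
  structure(list(geno = geno, map = map, role = role),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals (%d parents, %d F1) x %d markers on %d chromosome(s)\n",
              nrow(x$geno), sum(x$role == "parent"), sum(x$role == "F1"),
              ncol(x$geno), length(unique(x$map$chrom))))
  invisible(x)
}

#' Simulate inbred parental genotypes on a linkage map
#'
#' Each parent is a doubled haplotype: one haplotype is generated by a
#' first-order Markov chain along each chromosome and then doubled. The first
#' marker on a chromosome carries allele \code{Q} with probability \code{p};
#' across an interval of \code{d} cM the allele is retained with probability
#' \code{1 - c} and switched with probability \code{c}, where \code{c} is the
#' Haldane recombination fraction \code{\link{haldane}(d)}. The marginal
#' allele frequency is \code{p} at every marker and linkage disequilibrium
#' decays with map distance (correlation \code{exp(-2d/100)} at \code{p = 0.5}).
#' Chromosomes are independent.
#'
#' @param map a \code{\link{genome_map}}.
#' @param n number of parents.
#' @param p allele frequency of \code{Q}, in (0, 1).
#' @param ids individual labels.
#' @param seed optional integer seed (sets the RNG locally via
#'   \code{set.seed}).
#' @return A \code{\link{genotype_table}} of homozygous parents
#'   (dosages 0 / 2).
#' @export
simulate_parents <- function(map, n, p = 0.5, ids = paste0("L", seq_len(n)),
                             seed = NULL) {
  if (n < 1) stop("'n' must be positive")
  if (p <= 0 || p >= 1) stop("'p' must lie strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(map)
  hap <- matrix(0L, n, m)
  for (c in unique(map$chrom)) {
    idx <- which(map$chrom == c)
    cc <- haldane(diff(map$pos[idx]))
    hap[, idx[1]] <- as.integer(stats::runif(n) < p)
    if (length(idx) > 1L) for (j in seq_along(cc)) {
      cur <- hap[, idx[j]]
      # retain with probability 1-2c, else redraw from Bernoulli(p): keeps the
      # marginal frequency at p and gives adjacent-allele correlation 1-2c
      # (at p = 1/2 this is "switch with probability c")
      redraw <- stats::runif(n) < 2 * cc[j]
      hap[, idx[j + 1]] <- ifelse(redraw, as.integer(stats::runif(n) < p), cur)
    }
  }
  geno <- 2L * hap
  rownames(geno) <- ids
  colnames(geno) <- map$marker
  genotype_table(geno, map, role = "parent")
}

#' Deduce F1 genotypes from inbred parents
#'
#' For homozygous parents the F1 genotype at each marker is the union of the
#' two parental alleles: QQ x QQ gives QQ, qq x qq gives qq, and QQ x qq (in
#' either direction) gives Qq. In dosage terms the F1 dosage is the mean of
#' the parental dosages.
#'
#' @param parents a \code{\link{genotype_table}} of parents; every individual
#'   referenced by \code{design} must be present and homozygous.
#' @param design an \code{\link{ncii_design}}. Maternal labels are looked up
#'   first; a label present in both rosters resolves within its own roster
#'   because F1 rows are indexed by cross, not by line.
#' @return A \code{\link{genotype_table}} of F1 individuals, one per cross,
#'   labelled \code{"maternal x paternal"}.
#' @export
deduce_f1 <- function(parents, design) {
  stopifnot(inherits(parents, "genotype_table"), inherits(design, "ncii_design"))
  if (any(parents$role != "parent")) stop("'parents' must contain only parents")
  need <- unique(c(design$crosses$maternal, design$crosses$paternal))
  miss <- setdiff(need, rownames(parents$geno))
  if (length(miss))
    stop("parents missing from genotype table: ",
         paste(utils::head(miss, 5), collapse = ", "))
  gm <- parents$geno[design$crosses$maternal, , drop = FALSE]
  gp <- parents$geno[design$crosses$paternal, , drop = FALSE]
  f1 <- (gm + gp) %/% 2L
  rownames(f1) <- paste(design$crosses$maternal, design$crosses$paternal,
                        sep = " x ")
  genotype_table(f1, parents$map, role = "F1")
}

#' Specify a generative QTL model
#'
#' Each row of \code{effects} places one QTL term on the map: a main effect
#' (\code{type} \code{"a"} or \code{"d"}) at \code{marker1}, or a two-locus
#' epistatic effect (\code{"aa"}, \code{"ad"}, \code{"da"}, \code{"dd"}) at
#' the pair \code{(marker1, marker2)}. \code{h2} is the heritability
#' contributed by the term. A main-effect row of type \code{"a"} may carry a
#' dominance degree \code{degree = d/a}, in which case the locus has both an
#' additive effect \code{a} and a dominance effect \code{d = degree * a},
#' jointly calibrated to \code{h2} (degree 0.5 = partial, 1 = complete,
#' 2 = over-dominance).
#'
#' @param effects data frame with columns \code{type}, \code{marker1},
#'   \code{marker2} (NA for main effects), \code{h2}, and optionally
#'   \code{degree}.
#' @param mu baseline (population mean) of the trait. Mid-parent heterosis is
#'   a percentage of the mid-parent value, so \code{mu} fixes its scale.
#' @param sigma2_e residual variance.
#' @param p allele frequency used in calibration.
#' @return An object of class \code{qtl_model}.
#' @export
qtl_model <- function(effects, mu = 100, sigma2_e = 1, p = 0.5) {
  effects <- as.data.frame(effects)
  need <- c("type", "marker1", "h2")
  if (!all(need %in% names(effects))) stop("'effects' needs columns type, marker1, h2")
  if (!"marker2" %in% names(effects)) effects$marker2 <- NA_character_
  if (!"degree" %in% names(effects)) effects$degree <- NA_real_
  if (!all(effects$type %in% c("a", "d", "aa", "ad", "da", "dd")))
    stop("effect type must be one of a, d, aa, ad, da, dd")
  epi <- effects$type %in% c("aa", "ad", "da", "dd")
  if (any(epi & is.na(effects$marker2)))
    stop("epistatic effects need marker2")
  if (any(!epi & !is.na(effects$marker2)))
    stop("main effects must not carry marker2")
  if (any(effects$h2 < 0 | effects$h2 >= 1)) stop("h2 must lie in [0, 1)")
  if (sum(effects$h2) >= 1) stop("sum of heritabilities must be < 1")
  if (sigma2_e <= 0) stop("sigma2_e must be positive")
  structure(list(effects = effects, mu = mu, sigma2_e = sigma2_e, p = p),
            class = "qtl_model")
}

# centered variance of the coded predictor column for one QTL term in an F1
# population from random inbred parents at allele frequency 1/2.
# rho = exp(-2d/100) is the parental allele correlation between the two loci
# (0 when unlinked); derived from w_F1 = (w_mat + w_pat)/2, v_F1 =
# |w_mat - w_pat|/2 with w_parent = +/-1.
.coded_variance <- function(type, rho = 0) {
  switch(type,
         a  = 1 / 2,
         d  = 1 / 4,
         aa = 1 / 4,
         ad = (1 - rho^2) / 4,
         da = (1 - rho^2) / 4,
         dd = (1 + rho^2) / 4 - ((1 + rho^2) / 4)^2,
         stop("unknown effect type"))
}

.pair_rho <- function(model_effects_row, map) {
  i1 <- match(model_effects_row$marker1, map$marker)
  i2 <- match(model_effects_row$marker2, map$marker)
  if (is.na(i2)) return(0)
  if (map$chrom[i1] != map$chrom[i2]) return(0)
  exp(-2 * abs(map$pos[i1] - map$pos[i2]) / 100)
}

#' Calibrate QTL effect sizes from heritabilities
#'
#' Total phenotypic variance is \code{sigma2_P = sigma2_e / (1 - sum(h2))};
#' QTL term k receives genetic variance \code{h2_k * sigma2_P}, and its effect
#' size is the positive value whose squared effect times the centered variance
#' of its coded design column (in the F1 population implied by the mating
#' scheme, allele frequency 1/2) equals that genetic variance. For linked
#' pairs the column variance accounts for the parental allele correlation
#' \code{exp(-2d/100)}. A main-effect row with a dominance degree
#' \code{k = d/a} is calibrated jointly: \code{a = sqrt(h2 * sigma2_P /
#' (1/2 + k^2/4))}, \code{d = k * a}.
#'
#' @param model a \code{\link{qtl_model}}.
#' @param map the \code{\link{genome_map}} carrying the QTL markers.
#' @return The model with columns \code{effect} (the additive or named effect
#'   size) and \code{effect_d} (the dominance effect for degree rows, else NA)
#'   added to \code{model$effects}, plus \code{sigma2_P}.
#' @export
calibrate_effects <- function(model, map) {
  stopifnot(inherits(model, "qtl_model"))
  eff <- model$effects
  miss <- setdiff(na.omit(c(eff$marker1, eff$marker2)), map$marker)
  if (length(miss))
    stop("QTL at position with no marker: ", paste(miss, collapse = ", "))
  s2P <- model$sigma2_e / (1 - sum(eff$h2))
  effect <- numeric(nrow(eff)); effect_d <- rep(NA_real_, nrow(eff))
  for (i in seq_len(nrow(eff))) {
    gv <- eff$h2[i] * s2P
    if (eff$type[i] == "a" && !is.na(eff$degree[i])) {
      k <- eff$degree[i]
      effect[i] <- sqrt(gv / (.coded_variance("a") + k^2 * .coded_variance("d")))
      effect_d[i] <- k * effect[i]
    } else {
      rho <- .pair_rho(eff[i, ], map)
      effect[i] <- sqrt(gv / .coded_variance(eff$type[i], rho))
    }
  }
  model$effects$effect <- effect
  model$effects$effect_d <- effect_d
  model$sigma2_P <- s2P
  model
}

#' Simulate phenotypes under a QTL model
#'
#' The trait value is \code{mu} plus the sum of all QTL term contributions
#' (using the Cockerham-type codings \code{w = dosage - 1}, \code{v =
#' \[dosage == 1\]}, and their products for epistatic terms) plus Gaussian
#' noise with variance \code{sigma2_e}. Works for parents, F1s, or mixed
#' tables; homozygous parents get zero from every dominance-bearing term.
#'
#' @param genotypes a \code{\link{genotype_table}}.
#' @param model a calibrated \code{\link{qtl_model}} (see
#'   \code{\link{calibrate_effects}}; an uncalibrated model is calibrated on
#'   the fly against \code{genotypes$map}).
#' @param seed optional integer seed.
#' @return Named numeric vector of trait values, one per individual.
#' @export
simulate_phenotypes <- function(genotypes, model, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_table"), inherits(model, "qtl_model"))
  if (is.null(model$effects$effect)) model <- calibrate_effects(model, genotypes$map)
  if (!is.null(seed)) set.seed(seed)
  g <- genetic_values(genotypes, model)
  y <- model$mu + g + stats::rnorm(length(g), 0, sqrt(model$sigma2_e))
  names(y) <- rownames(genotypes$geno)
  y
}

#' Genetic values (no noise) under a QTL model
#'
#' @inheritParams simulate_phenotypes
#' @return Named numeric vector of genetic values (deviations from \code{mu}).
#' @export
genetic_values <- function(genotypes, model) {
  stopifnot(inherits(genotypes, "genotype_table"), inherits(model, "qtl_model"))
  if (is.null(model$effects$effect)) model <- calibrate_effects(model, genotypes$map)
  eff <- model$effects
  G <- genotypes$geno
  w <- function(mk) as.numeric(G[, mk]) - 1
  v <- function(mk) as.numeric(G[, mk] == 1L)
  g <- numeric(nrow(G))
  for (i in seq_len(nrow(eff))) {
    m1 <- eff$marker1[i]; m2 <- eff$marker2[i]
    g <- g + eff$effect[i] * switch(eff$type[i],
      a  = w(m1), d = v(m1),
      aa = w(m1) * w(m2), ad = w(m1) * v(m2),
      da = v(m1) * w(m2), dd = v(m1) * v(m2))
    if (!is.na(eff$effect_d[i])) g <- g + eff$effect_d[i] * v(m1)
  }
  names(g) <- rownames(G)
  g
}

# locate markers by position on the concatenated cM axis (chromosomes laid
# end to end in map order); used only to translate published QTL positions.
.marker_at_concat <- function(map, pos_concat) {
  offs <- c(0, cumsum(tapply(map$pos, map$chrom, max)))
  conc <- map$pos + offs[map$chrom]
  vapply(pos_concat, function(p) {
    # the first chromosome whose span contains p, matching a marker exactly
    hit <- which(abs(conc - p) < 1e-8)
    if (!length(hit)) stop("no marker at concatenated position ", p)
    map$marker[hit[1]]
  }, character(1))
}

#' Preset simulation experiments
#'
#' Returns the map, mating design and QTL model for the built-in Monte Carlo
#' experiment configurations:
#' \itemize{
#' \item Presets \code{1}..\code{6}: three 95 cM chromosomes with 20 equally
#'   spaced markers each (60 markers); 120 maternal + 120 paternal lines; the
#'   mapping cross schedule is the \code{t = 2} partial design (240 F1s). Six
#'   QTL, two each at heritability 0.05, 0.10 and 0.15. Presets 1 and 2 place
#'   additive resp. dominance QTL at 25, 75, 135, 175, 220 and 270 cM on the
#'   concatenated axis; presets 3-6 place aa, ad, da and dd pairs at
#'   20 & 60, 90 & 125, 155 & 205, 180 & 235, 40 & 275 and 75 & 220 cM.
#' \item \code{"partial-dominance"}, \code{"complete-dominance"},
#'   \code{"over-dominance"}: as preset 1 but with dominance degree 0.5, 1, 2.
#' \item \code{"mating-proportion"}: one 100 cM chromosome with 21 equally
#'   spaced markers; six heritability-0.05 QTL (additive at 20 cM, dominant at
#'   85 cM, aa at 10 & 30, ad at 40 & 55, da at 45 & 80, dd at 65 & 95 cM);
#'   the design for crosses-per-maternal-line \code{t} uses the rosters
#'   80/60/48/40/34/30/26/15 (with 2 resp. 6 padding crosses at t = 5, 7) so
#'   that the population totals 240 individuals (255 at t = 15).
#' }
#'
#' @param name preset id: 1..6, \code{"partial-dominance"},
#'   \code{"complete-dominance"}, \code{"over-dominance"} or
#'   \code{"mating-proportion"}.
#' @param t crosses per maternal line for the mating-proportion preset
#'   (one of 1, 2, 3, 4, 5, 6, 7, 15).
#' @param mu,sigma2_e baseline mean and residual variance of the generator.
#' @return List with elements \code{map}, \code{design} (the mapping cross
#'   schedule), \code{full_design} (the complete factorial, used to compute
#'   combining abilities), \code{qtl} (calibrated \code{\link{qtl_model}}),
#'   and \code{n_maternal}, \code{n_paternal}.
#' @export
preset_experiment <- function(name, t = NULL, mu = 100, sigma2_e = 1) {
  h2_6 <- c(0.05, 0.05, 0.10, 0.10, 0.15, 0.15)
  main_pos <- c(25, 75, 135, 175, 220, 270)
  pair_pos <- list(c(20, 60), c(90, 125), c(155, 205),
                   c(180, 235), c(40, 275), c(75, 220))
  degree_presets <- c("partial-dominance" = 0.5, "complete-dominance" = 1,
                      "over-dominance" = 2)
  key <- as.character(name)
  if (key %in% as.character(1:6) || key %in% names(degree_presets)) {
    map <- genome_map(3, 95, 20)
    a <- 120; b <- 120
    design <- partial_ncii(a, b, t = 2)
    if (key %in% c("1", "2", names(degree_presets))) {
      mk <- .marker_at_concat(map, main_pos)
      eff <- data.frame(type = if (key == "2") "d" else "a",
                        marker1 = mk, marker2 = NA_character_, h2 = h2_6,
                        stringsAsFactors = FALSE)
      if (key %in% names(degree_presets)) eff$degree <- degree_presets[[key]]
    } else {
      type <- c("3" = "aa", "4" = "ad", "5" = "da", "6" = "dd")[[key]]
      mk <- t(vapply(pair_pos, function(p) .marker_at_concat(map, p), character(2)))
      eff <- data.frame(type = type, marker1 = mk[, 1], marker2 = mk[, 2],
                        h2 = h2_6, stringsAsFactors = FALSE)
    }
  } else if (key == "mating-proportion") {
    if (is.null(t)) stop("mating-proportion preset needs 't'")
    roster <- list(`1` = c(80, 0), `2` = c(60, 0), `3` = c(48, 0),
                   `4` = c(40, 0), `5` = c(34, 2), `6` = c(30, 0),
                   `7` = c(26, 6), `15` = c(15, 0))
    rk <- as.character(t)
    if (!rk %in% names(roster)) stop("'t' must be one of 1,2,3,4,5,6,7,15")
    map <- genome_map(1, 100, 21)
    a <- roster[[rk]][1]; b <- a
    design <- partial_ncii(a, b, t = t, extra = roster[[rk]][2])
    eff <- data.frame(
      type = c("a", "d", "aa", "ad", "da", "dd"),
      marker1 = .marker_at_concat(map, c(20, 85, 10, 40, 45, 65)),
      marker2 = c(NA, NA, .marker_at_concat(map, c(30, 55, 80, 95))),
      h2 = 0.05, stringsAsFactors = FALSE)
  } else stop("unknown preset: ", name)
  qtl <- calibrate_effects(qtl_model(eff, mu = mu, sigma2_e = sigma2_e), map)
  list(map = map, design = design,
       full_design = partial_ncii(a, b, t = b,
                                  maternal = design$maternal,
                                  paternal = design$paternal),
       qtl = qtl, n_maternal = a, n_paternal = b)
}
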