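# ---- internal helpers for the Monte Carlo drivers ----------------------

# per-replicate seeds derived once from the master seed
.spawn_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(2147483646L, n)
}

# distance between two markers (Inf across chromosomes)
.marker_dist <- function(map, m1, m2) {
  i <- match(m1, map$marker); j <- match(m2, map$marker)
  ifelse(map$chrom[i] == map$chrom[j], abs(map$pos[i] - map$pos[j]), Inf)
}

# strict and relaxed detection of one simulated QTL term in an effect table.
# strict: significant effect of the correct type at the exact marker(s).
# relaxed: significant effect of the correct type with every marker within
# `window` cM of the corresponding true marker (pair order respected).
.detect_qtl <- function(tab, type, m1, m2, map, window = 10) {
  if (!nrow(tab)) return(c(strict = FALSE, relaxed = FALSE, estimate = 0))
  rows <- tab[tab$type == type & tab$significant, , drop = FALSE]
  if (is.na(m2)) {
    strict <- any(rows$marker1 == m1)
    relaxed <- any(.marker_dist(map, rows$marker1, m1) <= window)
  } else {
    strict <- any(rows$marker1 == m1 & rows$marker2 == m2)
    relaxed <- any(.marker_dist(map, rows$marker1, m1) <= window &
                     .marker_dist(map, rows$marker2, m2) <= window)
  }
  est_row <- tab[tab$type == type &
                   tab$marker1 == m1 &
                   (is.na(m2) | (!is.na(tab$marker2) & tab$marker2 == m2)), ,
                 drop = FALSE]
  est <- if (nrow(est_row)) est_row$estimate[1] else 0
  c(strict = strict, relaxed = isTRUE(relaxed) || strict, estimate = est)
}

# simulate one replicate of a preset and return the fitted effect table
.one_replicate <- function(pre, kind, a_gamma, b_gamma, alpha) {
  ids <- c(pre$design$maternal, pre$design$paternal)
  parents <- simulate_parents(pre$map, length(ids), p = 0.5, ids = ids)
  need_full <- kind %in% c("gca", "sca")
  if (need_full) {
    f1_full <- deduce_f1(parents, pre$full_design)
    y_full <- simulate_phenotypes(f1_full, pre$qtl)
  }
  if (kind == "gca") {
    dv <- dependent_variable("gca", y_full, pre$full_design)
    pop <- parents
    response <- dv$response[rownames(parents$geno)]
  } else if (kind == "sca") {
    key_full <- paste(pre$full_design$crosses$maternal,
                      pre$full_design$crosses$paternal)
    key_map <- paste(pre$design$crosses$maternal, pre$design$crosses$paternal)
    sub <- match(key_map, key_full)
    dv <- dependent_variable("sca", y_full, pre$full_design, subset = sub)
    pop <- deduce_f1(parents, pre$design)
    response <- dv$response
  } else {
    pop <- deduce_f1(parents, pre$design)
    y_f1 <- simulate_phenotypes(pop, pre$qtl)
    if (kind == "mph") {
      y_par <- simulate_phenotypes(parents, pre$qtl)
      dv <- dependent_variable("mph", y_f1, pre$design, parent_values = y_par)
      response <- dv$response
    } else response <- y_f1
  }
  des <- build_design(pop, response)
  fit <- eblasso(des, a_gamma = a_gamma, b_gamma = b_gamma)
  test_effects(fit, alpha)
}

#' Monte Carlo power study for one preset and dependent variable
#'
#' For each replicate the study simulates the parental lines of the preset,
#' deduces the F1 genotypes, simulates phenotypes under the preset's QTL
#' model, forms the requested dependent variable (computing GCA/SCA from the
#' complete factorial and mapping them on the stated population), builds the
#' full additive-dominance-epistasis design and fits it by
#' \code{\link{eblasso}}. A simulated QTL counts as detected when its true
#' effect term (correct type at the correct marker or marker pair) is
#' significant at \code{P < alpha}; a relaxed tally also accepts the correct
#' type within \code{window} cM. Empirical power is detections / replicates.
#'
#' @param preset preset id passed to \code{\link{preset_experiment}}.
#' @param kind dependent variable: \code{"trait"}, \code{"gca"},
#'   \code{"sca"} or \code{"mph"}.
#' @param replicates number of Monte Carlo replicates.
#' @param seed master seed; per-replicate seeds are spawned deterministically.
#' @param alpha significance level for declaring an effect.
#' @param a_gamma,b_gamma EBLASSO hyperprior.
#' @param window relaxed-detection window in cM.
#' @param t forwarded to \code{\link{preset_experiment}} (mating-proportion
#'   preset only).
#' @return Object of class \code{power_report}: data frame with one row per
#'   simulated QTL (type, markers, h2, true effect, detections, power,
#'   power_relaxed, mean_estimate, mean_abs_deviation) and attributes
#'   \code{replicates}, \code{failed}, \code{kind}, \code{preset}.
#' @export
run_power_study <- function(preset, kind = c("trait", "gca", "sca", "mph"),
                            replicates = 1000, seed = NULL, alpha = 0.05,
                            a_gamma = 1, b_gamma = 0.01, window = 10,
                            t = NULL) {
  kind <- match.arg(kind)
  pre <- preset_experiment(preset, t = t)
  eff <- pre$qtl$effects
  nq <- nrow(eff)
  seeds <- .spawn_seeds(seed, replicates)
  det <- det_rel <- matrix(0, replicates, nq)
  est <- matrix(NA_real_, replicates, nq)
  failed <- 0L
  for (r in seq_len(replicates)) {
    set.seed(seeds[r])
    tab <- tryCatch(.one_replicate(pre, kind, a_gamma, b_gamma, alpha),
                    error = function(e) {
                      warning("replicate ", r, " failed: ", conditionMessage(e))
                      NULL
                    })
    if (is.null(tab)) { failed <- failed + 1L; det[r, ] <- NA; next }
    for (q in seq_len(nq)) {
      d <- .detect_qtl(tab, eff$type[q], eff$marker1[q], eff$marker2[q],
                       pre$map, window)
      det[r, q] <- d["strict"]; det_rel[r, q] <- d["relaxed"]
      est[r, q] <- d["estimate"]
    }
  }
  used <- replicates - failed
  out <- data.frame(
    qtl = seq_len(nq), type = eff$type,
    marker1 = eff$marker1, marker2 = eff$marker2, h2 = eff$h2,
    true_effect = eff$effect,
    detections = colSums(det, na.rm = TRUE),
    power = colSums(det, na.rm = TRUE) / used,
    power_relaxed = colSums(det_rel, na.rm = TRUE) / used,
    mean_estimate = colMeans(est, na.rm = TRUE),
    mean_abs_deviation = colMeans(abs(est - rep(eff$effect, each = replicates)),
                                  na.rm = TRUE),
    stringsAsFactors = FALSE)
  structure(out, class = c("power_report", "data.frame"),
            replicates = used, failed = failed, kind = kind,
            preset = as.character(preset))
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("Power report: preset %s, dependent variable %s, %d replicates (%d failed)\n",
              attr(x, "preset"), attr(x, "kind"), attr(x, "replicates"),
              attr(x, "failed")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Bar chart of empirical power per QTL
#'
#' @param x a \code{power_report}.
#' @param relaxed plot the relaxed tally instead of the strict one.
#' @param ... passed to \code{barplot}.
#' @export
plot.power_report <- function(x, relaxed = FALSE, ...) {
  h <- if (relaxed) x$power_relaxed else x$power
  graphics::barplot(h, names.arg = paste0(x$type, "\nh2=", x$h2),
                    ylim = c(0, 1), ylab = "empirical power", ...)
  invisible(x)
}

#' Mean absolute mid-parent heterosis under nine genetic models
#'
#' For each genetic architecture (additive; partial, complete and
#' over-dominance with d/a = 0.5, 1, 2; pure dominance; and the four
#' epistasis types aa, ad, da, dd) the full factorial of F1 hybrids plus
#' their parents is simulated under the same six-QTL layout and
#' heritabilities, mid-parent heterosis is computed for every hybrid, and the
#' mean of |MPH| over all replicates is reported. Only the ranking of the
#' models is comparable across studies: the absolute percentages scale with
#' the baseline mean \code{mu} (doubling \code{mu} halves every value).
#'
#' @param replicates replicates of the full factorial per model.
#' @param seed master seed.
#' @param mu,sigma2_e generator baseline mean and residual variance.
#' @return Object of class \code{mph_summary}: data frame (model,
#'   mean_abs_mph, hybrids) sorted by decreasing mean |MPH|.
#' @export
run_mph_ranking <- function(replicates = 10, seed = NULL, mu = 100,
                            sigma2_e = 1) {
  models <- c(additive = "1", `partial-dom` = "partial-dominance",
              `complete-dom` = "complete-dominance",
              `over-dom` = "over-dominance", dominance = "2",
              aa = "3", ad = "4", da = "5", dd = "6")
  seeds <- .spawn_seeds(seed, replicates * length(models))
  dim(seeds) <- c(replicates, length(models))
  res <- vapply(seq_along(models), function(mi) {
    pre <- preset_experiment(models[[mi]], mu = mu, sigma2_e = sigma2_e)
    ids <- c(pre$design$maternal, pre$design$paternal)
    tot <- 0; cnt <- 0
    for (r in seq_len(replicates)) {
      set.seed(seeds[r, mi])
      parents <- simulate_parents(pre$map, length(ids), p = 0.5, ids = ids)
      f1 <- deduce_f1(parents, pre$full_design)
      y_f1 <- simulate_phenotypes(f1, pre$qtl)
      y_par <- simulate_phenotypes(parents, pre$qtl)
      h <- mph(y_f1, y_par[pre$full_design$crosses$maternal],
               y_par[pre$full_design$crosses$paternal])
      tot <- tot + sum(abs(h)); cnt <- cnt + length(h)
    }
    c(tot / cnt, cnt)
  }, numeric(2))
  out <- data.frame(model = names(models), mean_abs_mph = res[1, ],
                    hybrids = as.integer(res[2, ]), stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs_mph), ]
  rownames(out) <- NULL
  structure(out, class = c("mph_summary", "data.frame"))
}

#' @export
print.mph_summary <- function(x, ...) {
  cat("Mean |MPH| (%) by genetic model:\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Effect of the F1 proportion on association mapping
#'
#' Runs the mating-proportion experiment: for each crosses-per-maternal-line
#' value \code{t}, the mapping population is the parents plus the partial-NCII
#' F1s (240 individuals, 255 at t = 15), the trait phenotype is the dependent
#' variable, and power / absolute effect deviation are tallied per effect
#' type exactly as in \code{\link{run_power_study}}.
#'
#' @param t_values subset of \code{c(1, 2, 3, 4, 5, 6, 7, 15)}.
#' @param replicates Monte Carlo replicates per design.
#' @param seed master seed.
#' @param alpha significance level.
#' @param a_gamma,b_gamma EBLASSO hyperprior.
#' @param window relaxed-detection window in cM.
#' @return Object of class \code{proportion_report}: data frame with one row
#'   per (t, QTL term): t, f1_proportion, type, power, power_relaxed,
#'   mean_abs_deviation.
#' @export
run_proportion_study <- function(t_values = c(1, 2, 3, 4, 5, 6, 7, 15),
                                 replicates = 100, seed = NULL, alpha = 0.05,
                                 a_gamma = 1, b_gamma = 0.01, window = 10) {
  seeds <- .spawn_seeds(seed, length(t_values))
  rows <- list()
  for (ti in seq_along(t_values)) {
    t <- t_values[ti]
    pre <- preset_experiment("mating-proportion", t = t)
    eff <- pre$qtl$effects
    nq <- nrow(eff)
    rep_seeds <- .spawn_seeds(seeds[ti], replicates)
    det <- det_rel <- matrix(0, replicates, nq)
    est <- matrix(NA_real_, replicates, nq)
    failed <- 0L
    for (r in seq_len(replicates)) {
      set.seed(rep_seeds[r])
      tab <- tryCatch({
        ids <- c(pre$design$maternal, pre$design$paternal)
        parents <- simulate_parents(pre$map, length(ids), p = 0.5, ids = ids)
        f1 <- deduce_f1(parents, pre$design)
        # mapping population: parents and F1 hybrids together
        pop <- genotype_table(rbind(parents$geno, f1$geno), pre$map,
                              role = c(parents$role, f1$role))
        y <- simulate_phenotypes(pop, pre$qtl)
        fit <- eblasso(build_design(pop, y), a_gamma = a_gamma,
                       b_gamma = b_gamma)
        test_effects(fit, alpha)
      }, error = function(e) {
        warning("t = ", t, ", replicate ", r, " failed: ", conditionMessage(e))
        NULL
      })
      if (is.null(tab)) { failed <- failed + 1L; det[r, ] <- NA; next }
      for (q in seq_len(nq)) {
        d <- .detect_qtl(tab, eff$type[q], eff$marker1[q], eff$marker2[q],
                         pre$map, window)
        det[r, q] <- d["strict"]; det_rel[r, q] <- d["relaxed"]
        est[r, q] <- d["estimate"]
      }
    }
    used <- replicates - failed
    rows[[ti]] <- data.frame(
      t = t, f1_proportion = f1_proportion(pre$design), type = eff$type,
      power = colSums(det, na.rm = TRUE) / used,
      power_relaxed = colSums(det_rel, na.rm = TRUE) / used,
      mean_abs_deviation = colMeans(abs(est - rep(eff$effect, each = replicates)),
                                    na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("proportion_report", "data.frame"),
            replicates = replicates)
}

#' @export
print.proportion_report <- function(x, ...) {
  cat(sprintf("Mating-proportion study (%d replicates per design):\n",
              attr(x, "replicates")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Power versus F1 proportion, per effect type
#'
#' @param x a \code{proportion_report}.
#' @param ... passed to \code{matplot}.
#' @export
plot.proportion_report <- function(x, ...) {
  types <- unique(x$type)
  tv <- unique(x$t)
  m <- sapply(types, function(ty) x$power[x$type == ty])
  graphics::matplot(unique(x$f1_proportion), m, type = "b", pch = 1:6,
                    xlab = "F1 proportion in mapping population (%)",
                    ylab = "empirical power", ylim = c(0, 1), ...)
  graphics::legend("topleft", legend = types, pch = 1:6, col = 1:6, bty = "n")
  invisible(x)
}
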