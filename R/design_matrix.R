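#' Cockerham-type marker coding
#'
#' Maps a genotype to the additive and dominance dummy variables used
#' throughout the package: QQ (dosage 2) to \code{(w, v) = (1, 0)}, Qq
#' (dosage 1) to \code{(0, 1)}, qq (dosage 0) to \code{(-1, 0)}. Under this
#' coding the additive and dominance predictors are uncorrelated at F1
#' genotype frequencies 1/4 : 1/2 : 1/4.
#'
#' @param genotype dosage vector in \{0, 1, 2\} or character in
#'   \{"qq", "Qq", "QQ"\}.
#' @return A two-column matrix with columns \code{w} and \code{v}.
#' @export
encode_marker <- function(genotype) {
  if (is.character(genotype)) {
    genotype <- c(qq = 0L, Qq = 1L, qQ = 1L, QQ = 2L)[genotype]
    if (anyNA(genotype)) stop("unknown genotype code")
  }
  if (any(!genotype %in% 0:2)) stop("genotype dosage must be 0, 1 or 2")
  cbind(w = as.numeric(genotype) - 1, v = as.numeric(genotype == 1))
}

#' Model dimension accounting
#'
#' Number of effect columns in the joint additive-dominance-epistasis model
#' for \code{m} markers: \code{2m} main effects (one additive and one
#' dominance per marker), \code{4 * m(m-1)/2} epistatic effects (aa, ad, da,
#' dd per ordered pair), and with two or more environments one environment
#' main effect plus one environment-interaction copy of every genetic effect.
#'
#' @param m number of markers.
#' @param envs number of environments.
#' @return List with components \code{main}, \code{epistatic}, \code{env},
#'   \code{main_env}, \code{epistatic_env}, \code{total}.
#' @examples
#' count_effects(205, 1)$total   # 84050
#' count_effects(15, 2)          # 30 + 420 + 1 + 30 + 420 = 901
#' @export
count_effects <- function(m, envs = 1) {
  m <- as.integer(m); envs <- as.integer(envs)
  if (m < 1L || envs < 1L) stop("'m' and 'envs' must be >= 1")
  main <- 2L * m
  epi <- 4L * m * (m - 1L) %/% 2L
  env <- if (envs >= 2L) 1L else 0L
  main_env <- if (envs >= 2L) main else 0L
  epi_env <- if (envs >= 2L) epi else 0L
  list(main = main, epistatic = epi, env = env,
       main_env = main_env, epistatic_env = epi_env,
       total = main + epi + env + main_env + epi_env)
}

#' Build the full additive-dominance-epistasis design
#'
#' For each marker k the penalized block contains the additive column
#' \code{w_k} and dominance column \code{v_k}; for each marker pair k < s the
#' four element-wise products \code{w_k w_s} (aa), \code{w_k v_s} (ad),
#' \code{v_k w_s} (da) and \code{v_k v_s} (dd). With two environments, a
#' +1/-1-coded environment covariate joins the unpenalized block and one
#' environment-interaction column (genetic column times environment code) is
#' appended per genetic effect. Population-structure (Q) covariates are
#' appended to the unpenalized block. Effect labels follow the grammar
#' \code{"a@M7"}, \code{"dd@M3:M12"}, \code{"ad@M3:M12xE"}.
#'
#' Columns that are constant in the data (sample variance below 1e-12) are
#' flagged and excluded from estimation but retained in the labelling; for an
#' all-parent (inbred) population every dominance-bearing column is constant
#' zero, so dominance and dd effects can never be retained from GCA.
#'
#' @param genotypes a \code{\link{genotype_table}} with one row per
#'   observation (rows repeated across environments when \code{env} is
#'   given).
#' @param response numeric vector, one value per observation.
#' @param env optional environment labels (exactly 2 distinct values when
#'   given), coded +1/-1.
#' @param Q optional numeric matrix of population-structure covariates (rows
#'   = observations).
#' @param missing missing-genotype handling: \code{"mean"} (default) imputes
#'   the column mean of the w and v codings, keeping n fixed; \code{"drop"}
#'   removes observations with any missing genotype.
#' @return An object of class \code{effect_design}: list with \code{y},
#'   \code{X} (penalized columns, labelled), \code{U} (unpenalized block:
#'   intercept, environment, Q), \code{labels} (data frame label/type/
#'   marker1/marker2/env_int), \code{constant} (logical flag per column).
#' @export
build_design <- function(genotypes, response, env = NULL, Q = NULL,
                         missing = "mean") {
  missing <- match.arg(missing, c("mean", "drop"))
  stopifnot(inherits(genotypes, "genotype_table"))
  G <- genotypes$geno
  if (anyNA(G) && missing == "drop") {
    keep <- !apply(is.na(G), 1, any)
    G <- G[keep, , drop = FALSE]
    response <- response[keep]
    if (!is.null(env)) env <- env[keep]
    if (!is.null(Q)) Q <- as.matrix(Q)[keep, , drop = FALSE]
  }
  n <- nrow(G)
  if (length(response) != n)
    stop("response length (", length(response), ") != observations (", n, ")")
  mk <- colnames(G)
  m <- length(mk)
  W <- matrix(as.numeric(G) - 1, n, m, dimnames = list(NULL, mk))
  V <- matrix(as.numeric(G == 1L), n, m, dimnames = list(NULL, mk))
  if (anyNA(W)) {  # mean-impute the codings column-wise
    for (j in which(colSums(is.na(W)) > 0)) {
      W[is.na(W[, j]), j] <- mean(W[, j], na.rm = TRUE)
      V[is.na(V[, j]), j] <- mean(V[, j], na.rm = TRUE)
    }
  }
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  k <- pairs[, 1]; s <- pairs[, 2]
  main_lab <- data.frame(
    label = c(paste0("a@", mk), paste0("d@", mk)),
    type = rep(c("a", "d"), each = m),
    marker1 = c(mk, mk), marker2 = NA_character_,
    env_int = FALSE, stringsAsFactors = FALSE)
  pair_mk1 <- mk[k]; pair_mk2 <- mk[s]
  epi_lab <- data.frame(
    label = c(paste0("aa@", pair_mk1, ":", pair_mk2),
              paste0("ad@", pair_mk1, ":", pair_mk2),
              paste0("da@", pair_mk1, ":", pair_mk2),
              paste0("dd@", pair_mk1, ":", pair_mk2)),
    type = rep(c("aa", "ad", "da", "dd"), each = length(k)),
    marker1 = rep(pair_mk1, 4), marker2 = rep(pair_mk2, 4),
    env_int = FALSE, stringsAsFactors = FALSE)
  X <- cbind(W, V,
             W[, k, drop = FALSE] * W[, s, drop = FALSE],
             W[, k, drop = FALSE] * V[, s, drop = FALSE],
             V[, k, drop = FALSE] * W[, s, drop = FALSE],
             V[, k, drop = FALSE] * V[, s, drop = FALSE])
  labels <- rbind(main_lab, epi_lab)
  U <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(env)) {
    ef <- factor(env)
    if (length(ef) != n) stop("'env' must have one label per observation")
    if (nlevels(ef) != 2L)
      stop("exactly two environments are supported (got ", nlevels(ef), ")")
    ecol <- ifelse(as.integer(ef) == 1L, 1, -1)
    # one observation per individual-environment combination
    if (anyDuplicated(paste(rownames(G), as.character(ef))))
      stop("more than one response per individual-environment combination")
    XE <- X * ecol
    labE <- labels
    labE$label <- paste0(labE$label, "xE")
    labE$env_int <- TRUE
    X <- cbind(X, XE)
    labels <- rbind(labels, labE)
    U <- cbind(U, E = ecol)
  }
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    if (nrow(Q) != n) stop("Q matrix must have one row per observation")
    if (is.null(colnames(Q))) colnames(Q) <- paste0("Q", seq_len(ncol(Q)))
    U <- cbind(U, Q)
  }
  colnames(X) <- labels$label
  v <- .colVars(X)
  constant <- v < 1e-12
  structure(list(y = as.numeric(response), X = X, U = U, labels = labels,
                 constant = constant, n = n),
            class = "effect_design")
}

.colVars <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(0, ncol(X)))
  mu <- colMeans(X)
  (colSums(X^2) - n * mu^2) / (n - 1)
}

#' @export
print.effect_design <- function(x, ...) {
  cat(sprintf("effect_design: n = %d, %d penalized effect columns (%d constant, excluded), %d unpenalized covariate(s)\n",
              x$n, ncol(x$X), sum(x$constant), ncol(x$U)))
  invisible(x)
}

#' Export an effect design as delimited text
#'
#' Debugging aid: writes the response, unpenalized covariates and the
#' labelled penalized matrix as one wide tab-delimited table.
#'
#' @param design an \code{effect_design}.
#' @param path file path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "effect_design"))
  tab <- data.frame(y = design$y, design$U, design$X, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
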