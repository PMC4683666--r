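#' Read and write genotype tables
#'
#' Genotype files are tab-delimited text with a header: an \code{id} column,
#' an optional \code{role} column (\code{parent} or \code{F1}; default
#' \code{parent}), and one column per marker. Cells are \code{QQ}, \code{Qq},
#' \code{qq} (the numeric dosage alias \code{2}, \code{1}, \code{0} is
#' accepted) or \code{NA}. Parents are validated as homozygous on read.
#'
#' @param path file path.
#' @param map a \code{\link{genome_map}} whose markers match the file's
#'   marker columns.
#' @return \code{read_genotypes} returns a \code{\link{genotype_table}}.
#' @export
read_genotypes <- function(path, map) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (!"id" %in% names(tab)) stop("genotype file needs an 'id' column")
  if (anyDuplicated(tab$id))
    stop("duplicated individual id(s): ",
         paste(utils::head(unique(tab$id[duplicated(tab$id)]), 5), collapse = ", "))
  role <- if ("role" %in% names(tab)) tab$role else rep("parent", nrow(tab))
  mk_cols <- setdiff(names(tab), c("id", "role"))
  miss <- setdiff(map$marker, mk_cols)
  if (length(miss))
    stop("marker(s) in map but not in file: ", paste(utils::head(miss, 5), collapse = ", "))
  G <- as.matrix(tab[, map$marker, drop = FALSE])
  codes <- c(QQ = 2L, Qq = 1L, qQ = 1L, qq = 0L, `2` = 2L, `1` = 1L, `0` = 0L)
  num <- codes[G]
  bad <- !is.na(G) & is.na(num)
  if (any(bad))
    stop("unknown genotype token(s): ",
         paste(utils::head(unique(G[bad]), 5), collapse = ", "))
  dim(num) <- dim(G)
  rownames(num) <- tab$id
  colnames(num) <- map$marker
  genotype_table(num, map, role = role)
}

#' @rdname read_genotypes
#' @param genotypes a \code{\link{genotype_table}} (for writing).
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_table"))
  G <- genotypes$geno
  sym <- matrix(c("qq", "Qq", "QQ")[G + 1L], nrow(G), ncol(G),
                dimnames = dimnames(G))
  tab <- data.frame(id = rownames(G), role = genotypes$role, sym,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write linkage maps
#'
#' Tab-delimited text with header columns \code{chrom}, \code{marker},
#' \code{pos} (cM within chromosome).
#'
#' @param path file path.
#' @export
read_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "marker", "pos") %in% names(tab)))
    stop("map file needs columns chrom, marker, pos")
  for (c in unique(tab$chrom)) {
    p <- tab$pos[tab$chrom == c]
    if (any(diff(p) <= 0)) stop("marker positions must be strictly increasing within chromosome ", c)
  }
  map <- tab[c("chrom", "marker", "pos")]
  class(map) <- c("genome_map", "data.frame")
  map
}

#' @rdname read_map
#' @param map a \code{\link{genome_map}} (for writing).
#' @export
write_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[c("chrom", "marker", "pos")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write phenotype tables
#'
#' Tab-delimited text with header columns \code{id} (parent label or
#' \code{"maternal x paternal"} cross label), \code{env} and \code{value}.
#'
#' @param path file path.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "env", "value") %in% names(tab)))
    stop("phenotype file needs columns id, env, value")
  if (anyDuplicated(tab[c("id", "env")]))
    stop("more than one value per (individual, environment)")
  if (any(!is.finite(tab$value))) stop("non-finite phenotype value(s)")
  tab[c("id", "env", "value")]
}

#' @rdname read_phenotypes
#' @param phenotypes data frame with columns id, env, value (for writing).
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes[c("id", "env", "value")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' Flat key-value YAML. Recognized keys: \code{genotypes}, \code{map},
#' \code{crosses}, \code{phenotypes}, \code{q_matrix} (optional path),
#' \code{kind} (trait/gca/sca/mph), \code{outdir}, \code{seed},
#' \code{a_gamma}, \code{b_gamma}, \code{alpha}, \code{ldsc} (logical).
#'
#' @param path YAML file path.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return Validated configuration list of class \code{run_config}.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  defaults <- list(kind = "trait", seed = 1L, a_gamma = 1, b_gamma = 0.01,
                   alpha = 0.05, ldsc = TRUE, q_matrix = NULL)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("genotypes", "map", "crosses", "phenotypes", "outdir"))
    if (is.null(cfg[[k]])) stop("config key '", k, "' is required")
  for (k in c("genotypes", "map", "crosses", "phenotypes"))
    if (!file.exists(cfg[[k]])) stop("config path does not exist: ", cfg[[k]])
  if (!is.null(cfg$q_matrix) && !file.exists(cfg$q_matrix))
    stop("config path does not exist: ", cfg$q_matrix)
  if (!cfg$kind %in% c("trait", "gca", "sca", "mph"))
    stop("kind must be trait, gca, sca or mph")
  if (length(cfg$seed) != 1 || cfg$seed != as.integer(cfg$seed))
    stop("seed must be a single integer")
  class(cfg) <- "run_config"
  cfg
}

#' Run the association-mapping pipeline on user data
#'
#' Reads the map, parental genotypes, cross schedule and phenotypes, deduces
#' F1 genotypes, computes the configured dependent variable within each
#' environment, builds the joint effect design (with a +1/-1 environment
#' covariate and interaction block when two environments are present, and the
#' Q matrix in the unpenalized block), fits it by \code{\link{eblasso}}, and
#' writes the dependent-variable table, the effect table, the LD score
#' regression summary and a run log into \code{outdir}. Identical
#' configuration and seed give identical numeric output.
#'
#' @param config a \code{run_config} (see \code{\link{read_run_config}}) or
#'   path to one.
#' @return Invisibly, a list with the fit, the dependent variable, the
#'   \code{\link{ldsc}} result (or NULL) and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  map <- read_map(config$map)
  geno <- read_genotypes(config$genotypes, map)
  design <- read_crosses(config$crosses)
  phen <- read_phenotypes(config$phenotypes)
  parents <- genotype_table(geno$geno[geno$role == "parent", , drop = FALSE],
                            map, role = "parent")
  f1 <- deduce_f1(parents, design)
  envs <- sort(unique(phen$env))
  if (length(envs) > 2) stop("at most two environments are supported")
  cross_ids <- rownames(f1$geno)

  resp <- list(); env_lab <- list(); rows <- list()
  for (e in envs) {
    pe <- phen[phen$env == e, ]
    val <- stats::setNames(pe$value, pe$id)
    miss <- setdiff(cross_ids, names(val))
    if (config$kind != "gca" && length(miss))
      stop("missing F1 phenotype(s) in environment ", e, ": ",
           paste(utils::head(miss, 5), collapse = ", "))
    f1_val <- as.numeric(val[cross_ids])
    dv <- dependent_variable(config$kind, f1_val, design,
                             parent_values = val)
    resp[[e]] <- dv$response
    if (dv$population == "parents") {
      rows[[e]] <- match(names(dv$response), rownames(parents$geno))
      pop <- parents
    } else {
      rows[[e]] <- seq_len(nrow(f1$geno))
      pop <- f1
    }
    env_lab[[e]] <- rep(e, length(dv$response))
  }
  y <- unlist(resp, use.names = FALSE)
  G <- pop$geno[unlist(rows), , drop = FALSE]
  rn <- rownames(pop$geno)[unlist(rows)]
  rownames(G) <- make.unique(rn)
  pop_all <- genotype_table(G, map, role = rep_len(unique(pop$role), nrow(G)))
  env_vec <- if (length(envs) == 2) unlist(env_lab, use.names = FALSE) else NULL

  Q <- NULL
  if (!is.null(config$q_matrix)) {
    qt <- utils::read.delim(config$q_matrix, stringsAsFactors = FALSE)
    if (!"id" %in% names(qt)) stop("Q matrix file needs an 'id' column")
    qm <- as.matrix(qt[setdiff(names(qt), "id")])
    rownames(qm) <- qt$id
    if (!all(rn %in% rownames(qm)))
      stop("Q matrix missing row(s) for mapping individuals")
    Q <- qm[rn, , drop = FALSE]
  }

  des <- build_design(pop_all, y, env = env_vec, Q = Q)
  fit <- eblasso(des, a_gamma = config$a_gamma, b_gamma = config$b_gamma)

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    dependent = file.path(config$outdir, "dependent_variable.tsv"),
    effects = file.path(config$outdir, "effects.tsv"),
    ldsc = file.path(config$outdir, "ldsc.tsv"),
    log = file.path(config$outdir, "run_log.txt"))
  write_dependent_variable(list(response = stats::setNames(y, rn)),
                           config$kind, paths$dependent)
  write_effects(fit, paths$effects, alpha = config$alpha)
  ld <- NULL
  if (isTRUE(config$ldsc)) {
    ld <- tryCatch(ldsc(pop_all, y), error = function(e) {
      warning("LD score regression skipped: ", conditionMessage(e)); NULL })
    if (!is.null(ld)) write_ldsc(ld, paths$ldsc)
  }
  writeLines(c(
    sprintf("nciimap %s", as.character(utils::packageVersion("nciimap"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", as.integer(config$seed)),
    sprintf("kind: %s", config$kind),
    sprintf("n: %d  candidates: %d  retained: %d", fit$n,
            sum(fit$candidate), length(fit$retained)),
    sprintf("sigma0^2: %.10g  lambda: %.10g", fit$sigma02, fit$lambda)),
    paths$log)
  invisible(list(fit = fit, response = y, ldsc = ld, paths = paths))
}
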