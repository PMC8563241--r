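#' Run the full analysis pipeline
#'
#' Wires the stages into the analysis order: simulate (or load) data,
#' relationship matrices, REML/BLUP, heterosis, genotype association and
#' body-weight/dominance correlation. All outputs are CSV files written to
#' `out_dir` (the input files are never modified), plus a `manifest.json`
#' recording the command, a config hash, input checksums, the seed and the
#' package version. Re-running with an identical config reproduces identical
#' numeric outputs.
#'
#' The configuration is a flat YAML file (or an equivalent named list):
#' either `simulate: true` with [simulation_config()] fields, or `pedigree:`
#' and `pheno:` CSV paths; plus optional `age_wk`, `fixed` (fixed-effect
#' columns), `loci` (genotype column prefixes), `alpha`, `tol`, `max_iter`
#' and `stages` (subset of `relmat`, `reml`, `heterosis`, `assoc`, `corr`).
#'
#' @param config path to a YAML config file, or a named list.
#' @param out_dir output directory (created if needed).
#' @param seed overrides the config seed when not `NULL`.
#' @return invisibly, a list with the fitted objects and a `converged` flag.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  stages <- config$stages %||% c("relmat", "reml", "heterosis", "assoc",
                                 "corr")
  fixed <- config$fixed %||% c("sex", "hatch")
  loci <- config$loci %||% c("gh", "igf1")
  alpha <- config$alpha %||% 0.05
  age_wk <- config$age_wk %||% NULL

  # ---- inputs: simulate or load (validated before any computation) -------
  inputs <- character(0)
  if (isTRUE(config$simulate)) {
    sim_args <- config[intersect(names(config), names(formals(simulation_config)))]
    sim_cfg <- do.call(simulation_config, sim_args)
    message("simulating dataset (seed ", sim_cfg$seed, ")")
    sim <- simulate_dataset(sim_cfg)
    ped <- sim$pedigree
    pheno <- sim$phenotypes
  } else {
    if (is.null(config$pedigree) || is.null(config$pheno))
      stop("config must set simulate: true or give pedigree: and pheno: paths")
    for (f in c(config$pedigree, config$pheno))
      if (!file.exists(f)) stop("input file not found: ", f)
    inputs <- c(config$pedigree, config$pheno)
    ped <- topological_order(read_pedigree(config$pedigree))
    pheno <- read_phenotypes(config$pheno)
    sim <- NULL
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim)) write_simulation(sim, out_dir)

  out <- list(converged = TRUE)
  A <- D <- NULL
  if (any(c("relmat", "reml", "assoc", "corr") %in% stages)) {
    message("building relationship matrices (", nrow(ped), " animals)")
    A <- additive_relationship_matrix(ped)
    D <- dominance_relationship_matrix(ped, A)
    if ("relmat" %in% stages) {
      write_relmat_triplets(A, file.path(out_dir, "A_triplets.csv"))
      write_relmat_triplets(D, file.path(out_dir, "D_triplets.csv"))
    }
  }

  vc <- sol <- NULL
  if ("reml" %in% stages) {
    message("fitting additive + dominance animal model by REML")
    dm <- build_design_matrices(pheno, ped,
                                model_spec(fixed = fixed, age_wk = age_wk))
    vc <- reml_estimate(dm, A, D, tol = config$tol %||% 1e-8,
                        max_iter = config$max_iter %||% 100L)
    gp <- genetic_parameters(vc)
    gp$age_wk <- age_wk %||% NA
    gp$se_h2 <- vc$se_h2
    gp$converged <- vc$converged
    utils::write.csv(gp, file.path(out_dir, "genetic_parameters.csv"),
                     row.names = FALSE)
    sol <- solve_mme(dm, A, D, vc)
    utils::write.csv(
      data.frame(animal = names(sol$a_hat), a_hat = unname(sol$a_hat),
                 d_hat = unname(sol$d_hat)),
      file.path(out_dir, "blup.csv"), row.names = FALSE)
    if (!vc$converged) out$converged <- FALSE
    pheno$d_hat <- sol$d_hat[pheno$animal]
    pheno$a_hat <- sol$a_hat[pheno$animal]
  }

  if ("heterosis" %in% stages) {
    message("computing per-age heterosis")
    het <- heterosis_table(pheno, fixed = fixed)
    utils::write.csv(het, file.path(out_dir, "heterosis.csv"),
                     row.names = FALSE)
    out$heterosis <- het
  }

  if ("assoc" %in% stages) {
    cross <- pheno[pheno$line == "KR", , drop = FALSE]
    if (!is.null(age_wk)) cross <- cross[cross$age_wk == age_wk, , drop = FALSE]
    for (locus in loci) {
      col <- paste0(locus, "_genotype")
      if (!col %in% names(cross)) next
      message("association: ", locus)
      traits <- c("bw_g", if ("d_hat" %in% names(cross)) "d_hat")
      tabs <- lapply(traits, function(tr) {
        gc <- genotype_effect(cross[[tr]], cross[[col]],
                              sex = cross$sex, alpha = alpha)
        cbind(trait = tr, gc$table, overall_p = gc$overall_p)
      })
      utils::write.csv(do.call(rbind, tabs),
                       file.path(out_dir, paste0("assoc_", locus, ".csv")),
                       row.names = FALSE)
    }
  }

  if ("corr" %in% stages && "d_hat" %in% names(pheno)) {
    cross <- pheno[pheno$line == "KR", , drop = FALSE]
    ct <- pearson_correlation(cross$bw_g, cross$d_hat)
    utils::write.csv(
      data.frame(x = "bw_g", y = "d_hat", r = ct$r, p = ct$p, n = ct$n),
      file.path(out_dir, "correlation.csv"), row.names = FALSE)
    out$correlation <- ct
  }

  manifest <- list(
    command = "run_pipeline",
    config_hash = unname(tools::md5sum(write_config_tmp(config))),
    input_checksums = as.list(tools::md5sum(inputs)),
    seed = config$seed %||% NA,
    package_version = as.character(utils::packageVersion("kradom")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$varcomp <- vc
  out$mme <- sol
  invisible(out)
}

# canonical serialization of the config for hashing
write_config_tmp <- function(config) {
  f <- tempfile(fileext = ".yaml")
  config <- config[order(names(config))]
  config$stages <- NULL
  yaml::write_yaml(config, f)
  f
}
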