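#' Default two-locus marker design
#'
#' Founder genotype frequencies at the growth-hormone (GH, alleles A1/A3)
#' and IGF-I (alleles A/C) loci, per parental line, matching the genotype
#' groups used to design the sire-line x dam-line matings (sire line LK,
#' dam line SUT). Counts are used as sampling weights for founder genotypes;
#' offspring genotypes follow by Mendelian transmission.
#'
#' @return a named list with one entry per locus: `alleles` and
#'   `founder_freq` (per-line named genotype weights).
#' @export
default_marker_design <- function() {
  list(
    gh = list(
      alleles = c("A1", "A3"),
      founder_freq = list(
        LK = c(A1A1 = 13, A3A3 = 48),
        SUT = c(A1A1 = 57, A3A3 = 34)
      )
    ),
    igf1 = list(
      alleles = c("A", "C"),
      founder_freq = list(
        LK = c(AC = 18, CC = 63),
        SUT = c(AA = 143, CC = 25)
      )
    )
  )
}

#' Simulation configuration
#'
#' Defines a two-line crossbreeding design (sire line LK x dam line SUT ->
#' cross KR) with known ground truth. Defaults are study-shaped: 142 LK
#' sires, 259 SUT dams, variance components of six-week body weight
#' (sigma2_a = 14250, sigma2_d = 3315, sigma2_e = 713 grams^2), and line
#' mean offsets giving 25% midparent heterosis.
#'
#' @param n_sires number of sire-line (LK) males available for the cross.
#' @param n_dams number of dam-line (SUT) females.
#' @param n_offspring_per_mating crossbred offspring per mating pair (>= 1).
#' @param n_generations total generations including the cross (>= 2);
#'   generations before the final one are bred within line.
#' @param sigma2_a,sigma2_d,sigma2_e true variance components (grams^2).
#' @param mu baseline mean (grams).
#' @param line_mean_offsets named line -> grams offsets (creates true
#'   heterosis when the cross offset exceeds the parental average).
#' @param sex_effects,hatch_effects named fixed-effect sizes (grams); hatch
#'   levels are assigned round-robin, sexes 50:50.
#' @param age_wk age label attached to the phenotype records (weeks).
#' @param markers marker design, see [default_marker_design()].
#' @param marker_effects optional named list per locus, each a numeric
#'   vector with elements `add` and `dom` in grams: `add` is half the
#'   difference between the
#'   two homozygotes (positive favors the first allele), `dom` the
#'   heterozygote deviation from the homozygote midpoint. `NULL` (default)
#'   simulates null markers.
#' @param seed integer seed; all generator functions derive their streams
#'   from it, so outputs are bit-reproducible.
#' @return a validated list of class `kr_sim_config`.
#' @export
simulation_config <- function(n_sires = 142L, n_dams = 259L,
                              n_offspring_per_mating = 2L,
                              n_generations = 2L,
                              sigma2_a = 14250, sigma2_d = 3315,
                              sigma2_e = 713,
                              mu = 572,
                              line_mean_offsets = c(LK = 28, SUT = -28,
                                                    KR = 143),
                              sex_effects = c(M = 30, F = -30),
                              hatch_effects = c(H1 = -15, H2 = 0, H3 = 15),
                              age_wk = 6L,
                              markers = default_marker_design(),
                              marker_effects = NULL,
                              seed = 1L) {
  if (n_sires < 1 || n_dams < 1) stop("need at least one founder per line")
  if (n_offspring_per_mating < 1) stop("n_offspring_per_mating must be >= 1")
  if (n_generations < 2) stop("n_generations must be >= 2")
  if (any(c(sigma2_a, sigma2_d, sigma2_e) < 0))
    stop("variance components must be >= 0")
  structure(list(
    n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
    n_offspring_per_mating = as.integer(n_offspring_per_mating),
    n_generations = as.integer(n_generations),
    sigma2_a = sigma2_a, sigma2_d = sigma2_d, sigma2_e = sigma2_e,
    mu = mu, line_mean_offsets = line_mean_offsets,
    sex_effects = sex_effects, hatch_effects = hatch_effects,
    age_wk = as.integer(age_wk), markers = markers,
    marker_effects = marker_effects, seed = as.integer(seed)
  ), class = "kr_sim_config")
}

#' Simulate a crossbreeding pedigree
#'
#' Generation 1 founders are line LK males and line SUT females (for deeper
#' pedigrees, each pre-final generation carries both sexes per line and is
#' bred within line). In the final generation each SUT dam is paired with an
#' LK sire round-robin and produces `n_offspring_per_mating` KR offspring
#' with sex alternating 50:50 and hatch dates assigned round-robin. The
#' returned pedigree is topologically ordered by construction and
#' reproducible from the config seed.
#'
#' @param cfg a [simulation_config()].
#' @return a `kr_pedigree`.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "kr_sim_config"))
  G <- cfg$n_generations
  hatches <- names(cfg$hatch_effects)
  rr <- function(n, values) values[((seq_len(n) - 1L) %% length(values)) + 1L]

  rows <- list()
  line_members <- list()  # line -> list(males = ids, females = ids) per gen
  with_seed(cfg$seed + 11L, {
    for (line in c("LK", "SUT")) {
      n_line <- if (line == "LK") cfg$n_sires else cfg$n_dams
      prev <- NULL
      for (g in seq_len(G - 1L)) {
        if (G == 2L) {
          sexes <- rep(if (line == "LK") "M" else "F", n_line)
        } else {
          sexes <- rep(c("M", "F"), each = n_line)
        }
        n_g <- length(sexes)
        ids <- sprintf("%s%d_%04d", line, g, seq_len(n_g))
        if (is.null(prev)) {
          sire <- dam <- rep(NA_character_, n_g)
        } else {
          sire <- sample(prev$males, n_g, replace = TRUE)
          dam <- sample(prev$females, n_g, replace = TRUE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          animal = ids, sire = sire, dam = dam, line = line,
          sex = sexes, hatch = rr(n_g, hatches), generation = g,
          stringsAsFactors = FALSE)
        prev <- list(males = ids[sexes == "M"], females = ids[sexes == "F"])
      }
      line_members[[line]] <- prev
    }
  })
  sires <- line_members$LK$males
  dams <- line_members$SUT$females
  if (!length(sires) || !length(dams))
    stop("internal error: no cross parents generated")

  n_kr <- cfg$n_dams * cfg$n_offspring_per_mating
  dam_of <- rep(dams, each = cfg$n_offspring_per_mating)
  sire_idx <- ((match(dam_of, dams) - 1L) %% length(sires)) + 1L
  kr <- data.frame(
    animal = sprintf("KR%d_%05d", G, seq_len(n_kr)),
    sire = sires[sire_idx], dam = dam_of, line = "KR",
    sex = rr(n_kr, c("M", "F")), hatch = rr(n_kr, hatches),
    generation = G, stringsAsFactors = FALSE)
  as_pedigree(do.call(rbind, c(rows, list(kr))))
}

# split a genotype string like "A1A3" into its two alleles (longest-first
# greedy match against the locus allele set)
parse_genotype <- function(g, alleles) {
  al <- alleles[order(-nchar(alleles))]
  out <- character(0)
  rest <- g
  while (nzchar(rest)) {
    hit <- al[startsWith(rest, al)][1]
    if (is.na(hit)) stop("cannot parse genotype '", g, "'")
    out <- c(out, hit)
    rest <- substring(rest, nchar(hit) + 1L)
  }
  if (length(out) != 2L) stop("genotype '", g, "' is not biallelic")
  out
}

genotype_string <- function(a1, a2, alleles) {
  pair <- c(a1, a2)[order(match(c(a1, a2), alleles))]
  paste0(pair, collapse = "")
}

#' Simulate marker genotypes by Mendelian transmission
#'
#' Founders draw a genotype from their line's genotype-group weights in the
#' marker design; every non-founder receives one allele from each parent by
#' Mendelian sampling. A founder belonging to a line with no genotype
#' assignment is an error.
#'
#' @param ped a topologically ordered `kr_pedigree`.
#' @param cfg a [simulation_config()].
#' @param founder_genotypes optional data frame (`animal` plus
#'   `<locus>_genotype` columns) overriding the sampled founder genotypes.
#' @return a data frame with `animal` and one `<locus>_genotype` column per
#'   locus.
#' @export
simulate_marker_genotypes <- function(ped, cfg, founder_genotypes = NULL) {
  stopifnot(inherits(ped, "kr_pedigree"), inherits(cfg, "kr_sim_config"))
  if (!is_topologically_ordered(ped))
    stop("pedigree is not topologically ordered")
  ids <- ped$animal
  q <- length(ids)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  is_founder <- is.na(si) & is.na(di)
  if (any(is.na(si) != is.na(di)))
    stop("animals with exactly one known parent are not supported by the marker simulator")
  out <- data.frame(animal = ids, stringsAsFactors = FALSE)

  with_seed(cfg$seed + 23L, {
    for (locus in names(cfg$markers)) {
      spec <- cfg$markers[[locus]]
      col <- paste0(locus, "_genotype")
      a1 <- a2 <- character(q)
      for (i in seq_len(q)) {
        if (is_founder[i]) {
          g <- NULL
          if (!is.null(founder_genotypes) &&
              ids[i] %in% founder_genotypes$animal) {
            g <- founder_genotypes[[col]][
              match(ids[i], founder_genotypes$animal)]
          } else {
            freq <- spec$founder_freq[[ped$line[i]]]
            if (is.null(freq))
              stop("founder ", ids[i], " (line ", ped$line[i],
                   ") has no genotype assignment at locus ", locus)
            g <- sample(names(freq), 1L, prob = freq)
          }
          al <- parse_genotype(g, spec$alleles)
          a1[i] <- al[1]; a2[i] <- al[2]
        } else {
          s <- si[i]; d <- di[i]
          a1[i] <- if (stats::runif(1) < 0.5) a1[s] else a2[s]
          a2[i] <- if (stats::runif(1) < 0.5) a1[d] else a2[d]
        }
      }
      out[[col]] <- mapply(genotype_string, a1, a2,
                           MoreArgs = list(alleles = spec$alleles),
                           USE.NAMES = FALSE)
    }
  })
  out
}

#' Simulate additive and dominance genetic effects
#'
#' Draws the true additive values from a zero-mean multivariate normal with
#' covariance `A * sigma2_a` and the dominance deviations with covariance
#' `D * sigma2_d`, via Cholesky factorization with jitter escalation. A zero
#' variance yields an exact zero vector. Drawing directly from the
#' relationship-structured normal is exactly the covariance structure the
#' analysis model assumes, which makes parameter recovery a clean test.
#'
#' @param ped a `kr_pedigree`.
#' @param A,D relationship matrices of the pedigree (either may be `NULL`
#'   when the corresponding variance is zero).
#' @param cfg a [simulation_config()].
#' @return a data frame with columns `animal`, `a`, `d`.
#' @export
simulate_genetic_effects <- function(ped, A, D, cfg) {
  stopifnot(inherits(ped, "kr_pedigree"), inherits(cfg, "kr_sim_config"))
  q <- nrow(ped)
  draw <- function(M, s2) {
    if (s2 == 0) return(rep(0, q))
    if (is.null(M)) stop("relationship matrix required when variance > 0")
    if (nrow(M) != q) stop("relationship matrix does not match the pedigree")
    U <- chol_jitter(unclass(M))
    as.numeric(crossprod(U, stats::rnorm(q))) * sqrt(s2)
  }
  with_seed(cfg$seed + 37L, {
    a <- draw(A, cfg$sigma2_a)
    d <- draw(D, cfg$sigma2_d)
  })
  data.frame(animal = ped$animal, a = a, d = d, stringsAsFactors = FALSE)
}

# additive + dominance marker contribution to the phenotype for one locus
marker_contribution <- function(geno, alleles, eff) {
  n1 <- vapply(geno, function(g) sum(parse_genotype(g, alleles) == alleles[1]),
               numeric(1))
  add <- unname(eff["add"]) * (n1 - 1)
  dom <- unname(eff["dom"]) * as.numeric(n1 == 1)
  add + dom
}

#' Simulate phenotypes
#'
#' `y = mu + line offset + sex effect + hatch effect + a + d + (marker
#' effects) + e`, with `e` i.i.d. normal with variance `sigma2_e`. Every
#' animal in the pedigree receives one record at `cfg$age_wk`.
#'
#' @param ped a `kr_pedigree`.
#' @param truth data frame from [simulate_genetic_effects()].
#' @param cfg a [simulation_config()].
#' @param genotypes optional data frame from [simulate_marker_genotypes()];
#'   its columns are carried into the phenotype table (and contribute to the
#'   phenotype when `cfg$marker_effects` is set).
#' @return a phenotype data frame with columns `animal`, `line`, `sex`,
#'   `hatch`, `generation`, `age_wk`, `bw_g` plus any genotype columns.
#' @export
simulate_phenotypes <- function(ped, truth, cfg, genotypes = NULL) {
  stopifnot(inherits(ped, "kr_pedigree"), inherits(cfg, "kr_sim_config"))
  if (!identical(truth$animal, ped$animal))
    stop("truth table does not align with the pedigree")
  q <- nrow(ped)
  lookup <- function(values, keys) {
    out <- values[keys]
    out[is.na(out)] <- 0
    unname(out)
  }
  y <- cfg$mu +
    lookup(cfg$line_mean_offsets, ped$line) +
    lookup(cfg$sex_effects, ped$sex) +
    lookup(cfg$hatch_effects, ped$hatch) +
    truth$a + truth$d
  if (!is.null(genotypes) && !is.null(cfg$marker_effects)) {
    for (locus in names(cfg$marker_effects)) {
      col <- paste0(locus, "_genotype")
      y <- y + marker_contribution(genotypes[[col]][
        match(ped$animal, genotypes$animal)],
        cfg$markers[[locus]]$alleles, cfg$marker_effects[[locus]])
    }
  }
  y <- y + with_seed(cfg$seed + 53L,
                     stats::rnorm(q, 0, sqrt(cfg$sigma2_e)))
  out <- data.frame(animal = ped$animal, line = ped$line, sex = ped$sex,
                    hatch = ped$hatch, generation = ped$generation,
                    age_wk = cfg$age_wk, bw_g = y,
                    stringsAsFactors = FALSE)
  if (!is.null(genotypes))
    out <- merge(out, genotypes, by = "animal", sort = FALSE)
  out[match(ped$animal, out$animal), , drop = FALSE]
}

#' Simulate a complete dataset
#'
#' Runs the full generator: pedigree, relationship matrices (skipped when
#' both genetic variances are zero), marker genotypes, genetic effects and
#' phenotypes, all reproducible from `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @param markers simulate marker genotypes (default `TRUE`).
#' @return a list of class `kr_sim`: `pedigree`, `phenotypes`, `truth`,
#'   `A`, `D` (may be `NULL`), `config`.
#' @export
simulate_dataset <- function(cfg, markers = TRUE) {
  stopifnot(inherits(cfg, "kr_sim_config"))
  ped <- simulate_pedigree(cfg)
  A <- D <- NULL
  if (cfg$sigma2_a > 0 || cfg$sigma2_d > 0) {
    A <- additive_relationship_matrix(ped)
    if (cfg$sigma2_d > 0) D <- dominance_relationship_matrix(ped, A)
  }
  truth <- simulate_genetic_effects(ped, A, D, cfg)
  geno <- if (markers) simulate_marker_genotypes(ped, cfg) else NULL
  pheno <- simulate_phenotypes(ped, truth, cfg, genotypes = geno)
  structure(list(pedigree = ped, phenotypes = pheno, truth = truth,
                 A = A, D = D, config = cfg),
            class = "kr_sim")
}

#' Write a simulated dataset to CSV files
#'
#' Produces `ped.csv`, `pheno.csv` and `truth.csv` in `dir`.
#'
#' @param sim a `kr_sim` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "kr_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pedigree(sim$pedigree, file.path(dir, "ped.csv"))
  utils::write.csv(sim$phenotypes, file.path(dir, "pheno.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a phenotype CSV
#'
#' Long format, one row per animal x age; numeric columns (`bw_g`,
#' `age_wk`) are coerced, everything else kept as character.
#'
#' @param path CSV path.
#' @return a data frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$animal <- trimws(as.character(d$animal))
  for (col in intersect(c("bw_g", "age_wk"), names(d)))
    d[[col]] <- as.numeric(d[[col]])
  d
}
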