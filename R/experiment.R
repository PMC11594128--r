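# End-to-end experiment orchestration: simulate -> QC -> trait -> scenario ->
# GBLUP -> accuracy/bias, over replicates, emitting one long results tibble.

#' Configure a replicated prediction experiment
#'
#' Three experiment families cover the study designs:
#' * `"cross_pairs"` — for each breed pair, a reference of `n_ref_a` breed-A
#'   plus `n_ref_b` breed-B individuals predicts held-out individuals of both
#'   breeds; accuracy is `cor(GEBV, TBV)`. Reproduces the
#'   consistency-vs-accuracy grid.
#' * `"added_b"` — one breed pair, a grid over the number of B individuals
#'   added to a 400-A reference. Reproduces the added-reference design
#'   (`n_b = 0` rows are the pure within-A design).
#' * `"scenario_cv"` — replicated k-fold cross-validation of arbitrary
#'   reference compositions (within-breed, k-means group, or pooled
#'   scenarios); accuracy is `cor(adjusted y, GEBV)`.
#'
#' Traits are simulated per replicate (QTL draw shared across the
#' heritability grid, as the study simulates three traits per scenario) and
#' phenotypes are scaled per breed so each breed's realized heritability
#' matches the target. GBLUP always runs with the simulation-truth variance
#' components computed on the reference set.
#'
#' @param type experiment family (above).
#' @param panels named list of [haplotype_panel()] objects.
#' @param pairs tibble with columns `a`, `b` (cross_pairs) or a single pair
#'   (`added_b`).
#' @param scenarios list of `scenario_spec` objects (scenario_cv).
#' @param h2 heritability grid.
#' @param strategy trait architecture: a preset name or a
#'   [trait_architecture()] object.
#' @param n_sim resampled population size per breed.
#' @param block_len resampling block length.
#' @param n_ref_a,n_ref_b,n_val cross-design sizes.
#' @param n_b_grid added-B grid.
#' @param replicates trait replicates.
#' @param redraw_scenario draw a fresh reference/validation split every
#'   replicate (default) or fix one split per pair and replicate only the
#'   trait, which reuses the relationship matrix across replicates.
#' @param folds,cv_repeats CV layout for scenario_cv.
#' @param qc apply [qc_filter()] to the analysis genotypes.
#' @param consistency_window_bp window for the reported phase consistency.
#' @param seed global seed; every stage seed derives from it.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(type = c("cross_pairs", "added_b", "scenario_cv"),
                              panels, pairs = NULL, scenarios = NULL,
                              h2 = c(0.1, 0.3, 0.6), strategy = "II",
                              n_sim = 1500, block_len = 500,
                              n_ref_a = 400, n_ref_b = 200, n_val = 200,
                              n_b_grid = c(0, 100, 200, 300, 400),
                              replicates = 5, folds = 5, cv_repeats = 5,
                              qc = TRUE, consistency_window_bp = 1e5,
                              redraw_scenario = TRUE, seed = 1) {
  type <- match.arg(type)
  if (type %in% c("cross_pairs", "added_b") && is.null(pairs)) {
    stop_input("cross designs need a `pairs` tibble with columns a, b")
  }
  if (type == "scenario_cv" && is.null(scenarios)) {
    stop_input("scenario_cv needs a list of scenario_spec objects")
  }
  structure(
    list(type = type, panels = panels, pairs = pairs, scenarios = scenarios,
         h2 = h2, strategy = strategy, n_sim = n_sim, block_len = block_len,
         n_ref_a = n_ref_a, n_ref_b = n_ref_b, n_val = n_val,
         n_b_grid = sort(unique(n_b_grid)), replicates = replicates,
         folds = folds, cv_repeats = cv_repeats, qc = qc,
         consistency_window_bp = consistency_window_bp,
         redraw_scenario = redraw_scenario, seed = seed),
    class = "experiment_config"
  )
}

#' Run a configured experiment
#'
#' Orchestrates the full pipeline over all replicates and returns a long
#' results table suitable for trend summaries and plotting.
#'
#' @param config an [experiment_config()].
#' @return A tibble with one row per evaluated validation set:
#'   `experiment`, `breed_a`, `breed_b`, `consistency`, `h2`, `strategy`,
#'   `replicate`, `val_breed` (or `fold`/`rep` for CV), `n_ref_a`, `n_ref_b`,
#'   `n_val`, `accuracy`, `bias`, `mode`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  switch(config$type,
    cross_pairs = run_cross_pairs(config),
    added_b = run_added_b(config),
    scenario_cv = run_scenario_cv(config)
  )
}

# Accept either a preset name or a full trait_architecture in config$strategy.
config_arch <- function(config) {
  if (inherits(config$strategy, "trait_architecture")) config$strategy
  else trait_architecture(config$strategy)
}

arch_label <- function(config) config_arch(config)$strategy

# Resample a breed panel to the analysis population size, seeded by breed.
expand_breed <- function(config, breed) {
  resample_population(config$panels[[breed]], n_out = config$n_sim,
                      block_len = config$block_len,
                      seed = derive_seed(config$seed, paste0("resample_", breed)))
}

# Per-breed phenotype simulation from one TBV vector: each breed's Ve is set
# from its own realized TBV variance so realized h2 matches the target
# within every breed.
simulate_breed_phenotypes <- function(tbv, breed_labels, h2, seed) {
  parts <- lapply(unique(breed_labels), function(b) {
    rows <- which(breed_labels == b)
    ph <- simulate_phenotypes(tbv[rows], h2, seed = derive_seed(seed, b))
    dplyr::mutate(ph, breed = b)
  })
  dplyr::bind_rows(parts)
}

# Joint QC wrapper returning the (possibly) filtered genotype matrix.
maybe_qc <- function(geno, apply_qc) {
  if (!apply_qc) return(geno)
  qc_filter(geno)$genotypes
}

# Truth variance components on the reference set.
truth_varcomp <- function(pheno, ref_ids) {
  rows <- match(ref_ids, pheno$sample_id)
  list(sigma_g2 = stats::var(pheno$tbv[rows]),
       sigma_e2 = stats::var(pheno$e[rows]))
}

eval_validation <- function(fit, pheno, val_tbl, mode) {
  purrr::map_dfr(split(val_tbl, val_tbl$breed), function(v) {
    gv <- gebv(fit, v$sample_id)
    rows <- match(v$sample_id, pheno$sample_id)
    yadj <- unname(adjusted_phenotype(fit, pheno, v$sample_id))
    truth <- if (mode == "cor_tbv_gebv") pheno$tbv[rows] else yadj
    tibble::tibble(val_breed = v$breed[1], n_val = nrow(v),
                   accuracy = accuracy(truth, gv),
                   bias = bias_slope(yadj, gv),
                   mode = mode)
  })
}

run_cross_pairs <- function(config) {
  purrr::map_dfr(seq_len(nrow(config$pairs)), function(k) {
    a <- config$pairs$a[k]
    b <- config$pairs$b[k]
    pop <- maybe_qc(bind_genotypes(expand_breed(config, a), expand_breed(config, b)),
                    config$qc)
    cons <- pair_consistency(pop, a, b, config$consistency_window_bp)
    samples <- tibble::tibble(sample_id = pop$sample_ids, breed = pop$breed_labels)
    spec <- scenario_cross(a, b, config$n_ref_a, config$n_ref_b, config$n_val)
    fixed <- if (!config$redraw_scenario) {
      scen <- build_scenario(spec, samples,
                             seed = derive_seed(config$seed, paste0("scen", k)))
      list(scen = scen, grm = compute_grm(subset_individuals(pop, scen$sample_id)))
    }
    purrr::map_dfr(seq_len(config$replicates), function(r) {
      rep_seed <- derive_seed(config$seed, sprintf("pair%d_rep%d", k, r))
      qtl <- sample_qtls(pop$map, config_arch(config),
                         seed = derive_seed(rep_seed, "qtl"))
      tbv <- compute_tbv(pop, qtl)
      if (is.null(fixed)) {
        scen <- build_scenario(spec, samples, seed = derive_seed(rep_seed, "scen"))
        grm <- compute_grm(subset_individuals(pop, scen$sample_id))
      } else {
        scen <- fixed$scen
        grm <- fixed$grm
      }
      ref <- scen[scen$role == "reference", ]
      val <- scen[scen$role == "validation", ]
      form <- if (length(unique(ref$breed)) > 1) y ~ breed else y ~ 1
      purrr::map_dfr(config$h2, function(h2) {
        pheno <- simulate_breed_phenotypes(tbv, pop$breed_labels, h2,
                                           seed = derive_seed(rep_seed, paste0("ph", h2)))
        vc <- truth_varcomp(pheno, ref$sample_id)
        fit <- solve_gblup(pheno, grm, train_ids = ref$sample_id,
                           predict_ids = val$sample_id, formula = form,
                           sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2)
        res <- eval_validation(fit, pheno, val, "cor_tbv_gebv")
        dplyr::mutate(res,
          experiment = "cross_pairs", breed_a = a, breed_b = b,
          consistency = cons, h2 = h2, strategy = arch_label(config),
          replicate = r, n_ref_a = config$n_ref_a, n_ref_b = config$n_ref_b,
          .before = 1)
      })
    })
  })
}

run_added_b <- function(config) {
  a <- config$pairs$a[1]
  b <- config$pairs$b[1]
  pop <- maybe_qc(bind_genotypes(expand_breed(config, a), expand_breed(config, b)),
                  config$qc)
  cons <- pair_consistency(pop, a, b, config$consistency_window_bp)
  samples <- tibble::tibble(sample_id = pop$sample_ids, breed = pop$breed_labels)
  nb_max <- max(config$n_b_grid)
  purrr::map_dfr(seq_len(config$replicates), function(r) {
    rep_seed <- derive_seed(config$seed, sprintf("addb_rep%d", r))
    qtl <- sample_qtls(pop$map, config_arch(config),
                       seed = derive_seed(rep_seed, "qtl"))
    tbv <- compute_tbv(pop, qtl)
    spec <- scenario_cross(a, b, config$n_ref_a, nb_max, config$n_val)
    scen <- build_scenario(spec, samples, seed = derive_seed(rep_seed, "scen"))
    grm <- compute_grm(subset_individuals(pop, scen$sample_id))
    ref_a <- scen$sample_id[scen$role == "reference" & scen$breed == a]
    ref_b <- scen$sample_id[scen$role == "reference" & scen$breed == b]
    val <- scen[scen$role == "validation", ]
    purrr::map_dfr(config$h2, function(h2) {
      pheno <- simulate_breed_phenotypes(tbv, pop$breed_labels, h2,
                                         seed = derive_seed(rep_seed, paste0("ph", h2)))
      purrr::map_dfr(config$n_b_grid, function(nb) {
        train <- c(ref_a, ref_b[seq_len(nb)])
        form <- if (nb > 0) y ~ breed else y ~ 1
        vc <- truth_varcomp(pheno, train)
        fit <- solve_gblup(pheno, grm, train_ids = train,
                           predict_ids = val$sample_id, formula = form,
                           sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2)
        res <- eval_validation(fit, pheno, val, "cor_tbv_gebv")
        dplyr::mutate(res,
          experiment = "added_b", breed_a = a, breed_b = b,
          consistency = cons, h2 = h2, strategy = arch_label(config),
          replicate = r, n_ref_a = config$n_ref_a, n_ref_b = nb,
          .before = 1)
      })
    })
  })
}

run_scenario_cv <- function(config) {
  pops <- new.env(parent = emptyenv())
  get_pop <- function(breed) {
    if (is.null(pops[[breed]])) pops[[breed]] <- expand_breed(config, breed)
    pops[[breed]]
  }
  purrr::map_dfr(config$scenarios, function(spec) {
    breeds <- names(spec$reference)
    full <- lapply(breeds, get_pop)
    samples <- dplyr::bind_rows(lapply(full, function(p) {
      tibble::tibble(sample_id = p$sample_ids, breed = p$breed_labels)
    }))
    names(full) <- breeds
    purrr::map_dfr(seq_len(config$replicates), function(r) {
      rep_seed <- derive_seed(config$seed, paste0(spec$name, "_rep", r))
      scen <- build_scenario(spec, samples, seed = derive_seed(rep_seed, "scen"))
      sub <- bind_genotypes(lapply(breeds, function(b) {
        ids <- scen$sample_id[scen$breed == b]
        subset_individuals(full[[b]], ids)
      }))
      sub <- maybe_qc(sub, config$qc)
      qtl <- sample_qtls(sub$map, config_arch(config),
                         seed = derive_seed(rep_seed, "qtl"))
      tbv <- compute_tbv(sub, qtl)
      grm <- compute_grm(sub)
      form <- if (length(breeds) > 1) y ~ breed else y ~ 1
      purrr::map_dfr(config$h2, function(h2) {
        pheno <- simulate_breed_phenotypes(tbv, sub$breed_labels, h2,
                                           seed = derive_seed(rep_seed, paste0("ph", h2)))
        vc <- truth_varcomp(pheno, scen$sample_id)
        cv <- cross_validate(pheno, grm, ref_ids = scen$sample_id,
                             formula = form, folds = config$folds,
                             repeats = config$cv_repeats,
                             sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2,
                             seed = derive_seed(rep_seed, paste0("cv", h2)))
        dplyr::mutate(cv,
          experiment = spec$name, breed_a = paste(breeds, collapse = "+"),
          breed_b = NA_character_, consistency = NA_real_, h2 = h2,
          strategy = arch_label(config), replicate = r, mode = "cor_y_gebv",
          .before = 1)
      })
    })
  })
}

# Phase consistency between the two breeds of a combined phased population.
pair_consistency <- function(pop, a, b, window_bp) {
  pa <- as_haplotype_panel(subset_individuals(pop, which(pop$breed_labels == a)),
                           breed_id = a)
  pb <- as_haplotype_panel(subset_individuals(pop, which(pop$breed_labels == b)),
                           breed_id = b)
  phase_consistency(pa, pb, window_bp = window_bp)$consistency
}

#' Summarise an experiment results table
#'
#' Mean and standard error of accuracy and bias over replicates, grouped by
#' the design cells present in the table.
#'
#' @param results tibble from [run_experiment()].
#' @param ... grouping columns (defaults to the design cell columns found).
#' @return aggregated tibble.
#' @export
summarize_experiment <- function(results, ...) {
  groups <- rlang::enquos(...)
  if (length(groups) == 0) {
    cand <- intersect(c("experiment", "breed_a", "breed_b", "consistency",
                        "h2", "strategy", "n_ref_a", "n_ref_b", "val_breed"),
                      names(results))
    groups <- rlang::syms(cand)
  }
  dplyr::summarise(
    dplyr::group_by(results, !!!groups),
    n = dplyr::n(),
    mean_accuracy = mean(.data$accuracy),
    se_accuracy = stats::sd(.data$accuracy) / sqrt(dplyr::n()),
    mean_bias = mean(.data$bias),
    se_bias = stats::sd(.data$bias) / sqrt(dplyr::n()),
    .groups = "drop"
  )
}
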