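#' Generate an ancestral haplotype pool
#'
#' Forward-in-time founder population for the breed simulator. Allele
#' frequencies are initialised uniformly on \[0.05, 0.95\] (no mutation is
#' simulated, so the uniform floor avoids immediate fixation), haplotypes are
#' drawn independently per marker, and the pool of `ancestral_ne` diploids
#' then random-mates for `burn_in` discrete generations with recombination
#' (crossovers per chromosome ~ Poisson(genetic length in Morgans), positions
#' uniform in cM, no interference). Drift during the burn-in builds
#' distance-dependent LD; the burn-in default of `ancestral_ne / 2`
#' generations produces cattle-chip-like LD at the default marker spacing
#' while keeping most markers polymorphic.
#'
#' @param n_hap number of haplotypes returned (even). If smaller than
#'   `2 * ancestral_ne`, a random subset of individuals is returned; if
#'   larger, extra offspring of the pool are generated.
#' @param map marker map (see [sim_genome()]).
#' @param ancestral_ne effective (census) size of the random-mating pool.
#' @param burn_in number of burn-in generations.
#' @param seed integer seed; the call is fully reproducible.
#' @return A [haplotype_panel()] with `breed_id = "ancestral"`.
#' @examples
#' map <- sim_genome(n_chrom = 1, markers_per_chrom = 200)
#' pool <- generate_ancestral_pool(100, map, ancestral_ne = 50, seed = 1)
#' @export
generate_ancestral_pool <- function(n_hap, map, ancestral_ne = 200,
                                    burn_in = ceiling(ancestral_ne / 2),
                                    seed = NULL) {
  validate_marker_map(map)
  if (n_hap %% 2 != 0 || n_hap < 2) stop_input("n_hap must be a positive even count")
  if (ancestral_ne < 2) stop_input("ancestral_ne must be at least 2")
  m <- nrow(map)
  with_seed(seed, {
    p0 <- runif(m, 0.05, 0.95)
    pool <- matrix(rbinom(2L * ancestral_ne * m, 1L, rep(p0, each = 2L * ancestral_ne)),
                   nrow = 2L * ancestral_ne, ncol = m)
    storage.mode(pool) <- "integer"
    if (burn_in > 0) {
      pool <- wf_generations_cpp(pool, as.integer(map$chrom), map$pos_cm,
                                 burn_in, matrix(0L, 0, m), 0)
    }
    out <- if (n_hap <= 2L * ancestral_ne) {
      keep <- sort(sample.int(ancestral_ne, n_hap / 2L))
      pool[as.vector(rbind(2L * keep - 1L, 2L * keep)), , drop = FALSE]
    } else {
      offspring_cpp(pool, as.integer(map$chrom), map$pos_cm, n_hap / 2L)
    }
    haplotype_panel(out, map, breed_id = "ancestral")
  })
}

#' Derive a breed from an ancestral pool by founder sampling, drift and
#' breed-specific admixture
#'
#' Samples `n_founders` diploids without replacement, random-mates them for
#' `generations` generations at constant size `n_founders`, then returns
#' `out_size` diploids (a subsample when `out_size <= n_founders`, one extra
#' round of offspring otherwise). Markers that fix during drift are retained;
#' QC is a separate stage.
#'
#' Besides drift, each generation every parent is, with probability
#' `migration_rate`, a migrant from a breed-specific donor pool whose LD
#' phase is independent of the ancestral pool (built by flipping the allele
#' labels of the ancestral haplotypes at a random half of the markers, which
#' preserves LD magnitude and allele-frequency spectrum while randomising
#' the sign of r). This emulates breeds sitting on an admixture gradient
#' between divergent lineages — the mechanism that lets between-breed phase
#' consistency span the full observed range: drift alone decorrelates phase
#' very slowly at short range, while admixed ancestry fractions compound as
#' `(1 - migration_rate)^generations` per branch.
#'
#' @param ancestral a [haplotype_panel()].
#' @param n_founders breed founder count (also the breeding population size).
#' @param generations generations of drift since the split.
#' @param out_size diploids in the returned panel.
#' @param breed_id label for the derived panel.
#' @param seed integer seed.
#' @param migration_rate per-parent, per-generation probability of a donor
#'   migrant (default 0.01).
#' @param donor_flips optional logical vector (one per marker) defining the
#'   breed's donor pool: the ancestral haplotypes with alleles relabelled at
#'   the flagged markers. When omitted a random half of the markers is
#'   flipped. Sharing (parts of) the flip vector between breeds makes their
#'   donors phase-correlated, which raises the pair's phase consistency
#'   without touching drift depth (see [make_breed_panels()]).
#' @return A [haplotype_panel()].
#' @export
derive_breed <- function(ancestral, n_founders, generations, out_size,
                         breed_id = "breed", seed = NULL,
                         migration_rate = 0.01, donor_flips = NULL) {
  stopifnot(inherits(ancestral, "haplotype_panel"))
  if (n_founders > n_ind(ancestral)) {
    stop_input("n_founders exceeds the ancestral panel size")
  }
  if (generations < 0) stop_input("generations must be >= 0")
  if (migration_rate < 0 || migration_rate >= 1) {
    stop_input("migration_rate must lie in [0, 1)")
  }
  map <- ancestral$map
  with_seed(seed, {
    founders <- subset_panel(ancestral, sort(sample.int(n_ind(ancestral), n_founders)))
    h <- founders$haplotypes
    if (generations > 0) {
      outgroup <- if (migration_rate > 0) {
        flip <- donor_flips %||% (runif(ncol(h)) < 0.5)
        stopifnot(length(flip) == ncol(h))
        og <- ancestral$haplotypes
        og[, flip] <- 1L - og[, flip]
        og
      } else {
        matrix(0L, 0, ncol(h))
      }
      h <- wf_generations_cpp(h, as.integer(map$chrom), map$pos_cm,
                              as.integer(generations), outgroup,
                              migration_rate)
    }
    out <- if (out_size <= n_founders) {
      keep <- sample.int(n_founders, out_size)
      h[as.vector(rbind(2L * keep - 1L, 2L * keep)), , drop = FALSE]
    } else {
      offspring_cpp(h, as.integer(map$chrom), map$pos_cm, as.integer(out_size))
    }
    haplotype_panel(out, map, breed_id = breed_id)
  })
}

# Mean phase consistency between two sibling breeds split g generations ago
# (shared founder sample, independent drift branches), averaged over n_mc
# Monte-Carlo replicates.
split_consistency <- function(ancestral, generations, n_founders, panel_size,
                              window_bp, n_mc, seed, migration_rate = 0.01) {
  vals <- vapply(seq_len(n_mc), function(r) {
    s <- derive_seed(seed, paste0("split", generations, "rep", r))
    with_seed(s, {
      founders <- subset_panel(
        ancestral, sort(sample.int(n_ind(ancestral), n_founders))
      )
      a <- derive_breed(founders, n_founders, generations, panel_size,
                        breed_id = "a", seed = derive_seed(s, "a"),
                        migration_rate = migration_rate)
      b <- derive_breed(founders, n_founders, generations, panel_size,
                        breed_id = "b", seed = derive_seed(s, "b"),
                        migration_rate = migration_rate)
      # Panels drifted to (near-)fixation share no polymorphic pairs; that is
      # the zero-consistency limit, not a failure of the search.
      tryCatch(phase_consistency(a, b, window_bp = window_bp)$consistency,
               crossblup_input_error = function(e) 0)
    })
  }, numeric(1))
  mean(vals)
}

#' Calibrate breed divergence to a target phase consistency
#'
#' Finds, by bisection, the number of post-split drift generations `g` such
#' that two sibling breeds (shared founders, independent Wright-Fisher
#' branches of size `n_founders`) show a cor100-style phase consistency within
#' `tolerance` of `target_consistency`. Relies on consistency being
#' monotonically non-increasing in `g`. Panels of `panel_size` individuals
#' (default 70, the usual minimum for a reliable LD-consistency estimate) are
#' used for the Monte-Carlo measurement.
#'
#' @param ancestral a [haplotype_panel()].
#' @param target_consistency target in (0, 1).
#' @param tolerance acceptable absolute deviation of the Monte-Carlo mean.
#' @param seed integer seed.
#' @param n_founders breeding size of each branch.
#' @param panel_size individuals per measured panel.
#' @param window_bp pair-distance window for consistency (default 100 kb).
#' @param n_mc Monte-Carlo replicates per evaluated `g`.
#' @param g_max upper search bound on generations.
#' @param migration_rate breed-specific admixture rate (see [derive_breed()]).
#' @return A list with `generations`, `consistency` (Monte-Carlo mean at the
#'   returned value), and the evaluated `trace` tibble.
#' @export
calibrate_divergence <- function(ancestral, target_consistency,
                                 tolerance = 0.05, seed = NULL,
                                 n_founders = 70, panel_size = 70,
                                 window_bp = 1e5, n_mc = 3, g_max = 256,
                                 migration_rate = 0.01) {
  if (target_consistency <= 0 || target_consistency >= 1) {
    stop_input("target_consistency must lie strictly between 0 and 1")
  }
  seed <- seed %||% 1L
  trace <- list()
  eval_g <- function(g) {
    v <- split_consistency(ancestral, g, n_founders, panel_size,
                           window_bp, n_mc, seed, migration_rate)
    trace[[length(trace) + 1]] <<- tibble::tibble(generations = g, consistency = v)
    v
  }
  lo <- 0L
  hi <- as.integer(g_max)
  c_lo <- eval_g(lo)
  if (abs(c_lo - target_consistency) <= tolerance) {
    return(list(generations = lo, consistency = c_lo,
                trace = dplyr::bind_rows(trace)))
  }
  if (c_lo < target_consistency - tolerance) {
    stop_input(sprintf(
      "target %.3f unreachable: consistency at 0 generations is only %.3f",
      target_consistency, c_lo))
  }
  # Expand the bracket geometrically instead of probing g_max directly:
  # evaluating g costs O(g), so early doubling keeps the search cheap.
  hi <- 16L
  c_hi <- eval_g(hi)
  while (c_hi > target_consistency && hi < g_max) {
    lo <- hi
    c_lo <- c_hi
    hi <- min(2L * hi, as.integer(g_max))
    c_hi <- eval_g(hi)
  }
  if (abs(c_hi - target_consistency) <= tolerance) {
    return(list(generations = hi, consistency = c_hi,
                trace = dplyr::bind_rows(trace)))
  }
  if (c_hi > target_consistency + tolerance) {
    stop_input(sprintf(
      "target %.3f unreachable: consistency still %.3f after %d generations (bracket [%d, %d])",
      target_consistency, c_hi, hi, lo, hi))
  }
  best <- if (abs(c_hi - target_consistency) < abs(c_lo - target_consistency)) {
    list(generations = hi, consistency = c_hi)
  } else {
    list(generations = lo, consistency = c_lo)
  }
  while (hi - lo > 1) {
    mid <- as.integer(floor((lo + hi) / 2))
    c_mid <- eval_g(mid)
    if (abs(c_mid - target_consistency) < abs(best$consistency - target_consistency)) {
      best <- list(generations = mid, consistency = c_mid)
    }
    if (abs(c_mid - target_consistency) <= tolerance) {
      return(list(generations = mid, consistency = c_mid,
                  trace = dplyr::bind_rows(trace)))
    }
    if (c_mid > target_consistency) lo <- mid else hi <- mid
  }
  if (abs(best$consistency - target_consistency) <= tolerance) {
    return(c(best, list(trace = dplyr::bind_rows(trace))))
  }
  stop_input(sprintf(
    "bisection exhausted: best consistency %.3f at %d generations for target %.3f (bracket [%d, %d])",
    best$consistency, best$generations, target_consistency, lo, hi))
}

#' Configuration for a multi-breed panel set
#'
#' Defaults reproduce the study design this package emulates: ten Chinese
#' indigenous cattle breeds with panel sizes 21-26 (MGC 21, YHC 24, CDM 25,
#' XZC 26, PWC 24, LSC 22, ZTC 23, WSC 24, HNC 26, NDC 25), a desk-scale
#' 10-chromosome genome, an ancestral pool of 200 diploids, and per-breed
#' split generations spanning enough drift to cover pairwise phase
#' consistencies from roughly 0.1 to 0.5.
#'
#' @param breed_ids character vector of breed labels.
#' @param panel_sizes diploid count per breed panel.
#' @param split_generations per-breed drift generations since the shared split.
#' @param donor_affinity optional per-breed weights in \[0, 1\] correlating
#'   the breeds' admixture donors: breed b's donor flip vector copies a
#'   global flip vector at a fraction `donor_affinity[b]` of markers and is
#'   random elsewhere, so the donor-phase correlation of breeds a and b is
#'   `(donor_affinity[a] * donor_affinity[b])^2`. This varies pairwise phase
#'   consistency while every breed keeps the same drift depth (and hence the
#'   same within-breed diversity). `NULL` (default) gives every breed an
#'   independent donor.
#' @param n_founders founder/breeding size of every breed branch.
#' @param migration_rate breed-specific admixture rate during divergence
#'   (see [derive_breed()]).
#' @param ancestral_ne ancestral pool size.
#' @param burn_in ancestral burn-in generations.
#' @param map marker map; defaults to the desk-scale genome.
#' @param seed global seed for the set.
#' @return A `breed_set_config` list.
#' @export
breed_set_config <- function(
    breed_ids = c("simmg", "simyh", "simcdm", "simxz", "simpw",
                  "simls", "simzt", "simws", "simhn", "simnd"),
    panel_sizes = c(21, 24, 25, 26, 24, 22, 23, 24, 26, 25),
    split_generations = rep(100L, length(breed_ids)),
    donor_affinity = if (length(breed_ids) == 10) {
      c(1, 1, 0.95, 0.9, 0.85, 0.8, 0.7, 0.6, 0.45, 0.25)
    },
    n_founders = 70,
    migration_rate = 0.01,
    ancestral_ne = 200,
    burn_in = ceiling(ancestral_ne / 2),
    map = sim_genome(),
    seed = 1) {
  if (anyDuplicated(breed_ids)) stop_input("duplicate breed_id in configuration")
  if (length(panel_sizes) != length(breed_ids) ||
      length(split_generations) != length(breed_ids)) {
    stop_input("panel_sizes and split_generations must match breed_ids in length")
  }
  if (!is.null(donor_affinity) &&
      (length(donor_affinity) != length(breed_ids) ||
       any(donor_affinity < 0 | donor_affinity > 1))) {
    stop_input("donor_affinity needs one weight in [0, 1] per breed")
  }
  if (any(panel_sizes < 1)) stop_input("panel sizes must be >= 1")
  if (any(split_generations < 0)) stop_input("split_generations must be >= 0")
  if (n_founders > ancestral_ne) {
    stop_input("n_founders cannot exceed the ancestral pool size")
  }
  structure(
    list(breed_ids = breed_ids, panel_sizes = as.integer(panel_sizes),
         split_generations = as.integer(split_generations),
         donor_affinity = donor_affinity,
         n_founders = as.integer(n_founders),
         migration_rate = migration_rate,
         ancestral_ne = as.integer(ancestral_ne),
         burn_in = as.integer(burn_in), map = map, seed = seed),
    class = "breed_set_config"
  )
}

#' Generate one haplotype panel per configured breed
#'
#' All breeds share one founder sample from the ancestral pool and then drift
#' independently for their configured number of generations, so the pairwise
#' divergence of breeds `i` and `j` is governed by
#' `split_generations[i] + split_generations[j]`.
#'
#' @param config a [breed_set_config()].
#' @param ancestral optional pre-built ancestral pool (a [haplotype_panel()]);
#'   generated from the config when omitted.
#' @return A named list of [haplotype_panel()] objects.
#' @export
make_breed_panels <- function(config = breed_set_config(), ancestral = NULL) {
  stopifnot(inherits(config, "breed_set_config"))
  if (is.null(ancestral)) {
    ancestral <- generate_ancestral_pool(
      2L * config$ancestral_ne, config$map,
      ancestral_ne = config$ancestral_ne, burn_in = config$burn_in,
      seed = derive_seed(config$seed, "ancestral")
    )
  }
  founders <- with_seed(derive_seed(config$seed, "founders"), {
    subset_panel(ancestral,
                 sort(sample.int(n_ind(ancestral), config$n_founders)))
  })
  m <- nrow(config$map)
  global_flips <- with_seed(derive_seed(config$seed, "global_flips"),
                            runif(m) < 0.5)
  panels <- purrr::map2(config$breed_ids, seq_along(config$breed_ids), function(id, i) {
    flips <- if (!is.null(config$donor_affinity)) {
      with_seed(derive_seed(config$seed, paste0("flips_", id)), {
        keep <- runif(m) < config$donor_affinity[i]
        ifelse(keep, global_flips, runif(m) < 0.5)
      })
    }
    derive_breed(founders, config$n_founders, config$split_generations[i],
                 config$panel_sizes[i], breed_id = id,
                 seed = derive_seed(config$seed, paste0("breed_", id)),
                 migration_rate = config$migration_rate,
                 donor_flips = flips)
  })
  stats::setNames(panels, config$breed_ids)
}
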