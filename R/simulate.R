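## Synthetic-data generators.  The coalescent simulator is implemented
## directly (exponential coalescence times, uniform mutation placement on
## branches, infinite sites) so that the diversity estimators can be tested
## against analytically known expectations; the island model uses standard
## rate competition between within-deme coalescence and migration.

#' Parameters for the coalescent sequence simulator
#'
#' @param n_samples Number of haploid sequences (>= 2).
#' @param theta Population mutation rate per locus (`2*Ne*u*L` for
#'   haploids), >= 0.
#' @param seq_length Number of sites (>= 1).
#' @param n_demes Number of demes (1 = panmictic neutral coalescent).
#' @param migration_rate Scaled migration rate per lineage per coalescent
#'   time unit (>= 0).  With `n_demes > 1` and `migration_rate = 0` the
#'   demes are treated as long-isolated populations that merge into a
#'   single ancestral deme at a deep fixed time.
#' @param seed Optional integer seed (same seed, identical output).
#' @return An object of class `"coalescent_params"`.
#' @export
coalescent_params <- function(n_samples, theta, seq_length,
                              n_demes = 1L, migration_rate = 1,
                              seed = NULL) {
  if (n_samples < 2L) stop("coalescent_params: n_samples must be >= 2")
  if (theta < 0) stop("coalescent_params: theta must be >= 0")
  if (seq_length < 1L) stop("coalescent_params: seq_length must be >= 1")
  if (n_demes < 1L) stop("coalescent_params: n_demes must be >= 1")
  if (migration_rate < 0) stop("coalescent_params: migration_rate must be >= 0")
  structure(list(n_samples = as.integer(n_samples), theta = theta,
                 seq_length = as.integer(seq_length),
                 n_demes = as.integer(n_demes),
                 migration_rate = migration_rate, seed = seed),
            class = "coalescent_params")
}

## Simulate a coalescent genealogy.  Returns a list of edges
## (parent, child, length) plus per-sample deme labels.  Time is measured
## in units of 2N generations per deme; within-deme coalescence occurs at
## rate choose(k_d, 2) and each lineage migrates at rate migration_rate.
.sim_genealogy <- function(n, n_demes, mig) {
  node_deme <- rep_len(seq_len(n_demes), n)      # initial deme labels
  sample_deme <- node_deme
  active <- seq_len(n)
  deme <- node_deme
  next_node <- n + 1L
  t <- 0
  parent <- integer(0); child <- integer(0); blen <- numeric(0)
  node_time <- numeric(n)       # sample tips at time 0
  merged <- FALSE
  repeat {
    k <- length(active)
    if (k == 1L) break
    kd <- tabulate(deme, n_demes)
    coal_rate <- sum(choose(kd, 2))
    mig_rate <- if (n_demes > 1L && !merged) k * mig else 0
    tot <- coal_rate + mig_rate
    if (tot == 0) {
      ## isolated demes with no further within-deme coalescence possible:
      ## merge all lineages into one ancestral deme at a deep time
      t <- t + 20
      deme[] <- 1L
      merged <- TRUE
      next
    }
    t <- t + stats::rexp(1L, tot)
    if (stats::runif(1L) < coal_rate / tot) {
      ## coalescence: pick a deme weighted by choose(kd,2), then a pair
      d <- sample.int(n_demes, 1L, prob = choose(kd, 2))
      in_d <- which(deme == d)
      pair <- if (length(in_d) == 2L) in_d else sample(in_d, 2L)
      anc <- next_node; next_node <- next_node + 1L
      node_time <- c(node_time, t)
      parent <- c(parent, anc, anc)
      child <- c(child, active[pair[1L]] , active[pair[2L]])
      ## edge lengths filled in afterwards from node times
      active <- c(active[-pair], anc)
      deme <- c(deme[-pair], d)
    } else {
      i <- sample.int(k, 1L)
      new_d <- sample.int(n_demes, 1L)
      deme[i] <- new_d
    }
  }
  blen <- node_time[parent] - node_time[child]
  list(parent = parent, child = child, blen = blen,
       node_time = node_time, sample_deme = sample_deme,
       n_nodes = next_node - 1L)
}

#' Simulate an alignment under the neutral (or island-model) coalescent
#'
#' Builds a Kingman coalescent genealogy (single deme) or a structured
#' island-model genealogy (symmetric migration among equal demes), then
#' drops mutations on branches as a Poisson process with rate `theta/2`
#' per unit branch length and places each mutation at a distinct site
#' (infinite sites: every segregating site is biallelic).  Under this
#' scaling `E[S] = theta * a1` with `a1` the harmonic number of
#' `n_samples - 1`.
#'
#' @param params A `coalescent_params`.
#' @return A `locus_alignment` with `deme` labels attached; attribute
#'   `"n_mutations"` records the mutation count before site collision
#'   handling (equal to S).
#' @examples
#' aln <- simulate_coalescent(coalescent_params(10, 5, 500, seed = 1))
#' segregating_sites(aln)
#' @export
simulate_coalescent <- function(params) {
  stopifnot(inherits(params, "coalescent_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_samples
  g <- .sim_genealogy(n, params$n_demes, params$migration_rate)

  total_len <- sum(g$blen)
  n_mut <- stats::rpois(1L, params$theta / 2 * total_len)
  n_mut <- min(n_mut, params$seq_length)   # infinite sites needs free sites

  ## descendants of each edge's child node
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, params$seq_length, replace = TRUE)
  mat <- matrix(rep(anc, each = n), nrow = n)

  if (n_mut > 0L) {
    ## choose an edge per mutation, weighted by branch length
    edges <- sample.int(length(g$blen), n_mut, replace = TRUE,
                        prob = g$blen)
    sites <- sample.int(params$seq_length, n_mut)   # distinct sites
    kids_of <- vector("list", g$n_nodes)
    for (e in seq_along(g$parent))
      kids_of[[g$parent[e]]] <- c(kids_of[[g$parent[e]]], g$child[e])
    desc <- vector("list", g$n_nodes)
    for (node in seq_len(g$n_nodes))      # children precede parents
      desc[[node]] <- if (node <= n) node else
        unlist(desc[kids_of[[node]]], use.names = FALSE)
    descendants <- function(node) desc[[node]]
    for (i in seq_len(n_mut)) {
      carriers <- descendants(g$child[edges[i]])
      site <- sites[i]
      derived <- sample(setdiff(bases, anc[site]), 1L)
      mat[carriers, site] <- derived
    }
  }
  out <- locus_alignment(mat,
                         strains = sprintf("sim%03d", seq_len(n)),
                         deme = g$sample_deme)
  attr(out, "n_mutations") <- n_mut
  out
}

#' Parameters for the three-phase growth-curve generator
#'
#' @param lag_h Lag (population adaptation time) in hours, >= 0.
#' @param mu_max Maximum specific growth rate per hour, > 0.
#' @param od_start,od_final Initial and asymptotic optical density,
#'   `od_final > od_start > 0`.
#' @param noise_sd SD of additive Gaussian measurement noise (OD units).
#' @param sample_interval_min Sampling interval in minutes (default 20).
#' @param duration_h Total duration in hours (typically 48 or 72).
#' @param seed Optional integer seed.
#' @return An object of class `"growth_params"`.
#' @export
growth_params <- function(lag_h = 4, mu_max = 0.35, od_start = 0.1,
                          od_final = 1.3, noise_sd = 0.01,
                          sample_interval_min = 20, duration_h = 48,
                          seed = NULL) {
  if (!(od_final > od_start && od_start > 0))
    stop("growth_params: need od_final > od_start > 0")
  if (mu_max <= 0) stop("growth_params: mu_max must be > 0")
  if (lag_h < 0) stop("growth_params: lag_h must be >= 0")
  if (sample_interval_min <= 0)
    stop("growth_params: sample_interval_min must be > 0")
  structure(list(lag_h = lag_h, mu_max = mu_max, od_start = od_start,
                 od_final = od_final, noise_sd = noise_sd,
                 sample_interval_min = sample_interval_min,
                 duration_h = duration_h, seed = seed),
            class = "growth_params")
}

#' Simulate a microcultivation growth curve
#'
#' Three-phase model: OD stays at `od_start` until `lag_h`, grows
#' exponentially at rate `mu_max`, and saturates at `od_final` (the
#' exponential capped at the asymptote, so log(OD) is exactly piecewise
#' linear in the noise-free case and the ground-truth lag, rate and
#' efficiency are analytic).  Additive Gaussian noise; values are floored
#' at 0.001 so downstream log transforms stay defined.
#'
#' @param params A `growth_params`.
#' @param strain,environment,run Labels attached to the curve.
#' @return An object of class `"growth_curve"`: list with `time_min`,
#'   `od`, labels and the generating parameters.
#' @export
simulate_growth_curve <- function(params, strain = "sim", environment = "YES",
                                  run = 1L) {
  stopifnot(inherits(params, "growth_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  time_min <- seq(0, params$duration_h * 60, by = params$sample_interval_min)
  t_h <- time_min / 60
  od <- ifelse(t_h <= params$lag_h, params$od_start,
               pmin(params$od_start * exp(params$mu_max * (t_h - params$lag_h)),
                    params$od_final))
  if (params$noise_sd > 0)
    od <- od + stats::rnorm(length(od), 0, params$noise_sd)
  od <- pmax(od, 0.001)
  structure(list(strain = strain, environment = environment, run = run,
                 time_min = time_min, od = od, blank = 0,
                 params = params),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %s / %s run %s: %d points over %.1f h\n",
              x$strain, x$environment, x$run, length(x$od),
              max(x$time_min) / 60))
  invisible(x)
}

#' Parameters for the planted-structure trait-matrix generator
#'
#' @param n_strains,n_traits Matrix dimensions.
#' @param n_groups Number of planted groups (`<= n_strains`).
#' @param group_effect_sd SD of per-group, per-trait mean effects.
#' @param noise_sd SD of per-strain residual noise.
#' @param outlier_ids Strain indices given planted deviant traits.
#' @param outlier_fraction Fraction of traits shifted in each outlier
#'   (in `[0, 1]`).
#' @param outlier_shift Size of the planted shift in units of `noise_sd`
#'   (default 5; must be >= 3 so outliers are separable).
#' @param seed Optional integer seed.
#' @return An object of class `"trait_matrix_params"`.
#' @export
trait_matrix_params <- function(n_strains = 40L, n_traits = 126L,
                                n_groups = 4L, group_effect_sd = 1,
                                noise_sd = 0.25, outlier_ids = integer(0),
                                outlier_fraction = 0.2, outlier_shift = 5,
                                seed = NULL) {
  if (n_groups > n_strains)
    stop("trait_matrix_params: n_groups must be <= n_strains")
  if (outlier_fraction < 0 || outlier_fraction > 1)
    stop("trait_matrix_params: outlier_fraction must be in [0, 1]")
  if (outlier_shift < 3)
    stop("trait_matrix_params: outlier_shift must be >= 3 (noise SD units)")
  structure(list(n_strains = as.integer(n_strains),
                 n_traits = as.integer(n_traits),
                 n_groups = as.integer(n_groups),
                 group_effect_sd = group_effect_sd, noise_sd = noise_sd,
                 outlier_ids = as.integer(outlier_ids),
                 outlier_fraction = outlier_fraction,
                 outlier_shift = outlier_shift, seed = seed),
            class = "trait_matrix_params")
}

#' Simulate a strain-by-trait matrix with planted group structure
#'
#' Each entry is a group mean (drawn once per group and trait from
#' `N(0, group_effect_sd)`) plus strain-level noise `N(0, noise_sd)`.
#' Planted outlier strains additionally have a random `outlier_fraction`
#' of their traits shifted by `outlier_shift * noise_sd` (random sign).
#'
#' @param params A `trait_matrix_params`.
#' @return List with `matrix` (strains x traits), `group` (ground-truth
#'   labels), `outliers`, and `shifted_traits` (named list per outlier).
#' @export
simulate_trait_matrix <- function(params) {
  stopifnot(inherits(params, "trait_matrix_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  ns <- params$n_strains; nt <- params$n_traits; ng <- params$n_groups
  group <- rep_len(seq_len(ng), ns)
  gmeans <- matrix(stats::rnorm(ng * nt, 0, params$group_effect_sd), ng, nt)
  m <- gmeans[group, , drop = FALSE] +
    matrix(stats::rnorm(ns * nt, 0, params$noise_sd), ns, nt)
  shifted <- list()
  for (id in params$outlier_ids) {
    k <- max(1L, round(params$outlier_fraction * nt))
    tr <- sample.int(nt, k)
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    m[id, tr] <- m[id, tr] + sgn * params$outlier_shift * params$noise_sd
    shifted[[as.character(id)]] <- sort(tr)
  }
  rownames(m) <- sprintf("strain%02d", seq_len(ns))
  colnames(m) <- sprintf("trait%03d", seq_len(nt))
  list(matrix = m, group = stats::setNames(group, rownames(m)),
       outliers = params$outlier_ids, shifted_traits = shifted)
}
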