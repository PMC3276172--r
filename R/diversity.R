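## Per-locus diversity and neutrality statistics for haploid sequence data.
## pi is the mean pairwise difference, Watterson's theta the S-based
## estimate, and Tajima's D their normalised difference; all follow the
## standard haploid (per-sequence) parameterisation.

#' Harmonic-number coefficients used by the S-based estimators
#' @param n Sample size (number of sequences).
#' @return `a1` = sum_{i=1}^{n-1} 1/i, computed by direct summation.
#' @keywords internal
harmonic_a1 <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1L))
}

## columns that count for diversity: A/C/G/T only
.valid_base <- function(x) x %in% c("A", "C", "G", "T")

#' Segregating sites of an alignment
#'
#' A segregating site is a column with more than one distinct valid base
#' (gaps and `N` are ignored; filtered alignments normally contain none).
#'
#' @param aln A `locus_alignment`.
#' @return Integer count `S`.
#' @export
segregating_sites <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  cnt <- .base_counts(aln$mat)
  sum(colSums(cnt > 0L) > 1L)
}

## 4 x L matrix of per-column A/C/G/T counts (vectorised)
.base_counts <- function(m) {
  rbind(A = colSums(m == "A"), C = colSums(m == "C"),
        G = colSums(m == "G"), T = colSums(m == "T"))
}

#' Nucleotide diversity pi (mean pairwise difference)
#'
#' Mean number of nucleotide differences over all n(n-1)/2 unordered pairs
#' of sequences, per sequence (`pi_seq`) and per site (`pi_site =
#' pi_seq / L`).  Site comparison is skipped within a pair where either
#' base is not A/C/G/T (pairwise deletion); on filtered alignments this is
#' identical to complete deletion.
#'
#' @param aln A `locus_alignment` with at least two sequences.
#' @return List with `pi_site`, `pi_seq`, `n`, `L`.
#' @export
pairwise_pi <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  n <- n_sequences(aln)
  if (n < 2L) stop("pairwise_pi: need at least 2 sequences")
  L <- n_sites(aln)
  total <- 0
  if (L > 0L) {
    ## per column: differing pairs = (n_valid choose 2) - sum_b (n_b choose 2)
    cnt <- .base_counts(aln$mat)
    nv <- colSums(cnt)
    total <- sum(choose(nv, 2) - colSums(choose(cnt, 2)))
  }
  npairs <- choose(n, 2)
  pi_seq <- total / npairs
  list(pi_site = if (L > 0L) pi_seq / L else 0, pi_seq = pi_seq, n = n, L = L)
}

#' Watterson's theta from the segregating-site count
#'
#' `theta_seq = S / a1` with `a1 = sum_{i=1}^{n-1} 1/i`;
#' `theta_site = theta_seq / L`.
#'
#' @param S Number of segregating sites.
#' @param n Number of sequences (>= 2).
#' @param L Number of sites (>= 1).
#' @return List with `theta_site`, `theta_seq`, `a1`.
#' @examples
#' watterson_theta(S = 21, n = 40, L = 719)$theta_site * 1e3  # 6.866
#' @export
watterson_theta <- function(S, n, L) {
  stopifnot(S >= 0, n >= 2, L >= 1)
  a1 <- harmonic_a1(n)
  theta_seq <- S / a1
  list(theta_site = theta_seq / L, theta_seq = theta_seq, a1 = a1)
}

#' Tajima's D
#'
#' `D = (pi_seq - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard
#' coefficient chain `a1, a2, b1, b2, c1, c2, e1, e2` evaluated by direct
#' summation.  Undefined (NaN, with a warning) when `S = 0`.
#'
#' @param pi_seq Mean pairwise difference per sequence.
#' @param S Number of segregating sites.
#' @param n Number of sequences (>= 4).
#' @return The statistic (numeric scalar).
#' @examples
#' tajimas_d(pi_seq = 1.603e-3 * 743, S = 12, n = 40)  # -1.7796
#' @export
tajimas_d <- function(pi_seq, S, n) {
  stopifnot(n >= 4, S >= 0)
  if (S == 0) {
    warning("tajimas_d: undefined for S = 0")
    return(NaN)
  }
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_seq - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Tajima's total variances of pi and theta estimates
#'
#' Standard deviations combining the evolutionary (coalescent) and sampling
#' variance, used for the +/- columns of a diversity table.  `Var(pi) =
#' b1*theta + b2*theta^2` and `Var(theta_W) = theta/a1 + (a2/a1^2)*theta^2`
#' on the per-sequence scale, each evaluated at its own estimate.
#'
#' @param pi_seq,theta_seq Per-sequence estimates.
#' @param n Sample size.
#' @return List with `sd_pi_seq`, `sd_theta_seq`.
#' @keywords internal
diversity_sds <- function(pi_seq, theta_seq, n) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  list(sd_pi_seq = sqrt(b1 * pi_seq + b2 * pi_seq^2),
       sd_theta_seq = sqrt(theta_seq / a1 + (a2 / a1^2) * theta_seq^2))
}

#' Effective population size from pi
#'
#' For haploids under neutrality, `pi = 2 * Ne * mu` per site, so
#' `Ne = pi_site / (2 * mu)`.
#'
#' @param pi_site Per-site nucleotide diversity.
#' @param mu Mutation rate per bp per generation (> 0); default the budding
#'   yeast rate 0.33e-9 commonly borrowed for fission yeast.
#' @return List with `pi_site`, `mu`, `ne` and `ne_rounded` (one
#'   significant figure, the headline reporting convention).
#' @examples
#' effective_population_size(7e-3)$ne_rounded  # 1e7
#' @export
effective_population_size <- function(pi_site, mu = 0.33e-9) {
  if (!is.numeric(mu) || mu <= 0)
    stop("effective_population_size: mu must be positive")
  if (pi_site < 0) stop("effective_population_size: pi_site must be >= 0")
  ne <- pi_site / (2 * mu)
  list(pi_site = pi_site, mu = mu, ne = ne, ne_rounded = signif(ne, 1))
}

#' Per-locus diversity summary table
#'
#' Computes n, L, S, pi, Watterson's theta (per site and per sequence),
#' their total-variance SDs and Tajima's D for each alignment.  By default
#' the statistics are computed over one representative sequence per
#' compound haplotype (collapse the supplied alignments first), mirroring
#' analyses that de-duplicate clonally resampled strains; set
#' `collapse = FALSE` to use all sequences.
#'
#' @param alns List of filtered `locus_alignment` objects.
#' @param collapse Reduce to haplotype representatives of the concatenated
#'   loci before computing? Default `TRUE`.
#' @param mu Mutation rate for the Ne column.
#' @return A `data.frame` with one row per locus: `locus, n, L, S, pi_site,
#'   pi_seq, sd_pi_seq, theta_site, theta_seq, sd_theta_seq, tajima_d, ne`.
#' @export
diversity_table <- function(alns, collapse = TRUE, mu = 0.33e-9) {
  if (inherits(alns, "locus_alignment")) alns <- list(alns)
  if (collapse && n_sequences(alns[[1L]]) > 2L) {
    ht <- collapse_haplotypes(alns)
    reps <- haplotype_representatives(ht)
    if (length(reps) >= 2L) {   # degenerate: everything one haplotype
      alns <- lapply(alns, function(a) {
        locus_alignment(a$mat[match(reps, a$strains), , drop = FALSE],
                        strains = reps, locus = a$locus)
      })
    }
  }
  rows <- lapply(seq_along(alns), function(i) {
    a <- alns[[i]]
    nm <- if (!is.null(a$locus)) a$locus$name else paste0("locus", i)
    S <- segregating_sites(a)
    p <- pairwise_pi(a)
    th <- watterson_theta(S, p$n, p$L)
    sds <- diversity_sds(p$pi_seq, th$theta_seq, p$n)
    D <- if (S > 0 && p$n >= 4) tajimas_d(p$pi_seq, S, p$n) else NA_real_
    data.frame(locus = nm, n = p$n, L = p$L, S = S,
               pi_site = p$pi_site, pi_seq = p$pi_seq,
               sd_pi_seq = sds$sd_pi_seq,
               theta_site = th$theta_site, theta_seq = th$theta_seq,
               sd_theta_seq = sds$sd_theta_seq,
               tajima_d = D,
               ne = effective_population_size(p$pi_site, mu)$ne,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
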