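## Reference-relative trait matrices and their downstream analyses:
## average-linkage clustering on 1 - Pearson distance, within- vs
## between-group similarity tests, atypicality ranking against the mean
## profile, and FDR-controlled per-trait deviation fractions.

#' Build a reference-relative trait matrix
#'
#' A trait is a fitness component in an environment; each entry is
#' `log2(strain value / reference value)` for that trait, so the reference
#' strain's own row is identically zero and positive entries mean a larger
#' raw value than the reference.
#'
#' @param components Data frame with columns `strain, environment` and one
#'   column per fitness component (e.g. `lag_h, doubling_h, efficiency`);
#'   one row per strain x environment (replicates pre-averaged).
#' @param reference Label of the reference strain; must be present in
#'   every environment.
#' @param component_cols Which component columns to spread into traits;
#'   default all numeric columns apart from the keys.
#' @return A strains x traits numeric matrix of class `"trait_matrix"`
#'   (trait names `component.environment`); missing measurements give
#'   `NA` entries.
#' @export
build_trait_matrix <- function(components, reference,
                               component_cols = NULL) {
  stopifnot(all(c("strain", "environment") %in% names(components)))
  if (is.null(component_cols)) {
    component_cols <- setdiff(names(components)[vapply(components,
      is.numeric, logical(1))], c("run"))
  }
  if (!reference %in% components$strain)
    stop("build_trait_matrix: reference strain '", reference, "' absent")
  strains <- unique(components$strain)
  envs <- unique(components$environment)
  ref_rows <- components[components$strain == reference, , drop = FALSE]
  if (!all(envs %in% ref_rows$environment))
    stop("build_trait_matrix: reference missing in environment(s): ",
         paste(setdiff(envs, ref_rows$environment), collapse = ", "))
  traits <- as.vector(outer(component_cols, envs, paste, sep = "."))
  m <- matrix(NA_real_, length(strains), length(traits),
              dimnames = list(strains, traits))
  for (e in envs) {
    re <- ref_rows[ref_rows$environment == e, , drop = FALSE][1L, ]
    se <- components[components$environment == e, , drop = FALSE]
    for (cc in component_cols) {
      refv <- re[[cc]]
      tname <- paste(cc, e, sep = ".")
      v <- se[[cc]]
      okv <- !is.na(v) & v > 0 & !is.na(refv) & refv > 0
      m[match(se$strain[okv], strains), tname] <- log2(v[okv] / refv)
    }
  }
  class(m) <- c("trait_matrix", class(m))
  m
}

## pairwise-complete centered Pearson correlation between strain rows
.profile_cor <- function(m, min_shared = 3L) {
  sds <- apply(m, 1L, stats::sd, na.rm = TRUE)
  flat <- !is.finite(sds) | sds == 0
  if (any(flat))
    stop("constant (zero-variance) trait profile(s): ",
         paste(rownames(m)[flat], collapse = ", "),
         " -- correlation undefined; drop them first")
  cc <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  shared <- tcrossprod(!is.na(unclass(m)) * 1)
  bad <- which(shared < min_shared & upper.tri(shared), arr.ind = TRUE)
  if (nrow(bad))
    stop("trait profiles share < ", min_shared, " traits for pair(s): ",
         paste(apply(bad, 1L, function(ij)
       paste(rownames(m)[ij], collapse = "/")), collapse = ", "))
  cc
}

#' Hierarchical clustering of trait profiles
#'
#' Distance is `1 - r` with `r` the centered Pearson correlation between
#' strain profiles (pairwise-complete over shared non-missing traits);
#' agglomeration is average linkage.  Ties are resolved deterministically
#' by `stats::hclust`'s ordering (smaller index first).
#'
#' @param tm A `trait_matrix` (or plain numeric matrix, strains in rows)
#'   with >= 3 strains.
#' @param min_shared Minimum shared traits per pair (default 3); pairs
#'   below this are an error naming the offenders.
#' @return An `hclust` object (plot with `plot()`, cut with `cutree()`).
#' @export
cluster_profiles <- function(tm, min_shared = 3L) {
  m <- unclass(tm)
  if (nrow(m) < 3L) stop("cluster_profiles: need >= 3 strains")
  cc <- .profile_cor(m, min_shared)
  d <- stats::as.dist(1 - cc)
  stats::hclust(d, method = "average")
}

#' Within- versus between-group profile similarity
#'
#' Splits all unordered strain pairs into same-group and different-group
#' sets by the given labels, reports mean pairwise Pearson correlation and
#' SEM for each set, and a two-sample t-test between them (Welch by
#' default, pooled-variance optionally).
#'
#' @param tm A `trait_matrix`.
#' @param grouping Named vector of group labels (haplotype id or origin),
#'   names matching the matrix rows.
#' @param var_equal Pooled-variance t-test? Default `FALSE` (Welch).
#' @return An object of class `"similarity_report"`: list with
#'   `within_mean, within_sem, n_within, between_mean, between_sem,
#'   n_between, t_statistic, p_value`.
#' @export
group_similarity <- function(tm, grouping, var_equal = FALSE) {
  m <- unclass(tm)
  grouping <- grouping[rownames(m)]
  if (anyNA(grouping))
    stop("group_similarity: grouping missing for some strains")
  cc <- .profile_cor(m)
  n <- nrow(m)
  same <- outer(grouping, grouping, "==")
  ut <- upper.tri(cc)
  within <- cc[ut & same]
  between <- cc[ut & !same]
  within <- within[!is.na(within)]; between <- between[!is.na(between)]
  if (!length(within)) stop("group_similarity: no same-group pairs")
  if (!length(between)) stop("group_similarity: no different-group pairs")
  tt <- stats::t.test(within, between, var.equal = var_equal)
  structure(list(within_mean = mean(within),
                 within_sem = stats::sd(within) / sqrt(length(within)),
                 n_within = length(within),
                 between_mean = mean(between),
                 between_sem = stats::sd(between) / sqrt(length(between)),
                 n_between = length(between),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, digits = 3, ...) {
  cat("<similarity_report>\n")
  cat(sprintf("  within-group  r: %.*f +/- %.*f SEM (%d pairs)\n",
              digits, x$within_mean, digits, x$within_sem, x$n_within))
  cat(sprintf("  between-group r: %.*f +/- %.*f SEM (%d pairs)\n",
              digits, x$between_mean, digits, x$between_sem, x$n_between))
  cat(sprintf("  t = %.*f, p = %.3g\n", digits, x$t_statistic, x$p_value))
  invisible(x)
}

#' Rank strains by atypicality against the mean trait profile
#'
#' Computes the per-trait mean profile over all strains
#' (pairwise-complete), then the Pearson correlation of each strain's
#' profile with the mean; strains are returned most-atypical first
#' (ascending correlation).
#'
#' @param tm A `trait_matrix` with >= 3 strains.
#' @return Data frame with columns `strain, similarity, rank`, ordered by
#'   ascending similarity (rank 1 = most atypical).
#' @export
atypicality_ranking <- function(tm) {
  m <- unclass(tm)
  if (nrow(m) < 3L) stop("atypicality_ranking: need >= 3 strains")
  mean_profile <- colMeans(m, na.rm = TRUE)
  r <- apply(m, 1L, function(row)
    suppressWarnings(stats::cor(row, mean_profile,
                                use = "pairwise.complete.obs")))
  ord <- order(r)
  out <- data.frame(strain = rownames(m)[ord], similarity = r[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fraction of traits on which a strain deviates from the population
#'
#' Per trait, the strain's replicate-level values are compared with the
#' pooled values of all other strains by a two-sample t-test; p-values are
#' Benjamini-Hochberg adjusted and the fraction of traits significant at
#' the given FDR is returned.
#'
#' @param replicates Data frame with columns `strain, trait, value`, one
#'   row per replicate measurement.
#' @param strain The focal strain label.
#' @param fdr FDR level (default 0.05).
#' @param var_equal Pooled-variance t-test? Default `FALSE` (Welch).
#' @return List with `fraction`, `n_significant`, `n_tested`, and the
#'   per-trait data frame `tests` (`trait, t, p, p_adj, significant`).
#'   Traits where the focal strain has < 2 replicates are skipped with a
#'   warning.
#' @export
deviant_trait_fraction <- function(replicates, strain, fdr = 0.05,
                                   var_equal = FALSE) {
  stopifnot(all(c("strain", "trait", "value") %in% names(replicates)))
  traits <- unique(replicates$trait)
  skipped <- 0L
  rows <- lapply(traits, function(tr) {
    d <- replicates[replicates$trait == tr, , drop = FALSE]
    xs <- d$value[d$strain == strain]
    ys <- d$value[d$strain != strain]
    xs <- xs[!is.na(xs)]; ys <- ys[!is.na(ys)]
    if (length(xs) < 2L || length(ys) < 2L) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    tt <- tryCatch(stats::t.test(xs, ys, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) {   # zero variance in both samples
      p <- if (isTRUE(all.equal(mean(xs), mean(ys)))) 1 else 0
      return(data.frame(trait = tr, t = NA_real_, p = p))
    }
    data.frame(trait = tr, t = unname(tt$statistic), p = tt$p.value)
  })
  if (skipped > 0L)
    warning("deviant_trait_fraction: skipped ", skipped,
            " trait(s) with < 2 replicates")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("deviant_trait_fraction: no testable traits")
  tests <- do.call(rbind, rows)
  tests$p_adj <- stats::p.adjust(tests$p, method = "BH")
  tests$significant <- tests$p_adj < fdr
  list(fraction = mean(tests$significant),
       n_significant = sum(tests$significant),
       n_tested = nrow(tests), tests = tests)
}
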