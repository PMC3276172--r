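## Population differentiation and linkage disequilibrium on haploid
## haplotype sequences.  Pairwise F_st defaults to the Hudson/AMOVA
## pairwise-difference form (the estimator haplotype-level AMOVA software
## uses, which can legitimately be negative); a Weir-Cockerham per-site
## option is provided.  LD statistics use the classical gametic 2x2 table without
## continuity correction, so chi2 = n * r^2 holds exactly.

#' Population assignment map
#'
#' Maps each sequence (or haplotype) to one or more populations; a
#' haplotype whose members have different known origins may be assigned
#' to several populations and then contributes one sequence to each.
#'
#' @param assignment Named list: sequence label -> character vector of
#'   population labels (>= 1 each).
#' @return An object of class `"population_map"` with `assignment`,
#'   `populations` and per-population `sizes`.
#' @export
population_map <- function(assignment) {
  if (is.character(assignment)) assignment <- as.list(assignment)
  if (is.null(names(assignment)) || any(names(assignment) == ""))
    stop("population_map: assignment must be a named list")
  if (any(lengths(assignment) < 1L))
    stop("population_map: every sequence needs >= 1 population")
  pops <- sort(unique(unlist(assignment)))
  sizes <- vapply(pops, function(p)
    sum(vapply(assignment, function(a) p %in% a, logical(1))), integer(1))
  structure(list(assignment = assignment, populations = pops,
                 sizes = stats::setNames(sizes, pops)),
            class = "population_map")
}

## mean pairwise difference between two sets of sequences (character rows)
.mean_diff <- function(m1, m2 = NULL) {
  if (is.null(m2)) {
    n <- nrow(m1)
    if (n < 2L) return(NA_real_)
    tot <- 0
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n)
        tot <- tot + sum(m1[i, ] != m1[j, ])
    tot / choose(n, 2)
  } else {
    tot <- 0
    for (i in seq_len(nrow(m1)))
      for (j in seq_len(nrow(m2)))
        tot <- tot + sum(m1[i, ] != m2[j, ])
    tot / (nrow(m1) * nrow(m2))
  }
}

#' Pairwise F_st between populations
#'
#' For each population pair, the default `"hudson"` estimator is the
#' pairwise-difference (AMOVA-style) form
#' `F_st = (pi_between - pi_within) / pi_between`, where `pi_within` is
#' the unweighted mean of the two within-population mean pairwise
#' differences and `pi_between` the mean difference across populations.
#' Negative estimates are retained.  `"weir-cockerham"` gives the
#' per-site variance-components estimator summed over sites.
#'
#' @param aln A `locus_alignment` of (concatenated, filtered) haplotype
#'   sequences.
#' @param pops A `population_map` over the alignment's strain labels.
#'   Multiply-assigned sequences enter each of their populations.
#' @param method `"hudson"` (default) or `"weir-cockerham"`.
#' @return An object of class `"fst_matrix"`: symmetric matrix with zero
#'   diagonal, labels from the map.  Populations with fewer than two
#'   members are excluded with a warning.
#' @export
pairwise_fst <- function(aln, pops, method = c("hudson", "weir-cockerham")) {
  stopifnot(inherits(aln, "locus_alignment"), inherits(pops, "population_map"))
  method <- match.arg(method)
  members <- lapply(pops$populations, function(p) {
    names(pops$assignment)[vapply(pops$assignment, function(a)
      p %in% a, logical(1))]
  })
  names(members) <- pops$populations
  members <- lapply(members, intersect, y = aln$strains)
  ok <- lengths(members) >= 2L
  if (any(!ok))
    warning("pairwise_fst: excluding populations with < 2 members: ",
            paste(names(members)[!ok], collapse = ", "))
  members <- members[ok]
  if (length(members) < 2L)
    stop("pairwise_fst: need >= 2 populations with >= 2 sequences")
  labs <- names(members)
  k <- length(labs)
  out <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      m1 <- aln$mat[match(members[[i]], aln$strains), , drop = FALSE]
      m2 <- aln$mat[match(members[[j]], aln$strains), , drop = FALSE]
      f <- if (method == "hudson") .fst_hudson(m1, m2) else .fst_wc(m1, m2)
      out[i, j] <- out[j, i] <- f
    }
  }
  structure(out, class = c("fst_matrix", "matrix"), method = method)
}

.fst_hudson <- function(m1, m2) {
  pw <- mean(c(.mean_diff(m1), .mean_diff(m2)))
  pb <- .mean_diff(m1, m2)
  if (!is.finite(pb) || pb == 0) return(0)
  (pb - pw) / pb
}

## Weir & Cockerham (1984) haploid per-site estimator, summed components
.fst_wc <- function(m1, m2) {
  r <- 2
  n1 <- nrow(m1); n2 <- nrow(m2)
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  num <- den <- 0
  for (j in seq_len(ncol(m1))) {
    alleles <- unique(c(m1[, j], m2[, j]))
    alleles <- alleles[alleles %in% c("A", "C", "G", "T")]
    if (length(alleles) < 2L) next
    for (a in alleles) {
      p1 <- mean(m1[, j] == a); p2 <- mean(m2[, j] == a)
      pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      ## haploid: no heterozygotes; MSP/MSG decomposition
      msp <- (r - 1) * nbar * s2 / (r - 1)
      msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 + n2 - r)
      num <- num + (msp - msg)
      den <- den + (msp + (nc - 1) * msg)
    }
  }
  if (den == 0) return(0)
  num / den
}

#' @export
print.fst_matrix <- function(x, digits = 3, ...) {
  cat("<fst_matrix> pairwise F_st (", attr(x, "method"), ")\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Parsimony-informative SNPs of an alignment
#'
#' Biallelic columns whose minor allele is carried by at least two
#' sequences.  Singleton variants and columns with three or more alleles
#' are excluded.  Positions are genome coordinates when the alignment
#' carries a `locus_def` (offset from `locus$start`), else column indices.
#'
#' @param aln A filtered `locus_alignment`.
#' @param min_minor Minimum minor-allele count (default 2).
#' @return Data frame with columns `position, column, allele1, allele2,
#'   minor_count` plus a `states` attribute: marker x sequence 0/1 matrix
#'   (1 = allele2, the minor allele at detection; `NA` for non-ACGT).
#' @export
informative_snps <- function(aln, min_minor = 2L) {
  stopifnot(inherits(aln, "locus_alignment"))
  m <- aln$mat
  rows <- list(); states <- list()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    valid <- .valid_base(col)
    tb <- table(col[valid])
    if (length(tb) != 2L) next
    tb <- sort(tb, decreasing = TRUE)
    if (tb[2L] < min_minor) next
    a1 <- names(tb)[1L]; a2 <- names(tb)[2L]
    pos <- if (!is.null(aln$locus)) aln$locus$start + j - 1L else j
    rows[[length(rows) + 1L]] <-
      data.frame(position = pos, column = j, allele1 = a1, allele2 = a2,
                 minor_count = as.integer(tb[2L]), stringsAsFactors = FALSE)
    st <- ifelse(valid, as.integer(col == a2), NA_integer_)
    states[[length(states) + 1L]] <- st
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), column = integer(0),
               allele1 = character(0), allele2 = character(0),
               minor_count = integer(0))
  if (length(states)) {
    sm <- do.call(rbind, states)
    dimnames(sm) <- list(as.character(out$position), aln$strains)
    attr(out, "states") <- sm
  } else {
    attr(out, "states") <- matrix(integer(0), 0, n_sequences(aln))
  }
  class(out) <- c("snp_markers", "data.frame")
  out
}

#' Pairwise linkage-disequilibrium statistics
#'
#' For every marker pair (0/1 states, missing excluded pairwise):
#' `D = p_AB - p_A*p_B`; `D' = D / D_max` with
#' `D_max = min(p_A*q_B, q_A*p_B)` for `D > 0` and
#' `min(p_A*p_B, q_A*q_B)` for `D < 0` (sign preserved);
#' `r = D / sqrt(p_A*q_A*p_B*q_B)`; `chi2 = n * r^2` with `n` the
#' pairwise-complete sample size (no continuity correction).
#' Significance stars mark chi-square (df = 1) thresholds at 0.05 (*),
#' 0.01 (**) and 0.001 (***).
#'
#' @param markers A `snp_markers` object (or its 0/1 `states` matrix,
#'   markers in rows).
#' @return An object of class `"ld_result"`: list of matrices `D, Dprime,
#'   r, chi2, n`, character matrix `stars`, logical `four_gamete`.
#' @export
ld_statistics <- function(markers) {
  sm <- if (inherits(markers, "snp_markers")) attr(markers, "states")
        else as.matrix(markers)
  k <- nrow(sm)
  if (k < 2L) stop("ld_statistics: need >= 2 markers")
  labs <- rownames(sm)
  if (is.null(labs)) labs <- paste0("m", seq_len(k))
  mk <- function() matrix(NA_real_, k, k, dimnames = list(labs, labs))
  D <- mk(); Dp <- mk(); r <- mk(); chi2 <- mk(); nn <- mk()
  stars <- matrix("", k, k, dimnames = list(labs, labs))
  fg <- matrix(NA, k, k, dimnames = list(labs, labs))
  crit <- stats::qchisq(c(0.95, 0.99, 0.999), df = 1)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- !is.na(sm[i, ]) & !is.na(sm[j, ])
      n <- sum(ok)
      a <- sm[i, ok]; b <- sm[j, ok]
      pA <- mean(a); pB <- mean(b)
      nn[i, j] <- nn[j, i] <- n
      gam <- unique(paste0(a, b))
      fg[i, j] <- fg[j, i] <- length(gam) == 4L
      if (n < 2L || pA %in% c(0, 1) || pB %in% c(0, 1)) next
      pAB <- mean(a == 1 & b == 1)
      d <- pAB - pA * pB
      dmax <- if (d >= 0) min(pA * (1 - pB), (1 - pA) * pB)
              else min(pA * pB, (1 - pA) * (1 - pB))
      D[i, j] <- D[j, i] <- d
      Dp[i, j] <- Dp[j, i] <- if (dmax > 0) d / dmax else 0
      rr <- d / sqrt(pA * (1 - pA) * pB * (1 - pB))
      r[i, j] <- r[j, i] <- rr
      x2 <- n * rr^2
      chi2[i, j] <- chi2[j, i] <- x2
      stars[i, j] <- stars[j, i] <-
        paste(rep("*", sum(x2 > crit)), collapse = "")
    }
  }
  structure(list(D = D, Dprime = Dp, r = r, chi2 = chi2, n = nn,
                 stars = stars, four_gamete = fg, markers = labs),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, digits = 3, ...) {
  k <- length(x$markers)
  cat(sprintf("<ld_result> %d markers, %d pairs\n", k, choose(k, 2)))
  cat("r (upper) / chi2 with significance (lower):\n")
  m <- matrix("", k, k, dimnames = list(x$markers, x$markers))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j > i) m[i, j] <- formatC(x$r[i, j], digits = digits, format = "g")
    if (j < i) m[i, j] <- paste0(
      formatC(x$chi2[i, j], digits = digits, format = "g"), x$stars[i, j])
  }
  print(m, quote = FALSE)
  invisible(x)
}

#' Four-gamete test and minimum-recombination bound
#'
#' A marker pair passes the four-gamete test (evidence of recombination
#' under infinite sites) iff all four gametic types are observed.  `Rm` is
#' the Hudson-Kaplan lower bound on the number of recombination events:
#' the maximum number of non-overlapping marker intervals whose endpoint
#' pair shows all four gametes, computed by the standard interval-reduction
#' (greedy left-to-right) rule on marker order.
#'
#' @param markers A `snp_markers` object or 0/1 states matrix (markers in
#'   rows, ordered along the chromosome).
#' @return List with `four_gamete` (logical matrix) and `rm` (integer).
#' @export
four_gamete_test <- function(markers) {
  sm <- if (inherits(markers, "snp_markers")) attr(markers, "states")
        else as.matrix(markers)
  k <- nrow(sm)
  if (k < 2L) stop("four_gamete_test: need >= 2 markers")
  labs <- rownames(sm); if (is.null(labs)) labs <- paste0("m", seq_len(k))
  fg <- matrix(FALSE, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- !is.na(sm[i, ]) & !is.na(sm[j, ])
      gam <- unique(paste0(sm[i, ok], sm[j, ok]))
      fg[i, j] <- fg[j, i] <- length(gam) == 4L
    }
  }
  ## Hudson-Kaplan greedy disjoint-interval count
  rm_count <- 0L
  left <- 1L
  while (left < k) {
    hit <- NA_integer_
    for (j in (left + 1L):k) {
      if (any(fg[left:(j - 1L), j])) { hit <- j; break }
    }
    if (is.na(hit)) break
    rm_count <- rm_count + 1L
    left <- hit                 # next interval must start at/after the hit
  }
  list(four_gamete = fg, rm = rm_count)
}
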