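#' Construct a locus alignment
#'
#' A strain-by-site character matrix over `{A,C,G,T,-,N}` for one locus.
#' All rows must have equal length and strain labels must be unique.
#'
#' @param mat Character matrix (strains in rows, sites in columns) or a
#'   character vector of equal-length sequences.
#' @param strains Strain labels; default taken from row names.
#' @param locus Optional `locus_def` describing the genomic interval.
#' @param deme Optional integer vector of deme labels (simulated data).
#' @return An object of class `"locus_alignment"` with elements `strains`,
#'   `mat`, `locus`, `deme`.
#' @export
locus_alignment <- function(mat, strains = NULL, locus = NULL, deme = NULL) {
  if (is.character(mat) && is.null(dim(mat))) {
    lens <- nchar(mat)
    if (length(unique(lens)) > 1L)
      stop("locus_alignment: sequences have unequal lengths")
    nm <- names(mat)
    mat <- do.call(rbind, strsplit(toupper(mat), ""))
    rownames(mat) <- nm
  }
  if (!is.matrix(mat) || !is.character(mat))
    stop("locus_alignment: 'mat' must be a character matrix")
  mat[] <- toupper(mat)
  if (is.null(strains)) strains <- rownames(mat)
  if (is.null(strains)) strains <- paste0("seq", seq_len(nrow(mat)))
  strains <- as.character(strains)
  if (length(strains) != nrow(mat))
    stop("locus_alignment: strain labels do not match row count")
  if (anyDuplicated(strains))
    stop("locus_alignment: duplicate strain labels: ",
         paste(unique(strains[duplicated(strains)]), collapse = ", "))
  rownames(mat) <- strains
  structure(list(strains = strains, mat = mat, locus = locus, deme = deme),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %d strains x %d sites",
              nrow(x$mat), ncol(x$mat)))
  if (!is.null(x$locus)) cat(sprintf("  [%s]", x$locus$name))
  cat("\n")
  invisible(x)
}

#' @export
dim.locus_alignment <- function(x) dim(x$mat)

#' Number of sequences / alignment width
#' @param aln A `locus_alignment`.
#' @return Integer count.
#' @export
n_sequences <- function(aln) nrow(aln$mat)

#' @rdname n_sequences
#' @export
n_sites <- function(aln) ncol(aln$mat)

#' Read an aligned FASTA file for one locus
#'
#' Records must be equal length (the file is an alignment, not raw reads);
#' bases are uppercased and input strain order is preserved.
#'
#' @param path Path to an aligned FASTA file.
#' @param locus Optional `locus_def` to attach.
#' @return A `locus_alignment`.
#' @export
read_locus_fasta <- function(path, locus = NULL) {
  if (!file.exists(path)) stop("read_locus_fasta: file not found: ", path)
  dna <- tryCatch(suppressWarnings(
    ape::read.dna(path, format = "fasta", as.character = TRUE,
                  as.matrix = FALSE)),
    error = function(e) stop("read_locus_fasta: ", conditionMessage(e)))
  if (length(dna) == 0L) stop("read_locus_fasta: empty FASTA: ", path)
  lens <- vapply(dna, length, integer(1))
  if (length(unique(lens)) > 1L)
    stop("read_locus_fasta: ragged record lengths (not an alignment): ", path)
  mat <- do.call(rbind, dna)
  rownames(mat) <- names(dna)
  locus_alignment(mat, locus = locus)
}

#' Write a locus alignment as FASTA
#' @param aln A `locus_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "locus_alignment"))
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", aln$strains[i]), seqs[[i]]), con)
  invisible(path)
}

#' Site filter specification
#'
#' Describes which alignment columns to drop before analysis: columns
#' containing gaps (indel stripping), explicitly masked column ranges
#' (micro/minisatellite tracts), and columns containing missing bases.
#'
#' @param drop_indel_columns Drop any column containing `-`? Default `TRUE`.
#' @param masked_ranges List of `c(start, end)` 1-based inclusive column
#'   intervals to remove.
#' @param drop_missing_columns Drop any column containing `N`? Default `TRUE`
#'   (a conservative identity test for haplotype collapse).
#' @return An object of class `"site_filter"`.
#' @export
site_filter <- function(drop_indel_columns = TRUE, masked_ranges = list(),
                        drop_missing_columns = TRUE) {
  if (length(masked_ranges) && !all(vapply(masked_ranges, length, 1L) == 2L))
    stop("site_filter: masked_ranges must be c(start, end) pairs")
  structure(list(drop_indel_columns = isTRUE(drop_indel_columns),
                 masked_ranges = masked_ranges,
                 drop_missing_columns = isTRUE(drop_missing_columns)),
            class = "site_filter")
}

#' Apply a site filter to an alignment
#'
#' Removes masked column ranges, then columns containing any gap when
#' `drop_indel_columns` (complete deletion of indel columns), then columns
#' containing any `N` when `drop_missing_columns`.
#'
#' @param aln A `locus_alignment`.
#' @param filter A `site_filter`.
#' @return The filtered `locus_alignment`; attribute `"retained_sites"`
#'   records the surviving column count.
#' @export
apply_site_filter <- function(aln, filter = site_filter()) {
  stopifnot(inherits(aln, "locus_alignment"), inherits(filter, "site_filter"))
  w <- ncol(aln$mat)
  keep <- rep(TRUE, w)
  for (rng in filter$masked_ranges) {
    if (rng[1] < 1 || rng[2] > w || rng[2] < rng[1])
      stop("apply_site_filter: masked range [", rng[1], ",", rng[2],
           "] outside alignment width ", w)
    keep[rng[1]:rng[2]] <- FALSE
  }
  if (filter$drop_indel_columns && any(keep))
    keep[keep] <- keep[keep] & !apply(aln$mat[, keep, drop = FALSE] == "-", 2L, any)
  if (filter$drop_missing_columns && any(keep))
    keep[keep] <- keep[keep] & !apply(aln$mat[, keep, drop = FALSE] == "N", 2L, any)
  if (!any(keep))
    warning("apply_site_filter: no columns retained")
  out <- locus_alignment(aln$mat[, keep, drop = FALSE],
                         strains = aln$strains, locus = aln$locus,
                         deme = aln$deme)
  attr(out, "retained_sites") <- sum(keep)
  attr(out, "kept_columns") <- which(keep)
  out
}
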