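#' Define a sequenced locus
#'
#' A locus is an interval on a chromosome with end-exclusive coordinates,
#' so that `end - start` is the number of base pairs sequenced.
#'
#' @param name Locus label.
#' @param chromosome Chromosome label (e.g. `"I"`, `"II"`, `"III"`).
#' @param start,end Genome coordinates; `end` is exclusive, `end > start`.
#' @param role One of `"centromere-core"`, `"gene"`, `"intron"`, `"flank"`.
#' @return An object of class `"locus_def"`.
#' @examples
#' locus_def("cen2_core", "II", 1621085, 1621800, "centromere-core")
#' @export
locus_def <- function(name, chromosome, start, end,
                      role = c("flank", "centromere-core", "gene", "intron")) {
  role <- match.arg(role)
  if (!is.numeric(start) || !is.numeric(end) || end <= start)
    stop("locus_def: 'end' must be greater than 'start' (end-exclusive coordinates)")
  structure(
    list(name = as.character(name), chromosome = as.character(chromosome),
         start = as.numeric(start), end = as.numeric(end), role = role),
    class = "locus_def")
}

#' @export
print.locus_def <- function(x, ...) {
  cat(sprintf("<locus_def> %s  chr%s:%s-%s (%d bp, %s)\n",
              x$name, x$chromosome,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              locus_span(x), x$role))
  invisible(x)
}

#' Span of one locus in base pairs
#' @param locus A `locus_def`.
#' @return Integer span `end - start`.
#' @export
locus_span <- function(locus) {
  stopifnot(inherits(locus, "locus_def"))
  as.integer(locus$end - locus$start)
}

#' Total sequenced span over a list of loci
#'
#' Sums `end - start` over all loci under the end-exclusive convention.
#'
#' @param loci List of `locus_def` objects (an empty list gives 0).
#' @return Total base-pair count.
#' @examples
#' total_locus_span(pombe_loci())  # 5777
#' @export
total_locus_span <- function(loci) {
  if (length(loci) == 0L) return(0L)
  sum(vapply(loci, locus_span, integer(1)))
}

#' The seven sequenced loci of the fission-yeast isolate survey
#'
#' The three primary non-coding loci (the central core of the chromosome II
#' centromere, the telomerase RNA gene TER1, and the large second intron of
#' SPBC660.16) plus two centromere-flanking and two TER1-distal segments.
#' Coordinates are end-exclusive and sum to 5,777 bp.
#'
#' @return Named list of `locus_def` objects.
#' @export
pombe_loci <- function() {
  l <- list(
    locus_def("cen2_core",    "II", 1621085, 1621800, "centromere-core"),
    locus_def("TER1",         "I",  3084446, 3086143, "gene"),
    locus_def("SPBC660.16i2", "II",  230740,  231501, "intron"),
    locus_def("cen2_left",    "II", 1572330, 1572988, "flank"),
    locus_def("cen2_right",   "II", 1658033, 1658751, "flank"),
    locus_def("ter1_distal1", "I",  3113975, 3114540, "flank"),
    locus_def("ter1_distal2", "I",  3194538, 3195201, "flank"))
  names(l) <- vapply(l, `[[`, character(1), "name")
  l
}
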