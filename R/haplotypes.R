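#' Collapse strains into compound haplotypes
#'
#' Concatenates the (filtered) per-locus sequences of every strain and groups
#' strains whose concatenated sequence is exactly identical.  Haplotype ids
#' are 1-based integers assigned in first-occurrence order over the input
#' strain order; per-locus haplotype ids are assigned the same way within
#' each locus.
#'
#' @param alns List of `locus_alignment` objects sharing one strain set
#'   (order may differ across loci; the first alignment fixes the reporting
#'   order).
#' @param filter Optional `site_filter` applied to every alignment first;
#'   `NULL` (default) uses the alignments as given.
#' @return An object of class `"haplotype_table"`: a list with
#'   \describe{
#'     \item{groups}{named list, haplotype id -> character vector of members}
#'     \item{strain_to_group}{named integer vector, strain -> haplotype id}
#'     \item{per_locus}{named list, locus -> named integer vector of
#'       per-locus haplotype ids}
#'     \item{n_strains, n_groups}{counts}
#'   }
#' @examples
#' fx <- sim_strain_collection()
#' ht <- collapse_haplotypes(fx$alignments)
#' ht$n_groups  # 40
#' @export
collapse_haplotypes <- function(alns, filter = NULL) {
  if (inherits(alns, "locus_alignment")) alns <- list(alns)
  stopifnot(length(alns) >= 1L,
            all(vapply(alns, inherits, logical(1), "locus_alignment")))
  if (!is.null(filter))
    alns <- lapply(alns, apply_site_filter, filter = filter)
  strains <- alns[[1L]]$strains
  for (a in alns[-1L]) {
    if (!setequal(a$strains, strains))
      stop("collapse_haplotypes: strain sets differ across loci")
  }
  seq_of <- function(a) {
    s <- apply(a$mat, 1L, paste, collapse = "")
    s[match(strains, a$strains)]
  }
  per_locus_seq <- lapply(alns, seq_of)
  concat <- do.call(paste0, per_locus_seq)

  ids <- match(concat, unique(concat))     # first-occurrence order
  names(ids) <- strains
  groups <- split(strains, ids)
  names(groups) <- as.character(sort(unique(ids)))

  per_locus <- lapply(per_locus_seq, function(s) {
    v <- match(s, unique(s)); names(v) <- strains; v
  })
  locus_names <- vapply(seq_along(alns), function(i) {
    if (!is.null(alns[[i]]$locus)) alns[[i]]$locus$name else paste0("locus", i)
  }, character(1))
  names(per_locus) <- locus_names

  structure(list(groups = groups, strain_to_group = ids,
                 per_locus = per_locus,
                 n_strains = length(strains), n_groups = length(groups)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("<haplotype_table> %d strains in %d compound-haplotype groups\n",
              x$n_strains, x$n_groups))
  sizes <- lengths(x$groups)
  cat("  group sizes: ", paste(sort(unique(sizes)), collapse = " "),
      "  (largest ", max(sizes), ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.haplotype_table <- function(x, ...) {
  df <- data.frame(strain = names(x$strain_to_group),
                   haplotype_id = unname(x$strain_to_group),
                   stringsAsFactors = FALSE)
  for (loc in names(x$per_locus))
    df[[paste0("hap_", loc)]] <- unname(x$per_locus[[loc]][df$strain])
  df
}

#' One representative strain per compound haplotype
#'
#' Diversity in a clonally structured collection is usually computed over
#' haplotype representatives (one sequence per identity group) to avoid
#' weighting by collection effort.
#'
#' @param ht A `haplotype_table`.
#' @return Character vector of strain names, one per group, the first
#'   member of each group in input order.
#' @export
haplotype_representatives <- function(ht) {
  stopifnot(inherits(ht, "haplotype_table"))
  vapply(ht$groups, `[`, character(1), 1L)
}

#' Write a haplotype table as TSV
#' @param ht A `haplotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_tsv <- function(ht, path) {
  utils::write.table(as.data.frame(ht), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
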