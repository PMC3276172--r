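## Synthetic reconstruction of the published 84-strain fission-yeast
## collection: strain names, compound-haplotype group memberships and
## geographic origins follow the published survey; the sequences
## themselves are synthetic (the study deposited no accessions), built so
## that exact-identity collapse of the concatenated seven loci reproduces
## the published 40-group partition.

.strain_groups <- function() {
  g <- list(
    `1`  = list(c("UWOPS 92.229.4"), "Mexico"),
    `2`  = list(c("UWOPS 94.422.2"), "Mexico"),
    `3`  = list(c("UFMG A529", "UFMG 790", "UFMG A826"),
                "Brazil, Belo Horizonte and Vicosa"),
    `4`  = list(c("UFMG R416", "UFMG R418", "UFMG R420", "UFMG R424",
                  "UFMG R435"), "Brazil; Aracaju"),
    `5`  = list(c("UFMG R427"), "Brazil; Aracaju"),
    `6`  = list(c("UFMG A1263"), "Brazil, Vicosa"),
    `7`  = list(c("UFMG A521", "UFMG A571", "UFMG A602"),
                "Brazil, Belo Horizonte"),
    `8`  = list(c("UFMG A1000", "UFMG A1153"),
                "Brazil, Belo Horizonte and Salinas"),
    `9`  = list(c("UFMG R434"), "Brazil; Aracaju"),
    `10` = list(c("UFMG R428"), "Brazil; Aracaju"),
    `11` = list(c("UFMG A1152"), "Brazil, Salinas"),
    `12` = list(c("UFMG R437"), "Brazil; Aracaju"),
    `13` = list(c("UFMG A738"), "Brazil, Belo Horizonte"),
    `14` = list(c("NCYC 683", "NCYC 2387", "DBVPG 4435", "AWRI 442"),
                "Spain, Italy, South Australia"),
    `15` = list(c("NCYC 936", "NCYC 2355-1"), "Sri Lanka, Japan"),
    `16` = list(c("CBS 356", "NCYC 132", "NCYC 535", "DBVPG 2817",
                  "DBVPG 4437", "AWRI 141"),
                "Eastern Mediterranean, Africa, Italy, Australia"),
    `17` = list(c("NCYC 380", "CBS 1063", "DBVPG 6281", "CBS 355",
                  "DBVPG 6417"), "Sicily, Spain"),
    `18` = list(c("DBVPG 4433", "DBVPG 6279", "DBVPG 6610", "DBVPG 6699",
                  "Y0036", "Y0037", "CRUK 972", "CRUK 975", "Y 468",
                  "Y 469"), "Germany, Indo-China, South Africa, France"),
    `19` = list(c("CBS 2628"), "Pakistan"),
    `20` = list(c("CBS 2775", "CBS 2776", "CBS 2777"), "Japan (all)"),
    `21` = list(c("CBS 5680"), "Poland"),
    `22` = list(c("CBS 5682"), "South Africa"),
    `23` = list(c("CBS 7335"), "Spain"),
    `24` = list(c("DBVPG 2801"), "Tunisia"),
    `25` = list(c("DBVPG 2805"), "Malta"),
    `26` = list(c("DBVPG 2804", "DBVPG 2806", "DBVPG 2807", "DBVPG 2808",
                  "DBVPG 2809"), "Malta (all)"),
    `27` = list(c("DBVPG 2810"), "Malta"),
    `28` = list(c("DBVPG 2811", "DBVPG 2812", "DBVPG 2814", "DBVPG 2815",
                  "DBVPG 2816", "DBVPG 2818"), "Sicily (all)"),
    `29` = list(c("Y470"), NA_character_),
    `30` = list(c("Y 831", "Y 832"), "South Africa (both)"),
    `31` = list(c("CBS 374"), "Delft"),
    `32` = list(c("DBVPG 6447", "DBVPG 6449"), NA_character_),
    `33` = list(c("CBS 358"), NA_character_),
    `34` = list(c("CBS 1058"), "Java"),
    `35` = list(c("CBS 357"), "Jamaica"),
    `36` = list(c("CBS 352"), "Indonesia"),
    `37` = list(c("CBS 1057"), "Sweden"),
    `38` = list(c("CBS 1059"), "Mauritius"),
    `39` = list(c("CBS 1044"), NA_character_),
    `40` = list(c("L2470"), "Chile")
  )
  g
}

#' Strain metadata of the published collection
#'
#' @return Data frame with columns `strain`, `haplotype_group` (the
#'   published 1..40 group numbering) and `origin` (free text as
#'   published; `NA` where unknown), 84 rows.
#' @export
strain_collection_metadata <- function() {
  g <- .strain_groups()
  rows <- lapply(names(g), function(id)
    data.frame(strain = g[[id]][[1L]], haplotype_group = as.integer(id),
               origin = g[[id]][[2L]], stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic seven-locus alignments for the 84-strain collection
#'
#' Generates one aligned sequence per strain at each of the seven loci
#' (`pombe_loci()`, full printed spans) such that strains of the same
#' published compound-haplotype group have identical sequences at every
#' locus and strains of different groups differ at group-diagnostic sites;
#' exact-identity collapse of the concatenation therefore reproduces the
#' published 40-group partition.  Sequences are labelled synthetic: the
#' study deposited no accessions, so only the partition (not the bases) is
#' faithful.  Per-locus haplotype diversity is made coarser than the
#' compound partition by reusing a smaller number of locus haplotypes,
#' mimicking how compound haplotypes refine per-locus ones.
#'
#' @param seed Integer seed for the synthetic bases (default 421).
#' @param seq_fraction Fraction of each locus span to synthesise (default
#'   1 = full spans; smaller values give faster toy alignments while
#'   preserving the partition).
#' @return List with `alignments` (named list of `locus_alignment`),
#'   `metadata` (the strain table) and `loci`.
#' @examples
#' fx <- sim_strain_collection(seq_fraction = 0.1)
#' collapse_haplotypes(fx$alignments)$n_groups  # 40
#' @export
sim_strain_collection <- function(seed = 421L, seq_fraction = 1) {
  stopifnot(seq_fraction > 0, seq_fraction <= 1)
  set.seed(seed)
  meta <- strain_collection_metadata()
  loci <- pombe_loci()
  n_groups <- max(meta$haplotype_group)
  bases <- c("A", "C", "G", "T")

  ## per-locus haplotype count: fewer locus haplotypes than compound
  ## groups, but jointly the seven loci separate all 40 groups
  n_loc_haps <- c(14L, 12L, 10L, 8L, 8L, 6L, 6L)
  ## group -> locus-haplotype assignment; retry until jointly distinctive
  repeat {
    assign_mat <- sapply(n_loc_haps, function(k)
      sample.int(k, n_groups, replace = TRUE))
    key <- apply(assign_mat, 1L, paste, collapse = "-")
    if (!anyDuplicated(key)) break
  }

  alignments <- vector("list", length(loci))
  names(alignments) <- names(loci)
  for (li in seq_along(loci)) {
    L <- max(10L, round(locus_span(loci[[li]]) * seq_fraction))
    ref <- sample(bases, L, replace = TRUE)
    k <- n_loc_haps[li]
    ## each locus haplotype carries one diagnostic (barcode) mutation at
    ## its own dedicated site -- guaranteeing pairwise-distinct locus
    ## haplotypes -- plus a few shared-pool mutations for realism
    n_var <- min(L - 1L, 3L * k)
    var_sites <- sample.int(L, n_var)
    extra_pool <- if (n_var > k) var_sites[(k + 1L):n_var] else integer(0)
    hap_seqs <- matrix(rep(ref, each = k), nrow = k)
    for (h in seq_len(k)) {
      s0 <- var_sites[h]
      hap_seqs[h, s0] <- setdiff(bases, ref[s0])[1L]
      if (length(extra_pool)) {
        mine <- sample(extra_pool, min(length(extra_pool),
                                       stats::rpois(1L, 2)))
        for (s in mine)
          hap_seqs[h, s] <- sample(setdiff(bases, ref[s]), 1L)
      }
    }
    rows <- hap_seqs[assign_mat[meta$haplotype_group, li], , drop = FALSE]
    alignments[[li]] <- locus_alignment(rows, strains = meta$strain,
                                        locus = loci[[li]])
  }
  list(alignments = alignments, metadata = meta, loci = loci)
}

#' Map published origin strings to coarse populations
#'
#' Coarse-grains the free-text origins of the collection into the
#' populations used for differentiation analysis (American, African,
#' European, Asian) with `Unknown` for missing origins.  A group whose
#' origin string spans several continents maps to several populations.
#'
#' @param origin Character vector of origin strings (`NA` = unknown).
#' @return List of character vectors, one per input element.
#' @export
origin_to_population <- function(origin) {
  lapply(origin, function(o) {
    if (is.na(o) || !nzchar(o)) return("Unknown")
    pops <- character(0)
    if (grepl("Mexico|Brazil|Jamaica|Chile|Delft", o)) {
      pops <- c(pops, if (grepl("Delft", o)) "European" else "American")
    }
    if (grepl("Africa|Tunisia|Mauritius", o)) pops <- c(pops, "African")
    if (grepl("Spain|Italy|Sicily|Malta|Poland|Sweden|Germany|France|Mediterranean|Australia",
              o)) pops <- c(pops, "European")
    if (grepl("Japan|Sri Lanka|Pakistan|Java|Indonesia|Indo-China", o))
      pops <- c(pops, "Asian")
    if (!length(pops)) pops <- "Unknown"
    unique(pops)
  })
}
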