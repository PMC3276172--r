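## End-to-end orchestration: a YAML config drives the sequence pipeline
## (read -> filter -> collapse -> diversity -> F_st -> LD) and the
## phenomics pipeline (curves -> components -> LSC -> trait matrix ->
## clustering/similarity/atypicality), writing TSV reports.  Every report
## directory records the config hash and seed for reproducibility.

#' Read a pipeline configuration
#'
#' YAML with (all optional unless the stage is run):
#' \preformatted{
#' loci:                 # list: name, chromosome, start, end, role, fasta
#' metadata: path.tsv    # strain, population columns
#' curves: path.tsv      # strain, environment, run, time_min, od
#' reference: strain     # reference strain for trait matrix / LSC
#' mu: 0.33e-9
#' fdr: 0.05
#' seed: 1
#' out_dir: results
#' masked_ranges:        # locus name -> list of [start, end] column pairs
#' }
#'
#' @param path Path to a YAML file.
#' @return A list of class `"pipeline_config"`; `config_hash` attribute
#'   is the md5 of the file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("read_pipeline_config: no such file: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(mu = 0.33e-9, fdr = 0.05, seed = 1L, out_dir = "results")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  attr(cfg, "config_hash") <- unname(tools::md5sum(path))
  class(cfg) <- "pipeline_config"
  cfg
}

.write_report <- function(df, dir, name, cfg) {
  path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stamp <- function(dir, cfg) {
  writeLines(c(paste0("config_hash: ",
                      attr(cfg, "config_hash") %||% "unhashed"),
               paste0("seed: ", cfg$seed)),
             file.path(dir, "run_info.txt"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the population-genetics pipeline
#'
#' Reads one FASTA per configured locus, applies the site filter (indel
#' columns dropped, configured column ranges masked), collapses compound
#' haplotypes, and writes haplotype, diversity, F_st and LD reports.
#'
#' @param config A `pipeline_config` (or path to one).
#' @return Invisibly, a list with `haplotypes`, `diversity`, `fst`
#'   (or `NULL` without metadata), `ld`, and the report paths.
#' @export
run_popgen <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  if (is.null(cfg$loci)) stop("run_popgen: config has no 'loci'")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  alns <- list()
  for (lc in cfg$loci) {
    if (is.null(lc$fasta) || !file.exists(lc$fasta))
      stop("run_popgen [locus_io]: missing FASTA for locus '",
           lc$name %||% "?", "'")
    ld <- locus_def(lc$name, lc$chromosome %||% "?",
                    lc$start %||% 1, lc$end %||% 2,
                    lc$role %||% "flank")
    aln <- read_locus_fasta(lc$fasta, ld)
    mr <- cfg$masked_ranges[[lc$name]] %||% list()
    flt <- site_filter(masked_ranges = mr)
    alns[[lc$name]] <- apply_site_filter(aln, flt)
  }
  message("run_popgen: ", length(alns), " loci, ",
          n_sequences(alns[[1]]), " strains")

  ht <- collapse_haplotypes(alns)
  p_h <- .write_report(as.data.frame(ht), cfg$out_dir, "haplotypes", cfg)

  div <- diversity_table(alns, collapse = TRUE, mu = cfg$mu)
  p_d <- .write_report(div, cfg$out_dir, "diversity", cfg)
  for (i in seq_len(nrow(div)))
    message(sprintf("  %s: n=%d L=%d S=%d", div$locus[i], div$n[i],
                    div$L[i], div$S[i]))

  ## concatenated haplotype representatives for F_st and LD
  reps <- haplotype_representatives(ht)
  cat_mat <- do.call(cbind, lapply(alns, function(a)
    a$mat[match(reps, a$strains), , drop = FALSE]))
  concat <- locus_alignment(cat_mat, strains = reps)

  fst <- NULL
  if (!is.null(cfg$metadata) && file.exists(cfg$metadata)) {
    md <- utils::read.delim(cfg$metadata, stringsAsFactors = FALSE)
    if (all(c("strain", "population") %in% names(md))) {
      asg <- lapply(split(md$population, md$strain), unique)
      asg <- asg[names(asg) %in% reps]
      if (length(asg) >= 4L) {
        fst <- tryCatch(pairwise_fst(concat, population_map(asg)),
                        error = function(e) {
                          warning("run_popgen [structure_ld]: ",
                                  conditionMessage(e)); NULL
                        })
        if (!is.null(fst))
          .write_report(as.data.frame(unclass(fst)), cfg$out_dir,
                        "fst", cfg)
      }
    }
  }

  snps <- informative_snps(concat)
  ld_res <- NULL
  if (nrow(snps) >= 2L) {
    ld_res <- ld_statistics(snps)
    .write_report(as.data.frame(ld_res$chi2), cfg$out_dir, "ld_chi2", cfg)
    .write_report(as.data.frame(ld_res$r), cfg$out_dir, "ld_r", cfg)
    .write_report(as.data.frame(ld_res$Dprime), cfg$out_dir,
                  "ld_dprime", cfg)
  }
  .stamp(cfg$out_dir, cfg)
  invisible(list(haplotypes = ht, diversity = div, fst = fst, ld = ld_res,
                 reports = c(haplotypes = p_h, diversity = p_d)))
}

#' Run the phenomics pipeline
#'
#' Reads the growth-curve table, extracts fitness components per strain,
#' environment and run, computes LSC scores against the reference strain,
#' builds the reference-relative trait matrix, and writes component, LSC,
#' dendrogram (Newick), similarity and atypicality reports.
#'
#' @param config A `pipeline_config` (or path to one) with `curves` and
#'   `reference`.
#' @return Invisibly, a list with `components`, `lsc`, `trait_matrix`,
#'   `tree`, `atypicality`.
#' @export
run_phenomics <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  if (is.null(cfg$curves) || !file.exists(cfg$curves))
    stop("run_phenomics [growth_fitness]: curve table not found")
  if (is.null(cfg$reference))
    stop("run_phenomics [growth_fitness]: no reference strain configured")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  curves <- utils::read.delim(cfg$curves, stringsAsFactors = FALSE)
  need <- c("strain", "environment", "run", "time_min", "od")
  bad <- !stats::complete.cases(curves[, intersect(need, names(curves))])
  if (any(bad)) {
    message("run_phenomics: skipped ", sum(bad), " corrupt curve row(s)")
    curves <- curves[!bad, , drop = FALSE]
  }
  comp <- fitness_components(curves)
  .write_report(comp, cfg$out_dir, "fitness_components", cfg)

  lsc <- lsc_table(comp, reference = cfg$reference)
  .write_report(lsc, cfg$out_dir, "lsc_scores", cfg)

  ## replicate-averaged raw components -> reference-relative trait matrix
  agg <- stats::aggregate(
    comp[, c("lag_h", "doubling_h", "efficiency")],
    by = list(strain = comp$strain, environment = comp$environment),
    FUN = function(v) mean(v, na.rm = TRUE))
  tm <- build_trait_matrix(agg, reference = cfg$reference,
                           component_cols = c("lag_h", "doubling_h",
                                              "efficiency"))
  .write_report(data.frame(strain = rownames(tm),
                           as.data.frame(unclass(tm),
                                         check.names = FALSE)),
                cfg$out_dir, "trait_matrix", cfg)

  tree <- NULL; atyp <- NULL
  ## the reference-relative profile of the reference itself is identically
  ## zero (and any constant profile has no defined correlation): cluster
  ## and rank only strains with varying profiles
  sds <- apply(unclass(tm), 1L, stats::sd, na.rm = TRUE)
  keep <- is.finite(sds) & sds > 0
  if (any(!keep))
    message("run_phenomics: excluding constant profile(s) from clustering: ",
            paste(rownames(tm)[!keep], collapse = ", "))
  tm_var <- tm[keep, , drop = FALSE]
  if (nrow(tm_var) >= 3L) {
    tree <- cluster_profiles(tm_var)
    ape::write.tree(ape::as.phylo(tree),
                    file.path(cfg$out_dir, "dendrogram.nwk"))
    atyp <- atypicality_ranking(tm_var)
    .write_report(atyp, cfg$out_dir, "atypicality", cfg)
  }
  .stamp(cfg$out_dir, cfg)
  invisible(list(components = comp, lsc = lsc, trait_matrix = tm,
                 tree = tree, atypicality = atyp))
}

#' LSC scores for every strain and trait of a component table
#'
#' Applies `lsc_score()` across a `fitness_components()` table: for each
#' strain and trait (log component x environment), the reference strain's
#' replicate log measurements per run form the wild-type set and each
#' other strain contributes one measurement per run.  Efficiency must
#' already be inverted in the `ln_efficiency` column (the
#' `fitness_components()` default) so larger is worse for all components.
#'
#' @param components Output of `fitness_components()`.
#' @param reference Reference strain label.
#' @return Data frame `strain, environment, component, lsc, n_runs`.
#' @export
lsc_table <- function(components, reference) {
  log_cols <- c(lag = "ln_lag", doubling = "ln_doubling",
                efficiency = "ln_efficiency")
  if (!reference %in% components$strain)
    stop("lsc_table: reference strain '", reference, "' not in components")
  out <- list()
  for (env in unique(components$environment)) {
    d <- components[components$environment == env & components$grower, ]
    runs <- sort(unique(d$run))
    for (comp_name in names(log_cols)) {
      cl <- log_cols[[comp_name]]
      wt_logs <- lapply(runs, function(r)
        d[[cl]][d$strain == reference & d$run == r &
                  !is.na(d[[cl]])])
      usable <- vapply(wt_logs, length, integer(1)) >= 1L
      if (!any(usable)) next
      for (s in setdiff(unique(d$strain), reference)) {
        x <- vapply(runs, function(r) {
          v <- d[[cl]][d$strain == s & d$run == r]
          if (length(v) == 1L && !is.na(v)) v else NA_real_
        }, numeric(1))
        keep <- usable & !is.na(x)
        if (!any(keep)) next
        sc <- lsc_score(x[keep], wt_logs[keep])
        out[[length(out) + 1L]] <- data.frame(
          strain = s, environment = env, component = comp_name,
          lsc = sc$value, n_runs = sc$n_runs, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
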