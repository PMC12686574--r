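#' Default pipeline configuration
#'
#' The flat, dotted-key configuration driving [run_pipeline()]. By default
#' the pipeline runs on a synthetic experiment generated at the design's
#' default study conditions; supply `input.*` keys instead to run on files on
#' disk (exactly one of the two modes must be configured). Unknown keys are
#' an error, so every run is driven by an explicit, auditable configuration.
#'
#' Keys and defaults:
#' * `seed` (1), `outdir` (NA = no files written)
#' * `synthetic.n_genes` (5000), `synthetic.n_reps` (3),
#'   `synthetic.effect_lfc` (2), `synthetic.dispersion` (0.1),
#'   `synthetic.frac_immune_up` (0.06), `synthetic.frac_cycling_down` (0.06),
#'   `synthetic.frac_accelerated` (0.04),
#'   `synthetic.unannotated_fraction` (0.2)
#' * `input.counts`, `input.metadata`, `input.ontology`, `input.gene2go`,
#'   `input.keyword_map`, `input.markers_gmt`, `input.sasp_gmt` (all NA)
#' * `dge.alpha` (0.05), `dge.lfc_min` (0)
#' * `stem.c` (1), `stem.m` (50), `stem.n_perm` (1000),
#'   `stem.pseudocount` (1), `stem.alpha` (0.05)
#' * `accel.baseline` ("within_mutant" or "wt_young"),
#'   `accel.stem_threshold` (0.5)
#' * `enrich.top_k` (10), `enrich.min_set` (5)
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1, outdir = NA,
    synthetic.n_genes = 5000, synthetic.n_reps = 3,
    synthetic.effect_lfc = 2, synthetic.dispersion = 0.1,
    synthetic.frac_immune_up = 0.06, synthetic.frac_cycling_down = 0.06,
    synthetic.frac_accelerated = 0.04, synthetic.unannotated_fraction = 0.2,
    input.counts = NA, input.metadata = NA, input.ontology = NA,
    input.gene2go = NA, input.keyword_map = NA, input.markers_gmt = NA,
    input.sasp_gmt = NA,
    dge.alpha = 0.05, dge.lfc_min = 0,
    stem.c = 1, stem.m = 50, stem.n_perm = 1000, stem.pseudocount = 1,
    stem.alpha = 0.05,
    accel.baseline = "within_mutant", accel.stem_threshold = 0.5,
    enrich.top_k = 10, enrich.min_set = 5)
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line, `#` comments and blank lines allowed.
#' Keys must be known configuration keys (see [default_config()]); unknown
#' keys are an error. Values are parsed as numbers where possible.
#'
#' @param file Path to the configuration file.
#' @return Full configuration list (file values over defaults).
#' @export
read_config <- function(file) {
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

resolveConfig <- function(config) {
  cfg <- default_config()
  if (!is.null(config)) {
    extra <- setdiff(names(config), names(cfg))
    if (length(extra)) stop("unknown config key(s): ",
                            paste(extra, collapse = ", "))
    cfg[names(config)] <- config
  }
  if (!cfg$accel.baseline %in% c("within_mutant", "wt_young"))
    stop("accel.baseline must be 'within_mutant' or 'wt_young'")
  input_keys <- grep("^input\\.", names(cfg), value = TRUE)
  has_input <- any(!is.na(unlist(cfg[input_keys])))
  if (has_input) {
    missing <- input_keys[is.na(unlist(cfg[input_keys]))]
    if (length(missing))
      stop("file mode needs every input.* key; missing: ",
           paste(missing, collapse = ", "))
    for (k in input_keys)
      if (!file.exists(cfg[[k]])) stop("input file not found: ", cfg[[k]])
  }
  cfg$mode <- if (has_input) "files" else "synthetic"
  cfg
}

# 32-bit FNV-1a over a string, as a short reproducible config fingerprint.
# Kept in doubles: the xor only ever touches the low byte, and the modular
# product is split 16/16 to stay inside exact double-integer range.
fnv1a <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in as.integer(charToRaw(s))) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    h <- ((h %% 65536) * p + (((h %/% 65536) * p) %% 65536) * 65536) %% 2^32
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

configString <- function(cfg) {
  keys <- sort(setdiff(names(cfg), "mode"))
  paste(vapply(keys, function(k) paste0(k, "=", format(cfg[[k]], digits = 15)),
               ""), collapse = ";")
}

#' Arithmetic summary of an acceleration analysis
#'
#' Combines a signature size with per-onset-age accelerated counts into the
#' headline numbers: the total accelerated count, the percentage of the
#' signature it represents (also rounded to integer precision, the way such
#' percentages are reported), and a consistency flag checking that the
#' per-onset counts sum to the stated total.
#'
#' @param n_signature Size of the old-age signature.
#' @param onset_counts Named (by onset age) or bare integer vector of
#'   per-onset accelerated counts.
#' @param n_accelerated Total accelerated count; defaults to
#'   `sum(onset_counts)`.
#' @return List: `n_signature`, `onset_counts`, `onset_sum`, `n_accelerated`,
#'   `pct_of_signature`, `pct_integer`, `consistent`.
#' @examples
#' acceleration_summary(2887, c(4, 639, 109), n_accelerated = 1049)
#' @export
acceleration_summary <- function(n_signature, onset_counts,
                                 n_accelerated = sum(onset_counts)) {
  if (n_signature < 0 || any(onset_counts < 0))
    stop("counts must be non-negative")
  pct <- if (n_signature > 0) 100 * n_accelerated / n_signature else 0
  list(n_signature = n_signature, onset_counts = onset_counts,
       onset_sum = sum(onset_counts), n_accelerated = n_accelerated,
       pct_of_signature = pct, pct_integer = round(pct),
       consistent = sum(onset_counts) == n_accelerated &&
         n_accelerated <= n_signature)
}

emptyDeg <- function(genes, reference, test) {
  # placeholder contrast of a group against itself: nothing can be significant
  res <- data.frame(gene = genes, baseMean = NA_real_, log2FC = 0,
                    se = NA_real_, stat = 0, pvalue = 1, padj = 1,
                    direction = NA_character_, significant = FALSE,
                    stringsAsFactors = FALSE)
  structure(res, class = c("deg_table", "data.frame"),
            reference = reference, test = test, alpha_fdr = NA_real_,
            lfc_min = 0,
            contrast = paste(paste(unlist(reference), collapse = ":"),
                             "vs", paste(unlist(test), collapse = ":")))
}

#' Run the full analysis pipeline
#'
#' Executes the stages end to end: data (synthetic generation or file
#' loading), normalisation and differential expression over the
#' genotype-by-age contrast scheme, profile clustering per genotype,
#' acceleration classification (both the DEG route and the profile-overlap
#' route), enrichment (GO-BP over-representation, cell-type marker
#' programmes, SASP overlap) and hallmark mapping, then assembles a
#' machine-readable run summary. With an `outdir` configured, every stage
#' writes its TSV and the summary is written as JSON; an identical
#' configuration and seed reproduces the summary byte for byte.
#'
#' @param config Configuration list (partial lists are completed with
#'   [default_config()]) or a path to a [read_config()] file. `NULL` runs the
#'   default synthetic configuration.
#' @return A list of class `pipeline_run` holding the stage outputs
#'   (`data`, `deg`, `signature`, `acceleration`, `stem`, `stem_overlap`,
#'   `enrichment`, `hallmarks`, `sasp`) and `summary` (class
#'   `pipeline_summary`).
#' @export
run_pipeline <- function(config = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- resolveConfig(config)
  seed <- as.integer(cfg$seed)

  # ---- stage: data ----------------------------------------------------------
  truth <- NULL
  if (cfg$mode == "synthetic") {
    fr_acc <- cfg$synthetic.frac_accelerated
    fr_imm <- cfg$synthetic.frac_immune_up
    fr_cyc <- cfg$synthetic.frac_cycling_down
    design <- sim_design(
      n_genes = cfg$synthetic.n_genes, n_reps = cfg$synthetic.n_reps,
      class_fractions = c(immune_up = fr_imm, cycling_down = fr_cyc,
                          accelerated = fr_acc,
                          null = 1 - fr_imm - fr_cyc - fr_acc),
      dispersion = cfg$synthetic.dispersion,
      effect_lfc = cfg$synthetic.effect_lfc,
      unannotated_fraction = cfg$synthetic.unannotated_fraction,
      seed = seed)
    sim <- simulate_experiment(design)
    ann <- simulate_annotation(sim)
    counts <- sim$counts
    truth <- sim$truth
    ontology <- ann$ontology; gene2go <- ann$gene2go
    keyword_map <- ann$keyword_map
    markers <- ann$markers; sasp_sets <- ann$sasp
  } else {
    counts <- read_counts(cfg$input.counts, cfg$input.metadata)
    ontology <- read_obo(cfg$input.ontology)
    gene2go <- utils::read.delim(cfg$input.gene2go, stringsAsFactors = FALSE)
    keyword_map <- read_keyword_map(cfg$input.keyword_map)
    markers <- read_gmt(cfg$input.markers_gmt,
                        universe = rownames(counts$counts))
    sasp_sets <- read_gmt(cfg$input.sasp_gmt,
                          universe = rownames(counts$counts))
  }
  genes <- rownames(counts$counts)
  genotypes <- unique(counts$samples$genotype)
  wt <- "WT"
  if (!wt %in% genotypes) stop("no WT genotype in the sample metadata")
  mut <- setdiff(genotypes, wt)
  if (length(mut) != 1) stop("expected exactly one mutant genotype")
  ageOf <- function(g) {
    s <- counts$samples$genotype == g
    levels(droplevels(counts$samples$age_group[s]))
  }
  wt_ages <- ageOf(wt); mut_ages <- ageOf(mut)
  age_levels <- levels(counts$samples$age_group)

  # ---- stage: differential expression --------------------------------------
  sf <- size_factors(counts, fallback = TRUE)
  grp <- function(g, a) list(genotype = g, age_group = a)
  contrast_fun <- function(ref, tst)
    nb_test(counts, ref, tst, alpha_fdr = cfg$dge.alpha,
            lfc_min = cfg$dge.lfc_min, sf = sf)
  wt_deg <- lapply(wt_ages[-1], function(a)
    contrast_fun(grp(wt, wt_ages[1]), grp(wt, a)))
  names(wt_deg) <- wt_ages[-1]
  if (cfg$accel.baseline == "within_mutant") {
    contrast_ages <- mut_ages[-1]
    mut_deg <- lapply(contrast_ages, function(a)
      contrast_fun(grp(mut, mut_ages[1]), grp(mut, a)))
  } else {
    contrast_ages <- mut_ages
    mut_deg <- lapply(contrast_ages, function(a)
      contrast_fun(grp(wt, wt_ages[1]), grp(mut, a)))
  }
  names(mut_deg) <- contrast_ages
  sibling_deg <- lapply(contrast_ages, function(a) {
    if (a == wt_ages[1])
      emptyDeg(genes, grp(wt, wt_ages[1]), grp(wt, a))
    else wt_deg[[a]]
  })
  names(sibling_deg) <- contrast_ages

  # ---- stage: acceleration (DEG route) -------------------------------------
  signature <- old_age_signature(wt_deg[[length(wt_deg)]], wt_genotype = wt,
                                 age_levels = age_levels)
  accel <- classify_acceleration(signature, mut_deg, sibling_deg,
                                 age_levels = age_levels)

  # ---- stage: profile clustering -------------------------------------------
  stem_wt <- stem_fit(counts, wt, c_max = cfg$stem.c, m = cfg$stem.m,
                      n_perm = cfg$stem.n_perm, seed = seed + 101L,
                      pseudocount = cfg$stem.pseudocount, sf = sf,
                      alpha = cfg$stem.alpha)
  stem_mut <- stem_fit(counts, mut, c_max = cfg$stem.c, m = cfg$stem.m,
                       n_perm = cfg$stem.n_perm, seed = seed + 102L,
                       pseudocount = cfg$stem.pseudocount, sf = sf,
                       alpha = cfg$stem.alpha)
  stem_overlap <- stem_acceleration_overlap(stem_wt, stem_mut,
                                            threshold = cfg$accel.stem_threshold)

  # ---- stage: enrichment ----------------------------------------------------
  go_sets <- split(gene2go$gene, gene2go$term)
  go_sets <- go_sets[lengths(go_sets) >= cfg$enrich.min_set]
  nm <- ontology$name[match(names(go_sets), ontology$id)]
  names(go_sets) <- ifelse(is.na(nm), names(go_sets),
                           paste0(names(go_sets), " ", nm))
  go_coll <- gene_set_collection(go_sets, universe = genes,
                                 provenance = "GO-BP fixture")
  profGenes <- function(fit) {
    sig <- significant_profile_genes(fit)
    split(sig$gene, paste0(fit$genotype, "_profile", sig$profile_id))
  }
  profile_lists <- c(profGenes(stem_wt), profGenes(stem_mut))
  profile_lists <- profile_lists[lengths(profile_lists) > 0]
  go_ora <- lapply(profile_lists, function(g)
    tryCatch(ora(g, go_coll, correction = "bh", top_k = cfg$enrich.top_k),
             error = function(e) NULL))
  ct_enrich <- celltype_enrichment(profile_lists, markers)

  # ---- stage: hallmarks -----------------------------------------------------
  term_map <- build_term_map(ontology, keyword_map)
  assignments <- assign_hallmarks(gene2go, term_map, genes = genes)
  accel_genes <- accel$records$gene[accel$records$accelerated]
  hp_sets <- c(profile_lists,
               list(old_age_signature = signature$gene,
                    accelerated_deg = accel_genes))
  hp_sets <- hp_sets[lengths(hp_sets) > 0]
  hallmark_props <- lapply(hp_sets, hallmark_proportions,
                           assignments = assignments)

  # ---- stage: SASP overlap --------------------------------------------------
  deg_route <- accel$records[accel$records$accelerated,
                             c("gene", "onset_age"), drop = FALSE]
  sasp_tab <- sasp_overlap(list(deg = deg_route, stem = stem_overlap),
                           sasp_sets)

  stages <- list(data = counts, truth = truth, size_factors = sf,
                 deg = list(wt = wt_deg, mutant = mut_deg,
                            sibling = sibling_deg),
                 signature = signature, acceleration = accel,
                 stem = list(wt = stem_wt, mutant = stem_mut),
                 stem_overlap = stem_overlap,
                 enrichment = list(go = go_ora, celltype = ct_enrich),
                 hallmarks = list(assignments = assignments,
                                  proportions = hallmark_props),
                 sasp = sasp_tab)
  summ <- summarize(stages, cfg)
  run <- structure(c(stages, list(summary = summ, config = cfg)),
                   class = "pipeline_run")
  if (!is.na(cfg$outdir)) writeRunFiles(run, cfg$outdir)
  run
}

#' Assemble and cross-check the run summary
#'
#' Recomputes the headline numbers from the raw stage outputs (DEG counts per
#' contrast, signature size, accelerated counts per onset age and their
#' percentage of the signature, significant profiles per genotype, SASP
#' overlap counts) and verifies they are internally consistent; any
#' disagreement between a stage's stored totals and the recomputation is an
#' error.
#'
#' @param stages Stage-output list as produced inside [run_pipeline()].
#' @param cfg Resolved configuration.
#' @return A list of class `pipeline_summary`.
#' @export
summarize <- function(stages, cfg = default_config()) {
  accel <- stages$acceleration
  rec_total <- sum(accel$records$accelerated)
  if (rec_total != accel$n_accelerated)
    stop("summary inconsistency: accelerated records disagree with the total")
  asum <- acceleration_summary(nrow(stages$signature), accel$onset_counts,
                               n_accelerated = accel$n_accelerated)
  if (!asum$consistent)
    stop("summary inconsistency: per-onset counts do not sum to the total")
  if (abs(asum$pct_of_signature - accel$pct_of_signature) > 1e-9)
    stop("summary inconsistency: accelerated percentage mismatch")
  deg_counts <- lapply(stages$deg[c("wt", "mutant")], function(lst)
    vapply(lst, function(d) sum(d$significant, na.rm = TRUE), 0L))
  sigprof <- function(fit) {
    s <- fit$significance[fit$significance$significant, , drop = FALSE]
    stats::setNames(s$direction, sprintf("profile%d", s$profile_id))
  }
  stem_onsets <- table(factor(stages$stem_overlap$onset_age,
                              levels = attr(stages$stem$mutant$vectors, "ages")))
  structure(list(
    deg_counts = deg_counts,
    n_signature = asum$n_signature,
    n_accelerated = asum$n_accelerated,
    pct_of_signature = asum$pct_of_signature,
    pct_integer = asum$pct_integer,
    onset_counts = as.list(asum$onset_counts),
    stem_significant = lapply(stages$stem, sigprof),
    stem_overlap_total = nrow(stages$stem_overlap),
    stem_overlap_by_onset = as.list(stem_onsets),
    sasp_overlap_counts = as.list(table(stages$sasp$route)),
    version = as.character(utils::packageVersion("ageaccel")),
    seed = cfg$seed,
    config_hash = fnv1a(configString(cfg))),
    class = "pipeline_summary")
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("pipeline run summary\n")
  cat(sprintf("  old-age signature: %d genes\n", x$n_signature))
  cat(sprintf("  accelerated (DEG route): %d (%.1f%% of signature; ~%d%%)\n",
              x$n_accelerated, x$pct_of_signature, x$pct_integer))
  cat("  accelerated per onset age:",
      paste(names(x$onset_counts), unlist(x$onset_counts),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  profile route: %d accelerated genes\n", x$stem_overlap_total))
  cat(sprintf("  significant profiles: WT %d, mutant %d\n",
              length(x$stem_significant$wt), length(x$stem_significant$mutant)))
  cat(sprintf("  seed %s, config %s, version %s\n",
              format(x$seed), x$config_hash, x$version))
  invisible(x)
}

#' @export
print.pipeline_run <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

writeRunFiles <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  write_counts(run$data, fp("counts.tsv"), fp("samples.tsv"))
  if (!is.null(run$truth))
    utils::write.table(run$truth, fp("truth.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  for (arm in names(run$deg))
    for (a in names(run$deg[[arm]]))
      write_deg(run$deg[[arm]][[a]], fp(sprintf("deg_%s_%s.tsv", arm, a)))
  write_acceleration(run$acceleration, fp("acceleration_deg.tsv"), "deg")
  write_acceleration(run$stem_overlap, fp("acceleration_stem.tsv"), "stem")
  for (g in names(run$stem)) {
    fit <- run$stem[[g]]
    utils::write.table(fit$significance, fp(sprintf("stem_%s_profiles.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fit$assignments, fp(sprintf("stem_%s_genes.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(run$hallmarks$assignments, fp("hallmark_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$sasp, fp("sasp_overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(run$summary), fp("summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(outdir)
}
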