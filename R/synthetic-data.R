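#' Design of a synthetic two-genotype ageing time course
#'
#' Describes the simulated study: a wild-type arm sampled at every age group
#' and a mutant arm lacking the oldest group (the mutant's shorter lifespan
#' truncates its series), with negative-binomial counts and planted gene
#' classes. The defaults mirror the study conditions the pipeline targets:
#' four wild-type age groups, three mutant age groups, three brains per
#' genotype-by-age cell, a global dispersion of 0.1 and a planted log2 effect
#' of 2 at the final age.
#'
#' Planted classes and their trajectories (see the methods vignette for the
#' rationale):
#' * `immune_up` / `cycling_down`: a step of `+effect_lfc` / `-effect_lfc`
#'   from a per-gene onset age onward, identical in both genotypes (these
#'   genes age, but are not telomerase-dependent).
#' * `accelerated`: a step in the wild type at one of the two oldest ages;
#'   the mutant trajectory is the wild-type trajectory shifted one age group
#'   left (mutant offset at rank r equals the wild-type offset at rank r+1),
#'   so the change arrives one age group earlier in the mutant.
#' * `null`: flat in both genotypes.
#'
#' @param n_genes Number of genes.
#' @param n_reps Replicates (brains) per genotype-by-age cell.
#' @param wt_ages Ordered wild-type age-group labels.
#' @param mut_ages Ordered mutant age-group labels; must be a strict prefix of
#'   `wt_ages`.
#' @param class_fractions Named proportions for `immune_up`, `cycling_down`,
#'   `accelerated` and `null`; must be non-negative and sum to 1.
#' @param base_mean_log Location (`meanlog`) and scale (`sdlog`) of the
#'   log-normal baseline mean expression.
#' @param dispersion Negative-binomial dispersion alpha, with
#'   Var = mu + alpha * mu^2. A single value (recycled) or one per gene.
#' @param effect_lfc Planted log2 fold-change magnitude at the final age.
#' @param libsize_range Range of the per-sample size factors, drawn
#'   log-uniformly.
#' @param unannotated_fraction Fraction of genes that receive no GO
#'   annotation in the annotation fixture.
#' @param seed Integer seed; every generator draw is derived from it.
#' @return A list of class `sim_design`.
#' @seealso [simulate_experiment()], [simulate_annotation()]
#' @export
sim_design <- function(n_genes = 5000,
                       n_reps = 3,
                       wt_ages = AGE_GROUPS,
                       mut_ages = AGE_GROUPS[1:3],
                       class_fractions = c(immune_up = 0.06,
                                           cycling_down = 0.06,
                                           accelerated = 0.04,
                                           null = 0.84),
                       base_mean_log = c(meanlog = log(100), sdlog = 1.2),
                       dispersion = 0.1,
                       effect_lfc = 2,
                       libsize_range = c(0.7, 1.4),
                       unannotated_fraction = 0.2,
                       seed = 1L) {
  classes <- c("immune_up", "cycling_down", "accelerated", "null")
  if (!setequal(names(class_fractions), classes))
    stop("class_fractions must be named: ", paste(classes, collapse = ", "))
  class_fractions <- class_fractions[classes]
  if (any(class_fractions < 0)) stop("class_fractions must be >= 0")
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop("class_fractions must sum to 1")
  if (n_genes < 1) stop("n_genes must be positive")
  if (n_reps < 1) stop("n_reps must be at least 1")
  if (length(wt_ages) < 2) stop("need at least two wild-type age groups")
  np <- length(mut_ages)
  if (np >= length(wt_ages) || !identical(as.character(mut_ages),
                                          as.character(wt_ages[seq_len(np)])))
    stop("mut_ages must be a strict prefix of wt_ages")
  if (any(dispersion <= 0)) stop("dispersion must be positive")
  if (length(libsize_range) != 2 || any(libsize_range <= 0) ||
      libsize_range[1] > libsize_range[2])
    stop("libsize_range must be a positive increasing pair")
  structure(list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
                 wt_ages = as.character(wt_ages),
                 mut_ages = as.character(mut_ages),
                 class_fractions = class_fractions,
                 base_mean_log = base_mean_log,
                 dispersion = dispersion, effect_lfc = effect_lfc,
                 libsize_range = libsize_range,
                 unannotated_fraction = unannotated_fraction,
                 seed = as.integer(seed)),
            class = "sim_design")
}

# Run code with a private, restored RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# integer class sizes that sum to n, largest-remainder rounding
class_counts <- function(fractions, n) {
  raw <- fractions * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  k
}

#' Simulate a count matrix with planted truth
#'
#' Draws negative-binomial counts for every genotype-by-age-by-replicate cell
#' of a [sim_design()], with mean `size_factor * baseline * 2^offset` and
#' `Var = mu + alpha * mu^2`. The planted per-gene, per-genotype log2 offsets,
#' the gene classes and the drawn size factors are all recorded in the
#' returned truth table, so downstream classifiers can be scored against
#' known ground truth.
#'
#' @param design A `sim_design`.
#' @return A list of class `sim_experiment` with elements:
#' \describe{
#'   \item{counts}{A [count_matrix()].}
#'   \item{truth}{Data frame: `gene`, `class`, `direction`, `wt_onset_age`,
#'     `mut_onset_age`, `base_mean`, `dispersion`, and one
#'     `offset_<genotype>_<age>` column per genotype-by-age cell.}
#'   \item{size_factors}{Named per-sample size factors used in the draw.}
#'   \item{design}{The design.}
#' }
#' @examples
#' sim <- simulate_experiment(sim_design(n_genes = 200, seed = 7))
#' table(sim$truth$class)
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(design$seed, {
    G <- design$n_genes
    wt_ages <- design$wt_ages
    mut_ages <- design$mut_ages
    Tw <- length(wt_ages)
    Tm <- length(mut_ages)
    e <- design$effect_lfc

    nk <- class_counts(design$class_fractions, G)
    cls <- rep(names(nk), nk)
    cls <- sample(cls)  # shuffle class labels over gene indices
    genes <- sprintf("gene%05d", seq_len(G))

    dir <- integer(G)
    wt_onset <- rep(NA_integer_, G)  # age rank (1-based) where the step begins
    i_up <- which(cls == "immune_up")
    i_dn <- which(cls == "cycling_down")
    i_ac <- which(cls == "accelerated")
    dir[i_up] <- 1L
    dir[i_dn] <- -1L
    dir[i_ac] <- sample(c(-1L, 1L), length(i_ac), replace = TRUE)
    # non-accelerated ageing genes switch on at any age after the first
    wt_onset[i_up] <- sample(2:Tw, length(i_up), replace = TRUE)
    wt_onset[i_dn] <- sample(2:Tw, length(i_dn), replace = TRUE)
    # accelerated genes are late-onset in the WT (the two oldest groups), so
    # the one-group left shift lands their mutant onset inside the mutant series
    wt_onset[i_ac] <- sample((Tw - 1):Tw, length(i_ac), replace = TRUE)

    off_wt <- matrix(0, G, Tw, dimnames = list(genes, wt_ages))
    for (t in seq_len(Tw)) {
      hit <- !is.na(wt_onset) & wt_onset <= t
      off_wt[hit, t] <- dir[hit] * e
    }
    # mutant: accelerated genes are left-shifted by one age group, others
    # follow the WT trajectory at the same ages
    off_mut <- off_wt[, seq_len(Tm), drop = FALSE]
    colnames(off_mut) <- mut_ages
    if (length(i_ac))
      off_mut[i_ac, ] <- off_wt[i_ac, 1L + seq_len(Tm), drop = FALSE]

    base_mean <- stats::rlnorm(G, design$base_mean_log[["meanlog"]],
                               design$base_mean_log[["sdlog"]])
    alpha <- rep_len(design$dispersion, G)

    cells <- rbind(
      data.frame(genotype = "WT", age_group = rep(wt_ages, each = design$n_reps),
                 replicate = rep(seq_len(design$n_reps), Tw)),
      data.frame(genotype = "tert", age_group = rep(mut_ages, each = design$n_reps),
                 replicate = rep(seq_len(design$n_reps), Tm)))
    cells$sample <- sprintf("%s_%s_R%d", cells$genotype, cells$age_group,
                            cells$replicate)
    S <- nrow(cells)
    sf <- exp(stats::runif(S, log(design$libsize_range[1]),
                           log(design$libsize_range[2])))
    names(sf) <- cells$sample

    counts <- matrix(0, G, S, dimnames = list(genes, cells$sample))
    for (j in seq_len(S)) {
      off <- if (cells$genotype[j] == "WT") off_wt[, cells$age_group[j]]
             else off_mut[, cells$age_group[j]]
      mu <- sf[j] * base_mean * 2^off
      counts[, j] <- stats::rnbinom(G, mu = mu, size = 1 / alpha)
    }

    mut_onset <- rep(NA_integer_, G)
    mut_onset[i_up] <- ifelse(wt_onset[i_up] <= Tm, wt_onset[i_up], NA_integer_)
    mut_onset[i_dn] <- ifelse(wt_onset[i_dn] <= Tm, wt_onset[i_dn], NA_integer_)
    mut_onset[i_ac] <- wt_onset[i_ac] - 1L

    truth <- data.frame(
      gene = genes, class = cls,
      direction = c("down", "none", "up")[dir + 2L],
      wt_onset_age = ifelse(is.na(wt_onset), NA_character_, wt_ages[wt_onset]),
      mut_onset_age = ifelse(is.na(mut_onset), NA_character_, wt_ages[mut_onset]),
      base_mean = base_mean, dispersion = alpha,
      stringsAsFactors = FALSE)
    ow <- as.data.frame(off_wt); names(ow) <- paste0("offset_wt_", wt_ages)
    om <- as.data.frame(off_mut); names(om) <- paste0("offset_mut_", mut_ages)
    truth <- cbind(truth, ow, om)
    rownames(truth) <- NULL

    cm <- count_matrix(counts, cells[, c("sample", "genotype", "age_group",
                                         "replicate")],
                       age_levels = wt_ages)
    structure(list(counts = cm, truth = truth, size_factors = sf,
                   design = design),
              class = "sim_experiment")
  })
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("sim_experiment: %d genes, %d samples (seed %d)\n",
              nrow(x$counts$counts), ncol(x$counts$counts), x$design$seed))
  print(table(x$truth$class))
  invisible(x)
}

# ---- annotation fixture -----------------------------------------------------

# Term-name vocabularies used to build the fixture ontology. The themed names
# contain the keywords the default hallmark map looks for; filler names do not.
.fixture_terms <- list(
  immune = c("immune response", "innate immune response",
             "regulation of immune effector process", "inflammatory response",
             "leukocyte activation", "cytokine production",
             "response to interferon-gamma", "leukocyte migration",
             "positive regulation of cytokine secretion",
             "acute inflammatory response"),
  cycle = c("cell cycle", "mitotic cell cycle", "cell division",
            "chromosome segregation", "DNA replication",
            "regulation of cell cycle phase transition",
            "spindle assembly", "sister chromatid cohesion"),
  stress = c("response to oxidative stress", "cellular response to stress",
             "DNA damage response", "response to heat shock",
             "regulation of apoptotic process", "response to unfolded protein"),
  expression = c("regulation of transcription by RNA polymerase II",
                 "chromatin remodeling", "mRNA processing",
                 "regulation of gene expression", "histone modification",
                 "RNA splicing"),
  filler = c("ribosome biogenesis", "lipid transport", "ion homeostasis",
             "axon guidance", "synaptic vesicle cycle", "cilium assembly",
             "glucose metabolic process", "protein folding",
             "vesicle-mediated transport", "actin filament organization",
             "calcium ion transmembrane transport", "neurotransmitter secretion",
             "myelination", "wound healing", "bone mineralization",
             "heart contraction", "visual perception", "olfactory learning",
             "phototransduction", "tissue regeneration"))

#' Default hallmark keyword map
#'
#' A small keyword dictionary mapping lowercase keywords to ageing
#' transcriptomic hallmark labels, in the two-column layout
#' (`hallmark`, `keyword`) accepted by [read_keyword_map()]. It is a synthetic
#' stand-in shipped for examples and fixtures (also as the file
#' `system.file("extdata", "hallmark_keywords_synthetic.csv", package =
#' "ageaccel")`); real analyses should supply a curated map.
#'
#' @return Data frame with columns `hallmark` and `keyword`.
#' @export
default_keyword_map <- function() {
  data.frame(
    hallmark = c(rep("immune_dysregulation", 5),
                 rep("stress_response", 5),
                 rep("gene_expression_dysregulation", 5)),
    keyword = c("immune", "inflammat", "leukocyte", "cytokine", "interferon",
                "stress", "dna damage", "heat shock", "apoptot", "unfolded protein",
                "transcription", "chromatin", "mrna processing",
                "gene expression", "rna splicing"),
    stringsAsFactors = FALSE)
}

#' Generate annotation fixtures matched to a simulated experiment
#'
#' Builds the annotation inputs the downstream stages need — a minimal
#' ontology, a gene-to-GO-term table, a hallmark keyword map, cell-type
#' marker programmes and SASP-like gene sets — with their structure aligned
#' to the planted gene classes: immune-class genes always carry at least one
#' term whose name matches an immune-hallmark keyword, cycling-class genes
#' carry cell-cycle terms, the microglia/leukocyte marker programmes are
#' drawn mostly from immune-class genes and the cycling programme from
#' cycling-class genes, and the SASP sets contain a known number of
#' accelerated-class genes. All draws are seeded from the design.
#'
#' @param sim A `sim_experiment` from [simulate_experiment()].
#' @param n_background_terms Number of unthemed filler terms in the ontology.
#' @param sasp_accelerated How many accelerated-class genes to plant inside
#'   the SASP sets (capped at the number available).
#' @return A list of class `sim_annotation` with elements `ontology` (data
#'   frame: `id`, `name`, `namespace`, `is_obsolete`), `gene2go` (data frame:
#'   `gene`, `term`), `keyword_map` (data frame: `hallmark`, `keyword`),
#'   `markers` and `sasp` (both [gene_set_collection()]s).
#' @export
simulate_annotation <- function(sim, n_background_terms = 40,
                                sasp_accelerated = 52) {
  stopifnot(inherits(sim, "sim_experiment"))
  design <- sim$design
  truth <- sim$truth
  with_seed(design$seed + 1L, {
    v <- .fixture_terms
    filler <- c(v$filler,
                if (n_background_terms > length(v$filler))
                  sprintf("biological process %02d",
                          seq_len(n_background_terms - length(v$filler))))
    filler <- filler[seq_len(min(n_background_terms, length(filler)))]
    names_all <- c(v$immune, v$cycle, v$stress, v$expression, filler)
    ns <- rep("biological_process", length(names_all))
    obs <- rep(FALSE, length(names_all))
    # a couple of non-BP and obsolete terms so readers and term maps must filter
    names_all <- c(names_all, "immune receptor activity", "nuclear chromatin",
                   "obsolete immune process")
    ns <- c(ns, "molecular_function", "cellular_component", "biological_process")
    obs <- c(obs, FALSE, FALSE, TRUE)
    ontology <- data.frame(
      id = sprintf("GO:%07d", seq_along(names_all)),
      name = names_all, namespace = ns, is_obsolete = obs,
      stringsAsFactors = FALSE)

    theme_ids <- function(theme) ontology$id[match(v[[theme]], ontology$name)]
    id_immune <- theme_ids("immune"); id_cycle <- theme_ids("cycle")
    id_stress <- theme_ids("stress"); id_expr <- theme_ids("expression")
    id_filler <- ontology$id[match(filler, ontology$name)]

    genes <- truth$gene
    cls <- truth$class
    annotated <- stats::runif(length(genes)) >= design$unannotated_fraction
    # class genes always carry their theme annotation
    annotated[cls != "null"] <- TRUE

    ann <- vector("list", length(genes))
    for (i in seq_along(genes)) {
      if (!annotated[i]) next
      terms <- sample(id_filler, sample(1:4, 1))
      if (cls[i] == "immune_up") {
        terms <- c(sample(id_immune, sample(2:4, 1)), terms)
      } else if (cls[i] == "cycling_down") {
        terms <- c(sample(id_cycle, sample(2:4, 1)), terms)
      } else if (cls[i] == "accelerated") {
        extra <- if (truth$direction[i] == "up") id_immune else id_cycle
        terms <- c(sample(c(id_stress, id_expr, extra), sample(2:4, 1)), terms)
      } else if (stats::runif(1) < 0.15) {
        # a sprinkling of hallmark terms on null genes, as in real annotation
        terms <- c(sample(c(id_immune, id_cycle, id_stress, id_expr), 1), terms)
      }
      ann[[i]] <- unique(terms)
    }
    gene2go <- data.frame(
      gene = rep(genes, lengths(ann)),
      term = unlist(ann, use.names = FALSE),
      stringsAsFactors = FALSE)

    g_imm <- genes[cls == "immune_up"]
    g_cyc <- genes[cls == "cycling_down"]
    g_acc <- genes[cls == "accelerated"]
    g_null <- genes[cls == "null"]
    take <- function(x, frac) {
      n <- max(1L, round(frac * length(x)))
      sample(x, min(n, length(x)))
    }
    markers <- gene_set_collection(list(
      microglia = c(take(g_imm, 0.6), take(g_null, 0.01)),
      leukocyte = c(take(g_imm, 0.5), take(g_null, 0.01)),
      cycling_cells = c(take(g_cyc, 0.6), take(g_null, 0.01)),
      neural_progenitors = c(take(g_cyc, 0.25), take(g_null, 0.02)),
      oligodendrocytes = c(take(g_cyc, 0.15), take(g_null, 0.02)),
      neurons = take(g_null, 0.04)),
      universe = genes, provenance = "synthetic marker programmes")

    n_sasp <- min(sasp_accelerated, length(g_acc))
    sasp_core <- if (n_sasp) sample(g_acc, n_sasp) else character()
    sasp <- gene_set_collection(list(
      sasp_atlas_like = unique(c(sasp_core, take(g_null, 0.02), take(g_imm, 0.1))),
      senmayo_like = unique(c(sample(sasp_core, ceiling(n_sasp / 3)),
                              take(g_null, 0.015), take(g_imm, 0.15)))),
      universe = genes, provenance = "synthetic SASP sets")

    structure(list(ontology = ontology, gene2go = gene2go,
                   keyword_map = default_keyword_map(),
                   markers = markers, sasp = sasp),
              class = "sim_annotation")
  })
}

#' Write every annotation fixture to disk
#'
#' Writes the ontology as a minimal OBO file, the gene-to-term table as TSV,
#' the keyword map as CSV, and the marker / SASP collections as GMT, using the
#' formats the corresponding readers expect.
#'
#' @param ann A `sim_annotation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of file paths.
#' @export
write_annotation <- function(ann, dir) {
  stopifnot(inherits(ann, "sim_annotation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ontology = file.path(dir, "ontology.obo"),
             gene2go = file.path(dir, "gene2go.tsv"),
             keyword_map = file.path(dir, "hallmark_keywords.csv"),
             markers = file.path(dir, "markers.gmt"),
             sasp = file.path(dir, "sasp.gmt"))
  write_obo(ann$ontology, paths[["ontology"]])
  utils::write.table(ann$gene2go, paths[["gene2go"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(ann$keyword_map, paths[["keyword_map"]], row.names = FALSE)
  write_gmt(ann$markers, paths[["markers"]])
  write_gmt(ann$sasp, paths[["sasp"]])
  invisible(paths)
}
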