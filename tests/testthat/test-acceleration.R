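genes <- sprintf("g%02d", 1:10)

wt_old_deg <- function(sig, dirs)
  make_deg(genes, sig, dirs,
           reference = list(genotype = "WT", age_group = "2-6"),
           test = list(genotype = "WT", age_group = "30-36"))

test_that("old-age signature filters the right contrast and genes", {
  deg <- wt_old_deg(c("g01", "g02", "g03", "g04", "g05"),
                    c("up", "up", "up", "down", "down"))
  sig <- old_age_signature(deg)
  expect_equal(nrow(sig), 5)
  expect_equal(sum(sig$direction == "up"), 3)
  expect_equal(sum(sig$direction == "down"), 2)

  empty <- old_age_signature(wt_old_deg(character(), character()))
  expect_equal(nrow(empty), 0)

  wrong <- make_deg(genes, "g01", "up",
                    reference = list(genotype = "WT", age_group = "2-6"),
                    test = list(genotype = "WT", age_group = "18-24"))
  expect_error(old_age_signature(wrong), "youngest-vs-oldest")
})

test_that("acceleration rules: onset, direction and sibling checks", {
  sig <- old_age_signature(wt_old_deg(c("g01", "g02", "g03", "g04"),
                                      c("up", "up", "up", "down")))
  mut <- list(
    "9-16" = make_deg(genes, c("g01", "g02", "g04"), c("up", "down", "down")),
    "18-24" = make_deg(genes, c("g01", "g03"), c("up", "up")))
  sib <- list(
    "9-16" = make_deg(genes, "g02", "up"),
    "18-24" = make_deg(genes, "g03", "up"))
  res <- classify_acceleration(sig, mut, sib)
  r <- res$records

  # g01: up in mutant at 9-16, sibling WT silent there -> accelerated, onset 9-16
  expect_true(r$accelerated[r$gene == "g01"])
  expect_equal(r$onset_age[r$gene == "g01"], "9-16")  # earliest onset wins
  # g02: mutant goes the wrong way -> direction rule excludes it
  expect_false(r$accelerated[r$gene == "g02"])
  # g03: mutant onset 18-24 but sibling WT already significant there
  expect_false(r$accelerated[r$gene == "g03"])
  expect_true(r$sibling_significant[r$gene == "g03"])
  # g04: down in WT old and down in mutant early -> accelerated
  expect_true(r$accelerated[r$gene == "g04"])

  expect_equal(unname(res$onset_counts), c(2, 0))
  expect_equal(res$n_accelerated, 2)
  expect_equal(res$pct_of_signature, 50)

  expect_error(classify_acceleration(sig, mut, sib["9-16"]), "same age groups")
})

test_that("negative control: mutant cloned from sibling WT yields nothing", {
  sig <- old_age_signature(wt_old_deg(c("g01", "g02"), c("up", "down")))
  wt_tab <- list("9-16" = make_deg(genes, "g01", "up"),
                 "18-24" = make_deg(genes, c("g01", "g02"), c("up", "down")))
  res <- classify_acceleration(sig, wt_tab, wt_tab)
  expect_equal(res$n_accelerated, 0)
  expect_equal(res$pct_of_signature, 0)
})

test_that("onset lists are disjoint subsets of the signature and direction
           filtering is monotone", {
  sim <- small_sim()
  sf <- size_factors(sim$counts, fallback = TRUE)
  ct <- function(ref, tst) nb_test(sim$counts, ref, tst, sf = sf)
  wt <- list(
    "9-16" = ct(list(genotype = "WT", age_group = "2-6"),
                list(genotype = "WT", age_group = "9-16")),
    "18-24" = ct(list(genotype = "WT", age_group = "2-6"),
                 list(genotype = "WT", age_group = "18-24")))
  mut <- list(
    "9-16" = ct(list(genotype = "tert", age_group = "2-6"),
                list(genotype = "tert", age_group = "9-16")),
    "18-24" = ct(list(genotype = "tert", age_group = "2-6"),
                 list(genotype = "tert", age_group = "18-24")))
  old <- ct(list(genotype = "WT", age_group = "2-6"),
            list(genotype = "WT", age_group = "30-36"))
  sig <- old_age_signature(old)
  res <- classify_acceleration(sig, mut, wt)
  acc <- res$records[res$records$accelerated, ]
  by_onset <- split(acc$gene, acc$onset_age)
  expect_equal(sum(lengths(by_onset)), length(unique(acc$gene)))
  expect_true(all(acc$gene %in% sig$gene))
  expect_true(all(match(acc$onset_age, AGE_GROUPS) < length(AGE_GROUPS)))
  # dropping the direction-consistency requirement can only grow the set
  relaxed <- classify_acceleration(sig, mut, wt, require_direction = FALSE)
  expect_true(all(acc$gene %in%
                    relaxed$records$gene[relaxed$records$accelerated]))
})

test_that("profile-overlap acceleration applies direction and onset rules", {
  v_wt <- rbind(g1 = c(0, 0.1, 0.2, 2), g2 = c(0, 0.1, 0.3, 1.8),
                g3 = c(0, -0.2, -0.4, -2))
  colnames(v_wt) <- AGE_GROUPS
  v_mut <- rbind(g1 = c(0, 1.9, 2), g2 = c(0, 0.2, 0.3),
                 g3 = c(0, -0.1, -1.7))
  colnames(v_mut) <- AGE_GROUPS[1:3]
  asn <- function(g, p, d) data.frame(gene = g, profile_id = p,
                                      correlation = 0.99, direction = d,
                                      stringsAsFactors = FALSE)
  sig <- function(p, d) data.frame(profile_id = p, direction = d, n_genes = 3,
                                   pvalue = 0.001, padj = 0.01,
                                   significant = TRUE,
                                   stringsAsFactors = FALSE)
  wt_fit <- make_stem_fit("WT", v_wt,
                          asn(c("g1", "g2", "g3"), c(5L, 5L, 9L),
                              c("up", "up", "down")),
                          sig(c(5L, 9L), c("up", "down")))
  mut_fit <- make_stem_fit("tert", v_mut,
                           asn(c("g1", "g2", "g3"), c(7L, 7L, 2L),
                               c("up", "up", "down")),
                           sig(c(7L, 2L), c("up", "down")))
  ov <- stem_acceleration_overlap(wt_fit, mut_fit, threshold = 0.5)
  # g1 crosses +0.5 at mutant age rank 2 while WT only crosses at rank 4
  expect_true("g1" %in% ov$gene)
  expect_equal(ov$onset_age[ov$gene == "g1"], "9-16")
  # g2 never crosses the threshold in the mutant
  expect_false("g2" %in% ov$gene)
  # g3 is a down gene accelerated to 18-24
  expect_equal(ov$onset_age[ov$gene == "g3"], "18-24")

  # direction mismatch excludes a gene even when both profiles are significant
  mut_flip <- make_stem_fit("tert", v_mut,
                            asn("g1", 2L, "down"), sig(2L, "down"))
  expect_equal(nrow(stem_acceleration_overlap(wt_fit, mut_flip)), 0)
})

test_that("the overlap rule recovers its candidates on synthetic truth", {
  # a generously planted fixture, so that both genotypes carry clearly
  # significant profiles and the overlap logic itself is what is under test
  sim <- simulate_experiment(sim_design(
    n_genes = 3000,
    class_fractions = c(immune_up = 0.1, cycling_down = 0.1,
                        accelerated = 0.1, null = 0.7),
    seed = 404))
  sf <- size_factors(sim$counts, fallback = TRUE)
  fw <- stem_fit(sim$counts, "WT", n_perm = 1000, seed = 11, sf = sf)
  fm <- stem_fit(sim$counts, "tert", n_perm = 1000, seed = 12, sf = sf)
  ov <- stem_acceleration_overlap(fw, fm, threshold = 0.5)
  truth_acc <- sim$truth$gene[sim$truth$class == "accelerated"]
  # listed planted genes carry the planted mutant onset age
  hit <- ov[ov$gene %in% truth_acc, ]
  tr <- sim$truth[match(hit$gene, sim$truth$gene), ]
  expect_gt(nrow(hit), 0)
  expect_gte(mean(hit$onset_age == tr$mut_onset_age), 0.9)
  # among genes in significant profiles of both genotypes with matching
  # direction, planted accelerated genes are recovered essentially completely
  cand <- intersect(significant_profile_genes(fw)$gene,
                    significant_profile_genes(fm)$gene)
  cand_acc <- intersect(cand, truth_acc)
  expect_gt(length(cand_acc), 0)
  expect_gte(mean(cand_acc %in% ov$gene), 0.9)
})
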