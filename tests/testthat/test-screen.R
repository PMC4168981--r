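mk_tab <- function(...) {
  tab <- data.frame(..., stringsAsFactors = FALSE)
  class(tab) <- c("mutation_table", "data.frame")
  tab
}

test_that("mutation summary computes per-sample counts and class percentages", {
  tab <- mk_tab(gene = c(paste0("g", 1:2), paste0("g", 1:5), paste0("g", 1:8)),
                sample = rep(c("s1", "s2", "s3"), c(2, 5, 8)),
                mclass = "missense", fis = 1)
  s <- mutation_summary(tab)
  expect_equal(s$median, 5)
  expect_equal(s$mean, 5)
  tab2 <- mk_tab(gene = paste0("g", 1:10), sample = "s1",
                 mclass = rep(c("missense", "silent"), c(6, 4)), fis = 1)
  expect_equal(unname(mutation_summary(tab2)$per_class["missense"]), 60)
  expect_equal(sum(mutation_summary(tab2)$per_class), 100)
  expect_warning(s0 <- mutation_summary(mk_tab(gene = character(0),
                                               sample = character(0),
                                               mclass = character(0))),
                 "empty")
  expect_equal(nrow(s0$per_sample), 0)
})

test_that("recurrence threshold arithmetic follows the 5% rule", {
  tab <- mk_tab(gene = c(rep("gA", 3), rep("gB", 2), rep("gC", 2)),
                sample = c("s1", "s2", "s3", "s1", "s2", "s1", "s1"),
                mclass = "missense", fis = 3)
  out <- recurrence_filter(tab, n_samples = 44)
  expect_true("gA" %in% out$gene)        # 3/44 = 6.8%
  expect_false("gB" %in% out$gene)       # 2/44 = 4.5%
  # duplicate records in one sample count once
  expect_equal(out$n_mutated_samples[out$gene == "gA"], 3)
  expect_false("gC" %in% out$gene)       # 1 distinct sample
  expect_error(recurrence_filter(tab, 44, threshold = 0), "threshold")
  # boundary: exactly 5% is retained (>= rule)
  tab5 <- mk_tab(gene = rep("gD", 2), sample = c("s1", "s2"),
                 mclass = "missense", fis = 3)
  expect_true("gD" %in% recurrence_filter(tab5, 40)$gene)
})

test_that("transporter-only genes are excluded when a model is given", {
  m <- generate_toy_model(synthetic_scenario(1))
  tab <- mk_tab(gene = rep(c("g_pyrt", "g_sdh"), each = 4),
                sample = rep(paste0("s", 1:4), 2),
                mclass = "nonsense", fis = 3)
  out <- recurrence_filter(tab, 40, model = m)
  expect_false("g_pyrt" %in% out$gene)
  expect_true("g_sdh" %in% out$gene)
})

test_that("arm classification is per-class recurrence", {
  n <- 40
  tab <- mk_tab(
    gene = c(rep("lofg", 3), rep("both", 6), rep("sil", 4)),
    sample = c(paste0("s", 1:3), paste0("s", 1:6), paste0("s", 1:4)),
    mclass = c(rep("nonsense", 3),
               rep(c("missense", "frameshift_indel"), 3),
               rep("silent", 4)),
    fis = 3)
  arms <- classify_arms(tab, n)
  expect_equal(arms[["lofg"]], "LoF")
  expect_setequal(arms[["both"]], c("LoF", "GoF"))
  expect_length(arms[["sil"]], 0)
  expect_error(classify_arms(mk_tab(gene = "g", sample = "s",
                                    mclass = "weird", fis = 1), n),
               "unknown mutation classes")
})

test_that("isoenzyme filter keeps genes with at least one unsubstitutable reaction", {
  mets <- data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                     compartment = "c")
  rx <- list(
    list(id = "EX_A", stoichiometry = c(A = 1), lower_bound = 0, upper_bound = 10),
    list(id = "R1", stoichiometry = c(A = -1, B = 1), lower_bound = 0,
         upper_bound = 10, gpr = "g1 or g2"),
    list(id = "R2", stoichiometry = c(B = -1, C = 1), lower_bound = 0,
         upper_bound = 10, gpr = "g3 and g4"),
    list(id = "R3", stoichiometry = c(C = -1), lower_bound = 0,
         upper_bound = 10, gpr = "g2"))
  m <- metabolic_model(mets, rx)
  kept <- isoenzyme_filter(c("g1", "g2", "g3", "g5"), m)
  expect_false("g1" %in% kept)   # fully substitutable (OR partner)
  expect_true("g3" %in% kept)    # AND-complex member
  expect_true("g2" %in% kept)    # redundant in R1 but sole catalyst of R3
  expect_false("g5" %in% kept)   # in no GPR, removed with note
  expect_match(attr(kept, "notes"), "g5")
})

test_that("FIS filter aggregates by maximum", {
  tab <- mk_tab(gene = c("gA", "gA", "gB", "gB"), sample = paste0("s", 1:4),
                mclass = "missense", fis = c(1.2, 3.9, 1.0, 1.5))
  expect_equal(fis_filter(c("gA", "gB"), tab, min_fis = 3.5), "gA")
  expect_equal(fis_filter(c("gA", "gB"), tab, min_fis = NULL), c("gA", "gB"))
  tab$fis[3:4] <- NA
  expect_error(fis_filter(c("gB"), tab, 1.9), "gB")
})

test_that("pathway enrichment equals the exact combinatorial sum", {
  # universe 20 genes, one subsystem of 5, 4 selected with overlap 3
  mets <- data.frame(id = "A", name = "A", compartment = "c")
  rx <- list(list(id = "EX", stoichiometry = c(A = 1), lower_bound = 0,
                  upper_bound = 1),
             list(id = "R1", stoichiometry = c(A = -1), lower_bound = 0,
                  upper_bound = 1, subsystem = "path1",
                  gpr = paste(paste0("u", 1:5), collapse = " or ")))
  universe <- paste0("u", 1:20)
  m <- metabolic_model(mets, rx, genes = universe)
  selected <- c("u1", "u2", "u3", "u10")
  out <- pathway_enrichment(selected, m, universe = universe)
  expect_equal(out$p_value[out$subsystem == "path1"],
               oracle_hyper_upper(3, 5, 20, 4), tolerance = 1e-12)
  # zero overlap is not enriched; saturated subsystem has P = 1
  out0 <- pathway_enrichment(c("u10", "u11"), m, universe = universe)
  expect_gt(out0$p_value[1], 0.4)
  rx[[2]]$gpr <- paste(universe, collapse = " or ")
  m2 <- metabolic_model(mets, rx, genes = universe)
  expect_equal(pathway_enrichment(selected, m2, universe)$p_value[1], 1)
  expect_error(pathway_enrichment(selected, m, universe = character(0)),
               "empty")
})

test_that("the funnel is monotone and recovers planted genes", {
  sc <- synthetic_scenario(6)
  m <- generate_toy_model(sc)
  muts <- generate_mutations(sc, m)
  scr <- mutation_screen(muts, sc$n_samples_cancer, m)
  sel <- scr$gene[scr$selected]
  rec <- recurrence_filter(muts, sc$n_samples_cancer, model = m)$gene
  expect_true(all(sel %in% rec))
  expect_true(all(rec %in% unique(muts$gene)))
  expect_true(all(c("g_sdh", "g_fh", "g_idh") %in% sel))
  # decoys rejected: isoenzyme, transporter, silent-only, low-FIS
  expect_false(any(c("g_hk1", "g_pyrt", "g_gly", "g_ldh") %in% sel))
})
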