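test_that("GPR rules parse, evaluate and round-trip", {
  tree <- gpr_parse("(g1 and g2) or g3")
  expect_equal(sort(gpr_genes(tree)), c("g1", "g2", "g3"))
  expect_equal(gpr_deparse(tree), "(g1 and g2) or g3")
  pres <- c(g1 = FALSE, g2 = TRUE, g3 = FALSE)
  expect_false(gpr_eval(tree, pres))
  expect_true(gpr_eval(tree, c(g1 = TRUE, g2 = TRUE, g3 = FALSE)))
  # operator keywords are case-insensitive
  expect_false(gpr_eval(gpr_parse("G1 AND g2"), c(G1 = TRUE, g2 = FALSE)))
  expect_null(gpr_parse(""))
  expect_error(gpr_parse("g1 and g2 or g3"), "parentheses")
  expect_error(gpr_parse("g1 and (g2"), "\\)")
})

test_that("gene deletion closes reactions per AND/OR semantics", {
  m <- generate_toy_model(synthetic_scenario(1))
  # isoenzyme OR survives single deletion
  d1 <- delete_genes(m, "g_hk1")
  expect_length(attr(d1, "closed_reactions"), 0)
  # both isoenzymes gone closes the reaction
  d2 <- delete_genes(m, c("g_hk1", "g_hk2"))
  expect_equal(attr(d2, "closed_reactions"), "HK")
  expect_equal(unname(model_bounds(d2)$ub["HK"]), 0)
  expect_error(delete_genes(m, "nonexistent"), "unknown genes")
})

test_that("nested GPR evaluation and deletion idempotence/order-independence", {
  mets <- data.frame(id = "A", name = "A", compartment = "c")
  rx <- list(list(id = "R1", stoichiometry = c(A = 1), lower_bound = 0,
                  upper_bound = 10, gpr = "(g1 and g2) or g3"),
             list(id = "EX", stoichiometry = c(A = -1), lower_bound = 0,
                  upper_bound = 10))
  m <- metabolic_model(mets, rx)
  d <- delete_genes(m, c("g1", "g3"))
  expect_equal(attr(d, "closed_reactions"), "R1")
  set.seed(1)
  for (k in 1:5) {
    gs <- sample(m$genes, sample(1:3, 1))
    a <- delete_genes(m, gs)
    b <- delete_genes(delete_genes(m, gs), gs)          # idempotent
    c_ <- delete_genes(m, rev(gs))                      # order-independent
    expect_equal(model_bounds(a), model_bounds(b))
    expect_equal(model_bounds(a), model_bounds(c_))
  }
})

test_that("FBA solves the chain model and signals infeasibility", {
  m <- chain_model()
  expect_equal(fba(m)$objective_value, 3)
  # starvation: no uptake, objective zero
  m0 <- set_bounds(m, "E_in", ub = 0)
  expect_equal(fba(m0)$objective_value, 0)
  # forced demand above capacity is infeasible, never a zero vector
  m_inf <- set_bounds(m, "BIO", lb = 7)
  expect_error(fba(m_inf), "infeasible")
})

test_that("FBA matches the independent LP oracle on all fixtures", {
  for (m in list(chain_model(), cycle_model(),
                 generate_toy_model(synthetic_scenario(1)),
                 box_model(c(-2, 0, 1), c(3, 5, 4)))) {
    got <- fba(m)$objective_value
    want <- oracle_fba_max(m)
    expect_lt(abs(got - want) / max(1, abs(want)), 1e-6)
  }
})

test_that("flux vectors respect steady state and bounds", {
  m <- generate_toy_model(synthetic_scenario(1))
  v <- fba(m)$values
  expect_lt(max(abs(stoich_matrix(m) %*% v)), 1e-6)
  b <- model_bounds(m)
  expect_true(all(v >= b$lb - 1e-9 & v <= b$ub + 1e-9))
})

test_that("deletion screen categories follow the growth-ratio thresholds", {
  m <- generate_toy_model(synthetic_scenario(1))
  scr <- single_gene_deletion_screen(m)
  expect_setequal(scr$gene, m$genes)
  # categories partition the gene set
  expect_true(all(scr$category %in% c("essential", "reduced_1_10", "no_change")))
  expect_equal(sum(table(scr$category)), length(m$genes))
  # isoenzyme pair is neutral
  expect_equal(scr$category[scr$gene %in% c("g_hk1", "g_hk2")],
               rep("no_change", 2))
  # sole-path gene kills growth
  expect_equal(scr$growth_ratio[scr$gene == "g_gly"], 0)
  expect_equal(scr$category[scr$gene == "g_gly"], "essential")
  # planted throttling transporter: ~95% capacity -> mild reduction
  expect_equal(scr$category[scr$gene == "g_glct2"], "reduced_1_10")
  r <- scr$growth_ratio[scr$gene == "g_glct2"]
  # oracle: re-solve with the tightened glucose bound
  m2 <- delete_genes(m, "g_glct2")
  expect_equal(r, oracle_fba_max(m2) / oracle_fba_max(m), tolerance = 1e-6)
  expect_true(all(scr$growth_ratio >= 0 & scr$growth_ratio <= 1 + 1e-9))
})

test_that("FVA brackets FBA and respects the optimality fraction", {
  m <- chain_model()
  out <- fva(m, fraction = 0.9)
  expect_equal(out$min[out$reaction == "BIO"], 2.7, tolerance = 1e-9)
  expect_equal(out$max[out$reaction == "BIO"], 3, tolerance = 1e-9)
})
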