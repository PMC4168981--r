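test_that("presence calls implement strict consensus", {
  expr <- matrix(20, nrow = 2, ncol = 100,
                 dimnames = list(c("gA", "gB"), NULL))
  expr["gB", 1] <- 0                      # detected in 99/100
  calls <- presence_calls(expr, threshold = 10, consensus = 0.99)
  expect_true(calls[["gA"]])
  expect_false(calls[["gB"]])             # strict "more than 99%"
  expr0 <- matrix(0, 1, 10, dimnames = list("gC", NULL))
  expect_false(presence_calls(expr0)[["gC"]])
  dup <- matrix(1, 2, 3, dimnames = list(c("g", "g"), NULL))
  expect_error(presence_calls(dup), "duplicated")
  expect_error(presence_calls(expr, consensus = 0), "consensus")
})

test_that("objective scaling divides by each term's maximum flux", {
  m <- chain_model()
  # second demand branch from B so ATP-like term has its own max
  m$reactions[["DEM"]] <- list(id = "DEM", stoichiometry = c(B = -1),
                               lower_bound = 0, upper_bound = 6, gpr = "",
                               subsystem = "", is_exchange = TRUE,
                               is_transport = FALSE, gpr_tree = NULL)
  obj <- scale_objective(m, c("BIO", "DEM"), c(1, 1))
  scales <- attr(obj, "scales")
  expect_equal(unname(obj["BIO"]), 1 / scales[["BIO"]])
  expect_equal(unname(obj["DEM"]), 1 / scales[["DEM"]])
  expect_equal(unname(scales), c(3, 3))   # both limited by AB <= 3
  # b = 0 reduces to pure scaled biomass maximization
  obj10 <- scale_objective(m, c("BIO", "DEM"), c(1, 0))
  expect_equal(names(obj10), "BIO")
  f1 <- fba(m, objective = obj10)
  expect_equal(f1$objective_value, 1, tolerance = 1e-9)  # scaled optimum
  expect_equal(unname(f1$values["BIO"]), 3, tolerance = 1e-9)
  # combined optimum between each single-term optimum and a + b
  fc <- fba(m, objective = obj)$objective_value
  expect_gte(fc + 1e-9, 1)
  expect_lte(fc, 2 + 1e-9)
  # unscalable term errors
  m0 <- set_bounds(m, "E_in", ub = 0)
  expect_error(scale_objective(m0, c("BIO"), 1), "zero maximum")
})

test_that("GIMME keeps the objective path and prunes unused absent branches", {
  # A can reach biomass through main (gene gm) or bypass (gene gb)
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c")
  rx <- list(
    list(id = "IN", stoichiometry = c(A = 1), lower_bound = 0, upper_bound = 5),
    list(id = "MAIN", stoichiometry = c(A = -1, B = 1), lower_bound = 0,
         upper_bound = 10, gpr = "gm"),
    list(id = "BYPASS", stoichiometry = c(A = -1, B = 1), lower_bound = 0,
         upper_bound = 10, gpr = "gb"),
    list(id = "BIO", stoichiometry = c(B = -1), lower_bound = 0,
         upper_bound = 10))
  m <- metabolic_model(mets, rx, objective = c(BIO = 1))
  # all present: identity, inconsistency 0
  res_all <- gimme_extract(m, c(gm = TRUE, gb = TRUE))
  expect_equal(res_all$inconsistency, 0)
  expect_setequal(reaction_ids(res_all$model), reaction_ids(m))
  # absent bypass carries no flux and is removed
  res_b <- gimme_extract(m, c(gm = TRUE, gb = FALSE))
  expect_equal(res_b$removed, "BYPASS")
  expect_equal(res_b$inconsistency, 0)
  # absent sole path: retained with positive inconsistency equal to the
  # LP-oracle minimum |v| needed for 90% of the optimum
  res_m <- gimme_extract(m, c(gm = FALSE, gb = FALSE))
  expect_true(all(c("MAIN", "BYPASS") %in% reaction_ids(res_m$model)) ||
              res_m$inconsistency > 0)
  expect_equal(res_m$inconsistency, 0.9 * 5, tolerance = 1e-6)
  expect_true("MAIN" %in% reaction_ids(res_m$model) ||
              "BYPASS" %in% reaction_ids(res_m$model))
})

test_that("GIMME output is a feasible sub-network at the required fraction", {
  sc <- synthetic_scenario(2)
  m <- generate_toy_model(sc)
  expr <- generate_expression(sc, m)
  calls <- presence_calls(expr$cancer, threshold = sc$detection_threshold)
  res <- gimme_extract(m, calls, required_fraction = 0.9)
  expect_true(all(reaction_ids(res$model) %in% reaction_ids(m)))
  opt_full <- fba(m)$objective_value
  expect_gte(fba(res$model)$objective_value, 0.9 * opt_full - 1e-6)
  # inconsistency non-increasing when a present gene is added back
  calls2 <- calls
  calls2[["g_byp"]] <- TRUE
  res2 <- gimme_extract(m, calls2, required_fraction = 0.9)
  expect_lte(res2$inconsistency, res$inconsistency + 1e-9)
})

test_that("medium application is idempotent and controls feasibility", {
  m <- generate_toy_model(synthetic_scenario(1))
  medium <- read_medium(system.file("extdata", "medium_toy.yaml",
                                    package = "oncoflux"))
  closed <- set_bounds(m, c("EX_glc", "EX_o2"), lb = 0)
  expect_error(fba(closed), "infeasible")   # maintenance unmet without carbon
  reopened <- apply_medium(closed, medium)
  expect_gt(fba(reopened)$objective_value, 0)
  again <- apply_medium(reopened, medium)
  expect_equal(model_bounds(again), model_bounds(reopened))
  no_carbon <- apply_medium(m, list(uptakes = c(EX_o2 = 25)))
  expect_error(fba(no_carbon), "infeasible")
  expect_error(apply_medium(m, list(uptakes = c(EX_nope = 1))), "unknown")
})

test_that("structure-expression correlation separates planted clusters", {
  genes <- paste0("g", 1:30)
  base_m <- generate_toy_model(synthetic_scenario(1))
  mk_calls <- function(absent) {
    v <- rep(TRUE, 30); names(v) <- genes; v[absent] <- FALSE; v
  }
  mk_model <- function(drop) subset_model(base_m,
                                          setdiff(reaction_ids(base_m), drop))
  calls <- list(a = mk_calls(1:5), b = mk_calls(1:5),
                c = mk_calls(10:18), d = mk_calls(10:18),
                e = mk_calls(20:28), f = mk_calls(20:28))
  models <- list(a = mk_model(c("LDH", "BYP")), b = mk_model(c("LDH", "BYP")),
                 c = mk_model("SUCCt"), d = mk_model("SUCCt"),
                 e = mk_model(c("FUMt", "PC", "LACt")),
                 f = mk_model(c("FUMt", "PC", "LACt")))
  out <- structure_expression_correlation(calls, models, n_perm = 200,
                                          seed = 7)
  expect_true(all(out$pcc > 0.9))
  expect_true(all(out$permutation_p < 0.05))
  # identical everything: degenerate, PCC 1 by convention
  same <- structure_expression_correlation(
    list(a = mk_calls(1), b = mk_calls(1), c = mk_calls(1)),
    list(a = base_m, b = base_m, c = base_m), n_perm = 10, seed = 1)
  expect_true(all(same$pcc == 1))
  expect_true(all(same$degenerate))
  expect_error(structure_expression_correlation(calls[1:2], models[1:2]),
               "three")
})
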