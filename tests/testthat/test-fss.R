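norm_cols <- function(m) {
  fake_samples(m / rowSums(abs(m)), normalized = TRUE)
}

test_that("flux change P-values hit the defining limits", {
  set.seed(1)
  a <- matrix(runif(800, 1, 2), ncol = 1, dimnames = list(NULL, "r"))
  b <- matrix(runif(800, 3, 4), ncol = 1, dimnames = list(NULL, "r"))
  # identical sets: no shift
  same <- suppressWarnings(flux_change(norm_cols(a), norm_cols(a)))
  expect_equal(same$p_value, 1)
  # disjoint supports: complete separation, A below B; a second constant
  # column makes the normalized fold/direction interpretable
  A <- cbind(r = a[, 1], s = 3.5)
  B <- cbind(r = b[, 1], s = 3.5)
  res <- suppressWarnings(flux_change(norm_cols(A), norm_cols(B)))
  expect_lt(res$p_value[res$reaction == "r"], 1e-3)
  expect_equal(res$direction[res$reaction == "r"], "down")
  expect_lt(res$fold_change[res$reaction == "r"], 1)
})

test_that("flux change matches the O(n^2) brute-force oracle", {
  set.seed(42)
  n <- 5000
  a <- rnorm(n, 1, 1)
  b <- rnorm(n, 0, 1)
  idx <- sample(n, 500)
  A <- cbind(r = a[idx], s = 10)
  B <- cbind(r = b[idx], s = 10)
  res <- suppressWarnings(flux_change(norm_cols(A), norm_cols(B)))
  want <- oracle_overlap_p(A[, "r"] / rowSums(abs(A)),
                           B[, "r"] / rowSums(abs(B)))
  expect_lt(abs(res$p_value[res$reaction == "r"] - want), 0.005)
  # symmetry: swapping conditions preserves p, flips direction
  rev_ <- suppressWarnings(flux_change(norm_cols(B), norm_cols(A)))
  expect_equal(rev_$p_value, res$p_value, tolerance = 1e-12)
  expect_false(any(rev_$direction == res$direction &
                   abs(res$fold_change - 1) > 1e-6))
})

test_that("BH adjustment is monotone and bounded", {
  set.seed(2)
  k <- 30
  A <- matrix(rnorm(500 * k, mean = rep(c(0, 1), length.out = k)[col(matrix(0, 500, k))]),
              500, k, dimnames = list(NULL, paste0("r", 1:k)))
  B <- matrix(rnorm(500 * k), 500, k, dimnames = list(NULL, paste0("r", 1:k)))
  res <- suppressWarnings(flux_change(norm_cols(abs(A) + 0.1),
                                      norm_cols(abs(B) + 0.1)))
  ord <- order(res$p_value)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_lte(sum(res$q_value <= 0.01), sum(res$p_value <= 0.01))
})

test_that("deficient models are kept only when they still grow", {
  m <- generate_toy_model(synthetic_scenario(1))
  # redundant isoenzyme: behaviorally unchanged
  red <- build_deficient_model(m, "g_hk1")
  expect_true(red$feasible)
  expect_equal(red$objective_value, fba(m)$objective_value, tolerance = 1e-9)
  # glycolysis knockout cannot meet maintenance: excluded
  ess <- build_deficient_model(m, "g_gly")
  expect_false(ess$feasible)
  # planted LoF gene keeps a reduced but positive optimum
  sdh <- build_deficient_model(m, "g_sdh")
  expect_true(sdh$feasible)
  expect_lt(sdh$objective_value, fba(m)$objective_value)
})

test_that("LoF calling restricts to the enzyme neighborhood minus currency", {
  sc <- synthetic_scenario(1)
  res <- run_lof_pipeline(sc, n_points = 1000, n_steps = 50)
  expect_setequal(res$lof_genes, c("g_sdh", "g_fh"))
  calls <- res$calls[["g_sdh"]]
  expect_true("succ" %in% calls$metabolite)
  # currency species never called
  expect_false(any(calls$metabolite %in% currency_species()))
  # every evidence reaction touches the called metabolite
  expect_true(all(nzchar(calls$evidence)))
  # unknown enzyme errors
  m <- generate_toy_model(sc)
  s <- achr_sample(m, 50, 10, seed = 1)
  ns <- normalize_fluxes(s)
  expect_error(suppressWarnings(
    call_lof_oncometabolites(ns, ns, "g_nonexistent", m)), "no reaction")
})

test_that("accuracy follows the confusion-matrix formula with exclusions", {
  m <- generate_toy_model(synthetic_scenario(1))
  # synthetic change table: 10 unambiguous single-gene reactions
  changes <- data.frame(
    reaction = c("PDH", "CS", "IDH", "AKGDH", "SDH", "FUM", "MDH", "PC",
                 "PYK", "LDH"),
    p_value = 1e-6, q_value = 1e-5, fold_change = 4,
    direction = c(rep("up", 6), rep("down", 4)),
    stringsAsFactors = FALSE)
  genes <- c("g_pdh", "g_cs", "g_idh", "g_akgdh", "g_sdh", "g_fh", "g_mdh",
             "g_pc", "g_gly", "g_ldh")
  delta <- stats::setNames(c(1, 1, 1, 1, 1, 1, -1, -1, -1, -1), genes)
  # predicted: 6 up, 4 down; observed: first 6 up except g_fh mismatch etc.
  out <- flux_expression_accuracy(changes, delta, m, n_perm = 2000, seed = 9)
  expect_equal(out$tp, 6)
  expect_equal(out$tn, 4)
  expect_equal(out$accuracy, 1)
  expect_lt(out$permutation_p, 0.05)
  # 8 of 10 correct
  delta2 <- delta
  delta2[c("g_pdh", "g_ldh")] <- -delta2[c("g_pdh", "g_ldh")]
  out2 <- flux_expression_accuracy(changes, delta2, m, n_perm = 500, seed = 9)
  expect_equal(out2$accuracy, 0.8)
  # ambiguous gene (up and down reactions) is dropped: give g_gly both
  changes3 <- rbind(changes,
                    data.frame(reaction = "HK", p_value = 1e-6, q_value = 1e-5,
                               fold_change = 4, direction = "up"))
  # HK is isoenzyme-catalyzed -> filtered, so predictions are unchanged
  out3 <- flux_expression_accuracy(changes3, delta, m, n_perm = 500, seed = 9)
  expect_equal(nrow(out3$predictions), nrow(out$predictions))
  expect_error(flux_expression_accuracy(changes[0, ], delta, m),
               "undefined")
})

test_that("ambiguous-direction genes are excluded from the confusion matrix", {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c")
  rx <- list(
    list(id = "R1", stoichiometry = c(A = 1), lower_bound = 0,
         upper_bound = 10, gpr = "gq"),
    list(id = "R2", stoichiometry = c(A = -1, B = 1), lower_bound = 0,
         upper_bound = 10, gpr = "gq"),
    list(id = "R3", stoichiometry = c(B = -1), lower_bound = 0,
         upper_bound = 10, gpr = "gz"))
  m <- metabolic_model(mets, rx, objective = c(R3 = 1))
  changes <- data.frame(reaction = c("R1", "R2", "R3"), p_value = 1e-6,
                        q_value = 1e-5, fold_change = 3,
                        direction = c("up", "down", "up"),
                        stringsAsFactors = FALSE)
  out <- flux_expression_accuracy(changes, c(gq = 1, gz = 1), m,
                                  n_perm = 100, seed = 1)
  expect_equal(out$predictions$gene, "gz")
})

test_that("essentiality enrichment equals the exact tail sum with probit z", {
  universe <- paste0("g", 1:20)
  in_vivo <- paste0("g", 1:5)
  in_silico <- c("g1", "g2", "g3", "g19")
  res <- essentiality_enrichment(in_silico, in_vivo, universe)
  expect_equal(res$overlap, 3)
  expect_equal(res$p_value, oracle_hyper_upper(3, 5, 20, 4), tolerance = 1e-12)
  expect_equal(res$z_score, qnorm(1 - res$p_value), tolerance = 1e-9)
  # zero overlap of small sets is depleted (z at or below 0 region)
  res0 <- essentiality_enrichment(c("g19", "g20"), in_vivo, universe)
  expect_lte(res0$z_score, 1)
  # saturation
  resS <- essentiality_enrichment(universe, universe, universe)
  expect_equal(resS$p_value, 1)
  # empty prediction set floors out
  resE <- essentiality_enrichment(character(0), in_vivo, universe)
  expect_equal(resE$p_value, 1)
  expect_lt(resE$z_score, -5)
})
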