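#' Synthetic study scenario
#'
#' Bundles every knob of the synthetic cohort: a three-compartment toy
#' metabolic network with a central-carbon backbone (glycolysis-like chain,
#' TCA-like cycle with NADH/oxidative phosphorylation coupling, overflow
#' secretion routes), paired cancer/normal expression matrices whose
#' presence/absence structure encodes planted reaction removals, somatic
#' mutation tables with controlled recurrence, and a compound library with
#' native substrates, a structural analog and decoys.
#'
#' Planted ground truth, mirroring the canonical oncometabolite cases:
#' \itemize{
#'   \item \code{g_sdh} (succinate-dehydrogenase-like) and \code{g_fh}
#'     (fumarase-like) carry recurrent loss-of-function mutations; deleting
#'     them reroutes TCA flux into secretion branches so that succinate/
#'     fumarate (and the downstream malate) fluxes shift.
#'   \item \code{g_idh} (isocitrate-dehydrogenase-like) carries recurrent
#'     missense mutations; its native reaction (isocitrate oxidative
#'     decarboxylation) has the alpha-ketoglutarate -> 2-hydroxyglutarate
#'     reduction as the planted promiscuous gain-of-function pair.
#'   \item \code{g_hk1}/\code{g_hk2} form an OR-isoenzyme pair, \code{g_pyrt}
#'     is a pure transporter, \code{g_ldh} recurs with low functional-impact
#'     scores: decoys for the screen filters.
#' }
#'
#' @param seed integer master seed; generators derive sub-seeds by fixed
#'   offsets so each output is an independent pure function of the scenario.
#' @param n_samples_cancer,n_samples_normal cohort sizes (default 40/40,
#'   within the 12-99 range of typical expression series).
#' @param background_rate expected silent/passenger mutation records per
#'   decoy gene-sample pair.
#' @return object of class \code{synthetic_scenario}.
#' @export
synthetic_scenario <- function(seed = 1L, n_samples_cancer = 40L,
                               n_samples_normal = 40L,
                               background_rate = 0.02) {
  if (n_samples_cancer < 1L || n_samples_normal < 1L) {
    stop("scenario requires at least one sample per condition")
  }
  structure(list(
    seed = as.integer(seed),
    n_samples_cancer = as.integer(n_samples_cancer),
    n_samples_normal = as.integer(n_samples_normal),
    planted_lof = list(g_sdh = c("succ", "fum"), g_fh = c("fum", "mal")),
    planted_gof = list(g_idh = list(native = "icit", analog = "akg")),
    recurrence_map = c(g_sdh = 0.10, g_fh = 0.08, g_idh = 0.12,
                       g_hk1 = 0.10, g_pyrt = 0.10, g_ldh = 0.07,
                       g_gly = 0.08, g_mdh = 0.02, g_pc = 0.03),
    pa_shift = list(cancer_absent = "g_byp", normal_absent = "g_ldh"),
    # log2 cancer/normal expression shifts for genes whose reactions reroute
    # when the bypass disappears (flux up in cancer -> expression up)
    expr_shift = c(g_presyn = 1.5, g_pyrt = 1, g_gly = 1),
    detection_threshold = 10,
    background_rate = background_rate
  ), class = "synthetic_scenario")
}

#' Generate the packaged toy metabolic model
#'
#' A 3-compartment (extracellular/cytosol/mitochondria) network of ~30
#' reactions: glucose uptake and lumped glycolysis, a TCA-like cycle coupled
#' to a generic redox carrier and oxidative phosphorylation, anaplerosis,
#' overflow secretion of lactate/succinate/fumarate, an ATP maintenance
#' demand and a biomass reaction. The succinate/fumarate secretion branches
#' are the escape valves that keep enzyme-deficient models feasible and make
#' the planted flux rerouting observable. Structure is deterministic; the
#' scenario seed is recorded in the model id.
#'
#' @param scenario a \code{synthetic_scenario}.
#' @return a \code{metabolic_model} with biomass objective.
#' @export
generate_toy_model <- function(scenario = synthetic_scenario()) {
  if (length(scenario$planted_lof) == 0L) {
    stop("scenario too small: no planted loss-of-function structure to host")
  }
  mets <- expand_mets(list(
    e = c("glc", "o2", "co2", "succ", "fum", "lac", "bm"),
    c = c("glc", "g6p", "pyr", "lac", "pre", "atp", "adp"),
    m = c("pyr", "acc", "icit", "akg", "succ", "fum", "mal", "oaa",
          "nad", "nadh", "co2", "o2")))
  rx <- function(id, st, lb = 0, ub = 1000, gpr = "", subsystem = "",
                 transport = FALSE) {
    list(id = id, stoichiometry = st, lower_bound = lb, upper_bound = ub,
         gpr = gpr, subsystem = subsystem, is_transport = transport)
  }
  reactions <- list(
    rx("EX_glc", c(glc_e = -1), lb = -10, ub = 0, subsystem = "exchange"),
    rx("EX_o2", c(o2_e = -1), lb = -25, ub = 0, subsystem = "exchange"),
    rx("EX_co2", c(co2_e = -1), subsystem = "exchange"),
    rx("EX_succ", c(succ_e = -1), subsystem = "exchange"),
    rx("EX_fum", c(fum_e = -1), subsystem = "exchange"),
    rx("EX_lac", c(lac_e = -1), subsystem = "exchange"),
    rx("EX_bm", c(bm_e = -1), subsystem = "exchange"),
    rx("GLCt", c(glc_e = -1, glc_c = 1), ub = 9.5, gpr = "g_glct",
       subsystem = "transport", transport = TRUE),
    rx("GLCt2", c(glc_e = -1, glc_c = 1), ub = 10, gpr = "g_glct2",
       subsystem = "transport", transport = TRUE),
    rx("O2t", c(o2_e = -1, o2_m = 1), subsystem = "transport",
       transport = TRUE),
    rx("CO2t", c(co2_m = -1, co2_e = 1), subsystem = "transport",
       transport = TRUE),
    rx("LACt", c(lac_c = -1, lac_e = 1), subsystem = "transport",
       transport = TRUE),
    rx("SUCCt", c(succ_m = -1, succ_e = 1), subsystem = "transport",
       transport = TRUE),
    rx("FUMt", c(fum_m = -1, fum_e = 1), subsystem = "transport",
       transport = TRUE),
    rx("PYRt", c(pyr_c = -1, pyr_m = 1), gpr = "g_pyrt",
       subsystem = "transport", transport = TRUE),
    rx("HK", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
       gpr = "g_hk1 or g_hk2", subsystem = "glycolysis"),
    rx("PYK", c(g6p_c = -1, adp_c = -2, pyr_c = 2, atp_c = 2),
       gpr = "g_gly", subsystem = "glycolysis"),
    rx("LDH", c(pyr_c = -1, lac_c = 1), gpr = "g_ldh",
       subsystem = "fermentation"),
    rx("PDH", c(pyr_m = -1, nad_m = -1, acc_m = 1, co2_m = 1, nadh_m = 1),
       gpr = "g_pdh", subsystem = "tca"),
    rx("CS", c(acc_m = -1, oaa_m = -1, icit_m = 1), gpr = "g_cs",
       subsystem = "tca"),
    rx("IDH", c(icit_m = -1, nad_m = -1, akg_m = 1, co2_m = 1, nadh_m = 1),
       gpr = "g_idh", subsystem = "tca"),
    rx("AKGDH", c(akg_m = -1, nad_m = -1, succ_m = 1, co2_m = 1, nadh_m = 1),
       gpr = "g_akgdh", subsystem = "tca"),
    rx("SDH", c(succ_m = -1, nad_m = -1, fum_m = 1, nadh_m = 1),
       gpr = "g_sdh", subsystem = "tca"),
    rx("FUM", c(fum_m = -1, mal_m = 1), gpr = "g_fh", subsystem = "tca"),
    rx("MDH", c(mal_m = -1, nad_m = -1, oaa_m = 1, nadh_m = 1),
       gpr = "g_mdh", subsystem = "tca"),
    rx("PC", c(pyr_m = -1, co2_m = -1, atp_c = -1, oaa_m = 1, adp_c = 1),
       gpr = "g_pc", subsystem = "anaplerosis"),
    rx("OXPHOS", c(nadh_m = -2, o2_m = -1, adp_c = -5, nad_m = 2, atp_c = 5),
       gpr = "g_ox", subsystem = "oxphos"),
    rx("PRESYN", c(pyr_c = -1, atp_c = -1, pre_c = 1, adp_c = 1),
       gpr = "g_presyn", subsystem = "biosynthesis"),
    rx("BYP", c(g6p_c = -1, pre_c = 2), gpr = "g_byp",
       subsystem = "biosynthesis"),
    rx("ATPM", c(atp_c = -1, adp_c = 1), lb = 1, subsystem = "maintenance"),
    rx("BIOMASS", c(pre_c = -1, atp_c = -10, adp_c = 10, bm_e = 1),
       subsystem = "biomass")
  )
  metabolic_model(mets, reactions, objective = c(BIOMASS = 1),
                  id = sprintf("toy_model_seed%d", scenario$seed))
}

expand_mets <- function(by_comp) {
  do.call(rbind, lapply(names(by_comp), function(cp) {
    sp <- by_comp[[cp]]
    data.frame(id = paste0(sp, "_", cp), name = sp, compartment = cp,
               species = sp, stringsAsFactors = FALSE)
  }))
}

#' Generate paired cancer/normal expression matrices
#'
#' Log-normal intensities for every model gene; genes listed in the
#' scenario's \code{pa_shift} receive below-detection values (1% of the
#' detection threshold) in the designated condition and ordinary expressed
#' values in the other, so the downstream presence/absence caller separates
#' them unambiguously.
#'
#' @param scenario a \code{synthetic_scenario}.
#' @param model the matching toy model.
#' @return list with matrices \code{cancer} and \code{normal}
#'   (genes x samples).
#' @export
generate_expression <- function(scenario, model) {
  genes <- model$genes
  bad <- setdiff(unlist(scenario$pa_shift), genes)
  if (length(bad)) stop("pa_shift genes not in model: ", paste(bad, collapse = ", "))
  gen <- function(n, absent_genes, sub_seed) {
    set.seed(scenario$seed * 1000L + sub_seed)
    m <- matrix(exp(stats::rnorm(length(genes) * n,
                                 mean = log(20 * scenario$detection_threshold),
                                 sd = 0.4)),
                nrow = length(genes), dimnames = list(genes, NULL))
    m[absent_genes, ] <- scenario$detection_threshold * 0.01 *
      exp(stats::rnorm(length(absent_genes) * n, 0, 0.2))
    colnames(m) <- sprintf("s%02d", seq_len(n))
    m
  }
  cancer <- gen(scenario$n_samples_cancer, scenario$pa_shift$cancer_absent, 11L)
  if (length(scenario$expr_shift)) {
    sh <- scenario$expr_shift[names(scenario$expr_shift) %in% rownames(cancer)]
    cancer[names(sh), ] <- cancer[names(sh), ] * 2^unname(sh)
  }
  list(cancer = cancer,
       normal = gen(scenario$n_samples_normal,
                    scenario$pa_shift$normal_absent, 12L))
}

#' Generate a somatic mutation table
#'
#' One record per (gene, sample, class). Planted loss-of-function genes
#' receive nonsense/frameshift/splice-site records, planted gain-of-function
#' genes missense records; both get high functional-impact scores (FIS).
#' Decoy recurrences use silent or low-FIS missense records;
#' \code{background_rate} sprinkles silent passengers. Mutated-sample counts
#' follow the scenario's recurrence map to within rounding.
#'
#' @param scenario a \code{synthetic_scenario}.
#' @param model the matching toy model.
#' @return data.frame of class \code{mutation_table} with columns
#'   \code{gene}, \code{sample}, \code{mclass}, \code{fis}.
#' @export
generate_mutations <- function(scenario, model) {
  stopifnot(all(names(scenario$recurrence_map) %in% model$genes))
  set.seed(scenario$seed * 1000L + 13L)
  n <- scenario$n_samples_cancer
  samples <- sprintf("s%02d", seq_len(n))
  lof_classes <- c("nonsense", "frameshift_indel", "splice_site")
  rows <- list()
  for (g in names(scenario$recurrence_map)) {
    k <- round(scenario$recurrence_map[[g]] * n)
    if (k < 1L) k <- max(1L, k)
    hit <- sample(samples, k)
    if (g %in% names(scenario$planted_lof)) {
      cls <- sample(lof_classes, k, replace = TRUE)
      fis <- stats::runif(k, 3.0, 5.0)
    } else if (g %in% names(scenario$planted_gof)) {
      cls <- rep("missense", k)
      fis <- stats::runif(k, 3.0, 5.0)
    } else if (g == "g_gly") {
      cls <- rep("silent", k)           # recurrent but consequence-free
      fis <- stats::runif(k, 0, 0.5)
    } else if (g == "g_ldh") {
      cls <- rep("missense", k)         # recurrent but low functional impact
      fis <- stats::runif(k, 0.2, 1.0)
    } else {
      cls <- sample(c("missense", "inframe_indel"), k, replace = TRUE)
      fis <- stats::runif(k, 2.0, 5.0)
    }
    rows[[g]] <- data.frame(gene = g, sample = hit, mclass = cls, fis = fis,
                            stringsAsFactors = FALSE)
  }
  bg_genes <- setdiff(model$genes, names(scenario$recurrence_map))
  n_bg <- stats::rpois(1, scenario$background_rate * n * length(bg_genes))
  if (n_bg > 0) {
    rows$bg <- data.frame(gene = sample(bg_genes, n_bg, replace = TRUE),
                          sample = sample(samples, n_bg, replace = TRUE),
                          mclass = "silent",
                          fis = stats::runif(n_bg, 0, 0.5),
                          stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("mutation_table", "data.frame")
  tab
}

#' Generate the packaged compound library
#'
#' SMILES for the toy network's carbon metabolites (native substrates of the
#' planted reactions included), the 2-hydroxy analog pair around the planted
#' gain-of-function case (alpha-ketoglutarate-like dicarboxylate and its
#' reduction product 2-hydroxyglutarate-like), and structurally dissimilar
#' decoys. All entries are neutral, Kekule-form aliphatic structures.
#'
#' @param scenario a \code{synthetic_scenario}.
#' @return data.frame with \code{compound}, \code{smiles}, \code{metabolite}
#'   (model metabolite species or NA), \code{role} in
#'   \{native, analog, decoy\}.
#' @export
generate_compound_library <- function(scenario = synthetic_scenario()) {
  lib <- data.frame(
    compound = c("isocitrate", "alpha_ketoglutarate", "2_hydroxyglutarate",
                 "succinate", "fumarate", "malate", "pyruvate", "lactate",
                 "glucose", "hexanol", "octanoate", "ethanolamine",
                 "glycerol", "ribitol", "isopropanol", "urea"),
    smiles = c("OC(C(=O)O)C(CC(=O)O)C(=O)O",
               "OC(=O)CCC(=O)C(=O)O",
               "OC(=O)CCC(O)C(=O)O",
               "OC(=O)CCC(=O)O",
               "OC(=O)C=CC(=O)O",
               "OC(=O)CC(O)C(=O)O",
               "CC(=O)C(=O)O",
               "CC(O)C(=O)O",
               "OCC1OC(O)C(O)C(O)C1O",
               "CCCCCCO",
               "CCCCCCCC(=O)O",
               "NCCO",
               "OCC(O)CO",
               "OCC(O)C(O)C(O)CO",
               "CC(C)O",
               "NC(=O)N"),
    metabolite = c("icit", "akg", NA, "succ", "fum", "mal", "pyr", "lac",
                   "glc", NA, NA, NA, NA, NA, NA, NA),
    role = c("native", "native", "analog", "native", "native", "native",
             "native", "native", "native", "decoy", "decoy", "decoy",
             "decoy", "decoy", "decoy", "decoy"),
    stringsAsFactors = FALSE)
  bad <- !grepl("^[A-Za-z0-9@+\\-\\[\\]()=#/\\\\]+$", lib$smiles, perl = TRUE)
  if (any(bad)) stop("invalid SMILES in template set: ",
                     paste(lib$compound[bad], collapse = ", "))
  lib
}

#' Write all scenario artifacts to disk
#'
#' Emits the toy model (SBML), expression matrices and mutation table (TSV),
#' compound library (TSV of SMILES) and a YAML manifest of the scenario.
#'
#' @param scenario a \code{synthetic_scenario}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named list of written paths.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- generate_toy_model(scenario)
  expr <- generate_expression(scenario, model)
  muts <- generate_mutations(scenario, model)
  lib <- generate_compound_library(scenario)
  paths <- list(
    model = file.path(dir, "toy_model.xml"),
    cancer = file.path(dir, "expression_cancer.tsv"),
    normal = file.path(dir, "expression_normal.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    library = file.path(dir, "compound_library.tsv"),
    manifest = file.path(dir, "scenario.yaml"))
  write_sbml(model, paths$model)
  utils::write.table(expr$cancer, paths$cancer, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(expr$normal, paths$normal, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(muts, paths$mutations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(lib, paths$library, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(unclass(scenario), paths$manifest)
  invisible(paths)
}
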