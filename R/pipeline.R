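pipeline_defaults <- function() {
  list(
    tree_file = NULL,            # Newick chronogram
    trait_file = NULL,           # species trait table (CSV/TSV)
    use_recipe = FALSE,          # generate inputs from the study recipe
    clade_file = NULL,           # optional CSV: species, clade
    n_maps = 500L,               # stochastic maps per regime set
    n_bootstrap = 1000L,         # parametric-bootstrap replicates
    mk_structure = "ER",         # Mk structure for stochastic mapping
    rjmcmc_gens = 200000L,       # generations per chain
    rjmcmc_thin = 100L,
    rjmcmc_chains = 2L,
    shift_rate = 15,             # Poisson prior mean on shift count
    pp_threshold = 0.5,
    burn_in = 0.30,
    alpha_level = 0.05,
    seed = 1L,
    out_dir = "ssdevol-run",
    stages = c("sdi", "rma", "map", "oufit", "bootstrap", "shifts")
  )
}

#' Validate a pipeline configuration
#'
#' Fills in defaults (the headline analysis settings: 500 stochastic
#' maps, 1000 bootstrap replicates, pp threshold 0.5, burn-in 0.30),
#' rejects unknown keys with a spelling suggestion, and collects all
#' invalid values into a single error.
#'
#' @param config path to a YAML config file, a list, or `NULL` (all
#'   defaults).
#' @return a validated `run_config` list.
#' @export
validate_config <- function(config = NULL) {
  defaults <- pipeline_defaults()
  user <- if (is.null(config)) list()
  else if (is.character(config)) yaml::read_yaml(config)
  else if (is.list(config)) config
  else stop("`config` must be a file path, a list, or NULL")
  if (is.null(user)) user <- list()  # empty YAML file
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    hints <- vapply(unknown, function(u) {
      cand <- agrep(u, names(defaults), max.distance = 2, value = TRUE)
      if (length(cand) > 0L) paste0(" (did you mean '", cand[1L], "'?)")
      else ""
    }, character(1))
    stop("unknown config key(s): ",
         paste0("'", unknown, "'", hints, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, user)
  errs <- character()
  chk_count <- function(field, min = 1) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < min ||
        v != floor(v))
      errs <<- c(errs, sprintf("'%s' must be an integer >= %g (got %s)",
                               field, min, deparse(v)))
  }
  chk_frac <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1)
      errs <<- c(errs, sprintf("'%s' must lie in (0, 1) (got %s)", field,
                               deparse(v)))
  }
  for (f in c("n_maps", "n_bootstrap", "rjmcmc_gens", "rjmcmc_thin",
              "rjmcmc_chains", "seed"))
    chk_count(f)
  for (f in c("pp_threshold", "burn_in", "alpha_level")) chk_frac(f)
  if (!is.numeric(cfg$shift_rate) || cfg$shift_rate <= 0)
    errs <- c(errs, "'shift_rate' must be positive")
  if (!cfg$mk_structure %in% c("ER", "SYM", "ARD"))
    errs <- c(errs, "'mk_structure' must be ER, SYM or ARD")
  bad_stage <- setdiff(cfg$stages, pipeline_defaults()$stages)
  if (length(bad_stage) > 0L)
    errs <- c(errs, paste0("unknown stage(s): ",
                           paste(bad_stage, collapse = ", ")))
  if (!cfg$use_recipe && (is.null(cfg$tree_file) || is.null(cfg$trait_file)))
    errs <- c(errs,
              "either set use_recipe: true or supply tree_file and trait_file")
  if (length(errs) > 0L)
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Run the full SSD analysis pipeline
#'
#' Executes, per the enabled stages: data loading/validation (or
#' synthetic generation from the study recipe), SDI and regime encoding,
#' per-clade phylogenetic RMA, stochastic mapping of the social, diet
#' and combined regimes, five-model OU comparison across maps,
#' parametric-bootstrap CIs of the best OUM model, RJ-MCMC shift
#' detection, and map summaries with transition counts. All outputs are
#' TSV/CSV/JSON files under `config$out_dir`, plus a JSON manifest
#' recording the config, seeds, per-stage status and runtimes. Every
#' stochastic stage uses a seed derived deterministically from the
#' master seed, so a rerun with the same config is numerically
#' identical. A stage failure preserves earlier outputs and is recorded
#' in the manifest.
#'
#' @param config a `run_config` (see [validate_config()]), a YAML path,
#'   a list of overrides, or `NULL` for all defaults.
#' @return invisibly, a list with the in-memory results of each stage
#'   and the manifest.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stage_seeds <- setNames(sample.int(.Machine$integer.max - 1L, 8L),
                          c("simulate_tree", "simulate_regimes",
                            "simulate_traits", "map_social", "map_diet",
                            "map_combined", "bootstrap", "rjmcmc"))
  manifest <- list(package = "ssdevol",
                   version = as.character(utils::packageVersion("ssdevol")),
                   config = unclass(cfg), stage_seeds = as.list(stage_seeds),
                   stages = list())
  results <- list()
  t_all <- proc.time()[3L]

  run_stage <- function(name, expr) {
    t0 <- proc.time()[3L]
    res <- tryCatch(expr, error = function(e) e)
    status <- if (inherits(res, "error")) {
      warning("stage '", name, "' failed: ", conditionMessage(res))
      list(status = "failed", error = conditionMessage(res))
    } else list(status = "ok")
    status$seconds <- round(proc.time()[3L] - t0, 2)
    manifest$stages[[name]] <<- status
    if (inherits(res, "error")) NULL else res
  }

  # --- inputs -------------------------------------------------------------
  inputs <- run_stage("load", {
    if (cfg$use_recipe) {
      recipe <- paper_like_recipe()
      tree <- simulate_tree(recipe, seed = stage_seeds["simulate_tree"])
      sim <- simulate_regimes(tree, recipe$Q, recipe$root_state,
                              seed = stage_seeds["simulate_regimes"])
      table <- simulate_species_table(sim$map, recipe,
                                      seed = stage_seeds["simulate_traits"])
      write_recipe(recipe, file.path(cfg$out_dir, "recipe.yml"))
      ape::write.tree(tree, file.path(cfg$out_dir, "tree.nwk"))
      list(tree = tree, table = table, true_map = sim$map)
    } else {
      tree <- read_tree(file = cfg$tree_file)
      table <- load_trait_table(cfg$trait_file)
      tree$tip.label <- normalize_label(tree$tip.label)
      common <- intersect(tree$tip.label, table$species)
      dropped_tips <- setdiff(tree$tip.label, common)
      dropped_rows <- setdiff(table$species, common)
      if (length(dropped_tips) > 0L)
        message("dropping ", length(dropped_tips), " tree tip(s) without trait data")
      if (length(dropped_rows) > 0L)
        message("dropping ", length(dropped_rows), " table row(s) without a tip")
      tree <- prune_to_taxa(tree, common)
      table <- table[table$species %in% common, ]
      list(tree = tree, table = table)
    }
  })
  if (is.null(inputs)) stop("input stage failed; nothing to analyse")
  tree <- inputs$tree
  table <- inputs$table
  results$tree <- tree
  results$table <- table

  if ("sdi" %in% cfg$stages) {
    run_stage("sdi", {
      write_trait_table(table, file.path(cfg$out_dir, "analysis_table.csv"))
      TRUE
    })
  }

  sdi <- setNames(table$sdi_percent, table$species)

  if ("rma" %in% cfg$stages) {
    results$rma <- run_stage("rma", {
      lnf <- setNames(log(table$female_mass_g), table$species)
      lnm <- setNames(log(table$male_mass_g), table$species)
      clades <- if (!is.null(cfg$clade_file)) {
        cl <- read.csv(cfg$clade_file, stringsAsFactors = FALSE)
        setNames(cl$clade, normalize_label(cl$species))
      } else setNames(rep("all_species", nrow(table)), table$species)
      tab <- rma_by_clade(tree, lnf, lnm, clades, alpha = cfg$alpha_level)
      write_rma_table(tab, file.path(cfg$out_dir, "rma_table.tsv"))
      tab
    })
  }

  maps <- NULL
  if ("map" %in% cfg$stages) {
    maps <- run_stage("map", {
      chars <- list(
        social = setNames(collapse_social(table$social_system),
                          table$species),
        diet = setNames(collapse_diet(table$diet), table$species),
        combined = setNames(table$combined_regime, table$species))
      out <- list()
      for (nm in names(chars)) {
        mk <- fit_mk(tree, chars[[nm]], structure = cfg$mk_structure)
        out[[nm]] <- sample_simmaps(tree, mk, chars[[nm]],
                                    n_maps = cfg$n_maps,
                                    seed = stage_seeds[paste0("map_", nm)])
        summ <- summarize_maps(out[[nm]])
        write_map_summary(
          summ,
          node_file = file.path(cfg$out_dir,
                                paste0("ancestral_", nm, ".tsv")),
          count_file = file.path(cfg$out_dir,
                                 paste0("transitions_", nm, ".tsv")))
      }
      out
    })
    results$maps <- maps
  }

  comparison <- NULL
  if ("oufit" %in% cfg$stages && !is.null(maps)) {
    comparison <- run_stage("oufit", {
      cmp <- compare_models(maps, sdi, tree = tree)
      write_model_comparison(cmp,
                             file.path(cfg$out_dir, "model_comparison.tsv"))
      cmp
    })
    results$comparison <- comparison
  }

  if ("bootstrap" %in% cfg$stages && !is.null(comparison)) {
    results$bootstrap <- run_stage("bootstrap", {
      best <- comparison$best_model
      fit <- comparison$fits[[best]]
      best_map <- if (startsWith(best, "OUM_"))
        maps[[sub("^OUM_", "", best)]][[1L]] else tree
      ci <- parametric_bootstrap(fit, best_map, n_reps = cfg$n_bootstrap,
                                 seed = stage_seeds["bootstrap"])
      out <- list(best_model = best, half_life_myr = half_life(fit$alpha),
                  point = list(alpha = fit$alpha, sigma2 = fit$sigma2,
                               theta = as.list(fit$theta)),
                  ci = ci$table, n_ok = ci$n_ok,
                  seed = unname(stage_seeds["bootstrap"]))
      jsonlite::write_json(out, file.path(cfg$out_dir, "bootstrap.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      ci
    })
  }

  if ("shifts" %in% cfg$stages) {
    results$shifts <- run_stage("shifts", {
      run <- run_rjmcmc(tree, sdi, n_gens = cfg$rjmcmc_gens,
                        thin = cfg$rjmcmc_thin,
                        n_chains = cfg$rjmcmc_chains,
                        seed = stage_seeds["rjmcmc"],
                        hyper = rjmcmc_hyperprior(tree, sdi,
                                                  shift_rate = cfg$shift_rate))
      post <- summarize_posterior(run, burn_in = cfg$burn_in,
                                  pp_threshold = cfg$pp_threshold)
      write_shift_posterior(post, file.path(cfg$out_dir, "shifts.tsv"))
      anc <- bm_ancestral_states(tree, sdi)
      write.table(anc, file.path(cfg$out_dir, "ancestral_sdi.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(seed = unname(stage_seeds["rjmcmc"]),
             n_gens = cfg$rjmcmc_gens, thin = cfg$rjmcmc_thin,
             burn_in = cfg$burn_in, diagnostics = post$diagnostics),
        file.path(cfg$out_dir, "rjmcmc_manifest.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      post
    })
  }

  manifest$total_seconds <- round(proc.time()[3L] - t_all, 2)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
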