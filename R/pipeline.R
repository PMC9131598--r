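# Full-analysis orchestration: read -> clonality -> diversity table ->
# theta matrix -> FCA -> pooling -> ABC, with seed control, logging and a
# machine-readable manifest. A single master seed spawns per-stage
# substreams by fixed offsets so any stage is individually reproducible.

stage_seed <- function(master, stage) {
  master + c(clonality = 1000L, stats = 2000L, fst = 3000L, fca = 4000L,
             abc = 5000L, synth = 6000L, ppc = 7000L)[[stage]]
}

default_config <- function() {
  list(
    input = NULL,                 # genepop path; NULL -> synthetic data
    synth = list(scale = 0.25, clone_pairs = 3L, null_freq = 0),
    mll_threshold = 2L,
    B = 10000L, alpha = 0.05,
    pooling = NULL,               # named list/vector label -> group
    drop = character(0),
    use_representatives = TRUE,   # one sample per MLL for the ABC stage
    abc = list(n_per_scenario = 1000L, n_loci = NULL, retain = 0.05,
               n_delta = 500L, sizes_scale = 1),
    seed = 1L,
    out_dir = NULL)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load (genepop file or synthetic bundle), clonality
#' (MLG/MLL), per-population diversity table, pairwise theta matrix with
#' permutation significance, FCA ordination, pooling to regional demes, and
#' ABC scenario choice plus parameter estimation. Each stage's outputs are
#' written to `out_dir` as TSV/JSON together with a log and a manifest;
#' identical config and seed give byte-identical numeric outputs. A stage
#' failure aborts with the stage name; outputs of completed stages are
#' preserved.
#'
#' @param config a list (see Details) or path to a YAML file; unset keys
#'   take defaults. Keys: `input` (genepop path; `NULL` simulates a
#'   synthetic bundle per `synth`), `mll_threshold`, `B`, `alpha`,
#'   `pooling` (label -> deme map; default [deme_pooling_map]), `drop`
#'   (labels excluded from the ABC stage, default `"CYP"` when present),
#'   `use_representatives`, `abc` (`n_per_scenario`, `retain`, `n_delta`),
#'   `seed`, `out_dir`.
#' @param out_dir overrides `config$out_dir`; default a tempdir.
#' @return (invisibly) list with per-stage results and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) cfg$out_dir <- tempfile("msatabc_run_")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  logmsg <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config.yaml"))
  manifest <- list(package_version = as.character(utils::packageVersion("msatABC")),
                   seed = cfg$seed, outputs = list())
  add_out <- function(stage, path) {
    manifest$outputs[[stage]] <<- c(manifest$outputs[[stage]], basename(path))
    path
  }
  run_stage <- function(stage, expr) {
    logmsg("stage ", stage, " ...")
    tryCatch(expr, error = function(e) {
      logmsg("stage ", stage, " FAILED: ", conditionMessage(e))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list()

  # load
  gm <- run_stage("load", {
    if (!is.null(cfg$input)) {
      read_genepop(cfg$input)
    } else {
      b <- make_study_like(seed = stage_seed(cfg$seed, "synth"),
                           scale = cfg$synth$scale,
                           clone_pairs = cfg$synth$clone_pairs,
                           null_freq = cfg$synth$null_freq)
      write_truth_bundle(b, cfg$out_dir)
      add_out("load", file.path(cfg$out_dir, "synthetic_genotypes.gen"))
      results$truth <- b
      b$corrupted
    }
  })
  results$genotypes <- gm

  # clonality
  part <- run_stage("clonality", {
    p <- identify_mlg(gm)
    p <- collapse_mll(p, gm, cfg$mll_threshold)
    f <- file.path(cfg$out_dir, "clonality.tsv")
    utils::write.table(merge(mll_summary(p), mll_members(p), by = "pop"),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    add_out("clonality", f)
    p
  })
  results$mll <- part

  # per-population diversity (Table-1 shape)
  results$diversity <- run_stage("diversity", {
    set.seed(stage_seed(cfg$seed, "stats"))
    dt <- diversity_table(gm, B = cfg$B, alpha = cfg$alpha)
    add_out("diversity", write_stats_tsv(dt, file.path(cfg$out_dir,
                                                       "diversity.tsv")))
    dt
  })

  # pairwise theta matrix (Table-2 shape)
  results$fst <- run_stage("fst", {
    set.seed(stage_seed(cfg$seed, "fst"))
    fm <- fst_matrix(gm, B = cfg$B, alpha = cfg$alpha)
    add_out("fst", write_stats_tsv(fm, file.path(cfg$out_dir,
                                                 "fst_matrix.tsv")))
    pv <- file.path(cfg$out_dir, "fst_pvalues.tsv")
    utils::write.table(fm$p_value, pv, sep = "\t", quote = FALSE)
    add_out("fst", pv)
    fm
  })

  # ordination
  results$fca <- run_stage("fca", {
    fc <- fca(gm)
    co <- file.path(cfg$out_dir, "fca_coordinates.tsv")
    utils::write.table(data.frame(sample = rownames(fc$row_coord),
                                  pop = as.character(gm$pop),
                                  fc$row_coord),
                       co, sep = "\t", quote = FALSE, row.names = FALSE)
    add_out("fca", co)
    ce <- file.path(cfg$out_dir, "fca_centroids.tsv")
    utils::write.table(data.frame(pop = rownames(population_centroids(fc)),
                                  population_centroids(fc)),
                       ce, sep = "\t", quote = FALSE, row.names = FALSE)
    add_out("fca", ce)
    fc
  })

  # ABC on pooled demes
  results$abc <- run_stage("abc", {
    pooling <- cfg$pooling
    drop <- cfg$drop
    labs <- levels(gm$pop)
    if (is.null(pooling)) {
      if (all(labs %in% meadow_design()$meadow)) {
        if (!length(drop) && "CYP" %in% labs) drop <- "CYP"
        pooling <- deme_pooling_map(drop = drop)
      } else {
        pooling <- stats::setNames(labs, labs)  # demes already
      }
    } else pooling <- unlist(pooling)
    gm_abc <- gm
    if (isTRUE(cfg$use_representatives))
      gm_abc <- representatives(gm_abc, part)
    pooled <- pool_populations(gm_abc, pooling, drop = drop)
    obs <- summary_stats(pooled)
    scns <- list(scenario13 = scenario13(),
                 alternative = scenario_alternative())
    sizes <- vapply(scns[[1]]$demes, function(d)
      sum(pooled$pop == d), integer(1))
    nl <- if (is.null(cfg$abc$n_loci)) length(pooled$loci) else cfg$abc$n_loci
    ref <- build_reference_table(scns, sizes,
                                 n_per_scenario = cfg$abc$n_per_scenario,
                                 n_loci = nl,
                                 seed = stage_seed(cfg$seed, "abc"))
    res <- abc_analysis(ref, obs, retain_fraction = cfg$abc$retain,
                        n_delta = cfg$abc$n_delta)
    post <- res$posterior
    out <- list(
      observed_stats = as.list(obs),
      scenario_probabilities = list(direct = as.list(res$direct),
                                    logistic = as.list(res$logistic)),
      best_scenario = res$best,
      parameters = if (!is.null(post)) {
        pri <- ref$scenarios[[res$best]]$priors
        tab <- cbind(prior_low = c(vapply(pri, `[[`, 0, "lower"),
                                   mu_mean = ref$mu_prior[1], P = ref$P_prior[1])[rownames(post)],
                     prior_high = c(vapply(pri, `[[`, 0, "upper"),
                                    mu_mean = ref$mu_prior[2], P = ref$P_prior[2])[rownames(post)],
                     as.matrix(post))
        apply(tab, 1L, as.list)
      } else NULL)
    jf <- file.path(cfg$out_dir, "abc_result.json")
    jsonlite::write_json(out, jf, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    add_out("abc", jf)
    c(res, list(observed = obs, reference = ref))
  })

  mf <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  logmsg("pipeline complete: ", length(manifest$outputs), " stage outputs")
  results$manifest <- manifest
  results$out_dir <- cfg$out_dir
  invisible(results)
}
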