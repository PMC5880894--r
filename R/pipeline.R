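# End-to-end orchestration: simulate or ingest, then entropy decomposition,
# clr transforms, conditionally-rare-taxa analysis, compositional
# correlation, latent variable models, and distance-decay regressions, with
# per-stage seeds and a machine-readable manifest.

#' Derive a stage seed from the run seed
#'
#' Deterministic and independent per stage name, so adding a stage never
#' perturbs another stage's stream. Kept below 2^31.
#'
#' @param seed integer run seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483587) + 1L
}

#' Default pipeline configuration
#'
#' @param seed run seed.
#' @param out output directory.
#' @param simulate a [sim_config()] (NULL to ingest files instead).
#' @param inputs list with `counts`, `env`, `fasta` paths when not
#'   simulating.
#' @param med,clr,crt,sparcc,lvm,decay per-stage parameter blocks; defaults
#'   follow each stage's documented defaults.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out = "nichepart_out",
                            simulate = sim_config(seed = seed),
                            inputs = NULL,
                            med = list(M = 500, entropy_threshold = 0.0965),
                            clr = list(delta = NULL),
                            crt = list(b_thresh = 0.90,
                                       maxrel_thresh = 0.005),
                            sparcc = list(n_resample = 20, bootstraps = 500,
                                          r_thresh = 0.6, p_thresh = 0.01),
                            lvm = list(latent = 2, quadratic = TRUE,
                                       prevalence = 0.70, bootstrap = 100),
                            decay = list(max_degree = 2,
                                         only_significant = TRUE,
                                         p_thresh = 0.05)) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown pipeline config keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$simulate) &&
      (is.null(config$inputs) || is.null(config$inputs$counts)))
    stop("config needs either a simulate block or input paths")
  invisible(config)
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file; keys mirror [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$simulate)) {
    raw$simulate <- do.call(sim_config, raw$simulate)
  }
  cfg <- do.call(pipeline_config, raw)
  validate_pipeline_config(cfg)
}

file_checksum <- function(path) {
  rlang::hash(readChar(path, file.size(path), useBytes = TRUE))
}

#' Run the full analysis pipeline
#'
#' Stages in order: `simulate` (or ingest), `med`, `clr`, `crt`, `sparcc`,
#' `lvm`, `decay`. Each stage writes its outputs under the configured
#' output directory and records parameters and file checksums in
#' `manifest.json`; a stage failure aborts with the stage name. Re-running
#' with the same config and seed reproduces identical checksums.
#'
#' @param config a [pipeline_config()].
#' @param verbose log progress (default TRUE).
#' @return the manifest (list), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  validate_pipeline_config(config)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   config_hash = rlang::hash(unclass(config)),
                   stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (verbose) log_msg("stage %s ...", name)
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res$params <- res$params %||0% list()
    res$outputs <- res$outputs %||0% character()
    res$checksums <- vapply(res$outputs, file_checksum, "")
    manifest$stages[[name]] <<- res[c("params", "outputs", "checksums")]
    invisible(res)
  }

  run_stage("simulate", function() {
    if (!is.null(config$simulate)) {
      sim_dir <- file.path(out, "sim")
      study <- generate_study(config$simulate, out_dir = sim_dir,
                              force = TRUE)
      state$study <- study
      state$ct <- filter_low_depth_samples(study$ct, 1000)
      state$env <- study$env
      state$seqs <- study$seqs
      state$genus_map <- study$truth$genus_map
      list(params = list(seed = config$simulate$seed),
           outputs = unlist(study$paths, use.names = FALSE))
    } else {
      ct <- read_count_table(config$inputs$counts)
      state$ct <- filter_low_depth_samples(ct, 1000)
      if (is.null(config$inputs$env)) stop("missing env table")
      state$env <- read_env_table(config$inputs$env)
      state$seqs <- if (!is.null(config$inputs$fasta))
        read_fasta(config$inputs$fasta) else NULL
      state$genus_map <- if (!is.null(config$inputs$genus_map)) {
        gm <- utils::read.delim(config$inputs$genus_map,
                                stringsAsFactors = FALSE)
        stats::setNames(gm[[2]], gm[[1]])
      } else NULL
      list(params = list(ingested = TRUE), outputs = character())
    }
  })

  run_stage("med", function() {
    if (is.null(state$seqs))
      return(list(params = list(skipped = "no sequences")))
    w <- rowSums(state$ct$counts)[names(state$seqs)]
    w[is.na(w)] <- 1
    med <- med_decompose(state$seqs, weights = pmax(1, round(w)),
                         M = config$med$M,
                         entropy_threshold = config$med$entropy_threshold)
    node_fa <- file.path(out, "med_nodes.fasta")
    if (length(med$nodes)) {
      reps <- vapply(med$nodes, `[[`, "", "representative")
      names(reps) <- vapply(med$nodes, `[[`, "", "node_id")
      write_fasta(sequence_set(reps, uniform = FALSE), node_fa)
    } else writeLines(character(), node_fa)
    tsv <- file.path(out, "med_nodes.tsv")
    utils::write.table(
      data.frame(node_id = vapply(med$nodes, `[[`, "", "node_id"),
                 reads = vapply(med$nodes, `[[`, 0, "read_count")),
      tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    state$med <- med
    list(params = config$med, outputs = c(node_fa, tsv))
  })

  run_stage("clr", function() {
    gm <- state$genus_map
    if (is.null(gm)) stop("no genus map available for clr stage")
    inter <- clr_inter_genus(state$ct, gm, delta = config$clr$delta)
    paths <- file.path(out, "clr_inter.tsv")
    write_clr_matrix(inter, paths)
    state$clr_intra <- list()
    for (g in unique(gm)) {
      taxa <- names(gm)[gm == g]
      intra <- clr_intra_genus(state$ct, taxa, delta = config$clr$delta)
      p <- file.path(out, paste0("clr_intra_", g, ".tsv"))
      write_clr_matrix(intra, p)
      paths <- c(paths, p)
      state$clr_intra[[g]] <- intra
    }
    state$clr_inter <- inter
    list(params = config$clr, outputs = paths)
  })

  run_stage("crt", function() {
    res <- detect_crt(state$ct, config$crt$b_thresh,
                      config$crt$maxrel_thresh)
    gm <- state$genus_map
    enrich <- lapply(unique(gm), function(g) {
      t <- crt_enrichment_test(res$is_crt,
                               taxon_ids(state$ct) %in% names(gm)[gm == g])
      data.frame(group = g, crt = t$table[1, 1],
                 total = sum(t$table[1, ]),
                 proportion = t$proportion, p_value = t$p_value)
    })
    enrich <- do.call(rbind, enrich)
    p1 <- file.path(out, "crt_per_taxon.tsv")
    p2 <- file.path(out, "crt_enrichment.tsv")
    utils::write.table(res, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enrich, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    state$crt <- res
    list(params = config$crt, outputs = c(p1, p2))
  })

  run_stage("sparcc", function() {
    res <- sparcc_correlation(state$ct,
                              n_resample = config$sparcc$n_resample,
                              seed = stage_seed(config$seed, "sparcc"))
    res <- bootstrap_pvalues(state$ct, res, B = config$sparcc$bootstraps,
                             seed = stage_seed(config$seed, "sparcc_boot"))
    net <- build_network(res, config$sparcc$r_thresh,
                         config$sparcc$p_thresh)
    p1 <- file.path(out, "sparcc_rho.tsv")
    p2 <- file.path(out, "sparcc_pvals.tsv")
    p3 <- file.path(out, "sparcc_edges.tsv")
    utils::write.table(res$rho, p1, sep = "\t", quote = FALSE)
    utils::write.table(res$pvals, p2, sep = "\t", quote = FALSE)
    utils::write.table(net, p3, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    state$sparcc <- res
    list(params = config$sparcc, outputs = c(p1, p2, p3))
  })

  run_stage("lvm", function() {
    if (is.null(state$env)) stop("missing environmental table")
    env <- align_env(state$env, state$ct)
    X <- build_design(env, include_quadratic = config$lvm$quadratic)
    paths <- character()
    state$envcorr <- list()
    for (g in names(state$clr_intra)) {
      y <- prevalence_filter(state$clr_intra[[g]], state$ct,
                             config$lvm$prevalence)
      fit <- fit_lvm(y, X, d = config$lvm$latent,
                     seed = stage_seed(config$seed, paste0("lvm_", g)))
      ec <- environmental_correlations(
        fit, B = config$lvm$bootstrap,
        seed = stage_seed(config$seed, paste0("lvm_boot_", g)))
      p <- file.path(out, paste0("lvm_beta_", g, ".tsv"))
      utils::write.table(cbind(beta0 = fit$beta0, fit$beta), p, sep = "\t",
                         quote = FALSE)
      paths <- c(paths, p)
      p <- file.path(out, paste0("lvm_envcorr_", g, ".tsv"))
      utils::write.table(ec$correlation, p, sep = "\t", quote = FALSE)
      paths <- c(paths, p)
      p <- file.path(out, paste0("lvm_residcorr_", g, ".tsv"))
      utils::write.table(residual_correlations(fit), p, sep = "\t",
                         quote = FALSE)
      paths <- c(paths, p)
      state$envcorr[[g]] <- ec
      state$lvm_fit <- fit
    }
    list(params = config$lvm, outputs = paths)
  })

  run_stage("decay", function() {
    if (is.null(state$seqs)) stop("no sequences: cannot compute distances")
    gm <- state$genus_map
    dist_all <- pairwise_distance_matrix(state$seqs)
    results <- list()
    for (g in unique(gm)) {
      taxa <- intersect(names(gm)[gm == g], rownames(dist_all))
      if (length(taxa) < 3) next
      dsub <- dist_all[taxa, taxa]
      # co-occurrence decay from compositional correlations
      rho <- state$sparcc$rho[taxa, taxa]
      sig <- state$sparcc$pvals[taxa, taxa] < config$decay$p_thresh
      co <- tryCatch(
        cooccurrence_decay(rho, dsub, sig,
                           only_significant = config$decay$only_significant),
        error = function(e) list(error = conditionMessage(e)))
      # niche-similarity decay from the LVM environmental correlations
      ni <- NULL
      if (!is.null(state$envcorr[[g]])) {
        ec <- state$envcorr[[g]]
        keep <- intersect(rownames(ec$correlation), taxa)
        if (length(keep) >= 3) {
          sigm <- if (all(is.na(ec$significant))) NULL
                  else ec$significant[keep, keep]
          ni <- tryCatch(
            niche_decay(ec$correlation[keep, keep], dist_all[keep, keep],
                        sigm,
                        only_significant = config$decay$only_significant &&
                          !is.null(sigm),
                        max_degree = config$decay$max_degree),
            error = function(e) list(error = conditionMessage(e)))
        }
      }
      results[[g]] <- list(cooccurrence = co, niche = ni)
    }
    p <- file.path(out, "decay.json")
    jsonlite::write_json(
      lapply(results, function(r) lapply(r, function(x)
        x[setdiff(names(x), "pairs")])),
      p, auto_unbox = TRUE, digits = NA, force = TRUE)
    state$decay <- results
    list(params = config$decay, outputs = p)
  })

  mpath <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  if (verbose) log_msg("pipeline complete: %d stages, manifest at %s",
                       length(manifest$stages), mpath)
  invisible(list(manifest = manifest, state = state))
}

`%||0%` <- function(a, b) if (is.null(a)) b else a
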