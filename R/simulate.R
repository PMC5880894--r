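# Synthetic study generator: pure-birth trees and mutated sequences for two
# focal genera, AR(1)+seasonal environmental series, niche coefficients drawn
# from a Gaussian process whose between-taxon correlation decays with
# realized genetic distance under a tunable kernel, latent-factor residual
# structure, logistic-normal-multinomial counts, and planted
# conditionally-rare burst taxa. Ground truth is kept alongside the data so
# every pipeline stage has a recovery oracle.

#' Default simulation configuration
#'
#' The defaults emulate an 8-year, ~135-sample lake time series with two
#' focal bloom-forming genera of 25 and 6 strains (maximum within-genus
#' p-distance about 0.05 and 0.01), six nutrient/climate covariates plus a
#' toxin concentration, a read depth scaled down to a median of 5000, and a
#' set of planted conditionally rare taxa (about 10% of the community) bursting in about 5% of
#' samples at 100x their baseline.
#'
#' @param seed integer RNG seed.
#' @param n_samples number of samples (default 135).
#' @param genera named list; per genus `n_taxa` and `target_dist` (target
#'   maximum pairwise p-distance).
#' @param n_background number of non-focal community taxa (default 60).
#' @param seq_length alignment length (default 250).
#' @param kernel niche-similarity kernel: `list(name = "exponential", ell)`
#'   or `list(name = "damped_cosine", ell, ell2, weight, period)`.
#' @param beta_sd_linear,beta_sd_quad GP scale of linear / quadratic niche
#'   coefficients for focal taxa.
#' @param bg_beta_sd coefficient scale for background taxa (weak responders).
#' @param beta0_focal_mean,beta0_focal_sd,beta0_bg_sd intercept distribution.
#' @param latent_d,loading_sd latent factors and loading scale.
#' @param eta_noise_sd sample-by-taxon logistic-normal noise.
#' @param env_ar1,env_season_amp,env_period environmental series structure.
#' @param depth_median,depth_sdlog log-normal read depth.
#' @param crt planted-burst block: `n`, `baseline` (relative abundance),
#'   `burst` (multiplicative magnitude), `burst_fraction` of samples.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_samples = 135,
                       genera = list(
                         genusA = list(n_taxa = 25, target_dist = 0.05),
                         genusB = list(n_taxa = 6, target_dist = 0.01)),
                       n_background = 60,
                       seq_length = 250,
                       kernel = list(name = "exponential", ell = 0.02),
                       beta_sd_linear = 0.5,
                       beta_sd_quad = 0.25,
                       bg_beta_sd = 0.2,
                       beta0_focal_mean = 0.5,
                       beta0_focal_sd = 0.8,
                       beta0_bg_sd = 1.5,
                       latent_d = 2,
                       loading_sd = 0.3,
                       eta_noise_sd = 0.15,
                       env_ar1 = 0.6,
                       env_season_amp = 1,
                       env_period = 17,
                       depth_median = 5000,
                       depth_sdlog = 0.5,
                       crt = list(n = 10, baseline = 2e-4, burst = 100,
                                  burst_fraction = 0.05)) {
  cfg <- as.list(environment())
  stopifnot(n_samples > 0, n_background >= 0, seq_length > 0,
            all(vapply(genera, function(g) g$n_taxa >= 2, TRUE)))
  structure(cfg, class = "sim_config")
}

env_variable_units <- c(PP = "ug/L", PN = "mg/L", DP = "ug/L", DN = "mg/L",
                        precip = "mm", temp = "C", microcystin = "ug/L")

#' Evaluate a niche kernel on a distance matrix
#'
#' Supported kernels: `exponential`, `K(d) = exp(-d/ell)`, and
#' `damped_cosine`, `K(d) = (1-w) exp(-d/ell) + w cos(2 pi d / period)
#' exp(-d/ell2)` (non-monotone: decay, dip, rebound). The matrix is
#' projected to the nearest positive semidefinite matrix when `jitter` is
#' TRUE (negative eigenvalues clipped, logged); otherwise a non-PSD kernel
#' is an error.
#'
#' @param dist_mat symmetric distance matrix.
#' @param kernel kernel specification list (see [sim_config()]).
#' @param jitter clip negative eigenvalues (default TRUE).
#' @return positive semidefinite kernel matrix.
#' @export
kernel_matrix <- function(dist_mat, kernel, jitter = TRUE) {
  K <- switch(kernel$name,
    exponential = exp(-dist_mat / kernel$ell),
    damped_cosine = {
      w <- kernel$weight
      (1 - w) * exp(-dist_mat / kernel$ell) +
        w * cos(2 * pi * dist_mat / kernel$period) *
        exp(-dist_mat / kernel$ell2)
    },
    stop("unknown kernel: ", kernel$name))
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    if (!jitter) stop("kernel matrix is not positive semidefinite")
    log_msg("kernel not PSD (min eigenvalue %.3g); clipping", min(eg$values))
    K <- eg$vectors %*% diag(pmax(eg$values, 1e-8)) %*% t(eg$vectors)
    K <- (K + t(K)) / 2
  }
  K
}

#' Simulate a tree and aligned sequences for one genus
#'
#' A coalescent tree is rescaled so the maximum patristic distance matches
#' `target_dist` (expected substitutions per site); a random root sequence
#' is then mutated along each branch under equal-rate substitution. The
#' realized pairwise p-distances are returned alongside.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seq_length alignment length.
#' @param target_dist target maximum pairwise distance; 0 gives identical
#'   sequences.
#' @param seed RNG seed.
#' @param prefix tip-label prefix.
#' @return list with `tree` (ape phylo), `seqs` ([sequence_set()]), and
#'   `dist` (realized p-distance matrix).
#' @export
simulate_tree_and_sequences <- function(n_taxa, seq_length, target_dist,
                                        seed = NULL, prefix = "t") {
  stopifnot(n_taxa >= 2)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rcoal(n_taxa, tip.label = sprintf("%s%02d", prefix,
                                                 seq_len(n_taxa)))
  patristic <- ape::cophenetic.phylo(tree)
  if (target_dist > 0 && max(patristic) > 0)
    tree$edge.length <- tree$edge.length * target_dist / max(patristic)
  else tree$edge.length <- tree$edge.length * 0

  bases <- c("A", "C", "G", "T")
  n_node <- ape::Nnode(tree) + n_taxa
  seq_by_node <- vector("list", n_node)
  root <- n_taxa + 1L
  seq_by_node[[root]] <- sample(bases, seq_length, replace = TRUE)
  # preorder edge traversal so parents are filled before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    s <- seq_by_node[[parent]]
    p_mut <- min(1, ord$edge.length[e])
    n_mut <- stats::rbinom(1, seq_length, p_mut)
    if (n_mut > 0) {
      pos <- sample.int(seq_length, n_mut)
      s[pos] <- vapply(s[pos],
                       function(b) sample(setdiff(bases, b), 1), "")
    }
    seq_by_node[[child]] <- s
  }
  seqs <- vapply(seq_len(n_taxa), function(i)
    paste0(seq_by_node[[i]], collapse = ""), "")
  names(seqs) <- tree$tip.label
  ss <- sequence_set(seqs)
  list(tree = tree, seqs = ss, dist = pairwise_distance_matrix(ss))
}

#' Simulate niche coefficients over a distance matrix
#'
#' Each coefficient column is an independent zero-mean Gaussian-process draw
#' over taxa with covariance `sd^2 * K(d)`; the implied true niche
#' correlation between taxa is the (common) kernel correlation.
#'
#' @param dist_mat realized pairwise distance matrix.
#' @param kernel kernel specification (see [kernel_matrix()]).
#' @param n_covariates number of coefficient columns.
#' @param sd GP marginal standard deviation (scalar or per column).
#' @param seed RNG seed.
#' @param jitter passed to [kernel_matrix()].
#' @return list with `beta` (taxa x covariates), `true_corr` (implied niche
#'   correlation), `K`.
#' @export
simulate_niche_coefficients <- function(dist_mat, kernel, n_covariates,
                                        sd = 1, seed = NULL, jitter = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  K <- kernel_matrix(dist_mat, kernel, jitter = jitter)
  n <- nrow(K)
  L <- chol(K + diag(1e-8, n))
  sd <- rep_len(sd, n_covariates)
  Z <- matrix(stats::rnorm(n * n_covariates), n, n_covariates)
  beta <- t(L) %*% Z
  beta <- sweep(beta, 2L, sd, "*")
  rownames(beta) <- rownames(dist_mat)
  list(beta = beta, true_corr = stats::cov2cor(K), K = K)
}

# AR(1) + seasonal environmental series, one column per variable
simulate_env <- function(n_samples, ar1, season_amp, period, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vars <- names(env_variable_units)
  t_idx <- seq_len(n_samples)
  vals <- sapply(vars, function(v) {
    phase <- stats::runif(1, 0, 2 * pi)
    innov <- stats::rnorm(n_samples, sd = sqrt(1 - ar1^2))
    ar <- as.numeric(stats::filter(innov, ar1, method = "recursive"))
    season_amp * sin(2 * pi * t_idx / period + phase) + ar
  })
  rownames(vals) <- sprintf("S%03d", t_idx)
  env_matrix(vals, env_variable_units)
}

#' Simulate a count table from niche coefficients
#'
#' Linear predictor `eta_ij = beta0_j + x_i' beta_j + z_i' lambda_j +
#' noise`; per-sample compositions are the softmax of `eta` over taxa, with
#' planted burst taxa receiving a multiplicative `burst` factor in a random
#' subset of samples; counts are multinomial at the drawn depth.
#'
#' @param beta0 per-taxon intercepts.
#' @param beta taxa x design-column coefficient matrix.
#' @param X samples x design-column matrix.
#' @param Lambda taxa x d latent loadings (or NULL).
#' @param eta_noise_sd per-cell logistic-normal noise sd.
#' @param depths per-sample total read counts.
#' @param burst_taxa indices (into taxa) of planted burst taxa.
#' @param burst multiplicative burst magnitude.
#' @param burst_fraction fraction of samples in which each planted taxon
#'   bursts.
#' @param burst_baseline when given, the burst height is pinned on the
#'   composition scale at `burst * burst_baseline` (bloom events reach a
#'   characteristic share of the community, up to the log-normal cell
#'   noise); when NULL the factor is applied to `eta`, so burst heights
#'   inherit the community normalizer's variation.
#' @param seed RNG seed.
#' @param taxa,samples id vectors.
#' @return list with `ct` ([count_table()]), `eta`, `burst_samples` (list
#'   per planted taxon), `scores`.
#' @export
simulate_counts <- function(beta0, beta, X, Lambda = NULL,
                            eta_noise_sd = 0.15, depths, burst_taxa = integer(),
                            burst = 100, burst_fraction = 0.05,
                            burst_baseline = NULL, seed = NULL,
                            taxa = NULL, samples = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X); D <- length(beta0)
  stopifnot(nrow(beta) == D, ncol(beta) == ncol(X), length(depths) == n)
  eta <- matrix(beta0, n, D, byrow = TRUE) + X %*% t(beta)
  scores <- NULL
  if (!is.null(Lambda) && ncol(Lambda) > 0) {
    scores <- matrix(stats::rnorm(n * ncol(Lambda)), n)
    eta <- eta + scores %*% t(Lambda)
  }
  eta <- eta + matrix(stats::rnorm(n * D, sd = eta_noise_sd), n, D)
  burst_samples <- list()
  for (j in burst_taxa) {
    nb <- max(1L, round(burst_fraction * n))
    hit <- sample.int(n, nb)
    if (is.null(burst_baseline))
      eta[hit, j] <- eta[hit, j] + log(burst)
    burst_samples[[as.character(j)]] <- hit
  }
  W <- exp(eta - apply(eta, 1L, max))
  P <- W / rowSums(W)
  if (!is.null(burst_baseline) && length(burst_taxa)) {
    # pin burst heights on the composition scale, then renormalize the rest
    for (j in burst_taxa) {
      hit <- burst_samples[[as.character(j)]]
      P[hit, j] <- pmin(0.4, burst * burst_baseline *
                          exp(stats::rnorm(length(hit), sd = eta_noise_sd)))
    }
    pinned <- rowSums(P[, burst_taxa, drop = FALSE])
    free <- setdiff(seq_len(D), burst_taxa)
    freemass <- rowSums(P[, free, drop = FALSE])
    P[, free] <- P[, free] * (1 - pinned) / freemass
  }
  counts <- vapply(seq_len(n), function(i)
    as.numeric(stats::rmultinom(1, size = depths[i], prob = P[i, ])),
    numeric(D))
  if (is.null(taxa)) taxa <- sprintf("tax%03d", seq_len(D))
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(n))
  dimnames(counts) <- list(taxa, samples)
  list(ct = count_table(counts), eta = eta, burst_samples = burst_samples,
       scores = scores)
}

#' Generate a complete synthetic study
#'
#' Runs the full generator under one [sim_config()]: per-genus trees and
#' sequences, environmental series, distance-structured niche coefficients
#' for focal taxa, weak independent coefficients for background taxa, latent
#' loadings, planted conditionally rare taxa (the rarest background taxa,
#' set to a fixed baseline relative abundance with bursts), multinomial
#' counts, and the ground truth. Optionally writes the bundle in the
#' pipeline's input formats.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory; refused if it already exists
#'   unless `force`.
#' @param force overwrite an existing output directory.
#' @return a list (`study` bundle): `ct`, `env`, `seqs`, `trees`, `truth`,
#'   `config`, and when written, `paths`.
#' @export
generate_study <- function(cfg = sim_config(), out_dir = NULL,
                           force = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  seed <- cfg$seed

  # per-genus trees, sequences, realized distances
  trees <- list(); seq_all <- character(); dists <- list()
  for (g in names(cfg$genera)) {
    gs <- cfg$genera[[g]]
    sim <- simulate_tree_and_sequences(gs$n_taxa, cfg$seq_length,
                                       gs$target_dist,
                                       seed = stage_seed(seed, paste0("tree_", g)),
                                       prefix = paste0(g, "_"))
    trees[[g]] <- sim$tree
    seq_all <- c(seq_all, stats::setNames(unclass(sim$seqs), names(sim$seqs)))
    dists[[g]] <- sim$dist
  }
  seqs <- sequence_set(seq_all)

  env <- simulate_env(cfg$n_samples, cfg$env_ar1, cfg$env_season_amp,
                      cfg$env_period, seed = stage_seed(seed, "env"))
  X <- build_design(env, include_quadratic = TRUE)
  p_lin <- length(env_variable_units)

  # focal niche coefficients: GP over realized distances, per genus
  beta_focal <- list(); true_corr <- list()
  sd_cols <- c(rep(cfg$beta_sd_linear, p_lin), rep(cfg$beta_sd_quad, p_lin))
  for (g in names(cfg$genera)) {
    nc <- simulate_niche_coefficients(dists[[g]], cfg$kernel, 2 * p_lin,
                                      sd = sd_cols,
                                      seed = stage_seed(seed, paste0("beta_", g)))
    beta_focal[[g]] <- nc$beta
    true_corr[[g]] <- nc$true_corr
  }

  set.seed(stage_seed(seed, "assemble"))
  bg_ids <- if (cfg$n_background > 0)
    sprintf("bg%03d", seq_len(cfg$n_background)) else character()
  beta_bg <- matrix(stats::rnorm(cfg$n_background * 2 * p_lin,
                                 sd = cfg$bg_beta_sd),
                    nrow = cfg$n_background,
                    dimnames = list(bg_ids, colnames(X)))
  beta <- do.call(rbind, c(unname(beta_focal), list(beta_bg)))
  colnames(beta) <- colnames(X)
  taxa <- rownames(beta)
  D <- length(taxa)
  focal_ids <- unlist(lapply(trees, function(t) t$tip.label), use.names = FALSE)

  beta0 <- c(stats::rnorm(length(focal_ids), cfg$beta0_focal_mean,
                          cfg$beta0_focal_sd),
             stats::rnorm(cfg$n_background, 0, cfg$beta0_bg_sd))
  names(beta0) <- taxa

  Lambda <- matrix(stats::rnorm(D * cfg$latent_d, sd = cfg$loading_sd), D,
                   dimnames = list(taxa, NULL))

  # planted conditionally rare taxa: background taxa pinned near a fixed
  # baseline relative abundance, bursting in a few samples
  crt_ids <- character()
  if (cfg$crt$n > 0) {
    if (cfg$crt$n > cfg$n_background)
      stop("more planted CRT taxa than background taxa")
    crt_ids <- bg_ids[seq_len(cfg$crt$n)]
    # typical softmax normalizer of the non-CRT community
    others <- setdiff(taxa, crt_ids)
    typ <- sum(exp(beta0[others]))
    beta0[crt_ids] <- log(cfg$crt$baseline * typ)
    beta[crt_ids, ] <- 0            # rare taxa: no strong env response
    Lambda[crt_ids, ] <- 0
  }

  depths <- round(stats::rlnorm(cfg$n_samples, log(cfg$depth_median),
                                cfg$depth_sdlog))
  depths <- pmax(depths, 100)

  simc <- simulate_counts(beta0, beta, X, Lambda,
                          eta_noise_sd = cfg$eta_noise_sd,
                          depths = depths,
                          burst_taxa = match(crt_ids, taxa),
                          burst = cfg$crt$burst,
                          burst_fraction = cfg$crt$burst_fraction,
                          burst_baseline = cfg$crt$baseline,
                          seed = stage_seed(seed, "counts"),
                          taxa = taxa, samples = rownames(X))

  # sample metadata: open-water dates over 8 years, two alternating sites
  years <- 2006 + ((seq_len(cfg$n_samples) - 1) %/%
                     ceiling(cfg$n_samples / 8))
  doy <- 100 + ((seq_len(cfg$n_samples) - 1) %% ceiling(cfg$n_samples / 8)) *
    round(210 / ceiling(cfg$n_samples / 8))
  meta <- data.frame(
    sample_id = rownames(X),
    date = format(as.Date(doy - 1, origin = paste0(years, "-01-01"))),
    site = rep_len(c("littoral", "pelagic"), cfg$n_samples),
    stringsAsFactors = FALSE)
  ct <- count_table(simc$ct$counts, meta)

  truth <- list(beta0 = beta0, beta = beta, Lambda = Lambda,
                distances = dists, true_niche_corr = true_corr,
                crt_taxa = crt_ids,
                burst_samples = simc$burst_samples,
                genus_map = stats::setNames(
                  rep(names(cfg$genera),
                      vapply(cfg$genera, function(g) g$n_taxa, 0)),
                  focal_ids))

  study <- list(ct = ct, env = env, seqs = seqs, trees = trees,
                truth = truth, config = cfg)
  if (!is.null(out_dir)) study$paths <- write_study(study, out_dir, force)
  study
}

# write the bundle in the pipeline's input formats
write_study <- function(study, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && !force)
    stop("output directory exists (use force = TRUE): ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    counts = file.path(out_dir, "counts.tsv"),
    env = file.path(out_dir, "env.tsv"),
    fasta = file.path(out_dir, "sequences.fasta"),
    truth = file.path(out_dir, "truth.json"),
    manifest = file.path(out_dir, "manifest.json"))
  write_count_table(study$ct, paths$counts)
  write_env_table(study$env, paths$env)
  write_fasta(study$seqs, paths$fasta)
  for (g in names(study$trees)) {
    paths[[paste0("tree_", g)]] <- file.path(out_dir,
                                             paste0("tree_", g, ".nwk"))
    ape::write.tree(study$trees[[g]], paths[[paste0("tree_", g)]])
  }
  truth_json <- list(
    beta0 = as.list(study$truth$beta0),
    crt_taxa = study$truth$crt_taxa,
    genus_map = as.list(study$truth$genus_map),
    true_niche_corr = lapply(study$truth$true_niche_corr, function(m)
      list(taxa = rownames(m), values = unname(as.data.frame(m)))))
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(list(seed = study$config$seed,
                            config_hash = rlang::hash(study$config),
                            created = "generated by nichepart"),
                       paths$manifest, auto_unbox = TRUE)
  paths
}
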