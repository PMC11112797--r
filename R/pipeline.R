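#' Configuration for an end-to-end pipeline run
#'
#' Bundles every tunable of the pipeline.  The `platform` preset sets the
#' spatial-neighbour count `k` (visium: 6, slide_seq: 8, stereo_seq: 8,
#' imaging: 15); an explicit `k` overrides the preset with a warning when
#' they disagree.  Exactly one of `target_K` / `resolution` must be given.
#'
#' @param counts,coords,labels input file paths (may be `NULL` when a slice
#'   object is passed to [run_pipeline()] directly).
#' @param platform one of `"visium"`, `"slide_seq"`, `"stereo_seq"`,
#'   `"imaging"`, `"custom"`.
#' @param k spatial neighbours per spot; `NULL` uses the platform preset.
#' @param min_spots_per_gene,n_hvg,n_pcs,target_sum,mu preprocessing
#'   parameters, see [preprocess_slice()].
#' @param kappa,clip_negative_pmi PMI parameters, see [pmi_matrix()].
#' @param alpha,beta,srl_tol,srl_max_iter expression-graph parameters, see
#'   [learn_expression_graph()].
#' @param d,gamma,lambda,joint_tol,joint_max_iter joint-factorization
#'   parameters, see [joint_params()].
#' @param target_K,resolution clustering control, see [leiden_domains()].
#' @param high_order use the PMI lift of the spatial graph as the spatial
#'   layer (default); `FALSE` uses the first-order KNN graph itself (ablation).
#' @param sequential use [sequential_fit()] instead of [joint_fit()]
#'   (non-joint ablation).
#' @param out_dir optional output directory for artifacts.
#' @param seed master seed for all randomized steps.
#' @param verbose print stage progress.
#' @return A list of class `run_config`.
#' @export
run_config <- function(counts = NULL, coords = NULL, labels = NULL,
                       platform = c("visium", "slide_seq", "stereo_seq",
                                    "imaging", "custom"),
                       k = NULL, min_spots_per_gene = 10L, n_hvg = 3000L,
                       n_pcs = 50L, target_sum = NULL, mu = 0.2,
                       kappa = 1L, clip_negative_pmi = TRUE,
                       alpha = 0.2, beta = 1, srl_tol = 1e-6,
                       srl_max_iter = 200L,
                       d = 100L, gamma = 1, lambda = 0.1, joint_tol = 1e-6,
                       joint_max_iter = 200L,
                       target_K = NULL, resolution = NULL,
                       high_order = TRUE, sequential = FALSE,
                       out_dir = NULL, seed = 0L, verbose = FALSE) {
  platform <- match.arg(platform)
  preset <- c(visium = 6L, slide_seq = 8L, stereo_seq = 8L,
              imaging = 15L, custom = 6L)[[platform]]
  if (is.null(k)) {
    k <- preset
  } else if (platform != "custom" && k != preset) {
    warning("explicit k = ", k, " overrides ", platform,
            " preset k = ", preset)
  }
  if (is.null(target_K) == is.null(resolution))
    stop_param("give exactly one of target_K or resolution")
  structure(list(counts = counts, coords = coords, labels = labels,
                 platform = platform, k = as.integer(k),
                 min_spots_per_gene = as.integer(min_spots_per_gene),
                 n_hvg = as.integer(n_hvg), n_pcs = as.integer(n_pcs),
                 target_sum = target_sum, mu = mu, kappa = as.integer(kappa),
                 clip_negative_pmi = clip_negative_pmi, alpha = alpha,
                 beta = beta, srl_tol = srl_tol,
                 srl_max_iter = as.integer(srl_max_iter),
                 d = as.integer(d), gamma = gamma, lambda = lambda,
                 joint_tol = joint_tol,
                 joint_max_iter = as.integer(joint_max_iter),
                 target_K = target_K, resolution = resolution,
                 high_order = isTRUE(high_order),
                 sequential = isTRUE(sequential),
                 out_dir = out_dir, seed = as.integer(seed),
                 verbose = verbose),
            class = "run_config")
}

#' Run the full spatial-domain identification pipeline
#'
#' Executes read, gene filter, normalization, highly-variable-gene
#' selection, spatial KNN graph, neighbour smoothing, PCA, PMI lift,
#' expression-graph learning, joint factorization, affinity symmetrization,
#' Leiden clustering, and evaluation.  Deterministic: rerunning with the
#' same config (and input) reproduces identical labels.
#'
#' @param config a [run_config()].
#' @param slice optional [slice_data()]; when given, the file paths in
#'   `config` are ignored.
#' @return A list with the intermediate and final artifacts: `slice`,
#'   `spatial`, `pmi`, `features`, `expression_graph`, `model`, `affinity`,
#'   `domains`, `scores`, `config`.  If `config$out_dir` is set, labels,
#'   scores, traces, a model checkpoint, and a manifest are written there.
#' @export
run_pipeline <- function(config, slice = NULL) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message("[multinetST] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_opt(paste0("pipeline stage '", name, "' failed: ",
                      conditionMessage(e)))
    })
  }
  if (is.null(slice)) {
    if (is.null(config$counts) || is.null(config$coords))
      stop_param("config must provide counts and coords paths, or pass a slice")
    say("reading input")
    slice <- stage("read", read_slice(config$counts, config$coords,
                                      config$labels))
  }
  say("building spatial KNN graph (k = ", config$k, ")")
  spatial <- stage("spatial_knn", build_spatial_knn(slice$coords, config$k))
  say("preprocessing ", nrow(slice$counts), " spots")
  feats <- stage("preprocess",
                 preprocess_slice(slice, spatial = spatial,
                                  min_spots_per_gene = config$min_spots_per_gene,
                                  n_hvg = config$n_hvg, n_pcs = config$n_pcs,
                                  target_sum = config$target_sum,
                                  mu = config$mu, seed = config$seed))
  say("PMI lift of the spatial graph")
  pmi <- stage("pmi", pmi_matrix(spatial, config$kappa,
                                 config$clip_negative_pmi))
  # feature-scale convention: unit mean squared cell norm, so the sparsity
  # weight alpha is a dimensionless ratio against the representation residual
  feats$X <- feats$X / sqrt(mean(rowSums(feats$X^2)))
  say("learning expression graph")
  eg <- stage("srl",
              learn_expression_graph(feats, alpha = config$alpha,
                                     beta = config$beta,
                                     laplacian = graph_laplacian(spatial),
                                     tol = config$srl_tol,
                                     max_iter = config$srl_max_iter))
  n <- nrow(slice$counts)
  jp <- joint_params(d = min(config$d, n - 1L), gamma = config$gamma,
                     lambda = config$lambda, tol = config$joint_tol,
                     max_iter = config$joint_max_iter, seed = config$seed)
  # layer conditioning for the joint factorization: per-cell normalized
  # expression coefficients, then both layers balanced to equal Frobenius
  # norm so neither dominates the shared basis
  spatial_layer <- if (config$high_order) pmi$M_s else as_dense(spatial$W_s)
  layers <- stage("balance", balance_layers(eg$W_e, spatial_layer))
  say(if (config$sequential) "sequential factorization (d = " else
      "joint factorization (d = ", jp$d, ")")
  model <- stage("joint_fit",
                 if (config$sequential)
                   sequential_fit(layers$W_e, layers$M_s, jp)
                 else joint_fit(layers$W_e, layers$M_s, jp))
  S <- stage("affinity", affinity_from_Z(model$Z))
  say("Leiden clustering")
  dom <- stage("leiden",
               leiden_domains(S, target_K = config$target_K,
                              resolution = config$resolution,
                              seed = config$seed))
  scores <- stage("scores",
                  clustering_scores(dom, truth = slice$labels,
                                    features = model$B, S = S))
  say("done: ", dom$K, " domains",
      if (!is.na(scores$ari)) paste0(", ARI = ", round(scores$ari, 3)))
  result <- list(slice = slice, spatial = spatial, pmi = pmi,
                 features = feats, expression_graph = eg, model = model,
                 affinity = S, domains = dom, scores = scores,
                 config = config)
  if (!is.null(config$out_dir)) write_run(result, config$out_dir)
  invisible(result)
}

#' Condition the two network layers for joint factorization
#'
#' Row-normalizes the expression graph (each cell's self-representation
#' coefficients sum to 1, equalizing cells regardless of their feature
#' magnitude) and rescales both layers to a common Frobenius norm (the
#' number of cells `n`), so neither layer dominates the shared basis and the
#' nuclear-norm / l2,1 weights operate on a predictable scale.
#'
#' @param W_e expression layer (matrix or `expression_graph`).
#' @param M_s spatial layer (matrix or `high_order_matrix`).
#' @param target common Frobenius norm; default `nrow(W_e)`.
#' @return List with conditioned `W_e` and `M_s`.
#' @export
balance_layers <- function(W_e, M_s, target = NULL) {
  We <- layer_matrix(W_e); Ms <- layer_matrix(M_s)
  if (!all(dim(We) == dim(Ms))) stop_valid("layer dimension mismatch")
  n <- nrow(We)
  if (is.null(target)) target <- n
  rs <- rowSums(We)
  We <- We / pmax(rs, .Machine$double.eps)
  nw <- fnorm(We); nm <- fnorm(Ms)
  if (nw == 0 || nm == 0) stop_valid("a layer is identically zero")
  list(W_e = We * (target / nw), M_s = Ms * (target / nm))
}

# write run artifacts: labels, scores, traces, checkpoint, manifest
write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(spot_id = result$slice$spot_ids,
                              domain = result$domains$labels),
                   file.path(out_dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(result$scores, file.path(out_dir, "scores.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(result$expression_graph$trace,
                   file.path(out_dir, "srl_trace.csv"), row.names = FALSE)
  utils::write.csv(result$model$report$trace,
                   file.path(out_dir, "joint_trace.csv"), row.names = FALSE)
  saveRDS(result$model, file.path(out_dir, "model.rds"), compress = "xz")
  manifest <- list(package_version = as.character(utils::packageVersion("multinetST")),
                   n_spots = nrow(result$slice$counts),
                   n_genes = ncol(result$slice$counts),
                   K = result$domains$K,
                   resolution = result$domains$resolution,
                   stop_reason = result$model$report$stop_reason,
                   config = result$config[setdiff(names(result$config),
                                                  c("verbose"))])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(out_dir)
}
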