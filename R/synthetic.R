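#' Specification for a synthetic spatial-transcriptomics slice
#'
#' Describes the generative model used by [generate_synthetic_slice()]: spots
#' on a `grid_w` x `grid_h` lattice partitioned into `n_domains` contiguous
#' spatial domains; each domain owns `markers_per_domain` marker genes whose
#' mean expression is multiplied by `2^log2_effect` inside that domain; UMI
#' counts are drawn negative-binomially with log-normal per-spot library-size
#' factors.  This emulates the structure the method assumes — spatially
#' contiguous regions with coherent expression — under realistic UMI
#' overdispersion; it does not emulate platform artifacts (tissue boundaries,
#' bead mixing, image features).
#'
#' @param grid_w,grid_h lattice dimensions (spots are placed at integer
#'   coordinates).
#' @param n_domains number of planted spatial domains K.
#' @param n_genes total number of genes.
#' @param markers_per_domain marker genes per domain; requires
#'   `markers_per_domain * n_domains <= n_genes`.
#' @param log2_effect log2 fold change of marker genes inside their domain.
#' @param nb_dispersion negative-binomial dispersion (1/size); 0 gives Poisson.
#' @param libsize_sigma standard deviation of the log-normal per-spot library
#'   factor.
#' @param coord_jitter Gaussian jitter (in lattice-spacing units) added to
#'   spot positions; 0 gives a regular lattice, positive values give
#'   scattered points with heterogeneous neighbour distances as in
#'   bead-based platforms.
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters for the
#'   baseline per-gene mean.
#' @param domain_geometry one of `"stripes"`, `"blocks"`, `"voronoi"`.
#' @param seed integer RNG seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid_w = 30L, grid_h = 30L, n_domains = 4L,
                           n_genes = 200L, markers_per_domain = 20L,
                           log2_effect = 2, nb_dispersion = 0.3,
                           libsize_sigma = 0.2, coord_jitter = 0,
                           base_mean_meanlog = log(1.5), base_mean_sdlog = 0.5,
                           domain_geometry = c("stripes", "blocks", "voronoi"),
                           seed = 0L) {
  domain_geometry <- match.arg(domain_geometry)
  spec <- list(grid_w = as.integer(grid_w), grid_h = as.integer(grid_h),
               n_domains = as.integer(n_domains), n_genes = as.integer(n_genes),
               markers_per_domain = as.integer(markers_per_domain),
               log2_effect = log2_effect, nb_dispersion = nb_dispersion,
               libsize_sigma = libsize_sigma, coord_jitter = coord_jitter,
               base_mean_meanlog = base_mean_meanlog,
               base_mean_sdlog = base_mean_sdlog,
               domain_geometry = domain_geometry, seed = as.integer(seed))
  n <- spec$grid_w * spec$grid_h
  if (spec$n_domains > n) stop_param("n_domains exceeds number of lattice spots")
  if (spec$markers_per_domain * spec$n_domains > spec$n_genes)
    stop_param("markers_per_domain * n_domains exceeds n_genes")
  if (spec$nb_dispersion < 0 || spec$libsize_sigma < 0 || spec$coord_jitter < 0)
    stop_param("noise parameters must be non-negative")
  class(spec) <- "synthetic_spec"
  spec
}

# contiguous domain labels on the lattice, equal sizes where possible
plant_domains <- function(coords, K, geometry, rng_ready = TRUE) {
  n <- nrow(coords)
  if (geometry == "stripes") {
    # order spots by x (then y) and cut into K equal consecutive runs:
    # stripes perpendicular to the x axis, each contiguous, sizes n/K
    ord <- order(coords[, 1], coords[, 2])
    lab <- integer(n)
    lab[ord] <- ceiling(seq_len(n) * K / n)
  } else if (geometry == "blocks") {
    k1 <- max(which(seq_len(K) <= sqrt(K) & K %% seq_len(K) == 0))  # largest divisor <= sqrt(K)
    k2 <- K / k1
    qx <- ceiling(rank(coords[, 1], ties.method = "first") * k2 / n)
    qy <- ceiling(rank(coords[, 2], ties.method = "first") * k1 / n)
    lab <- as.integer(factor(paste(qx, qy)))
  } else { # voronoi
    centers <- coords[sample.int(n, K), , drop = FALSE]
    d2 <- outer(coords[, 1], centers[, 1], "-")^2 + outer(coords[, 2], centers[, 2], "-")^2
    lab <- max.col(-d2)
    # guard: make sure all K domains are non-empty
    miss <- setdiff(seq_len(K), unique(lab))
    for (k in miss) lab[sample.int(n, 1)] <- k
  }
  lab
}

#' Generate a synthetic spatial slice with planted domains
#'
#' Draws a `slice_data` object from the generative model in
#' [synthetic_spec()].  Fully reproducible: the same spec (including `seed`)
#' yields byte-identical output.
#'
#' @param spec a [synthetic_spec()] object.
#' @return A [slice_data()] with `labels` filled with the planted domain of
#'   each spot.
#' @export
generate_synthetic_slice <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) stop_param("spec must be a synthetic_spec")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$grid_w * spec$grid_h
  coords <- cbind(x = rep(seq_len(spec$grid_w), each = spec$grid_h),
                  y = rep(seq_len(spec$grid_h), times = spec$grid_w))
  labels <- plant_domains(coords, spec$n_domains, spec$domain_geometry)
  if (spec$coord_jitter > 0)
    coords <- coords + matrix(stats::rnorm(2 * n, 0, spec$coord_jitter), n, 2)

  base_mu <- stats::rlnorm(spec$n_genes, spec$base_mean_meanlog, spec$base_mean_sdlog)
  # markers: first markers_per_domain*K genes, in domain order
  marker_of <- rep(NA_integer_, spec$n_genes)
  if (spec$markers_per_domain > 0)
    marker_of[seq_len(spec$markers_per_domain * spec$n_domains)] <-
      rep(seq_len(spec$n_domains), each = spec$markers_per_domain)

  mu <- matrix(base_mu, nrow = n, ncol = spec$n_genes, byrow = TRUE)
  fold <- 2^spec$log2_effect
  for (k in seq_len(spec$n_domains)) {
    g <- which(marker_of == k)
    if (length(g)) mu[labels == k, g] <- mu[labels == k, g] * fold
  }
  libf <- stats::rlnorm(n, 0, spec$libsize_sigma)
  mu <- mu * libf
  counts <- if (spec$nb_dispersion > 0) {
    matrix(stats::rnbinom(n * spec$n_genes, mu = mu, size = 1 / spec$nb_dispersion),
           nrow = n)
  } else {
    matrix(stats::rpois(n * spec$n_genes, lambda = mu), nrow = n)
  }
  gene_ids <- sprintf("gene%03d", seq_len(spec$n_genes))
  gene_ids[!is.na(marker_of)] <- sprintf("marker_d%d_%02d",
                                         marker_of[!is.na(marker_of)],
                                         stats::ave(seq_len(spec$n_genes), marker_of,
                                                    FUN = seq_along)[!is.na(marker_of)])
  rownames(counts) <- sprintf("spot%04d", seq_len(n))
  colnames(counts) <- gene_ids
  slice_data(counts, coords, labels = labels)
}

#' Generate a planted-block two-layer network fixture
#'
#' Produces two symmetric non-negative n x n matrices sharing the same
#' planted K-block structure but with independent additive Gaussian noise —
#' a drop-in input pair for [joint_fit()] that bypasses preprocessing.
#'
#' @param n number of nodes.
#' @param K number of planted blocks (balanced sizes).
#' @param within_weight,between_weight edge weights inside / across blocks;
#'   requires `within_weight > between_weight >= 0`.
#' @param noise_sd standard deviation of the symmetric Gaussian noise added
#'   independently to each layer (result clamped at 0, diagonal zeroed).
#' @param seed integer RNG seed.
#' @return A list with elements `W_e`, `M_s` (the two layers) and `labels`
#'   (planted block of each node).
#' @export
generate_block_multilayer <- function(n = 120L, K = 3L, within_weight = 1,
                                      between_weight = 0.05, noise_sd = 0.1,
                                      seed = 0L) {
  if (within_weight <= between_weight || between_weight < 0)
    stop_param("need within_weight > between_weight >= 0")
  if (K > n) stop_param("K exceeds n")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  labels <- rep(seq_len(K), length.out = n)
  labels <- sort(labels)
  signal <- matrix(between_weight, n, n)
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    signal[idx, idx] <- within_weight
  }
  diag(signal) <- 0
  make_layer <- function() {
    if (noise_sd == 0) return(signal)
    eps <- matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
    eps <- (eps + t(eps)) / 2
    out <- pmax(signal + eps, 0)
    diag(out) <- 0
    out
  }
  list(W_e = make_layer(), M_s = make_layer(), labels = labels)
}

# save/restore the global RNG state so generators do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
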