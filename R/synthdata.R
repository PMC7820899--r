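#' Configuration for the synthetic EMT single-cell generator
#'
#' Bundles and validates every knob of the generator. The defaults emulate the
#' structure of a time-series EMT induction experiment: four cell states along
#' a linear E -> I1 -> I2 -> M trajectory, 50 cells per state, 10% transition
#' cells with mixed membership between adjacent states, bimodal marker genes,
#' five collection time points, and negative-binomial counts with dropout.
#'
#' @param n_clusters Number of planted cell states `K` (>= 2).
#' @param cells_per_cluster Cells per state; total cells `n = K * cells_per_cluster`.
#' @param tc_fraction Fraction of all cells that are transition cells, in
#'   `[0, 0.5]`. Transition cells sit between adjacent states on the trajectory
#'   with both memberships in `[0.25, 0.75]`.
#' @param n_genes Total genes, including markers, pathway genes and flat fillers.
#' @param markers_per_cluster Bimodal marker genes planted per state.
#' @param n_timepoints Number of collection time points (>= 1).
#' @param sync_mode `"synchronous"` (time label tracks trajectory position with
#'   small jitter) or `"asynchronous"` (time label near-uniform across
#'   positions, with a weak linear drift).
#' @param mean_high,mean_low Negative-binomial means for the "on" and "off"
#'   state of planted bimodal genes (counts scale).
#' @param dispersion Negative-binomial overdispersion; `0` gives Poisson counts.
#' @param dropout_rate Probability that any count is zeroed, in `[0, 1)`.
#' @param seed Integer seed; the full dataset is deterministic given the config.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_clusters = 4, cells_per_cluster = 50,
                         tc_fraction = 0.1, n_genes = 250,
                         markers_per_cluster = 25, n_timepoints = 5,
                         sync_mode = c("synchronous", "asynchronous"),
                         mean_high = 20, mean_low = 0.2, dispersion = 0.3,
                         dropout_rate = 0.2, seed = 1L) {
  sync_mode <- match.arg(sync_mode)
  assert_count(n_clusters, "n_clusters", min = 2L)
  assert_count(cells_per_cluster, "cells_per_cluster")
  assert_fraction(tc_fraction, "tc_fraction", 0, 0.5)
  assert_count(n_genes, "n_genes")
  assert_count(markers_per_cluster, "markers_per_cluster")
  assert_count(n_timepoints, "n_timepoints")
  if (!is.numeric(mean_high) || !is.numeric(mean_low) ||
      mean_high <= mean_low || mean_low < 0) {
    abort("`mean_high` must exceed `mean_low` and both must be non-negative.")
  }
  if (!is.numeric(dispersion) || dispersion < 0) abort("`dispersion` must be >= 0.")
  assert_fraction(dropout_rate, "dropout_rate", 0, 1, hi_open = TRUE)
  structure(list(
    n_clusters = as.integer(n_clusters),
    cells_per_cluster = as.integer(cells_per_cluster),
    tc_fraction = tc_fraction, n_genes = as.integer(n_genes),
    markers_per_cluster = as.integer(markers_per_cluster),
    n_timepoints = as.integer(n_timepoints), sync_mode = sync_mode,
    mean_high = mean_high, mean_low = mean_low, dispersion = dispersion,
    dropout_rate = dropout_rate, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Generate a synthetic ligand-receptor pathway specification
#'
#' Builds a pathway with `n_pairs` ligand-receptor pairs sharing one set of
#' up-regulated and one set of down-regulated target genes, with disjoint,
#' self-describing gene names (`LIG*`, `REC*`, `TUP*`, `TDN*`).
#'
#' @param n_pairs Number of ligand-receptor pairs (>= 1).
#' @param n_up,n_down Number of up-/down-regulated target genes (>= 1).
#' @param seed Integer seed (the spec is deterministic given the seed).
#' @param pathway_name Pathway name recorded in the returned object.
#' @return An object of class `emt_pathway_spec`: a list with `pathway`,
#'   `pairs` (tibble with `ligand`, `receptor`), `targets_up`, `targets_down`.
#' @export
generate_pathway_spec <- function(n_pairs, n_up, n_down, seed = 0L,
                                  pathway_name = "SYNTH_TGFB") {
  assert_count(n_pairs, "n_pairs"); assert_count(n_up, "n_up")
  assert_count(n_down, "n_down")
  spec <- list(
    pathway = pathway_name,
    pairs = tibble(
      ligand = sprintf("LIG%d", seq_len(n_pairs)),
      receptor = sprintf("REC%d", seq_len(n_pairs))
    ),
    targets_up = sprintf("TUP%d", seq_len(n_up)),
    targets_down = sprintf("TDN%d", seq_len(n_down)),
    seed = as.integer(seed)
  )
  structure(spec, class = "emt_pathway_spec")
}

pathway_genes <- function(pathway) {
  c(pathway$pairs$ligand, pathway$pairs$receptor,
    pathway$targets_up, pathway$targets_down)
}

#' @export
print.emt_pathway_spec <- function(x, ...) {
  cat(sprintf("<emt_pathway_spec> %s: %d ligand-receptor pair(s), %d up-, %d down-target(s)\n",
              x$pathway, nrow(x$pairs), length(x$targets_up), length(x$targets_down)))
  invisible(x)
}

# Per-state mean profiles (K x G): markers on in their own state, pathway
# genes wired so each planted sender expresses the ligand and each receiver
# expresses receptor + up-targets while down-targets are suppressed there.
build_profiles <- function(config, pathway, planted) {
  K <- config$n_clusters
  m <- config$markers_per_cluster
  marker_ids <- as.vector(vapply(seq_len(K), function(k)
    sprintf("M%d_%d", k, seq_len(m)), character(m)))
  pw_ids <- pathway_genes(pathway)
  n_fill <- config$n_genes - length(marker_ids) - length(pw_ids)
  if (n_fill < 0) {
    abort("pathway and marker genes exceed `n_genes`; increase gene capacity.")
  }
  fill_ids <- if (n_fill > 0) sprintf("G%d", seq_len(n_fill)) else character()
  genes <- c(marker_ids, pw_ids, fill_ids)

  prof <- matrix(config$mean_low, K, length(genes), dimnames = list(NULL, genes))
  for (k in seq_len(K)) prof[k, sprintf("M%d_%d", k, seq_len(m))] <- config$mean_high
  senders <- unique(planted$sender); receivers <- unique(planted$receiver)
  prof[, pathway$pairs$ligand] <- config$mean_low
  prof[senders, pathway$pairs$ligand] <- config$mean_high
  prof[receivers, pathway$pairs$receptor] <- config$mean_high
  prof[receivers, pathway$targets_up] <- config$mean_high
  prof[, pathway$targets_down] <- config$mean_high
  prof[receivers, pathway$targets_down] <- config$mean_low
  # fillers sit at a mid expression level in every state: informative about
  # nothing, and unimodal (a low filler mean would be zero-inflated into a
  # spuriously bimodal profile by dropout)
  if (n_fill > 0) prof[, fill_ids] <- (config$mean_high + config$mean_low) / 2
  prof
}

#' Generate a synthetic EMT single-cell dataset with known ground truth
#'
#' Plants `K` cell states along a linear trajectory with transition cells of
#' mixed membership between adjacent states, bimodal per-state marker genes,
#' sender -> receiver ligand-receptor signaling (ligand high in the sender
#' state; receptor and up-regulated targets high, down-regulated targets low
#' in the receiver state), time-point labels in synchronous or asynchronous
#' mode, and negative-binomial count noise with dropout. Every downstream
#' stage of the pipeline can be validated against the returned truth.
#'
#' @param config A [synth_config()].
#' @param pathway An [generate_pathway_spec()] result; default builds a
#'   2-pair pathway with 4 up- and 3 down-targets from `config$seed`.
#' @param planted_signaling Tibble/data frame with columns `sender`,
#'   `receiver` (1-based state indices); default one pair, first state ->
#'   last state on the trajectory.
#' @return An object of class `emt_dataset`: list with `expression` (counts,
#'   cells x genes), `true_membership` (cells x K, rows on the simplex),
#'   `true_labels`, `is_tc`, `true_path`, `time_labels`, `pathway`,
#'   `planted_signaling`, `config`.
#' @export
generate_emt_dataset <- function(config = synth_config(), pathway = NULL,
                                 planted_signaling = NULL) {
  stopifnot(inherits(config, "synth_config"))
  K <- config$n_clusters
  if (is.null(pathway)) {
    pathway <- generate_pathway_spec(2, 4, 3, seed = config$seed)
  }
  if (is.null(planted_signaling)) {
    planted_signaling <- tibble(sender = 1L, receiver = K)
  }
  planted_signaling <- as_tibble(planted_signaling)
  if (any(planted_signaling$sender < 1 | planted_signaling$sender > K |
          planted_signaling$receiver < 1 | planted_signaling$receiver > K)) {
    abort("planted_signaling indices must lie in 1..K.")
  }

  n <- K * config$cells_per_cluster
  n_tc <- round(config$tc_fraction * n)
  path <- seq_len(K)

  with_local_seed(config$seed, {
    # membership: non-TCs one-hot spread near-evenly over states, TCs split
    # between adjacent states on the path with weight in [0.25, 0.75]
    H <- matrix(0, n, K)
    core_lab <- rep(path, length.out = n - n_tc)
    for (i in seq_len(n - n_tc)) H[i, core_lab[i]] <- 1
    if (n_tc > 0) {
      pair_pos <- rep(seq_len(K - 1), length.out = n_tc)
      w <- runif(n_tc, 0.25, 0.75)
      for (t in seq_len(n_tc)) {
        i <- n - n_tc + t
        H[i, path[pair_pos[t]]] <- w[t]
        H[i, path[pair_pos[t] + 1]] <- 1 - w[t]
      }
    }
    labels <- max.col(H, ties.method = "first")
    is_tc <- c(rep(FALSE, n - n_tc), rep(TRUE, n_tc))

    prof <- build_profiles(config, pathway, planted_signaling)
    mu <- H %*% prof

    counts <- matrix(0L, n, ncol(mu))
    if (config$dispersion > 0) {
      counts[] <- rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    } else {
      counts[] <- rpois(length(mu), lambda = mu)
    }
    if (config$dropout_rate > 0) {
      keep <- rbinom(length(counts), 1, 1 - config$dropout_rate)
      counts <- counts * keep
    }
    dimnames(counts) <- list(sprintf("cell_%04d", seq_len(n)), colnames(mu))

    # trajectory position in [0,1]; time labels follow it (synchronous) or
    # are near-uniform with a weak drift (asynchronous)
    pos <- (H %*% (match(seq_len(K), path) - 1)) / (K - 1)
    Tn <- config$n_timepoints
    if (Tn == 1L) {
      tl <- rep(1L, n)
    } else if (config$sync_mode == "synchronous") {
      jit <- pmin(pmax(pos + stats::rnorm(n, 0, 0.05), 0), 1)
      tl <- 1L + as.integer(round(jit * (Tn - 1)))
    } else {
      u <- 0.9 * runif(n) + 0.1 * pos
      tl <- pmin(1L + as.integer(floor(u * Tn)), Tn)
    }
    names(tl) <- rownames(counts)

    structure(list(
      expression = counts,
      true_membership = H,
      true_labels = labels,
      is_tc = is_tc,
      true_path = path,
      time_labels = tl,
      pathway = pathway,
      planted_signaling = planted_signaling,
      config = config
    ), class = "emt_dataset")
  })
}

#' @export
print.emt_dataset <- function(x, ...) {
  cat(sprintf("<emt_dataset> %d cells x %d genes, K = %d, %d transition cell(s), %s time labels\n",
              nrow(x$expression), ncol(x$expression), x$config$n_clusters,
              sum(x$is_tc), x$config$sync_mode))
  invisible(x)
}

#' Ground-truth cluster-signaling indicator for a synthetic dataset
#'
#' Returns the K x K indicator matrix of planted sender -> receiver pairs
#' (1 where signaling was planted, 0 elsewhere), for rank-agreement comparison
#' with an inferred cluster-signaling matrix.
#'
#' @param dataset An [generate_emt_dataset()] result with at least one planted
#'   signaling pair.
#' @return K x K numeric matrix.
#' @export
expected_cluster_signaling <- function(dataset) {
  stopifnot(inherits(dataset, "emt_dataset"))
  ps <- dataset$planted_signaling
  if (is.null(ps) || nrow(ps) == 0) {
    abort("dataset has no planted signaling pairs.")
  }
  K <- dataset$config$n_clusters
  M <- matrix(0, K, K)
  for (i in seq_len(nrow(ps))) M[ps$sender[i], ps$receiver[i]] <- 1
  M
}
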