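#' Configuration for the synthetic multi-omics generator
#'
#' The generator plants `n_clusters` sample groups shared across all layers.
#' Informative features (a random `frac_informative` fraction per layer) carry
#' cluster-specific mean shifts of typical size `cluster_sep` (in SD units of
#' the unit noise). One designated cluster additionally over-expresses the
#' nine-gene Treg signature, the exhaustion-marker panel and a block of
#' immune-response genes on the mRNA layer by `treg_effect` SD units, so the
#' immunosuppressive subtype the pipeline is meant to find has a known
#' identity. Values are pushed into each layer's value domain by a monotone
#' transform, and missing entries are injected uniformly at random.
#'
#' @param n_samples number of samples shared by all layers.
#' @param n_clusters true number of planted clusters (K).
#' @param layer_specs named list; each element is
#'   `list(n_features =, value_domain =)`. Defaults mirror a four-layer
#'   mRNA/miRNA/methylation/protein design with 2000/482/2000/217 features.
#' @param cluster_sep effect-size scale (SD units) of cluster mean shifts on
#'   informative features; 0 means no cluster signal.
#' @param frac_informative fraction of features per layer carrying cluster
#'   signal.
#' @param treg_cluster index (1-based) of the cluster receiving the Treg
#'   spike.
#' @param treg_effect additive shift (SD units) applied to Treg-signature,
#'   exhaustion and immune genes in `treg_cluster` samples.
#' @param treg_in_protein mirror the Treg spike onto the first
#'   `length(treg genes)` protein features (default `FALSE`: the Treg
#'   evidence is transcriptomic).
#' @param n_immune_genes size of the immune-response gene block spiked
#'   alongside the Treg signature on the mRNA layer.
#' @param layer_noise_corr weight of a shared per-sample latent noise factor
#'   added to every layer; 0 (default) makes layer noise independent. The
#'   strength of technical inter-layer correlation is exposed as a knob
#'   because no single value is canonical.
#' @param missing_rate fraction of entries set missing per layer, in [0, 1).
#' @param seed RNG seed; identical configs give byte-identical output.
#' @return a `synthetic_omics_config` list.
#' @export
synthetic_omics_config <- function(n_samples = 300,
                                   n_clusters = 3,
                                   layer_specs = default_layer_specs(),
                                   cluster_sep = 3,
                                   frac_informative = 0.2,
                                   treg_cluster = 2,
                                   treg_effect = 2,
                                   treg_in_protein = FALSE,
                                   n_immune_genes = 25,
                                   layer_noise_corr = 0,
                                   missing_rate = 0,
                                   seed = 1) {
  stopifnot(n_clusters >= 1, n_samples >= 1,
            frac_informative >= 0, frac_informative <= 1,
            treg_cluster >= 1, treg_cluster <= n_clusters,
            missing_rate >= 0, missing_rate < 1,
            cluster_sep >= 0, treg_effect >= 0)
  if (n_samples < n_clusters)
    stop("n_samples must be >= n_clusters")
  domains <- vapply(layer_specs, `[[`, "", "value_domain")
  ok <- domains %in% c("continuous", "unit_interval", "nonneg_continuous")
  if (!all(ok))
    stop("unknown value_domain: ", paste(domains[!ok], collapse = ", "))
  structure(
    list(n_samples = n_samples, n_clusters = n_clusters,
         layer_specs = layer_specs, cluster_sep = cluster_sep,
         frac_informative = frac_informative, treg_cluster = treg_cluster,
         treg_effect = treg_effect, treg_in_protein = treg_in_protein,
         n_immune_genes = n_immune_genes,
         layer_noise_corr = layer_noise_corr,
         missing_rate = missing_rate, seed = seed),
    class = "synthetic_omics_config"
  )
}

#' Default four-layer design for the synthetic generator
#'
#' mRNA and miRNA are counts-like nonnegative, methylation is beta-valued in
#' \[0, 1\], protein is continuous; feature counts match the retained
#' dimensions of the preprocessing defaults (2000/482/2000/217).
#'
#' @param n_mrna,n_mirna,n_meth,n_protein per-layer feature counts.
#' @return a named list of layer specs suitable for
#'   [synthetic_omics_config()].
#' @export
default_layer_specs <- function(n_mrna = 2000, n_mirna = 482,
                                n_meth = 2000, n_protein = 217) {
  list(
    mRNA = list(n_features = n_mrna, value_domain = "nonneg_continuous"),
    miRNA = list(n_features = n_mirna, value_domain = "nonneg_continuous"),
    methylation = list(n_features = n_meth, value_domain = "unit_interval"),
    protein = list(n_features = n_protein, value_domain = "continuous")
  )
}

# monotone push of an unbounded score matrix into a value domain
to_domain <- function(x, domain) {
  switch(domain,
         continuous = x,
         unit_interval = stats::plogis(x),
         nonneg_continuous = log1p(exp(pmin(x, 30))),  # softplus, overflow-safe
         stop("unknown value_domain: ", domain))
}

mrna_feature_names <- function(n, n_immune) {
  treg <- treg_signature()$genes
  exh <- exhaustion_markers()$genes
  imm <- sprintf("IMMUNE_%03d", seq_len(n_immune))
  special <- c(treg, exh, imm)
  if (n < length(special))
    stop("mRNA layer needs at least ", length(special), " features")
  c(special, sprintf("GENE_%05d", seq_len(n - length(special))))
}

#' Generate a synthetic multi-omics dataset with planted structure
#'
#' @param config a [synthetic_omics_config()].
#' @return a list with elements `dataset` (a [multiomics_dataset()]) and
#'   `truth` (planted `labels` named by sample id, per-layer
#'   `informative_features`, `treg_genes`, `immune_genes`, and
#'   `treg_cluster`).
#' @export
generate_multiomics <- function(config) {
  stopifnot(inherits(config, "synthetic_omics_config"))
  withr::with_seed(config$seed, {
    n <- config$n_samples
    K <- config$n_clusters
    samples <- sprintf("S%04d", seq_len(n))
    labels <- sample(rep_len(seq_len(K), n))
    names(labels) <- samples
    shared_noise <- stats::rnorm(n)

    treg <- treg_signature()$genes
    spike_targets <- c(treg, exhaustion_markers()$genes,
                       sprintf("IMMUNE_%03d", seq_len(config$n_immune_genes)))
    informative <- list()
    layers <- list()
    for (lname in names(config$layer_specs)) {
      spec <- config$layer_specs[[lname]]
      p <- spec$n_features
      feats <- if (lname == "mRNA") {
        mrna_feature_names(p, config$n_immune_genes)
      } else {
        sprintf("%s_%05d", toupper(lname), seq_len(p))
      }
      n_info <- round(config$frac_informative * p)
      info <- sort(sample.int(p, n_info))
      informative[[lname]] <- feats[info]

      # cluster-mean design: informative features get cluster-specific means
      mu <- matrix(0, K, p)
      if (n_info > 0 && config$cluster_sep > 0)
        mu[, info] <- config$cluster_sep * stats::rnorm(K * n_info)
      x <- mu[labels, , drop = FALSE] + stats::rnorm(n * p)
      if (config$layer_noise_corr != 0)
        x <- x + config$layer_noise_corr * shared_noise

      # Treg spike: transcriptomic by default, optionally mirrored on protein
      spiked <- labels == config$treg_cluster
      if (config$treg_effect > 0 && any(spiked)) {
        if (lname == "mRNA") {
          idx <- match(spike_targets, feats)
          x[spiked, idx] <- x[spiked, idx] + config$treg_effect
        } else if (lname == "protein" && isTRUE(config$treg_in_protein)) {
          idx <- seq_len(min(length(treg), p))
          x[spiked, idx] <- x[spiked, idx] + config$treg_effect
        }
      }

      x <- to_domain(x, spec$value_domain)
      dimnames(x) <- list(samples, feats)
      layer <- omics_layer(lname, x, spec$value_domain)
      if (config$missing_rate > 0)
        layer <- inject_missing(layer, config$missing_rate,
                                seed = config$seed + match(lname, names(config$layer_specs)))
      layers[[lname]] <- layer
    }

    truth <- list(labels = labels,
                  informative_features = informative,
                  treg_genes = treg,
                  immune_genes = sprintf("IMMUNE_%03d",
                                         seq_len(config$n_immune_genes)),
                  treg_cluster = config$treg_cluster)
    list(dataset = multiomics_dataset(layers, provenance = "synthetic"),
         truth = truth)
  })
}

#' Inject missing values into a layer at an exact rate
#'
#' Sets exactly `round(rate * n_entries)` entries to `NA`, positions chosen
#' uniformly at random and reproducible by `seed`.
#'
#' @param layer an [omics_layer()].
#' @param rate fraction of entries to blank, in [0, 1).
#' @param seed RNG seed for the position draw.
#' @return the layer with missing entries injected.
#' @export
inject_missing <- function(layer, rate, seed = 1) {
  stopifnot(inherits(layer, "omics_layer"))
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  n_entries <- length(layer$values)
  n_miss <- round(rate * n_entries)
  if (n_miss == 0) return(layer)
  withr::with_seed(seed, {
    pos <- sample.int(n_entries, n_miss)
    layer$values[pos] <- NA_real_
  })
  layer
}

#' Generate a ranked expression list with a planted gene set
#'
#' Fixture generator for enrichment tests: a strictly decreasing ranked list
#' of `n_genes` scores with a gene set occupying the top, the bottom, or
#' random positions.
#'
#' @param n_genes total number of genes.
#' @param set_size size of the planted set.
#' @param set_position `"top"`, `"bottom"` or `"random"`.
#' @param seed RNG seed.
#' @return a list with `ranked` (named numeric vector, sorted decreasing)
#'   and `geneset` (a [gene_set()]).
#' @export
make_ranked_expression <- function(n_genes, set_size = 10,
                                   set_position = c("top", "bottom", "random"),
                                   seed = 1) {
  set_position <- match.arg(set_position)
  stopifnot(n_genes >= set_size, set_size >= 1)
  withr::with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    scores <- sort(stats::rnorm(n_genes), decreasing = TRUE)
    names(scores) <- genes
    members <- switch(set_position,
                      top = genes[seq_len(set_size)],
                      bottom = genes[seq(n_genes - set_size + 1, n_genes)],
                      random = sample(genes, set_size))
    list(ranked = scores,
         geneset = gene_set(paste0("PLANTED_", toupper(set_position)), members))
  })
}

#' Configuration for the synthetic tumor-growth study
#'
#' Per-animal volumes follow `V(t) = V0 * exp(rate * effect * t) * noise`
#' with multiplicative lognormal noise (volumes are positive and
#' right-skewed). Defaults emulate a four-arm checkpoint-combination design:
#' IgG control, a monotherapy that mildly accelerates growth, a neutral
#' monotherapy, and a combination that slows growth, with n = 5 animals per
#' arm, baseline 96.45 +/- 12.93 mm3 and measurements on days 0, 2, 4, 7, 9,
#' 11 and 14.
#'
#' @param arms named numeric vector of per-arm multipliers on the daily
#'   growth rate; must contain `control = 1`.
#' @param n_per_arm animals per arm.
#' @param v0_mean,v0_sd baseline volume mean and SD (mm3).
#' @param growth_rate control-arm exponential growth rate per day.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise; 0 gives exact closed-form trajectories.
#' @param days measurement schedule (days), strictly increasing, nonnegative.
#' @param seed RNG seed.
#' @return a `growth_sim_config` list.
#' @export
growth_sim_config <- function(arms = c(control = 1.0, IPG7236 = 1.05,
                                       antiPDL1 = 1.0, combo = 0.90),
                              n_per_arm = 5,
                              v0_mean = 96.45, v0_sd = 12.93,
                              growth_rate = 0.21,
                              noise_cv = 0.1,
                              days = c(0, 2, 4, 7, 9, 11, 14),
                              seed = 1) {
  stopifnot(v0_mean > 0, all(days >= 0), !is.unsorted(days, strictly = TRUE),
            n_per_arm >= 1)
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (!"control" %in% names(arms) || arms[["control"]] != 1)
    stop("arms must contain an arm named 'control' with effect 1.0")
  structure(
    list(arms = arms, n_per_arm = n_per_arm, v0_mean = v0_mean,
         v0_sd = v0_sd, growth_rate = growth_rate, noise_cv = noise_cv,
         days = days, seed = seed),
    class = "growth_sim_config"
  )
}

#' Simulate a tumor-growth study with known arm effects
#'
#' @param config a [growth_sim_config()].
#' @return a [growth_study()] with columns `animal`, `arm`, `day`,
#'   `volume_mm3`.
#' @export
generate_growth_study <- function(config) {
  stopifnot(inherits(config, "growth_sim_config"))
  withr::with_seed(config$seed, {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    rows <- list()
    for (arm in names(config$arms)) {
      eff <- config$arms[[arm]]
      for (i in seq_len(config$n_per_arm)) {
        v0 <- max(stats::rnorm(1, config$v0_mean, config$v0_sd), 1)
        noise <- if (config$noise_cv > 0)
          stats::rlnorm(length(config$days), -sdlog^2 / 2, sdlog)
        else rep(1, length(config$days))
        vol <- v0 * exp(config$growth_rate * eff * config$days) * noise
        rows[[length(rows) + 1L]] <- data.frame(
          animal = sprintf("%s_%02d", arm, i), arm = arm,
          day = config$days, volume_mm3 = vol)
      }
    }
    growth_study(do.call(rbind, rows))
  })
}
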