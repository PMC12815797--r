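#' End-to-end pipeline configuration
#'
#' Nested per-stage configs plus a global seed. The global seed drives every
#' stage deterministically: stage i runs with seed `global seed + i` (stages
#' are numbered synthetic = 1, preprocess = 2, embed = 3, consensus = 4,
#' characterize = 5, select = 6, efficacy = 7).
#'
#' @param synthetic a [synthetic_omics_config()].
#' @param preprocess a [preprocess_config()].
#' @param embed_method `"pca"` (fast, deterministic) or `"ae"`.
#' @param pca_dim latent dimensionality for the PCA path.
#' @param ae an [ae_config()] for the autoencoder path.
#' @param consensus a [consensus_config()].
#' @param gsea_n_perm permutations for per-cluster enrichment.
#' @param ora_top_frac fraction of the ranking taken as the ORA hit list.
#' @param growth a [growth_sim_config()].
#' @param seed global seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_omics_config(),
                            preprocess = preprocess_config(),
                            embed_method = c("pca", "ae"),
                            pca_dim = 20,
                            ae = ae_config(),
                            consensus = consensus_config(),
                            gsea_n_perm = 200,
                            ora_top_frac = 0.1,
                            growth = growth_sim_config(),
                            seed = 1) {
  embed_method <- match.arg(embed_method)
  structure(list(synthetic = synthetic, preprocess = preprocess,
                 embed_method = embed_method, pca_dim = pca_dim, ae = ae,
                 consensus = consensus, gsea_n_perm = gsea_n_perm,
                 ora_top_frac = ora_top_frac, growth = growth, seed = seed),
            class = "pipeline_config")
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Characterize clusters of a multi-omics dataset
#'
#' Scores the Treg signature and an immune gene set on the mRNA layer,
#' compares scores across clusters (Kruskal-Wallis/Dunn/Wilcoxon), ranks
#' genes one-vs-rest per cluster, runs GSEA (Treg + immune sets) and ORA
#' (hit list = top `ora_top_frac` of the ranking), and computes the
#' exhaustion panel.
#'
#' @param expr complete numeric matrix, samples in rows, genes in columns
#'   (mRNA layer).
#' @param labels per-sample cluster labels.
#' @param genesets named list of [gene_set()]s; must contain `treg`, may
#'   contain `immune` and others.
#' @param gsea_n_perm permutations per enrichment test.
#' @param ora_top_frac fraction of top-ranked genes forming the ORA hits.
#' @param seed RNG seed.
#' @return a `cluster_characterization` list with `treg_scores`,
#'   `score_tests`, per-cluster `gsea` and `ora` tables, `exhaustion`, and
#'   per-cluster mean scores.
#' @export
characterize_clusters <- function(expr, labels, genesets,
                                  gsea_n_perm = 200, ora_top_frac = 0.1,
                                  seed = 1) {
  stopifnot("treg" %in% names(genesets))
  clusters <- sort(unique(labels))
  treg_scores <- signature_score(expr, genesets$treg)
  score_tests <- group_tests(treg_scores, labels)
  immune_scores <- if ("immune" %in% names(genesets))
    signature_score(expr, genesets$immune) else NULL

  gsea_tabs <- list(); ora_tabs <- list()
  for (cl in clusters) {
    ranked <- rank_genes(expr, labels, cl)
    g <- gsea(ranked, genesets, n_perm = gsea_n_perm, seed = seed)
    g$cluster <- cl
    gsea_tabs[[as.character(cl)]] <- g
    n_hit <- max(1, round(ora_top_frac * length(ranked)))
    o <- ora(names(ranked)[seq_len(n_hit)], names(ranked), genesets)
    o$cluster <- cl
    ora_tabs[[as.character(cl)]] <- o
  }
  mean_by_cluster <- function(v) stats::setNames(
    vapply(clusters, function(cl) mean(v[labels == cl]), numeric(1)),
    as.character(clusters))
  structure(list(
    clusters = clusters,
    treg_scores = treg_scores,
    immune_scores = immune_scores,
    score_tests = score_tests,
    gsea = do.call(rbind, gsea_tabs),
    ora = do.call(rbind, ora_tabs),
    exhaustion = tryCatch(exhaustion_panel(expr, treg_scores, labels),
                          error = function(e) NULL),
    mean_treg_score = mean_by_cluster(treg_scores),
    mean_immune_score = if (is.null(immune_scores)) NULL
                        else mean_by_cluster(immune_scores)),
    class = "cluster_characterization")
}

#' Build selection criteria from a characterization
#'
#' Operationalizes the multi-criteria framework: count of gene sets passing
#' ORA FDR < 0.05 per cluster (`go_terms`), immune-set GSEA NES
#' (`kegg_nes`), Treg-set GSEA NES (`gsea_nes`), mean Treg signature score
#' (`treg_fraction` stand-in) and mean immune score (`immune_score`). All
#' are higher-is-more-Treg.
#'
#' @param ch a [characterize_clusters()] result.
#' @param treg_set_name,immune_set_name set names as they appear in the
#'   GSEA/ORA tables.
#' @param fdr_cutoff ORA FDR threshold for the term-count criterion.
#' @return a list of [criterion_result()]s.
#' @export
criteria_from_characterization <- function(ch,
                                           treg_set_name = "TREG_SIGNATURE",
                                           immune_set_name = "IMMUNE_RESPONSE",
                                           fdr_cutoff = 0.05) {
  clusters <- as.character(ch$clusters)
  pick <- function(tab, set, col) {
    v <- vapply(clusters, function(cl)
      tab[tab$cluster == cl & tab$set == set, col][1], numeric(1))
    names(v) <- clusters
    v
  }
  crit <- list(
    criterion_result("go_terms", vapply(clusters, function(cl) {
      sub <- ch$ora[ch$ora$cluster == cl, ]
      sum(sub$q < fdr_cutoff)
    }, numeric(1))),
    criterion_result("gsea_nes", pick(ch$gsea, treg_set_name, "NES")),
    criterion_result("treg_fraction", ch$mean_treg_score[clusters])
  )
  if (immune_set_name %in% ch$gsea$set)
    crit <- append(crit, list(
      criterion_result("kegg_nes", pick(ch$gsea, immune_set_name, "NES"))),
      after = 1)
  if (!is.null(ch$mean_immune_score))
    crit <- c(crit, list(
      criterion_result("immune_score", ch$mean_immune_score[clusters])))
  crit
}

#' Run the full discovery pipeline on synthetic data
#'
#' Executes synthetic generation, preprocessing, embedding, consensus
#' clustering with PAC-based K selection, cluster characterization,
#' Treg-cluster selection and the efficacy simulation in order, writing
#' stage artifacts and a reproducibility manifest (config echo, per-file
#' MD5 checksums, wall-clock per stage) to `out_dir`. On stage failure a
#' partial manifest is still written and the error is re-raised tagged with
#' the stage name.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed; `NULL` skips all
#'   file output.
#' @return invisibly, a list with per-stage results and the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stages <- c("synthetic", "preprocess", "embed", "consensus",
              "characterize", "select", "efficacy")
  manifest <- list(config = config,
                   versions = list(r = R.version.string,
                                   tregstrat = as.character(
                                     utils::packageVersion("tregstrat"))),
                   stages = list())
  results <- list()
  emit <- function(name, m) {
    if (is.null(out_dir)) return(NULL)
    path <- file.path(out_dir, name)
    m(path)
    unname(tools::md5sum(path))
  }
  finish_manifest <- function() {
    if (!is.null(out_dir))
      jsonlite::write_json(
        manifest[c("versions", "stages")],
        file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }

  for (i in seq_along(stages)) {
    stage <- stages[i]
    t0 <- proc.time()[["elapsed"]]
    # stage seed: global seed + stage index, offset by the stage config's
    # own seed so one stage can be re-seeded without touching the others
    seed_i <- stage_seed(config$seed, i)
    res <- tryCatch(switch(
      stage,
      synthetic = {
        cfg <- config$synthetic; cfg$seed <- stage_seed(cfg$seed, seed_i)
        gen <- generate_multiomics(cfg)
        files <- c(
          vapply(gen$dataset$layers, function(l)
            emit(paste0("layer_", l$name, ".tsv"),
                 function(p) write_layer_tsv(l, p)) %||% NA_character_,
            NA_character_),
          truth = emit("truth.json", function(p)
            jsonlite::write_json(gen$truth, p, auto_unbox = TRUE)) %||%
            NA_character_)
        list(value = gen, files = files)
      },
      preprocess = {
        pp <- preprocess(results$synthetic$dataset$layers, config$preprocess)
        list(value = pp,
             files = c(joint = emit("joint.tsv", function(p)
               write_matrix_tsv(pp$joint, p, "sample_id")) %||% NA_character_))
      },
      embed = {
        emb <- if (config$embed_method == "pca") {
          pca_embed(results$preprocess$joint,
                    min(config$pca_dim, nrow(results$preprocess$joint) - 1,
                        ncol(results$preprocess$joint)))
        } else {
          cfg <- config$ae; cfg$seed <- stage_seed(cfg$seed, seed_i)
          model <- train_autoencoder(results$preprocess$joint, cfg)
          encode(model, results$preprocess$joint)
        }
        list(value = emb,
             files = c(latent = emit("latent.tsv", function(p)
               write_matrix_tsv(emb$latent, p, "sample_id")) %||%
               NA_character_))
      },
      consensus = {
        cfg <- config$consensus; cfg$seed <- stage_seed(cfg$seed, seed_i)
        cc <- consensus_cluster(results$embed$latent, cfg)
        files <- c(
          labels = emit("labels.csv", function(p)
            utils::write.csv(data.frame(sample_id = names(cc$labels),
                                        cluster = cc$labels),
                             p, row.names = FALSE, quote = FALSE)) %||%
            NA_character_,
          pac = emit("pac_by_k.csv", function(p)
            utils::write.csv(data.frame(K = names(cc$pac_by_k),
                                        PAC = cc$pac_by_k),
                             p, row.names = FALSE, quote = FALSE)) %||%
            NA_character_,
          consensus = emit("consensus_matrix.tsv", function(p)
            write_matrix_tsv(cc$results[[as.character(cc$best_k)]]$matrix,
                             p, "sample_id")) %||% NA_character_)
        list(value = cc, files = files)
      },
      characterize = {
        mrna <- results$synthetic$dataset$layers$mRNA
        if (is.null(mrna)) stop("no mRNA layer available")
        mrna <- knn_impute(mrna, config$preprocess$knn_k)
        genesets <- list(
          treg = treg_signature(),
          immune = gene_set("IMMUNE_RESPONSE",
                            results$synthetic$truth$immune_genes),
          exhaustion = exhaustion_markers())
        ch <- characterize_clusters(mrna$values, results$consensus$labels,
                                    genesets,
                                    gsea_n_perm = config$gsea_n_perm,
                                    ora_top_frac = config$ora_top_frac,
                                    seed = seed_i)
        list(value = ch,
             files = c(gsea = emit("gsea.csv", function(p)
               utils::write.csv(ch$gsea, p, row.names = FALSE)) %||%
                 NA_character_))
      },
      select = {
        crit <- criteria_from_characterization(results$characterize)
        rep <- select_treg_cluster(build_selection_matrix(crit))
        list(value = rep,
             files = c(report = emit("selection.json", function(p)
               jsonlite::write_json(
                 rep[c("selected_cluster", "per_criterion_winner",
                       "tie_break_used", "evidence")],
                 p, auto_unbox = TRUE)) %||% NA_character_))
      },
      efficacy = {
        cfg <- config$growth; cfg$seed <- stage_seed(cfg$seed, seed_i)
        study <- generate_growth_study(cfg)
        rep <- synergy_report(study, roles = c(control = "control",
                                               mono_a = "IPG7236",
                                               mono_b = "antiPDL1",
                                               combo = "combo"))
        files <- c(
          study = emit("growth_study.csv", function(p)
            write_growth_csv(study, p)) %||% NA_character_,
          report = emit("synergy_report.json", function(p)
            jsonlite::write_json(
              rep[c("day", "tgi_method", "tgi", "delta_tgi",
                    "normalized_auc", "bliss_expected", "bliss_exceedance",
                    "hsa_excess")],
              p, auto_unbox = TRUE, digits = NA)) %||% NA_character_)
        list(value = list(study = study, report = rep), files = files)
      }),
      error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[stage]] <- list(status = "failed",
                                       error = conditionMessage(res))
      finish_manifest()
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(res))
    }
    results[[stage]] <- res$value
    manifest$stages[[stage]] <- list(
      status = "ok", seed = seed_i,
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      files = as.list(res$files[!is.na(res$files)]))
  }
  finish_manifest()
  invisible(c(results, list(manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an external single-layer cohort
#'
#' Applies the discovery pipeline to an expression-only cohort with a fixed
#' cluster number (default K = 3): top-variance gene selection to a
#' retention count comparable to the discovery run (all genes, with a
#' warning, if fewer are available), min-max scaling, embedding, consensus
#' K-means at the fixed K, per-cluster Treg signature scores and GSEA NES,
#' and silhouette scores.
#'
#' @param expr numeric matrix, samples in rows, genes in columns.
#' @param k fixed number of clusters (default 3); set `rescan_k = TRUE` to
#'   rescan a K range by PAC instead.
#' @param retain number of highly variable genes to keep (default 2000).
#' @param embed_method `"pca"` or `"ae"`.
#' @param pca_dim latent dimensionality for the PCA path.
#' @param ae an [ae_config()] for the autoencoder path.
#' @param consensus a [consensus_config()]; its `k_range` is replaced by
#'   `k` unless `rescan_k`.
#' @param rescan_k rescan the config's K range by PAC instead of fixing K.
#' @param genesets named list of [gene_set()]s with at least `treg`.
#' @param gsea_n_perm permutations for the per-cluster GSEA.
#' @param seed RNG seed.
#' @return a list with `labels`, `pac`, `mean_treg_score` and `gsea_nes`
#'   per cluster, and `silhouette`.
#' @export
validate_external_cohort <- function(expr, k = 3, retain = 2000,
                                     embed_method = c("pca", "ae"),
                                     pca_dim = 20, ae = ae_config(),
                                     consensus = consensus_config(),
                                     rescan_k = FALSE,
                                     genesets = list(treg = treg_signature()),
                                     gsea_n_perm = 200, seed = 1) {
  embed_method <- match.arg(embed_method)
  stopifnot(is.matrix(expr), "treg" %in% names(genesets))
  layer <- omics_layer("expr", expr)
  layer <- knn_impute(layer)
  if (retain > ncol(layer$values)) {
    warning("only ", ncol(layer$values),
            " genes available; keeping all")
    retain <- ncol(layer$values)
  }
  selected <- select_top_variance(minmax_normalize(layer), retain)
  joint <- selected$values
  emb <- if (embed_method == "pca") {
    pca_embed(joint, min(pca_dim, nrow(joint) - 1, ncol(joint)))
  } else {
    cfg <- ae; cfg$seed <- seed
    encode(train_autoencoder(joint, cfg), joint)
  }
  cfg <- consensus
  cfg$seed <- seed
  if (!rescan_k) cfg$k_range <- as.integer(k)
  cc <- consensus_cluster(emb$latent, cfg)
  labels <- cc$labels
  ch <- characterize_clusters(expr, labels, genesets,
                              gsea_n_perm = gsea_n_perm, seed = seed)
  treg_nes <- ch$gsea[ch$gsea$set == genesets$treg$name, c("cluster", "NES")]
  list(labels = labels, best_k = cc$best_k, pac = cc$pac_by_k,
       mean_treg_score = ch$mean_treg_score,
       gsea_nes = stats::setNames(treg_nes$NES, treg_nes$cluster),
       silhouette = silhouette_score(emb$latent, labels))
}
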