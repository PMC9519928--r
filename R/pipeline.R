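#' Pipeline configuration
#'
#' Settings for the end-to-end run: message-passing iterations, the number of
#' PCGs kept by feature selection, the SDNE settings, classifier settings,
#' and test-time negative rate. The ablation switches drop the
#' message-passing or feature-selection stage (the remaining stages then see
#' raw profiles / all PCGs).
#'
#' @param iterations Message-passing iterations (default 1).
#' @param K PCGs kept by ReliefF selection (default 100).
#' @param sdne An [sdne_config()].
#' @param n_estimators Random-forest size (default 350).
#' @param train_neg_ratio Training negatives per positive (default 1).
#' @param test_neg_ratio Test negatives per positive (default 1).
#' @param delta Semantic-similarity decay factor.
#' @param k_neighbors ReliefF neighbours per class.
#' @param min_category_size Rare-category collapse threshold.
#' @param message_passing,feature_selection Ablation switches.
#' @param threshold Classification threshold for the thresholded metrics.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(iterations = 1L, K = 100L,
                            sdne = sdne_config(), n_estimators = 350,
                            train_neg_ratio = 1, test_neg_ratio = 1,
                            delta = 0.5, k_neighbors = 10,
                            min_category_size = 10,
                            message_passing = TRUE, feature_selection = TRUE,
                            threshold = 0.5) {
  structure(
    list(
      iterations = as.integer(iterations), K = as.integer(K), sdne = sdne,
      n_estimators = n_estimators, train_neg_ratio = train_neg_ratio,
      test_neg_ratio = test_neg_ratio, delta = delta,
      k_neighbors = k_neighbors, min_category_size = min_category_size,
      message_passing = isTRUE(message_passing),
      feature_selection = isTRUE(feature_selection), threshold = threshold
    ),
    class = "pipeline_config"
  )
}

#' Run the full association-prediction pipeline
#'
#' Stages, in order: enrich the miRNA-PCG and disease-PCG profiles by
#' message passing over the directed PCG network; label diseases with
#' ontology categories and select the top-K PCGs by ReliefF; build the
#' heterogeneous miRNA-disease-PCG adjacency from the *training*
#' associations plus enriched profiles; train SDNE embeddings; assemble pair
#' features (embeddings, miRNA family one-hot, disease semantic similarity);
#' train the random forest on training positives plus sampled negatives;
#' score the test pairs and compute the metric report.
#'
#' @param data A list with elements `pcg_edges` (or a `pcg_network`),
#'   `mirna_pcg`, `disease_pcg`, `mirna_disease`, `ontology_records`,
#'   `families` — e.g. a [simulate_world()] result.
#' @param split An `md_split` from [make_splits()]; defaults to a seeded
#'   transductive split of `data$mirna_disease`.
#' @param config A [pipeline_config()].
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return An `md_pipeline_fit`: trained model, labeled prediction table,
#'   metric report, selected PCGs, embeddings, and a reproducibility
#'   manifest.
#' @export
run_pipeline <- function(data, split = NULL, config = pipeline_config(),
                         seed = 0L) {
  t0 <- Sys.time()
  seeds <- derive_seeds(seed, 4L)

  net <- if (inherits(data$pcg_edges, "pcg_network")) data$pcg_edges else
    pcg_network(data$pcg_edges)
  mirna_assoc <- association_table(data$mirna_pcg, "miRNA", "PCG", "binary")
  disease_assoc <- association_table(data$disease_pcg, "disease", "PCG", "score")
  tree <- ontology(data$ontology_records)
  all_mirnas <- sort(unique(c(data$mirna_pcg[[1]], data$mirna_disease$miRNA_id)))
  all_diseases <- sort(unique(c(data$disease_pcg[[1]],
                                data$mirna_disease$disease_id)))

  if (is.null(split)) {
    split <- make_splits(data$mirna_disease, "transductive", seed = seed)[[1]]
  }

  # 1. message passing enrichment (identity when ablated)
  M <- profiles_from_association(mirna_assoc, net, all_mirnas)
  D <- profiles_from_association(disease_assoc, net, all_diseases)
  t_mp <- if (config$message_passing) config$iterations else 0L
  M_e <- enrich_matrix(net, M, iterations = t_mp)
  D_e <- enrich_matrix(net, D, iterations = t_mp)

  # 2. ontology-supervised feature selection on the disease profiles
  if (config$feature_selection) {
    labeling <- assign_disease_categories(tree, all_diseases) |>
      collapse_rare_categories(config$min_category_size)
    importance <- relieff_importance(
      D_e, labeling$category[match(all_diseases, labeling$disease_id)],
      k_neighbors = config$k_neighbors
    )
    selected <- select_top_pcgs(
      importance, min(config$K, length(net$pcg_registry))
    )
  } else {
    labeling <- NULL
    importance <- NULL
    selected <- net$pcg_registry$ids
  }

  # 3. heterogeneous network from TRAINING associations only
  hetnet <- build_heterogeneous_adjacency(
    split$train, M_e, D_e, net, selected,
    forbidden_pairs = split$test_pos
  )

  # 4. structural embeddings
  embedding <- train_sdne(hetnet, config$sdne)

  # 5. biological features fitted on the training universe
  train_diseases <- sort(unique(split$train$disease_id))
  fam <- family_encoder(data$families, unique(split$train$miRNA_id))

  # 6. classifier on training positives + sampled negatives; the negative
  # universe is the training entities only, so held-out entities never leak
  # label information into the forest
  neg <- sample_training_negatives(split$train,
                                   unique(split$train$miRNA_id),
                                   unique(split$train$disease_id),
                                   ratio = config$train_neg_ratio,
                                   seed = seeds[1])
  train_pairs <- dplyr::bind_rows(split$train, neg)
  train_labels <- rep(c(1L, 0L), c(nrow(split$train), nrow(neg)))
  X_train <- assemble_pair_features(train_pairs, embedding, fam, tree,
                                    train_diseases, config$delta)
  model <- train_model(X_train, train_labels,
                       n_estimators = config$n_estimators, seed = seeds[2])

  # 7. score the test set at the configured negative rate
  test_neg <- sample_test_negatives(split, nr = config$test_neg_ratio,
                                    seed = seeds[3])
  test_pairs <- dplyr::bind_rows(split$test_pos, test_neg)
  test_labels <- rep(c(1L, 0L), c(nrow(split$test_pos), nrow(test_neg)))
  X_test <- assemble_pair_features(test_pairs, embedding, fam, tree,
                                   train_diseases, config$delta)
  predictions <- predict_scores(model, test_pairs, X_test)
  predictions$label <- test_labels

  metrics <- evaluate_predictions(predictions, nr = config$test_neg_ratio,
                                  threshold = config$threshold)

  manifest <- list(
    seed = seed, stage_seeds = seeds, split_mode = split$mode,
    split_seed = split$seed, n_train_pos = nrow(split$train),
    n_test_pos = nrow(split$test_pos), n_selected_pcgs = length(selected),
    config_hash = rlang::hash(config),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(
    list(model = model, predictions = predictions, metrics = metrics,
         selected_pcgs = selected, importance = importance,
         labeling = labeling, embedding = embedding, split = split,
         config = config, manifest = manifest),
    class = "md_pipeline_fit"
  )
}

#' @export
print.md_pipeline_fit <- function(x, ...) {
  cat(sprintf(
    "<md_pipeline_fit: %s split, AUC %.3f, AP %.3f (%d test pairs)>\n",
    x$split$mode, x$metrics$AUC, x$metrics$AP, nrow(x$predictions)
  ))
  invisible(x)
}
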