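#' Configuration for the synthetic association world
#'
#' The generator plants a category structure: each disease category owns a
#' disjoint set of "signal" PCGs; diseases link their category's signal PCGs
#' with high confidence scores and random background PCGs with low scores;
#' miRNAs carry a latent category and link its signal PCGs (binary) plus
#' background; a miRNA-disease pair is truly associated when their categories
#' match, then flipped with a small noise probability. This mirrors the
#' premise that miRNA-disease relevance is mediated by shared PCG
#' neighbourhoods, and makes every downstream stage testable offline.
#'
#' @param n_pcg,n_mirna,n_disease Entity counts.
#' @param n_categories Number of disease categories (ontology roots).
#' @param edges_per_pcg Mean out-degree of the directed PCG network
#'   (Poisson-distributed per node).
#' @param signal_pcgs_per_category Size of each category's disjoint signal
#'   PCG set.
#' @param profile_density Background link probability for miRNA-PCG and
#'   disease-PCG profiles.
#' @param assoc_noise Probability that a pair's true association label is
#'   flipped.
#' @param seed Integer seed; the whole world is a deterministic function of
#'   the config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_pcg = 200, n_mirna = 50, n_disease = 30,
                             n_categories = 3, edges_per_pcg = 4,
                             signal_pcgs_per_category = 15,
                             profile_density = 0.05, assoc_noise = 0.05,
                             seed = 1L) {
  cfg <- list(
    n_pcg = as.integer(n_pcg), n_mirna = as.integer(n_mirna),
    n_disease = as.integer(n_disease), n_categories = as.integer(n_categories),
    edges_per_pcg = edges_per_pcg,
    signal_pcgs_per_category = as.integer(signal_pcgs_per_category),
    profile_density = profile_density, assoc_noise = assoc_noise,
    seed = as.integer(seed)
  )
  counts <- c("n_pcg", "n_mirna", "n_disease", "n_categories",
              "signal_pcgs_per_category")
  if (any(vapply(cfg[counts], function(v) v < 1L, TRUE))) {
    abort("all counts must be >= 1")
  }
  probs <- c(cfg$profile_density, cfg$assoc_noise)
  if (any(probs < 0 | probs > 1)) abort("probabilities must be in [0, 1]")
  if (cfg$n_categories * cfg$signal_pcgs_per_category > cfg$n_pcg) {
    abort("signal PCG sets cannot be disjoint: n_categories * signal_pcgs_per_category > n_pcg")
  }
  structure(cfg, class = "synthetic_config")
}

# one independent sub-stream per artifact so outputs do not depend on the
# order in which artifacts are generated
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_stream <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic miRNA-PCG-disease world
#'
#' Produces the six input tables the pipeline consumes — directed PCG-PCG
#' edges, miRNA-PCG interactions (binary), disease-PCG associations (scored),
#' known miRNA-disease associations, a tree-coded disease ontology (one root
#' per category, diseases as leaves), and a miRNA family map (one family per
#' latent category) — together with the planted ground truth.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `synthetic_world` with elements `pcg_edges`,
#'   `mirna_pcg`, `disease_pcg`, `mirna_disease`, `ontology_records`,
#'   `families`, and `truth` (category maps, signal PCG sets, true pairs).
#' @examples
#' world <- simulate_world(synthetic_config(n_pcg = 60, n_mirna = 10,
#'                                          n_disease = 8, seed = 42))
#' nrow(world$mirna_disease)
#' @export
simulate_world <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ss <- derive_seeds(cfg$seed, 6L)
  pcg_ids <- sprintf("PCG%04d", seq_len(cfg$n_pcg))
  mirna_ids <- sprintf("mir-%03d", seq_len(cfg$n_mirna))
  disease_ids <- sprintf("DIS%03d", seq_len(cfg$n_disease))
  relations <- c("binding", "inhibits", "activates", "regulates", "catalyzes")

  # (a) directed PCG network: Poisson out-degree, uniform relation labels
  pcg_edges <- with_stream(ss[1], {
    deg <- rpois(cfg$n_pcg, cfg$edges_per_pcg)
    deg <- pmin(deg, cfg$n_pcg - 1L)
    src <- rep(seq_len(cfg$n_pcg), deg)
    tgt <- unlist(lapply(seq_len(cfg$n_pcg), function(i) {
      if (deg[i] == 0) integer() else sample(setdiff(seq_len(cfg$n_pcg), i), deg[i])
    }))
    tibble::tibble(
      source = pcg_ids[src], target = pcg_ids[tgt],
      relation = sample(relations, length(src), replace = TRUE)
    )
  })

  # (b) category structure: disjoint signal PCG sets, diseases per category
  sig_total <- cfg$n_categories * cfg$signal_pcgs_per_category
  truth <- with_stream(ss[2], {
    sig <- sample(cfg$n_pcg, sig_total)
    signal_sets <- split(sig, rep(seq_len(cfg$n_categories),
                                  each = cfg$signal_pcgs_per_category))
    list(
      signal_pcg_sets = lapply(signal_sets, function(ix) pcg_ids[sort(ix)]),
      category_of_disease = setNames(
        sample(cfg$n_categories, cfg$n_disease, replace = TRUE), disease_ids
      ),
      category_of_mirna = setNames(
        sample(cfg$n_categories, cfg$n_mirna, replace = TRUE), mirna_ids
      )
    )
  })

  # (b cont.) disease-PCG: signal links score U(0.6,1), background U(0,0.4)
  disease_pcg <- with_stream(ss[3], {
    purrr::map_dfr(seq_len(cfg$n_disease), function(d) {
      cat_d <- truth$category_of_disease[[d]]
      sig <- truth$signal_pcg_sets[[cat_d]]
      bg_pool <- setdiff(pcg_ids, sig)
      bg <- bg_pool[runif(length(bg_pool)) < cfg$profile_density]
      tibble::tibble(
        disease_id = disease_ids[d],
        pcg_id = c(sig, bg),
        score = c(runif(length(sig), 0.6, 1), runif(length(bg), 0, 0.4))
      )
    })
  })

  # (c) miRNA-PCG: binary signal links plus background
  mirna_pcg <- with_stream(ss[4], {
    purrr::map_dfr(seq_len(cfg$n_mirna), function(m) {
      cat_m <- truth$category_of_mirna[[m]]
      sig <- truth$signal_pcg_sets[[cat_m]]
      bg_pool <- setdiff(pcg_ids, sig)
      bg <- bg_pool[runif(length(bg_pool)) < cfg$profile_density]
      tibble::tibble(mirna_id = mirna_ids[m], pcg_id = c(sig, bg))
    })
  })

  # (d) true pairs: category match, then independent noise flips
  pairs <- tidyr::expand_grid(miRNA_id = mirna_ids, disease_id = disease_ids)
  match_cat <- truth$category_of_mirna[pairs$miRNA_id] ==
    truth$category_of_disease[pairs$disease_id]
  assoc <- with_stream(ss[5], {
    flip <- runif(nrow(pairs)) < cfg$assoc_noise
    xor(match_cat, flip)
  })
  mirna_disease <- pairs[assoc, ]

  # (e) ontology: one root code per category, diseases as leaf codes; root
  # numbering starts at C02 because C01 is the infection branch, whose
  # categories are defined one level deeper than these flat synthetic ones
  ontology_records <- tibble::tibble(
    disease_id = disease_ids,
    tree_code = sprintf(
      "C%02d.%03d", truth$category_of_disease[disease_ids] + 1L,
      seq_len(cfg$n_disease)
    )
  )

  # (f) families: one family per latent miRNA category
  families <- tibble::tibble(
    mirna_id = mirna_ids,
    family = sprintf("fam-%02d", truth$category_of_mirna[mirna_ids])
  )

  truth$true_pairs <- mirna_disease
  structure(
    list(
      pcg_edges = pcg_edges, mirna_pcg = mirna_pcg, disease_pcg = disease_pcg,
      mirna_disease = mirna_disease, ontology_records = ontology_records,
      families = families, truth = truth, config = cfg
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world: %d PCGs, %d miRNAs, %d diseases, %d known associations>\n",
    x$config$n_pcg, x$config$n_mirna, x$config$n_disease,
    nrow(x$mirna_disease)
  ))
  invisible(x)
}

#' Write a synthetic world to a directory of TSV files
#'
#' @param world A [simulate_world()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(world$pcg_edges, file.path(dir, "pcg_edges.tsv"), progress = FALSE)
  readr::write_tsv(world$mirna_pcg, file.path(dir, "mirna_pcg.tsv"), progress = FALSE)
  readr::write_tsv(world$disease_pcg, file.path(dir, "disease_pcg.tsv"), progress = FALSE)
  readr::write_tsv(world$mirna_disease, file.path(dir, "mirna_disease.tsv"), progress = FALSE)
  readr::write_tsv(world$ontology_records, file.path(dir, "ontology.tsv"), progress = FALSE)
  readr::write_tsv(world$families, file.path(dir, "families.tsv"), progress = FALSE)
  invisible(dir)
}
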