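# Synthetic benchmark generator.  Produces complete, self-contained
# datasets with the statistical structure the pipeline assumes: drugs in
# latent clusters, per-cluster SMILES scaffold families, a modular PPI
# network with cluster-linked protein associations, templated descriptions
# carrying cluster keywords for the mock embedding provider, and ordered
# pair labels that are a deterministic function of the two drugs' clusters
# plus label noise.

# Hard-coded scaffold template families: each family is a base ring/chain
# scaffold with small enumerated decorations, guaranteeing parseable
# SMILES while keeping within-family Tanimoto well above between-family.
scaffold_families <- function() {
  subs <- c("", "C", "CC", "CCC", "CCCC", "O", "OC", "OCC", "N", "NC",
            "NCC", "Cl", "F", "Br", "I", "C(C)C", "C(C)(C)C", "CO",
            "CCO", "CCN", "C=C")
  rings <- c(benzene = "c1ccccc1",
             naphthalene = "c1ccc2ccccc2c1",
             pyridine = "c1ccncc1",
             cyclohexane = "C1CCCCC1",
             furan = "c1ccoc1",
             piperidine = "C1CCNCC1",
             thiophene = "c1ccsc1")
  fams <- lapply(rings, function(r) paste0(subs, r))
  chains <- c("CCCCC", "CCCCCC", "CCCCCCC", "CCCCCCCC")
  fams$alkane <- unique(as.vector(outer(
    c("", "C", "O", "N", "Cl", "C(C)C"), chains, paste0)))
  # order: maximally dissimilar scaffolds first, so small cluster counts
  # get well-separated families
  fams[c("benzene", "alkane", "naphthalene", "pyridine",
         "cyclohexane", "furan", "piperidine", "thiophene")]
}

# Modality-specific confusable-partner maps.  When a drug's
# modality-visible cluster is corrupted it is replaced by that modality's
# partner of the true cluster; each modality pairs up different clusters,
# so different modalities carry complementary information (their
# corruptions preserve different coarse groupings), the way structural and
# textual evidence err differently on real drugs.
confusable_partner <- function(n_clusters, modality) {
  i <- seq_len(n_clusters)
  p <- switch(modality,
    smiles = ifelse(i %% 2 == 1, pmin(i + 1, n_clusters), i - 1),
    text = ((i - 1 + n_clusters %/% 2) %% n_clusters) + 1,
    ppi = n_clusters + 1 - i,
    stop("unknown modality: ", modality))
  fix <- p == i  # degenerate self-partners (odd cluster counts)
  p[fix] <- (i[fix] %% n_clusters) + 1
  as.integer(p)
}

#' Synthetic dataset configuration
#'
#' Defaults define the package's reference benchmark: 60 drugs in 4 latent
#' clusters, a 120-protein modular PPI network, 8 directional interaction
#' classes (an injective map from ordered cluster pairs), up to 400
#' ordered pairs per class (capped by availability), 5% label noise, and
#' per-modality informativeness 0.9 (probability that a drug's
#' modality-visible cluster is its true cluster rather than that
#' modality's confusable partner).
#'
#' @param n_drugs,n_proteins,n_clusters,n_classes,pairs_per_class sizes;
#'   `n_classes <= n_clusters^2`, `pairs_per_class >= 5`.
#' @param label_noise fraction of pair labels flipped uniformly to another
#'   class, in \[0, 1).
#' @param modality_informativeness named numeric vector for `smiles`,
#'   `ppi`, `text`, each in \[0, 1\].
#' @param seed integer; the whole dataset is deterministic given it.
#' @return object of class `ddi_synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 60, n_proteins = 120, n_clusters = 4,
                             n_classes = 8, pairs_per_class = 400,
                             label_noise = 0.05,
                             modality_informativeness =
                               c(smiles = 0.9, ppi = 0.9, text = 0.9),
                             seed = 1) {
  stopifnot(n_drugs >= n_clusters, n_clusters >= 2,
            label_noise >= 0, label_noise < 1)
  if (n_classes > n_clusters^2)
    stop("infeasible config: n_classes > n_clusters^2")
  if (pairs_per_class < 5)
    stop("pairs_per_class must be >= 5 so filtering and stratification succeed")
  mi <- modality_informativeness
  stopifnot(all(c("smiles", "ppi", "text") %in% names(mi)),
            all(mi >= 0 & mi <= 1))
  if (n_clusters > length(scaffold_families()))
    stop("at most ", length(scaffold_families()),
         " clusters supported (one scaffold family each)")
  structure(list(n_drugs = as.integer(n_drugs),
                 n_proteins = as.integer(n_proteins),
                 n_clusters = as.integer(n_clusters),
                 n_classes = as.integer(n_classes),
                 pairs_per_class = as.integer(pairs_per_class),
                 label_noise = label_noise,
                 modality_informativeness = mi,
                 seed = as.integer(seed)),
            class = "ddi_synthetic_config")
}

#' Generate a synthetic DDI dataset
#'
#' Deterministic given the config seed: two calls produce identical
#' objects and [write_synthetic_dataset()] writes byte-identical files.
#'
#' @param config a [synthetic_config()].
#' @return object of class `ddi_synthetic_dataset`: list with `drugs`
#'   (drug_id, name, smiles, description), `ppi` (protein_a, protein_b,
#'   score), `associations` (drug_id, protein_id), `pairs` (drug_a,
#'   drug_b, class_id), `catalog` (class_id, description), `ground_truth`
#'   (per-drug true and per-modality observed clusters, the cluster-pair
#'   to class map, cluster keywords and the mock provider's keyword map),
#'   the `config`, and `scales` (per-modality feature scale factors set by
#'   [degrade()]).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "ddi_synthetic_config"))
  k <- config$n_clusters
  n <- config$n_drugs
  mi <- config$modality_informativeness
  with_preserved_rng(config$seed, {
    cluster <- rep(seq_len(k), length.out = n)
    observe <- function(modality) {
      partner <- confusable_partner(k, modality)
      keep <- stats::runif(n) < mi[[modality]]
      ifelse(keep, cluster, partner[cluster])
    }
    smiles_cluster <- observe("smiles")
    ppi_cluster <- observe("ppi")
    text_cluster <- observe("text")

    drug_id <- sprintf("D%03d", seq_len(n))
    name <- sprintf("Synthodrug-%03d", seq_len(n))

    fams <- scaffold_families()[seq_len(k)]
    smiles <- character(n)
    for (cl in seq_len(k)) {
      members <- which(smiles_cluster == cl)
      pool <- fams[[cl]]
      smiles[members] <- if (length(members) <= length(pool))
        sample(pool, length(members)) else
        sample(pool, length(members), replace = TRUE)
    }

    keywords <- stats::setNames(sprintf("mechanotype-%s", letters[seq_len(k)]),
                                seq_len(k))
    description <- sprintf(
      "%s is a synthetic small-molecule agent of the %s family studied in simulated pharmacology benchmarks.",
      name, keywords[text_cluster])
    drugs <- data.frame(drug_id = drug_id, name = name, smiles = smiles,
                        description = description, stringsAsFactors = FALSE)

    # modular PPI network: a connectivity ring plus random extra edges
    # inside each module (high-confidence scores), deliberate
    # high-confidence bridges between consecutive modules, and sparse
    # low-confidence cross edges that a standard threshold removes.
    m <- config$n_proteins
    protein_id <- sprintf("P%04d", seq_len(m))
    module <- rep(seq_len(k), each = ceiling(m / k))[seq_len(m)]
    ea <- integer(0); eb <- integer(0); sc <- integer(0)
    for (cl in seq_len(k)) {
      idx <- which(module == cl)
      ring_a <- idx; ring_b <- idx[c(seq_along(idx)[-1], 1)]
      ea <- c(ea, ring_a); eb <- c(eb, ring_b)
      sc <- c(sc, sample(700:999, length(idx), replace = TRUE))
      cmb <- utils::combn(idx, 2)
      extra <- which(stats::runif(ncol(cmb)) < 0.15)
      ea <- c(ea, cmb[1, extra]); eb <- c(eb, cmb[2, extra])
      sc <- c(sc, sample(700:999, length(extra), replace = TRUE))
    }
    for (cl in seq_len(k - 1)) {
      a <- sample(which(module == cl), 2)
      b <- sample(which(module == cl + 1), 2)
      ea <- c(ea, a); eb <- c(eb, b)
      sc <- c(sc, sample(700:850, 2, replace = TRUE))
    }
    n_low <- max(4L, k)
    a <- sample.int(m, n_low, replace = TRUE)
    b <- sample.int(m, n_low, replace = TRUE)
    keep <- a != b
    ea <- c(ea, a[keep]); eb <- c(eb, b[keep])
    sc <- c(sc, sample(400:699, sum(keep), replace = TRUE))
    ppi <- data.frame(protein_a = protein_id[ea], protein_b = protein_id[eb],
                      score = as.integer(sc), stringsAsFactors = FALSE)

    assoc <- do.call(rbind, lapply(seq_len(n), function(i) {
      pool <- which(module == ppi_cluster[i])
      take <- sample(pool, min(sample(3:6, 1), length(pool)))
      data.frame(drug_id = drug_id[i], protein_id = protein_id[sort(take)],
                 stringsAsFactors = FALSE)
    }))
    rownames(assoc) <- NULL

    # ordered cluster-pair cells in row-major order; the first n_classes
    # cells define the injective map f(cluster_a, cluster_b) -> class id
    cells <- expand.grid(cluster_b = seq_len(k), cluster_a = seq_len(k))
    cells <- cells[, c("cluster_a", "cluster_b")]
    cells <- cells[order(cells$cluster_a, cells$cluster_b), ][seq_len(config$n_classes), ]
    class_map <- data.frame(class_id = seq_len(config$n_classes) - 1L,
                            cluster_a = cells$cluster_a,
                            cluster_b = cells$cluster_b, row.names = NULL)
    pair_list <- lapply(seq_len(nrow(class_map)), function(j) {
      ca <- class_map$cluster_a[j]; cb <- class_map$cluster_b[j]
      grid <- expand.grid(a = which(cluster == ca), b = which(cluster == cb))
      grid <- grid[grid$a != grid$b, , drop = FALSE]
      take <- grid[sample.int(nrow(grid),
                              min(config$pairs_per_class, nrow(grid))), ]
      data.frame(drug_a = drug_id[take$a], drug_b = drug_id[take$b],
                 class_id = class_map$class_id[j], stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, pair_list)
    rownames(pairs) <- NULL
    if (config$label_noise > 0) {
      flip <- stats::runif(nrow(pairs)) < config$label_noise
      shift <- sample.int(config$n_classes - 1L, sum(flip), replace = TRUE)
      pairs$class_id[flip] <-
        (pairs$class_id[flip] + shift) %% config$n_classes
    }

    catalog <- data.frame(
      class_id = class_map$class_id,
      description = sprintf(
        "Interaction type %d: a cluster-%d drug modifies the effect of a cluster-%d drug.",
        class_map$class_id, class_map$cluster_a, class_map$cluster_b),
      stringsAsFactors = FALSE)

    structure(list(
      drugs = drugs, ppi = ppi, associations = assoc, pairs = pairs,
      catalog = catalog,
      ground_truth = list(
        clusters = data.frame(drug_id = drug_id, cluster = cluster,
                              smiles_cluster = smiles_cluster,
                              ppi_cluster = ppi_cluster,
                              text_cluster = text_cluster,
                              stringsAsFactors = FALSE),
        class_map = class_map,
        keywords = keywords,
        keyword_map = stats::setNames(seq_len(k), unname(keywords))),
      config = config, scales = list()),
      class = "ddi_synthetic_dataset")
  })
}

#' @export
print.ddi_synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic DDI dataset: %d drugs, %d clusters, ",
                     "%d classes, %d pairs, %d proteins\n"),
              nrow(x$drugs), x$config$n_clusters, x$config$n_classes,
              nrow(x$pairs), x$config$n_proteins))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits exactly the file formats the readers consume: `drugs.tsv`,
#' `ppi.tsv`, `associations.tsv`, `pairs.tsv`, `classes.tsv`, plus
#' `ground_truth.json` and `config.json`.  Byte-identical across calls for
#' the same dataset.
#'
#' @param dataset a [generate_synthetic()] result.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ddi_synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(drugs = wt(dataset$drugs, "drugs.tsv"),
             ppi = wt(dataset$ppi, "ppi.tsv"),
             associations = wt(dataset$associations, "associations.tsv"),
             pairs = wt(dataset$pairs, "pairs.tsv"),
             classes = wt(dataset$catalog, "classes.tsv"))
  gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(dataset$ground_truth, gt, digits = NA, pretty = TRUE)
  cfg <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(dataset$config), cfg, digits = NA,
                       pretty = TRUE, auto_unbox = TRUE)
  invisible(c(paths, ground_truth = gt, config = cfg))
}

#' Controlled degradation of a synthetic dataset
#'
#' Ablation tooling: `shuffle` permutes the modality's drug assignment
#' (destroying its information while preserving marginals), `scale`
#' records a constant factor applied to the modality's derived features by
#' [build_feature_store()] (exercising projection re-weighting), and
#' `drop` removes the modality's data entirely so featurizers fail loudly.
#'
#' @param dataset a `ddi_synthetic_dataset`.
#' @param which modality: `"smiles"`, `"ppi"` or `"text"`.
#' @param mode `"shuffle"`, `"scale"` or `"drop"`.
#' @param factor scale factor for `mode = "scale"` (default 100).
#' @param seed RNG seed for `mode = "shuffle"`.
#' @return the modified dataset.
#' @export
degrade <- function(dataset, which = c("smiles", "ppi", "text"),
                    mode = c("shuffle", "scale", "drop"),
                    factor = 100, seed = 1) {
  stopifnot(inherits(dataset, "ddi_synthetic_dataset"))
  which <- match.arg(which)
  mode <- match.arg(mode)
  n <- nrow(dataset$drugs)
  if (mode == "shuffle") {
    perm <- with_preserved_rng(seed, sample.int(n))
    if (which == "smiles") {
      dataset$drugs$smiles <- dataset$drugs$smiles[perm]
    } else if (which == "text") {
      dataset$drugs$description <- dataset$drugs$description[perm]
    } else {
      ids <- dataset$drugs$drug_id
      dataset$associations$drug_id <-
        ids[perm][match(dataset$associations$drug_id, ids)]
    }
  } else if (mode == "scale") {
    dataset$scales[[which]] <- factor
  } else {
    if (which == "smiles") dataset$drugs$smiles <- NULL
    else if (which == "text") dataset$drugs$description <- NULL
    else { dataset$ppi <- NULL; dataset$associations <- NULL }
  }
  dataset
}
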