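# Bipartite interaction data: adjacency / edge-list readers and writers, and
# a seeded synthetic generator with low-rank latent structure that emits
# per-pair sequences and multilabel targets for the MLSTM-AE.

#' Construct a drug-target interaction dataset
#'
#' @param drugs Character vector of drug ids.
#' @param targets Character vector of target ids.
#' @param interactions Binary matrix, `length(targets)` rows x
#'   `length(drugs)` columns (the orientation of the distributed gold-standard
#'   adjacency files).
#' @param drug_features,target_features Optional per-entity feature matrices
#'   (rows aligned with the id lists) used to build pair sequences.
#' @param spec Optional list of generator settings (kept for reproducible
#'   sequence regeneration).
#' @return Object of class `dti_dataset`.
#' @export
dti_dataset <- function(drugs, targets, interactions, drug_features = NULL,
                        target_features = NULL, spec = NULL) {
  stopifnot(is.character(drugs), is.character(targets))
  if (!is.matrix(interactions) || nrow(interactions) != length(targets) ||
      ncol(interactions) != length(drugs)) {
    stop_input("interactions must be a |targets| x |drugs| matrix")
  }
  if (!all(interactions %in% c(0, 1))) {
    stop_input("interaction entries must be 0/1")
  }
  dimnames(interactions) <- list(targets, drugs)
  structure(list(drugs = drugs, targets = targets,
                 interactions = interactions, drug_features = drug_features,
                 target_features = target_features, spec = spec),
            class = "dti_dataset")
}

#' @export
print.dti_dataset <- function(x, ...) {
  cat(sprintf("DTI dataset: %d drugs x %d targets, %d interactions\n",
              length(x$drugs), length(x$targets), sum(x$interactions)))
  if (!is.null(x$drug_features)) {
    cat(sprintf("  features: d = %d per entity\n", ncol(x$drug_features)))
  }
  invisible(x)
}

#' Read a bipartite interaction matrix
#'
#' Two dialects are supported. `"adjacency"`: a TSV whose header row lists the
#' drug ids (first cell blank or a label), each following row a target id and
#' 0/1 cells. `"edge_list"`: two tab-separated columns `drug_id`, `target_id`,
#' one interacting pair per line (with or without a `drug target` header);
#' entity lists are the sorted unique ids.
#'
#' @param path Input TSV path.
#' @param dialect `"adjacency"` or `"edge_list"`.
#' @return A [dti_dataset()].
#' @export
read_interaction_matrix <- function(path, dialect = c("adjacency",
                                                      "edge_list")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_input(path, ": empty file")
  if (dialect == "adjacency") {
    hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    drugs <- hdr[-1L]
    nd <- length(drugs)
    targets <- character(length(lines) - 1L)
    A <- matrix(0, length(lines) - 1L, nd)
    for (i in seq_along(lines)[-1L]) {
      fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
      if (length(fields) != nd + 1L) {
        stop_input(path, " line ", i, ": expected ", nd + 1L,
                   " fields, found ", length(fields))
      }
      vals <- suppressWarnings(as.numeric(fields[-1L]))
      bad <- which(is.na(vals) | !(vals %in% c(0, 1)))
      if (length(bad) > 0L) {
        stop_input(path, " line ", i, ", column ", bad[1L] + 1L,
                   ": cell '", fields[bad[1L] + 1L], "' is not 0/1")
      }
      targets[i - 1L] <- fields[1L]
      A[i - 1L, ] <- vals
    }
    if (anyDuplicated(targets) || anyDuplicated(drugs)) {
      stop_input(path, ": duplicate drug or target ids")
    }
    dti_dataset(drugs, targets, A)
  } else {
    start <- if (grepl("^drug\tt", lines[1L])) 2L else 1L
    pairs <- lapply(seq.int(start, length(lines)), function(i) {
      fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
      if (length(fields) != 2L) {
        stop_input(path, " line ", i, ": expected 'drug<TAB>target'")
      }
      fields
    })
    drugs <- sort(unique(vapply(pairs, `[[`, "", 1L)))
    targets <- sort(unique(vapply(pairs, `[[`, "", 2L)))
    A <- matrix(0, length(targets), length(drugs),
                dimnames = list(targets, drugs))
    for (pr in pairs) A[pr[2L], pr[1L]] <- 1
    dti_dataset(drugs, targets, A)
  }
}

#' Write a bipartite interaction matrix
#'
#' Inverse of [read_interaction_matrix()]; adjacency writes the full 0/1
#' matrix, edge list writes one interacting `drug<TAB>target` pair per line
#' (with header), sorted by target then drug.
#'
#' @param dataset A [dti_dataset()].
#' @param path Output TSV path.
#' @param dialect `"adjacency"` or `"edge_list"`.
#' @return `path`, invisibly.
#' @export
write_interaction_matrix <- function(dataset, path,
                                     dialect = c("adjacency", "edge_list")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dataset, "dti_dataset"))
  if (dialect == "adjacency") {
    hdr <- paste(c("target", dataset$drugs), collapse = "\t")
    rows <- vapply(seq_along(dataset$targets), function(i) {
      paste(c(dataset$targets[i],
              format(dataset$interactions[i, ], trim = TRUE)),
            collapse = "\t")
    }, character(1L))
    writeLines(c(hdr, rows), path, useBytes = TRUE)
  } else {
    idx <- which(dataset$interactions == 1, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    lines <- c("drug\ttarget",
               paste(dataset$drugs[idx[, 2L]], dataset$targets[idx[, 1L]],
                     sep = "\t"))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Synthetic dataset specification
#'
#' Defaults define the package's reference simulation: a bipartite system of
#' 80 drugs x 50 targets whose interaction propensity is a rank-4 bilinear
#' form of latent factors; the densest 5% of pairs interact. Each emitted
#' pair carries a length-`T` sequence (drug features then target features,
#' Gaussian noise added) and a `C`-column label row.
#'
#' @param n_drugs,n_targets Entity counts. Defaults 80 and 50.
#' @param r Latent rank. Default 4.
#' @param density Fraction of pairs that interact, in `(0, 1)`. Default 0.05.
#' @param noise_sd Gaussian noise s.d. added to sequences. Default 0.1.
#' @param T Sequence length (even, >= 2). Default 4.
#' @param d Feature width per step. Default 8.
#' @param C Label columns (>= 2; col 1 = interacting, col 2 =
#'   non-interacting, extra columns are interaction-strength type bits).
#'   Default 2.
#' @param seed Integer seed. Default 7.
#' @return Named list (class `synth_spec`).
#' @export
synth_spec <- function(n_drugs = 80L, n_targets = 50L, r = 4L,
                       density = 0.05, noise_sd = 0.1, T = 4L, d = 8L,
                       C = 2L, seed = 7L) {
  stopifnot(n_drugs >= 1, n_targets >= 1, r >= 1, noise_sd >= 0, d >= 1,
            C >= 2)
  if (!(density > 0 && density < 1) ||
      density * n_drugs * n_targets < 1) {
    stop_input("infeasible density: need at least one interacting pair")
  }
  if (!is_count(T) || T < 2 || T %% 2 != 0) {
    stop_input("T must be an even integer >= 2")
  }
  structure(list(n_drugs = as.integer(n_drugs),
                 n_targets = as.integer(n_targets), r = as.integer(r),
                 density = density, noise_sd = noise_sd, T = as.integer(T),
                 d = as.integer(d), C = as.integer(C),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Tile a drug/target feature pair into a sequence
#'
#' The first `T/2` time steps carry the drug feature vector, the last `T/2`
#' the target feature vector — the explicit featurization bridging bipartite
#' pair data to the sequence model.
#'
#' @param drug_features,target_features Numeric vectors of equal length `d`.
#' @param T Even sequence length >= 2.
#' @return `T x d` numeric matrix.
#' @export
pair_to_sequence <- function(drug_features, target_features, T) {
  if (!is_count(T) || T < 2 || T %% 2 != 0) {
    stop_input("T must be an even integer >= 2")
  }
  if (length(drug_features) != length(target_features)) {
    stop_input("drug and target feature vectors must have equal length")
  }
  rbind(matrix(drug_features, T / 2, length(drug_features), byrow = TRUE),
        matrix(target_features, T / 2, length(target_features), byrow = TRUE))
}

# Sequences for a set of (target_row, drug_col) index pairs. Noise is seeded
# per pair from the dataset seed, so any pair's sequence is reproducible
# regardless of which subset is requested.
pair_sequences <- function(dataset, pairs) {
  stopifnot(inherits(dataset, "dti_dataset"))
  if (is.null(dataset$drug_features)) {
    stop_input("dataset carries no features; run profile_features() first")
  }
  sp <- dataset$spec
  n <- nrow(pairs)
  x <- array(0, c(n, sp$T, sp$d))
  for (k in seq_len(n)) {
    ti <- pairs[k, 1L]; di <- pairs[k, 2L]
    seq_k <- pair_to_sequence(dataset$drug_features[di, ],
                              dataset$target_features[ti, ], sp$T)
    if (sp$noise_sd > 0) {
      eps <- with_seed(
        derive_seed(sp$seed, paste0("pair:", dataset$drugs[di], ":",
                                    dataset$targets[ti])),
        matrix(stats::rnorm(sp$T * sp$d, 0, sp$noise_sd), sp$T, sp$d))
      seq_k <- seq_k + eps
    }
    x[k, , ] <- seq_k
  }
  x
}

#' Generate a synthetic drug-target interaction dataset
#'
#' Latent drug factors `U` (`n_drugs x r`) and target factors `V`
#' (`n_targets x r`) are drawn standard normal; the pair score is the
#' bilinear form `V U'` and exactly the top `ceiling(density * n_pairs)`
#' scores become interactions (deterministic thresholding, so positive counts
#' are exact). Observable features are a fixed random linear read-out of the
#' latent rows; each emitted pair's sequence tiles drug then target features
#' with i.i.d. Gaussian noise. All positives are emitted together with an
#' equal-sized seeded sample of non-interacting pairs; labels are one-hot
#' interaction indicators (plus interaction-strength type bits when `C > 2`).
#'
#' @param spec A [synth_spec()].
#' @return A [dti_dataset()] with extra fields `pairs` (data frame: `drug`,
#'   `target`, `label` and matrix indices), `x` (`N x T x d` sequence array),
#'   `y` (`N x C` label matrix). Fully reproducible from `spec$seed`.
#' @export
generate_synthetic_dti <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  drugs <- sprintf("d%03d", seq_len(spec$n_drugs))
  targets <- sprintf("t%03d", seq_len(spec$n_targets))
  n_pairs <- spec$n_drugs * spec$n_targets
  n_pos <- ceiling(spec$density * n_pairs)
  st <- with_seed(spec$seed, {
    U <- matrix(stats::rnorm(spec$n_drugs * spec$r), spec$n_drugs)
    V <- matrix(stats::rnorm(spec$n_targets * spec$r), spec$n_targets)
    Pd <- matrix(stats::rnorm(spec$r * spec$d), spec$r) / sqrt(spec$r)
    Pt <- matrix(stats::rnorm(spec$r * spec$d), spec$r) / sqrt(spec$r)
    list(U = U, V = V, Pd = Pd, Pt = Pt)
  })
  score <- st$V %*% t(st$U) # targets x drugs
  A <- matrix(0, spec$n_targets, spec$n_drugs)
  A[utils::head(order(score, decreasing = TRUE), n_pos)] <- 1
  ds <- dti_dataset(drugs, targets, A,
                    drug_features = st$U %*% st$Pd,
                    target_features = st$V %*% st$Pt,
                    spec = spec)
  pos <- which(A == 1, arr.ind = TRUE)
  neg_pool <- which(A == 0, arr.ind = TRUE)
  neg_idx <- with_seed(derive_seed(spec$seed, "negatives"),
                       sample.int(nrow(neg_pool),
                                  min(n_pos, nrow(neg_pool))))
  neg <- neg_pool[neg_idx, , drop = FALSE]
  pairs_idx <- rbind(pos, neg)
  lab <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  y <- matrix(0, nrow(pairs_idx), spec$C)
  y[, 1L] <- lab
  y[, 2L] <- 1 - lab
  if (spec$C > 2L) {
    # interaction-strength type bits: positives split into C-2 score bands
    s_pos <- score[pos]
    band <- cut(rank(s_pos, ties.method = "first"), spec$C - 2L,
                labels = FALSE)
    for (k in seq_len(nrow(pos))) y[k, 2L + band[k]] <- 1
  }
  ds$pairs <- data.frame(drug = drugs[pairs_idx[, 2L]],
                         target = targets[pairs_idx[, 1L]],
                         target_row = as.integer(pairs_idx[, 1L]),
                         drug_col = as.integer(pairs_idx[, 2L]),
                         label = lab, stringsAsFactors = FALSE)
  ds$x <- pair_sequences(ds, pairs_idx)
  ds$y <- y
  ds
}

#' Derive per-entity features from interaction profiles
#'
#' For datasets read from file (which carry no latent features), uses the
#' leading `d`-dimensional SVD projection of the interaction matrix as drug
#' and target features. Note these features are computed from the full matrix,
#' so cross-validated metrics on them are optimistic; they are intended for
#' demonstration pipelines, not benchmarking.
#'
#' @param dataset A [dti_dataset()].
#' @param d Feature width. Default 8.
#' @param T Sequence length for downstream pairing. Default 4.
#' @param C Label columns. Default 2.
#' @param noise_sd Per-pair sequence noise. Default 0.
#' @param seed Seed recorded for sequence regeneration. Default 1.
#' @return The dataset with `drug_features`, `target_features` and a `spec`
#'   attached.
#' @export
profile_features <- function(dataset, d = 8L, T = 4L, C = 2L, noise_sd = 0,
                             seed = 1L) {
  stopifnot(inherits(dataset, "dti_dataset"))
  A <- dataset$interactions
  k <- min(d, nrow(A), ncol(A))
  sv <- svd(A, nu = k, nv = k)
  pad <- function(m) {
    if (ncol(m) < d) cbind(m, matrix(0, nrow(m), d - ncol(m))) else m
  }
  dataset$target_features <- pad(sv$u %*% diag(sqrt(sv$d[seq_len(k)]),
                                               k, k))
  dataset$drug_features <- pad(sv$v %*% diag(sqrt(sv$d[seq_len(k)]), k, k))
  dataset$spec <- list(T = as.integer(T), d = as.integer(d),
                       C = as.integer(C), noise_sd = noise_sd,
                       seed = as.integer(seed))
  dataset
}
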