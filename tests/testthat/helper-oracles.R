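# Independent definitional oracles and fixture builders. These deliberately
# use naive loops / enumeration so they share no code with the implementation
# they check.

# AUC as the explicit probability that a positive outranks a negative,
# ties counted 1/2.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# Average precision by walking the ranking one item at a time.
aupr_bruteforce <- function(scores, labels) {
  ord <- order(-scores)
  lab <- labels[ord]
  tp <- 0
  ap <- 0
  for (i in seq_along(lab)) {
    if (lab[i] == 1) {
      tp <- tp + 1
      ap <- ap + tp / i
    }
  }
  ap / sum(lab)
}

# Eq.-style losses as explicit double/triple loops.
rec_loss_loop <- function(x, x_hat) {
  N <- dim(x)[1]
  total <- 0
  for (i in seq_len(N)) {
    for (t in seq_len(dim(x)[2])) {
      for (j in seq_len(dim(x)[3])) {
        total <- total + (x[i, t, j] - x_hat[i, t, j])^2
      }
    }
  }
  total / N
}

cls_loss_loop <- function(p, y) {
  total <- 0
  n_used <- 0
  for (i in seq_len(nrow(p))) {
    s <- sum(y[i, ])
    if (s == 0) next
    n_used <- n_used + 1
    for (c in seq_len(ncol(p))) {
      total <- total + (p[i, c] - y[i, c] / s)^2
    }
  }
  total / n_used
}

error_rate_loop <- function(pred, truth) {
  bad <- 0
  for (i in seq_len(nrow(pred))) {
    if (any(pred[i, ] != truth[i, ])) bad <- bad + 1
  }
  bad / nrow(pred) * 100
}

# A random sentence with n non-overlapping single-token drug mentions.
random_drug_sentence <- function(n, n_filler = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  drugs <- sprintf("drug%02d", sample(99, n))
  fillers <- sample(c("the", "dose", "of", "may", "increase", "plasma",
                      "levels", "when", "taken", "with", "orally", "daily"),
                    n_filler, replace = TRUE)
  tokens <- fillers
  pos <- sort(sample(seq_len(n_filler + n) - 1L, n))
  out <- character(0)
  cursor <- 0L
  fi <- 1L
  mentions <- data.frame(start = integer(), end = integer(),
                         name = character())
  for (k in seq_len(n_filler + n)) {
    if ((k - 1L) %in% pos) {
      di <- which(pos == k - 1L)
      mentions <- rbind(mentions,
                        data.frame(start = k - 1L, end = k,
                                   name = drugs[di]))
      out <- c(out, drugs[di])
    } else {
      out <- c(out, fillers[fi])
      fi <- fi + 1L
    }
  }
  annotated_sentence(out, mentions)
}

# Write a tiny sentence-corpus TSV; returns its path.
write_demo_corpus <- function(path = tempfile(fileext = ".tsv")) {
  lines <- c(
    "sentence_id\ttext\tmentions",
    paste0("s1\tAspirin might reduce the effect of probenecid\t",
           "0:1:Aspirin;6:7:probenecid"),
    paste0("s2\twarfarin with amiodarone may cause severe bleeding\t",
           "0:1:warfarin;2:3:amiodarone"),
    paste0("s3\tvitamin supplements improve tolerated outcomes\t", "")
  )
  writeLines(lines, path)
  path
}

# A small deterministic synthetic dataset for fast model tests.
small_synth <- function(seed = 7, noise_sd = 0.1) {
  generate_synthetic_dti(synth_spec(n_drugs = 30, n_targets = 20, r = 3,
                                    density = 0.08, noise_sd = noise_sd,
                                    seed = seed))
}
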