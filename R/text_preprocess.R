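# Sentence-level preprocessing for interaction text: drug-pair enumeration,
# drug blinding, vocabulary construction and word-embedding lookup.

PAD_TOKEN <- "<pad>"
UNK_TOKEN <- "<unk>"

#' Construct an annotated sentence
#'
#' An annotated sentence is an ordered token vector plus the spans of its drug
#' mentions. Spans are 0-based, half-open `[start, end)` token intervals; they
#' must lie inside the sentence and must not overlap.
#'
#' @param tokens Character vector of tokens.
#' @param mentions A `data.frame` with columns `start`, `end` (integer token
#'   indices) and `name` (the drug string), or `NULL` for no mentions.
#' @return An object of class `annotated_sentence`.
#' @export
#' @examples
#' annotated_sentence(
#'   c("aspirin", "might", "reduce", "the", "effect", "of", "probenecid"),
#'   data.frame(start = c(0L, 6L), end = c(1L, 7L),
#'              name = c("aspirin", "probenecid"))
#' )
annotated_sentence <- function(tokens, mentions = NULL) {
  stopifnot(is.character(tokens))
  if (is.null(mentions)) {
    mentions <- data.frame(start = integer(), end = integer(),
                           name = character(), stringsAsFactors = FALSE)
  }
  if (!all(c("start", "end", "name") %in% names(mentions))) {
    stop_input("mentions must have columns start, end, name")
  }
  mentions <- mentions[order(mentions$start), , drop = FALSE]
  rownames(mentions) <- NULL
  n <- length(tokens)
  if (nrow(mentions) > 0L) {
    if (any(mentions$start < 0L) || any(mentions$end > n) ||
        any(mentions$start >= mentions$end)) {
      stop_input("mention spans must satisfy 0 <= start < end <= n_tokens")
    }
    if (nrow(mentions) > 1L &&
        any(mentions$start[-1L] < mentions$end[-nrow(mentions)])) {
      stop_input("mention spans must not overlap")
    }
  }
  structure(list(tokens = tokens, mentions = mentions),
            class = "annotated_sentence")
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat("Annotated sentence:", paste(x$tokens, collapse = " "), "\n")
  cat(nrow(x$mentions), "drug mention(s)\n")
  invisible(x)
}

#' Number of unordered drug pairs in a sentence
#'
#' For a sentence mentioning `n` drugs the number of candidate interacting
#' pairs is `max(0, sum_{i=1..n} (i - 1))`, i.e. `n (n - 1) / 2`.
#'
#' @param n Non-negative integer count of drug mentions.
#' @return Non-negative integer pair count.
#' @export
#' @examples
#' count_drug_pairs(4) # 6
count_drug_pairs <- function(n) {
  if (!is_count(n)) stop_input("n must be a single non-negative integer")
  max(0, sum(seq_len(n) - 1L))
}

#' Blind the drug mentions of a sentence, one instance per candidate pair
#'
#' Drug blinding replaces drug names by generic placeholders so the classifier
#' learns relational rather than lexical cues. For every unordered pair of
#' mentions one blinded instance is emitted: the mention appearing first in
#' token order becomes `"DrugA"`, the second `"DrugB"`, and every non-focal
#' mention `"DrugN"`. Multi-token mentions collapse to a single placeholder
#' token. Sentences with fewer than two mentions yield an empty list.
#'
#' @param sentence An [annotated_sentence()].
#' @return List of `blinded_sentence` objects, each with fields `tokens` and
#'   `pair` (the `(DrugA, DrugB)` names it encodes); length equals
#'   [count_drug_pairs()] of the mention count.
#' @export
blind_drugs <- function(sentence) {
  stopifnot(inherits(sentence, "annotated_sentence"))
  m <- sentence$mentions
  n <- nrow(m)
  if (n < 2L) return(list())
  out <- vector("list", count_drug_pairs(n))
  k <- 0L
  for (a in seq_len(n - 1L)) {
    for (b in seq((a + 1L), n)) {
      labels <- rep("DrugN", n)
      labels[a] <- "DrugA"
      labels[b] <- "DrugB"
      tokens <- character(0)
      cursor <- 0L # 0-based index of next unconsumed token
      for (j in seq_len(n)) {
        if (m$start[j] > cursor) {
          tokens <- c(tokens, sentence$tokens[(cursor + 1L):m$start[j]])
        }
        tokens <- c(tokens, labels[j])
        cursor <- m$end[j]
      }
      if (cursor < length(sentence$tokens)) {
        tokens <- c(tokens, sentence$tokens[(cursor + 1L):length(sentence$tokens)])
      }
      k <- k + 1L
      out[[k]] <- structure(list(tokens = tokens,
                                 pair = c(m$name[a], m$name[b])),
                            class = "blinded_sentence")
    }
  }
  out
}

#' @export
print.blinded_sentence <- function(x, ...) {
  cat(paste(x$tokens, collapse = " "), "\n")
  cat("pair:", x$pair[1L], "/", x$pair[2L], "\n")
  invisible(x)
}

#' Clean and normalise tokens
#'
#' Lower-cases, strips punctuation characters, and (optionally) applies a small
#' rule-based suffix normaliser (plural, gerund and past-tense stripping) as a
#' light-weight stand-in for full lemmatization. Token positions are preserved
#' so mention spans remain valid; blinding placeholders pass through untouched.
#'
#' @param tokens Character vector.
#' @param lemmatize Apply the suffix rules? Default `TRUE`.
#' @return Character vector of the same length.
#' @export
clean_tokens <- function(tokens, lemmatize = TRUE) {
  keep <- tokens %in% c("DrugA", "DrugB", "DrugN")
  out <- tolower(tokens)
  out <- gsub("[[:punct:]]", "", out)
  if (lemmatize) {
    out <- vapply(out, normalise_suffix, character(1L), USE.NAMES = FALSE)
  }
  out[keep] <- tokens[keep]
  out
}

# Heuristic suffix rules; intentionally conservative (never empties a token).
normalise_suffix <- function(tok) {
  n <- nchar(tok)
  if (n > 4L && endsWith(tok, "ies")) return(paste0(substr(tok, 1L, n - 3L), "y"))
  if (n > 5L && endsWith(tok, "ing")) return(substr(tok, 1L, n - 3L))
  if (n > 4L && endsWith(tok, "ed"))  return(substr(tok, 1L, n - 2L))
  if (n > 3L && endsWith(tok, "s") && !endsWith(tok, "ss")) {
    return(substr(tok, 1L, n - 1L))
  }
  tok
}

#' Build a vocabulary from a token corpus
#'
#' Indices are 0-based and contiguous: `<pad>` is always 0 and `<unk>` is
#' always 1; remaining tokens with corpus frequency at least `min_count` follow
#' in decreasing frequency (ties broken alphabetically).
#'
#' @param corpus List of character token vectors.
#' @param min_count Minimum corpus frequency for inclusion. Default 1.
#' @return Named integer vector mapping token to 0-based index.
#' @export
#' @examples
#' build_vocab(list(c("a", "b"), c("b", "c")))
build_vocab <- function(corpus, min_count = 1L) {
  if (!is.list(corpus) || length(corpus) == 0L) {
    stop_input("corpus must be a non-empty list of token vectors")
  }
  freq <- table(unlist(corpus, use.names = FALSE))
  freq <- freq[freq >= min_count]
  toks <- names(freq)[order(-as.integer(freq), names(freq))]
  toks <- setdiff(toks, c(PAD_TOKEN, UNK_TOKEN))
  idx <- seq_along(toks) + 1L
  vocab <- c(stats::setNames(0:1, c(PAD_TOKEN, UNK_TOKEN)),
             stats::setNames(idx, toks))
  vocab
}

#' Construct a word-embedding matrix
#'
#' Wraps a `ds x |V|` real matrix whose column `j` is the vector of the token
#' with 0-based index `j - 1`. The `<pad>` column is fixed to zero.
#'
#' @param matrix Numeric matrix, `ds` rows, `|V|` columns.
#' @param vocab Named 0-based index vector from [build_vocab()].
#' @return Object of class `embedding_matrix` with fields `matrix`, `vocab`,
#'   `ds`.
#' @export
embedding_matrix <- function(matrix, vocab) {
  stopifnot(is.matrix(matrix), is.integer(vocab) || is.numeric(vocab))
  if (ncol(matrix) != length(vocab)) {
    stop_input("embedding matrix must have one column per vocabulary entry")
  }
  if (!all(c(PAD_TOKEN, UNK_TOKEN) %in% names(vocab))) {
    stop_input("vocab must contain the reserved <pad> and <unk> entries")
  }
  matrix[, vocab[[PAD_TOKEN]] + 1L] <- 0
  structure(list(matrix = matrix, vocab = vocab, ds = nrow(matrix)),
            class = "embedding_matrix")
}

#' Random word embeddings for a vocabulary
#'
#' @param vocab Named 0-based index vector.
#' @param ds Embedding dimension.
#' @param seed Integer seed.
#' @param scale Half-width of the uniform initialisation. Default 0.5.
#' @return An [embedding_matrix()].
#' @export
random_embedding <- function(vocab, ds, seed = 1L, scale = 0.5) {
  stopifnot(is_count(ds), ds >= 1)
  m <- with_seed(seed, matrix(stats::runif(ds * length(vocab), -scale, scale),
                              nrow = ds))
  colnames(m) <- names(sort(vocab))
  embedding_matrix(m, vocab)
}

#' Embed a (blinded) sentence into a fixed-length real sequence
#'
#' Each token maps to its column of the embedding matrix; out-of-vocabulary
#' tokens map to the `<unk>` vector. Sequences shorter than `T` are post-padded
#' with the `<pad>` vector (all zeros); longer sequences are truncated.
#'
#' @param blinded A `blinded_sentence` or a plain character token vector.
#' @param emb An [embedding_matrix()].
#' @param T Output sequence length (rows), at least 1.
#' @return A `T x ds` numeric matrix.
#' @export
embed_sentence <- function(blinded, emb, T) {
  stopifnot(inherits(emb, "embedding_matrix"))
  if (!is_count(T) || T < 1) stop_input("T must be a positive integer")
  tokens <- if (inherits(blinded, "blinded_sentence")) blinded$tokens else blinded
  stopifnot(is.character(tokens))
  idx <- emb$vocab[tokens]
  idx[is.na(idx)] <- emb$vocab[[UNK_TOKEN]]
  idx <- utils::head(idx, T)
  pad <- emb$vocab[[PAD_TOKEN]]
  idx <- c(idx, rep(pad, T - length(idx)))
  t(emb$matrix[, idx + 1L, drop = FALSE])
}

#' Read a sentence corpus from TSV
#'
#' Expected columns: `sentence_id`, `text` (whitespace-tokenised), `mentions`
#' (semicolon-separated `start:end:name` triples with 0-based half-open token
#' spans; empty for none).
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @return Named list of [annotated_sentence()] objects keyed by sentence id.
#' @export
read_sentence_corpus <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("sentence_id", "text", "mentions")
  if (!all(need %in% names(df))) {
    stop_input("corpus TSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    tokens <- strsplit(trimws(df$text[i]), "[[:space:]]+")[[1L]]
    ms <- df$mentions[i]
    mentions <- NULL
    if (nzchar(trimws(ms))) {
      parts <- strsplit(strsplit(ms, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
      bad <- vapply(parts, length, integer(1L)) != 3L
      if (any(bad)) {
        stop_input("malformed mention triple in sentence ", df$sentence_id[i])
      }
      mentions <- data.frame(
        start = as.integer(vapply(parts, `[[`, "", 1L)),
        end = as.integer(vapply(parts, `[[`, "", 2L)),
        name = vapply(parts, `[[`, "", 3L),
        stringsAsFactors = FALSE
      )
    }
    annotated_sentence(tokens, mentions)
  })
  names(out) <- df$sentence_id
  out
}

#' Write word embeddings in the plain-text word2vec format
#'
#' First line `count dim`, then one `token v1 ... v_ds` line per token in
#' index order.
#'
#' @param emb An [embedding_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_word_embeddings <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_matrix"))
  ord <- order(emb$vocab)
  toks <- names(emb$vocab)[ord]
  lines <- c(paste(length(toks), emb$ds),
             vapply(seq_along(toks), function(j) {
               paste(c(toks[j],
                       formatC(emb$matrix[, emb$vocab[[toks[j]]] + 1L],
                               format = "g", digits = 17)),
                     collapse = " ")
             }, character(1L)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read word embeddings from the plain-text word2vec format
#'
#' @param path Input file path.
#' @return An [embedding_matrix()]; tokens are indexed in file order, so a file
#'   written by [write_word_embeddings()] round-trips exactly.
#' @export
read_word_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]])
  if (length(hdr) != 2L || anyNA(hdr)) {
    stop_input("line 1: expected header 'count dim'")
  }
  n <- hdr[1L]; ds <- hdr[2L]
  if (length(lines) - 1L != n) {
    stop_input("header announces ", n, " tokens but file has ",
               length(lines) - 1L)
  }
  toks <- character(n)
  m <- matrix(0, nrow = ds, ncol = n)
  for (j in seq_len(n)) {
    fields <- strsplit(trimws(lines[j + 1L]), "[[:space:]]+")[[1L]]
    if (length(fields) != ds + 1L) {
      stop_input("line ", j + 1L, ": expected 1 token + ", ds, " values")
    }
    toks[j] <- fields[1L]
    m[, j] <- as.numeric(fields[-1L])
  }
  if (!all(c(PAD_TOKEN, UNK_TOKEN) %in% toks)) {
    stop_input("embedding file must contain the reserved <pad> and <unk> tokens")
  }
  vocab <- stats::setNames(seq_len(n) - 1L, toks)
  embedding_matrix(m, vocab)
}
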