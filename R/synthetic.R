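#' Synthetic corpus configuration
#'
#' Parameters for the seeded question-pair generator. Generated questions
#' are short strings of single-character tokens built from topic templates,
#' so character tokenization applies unchanged. Matched pairs share a topic
#' and differ by synonym substitutions and local token swaps; unmatched
#' pairs mix topics, half of them as *hard negatives* that keep the sentence
#' frame and swap only the topic-defining tokens.
#'
#' @param n_pairs Total number of pairs across the three splits (>= 2).
#' @param positive_fraction Fraction of matched pairs in every split,
#'   in (0, 1). The default 0.39 mirrors the class balance of the medical
#'   question-matching corpus this generator emulates (12,610 positive vs
#'   19,750 negative training pairs).
#' @param vocab_size Number of distinct tokens (> n_topics).
#' @param n_topics Number of latent topics.
#' @param template_length Tokens per question.
#' @param paraphrase_ops Per-token synonym-substitution rate in \[0, 1\];
#'   also the rate of one adjacent-token swap per positive pair. 0 makes
#'   every positive pair verbatim-identical.
#' @param hard_negative_fraction Fraction of negatives built as topic-swap
#'   hard negatives (same frame and fillers, different topic tokens).
#' @param split Named train/dev/test counts summing to `n_pairs`; default
#'   80/10/10 rounded.
#' @param seed Integer seed; corpora are byte-identical for equal seeds.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_pairs = 2800L,
                         positive_fraction = 0.39,
                         vocab_size = 80L,
                         n_topics = 8L,
                         template_length = 10L,
                         paraphrase_ops = 0.2,
                         hard_negative_fraction = 0.5,
                         split = NULL,
                         seed = 1L) {
  if (n_pairs < 2L) stop("n_pairs must be >= 2", call. = FALSE)
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    stop("positive_fraction must be in (0, 1)", call. = FALSE)
  }
  if (vocab_size <= n_topics) stop("vocab_size must exceed n_topics", call. = FALSE)
  if (paraphrase_ops < 0 || paraphrase_ops > 1) {
    stop("paraphrase_ops must be in [0, 1]", call. = FALSE)
  }
  if (is.null(split)) {
    n_dev <- max(1L, round(0.1 * n_pairs))
    n_test <- max(1L, round(0.1 * n_pairs))
    split <- c(train = n_pairs - n_dev - n_test, dev = n_dev, test = n_test)
  }
  split <- as.integer(split)
  names(split) <- c("train", "dev", "test")
  if (sum(split) != n_pairs || any(split < 1L)) {
    stop("split counts must be positive and sum to n_pairs", call. = FALSE)
  }
  structure(
    list(n_pairs = as.integer(n_pairs), positive_fraction = positive_fraction,
         vocab_size = as.integer(vocab_size), n_topics = as.integer(n_topics),
         template_length = as.integer(template_length),
         paraphrase_ops = paraphrase_ops,
         hard_negative_fraction = hard_negative_fraction,
         split = split, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Token inventory: single CJK-range characters partitioned into one marker
# per topic, per-topic content synonym pairs, and shared filler synonym
# pairs. Substitutable tokens always come in (token, synonym) pairs.
synth_inventory <- function(config) {
  V <- config$vocab_size
  K <- config$n_topics
  tokens <- vapply(seq_len(V), function(i) intToUtf8(0x4E00 + i - 1L), "")
  markers <- tokens[seq_len(K)]
  rest <- tokens[-seq_len(K)]
  n_rest_pairs <- length(rest) %/% 2L
  if (n_rest_pairs < K + 1L) {
    stop("vocab too small to honor n_topics: need at least ",
         K + 2L * (K + 1L), " tokens", call. = FALSE)
  }
  n_content_pairs <- max(K, floor(0.6 * n_rest_pairs))
  n_content_pairs <- K * (n_content_pairs %/% K) # equal share per topic
  pair_of <- matrix(rest[seq_len(2L * n_rest_pairs)], ncol = 2L, byrow = TRUE)
  content_pairs <- pair_of[seq_len(n_content_pairs), , drop = FALSE]
  filler_pairs <- pair_of[-seq_len(n_content_pairs), , drop = FALSE]
  synonym <- c(
    stats::setNames(pair_of[, 2L], pair_of[, 1L]),
    stats::setNames(pair_of[, 1L], pair_of[, 2L])
  )
  per_topic <- n_content_pairs %/% K
  content_by_topic <- lapply(seq_len(K), function(k) {
    content_pairs[(k - 1L) * per_topic + seq_len(per_topic), , drop = FALSE]
  })
  list(markers = markers, content_by_topic = content_by_topic,
       filler_pairs = filler_pairs, synonym = synonym, tokens = tokens)
}

# Draw one token per requested slot from a two-column synonym-pair matrix:
# pair row and column are both random, so either member of a pair is equally
# likely anywhere — token identity alone carries no label signal.
draw_from_pairs <- function(pairs, n) {
  rows <- sample.int(nrow(pairs), n, replace = n > nrow(pairs))
  cols <- sample.int(2L, n, replace = TRUE)
  pairs[cbind(rows, cols)]
}

# Sentence frames: length-L slot patterns with one marker slot, up to three
# content slots, fillers elsewhere. Drawn once per corpus from the seed.
synth_frames <- function(config, n_frames = 4L) {
  L <- config$template_length
  n_content <- min(3L, L - 1L)
  lapply(seq_len(n_frames), function(f) {
    slots <- rep("F", L)
    pos <- sample.int(L, 1L + n_content)
    slots[pos[1L]] <- "M"
    slots[pos[-1L]] <- "C"
    slots
  })
}

synth_sentence <- function(frame, topic, inv) {
  out <- character(length(frame))
  out[frame == "M"] <- inv$markers[[topic]]
  out[frame == "C"] <- draw_from_pairs(inv$content_by_topic[[topic]],
                                       sum(frame == "C"))
  out[frame == "F"] <- draw_from_pairs(inv$filler_pairs, sum(frame == "F"))
  out
}

synth_paraphrase <- function(toks, inv, rate) {
  if (rate > 0) {
    sub <- stats::runif(length(toks)) < rate & toks %in% names(inv$synonym)
    toks[sub] <- unname(inv$synonym[toks[sub]])
    if (stats::runif(1L) < rate && length(toks) >= 2L) {
      i <- sample.int(length(toks) - 1L, 1L)
      toks[c(i, i + 1L)] <- toks[c(i + 1L, i)]
    }
  }
  toks
}

# Swap the topic-defining tokens (marker + content slots) of a sentence for
# those of another topic, keeping frame and fillers: a hard negative.
synth_topic_swap <- function(toks, frame, new_topic, inv) {
  toks[frame == "M"] <- inv$markers[[new_topic]]
  toks[frame == "C"] <- draw_from_pairs(inv$content_by_topic[[new_topic]],
                                        sum(frame == "C"))
  toks
}

#' Generate a synthetic question-pair corpus
#'
#' Fully reproducible from `config$seed`. Labels are correct by construction:
#' a pair is positive iff both sides were generated from the same topic.
#' Every split contains exactly `round(positive_fraction * n)` positives.
#'
#' @param config A [synth_config()].
#' @return A `synth_corpus`: list with tibbles `train`, `dev`, `test` (columns
#'   `pair_id`, `text_a`, `text_b`, `label`, plus generator bookkeeping
#'   columns `topic_a`, `topic_b`, `hard_negative`) and `config`.
#' @examples
#' corp <- generate_corpus(synth_config(n_pairs = 100, seed = 7))
#' dplyr::count(corp$train, label)
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  inv <- synth_inventory(config)
  frames <- synth_frames(config)
  K <- config$n_topics
  next_id <- 0L
  gen_split <- function(n) {
    n_pos <- round(config$positive_fraction * n)
    labels <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
    rows <- lapply(labels, function(y) {
      f <- sample.int(length(frames), 1L)
      frame <- frames[[f]]
      if (y == 1L) {
        k <- sample.int(K, 1L)
        a <- synth_sentence(frame, k, inv)
        b <- synth_paraphrase(a, inv, config$paraphrase_ops)
        list(a = a, b = b, ta = k, tb = k, hard = FALSE)
      } else {
        ks <- sample.int(K, 2L)
        a <- synth_sentence(frame, ks[1L], inv)
        if (stats::runif(1L) < config$hard_negative_fraction) {
          b <- synth_topic_swap(a, frame, ks[2L], inv)
          hard <- TRUE
        } else {
          frame_b <- frames[[sample.int(length(frames), 1L)]]
          b <- synth_sentence(frame_b, ks[2L], inv)
          hard <- FALSE
        }
        list(a = a, b = b, ta = ks[1L], tb = ks[2L], hard = hard)
      }
    })
    ids <- sprintf("pair_%06d", next_id + seq_len(n))
    next_id <<- next_id + n
    tibble::tibble(
      pair_id = ids,
      text_a = vapply(rows, function(r) paste(r$a, collapse = ""), ""),
      text_b = vapply(rows, function(r) paste(r$b, collapse = ""), ""),
      label = labels,
      topic_a = vapply(rows, function(r) r$ta, 0L),
      topic_b = vapply(rows, function(r) r$tb, 0L),
      hard_negative = vapply(rows, function(r) r$hard, NA)
    )
  }
  corpus <- list(
    train = gen_split(config$split[["train"]]),
    dev = gen_split(config$split[["dev"]]),
    test = gen_split(config$split[["test"]]),
    config = config
  )
  structure(corpus, class = "synth_corpus")
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat(sprintf(
    "<synth_corpus> train=%d dev=%d test=%d, positive_fraction=%.2f, seed=%d\n",
    nrow(x$train), nrow(x$dev), nrow(x$test),
    x$config$positive_fraction, x$config$seed
  ))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Writes `train.tsv`, `dev.tsv`, `test.tsv` in the standard TSV dialect and
#' a `metadata.json` sidecar holding the generator configuration.
#'
#' @param corpus A `synth_corpus`.
#' @param dir Output directory (created if needed).
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synth_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in c("train", "dev", "test")) {
    write_pairs(corpus[[s]], file.path(dir, paste0(s, ".tsv")))
  }
  meta <- unclass(corpus$config)
  meta$split <- as.list(meta$split)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Fixed two-example worked batch
#'
#' A deterministic miniature fixture shared by layer-level examples and
#' tests: one matched and one unmatched pair over a six-token Latin
#' vocabulary, padded to n = 6, labels `c(1, 0)`.
#'
#' @return A list with `pairs` (tibble), `vocab` and `batch`
#'   (`tokenized_batch` of 2 examples).
#' @export
make_worked_batch <- function() {
  pairs <- tibble::tibble(
    pair_id = c("wk_1", "wk_2"),
    text_a = c("abcd", "abcd"),
    text_b = c("abce", "deff"),
    label = c(1L, 0L)
  )
  vocab <- build_vocab(pairs, min_count = 1L, mode = "char")
  list(pairs = pairs, vocab = vocab, batch = encode_batch(pairs, vocab, n = 6L))
}
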