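#' Read a question-pair corpus
#'
#' Reads labeled (or unlabeled) text pairs from a UTF-8 TSV file with no
#' header and exactly three tab-separated fields `text_a<TAB>text_b<TAB>label`
#' (two fields in prediction mode), or from JSONL with keys `text_a`,
#' `text_b` and optional `label`. Labels must be 0 or 1.
#'
#' @param path File path.
#' @param format `"auto"` (by extension; `.jsonl`/`.json` is JSONL, anything
#'   else TSV), `"tsv"` or `"jsonl"`.
#' @return A tibble with columns `pair_id`, `text_a`, `text_b`, `label`
#'   (`label` is `NA` in prediction mode), one row per record in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("a b\tc d\t1", "a\tb\t0"), tf)
#' read_pairs(tf)
#' @export
read_pairs <- function(path, format = c("auto", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "tsv"
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      pair_id = character(), text_a = character(),
      text_b = character(), label = integer()
    ))
  }
  if (format == "tsv") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < 2L | nf > 3L)
    if (length(bad)) {
      stop("malformed TSV line ", bad[1L], ": expected 2 or 3 fields, got ",
           nf[bad[1L]], call. = FALSE)
    }
    if (length(unique(nf)) > 1L) {
      stop("mixed labeled/unlabeled TSV lines (first offender: line ",
           which(nf != nf[1L])[1L], ")", call. = FALSE)
    }
    text_a <- vapply(fields, `[[`, "", 1L)
    text_b <- vapply(fields, `[[`, "", 2L)
    label <- if (nf[1L] == 3L) {
      parse_labels(vapply(fields, `[[`, "", 3L))
    } else {
      rep(NA_integer_, length(lines))
    }
  } else {
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) stop("malformed JSONL line ", i, ": ",
                                               conditionMessage(e), call. = FALSE))
      if (is.null(rec$text_a) || is.null(rec$text_b)) {
        stop("malformed JSONL line ", i, ": missing text_a/text_b", call. = FALSE)
      }
      rec
    })
    text_a <- vapply(recs, function(r) as.character(r$text_a), "")
    text_b <- vapply(recs, function(r) as.character(r$text_b), "")
    label <- vapply(recs, function(r) {
      if (is.null(r$label)) NA_character_ else as.character(r$label)
    }, "")
    label <- parse_labels(label, allow_na = TRUE)
  }
  if (any(!nzchar(trimws(text_a))) || any(!nzchar(trimws(text_b)))) {
    bad <- which(!nzchar(trimws(text_a)) | !nzchar(trimws(text_b)))[1L]
    stop("empty text at line ", bad, call. = FALSE)
  }
  tibble::tibble(
    pair_id = sprintf("pair_%06d", seq_along(text_a)),
    text_a = text_a, text_b = text_b, label = label
  )
}

parse_labels <- function(x, allow_na = FALSE) {
  out <- suppressWarnings(as.integer(x))
  na_in <- is.na(x) | x == "NA"
  bad <- which((is.na(out) & !(allow_na & na_in)) |
                 (!is.na(out) & !out %in% c(0L, 1L)))
  if (length(bad)) {
    stop("label outside {0,1} at line ", bad[1L], ": '", x[bad[1L]], "'",
         call. = FALSE)
  }
  out
}

#' Write question pairs as TSV
#'
#' Inverse of [read_pairs()] for the TSV dialect: three tab-separated columns
#' when labels are present, two otherwise.
#'
#' @param pairs Tibble with `text_a`, `text_b` and optional `label`.
#' @param path Output path.
#' @export
write_pairs <- function(pairs, path) {
  has_label <- "label" %in% names(pairs) && !anyNA(pairs$label)
  lines <- if (has_label) {
    paste(pairs$text_a, pairs$text_b, pairs$label, sep = "\t")
  } else {
    paste(pairs$text_a, pairs$text_b, sep = "\t")
  }
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Tokenize text
#'
#' Character mode splits into Unicode characters and drops whitespace (the
#' default for unsegmented Chinese questions); whitespace mode splits on runs
#' of whitespace.
#'
#' @param text Character vector.
#' @param mode `"char"` or `"whitespace"`.
#' @return A list of character vectors, one per input string.
#' @examples
#' tokenize_text("a b", "whitespace")
#' @export
tokenize_text <- function(text, mode = c("char", "whitespace")) {
  mode <- match.arg(mode)
  if (mode == "char") {
    lapply(strsplit(text, "", fixed = FALSE), function(ch) ch[!grepl("^\\s$", ch)])
  } else {
    lapply(strsplit(trimws(text), "\\s+"), function(tok) tok[nzchar(tok)])
  }
}

#' Build a token vocabulary
#'
#' Tokens occurring at least `min_count` times across both sides of all
#' pairs are indexed. Index 0 is reserved for the padding token and index 1
#' for unknown tokens; remaining indices follow first-occurrence order, so
#' the vocabulary is a deterministic function of the input.
#'
#' @param pairs Tibble with `text_a`, `text_b`.
#' @param min_count Minimum frequency (>= 1).
#' @param mode Tokenization mode, see [tokenize_text()].
#' @return A `capstm_vocab`: named integer vector of 0-based indices with
#'   attributes `tokens` (index order) and `mode`.
#' @export
build_vocab <- function(pairs, min_count = 1L, mode = c("char", "whitespace")) {
  mode <- match.arg(mode)
  stopifnot(nrow(pairs) >= 1L, min_count >= 1L)
  toks <- unlist(tokenize_text(c(rbind(pairs$text_a, pairs$text_b)), mode))
  first <- !duplicated(toks)
  counts <- table(factor(toks, levels = toks[first]))
  keep <- names(counts)[as.vector(counts) >= min_count]
  tokens <- c("<pad>", "<unk>", keep)
  idx <- seq_along(tokens) - 1L
  names(idx) <- tokens
  structure(idx, tokens = tokens, mode = mode, class = "capstm_vocab")
}

#' @export
print.capstm_vocab <- function(x, ...) {
  cat("<capstm_vocab>", length(x), "tokens (incl. <pad>, <unk>), mode:",
      attr(x, "mode"), "\n")
  invisible(x)
}

#' Encode pairs into a padded, masked batch
#'
#' Tokenizes both texts, maps tokens through the vocabulary (unknown tokens
#' to index 1), truncates to `n` and right-pads with the padding index 0.
#' Both sides share the same length `n`.
#'
#' @param pairs Tibble with `text_a`, `text_b`, optional `label`.
#' @param vocab A `capstm_vocab`.
#' @param n Shared maximum length (>= 1).
#' @return A `tokenized_batch`: list with integer id matrices `ids_a`,
#'   `ids_b` (batch x n, 0-based ids), 0/1 matrices `mask_a`, `mask_b`,
#'   integer vectors `lengths_a`, `lengths_b` (true lengths, uncapped),
#'   `labels` (or `NULL`) and `n`.
#' @export
encode_batch <- function(pairs, vocab, n) {
  stopifnot(inherits(vocab, "capstm_vocab"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  mode <- attr(vocab, "mode")
  enc_side <- function(text) {
    toks <- tokenize_text(text, mode)
    B <- length(toks)
    ids <- matrix(0L, B, n)
    mask <- matrix(0L, B, n)
    for (b in seq_len(B)) {
      id <- unname(vocab[toks[[b]]])
      id[is.na(id)] <- 1L
      k <- min(length(id), n)
      if (k > 0L) {
        ids[b, seq_len(k)] <- id[seq_len(k)]
        mask[b, seq_len(k)] <- 1L
      }
    }
    list(ids = ids, mask = mask, lengths = lengths(toks))
  }
  a <- enc_side(pairs$text_a)
  b <- enc_side(pairs$text_b)
  labels <- if ("label" %in% names(pairs) && !anyNA(pairs$label)) {
    as.integer(pairs$label)
  }
  structure(
    list(ids_a = a$ids, ids_b = b$ids, mask_a = a$mask, mask_b = b$mask,
         lengths_a = a$lengths, lengths_b = b$lengths, labels = labels, n = n),
    class = "tokenized_batch"
  )
}

#' @export
print.tokenized_batch <- function(x, ...) {
  cat("<tokenized_batch>", nrow(x$ids_a), "pairs, padded to n =", x$n,
      if (is.null(x$labels)) "(unlabeled)" else "(labeled)", "\n")
  invisible(x)
}

#' Load pretrained token vectors (word2vec text format)
#'
#' Reads vectors in the word2vec text format (header line
#' `"vocab_size dim"`, then one `token v1 ... vdim` line each). Vocabulary
#' tokens found in the file get the file's vector; missing tokens are
#' initialised from a seeded uniform distribution on \[-0.05, 0.05\]; the
#' padding row is all zeros regardless of file content.
#'
#' @param path Vector file path.
#' @param vocab A `capstm_vocab`.
#' @param dim Expected vector dimensionality; must match the file header.
#' @param seed Seed for the missing-token initialisation.
#' @return Numeric matrix, `length(vocab)` rows by `dim` columns, rows in
#'   vocabulary index order (row 1 = padding index 0).
#' @export
read_word_vectors <- function(path, vocab, dim, seed = 1L) {
  stopifnot(inherits(vocab, "capstm_vocab"))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1L) stop("empty vector file", call. = FALSE)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(header) != 2L) stop("malformed word2vec header", call. = FALSE)
  fdim <- as.integer(header[[2L]])
  if (is.na(fdim) || fdim != dim) {
    stop("vector file declares dim ", header[[2L]], ", requested ", dim,
         call. = FALSE)
  }
  tokens <- attr(vocab, "tokens")
  V <- length(tokens)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tab <- matrix(stats::runif(V * dim, -0.05, 0.05), V, dim)
  for (i in seq_along(lines)[-1L]) {
    if (!nzchar(trimws(lines[[i]]))) next
    parts <- strsplit(lines[[i]], " ", fixed = TRUE)[[1L]]
    parts <- parts[nzchar(parts)]
    if (length(parts) != dim + 1L) {
      stop("malformed vector line ", i, ": expected ", dim + 1L,
           " fields, got ", length(parts), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (anyNA(vals)) stop("malformed vector line ", i, call. = FALSE)
    j <- unname(vocab[parts[[1L]]])
    if (!is.na(j)) tab[j + 1L, ] <- vals
  }
  tab[1L, ] <- 0 # padding row
  tab
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
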