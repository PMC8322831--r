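#' Attention matrix for one question pair
#'
#' Runs a fitted model on a single pair and extracts the normalized
#' attention weights of the representation layer: rows are the tokens of
#' `text_a`, columns the tokens of `text_b`, and each row sums to 1 over
#' the real (unpadded) columns in softmax mode. Useful to inspect which
#' tokens of one question the model aligns with the other.
#'
#' @param model A fitted `capstm_model` trained with `use_attention = TRUE`.
#' @param text_a,text_b The two question strings.
#' @return A `capstm_attention` object: list with `weights` (len_a x len_b
#'   matrix, dimnames = tokens), `tokens_a`, `tokens_b`, `probability`.
#' @export
capstm_attention <- function(model, text_a, text_b) {
  stopifnot(inherits(model, "capstm_model"))
  if (!model$config$use_attention) {
    stop("this model was trained without attention (w/o-attention ablation); ",
         "no attention matrix exists", call. = FALSE)
  }
  pair <- tibble::tibble(pair_id = "att", text_a = text_a, text_b = text_b)
  enc <- encode_batch(pair, model$vocab, model$config$max_len)
  fwd <- capstm_forward(model$params, enc, model$config,
                        return_attention = TRUE)
  toks_a <- tokenize_text(text_a, attr(model$vocab, "mode"))[[1L]]
  toks_b <- tokenize_text(text_b, attr(model$vocab, "mode"))[[1L]]
  la <- min(length(toks_a), model$config$max_len)
  lb <- min(length(toks_b), model$config$max_len)
  w <- fwd$attention[[1L]][seq_len(la), seq_len(lb), drop = FALSE]
  dimnames(w) <- list(toks_a[seq_len(la)], toks_b[seq_len(lb)])
  structure(
    list(weights = w, tokens_a = toks_a[seq_len(la)],
         tokens_b = toks_b[seq_len(lb)], probability = fwd$prob[1L]),
    class = "capstm_attention"
  )
}

#' @export
print.capstm_attention <- function(x, ...) {
  cat(sprintf("<capstm_attention> %d x %d tokens, match probability %.3f\n",
              nrow(x$weights), ncol(x$weights), x$probability))
  print(round(x$weights, 3))
  invisible(x)
}

#' Write an attention matrix as TSV
#'
#' The header row holds the tokens of `text_b`; the first column holds the
#' tokens of `text_a`; cells are the normalized weights.
#'
#' @param att A `capstm_attention`.
#' @param path Output path.
#' @export
write_attention <- function(att, path) {
  stopifnot(inherits(att, "capstm_attention"))
  header <- paste(c("", att$tokens_b), collapse = "\t")
  rows <- vapply(seq_along(att$tokens_a), function(k) {
    paste(c(att$tokens_a[[k]],
            format(att$weights[k, ], digits = 8, scientific = FALSE)),
          collapse = "\t")
  }, "")
  writeLines(c(header, rows), path, useBytes = FALSE)
  invisible(path)
}

#' Tidy an attention matrix into long form
#'
#' @param x A `capstm_attention`.
#' @param ... Unused.
#' @return Tibble with `pos_a`, `pos_b`, `token_a`, `token_b`, `weight`.
#' @method tidy capstm_attention
#' @export
tidy.capstm_attention <- function(x, ...) {
  la <- nrow(x$weights); lb <- ncol(x$weights)
  tibble::tibble(
    pos_a = rep(seq_len(la), lb),
    pos_b = rep(seq_len(lb), each = la),
    token_a = rep(x$tokens_a, lb),
    token_b = rep(x$tokens_b, each = la),
    weight = as.vector(x$weights)
  )
}

#' Heatmap of an attention matrix
#'
#' @param object A `capstm_attention`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot capstm_attention
#' @export
autoplot.capstm_attention <- function(object, ...) {
  df <- tidy.capstm_attention(object)
  df$token_a <- factor(paste0(df$pos_a, ":", df$token_a),
                       levels = unique(paste0(df$pos_a, ":", df$token_a)))
  df$token_b <- factor(paste0(df$pos_b, ":", df$token_b),
                       levels = unique(paste0(df$pos_b, ":", df$token_b)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$token_b, y = .data$token_a,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "question B tokens", y = "question A tokens",
                  fill = "weight",
                  title = "Attention weights (rows sum to 1)") +
    ggplot2::theme_minimal()
}
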