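#' Default English stopword list
#'
#' A standard list of high-frequency English function words shipped with the
#' package (one word per line in `inst/extdata/stopwords_en.txt`) so that
#' cleaning is reproducible bit-for-bit. Stopword filtering applies to
#' running-text tokens only, never to hashtags.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "dealerscan",
                      mustWork = TRUE)
  readLines(path, warn = FALSE)
}

#' Clean a caption into tokens
#'
#' Implements the cleaning step of the processing pipeline: lowercase,
#' strip hyperlinks, delete every character outside the whitelist
#' `[a-z0-9#]` plus whitespace (so emoji, punctuation and other special
#' characters vanish), split on whitespace, and drop stopwords. The `#`
#' character is deliberately kept, but only as a token-leading hashtag
#' marker; interior `#` characters are deleted.
#'
#' @param caption A caption string (may be empty).
#' @param stopwords Character vector of stopwords to drop
#'   (non-hashtag tokens only).
#' @return Character vector of cleaned tokens, in caption order. Hashtag
#'   tokens keep their leading `#`.
#' @examples
#' clean_text("Order NOW!! http://x.co #Xanax \U0001F600",
#'            stopwords = "now")
#' @export
clean_text <- function(caption, stopwords = default_stopwords()) {
  if (is.na(caption) || !nzchar(caption)) return(character())
  x <- tolower(caption)
  x <- gsub("(https?://|www\\.)[^[:space:]]+", " ", x)
  x <- gsub("[^a-z0-9#[:space:]]+", "", x)
  toks <- strsplit(x, "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) return(character())
  lead <- startsWith(toks, "#")
  body <- gsub("#", "", toks, fixed = TRUE)
  keep <- nzchar(body)
  toks <- ifelse(lead, paste0("#", body), body)[keep]
  lead <- lead[keep]
  drop <- !lead & toks %in% stopwords
  toks[!drop]
}

#' Separate cleaned tokens into text part and hashtag part
#'
#' Tokens carrying the leading `#` marker go to the hashtag part with the
#' marker stripped (hashtags and plain words share one dictionary); all
#' other tokens go to the text part. Both parts preserve the original
#' relative order, and the two parts partition the input exactly.
#'
#' @param tokens Output of [clean_text()].
#' @return A list with elements `text` and `hashtags` (both character
#'   vectors, hashtags without the `#`).
#' @export
split_text_hashtags <- function(tokens) {
  is_tag <- startsWith(tokens, "#")
  list(text = tokens[!is_tag], hashtags = sub("^#", "", tokens[is_tag]))
}

#' Clean a corpus of raw posts
#'
#' Applies [clean_text()] and [split_text_hashtags()] to every caption and
#' attaches labels when supplied, yielding the cleaned-post records that
#' the vocabulary builder, the dataset-variant constructor and the
#' characterization counters consume.
#'
#' @param posts List of [raw_post()] objects.
#' @param labels Optional data.frame `post_id,label` (see [read_labels()]).
#' @param stopwords Stopword vector, see [default_stopwords()].
#' @return A list of `clean_post` records: `post_id`, `text_tokens`,
#'   `hashtag_tokens` (no `#`), `label` (`NA` if unknown).
#' @export
clean_posts <- function(posts, labels = NULL,
                        stopwords = default_stopwords()) {
  lab_map <- NULL
  if (!is.null(labels)) {
    lab_map <- stats::setNames(as.integer(labels$label), labels$post_id)
  }
  lapply(posts, function(p) {
    parts <- split_text_hashtags(clean_text(p$caption, stopwords))
    structure(list(
      post_id = p$post_id,
      text_tokens = parts$text,
      hashtag_tokens = parts$hashtags,
      label = if (is.null(lab_map)) NA_integer_ else
        unname(lab_map[p$post_id])
    ), class = "clean_post")
  })
}

#' Build the token dictionary of a cleaned corpus
#'
#' Every distinct token across the text and hashtag parts receives a
#' positive integer index in first-occurrence order (text part before
#' hashtag part within each post). Index 0 is reserved for sequence
#' padding and index `size + 1` is the unknown-token index used when
#' encoding tokens unseen at build time.
#'
#' @param clean_corpus List of cleaned posts from [clean_posts()].
#' @return An object of class `vocabulary`: list with `word_to_index`
#'   (named integer vector), `size`, and `unknown_index = size + 1`.
#' @export
build_vocabulary <- function(clean_corpus) {
  if (length(clean_corpus) == 0L) stop("cannot build vocabulary: empty corpus")
  toks <- unlist(lapply(clean_corpus, function(p) {
    c(p$text_tokens, p$hashtag_tokens)
  }), use.names = FALSE)
  words <- unique(toks)
  if (length(words) == 0L) stop("cannot build vocabulary: no tokens")
  structure(
    list(word_to_index = stats::setNames(seq_along(words), words),
         size = length(words), unknown_index = length(words) + 1L),
    class = "vocabulary"
  )
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary of %d tokens (+1 unknown index)>\n", x$size))
  invisible(x)
}

#' Write / read a vocabulary as a two-column CSV
#'
#' @param vocab A [build_vocabulary()] object.
#' @param path CSV path with header `token,index`.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.csv(
    data.frame(token = names(vocab$word_to_index),
               index = unname(vocab$word_to_index)),
    path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "integer"))
  structure(
    list(word_to_index = stats::setNames(df$index, df$token),
         size = nrow(df), unknown_index = nrow(df) + 1L),
    class = "vocabulary"
  )
}

#' Encode tokens as a fixed-length index vector
#'
#' The first `min(length(tokens), length)` positions hold dictionary
#' indices (unknown tokens map to the reserved unknown index); sequences
#' longer than `length` are truncated keeping the earliest tokens, and
#' shorter sequences are padded with 0.
#'
#' @param tokens Character vector of tokens.
#' @param vocab A `vocabulary`.
#' @param length Fixed output length (positive integer).
#' @return Integer vector of exactly `length` entries.
#' @export
encode <- function(tokens, vocab, length) {
  stopifnot(length >= 1L)
  out <- integer(length)
  n <- min(base::length(tokens), length)
  if (n > 0L) {
    idx <- unname(vocab$word_to_index[tokens[seq_len(n)]])
    idx[is.na(idx)] <- vocab$unknown_index
    out[seq_len(n)] <- idx
  }
  out
}

#' Decode an index vector back to tokens
#'
#' Inverse of [encode()] up to truncation: padding (0) stops the decode,
#' the unknown index decodes to `"<unk>"`.
#'
#' @inheritParams encode
#' @param indices Integer vector produced by [encode()].
#' @export
decode <- function(indices, vocab) {
  words <- names(vocab$word_to_index)
  indices <- indices[indices != 0L]
  vapply(indices, function(i) {
    if (i == vocab$unknown_index) "<unk>" else words[[i]]
  }, character(1))
}

variant_key <- function(post, name) {
  toks <- switch(name,
    text_with_hashtags = c(post$text_tokens,
                           paste0("#", post$hashtag_tokens, recycle0 = TRUE)),
    hashtags_only = post$hashtag_tokens,
    text_without_hashtags = post$text_tokens)
  paste(toks, collapse = "\x1f")
}

#' Materialize the three text/hashtag ablation variants
#'
#' From a cleaned, labeled corpus builds the three dataset variants used
#' throughout evaluation: `text_with_hashtags` (all tokens),
#' `hashtags_only` (hashtag part only; posts with no hashtags dropped) and
#' `text_without_hashtags` (text part only; posts with no remaining words
#' dropped). After restriction each variant is deduplicated on its own
#' cleaned-token representation, first occurrence kept, so every remaining
#' example has a distinct pattern.
#'
#' @param clean_corpus List of cleaned posts (with labels) from
#'   [clean_posts()].
#' @return A named list of three `dataset_variant` objects, each a list
#'   with `name` and `posts` (the restricted, deduplicated clean posts).
#' @export
make_variants <- function(clean_corpus) {
  variants <- lapply(c(text_with_hashtags = "text_with_hashtags",
                       hashtags_only = "hashtags_only",
                       text_without_hashtags = "text_without_hashtags"),
                     function(name) {
    restricted <- lapply(clean_corpus, function(p) {
      if (name == "hashtags_only") p$text_tokens <- character()
      if (name == "text_without_hashtags") p$hashtag_tokens <- character()
      p
    })
    n_tok <- vapply(restricted, function(p) {
      length(p$text_tokens) + length(p$hashtag_tokens)
    }, integer(1))
    restricted <- restricted[n_tok > 0L]
    keys <- vapply(restricted, variant_key, character(1), name = name)
    structure(list(name = name, posts = restricted[!duplicated(keys)]),
              class = "dataset_variant")
  })
  variants
}

#' @export
print.dataset_variant <- function(x, ...) {
  cat(sprintf("<dataset_variant '%s': %d posts>\n", x$name, length(x$posts)))
  invisible(x)
}

#' Encode a dataset variant into fixed-length example matrices
#'
#' Produces the index-matrix representation the classifiers consume: a
#' text matrix of `l_text` columns and a hashtag matrix of `l_hash`
#' columns (rows are examples, trailing columns 0-padded). Variants that
#' exclude a part yield an all-zero matrix for that part.
#'
#' @param variant A `dataset_variant` from [make_variants()].
#' @param vocab A `vocabulary`; per the default evaluation protocol it is
#'   built on training folds only.
#' @param config A [model_config()] supplying `l_text` and `l_hash`.
#' @return List of class `encoded_examples`: integer matrices `text`
#'   (n x l_text) and `hash` (n x l_hash), integer `label`, character
#'   `post_id`.
#' @export
encode_variant <- function(variant, vocab, config = model_config()) {
  posts <- variant$posts
  n <- length(posts)
  text <- matrix(0L, n, config$l_text)
  hash <- matrix(0L, n, config$l_hash)
  for (i in seq_len(n)) {
    text[i, ] <- encode(posts[[i]]$text_tokens, vocab, config$l_text)
    hash[i, ] <- encode(posts[[i]]$hashtag_tokens, vocab, config$l_hash)
  }
  structure(list(
    text = text, hash = hash,
    label = vapply(posts, function(p) as.integer(p$label), integer(1)),
    post_id = vapply(posts, function(p) p$post_id, character(1))
  ), class = "encoded_examples")
}

#' Write / read a cleaned-corpus cache
#'
#' JSON Lines cache of cleaned posts (`post_id`, `text_tokens`,
#' `hashtag_tokens`, `label`) so downstream stages can skip re-cleaning.
#'
#' @param clean_corpus List of cleaned posts.
#' @param path JSON Lines path.
#' @export
write_clean_posts <- function(clean_corpus, path) {
  lines <- vapply(clean_corpus, function(p) {
    jsonlite::toJSON(list(post_id = p$post_id,
                          text_tokens = p$text_tokens,
                          hashtag_tokens = p$hashtag_tokens,
                          label = if (is.na(p$label)) NULL else p$label),
                     auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_clean_posts
#' @export
read_clean_posts <- function(path) {
  lapply(readLines(path, warn = FALSE), function(line) {
    rec <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    structure(list(
      post_id = rec$post_id,
      text_tokens = as.character(rec$text_tokens),
      hashtag_tokens = as.character(rec$hashtag_tokens),
      label = if (is.null(rec$label)) NA_integer_ else as.integer(rec$label)
    ), class = "clean_post")
  })
}
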