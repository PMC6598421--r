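# Shared fixture builders. Everything is generated in code at test time.

tiny_post <- function(id, caption = "hello #world", user = "u1",
                      ts = "2020-06-01T10:00:00Z",
                      comments = NULL) {
  raw_post(id, user, ts, caption,
           comments = comments %||% data.frame(user_id = character(),
                                               text = character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A random corpus with awkward captions (emoji, links, punctuation) for
# round-trip and property tests.
random_corpus <- function(n, seed) {
  pieces <- c("Order NOW!!", "#Xanax", "#2mgXanax", "hello world",
              "http://example.com/x?y=1", "\U0001F600\U0001F48A",
              "wickr me: pharmking", "café résumé",
              "123-456-7890", "@someone", "#", "a#b", "", "the and of")
  withr_seed <- function(code) code
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cap <- paste(sample(pieces, sample(0:6, 1), replace = TRUE),
                 collapse = " ")
    ncom <- sample(0:2, 1)
    comments <- data.frame(
      user_id = sprintf("c%d", seq_len(ncom)),
      text = sample(c("nice", "how much for 10?", "great photo"), ncom,
                    replace = TRUE))
    raw_post(sprintf("p%04d", i), sprintf("u%02d", sample(20, 1)),
             as.POSIXct("2020-01-01", tz = "UTC") + i * 3600, cap,
             comments = comments,
             image_refs = if (i %% 3 == 0) sprintf("img%d", i) else
               character())
  })
}

# Small labeled clean corpus with a planted separable signal, for fast
# classifier tests: positives contain "order" + "delivery", negatives
# never do.
separable_clean_corpus <- function(n, seed, p_pos = 0.3) {
  set.seed(seed)
  bgwords <- c("beach", "sunset", "coffee", "guitar", "painting", "travel",
               "workout", "recipe", "vinyl", "canvas")
  lapply(seq_len(n), function(i) {
    pos <- i <= round(p_pos * n)
    toks <- sample(bgwords, 5)
    if (pos) toks <- c("order", "delivery", toks[1:3], sample(99:999, 1))
    tags <- sample(c("love", "beach", "art", "fun", "music", "sun", "dog",
                     "cat"), sample(0:2, 1))
    structure(list(post_id = sprintf("s%04d", i),
                   text_tokens = as.character(toks),
                   hashtag_tokens = tags,
                   label = as.integer(pos)),
              class = "clean_post")
  })
}

encode_clean <- function(posts, vocab, cfg) {
  encode_variant(structure(list(name = "text_with_hashtags", posts = posts),
                           class = "dataset_variant"), vocab, cfg)
}
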