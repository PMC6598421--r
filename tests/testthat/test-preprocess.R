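test_that("cleaning lowercases, strips links/specials and keeps hashtags", {
  expect_equal(clean_text("Order NOW!! http://x.co #Xanax \U0001F600",
                          stopwords = "now"),
               c("order", "#xanax"))
  expect_equal(clean_text(""), character())
  expect_equal(clean_text("   "), character())
  # '#' survives only as a token-leading marker
  expect_equal(clean_text("a#b ##tag #", stopwords = character()),
               c("ab", "#tag"))
  # stopwords are dropped from text but never from hashtags
  expect_equal(clean_text("the #the", stopwords = "the"), "#the")
})

test_that("cleaned output never leaves the character whitelist", {
  set.seed(99)
  pool <- c(letters, LETTERS, 0:9, "#", "@", "!", ".", ",", "?", " ",
            "\U0001F600", "é", "中", "-", "_", "/", ":")
  for (i in 1:200) {
    s <- paste(sample(pool, sample(0:40, 1), replace = TRUE), collapse = "")
    toks <- clean_text(s, stopwords = character())
    if (length(toks) > 0) {
      expect_true(all(grepl("^#?[a-z0-9]+$", toks)), info = s)
    }
  }
})

test_that("text/hashtag separation partitions tokens and keeps order", {
  out <- split_text_hashtags(c("order", "#xanax", "fast", "#2mgxanax"))
  expect_equal(out$text, c("order", "fast"))
  expect_equal(out$hashtags, c("xanax", "2mgxanax"))
  out2 <- split_text_hashtags(c("#a", "#b"))
  expect_equal(out2$text, character())
  expect_equal(out2$hashtags, c("a", "b"))
  # conservation over random token sequences
  set.seed(5)
  for (i in 1:50) {
    toks <- sample(c("w1", "w2", "#h1", "#h2", "w3"), sample(0:10, 1),
                   replace = TRUE)
    parts <- split_text_hashtags(toks)
    expect_equal(length(parts$text) + length(parts$hashtags), length(toks))
    expect_equal(sort(c(parts$text,
                        paste0("#", parts$hashtags, recycle0 = TRUE))),
                 sort(toks))
  }
})

test_that("vocabulary indexes distinct tokens from 1 with 0 reserved", {
  cp <- list(structure(list(post_id = "1", text_tokens = c("a", "b", "a"),
                            hashtag_tokens = character(), label = NA_integer_),
                       class = "clean_post"))
  v <- build_vocabulary(cp)
  expect_equal(v$size, 2)
  expect_equal(unname(v$word_to_index[c("a", "b")]), c(1L, 2L))
  expect_equal(sort(unname(v$word_to_index)), seq_len(v$size))
  expect_false(0L %in% v$word_to_index)
  expect_equal(v$unknown_index, 3L)
  expect_error(build_vocabulary(list()), "empty")
})

test_that("vocabulary building is deterministic and CSV round trips", {
  posts <- clean_posts(random_corpus(30, seed = 2))
  v1 <- build_vocabulary(posts)
  v2 <- build_vocabulary(posts)
  expect_identical(v1, v2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_vocabulary(v1, path)
  v3 <- read_vocabulary(path)
  expect_equal(v3$word_to_index, v1$word_to_index)
  expect_equal(v3$size, v1$size)
})

test_that("encoding is length-exact, zero-padded and truncates early tokens", {
  cp <- list(structure(list(post_id = "1",
                            text_tokens = c("a", "b", "c"),
                            hashtag_tokens = character(),
                            label = NA_integer_), class = "clean_post"))
  v <- build_vocabulary(cp)
  e <- encode(c("a", "b", "c"), v, 50)
  expect_length(e, 50)
  expect_equal(sum(e != 0), 3)
  expect_equal(e[4:50], rep(0L, 47))
  long <- rep(c("a", "b"), 30)
  e2 <- encode(long, v, 50)
  expect_length(e2, 50)
  expect_equal(e2, unname(v$word_to_index[long[1:50]]))
  expect_equal(encode(character(), v, 5), rep(0L, 5))
  # unknown tokens hit the reserved index; decode inverts known prefixes
  expect_equal(encode("zzz", v, 2), c(v$unknown_index, 0L))
  expect_equal(decode(encode(c("a", "zzz", "b"), v, 5), v),
               c("a", "<unk>", "b"))
})

test_that("variant construction restricts, drops empties and deduplicates", {
  mk <- function(id, text, tags, label = 0L) {
    structure(list(post_id = id, text_tokens = text, hashtag_tokens = tags,
                   label = label), class = "clean_post")
  }
  corpus <- list(
    mk("t1", c("order", "fast"), character(), 1L),  # text only
    mk("t2", character(), c("xanax"), 1L),          # hashtags only
    mk("t3", c("beach", "day"), c("love")),
    mk("t4", c("beach", "day"), c("sun")),          # dup after tag removal
    mk("t5", c("order", "fast"), c("xanax"), 1L)
  )
  vars <- make_variants(corpus)
  ids <- function(v) vapply(v$posts, `[[`, "", "post_id")
  expect_false("t1" %in% ids(vars$hashtags_only))
  expect_true("t1" %in% ids(vars$text_without_hashtags))
  expect_false("t2" %in% ids(vars$text_without_hashtags))
  expect_true("t2" %in% ids(vars$hashtags_only))
  # t3/t4 collapse in text_without_hashtags (same text after tag removal)
  expect_true("t3" %in% ids(vars$text_without_hashtags))
  expect_false("t4" %in% ids(vars$text_without_hashtags))
  # but stay distinct where hashtags differ
  expect_true(all(c("t3", "t4") %in% ids(vars$text_with_hashtags)))

  # restriction property on generated corpora
  for (seed in 1:2) {
    cc <- clean_posts(random_corpus(60, seed))
    vv <- make_variants(cc)
    expect_lte(length(vv$hashtags_only$posts),
               length(vv$text_with_hashtags$posts))
    expect_lte(length(vv$text_without_hashtags$posts),
               length(vv$text_with_hashtags$posts))
  }
})

test_that("encoded variants have exact shapes and honor restrictions", {
  cfg <- model_config(l_text = 10, l_hash = 4, desk_scale = TRUE)
  corpus <- separable_clean_corpus(30, seed = 3)
  vars <- make_variants(corpus)
  v <- vars$hashtags_only
  vocab <- build_vocabulary(v$posts)
  enc <- encode_variant(v, vocab, cfg)
  expect_equal(dim(enc$text), c(length(v$posts), 10))
  expect_equal(dim(enc$hash), c(length(v$posts), 4))
  expect_true(all(enc$text == 0))  # restricted away
  expect_true(any(enc$hash != 0))
})

test_that("cleaned-corpus cache round trips", {
  cc <- clean_posts(random_corpus(15, seed = 4),
                    labels = data.frame(post_id = sprintf("p%04d", 1:15),
                                        label = rep(c(0L, 1L), length.out = 15)))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_clean_posts(cc, path)
  back <- read_clean_posts(path)
  expect_equal(length(back), length(cc))
  for (i in seq_along(cc)) {
    expect_equal(back[[i]]$text_tokens, cc[[i]]$text_tokens)
    expect_equal(back[[i]]$hashtag_tokens, cc[[i]]$hashtag_tokens)
    expect_equal(back[[i]]$label, cc[[i]]$label)
  }
})
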