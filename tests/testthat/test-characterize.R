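mk_clean <- function(id, tags, label = 1L) {
  structure(list(post_id = id, text_tokens = character(),
                 hashtag_tokens = tags, label = label),
            class = "clean_post")
}

test_that("drug counting uses union semantics for per-drug totals", {
  lex <- default_drug_lexicon()
  posts <- list(mk_clean("a", c("xanax", "2mgxanax")))
  out <- count_drug_hashtags(posts, lex)
  cx <- out$counts[out$counts$drug == "xanax", ]
  expect_equal(cx$posts[cx$hashtag == "xanax"], 1)
  expect_equal(cx$posts[cx$hashtag == "2mgxanax"], 1)
  # union: one distinct post, not two
  expect_equal(out$totals$posts[out$totals$drug == "xanax"], 1)

  empty <- count_drug_hashtags(list(), lex)
  expect_true(all(empty$counts$posts == 0))
  expect_true(all(empty$totals$posts == 0))
})

test_that("per-drug totals equal a brute-force set union on random corpora", {
  lex <- default_drug_lexicon()
  drug_rows <- lex[lex$category != "sale_or_shipping", ]
  set.seed(31)
  for (rep in 1:5) {
    posts <- lapply(1:40, function(i) {
      mk_clean(sprintf("p%d", i),
               sample(c(drug_rows$hashtag, "love", "beach"),
                      sample(0:4, 1)))
    })
    out <- count_drug_hashtags(posts, lex)
    for (d in unique(drug_rows$drug)) {
      vs <- drug_rows$hashtag[drug_rows$drug == d]
      matched <- unique(unlist(lapply(posts, function(p) {
        if (length(intersect(p$hashtag_tokens, vs)) > 0) p$post_id
      })))
      expect_equal(out$totals$posts[out$totals$drug == d], length(matched))
      # union never exceeds the per-hashtag sum
      expect_lte(out$totals$posts[out$totals$drug == d],
                 sum(out$counts$posts[out$counts$drug == d]))
    }
  }
})

test_that("contact extraction finds emails, phones and app handles", {
  p <- tiny_post("x", "wickr me: pharmking")
  expect_equal(extract_contacts(p)$channels, "app:wickr")
  expect_equal(extract_contacts(tiny_post("x", "great photo!"))$channels,
               character())
  expect_equal(extract_contacts(
    tiny_post("x", "email dealz99@gmail.com now"))$channels, "email")
  expect_equal(extract_contacts(
    tiny_post("x", "call or text +1 424 555 0133"))$channels, "phone")
  expect_equal(extract_contacts(
    tiny_post("x", "telegram @pharmaplug for menu"))$channels,
    "app:telegram")
  expect_equal(extract_contacts(tiny_post("x", "kik pillking77"))$channels,
               "app:kik")
  # dosage digits never count as a phone; app word without a handle is not
  # a channel
  expect_equal(extract_contacts(
    tiny_post("x", "took 2mg then 5mg #oxy80s"))$channels, character())
  expect_equal(extract_contacts(
    tiny_post("x", "join our telegram group tonight"))$channels,
    character())
  # comments are scanned too, and every channel is backed by a match
  pc <- tiny_post("x", "nice pic",
                  comments = data.frame(user_id = "u9",
                                        text = "wickr: plugman404"))
  rec <- extract_contacts(pc)
  expect_equal(rec$channels, "app:wickr")
  expect_gt(length(rec$matches), 0)
})

test_that("transaction detection needs dealer label, contact and a buyer", {
  buyer <- data.frame(user_id = "buyer1", text = "how much for 30?")
  dealer <- tiny_post("d", "order now wickr me plugman404", user = "seller",
                      comments = buyer)
  expect_true(detect_transactions(dealer, 1))
  expect_false(detect_transactions(dealer, 0))          # not dealer-labeled
  no_comments <- tiny_post("d", "order now wickr me plugman404",
                           user = "seller")
  expect_false(detect_transactions(no_comments, 1))
  no_contact <- tiny_post("d", "order now fast delivery", user = "seller",
                          comments = buyer)
  expect_false(detect_transactions(no_contact, 1))
  self_comment <- tiny_post("d", "order now wickr me plugman404",
                            user = "seller",
                            comments = data.frame(user_id = "seller",
                                                  text = "how much for 30?"))
  expect_false(detect_transactions(self_comment, 1))
  innocuous <- tiny_post("d", "order now wickr me plugman404",
                         user = "seller",
                         comments = data.frame(user_id = "u2",
                                               text = "great photo"))
  expect_false(detect_transactions(innocuous, 1))
})

test_that("contact and transaction extraction recover the planted truth", {
  out <- generate_corpus(synthetic_config(n_posts = 1500, seed = 17))
  truth <- out$truth
  recs <- lapply(out$posts, extract_contacts)
  pred_has <- vapply(recs, function(r) length(r$channels) > 0, logical(1))
  true_has <- !is.na(truth$planted_contact)
  precision <- sum(pred_has & true_has) / sum(pred_has)
  recall <- sum(pred_has & true_has) / sum(true_has)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
  # the planted channel kind is among the extracted ones
  kinds_ok <- mapply(function(r, k) is.na(k) || k %in% r$channels,
                     recs, truth$planted_contact)
  expect_gte(mean(kinds_ok[true_has]), 0.95)
  flags <- mapply(detect_transactions, out$posts, out$labels$label)
  expect_gte(sum(flags & truth$planted_transaction) /
               sum(truth$planted_transaction), 0.9)
})

test_that("the characterization report restricts to detected posts", {
  out <- generate_corpus(synthetic_config(n_posts = 400, seed = 19))
  rep <- summarize_detected(out$posts, out$labels)
  expect_equal(rep$n_detected, sum(out$labels$label))
  expect_lte(rep$n_unique_users, rep$n_detected)
  # percentage arithmetic recomputation
  expect_equal(rep$drug_totals$pct,
               100 * rep$drug_totals$posts / rep$n_detected)
  expect_true(all(rep$contact_channels$posts <= rep$n_detected))

  # zero predicted positives: explicit zero rows, not an error
  none <- out$labels
  none$label <- 0L
  rep0 <- summarize_detected(out$posts, none)
  expect_equal(rep0$n_detected, 0)
  expect_true(all(rep0$drug_totals$posts == 0))
  expect_equal(rep0$n_transactions, 0)
  expect_error(summarize_detected(out$posts, none[-1, ]), "cover")

  dir <- withr::local_tempdir()
  write_characterization(rep, dir)
  expect_true(file.exists(file.path(dir, "summary.txt")))
  expect_true(file.exists(file.path(dir, "drug_totals.csv")))
})
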