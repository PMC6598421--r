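#' Default drug-hashtag lexicon
#'
#' The hashtag taxonomy shipped with the package
#' (`inst/extdata/drug_lexicon.csv`): four drug groups (xanax, oxycodone,
#' lsd, mdma) with their hashtag variants tagged as `drug_name`,
#' `codeword_misspelling` (e.g. "zanax", "oxicotin"), `codeword_extended`
#' (e.g. "2mgxanax", "mdmaforsale") or `codeword_street` (e.g.
#' "whitebar"), plus generic `sale_or_shipping` keywords ("forsale",
#' "shipping"). Users may supply their own file via [read_lexicon()].
#'
#' @return A data.frame with columns `drug`, `hashtag`, `category`.
#' @export
default_drug_lexicon <- function() {
  read_lexicon(system.file("extdata", "drug_lexicon.csv",
                           package = "dealerscan", mustWork = TRUE))
}

default_promo_phrases <- function() {
  c("order now for quick delivery",
    "interested in placing order without prescription",
    "fast and discreet overnight shipping",
    "dm me to place your order",
    "top quality available for sale",
    "no prescription needed order today",
    "message me for price list and menu",
    "wholesale and retail discreet packaging",
    "quality meds delivered right to your door",
    "serious buyers only fast delivery guaranteed")
}

default_background_topics <- function() {
  list(
    fitness = c("gym", "workout", "fitness", "gains", "protein", "lifting",
                "cardio", "sweat", "muscle", "training", "reps", "squat",
                "running", "morning", "routine", "stronger"),
    travel = c("travel", "wanderlust", "beach", "sunset", "mountains",
               "adventure", "passport", "flight", "island", "hiking",
               "views", "vacation", "explore", "city", "roadtrip"),
    food = c("coffee", "brunch", "recipe", "homemade", "dinner", "foodie",
             "delicious", "baking", "chocolate", "kitchen", "vegan",
             "tasty", "lunch", "flavors", "fresh"),
    music = c("studio", "mixtape", "beats", "vinyl", "concert", "festival",
              "guitar", "drums", "melody", "playlist", "singer", "band",
              "stage", "tour", "rehearsal"),
    art = c("painting", "sketch", "canvas", "gallery", "artist", "portrait",
            "colors", "creative", "drawing", "design", "exhibition",
            "print", "palette", "mural"),
    smallbiz = c("shop", "handmade", "boutique", "candles", "jewelry",
                 "restock", "smallbusiness", "sale", "discount", "customer",
                 "package", "thanks", "support", "order", "shipping"),
    recovery = c("recovery", "sober", "awareness", "addiction", "clean",
                 "support", "struggle", "healing", "hope", "journey",
                 "community", "oneday", "grateful")
  )
}

default_stray_hashtags <- function() {
  c("love", "instagood", "photooftheday", "happy", "cute", "follow",
    "summer", "friends", "smile", "fun", "life", "vibes")
}

buy_comment_templates <- function() {
  c("how much for %d?", "whats the price for %d", "can i order %d",
    "do you ship to my state? i want %d", "i want to buy %d",
    "price for %d please", "still available? how much for %d",
    "dm me the price i need %d")
}

innocuous_comments <- function() {
  c("great photo", "love this", "so cool", "amazing shot", "nice one",
    "awesome", "beautiful", "goals", "wow", "incredible")
}

#' Configuration for the synthetic corpus generator
#'
#' Fixes every statistical knob of the generated study corpus: the dealer
#' prevalence, the drug-hashtag lexicon, the sale-promotion phrase pool,
#' contact-channel mix, background topic pools, and the seed. Identical
#' configurations produce byte-identical corpora.
#'
#' @param n_posts Number of posts to generate.
#' @param dealer_fraction Fraction of dealer posts; the dealer count is
#'   exactly `round(n_posts * dealer_fraction)`. Default 0.096, the
#'   prevalence regime of a low-signal infoveillance corpus
#'   (roughly 1 dealer post in 10).
#' @param seed Integer seed; the corpus is a pure function of the config.
#' @param drug_lexicon Data.frame `drug,hashtag,category`, see
#'   [default_drug_lexicon()].
#' @param promo_phrases Character pool of sale-promotion phrases.
#' @param background_topics Named list of background token pools.
#' @param stray_hashtags Pool of generic decorative hashtags.
#' @param contact_prob Probability a dealer post carries contact
#'   information (default 0.9).
#' @param buyer_comment_prob Probability a dealer post receives a seeded
#'   buy-intent comment from another user (default 0.35).
#' @param hard_negative_prob Probability a background post reuses drug
#'   hashtags without dealer syntax (default 0.25) -- the hard negatives
#'   that make classification non-trivial.
#' @param noise Per-post probability of stray decorative hashtags
#'   (default 0.5).
#' @param time_span_days Posts are timestamped uniformly over this many
#'   days before `snapshot_time` (default 90).
#' @param snapshot_time Fixed reference instant for timestamps.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_posts, dealer_fraction = 0.096, seed = 1L,
                             drug_lexicon = default_drug_lexicon(),
                             promo_phrases = default_promo_phrases(),
                             background_topics = default_background_topics(),
                             stray_hashtags = default_stray_hashtags(),
                             contact_prob = 0.9,
                             buyer_comment_prob = 0.35,
                             hard_negative_prob = 0.25,
                             noise = 0.5,
                             time_span_days = 90,
                             snapshot_time = as.POSIXct("2020-06-30 12:00:00",
                                                        tz = "UTC")) {
  stopifnot(n_posts >= 1, dealer_fraction > 0, dealer_fraction < 1,
            nrow(drug_lexicon) > 0, length(promo_phrases) > 0,
            length(background_topics) > 0,
            all(lengths(background_topics) > 0),
            length(stray_hashtags) > 0,
            contact_prob >= 0, contact_prob <= 1)
  structure(list(
    n_posts = as.integer(n_posts), dealer_fraction = dealer_fraction,
    seed = as.integer(seed), drug_lexicon = drug_lexicon,
    promo_phrases = promo_phrases, background_topics = background_topics,
    stray_hashtags = stray_hashtags, contact_prob = contact_prob,
    buyer_comment_prob = buyer_comment_prob,
    hard_negative_prob = hard_negative_prob, noise = noise,
    time_span_days = time_span_days, snapshot_time = snapshot_time
  ), class = "synthetic_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_handle <- function() {
  stems <- c("pharm", "med", "pill", "plug", "doc", "chem", "supply",
             "candy", "script", "remedy")
  tails <- c("king", "man", "store", "house", "lab", "dealer", "zone",
             "direct", "hub", "line")
  paste0(sample(stems, 1), sample(tails, 1), sample(100:999, 1))
}

rand_phone <- function() {
  paste0("+1 ", sample(200:989, 1), " ", sample(200:999, 1), " ",
         sprintf("%04d", sample(0:9999, 1)))
}

# Draw one contact snippet; returns list(text=, kind=) where kind is one of
# email / phone / app:<name>. App mix loosely follows observed channel
# frequencies (wickr > telegram > kik > whatsapp).
rand_contact <- function() {
  kind <- sample(c("email", "phone", "app"), 1, prob = c(0.18, 0.12, 0.70))
  if (kind == "email") {
    dom <- sample(c("gmail.com", "protonmail.com", "yahoo.com"), 1)
    return(list(text = paste0("email ", rand_handle(), "@", dom),
                kind = "email"))
  }
  if (kind == "phone") {
    return(list(text = paste("call or text", rand_phone()), kind = "phone"))
  }
  app <- sample(c("wickr", "telegram", "kik", "whatsapp"), 1,
                prob = c(0.3623, 0.1995, 0.1832, 0.1530))
  text <- switch(app,
    wickr = sample(c(paste("wickr me", rand_handle()),
                     paste0("wickr: ", rand_handle())), 1),
    telegram = paste0("telegram @", sub("[0-9]+$", "", rand_handle())),
    kik = paste("kik", rand_handle()),
    whatsapp = paste("whatsapp", rand_phone()))
  list(text = text, kind = paste0("app:", app))
}

dealer_caption <- function(config) {
  lex <- config$drug_lexicon
  drug_rows <- lex[lex$category != "sale_or_shipping", ]
  drugs <- sample(unique(drug_rows$drug), sample(1:2, 1))
  tags <- unlist(lapply(drugs, function(d) {
    pool <- drug_rows$hashtag[drug_rows$drug == d]
    sample(pool, min(length(pool), sample(1:3, 1)))
  }))
  promo <- sample(config$promo_phrases, sample(1:2, 1))
  contact <- NULL
  contact_kind <- NA_character_
  if (stats::runif(1) < config$contact_prob) {
    ct <- rand_contact()
    contact <- ct$text
    contact_kind <- ct$kind
  }
  sale_tag <- if (stats::runif(1) < 0.4) {
    paste0("#", sample(lex$hashtag[lex$category == "sale_or_shipping"], 1))
  }
  stray <- if (stats::runif(1) < config$noise) {
    paste0("#", sample(config$stray_hashtags, sample(1:3, 1)))
  }
  caption <- paste(c(promo, contact, paste0("#", tags), sale_tag, stray),
                   collapse = " ")
  list(caption = caption, drug = drugs[[1]], contact_kind = contact_kind,
       has_contact = !is.null(contact))
}

background_caption <- function(config) {
  topic <- sample(names(config$background_topics), 1)
  pool <- config$background_topics[[topic]]
  words <- sample(pool, min(length(pool), sample(6:14, 1)), replace = FALSE)
  hard_neg <- stats::runif(1) < config$hard_negative_prob
  tags <- character()
  if (hard_neg) {
    lex <- config$drug_lexicon
    drug_rows <- lex[lex$category != "sale_or_shipping", ]
    tags <- paste0("#", sample(drug_rows$hashtag, sample(1:2, 1)))
    # hard negatives read like awareness/recovery posts, not sales
    words <- c(words, sample(config$background_topics$recovery %||%
                               c("awareness", "recovery"), 2))
  }
  stray <- if (stats::runif(1) < config$noise) {
    paste0("#", sample(config$stray_hashtags, sample(1:3, 1)))
  }
  list(caption = paste(c(words, tags, stray), collapse = " "),
       hard_neg = hard_neg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

salt_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + salt) %% 2147483629)
}

#' Generate a labeled synthetic post corpus with planted ground truth
#'
#' Emulates the statistical structure of a scraped hashtag-search corpus:
#' dealer posts combine at least one drug hashtag, at least one
#' sale-promotion phrase and (with probability `contact_prob`) one contact
#' snippet, while background posts draw from everyday topic pools and --
#' as hard negatives -- may reuse drug hashtags without dealer syntax. A
#' configurable fraction of dealer posts receives a seeded buy-intent
#' comment from a different user. The dealer count is exact:
#' `round(n_posts * dealer_fraction)`.
#'
#' @param config A [synthetic_config()].
#' @return A list with `posts` (list of [raw_post()]), `labels`
#'   (data.frame `post_id,label`) and `truth` (data.frame
#'   `post_id,label,planted_drug,planted_contact,planted_transaction`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_posts
    n_dealer <- round(n * config$dealer_fraction)
    is_dealer <- rep(FALSE, n)
    if (n_dealer > 0) is_dealer[sample(n, n_dealer)] <- TRUE

    n_dealer_users <- max(1L, round(n_dealer / 4.6))
    dealer_users <- sprintf("dealer%03d", seq_len(n_dealer_users))
    n_bg_users <- max(1L, round((n - n_dealer) / 1.5))
    bg_users <- sprintf("user%05d", seq_len(n_bg_users))

    ts <- config$snapshot_time -
      stats::runif(n, 0, config$time_span_days * 86400)

    posts <- vector("list", n)
    truth <- data.frame(
      post_id = sprintf("post%06d", seq_len(n)),
      label = as.integer(is_dealer),
      planted_drug = NA_character_, planted_contact = NA_character_,
      planted_transaction = FALSE, stringsAsFactors = FALSE
    )
    for (i in seq_len(n)) {
      pid <- truth$post_id[i]
      comments <- empty_comments()
      if (is_dealer[i]) {
        dc <- dealer_caption(config)
        uid <- sample(dealer_users, 1)
        truth$planted_drug[i] <- dc$drug
        if (dc$has_contact) truth$planted_contact[i] <- dc$contact_kind
        if (dc$has_contact &&
            stats::runif(1) < config$buyer_comment_prob) {
          tmpl <- sample(buy_comment_templates(), 1)
          comments <- rbind(comments, data.frame(
            user_id = sample(bg_users, 1),
            text = sprintf(tmpl, sample(c(10, 20, 30, 50, 100), 1)),
            stringsAsFactors = FALSE))
          truth$planted_transaction[i] <- TRUE
        }
        caption <- dc$caption
      } else {
        bc <- background_caption(config)
        uid <- sample(bg_users, 1)
        caption <- bc$caption
      }
      if (stats::runif(1) < 0.3) {
        comments <- rbind(comments, data.frame(
          user_id = sample(bg_users, 1),
          text = sample(innocuous_comments(), 1), stringsAsFactors = FALSE))
      }
      posts[[i]] <- raw_post(pid, uid, ts[i], caption, comments)
    }
    list(posts = posts,
         labels = truth[c("post_id", "label")],
         truth = truth)
  })
}

#' Write the generator's ground truth as CSV
#'
#' @param truth The `truth` data.frame from [generate_corpus()].
#' @param path Destination CSV.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Wrap a post corpus as a queryable hashtag post source
#'
#' The post-source contract used by the discovery crawler: `query(hashtag)`
#' returns the posts carrying that hashtag, newest first; repeated queries
#' return identical results (the source is a snapshot). Hashtags are
#' matched on their cleaned, lowercase, `#`-stripped form.
#'
#' @param posts List of [raw_post()] objects.
#' @param snapshot_time The instant the snapshot was taken (crawl start).
#' @return An object of class `post_source` with elements `query`
#'   (function), `hashtags` (all hashtags present), `posts`, and
#'   `snapshot_time`.
#' @export
post_source <- function(posts, snapshot_time) {
  tag_sets <- lapply(posts, function(p) {
    unique(split_text_hashtags(clean_text(p$caption,
                                          stopwords = character()))$hashtags)
  })
  universe <- unique(unlist(tag_sets))
  index <- lapply(stats::setNames(universe, universe), function(tag) {
    hits <- which(vapply(tag_sets, function(s) tag %in% s, logical(1)))
    ts <- vapply(posts[hits], function(p) as.numeric(p$timestamp),
                 numeric(1))
    hits[order(ts, decreasing = TRUE)]
  })
  force(posts)
  structure(list(
    query = function(hashtag) {
      hashtag <- sub("^#", "", tolower(hashtag))
      posts[index[[hashtag]] %||% integer()]
    },
    hashtags = universe, posts = posts, snapshot_time = snapshot_time
  ), class = "post_source")
}

#' Generate a fixture hashtag graph for the discovery crawler
#'
#' Builds a deterministic snapshot post source in which drug hashtags
#' co-occur on dealer posts along a connected backbone (a cycle through
#' all drug variants), so that crawling any single drug seed can reach
#' every planted drug hashtag, and timestamps span twice the usual
#' recency window so the crawler's cutoff is exercised: the first 60% of
#' dealer posts (and half the background posts) fall inside the window,
#' the remainder are older.
#'
#' @param config A [synthetic_config()]; `n_posts` and `seed` are used.
#' @param n_hashtags Total number of distinct hashtags in the fixture
#'   (drug variants plus decorative tags), at least the number of drug
#'   variants in the lexicon.
#' @param cutoff_days Recency window the fixture straddles (default 90).
#' @return A `post_source` whose attribute `"planted_drug_hashtags"`
#'   names the drug hashtags placed on dealer posts.
#' @export
generate_hashtag_graph <- function(config, n_hashtags = 30,
                                   cutoff_days = 90) {
  stopifnot(inherits(config, "synthetic_config"))
  lex <- config$drug_lexicon
  drug_tags <- unique(lex$hashtag[lex$category != "sale_or_shipping"])
  if (n_hashtags < length(drug_tags)) {
    stop("n_hashtags must be at least the number of drug hashtag variants (",
         length(drug_tags), ")")
  }
  extra <- utils::head(config$stray_hashtags, n_hashtags - length(drug_tags))
  with_seed(config$seed + 1L, {
    n <- config$n_posts
    n_dealer <- max(length(drug_tags), round(n * config$dealer_fraction))
    v <- length(drug_tags)
    now <- config$snapshot_time
    cutoff_s <- cutoff_days * 86400
    posts <- vector("list", n)
    for (i in seq_len(n)) {
      dealer <- i <= n_dealer
      if (dealer) {
        k <- ((i - 1L) %% v) + 1L
        tags <- c(drug_tags[k], drug_tags[(k %% v) + 1L])
        if (stats::runif(1) < 0.35) {
          tags <- unique(c(tags, sample(drug_tags, 1)))
        }
        in_window <- i <= ceiling(0.6 * n_dealer)
        caption <- paste(c(sample(config$promo_phrases, 1),
                           rand_contact()$text, paste0("#", tags)),
                         collapse = " ")
      } else {
        tags <- sample(extra, min(length(extra), sample(1:3, 1)))
        in_window <- stats::runif(1) < 0.5
        caption <- paste(c(sample(config$background_topics[[
          sample(length(config$background_topics), 1)]], 4),
          paste0("#", tags)), collapse = " ")
      }
      age <- if (in_window) stats::runif(1, 0, cutoff_s * 0.99) else
        stats::runif(1, cutoff_s * 1.01, cutoff_s * 2)
      posts[[i]] <- raw_post(sprintf("fix%05d", i),
                             sprintf("fixuser%04d", sample(200, 1)),
                             now - age, caption)
    }
    src <- post_source(posts, snapshot_time = now)
    attr(src, "planted_drug_hashtags") <- drug_tags
    src
  })
}
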