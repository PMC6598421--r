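#' Read a drug-hashtag lexicon file
#'
#' CSV with columns `drug,hashtag,category`; hashtags are lowercased and
#' stripped of any leading `#`. Categories tag each variant as
#' `drug_name`, `codeword_misspelling`, `codeword_extended`,
#' `codeword_street` or `sale_or_shipping`.
#'
#' @param path CSV path; see [default_drug_lexicon()] for the shipped one.
#' @return A data.frame `drug,hashtag,category`.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("drug", "hashtag", "category") %in% names(df)))
  df$hashtag <- sub("^#", "", tolower(df$hashtag))
  df$drug <- tolower(df$drug)
  df
}

#' Default buy-intent phrase list
#'
#' Shipped phrase list (`inst/extdata/buy_intent.txt`) used by
#' [detect_transactions()] to recognize comments asking for price,
#' shipping or offering to buy.
#'
#' @return Character vector of lowercase phrases.
#' @export
default_buy_phrases <- function() {
  readLines(system.file("extdata", "buy_intent.txt", package = "dealerscan",
                        mustWork = TRUE), warn = FALSE)
}

#' Count posts per drug hashtag with union totals
#'
#' Per-hashtag counts are the number of posts whose hashtag set contains
#' that variant; the per-drug total is the number of *distinct* posts
#' matched by any variant of that drug (set-union semantics, so the total
#' is at most the sum of the per-hashtag counts and a post carrying two
#' variants of one drug is counted once). A post may contribute to
#' several drugs.
#'
#' @param posts List of clean posts (from [clean_posts()]).
#' @param lexicon Lexicon data.frame (see [read_lexicon()]); rows with
#'   category `sale_or_shipping` are excluded from drug rows.
#' @return List with `counts` (data.frame `drug,hashtag,category,posts`)
#'   and `totals` (data.frame `drug,posts`).
#' @export
count_drug_hashtags <- function(posts, lexicon = default_drug_lexicon()) {
  drug_rows <- lexicon[lexicon$category != "sale_or_shipping", ]
  tag_sets <- lapply(posts, function(p) unique(p$hashtag_tokens))
  counts <- drug_rows
  counts$posts <- vapply(drug_rows$hashtag, function(tag) {
    sum(vapply(tag_sets, function(s) tag %in% s, logical(1)))
  }, numeric(1))
  totals <- do.call(rbind, lapply(unique(drug_rows$drug), function(d) {
    variants <- drug_rows$hashtag[drug_rows$drug == d]
    hit <- vapply(tag_sets, function(s) any(variants %in% s), logical(1))
    data.frame(drug = d, posts = sum(hit))
  }))
  rownames(counts) <- rownames(totals) <- NULL
  list(counts = counts, totals = totals)
}

app_names <- c("wickr", "telegram", "kik", "whatsapp")

handle_like <- function(tok) {
  grepl("^@[a-z0-9_.]+$", tok) |
    (grepl("[0-9]", tok) & grepl("^[+@a-z0-9_.()-]+$", tok))
}

scan_contacts <- function(text) {
  channels <- character()
  matches <- character()
  low <- tolower(text)
  em <- regmatches(low,
                   gregexpr("[a-z0-9._%+-]+@[a-z0-9.-]+\\.[a-z]{2,}", low))[[1]]
  if (length(em) > 0) {
    channels <- c(channels, "email")
    matches <- c(matches, em)
  }
  ph <- regmatches(low, gregexpr("\\+?[0-9][0-9(). -]{4,24}[0-9]",
                                 low))[[1]]
  ph <- ph[vapply(ph, function(m) {
    d <- nchar(gsub("[^0-9]", "", m))
    d >= 7 && d <= 15
  }, logical(1))]
  if (length(ph) > 0) {
    channels <- c(channels, "phone")
    matches <- c(matches, ph)
  }
  toks <- strsplit(low, "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  clean_tok <- gsub("[,.!?;]+$", "", toks)
  for (i in seq_along(clean_tok)) {
    tok <- clean_tok[i]
    # "app:handle" in one token
    m <- regmatches(tok, regexec(
      sprintf("^(%s):(.+)$", paste(app_names, collapse = "|")), tok))[[1]]
    if (length(m) == 3 && nzchar(m[3])) {
      channels <- c(channels, paste0("app:", m[2]))
      matches <- c(matches, tok)
      next
    }
    base <- sub(":+$", "", tok)
    if (base %in% app_names && i < length(clean_tok)) {
      ahead <- clean_tok[(i + 1):min(i + 3, length(clean_tok))]
      cand <- sub(":+$", "", ahead)
      # a colon marks the next token as a handle even without digits
      colon_prev <- endsWith(c(tok, utils::head(ahead, -1)), ":")
      ok <- handle_like(cand) |
        (colon_prev & grepl("^@?[a-z0-9_.]{3,}$", cand))
      if (any(ok)) {
        channels <- c(channels, paste0("app:", base))
        matches <- c(matches, paste(tok, cand[which(ok)[1]]))
      }
    }
  }
  list(channels = unique(channels), matches = matches)
}

#' Extract contact channels from a post
#'
#' Scans the caption and all comments for e-mail addresses
#' (`local@domain.tld`), phone numbers (7-15 digits allowing separators
#' and a leading `+`; the 7-digit floor avoids dosage strings like
#' "2mg"), and messaging-app mentions -- an app name (wickr, telegram,
#' kik, whatsapp) within 3 tokens of a handle-like token (`@`-prefixed or
#' containing a digit) or an `app:handle` pattern.
#'
#' @param post A [raw_post()].
#' @return A `contact_record`: list with `post_id`, `channels` (character
#'   vector drawn from `email`, `phone`, `app:<name>`) and `matches`
#'   (the matched text spans backing each channel).
#' @export
extract_contacts <- function(post) {
  texts <- c(post$caption, post$comments$text)
  found <- lapply(texts, scan_contacts)
  structure(list(
    post_id = post$post_id,
    channels = unique(unlist(lapply(found, `[[`, "channels"))),
    matches = unlist(lapply(found, `[[`, "matches"))
  ), class = "contact_record")
}

#' Detect a buyer-seller exchange on a post
#'
#' `TRUE` iff the post (a) is dealer-labeled and carries at least one
#' contact channel, and (b) has at least one comment from a *different*
#' user matching a buy-intent pattern: one of the shipped phrases, or an
#' interrogative mentioning price/order/shipping/availability.
#'
#' @param post A [raw_post()].
#' @param dealer_label Binary dealer label (or prediction) for the post.
#' @param buy_phrases Phrase list, see [default_buy_phrases()].
#' @return Logical flag.
#' @export
detect_transactions <- function(post, dealer_label,
                                buy_phrases = default_buy_phrases()) {
  if (!isTRUE(dealer_label == 1)) return(FALSE)
  if (nrow(post$comments) == 0) return(FALSE)
  if (length(extract_contacts(post)$channels) == 0) return(FALSE)
  others <- post$comments[post$comments$user_id != post$user_id, ,
                          drop = FALSE]
  if (nrow(others) == 0) return(FALSE)
  any(vapply(others$text, function(txt) {
    low <- tolower(txt)
    phrase_hit <- any(vapply(buy_phrases, grepl, logical(1), x = low,
                             fixed = TRUE))
    question_hit <- grepl("\\?", low) &&
      grepl("price|much|order|ship|available|buy", low)
    phrase_hit || question_hit
  }, logical(1)))
}

#' Characterize the detected dealer posts
#'
#' Restricts the corpus to predicted-positive posts and summarizes them:
#' drug-hashtag counts with union totals and percentages of detected
#' posts, contact-channel frequencies, buyer-seller transaction count,
#' and the number of unique posting users.
#'
#' @param posts List of [raw_post()] objects.
#' @param predictions Data.frame with `post_id` and predicted `label`
#'   (1 = detected) covering all posts.
#' @param lexicon Lexicon data.frame.
#' @param stopwords Stopword list used when re-cleaning captions.
#' @return A `characterization_report` list: `n_detected`, `drug_counts`
#'   (per-hashtag), `drug_totals` (union totals with `pct` of detected),
#'   `contact_channels` (data.frame `channel,posts`), `n_transactions`,
#'   `n_unique_users`.
#' @export
summarize_detected <- function(posts, predictions,
                               lexicon = default_drug_lexicon(),
                               stopwords = default_stopwords()) {
  stopifnot(all(c("post_id", "label") %in% names(predictions)))
  pred_map <- stats::setNames(predictions$label, predictions$post_id)
  ids <- vapply(posts, function(p) p$post_id, character(1))
  if (anyNA(pred_map[ids])) stop("predictions must cover all posts")
  detected <- posts[pred_map[ids] == 1]
  n_det <- length(detected)
  clean_det <- clean_posts(detected, stopwords = stopwords)
  dc <- count_drug_hashtags(clean_det, lexicon)
  dc$totals$pct <- if (n_det > 0) 100 * dc$totals$posts / n_det else 0
  contact_recs <- lapply(detected, extract_contacts)
  all_channels <- unlist(lapply(contact_recs, `[[`, "channels"))
  channel_levels <- c("email", "phone", paste0("app:", app_names))
  chan <- data.frame(
    channel = channel_levels,
    posts = vapply(channel_levels, function(ch) {
      sum(vapply(contact_recs, function(r) ch %in% r$channels, logical(1)))
    }, numeric(1)))
  rownames(chan) <- NULL
  n_trans <- sum(vapply(detected, detect_transactions, logical(1),
                        dealer_label = 1))
  users <- unique(vapply(detected, function(p) p$user_id, character(1)))
  structure(list(
    n_detected = n_det, drug_counts = dc$counts, drug_totals = dc$totals,
    contact_channels = chan, n_transactions = n_trans,
    n_unique_users = length(users)
  ), class = "characterization_report")
}

#' @export
print.characterization_report <- function(x, ...) {
  cat(sprintf("Characterization of %d detected posts (%d unique users)\n",
              x$n_detected, x$n_unique_users))
  cat("\nDrug totals (union over hashtag variants):\n")
  print(transform(x$drug_totals, pct = round(pct, 1)), row.names = FALSE)
  cat("\nContact channels:\n")
  print(x$contact_channels, row.names = FALSE)
  cat(sprintf("\nBuyer-seller exchanges detected: %d\n", x$n_transactions))
  invisible(x)
}

#' Write a characterization report
#'
#' Emits `drug_counts.csv`, `drug_totals.csv`, `contact_channels.csv` and
#' a human-readable `summary.txt` under `dir`.
#'
#' @param report A [summarize_detected()] result.
#' @param dir Output directory.
#' @export
write_characterization <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$drug_counts, file.path(dir, "drug_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(report$drug_totals, file.path(dir, "drug_totals.csv"),
                   row.names = FALSE)
  utils::write.csv(report$contact_channels,
                   file.path(dir, "contact_channels.csv"), row.names = FALSE)
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(dir)
}
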