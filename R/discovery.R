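#' Default drug-keyword filter list
#'
#' Substring keywords (`inst/extdata/drug_keywords.txt`) used to vet
#' harvested hashtags during the expansion crawl: a candidate hashtag is
#' kept when it contains any keyword as a substring. This automates what
#' is otherwise a manual inspection step; [crawl_loop1()] can also dump
#' candidates for human review via its `review_file` argument.
#'
#' @return Character vector of lowercase keywords.
#' @export
default_drug_keywords <- function() {
  readLines(system.file("extdata", "drug_keywords.txt",
                        package = "dealerscan", mustWork = TRUE),
            warn = FALSE)
}

matches_keywords <- function(tags, keywords) {
  vapply(tags, function(tag) {
    any(vapply(keywords, grepl, logical(1), x = tag, fixed = TRUE))
  }, logical(1))
}

normalize_tag <- function(x) sub("^#", "", tolower(x))

post_hashtags <- function(post) {
  unique(split_text_hashtags(clean_text(post$caption,
                                        stopwords = character()))$hashtags)
}

window_posts <- function(source, hashtag, cutoff_days) {
  res <- source$query(hashtag)
  limit <- source$snapshot_time - cutoff_days * 86400
  keep <- integer()
  for (i in seq_along(res)) {  # newest first; stop at the first older post
    if (res[[i]]$timestamp < limit) break
    keep <- c(keep, i)
  }
  res[keep]
}

new_crawl_state <- function(seeds, cutoff_days, start_time) {
  structure(list(
    seeds = seeds, discovered = seeds,
    loop_found = stats::setNames(rep(0L, length(seeds)), seeds),
    visited = character(), posts = list(),
    cutoff_days = cutoff_days, start_time = start_time
  ), class = "crawl_state")
}

add_posts <- function(state, posts) {
  for (p in posts) {
    if (is.null(state$posts[[p$post_id]])) state$posts[[p$post_id]] <- p
  }
  state
}

#' First loop of the hashtag-expansion crawl
#'
#' For each seed hashtag, collects posts newest-to-oldest until one is
#' older than the recency cutoff, harvests all hashtags appearing on the
#' collected posts, and appends -- in first-seen order -- those passing
#' the drug-keyword filter to the discovered list for the second loop.
#' A seed unknown to the source yields an empty result, not an error.
#'
#' @param source A [post_source()].
#' @param seeds Character vector of seed hashtags (with or without `#`).
#' @param cutoff_days Recency cutoff in days (default 90, i.e. 3 months).
#' @param keywords Keyword filter list, see [default_drug_keywords()].
#' @param review_file Optional path: all harvested candidate hashtags
#'   (before filtering) are written there, one per line, for manual
#'   review and editing.
#' @return A `crawl_state`: `seeds`, `discovered` (ordered), `visited`,
#'   `posts` (deduplicated by post id), `cutoff_days`, `start_time`.
#' @export
crawl_loop1 <- function(source, seeds, cutoff_days = 90,
                        keywords = default_drug_keywords(),
                        review_file = NULL) {
  stopifnot(length(seeds) > 0)
  seeds <- unique(normalize_tag(seeds))
  state <- new_crawl_state(seeds, cutoff_days, source$snapshot_time)
  collected <- list()
  for (s in seeds) {
    hits <- window_posts(source, s, cutoff_days)
    state <- add_posts(state, hits)
    collected <- c(collected, hits)
    state$visited <- union(state$visited, s)
  }
  harvested <- unique(unlist(lapply(collected, post_hashtags)))
  if (!is.null(review_file)) {
    writeLines(sort(harvested %||% character()), review_file)
  }
  candidates <- harvested[matches_keywords(harvested, keywords)]
  new_tags <- setdiff(candidates, state$discovered)
  state$discovered <- c(state$discovered, new_tags)
  state$loop_found <- c(state$loop_found,
                        stats::setNames(rep(1L, length(new_tags)), new_tags))
  state
}

#' Second loop of the hashtag-expansion crawl
#'
#' Queries every discovered-but-unvisited hashtag once under the same
#' recency cutoff and adds the posts, deduplicated by post id, to the
#' collection. No further expansion happens beyond this loop; running it
#' again is a no-op because everything is then visited.
#'
#' @param source A [post_source()].
#' @param state A `crawl_state` from [crawl_loop1()].
#' @return The updated `crawl_state`.
#' @export
crawl_loop2 <- function(source, state) {
  stopifnot(inherits(state, "crawl_state"))
  for (tag in setdiff(state$discovered, state$visited)) {
    hits <- window_posts(source, tag, state$cutoff_days)
    state <- add_posts(state, hits)
    state$visited <- union(state$visited, tag)
  }
  state
}

#' @export
print.crawl_state <- function(x, ...) {
  cat(sprintf(
    "<crawl_state: %d seeds, %d discovered, %d visited, %d posts, %dd cutoff>\n",
    length(x$seeds), length(x$discovered), length(x$visited),
    length(x$posts), x$cutoff_days))
  invisible(x)
}

#' Run the full two-loop discovery crawl
#'
#' Convenience wrapper: [crawl_loop1()] on the seeds followed by
#' [crawl_loop2()] (repeated expansion loops via `max_loops`, though the
#' standard procedure stops at two).
#'
#' @inheritParams crawl_loop1
#' @param max_loops Total number of loops (default 2). Values above 2
#'   re-harvest and re-filter hashtags from newly collected posts before
#'   each extra loop.
#' @return The final `crawl_state`.
#' @export
discover <- function(source, seeds, cutoff_days = 90,
                     keywords = default_drug_keywords(), max_loops = 2L) {
  stopifnot(max_loops >= 1)
  state <- crawl_loop1(source, seeds, cutoff_days, keywords)
  loop <- 2L
  while (loop <= max_loops) {
    state <- crawl_loop2(source, state)
    if (loop < max_loops) {
      harvested <- unique(unlist(lapply(state$posts, post_hashtags)))
      new_tags <- setdiff(harvested[matches_keywords(harvested, keywords)],
                          state$discovered)
      if (length(new_tags) == 0) break
      state$discovered <- c(state$discovered, new_tags)
      state$loop_found <- c(state$loop_found,
                            stats::setNames(rep(loop, length(new_tags)),
                                            new_tags))
    }
    loop <- loop + 1L
  }
  state
}

#' Tabulate a crawl's discovered hashtags
#'
#' @param state A `crawl_state`.
#' @return Data.frame `hashtag, loop_found` (0 for seeds), `post_count`
#'   (collected posts carrying the hashtag).
#' @export
crawl_report <- function(state) {
  tag_sets <- lapply(state$posts, post_hashtags)
  data.frame(
    hashtag = state$discovered,
    loop_found = unname(state$loop_found[state$discovered]),
    post_count = vapply(state$discovered, function(tag) {
      sum(vapply(tag_sets, function(s) tag %in% s, logical(1)))
    }, numeric(1)),
    row.names = NULL)
}
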