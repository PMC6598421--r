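#' Construct a raw post record
#'
#' A raw post is one scraped record from a hashtag-driven platform: the
#' caption (free text with inline hashtags), the comment thread, and
#' minimal metadata. Raw posts are the unit stored in JSON Lines corpora
#' and consumed by [clean_posts()] and [extract_contacts()].
#'
#' @param post_id Non-empty string uniquely identifying the post.
#' @param user_id String identifying the posting account.
#' @param timestamp A `POSIXct` instant (coerced to UTC) or an ISO-8601
#'   string.
#' @param caption Caption text; may be empty, may contain inline hashtags,
#'   links and emoji.
#' @param comments A data.frame with columns `user_id` and `text`, one row
#'   per comment in thread order. Defaults to no comments.
#' @param image_refs Character vector of opaque image identifiers.
#' @return An object of class `raw_post` (a named list).
#' @examples
#' raw_post("p1", "u1", "2018-08-01T12:00:00Z", "hello #world")
#' @export
raw_post <- function(post_id, user_id = "", timestamp = Sys.time(),
                     caption = "", comments = empty_comments(),
                     image_refs = character()) {
  if (!is.character(post_id) || length(post_id) != 1L || !nzchar(post_id)) {
    stop("post_id must be a non-empty string")
  }
  ts <- parse_timestamp(timestamp)
  comments <- as_comments(comments)
  structure(
    list(post_id = post_id, user_id = as.character(user_id)[1L],
         timestamp = ts, caption = as.character(caption)[1L],
         comments = comments, image_refs = as.character(image_refs)),
    class = "raw_post"
  )
}

empty_comments <- function() {
  data.frame(user_id = character(), text = character(),
             stringsAsFactors = FALSE)
}

as_comments <- function(x) {
  if (is.null(x) || length(x) == 0L) return(empty_comments())
  if (is.data.frame(x)) {
    stopifnot(all(c("user_id", "text") %in% names(x)))
    return(data.frame(user_id = as.character(x$user_id),
                      text = as.character(x$text), stringsAsFactors = FALSE))
  }
  # list of lists with $user_id / $text (as parsed from JSON)
  data.frame(
    user_id = vapply(x, function(cm) as.character(cm$user_id), character(1)),
    text = vapply(x, function(cm) as.character(cm$text), character(1)),
    stringsAsFactors = FALSE
  )
}

parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  out <- as.POSIXct(as.character(x), tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                   "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d"))
  if (is.na(out)) stop("unparseable timestamp: ", x)
  out
}

format_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' @export
print.raw_post <- function(x, ...) {
  cat(sprintf("<raw_post %s by %s at %s>\n", x$post_id, x$user_id,
              format_timestamp(x$timestamp)))
  cat("  caption: ", substr(x$caption, 1, 70), "\n", sep = "")
  cat(sprintf("  %d comment(s), %d image ref(s)\n",
              nrow(x$comments), length(x$image_refs)))
  invisible(x)
}

#' Read a JSON Lines post corpus
#'
#' Each line of the file is one JSON object with keys `post_id`, `user_id`,
#' `timestamp` (ISO-8601), `caption`, `comments` (array of
#' `{user_id, text}`) and `image_refs` (array of strings). Missing
#' `comments` / `image_refs` default to empty; a missing `post_id` or
#' `caption`, or a syntactically malformed line, is an error naming the
#' offending line number.
#'
#' @param path Path to a JSON Lines file.
#' @return A list of [raw_post()] objects, in file order.
#' @seealso [write_posts()] for the inverse operation.
#' @export
read_posts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) stop(sprintf("malformed JSON on line %d: %s",
                                       i, conditionMessage(e)), call. = FALSE)
    )
    for (key in c("post_id", "caption")) {
      if (is.null(rec[[key]])) {
        stop(sprintf("line %d: missing required key '%s'", i, key),
             call. = FALSE)
      }
    }
    out[[i]] <- raw_post(
      post_id = as.character(rec$post_id),
      user_id = if (is.null(rec$user_id)) "" else rec$user_id,
      timestamp = if (is.null(rec$timestamp)) "1970-01-01T00:00:00Z" else
        rec$timestamp,
      caption = rec$caption,
      comments = rec$comments,
      image_refs = if (is.null(rec$image_refs)) character() else
        unlist(rec$image_refs)
    )
  }
  out
}

#' Write a post corpus as JSON Lines
#'
#' One JSON object per line; [read_posts()] inverts it exactly (round-trip
#' identity on valid corpora).
#'
#' @param posts A list of [raw_post()] objects.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path) {
  lines <- vapply(posts, function(p) {
    jsonlite::toJSON(list(
      post_id = p$post_id, user_id = p$user_id,
      timestamp = format_timestamp(p$timestamp), caption = p$caption,
      comments = lapply(seq_len(nrow(p$comments)), function(i) {
        list(user_id = p$comments$user_id[i], text = p$comments$text[i])
      }),
      image_refs = p$image_refs
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Deduplicate a post corpus
#'
#' Collection under overlapping hashtag searches returns the same post more
#' than once; a later processing pass also collapses posts whose caption
#' text is identical. The first occurrence is kept, later duplicates are
#' dropped, and relative order is preserved. The operation is idempotent.
#'
#' @param posts A list of [raw_post()] objects.
#' @param key Duplicate identity: `"post_id"` (collection-stage dedup) or
#'   `"caption_text"` (processing-stage dedup on the raw caption string).
#' @return The deduplicated list.
#' @export
dedup_posts <- function(posts, key = c("post_id", "caption_text")) {
  key <- match.arg(key)
  ids <- vapply(posts, function(p) {
    if (key == "post_id") p$post_id else p$caption
  }, character(1))
  posts[!duplicated(ids)]
}

#' Read / write binary label files
#'
#' Labels are stored as a two-column CSV with header `post_id,label`,
#' label 1 marking a drug-dealer post and 0 an unrelated post.
#'
#' @param path CSV file path.
#' @return `read_labels()`: a data.frame with character `post_id` and
#'   integer `label`.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "integer"))
  stopifnot(identical(names(df), c("post_id", "label")),
            all(df$label %in% c(0L, 1L)))
  df
}

#' @rdname read_labels
#' @param labels A data.frame with columns `post_id` and `label` in `{0,1}`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("post_id", "label") %in% names(labels)),
            all(labels$label %in% c(0, 1)))
  utils::write.csv(labels[c("post_id", "label")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
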