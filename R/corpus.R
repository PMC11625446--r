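#' Normalize an action token
#'
#' An action is the bigram of a manipulation and the object it is directed at
#' (e.g. "grasp NUT"). Labels are normalized so that corpora round-trip
#' byte-identically: whitespace is trimmed, the manipulation is case-folded to
#' lower case, the object to upper case, and the two are joined by a single
#' space.
#'
#' @param manipulation character vector of manipulation labels.
#' @param object character vector of object labels.
#' @return character vector of rendered action symbols.
#' @export
action_token <- function(manipulation, object) {
  m <- tolower(trimws(manipulation))
  o <- toupper(trimws(object))
  if (any(!nzchar(m)) || any(!nzchar(o))) {
    stop("action labels must be non-empty", call. = FALSE)
  }
  paste(m, o)
}

#' Construct a token stream
#'
#' A token stream is an ordered categorical sequence: the atomic data type of
#' all MI computations. Symbols are stored as integer codes over a fixed
#' alphabet so that pair tabulation is cheap.
#'
#' @param symbols character vector of action symbols, in temporal order.
#' @param alphabet optional character vector fixing the alphabet (defaults to
#'   the sorted set of distinct symbols present).
#' @param boundaries optional integer vector of source-sequence ids, one per
#'   symbol, used when cross-boundary pairs are to be excluded.
#' @return an object of class `token_stream` with elements `codes`,
#'   `alphabet`, `N` and optionally `boundaries`.
#' @export
token_stream <- function(symbols, alphabet = NULL, boundaries = NULL) {
  if (length(symbols) < 1L) stop("token stream must be non-empty", call. = FALSE)
  symbols <- as.character(symbols)
  if (is.null(alphabet)) alphabet <- sort(unique(symbols))
  codes <- match(symbols, alphabet)
  if (anyNA(codes)) stop("symbols outside the supplied alphabet", call. = FALSE)
  if (!is.null(boundaries) && length(boundaries) != length(symbols)) {
    stop("boundaries must have one entry per symbol", call. = FALSE)
  }
  structure(
    list(codes = codes, alphabet = alphabet, N = length(codes),
         boundaries = boundaries),
    class = "token_stream"
  )
}

#' @export
print.token_stream <- function(x, ...) {
  cat("<token_stream> N =", x$N, ", alphabet size =", length(x$alphabet), "\n")
  head_n <- min(10L, x$N)
  cat(" ", paste(x$alphabet[x$codes[seq_len(head_n)]], collapse = ", "),
      if (x$N > head_n) "...", "\n")
  invisible(x)
}

#' @export
length.token_stream <- function(x) x$N

#' Symbols of a token stream
#' @param stream a `token_stream`.
#' @return character vector of symbols in order.
#' @export
stream_symbols <- function(stream) stream$alphabet[stream$codes]

#' Collapse runs of repeated actions
#'
#' Every maximal run of identical consecutive symbols is replaced by a single
#' codon, so e.g. "strike HAMMER, strike HAMMER, strike HAMMER" becomes one
#' "strike HAMMER". Condensing removes dependencies generated purely by
#' action repetition; the decay analysis is typically run on both the raw and
#' the condensed stream. Idempotent.
#'
#' @param stream a `token_stream`.
#' @return a `token_stream` with no two equal adjacent symbols. The alphabet
#'   is preserved; boundary labels (if any) follow the first element of each
#'   run.
#' @export
condense <- function(stream) {
  stopifnot(inherits(stream, "token_stream"))
  keep <- c(TRUE, stream$codes[-1L] != stream$codes[-stream$N])
  structure(
    list(codes = stream$codes[keep], alphabet = stream$alphabet,
         N = sum(keep),
         boundaries = if (!is.null(stream$boundaries)) stream$boundaries[keep]),
    class = "token_stream"
  )
}

required_corpus_cols <- c("individual", "sequence_id", "collection_index",
                          "order", "manipulation", "object")

#' Read an ethogram-coded corpus from delimited text
#'
#' Reads one row per coded action. Required columns: `individual`,
#' `sequence_id`, `collection_index`, `order`, `manipulation`, `object`;
#' optional `nut_episode` labels mark which nut-cracking episode an action
#' belongs to. The `boris` dialect maps a BORIS-style export (`Subject`,
#' `Observation id`, `Time`, `Behavior`, `Modifier`) onto this schema, using
#' the within-observation rank of `Time` as the order and the file order of
#' first appearance of each observation as the collection index.
#'
#' Sequences of each individual are concatenated in order of collection
#' (by `collection_index`, then `order` within a sequence) to form the
#' analysis stream; file row order is irrelevant.
#'
#' @param path path to a TSV or CSV file.
#' @param dialect one of "tsv", "csv", "boris".
#' @return a named list of `action_corpus` objects, one per individual.
#' @export
load_corpus <- function(path, dialect = c("tsv", "csv", "boris")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE)
  if (nrow(df) == 0L) stop("empty input file: ", path, call. = FALSE)
  if (dialect == "boris") df <- map_boris(df)
  missing_cols <- setdiff(required_corpus_cols, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  corpus_from_rows(df)
}

map_boris <- function(df) {
  need <- c("Subject", "Observation id", "Time", "Behavior", "Modifier")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing BORIS column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  obs <- df[["Observation id"]]
  out <- data.frame(
    individual = df[["Subject"]],
    sequence_id = obs,
    collection_index = match(obs, unique(obs)),
    order = stats::ave(as.numeric(df[["Time"]]), obs, FUN = rank),
    manipulation = df[["Behavior"]],
    object = df[["Modifier"]],
    stringsAsFactors = FALSE
  )
  if ("nut_episode" %in% names(df)) out$nut_episode <- df$nut_episode
  out
}

#' Build corpora directly from a data frame of coded actions
#'
#' @param df data frame with the columns described in [load_corpus()].
#' @return named list of `action_corpus` objects.
#' @export
corpus_from_rows <- function(df) {
  bad_manip <- !nzchar(trimws(as.character(df$manipulation))) |
    is.na(df$manipulation)
  bad_obj <- !nzchar(trimws(as.character(df$object))) | is.na(df$object)
  if (any(bad_manip | bad_obj)) {
    rows <- which(bad_manip | bad_obj)
    stop("schema error: empty manipulation/object label at row(s) ",
         paste(utils::head(rows, 5L), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df[, c("individual", "sequence_id", "order")])
  if (any(dup)) {
    stop("integrity error: duplicate (sequence, order) pair at row(s) ",
         paste(utils::head(which(dup), 5L), collapse = ", "), call. = FALSE)
  }
  df$symbol <- action_token(df$manipulation, df$object)
  out <- lapply(split(df, df$individual), function(d) {
    d <- d[order(d$collection_index, d$order), , drop = FALSE]
    ci <- tapply(d$collection_index, d$sequence_id, unique)
    if (any(lengths(ci) > 1L)) {
      stop("integrity error: sequence with inconsistent collection_index",
           call. = FALSE)
    }
    if (anyDuplicated(unlist(ci))) {
      stop("integrity error: duplicate collection_index within individual",
           call. = FALSE)
    }
    structure(
      list(individual_id = as.character(d$individual[1L]),
           rows = d,
           stream = token_stream(d$symbol,
                                 boundaries = match(d$sequence_id,
                                                    unique(d$sequence_id)))),
      class = "action_corpus"
    )
  })
  out[order(names(out))]
}

#' @export
print.action_corpus <- function(x, ...) {
  cat("<action_corpus>", x$individual_id, ":",
      length(unique(x$rows$sequence_id)), "sequences,",
      x$stream$N, "tokens,", length(x$stream$alphabet), "action types\n")
  invisible(x)
}

#' Descriptive statistics of a corpus
#'
#' Mean sequence lengths and their standard errors use the normal
#' approximation of the Poisson distribution, SE = sqrt(mean / n): sequence
#' lengths are counts, so the variance of a length is approximated by its
#' mean. Per-nut statistics are computed over successfully cracked nut
#' episodes when `nut_episode` annotations are present, otherwise reported
#' as unavailable (NA), never as zero.
#'
#' @param corpus an `action_corpus`.
#' @return a one-row data frame of class `corpus_summary` with columns
#'   `individual`, `n_sequences`, `n_elements`, `n_action_types`,
#'   `mean_seq_length`, `se_seq_length`, `nuts_cracked`,
#'   `mean_per_nut_length`, `se_per_nut_length`.
#' @export
summarize_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "action_corpus"))
  d <- corpus$rows
  n_seq <- length(unique(d$sequence_id))
  n_el <- nrow(d)
  mean_len <- n_el / n_seq
  if (!is.null(d$nut_episode) && any(!is.na(d$nut_episode) & nzchar(as.character(d$nut_episode)))) {
    ep <- as.character(d$nut_episode)
    ep[!nzchar(ep)] <- NA
    per_nut <- table(ep[!is.na(ep)])
    nuts <- length(per_nut)
    mean_nut <- mean(per_nut)
    se_nut <- sqrt(mean_nut / nuts)
  } else {
    nuts <- NA_integer_; mean_nut <- NA_real_; se_nut <- NA_real_
  }
  out <- data.frame(
    individual = corpus$individual_id,
    n_sequences = n_seq,
    n_elements = n_el,
    n_action_types = length(unique(d$symbol)),
    mean_seq_length = mean_len,
    se_seq_length = sqrt(mean_len / n_seq),
    nuts_cracked = as.integer(nuts),
    mean_per_nut_length = as.numeric(mean_nut),
    se_per_nut_length = se_nut,
    stringsAsFactors = FALSE
  )
  class(out) <- c("corpus_summary", "data.frame")
  out
}

#' Poisson-approximation summary from printed counts
#'
#' Computes mean sequence length and its standard error from total element
#' and sequence counts alone, SE = sqrt(mean / n). Used to reproduce
#' published summary-table cells from their printed counts.
#'
#' @param n_elements total number of coded elements.
#' @param n_sequences number of sequences.
#' @return list with `mean` and `se`.
#' @export
poisson_mean_se <- function(n_elements, n_sequences) {
  m <- n_elements / n_sequences
  list(mean = m, se = sqrt(m / n_sequences))
}

#' Relative frequency of action types
#'
#' @param x an `action_corpus` or `token_stream`.
#' @param threshold minimum relative frequency to retain (rows below are
#'   dropped, e.g. 0.01 for display).
#' @return data frame with columns `symbol` and `frequency`, sorted by
#'   decreasing frequency; frequencies over the full corpus sum to 1 before
#'   thresholding.
#' @export
action_type_profile <- function(x, threshold = 0) {
  stream <- if (inherits(x, "action_corpus")) x$stream else x
  stopifnot(inherits(stream, "token_stream"))
  cnt <- tabulate(stream$codes, nbins = length(stream$alphabet))
  freq <- cnt / stream$N
  out <- data.frame(symbol = stream$alphabet, frequency = freq,
                    stringsAsFactors = FALSE)
  out <- out[out$frequency > 0 & out$frequency >= threshold, , drop = FALSE]
  out[order(-out$frequency), , drop = FALSE]
}

#' Write a normalized corpus back to TSV
#'
#' @param corpora named list of `action_corpus` objects (as returned by
#'   [load_corpus()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpora, path) {
  keep <- c(required_corpus_cols, "nut_episode")
  rows <- do.call(rbind, lapply(corpora, function(cp) {
    d <- cp$rows
    if (is.null(d$nut_episode)) d$nut_episode <- NA
    d[, keep]
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
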