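#' LTSv tree-representation vectors
#'
#' A vector of length `2n` over the taxon indices `1..n` is a tree
#' representation (an LTSv vector) when
#' \enumerate{
#'   \item every taxon `i` occurs exactly twice;
#'   \item the first token is `1` (and is a first occurrence);
#'   \item for `i >= 2`, the first occurrence of `i` precedes the second
#'     occurrence of `i - 1`;
#'   \item the second occurrences appear in increasing order.
#' }
#' Such vectors are in bijection with the rooted binary leaf-labelled trees
#' on `n` indexed taxa.  Whether a token is a first or a second occurrence is
#' determined positionally by a left-to-right scan, so no marker is stored.
#'
#' @param tokens integer vector of taxon indices.
#' @return `ltsv()` returns the validated vector with class `ltsv`.
#' @examples
#' ltsv(c(1, 3, 2, 1, 2, 4, 3, 4))
#' @export
ltsv <- function(tokens) {
  tokens <- as.integer(tokens)
  v <- validate_ltsv(tokens)
  if (!v$valid)
    stop("invalid LTSv vector: condition (", v$condition,
         ") violated at position ", v$position)
  structure(tokens, class = "ltsv")
}

#' @rdname ltsv
#' @param x object to test.
#' @export
is_ltsv <- function(x) inherits(x, "ltsv")

#' @export
print.ltsv <- function(x, ...) {
  n <- length(x) %/% 2L
  sec <- second_occurrence_flags(x)
  shown <- ifelse(sec, paste0(unclass(x), "_"), as.character(unclass(x)))
  cat("ltsv (n = ", n, "): (", paste(shown, collapse = ","), ")\n", sep = "")
  invisible(x)
}

# Logical flags: TRUE at second occurrences (left-to-right scan).
second_occurrence_flags <- function(tokens) duplicated(as.integer(tokens))

#' @rdname ltsv
#' @return `validate_ltsv()` returns a list with `valid` (logical) and, when
#'   invalid, the violated condition id (`"i"`, `"ii"`, `"iii"`, `"iv"`, as
#'   numbered above) and the offending 1-based `position`.
#' @export
validate_ltsv <- function(tokens) {
  tokens <- as.integer(tokens)
  if (length(tokens) == 0L) stop("empty token sequence")
  if (length(tokens) %% 2L != 0L)
    return(list(valid = FALSE, condition = "i", position = length(tokens)))
  n <- length(tokens) %/% 2L
  if (anyNA(tokens) || any(tokens < 1L) || any(tokens > n))
    stop("token out of range 1..n for n = ", n)
  cnt <- tabulate(tokens, nbins = n)
  if (any(cnt != 2L)) {
    bad <- which(cnt != 2L)[1L]
    pos <- if (cnt[bad] > 2L) which(tokens == bad)[3L] else length(tokens)
    return(list(valid = FALSE, condition = "i", position = pos))
  }
  if (tokens[1L] != 1L)
    return(list(valid = FALSE, condition = "ii", position = 1L))
  sec <- second_occurrence_flags(tokens)
  first_pos <- integer(n); second_pos <- integer(n)
  first_pos[tokens[!sec]] <- which(!sec)
  second_pos[tokens[sec]] <- which(sec)
  if (n >= 2L) {
    viol <- which(first_pos[2:n] > second_pos[1:(n - 1L)])
    if (length(viol))
      return(list(valid = FALSE, condition = "iii",
                  position = first_pos[viol[1L] + 1L]))
    viol4 <- which(diff(second_pos) < 0L)
    if (length(viol4))
      return(list(valid = FALSE, condition = "iv",
                  position = second_pos[viol4[1L] + 1L]))
  }
  list(valid = TRUE)
}

# Positions p_k of the second occurrence of each taxon k (p_n = 2n).
second_positions <- function(v) {
  tokens <- as.integer(v)
  sec <- second_occurrence_flags(tokens)
  p <- integer(length(tokens) %/% 2L)
  p[tokens[sec]] <- which(sec)
  p
}

# Position of each taxon's first occurrence.
first_positions <- function(v) {
  tokens <- as.integer(v)
  sec <- second_occurrence_flags(tokens)
  p <- integer(length(tokens) %/% 2L)
  p[tokens[!sec]] <- which(!sec)
  p
}

#' Canonical decomposition of an LTSv vector
#'
#' Cuts the vector just before each second occurrence: block `i` is the
#' maximal run of first occurrences immediately preceding the second
#' occurrence of `i`.  The decomposition has `n - 1` blocks (the block in
#' front of the final second occurrence is empty for every valid vector with
#' `n >= 2` and is omitted, matching the definition of the HOP similarity).
#' When the vector encodes a tree, block `i` is the lineage taxon sequence of
#' taxon `i`.
#'
#' @param v an [ltsv] vector.
#' @return List of `n - 1` integer vectors (possibly empty); an empty list
#'   for `n = 1`.
#' @examples
#' canonical_decomposition(ltsv(c(1, 3, 2, 1, 2, 5, 4, 3, 4, 5)))
#' @export
canonical_decomposition <- function(v) {
  if (!is_ltsv(v)) v <- ltsv(v)
  tokens <- as.integer(v)
  n <- length(tokens) %/% 2L
  if (n == 1L) return(list())
  sec <- second_occurrence_flags(tokens)
  p <- which(sec)                      # positions of 1_, 2_, ..., n_
  out <- vector("list", n - 1L)
  lo <- 1L
  for (i in seq_len(n - 1L)) {
    out[[i]] <- if (p[i] > lo) tokens[lo:(p[i] - 1L)] else integer(0)
    lo <- p[i] + 1L
  }
  out
}

#' Serialize and parse LTSv vectors on disk
#'
#' Plain-text format: a header line `#ltsv <n>`, a line
#' `taxa: <lab1>,<lab2>,...` giving the taxon order, and one body line of
#' `2n` comma-separated tokens.  A plain token is the bare taxon index;
#' second occurrences carry no marker (they are positionally implied).  In
#' annotated mode each token is a triplet `index:name:length` carrying the
#' node name and the length of the branch entering that node (either part
#' may be empty); the name of the very first token is always empty.
#'
#' @param v an [ltsv] vector.
#' @param order a [taxon_order] with `n` labels.
#' @param annotations optional list with character vector `name` and numeric
#'   vector `length`, each of length `2n` (NA entries are emitted empty).
#' @param digits decimal digits used when formatting branch lengths in
#'   annotated mode.
#' @return `serialize_ltsv()`: a single string (three lines separated by
#'   newlines).  `parse_ltsv()`: a list with elements `vector` ([ltsv]),
#'   `order` ([taxon_order]) and, when the body is annotated, `name` and
#'   `length` vectors aligned with token positions.
#' @export
serialize_ltsv <- function(v, order, annotations = NULL, digits = 2) {
  if (!is_ltsv(v)) v <- ltsv(v)
  tokens <- as.integer(v)
  n <- length(tokens) %/% 2L
  order <- taxon_order(order)
  if (length(order) != n) stop("taxon order has ", length(order),
                               " labels but the vector has n = ", n)
  if (is.null(annotations)) {
    body <- paste(tokens, collapse = ",")
  } else {
    nm <- annotations$name
    ln <- annotations$length
    if (length(nm) != 2L * n || length(ln) != 2L * n)
      stop("annotation for nonexistent position: name/length must have ",
           "one entry per token")
    if (!is.na(nm[1L]) && nzchar(nm[1L]))
      stop("the first token must carry an empty name")
    nm <- ifelse(is.na(nm), "", nm)
    lns <- ifelse(is.na(ln), "",
                  formatC(ln, format = "f", digits = digits))
    body <- paste(paste0(tokens, ":", nm, ":", lns), collapse = ",")
  }
  paste0("#ltsv ", n, "\n",
         "taxa: ", paste(order, collapse = ","), "\n",
         body)
}

#' @rdname serialize_ltsv
#' @param text serialized LTSv text (three lines).
#' @export
parse_ltsv <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 3L) stop("LTSv parse error: expected 3 lines")
  if (!grepl("^#ltsv [0-9]+$", lines[1L]))
    stop("LTSv parse error: bad header line")
  n <- as.integer(sub("^#ltsv ", "", lines[1L]))
  if (!startsWith(lines[2L], "taxa: "))
    stop("LTSv parse error: bad taxa line")
  order <- taxon_order(strsplit(sub("^taxa: ", "", lines[2L]), ",",
                                fixed = TRUE)[[1L]])
  if (length(order) != n) stop("LTSv parse error: ", length(order),
                               " taxa listed but header says n = ", n)
  toks <- strsplit(lines[3L], ",", fixed = TRUE)[[1L]]
  if (length(toks) != 2L * n)
    stop("LTSv parse error: expected ", 2L * n, " tokens, found ",
         length(toks))
  annotated <- grepl(":", toks[1L], fixed = TRUE)
  if (!annotated) {
    if (any(grepl(":", toks, fixed = TRUE)))
      stop("LTSv parse error: mixed plain and annotated tokens")
    if (!all(grepl("^[0-9]+$", toks)))
      stop("LTSv parse error: non-integer plain token")
    v <- ltsv(as.integer(toks))
    return(list(vector = v, order = order))
  }
  parts <- strsplit(toks, ":", fixed = TRUE)
  grab <- function(p, k) if (length(p) >= k && nzchar(p[k])) p[k] else NA
  idx <- vapply(parts, function(p) as.integer(p[1L]), integer(1))
  nms <- vapply(parts, function(p) as.character(grab(p, 2L)), character(1))
  lns <- vapply(parts, function(p) as.numeric(grab(p, 3L)), numeric(1))
  v <- ltsv(idx)
  list(vector = v, order = order, name = nms, length = lns)
}

#' @rdname serialize_ltsv
#' @param path file to write to / read from.
#' @export
write_ltsv_file <- function(v, order, path, annotations = NULL) {
  writeLines(serialize_ltsv(v, order, annotations), path)
  invisible(path)
}

#' @rdname serialize_ltsv
#' @export
read_ltsv_file <- function(path) {
  parse_ltsv(paste(readLines(path), collapse = "\n"))
}
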