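# Information-theoretic grounding of the complexity indices: Shannon entropy
# of discrete distributions, and a minimal run-length description length for
# symbol sequences. Configurations that can be written in fewer characters
# (losslessly) are the less complex ones; the run-length scheme here is
# deliberately simple and illustrative -- description length is contingent
# on the encoding scheme, so it is not itself one of the profile indices.

#' Coerce to a symbol sequence
#'
#' Accepts a character vector of symbols, or a single string (split into
#' characters, or at commas if present).
#'
#' @param x symbols.
#' @return Character vector of class `symbol_sequence`.
#' @export
#' @examples
#' symbol_sequence("ABABABABCD")
#' symbol_sequence("A,B,A,B")
symbol_sequence <- function(x) {
  if (inherits(x, "symbol_sequence")) return(x)
  x <- as.character(x)
  if (length(x) == 1L) {
    x <- if (grepl(",", x, fixed = TRUE)) {
      trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    } else {
      strsplit(x, "")[[1]]
    }
  }
  if (!length(x) || any(!nzchar(x))) {
    stop("a symbol sequence must be non-empty", call. = FALSE)
  }
  structure(x, class = "symbol_sequence")
}

#' Shannon entropy in bits
#'
#' For a probability vector, `H = -sum(p * log2(p))` with `0 * log(0) := 0`;
#' for a symbol sequence, the entropy of its empirical symbol frequencies.
#' A fair coin gives 1 bit, a fair six-sided die `log2(6)` bits, certainty 0.
#'
#' @param x probability vector (non-negative, summing to 1 within 1e-9) or a
#'   [symbol_sequence] / character vector of symbols.
#' @return Entropy in bits.
#' @export
#' @examples
#' shannon_entropy(c(0.5, 0.5))       # 1
#' shannon_entropy(rep(1 / 6, 6))     # log2(6)
shannon_entropy <- function(x) {
  if (is.numeric(x)) {
    p <- as.numeric(x)
    if (any(!is.finite(p)) || any(p < 0)) {
      stop("probabilities must be finite and non-negative", call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop("probabilities must sum to 1 (got ", format(sum(p)), ")",
           call. = FALSE)
    }
  } else {
    s <- symbol_sequence(x)
    p <- as.numeric(table(unclass(s))) / length(s)
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Minimal run-length description of a symbol sequence
#'
#' Finds, by dynamic programming, the shortest lossless description of the
#' sequence under a fixed run-length scheme: a literal symbol costs 1
#' character, and `k >= 2` consecutive repeats of a block `B` may be written
#' `(B)k`, costing `length(B) + 2 + digits(k)` characters (the parentheses
#' and each count digit cost 1; separators cost nothing). Runs are not
#' nested. When a run saves nothing over literals, the literal form is kept.
#'
#' @param s a [symbol_sequence] (or anything [symbol_sequence] accepts).
#' @return List of class `compression_result`: `encoded` (string), `length`
#'   (character count), `tokens` (list of literal/run tokens), `scheme`.
#' @export
#' @examples
#' compress_min_rle("ABABABABCD")$encoded  # "(AB)4CD", 7 characters
#' compress_min_rle("ABDCBDAABD")$length   # 10: no compressible structure
compress_min_rle <- function(s) {
  s <- symbol_sequence(s)
  n <- length(s)
  best <- c(0, rep(Inf, n))        # best[i + 1]: minimal cost of s[1..i]
  back <- vector("list", n + 1L)
  for (i in seq_len(n)) {
    # literal symbol (preferred on ties)
    best[i + 1L] <- best[i] + 1
    back[[i + 1L]] <- list(type = "lit", prev = i - 1L, sym = s[[i]])
    # a run of some block ending at i
    for (L in seq_len(i %/% 2L)) {
      block <- s[(i - L + 1L):i]
      k <- 1L
      while (i - (k + 1L) * L >= 0L &&
             identical(s[(i - (k + 1L) * L + 1L):(i - k * L)], block)) {
        k <- k + 1L
        cost <- best[i - k * L + 1L] + L + 2L + n_digits(k)
        if (cost < best[i + 1L]) {
          best[i + 1L] <- cost
          back[[i + 1L]] <- list(type = "run", prev = i - k * L,
                                 block = block, k = k)
        }
      }
    }
  }
  # walk back to recover tokens
  tokens <- list()
  i <- n
  while (i > 0L) {
    b <- back[[i + 1L]]
    tokens <- c(list(b), tokens)
    i <- b$prev
  }
  encoded <- paste(vapply(tokens, function(tk) {
    if (tk$type == "lit") tk$sym
    else paste0("(", paste(tk$block, collapse = ""), ")", tk$k)
  }, character(1)), collapse = "")
  structure(list(encoded = encoded, length = as.integer(best[n + 1L]),
                 tokens = tokens, scheme = "min-rle-dp"),
            class = "compression_result")
}

#' @export
print.compression_result <- function(x, ...) {
  cat("<compression_result> \"", x$encoded, "\" (", x$length,
      " characters, scheme ", x$scheme, ")\n", sep = "")
  invisible(x)
}

#' Decode a run-length encoded string
#'
#' Inverse of [compress_min_rle] for single-character symbols; used to check
#' losslessness.
#'
#' @param encoded encoded string, e.g. `"(AB)4CD"`.
#' @return Character vector of class `symbol_sequence`.
#' @export
decode_rle <- function(encoded) {
  stopifnot(is.character(encoded), length(encoded) == 1L)
  chars <- strsplit(encoded, "")[[1]]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "(") {
      close <- i + which(chars[(i + 1):length(chars)] == ")")[1]
      if (is.na(close)) stop("unbalanced '(' in encoding", call. = FALSE)
      block <- chars[(i + 1L):(close - 1L)]
      j <- close + 1L
      while (j <= length(chars) && grepl("[0-9]", chars[j])) j <- j + 1L
      if (j == close + 1L) stop("run without a count", call. = FALSE)
      k <- as.integer(paste(chars[(close + 1L):(j - 1L)], collapse = ""))
      out <- c(out, rep(block, k))
      i <- j
    } else {
      out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  symbol_sequence(out)
}

#' Description length of a sequence
#'
#' Character count of the minimal run-length description
#' (see [compress_min_rle]).
#'
#' @inheritParams compress_min_rle
#' @return Integer.
#' @export
description_length <- function(s) compress_min_rle(s)$length
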