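#' Color alphabet of the guessing game
#'
#' The game colors a code of `L` positions with up to three colors: red
#' (`"R"`), blue (`"B"`) and yellow (`"Y"`). The symbol `"?"` marks an
#' unknown position in partial codes; a submitted proposal never contains it.
#'
#' @param n_colors Number of colors in play (2 or 3; the experiment uses 3).
#' @return Character vector of color symbols.
#' @export
code_alphabet <- function(n_colors = 3) {
  if (!is_count(n_colors) || n_colors < 2 || n_colors > 3) {
    stop_("n_colors must be 2 or 3 (symbols are drawn from R, B, Y)")
  }
  c("R", "B", "Y")[seq_len(n_colors)]
}

UNKNOWN <- "?"

#' Validate a color code
#'
#' @param code Character vector of single-character symbols, one per position.
#' @param L Required length.
#' @param alphabet Allowed symbols (see [code_alphabet()]).
#' @param partial If `TRUE`, the unknown symbol `"?"` is also allowed.
#' @return The code, invisibly, if valid; otherwise an error naming the
#'   offending symbol and position.
#' @export
validate_code <- function(code, L = 10, alphabet = code_alphabet(),
                          partial = FALSE) {
  if (length(code) != L) {
    stop_("code has length ", length(code), ", expected ", L)
  }
  ok <- code %in% c(alphabet, if (partial) UNKNOWN)
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop_("invalid symbol '", code[i], "' at position ", i)
  }
  invisible(code)
}

#' @rdname validate_code
#' @param string An `L`-character string such as `"RBYRRYBBYR"`.
#' @export
string_to_code <- function(string, L = 10, alphabet = code_alphabet(),
                           partial = FALSE) {
  code <- strsplit(string, "", fixed = TRUE)[[1]]
  validate_code(code, L = L, alphabet = alphabet, partial = partial)
  code
}

#' @rdname validate_code
#' @param code Character vector form of a code.
#' @export
code_to_string <- function(code) paste(code, collapse = "")

#' Draw a uniformly random complete code
#'
#' @inheritParams validate_code
#' @param seed Optional integer seed (`NULL` uses the current RNG stream).
#' @return Character vector of length `L`.
#' @export
random_code <- function(L = 10, alphabet = code_alphabet(), seed = NULL) {
  with_seed(seed, sample(alphabet, L, replace = TRUE))
}

#' Hamming distance between two codes
#'
#' Number of positions at which two complete codes differ.
#'
#' @param a,b Codes as character vectors or `L`-character strings.
#' @return Integer count of differing positions.
#' @export
hamming_distance <- function(a, b) {
  if (is.character(a) && length(a) == 1) a <- strsplit(a, "")[[1]]
  if (is.character(b) && length(b) == 1) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) stop_("codes differ in length")
  sum(a != b)
}
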