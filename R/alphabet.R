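#' Alphabets: bijective instance/index dictionaries
#'
#' An alphabet stores a bijective mapping between instances (words, characters,
#' labels or per-token features) and dense integer indices. Two indices are
#' reserved: index 1 is the padding symbol and index 2 the unknown symbol;
#' learned entries start at index 3. While open, lookups of unseen instances
#' grow the mapping in first-occurrence order; after \code{alphabet_freeze()},
#' unseen instances map to the unknown index and the mapping never grows.
#'
#' @param name short identifier ("word", "char", "label", "feature").
#' @return an object of class \code{drugner_alphabet}.
#' @examples
#' a <- alphabet("word")
#' alphabet_index(a, "aspirin")  # 3: first learned entry
#' alphabet_instance(a, 3)       # "aspirin"
#' @export
alphabet <- function(name = "alphabet") {
  e <- new.env(parent = emptyenv())
  e$name <- name
  e$map <- new.env(parent = emptyenv(), size = 256L)
  e$instances <- c(PAD_SYMBOL, UNK_SYMBOL)
  assign(PAD_SYMBOL, 1L, envir = e$map)
  assign(UNK_SYMBOL, 2L, envir = e$map)
  e$frozen <- FALSE
  class(e) <- "drugner_alphabet"
  e
}

PAD_SYMBOL <- "<PAD>"
UNK_SYMBOL <- "<UNK>"

#' @describeIn alphabet padding index (always 1).
#' @param a an alphabet.
#' @export
alphabet_pad <- function(a) 1L

#' @describeIn alphabet unknown index (always 2).
#' @export
alphabet_unk <- function(a) 2L

#' @describeIn alphabet number of entries including the two reserved ones.
#' @export
alphabet_size <- function(a) length(a$instances)

#' @describeIn alphabet stop accepting new entries.
#' @export
alphabet_freeze <- function(a) {
  a$frozen <- TRUE
  invisible(a)
}

#' @describeIn alphabet TRUE once frozen.
#' @export
alphabet_frozen <- function(a) a$frozen

#' Look up (and possibly learn) the index of an instance
#'
#' @param a an alphabet.
#' @param instance character vector of instances.
#' @return integer vector of indices; unseen instances under a frozen alphabet
#'   map to the unknown index.
#' @export
alphabet_index <- function(a, instance) {
  vapply(as.character(instance), function(s) {
    idx <- a$map[[s]]
    if (!is.null(idx)) return(idx)
    if (a$frozen) return(2L)
    idx <- length(a$instances) + 1L
    assign(s, idx, envir = a$map)
    a$instances <- c(a$instances, s)
    idx
  }, integer(1), USE.NAMES = FALSE)
}

#' Recover instances from indices
#'
#' @param a an alphabet.
#' @param index integer vector of indices in [1, alphabet_size(a)].
#' @return character vector of instances.
#' @export
alphabet_instance <- function(a, index) {
  index <- as.integer(index)
  if (any(index < 1L | index > length(a$instances)))
    stop("alphabet '", a$name, "': index out of range [1, ",
         length(a$instances), "]")
  a$instances[index]
}

#' @describeIn alphabet all learned instances (excluding reserved entries).
#' @export
alphabet_entries <- function(a) {
  if (length(a$instances) <= 2L) character(0) else a$instances[-(1:2)]
}

#' @export
print.drugner_alphabet <- function(x, ...) {
  cat(sprintf("<alphabet '%s': %d entries (%d learned)%s>\n", x$name,
              alphabet_size(x), alphabet_size(x) - 2L,
              if (x$frozen) ", frozen" else ""))
  invisible(x)
}
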