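#' Derive a stage seed from a global seed
#'
#' A single experiment seed fans out to per-stage streams through a fixed
#' integer mix of the seed and the stage name, so each stage (data build,
#' split, training repeat, ...) is independently reproducible.
#'
#' @param seed Non-negative integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
make_seed <- function(seed, stage) {
  h <- 7
  for (ch in utf8ToInt(as.character(stage)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(((seed %% 2147483647) * 48271 + h) %% 2147483646 + 1)
}

# polynomial rolling hash over a text rendering of the value; used for the
# self-describing run manifests, not for cryptographic purposes.
content_hash <- function(x) {
  bytes <- if (is.character(x)) utf8ToInt(paste(x, collapse = "\x1f"))
           else serialize_num(x)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

serialize_num <- function(x) {
  # stable byte rendering of numbers via their 15-digit decimal form
  utf8ToInt(paste(formatC(as.numeric(x), digits = 15, format = "g"),
                  collapse = ","))
}

one_hot <- function(labels, levels) {
  m <- matrix(0, length(labels), length(levels),
              dimnames = list(NULL, levels))
  m[cbind(seq_along(labels), match(labels, levels))] <- 1
  m
}
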