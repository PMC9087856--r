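## Internal helpers shared across modules.

.NUC <- c("A", "C", "G", "T")
.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

## Reverse complement of a character vector of DNA words (upper case).
.revcompChar <- function(x) {
  if (!length(x)) return(character())
  rc <- Biostrings::reverseComplement(Biostrings::DNAStringSet(x))
  as.character(rc)
}

## Deterministic child seed: offsets a base seed by a named substream so
## every simulator stage draws from its own stream (kept < 2^31).
.substreamSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.numeric(seed) * 1009 + h) %% 2147483647
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Ordered label pair key "a|b" with a < b.
.pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
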