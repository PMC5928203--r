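## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

dna_complement <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of nucleotide sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(dna_complement(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Integer codes 1..4 for A,C,G,T; NA for any other symbol.
base_codes <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
}

is_palindrome <- function(seq) identical(toupper(seq), revcomp(toupper(seq)))

## Run code under a temporary RNG state; the caller's .Random.seed is restored.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

## i.i.d. background sequence at a given GC content.
random_dna <- function(n, gc = 0.6) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

## Fisher-Yates shuffle of the letters of one sequence (composition-preserving).
shuffle_seq <- function(seq) {
  paste(sample(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
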