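#' Convert nucleotide strings between DNA and RNA alphabets
#'
#' miRBase distributes precursor and mature sequences in the RNA alphabet
#' (ACGU) while sequencers and most user files use DNA (ACGT). All internal
#' computation in mirarm is on uppercase RNA; sequencing reads are written
#' back out as DNA.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length, uppercased, with T<->U
#'   converted as requested.
#' @examples
#' as_rna("acgt")
#' as_dna("ACGU")
#' @export
as_rna <- function(x) {
  chartr("tT", "uU", toupper(x))
}

#' @rdname as_rna
#' @export
as_dna <- function(x) {
  chartr("uU", "tT", toupper(x))
}

#' Reverse complement of an RNA sequence
#'
#' @param x Character vector of RNA sequences (ACGU).
#' @return Character vector of reverse complements, 5'->3'.
#' @examples
#' revcomp_rna("ACGU")
#' @export
revcomp_rna <- function(x) {
  comp <- chartr("ACGU", "UGCA", as_rna(x))
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), character(1))
}

rna_alphabet_ok <- function(x) {
  !grepl("[^ACGU]", x)
}

assert_rna <- function(x, what = "sequence") {
  bad <- which(!rna_alphabet_ok(x))
  if (length(bad) > 0) {
    abort(sprintf("%s contains characters outside {A,C,G,U} (first offender: element %d)",
                  what, bad[1]))
  }
  invisible(x)
}

# Balanced-parentheses check for dot-bracket strings.
db_balanced <- function(structure) {
  vapply(strsplit(structure, ""), function(ch) {
    depth <- 0L
    for (c in ch) {
      if (c == "(") depth <- depth + 1L
      else if (c == ")") {
        depth <- depth - 1L
        if (depth < 0L) return(FALSE)
      } else if (c != ".") return(FALSE)
    }
    depth == 0L
  }, logical(1))
}

# Run code under a fixed RNG state when seed is non-NULL, leaving the
# caller's RNG untouched.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}
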