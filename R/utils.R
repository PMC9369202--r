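#' @importFrom stats rnorm runif setNames p.adjust
#' @importFrom utils read.delim write.table head
NULL

# IUPAC degenerate nucleotide codes -> base sets
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

BASES <- c("A", "C", "G", "T")

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores (or clears) the caller's `.Random.seed` afterwards, so generators
#' are pure functions of their seed and do not perturb the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

#' Validate an IUPAC pattern
#'
#' @param pattern character scalar over the 15-letter IUPAC alphabet.
#' @return the pattern, uppercased.
#' @keywords internal
check_iupac <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nchar(pattern) >= 1L)
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "")[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop("illegal IUPAC symbol '", chars[bad[1]], "' at position ", bad[1])
  }
  pattern
}

#' Convert an IUPAC pattern to a 0/1-probability PWM
#'
#' Each position gets equal probability over the bases the code allows and
#' zero elsewhere, so a full-score PWM match is exactly a degenerate match.
#'
#' @param pattern IUPAC string.
#' @param id motif id for the resulting model.
#' @return a `motif_model` (see [load_pwm()]).
#' @export
iupac_to_pwm <- function(pattern, id = pattern) {
  pattern <- check_iupac(pattern)
  chars <- strsplit(pattern, "")[[1]]
  mat <- t(vapply(chars, function(ch) {
    allowed <- IUPAC_SETS[[ch]]
    p <- setNames(numeric(4), BASES)
    p[allowed] <- 1 / length(allowed)
    p
  }, numeric(4)))
  dimnames(mat) <- list(NULL, BASES)
  motif_model(id = id, matrix = mat, iupac_consensus = pattern)
}

# Reverse complement of a character scalar (IUPAC-aware)
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Sample n i.i.d. uniform ACGT sequences of the given lengths
random_dna <- function(lengths) {
  seqs <- vapply(lengths, function(L) {
    paste(sample(BASES, L, replace = TRUE), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

# signed sign with 0 preserved
sgn <- function(x) sign(x)
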